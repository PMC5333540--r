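#' circchar: characterization of circular RNAs from chimeric alignments
#'
#' Coordinate convention used throughout: all intervals are 0-based,
#' half-open \code{[start, end)}, the BED convention. 1-based sources
#' (SAM POS, STAR chimeric-junction columns) are converted at the reader
#' boundary and never leak past it. Strand is carried through but never
#' used to match reads to circles.
#'
#' @keywords internal
"_PACKAGE"

#' Build the canonical circle identifier
#'
#' A circRNA candidate is identified by its back-splice boundaries:
#' chromosome plus the genomic start and end of the circularized interval.
#' The canonical encoding is \code{"chrom:start|end"} with 0-based
#' half-open coordinates; it is injective on valid triples and becomes a
#' safe filename after replacing \code{":"} and \code{"|"} with \code{"_"}.
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval; \code{end > start >= 0}.
#' @return Character vector of circle IDs.
#' @examples
#' make_circle_id("chrT", 300, 1000) # "chrT:300|1000"
#' @export
make_circle_id <- function(chrom, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0L))
    stop("invalid interval: start must be a non-negative integer")
  if (any(end <= start))
    stop("invalid interval: end must be > start")
  sprintf("%s:%d|%d", as.character(chrom), start, end)
}

#' Parse a canonical circle identifier back into its coordinates
#'
#' @param circle_id Character vector of \code{"chrom:start|end"} IDs.
#' @return data.frame with columns \code{circle_id}, \code{chrom},
#'   \code{start}, \code{end}.
#' @export
parse_circle_id <- function(circle_id) {
  m <- regmatches(circle_id, regexec("^(.+):([0-9]+)\\|([0-9]+)$", circle_id))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("unparsable circleID(s): ", paste(circle_id[bad], collapse = ", "))
  chrom <- vapply(m, `[`, "", 2L)
  start <- as.integer(vapply(m, `[`, "", 3L))
  end <- as.integer(vapply(m, `[`, "", 4L))
  if (any(end <= start))
    stop("invalid circleID interval(s): end <= start")
  data.frame(circle_id = circle_id, chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Filesystem-safe form of a circle ID
#' @param circle_id Character vector of circle IDs.
#' @return IDs with ":" and "|" replaced by "_".
#' @export
circle_id_filename <- function(circle_id) {
  gsub("[:|]", "_", circle_id)
}

#' Split a CIGAR string into aligned reference segments
#'
#' Walks the CIGAR along the reference and emits one interval per maximal
#' run of reference-consuming, non-gap operations. Skips (\code{N}) always
#' split blocks; deletions (\code{D}) split only when at least
#' \code{min_intron} long — shorter deletions are alignment noise and are
#' merged into the flanking block. Insertions, soft and hard clips and
#' padding consume no reference.
#'
#' @param ref_start 0-based reference start of the alignment.
#' @param cigar CIGAR string (single).
#' @param min_intron Minimum D length (bp) treated as a splice gap;
#'   default 30.
#' @return data.frame with columns \code{start}, \code{end} (0-based
#'   half-open), one row per aligned block, sorted by \code{start}.
#' @examples
#' cigar_to_segments(300, "100M100N100M") # blocks 300-400 and 500-600
#' @export
cigar_to_segments <- function(ref_start, cigar, min_intron = 30L) {
  stopifnot(length(cigar) == 1L, length(ref_start) == 1L)
  ref_start <- as.integer(ref_start)
  if (is.na(cigar) || cigar == "*" || !grepl("^([0-9]+[MIDNSHP=X])+$", cigar))
    stop("malformed CIGAR: ", cigar)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  pos <- ref_start
  blocks_s <- integer(0)
  blocks_e <- integer(0)
  cur_s <- NA_integer_
  flush <- function(end_pos) {
    if (!is.na(cur_s)) {
      blocks_s <<- c(blocks_s, cur_s)
      blocks_e <<- c(blocks_e, end_pos)
      cur_s <<- NA_integer_
    }
  }
  for (i in seq_along(ops)) {
    op <- ops[i]
    len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      if (is.na(cur_s)) cur_s <- pos
      pos <- pos + len
    } else if (op == "D") {
      if (len >= min_intron) flush(pos)   # long deletion: treat as gap
      if (is.na(cur_s) && len < min_intron) cur_s <- pos  # D opening a block
      pos <- pos + len
    } else if (op == "N") {
      flush(pos)
      pos <- pos + len
    }
    # I, S, H, P consume no reference
  }
  flush(pos)
  data.frame(start = blocks_s, end = blocks_e)
}

#' Gaps between the aligned blocks of one alignment
#'
#' The inter-segment gaps of a spliced alignment are its candidate introns.
#'
#' @param segments data.frame from [cigar_to_segments()].
#' @return data.frame with columns \code{start}, \code{end}; zero rows for
#'   a gapless alignment.
#' @export
segment_gaps <- function(segments) {
  n <- nrow(segments)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = segments$end[-n], end = segments$start[-1L])
}

# interval helpers (0-based half-open throughout)
.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
.contains <- function(outer_s, outer_e, inner_s, inner_e) {
  inner_s >= outer_s & inner_e <= outer_e
}
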