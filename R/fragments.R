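#' Which mates of each read span the back-splice junction?
#'
#' Two evidence channels are accepted. Preferred: STAR chimeric-junction
#' records (from [read_dcc_outputs()]), where a mate spans the junction
#' iff it appears in a junction record for this circle. Fallback: the
#' alignment itself, where a mate spans the junction iff its aligned
#' blocks are split across the back-splice — one block ending at the
#' circle end and one starting at the circle start (the primary +
#' supplementary record pair of a chimeric read).
#'
#' @param read_set A \code{circle_read_set}.
#' @param junction_reads Optional data.frame (read_name, circle_id,
#'   mate) as attached by [read_dcc_outputs()]; when NULL the alignment
#'   channel is used.
#' @param tol Breakpoint matching tolerance in bp for the alignment
#'   channel (default 0).
#' @return Named list: read name -> integer vector of junction-spanning
#'   mates (1, 2; 0 for unpaired/read-level evidence).
#' @export
junction_spanning_mates <- function(read_set, junction_reads = NULL,
                                    tol = 0L) {
  ci <- read_set$circle
  if (!is.null(junction_reads)) {
    jr <- junction_reads[junction_reads$circle_id == ci$circle_id, ,
                         drop = FALSE]
    return(lapply(split(jr$mate, jr$read_name), function(m)
      sort(unique(m))))
  }
  aln <- read_set$alignments
  if (nrow(aln) == 0L) return(list())
  out <- list()
  for (key in unique(paste(aln$qname, aln$mate))) {
    rows <- aln[paste(aln$qname, aln$mate) == key, , drop = FALSE]
    segs <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i)
      cigar_to_segments(rows$pos[i], rows$cigar[i])))
    spans <- any(abs(segs$end - ci$end) <= tol) &&
      any(abs(segs$start - ci$start) <= tol)
    if (spans) {
      q <- rows$qname[1L]
      out[[q]] <- sort(unique(c(out[[q]], rows$mate[1L])))
    }
  }
  out
}

#' Count single- vs double-breakpoint fragments for one circle
#'
#' A sequenced fragment (read pair) is a double-breakpoint fragment when
#' both mates span the back-splice junction — strong evidence that the
#' fragment derives from a circular molecule. A fragment with exactly
#' one junction-spanning mate is single (inconclusive: compatible with
#' trans-splicing or rearrangement). Unpaired reads and read-level
#' junction evidence that cannot be attributed to a specific mate count
#' as single. Read names on the circle's list with no junction-spanning
#' mate at all are excluded with a warning.
#'
#' @param read_set A \code{circle_read_set}.
#' @param junction_spanning Named list from [junction_spanning_mates()].
#' @return One-row data.frame: \code{circle_id}, \code{n_single},
#'   \code{n_double}, \code{n_fragments}, \code{double_fraction}
#'   (\code{NA} when no fragments).
#' @export
classify_fragments <- function(read_set, junction_spanning) {
  reads <- unique(c(read_set$alignments$qname, read_set$read_names))
  missing <- setdiff(reads, names(junction_spanning))
  if (length(missing))
    warning("read(s) with no junction-spanning mate excluded: ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ...")
  reads <- intersect(reads, names(junction_spanning))
  n_double <- 0L
  n_single <- 0L
  for (q in reads) {
    mates <- setdiff(junction_spanning[[q]], 0L)
    if (length(mates) >= 2L) n_double <- n_double + 1L
    else n_single <- n_single + 1L
  }
  n <- n_single + n_double
  data.frame(circle_id = read_set$circle$circle_id,
             n_single = n_single, n_double = n_double, n_fragments = n,
             double_fraction = if (n > 0L) n_double / n else NA_real_,
             stringsAsFactors = FALSE)
}

#' Estimate the transcribed length of a circle
#'
#' The spliced length is the sum of the lengths of covered annotated
#' exons inside the circle interval (exons clipped to the circle). When
#' no annotated exon overlaps the circle — or none is covered — the
#' genomic span is used as a fallback.
#'
#' @param circle One-row circle data.
#' @param annotation Exon annotation (used when \code{exon_coverage} is
#'   NULL: all overlapping exons count as covered).
#' @param exon_coverage Optional per-exon coverage table from
#'   [exonwise_coverage()]; rows with \code{n_reads > 0} are covered.
#' @return Length in bp (integer).
#' @export
estimate_circle_length <- function(circle, annotation = NULL,
                                   exon_coverage = NULL) {
  span <- circle$end - circle$start
  if (!is.null(exon_coverage) && nrow(exon_coverage) > 0L) {
    cov <- exon_coverage[exon_coverage$n_reads > 0L &
                           !exon_coverage$pseudo, , drop = FALSE]
    len <- sum(cov$exon_length_bp)
    return(if (len > 0L) as.integer(len) else as.integer(span))
  }
  if (!is.null(annotation) && nrow(annotation) > 0L) {
    ov <- annotation$chrom == circle$chrom &
      .overlaps(annotation$start, annotation$end, circle$start, circle$end)
    if (any(ov)) {
      s <- pmax(annotation$start[ov], circle$start)
      e <- pmin(annotation$end[ov], circle$end)
      return(as.integer(sum(e - s)))
    }
  }
  as.integer(span)
}

#' Flag circles whose fragment evidence contradicts circularity
#'
#' If a circle is short enough that the sequencing fragment can capture
#' it whole (circle length <= expected fragment length), a genuine
#' circle should yield double-breakpoint fragments. A circle in that
#' regime supported only by single-breakpoint fragments — given at
#' least \code{min_fragments} fragments of evidence — is flagged as a
#' likely false positive. Longer circles are never flagged: there the
#' single/double channels are uninformative.
#'
#' @param summary data.frame with columns \code{circle_length_bp},
#'   \code{n_double}, \code{n_fragments} (vectorized).
#' @param expected_fragment_length Library fragment (insert) size in bp.
#' @param min_fragments Minimum fragments before flagging (default 2).
#' @return Logical vector.
#' @export
flag_suspect_circles <- function(summary, expected_fragment_length,
                                 min_fragments = 2L) {
  stopifnot(expected_fragment_length > 0)
  summary$circle_length_bp <= expected_fragment_length &
    summary$n_double == 0L &
    summary$n_fragments >= min_fragments
}

#' Full fragment summary for a set of circles
#'
#' Runs [classify_fragments()], [estimate_circle_length()] and
#' [flag_suspect_circles()] per circle.
#'
#' @param read_sets List of \code{circle_read_set}s.
#' @param annotation Exon annotation.
#' @param expected_fragment_length Library fragment size in bp.
#' @param junction_reads Optional junction-record data.frame (see
#'   [junction_spanning_mates()]).
#' @param exon_coverages Optional named list of per-circle exon coverage
#'   tables.
#' @param min_fragments Minimum fragments before flagging.
#' @return data.frame, one row per circle, with the columns of
#'   [classify_fragments()] plus \code{circle_length_bp} and
#'   \code{suspect}.
#' @export
fragment_summary <- function(read_sets, annotation,
                             expected_fragment_length,
                             junction_reads = NULL,
                             exon_coverages = NULL,
                             min_fragments = 2L) {
  rows <- lapply(read_sets, function(rs) {
    js <- junction_spanning_mates(rs, junction_reads)
    cf <- classify_fragments(rs, js)
    cf$circle_length_bp <- estimate_circle_length(
      rs$circle, annotation,
      if (!is.null(exon_coverages)) exon_coverages[[rs$circle$circle_id]])
    cf
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$suspect <- flag_suspect_circles(out, expected_fragment_length,
                                      min_fragments)
  out
}
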