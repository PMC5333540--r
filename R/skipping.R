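#' Infer linear splice introns from a circle's reads
#'
#' Every inter-segment gap within one mate of a circular read is a linear
#' splicing event. Identical gap intervals across reads are merged and
#' their supporting read names unioned. Gaps not fully inside the circle
#' boundaries are dropped with a warning (they cross the back-splice and
#' cannot be linear introns of this circle).
#'
#' @param read_set A \code{circle_read_set}.
#' @param min_intron Minimum deletion length treated as a splice gap, in
#'   bp (passed to [cigar_to_segments()]).
#' @return data.frame with columns \code{start}, \code{end},
#'   \code{n_support} and list column \code{supporting_reads}, sorted by
#'   (start, end).
#' @export
infer_introns <- function(read_set, min_intron = 30L) {
  aln <- read_set$alignments
  ci <- read_set$circle
  if (nrow(aln) == 0L)
    return(.empty_introns())
  gap_rows <- lapply(seq_len(nrow(aln)), function(i) {
    segs <- cigar_to_segments(aln$pos[i], aln$cigar[i], min_intron)
    g <- segment_gaps(segs)
    if (nrow(g) == 0L) return(NULL)
    g$read <- aln$qname[i]
    g
  })
  gaps <- do.call(rbind, gap_rows)
  if (is.null(gaps) || nrow(gaps) == 0L) return(.empty_introns())
  inside <- gaps$start >= ci$start & gaps$end <= ci$end
  if (any(!inside))
    warning(sum(!inside), " gap(s) crossing the circle boundary dropped")
  gaps <- gaps[inside, , drop = FALSE]
  if (nrow(gaps) == 0L) return(.empty_introns())
  key <- paste(gaps$start, gaps$end)
  by_key <- split(gaps$read, key)
  uk <- unique(key)
  out <- data.frame(
    start = as.integer(sub(" .*", "", uk)),
    end = as.integer(sub(".* ", "", uk)))
  out$supporting_reads <- lapply(by_key[uk], unique)
  out$n_support <- vapply(out$supporting_reads, length, 1L)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_introns <- function() {
  out <- data.frame(start = integer(0), end = integer(0))
  out$supporting_reads <- list()
  out$n_support <- integer(0)
  out
}

#' Intersect inferred introns with annotated exons
#'
#' A skipped-exon candidate is an annotated exon fully contained in an
#' inferred intron interval: the splice gap jumps over the whole exon.
#' Exons merely abutting or partially overlapping an intron are not
#' candidates.
#'
#' @param introns Output of [infer_introns()].
#' @param annotation Exon annotation from [read_exon_annotation()].
#' @param circle One-row circle data (needs \code{chrom}, \code{start},
#'   \code{end}, \code{circle_id}).
#' @return data.frame, one row per (intron, contained exon) pair, with
#'   intron and exon coordinates, \code{gene_id}, \code{exon_number} and
#'   the intron's supporting reads.
#' @export
detect_skipped_exons <- function(introns, annotation, circle) {
  empty <- data.frame(circle_id = character(0), chrom = character(0),
                      intron_start = integer(0), intron_end = integer(0),
                      exon_start = integer(0), exon_end = integer(0),
                      gene_id = character(0), exon_number = integer(0))
  empty$gap_reads <- list()
  if (nrow(introns) == 0L || nrow(annotation) == 0L) return(empty)
  ann <- annotation[annotation$chrom == circle$chrom, , drop = FALSE]
  if (nrow(ann) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(introns))) {
    contained <- .contains(introns$start[i], introns$end[i],
                           ann$start, ann$end)
    for (j in which(contained)) {
      r <- data.frame(circle_id = circle$circle_id, chrom = circle$chrom,
                      intron_start = introns$start[i],
                      intron_end = introns$end[i],
                      exon_start = ann$start[j], exon_end = ann$end[j],
                      gene_id = ann$gene_id[j],
                      exon_number = ann$exon_number[j],
                      stringsAsFactors = FALSE)
      r$gap_reads <- list(introns$supporting_reads[[i]])
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign each circular read to the skipping or non-skipping isoform
#'
#' A read supports the skipping isoform when (any of its alignment
#' records) carries a splice gap fully containing the candidate exon; it
#' supports the non-skipping isoform when a segment overlaps the exon
#' body. Reads doing neither — e.g. junction-only fragments that never
#' reach the exon — count toward the total but toward neither isoform
#' and are reported as uninformative.
#'
#' @param read_set A \code{circle_read_set}.
#' @param candidate One row of [detect_skipped_exons()] output.
#' @param min_intron Splice-gap threshold, as in [infer_introns()].
#' @return One-row data.frame: circle boundaries, exon and intron
#'   coordinates, \code{skipping_reads} (list column), \code{n_skip},
#'   \code{n_cover}, \code{n_uninformative}, \code{n_total},
#'   \code{proportion_skipping}.
#' @export
assign_isoform_support <- function(read_set, candidate, min_intron = 30L) {
  aln <- read_set$alignments
  reads <- unique(aln$qname)
  n_total <- length(reads)
  if (n_total == 0L) stop("cannot assign isoforms: empty read set")
  es <- candidate$exon_start
  ee <- candidate$exon_end
  skip <- logical(n_total)
  cover <- logical(n_total)
  names(skip) <- names(cover) <- reads
  for (i in seq_len(nrow(aln))) {
    segs <- cigar_to_segments(aln$pos[i], aln$cigar[i], min_intron)
    g <- segment_gaps(segs)
    q <- aln$qname[i]
    if (nrow(g) && any(.contains(g$start, g$end, es, ee)))
      skip[q] <- TRUE
    if (any(.overlaps(segs$start, segs$end, es, ee)))
      cover[q] <- TRUE
  }
  cover <- cover & !skip   # a gapped read also has flanking segments
  out <- data.frame(
    circle_id = read_set$circle$circle_id,
    chrom = read_set$circle$chrom,
    circle_start = read_set$circle$start,
    circle_end = read_set$circle$end,
    gene_id = candidate$gene_id, exon_number = candidate$exon_number,
    exon_start = es, exon_end = ee,
    intron_start = candidate$intron_start,
    intron_end = candidate$intron_end,
    n_skip = sum(skip), n_cover = sum(cover),
    n_uninformative = sum(!skip & !cover), n_total = n_total,
    proportion_skipping = sum(skip) / n_total,
    stringsAsFactors = FALSE)
  out$skipping_reads <- list(sort(reads[skip]))
  out
}

#' Detect and quantify skipped exons for one circle
#'
#' Convenience wrapper: [infer_introns()], [detect_skipped_exons()],
#' then [assign_isoform_support()] for every candidate.
#'
#' @inheritParams infer_introns
#' @param annotation Exon annotation.
#' @return data.frame of skipped-exon calls (possibly zero rows).
#' @export
find_skipped_exons <- function(read_set, annotation, min_intron = 30L) {
  introns <- infer_introns(read_set, min_intron)
  cands <- detect_skipped_exons(introns, annotation, read_set$circle)
  if (nrow(cands) == 0L) {
    out <- assign_isoform_support(read_set, data.frame(
      exon_start = 0L, exon_end = 1L, gene_id = "", exon_number = 0L,
      intron_start = 0L, intron_end = 1L))[0L, ]
    return(out)
  }
  calls <- lapply(seq_len(nrow(cands)), function(i)
    assign_isoform_support(read_set, cands[i, ], min_intron))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Write skipped-exon calls to BED12 and TSV files
#'
#' \code{<prefix>.skipped_exons.bed} is browser-loadable BED12: one line
#' per call spanning the circle, with three blocks (upstream flank,
#' skipped exon, downstream flank) so the intron boundaries and the
#' exon's position relative to the circle start are visible; the score
#' is \code{round(100 * proportion_skipping)}.
#' \code{<prefix>.skipped_exons.txt} lists exact genomic coordinates,
#' the skipping read names, and the skip / cover / uninformative / total
#' read counts.
#'
#' @param calls data.frame from [find_skipped_exons()].
#' @param prefix Output path prefix (typically \code{dir/sample}).
#' @return Character vector of the two paths written, invisibly.
#' @export
write_skip_outputs <- function(calls, prefix) {
  bed_path <- paste0(prefix, ".skipped_exons.bed")
  txt_path <- paste0(prefix, ".skipped_exons.txt")
  header <- c("circle_id", "chrom", "exon_start", "exon_end", "gene_id",
              "exon_number", "intron_start", "intron_end",
              "skipping_reads", "n_skip", "n_cover", "n_uninformative",
              "n_total", "proportion_skipping")
  txt <- file(txt_path, "w")
  on.exit(close(txt))
  writeLines(paste(header, collapse = "\t"), txt)
  bed_lines <- character(0)
  for (i in seq_len(nrow(calls))) {
    x <- calls[i, ]
    writeLines(paste(c(
      x$circle_id, x$chrom, x$exon_start, x$exon_end, x$gene_id,
      x$exon_number, x$intron_start, x$intron_end,
      paste(x$skipping_reads[[1L]], collapse = ","),
      x$n_skip, x$n_cover, x$n_uninformative, x$n_total,
      format(x$proportion_skipping, digits = 6L)), collapse = "\t"), txt)
    bed_lines <- c(bed_lines, .skip_bed12_line(x))
  }
  writeLines(bed_lines, bed_path)
  invisible(c(bed_path, txt_path))
}

.skip_bed12_line <- function(x) {
  cs <- x$circle_start
  ce <- x$circle_end
  sizes <- c(max(1L, x$intron_start - cs),
             x$exon_end - x$exon_start,
             max(1L, ce - x$intron_end))
  starts <- c(0L, x$exon_start - cs, ce - cs - sizes[3L])
  paste(c(x$chrom, cs, ce, x$circle_id,
          round(100 * x$proportion_skipping), ".", cs, ce, "0", 3L,
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ",")),
        collapse = "\t")
}
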