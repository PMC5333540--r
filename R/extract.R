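#' Split an alignment file into per-circle BAM files
#'
#' The first characterization step: for every circle, collect the
#' alignment records whose read name is on the circle's supporting-read
#' list \emph{and} whose aligned span overlaps the circle interval (the
#' positional condition drops same-named multimappers elsewhere in the
#' genome), and write them to one coordinate-sorted, indexed BAM per
#' circle. Supplementary records are kept — they carry the second arm of
#' a chimeric read; secondary and unmapped records are dropped by
#' default.
#'
#' @param alignments Path to a SAM/BAM file, or the data.frame returned
#'   by [read_alignments()].
#' @param circles A circle table.
#' @param out_dir Output directory for the per-circle BAMs (created if
#'   missing).
#' @param sample Sample name used as the filename prefix.
#' @param include_secondary Keep secondary alignment records (default
#'   FALSE).
#' @return A list of circle read sets (class \code{circle_read_set}):
#'   each has \code{circle} (one-row circle info), \code{alignments}
#'   (the matching records), \code{read_names}, and \code{bam_path}.
#'   Attribute \code{summary} is a data.frame (circle_id, n_records,
#'   n_distinct_reads, bam_path).
#' @export
extract_circle_reads <- function(alignments, circles, out_dir,
                                 sample = "sample",
                                 include_secondary = FALSE) {
  if (nrow(circles) == 0L) stop("empty circle table")
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  bam <- attr(alignments, "bam_path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sets <- vector("list", nrow(circles))
  for (i in seq_len(nrow(circles))) {
    ci <- circles[i, ]
    keep <- alignments$qname %in% circles$read_names[[i]] &
      alignments$chrom == ci$chrom &
      .overlaps(alignments$pos, alignments$end, ci$start, ci$end)
    if (!include_secondary) keep <- keep & !alignments$secondary
    sub <- alignments[keep, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    rownames(sub) <- NULL
    dest <- file.path(out_dir, paste0(
      sample, "_", circle_id_filename(ci$circle_id), ".bam"))
    if (!is.null(bam)) {
      .write_circle_bam(bam, dest, ci, circles$read_names[[i]],
                        include_secondary)
    } else {
      dest <- NA_character_
    }
    if (nrow(sub) == 0L)
      warning("circle ", ci$circle_id, ": no alignment records survive")
    sets[[i]] <- structure(
      list(circle = ci, alignments = sub,
           read_names = circles$read_names[[i]], bam_path = dest),
      class = "circle_read_set")
  }
  names(sets) <- circles$circle_id
  attr(sets, "summary") <- data.frame(
    circle_id = circles$circle_id,
    n_records = vapply(sets, function(s) nrow(s$alignments), 1L),
    n_distinct_reads = vapply(sets, function(s)
      length(unique(s$alignments$qname)), 1L),
    bam_path = vapply(sets, function(s) s$bam_path, ""),
    stringsAsFactors = FALSE)
  sets
}

.write_circle_bam <- function(bam, dest, ci, read_names,
                              include_secondary) {
  which <- GenomicRanges::GRanges(
    ci$chrom, IRanges::IRanges(ci$start + 1L, ci$end))
  param <- Rsamtools::ScanBamParam(
    what = "qname", which = which,
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = if (include_secondary) NA else FALSE))
  rules <- S4Vectors::FilterRules(list(in_circle = function(x) {
    x$qname %in% read_names
  }))
  tmp <- tempfile(fileext = ".bam")
  ok <- tryCatch({
    Rsamtools::filterBam(bam, tmp, param = param, filter = rules,
                         indexDestination = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) return(invisible(NULL))
  Rsamtools::sortBam(tmp, sub("\\.bam$", "", dest))
  Rsamtools::indexBam(dest)
  unlink(tmp)
  invisible(dest)
}

#' @export
print.circle_read_set <- function(x, ...) {
  cat("circle read set:", x$circle$circle_id, "\n",
      length(unique(x$alignments$qname)), "distinct reads,",
      nrow(x$alignments), "alignment records\n")
  invisible(x)
}

#' Build in-memory circle read sets without writing BAM files
#'
#' Same record selection as [extract_circle_reads()] but purely
#' in-memory; used by downstream stages and tests.
#'
#' @inheritParams extract_circle_reads
#' @return List of \code{circle_read_set} objects with
#'   \code{bam_path = NA}.
#' @export
circle_read_sets <- function(alignments, circles,
                             include_secondary = FALSE) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  attr(alignments, "bam_path") <- NULL
  extract_circle_reads(alignments, circles, out_dir = tempfile(),
                       include_secondary = include_secondary)
}
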