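#' Per-base depth over a circle's genomic span
#'
#' Depth counts alignment segments (each mate and supplementary record
#' separately) covering each base of the circle interval.
#'
#' @param read_set A \code{circle_read_set}.
#' @param min_intron Splice-gap threshold for CIGAR segmentation.
#' @return Integer vector of length \code{end - start}; element i is
#'   the depth at genomic position \code{start + i - 1} (0-based).
#' @export
circle_depth <- function(read_set, min_intron = 30L) {
  ci <- read_set$circle
  span <- ci$end - ci$start
  aln <- read_set$alignments
  if (nrow(aln) == 0L) return(integer(span))
  delta <- integer(span + 1L)
  for (i in seq_len(nrow(aln))) {
    segs <- cigar_to_segments(aln$pos[i], aln$cigar[i], min_intron)
    s <- pmax(segs$start, ci$start) - ci$start
    e <- pmin(segs$end, ci$end) - ci$start
    keep <- e > s
    for (j in which(keep)) {
      delta[s[j] + 1L] <- delta[s[j] + 1L] + 1L
      delta[e[j] + 1L] <- delta[e[j] + 1L] - 1L
    }
  }
  cumsum(delta)[seq_len(span)]
}

#' Exon-wise coverage of a circle
#'
#' For every annotated exon overlapping the circle (clipped to the
#' circle interval): the number of distinct reads overlapping it by at
#' least 1 bp, the mean per-base depth, and the fraction of its bases
#' with depth > 0. A circle with no annotation overlap gets a single
#' pseudo-exon equal to its genomic span.
#'
#' @param read_set A \code{circle_read_set}.
#' @param annotation Exon annotation.
#' @param min_intron Splice-gap threshold for CIGAR segmentation.
#' @return data.frame: \code{circle_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{gene_id}, \code{exon_number},
#'   \code{exon_length_bp}, \code{n_reads}, \code{mean_depth},
#'   \code{fraction_covered}, \code{pseudo}.
#' @export
exonwise_coverage <- function(read_set, annotation, min_intron = 30L) {
  ci <- read_set$circle
  hit <- annotation$chrom == ci$chrom &
    .overlaps(annotation$start, annotation$end, ci$start, ci$end)
  if (any(hit)) {
    ex <- data.frame(chrom = ci$chrom,
                     start = pmax(annotation$start[hit], ci$start),
                     end = pmin(annotation$end[hit], ci$end),
                     gene_id = annotation$gene_id[hit],
                     exon_number = annotation$exon_number[hit],
                     pseudo = FALSE, stringsAsFactors = FALSE)
  } else {
    ex <- data.frame(chrom = ci$chrom, start = ci$start, end = ci$end,
                     gene_id = NA_character_, exon_number = 1L,
                     pseudo = TRUE, stringsAsFactors = FALSE)
  }
  ex <- ex[order(ex$start, ex$end), , drop = FALSE]
  depth <- circle_depth(read_set, min_intron)
  aln <- read_set$alignments
  seg_list <- lapply(seq_len(nrow(aln)), function(i)
    cbind(cigar_to_segments(aln$pos[i], aln$cigar[i], min_intron),
          qname = aln$qname[i]))
  segs <- if (length(seg_list)) do.call(rbind, seg_list) else
    data.frame(start = integer(0), end = integer(0), qname = character(0))
  out <- lapply(seq_len(nrow(ex)), function(j) {
    idx <- seq.int(ex$start[j] - ci$start + 1L, ex$end[j] - ci$start)
    d <- depth[idx]
    ov <- .overlaps(segs$start, segs$end, ex$start[j], ex$end[j])
    data.frame(circle_id = ci$circle_id, chrom = ex$chrom[j],
               start = ex$start[j], end = ex$end[j],
               gene_id = ex$gene_id[j], exon_number = ex$exon_number[j],
               exon_length_bp = ex$end[j] - ex$start[j],
               n_reads = length(unique(segs$qname[ov])),
               mean_depth = mean(d),
               fraction_covered = mean(d > 0L),
               pseudo = ex$pseudo[j], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Position-wise coverage profile of a circle
#'
#' The transcribed coordinate of the circle is the concatenation of its
#' covered exons in genomic order; bases of the genomic span outside
#' covered exons are excluded. One row per transcribed base records the
#' exon number, the relative position within the circle and within the
#' exon (both in [0, 1]), and the depth.
#'
#' @param read_set A \code{circle_read_set}.
#' @param exon_cov Exon coverage table from [exonwise_coverage()]; rows
#'   with \code{n_reads > 0} define the transcribed coordinate. When
#'   NULL it is computed with an annotation-free pseudo-exon.
#' @param min_intron Splice-gap threshold for CIGAR segmentation.
#' @return data.frame of class \code{coverage_profile} with columns
#'   \code{exon_number}, \code{rel_pos_circle}, \code{rel_pos_exon},
#'   \code{depth}; attributes \code{circle_id} and
#'   \code{circle_length_bp}.
#' @export
positionwise_coverage <- function(read_set, exon_cov = NULL,
                                  min_intron = 30L) {
  ci <- read_set$circle
  if (is.null(exon_cov))
    exon_cov <- exonwise_coverage(
      read_set,
      data.frame(chrom = character(0), start = integer(0),
                 end = integer(0), gene_id = character(0),
                 exon_number = integer(0)),
      min_intron)
  cov <- exon_cov[exon_cov$n_reads > 0L | exon_cov$pseudo, , drop = FALSE]
  if (nrow(cov) == 0L) cov <- exon_cov   # all-zero circle: keep structure
  cov <- cov[order(cov$start, cov$end), , drop = FALSE]
  depth <- circle_depth(read_set, min_intron)
  rows <- lapply(seq_len(nrow(cov)), function(j) {
    len <- cov$end[j] - cov$start[j]
    idx <- seq.int(cov$start[j] - ci$start + 1L, cov$end[j] - ci$start)
    data.frame(exon_number = cov$exon_number[j],
               exon_pos = seq_len(len),
               rel_pos_exon = if (len > 1L) (seq_len(len) - 1L) / (len - 1L)
                              else 0,
               depth = depth[idx])
  })
  prof <- do.call(rbind, rows)
  L <- nrow(prof)
  prof$rel_pos_circle <- if (L > 1L) (seq_len(L) - 1L) / (L - 1L) else 0
  prof <- prof[, c("exon_number", "rel_pos_circle", "rel_pos_exon",
                   "depth")]
  rownames(prof) <- NULL
  attr(prof, "circle_id") <- ci$circle_id
  attr(prof, "circle_length_bp") <- L
  class(prof) <- c("coverage_profile", "data.frame")
  prof
}

#' Plot a smoothed coverage profile to PNG
#'
#' Renders the position-wise profile with exons as coloured segments
#' after smoothing with a centered rolling mean (window
#' \code{max(3, circle_length / 50)} bases).
#'
#' @param profile A \code{coverage_profile}.
#' @param out_path PNG path to write.
#' @param window Smoothing window in bases; default as above.
#' @return \code{out_path}, invisibly.
#' @export
render_profile_plot <- function(profile, out_path, window = NULL) {
  if (nrow(profile) == 0L) stop("empty coverage profile")
  L <- attr(profile, "circle_length_bp")
  if (is.null(window)) window <- max(3L, round(L / 50))
  sm <- as.numeric(stats::filter(profile$depth, rep(1 / window, window),
                                 sides = 2L))
  sm[is.na(sm)] <- profile$depth[is.na(sm)]
  ok <- tryCatch({
    grDevices::png(out_path, width = 800L, height = 400L)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot open PNG device at ", out_path)
  on.exit(grDevices::dev.off())
  exons <- unique(profile$exon_number)
  cols <- grDevices::hcl.colors(max(3L, length(exons)), "Dark 3")
  graphics::plot(profile$rel_pos_circle, sm, type = "n",
                 xlab = "relative position in circle",
                 ylab = "smoothed depth",
                 main = attr(profile, "circle_id"),
                 ylim = c(0, max(1, sm, na.rm = TRUE)))
  for (k in seq_along(exons)) {
    sel <- profile$exon_number == exons[k]
    graphics::lines(profile$rel_pos_circle[sel], sm[sel],
                    col = cols[k], lwd = 2L)
  }
  graphics::legend("topright", legend = paste("exon", exons),
                   col = cols[seq_along(exons)], lwd = 2L, cex = 0.8)
  invisible(out_path)
}

# one browser-loadable BED12 line per circle: covered exons as blocks
.coverage_bed12_line <- function(exon_cov) {
  cov <- exon_cov[exon_cov$n_reads > 0L | exon_cov$pseudo, , drop = FALSE]
  if (nrow(cov) == 0L) cov <- exon_cov
  cov <- cov[order(cov$start), , drop = FALSE]
  cs <- min(cov$start)
  ce <- max(cov$end)
  paste(c(cov$chrom[1L], cs, ce, cov$circle_id[1L], 0L, ".", cs, ce, "0",
          nrow(cov),
          paste0(paste(cov$end - cov$start, collapse = ","), ","),
          paste0(paste(cov$start - cs, collapse = ","), ",")),
        collapse = "\t")
}
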