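#' Assign host genes to circles
#'
#' A gene is a host gene of a circle iff at least one of its annotated
#' exons overlaps the circle interval. Circles may have zero
#' (intergenic), one, or several host genes; multi-host circles
#' contribute to each gene's summary independently.
#'
#' @param circles A circle table.
#' @param annotation Exon annotation from [read_exon_annotation()].
#' @return The circle table with its \code{host_genes} list column
#'   filled.
#' @export
assign_host_genes <- function(circles, annotation) {
  circles$host_genes <- lapply(seq_len(nrow(circles)), function(i) {
    hit <- annotation$chrom == circles$chrom[i] &
      .overlaps(annotation$start, annotation$end,
                circles$start[i], circles$end[i])
    sort(unique(annotation$gene_id[hit]))
  })
  circles
}

.pair_categories <- c("same_start", "same_end", "within", "overlapping",
                      "non_overlapping")

#' Classify the relationship between two circles of one host gene
#'
#' Categories, in precedence order: \code{same_start} (equal starts,
#' different ends), \code{same_end} (equal ends, different starts),
#' \code{within} (one interval strictly inside the other),
#' \code{overlapping} (intersecting, none of the above), and
#' \code{non_overlapping} (disjoint). Containment sharing a boundary is
#' reported by the shared boundary (same_start / same_end). The
#' classification is symmetric; identical intervals are rejected — they
#' are the same circle.
#'
#' @param a,b Numeric length-2 vectors \code{c(start, end)} of two
#'   circles on the same chromosome.
#' @return One of \code{"same_start"}, \code{"same_end"},
#'   \code{"within"}, \code{"overlapping"}, \code{"non_overlapping"}.
#' @export
classify_circle_pair <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L, a[1L] < a[2L], b[1L] < b[2L])
  if (a[1L] == b[1L] && a[2L] == b[2L])
    stop("identical intervals are one circle, not a pair")
  if (a[1L] == b[1L]) return("same_start")
  if (a[2L] == b[2L]) return("same_end")
  if ((a[1L] > b[1L] && a[2L] < b[2L]) ||
      (b[1L] > a[1L] && b[2L] < a[2L])) return("within")
  if (a[1L] < b[2L] && b[1L] < a[2L]) return("overlapping")
  "non_overlapping"
}

#' Summarize circular isoforms per host gene
#'
#' Groups circles by host gene, counts them, and classifies every pair
#' of circles of one gene into the relationship categories of
#' [classify_circle_pair()]. The global single- vs multi-circle
#' proportion across genes is attached as attribute
#' \code{"single_multi"}.
#'
#' @param circles A circle table with host genes assigned
#'   ([assign_host_genes()]).
#' @return data.frame, one row per host gene: \code{gene_id},
#'   \code{n_circles}, \code{is_single}, and one count column per
#'   category.
#' @export
summarize_host_genes <- function(circles) {
  genes <- sort(unique(unlist(circles$host_genes)))
  rows <- lapply(genes, function(g) {
    idx <- which(vapply(circles$host_genes, function(h) g %in% h, TRUE))
    counts <- stats::setNames(integer(length(.pair_categories)),
                              .pair_categories)
    if (length(idx) >= 2L) {
      for (p in utils::combn(idx, 2L, simplify = FALSE)) {
        cat_ <- classify_circle_pair(
          c(circles$start[p[1L]], circles$end[p[1L]]),
          c(circles$start[p[2L]], circles$end[p[2L]]))
        counts[cat_] <- counts[cat_] + 1L
      }
    }
    cbind(data.frame(gene_id = g, n_circles = length(idx),
                     is_single = length(idx) == 1L,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(gene_id = character(0), n_circles = integer(0),
                     is_single = logical(0)),
          stats::setNames(as.data.frame(
            matrix(integer(0), 0L, length(.pair_categories))),
            .pair_categories))
  rownames(out) <- NULL
  n_genes <- nrow(out)
  attr(out, "single_multi") <- data.frame(
    n_genes = n_genes,
    n_single = sum(out$is_single),
    n_multi = sum(!out$is_single),
    prop_multi = if (n_genes > 0L) sum(!out$is_single) / n_genes
                 else NA_real_)
  out
}
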