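#' Length group of a circle
#'
#' Circles are partitioned into small (< 500 bp), medium (500–1,000 bp)
#' and long (>= 1,000 bp) before group-wise clustering, so that the
#' clustering within a group is not driven by length alone.
#'
#' @param circle_length_bp Lengths in bp (vectorized).
#' @return Character vector: \code{"small"}, \code{"medium"} or
#'   \code{"long"}.
#' @export
assign_length_group <- function(circle_length_bp) {
  stopifnot(all(circle_length_bp > 0))
  ifelse(circle_length_bp < 500, "small",
         ifelse(circle_length_bp < 1000, "medium", "long"))
}

#' Number of K-means clusters for a set of circles
#'
#' Piecewise rule on the set size n: no clustering for n <= 2; two
#' clusters for 3 <= n <= 9; four for 10 <= n <= 100; for n > 100,
#' round(n / 20) with half-away-from-zero rounding, capped at 10.
#'
#' @param n_circles Number of circles in the set (scalar, >= 1).
#' @return Integer, or \code{NA} when no clustering is performed.
#' @export
choose_cluster_count <- function(n_circles) {
  n <- as.integer(n_circles)
  if (is.na(n) || n < 1L) stop("n_circles must be >= 1")
  if (n <= 2L) return(NA_integer_)
  if (n <= 9L) return(2L)
  if (n <= 100L) return(4L)
  min(10L, as.integer(floor(n / 20 + 0.5)))
}

#' Normalize coverage profiles onto a common length
#'
#' Each profile is resampled onto \code{n_bins} equally spaced relative
#' positions in [0, 1] by linear interpolation, then amplitude-scaled
#' to maximum 1. All-zero profiles stay zero and are excluded with a
#' warning (they carry no shape).
#'
#' @param profiles Named list of \code{coverage_profile} objects (or
#'   plain numeric depth vectors).
#' @param n_bins Number of bins (default 100, minimum 10).
#' @return Numeric matrix of n_profiles x n_bins, rownames = circle
#'   IDs; attribute \code{"excluded"} names the all-zero profiles.
#' @export
normalize_profiles <- function(profiles, n_bins = 100L) {
  stopifnot(n_bins >= 10L)
  ids <- names(profiles)
  if (is.null(ids)) ids <- as.character(seq_along(profiles))
  grid <- seq(0, 1, length.out = n_bins)
  rows <- lapply(profiles, function(p) {
    d <- if (is.data.frame(p)) p$depth else as.numeric(p)
    if (length(d) == 1L) return(rep(as.numeric(d > 0), n_bins))
    x <- seq(0, 1, length.out = length(d))
    stats::approx(x, d, xout = grid)$y
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- ids
  zero <- apply(mat, 1L, function(r) all(r == 0))
  if (any(zero))
    warning(sum(zero), " all-zero profile(s) excluded from clustering: ",
            paste(utils::head(ids[zero], 5L), collapse = ", "))
  mx <- apply(mat, 1L, max)
  mat[!zero, ] <- mat[!zero, , drop = FALSE] / mx[!zero]
  out <- mat[!zero, , drop = FALSE]
  attr(out, "excluded") <- ids[zero]
  out
}

#' K-means clustering with Pearson correlation distance
#'
#' Lloyd-style K-means under the distance d(x, y) = 1 - cor(x, y)
#' (centered Pearson). Centroids are per-cluster mean profiles; an
#' emptied cluster is repaired by re-seeding it with the point farthest
#' from its centroid. The best of \code{n_restarts} seeded restarts by
#' total within-cluster distance is returned; results are deterministic
#' given \code{seed}.
#'
#' @param mat Profile matrix (rows = circles); rows must have nonzero
#'   variance (constant rows are excluded with a warning).
#' @param k Number of clusters (2 <= k <= nrow).
#' @param seed Random seed for the restarts (default 42).
#' @param n_restarts Number of random initializations (default 10).
#' @param max_iter Iteration cap per restart (default 100).
#' @return List: \code{assignments} (named integer vector, labels
#'   1..k), \code{centroids} (k x n_bins matrix),
#'   \code{tot_within} (sum of member-to-centroid distances).
#' @export
kmeans_correlation <- function(mat, k, seed = 42L, n_restarts = 10L,
                               max_iter = 100L) {
  stopifnot(is.matrix(mat), k >= 2L)
  keep <- apply(mat, 1L, stats::sd) > 0
  if (any(!keep))
    warning(sum(!keep), " zero-variance profile(s) excluded")
  mat <- mat[keep, , drop = FALSE]
  n <- nrow(mat)
  if (k > n) stop("k = ", k, " exceeds the number of profiles (", n, ")")
  cor_dist <- function(x, y) 1 - stats::cor(x, y)
  dist_to <- function(centroids) {
    # rows x centroids distance matrix
    1 - stats::cor(t(mat), t(centroids))
  }
  best <- NULL
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    centroids <- mat[sample.int(n, k), , drop = FALSE]
    assign_old <- rep(0L, n)
    for (it in seq_len(max_iter)) {
      dd <- dist_to(centroids)
      assign_new <- max.col(-dd, ties.method = "first")
      for (c_ in seq_len(k)) {           # empty-cluster repair
        if (!any(assign_new == c_)) {
          worst <- which.max(dd[cbind(seq_len(n), assign_new)])
          assign_new[worst] <- c_
          dd[worst, ] <- Inf
        }
      }
      if (identical(assign_new, assign_old)) break
      assign_old <- assign_new
      for (c_ in seq_len(k))
        centroids[c_, ] <- colMeans(mat[assign_new == c_, , drop = FALSE])
    }
    dd <- dist_to(centroids)
    tot <- sum(dd[cbind(seq_len(n), assign_old)])
    if (is.null(best) || tot < best$tot_within)
      best <- list(assignments = stats::setNames(assign_old,
                                                 rownames(mat)),
                   centroids = centroids, tot_within = tot)
  }
  best
}

#' Summaries and false-positive flags per cluster
#'
#' For each cluster: the mean normalized profile, member count, and
#' median member length. A cluster is flagged as junction-unbalanced
#' when the mean coverage of the first 10 percent of bins and of the
#' last 10 percent differ by more than \code{unbalanced_factor} — the
#' one-sided profile expected from a trans-splicing or rearrangement
#' junction rather than a true circle.
#'
#' @param clustering Result of [kmeans_correlation()].
#' @param mat The normalized profile matrix that was clustered.
#' @param lengths Named numeric vector: circle ID -> length in bp.
#' @param unbalanced_factor Flagging ratio (default 3).
#' @return data.frame per cluster: \code{cluster}, \code{n_members},
#'   \code{median_length_bp}, \code{edge_ratio}, \code{unbalanced};
#'   attribute \code{"mean_profiles"} holds the k x n_bins matrix.
#' @export
summarize_clusters <- function(clustering, mat, lengths,
                               unbalanced_factor = 3) {
  asg <- clustering$assignments
  k <- nrow(clustering$centroids)
  n_bins <- ncol(mat)
  edge <- max(1L, floor(n_bins / 10))
  means <- matrix(NA_real_, k, n_bins)
  rows <- lapply(seq_len(k), function(c_) {
    members <- names(asg)[asg == c_]
    mp <- colMeans(mat[members, , drop = FALSE])
    means[c_, ] <<- mp
    lo <- mean(mp[seq_len(edge)])
    hi <- mean(mp[seq.int(n_bins - edge + 1L, n_bins)])
    ratio <- (max(lo, hi) + 1e-9) / (min(lo, hi) + 1e-9)
    data.frame(cluster = c_, n_members = length(members),
               median_length_bp = stats::median(lengths[members]),
               edge_ratio = ratio,
               unbalanced = ratio > unbalanced_factor)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_profiles") <- means
  out
}

#' Group-wise clustering of all circle coverage profiles
#'
#' Runs the full clustering stage: normalize all profiles, then cluster
#' the complete set ("all") and each length group (small / medium /
#' long) separately, choosing k per group with
#' [choose_cluster_count()]. Groups with two or fewer circles are not
#' clustered.
#'
#' @param profiles Named list of \code{coverage_profile}s.
#' @param lengths Named numeric vector of circle lengths (bp).
#' @param n_bins Bins for [normalize_profiles()].
#' @param seed,n_restarts Passed to [kmeans_correlation()].
#' @param unbalanced_factor Passed to [summarize_clusters()].
#' @return Named list (all, small, medium, long) of cluster sets: each
#'   \code{NULL} when absent/too small, else a list with \code{group},
#'   \code{n_circles}, \code{k}, \code{assignments}, \code{clusters}
#'   (the [summarize_clusters()] table), \code{profiles}, \code{seed}.
#' @export
cluster_coverage_profiles <- function(profiles, lengths, n_bins = 100L,
                                      seed = 42L, n_restarts = 10L,
                                      unbalanced_factor = 3) {
  mat <- normalize_profiles(profiles, n_bins)
  lengths <- lengths[rownames(mat)]
  groups <- assign_length_group(lengths)
  sets <- list(all = rownames(mat),
               small = rownames(mat)[groups == "small"],
               medium = rownames(mat)[groups == "medium"],
               long = rownames(mat)[groups == "long"])
  out <- lapply(names(sets), function(g) {
    ids <- sets[[g]]
    n <- length(ids)
    if (n == 0L) return(NULL)
    k <- choose_cluster_count(n)
    if (is.na(k))
      return(list(group = g, n_circles = n, k = NA_integer_,
                  assignments = NULL, clusters = NULL,
                  profiles = mat[ids, , drop = FALSE], seed = seed))
    cl <- kmeans_correlation(mat[ids, , drop = FALSE], k, seed = seed,
                             n_restarts = n_restarts)
    list(group = g, n_circles = n, k = k,
         assignments = cl$assignments,
         clusters = summarize_clusters(cl, mat[ids, , drop = FALSE],
                                       lengths, unbalanced_factor),
         profiles = mat[ids, , drop = FALSE], seed = seed)
  })
  names(out) <- names(sets)
  out
}
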