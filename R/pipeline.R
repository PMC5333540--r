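.pipeline_steps <- c("skipped_exons", "mate_pairs", "isoforms",
                     "coverage", "clustering")

# tabular output with a commented parameter block + header
.write_tsv <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params))
    writeLines(sprintf("# %s = %s", names(params),
                       vapply(params, paste, "", collapse = ",")), con)
  listcols <- vapply(df, is.list, TRUE)
  for (cn in names(df)[listcols])
    df[[cn]] <- vapply(df[[cn]], paste, "", collapse = ",")
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full circRNA characterization pipeline
#'
#' Orchestrates the stages end to end: per-circle read extraction, then
#' the (independent) skipped-exon, mate-pair, host-gene isoform and
#' coverage analyses, then profile clustering. Steps may be skipped by
#' name; coverage is a prerequisite of clustering and is auto-enabled
#' when clustering is requested. A manifest JSON recording parameters,
#' seed and per-step status is written to the output directory.
#'
#' @param alignments SAM/BAM path with all chimerically mapped reads.
#' @param circles Path to a two-column circle table; alternatively pass
#'   \code{dcc_count} + \code{dcc_junctions}.
#' @param dcc_count,dcc_junctions DCC \code{CircRNACount} path and STAR
#'   chimeric-junction paths (named mate1/mate2 where mate-level).
#' @param annotation BED exon annotation path.
#' @param sample Sample name used as output prefix.
#' @param out_dir Output directory.
#' @param fragment_length Expected library fragment size in bp
#'   (required for the mate-pair analysis).
#' @param skip_steps Character vector of steps to skip, from
#'   \code{skipped_exons, mate_pairs, isoforms, coverage, clustering}.
#' @param seed Seed for the clustering restarts (default 42).
#' @param n_bins Bins for profile normalization (default 100).
#' @param min_intron Minimum splice-gap length in bp (default 30).
#' @param tolerance DCC junction-matching tolerance in bp (default 1).
#' @param min_fragments Fragments required before a circle can be
#'   flagged suspect (default 2).
#' @param plots Render per-circle and per-cluster PNGs (default TRUE).
#' @return Invisibly, a list with the per-stage results and the
#'   manifest; side effect: output files under \code{out_dir}.
#' @export
run_pipeline <- function(alignments, circles = NULL, dcc_count = NULL,
                         dcc_junctions = NULL, annotation, sample,
                         out_dir, fragment_length,
                         skip_steps = character(0), seed = 42L,
                         n_bins = 100L, min_intron = 30L,
                         tolerance = 1L, min_fragments = 2L,
                         plots = TRUE) {
  unknown <- setdiff(skip_steps, .pipeline_steps)
  if (length(unknown))
    stop("unknown step name(s) in skip list: ",
         paste(unknown, collapse = ", "))
  run <- setdiff(.pipeline_steps, skip_steps)
  if ("clustering" %in% run && !("coverage" %in% run))
    stop("clustering requires the coverage step; ",
         "remove 'coverage' from --skip-steps or also skip clustering")
  if (is.null(circles) && is.null(dcc_count))
    stop("either a circle table or DCC outputs must be given")
  for (p in c(alignments, circles, dcc_count, dcc_junctions, annotation))
    if (!file.exists(p)) stop("missing input file: ", p)
  stopifnot(fragment_length > 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(out_dir, sample)
  params <- list(sample = sample, fragment_length = fragment_length,
                 seed = seed, n_bins = n_bins, min_intron = min_intron,
                 tolerance = tolerance, min_fragments = min_fragments,
                 skip_steps = skip_steps)

  message("reading inputs")
  circ <- if (!is.null(circles)) read_circle_table(circles) else
    read_dcc_outputs(dcc_count, dcc_junctions, tolerance)
  junction_reads <- attr(circ, "junction_reads")
  ann <- read_exon_annotation(annotation)
  aln <- read_alignments(alignments)

  message("extracting reads for ", nrow(circ), " circles")
  sets <- extract_circle_reads(aln, circ, file.path(out_dir, "bams"),
                               sample = sample)
  summ <- attr(sets, "summary")
  summ$bam_path <- file.path("bams", basename(summ$bam_path))
  .write_tsv(summ, paste0(prefix, ".extraction_summary.txt"), params)
  status <- list(extract = "done")
  res <- list(circles = circ, read_sets = sets)

  if ("skipped_exons" %in% run) {
    message("detecting skipped exons")
    calls <- lapply(sets, function(rs) {
      message("  circle ", rs$circle$circle_id)
      find_skipped_exons(rs, ann, min_intron)
    })
    calls <- do.call(rbind, c(calls, make.row.names = FALSE))
    write_skip_outputs(calls, prefix)
    res$skipped_exons <- calls
    status$skipped_exons <- "done"
  } else status$skipped_exons <- "skipped"

  exon_covs <- NULL
  if ("coverage" %in% run) {
    message("computing coverage profiles")
    exon_covs <- lapply(sets, function(rs)
      exonwise_coverage(rs, ann, min_intron))
    names(exon_covs) <- names(sets)
    .write_tsv(do.call(rbind, c(exon_covs, make.row.names = FALSE)),
               paste0(prefix, ".exon_counts.txt"), params)
    writeLines(vapply(exon_covs, .coverage_bed12_line, ""),
               paste0(prefix, ".exon_counts.bed"))
    profiles <- lapply(names(sets), function(id)
      positionwise_coverage(sets[[id]], exon_covs[[id]], min_intron))
    names(profiles) <- names(sets)
    prof_dir <- file.path(out_dir, "coverage_profiles")
    dir.create(prof_dir, showWarnings = FALSE)
    for (id in names(profiles))
      .write_tsv(profiles[[id]],
                 file.path(prof_dir, paste0(circle_id_filename(id),
                                            ".coverage_profile.txt")))
    if (plots) {
      png_dir <- file.path(out_dir, "coverage_pictures")
      dir.create(png_dir, showWarnings = FALSE)
      for (id in names(profiles))
        if (nrow(profiles[[id]]) > 0L)
          render_profile_plot(profiles[[id]],
                              file.path(png_dir,
                                        paste0(circle_id_filename(id),
                                               ".png")))
    }
    res$exon_coverage <- exon_covs
    res$profiles <- profiles
    status$coverage <- "done"
  } else status$coverage <- "skipped"

  if ("mate_pairs" %in% run) {
    message("classifying fragments")
    fs <- fragment_summary(sets, ann, fragment_length,
                           junction_reads = junction_reads,
                           exon_coverages = exon_covs,
                           min_fragments = min_fragments)
    .write_tsv(fs, paste0(prefix, ".mate_status.txt"), params)
    res$fragments <- fs
    status$mate_pairs <- "done"
  } else status$mate_pairs <- "skipped"

  if ("isoforms" %in% run) {
    message("summarizing host genes")
    circ2 <- assign_host_genes(circ, ann)
    hg <- summarize_host_genes(circ2)
    .write_tsv(hg, paste0(prefix, ".hostgene_isoforms.txt"), params)
    .write_tsv(attr(hg, "single_multi"),
               paste0(prefix, ".hostgene_single_multi.txt"), params)
    res$host_genes <- hg
    status$isoforms <- "done"
  } else status$isoforms <- "skipped"

  if ("clustering" %in% run) {
    message("clustering coverage profiles")
    lengths <- vapply(names(sets), function(id)
      as.numeric(estimate_circle_length(sets[[id]]$circle, ann,
                                        exon_covs[[id]])), 1)
    cl <- cluster_coverage_profiles(res$profiles, lengths,
                                    n_bins = n_bins, seed = seed)
    asg_rows <- list()
    for (g in names(cl)) {
      if (is.null(cl[[g]]) || is.null(cl[[g]]$assignments)) next
      a <- cl[[g]]$assignments
      asg_rows[[g]] <- data.frame(circle_id = names(a), group = g,
                                  cluster = as.integer(a),
                                  circle_length_bp =
                                    lengths[names(a)],
                                  stringsAsFactors = FALSE)
      .write_tsv(cl[[g]]$clusters,
                 paste0(prefix, ".cluster_summary.", g, ".txt"), params)
      if (plots) {
        mp <- attr(cl[[g]]$clusters, "mean_profiles")
        for (c_ in seq_len(nrow(mp))) {
          grDevices::png(paste0(prefix, ".cluster_mean.", g, ".",
                                c_, ".png"), 800L, 400L)
          graphics::plot(seq(0, 1, length.out = ncol(mp)), mp[c_, ],
                         type = "l", lwd = 2L,
                         xlab = "relative position",
                         ylab = "mean normalized coverage",
                         main = sprintf("%s cluster %d", g, c_))
          grDevices::dev.off()
        }
      }
    }
    if (length(asg_rows))
      .write_tsv(do.call(rbind, c(asg_rows, make.row.names = FALSE)),
                 paste0(prefix, ".cluster_assignments.txt"), params)
    res$clustering <- cl
    status$clustering <- "done"
  } else status$clustering <- "skipped"

  manifest <- list(package = "circchar",
                   version = as.character(utils::packageVersion("circchar")),
                   parameters = params, steps = status)
  jsonlite::write_json(manifest, paste0(prefix, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
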