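test_that("the five-read worked example yields four introns and a 2/5 skip", {
  env <- skipping_example_sets()
  rs <- env$sets[[1L]]
  introns <- infer_introns(rs)
  expect_equal(nrow(introns), 4L)
  expect_equal(introns$start, c(400L, 400L, 600L, 800L))
  expect_equal(introns$end, c(500L, 700L, 700L, 900L))

  cands <- detect_skipped_exons(introns, env$annotation, rs$circle)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$exon_number, 3L)
  expect_equal(c(cands$exon_start, cands$exon_end), c(500L, 600L))
  expect_equal(c(cands$intron_start, cands$intron_end), c(400L, 700L))

  call <- assign_isoform_support(rs, cands[1L, ])
  expect_equal(call$n_skip, 2L)
  expect_equal(call$n_total, 5L)
  expect_equal(call$proportion_skipping, 0.4)
  expect_setequal(call$skipping_reads[[1L]], c("r4", "r5"))
  expect_equal(call$n_skip + call$n_cover + call$n_uninformative,
               call$n_total)
})

test_that("intron inference merges identical gaps and respects boundaries", {
  env <- skipping_example_sets()
  rs <- env$sets[[1L]]
  # two reads share the 400-700 gap: one call with two supporters
  skip <- infer_introns(rs)
  i <- which(skip$start == 400L & skip$end == 700L)
  expect_setequal(skip$supporting_reads[[i]], c("r4", "r5"))

  # gapless read set gives no introns
  rs2 <- rs
  rs2$alignments <- data.frame(qname = "q", flag = 0L, chrom = "chrT",
                               pos = 300L, cigar = "200M", strand = "+",
                               mate = 0L, secondary = FALSE,
                               supplementary = FALSE, end = 500L)
  expect_equal(nrow(infer_introns(rs2)), 0L)

  # a gap crossing the circle boundary is dropped with a warning
  rs3 <- rs
  rs3$alignments <- data.frame(qname = "q", flag = 0L, chrom = "chrT",
                               pos = 200L, cigar = "50M200N50M",
                               strand = "+", mate = 0L, secondary = FALSE,
                               supplementary = FALSE, end = 500L)
  expect_warning(out <- infer_introns(rs3), "boundary")
  expect_equal(nrow(out), 0L)
})

test_that("exons partially overlapping a gap are not skip candidates", {
  env <- skipping_example_sets()
  rs <- env$sets[[1L]]
  introns <- infer_introns(rs)
  # shift the annotation so exon 3 straddles the 400-700 intron edge
  ann <- env$annotation
  ann$start[ann$exon_number == 3L] <- 350L
  expect_equal(nrow(detect_skipped_exons(introns, ann, rs$circle)), 0L)
  # an annotation with no exon inside any intron gives nothing
  ann2 <- env$annotation[env$annotation$exon_number %in% c(2L, 5L), ]
  expect_equal(nrow(detect_skipped_exons(introns, ann2, rs$circle)), 0L)
})

test_that("all calls nest exon within intron within circle, and files round out", {
  env <- skipping_example_sets()
  rs <- env$sets[[1L]]
  calls <- find_skipped_exons(rs, env$annotation)
  expect_equal(nrow(calls), 1L)
  expect_true(all(calls$exon_start >= calls$intron_start &
                    calls$exon_end <= calls$intron_end))
  expect_true(all(calls$intron_start >= calls$circle_start &
                    calls$intron_end <= calls$circle_end))

  prefix <- file.path(tempfile(), "s")
  dir.create(dirname(prefix))
  paths <- write_skip_outputs(calls, prefix)
  txt <- read.delim(paste0(prefix, ".skipped_exons.txt"))
  expect_equal(txt$n_skip, 2L)
  expect_equal(txt$n_total, 5L)
  bed <- readLines(paste0(prefix, ".skipped_exons.bed"))
  expect_equal(length(bed), 1L)
  f <- strsplit(bed, "\t")[[1L]]
  expect_equal(f[1L], "chrT")
  expect_equal(as.integer(f[2L]), 300L)
  expect_equal(as.integer(f[5L]), 40L)   # score = 100 * 2/5

  # empty calls: header-only TSV, empty BED
  write_skip_outputs(calls[0L, ], prefix)
  expect_equal(nrow(read.delim(paste0(prefix, ".skipped_exons.txt"))), 0L)
  expect_equal(length(readLines(paste0(prefix, ".skipped_exons.bed"))), 0L)

  rs_empty <- rs
  rs_empty$alignments <- rs$alignments[0L, ]
  expect_error(assign_isoform_support(rs_empty, data.frame(
    exon_start = 1L, exon_end = 2L, gene_id = "g", exon_number = 1L,
    intron_start = 0L, intron_end = 3L)), "empty")
})

test_that("simulated skip fractions are recovered without bias", {
  # one seeded simulation per fraction; the full multi-seed sweep is the
  # acceptance check
  for (sf in c(0.3, 0.7)) {
    sim <- simulate_circles(1, 300, fragment_length = 350,
                            read_length = 300, skip_fraction = sf,
                            n_fragments_per_circle = 200, seed = 2)
    env <- load_sim(sim)
    calls <- find_skipped_exons(env$sets[[1L]], env$annotation)
    expect_equal(nrow(calls), 1L)
    # exact binomial 99% band around the true fraction at n = n_total
    n <- calls$n_total
    band <- qbinom(c(0.005, 0.995), n, sf) / n
    expect_gte(calls$proportion_skipping, band[1L])
    expect_lte(calls$proportion_skipping, band[2L])
  }
})
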