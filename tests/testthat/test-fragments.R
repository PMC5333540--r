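test_that("fragments classify as double, single, or excluded", {
  rs <- list(circle = data.frame(circle_id = "c:0|100", chrom = "c",
                                 start = 0L, end = 100L),
             alignments = data.frame(qname = character(0)),
             read_names = c("fboth", "fone", "funp", "fnone"))
  class(rs) <- "circle_read_set"
  js <- list(fboth = c(1L, 2L), fone = 2L, funp = 0L)
  expect_warning(out <- classify_fragments(rs, js), "excluded")
  expect_equal(out$n_double, 1L)
  expect_equal(out$n_single, 2L)   # one-mate + unpaired evidence
  expect_equal(out$n_fragments, 3L)
  expect_equal(out$double_fraction, 1 / 3)

  rs$read_names <- character(0)
  empty <- classify_fragments(rs, list())
  expect_equal(empty$n_fragments, 0L)
  expect_true(is.na(empty$double_fraction))
})

test_that("junction-file and alignment channels agree with simulation truth", {
  sim <- simulate_circles(6, c(200, 300), seed = 21,
                          n_fragments_per_circle = 25)
  env <- load_sim(sim, use_dcc = TRUE)
  jr <- attr(env$circles, "junction_reads")
  truth <- sim$truth[sim$truth$class != "none", ]
  for (rs in env$sets) {
    tr <- truth[truth$circle_id == rs$circle$circle_id, ]
    expected_double <- sum(tr$class == "double")
    expected_total <- nrow(tr)
    via_files <- classify_fragments(rs, junction_spanning_mates(rs, jr))
    expect_equal(via_files$n_double, expected_double)
    expect_equal(via_files$n_fragments, expected_total)
    # alignment channel: split records across the back-splice
    via_aln <- classify_fragments(rs, junction_spanning_mates(rs))
    expect_equal(via_aln$n_double, expected_double)
    expect_equal(via_aln$n_single, via_files$n_single)
  }
})

test_that("circle length is the covered exonic length, span as fallback", {
  env <- skipping_example_sets()
  rs <- env$sets[[1L]]
  ec <- exonwise_coverage(rs, env$annotation)
  expect_equal(estimate_circle_length(rs$circle, env$annotation, ec), 400L)

  lone <- data.frame(circle_id = "chrZ:0|700", chrom = "chrZ",
                     start = 0L, end = 700L)
  expect_equal(estimate_circle_length(lone, env$annotation), 700L)

  one_exon <- data.frame(chrom = "chrZ", start = 100L, end = 250L,
                         gene_id = "g", exon_number = 1L)
  circ <- data.frame(circle_id = "chrZ:50|400", chrom = "chrZ",
                     start = 50L, end = 400L)
  expect_equal(estimate_circle_length(circ, one_exon), 150L)
})

test_that("the suspect flag fires only for short all-single circles", {
  base <- data.frame(circle_length_bp = 300L, n_double = 0L,
                     n_fragments = 5L)
  expect_true(flag_suspect_circles(base, 350L))
  expect_false(flag_suspect_circles(transform(base, n_double = 3L), 350L))
  expect_false(flag_suspect_circles(
    transform(base, circle_length_bp = 2000L), 350L))
  expect_false(flag_suspect_circles(transform(base, n_fragments = 1L),
                                    350L))
})

test_that("double-breakpoint fraction falls with circle length", {
  sim <- simulate_circles(8, c(200, 400, 800, 1600), seed = 4,
                          n_fragments_per_circle = 30)
  env <- load_sim(sim)
  fs <- fragment_summary(env$sets, env$annotation, 350)
  med <- tapply(fs$double_fraction, fs$circle_length_bp, median)
  expect_true(all(diff(med) <= 0))
  expect_lt(cor(fs$circle_length_bp, fs$double_fraction), 0)
  # conservation: singles + doubles = junction-supporting fragments
  truth <- sim$truth[sim$truth$class != "none", ]
  expect_equal(sum(fs$n_fragments), nrow(truth))
})
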