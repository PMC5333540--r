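make_ct <- function(ivs, chrom = "chr1") {
  ids <- make_circle_id(chrom, ivs[, 1L], ivs[, 2L])
  p <- tempfile()
  writeLines(paste0(ids, "\tr", seq_along(ids)), p)
  read_circle_table(p)
}

test_that("host genes are every gene with an exon overlapping the circle", {
  ann <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                    start = c(100L, 900L, 950L, 100L),
                    end = c(500L, 1200L, 1100L, 500L),
                    gene_id = c("A", "B", "C", "D"),
                    exon_number = 1L)
  ct <- make_ct(rbind(c(150, 400),    # inside A
                      c(5000, 6000),  # intergenic
                      c(950, 1000)))  # overlaps B and C
  ct <- assign_host_genes(ct, ann)
  expect_equal(ct$host_genes[[1L]], "A")
  expect_equal(ct$host_genes[[2L]], character(0))
  expect_setequal(ct$host_genes[[3L]], c("B", "C"))
})

test_that("pair classification covers the schematic categories", {
  expect_equal(classify_circle_pair(c(100, 500), c(100, 700)),
               "same_start")
  expect_equal(classify_circle_pair(c(100, 500), c(300, 500)), "same_end")
  expect_equal(classify_circle_pair(c(200, 400), c(100, 500)), "within")
  expect_equal(classify_circle_pair(c(100, 500), c(300, 700)),
               "overlapping")
  expect_equal(classify_circle_pair(c(100, 200), c(300, 400)),
               "non_overlapping")
  # containment sharing a boundary reports the shared boundary
  expect_equal(classify_circle_pair(c(100, 500), c(100, 300)),
               "same_start")
  expect_error(classify_circle_pair(c(100, 500), c(100, 500)),
               "identical")
})

test_that("classification is symmetric and exhaustive on random pairs", {
  set.seed(13)
  cats <- c("same_start", "same_end", "within", "overlapping",
            "non_overlapping")
  for (i in 1:500) {
    a <- sort(sample.int(50L, 2L))
    b <- sort(sample.int(50L, 2L))
    if (a[1L] == a[2L] || b[1L] == b[2L] || identical(a, b)) next
    ab <- classify_circle_pair(a, b)
    expect_true(ab %in% cats)
    expect_identical(ab, classify_circle_pair(b, a))
  }
})

test_that("host-gene summaries count all pairs and the multi proportion", {
  ann <- data.frame(chrom = "chr1",
                    start = seq(0L, 9000L, by = 1000L),
                    end = seq(0L, 9000L, by = 1000L) + 500L,
                    gene_id = paste0("G", 1:10), exon_number = 1L)
  # 10 genes; G1 carries 3 circles, G2 carries 2, the rest one each
  ivs <- rbind(c(0, 300), c(0, 400), c(100, 400),
               c(1000, 1400), c(1000, 1500),
               cbind(seq(2000L, 9000L, by = 1000L),
                     seq(2000L, 9000L, by = 1000L) + 400L))
  ct <- assign_host_genes(make_ct(ivs), ann)
  hg <- summarize_host_genes(ct)
  expect_equal(nrow(hg), 10L)
  g1 <- hg[hg$gene_id == "G1", ]
  expect_equal(g1$n_circles, 3L)
  cat_cols <- c("same_start", "same_end", "within", "overlapping",
                "non_overlapping")
  expect_equal(sum(g1[, cat_cols]), 3L)   # 3 choose 2 pairs
  expect_equal(g1$same_start, 1L)
  expect_equal(g1$same_end, 1L)
  expect_equal(g1$overlapping, 1L)
  expect_true(all(hg$n_circles[hg$is_single] == 1L))
  sm <- attr(hg, "single_multi")
  expect_equal(sm$prop_multi, 0.2)
  # pair-count identity holds for every gene
  expect_equal(rowSums(hg[, cat_cols]),
               hg$n_circles * (hg$n_circles - 1L) / 2)
})
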