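test_that("circle tables parse, deduplicate and round-trip", {
  p <- tempfile()
  writeLines(c("chrT:300|1000\tr1,r2,r3,r4,r5",
               "chr2:10|500\ta1,a1,a2"), p)
  ct <- read_circle_table(p)
  expect_equal(nrow(ct), 2L)
  expect_equal(ct$n_reads, c(5L, 2L))
  expect_setequal(ct$read_names[[2L]], c("a1", "a2"))
  expect_equal(ct$chrom, c("chrT", "chr2"))
  expect_equal(ct$start, c(300L, 10L))

  empty <- tempfile()
  writeLines(character(0), empty)
  expect_equal(nrow(read_circle_table(empty)), 0L)

  bad <- tempfile()
  writeLines(c("chrT:300|1000\tr1", "only-one-column"), bad)
  expect_error(read_circle_table(bad), "line 2")
  badid <- tempfile()
  writeLines("not_an_id\tr1", badid)
  expect_error(read_circle_table(badid), "unparsable")

  out <- tempfile()
  write_circle_table(ct, out)
  ct2 <- read_circle_table(out)
  expect_equal(ct2$circle_id, ct$circle_id)
  expect_equal(lapply(ct2$read_names, sort), lapply(ct$read_names, sort))
})

test_that("DCC outputs yield circles with junction-matched read names", {
  sim <- simulate_circles(4, c(200, 400), n_fragments_per_circle = 10,
                          seed = 5)
  # tolerance 0 on exact fixture coordinates recovers the truth lists
  ct <- read_dcc_outputs(sim$circrnacount, sim$junctions, tolerance = 0L)
  truth <- read_circle_table(sim$circles)
  for (i in seq_len(nrow(truth))) {
    j <- match(truth$circle_id[i], ct$circle_id)
    expect_setequal(ct$read_names[[j]], truth$read_names[[i]])
  }
  jr <- attr(ct, "junction_reads")
  expect_true(all(jr$mate %in% c(1L, 2L)))

  # an entry 5 bp away from every boundary matches no circle
  cc <- tempfile()
  writeLines("chrJ\t100\t600\t3", cc)
  jx <- tempfile()
  writeLines(c(paste(c("chrJ", 101, "+", "chrJ", 600, "+", 0, -1, -1,
                       "rA", 101, "100M", 101, "100M"), collapse = "\t"),
               paste(c("chrJ", 106, "+", "chrJ", 605, "+", 0, -1, -1,
                       "rB", 106, "100M", 106, "100M"), collapse = "\t")),
             jx)
  ct2 <- suppressWarnings(read_dcc_outputs(cc, jx, tolerance = 1L))
  expect_setequal(ct2$read_names[[1L]], "rA")

  # a read matching two circles is kept under both, with a warning
  cc3 <- tempfile()
  writeLines(c("chrJ\t100\t600\t1", "chrJ\t101\t601\t1"), cc3)
  expect_warning(ct3 <- read_dcc_outputs(cc3, jx, tolerance = 1L),
                 "multiple circles")
  expect_true(all(vapply(ct3$read_names, function(r) "rA" %in% r, TRUE)))

  expect_error(read_dcc_outputs(cc, tempfile()), "no such junction file")
  short <- tempfile()
  writeLines("a\tb\tc", short)
  expect_error(read_dcc_outputs(cc, short), "columns")
})

test_that("BED annotations expand to numbered exons per gene", {
  bed12 <- tempfile(fileext = ".bed")
  writeLines(c(paste(c("chr1", 100, 1000, "GPLUS", 0, "+", 100, 1000, 0,
                       3, "100,100,100,", "0,400,800,"), collapse = "\t"),
               paste(c("chr1", 2000, 2900, "GMINUS", 0, "-", 2000, 2900,
                       0, 3, "100,100,100,", "0,400,800,"),
                     collapse = "\t")), bed12)
  ann <- read_exon_annotation(bed12)
  plus <- ann[ann$gene_id == "GPLUS", ]
  expect_equal(plus$start, c(100L, 500L, 900L))
  expect_equal(plus$end, c(200L, 600L, 1000L))
  expect_equal(plus$exon_number, 1:3)
  minus <- ann[ann$gene_id == "GMINUS", ]
  expect_equal(minus$exon_number, 3:1)   # genomic order, strand-flipped

  bed6 <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t50\tG1\t0\t+", "chr1\t100\t150\tG1\t0\t+",
               "chr1\t300\t350\tG2\t0\t+"), bed6)
  ann6 <- read_exon_annotation(bed6)
  expect_equal(ann6$exon_number[ann6$gene_id == "G1"], 1:2)
  expect_equal(sum(ann6$gene_id == "G2"), 1L)
})
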