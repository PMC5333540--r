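#' @name simulate
#' @title Synthetic back-spliced read sets with known truth
#'
#' @description
#' The simulators emulate the geometry of a circularized transcript
#' sequenced with paired-end reads: the library's random fragmentation
#' cuts each circle at a uniform position, the fragment occupies an arc
#' of the circle, and a mate spans the back-splice junction exactly when
#' its linearized coordinates wrap past the junction. A wrapped mate is
#' emitted as a primary plus a supplementary alignment record (the two
#' arms of the chimeric read), and every junction-spanning mate is also
#' written to a STAR-layout chimeric-junction file, so both evidence
#' channels of the fragment analysis are exercised. No sequencing-error
#' model is applied: none of the characterization steps use base
#' qualities or mismatches, and coverage noise enters only through the
#' random fragment positions.
NULL

# ---- transcript <-> genome plumbing ---------------------------------

# map transcript interval [ts, te) through an exon chain to genomic blocks
.chain_blocks <- function(chain, ts, te) {
  widths <- chain$end - chain$start
  offs <- cumsum(c(0L, widths))
  blocks <- list()
  for (i in seq_len(nrow(chain))) {
    s <- max(ts, offs[i])
    e <- min(te, offs[i + 1L])
    if (e > s)
      blocks[[length(blocks) + 1L]] <- data.frame(
        start = chain$start[i] + (s - offs[i]),
        end = chain$start[i] + (e - offs[i]))
  }
  do.call(rbind, blocks)
}

.blocks_cigar <- function(blocks) {
  n <- nrow(blocks)
  parts <- character(0)
  for (i in seq_len(n)) {
    parts <- c(parts, sprintf("%dM", blocks$end[i] - blocks$start[i]))
    if (i < n)
      parts <- c(parts, sprintf("%dN", blocks$start[i + 1L] - blocks$end[i]))
  }
  paste(parts, collapse = "")
}

# records for one mate arc [a, a+len) on a circle of transcript length Lt;
# wrapping arcs become primary + supplementary records
.mate_records <- function(chain, Lt, a, len, qname, mate_flag) {
  len <- min(len, Lt)
  a <- a %% Lt
  pieces <- if (a + len <= Lt) list(c(a, a + len)) else
    list(c(a, Lt), c(0, a + len - Lt))
  blocks <- lapply(pieces, function(p) .chain_blocks(chain, p[1L], p[2L]))
  sizes <- vapply(pieces, function(p) p[2L] - p[1L], 1)
  prim <- which.max(sizes)
  recs <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    data.frame(qname = qname,
               flag = mate_flag + if (i == prim) 0L else 2048L,
               pos = b$start[1L], cigar = .blocks_cigar(b),
               stringsAsFactors = FALSE)
  })
  list(records = do.call(rbind, recs),
       crosses = length(pieces) == 2L)
}

.write_sam <- function(records, chrom, chrom_len, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len)), con)
  if (nrow(records)) {
    records <- records[order(records$pos), , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                       records$qname, records$flag, chrom,
                       records$pos + 1L, records$cigar), con)
  }
  invisible(path)
}

.write_bed12 <- function(genes, path) {
  # genes: list of data.frame(start, end) exon chains, named by gene id,
  # plus attr "chrom" and "strand" per gene
  lines <- vapply(names(genes), function(g) {
    ch <- genes[[g]]
    gs <- min(ch$start)
    ge <- max(ch$end)
    paste(c(attr(ch, "chrom"), gs, ge, g, 0L,
            attr(ch, "strand") %||% "+", gs, ge, "0", nrow(ch),
            paste0(paste(ch$end - ch$start, collapse = ","), ","),
            paste0(paste(ch$start - gs, collapse = ","), ",")),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.star_junction_line <- function(chrom, start, end, qname, pos, cigar) {
  paste(c(chrom, start + 1L, "+", chrom, end, "+", 0L, -1L, -1L, qname,
          pos + 1L, cigar, pos + 1L, cigar), collapse = "\t")
}

# ---- worked five-read example ---------------------------------------

#' The worked five-read exon-skipping example
#'
#' A toy chromosome carries one five-exon gene (100 bp exons at
#' 100-200, 300-400, 500-600, 700-800, 900-1000) and a single circle
#' over exons 2-5 (300-1000). Five junction reads realize four distinct
#' linear introns — between exons 2-3, 3-4, 4-5, and 2-4 — and exactly
#' two of the five reads carry the exon-2-to-exon-4 gap that skips
#' exon 3. The fixture writes the SAM alignments, the two-column circle
#' table and the BED12 annotation, and returns the truth.
#'
#' @param out_dir Output directory (created).
#' @return List: \code{sam}, \code{circles} (path), \code{annotation}
#'   (path), \code{truth} (list with \code{circle_id},
#'   \code{n_reads}, \code{n_introns}, \code{skip_reads},
#'   \code{skipped_exon} interval).
#' @export
make_skipping_example <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chrom <- "chrT"
  circle_id <- make_circle_id(chrom, 300L, 1000L)
  # r1: exons 2-3-4; r2: exons 3-4-5; r3: exons 4-5;
  # r4, r5: exons 2-4 with exon 3 skipped
  recs <- data.frame(
    qname = c("r1", "r2", "r3", "r4", "r5"),
    flag = 0L,
    pos = c(300L, 500L, 700L, 300L, 300L),
    cigar = c("100M100N100M100N100M", "100M100N100M100N100M",
              "100M100N100M", "100M300N100M", "100M300N100M"),
    stringsAsFactors = FALSE)
  sam <- file.path(out_dir, "example.sam")
  .write_sam(recs, chrom, 2000L, sam)
  circ_path <- file.path(out_dir, "example.circles.txt")
  writeLines(paste0(circle_id, "\tr1,r2,r3,r4,r5"), circ_path)
  gene <- data.frame(start = c(100L, 300L, 500L, 700L, 900L),
                     end = c(200L, 400L, 600L, 800L, 1000L))
  attr(gene, "chrom") <- chrom
  attr(gene, "strand") <- "+"
  bed_path <- file.path(out_dir, "example.annotation.bed")
  .write_bed12(list(GENE1 = gene), bed_path)
  list(sam = sam, circles = circ_path, annotation = bed_path,
       truth = list(circle_id = circle_id, n_reads = 5L, n_introns = 4L,
                    skip_reads = c("r4", "r5"),
                    skipped_exon = c(start = 500L, end = 600L)))
}

# ---- general simulator ----------------------------------------------

#' Simulate circles with chimeric paired-end reads and known truth
#'
#' Each circle gets its own gene on one synthetic chromosome: a single
#' exon of the requested length, or — when \code{skip_fraction > 0} —
#' three exons (40/20/40 percent of the length, introns of 200 bp)
#' whose middle exon is skipped by a random subset of reads. Fragments
#' are cut at a uniformly random position of the circularized
#' transcript; a mate spans the back-splice iff its arc wraps past the
#' junction. A circle shorter than the fragment size escapes
#' fragmentation intact, so its fragment wraps past the junction
#' (rolling-circle reverse transcription); fragments that would wrap
#' more than once are rejected as inconsistent geometry. Only fragments
#' with at least one junction-spanning mate
#' support the circle and enter the circle table (the rest are still
#' written to the SAM as linear clutter). Defaults mirror a typical
#' rRNA-depleted paired-end library: 350 bp fragments, 150 bp reads.
#'
#' @param n_circles Number of circles.
#' @param length_grid Circle (transcript) lengths in bp, recycled over
#'   circles.
#' @param fragment_length Library fragment size in bp (default 350).
#' @param read_length Read length in bp (default 150).
#' @param skip_fraction Probability that a fragment derives from the
#'   middle-exon-skipping isoform (default 0 = single-exon genes).
#' @param n_fragments_per_circle Fragments simulated per circle
#'   (default 20).
#' @param seed Random seed; the output is deterministic given the seed.
#' @param out_dir Output directory (created).
#' @param chrom Synthetic chromosome name.
#' @return List of paths — \code{sam}, \code{circles},
#'   \code{annotation}, \code{circrnacount}, \code{junctions} (named
#'   mate1/mate2 vector) — plus \code{truth}: data.frame per fragment
#'   (circle_id, qname, skipping, class in double/single/none) and
#'   \code{circle_truth}: data.frame per circle (circle_id, length_bp,
#'   skip_fraction).
#' @export
simulate_circles <- function(n_circles, length_grid,
                             fragment_length = 350L, read_length = 150L,
                             skip_fraction = 0, n_fragments_per_circle = 20L,
                             seed = 1L, out_dir = tempfile(),
                             chrom = "chrS") {
  stopifnot(read_length < 2L * fragment_length, all(length_grid > 0))
  if (skip_fraction > 0 && any(length_grid < 50L))
    stop("circles shorter than 50 bp cannot carry a three-exon structure")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  lens <- rep_len(length_grid, n_circles)
  cursor <- 1000L
  genes <- list()
  circles <- character(n_circles)
  recs <- list()
  jx1 <- character(0)
  jx2 <- character(0)
  truth <- list()
  circle_truth <- list()
  read_lists <- character(n_circles)
  for (i in seq_len(n_circles)) {
    L <- as.integer(lens[i])
    if (skip_fraction > 0) {
      e1 <- as.integer(round(0.4 * L))
      e2 <- as.integer(round(0.2 * L))
      e3 <- L - e1 - e2
      chain <- data.frame(
        start = cursor + c(0L, e1 + 200L, e1 + e2 + 400L),
        end = cursor + c(e1, e1 + e2 + 200L, L + 400L))
      skip_chain <- chain[c(1L, 3L), ]
    } else {
      chain <- data.frame(start = cursor, end = cursor + L)
      skip_chain <- chain
    }
    gid <- sprintf("G%03d", i)
    attr(chain, "chrom") <- chrom
    attr(chain, "strand") <- "+"
    genes[[gid]] <- chain
    cstart <- min(chain$start)
    cend <- max(chain$end)
    cid <- make_circle_id(chrom, cstart, cend)
    circles[i] <- cid
    Lskip <- sum(skip_chain$end - skip_chain$start)
    supporting <- character(0)
    for (f in seq_len(n_fragments_per_circle)) {
      qname <- sprintf("c%03d_f%04d", i, f)
      skipping <- skip_fraction > 0 && stats::runif(1L) < skip_fraction
      ch <- if (skipping) skip_chain else chain
      Lt <- if (skipping) Lskip else L
      if (fragment_length > 2L * Lt)
        stop("fragment (", fragment_length, " bp) would wrap a ", Lt,
             " bp circle more than once")
      Fp <- fragment_length
      Rp <- min(read_length, Lt)
      u <- sample.int(Lt, 1L) - 1L
      m1 <- .mate_records(ch, Lt, u, Rp, qname, 65L)
      m2 <- .mate_records(ch, Lt, (u + Fp - Rp) %% Lt, Rp, qname, 129L)
      recs[[length(recs) + 1L]] <- rbind(m1$records, m2$records)
      cls <- if (m1$crosses && m2$crosses) "double"
             else if (m1$crosses || m2$crosses) "single" else "none"
      if (m1$crosses)
        jx1 <- c(jx1, .star_junction_line(chrom, cstart, cend, qname,
                                          m1$records$pos[1L],
                                          m1$records$cigar[1L]))
      if (m2$crosses)
        jx2 <- c(jx2, .star_junction_line(chrom, cstart, cend, qname,
                                          m2$records$pos[1L],
                                          m2$records$cigar[1L]))
      if (cls != "none") supporting <- c(supporting, qname)
      truth[[length(truth) + 1L]] <- data.frame(
        circle_id = cid, qname = qname, skipping = skipping,
        class = cls, stringsAsFactors = FALSE)
    }
    read_lists[i] <- paste(supporting, collapse = ",")
    circle_truth[[i]] <- data.frame(
      circle_id = cid, chrom = chrom, start = cstart, end = cend,
      length_bp = L, skip_fraction = skip_fraction,
      stringsAsFactors = FALSE)
    cursor <- cend + 1000L
  }
  all_recs <- do.call(rbind, recs)
  sam <- file.path(out_dir, "sim.sam")
  .write_sam(all_recs, chrom, cursor + 1000L, sam)
  circ_path <- file.path(out_dir, "sim.circles.txt")
  keep <- nzchar(read_lists)
  writeLines(paste0(circles[keep], "\t", read_lists[keep]), circ_path)
  bed_path <- file.path(out_dir, "sim.annotation.bed")
  .write_bed12(genes, bed_path)
  ct <- do.call(rbind, circle_truth)
  cc_path <- file.path(out_dir, "CircRNACount")
  utils::write.table(ct[, c("chrom", "start", "end")], cc_path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  j1 <- file.path(out_dir, "mate1.Chimeric.out.junction")
  j2 <- file.path(out_dir, "mate2.Chimeric.out.junction")
  writeLines(jx1, j1)
  writeLines(jx2, j2)
  tr <- do.call(rbind, truth)
  utils::write.table(tr, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(sam = sam, circles = circ_path, annotation = bed_path,
       circrnacount = cc_path,
       junctions = c(mate1 = j1, mate2 = j2),
       truth = tr, circle_truth = ct)
}

#' Simulate junction-unbalanced false-positive circles with controls
#'
#' Emulates trans-splice-like junctions: short "circles" (300 bp, below
#' the 350 bp fragment size) whose fragments always have exactly one
#' junction-spanning mate, and whose coverage piles up on one side of
#' the junction only (a 10 bp overhang reaches the other side). Mixed
#' in are genuine medium-length control circles (600 bp) simulated with
#' [simulate_circles()] geometry, which produce the length-typical
#' balanced profile, high near both junction flanks. Truth labels let
#' tests check that the false positives are flagged by the
#' circle-length rule and separate from the controls under clustering.
#'
#' @param seed Random seed.
#' @param n_fp Number of false-positive circles (default 22).
#' @param n_control Number of genuine control circles (default 64).
#' @param fragment_length,read_length Library geometry (350 / 150 bp).
#' @param n_fragments_per_circle Fragments per circle (default 30).
#' @param out_dir Output directory.
#' @return As [simulate_circles()], plus \code{circle_truth$is_fp}.
#' @export
make_false_positive_fixture <- function(seed = 1L, n_fp = 22L,
                                        n_control = 64L,
                                        fragment_length = 350L,
                                        read_length = 150L,
                                        n_fragments_per_circle = 30L,
                                        out_dir = tempfile()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  chrom <- "chrF"
  L_fp <- 300L
  L_ctl <- 600L
  cursor <- 1000L
  genes <- list()
  recs <- list()
  jx1 <- character(0)
  jx2 <- character(0)
  circles <- character(0)
  read_lists <- character(0)
  circle_truth <- list()
  truth <- list()
  add_circle <- function(i, is_fp) {
    L <- if (is_fp) L_fp else L_ctl
    chain <- data.frame(start = cursor, end = cursor + L)
    attr(chain, "chrom") <- chrom
    attr(chain, "strand") <- "+"
    gid <- sprintf("%s%03d", if (is_fp) "FP" else "CTL", i)
    genes[[gid]] <<- chain
    cid <- make_circle_id(chrom, cursor, cursor + L)
    supporting <- character(0)
    for (f in seq_len(n_fragments_per_circle)) {
      qname <- sprintf("%s_f%04d", gid, f)
      if (is_fp) {
        # trans-splice-like: mate1 split at the junction with a 10 bp
        # overhang, mate2 linear on the start side only
        o <- 10L
        m1 <- .mate_records(chain, L, L - o, read_length, qname, 65L)
        u2 <- sample.int(60L, 1L) - 1L
        m2 <- .mate_records(chain, L, u2, read_length, qname, 129L)
        cls <- "single"
        jx1 <<- c(jx1, .star_junction_line(chrom, cursor, cursor + L,
                                           qname, m1$records$pos[1L],
                                           m1$records$cigar[1L]))
      } else {
        Fp <- fragment_length
        Rp <- min(read_length, L)
        u <- sample.int(L, 1L) - 1L
        m1 <- .mate_records(chain, L, u, Rp, qname, 65L)
        m2 <- .mate_records(chain, L, (u + Fp - Rp) %% L, Rp, qname, 129L)
        cls <- if (m1$crosses && m2$crosses) "double"
               else if (m1$crosses || m2$crosses) "single" else "none"
        if (m1$crosses)
          jx1 <<- c(jx1, .star_junction_line(chrom, cursor, cursor + L,
                                             qname, m1$records$pos[1L],
                                             m1$records$cigar[1L]))
        if (m2$crosses)
          jx2 <<- c(jx2, .star_junction_line(chrom, cursor, cursor + L,
                                             qname, m2$records$pos[1L],
                                             m2$records$cigar[1L]))
      }
      recs[[length(recs) + 1L]] <<- rbind(m1$records, m2$records)
      if (cls != "none") supporting <- c(supporting, qname)
      truth[[length(truth) + 1L]] <<- data.frame(
        circle_id = cid, qname = qname, skipping = FALSE, class = cls,
        stringsAsFactors = FALSE)
    }
    circles <<- c(circles, cid)
    read_lists <<- c(read_lists, paste(supporting, collapse = ","))
    circle_truth[[length(circle_truth) + 1L]] <<- data.frame(
      circle_id = cid, chrom = chrom, start = cursor, end = cursor + L,
      length_bp = L, is_fp = is_fp, stringsAsFactors = FALSE)
    cursor <<- cursor + L + 1000L
  }
  for (i in seq_len(n_fp)) add_circle(i, TRUE)
  for (i in seq_len(n_control)) add_circle(i, FALSE)
  sam <- file.path(out_dir, "fp.sam")
  .write_sam(do.call(rbind, recs), chrom, cursor + 1000L, sam)
  circ_path <- file.path(out_dir, "fp.circles.txt")
  keep <- nzchar(read_lists)
  writeLines(paste0(circles[keep], "\t", read_lists[keep]), circ_path)
  bed_path <- file.path(out_dir, "fp.annotation.bed")
  .write_bed12(genes, bed_path)
  j1 <- file.path(out_dir, "mate1.Chimeric.out.junction")
  j2 <- file.path(out_dir, "mate2.Chimeric.out.junction")
  writeLines(jx1, j1)
  writeLines(jx2, j2)
  list(sam = sam, circles = circ_path, annotation = bed_path,
       junctions = c(mate1 = j1, mate2 = j2),
       truth = do.call(rbind, truth),
       circle_truth = do.call(rbind, circle_truth))
}
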