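# Independent oracles and shared fixture shortcuts for the test suite.

# reference-walking CIGAR oracle: advance a position pointer op by op,
# recording every reference-consuming aligned base, then merge adjacent
# bases into blocks (no gap-length logic shared with the implementation)
oracle_cigar_blocks <- function(ref_start, cigar, min_intron = 30L) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  pos <- ref_start
  covered <- integer(0)
  for (i in seq_along(ops)) {
    if (ops[i] %in% c("M", "=", "X")) {
      covered <- c(covered, seq.int(pos, pos + lens[i] - 1L))
      pos <- pos + lens[i]
    } else if (ops[i] == "D") {
      if (lens[i] < min_intron)
        covered <- c(covered, seq.int(pos, pos + lens[i] - 1L))
      pos <- pos + lens[i]
    } else if (ops[i] == "N") {
      pos <- pos + lens[i]
    }
  }
  covered <- sort(unique(covered))
  breaks <- which(diff(covered) > 1L)
  starts <- covered[c(1L, breaks + 1L)]
  ends <- covered[c(breaks, length(covered))] + 1L
  data.frame(start = starts, end = ends)
}

# brute-force per-base pileup: for every base of the circle span, count
# aligned segments covering it by direct looping
oracle_pileup <- function(read_set, min_intron = 30L) {
  ci <- read_set$circle
  aln <- read_set$alignments
  depth <- integer(ci$end - ci$start)
  for (i in seq_len(nrow(aln))) {
    segs <- cigar_to_segments(aln$pos[i], aln$cigar[i], min_intron)
    for (j in seq_len(nrow(segs))) {
      for (b in seq.int(segs$start[j], segs$end[j] - 1L)) {
        if (b >= ci$start && b < ci$end)
          depth[b - ci$start + 1L] <- depth[b - ci$start + 1L] + 1L
      }
    }
  }
  depth
}

# load a simulated dataset end to end into read sets + coverage
load_sim <- function(sim, use_dcc = FALSE, tolerance = 1L) {
  circ <- if (use_dcc)
    suppressWarnings(read_dcc_outputs(sim$circrnacount, sim$junctions,
                                      tolerance))
  else read_circle_table(sim$circles)
  ann <- read_exon_annotation(sim$annotation)
  aln <- read_alignments(sim$sam)
  sets <- suppressWarnings(circle_read_sets(aln, circ))
  list(circles = circ, annotation = ann, alignments = aln, sets = sets)
}

skipping_example_sets <- function() {
  fx <- make_skipping_example(tempfile("skipex"))
  env <- load_sim(fx)
  env$fx <- fx
  env
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
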