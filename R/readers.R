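#' Read a two-column circle table
#'
#' The basic circle input is a tab-separated file whose first column holds
#' circleIDs (\code{"chrom:start|end"}) and whose second column is a
#' comma-separated list of the names of reads spanning the back-splice
#' junction. Duplicate read names within one line are deduplicated.
#'
#' @param path Path to the table.
#' @return A circle table: data.frame with columns \code{circle_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{read_names} (list
#'   column of character vectors), \code{n_reads}; attribute
#'   \code{source = "custom_table"}.
#' @export
read_circle_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(.circle_table(character(0), list(), source = "custom_table"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 2L))
    stop("circle table line ", which(nf < 2L)[1L],
         ": expected 2 tab-separated columns")
  ids <- vapply(fields, `[`, "", 1L)
  reads <- lapply(fields, function(f) {
    unique(trimws(strsplit(f[2L], ",", fixed = TRUE)[[1L]]))
  })
  reads <- lapply(reads, function(r) r[nzchar(r)])
  if (any(vapply(reads, length, 1L) == 0L))
    stop("circle table line ", which(vapply(reads, length, 1L) == 0L)[1L],
         ": no read names")
  if (anyDuplicated(ids))
    stop("duplicate circleIDs in circle table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  .circle_table(ids, reads, source = "custom_table")
}

.circle_table <- function(ids, reads, source, flagged = NULL) {
  coords <- if (length(ids)) parse_circle_id(ids) else
    data.frame(circle_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0))
  tab <- data.frame(circle_id = coords$circle_id, chrom = coords$chrom,
                    start = coords$start, end = coords$end,
                    stringsAsFactors = FALSE)
  tab$read_names <- reads
  tab$n_reads <- vapply(reads, length, 1L)
  tab$flagged <- if (is.null(flagged)) rep(FALSE, nrow(tab)) else flagged
  tab$host_genes <- rep(list(character(0)), nrow(tab))
  attr(tab, "source") <- source
  class(tab) <- c("circle_table", "data.frame")
  tab
}

#' Write a circle table in the two-column format
#'
#' @param circles A circle table.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_circle_table <- function(circles, path) {
  lines <- vapply(seq_len(nrow(circles)), function(i) {
    paste0(circles$circle_id[i], "\t",
           paste(sort(circles$read_names[[i]]), collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Build a circle table from DCC output plus STAR chimeric junctions
#'
#' DCC reports circle boundaries in \code{CircRNACount} but not the
#' supporting read names; those are recovered from the STAR
#' \code{Chimeric.out.junction} files. A junction entry supports a circle
#' when the sorted (donor, acceptor) breakpoints, converted to 0-based
#' half-open, lie within \code{tolerance} bp of the circle boundaries.
#' Mate-level junction files (DCC paired-independent mode) are accepted;
#' each entry is tagged with its mate of origin, which the fragment
#' analysis uses to tell which mate spans the junction.
#'
#' @param circrnacount_path Path to DCC \code{CircRNACount} (TSV with
#'   chrom/start/end leading columns; header detected and skipped).
#' @param chimeric_junction_paths Character vector of STAR chimeric
#'   junction files. A name or filename containing \code{"mate1"} /
#'   \code{"mate2"} tags entries with that mate; untagged files count as
#'   mate 0 (read level).
#' @param tolerance Matching tolerance in bp after coordinate conversion
#'   (default 1; absorbs the 0/1-based ambiguity of upstream tools).
#' @return A circle table (see [read_circle_table()]) with attribute
#'   \code{junction_reads}: data.frame of (read_name, circle_id, mate).
#'   Circles with no matched junction read are kept with
#'   \code{flagged = TRUE}.
#' @export
read_dcc_outputs <- function(circrnacount_path, chimeric_junction_paths,
                             tolerance = 1L) {
  cc <- utils::read.table(circrnacount_path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(cc) < 3L)
    stop("CircRNACount: expected at least 3 columns (chrom, start, end)")
  if (is.na(suppressWarnings(as.integer(cc[1L, 2L]))))
    cc <- cc[-1L, , drop = FALSE]   # header row
  chrom <- as.character(cc[[1L]])
  start <- as.integer(cc[[2L]])
  end <- as.integer(cc[[3L]])
  jx <- .read_junction_files(chimeric_junction_paths)
  if (nrow(jx) == 0L) stop("no entries in any chimeric junction file")
  # junction breakpoints: sorted pair, 1-based -> 0-based half-open
  b1 <- pmin(jx$donor_pos, jx$acceptor_pos) - 1L
  b2 <- pmax(jx$donor_pos, jx$acceptor_pos)
  ids <- make_circle_id(chrom, start, end)
  reads <- vector("list", length(ids))
  hits_per_read <- integer(nrow(jx))
  for (i in seq_along(ids)) {
    hit <- jx$donor_chrom == chrom[i] & jx$acceptor_chrom == chrom[i] &
      abs(b1 - start[i]) <= tolerance & abs(b2 - end[i]) <= tolerance
    reads[[i]] <- unique(jx$read_name[hit])
    hits_per_read <- hits_per_read + as.integer(hit)
  }
  multi <- unique(jx$read_name[hits_per_read > 1L])
  if (length(multi))
    warning("read name(s) matching multiple circles (kept in all): ",
            paste(utils::head(multi, 5L), collapse = ", "),
            if (length(multi) > 5L) ", ...")
  flagged <- vapply(reads, length, 1L) == 0L
  if (any(flagged))
    warning(sum(flagged), " circle(s) with no matching junction read")
  tab <- .circle_table(ids, reads, source = "dcc", flagged = flagged)
  # per-circle mate evidence for fragment classification
  jr <- do.call(rbind, lapply(seq_along(ids), function(i) {
    hit <- jx$donor_chrom == chrom[i] & jx$acceptor_chrom == chrom[i] &
      abs(b1 - start[i]) <= tolerance & abs(b2 - end[i]) <= tolerance
    if (!any(hit)) return(NULL)
    data.frame(read_name = jx$read_name[hit], circle_id = ids[i],
               mate = jx$mate[hit], stringsAsFactors = FALSE)
  }))
  attr(tab, "junction_reads") <- if (is.null(jr))
    data.frame(read_name = character(0), circle_id = character(0),
               mate = integer(0)) else unique(jr)
  tab
}

.read_junction_files <- function(paths) {
  tags <- names(paths)
  if (is.null(tags)) tags <- rep("", length(paths))
  out <- lapply(seq_along(paths), function(i) {
    p <- paths[i]
    tag <- if (nzchar(tags[i])) tags[i] else basename(p)
    mate <- if (grepl("mate1", tag)) 1L else if (grepl("mate2", tag)) 2L else 0L
    if (!file.exists(p)) stop("no such junction file: ", p)
    empty <- data.frame(donor_chrom = character(0),
                        donor_pos = integer(0),
                        acceptor_chrom = character(0),
                        acceptor_pos = integer(0),
                        read_name = character(0), mate = integer(0))
    if (file.size(p) == 0L) return(empty)
    raw <- utils::read.table(p, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "")
    if (ncol(raw) < 10L)
      stop("junction file ", p, ": expected >= 10 STAR columns, got ",
           ncol(raw))
    data.frame(donor_chrom = as.character(raw[[1L]]),
               donor_pos = as.integer(raw[[2L]]),
               acceptor_chrom = as.character(raw[[4L]]),
               acceptor_pos = as.integer(raw[[5L]]),
               read_name = as.character(raw[[10L]]),
               mate = mate, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a BED exon annotation
#'
#' Accepts BED6 (one exon per line; lines sharing a name are grouped under
#' one gene) or BED12 (blocks expanded to exons). Exon numbers are
#' assigned per gene in transcription order: genomic order for \code{+}
#' and unstranded genes, reversed for \code{-} strand genes.
#'
#' @param path Path to the BED file.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), \code{gene_id}, \code{strand},
#'   \code{exon_number}, sorted by (chrom, start).
#' @export
read_exon_annotation <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED file ", path, ": ",
                                          conditionMessage(e)))
  if (length(gr) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0),
                      strand = character(0), exon_number = integer(0)))
  if (is.null(gr$name) || anyNA(gr$name))
    stop("BED annotation requires a name (gene) field on every line")
  if (!is.null(gr$blocks)) {
    # BED12: expand blocks to genomic exons
    exon_list <- lapply(seq_along(gr), function(i) {
      bl <- gr$blocks[[i]]
      if (length(bl) == 0L)
        bl <- IRanges::IRanges(1L, GenomicRanges::width(gr)[i])
      data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr))[i],
        start = GenomicRanges::start(gr)[i] - 1L + IRanges::start(bl) - 1L,
        end = GenomicRanges::start(gr)[i] - 1L + IRanges::end(bl),
        gene_id = gr$name[i],
        strand = as.character(GenomicRanges::strand(gr))[i],
        stringsAsFactors = FALSE)
    })
    ex <- do.call(rbind, exon_list)
  } else {
    ex <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     gene_id = gr$name,
                     strand = as.character(GenomicRanges::strand(gr)),
                     stringsAsFactors = FALSE)
  }
  ex <- ex[order(ex$chrom, ex$start, ex$end), , drop = FALSE]
  ex$exon_number <- NA_integer_
  for (g in unique(ex$gene_id)) {
    idx <- which(ex$gene_id == g)
    n <- seq_along(idx)
    if (ex$strand[idx[1L]] == "-") n <- rev(n)
    ex$exon_number[idx] <- n
  }
  rownames(ex) <- NULL
  ex
}

#' Read alignment records from a SAM or BAM file
#'
#' SAM input is converted to sorted, indexed BAM first. Positions are
#' converted to the package's 0-based half-open convention.
#'
#' @param path Path to a \code{.sam} or \code{.bam} file.
#' @return data.frame with columns \code{qname}, \code{flag},
#'   \code{chrom}, \code{pos} (0-based leftmost), \code{cigar},
#'   \code{strand}, \code{mate} (1, 2 or 0 for unpaired),
#'   \code{secondary}, \code{supplementary}, \code{end} (0-based
#'   half-open reference end); attribute \code{bam_path} points to the
#'   indexed BAM.
#' @export
read_alignments <- function(path) {
  bam <- ensure_bam(path)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  aln <- data.frame(qname = res$qname, flag = res$flag,
                    chrom = as.character(res$rname),
                    pos = res$pos - 1L, cigar = res$cigar,
                    strand = as.character(res$strand),
                    stringsAsFactors = FALSE)
  aln$mate <- ifelse(bitwAnd(aln$flag, 1L) == 0L, 0L,
                     ifelse(bitwAnd(aln$flag, 64L) > 0L, 1L, 2L))
  aln$secondary <- bitwAnd(aln$flag, 256L) > 0L
  aln$supplementary <- bitwAnd(aln$flag, 2048L) > 0L
  aln$end <- aln$pos + .cigar_ref_span(aln$cigar)
  attr(aln, "bam_path") <- bam
  aln
}

.cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1L]]
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, 1L, USE.NAMES = FALSE)
}

#' Ensure an alignment file is an indexed BAM
#'
#' @param path SAM or BAM path.
#' @return Path to a coordinate-sorted, indexed BAM.
#' @export
ensure_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- sub("\\.sam$", "", path, ignore.case = TRUE)
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = TRUE)
  } else {
    bam <- path
    if (!file.exists(paste0(bam, ".bai")))
      Rsamtools::indexBam(bam)
  }
  bam
}
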