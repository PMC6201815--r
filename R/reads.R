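#' Construct an aligned-read table
#'
#' The internal read representation is a data.table with one row per read:
#' `read_id`, `chrom`, `start`, `end` (0-based half-open span), `strand` (of
#' the transcribed RNA), `nblocks`, `bsizes`/`bstarts` (comma-separated block
#' sizes and starts relative to `start`, BED12 convention), `nm` (mismatch
#' count), `unique_map` and `aligned_length` (sum of block sizes). Adjacent
#' blocks with zero gap are merged, so block subdivision that does not change
#' the aligned bases yields an identical table.
#'
#' @param chrom,strand character vectors.
#' @param blocks list of integer matrices (one per read, columns start,end,
#'   absolute genomic, 0-based half-open) or NULL to make single-block reads
#'   from `start`/`end`.
#' @param start,end used when `blocks` is NULL.
#' @param nm,unique_map,read_id optional annotations.
#' @return a `net_reads` data.table.
#' @export
net_reads <- function(chrom, strand, blocks = NULL, start = NULL, end = NULL,
                      nm = 0L, unique_map = TRUE, read_id = NULL) {
  if (is.null(blocks)) {
    blocks <- Map(function(s, e) cbind(s, e), start, end)
  }
  blocks <- lapply(blocks, function(b) {
    b <- matrix(as.integer(b), ncol = 2L)
    b <- b[order(b[, 1L]), , drop = FALSE]
    if (nrow(b) > 1L) {  # merge zero-gap neighbours
      keep <- c(TRUE, b[-1L, 1L] != b[-nrow(b), 2L])
      grp <- cumsum(keep)
      b <- cbind(tapply(b[, 1L], grp, min), tapply(b[, 2L], grp, max))
    }
    if (any(b[, 2L] <= b[, 1L])) stopf("read block with non-positive length")
    if (nrow(b) > 1L && any(b[-1L, 1L] < b[-nrow(b), 2L])) {
      stopf("read blocks overlap")
    }
    b
  })
  n <- length(blocks)
  dt <- data.table(
    read_id = if (is.null(read_id)) sprintf("r%06d", seq_len(n)) else read_id,
    chrom = rep_len(chrom, n), strand = rep_len(strand, n),
    start = vapply(blocks, function(b) b[1L, 1L], 1L),
    end = vapply(blocks, function(b) b[nrow(b), 2L], 1L),
    nblocks = vapply(blocks, nrow, 1L),
    bsizes = vapply(blocks, function(b) paste(b[, 2L] - b[, 1L], collapse = ","), ""),
    bstarts = vapply(blocks, function(b) paste(b[, 1L] - b[1L, 1L], collapse = ","), ""),
    nm = rep_len(as.integer(nm), n),
    unique_map = rep_len(unique_map, n))
  dt[, aligned_length := vapply(csv_int(bsizes), sum, 1L)]
  dt[]
}

## expand reads to one row per block with absolute coordinates
read_blocks <- function(reads) {
  sizes <- csv_int(reads$bsizes)
  starts <- csv_int(reads$bstarts)
  nb <- lengths(sizes)
  out <- data.table(
    read_id = rep(reads$read_id, nb),
    chrom = rep(reads$chrom, nb),
    strand = rep(reads$strand, nb),
    block = unlist(lapply(nb, seq_len)),
    bs = rep(reads$start, nb) + unlist(starts),
    nblocks = rep(nb, nb))
  out[, be := bs + unlist(sizes)]
  out[]
}

## file strand -> RNA strand under a library-chemistry interpretation
apply_strandness <- function(strand, strandness = c("reverse", "forward")) {
  strandness <- match.arg(strandness)
  if (strandness == "forward") strand else ifelse(strand == "+", "-", "+")
}

#' Read blocked alignments from a BED12 file
#'
#' The `name` field may carry mismatch/uniqueness annotations in the form
#' `id;NM=<n>;U=<0|1>` (as written by [write_bed12()]); absent annotations
#' default to 0 mismatches, uniquely mapped.
#'
#' @param path BED12 file.
#' @param strandness library chemistry: `"reverse"` (default; the file strand
#'   is the opposite of the transcribed RNA, the common NET-seq convention) or
#'   `"forward"`.
#' @return a `net_reads` data.table.
#' @export
read_bed12 <- function(path, strandness = c("reverse", "forward")) {
  strandness <- match.arg(strandness)
  if (!file.exists(path)) stopf("BED12 file not found: %s", path)
  bed <- fread(path, header = FALSE, sep = "\t")
  if (ncol(bed) < 12L) stopf("expected 12 BED columns, got %d", ncol(bed))
  setnames(bed, 1:12, c("chrom", "start", "end", "name", "score", "strand",
                        "thickStart", "thickEnd", "rgb", "nblocks", "bsizes",
                        "bstarts"))
  nm <- rep(0L, nrow(bed)); uniq <- rep(TRUE, nrow(bed))
  has_nm <- grepl(";NM=", bed$name, fixed = TRUE)
  nm[has_nm] <- as.integer(sub(".*;NM=([0-9]+).*", "\\1", bed$name[has_nm]))
  has_u <- grepl(";U=", bed$name, fixed = TRUE)
  uniq[has_u] <- sub(".*;U=([01]).*", "\\1", bed$name[has_u]) == "1"
  dt <- data.table(
    read_id = sub(";.*", "", bed$name),
    chrom = bed$chrom,
    strand = apply_strandness(bed$strand, strandness),
    start = bed$start, end = bed$end,
    nblocks = bed$nblocks,
    bsizes = sub(",$", "", bed$bsizes),
    bstarts = sub(",$", "", bed$bstarts),
    nm = nm, unique_map = uniq)
  dt[, aligned_length := vapply(csv_int(bsizes), sum, 1L)]
  dt[]
}

#' Write alignments as BED12
#'
#' @param reads a `net_reads` table (RNA-strand convention).
#' @param path output file.
#' @param strandness chemistry used to encode the strand field; the default
#'   `"reverse"` round-trips with [read_bed12()] defaults.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(reads, path, strandness = c("reverse", "forward")) {
  strandness <- match.arg(strandness)
  out <- data.table(
    chrom = reads$chrom, start = reads$start, end = reads$end,
    name = sprintf("%s;NM=%d;U=%d", reads$read_id, reads$nm,
                   as.integer(reads$unique_map)),
    score = 0L,
    strand = apply_strandness(reads$strand, strandness),
    thickStart = reads$start, thickEnd = reads$end, rgb = "0",
    nblocks = reads$nblocks, bsizes = reads$bsizes, bstarts = reads$bstarts)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read alignments from a text SAM file
#'
#' Blocks are taken from the CIGAR (`N` opens a new block; `M`/`=`/`X`/`D`
#' consume reference within a block), mismatches from the `NM` tag when
#' present, and uniqueness from the `NH` tag (`NH > 1` means multi-mapped) or
#' the secondary-alignment flag. Unmapped records are dropped.
#'
#' @inheritParams read_bed12
#' @return a `net_reads` data.table.
#' @export
read_sam <- function(path, strandness = c("reverse", "forward")) {
  strandness <- match.arg(strandness)
  if (!file.exists(path)) stopf("SAM file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(net_reads(character(), character(), blocks = list()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2L]), 1L)
  keep <- bitwAnd(flag, 4L) == 0L
  f <- f[keep]; flag <- flag[keep]
  qname <- vapply(f, `[`, "", 1L)
  chrom <- vapply(f, `[`, "", 3L)
  pos0 <- vapply(f, function(x) as.integer(x[4L]), 1L) - 1L
  cigar <- vapply(f, `[`, "", 6L)
  file_strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  tagval <- function(x, tag) {
    hit <- grep(paste0("^", tag, ":i:"), x[-(1:11)], value = TRUE)
    if (length(hit)) as.integer(sub(".*:i:", "", hit[1L])) else NA_integer_
  }
  nm <- vapply(f, tagval, 1L, tag = "NM")
  nh <- vapply(f, tagval, 1L, tag = "NH")
  nm[is.na(nm)] <- 0L
  uniq <- (is.na(nh) | nh == 1L) & bitwAnd(flag, 256L) == 0L
  blocks <- Map(cigar_blocks, cigar, pos0)
  out <- net_reads(chrom = chrom,
                   strand = apply_strandness(file_strand, strandness),
                   blocks = blocks, nm = nm, unique_map = uniq,
                   read_id = qname)
  out
}

cigar_blocks <- function(cigar, pos0) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(ops)) stopf("unparseable CIGAR: %s", cigar)
  lens <- as.integer(sub("[A-Z=]", "", ops))
  type <- sub("[0-9]+", "", ops)
  cur <- pos0
  bstart <- pos0
  blocks <- NULL
  for (i in seq_along(ops)) {
    if (type[i] %in% c("M", "=", "X", "D")) {
      cur <- cur + lens[i]
    } else if (type[i] == "N") {
      blocks <- rbind(blocks, c(bstart, cur))
      cur <- cur + lens[i]
      bstart <- cur
    }
    ## I/S/H/P consume no reference
  }
  rbind(blocks, c(bstart, cur))
}

#' Write alignments as a text SAM file
#'
#' Emits minimal single-end records with CIGAR `<n>M` blocks joined by `N`
#' gaps, `NM` and `NH` tags, and a placeholder `*` sequence. Header `@SQ`
#' lines cover every chromosome present.
#'
#' @inheritParams write_bed12
#' @param seqlengths optional named integer vector of contig lengths; inferred
#'   from the reads (max end + 1000) when NULL.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, strandness = c("reverse", "forward"),
                      seqlengths = NULL) {
  strandness <- match.arg(strandness)
  if (is.null(seqlengths)) {
    sl <- reads[, .(len = max(end) + 1000L), by = chrom]
    seqlengths <- stats::setNames(sl$len, sl$chrom)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), seqlengths))
  sizes <- csv_int(reads$bsizes)
  starts <- csv_int(reads$bstarts)
  cigar <- mapply(function(sz, st) {
    if (length(sz) == 1L) return(sprintf("%dM", sz))
    gaps <- st[-1L] - (st[-length(st)] + sz[-length(sz)])
    paste0(paste0(sz[-length(sz)], "M", gaps, "N", collapse = ""),
           sz[length(sz)], "M")
  }, sizes, starts)
  file_strand <- apply_strandness(reads$strand, strandness)
  flag <- ifelse(file_strand == "-", 16L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*\tNM:i:%d\tNH:i:%d",
                 reads$read_id, flag, reads$chrom, reads$start + 1L, cigar,
                 reads$nm, ifelse(reads$unique_map, 1L, 2L))
  writeLines(c(hdr, rec), path)
  invisible(path)
}
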