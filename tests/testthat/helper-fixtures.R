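library(data.table)

## hand-built GTF covering the classification cases; internal 0-based
## coordinates are one less on the start than the GTF text below
tiny_gtf_lines <- function() {
  g <- function(chrom, s, e, strand, gid, tid) {
    sprintf('%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            chrom, s, e, strand, gid, tid)
  }
  c(
    "# tiny fixture",
    ## GA: + strand, 3 exons (100,200) (300,400) (500,600)
    g("chr1", 101, 200, "+", "GA", "GA.1"),
    g("chr1", 301, 400, "+", "GA", "GA.1"),
    g("chr1", 501, 600, "+", "GA", "GA.1"),
    ## GB: - strand, 3 exons; ordinal 0 is the rightmost (1400,1500)
    g("chr1", 1001, 1100, "-", "GB", "GB.1"),
    g("chr1", 1201, 1300, "-", "GB", "GB.1"),
    g("chr1", 1401, 1500, "-", "GB", "GB.1"),
    ## GC: two isoforms, the second skips the middle exon
    g("chr1", 2001, 2100, "+", "GC", "GC.1"),
    g("chr1", 2201, 2300, "+", "GC", "GC.1"),
    g("chr1", 2401, 2500, "+", "GC", "GC.1"),
    g("chr1", 2001, 2100, "+", "GC", "GC.2"),
    g("chr1", 2401, 2500, "+", "GC", "GC.2"),
    ## GD: two isoforms, middle exon with an alternative acceptor (start)
    g("chr1", 3001, 3100, "+", "GD", "GD.1"),
    g("chr1", 3201, 3300, "+", "GD", "GD.1"),
    g("chr1", 3401, 3500, "+", "GD", "GD.1"),
    g("chr1", 3001, 3100, "+", "GD", "GD.2"),
    g("chr1", 3221, 3300, "+", "GD", "GD.2"),
    g("chr1", 3401, 3500, "+", "GD", "GD.2"),
    ## GE/GF: overlapping single-exon genes on opposite strands
    g("chr1", 4001, 4200, "+", "GE", "GE.1"),
    g("chr1", 4101, 4300, "-", "GF", "GF.1"),
    ## G1X: single-exon gene
    g("chr1", 5001, 5150, "+", "G1X", "G1X.1")
  )
}

write_tiny_gtf <- function(path = tempfile(fileext = ".gtf")) {
  writeLines(tiny_gtf_lines(), path)
  path
}

tiny_annotation <- function() {
  classify_exons(parse_annotation(write_tiny_gtf()))
}

## annotation straight from an exon table (internal 0-based coordinates)
ann_from_exons <- function(exons, classify = TRUE) {
  ann <- netsplice:::build_annotation(as.data.table(exons))
  if (classify) ann <- classify_exons(ann)
  ann
}

## n single-exon genes of the given lengths: feature playground for the
## peak caller (each exon is its own feature)
ann_single_exons <- function(lengths, strand = "+", gap = 1000L,
                             chrom = "chrT") {
  lengths <- as.integer(lengths)
  starts <- cumsum(c(1000L, head(lengths, -1L) + gap))
  ann_from_exons(data.table(
    gene_id = sprintf("SG%05d", seq_along(lengths)),
    transcript_id = sprintf("SG%05d.1", seq_along(lengths)),
    chrom = chrom, strand = strand,
    start = starts, end = starts + lengths))
}

## end_coverage from explicit per-position counts
mk_cov <- function(chrom, strand, pos, count, library_total = sum(count)) {
  counts <- data.table(chrom = chrom, strand = strand, pos = as.integer(pos),
                       count = as.integer(count))[count > 0]
  setkey(counts, chrom, strand, pos)
  structure(list(counts = counts, library_total = as.integer(library_total),
                 n_excluded = 0L),
            class = "end_coverage")
}

## end_coverage for a vector of per-position counts laid along a feature
cov_from_vector <- function(counts, start, strand = "+", chrom = "chrT",
                            library_total = sum(counts)) {
  mk_cov(chrom, strand, start + seq_along(counts) - 1L, counts, library_total)
}

## brute-force peak oracles, recomputing mean/sd by definition
oracle_ss_peak <- function(counts, strand = "+", k_sd = 3, min_reads = 4) {
  mu <- mean(counts)
  sdv <- sqrt(mean((counts - mu)^2))
  term <- if (strand == "+") counts[length(counts)] else counts[1L]
  term >= min_reads && term >= mu + k_sd * sdv && term > mu
}

oracle_pause_peaks <- function(counts, strand = "+", k_sd = 3, min_reads = 4) {
  n <- length(counts)
  keep <- if (strand == "+") seq_len(n - 3L) else seq(4L, n)
  v <- counts[keep]
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))
  hit <- v >= min_reads & v >= mu + k_sd * sdv & v > mu
  keep[hit]  # positions as offsets within the feature (1-based)
}
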