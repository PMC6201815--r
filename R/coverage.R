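#' Single-nucleotide 3'-end coverage from aligned reads
#'
#' Counts, per chromosome and RNA strand, the 3'-most transcribed base of
#' each read: the last base of the last block on the plus strand, the first
#' base of the first block on the minus strand. This position is either the
#' Pol II active-site RNA terminus or the free 3' OH of a cleaved splicing
#' intermediate. Multi-mapped reads are excluded; the library total used for
#' RPM is the number of accepted reads.
#'
#' @param reads a `net_reads` table.
#' @return an `end_coverage` object: list with `counts`
#'   (chrom, strand, pos, count), `library_total` and `n_excluded`.
#' @export
end_coverage <- function(reads) {
  if (!nrow(reads)) {
    return(structure(list(counts = data.table(chrom = character(),
                                              strand = character(),
                                              pos = integer(),
                                              count = integer()),
                          library_total = 0L, n_excluded = 0L),
                     class = "end_coverage"))
  }
  bad <- reads$nblocks == 0L
  if (any(bad)) warnf("%d reads with zero blocks skipped", sum(bad))
  acc <- reads[!bad & unique_map == TRUE]
  n_excluded <- nrow(reads) - nrow(acc)
  ends <- acc[, .(chrom, strand,
                  pos = terminal_pos(start, end, strand))]
  counts <- ends[, .(count = .N), by = .(chrom, strand, pos)]
  setkey(counts, chrom, strand, pos)
  structure(list(counts = counts, library_total = nrow(acc),
                 n_excluded = n_excluded),
            class = "end_coverage")
}

#' @export
print.end_coverage <- function(x, ...) {
  cat(sprintf("end_coverage: %d positions, library total %d reads (%d excluded)\n",
              nrow(x$counts), x$library_total, x$n_excluded))
  invisible(x)
}

## reads-per-million scaling for this library
rpm_factor <- function(cov) {
  if (cov$library_total == 0L) return(NA_real_)
  1e6 / cov$library_total
}

## total 3'-end count inside intervals (data.table with chrom,strand,start,end)
counts_in <- function(cov, regions) {
  if (!nrow(regions) || !nrow(cov$counts)) return(0L)
  r <- as.data.table(regions)[, .(chrom, strand, start, end)]
  setkey(r, chrom, strand, start, end)
  pts <- cov$counts[, .(chrom, strand, start = pos, end = pos + 1L, count)]
  ov <- foverlaps(pts, r, type = "within", nomatch = NULL,
                  by.x = c("chrom", "strand", "start", "end"))
  sum(ov$count)
}

#' Read-length (footprint) histogram over first-exon windows
#'
#' Collects the aligned length of reads whose 3' end falls within a window of
#' the transcription start of qualifying first exons (default: first 150 nt of
#' first exons at least 200 nt long). Window offsets are transcription-
#' direction coordinates, half-open: the default `c(0, 150)` keeps offsets
#' 0..149. Alternative selectors (e.g. `c(100, 150)`) probe positions away
#' from the TSS.
#'
#' @param reads a `net_reads` table.
#' @param ann a `genome_annotation`.
#' @param window integer length-2, `(from, to)` offsets from the TSS,
#'   half-open.
#' @param min_first_exon_length minimum first-exon length in nt.
#' @return a `length_histogram`: list with `table` (length, count),
#'   `modal_length` and `n`.
#' @export
read_length_histogram <- function(reads, ann, window = c(0L, 150L),
                                  min_first_exon_length = 200L) {
  fe <- unique(ann$exons[first_ == TRUE & end - start >= min_first_exon_length,
                         .(chrom, strand, start, end)])
  empty <- structure(list(table = data.table(len = integer(), count = integer()),
                          modal_length = NA_integer_, n = 0L),
                     class = "length_histogram")
  if (!nrow(fe) || !nrow(reads)) return(empty)
  fe[, tss := head_pos(start, end, strand)]
  ## genomic window holding transcription offsets [window[1], window[2])
  win <- fe[, .(chrom, strand,
                start = ifelse(strand == "+", tss + window[1L],
                               tss - window[2L] + 1L),
                end = ifelse(strand == "+", tss + window[2L],
                             tss - window[1L] + 1L))]
  setkey(win, chrom, strand, start, end)
  acc <- reads[unique_map == TRUE]
  acc[, pos := terminal_pos(start, end, strand)]
  pts <- acc[, .(chrom, strand, start = pos, end = pos + 1L, aligned_length)]
  hits <- foverlaps(pts, win, type = "within", nomatch = NULL,
                    by.x = c("chrom", "strand", "start", "end"))
  if (!nrow(hits)) return(empty)
  tab <- hits[, .(count = .N), by = .(len = aligned_length)]
  setorder(tab, len)
  structure(list(table = tab, modal_length = tab$len[which.max(tab$count)],
                 n = sum(tab$count)),
            class = "length_histogram")
}

#' @export
print.length_histogram <- function(x, ...) {
  cat(sprintf("length_histogram: %d reads, modal length %s nt\n",
              x$n, x$modal_length))
  invisible(x)
}

#' Noise-robust modal length of a footprint histogram
#'
#' The raw `modal_length` is the argmax of single-nt bins; on flat-topped
#' length distributions (e.g. a truncated normal with sd 8) single-bin
#' Poisson noise makes it jitter by several nt. This estimator takes the
#' argmax of a centred `k`-bin moving average, estimating the same population
#' mode with much lower variance.
#'
#' @param hist a `length_histogram`.
#' @param k moving-average width in nt (odd; default 3).
#' @return modal length in nt (NA for an empty histogram).
#' @export
modal_length_smooth <- function(hist, k = 3L) {
  if (!nrow(hist$table)) return(NA_integer_)
  tab <- merge(data.table(len = seq(min(hist$table$len), max(hist$table$len))),
               hist$table, by = "len", all.x = TRUE)
  tab[is.na(count), count := 0]
  sm <- stats::filter(tab$count, rep(1 / k, k), sides = 2L)
  tab$len[which.max(sm)]
}

#' Fraction of histogram reads with length in a closed range
#'
#' @param hist a `length_histogram`.
#' @param lo,hi inclusive bounds in nt.
#' @return proportion in `[0, 1]` (NaN for an empty histogram).
#' @export
fraction_in_range <- function(hist, lo, hi) {
  with(hist, sum(table[len >= lo & len <= hi, count]) / n)
}

#' snRNA-class 3'-end read counts in RPM
#'
#' Per snRNA gene, 3'-end counts within the padded gene interval
#' `[start - pad, end + pad)` on the gene strand are summed. Genes with
#' log2(RPM) >= 1 in the reference sample form the expressed set; per-class
#' RPM is the sum over expressed member genes.
#'
#' @param cov an `end_coverage` for the sample of interest.
#' @param snrna_genes data.table with columns gene_id, class, chrom, strand,
#'   start, end (manually curated, non-overlapping genes).
#' @param pad padding in nt added on both sides (default 5, absorbing
#'   annotation-boundary uncertainty).
#' @param reference `end_coverage` used to define the expressed gene set
#'   (e.g. the nucleoplasm fraction); defaults to `cov` itself.
#' @return data.table with class, rpm, n_genes (expressed members); classes
#'   with no expressed genes report 0 with a warning.
#' @export
count_snrna <- function(cov, snrna_genes, pad = 5L, reference = NULL) {
  sn <- as.data.table(snrna_genes)
  if (!nrow(sn)) {
    warnf("empty snRNA gene set")
    return(data.table(class = character(), rpm = numeric(), n_genes = integer()))
  }
  reference <- reference %||% cov
  per_gene <- function(cv) {
    vapply(seq_len(nrow(sn)), function(i) {
      counts_in(cv, sn[i, .(chrom, strand, start = start - pad,
                            end = end + pad)])
    }, 1)
  }
  ref_rpm <- per_gene(reference) * rpm_factor(reference)
  expressed <- !is.na(ref_rpm) & log2(ref_rpm) >= 1
  cnt <- per_gene(cov) * rpm_factor(cov)
  out <- sn[, .(gene_id, class_ = class, rpm_gene = cnt, expressed)]
  res <- out[, .(rpm = sum(get("rpm_gene")[expressed]),
                 n_genes = sum(expressed)),
             by = .(class = class_)]
  res[is.na(rpm), rpm := 0]
  for (cl in res[n_genes == 0L, class]) {
    warnf("snRNA class %s has no expressed genes; RPM reported as 0", cl)
    res[class == cl, rpm := 0]
  }
  res[]
}

#' Read average density (RAD) over exons or introns
#'
#' RAD = TR / (EL - 3), where EL is the feature length and TR the total
#' 3'-end count after removing the positions contaminated by 5' ss splicing
#' intermediates: the 3 transcription-direction 3'-most nucleotides of exons
#' and the 3 5'-most nucleotides of introns. For exons, 3'-end counts
#' contributed by spliced reads can additionally be subtracted by passing
#' their end coverage. Features with EL <= 3 or no remaining reads are
#' excluded. Only exons/introns of expressed genes that do not intersect
#' another isoform's feature are considered.
#'
#' @param cov an `end_coverage`.
#' @param ann a classified `genome_annotation`.
#' @param kind `"exon"` or `"intron"`.
#' @param spliced_ends optional `end_coverage` of spliced-read 3' ends to
#'   subtract (exons only).
#' @return data.table with feature coordinates, TR, EL and RAD.
#' @export
read_average_density <- function(cov, ann, kind = c("exon", "intron"),
                                 spliced_ends = NULL) {
  kind <- match.arg(kind)
  feats <- eligible_features(ann, kind)
  if (!nrow(feats)) {
    return(data.table(chrom = character(), strand = character(),
                      start = integer(), end = integer(), TR = numeric(),
                      EL = integer(), RAD = numeric()))
  }
  feats[, EL := end - start]
  feats <- feats[EL > 3L]
  ## untrimmed sub-interval, transcription-direction aware
  if (kind == "exon") {
    feats[, `:=`(kstart = ifelse(strand == "+", start, start + 3L),
                 kend = ifelse(strand == "+", end - 3L, end))]
  } else {
    feats[, `:=`(kstart = ifelse(strand == "+", start + 3L, start),
                 kend = ifelse(strand == "+", end, end - 3L))]
  }
  feats[, feature_id := .I]
  r <- feats[, .(feature_id, chrom, strand, start = get("kstart"),
                 end = get("kend"))]
  feats[, TR := region_sums(cov, r)]
  if (kind == "exon" && !is.null(spliced_ends)) {
    feats[, TR := TR - region_sums(spliced_ends, r)]
  }
  out <- feats[TR > 0, .(chrom, strand, start, end, TR = as.numeric(TR), EL,
                         RAD = TR / (EL - 3L))]
  out[]
}

## per-region 3'-end count sums, keyed by a feature_id column in `regions`
region_sums <- function(cov, regions) {
  out <- numeric(nrow(regions))
  if (!nrow(cov$counts) || !nrow(regions)) return(out)
  r <- copy(regions)
  setkey(r, chrom, strand, start, end)
  pts <- cov$counts[, .(chrom, strand, start = pos, end = pos + 1L, count)]
  ov <- foverlaps(pts, r, type = "within", nomatch = NULL,
                  by.x = c("chrom", "strand", "start", "end"))
  if (!nrow(ov)) return(out)
  agg <- ov[, .(s = sum(get("count"))), by = feature_id]
  out[agg$feature_id] <- agg$s
  out
}

## deduplicated eligible features: expressed gene, not isoform-overlapping
eligible_features <- function(ann, kind = c("exon", "intron")) {
  kind <- match.arg(kind)
  eg <- expressed_gene_ids(ann)
  if (kind == "exon") {
    f <- ann$exons[gene_id %in% eg &
                     (is.na(overlaps_other_exon) | overlaps_other_exon == FALSE)]
    unique(f[, .(chrom, strand, start, end)])
  } else {
    f <- ann$introns[gene_id %in% eg &
                       (is.na(overlaps_other) | overlaps_other == FALSE)]
    unique(f[, .(chrom, strand, start, end)])
  }
}

#' Treatment-sensitivity ratio of mean RPM over region sets
#'
#' Used for detergent (empigen) comparisons: for each region set, the RPM of
#' 3'-end counts inside the set is computed in both libraries and the ratio
#' treated/untreated reported. A zero untreated RPM yields an NA ratio flagged
#' `undefined`, never 0.
#'
#' @param a untreated `end_coverage`.
#' @param b treated `end_coverage`.
#' @param regions data.table with chrom, strand, start, end and a `set`
#'   column naming the region group.
#' @return data.table with set, rpm_a, rpm_b, ratio, undefined.
#' @export
treatment_ratio <- function(a, b, regions) {
  regions <- as.data.table(regions)
  if (!nrow(regions)) {
    return(data.table(set = character(), rpm_a = numeric(), rpm_b = numeric(),
                      ratio = numeric(), undefined = logical()))
  }
  res <- regions[, .(
    rpm_a = counts_in(a, .SD) * rpm_factor(a),
    rpm_b = counts_in(b, .SD) * rpm_factor(b)),
    by = .(set = get("set")),
    .SDcols = c("chrom", "strand", "start", "end")]
  res[, undefined := is.na(rpm_a) | rpm_a == 0]
  res[, ratio := ifelse(undefined, NA_real_, rpm_b / rpm_a)]
  res[]
}

#' Metagene profile of 3'-end RPM around anchors
#'
#' Counts are re-indexed to transcription-direction offsets relative to each
#' anchor (TSS, exon 3' end, junction, ...), summed over anchors and scaled
#' to mean RPM per anchor. Anchors closer than the upstream window to the
#' contig start are skipped.
#'
#' @param cov an `end_coverage`.
#' @param anchors data.table with chrom, strand, pos.
#' @param window integer length-2 `(upstream, downstream)` in nt; offsets run
#'   from `-upstream` to `+downstream`.
#' @return data.table with offset and rpm (mean per anchor).
#' @export
metagene_profile <- function(cov, anchors, window = c(100L, 300L)) {
  anchors <- as.data.table(anchors)
  anchors <- anchors[pos - window[1L] >= 0L]
  offs <- seq(-window[1L], window[2L])
  if (!nrow(anchors) || !nrow(cov$counts)) {
    return(data.table(offset = offs, rpm = 0))
  }
  ## half-open interval covering offsets -up..down inclusive
  a <- anchors[, .(chrom, strand, apos = pos,
                   start = ifelse(strand == "+", pos - window[1L],
                                  pos - window[2L]),
                   end = ifelse(strand == "+", pos + window[2L] + 1L,
                                pos + window[1L] + 1L))]
  a[, feature_id := .I]
  setkey(a, chrom, strand, start, end)
  pts <- cov$counts[, .(chrom, strand, start = pos, end = pos + 1L, count)]
  ov <- foverlaps(pts, a, type = "within", nomatch = NULL,
                  by.x = c("chrom", "strand", "start", "end"))
  prof <- data.table(offset = offs, count = 0)
  if (nrow(ov)) {
    ov[, offset := tx_offset(get("i.start"), get("apos"), strand)]
    agg <- ov[, .(s = sum(get("count"))), by = offset]
    prof[agg, on = "offset", count := get("i.s")]
  }
  prof[, .(offset, rpm = count * rpm_factor(cov) / nrow(anchors))]
}

#' Export 3'-end coverage as per-strand bedGraph
#'
#' @param cov an `end_coverage`.
#' @param prefix output path prefix; files `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph` are written.
#' @param rpm scale counts to RPM when TRUE.
#' @return character vector of the two paths, invisibly.
#' @export
write_bedgraph <- function(cov, prefix, rpm = FALSE) {
  paths <- paste0(prefix, c(".plus.bedgraph", ".minus.bedgraph"))
  sc <- if (rpm) rpm_factor(cov) else 1
  for (i in 1:2) {
    s <- c("+", "-")[i]
    dt <- cov$counts[strand == s,
                     .(chrom, start = pos, end = pos + 1L, value = count * sc)]
    setorder(dt, chrom, start)
    fwrite(dt, paths[i], sep = "\t", col.names = FALSE)
  }
  invisible(paths)
}
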