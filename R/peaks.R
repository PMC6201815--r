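#' Peak-calling parameters
#'
#' Defaults follow the splicing-intermediate peak rule: a position qualifies
#' when its 3'-end count is at least `min_reads` (4), at least `k_sd` (3)
#' standard deviations above the feature mean, and strictly above the mean
#' (so zero-variance features never peak). Pause mode removes the last 3
#' exonic / first 3 intronic nucleotides before computing statistics.
#'
#' @param k_sd standard-deviation multiplier (> 0).
#' @param min_reads minimum raw read count at the position (>= 1).
#' @param trim_exon_3prime,trim_intron_5prime trimmed nucleotides, pause mode.
#' @return a `peak_params` list.
#' @export
peak_params <- function(k_sd = 3, min_reads = 4L, trim_exon_3prime = 3L,
                        trim_intron_5prime = 3L) {
  stopifnot(k_sd > 0, min_reads >= 1L)
  structure(list(k_sd = k_sd, min_reads = as.integer(min_reads),
                 trim_exon_3prime = as.integer(trim_exon_3prime),
                 trim_intron_5prime = as.integer(trim_intron_5prime)),
            class = "peak_params")
}

#' Per-feature mean and population SD of 3'-end counts
#'
#' Statistics are over every nucleotide of the feature, zeros included and
#' the candidate position included; the standard deviation is the population
#' (denominator n) form.
#'
#' @param cov an `end_coverage`.
#' @param chrom,strand,start,end feature interval (0-based half-open).
#' @return list with `mean` and `sd`.
#' @export
feature_stats <- function(cov, chrom, strand, start, end) {
  feats <- data.table(chrom = chrom, strand = strand, start = start, end = end)
  st <- feature_sums(cov, feats)
  list(mean = st$mu[1L], sd = st$sdv[1L])
}

## vectorised sums/sumsq -> mean and population sd per feature row
feature_sums <- function(cov, feats) {
  f <- copy(as.data.table(feats))
  f[, feature_id := .I]
  f[, EL := end - start]
  r <- f[, .(feature_id, chrom, strand, start, end)]
  out <- f[, .(feature_id, EL)]
  out[, s1 := 0]; out[, s2 := 0]
  if (nrow(cov$counts)) {
    setkey(r, chrom, strand, start, end)
    pts <- cov$counts[, .(chrom, strand, start = pos, end = pos + 1L, count)]
    ov <- foverlaps(pts, r, type = "within", nomatch = NULL,
                  by.x = c("chrom", "strand", "start", "end"))
    if (nrow(ov)) {
      agg <- ov[, .(s1 = sum(as.numeric(get("count"))),
                    s2 = sum(as.numeric(get("count"))^2)), by = feature_id]
      out[agg, on = "feature_id", `:=`(s1 = get("i.s1"), s2 = get("i.s2"))]
    }
  }
  out[, mu := get("s1") / EL]
  out[, sdv := sqrt(pmax(get("s2") / EL - mu^2, 0))]
  out[]
}

## shared peak predicate
is_peak <- function(count, mu, sdv, params) {
  count >= params$min_reads & count >= mu + params$k_sd * sdv & count > mu
}

#' Call splicing-intermediate peaks at feature 3' ends
#'
#' Tests the 3'-terminal nucleotide of every eligible exon and intron
#' (expressed gene, not intersecting another isoform's feature) against the
#' feature-local rule: count >= `min_reads`, count >= mean + `k_sd` * sd, and
#' count > mean, with mean/sd over the whole feature. An exon terminal that
#' qualifies is a `five_prime_ss` peak (cleaved upstream-exon intermediate);
#' an intron terminal is a `three_prime_ss` peak (released lariat).
#'
#' @param cov an `end_coverage`.
#' @param ann a classified `genome_annotation`.
#' @param params a [peak_params()] list.
#' @return data.table of peaks: chrom, strand, pos, count, kind,
#'   feature coordinates, feature_mean, feature_sd.
#' @export
call_ss_peaks <- function(cov, ann, params = peak_params()) {
  res <- list()
  for (kind_i in c("exon", "intron")) {
    feats <- eligible_features(ann, kind_i)
    if (!nrow(feats)) next
    st <- feature_sums(cov, feats)
    feats[, `:=`(mu = st$mu, sdv = st$sdv)]
    feats[, pos := terminal_pos(start, end, strand)]
    feats[, feature_id := .I]
    tc <- terminal_counts(cov, feats)
    feats[, count := tc]
    hit <- feats[is_peak(count, mu, sdv, params)]
    if (nrow(hit)) {
      hit[, kind := if (kind_i == "exon") "five_prime_ss" else "three_prime_ss"]
      res[[kind_i]] <- hit[, .(chrom, strand, pos, count, kind,
                               feature_start = start, feature_end = end,
                               feature_mean = mu, feature_sd = sdv)]
    }
  }
  out <- rbindlist(res)
  if (!nrow(out)) {
    out <- data.table(chrom = character(), strand = character(),
                      pos = integer(), count = integer(), kind = character(),
                      feature_start = integer(), feature_end = integer(),
                      feature_mean = numeric(), feature_sd = numeric())
  }
  setorder(out, chrom, strand, pos)
  out[]
}

terminal_counts <- function(cov, feats) {
  m <- cov$counts[feats[, .(chrom, strand, pos)], on = c("chrom", "strand", "pos")]
  out <- m$count
  out[is.na(out)] <- 0L
  out
}

#' Call Pol II pause peaks along exons and introns
#'
#' To avoid contamination by splicing intermediates, counts at the last 3
#' nucleotides of exons and the first 3 nucleotides of introns (transcription
#' direction) are removed; the mean and population SD are recomputed over the
#' remaining EL - 3 positions, and every remaining position is tested with
#' the same rule as [call_ss_peaks()]. All qualifying positions are reported.
#'
#' @inheritParams call_ss_peaks
#' @return data.table of pause peaks (kind = `"pause"`).
#' @export
call_pause_peaks <- function(cov, ann, params = peak_params()) {
  res <- list()
  for (kind_i in c("exon", "intron")) {
    feats <- eligible_features(ann, kind_i)
    if (!nrow(feats)) next
    feats[, EL := end - start]
    trim <- if (kind_i == "exon") params$trim_exon_3prime else params$trim_intron_5prime
    feats <- feats[EL - trim >= 1L]
    if (!nrow(feats)) next
    if (kind_i == "exon") {
      feats[, `:=`(kstart = ifelse(strand == "+", start, start + trim),
                   kend = ifelse(strand == "+", end - trim, end))]
    } else {
      feats[, `:=`(kstart = ifelse(strand == "+", start + trim, start),
                   kend = ifelse(strand == "+", end, end - trim))]
    }
    trimmed <- feats[, .(chrom, strand, start = get("kstart"),
                         end = get("kend"))]
    st <- feature_sums(cov, trimmed)
    ## statistics over EL - trim positions of the trimmed interval
    feats[, `:=`(mu = st$mu, sdv = st$sdv)]
    feats[, feature_id := .I]
    if (!nrow(cov$counts)) next
    r <- feats[, .(feature_id, chrom, strand, start = get("kstart"),
                   end = get("kend"))]
    setkey(r, chrom, strand, start, end)
    pts <- cov$counts[, .(chrom, strand, start = pos, end = pos + 1L, count)]
    ov <- foverlaps(pts, r, type = "within", nomatch = NULL,
                  by.x = c("chrom", "strand", "start", "end"))
    if (!nrow(ov)) next
    cand <- feats[ov$feature_id]
    cand[, `:=`(pos = ov$i.start, count = ov$count)]
    hit <- cand[is_peak(count, mu, sdv, params)]
    if (nrow(hit)) {
      res[[kind_i]] <- hit[, .(chrom, strand, pos, count, kind = "pause",
                               feature_start = start, feature_end = end,
                               feature_mean = mu, feature_sd = sdv)]
    }
  }
  out <- rbindlist(res)
  if (!nrow(out)) {
    out <- data.table(chrom = character(), strand = character(),
                      pos = integer(), count = integer(), kind = character(),
                      feature_start = integer(), feature_end = integer(),
                      feature_mean = numeric(), feature_sd = numeric())
  }
  setorder(out, chrom, strand, pos)
  out[]
}

#' Replicate-consensus peaks
#'
#' A peak survives iff a peak with identical (chromosome, strand, position,
#' kind) exists in every replicate set; per-replicate counts are reported as
#' `count_1..k`.
#'
#' @param peak_sets list of >= 2 peak tables from [call_ss_peaks()] /
#'   [call_pause_peaks()].
#' @return data.table of consensus peaks.
#' @export
consensus_peaks <- function(peak_sets) {
  if (length(peak_sets) < 2L) stopf("need >= 2 replicate peak sets")
  keycols <- c("chrom", "strand", "pos", "kind")
  base <- unique(as.data.table(peak_sets[[1L]])[, c(keycols, "count"),
                                                with = FALSE])
  setnames(base, "count", "count_1")
  for (i in seq_along(peak_sets)[-1L]) {
    nxt <- unique(as.data.table(peak_sets[[i]])[, c(keycols, "count"),
                                                with = FALSE])
    setnames(nxt, "count", paste0("count_", i))
    base <- merge(base, nxt, by = keycols)
  }
  setorder(base, chrom, strand, pos)
  base[]
}

#' Write peaks as BED6
#'
#' Name carries the peak kind, score the read count.
#'
#' @param peaks a peak table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  out <- as.data.table(peaks)[, .(chrom, start = pos, end = pos + 1L,
                                  name = kind, score = count, strand)]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
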