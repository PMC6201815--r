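#' Percent-spliced-in from junction counts
#'
#' Computes the canonical junction-read PSI for internal exons:
#' \deqn{PSI = \frac{(IJ_{up}+IJ_{down})/2}{(IJ_{up}+IJ_{down})/2 + EJ}}
#' where IJ are the two inclusion junctions flanking the exon and EJ the sum
#' of reads on junctions that skip it (any junction strictly containing the
#' exon on the same strand; no annotated skip isoform is required, and EJ = 0
#' is not an error). Structural filters, applied in order with the first
#' failing reason recorded: alternative 5'/3' splice-site exons (`alt_ss`),
#' exons overlapping other exons on the same strand (`overlap`), exon length
#' < 100 bp (`short_exon`), preceding intron (transcription direction)
#' < 100 bp (`short_intron`). Coverage filter (`low_coverage`): by default
#' each inclusion junction individually needs >= `min_junction_reads` reads
#' (`coverage_rule = "each_inclusion"`); the alternative reading of "both
#' regions" (`"inclusion_and_exclusion"`) requires the averaged inclusion and
#' the exclusion counts each to reach the threshold.
#'
#' @param junction_counts data.table with columns chrom, strand, start, end
#'   (junction = intron interval, 0-based half-open) and reads; duplicate
#'   keys are summed.
#' @param ann a classified `genome_annotation`.
#' @param min_junction_reads coverage threshold (default 5).
#' @param coverage_rule see above.
#' @return data.table with one row per internal exon: coordinates, IJ_up,
#'   IJ_down, EJ, psi (NA unless eligible), eligible, reason ("" when
#'   eligible).
#' @export
compute_psi <- function(junction_counts, ann, min_junction_reads = 5L,
                        coverage_rule = c("each_inclusion",
                                          "inclusion_and_exclusion")) {
  coverage_rule <- match.arg(coverage_rule)
  jc <- as.data.table(junction_counts)[
    , .(reads = sum(reads)), by = .(chrom, strand, start, end)]

  ## internal exons with both flanking introns, deduplicated by coordinates
  up <- ann$introns[, .(transcript_id, ordinal = ordinal + 1L,
                        upstart = start, upend = end)]
  dn <- ann$introns[, .(transcript_id, ordinal = copy(ordinal),
                        dnstart = start, dnend = end)]
  ex <- ann$exons[internal_ == TRUE]
  exu <- up[ex, on = c("transcript_id", "ordinal"), nomatch = NULL]
  exu <- dn[exu, on = c("transcript_id", "ordinal"), nomatch = NULL]
  if (!nrow(exu)) {
    return(data.table(chrom = character(), strand = character(),
                      start = integer(), end = integer(), IJ_up = numeric(),
                      IJ_down = numeric(), EJ = numeric(), psi = numeric(),
                      eligible = logical(), reason = character()))
  }
  recs <- exu[, .(
    alt = any(alt5ss | alt3ss), ov = any(overlaps_other_exon),
    upstart = upstart[1L], upend = upend[1L],
    dnstart = dnstart[1L], dnend = dnend[1L]),
    by = .(chrom, strand, start, end)]
  recs[, exon_len := end - start]
  recs[, intron_len := get("upend") - get("upstart")]

  jcount <- function(ch, st, s, e) {
    m <- jc[data.table(chrom = ch, strand = st, start = s, end = e),
            on = c("chrom", "strand", "start", "end")]
    out <- m$reads
    out[is.na(out)] <- 0
    out
  }
  recs[, IJ_up := jcount(chrom, strand, get("upstart"), get("upend"))]
  recs[, IJ_down := jcount(chrom, strand, get("dnstart"), get("dnend"))]

  ## EJ: junctions strictly containing the exon body
  recs[, feature_id := .I]
  recs[, EJ := 0]
  if (nrow(jc)) {
    r <- recs[, .(feature_id, chrom, strand, start, end)]
    setkey(r, chrom, strand, start, end)
    jiv <- jc[, .(chrom, strand, start, end, reads)]
    ov <- foverlaps(jiv, r, type = "any", nomatch = NULL,
                    by.x = c("chrom", "strand", "start", "end"))
    ov <- ov[get("i.start") < start & get("i.end") > end]
    if (nrow(ov)) {
      agg <- ov[, .(s = sum(get("reads"))), by = feature_id]
      recs[agg, on = "feature_id", EJ := get("i.s")]
    }
  }

  recs[, reason := ""]
  recs[get("alt") == TRUE, reason := "alt_ss"]
  recs[reason == "" & get("ov") == TRUE, reason := "overlap"]
  recs[reason == "" & exon_len < 100L, reason := "short_exon"]
  recs[reason == "" & intron_len < 100L, reason := "short_intron"]
  if (coverage_rule == "each_inclusion") {
    lowcov <- recs[, pmin(IJ_up, IJ_down) < min_junction_reads]
  } else {
    lowcov <- recs[, (IJ_up + IJ_down) / 2 < min_junction_reads |
                     EJ < min_junction_reads]
  }
  recs[reason == "" & lowcov, reason := "low_coverage"]
  recs[, eligible := reason == ""]
  inc <- recs[, (IJ_up + IJ_down) / 2]
  recs[, psi := ifelse(eligible & (inc + EJ) > 0, inc / (inc + EJ), NA_real_)]
  recs[eligible == TRUE & is.na(psi), `:=`(eligible = FALSE,
                                           reason = "low_coverage")]

  out <- recs[, .(chrom, strand, start, end, exon_len, intron_len,
                  IJ_up, IJ_down, EJ, psi, eligible, reason)]
  setorder(out, chrom, strand, start)
  out[]
}

#' Overlap of 5' ss peaks with PSI inclusion status
#'
#' Matches consensus `five_prime_ss` peaks to PSI records via the exon
#' 3'-terminal nucleotide and reports (a) the PSI distribution of
#' peak-bearing exons and (b) the fraction of high-inclusion exons
#' (psi > `psi_high`) that carry a 5' ss peak.
#'
#' @param peaks a peak table (only `five_prime_ss` rows are used).
#' @param psi_records output of [compute_psi()].
#' @param psi_high inclusion threshold (default 0.9).
#' @return a list: `table` (per eligible exon: psi, has_peak),
#'   `frac_high_psi_with_peak`, `frac_peak_exons_high_psi`, `n_peak_exons`,
#'   `n_high_psi`.
#' @export
peak_psi_overlap <- function(peaks, psi_records, psi_high = 0.9) {
  pk <- as.data.table(peaks)
  pk <- pk[kind == "five_prime_ss", .(chrom, strand, pos)]
  rec <- as.data.table(psi_records)[eligible == TRUE & !is.na(psi)]
  if (!nrow(rec)) {
    return(list(table = data.table(chrom = character(), strand = character(),
                                   start = integer(), end = integer(),
                                   psi = numeric(), has_peak = logical()),
                frac_high_psi_with_peak = NA_real_,
                frac_peak_exons_high_psi = NA_real_,
                n_peak_exons = 0L, n_high_psi = 0L))
  }
  rec[, terminal := terminal_pos(start, end, strand)]
  rec[, has_peak := interval_key(chrom, strand, terminal, terminal) %in%
        interval_key(pk$chrom, pk$strand, pk$pos, pk$pos)]
  high <- rec[psi > psi_high]
  pk_ex <- rec[has_peak == TRUE]
  list(
    table = rec[, .(chrom, strand, start, end, psi, has_peak)],
    frac_high_psi_with_peak = if (nrow(high)) mean(high$has_peak) else NA_real_,
    frac_peak_exons_high_psi = if (nrow(pk_ex)) mean(pk_ex$psi > psi_high)
                               else if (nrow(pk)) 0 else NA_real_,
    n_peak_exons = nrow(pk_ex), n_high_psi = nrow(high))
}
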