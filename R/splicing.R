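#' Detect spliced reads consistent with annotated junctions
#'
#' A read qualifies iff it is uniquely mapped, has zero mismatches, every
#' block gap coincides exactly with an annotated intron (same chromosome,
#' strand and both boundaries), and it aligns at least `min_overhang`
#' nucleotides on each side of every junction it spans (cumulative aligned
#' length, so block subdivision does not change the decision). Non-qualifying
#' reads are silently excluded; per-reason counts are attached as attribute
#' `rejections`.
#'
#' @param reads a `net_reads` table.
#' @param ann a `genome_annotation` with derived introns.
#' @param min_overhang minimum aligned nt flanking each junction (default 9,
#'   the strict reading of "more than 8 nucleotides across any junction").
#' @return data.table with one row per read x junction: read_id, chrom,
#'   strand, start, end (intron interval), donor, acceptor, overhang_left,
#'   overhang_right.
#' @export
find_spliced_reads <- function(reads, ann, min_overhang = 9L) {
  empty <- data.table(read_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), donor = integer(), acceptor = integer(),
                      overhang_left = integer(), overhang_right = integer())
  rej <- c(not_unique = 0L, mismatch = 0L, unspliced = 0L,
           unannotated_junction = 0L, short_overhang = 0L)
  if (!nrow(reads)) return(structure(empty, rejections = rej))
  rej["not_unique"] <- sum(!reads$unique_map)
  rej["mismatch"] <- sum(reads$unique_map & reads$nm > 0L)
  rej["unspliced"] <- sum(reads$unique_map & reads$nm == 0L & reads$nblocks < 2L)
  cand <- reads[unique_map == TRUE & nm == 0L & nblocks >= 2L]
  if (!nrow(cand)) return(structure(empty, rejections = rej))

  bl <- read_blocks(cand)
  setorder(bl, read_id, bs)
  bl[, len := be - bs]
  bl[, `:=`(cum_l = cumsum(len), cum_r = rev(cumsum(rev(len)))),
     by = read_id]
  ## junction i sits between block i and i+1
  jn <- bl[, .(chrom = chrom[1L], strand = strand[1L],
               start = be[-.N], end = bs[-1L],
               overhang_left = cum_l[-.N], overhang_right = cum_r[-1L]),
           by = read_id]

  ikeys <- unique(interval_key(ann$introns$chrom, ann$introns$strand,
                               ann$introns$start, ann$introns$end))
  jn[, key_ := interval_key(chrom, strand, start, end)]
  jn[, `:=`(annot = key_ %in% ikeys,
            deep = pmin(overhang_left, overhang_right) >= min_overhang)]
  bad <- jn[, .(all_annot = all(get("annot")), all_deep = all(get("deep"))),
            by = read_id]
  rej["unannotated_junction"] <- sum(!bad$all_annot)
  rej["short_overhang"] <- sum(bad$all_annot & !bad$all_deep)
  ok_ids <- bad[get("all_annot") & get("all_deep"), read_id]
  out <- jn[read_id %in% ok_ids,
            .(read_id, chrom, strand, start, end,
              donor = head_pos(start, end, strand),
              acceptor = terminal_pos(start, end, strand),
              overhang_left, overhang_right)]
  structure(out[], rejections = rej)
}

#' Aggregate spliced reads into splicing events
#'
#' One event per junction; an event passes when covered by at least
#' `min_reads` spliced reads. Passing-event sets keyed by (chromosome,
#' strand, donor, acceptor) are directly comparable across libraries
#' (Venn-style set intersections).
#'
#' @param spliced a table from [find_spliced_reads()].
#' @param min_reads pass threshold (default 3).
#' @return data.table with junction coordinates, n_reads and passes.
#' @export
call_splicing_events <- function(spliced, min_reads = 3L) {
  if (!nrow(spliced)) {
    return(data.table(chrom = character(), strand = character(),
                      start = integer(), end = integer(), donor = integer(),
                      acceptor = integer(), n_reads = integer(),
                      passes = logical()))
  }
  ev <- spliced[, .(n_reads = uniqueN(read_id)),
                by = .(chrom, strand, start, end, donor, acceptor)]
  ev[, passes := n_reads >= min_reads]
  setorder(ev, chrom, strand, start)
  ev[]
}

#' Classify 5' ss intermediate reads as spliced or unspliced
#'
#' Candidate reads are uniquely mapped, mismatch-free reads whose 3'-most
#' base sits exactly on an exon's 3'-terminal nucleotide (the position of the
#' cleaved 5' ss intermediate). Per exon (first exons, which have no upstream
#' junction, are skipped):
#' \itemize{
#'   \item SR (spliced): the read additionally qualifies as a spliced read
#'     across the exon's upstream junction;
#'   \item UR (unspliced): the read is contiguous (single block) and extends
#'     at least 1 nt upstream past the exon's 5' boundary into the preceding
#'     intron;
#'   \item ambiguous: contained entirely within the exon, or spliced across a
#'     junction other than the upstream one; informative of neither state.
#' }
#' spliced% = 100 * SR / (SR + UR), defined only when SR + UR >= `min_total`.
#'
#' @param reads a `net_reads` table.
#' @param ann a `genome_annotation`.
#' @param min_total minimum SR + UR for a defined spliced% (default 10).
#' @param min_overhang passed to [find_spliced_reads()].
#' @return data.table with one row per exon (keyed by coordinates): SR, UR,
#'   ambiguous, n_candidates, spliced_pct (NA when undefined).
#' @export
classify_intermediates <- function(reads, ann, min_total = 10L,
                                   min_overhang = 9L) {
  ## exons with an upstream junction, deduplicated by coordinates; the set of
  ## annotated upstream introns may differ across isoforms - all are accepted
  ex <- ann$exons[ordinal > 0L]
  empty <- data.table(chrom = character(), strand = character(),
                      start = integer(), end = integer(), SR = integer(),
                      UR = integer(), ambiguous = integer(),
                      n_candidates = integer(), spliced_pct = numeric())
  if (!nrow(ex) || !nrow(reads)) return(empty)
  up <- ann$introns[, .(transcript_id, ordinal = ordinal + 1L,
                        upstart = start, upend = end)]
  exu <- up[ex, on = c("transcript_id", "ordinal"), nomatch = NULL]
  exons <- unique(exu[, .(chrom, strand, start, end)])
  upjn <- unique(exu[, .(chrom, strand, start, end, upstart, upend)])
  exons[, terminal := terminal_pos(start, end, strand)]

  cand <- reads[unique_map == TRUE & nm == 0L]
  if (!nrow(cand)) return(empty)
  cand[, pos := terminal_pos(start, end, strand)]
  hits <- exons[cand[, .(read_id, chrom, strand, pos, start, end, nblocks)],
                on = c("chrom", "strand", terminal = "pos"), nomatch = NULL,
                allow.cartesian = TRUE]
  ## hits: exon columns start/end; read columns i.start/i.end
  if (!nrow(hits)) return(empty)

  spliced <- find_spliced_reads(cand, ann, min_overhang = min_overhang)
  ## last junction of each spliced read in transcription direction: the one
  ## abutting the read's 3'-terminal block
  if (nrow(spliced)) {
    skey <- spliced[, .(read_id, jkey = interval_key(chrom, strand, start, end))]
  } else {
    skey <- data.table(read_id = character(), jkey = character())
  }
  upkeys <- upjn[, .(chrom, strand, start, end,
                     jkey = interval_key(chrom, strand, upstart, upend))]

  hits[, ekey := interval_key(chrom, strand, start, end)]
  upkeys[, ekey := interval_key(chrom, strand, start, end)]
  ## SR: read has a spliced junction equal to one of this exon's upstream introns
  sr_pairs <- merge(
    merge(hits[, .(read_id, ekey)], skey, by = "read_id",
          allow.cartesian = TRUE),
    upkeys[, .(ekey, jkey)], by = c("ekey", "jkey"))
  sr_pairs <- unique(sr_pairs[, .(read_id, ekey)])
  sr_pairs[, cls := "SR"]

  ## UR: contiguous read extending >= 1 nt upstream past the exon 5' boundary
  hits[, upstream_ext := ifelse(strand == "+", start - get("i.start"),
                                get("i.end") - end)]
  ur_pairs <- unique(hits[get("nblocks") == 1L & upstream_ext >= 1L,
                          .(read_id, ekey)])
  ur_pairs[, cls := "UR"]

  lab <- merge(unique(hits[, .(read_id, ekey)]),
               rbind(sr_pairs, ur_pairs)[!duplicated(paste(read_id, ekey))],
               by = c("read_id", "ekey"), all.x = TRUE)
  lab[is.na(get("cls")), cls := "ambiguous"]

  agg <- lab[, .(SR = sum(get("cls") == "SR"),
                 UR = sum(get("cls") == "UR"),
                 ambiguous = sum(get("cls") == "ambiguous"),
                 n_candidates = .N), by = "ekey"]
  out <- merge(unique(hits[, .(ekey, chrom, strand, start, end)]), agg,
               by = "ekey")
  out[, spliced_pct := ifelse(SR + UR >= min_total, 100 * SR / (SR + UR),
                              NA_real_)]
  out[, ekey := NULL]
  setorder(out, chrom, strand, start)
  out[]
}

#' Compare spliced% distributions between exon groups
#'
#' Location is compared with an unpaired rank-sum (Mann-Whitney) test and the
#' distributions with a two-sample Kolmogorov-Smirnov test, on exons with a
#' defined spliced%. Groupings: constitutive vs skipped exons, or exons whose
#' preceding intron is U2- vs U12-type.
#'
#' @param records output of [classify_intermediates()].
#' @param ann a classified `genome_annotation` (U12 labels required for the
#'   u2_vs_u12 grouping).
#' @param grouping `"constitutive_vs_skipped"` or `"u2_vs_u12"`.
#' @param bins histogram bin breaks for the per-group frequency table.
#' @return a `group_comparison` list: values per group, location_p, ks_p,
#'   ks_stat, histogram; p-values NA (comparison undefined) when a group has
#'   fewer than 2 defined values.
#' @export
compare_groups <- function(records, ann,
                           grouping = c("constitutive_vs_skipped", "u2_vs_u12"),
                           bins = seq(0, 100, 10)) {
  grouping <- match.arg(grouping)
  rec <- as.data.table(records)[!is.na(spliced_pct)]
  if (grouping == "constitutive_vs_skipped") {
    fl <- ann$exons[, .(constitutive = all(constitutive),
                        skipped = any(skipped)),
                    by = .(chrom, strand, start, end)]
    rec <- fl[rec, on = c("chrom", "strand", "start", "end"), nomatch = NULL]
    g1 <- rec[constitutive == TRUE, spliced_pct]
    g2 <- rec[skipped == TRUE, spliced_pct]
    labels <- c("constitutive", "skipped")
  } else {
    up <- ann$introns[, .(transcript_id, ordinal = ordinal + 1L, u12)]
    exu <- up[ann$exons, on = c("transcript_id", "ordinal"), nomatch = NULL]
    fl <- exu[, .(u12 = any(u12)), by = .(chrom, strand, start, end)]
    rec <- fl[rec, on = c("chrom", "strand", "start", "end"), nomatch = NULL]
    g1 <- rec[u12 == FALSE, spliced_pct]
    g2 <- rec[u12 == TRUE, spliced_pct]
    labels <- c("U2", "U12")
  }
  comparable <- length(g1) >= 2L && length(g2) >= 2L
  loc_p <- ks_p <- ks_stat <- NA_real_
  if (comparable) {
    loc_p <- suppressWarnings(
      stats::wilcox.test(g1, g2, exact = FALSE)$p.value)
    ks <- suppressWarnings(stats::ks.test(g1, g2, exact = FALSE))
    ks_p <- ks$p.value
    ks_stat <- unname(ks$statistic)
  }
  histo <- data.table(
    bin = paste0("[", bins[-length(bins)], ",", bins[-1L], "]"),
    g1 = freq_bins(g1, bins), g2 = freq_bins(g2, bins))
  setnames(histo, c("g1", "g2"), labels)
  structure(list(labels = labels, values = stats::setNames(list(g1, g2), labels),
                 location_p = loc_p, ks_p = ks_p, ks_stat = ks_stat,
                 comparable = comparable, histogram = histo),
            class = "group_comparison")
}

freq_bins <- function(x, bins) {
  if (!length(x)) return(rep(0, length(bins) - 1L))
  h <- graphics::hist(x, breaks = bins, plot = FALSE, include.lowest = TRUE)
  h$counts / length(x)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison %s vs %s: n = %d / %d\n", x$labels[1L],
              x$labels[2L], length(x$values[[1L]]), length(x$values[[2L]])))
  if (x$comparable) {
    cat(sprintf("  rank-sum p = %.3g; KS D = %.3f, p = %.3g\n",
                x$location_p, x$ks_stat, x$ks_p))
  } else {
    cat("  comparison undefined (a group has < 2 defined values)\n")
  }
  invisible(x)
}
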