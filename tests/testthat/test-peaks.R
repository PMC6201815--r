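test_that("feature_stats computes whole-feature mean and population SD", {
  cov0 <- mk_cov("chrT", "+", pos = 9999L, count = 1L)
  st0 <- feature_stats(cov0, "chrT", "+", 100L, 150L)
  expect_equal(st0, list(mean = 0, sd = 0))  # all-zero feature

  ## length 10, nine zeros and one 30: mean 3, population sd 9
  cov1 <- cov_from_vector(c(rep(0L, 9), 30L), start = 100L)
  st1 <- feature_stats(cov1, "chrT", "+", 100L, 110L)
  expect_equal(st1, list(mean = 3, sd = 9))

  ## uniform c everywhere: sd exactly 0
  cov2 <- cov_from_vector(rep(7L, 50), start = 100L)
  st2 <- feature_stats(cov2, "chrT", "+", 100L, 150L)
  expect_equal(st2, list(mean = 7, sd = 0))
})

test_that("5' ss peak rule: min reads, 3-sd threshold and degenerate variance", {
  ann <- ann_single_exons(10L)
  s <- ann$exons$start
  term <- ann$exons$end - 1L

  ## terminal count 3 only: below min_reads
  expect_equal(nrow(call_ss_peaks(mk_cov("chrT", "+", term, 3L), ann)), 0L)

  ## nine zeros + terminal 30: 30 >= 3 + 3*9 = 30 (boundary) and 30 > 3
  cov <- mk_cov("chrT", "+", term, 30L)
  pk <- call_ss_peaks(cov, ann)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$kind, "five_prime_ss")
  expect_equal(pk$pos, term)
  expect_equal(pk$count, 30L)
  expect_equal(pk$feature_mean, 3)
  expect_equal(pk$feature_sd, 9)

  ## uniform coverage: not above the mean, no peak despite count >= 4
  unif <- cov_from_vector(rep(5L, 10), start = s)
  expect_equal(nrow(call_ss_peaks(unif, ann)), 0L)
})

test_that("intron terminals yield three_prime_ss peaks", {
  ex <- data.table(gene_id = "g", transcript_id = "g.1", chrom = "chrT",
                   strand = "+", start = c(1000L, 2000L), end = c(1500L, 2500L))
  ann <- ann_from_exons(ex)
  ## intron (1500,2000), terminal = 1999
  cov <- mk_cov("chrT", "+", pos = 1999L, count = 25L)
  pk <- call_ss_peaks(cov, ann)
  expect_true("three_prime_ss" %in% pk$kind)
  expect_equal(pk[kind == "three_prime_ss", pos], 1999L)
})

test_that("pause mode trims intermediate-contaminated positions and tests the rest", {
  ann <- ann_single_exons(10L)
  term <- ann$exons$end - 1L
  s <- ann$exons$start

  ## lone spike at the exon's last nucleotide: trimmed away, no pause peak
  expect_equal(nrow(call_pause_peaks(mk_cov("chrT", "+", term, 50L), ann)), 0L)

  ## lone spike of 30 among zeros, trimmed length 7: the 3-sd rule rejects it
  ## (mean 30/7, population sd pulls the threshold above 30) - oracle agrees
  cov <- mk_cov("chrT", "+", s + 3L, 30L)
  pk <- call_pause_peaks(cov, ann)
  counts <- integer(10); counts[4] <- 30L
  oracle <- oracle_pause_peaks(counts)
  expect_equal(length(oracle), 0L)
  expect_equal(nrow(pk), 0L)

  ## spike over a baseline does qualify, and matches the oracle exactly
  ann32 <- ann_single_exons(32L)
  s32 <- ann32$exons$start
  v <- rep(1L, 32); v[10] <- 30L
  cov32 <- cov_from_vector(v, start = s32)
  pk32 <- call_pause_peaks(cov32, ann32)
  oracle32 <- oracle_pause_peaks(v)
  expect_equal(pk32$pos, s32 + oracle32 - 1L)
  expect_equal(pk32$count, 30L)
  expect_equal(pk32$feature_mean, mean(v[1:29]))

  ## all-zero feature: no peaks
  expect_equal(nrow(call_pause_peaks(mk_cov("chrT", "+", 1L, 1L), ann)), 0L)
})

test_that("peak calls match the brute-force oracle on random features", {
  set.seed(77)
  n_feat <- 120L
  lens <- sample(5:200, n_feat, replace = TRUE)
  strands <- sample(c("+", "-"), n_feat, replace = TRUE)
  anns <- list("+" = ann_single_exons(lens, "+"),
               "-" = ann_single_exons(lens, "-", chrom = "chrM"))
  for (sgn in c("+", "-")) {
    ann <- anns[[sgn]]
    feats <- ann$exons[order(start)]
    vecs <- lapply(feats$end - feats$start, function(L) {
      v <- rpois(L, sample(c(0.5, 2, 5), 1))
      if (runif(1) < 0.5) v[sample(L, 1)] <- v[sample(L, 1)] + rpois(1, 25)
      v
    })
    counts <- rbindlist(lapply(seq_along(vecs), function(i) {
      data.table(pos = feats$start[i] + seq_along(vecs[[i]]) - 1L,
                 count = vecs[[i]])
    }))[count > 0]
    cov <- mk_cov(feats$chrom[1L], sgn, counts$pos, counts$count)
    ss <- call_ss_peaks(cov, ann)
    pause <- call_pause_peaks(cov, ann)
    for (i in seq_along(vecs)) {
      v <- if (sgn == "+") vecs[[i]] else rev(vecs[[i]])  # transcription order
      term <- terminal_called <- feats$end[i] - 1L
      if (sgn == "-") term <- feats$start[i]
      expect_equal(term %in% ss$pos, oracle_ss_peak(v, "+"),
                   info = sprintf("ss feature %d strand %s", i, sgn))
      oracle_off <- oracle_pause_peaks(v, "+")  # 1-based transcription offsets
      got <- sort(pause[pos >= feats$start[i] & pos < feats$end[i], pos])
      want <- if (sgn == "+") feats$start[i] + oracle_off - 1L
              else feats$end[i] - oracle_off
      expect_equal(got, sort(want),
                   info = sprintf("pause feature %d strand %s", i, sgn))
    }
  }
})

test_that("increasing the terminal count never un-calls a peak", {
  ann <- ann_single_exons(50L)
  s <- ann$exons$start
  term <- ann$exons$end - 1L
  set.seed(13)
  base <- rpois(49, 2)
  called <- logical(0)
  for (tc in seq(0L, 60L, 4L)) {
    cov <- mk_cov("chrT", "+", c(s + 0:48, term), c(base, tc))
    called <- c(called, nrow(call_ss_peaks(cov, ann)) == 1L)
  }
  expect_true(all(diff(called) >= 0))  # monotone in the terminal count
})

test_that("consensus keeps only peaks present in every replicate", {
  p1 <- data.table(chrom = "chrT", strand = "+", pos = c(10L, 20L, 30L),
                   count = c(10L, 12L, 14L), kind = "five_prime_ss")
  ## identical sets: idempotent
  expect_equal(nrow(consensus_peaks(list(p1, p1, p1))), 3L)
  ## 2-of-3: dropped
  p2 <- p1[pos != 20L]
  cons <- consensus_peaks(list(p1, p1, p2))
  expect_equal(cons$pos, c(10L, 30L))
  expect_true(all(c("count_1", "count_2", "count_3") %in% names(cons)))
  ## disjoint sets: empty consensus; kind mismatches never merge
  p3 <- copy(p1)[, pos := pos + 100L]
  expect_equal(nrow(consensus_peaks(list(p1, p3))), 0L)
  p4 <- copy(p1)[, kind := "three_prime_ss"]
  expect_equal(nrow(consensus_peaks(list(p1, p4))), 0L)
  expect_error(consensus_peaks(list(p1)), ">= 2")
})

test_that("peaks are only called on eligible features", {
  ## isoform-overlapping exons and unexpressed genes are excluded
  ex <- data.table(
    gene_id = c("g1", "g1", "g2"),
    transcript_id = c("g1.1", "g1.2", "g2.1"),
    chrom = "chrT", strand = "+",
    start = c(1000L, 1010L, 5000L), end = c(1100L, 1100L, 5100L))
  ann <- ann_from_exons(ex)
  cov <- mk_cov("chrT", "+", pos = c(1099L, 5099L), count = c(30L, 30L))
  pk_all <- call_ss_peaks(cov, ann)
  expect_equal(pk_all$pos, 5099L)  # g1 exons overlap non-identically
  ann2 <- set_expressed(ann, "g1")
  expect_equal(nrow(call_ss_peaks(cov, ann2)), 0L)
})
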