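## two-exon gene on '+': exons (1000,1100) and (2000,2100), intron (1100,2000)
two_exon_ann <- function(strand = "+") {
  ann_from_exons(data.table(
    gene_id = "g", transcript_id = "g.1", chrom = "chrT", strand = strand,
    start = c(1000L, 2000L), end = c(1100L, 2100L)))
}

test_that("spliced-read detection enforces uniqueness, mismatches, annotation and overhangs", {
  ann <- two_exon_ann()
  jn <- function(left, right, nm = 0L, uniq = TRUE) {
    net_reads("chrT", "+", blocks = list(cbind(c(1100L - left, 2000L),
                                               c(1100L, 2000L + right))),
              nm = nm, unique_map = uniq)
  }
  ## 20 nt each side over the annotated junction: accepted
  ok <- find_spliced_reads(jn(20L, 20L), ann)
  expect_equal(nrow(ok), 1L)
  expect_equal(ok[, c(start, end)], c(1100L, 2000L))
  expect_equal(ok$overhang_left, 20L)

  ## 8 nt on one side: rejected ("more than 8 nucleotides" rule)
  r8 <- find_spliced_reads(jn(8L, 20L), ann)
  expect_equal(nrow(r8), 0L)
  expect_equal(attr(r8, "rejections")[["short_overhang"]], 1L)
  expect_equal(nrow(find_spliced_reads(jn(9L, 9L), ann)), 1L)

  ## one mismatch or multi-mapping: rejected
  expect_equal(nrow(find_spliced_reads(jn(20L, 20L, nm = 1L), ann)), 0L)
  expect_equal(nrow(find_spliced_reads(jn(20L, 20L, uniq = FALSE), ann)), 0L)

  ## gap not matching an annotated intron: rejected
  off <- net_reads("chrT", "+", blocks = list(cbind(c(1080L, 2001L),
                                                    c(1100L, 2021L))))
  bad <- find_spliced_reads(off, ann)
  expect_equal(nrow(bad), 0L)
  expect_equal(attr(bad, "rejections")[["unannotated_junction"]], 1L)
})

test_that("spliced detection is invariant to block subdivision", {
  ann <- two_exon_ann()
  whole <- net_reads("chrT", "+", blocks = list(cbind(c(1080L, 2000L),
                                                      c(1100L, 2020L))))
  split <- net_reads("chrT", "+", blocks = list(cbind(c(1080L, 1090L, 2000L),
                                                      c(1090L, 1100L, 2020L))))
  a <- find_spliced_reads(whole, ann)
  b <- find_spliced_reads(split, ann)
  expect_equal(a[, .(start, end, overhang_left, overhang_right)],
               b[, .(start, end, overhang_left, overhang_right)])
})

test_that("splicing events pass at 3 or more junction reads", {
  ann <- two_exon_ann()
  mk <- function(n) net_reads(rep("chrT", n), "+",
                              blocks = replicate(n, cbind(c(1080L, 2000L),
                                                          c(1100L, 2020L)),
                                                 simplify = FALSE))
  ev2 <- call_splicing_events(find_spliced_reads(mk(2L), ann))
  expect_false(ev2$passes)
  ev3 <- call_splicing_events(find_spliced_reads(mk(3L), ann))
  expect_true(ev3$passes)
  expect_equal(ev3$n_reads, 3L)
  expect_equal(nrow(call_splicing_events(find_spliced_reads(mk(0L), ann))), 0L)
})

test_that("intermediate reads classify as SR/UR/ambiguous with conservation", {
  ann <- two_exon_ann()
  term <- 2099L  # 3'-terminal base of the downstream exon
  sr <- lapply(1:5, function(i) cbind(c(1100L - 20L, 2000L), c(1100L, 2100L)))
  ur <- lapply(1:5, function(i) cbind(2000L - 10L, 2100L))
  amb <- lapply(1:3, function(i) cbind(2040L, 2100L))  # contained in the exon
  reads <- net_reads(rep("chrT", 13), "+", blocks = c(sr, ur, amb))
  rec <- classify_intermediates(reads, ann, min_total = 10L)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$SR, 5L)
  expect_equal(rec$UR, 5L)
  expect_equal(rec$ambiguous, 3L)
  expect_equal(rec$SR + rec$UR + rec$ambiguous, rec$n_candidates)
  expect_equal(rec$spliced_pct, 50.0)

  ## total below 10: spliced% undefined
  reads8 <- net_reads(rep("chrT", 8), "+", blocks = c(sr[1:4], ur[1:4]))
  rec8 <- classify_intermediates(reads8, ann, min_total = 10L)
  expect_equal(rec8$SR + rec8$UR, 8L)
  expect_true(is.na(rec8$spliced_pct))

  ## a read stopping exactly at the exon 5' boundary is ambiguous
  bnd <- net_reads("chrT", "+", blocks = list(cbind(2000L, 2100L)))
  recb <- classify_intermediates(bnd, ann, min_total = 1L)
  expect_equal(recb$ambiguous, 1L)
  expect_equal(recb$UR, 0L)

  ## first exons are skipped: a read ending at exon 1's terminal yields no
  ## record (no upstream junction exists)
  fe <- net_reads("chrT", "+", blocks = list(cbind(1050L, 1100L)))
  expect_equal(nrow(classify_intermediates(fe, ann, min_total = 1L)), 0L)
})

test_that("strand mirror: classification works identically on '-' genes", {
  ann <- two_exon_ann("-")
  ## downstream (second transcribed) exon is (1000,1100); terminal = 1000
  sr <- list(cbind(c(1000L, 2000L), c(1100L, 2020L)))   # spliced to upstream
  ur <- list(cbind(1000L, 2110L))                        # contiguous past 2100
  amb <- list(cbind(1000L, 1080L))
  reads <- net_reads(rep("chrT", 3), "-", blocks = c(sr, ur, amb))
  rec <- classify_intermediates(reads, ann, min_total = 1L)
  expect_equal(rec[, .(SR, UR, ambiguous)], data.table(SR = 1L, UR = 1L,
                                                       ambiguous = 1L))
})

test_that("group comparisons report rank-sum and KS statistics", {
  recs <- function(vals_con, vals_skp) {
    ann <- ann_from_exons(data.table(
      gene_id = "g", transcript_id = "g.1", chrom = "chrT", strand = "+",
      start = 1000L * seq_len(length(vals_con) + length(vals_skp)),
      end = 1000L * seq_len(length(vals_con) + length(vals_skp)) + 100L))
    n <- length(vals_con) + length(vals_skp)
    ex <- ann$exons
    ex[, constitutive := seq_len(.N) <= length(vals_con)]
    ex[, skipped := !constitutive]
    rec <- ex[, .(chrom, strand, start, end)]
    rec[, spliced_pct := c(vals_con, vals_skp)]
    list(ann = ann, rec = rec)
  }
  ## identical groups: KS statistic ~ 0, p = 1
  f <- recs(c(10, 30, 50, 70, 90), c(10, 30, 50, 70, 90))
  cmp <- compare_groups(f$rec, f$ann)
  expect_equal(cmp$ks_stat, 0)
  expect_equal(cmp$ks_p, 1)

  ## extreme separation: KS statistic 1
  f2 <- recs(rep(100, 6), rep(0, 6))
  cmp2 <- compare_groups(f2$rec, f2$ann)
  expect_equal(cmp2$ks_stat, 1)
  expect_lt(cmp2$location_p, 0.05)

  ## a group with < 2 values: undefined
  f3 <- recs(c(50, 60), 10)
  cmp3 <- compare_groups(f3$rec, f3$ann)
  expect_false(cmp3$comparable)
  expect_true(is.na(cmp3$location_p))
})

test_that("planted Beta-distributed group difference is detected", {
  set.seed(31)
  n <- 200L
  g1 <- 100 * rbeta(n, 8, 2)    # mean 0.8
  g2 <- 100 * rbeta(n, 5, 5)    # mean 0.5; difference 0.3
  f <- local({
    starts <- 1000L * seq_len(2L * n)
    ann <- ann_from_exons(data.table(
      gene_id = "g", transcript_id = "g.1", chrom = "chrT", strand = "+",
      start = starts, end = starts + 100L))
    ex <- ann$exons
    ex[, constitutive := seq_len(.N) <= n]
    ex[, skipped := !constitutive]
    rec <- ex[, .(chrom, strand, start, end)]
    rec[, spliced_pct := c(g1, g2)]
    list(ann = ann, rec = rec)
  })
  cmp <- compare_groups(f$rec, f$ann)
  expect_lt(cmp$location_p, 0.01)
  expect_lt(cmp$ks_p, 0.01)
})

test_that("U2 vs U12 grouping uses the preceding-intron label", {
  cfg <- sim_config(seed = 8, n_genes = 30, u12_frac = 0.3,
                    exon_meanlog = log(40), exon_sdlog = 0.2,
                    short_exon_frac = 0, intermediate_rate = 40,
                    peak_prob_high = 1, peak_prob_low = 1,
                    background_lambda = 0.1, silent_frac = 0)
  g <- make_genome(cfg)
  reads <- simulate_mnetseq(g, size_select = FALSE)
  rec <- classify_intermediates(reads, g$ann)
  cmp <- compare_groups(rec, g$ann, grouping = "u2_vs_u12")
  expect_true(length(cmp$values$U12) > 0)
  expect_true(all(unlist(cmp$values) >= 0 & unlist(cmp$values) <= 100))
})
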