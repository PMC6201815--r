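test_that("3'-end extraction follows the strand convention and is additive", {
  r_plus <- net_reads("chr1", "+", start = 100L, end = 127L)
  expect_equal(end_coverage(r_plus)$counts$pos, 126L)
  r_minus <- net_reads("chr1", "-", start = 100L, end = 127L)
  expect_equal(end_coverage(r_minus)$counts$pos, 100L)

  ## blocked read: last base of the last block / first of the first
  r_blk <- net_reads("chr1", "+", blocks = list(cbind(c(100L, 300L),
                                                      c(120L, 350L))))
  expect_equal(end_coverage(r_blk)$counts$pos, 349L)

  ten <- net_reads(rep("chr1", 10), "+", start = rep(100L, 10),
                   end = rep(127L, 10))
  cov <- end_coverage(ten)
  expect_equal(cov$counts$count, 10L)
  expect_equal(cov$library_total, 10L)
})

test_that("multi-mapped reads are excluded and counts are conserved", {
  g <- make_genome(sim_config(seed = 5, n_genes = 5))
  reads <- simulate_mnetseq(g)
  reads$unique_map[1:50] <- FALSE
  cov <- end_coverage(reads)
  expect_equal(cov$library_total, nrow(reads) - 50L)
  expect_equal(sum(cov$counts$count), cov$library_total)  # conservation
  expect_equal(cov$n_excluded, 50L)
})

test_that("strand mirroring leaves coverage statistics unchanged", {
  g <- make_genome(sim_config(seed = 6, n_genes = 4))
  reads <- simulate_mnetseq(g, library_mode = "short")
  M <- max(reads$end) + 1000L
  sizes <- lapply(strsplit(reads$bsizes, ","), as.integer)
  starts <- lapply(strsplit(reads$bstarts, ","), as.integer)
  mirrored <- net_reads(
    chrom = reads$chrom,
    strand = ifelse(reads$strand == "+", "-", "+"),
    blocks = Map(function(s0, sz, st) {
      bs <- s0 + st; be <- bs + sz
      cbind(rev(M - be), rev(M - bs))
    }, reads$start, sizes, starts),
    read_id = reads$read_id)
  cov <- end_coverage(reads)
  cm <- end_coverage(mirrored)
  expect_equal(cm$library_total, cov$library_total)
  a <- cov$counts[order(strand, pos)]
  b <- cm$counts[, .(strand = ifelse(strand == "+", "-", "+"),
                     pos = M - 1L - pos, count)][order(strand, pos)]
  expect_equal(a[, .(strand, pos, count)], b[, .(strand, pos, count)])
})

test_that("footprint histogram windows and statistics behave as specified", {
  ## one qualifying first exon (GA would be 100 nt; build a 300 nt one)
  ann <- ann_single_exons(300L)
  fe_start <- ann$exons$start[1L]
  ## all lengths 27, 3' ends inside the first 150 nt
  r27 <- net_reads(rep("chrT", 20), "+",
                   start = fe_start + seq(20L, 115L, 5L),
                   end = fe_start + seq(20L, 115L, 5L) + 27L)
  h <- read_length_histogram(r27, ann, min_first_exon_length = 200L)
  expect_equal(h$modal_length, 27L)
  expect_equal(fraction_in_range(h, 18, 40), 1.0)

  ## 3' end beyond +150 is excluded; inside is kept
  edge <- net_reads(rep("chrT", 2), "+",
                    start = fe_start + c(120L, 125L),
                    end = fe_start + c(151L, 149L))  # ends at offsets 150, 148
  h2 <- read_length_histogram(edge, ann, min_first_exon_length = 200L)
  expect_equal(h2$n, 1L)

  ## no qualifying exon: empty histogram
  h3 <- read_length_histogram(r27, ann, min_first_exon_length = 400L)
  expect_equal(h3$n, 0L)

  ## planted truncated-normal mixture: recovered modes within +/- 2 nt
  set.seed(21)
  n <- 4000L
  comp <- sample(1:2, n, replace = TRUE, prob = c(0.5, 0.5))
  modes <- c(27, 60)[comp]; sds <- c(4, 8)[comp]
  lo <- c(18, 40)[comp]; hi <- c(40, 100)[comp]
  L <- as.integer(round(qnorm(runif(n, pnorm(lo, modes, sds),
                                    pnorm(hi, modes, sds)), modes, sds)))
  ends <- fe_start + sample(30:149, n, replace = TRUE)
  rmix <- net_reads(rep("chrT", n), "+", start = ends - L + 1L,
                    end = ends + 1L)
  hm <- read_length_histogram(rmix, ann, min_first_exon_length = 200L)
  tab <- hm$table
  m1 <- tab[len <= 40][which.max(count), len]
  m2 <- tab[len > 40][which.max(count), len]
  expect_lte(abs(m1 - 27L), 2L)
  expect_lte(abs(m2 - 60L), 2L)
})

test_that("snRNA counting pads intervals, applies the expressed rule and scales to RPM", {
  sn <- data.table(gene_id = c("U1A", "U2A"), class = c("U1", "U2"),
                   chrom = "chrT", strand = "+",
                   start = c(1000L, 5000L), end = c(1150L, 5150L))
  ## 10 reads at 3 nt downstream of U1A's annotated 3' end: inside the pad
  cov <- mk_cov("chrT", "+", pos = c(1152L, 5149L), count = c(10L, 8L),
                library_total = 2e6L)
  res <- count_snrna(cov, sn, pad = 5L)
  expect_equal(res[class == "U1", rpm], 10 / 2e6 * 1e6)  # = 5 RPM
  ## beyond the pad: not counted; class warning for empty expressed set
  cov2 <- mk_cov("chrT", "+", pos = 1156L, count = 10L, library_total = 2e6L)
  ## both classes lose their expressed set -> one warning per class
  expect_warning(expect_warning(res2 <- count_snrna(cov2, sn, pad = 5L),
                                "no expressed genes"),
                 "no expressed genes")
  expect_equal(res2[class == "U1", rpm], 0)
  ## low-RPM gene in the reference sample is excluded from the class sum
  ref <- mk_cov("chrT", "+", pos = c(1149L, 5149L), count = c(100L, 1L),
                library_total = 1e6L)
  expect_warning(res3 <- count_snrna(cov, sn, pad = 5L, reference = ref),
                 "no expressed genes")
  expect_equal(res3[class == "U2", n_genes], 0L)
  expect_warning(count_snrna(cov, data.table(gene_id = character(),
                                             class = character(),
                                             chrom = character(),
                                             strand = character(),
                                             start = integer(),
                                             end = integer())),
                 "empty snRNA")
})

test_that("RAD trimming and arithmetic follow the definition", {
  ann <- ann_single_exons(c(100L, 100L, 103L, 3L))
  s <- ann$exons[order(start), start]
  ## exon 1: uniform 1 read/nt -> untrimmed TR = 97, RAD = 1
  ## exon 2: all 50 reads on the last nucleotide -> TR = 0 -> excluded
  ## exon 3: 10 reads on the first 10 nt, EL = 103 -> RAD = 10/100
  ## exon 4: EL <= 3 -> excluded
  cov <- mk_cov("chrT", "+",
                pos = c(s[1] + 0:99, s[2] + 99L, s[3] + 0:9, s[4] + 0L),
                count = c(rep(1L, 100), 50L, rep(1L, 10), 5L))
  rad <- read_average_density(cov, ann, "exon")
  expect_equal(nrow(rad), 2L)
  expect_equal(rad[start == s[1], RAD], 1.0)
  expect_equal(rad[start == s[3], RAD], 0.1)
  expect_false(s[2] %in% rad$start)
  expect_false(s[4] %in% rad$start)

  ## spliced-read 3' ends are subtracted for exons
  spl <- mk_cov("chrT", "+", pos = s[3] + 0:4, count = rep(1L, 5))
  rad2 <- read_average_density(cov, ann, "exon", spliced_ends = spl)
  expect_equal(rad2[start == s[3], RAD], 0.05)
})

test_that("intron RAD trims the 5'-most 3 nucleotides strand-awarely", {
  ex <- data.table(gene_id = "g", transcript_id = "g.1", chrom = "chrT",
                   strand = "-", start = c(1000L, 2000L), end = c(1500L, 2500L))
  ann <- ann_from_exons(ex)
  ## intron (1500,2000) on '-': 5'-most bases are 1997..1999
  cov <- mk_cov("chrT", "-", pos = c(1997:1999, 1600L), count = c(9L, 9L, 9L, 5L))
  rad <- read_average_density(cov, ann, "intron")
  expect_equal(rad$TR, 5)  # the three 5'-terminal positions are removed
  expect_equal(rad$RAD, 5 / (500 - 3))
})

test_that("treatment ratio handles identity, planted scaling and zero denominators", {
  reg <- data.table(chrom = "chrT", strand = "+", start = 100L, end = 200L,
                    set = "roi")
  cov <- mk_cov("chrT", "+", pos = 150L, count = 100L, library_total = 1000L)
  same <- treatment_ratio(cov, cov, reg)
  expect_equal(same$ratio, 1.0)
  ## zero untreated RPM: undefined, not 0
  cov0 <- mk_cov("chrT", "+", pos = 500L, count = 10L, library_total = 1000L)
  z <- treatment_ratio(cov0, cov, reg)
  expect_true(z$undefined)
  expect_true(is.na(z$ratio))
  ## empty region set
  expect_equal(nrow(treatment_ratio(cov, cov, reg[0])), 0L)
})

test_that("metagene profiles re-index to transcription-direction offsets", {
  a1 <- data.table(chrom = "chrT", strand = "+", pos = 1000L)
  cov <- mk_cov("chrT", "+", pos = 1000L, count = 5L, library_total = 1000L)
  prof <- metagene_profile(cov, a1, window = c(50L, 50L))
  expect_equal(prof[rpm > 0, offset], 0L)

  ## '-' strand: a read 5 nt 3'-ward (decreasing coordinate) maps to +5
  a2 <- data.table(chrom = "chrT", strand = "-", pos = 1000L)
  cov2 <- mk_cov("chrT", "-", pos = 995L, count = 5L, library_total = 1000L)
  prof2 <- metagene_profile(cov2, a2, window = c(50L, 50L))
  expect_equal(prof2[rpm > 0, offset], 5L)

  ## planted spike at offset -1 across 100 anchors
  set.seed(9)
  anchors <- data.table(chrom = "chrT", strand = "+",
                        pos = sort(sample(5000:50000, 100)))
  spikes <- mk_cov("chrT", "+", pos = anchors$pos - 1L, count = rep(20L, 100),
                   library_total = 10000L)
  prof3 <- metagene_profile(spikes, anchors, window = c(20L, 20L))
  expect_equal(prof3[which.max(rpm), offset], -1L)
})
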