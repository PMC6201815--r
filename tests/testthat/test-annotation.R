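test_that("GTF parsing converts coordinates, orders exons and derives introns", {
  ann <- parse_annotation(write_tiny_gtf())
  ga <- ann$exons[gene_id == "GA"][order(ordinal)]
  expect_equal(ga$start, c(100L, 300L, 500L))  # 1-based closed -> 0-based half-open
  expect_equal(ga$end, c(200L, 400L, 600L))
  gi <- ann$introns[gene_id == "GA"][order(ordinal)]
  expect_equal(gi$start, c(200L, 400L))
  expect_equal(gi$end, c(300L, 500L))

  ## minus strand: ordinal 0 is the rightmost exon
  gb <- ann$exons[gene_id == "GB"]
  expect_equal(gb[ordinal == 0L, start], 1400L)
  expect_equal(gb[ordinal == 2L, start], 1000L)

  ## single-exon transcript has no introns
  expect_equal(nrow(ann$introns[gene_id == "G1X"]), 0L)

  ## round-trip: exons + introns tile the transcript exactly
  for (tid in ann$transcripts$transcript_id) {
    ex <- ann$exons[transcript_id == tid][order(start)]
    iv <- rbind(ex[, .(start, end)],
                ann$introns[transcript_id == tid, .(start, end)])[order(start)]
    expect_true(all(iv$start[-1L] == iv$end[-nrow(iv)]))
    tx <- ann$transcripts[transcript_id == tid]
    expect_equal(c(iv$start[1L], iv$end[nrow(iv)]), c(tx$start, tx$end))
  }
})

test_that("malformed GTF input produces named parse/validation errors", {
  p <- tempfile(fileext = ".gtf")
  lines <- tiny_gtf_lines()
  writeLines(c(lines[1:3], "chr1\tbroken\tline"), p)
  expect_error(parse_annotation(p), "line 4")
  writeLines(c(lines[2], sub("\\+", "*", lines[3])), p)
  expect_error(parse_annotation(p), "strand")
  ## overlapping exons within one transcript
  writeLines(c(
    'chr1\tt\texon\t101\t200\t.\t+\t.\tgene_id "g"; transcript_id "t1";',
    'chr1\tt\texon\t150\t300\t.\t+\t.\tgene_id "g"; transcript_id "t1";'), p)
  expect_error(parse_annotation(p), "validation")
})

test_that("exon classification flags skipped, alternative and overlap cases", {
  ann <- tiny_annotation()
  ex <- ann$exons

  ## single-isoform gene: internal exon constitutive
  expect_true(ex[gene_id == "GA" & ordinal == 1L, constitutive])
  expect_false(ex[gene_id == "GA" & ordinal == 1L, skipped])

  ## GC middle exon is absent from an isoform containing both neighbours
  skp <- ex[gene_id == "GC" & start == 2200L]
  expect_true(all(skp$skipped))
  expect_false(any(skp$constitutive))

  ## GD middle exon: different acceptor, same donor -> alt3ss (not alt5ss)
  gd <- ex[gene_id == "GD" & end == 3300L]
  expect_true(all(gd$alt3ss))
  expect_false(any(gd$alt5ss))
  ## the two variants overlap non-identically on the same strand
  expect_true(all(gd$overlaps_other_exon))

  ## opposite-strand overlap never counts
  expect_false(ex[gene_id == "GE", overlaps_other_exon])
  expect_false(ex[gene_id == "GF", overlaps_other_exon])

  ## constitutive and skipped are mutually exclusive everywhere
  expect_false(any(ex$constitutive & ex$skipped))
})

test_that("classification is invariant to transcript input order", {
  p1 <- write_tiny_gtf()
  lines <- tiny_gtf_lines()
  body <- lines[-1L]
  set.seed(42)
  p2 <- tempfile(fileext = ".gtf")
  writeLines(body[sample(length(body))], p2)
  a1 <- classify_exons(parse_annotation(p1))
  a2 <- classify_exons(parse_annotation(p2))
  key <- c("transcript_id", "start")
  setkeyv(a1$exons, key); setkeyv(a2$exons, key)
  flags <- c("constitutive", "skipped", "alt5ss", "alt3ss", "overlaps_other_exon")
  expect_equal(as.data.frame(a1$exons[, flags, with = FALSE]),
               as.data.frame(a2$exons[, flags, with = FALSE]))
})

test_that("U12 labelling is exact-match only", {
  ann <- tiny_annotation()
  ## empty list: everything stays U2
  empty_bed <- tempfile(fileext = ".bed")
  file.create(empty_bed)
  ann0 <- label_u12_introns(ann, empty_bed)
  expect_false(any(ann0$introns$u12))

  ## off-by-one interval: no match, warning
  expect_warning(
    ann1 <- label_u12_introns(ann, data.table(chrom = "chr1", start = 201L,
                                              end = 300L, strand = "+")),
    "matched no annotated intron")
  expect_false(any(ann1$introns$u12))

  ## one exact match among all introns
  ann2 <- label_u12_introns(ann, data.table(chrom = "chr1", start = 200L,
                                            end = 300L, strand = "+"))
  expect_equal(sum(ann2$introns$u12), 1L)
  expect_true(ann2$introns[start == 200L & end == 300L, u12])
})

test_that("expression threshold finds the bimodal valley and falls back when unimodal", {
  set.seed(11)
  x <- c(rnorm(400, -5, 1), rnorm(400, 5, 1))
  thr <- expression_threshold(2^x)
  expect_false(thr$unimodal)
  expect_lt(abs(thr$threshold), 1)  # valley of two well-separated modes

  expect_warning(u <- expression_threshold(rep(8, 50)), "falling back")
  expect_equal(u$threshold, 0)
  expect_true(u$unimodal)
})

test_that("a gene is expressed when any transcript clears the threshold", {
  ann <- tiny_annotation()
  tbl <- data.table(
    transcript_id = c("GC.1", "GC.2", "GA.1"),
    fpkm = c(2^6, 2^-6, 2^-6))
  eg <- expressed_genes(tbl, ann, threshold = 0)
  expect_true("GC" %in% eg)   # one isoform above threshold suffices
  expect_false("GA" %in% eg)
  ann <- set_expressed(ann, eg)
  expect_true(ann$genes[gene_id == "GC", is_expressed])
  expect_false(ann$genes[gene_id == "GA", is_expressed])
})
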