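#' Simulation configuration with the stated-world defaults
#'
#' Defaults encode the data-generating world the pipeline assumes: a compact
#' multi-isoform genome with constitutive, skipped and alternative-splice-site
#' exons, short (< 100 nt) exons/introns to exercise the PSI filters, a
#' U12-intron subset and snRNA-like single-exon genes; nascent 3'-end signal
#' with Poisson background (2 reads/nt), splicing-intermediate spikes at exon
#' 3' ends (Poisson mean 20), footprint-length mixtures with modes at 27 and
#' 60 nt truncated to 18-40 and 40-100 nt, and gel size selection of 20-60 nt
#' (short libraries) or 60-160 nt (long libraries); detergent treatment thins
#' intermediate and snRNA reads by `treatment_scale` using common random
#' numbers, so paired runs share the untreated stream. The planted inclusion
#' level `psi_true` is drawn once per gene, uniform on [0, 1] (see the
#' methods vignette for why per-gene rather than per-exon).
#'
#' @param seed integer seed fixing every generator output bit-exactly.
#' @param n_genes number of multi-exon genes.
#' @param ... overrides for any default listed in the function body.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 40L, ...) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    chrom = "chrS",
    n_exons_range = c(4L, 8L),
    first_exon_meanlog = log(300), first_exon_sdlog = 0.25,
    min_first_exon = 150L,
    exon_meanlog = log(120), exon_sdlog = 0.5, min_exon = 25L,
    short_exon_frac = 0.10, short_exon_range = c(40L, 90L),
    intron_meanlog = log(800), intron_sdlog = 0.6, min_intron = 110L,
    short_intron_frac = 0.08, short_intron_range = c(60L, 95L),
    intergenic_gap = 3000L,
    skip_frac = 0.30, alt5_frac = 0.08, alt3_frac = 0.08,
    alt_shift = 12L, overlap_gene_frac = 0.08,
    u12_frac = 0.07,
    silent_frac = 0.05,
    background_lambda = 2,
    intermediate_rate = 20,
    peak_prob_high = 0.9, peak_prob_low = 0.15, psi_high = 0.9,
    pause_prob = 0.3, pause_height = 30,
    footprint = list(
      short = list(modes = c(27, 60), sds = c(4, 8), weights = c(0.9, 0.1),
                   trunc = rbind(c(18, 40), c(40, 100)), select = c(20L, 60L)),
      ## the long gel fraction selects 60-160 nt RNA, but observed aligned
      ## lengths run 40-100 with the 60-nt mode intact: trimming makes the
      ## aligned length shorter than the selected RNA, so the effective
      ## aligned-length window is (40, 160)
      long = list(modes = c(27, 60), sds = c(4, 8), weights = c(0.1, 0.9),
                  trunc = rbind(c(18, 40), c(40, 100)), select = c(40L, 160L))),
    library_mode = "long",
    treatment_scale = 1,
    snrna_classes = c("U1", "U2", "U4", "U5", "U11", "U12", "U3", "U7"),
    snrna_per_class = 2L, snrna_rate = 150, snrna_len = c(120L, 180L),
    npseq_depth = 100L, npseq_low_depth = 4L, npseq_low_depth_frac = 0.05,
    proteomics = list(n_proteins = 2000L, n_enriched = 100L, n_rep = 3L,
                      true_lfc = 2, within_sd = 0.3, base_mean = 25,
                      base_sd = 2, dropout_mid = 22.5, dropout_scale = 1))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown sim_config field: %s", bad[1L])
  cfg[names(over)] <- over
  if (cfg$n_genes < 1L) stopf("config error: n_genes must be >= 1")
  if (with(cfg, exp(exon_meanlog) < min_exon / 4)) {
    stopf("config error: infeasible exon length parameters")
  }
  structure(cfg, class = "sim_config")
}

## sample one integer uniformly from [r[1], r[2]], safe for r[1] == r[2]
sample_range <- function(r) {
  r[1L] + sample.int(r[2L] - r[1L] + 1L, 1L) - 1L
}

rlen <- function(n, meanlog, sdlog, minimum) {
  pmax(as.integer(round(stats::rlnorm(n, meanlog, sdlog))), minimum)
}

## truncated-normal draws via inverse CDF
rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

draw_footprints <- function(n, fp) {
  if (n == 0L) return(integer())
  comp <- sample.int(2L, n, replace = TRUE, prob = fp$weights)
  as.integer(round(rtnorm(n, fp$modes[comp], fp$sds[comp],
                          fp$trunc[comp, 1L], fp$trunc[comp, 2L])))
}

#' Generate a synthetic genome annotation with planted truth
#'
#' See [sim_config()] for the gene-structure model. The returned truth tables
#' carry, per exon with an upstream junction: the planted spliced/inclusion
#' fraction `psi_true`, whether intermediates are emitted (`has_peak`,
#' drawn with probability `peak_prob_high` for high-inclusion exons and
#' `peak_prob_low` otherwise) and the intermediate Poisson rate; per gene:
#' background rate, pause position/height and expression status; plus the
#' snRNA gene table and the U12 intron list.
#'
#' @param config a [sim_config()].
#' @return list with `ann` (classified, U12-labelled, expression-flagged
#'   `genome_annotation`), `truth` (list of data.tables: genes, exons,
#'   snrna), `u12_bed` (data.table), and `fpkm` (bimodal transcript table
#'   for the expression-threshold stage).
#' @export
make_genome <- function(config = sim_config()) {
  set.seed(derive_seed(config$seed, "genome"))
  rows <- vector("list", config$n_genes)
  gtruth <- vector("list", config$n_genes)
  cursor <- 10000L
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("G%04d", g)
    strand <- if (g %% 2L == 1L) "+" else "-"
    n_ex <- sample_range(config$n_exons_range)
    ## lengths in transcription order
    ex_len <- integer(n_ex)
    ex_len[1L] <- max(config$min_first_exon,
                      as.integer(round(stats::rlnorm(1, config$first_exon_meanlog,
                                                     config$first_exon_sdlog))))
    for (k in 2:n_ex) {
      ex_len[k] <- if (stats::runif(1) < config$short_exon_frac) {
        sample_range(config$short_exon_range)
      } else rlen(1L, config$exon_meanlog, config$exon_sdlog, config$min_exon)
    }
    in_len <- integer(n_ex - 1L)
    for (k in seq_len(n_ex - 1L)) {
      in_len[k] <- if (stats::runif(1) < config$short_intron_frac) {
        sample_range(config$short_intron_range)
      } else rlen(1L, config$intron_meanlog, config$intron_sdlog, config$min_intron)
    }
    ## genomic layout left to right; '-' genes transcribe right to left
    lay_ex <- if (strand == "+") ex_len else rev(ex_len)
    lay_in <- if (strand == "+") in_len else rev(in_len)
    starts <- cursor + c(0L, cumsum(lay_ex[-n_ex] + lay_in))
    ends <- starts + lay_ex
    cursor <- ends[n_ex] + config$intergenic_gap

    tx1 <- data.table(gene_id = gid, transcript_id = paste0(gid, ".1"),
                      chrom = config$chrom, strand = strand,
                      start = starts, end = ends)
    iso <- list(tx1)
    ## at most one alternative-structure isoform per gene
    u <- stats::runif(1)
    internal_idx <- if (n_ex > 2L) seq(2L, n_ex - 1L) else integer()
    ## genomic index of a transcription-internal exon
    if (length(internal_idx)) {
      pick <- sample(internal_idx, 1L)
      pick_g <- if (strand == "+") pick else n_ex - pick + 1L
      if (u < config$skip_frac) {
        iso[[2L]] <- tx1[-pick_g][, transcript_id := paste0(gid, ".2")]
      } else if (u < config$skip_frac + config$alt5_frac) {
        tx2 <- copy(tx1)[, transcript_id := paste0(gid, ".2")]
        if (strand == "+") tx2[pick_g, end := end - config$alt_shift]
        else tx2[pick_g, start := start + config$alt_shift]
        iso[[2L]] <- tx2
      } else if (u < config$skip_frac + config$alt5_frac + config$alt3_frac) {
        tx2 <- copy(tx1)[, transcript_id := paste0(gid, ".2")]
        if (strand == "+") tx2[pick_g, start := start + config$alt_shift]
        else tx2[pick_g, end := end - config$alt_shift]
        iso[[2L]] <- tx2
      }
    }
    rows[[g]] <- rbindlist(iso)
    gtruth[[g]] <- data.table(
      gene_id = gid, strand = strand, psi_true = stats::runif(1),
      background_lambda = config$background_lambda,
      silent = stats::runif(1) < config$silent_frac,
      pause = stats::runif(1) < config$pause_prob)
    ## nested same-strand single-exon gene overlapping an internal exon:
    ## plants the PSI "overlap" exclusion (alt flags are same-gene only)
    if (length(internal_idx) && stats::runif(1) < config$overlap_gene_frac) {
      ov_pick <- sample(internal_idx, 1L)
      ov_g <- if (strand == "+") ov_pick else n_ex - ov_pick + 1L
      ngid <- paste0(gid, "N")
      rows[[g]] <- rbind(rows[[g]], data.table(
        gene_id = ngid, transcript_id = paste0(ngid, ".1"),
        chrom = config$chrom, strand = strand,
        start = starts[ov_g] + 15L, end = ends[ov_g] + 15L))
      gtruth[[g]] <- rbind(gtruth[[g]], data.table(
        gene_id = ngid, strand = strand, psi_true = stats::runif(1),
        background_lambda = config$background_lambda,
        silent = FALSE, pause = FALSE))
    }
  }
  exons <- rbindlist(rows)
  genes_truth <- rbindlist(gtruth)

  ## snRNA-like single-exon genes appended downstream of the coding block
  n_sn <- length(config$snrna_classes) * config$snrna_per_class
  sn_len <- sample(seq(config$snrna_len[1L], config$snrna_len[2L]), n_sn,
                   replace = TRUE)
  sn_start <- cursor + cumsum(rep(1000L, n_sn)) +
    c(0L, cumsum(sn_len[-n_sn]))
  snrna <- data.table(
    gene_id = sprintf("SN%02d", seq_len(n_sn)),
    class = rep(config$snrna_classes, each = config$snrna_per_class),
    chrom = config$chrom,
    strand = rep_len(c("+", "-"), n_sn),
    start = sn_start, end = sn_start + sn_len,
    rate = config$snrna_rate)
  sn_exons <- snrna[, .(gene_id, transcript_id = paste0(gene_id, ".1"),
                        chrom, strand, start, end)]
  ann <- build_annotation(rbind(exons, sn_exons))
  ann <- classify_exons(ann)

  ## U12 labels on primary-isoform introns
  prim <- ann$introns[grepl("\\.1$", transcript_id)]
  u12_idx <- which(stats::runif(nrow(prim)) < config$u12_frac)
  u12_bed <- prim[u12_idx, .(chrom, start, end, name = "u12_intron",
                             score = 0L, strand)]
  ann <- label_u12_introns(ann, u12_bed[, .(chrom, start, end, strand)])

  ## per-exon truth: primary-isoform exons with an upstream junction
  ex1 <- ann$exons[grepl("\\.1$", transcript_id) & !grepl("^SN", gene_id) &
                     ordinal > 0L]
  etr <- ex1[, .(gene_id, transcript_id, chrom, strand, start, end, ordinal)]
  etr <- genes_truth[, .(gene_id, psi_true, silent)][etr, on = "gene_id"]
  p_peak <- ifelse(etr$psi_true > config$psi_high, config$peak_prob_high,
                   config$peak_prob_low)
  ## exons the caller excludes by design (isoform overlap) never carry truth
  ## peaks, so sensitivity is measured on callable exons only
  ovflag <- ann$exons[etr, on = c("transcript_id", "ordinal"),
                      get("overlaps_other_exon")]
  etr[, has_peak := stats::rbinom(.N, 1L, p_peak) == 1L & !silent &
        !ovflag]
  etr[, intermediate_rate := config$intermediate_rate]
  etr[, terminal := terminal_pos(start, end, strand)]

  ## pause positions inside a random exon, away from the trimmed terminus
  gpause <- genes_truth[get("pause") == TRUE & !get("silent")]
  pause_tbl <- NULL
  if (nrow(gpause)) {
    cand <- ann$exons[grepl("\\.1$", transcript_id) &
                        gene_id %in% gpause$gene_id & end - start > 20L]
    cand <- cand[, .SD[sample(.N, 1L)], by = gene_id]
    off <- vapply(cand$end - cand$start - 10L, function(m) sample(m, 1L), 1L)
    pause_tbl <- cand[, .(gene_id, chrom, strand,
                          pos = ifelse(strand == "+", start + 3L + off,
                                       end - 4L - off),
                          height = config$pause_height)]
  } else {
    pause_tbl <- data.table(gene_id = character(), chrom = character(),
                            strand = character(), pos = integer(),
                            height = numeric())
  }

  ## bimodal FPKM table: silent genes in the low mode
  tx <- ann$transcripts[!grepl("^SN", gene_id)]
  silent_ids <- genes_truth[get("silent") == TRUE, gene_id]
  lo <- tx$gene_id %in% silent_ids
  fpkm <- data.table(
    transcript_id = tx$transcript_id,
    fpkm = 2^stats::rnorm(nrow(tx), mean = ifelse(lo, -5, 5), sd = 1))

  ann <- set_expressed(ann, unique(c(tx$gene_id[!lo], snrna$gene_id)))
  list(ann = ann,
       truth = list(genes = genes_truth, exons = etr, snrna = snrna,
                    pause = pause_tbl, config = config),
       u12_bed = u12_bed, fpkm = fpkm)
}

#' Simulate mNET-seq alignments with planted 3'-end structure
#'
#' Emits, as already-aligned reads: (a) background nascent reads whose 3'-end
#' counts are i.i.d. Poisson per transcribed nucleotide across each
#' non-silent gene span, with contiguous bodies clipped at the gene 5' end;
#' (b) splicing-intermediate reads ending exactly on exon 3'-terminal bases
#' (count Poisson(`intermediate_rate`), thinned by `treatment_scale` via
#' binomial thinning of a shared base stream), each spliced across the
#' upstream junction with probability `psi_true` (blocked body with >= 9 nt
#' overhangs) or contiguous into the upstream intron, and contained in the
#' exon (ambiguous by design) whenever the drawn footprint is shorter than
#' the exon; (c) snRNA 3'-end spikes, treatment-thinned like intermediates;
#' (d) pause spikes at planted positions. Footprint lengths come from the
#' `library_mode` mixture and the gel size selection is applied last.
#'
#' @param genome output of [make_genome()].
#' @param config a [sim_config()]; defaults to the genome's own.
#' @param library_mode `"short"` or `"long"`.
#' @param treatment_scale overrides the config (e.g. 0.2 for a detergent
#'   run paired with an untreated run at 1).
#' @param size_select apply the library size selection (default TRUE).
#' @return a `net_reads` table with an extra `source` column
#'   (background/intermediate/snrna/pause).
#' @export
simulate_mnetseq <- function(genome, config = genome$truth$config,
                             library_mode = config$library_mode,
                             treatment_scale = config$treatment_scale,
                             size_select = TRUE, seed = config$seed) {
  fp <- config$footprint[[library_mode]]
  ann <- genome$ann
  truth <- genome$truth
  parts <- list()

  ## (a) background over non-silent gene spans
  set.seed(derive_seed(seed, "background"))
  g <- truth$genes[get("silent") == FALSE]
  gg <- ann$genes[g$gene_id, on = "gene_id", nomatch = NULL]
  if (nrow(gg)) {
    spans <- gg[, .(gene_id, chrom, strand, start, end,
                    len = end - start)]
    lam <- g$background_lambda[match(spans$gene_id, g$gene_id)]
    cnt <- lapply(seq_len(nrow(spans)), function(i) {
      k <- stats::rpois(spans$len[i], lam[i])
      w <- which(k > 0L)
      if (!length(w)) return(NULL)
      data.table(chrom = spans$chrom[i], strand = spans$strand[i],
                 pos = rep(spans$start[i] + w - 1L, k[w]),
                 gstart = spans$start[i], gend = spans$end[i])
    })
    bg <- rbindlist(cnt)
    if (nrow(bg)) {
      bg[, source := "background"]
      parts$bg <- bg
    }
  }

  ## (d) pause spikes, bodies like background
  set.seed(derive_seed(seed, "pause"))
  if (nrow(truth$pause)) {
    ph <- truth$pause[, .(chrom, strand, pos, n = stats::rpois(.N, get("height"))),
                      by = gene_id]
    ph <- ph[n > 0L]
    if (nrow(ph)) {
      ph <- ann$genes[, .(gene_id, gstart = start, gend = end)][ph, on = "gene_id"]
      ps <- ph[rep(seq_len(.N), n), .(chrom, strand, pos, gstart, gend)]
      ps[, source := "pause"]
      parts$ps <- ps
    }
  }

  ## (c) snRNA spikes: base counts from a treatment-independent stream
  set.seed(derive_seed(seed, "snrna_counts"))
  sn <- copy(truth$snrna)
  sn[, n0 := stats::rpois(.N, get("rate"))]

  ## (b) intermediate base counts, same principle
  set.seed(derive_seed(seed, "intermediate_counts"))
  et <- copy(truth$exons)
  et[, n0 := ifelse(has_peak, stats::rpois(.N, intermediate_rate), 0L)]

  ## binomial thinning on a separate stream (common random numbers across
  ## treatment scales by construction of the base counts)
  set.seed(derive_seed(seed, "treatment"))
  sn[, n := if (treatment_scale < 1) stats::rbinom(.N, get("n0"), treatment_scale)
            else get("n0")]
  et[, n := if (treatment_scale < 1) stats::rbinom(.N, get("n0"), treatment_scale)
            else get("n0")]

  if (nrow(sn[n > 0L])) {
    snr <- sn[n > 0L][rep(seq_len(sum(n > 0L)), n[n > 0L]),
                      .(chrom, strand, pos = terminal_pos(start, end, strand),
                        gstart = start, gend = end)]
    snr[, source := "snrna"]
    parts$sn <- snr
  }

  ## single-block sources: draw lengths per source on separate substreams so
  ## treatment thinning of one source never perturbs another (common random
  ## numbers across paired runs)
  single <- rbindlist(parts, use.names = TRUE)
  reads1 <- NULL
  if (!is.null(single) && nrow(single)) {
    L <- integer(nrow(single))
    for (src in unique(single$source)) {
      set.seed(derive_seed(seed, paste0("lengths_", src)))
      idx <- which(single$source == src)
      L[idx] <- draw_footprints(length(idx), fp)
    }
    reads1 <- single[, .(chrom, strand, source,
      start = ifelse(strand == "+", pmax(gstart, pos - L + 1L), pos),
      end = ifelse(strand == "+", pos + 1L, pmin(gend, pos + L)))]
    reads1[, `:=`(nblocks = 1L, bsizes = as.character(end - start),
                  bstarts = "0", aligned_length = end - start)]
  }

  ## intermediate read bodies
  set.seed(derive_seed(seed, "intermediate_bodies"))
  reads2 <- NULL
  ei <- et[n > 0L]
  if (nrow(ei)) {
    ## upstream exon of the primary isoform, for spliced bodies
    upx <- ann$exons[, .(transcript_id, ordinal = ordinal + 1L,
                         upxs = start, upxe = end)]
    ei <- upx[ei, on = c("transcript_id", "ordinal"), nomatch = NULL]
    ei <- ei[rep(seq_len(.N), n)]
    m <- nrow(ei)
    L <- draw_footprints(m, fp)
    spliced <- stats::runif(m) < ei$psi_true
    exlen <- ei$end - ei$start
    ext <- L - exlen
    uplen <- ei$upxe - ei$upxs
    gs <- ann$genes[ei$gene_id, on = "gene_id", start]
    ge <- ann$genes[ei$gene_id, on = "gene_id", end]

    contained <- ext <= 0L
    spl <- spliced & !contained
    unspl <- !spliced & !contained
    ext_spl <- pmin(pmax(ext, 9L), uplen)  # guaranteed overhang, bounded
    plus <- ei$strand == "+"

    b_start <- b_end <- nb <- integer(m)
    alen <- integer(m)
    bsz <- bst <- character(m)
    ## contained: last L nt of the exon (transcription direction)
    i <- contained
    b_start[i] <- ifelse(plus[i], ei$end[i] - L[i], ei$start[i])
    b_end[i] <- ifelse(plus[i], ei$end[i], ei$start[i] + L[i])
    nb[i] <- 1L
    ## unspliced: contiguous past the exon 5' boundary into the upstream
    ## intron (clipped at gene ends)
    i <- unspl
    b_start[i] <- ifelse(plus[i], pmax(gs[i], ei$start[i] - ext[i]), ei$start[i])
    b_end[i] <- ifelse(plus[i], ei$end[i], pmin(ge[i], ei$end[i] + ext[i]))
    nb[i] <- 1L
    i <- nb == 1L
    bsz[i] <- as.character(b_end[i] - b_start[i])
    bst[i] <- "0"
    alen[i] <- b_end[i] - b_start[i]
    ## spliced: tail of the upstream exon joined to the full exon.
    ## '+': blocks [upxe-ext, upxe) + [es, ee); '-': [es, ee) + [upxs, upxs+ext)
    i <- spl
    if (any(i)) {
      b_start[i] <- ifelse(plus[i], ei$upxe[i] - ext_spl[i], ei$start[i])
      b_end[i] <- ifelse(plus[i], ei$end[i], ei$upxs[i] + ext_spl[i])
      sz1 <- ifelse(plus[i], ext_spl[i], exlen[i])
      sz2 <- ifelse(plus[i], exlen[i], ext_spl[i])
      blk2 <- ifelse(plus[i], ei$start[i], ei$upxs[i])
      nb[i] <- 2L
      bsz[i] <- paste(sz1, sz2, sep = ",")
      bst[i] <- paste(0L, blk2 - b_start[i], sep = ",")
      alen[i] <- sz1 + sz2
    }
    reads2 <- ei[, .(chrom, strand)]
    reads2[, `:=`(start = b_start, end = b_end, nblocks = nb,
                  bsizes = bsz, bstarts = bst, source = "intermediate",
                  aligned_length = alen)]
  }

  reads <- rbindlist(list(reads1, reads2), use.names = TRUE, fill = TRUE)
  if (is.null(reads) || !nrow(reads)) {
    out <- net_reads(character(), character(), blocks = list())
    out[, source := character()]
    return(out[])
  }
  if (size_select) {
    reads <- reads[aligned_length >= fp$select[1L] &
                     aligned_length <= fp$select[2L]]
  }
  reads[, `:=`(read_id = sprintf("%s_%07d", substr(source, 1L, 2L), seq_len(.N)),
               nm = 0L, unique_map = TRUE)]
  setcolorder(reads, c("read_id", "chrom", "strand", "start", "end", "nblocks",
                       "bsizes", "bstarts", "nm", "unique_map",
                       "aligned_length", "source"))
  reads[]
}

#' Simulate nucleoplasmic RNA-seq junction counts
#'
#' One coherent count per junction: each inclusion junction (primary-isoform
#' intron) gets reads ~ Binomial(depth, psi_true of its gene) and each
#' internal exon contributes a skip junction (spanning the exon and both
#' flanking introns) with reads ~ Binomial(depth, 1 - psi_true). This is the
#' generative model under which the canonical PSI estimator is unbiased. A
#' fraction of genes is sequenced at `npseq_low_depth` to plant low-coverage
#' exclusions.
#'
#' @param genome output of [make_genome()].
#' @param depth junction read depth per gene (default from config).
#' @param seed seed (default: derived from the config seed).
#' @return data.table with chrom, strand, start, end, reads.
#' @export
simulate_npseq <- function(genome, depth = NULL, seed = NULL) {
  cfg <- genome$truth$config
  depth <- depth %||% cfg$npseq_depth
  set.seed(derive_seed(seed %||% cfg$seed, "npseq"))
  ann <- genome$ann
  g <- genome$truth$genes
  low <- g$gene_id[stats::runif(nrow(g)) < cfg$npseq_low_depth_frac]
  gdepth <- function(gid) ifelse(gid %in% low, cfg$npseq_low_depth, depth)

  introns <- ann$introns[grepl("\\.1$", transcript_id)]
  introns <- g[, .(gene_id, psi_true)][introns, on = "gene_id"]
  inc <- introns[, .(chrom, strand, start, end,
                     reads = stats::rbinom(.N, gdepth(gene_id), psi_true))]

  up <- ann$introns[, .(transcript_id, ordinal = ordinal + 1L,
                        upstart = start, upend = end)]
  dn <- ann$introns[, .(transcript_id, ordinal, dnstart = start, dnend = end)]
  ex <- ann$exons[grepl("\\.1$", transcript_id) & internal_ == TRUE]
  exu <- dn[up[ex, on = c("transcript_id", "ordinal"), nomatch = NULL],
            on = c("transcript_id", "ordinal"), nomatch = NULL]
  exu <- g[, .(gene_id, psi_true)][exu, on = "gene_id"]
  skp <- exu[, .(chrom, strand,
                 start = pmin(get("upstart"), get("dnstart")),
                 end = pmax(get("upend"), get("dnend")),
                 reads = stats::rbinom(.N, gdepth(gene_id), 1 - psi_true))]
  out <- rbind(inc, skp)[reads > 0L]
  setorder(out, chrom, strand, start)
  out[]
}

#' Simulate a label-free IP-MS intensity matrix
#'
#' log2 intensities are normal around a protein base level, shifted by the
#' planted log2 fold change in the IP group; values drop out missing with a
#' logistic probability increasing as intensity decreases
#' (missing-not-at-random censoring).
#'
#' @param config a [sim_config()] (its `proteomics` sub-list is used).
#' @param seed overrides the config seed.
#' @param null_sim set TRUE to zero all planted fold changes.
#' @return list with `mat` (linear intensities, NA = missing), `groups`
#'   (column labels, IP then mock) and `truth` (protein, true_log2fc).
#' @export
simulate_proteomics <- function(config = sim_config(), seed = NULL,
                                null_sim = FALSE) {
  pc <- config$proteomics
  set.seed(derive_seed(seed %||% config$seed, "proteomics"))
  np <- pc$n_proteins
  lfc <- rep(0, np)
  if (!null_sim && pc$n_enriched > 0L) {
    lfc[sample.int(np, pc$n_enriched)] <- pc$true_lfc
  }
  base <- stats::rnorm(np, pc$base_mean, pc$base_sd)
  groups <- c(rep("IP", pc$n_rep), rep("mock", pc$n_rep))
  mu <- outer(base, rep(1, 2 * pc$n_rep)) +
    outer(lfc, as.numeric(groups == "IP"))
  x <- mu + matrix(stats::rnorm(np * 2L * pc$n_rep, 0, pc$within_sd), np)
  pmiss <- stats::plogis((pc$dropout_mid - x) / pc$dropout_scale)
  miss <- matrix(stats::runif(length(x)) < pmiss, np)
  mat <- 2^x
  mat[miss] <- NA_real_
  rownames(mat) <- sprintf("P%05d", seq_len(np))
  colnames(mat) <- paste0(groups, "_", rep(seq_len(pc$n_rep), 2L))
  list(mat = mat, groups = groups,
       truth = data.table(protein = rownames(mat), true_log2fc = lfc))
}

#' Write a genome annotation as Ensembl-dialect GTF
#'
#' Deterministic field order, so identical annotations serialize
#' byte-identically.
#'
#' @param ann a `genome_annotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  ex <- copy(ann$exons)
  setorder(ex, gene_id, transcript_id, start)
  lines <- sprintf(
    '%s\tnetsplice\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$transcript_id)
  writeLines(lines, path)
  invisible(path)
}
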