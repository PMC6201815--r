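#' Default pipeline run configuration
#'
#' Every numeric threshold defaults to the value the analysis is defined
#' with: peak rule k_sd = 3 / min_reads = 4, spliced-read overhang 9 nt,
#' splicing-event threshold 3 reads, spliced% minimum total 10, PSI junction
#' minimum 5, FDR 0.05, snRNA pad 5 nt.
#'
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param ... overrides, including `inputs` (list of paths: reads, gtf,
#'   u12_bed, fpkm, junctions, intensities) and `sim` (a [sim_config()] used
#'   by the simulate stage).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = "netsplice_out", ...) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir,
    strandness = "reverse",
    k_sd = 3, min_reads = 4L,
    min_overhang = 9L, min_event_reads = 3L, min_total = 10L,
    psi_min_junction_reads = 5L, psi_coverage_rule = "each_inclusion",
    fdr = 0.05, pad_snrna = 5L,
    impute_shift = 1.8, impute_width = 0.3,
    library_total_override = NULL,
    inputs = list(), sim = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown run_config field: %s", bad[1L])
  cfg[names(over)] <- over
  cfg
}

#' Load a run configuration from a JSON file
#'
#' @param path JSON file with `run_config` fields (nested `sim` fields are
#'   passed to [sim_config()]).
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(raw$sim)) {
    sim <- do.call(sim_config, as.list(raw$sim))
    raw$sim <- NULL
  }
  cfg <- do.call(run_config, raw)
  cfg$sim <- sim
  cfg
}

#' Run the analysis pipeline
#'
#' Subcommands: `simulate` (synthetic genome + alignments + junction counts +
#' intensity matrix into the output directory), `coverage` (3'-end tracks,
#' footprint histogram, snRNA counts, RAD tables), `peaks` (5' ss / 3' ss and
#' pause peaks), `splicing` (spliced reads, events, intermediate
#' classification, group comparisons), `psi` (PSI records and peak overlap),
#' `proteomics` (preprocessing + differential enrichment) and `all`. Each
#' stage writes plain-text TSV/BED artifacts and the run manifest
#' (`manifest.json`) records config, seed, package version, input checksums,
#' per-stage record counts and output checksums. Later stages read the
#' artifacts of earlier stages and fail with a named prerequisite when
#' missing.
#'
#' @param subcommand one of simulate, coverage, peaks, splicing, psi,
#'   proteomics, all.
#' @param config a [run_config()].
#' @return invisibly, a list of per-stage summaries (also serialized into the
#'   manifest).
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "coverage", "peaks",
                                        "splicing", "psi", "proteomics"),
                         config = run_config()) {
  subcommand <- match.arg(subcommand)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (subcommand == "all") {
    c("simulate", "coverage", "peaks", "splicing", "psi", "proteomics")
  } else subcommand
  manifest <- list(config = config[setdiff(names(config), "sim")],
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("netsplice")),
                   stages = list())
  summaries <- list()
  for (st in stages) {
    t0 <- Sys.time()
    message(sprintf("[netsplice] stage %s ...", st))
    res <- switch(st,
      simulate = stage_simulate(config),
      coverage = stage_coverage(config),
      peaks = stage_peaks(config),
      splicing = stage_splicing(config),
      psi = stage_psi(config),
      proteomics = stage_proteomics(config))
    res$seconds <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    manifest$stages[[st]] <- res
    summaries[[st]] <- res
    message(sprintf("[netsplice] stage %s done in %.1fs", st, res$seconds))
  }
  outs <- unlist(lapply(manifest$stages, `[[`, "outputs"))
  manifest$output_checksums <- as.list(tools::md5sum(
    file.path(config$out_dir, outs)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(summaries)
}

opath <- function(config, ...) file.path(config$out_dir, ...)

need_input <- function(config, key, default_artifact = NULL) {
  p <- config$inputs[[key]]
  if (is.null(p) && !is.null(default_artifact)) {
    p <- opath(config, default_artifact)
    if (!file.exists(p)) {
      stopf("stage prerequisite unmet: %s not found (run the simulate stage or provide inputs$%s)",
            p, key)
    }
    return(p)
  }
  if (is.null(p) || !file.exists(p)) {
    stopf("missing input: %s (inputs$%s)", p %||% "<unset>", key)
  }
  p
}

load_annotation <- function(config) {
  ann <- parse_annotation(need_input(config, "gtf", "simulated.gtf"))
  ann <- classify_exons(ann)
  u12 <- config$inputs$u12_bed %||% opath(config, "simulated_u12.bed")
  if (file.exists(u12)) ann <- label_u12_introns(ann, u12)
  fp <- config$inputs$fpkm %||% opath(config, "simulated_fpkm.tsv")
  if (file.exists(fp)) {
    tbl <- fread(fp)
    setnames(tbl, 1:2, c("transcript_id", "fpkm"))
    eg <- tryCatch(expressed_genes(tbl, ann),
                   warning = function(w) {
                     message("expression threshold: ", conditionMessage(w))
                     suppressWarnings(expressed_genes(tbl, ann))
                   })
    ann <- set_expressed(ann, eg)
  }
  ann
}

load_reads <- function(config) {
  p <- need_input(config, "reads", "simulated_reads.bed12")
  if (grepl("\\.sam$", p)) read_sam(p, strandness = config$strandness)
  else read_bed12(p, strandness = config$strandness)
}

load_coverage <- function(config) {
  cov <- end_coverage(load_reads(config))
  if (!is.null(config$library_total_override)) {
    cov$library_total <- as.integer(config$library_total_override)
  }
  cov
}

stage_simulate <- function(config) {
  sim <- config$sim %||% sim_config(seed = config$seed)
  genome <- make_genome(sim)
  reads <- simulate_mnetseq(genome)
  write_gtf(genome$ann, opath(config, "simulated.gtf"))
  write_bed12(reads, opath(config, "simulated_reads.bed12"),
              strandness = config$strandness)
  write_sam(reads, opath(config, "simulated_reads.sam"),
            strandness = config$strandness)
  fwrite(genome$u12_bed, opath(config, "simulated_u12.bed"), sep = "\t",
         col.names = FALSE)
  fwrite(genome$fpkm, opath(config, "simulated_fpkm.tsv"), sep = "\t")
  fwrite(simulate_npseq(genome), opath(config, "simulated_junctions.tsv"),
         sep = "\t")
  prot <- simulate_proteomics(sim)
  mt <- data.table(protein = rownames(prot$mat))
  mt <- cbind(mt, as.data.table(prot$mat))
  fwrite(mt, opath(config, "simulated_intensities.tsv"), sep = "\t")
  fwrite(data.table(sample = colnames(prot$mat), group = prot$groups),
         opath(config, "simulated_groups.tsv"), sep = "\t")
  fwrite(genome$truth$exons, opath(config, "truth_exons.tsv"), sep = "\t")
  fwrite(genome$truth$genes, opath(config, "truth_genes.tsv"), sep = "\t")
  fwrite(genome$truth$snrna, opath(config, "truth_snrna.tsv"), sep = "\t")
  list(n_genes = nrow(genome$ann$genes), n_reads = nrow(reads),
       outputs = c("simulated.gtf", "simulated_reads.bed12",
                   "simulated_reads.sam", "simulated_u12.bed",
                   "simulated_fpkm.tsv", "simulated_junctions.tsv",
                   "simulated_intensities.tsv", "simulated_groups.tsv",
                   "truth_exons.tsv", "truth_genes.tsv", "truth_snrna.tsv"))
}

stage_coverage <- function(config) {
  ann <- load_annotation(config)
  reads <- load_reads(config)
  cov <- end_coverage(reads)
  write_bedgraph(cov, opath(config, "end_coverage"))
  hist <- read_length_histogram(reads, ann)
  fwrite(hist$table, opath(config, "footprint_histogram.tsv"), sep = "\t")
  rad_ex <- read_average_density(cov, ann, "exon")
  rad_in <- read_average_density(cov, ann, "intron")
  fwrite(rad_ex, opath(config, "rad_exons.tsv"), sep = "\t")
  fwrite(rad_in, opath(config, "rad_introns.tsv"), sep = "\t")
  fwrite(annotation_summary(ann), opath(config, "annotation_summary.tsv"),
         sep = "\t")
  sn_path <- config$inputs$snrna %||% opath(config, "truth_snrna.tsv")
  outs <- c("end_coverage.plus.bedgraph", "end_coverage.minus.bedgraph",
            "footprint_histogram.tsv", "rad_exons.tsv", "rad_introns.tsv",
            "annotation_summary.tsv")
  n_snrna <- 0L
  if (file.exists(sn_path)) {
    sn <- fread(sn_path)
    snc <- count_snrna(cov, sn, pad = config$pad_snrna)
    fwrite(snc, opath(config, "snrna_rpm.tsv"), sep = "\t")
    outs <- c(outs, "snrna_rpm.tsv")
    n_snrna <- nrow(snc)
  }
  list(n_positions = nrow(cov$counts), library_total = cov$library_total,
       modal_footprint = hist$modal_length, n_rad_exons = nrow(rad_ex),
       n_snrna_classes = n_snrna, outputs = outs)
}

stage_peaks <- function(config) {
  ann <- load_annotation(config)
  cov <- load_coverage(config)
  params <- peak_params(k_sd = config$k_sd, min_reads = config$min_reads)
  ss <- call_ss_peaks(cov, ann, params)
  pause <- call_pause_peaks(cov, ann, params)
  fwrite(ss, opath(config, "ss_peaks.tsv"), sep = "\t")
  fwrite(pause, opath(config, "pause_peaks.tsv"), sep = "\t")
  write_peaks_bed(ss, opath(config, "ss_peaks.bed"))
  write_peaks_bed(pause, opath(config, "pause_peaks.bed"))
  list(n_five_prime_ss = sum(ss$kind == "five_prime_ss"),
       n_three_prime_ss = sum(ss$kind == "three_prime_ss"),
       n_pause = nrow(pause),
       outputs = c("ss_peaks.tsv", "pause_peaks.tsv", "ss_peaks.bed",
                   "pause_peaks.bed"))
}

stage_splicing <- function(config) {
  ann <- load_annotation(config)
  reads <- load_reads(config)
  spliced <- find_spliced_reads(reads, ann, min_overhang = config$min_overhang)
  events <- call_splicing_events(spliced, min_reads = config$min_event_reads)
  recs <- classify_intermediates(reads, ann, min_total = config$min_total,
                                 min_overhang = config$min_overhang)
  fwrite(events, opath(config, "splicing_events.tsv"), sep = "\t")
  fwrite(recs, opath(config, "intermediate_records.tsv"), sep = "\t")
  cmp <- compare_groups(recs, ann, "constitutive_vs_skipped")
  fwrite(data.table(comparison = "constitutive_vs_skipped",
                    location_p = cmp$location_p, ks_p = cmp$ks_p,
                    ks_stat = cmp$ks_stat),
         opath(config, "group_comparison.tsv"), sep = "\t")
  list(n_spliced_reads = uniqueN(spliced$read_id),
       n_events_passing = sum(events$passes),
       n_intermediate_exons = nrow(recs),
       n_defined_spliced_pct = sum(!is.na(recs$spliced_pct)),
       outputs = c("splicing_events.tsv", "intermediate_records.tsv",
                   "group_comparison.tsv"))
}

stage_psi <- function(config) {
  ann <- load_annotation(config)
  jc <- fread(need_input(config, "junctions", "simulated_junctions.tsv"))
  psi <- compute_psi(jc, ann,
                     min_junction_reads = config$psi_min_junction_reads,
                     coverage_rule = config$psi_coverage_rule)
  fwrite(psi, opath(config, "psi_records.tsv"), sep = "\t")
  peaks_path <- opath(config, "ss_peaks.tsv")
  if (!file.exists(peaks_path)) {
    stopf("stage prerequisite unmet: %s (run the peaks stage first)", peaks_path)
  }
  peaks <- fread(peaks_path)
  ovl <- peak_psi_overlap(peaks, psi)
  fwrite(ovl$table, opath(config, "peak_psi_overlap.tsv"), sep = "\t")
  list(n_eligible = sum(psi$eligible),
       frac_high_psi_with_peak = ovl$frac_high_psi_with_peak,
       frac_peak_exons_high_psi = ovl$frac_peak_exons_high_psi,
       outputs = c("psi_records.tsv", "peak_psi_overlap.tsv"))
}

stage_proteomics <- function(config) {
  mat <- read_intensity_tsv(need_input(config, "intensities",
                                       "simulated_intensities.tsv"))
  gp <- config$inputs$groups %||% opath(config, "simulated_groups.tsv")
  if (!file.exists(gp)) stopf("missing input: %s (inputs$groups)", gp)
  groups <- fread(gp)$group
  pre <- preprocess_intensities(mat, shift = config$impute_shift,
                                width = config$impute_width,
                                seed = derive_seed(config$seed, "impute"))
  res <- differential_enrichment(pre$mat, groups, ip = "IP", mock = "mock",
                                 fdr = config$fdr)
  fwrite(res, opath(config, "enrichment_results.tsv"), sep = "\t")
  fwrite(volcano_table(res), opath(config, "volcano.tsv"), sep = "\t")
  list(n_proteins = nrow(res), n_enriched = sum(res$enriched),
       outputs = c("enrichment_results.tsv", "volcano.tsv"))
}
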