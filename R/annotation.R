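#' Parse an Ensembl-dialect GTF into a genome annotation
#'
#' Reads exon records, groups them into transcripts and genes, orders exons in
#' transcription direction and derives introns as the gaps between consecutive
#' exons. GTF coordinates (1-based, closed) are converted to the internal
#' 0-based half-open convention at this single point; BED input/output keeps
#' its native convention.
#'
#' @param gtf_path path to a GTF file with `exon` features carrying `gene_id`
#'   and `transcript_id` attributes.
#' @return a `genome_annotation` object: a list with data.tables `genes`,
#'   `transcripts`, `exons` and `introns`. Exon classification flags are unset
#'   until [classify_exons()] is called; introns default to U2 until
#'   [label_u12_introns()].
#' @seealso [classify_exons()], [label_u12_introns()], [expressed_genes()]
#' @export
parse_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) stopf("GTF file not found: %s", gtf_path)
  raw <- readLines(gtf_path)
  keep <- !startsWith(raw, "#") & nzchar(raw)
  lineno <- which(keep)
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stopf("malformed GTF line %d: expected 9 tab-separated fields, got %d",
          lineno[which(nf != 9L)[1L]], nf[nf != 9L][1L])
  }
  m <- do.call(rbind, fields)
  is_exon <- m[, 3L] == "exon"
  if (!any(is_exon)) stopf("GTF contains no exon features: %s", gtf_path)
  m <- m[is_exon, , drop = FALSE]
  lineno <- lineno[is_exon]

  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(start1) | is.na(end1) | start1 > end1)
  if (length(bad)) {
    stopf("malformed GTF line %d: invalid coordinates '%s'..'%s'",
          lineno[bad[1L]], m[bad[1L], 4L], m[bad[1L], 5L])
  }
  bad <- which(!m[, 7L] %in% c("+", "-"))
  if (length(bad)) {
    stopf("malformed GTF line %d: strand must be '+' or '-', got '%s'",
          lineno[bad[1L]], m[bad[1L], 7L])
  }
  gid <- attr_value(m[, 9L], "gene_id")
  tid <- attr_value(m[, 9L], "transcript_id")
  bad <- which(is.na(gid) | is.na(tid))
  if (length(bad)) {
    stopf("malformed GTF line %d: missing gene_id/transcript_id attribute",
          lineno[bad[1L]])
  }

  exons <- data.table(
    gene_id = gid, transcript_id = tid, chrom = m[, 1L], strand = m[, 7L],
    start = start1 - 1L, end = end1  # 0-based half-open
  )
  build_annotation(exons)
}

attr_value <- function(attrs, name) {
  pat <- paste0(name, "[ =]+\"?([^\";]+)\"?")
  mm <- regmatches(attrs, regexec(pat, attrs))
  vapply(mm, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
}

## Assemble a genome_annotation from an exon table (internal coordinates).
## Shared by the GTF parser and the synthetic-genome generator.
build_annotation <- function(exons) {
  exons <- as.data.table(exons)[
    , .(gene_id, transcript_id, chrom, strand, start, end)]

  chk <- exons[, .(nc = uniqueN(chrom), ns = uniqueN(strand)), by = gene_id]
  if (any(chk$nc > 1L | chk$ns > 1L)) {
    stopf("validation error: gene %s has transcripts on multiple chromosomes or strands",
          chk[nc > 1L | ns > 1L, gene_id][1L])
  }

  setorder(exons, transcript_id, start)
  ## transcription-order ordinal (0-based); on '-' the rightmost exon is 0
  exons[, n_exons := .N, by = transcript_id]
  exons[, ordinal := ifelse(strand == "+", seq_len(.N) - 1L, .N - seq_len(.N)),
        by = transcript_id]
  bad <- exons[, any(start[-1L] < end[-.N]), by = transcript_id][V1 == TRUE]
  if (nrow(bad)) {
    stopf("validation error: transcript %s has overlapping or abutting-disordered exons",
          bad$transcript_id[1L])
  }
  exons[, `:=`(first_ = ordinal == 0L, last_ = ordinal == n_exons - 1L)]
  exons[, internal_ := !first_ & !last_]
  exons[, `:=`(constitutive = NA, skipped = NA, alt5ss = NA, alt3ss = NA,
               overlaps_other_exon = NA)]

  transcripts <- exons[, .(gene_id = gene_id[1L], chrom = chrom[1L],
                           strand = strand[1L], start = min(start),
                           end = max(end), n_exons = .N),
                       by = transcript_id]
  genes <- transcripts[, .(chrom = chrom[1L], strand = strand[1L],
                           start = min(start), end = max(end), n_tx = .N,
                           is_expressed = NA),
                       by = gene_id]

  ## introns: gaps between genomically consecutive exons of a transcript
  setorder(exons, transcript_id, start)
  introns <- exons[n_exons > 1L,
    .(gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
      start = end[-.N], end = start[-1L]),
    by = transcript_id]
  if (nrow(introns)) {
    if (any(introns$end - introns$start < 1L)) {
      stopf("validation error: derived intron of length < 1")
    }
    setorder(introns, transcript_id, start)
    introns[, n := .N, by = transcript_id]
    introns[, ordinal := ifelse(strand == "+", seq_len(.N) - 1L,
                                .N - seq_len(.N)), by = transcript_id]
    introns[, n := NULL]
  } else {
    introns <- data.table(transcript_id = character(), gene_id = character(),
                          chrom = character(), strand = character(),
                          start = integer(), end = integer(),
                          ordinal = integer())
  }
  introns[, u12 := FALSE]
  introns[, `:=`(donor = head_pos(start, end, strand),
                 acceptor = terminal_pos(start, end, strand))]
  introns[, overlaps_other := NA]

  ann <- structure(
    list(genes = genes, transcripts = transcripts, exons = exons,
         introns = introns),
    class = "genome_annotation")
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "genome_annotation: %d genes, %d transcripts, %d exons, %d introns\n",
    nrow(x$genes), nrow(x$transcripts), nrow(x$exons), nrow(x$introns)))
  if (!all(is.na(x$exons$constitutive))) {
    cat(sprintf("  exon flags: %d constitutive, %d skipped, %d alt5ss, %d alt3ss, %d overlapping\n",
                sum(x$exons$constitutive), sum(x$exons$skipped),
                sum(x$exons$alt5ss), sum(x$exons$alt3ss),
                sum(x$exons$overlaps_other_exon)))
  }
  if (any(x$introns$u12)) {
    cat(sprintf("  U12-type introns: %d\n", sum(x$introns$u12)))
  }
  if (!all(is.na(x$genes$is_expressed))) {
    cat(sprintf("  expressed genes: %d / %d\n",
                sum(x$genes$is_expressed, na.rm = TRUE), nrow(x$genes)))
  }
  invisible(x)
}

#' Classify exons across isoforms
#'
#' Sets the per-exon flags the downstream filters need: `constitutive` (the
#' exon body is present, with identical coordinates, in every isoform of its
#' gene), `skipped` (absent from at least one isoform that contains both of
#' its neighbours), `alt5ss`/`alt3ss` (another isoform of the gene uses a
#' different donor/acceptor boundary for an overlapping exon body) and
#' `overlaps_other_exon` (the exon intersects a non-identical exon of another
#' transcript on the same strand; opposite-strand overlap never counts).
#' Intron eligibility (`overlaps_other`) is computed with the same rule.
#'
#' Flags are invariant to transcript input order, and `constitutive`/`skipped`
#' are mutually exclusive by construction.
#'
#' @param ann a `genome_annotation`.
#' @return the annotation with flags filled in.
#' @export
classify_exons <- function(ann) {
  ex <- copy(ann$exons)
  ex[, exon_key := interval_key(chrom, strand, start, end)]
  ntx <- ann$genes[, .(gene_id, n_tx)]
  ex <- ntx[ex, on = "gene_id"]

  ## constitutive: identical coordinates present in every isoform of the gene
  pres <- unique(ex[, .(gene_id, exon_key, transcript_id)])
  cnt <- pres[, .(n_with = .N), by = .(gene_id, exon_key)]
  ex[cnt, on = c("gene_id", "exon_key"),
     constitutive := get("i.n_with") == n_tx]

  ## skipped: another isoform contains both neighbours but not this exon
  ex[, skipped := FALSE]
  multi <- ex[n_tx > 1L]
  if (nrow(multi)) {
    setorder(multi, transcript_id, ordinal)
    multi[, `:=`(prev_key = shift(exon_key, 1L), next_key = shift(exon_key, -1L)),
          by = transcript_id]
    cand <- multi[internal_ == TRUE & !is.na(prev_key) & !is.na(next_key)]
    if (nrow(cand)) {
      memb <- split(pres$exon_key, pres$transcript_id)
      txs_of_gene <- split(ann$transcripts$transcript_id, ann$transcripts$gene_id)
      skp <- vapply(seq_len(nrow(cand)), function(i) {
        g <- cand$gene_id[i]; t0 <- cand$transcript_id[i]
        others <- setdiff(txs_of_gene[[g]], t0)
        any(vapply(others, function(t2) {
          ks <- memb[[t2]]
          cand$prev_key[i] %in% ks && cand$next_key[i] %in% ks &&
            !(cand$exon_key[i] %in% ks)
        }, NA))
      }, NA)
      ex[cand[which(skp)], on = c("transcript_id", "ordinal"), skipped := TRUE]
    }
  }
  ## a skipped-coordinate exon is skipped in every isoform carrying it
  skp_keys <- unique(ex[skipped == TRUE, .(gene_id, exon_key)])
  if (nrow(skp_keys)) ex[skp_keys, on = c("gene_id", "exon_key"), skipped := TRUE]
  ex[, constitutive := constitutive & !skipped]

  ## alternative splice sites: overlapping exon bodies of the same gene whose
  ## transcription-direction boundaries disagree on one side only
  ex[, `:=`(alt5ss = FALSE, alt3ss = FALSE)]
  ue <- unique(ex[, .(gene_id, chrom, strand, start, end)])
  if (nrow(ue) > 1L) {
    pairs <- merge(ue, ue, by = c("gene_id", "chrom", "strand"),
                   allow.cartesian = TRUE, suffixes = c("", ".o"))
    pairs <- pairs[start < get("end.o") & get("start.o") < end &
                     !(start == get("start.o") & end == get("end.o"))]
    if (nrow(pairs)) {
      pairs[, `:=`(
        don = terminal_pos(start, end, strand),
        acc = head_pos(start, end, strand),
        don_o = terminal_pos(get("start.o"), get("end.o"), strand),
        acc_o = head_pos(get("start.o"), get("end.o"), strand))]
      a5 <- unique(pairs[get("acc") == get("acc_o") & get("don") != get("don_o"),
                         .(gene_id, chrom, strand, start, end)])
      a3 <- unique(pairs[get("don") == get("don_o") & get("acc") != get("acc_o"),
                         .(gene_id, chrom, strand, start, end)])
      if (nrow(a5)) ex[a5, on = names(a5), alt5ss := TRUE]
      if (nrow(a3)) ex[a3, on = names(a3), alt3ss := TRUE]
    }
  }

  ## overlap with a non-identical exon of another transcript, same strand
  ex[, overlaps_other_exon := flag_overlaps(
    ex[, .(chrom, strand, start, end, transcript_id)])]

  setorder(ex, transcript_id, start)
  ann$exons <- ex[, .(gene_id, transcript_id, chrom, strand, start, end,
                      n_exons, ordinal, first_, internal_, last_,
                      constitutive, skipped, alt5ss, alt3ss,
                      overlaps_other_exon, exon_key)]
  ann$introns[, overlaps_other := flag_overlaps(
    ann$introns[, .(chrom, strand, start, end, transcript_id)])]
  ann
}

## TRUE for rows intersecting a non-identical interval of another transcript
## on the same chrom+strand
flag_overlaps <- function(dt) {
  if (!nrow(dt)) return(logical(0))
  x <- copy(dt)[, xid := .I]
  setkey(x, chrom, strand, start, end)
  ov <- foverlaps(x, x, type = "any", which = TRUE)
  ov <- ov[get("xid") != get("yid")]
  if (!nrow(ov)) return(rep(FALSE, nrow(dt)))
  a <- x[ov$xid]  # row positions into keyed x
  b <- x[ov$yid]
  hit <- a$transcript_id != b$transcript_id &
    !(a$start == b$start & a$end == b$end) &
    pmax(a$start, b$start) < pmin(a$end, b$end)  # half-open intersection
  res <- rep(FALSE, nrow(dt))
  res[unique(a$xid[hit])] <- TRUE
  res
}

#' Label U12-type introns from an interval list
#'
#' An intron is labelled U12 iff its interval exactly matches a listed BED
#' interval (same chromosome, strand and both boundaries); everything else
#' stays U2. No build-lifting heuristics are attempted; list entries that
#' match no intron raise a warning.
#'
#' @param ann a `genome_annotation` with derived introns.
#' @param u12_bed path to a BED6 file (0-based half-open) of U12 intron
#'   intervals, or a data.frame with columns chrom, start, end, strand.
#' @return the annotation with `introns$u12` set.
#' @export
label_u12_introns <- function(ann, u12_bed) {
  if (is.character(u12_bed)) {
    if (!file.exists(u12_bed)) stopf("U12 BED file not found: %s", u12_bed)
    info <- file.info(u12_bed)
    if (info$size == 0) {
      bed <- data.table(chrom = character(), start = integer(),
                        end = integer(), strand = character())
    } else {
      bed <- fread(u12_bed, header = FALSE)
      if (ncol(bed) < 6L) stopf("U12 BED must have >= 6 columns (strand in column 6)")
      bed <- bed[, .(chrom = V1, start = V2, end = V3, strand = V6)]
    }
  } else {
    bed <- as.data.table(u12_bed)[, .(chrom, start, end, strand)]
  }
  ann$introns[, u12 := FALSE]
  if (nrow(bed)) {
    bed[, key_ := interval_key(chrom, strand, start, end)]
    ikeys <- interval_key(ann$introns$chrom, ann$introns$strand,
                          ann$introns$start, ann$introns$end)
    ann$introns[, u12 := ikeys %in% bed$key_]
    unmatched <- sum(!bed$key_ %in% ikeys)
    if (unmatched > 0) {
      warnf("%d U12 list entr%s matched no annotated intron",
            unmatched, if (unmatched == 1L) "y" else "ies")
    }
  }
  ann
}

#' Expression threshold from a bimodal log2-FPKM distribution
#'
#' Kernel-density estimate (Silverman bandwidth, 512-point grid) of the
#' log2 FPKM values of transcripts with FPKM > 0; the threshold is the grid
#' position of minimum density between the two highest local maxima. A
#' unimodal density falls back to log2 FPKM = 0 with a warning.
#'
#' @param fpkm numeric vector of transcript FPKM values.
#' @param fallback threshold used when the density has fewer than two local
#'   maxima (default 0, i.e. FPKM = 1).
#' @return a list with `threshold` (log2-FPKM units), `unimodal` flag and the
#'   `density` object, for audit.
#' @export
expression_threshold <- function(fpkm, fallback = 0) {
  x <- log2(fpkm[is.finite(fpkm) & fpkm > 0])
  if (length(x) < 2L) stopf("need >= 2 transcripts with FPKM > 0")
  if (diff(range(x)) == 0) {
    warnf("degenerate log2-FPKM distribution; falling back to threshold %g", fallback)
    return(list(threshold = fallback, unimodal = TRUE, density = NULL))
  }
  d <- stats::density(x, bw = "nrd0", n = 512L)
  y <- d$y
  ismax <- which(diff(sign(diff(y))) == -2L) + 1L
  if (length(ismax) < 2L) {
    warnf("log2-FPKM density is unimodal; falling back to threshold %g", fallback)
    return(list(threshold = fallback, unimodal = TRUE, density = d))
  }
  top2 <- sort(ismax[order(y[ismax], decreasing = TRUE)][1:2])
  valley <- seq(top2[1L], top2[2L])
  thr <- d$x[valley[which.min(y[valley])]]
  list(threshold = thr, unimodal = FALSE, density = d)
}

#' Expressed genes from a transcript FPKM table
#'
#' A gene is expressed iff any of its transcripts has log2 FPKM above the
#' bimodal-valley threshold (see [expression_threshold()]).
#'
#' @param tbl data.frame with columns `transcript_id` and `fpkm`.
#' @param ann a `genome_annotation` (maps transcripts to genes).
#' @param threshold optional fixed threshold in log2-FPKM units; computed from
#'   the table when NULL.
#' @return character vector of expressed gene ids with attribute `threshold`.
#' @export
expressed_genes <- function(tbl, ann, threshold = NULL) {
  tbl <- as.data.table(tbl)
  if (!all(c("transcript_id", "fpkm") %in% names(tbl))) {
    stopf("expression table needs columns transcript_id and fpkm")
  }
  if (is.null(threshold)) {
    threshold <- expression_threshold(tbl$fpkm)$threshold
  }
  tbl <- tbl[is.finite(fpkm) & fpkm > 0][log2(fpkm) > threshold]
  gids <- sort(unique(ann$transcripts[transcript_id %in% tbl$transcript_id, gene_id]))
  structure(gids, threshold = threshold)
}

#' Mark genes as expressed
#'
#' @param ann a `genome_annotation`.
#' @param gene_ids character vector of expressed gene ids (e.g. from
#'   [expressed_genes()]); all other genes are marked not expressed.
#' @return the annotation with `genes$is_expressed` set.
#' @export
set_expressed <- function(ann, gene_ids) {
  ann$genes[, is_expressed := gene_id %in% gene_ids]
  ann
}

## genes considered expressed for feature eligibility: flagged TRUE, or all
## genes when expression was never annotated
expressed_gene_ids <- function(ann) {
  if (all(is.na(ann$genes$is_expressed))) return(ann$genes$gene_id)
  ann$genes[is_expressed == TRUE, gene_id]
}

#' Per-exon annotation summary table
#'
#' One row per exon occurrence with coordinates, ordinal and all
#' classification flags; suitable for TSV export.
#'
#' @param ann a classified `genome_annotation`.
#' @return a data.table.
#' @export
annotation_summary <- function(ann) {
  ann$exons[, .(gene_id, transcript_id, chrom, strand, start, end, ordinal,
                first = first_, internal = internal_, last = last_,
                constitutive, skipped, alt5ss, alt3ss, overlaps_other_exon)]
}
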