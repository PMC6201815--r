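#' Read a protein intensity matrix from TSV
#'
#' First column is the protein id; remaining columns are samples. Empty
#' cells, `NA` and 0 are treated as missing.
#'
#' @param path TSV file.
#' @return numeric matrix (proteins x samples) with NA for missing values.
#' @export
read_intensity_tsv <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  mat <- as.matrix(dt[, -1L, with = FALSE])
  storage.mode(mat) <- "double"
  mat[!is.na(mat) & mat <= 0] <- NA_real_
  rownames(mat) <- as.character(dt[[1L]])
  mat
}

#' Preprocess an intensity matrix: log2, MNAR imputation, median centring
#'
#' Intensities are log2-transformed; missing values in each sample are
#' imputed from a normal distribution downshifted from that sample's observed
#' distribution (mean shifted down by `shift` observed SDs, width `width`
#' observed SDs — the convention of label-free proteomics workflows for
#' missing-not-at-random dropouts); finally each sample is centred so its
#' median is exactly 0. With no missing values, preprocessing is the identity
#' up to the per-sample median shifts.
#'
#' @param mat raw intensity matrix (proteins x samples), NA = missing.
#' @param shift downshift in observed-SD units (default 1.8).
#' @param width imputation width in observed-SD units (default 0.3).
#' @param seed optional seed making imputation reproducible.
#' @return list with `mat` (log2, imputed, median-centred), `imputed`
#'   (logical mask) and `params`.
#' @export
preprocess_intensities <- function(mat, shift = 1.8, width = 0.3,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_obs <- colSums(!is.na(mat))
  if (any(n_obs < 2L)) {
    stopf("sample %s has fewer than 2 observed values",
          colnames(mat)[which(n_obs < 2L)[1L]] %||% which(n_obs < 2L)[1L])
  }
  lg <- log2(mat)
  imputed <- is.na(lg)
  for (j in seq_len(ncol(lg))) {
    obs <- lg[!imputed[, j], j]
    nmiss <- sum(imputed[, j])
    if (nmiss > 0L) {
      lg[imputed[, j], j] <- stats::rnorm(nmiss,
                                          mean = mean(obs) - shift * stats::sd(obs),
                                          sd = width * stats::sd(obs))
    }
  }
  med <- apply(lg, 2L, stats::median)
  lg <- sweep(lg, 2L, med)
  list(mat = lg, imputed = imputed,
       params = list(shift = shift, width = width, median_shifts = med))
}

#' Differential IP enrichment vs mock
#'
#' Per protein, a two-sample t-test (Welch by default) of IP against mock
#' replicates on the preprocessed log2 scale, multiplicity-adjusted across
#' proteins (Benjamini-Hochberg by default, or a permutation-based FDR). A
#' protein is enriched iff q <= `fdr` and its log2 fold change (IP mean -
#' mock mean) is positive. Zero-variance proteins with equal group means get
#' p = 1.
#'
#' @param mat preprocessed log2 matrix (`$mat` from
#'   [preprocess_intensities()]).
#' @param groups character vector of group labels, one per column.
#' @param ip,mock group labels to compare.
#' @param fdr FDR threshold (default 0.05).
#' @param var_equal pooled-variance t-test instead of Welch.
#' @param fdr_method `"BH"` (default) or `"permutation"` (label permutations
#'   of the pooled columns; deterministic given `seed`).
#' @param n_perm permutations when `fdr_method = "permutation"`.
#' @param seed seed for the permutation FDR.
#' @return data.table with protein, lfc (log2 fold change), t, p, q,
#'   enriched.
#' @export
differential_enrichment <- function(mat, groups, ip, mock, fdr = 0.05,
                                    var_equal = FALSE,
                                    fdr_method = c("BH", "permutation"),
                                    n_perm = 250L, seed = 1L) {
  fdr_method <- match.arg(fdr_method)
  a <- mat[, groups == ip, drop = FALSE]
  b <- mat[, groups == mock, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) stopf("need >= 2 replicates per group")
  st <- welch_stats(a, b, var_equal = var_equal)
  p <- st$p
  if (fdr_method == "BH") {
    q <- stats::p.adjust(p, method = "BH")
  } else {
    q <- permutation_fdr(cbind(a, b), ncol(a), abs(st$t),
                         var_equal = var_equal, n_perm = n_perm, seed = seed)
  }
  res <- data.table(
    protein = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    lfc = st$lfc, t = st$t, p = p, q = q)
  res[, enriched := q <= fdr & lfc > 0]
  res[]
}

welch_stats <- function(a, b, var_equal = FALSE) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  lfc <- ma - mb
  if (var_equal) {
    sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2L, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      (va^2 / (na^2 * (na - 1L)) + vb^2 / (nb^2 * (nb - 1L)))
  }
  t <- lfc / se
  p <- 2 * stats::pt(-abs(t), df)
  ## degenerate variance: equal means -> no evidence; unequal -> certainty
  degen <- se == 0
  p[degen & lfc == 0] <- 1
  p[degen & lfc != 0] <- 0
  t[degen] <- ifelse(lfc[degen] == 0, 0, sign(lfc[degen]) * Inf)
  list(lfc = lfc, t = t, p = p)
}

## permutation FDR in the SAM style: for each |t| cutoff, expected number of
## null exceedances over observed exceedances, monotonised and capped at 1
permutation_fdr <- function(pooled, na, tobs, var_equal, n_perm, seed) {
  set.seed(as.integer(seed))
  n <- ncol(pooled)
  null_t <- matrix(NA_real_, nrow(pooled), n_perm)
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n)
    st <- welch_stats(pooled[, idx[seq_len(na)], drop = FALSE],
                      pooled[, idx[-seq_len(na)], drop = FALSE],
                      var_equal = var_equal)
    null_t[, k] <- abs(st$t)
  }
  nullv <- sort(as.vector(null_t))
  m <- length(tobs)
  exp_null <- (length(nullv) - findInterval(tobs, nullv)) / n_perm
  obs <- rank(-tobs, ties.method = "max")
  q <- pmin(exp_null / obs, 1)
  ## enforce monotonicity in t
  ord <- order(tobs, decreasing = TRUE)
  q[ord] <- cummax(q[ord])
  q
}

#' Volcano-plot coordinates
#'
#' @param res output of [differential_enrichment()].
#' @return data.table with protein, lfc, neglog10p, enriched.
#' @export
volcano_table <- function(res) {
  as.data.table(res)[, .(protein, lfc, neglog10p = -log10(pmax(p, 1e-300)),
                         enriched)]
}

#' Pairwise fold-enrichment scatter table
#'
#' Joins two enrichment results (e.g. S5P vs S2P, both against the same mock)
#' by protein for fold-enrichment scatterplots.
#'
#' @param res_a,res_b outputs of [differential_enrichment()].
#' @param labels length-2 axis labels.
#' @return data.table with protein, lfc_<a>, lfc_<b>, enriched_<a>,
#'   enriched_<b>.
#' @export
enrichment_scatter <- function(res_a, res_b, labels = c("a", "b")) {
  a <- as.data.table(res_a)[, .(protein, lfc, enriched)]
  b <- as.data.table(res_b)[, .(protein, lfc, enriched)]
  out <- merge(a, b, by = "protein", suffixes = paste0("_", labels))
  out[]
}
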