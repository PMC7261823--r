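# Differential expression: BH adjustment, PSM-count-aware moderated
# t-test for protein ratios, simplified negative-binomial Wald test for
# mRNA counts, significance calling at the study cutoffs, and
# correlation-distance sample clustering.

# study-wide significance cutoffs: |log2FC| and adjusted p
dea_cutoffs <- function(level) {
  switch(level,
         mrna    = list(lfc = 1.0, padj = 0.01),
         protein = list(lfc = 0.5, padj = 0.01),
         abort("unknown level '%s' (use 'protein' or 'mrna')", level))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of raw p-values. `NA`/`NaN` entries are
#' excluded from the ranking (they do not count towards the number of
#' tests) and propagated unchanged.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, capped at 1, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) abort("p-values must lie in (0, 1]")
  out <- p
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Moderated protein-level differential expression
#'
#' An empirical-Bayes moderated t-test for bridged protein log2 ratios in
#' which the amount of quantification evidence (number of unique PSMs per
#' gene) informs the variance prior: a smooth trend of log residual
#' variance over log2(PSM count) supplies the prior variance, and the
#' prior degrees of freedom are estimated by method of moments on the log
#' residual variances. Genes quantified by many PSMs are thereby shrunk
#' toward a smaller prior variance than single-PSM genes.
#'
#' @param prm A [protein_ratio_matrix()] (bridged and centred).
#' @param groups Named character vector mapping sample column names to
#'   condition labels.
#' @param contrast Character vector `c(test, reference)`; the reported
#'   `log2fc` is mean(test) - mean(reference).
#' @param min_genes_trend Minimum number of genes required to fit the
#'   variance trend; below this the global mean log variance is used.
#' @param prior_df_cap Upper bound for the estimated prior degrees of
#'   freedom (default 100).
#' @return A `DeaResult` data frame: `gene`, `log2fc`, `p_raw`, `p_adj`,
#'   `significant`, `evidence_n` (unique PSM count), `level`, `contrast`.
#' @export
moderated_protein_dea <- function(prm, groups, contrast,
                                  min_genes_trend = 50L,
                                  prior_df_cap = 100) {
  stopifnot(inherits(prm, "ProteinRatioMatrix"), length(contrast) == 2L)
  samples <- colnames(prm$mat)
  if (!all(samples %in% names(groups))) {
    abort("every sample column needs a condition label in `groups`")
  }
  cond <- groups[samples]
  s1 <- samples[cond == contrast[1L]]
  s2 <- samples[cond == contrast[2L]]
  if (length(s1) < 2L || length(s2) < 2L) {
    abort("need >=2 replicates per contrasted condition (got %d vs %d)",
          length(s1), length(s2))
  }
  x1 <- prm$mat[, s1, drop = FALSE]
  x2 <- prm$mat[, s2, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  df_resid <- pmax(n1 - 1L, 0L) + pmax(n2 - 1L, 0L)
  usable <- n1 >= 2L & n2 >= 2L & df_resid > 0L
  if (any(!usable)) {
    warnf("skipping %d gene(s) with zero residual df in contrast %s:%s",
          sum(!usable), contrast[1L], contrast[2L])
  }
  x1 <- x1[usable, , drop = FALSE]; x2 <- x2[usable, , drop = FALSE]
  n1 <- n1[usable]; n2 <- n2[usable]; df_resid <- df_resid[usable]
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  lfc <- m1 - m2
  ssr <- rowSums((x1 - m1)^2, na.rm = TRUE) + rowSums((x2 - m2)^2, na.rm = TRUE)
  s2_g <- ssr / df_resid
  n_psms <- prm$n_psms[rownames(x1)]

  # prior variance from the evidence trend; prior df by method of moments
  logvar <- log(pmax(s2_g, 1e-12))
  lv <- log2(n_psms)
  if (length(s2_g) >= min_genes_trend && length(unique(lv)) >= 3L) {
    lo <- stats::lowess(lv, logvar, f = 0.75)
    log_s0 <- stats::approx(lo$x, lo$y, xout = lv, rule = 2L,
                            ties = mean)$y
  } else {
    log_s0 <- rep(mean(logvar), length(logvar))
  }
  # log residual variances are shifted log chi-square: the trend fits
  # E[log s^2] = log s0^2 + digamma(df/2) - log(df/2), so the prior
  # variance de-biases the trend, and the spread of the residuals beyond
  # trigamma(df/2) reflects true gene-to-gene variance heterogeneity and
  # sets the prior df by method of moments
  e <- logvar - log_s0
  excess <- var(e) - mean(trigamma(df_resid / 2))
  d0 <- if (is.finite(excess) && excess > 0) {
    min(2 * trigamma_inverse(excess), prior_df_cap)
  } else {
    prior_df_cap
  }
  s0_sq <- exp(log_s0 - digamma(df_resid / 2) + log(df_resid / 2))
  s2_post <- (d0 * s0_sq + df_resid * s2_g) / (d0 + df_resid)
  tstat <- lfc / sqrt(s2_post * (1 / n1 + 1 / n2))
  p_raw <- 2 * pt(-abs(tstat), df = df_resid + d0)
  res <- data.frame(gene = rownames(x1), log2fc = lfc, p_raw = p_raw,
                    p_adj = bh_adjust(p_raw), evidence_n = as.numeric(n_psms),
                    level = "protein",
                    contrast = paste(contrast, collapse = ":"),
                    row.names = NULL, stringsAsFactors = FALSE)
  cut <- dea_cutoffs("protein")
  res$significant <- abs(res$log2fc) > cut$lfc & res$p_adj < cut$padj
  res[, c("gene", "log2fc", "p_raw", "p_adj", "significant",
          "evidence_n", "level", "contrast")]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across genes of
#' the ratio of a sample's counts to the geometric-mean pseudo-reference;
#' genes whose geometric mean is zero are excluded.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Named numeric vector of size factors, one per sample.
#' @export
nb_size_factors <- function(counts) {
  log_gm <- rowMeans(log(counts))            # -Inf where any count is 0
  use <- is.finite(log_gm)
  if (!any(use)) abort("no gene has positive counts in all samples")
  sf <- apply(counts[use, , drop = FALSE], 2L, function(cnt) {
    exp(median(log(cnt) - log_gm[use]))
  })
  sf
}

#' Simplified negative-binomial differential expression for counts
#'
#' A stand-in for a full NB GLM analysis, for single-factor two-level
#' contrasts: size factors by median-of-ratios, per-gene NB dispersion by
#' method of moments shrunk 50/50 toward a fitted mean-dispersion trend
#' `alpha(mu) = a0 + a1/mu`, and a Wald test of the condition log2 fold
#' change computed from normalized condition means with a delta-method
#' standard error.
#'
#' @param counts Integer matrix, genes x samples (rownames = genes).
#' @param groups Named character vector mapping sample names to
#'   conditions.
#' @param contrast Character vector `c(test, reference)`.
#' @return A `DeaResult` data frame as in [moderated_protein_dea()], with
#'   `evidence_n` the mean normalized count and `level = "mrna"`.
#' @export
nb_count_dea <- function(counts, groups, contrast) {
  stopifnot(is.matrix(counts), length(contrast) == 2L)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  samples <- colnames(counts)
  if (!all(samples %in% names(groups))) {
    abort("every sample needs a condition label in `groups`")
  }
  all_zero <- rowSums(counts) == 0L
  if (any(all_zero)) {
    log_stage("dea", "excluding %d all-zero gene(s)", sum(all_zero))
    counts <- counts[!all_zero, , drop = FALSE]
  }
  sf <- nb_size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  cond <- groups[samples]
  s1 <- samples[cond == contrast[1L]]
  s2 <- samples[cond == contrast[2L]]
  if (length(s1) < 2L || length(s2) < 2L) {
    abort("need >=2 replicates per contrasted condition")
  }
  k1 <- norm[, s1, drop = FALSE]; k2 <- norm[, s2, drop = FALSE]
  n1 <- length(s1); n2 <- length(s2)
  m1 <- rowMeans(k1); m2 <- rowMeans(k2)
  v1 <- apply(k1, 1L, var); v2 <- apply(k2, 1L, var)

  # method-of-moments dispersion pooled over the two conditions
  mom <- function(m, v) ifelse(m > 0, (v - m) / m^2, 0)
  a_raw <- pmax((mom(m1, v1) * (n1 - 1L) + mom(m2, v2) * (n2 - 1L)) /
                  (n1 + n2 - 2L), 1e-8)
  mu_bar <- (m1 * n1 + m2 * n2) / (n1 + n2)
  # mean-dispersion trend alpha(mu) = a0 + a1/mu, fit on genes with signal
  use <- mu_bar > 0
  a0 <- a1 <- 0
  if (sum(use) >= 10L) {
    tr <- tryCatch(lm(a_raw[use] ~ I(1 / mu_bar[use])), error = function(e) NULL)
    if (!is.null(tr)) {
      a0 <- max(coef(tr)[[1L]], 0)
      a1 <- max(coef(tr)[[2L]], 0)
    }
  }
  a_trend <- pmax(a0 + ifelse(mu_bar > 0, a1 / mu_bar, 0), 1e-8)
  alpha <- 0.5 * a_raw + 0.5 * a_trend

  # Wald test on log2(m1/m2); means floored at half a normalized count
  floor_m <- 0.5
  lfc <- log2(pmax(m1, floor_m) / pmax(m2, floor_m))
  inv_sf <- mean(1 / sf)
  var_mean <- function(m, n) (m + alpha * m^2) * inv_sf / n
  var_log <- function(m, n) ifelse(m > 0, var_mean(m, n) / m^2, Inf)
  se_lfc <- sqrt(var_log(pmax(m1, floor_m), n1) +
                   var_log(pmax(m2, floor_m), n2)) / log(2)
  z <- ifelse(se_lfc > 0, lfc / se_lfc, 0)
  # t reference rather than normal: the plug-in standard error is itself
  # estimated, which makes a normal reference too liberal in the far
  # tail at triplicate sample sizes. The 50/50 shrink toward the
  # (gene-pooled, nearly noise-free) trend reduces the variance of the
  # dispersion estimate four-fold, so the Satterthwaite-style effective
  # df is (n1 + n2 - 2) / 0.5^2.
  p_raw <- 2 * pt(-abs(z), df = 4L * (n1 + n2 - 2L))
  p_raw <- pmax(pmin(p_raw, 1), .Machine$double.xmin)
  res <- data.frame(gene = rownames(counts), log2fc = lfc, p_raw = p_raw,
                    p_adj = bh_adjust(p_raw),
                    evidence_n = (m1 * n1 + m2 * n2) / (n1 + n2),
                    level = "mrna",
                    contrast = paste(contrast, collapse = ":"),
                    row.names = NULL, stringsAsFactors = FALSE)
  cut <- dea_cutoffs("mrna")
  res$significant <- abs(res$log2fc) > cut$lfc & res$p_adj < cut$padj
  res[, c("gene", "log2fc", "p_raw", "p_adj", "significant",
          "evidence_n", "level", "contrast")]
}

#' Apply the study significance cutoffs and summarize direction counts
#'
#' Regulated mRNAs require |log2FC| > 1, regulated proteins |log2FC| >
#' 0.5, both with BH-adjusted p < 0.01.
#'
#' @param dea A `DeaResult` data frame with `log2fc` and `p_adj`.
#' @param level `"protein"` or `"mrna"`.
#' @return List with `results` (flagged table), `n_up` and `n_down`.
#' @export
call_significant <- function(dea, level) {
  cut <- dea_cutoffs(level)
  if (nrow(dea) == 0L) {
    dea$significant <- logical(0)
    return(list(results = dea, n_up = 0L, n_down = 0L))
  }
  assert_columns(dea, c("gene", "log2fc", "p_adj"), "DEA results")
  dea$significant <- abs(dea$log2fc) > cut$lfc & dea$p_adj < cut$padj
  dea$level <- level
  list(results = dea,
       n_up = sum(dea$significant & dea$log2fc > 0, na.rm = TRUE),
       n_down = sum(dea$significant & dea$log2fc < 0, na.rm = TRUE))
}

#' Hierarchical clustering of samples by correlation distance
#'
#' Distance between two samples is one minus the Pearson correlation of
#' their expression columns; samples are merged by average linkage.
#'
#' @param mat Numeric matrix with >= 3 sample columns.
#' @return An [stats::hclust] object.
#' @export
cluster_samples <- function(mat) {
  if (inherits(mat, "ProteinRatioMatrix")) mat <- mat$mat
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 3L) abort("need >= 3 samples to cluster")
  sds <- apply(mat, 2L, function(x) stats::sd(x, na.rm = TRUE))
  if (any(sds == 0 | is.na(sds))) {
    abort("zero-variance column(s): %s",
          paste(colnames(mat)[sds == 0 | is.na(sds)], collapse = ", "))
  }
  d <- as.dist(1 - cor(mat, use = "pairwise.complete.obs"))
  hclust(d, method = "average")
}
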