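# Isobaric (TMT 10-plex) proteome quantification: median sweeping,
# per-protein aggregation, column centering, internal-reference bridging
# and picked target/decoy protein FDR.

#' Construct a protein ratio matrix
#'
#' Container for gene x sample log2 relative abundances together with the
#' number of unique PSMs that supported each gene's quantification.
#'
#' @param mat Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample labels).
#' @param n_psms Named integer vector, one entry per row of `mat`: the
#'   number of unique PSMs aggregated for that gene.
#' @param set_id Optional multiplex-set identifier.
#' @return An object of class `ProteinRatioMatrix`.
#' @export
protein_ratio_matrix <- function(mat, n_psms, set_id = NA_character_) {
  stopifnot(is.matrix(mat), nrow(mat) == length(n_psms))
  if (is.null(rownames(mat))) abort("matrix must carry gene rownames")
  if (is.null(colnames(mat))) abort("matrix must carry sample colnames")
  n_psms <- as.integer(n_psms)
  names(n_psms) <- rownames(mat)
  if (any(n_psms < 1L)) abort("every retained gene needs n_psms >= 1")
  structure(list(mat = mat, n_psms = n_psms, set_id = set_id),
            class = "ProteinRatioMatrix")
}

#' @export
print.ProteinRatioMatrix <- function(x, ...) {
  cat(sprintf("ProteinRatioMatrix: %d genes x %d samples (set %s)\n",
              nrow(x$mat), ncol(x$mat), x$set_id))
  cat("samples:", paste(colnames(x$mat), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ProteinRatioMatrix <- function(x) dim(x$mat)

#' Row-median centre PSM reporter intensities (median sweeping, step 1)
#'
#' Converts each PSM's reporter intensities to log2 ratios by subtracting
#' the PSM's own median log2 intensity across channels, so that every PSM
#' becomes a self-normalized relative profile. PSMs with fewer than two
#' quantified channels carry no relative information and are dropped with
#' a warning.
#'
#' @param psm Data frame with columns `psm_id`, `gene`, `unique`,
#'   `set_id` and the ten reporter columns of [tmt10_channels()].
#'   Missing reporter values are `NA`; present values must be positive.
#' @return The same data frame with reporter columns replaced by
#'   row-centred log2 ratios (row median 0 for every PSM).
#' @export
sweep_psm_ratios <- function(psm) {
  chans <- tmt10_channels()
  assert_columns(psm, c("psm_id", "gene", "unique", "set_id", chans), "PSM table")
  intens <- as.matrix(psm[, chans])
  if (any(intens <= 0, na.rm = TRUE)) {
    abort("reporter intensities must be strictly positive where present")
  }
  n_obs <- rowSums(!is.na(intens))
  drop <- n_obs < 2L
  if (any(drop)) {
    warnf("dropping %d PSM(s) with <2 quantified channels", sum(drop))
    psm <- psm[!drop, , drop = FALSE]
    intens <- intens[!drop, , drop = FALSE]
  }
  lg <- log2(intens)
  med <- apply(lg, 1L, median, na.rm = TRUE)
  psm[, chans] <- lg - med
  psm
}

#' Aggregate PSM ratios to protein (gene) level (median sweeping, step 2)
#'
#' Per gene and channel, takes the median ratio over the PSMs unique to
#' that gene. Shared (non-unique) PSMs are excluded from quantification.
#'
#' @param psm_ratios Output of [sweep_psm_ratios()].
#' @param min_psms Minimum number of unique PSMs for a gene to be
#'   retained (default 1).
#' @return A [protein_ratio_matrix()] whose columns are the reporter
#'   channels of the input set.
#' @export
aggregate_protein_ratios <- function(psm_ratios, min_psms = 1L) {
  chans <- tmt10_channels()
  assert_columns(psm_ratios, c("gene", "unique", "set_id", chans), "PSM ratio table")
  uniq <- psm_ratios[as.logical(psm_ratios$unique), , drop = FALSE]
  n_dropped_genes <- length(setdiff(psm_ratios$gene, uniq$gene))
  if (n_dropped_genes > 0L) {
    log_stage("quant", "%d gene(s) had no unique PSMs and were excluded",
              n_dropped_genes)
  }
  if (nrow(uniq) == 0L) abort("no unique PSMs to aggregate")
  genes <- sort(unique(canon_gene(uniq$gene)))
  sp <- split(seq_len(nrow(uniq)), canon_gene(uniq$gene))
  n_psms <- vapply(sp, length, integer(1))[genes]
  keep <- n_psms >= min_psms
  genes <- genes[keep]
  mat <- t(vapply(genes, function(g) {
    apply(as.matrix(uniq[sp[[g]], chans, drop = FALSE]), 2L, median, na.rm = TRUE)
  }, numeric(length(chans))))
  dimnames(mat) <- list(genes, chans)
  set_id <- unique(as.character(uniq$set_id))
  protein_ratio_matrix(mat, n_psms[genes],
                       set_id = if (length(set_id) == 1L) set_id else NA_character_)
}

#' Column median centering (median sweeping, step 3)
#'
#' Subtracts each sample column's median so that every column of the
#' protein ratio matrix has median zero; corrects channel loading
#' differences without altering within-sample gene contrasts.
#'
#' @param prm A [protein_ratio_matrix()].
#' @return The centred `ProteinRatioMatrix`.
#' @export
center_columns <- function(prm) {
  stopifnot(inherits(prm, "ProteinRatioMatrix"))
  if (nrow(prm$mat) == 0L) abort("cannot centre an empty matrix")
  med <- apply(prm$mat, 2L, median, na.rm = TRUE)
  prm$mat <- sweep(prm$mat, 2L, med, "-")
  prm
}

#' Bridge two multiplex sets through their internal reference channel
#'
#' In a two-set design each 10-plex carries, in one dedicated channel, an
#' identical internal reference sample pooled from all study samples.
#' Expressing every sample relative to its own set's reference channel
#' cancels set-level batch offsets and puts both sets on a common scale.
#' The reference columns are consumed by the operation and dropped; the
#' output is restricted to genes quantified in both sets.
#'
#' @param set1,set2 `ProteinRatioMatrix` objects, each containing the
#'   reference column.
#' @param reference_label Column name of the internal reference channel
#'   in both sets (default `"tmt_131"`, the 10th label).
#' @return A combined `ProteinRatioMatrix` on the gene intersection, with
#'   columns `<set_id>.<channel>` for all non-reference channels and
#'   `n_psms` the per-gene minimum of the two sets' unique PSM counts.
#' @export
bridge_sets <- function(set1, set2, reference_label = "tmt_131") {
  stopifnot(inherits(set1, "ProteinRatioMatrix"),
            inherits(set2, "ProteinRatioMatrix"))
  for (s in list(set1, set2)) {
    if (!reference_label %in% colnames(s$mat)) {
      abort("reference column '%s' missing from set '%s'",
            reference_label, s$set_id)
    }
  }
  rel <- function(s) {
    m <- s$mat[, setdiff(colnames(s$mat), reference_label), drop = FALSE] -
      s$mat[, reference_label]
    colnames(m) <- paste(s$set_id, colnames(m), sep = ".")
    m
  }
  m1 <- rel(set1); m2 <- rel(set2)
  genes <- intersect(rownames(m1), rownames(m2))
  if (length(genes) == 0L) abort("no genes quantified in both sets")
  genes <- sort(genes)
  mat <- cbind(m1[genes, , drop = FALSE], m2[genes, , drop = FALSE])
  n_psms <- pmin(set1$n_psms[genes], set2$n_psms[genes])
  protein_ratio_matrix(mat, n_psms,
                       set_id = paste(set1$set_id, set2$set_id, sep = "+"))
}

#' Picked target/decoy protein FDR
#'
#' For every gene symbol, only the higher-scoring of its target and decoy
#' entries is kept ("picked" competition; score ties keep the target).
#' The picked entries are sorted by decreasing score and the FDR at each
#' rank is the running decoy/target count ratio (0/0 counts as 0); q-values
#' are the running minimum of FDR from the bottom of the list.
#'
#' @param scored Data frame with columns `gene`, `is_decoy` (logical) and
#'   `score` (finite, higher is better). A gene may contribute a target
#'   entry, a decoy entry, or both.
#' @param fdr_cutoff Target q-value threshold for the `passed` flag
#'   (default 0.01, i.e. 1% protein FDR).
#' @return Data frame (one row per gene, ranked by decreasing score) with
#'   columns `gene`, `is_decoy`, `score`, `fdr`, `q_value`, `passed`
#'   (targets with q <= cutoff).
#' @export
picked_protein_fdr <- function(scored, fdr_cutoff = 0.01) {
  assert_columns(scored, c("gene", "is_decoy", "score"), "scored table")
  if (any(!is.finite(scored$score))) abort("scores must be finite")
  scored$gene <- canon_gene(scored$gene)
  scored$is_decoy <- as.logical(scored$is_decoy)
  if (any(duplicated(scored[, c("gene", "is_decoy")]))) {
    abort("at most one target and one decoy entry per gene symbol")
  }
  # pick: higher score wins; tie keeps the target
  picked <- do.call(rbind, lapply(split(scored, scored$gene), function(g) {
    g[order(-g$score, g$is_decoy), , drop = FALSE][1L, , drop = FALSE]
  }))
  # rank by decreasing score; equal scores count the decoy first
  # (conservative: a tied decoy inflates the FDR at that score)
  picked <- picked[order(-picked$score, !picked$is_decoy), , drop = FALSE]
  n_decoy <- cumsum(picked$is_decoy)
  n_target <- cumsum(!picked$is_decoy)
  # 0/0 counts as 0; decoys before the first target saturate the FDR at 1
  fdr <- ifelse(n_target == 0L, ifelse(n_decoy == 0L, 0, 1),
                n_decoy / n_target)
  q <- rev(cummin(rev(pmin(fdr, 1))))
  out <- data.frame(gene = picked$gene, is_decoy = picked$is_decoy,
                    score = picked$score, fdr = fdr, q_value = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$passed <- !out$is_decoy & out$q_value <= fdr_cutoff
  out
}
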