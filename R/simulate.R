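# Synthetic-data generators with planted ground truth. Every generator
# is fully determined by its seed and emits tables in the same schemas
# the analysis modules consume, so each downstream stage can be verified
# against known truth without access to deposited datasets.

sim_gene_names <- function(n) sprintf("G%05d", seq_len(n))

#' Default two-set TMT 10-plex design
#'
#' Mirrors a silencing-response experiment: two 10-plex sets (control
#' siRNA and target siRNA), each with triplicates of three treatment
#' conditions in channels 1-9 and an internal reference pool in channel
#' 10.
#'
#' @param conditions Treatment condition labels (default untreated, 24 h
#'   and 48 h of drug).
#' @return List of two per-set designs, each with `set_id`, a
#'   `condition` vector over the 9 sample channels, and
#'   `ref_channel = 10`.
#' @export
default_tmt_design <- function(conditions = c("untreated", "gef24", "gef48")) {
  stopifnot(length(conditions) == 3L)
  make <- function(set_id, arm) {
    list(set_id = set_id,
         condition = paste(arm, rep(conditions, each = 3L), sep = "_"),
         ref_channel = 10L)
  }
  list(set1 = make("set1", "siCtrl"), set2 = make("set2", "siBCL6"))
}

#' Simulate PSM-level TMT reporter tables for a two-set design
#'
#' Each gene receives a log-normal baseline intensity and each PSM a
#' random offset (both absorbed by row centering during quantification).
#' Sample-channel intensities follow the gene's planted condition
#' effects; the reference channel of each set carries the pooled linear
#' mean of all sample channels' expected intensities across both sets,
#' emulating an internal reference pool of all study samples.
#'
#' @param n_genes Number of genes.
#' @param mean_psms Mean PSMs per gene (counts are `1 + Poisson(mean_psms
#'   - 1)`).
#' @param design Two-set design from [default_tmt_design()].
#' @param effects Named list: condition label -> named numeric vector of
#'   planted log2 fold changes (gene -> lfc) relative to baseline.
#' @param noise_sd Per-channel measurement noise, log2 units (>= 0).
#' @param shared_frac Fraction of PSMs flagged non-unique (excluded by
#'   quantification; default 0.1).
#' @param overlap_frac Fraction of genes observed in both sets (default
#'   0.9); the remainder is split between set-specific genes.
#' @param seed Integer seed; fully determines the output.
#' @return List with `sets` (named list of PSM data frames, schema of
#'   [sweep_psm_ratios()]) and `truth` (a `SimTruth` with `de_genes`).
#' @export
simulate_psm_tables <- function(n_genes = 1000L, mean_psms = 3,
                                design = default_tmt_design(),
                                effects = list(), noise_sd = 0.1,
                                shared_frac = 0.1, overlap_frac = 0.9,
                                seed = 1L) {
  if (length(design) == 0L) abort("empty design")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  stopifnot(n_genes >= 1L, mean_psms >= 1)
  set.seed(seed)
  genes <- sim_gene_names(n_genes)
  base <- stats::setNames(rnorm(n_genes, mean = 16, sd = 1), genes)

  all_conditions <- unlist(lapply(design, `[[`, "condition"))
  lfc_of <- function(g, cond) {
    e <- effects[[cond]]
    if (is.null(e)) 0 else if (g %in% names(e)) unname(e[[g]]) else 0
  }
  # genes observed per set: a shared core plus set-specific remainders
  n_shared <- round(overlap_frac * n_genes)
  shared <- genes[seq_len(n_shared)]
  rest <- setdiff(genes, shared)
  half <- length(rest) %/% 2L
  genes_by_set <- list(c(shared, rest[seq_len(half)]),
                       c(shared, rest[setdiff(seq_along(rest), seq_len(half))]))

  chans <- tmt10_channels()
  sets <- vector("list", length(design))
  names(sets) <- names(design)
  for (si in seq_along(design)) {
    d <- design[[si]]
    if (d$ref_channel < 1L || d$ref_channel > 10L) {
      abort("reference channel index must be in 1..10")
    }
    gs <- genes_by_set[[si]]
    n_psms <- 1L + rpois(length(gs), max(mean_psms - 1, 0))
    gene_vec <- rep(gs, n_psms)
    m <- length(gene_vec)
    offset <- rnorm(m, 0, 1)
    # expected log2 intensity per sample channel
    log2_sample <- matrix(0, m, 9L)
    for (ch in seq_len(9L)) {
      cond <- d$condition[ch]
      lfc <- vapply(gene_vec, lfc_of, numeric(1), cond = cond)
      log2_sample[, ch] <- base[gene_vec] + offset + lfc
    }
    # pooled reference expectation: linear mean over all sample channels
    # of both sets (same gene baseline/offset; effects differ by set)
    pooled <- rowMeans(do.call(cbind, lapply(design, function(dd) {
      vapply(seq_len(9L), function(ch) {
        lfc <- vapply(gene_vec, lfc_of, numeric(1), cond = dd$condition[ch])
        2^(base[gene_vec] + offset + lfc)
      }, numeric(m))
    })))
    intens <- matrix(NA_real_, m, 10L)
    sample_ch <- setdiff(seq_len(10L), d$ref_channel)
    for (k in seq_len(9L)) {
      intens[, sample_ch[k]] <- 2^(log2_sample[, k] + rnorm(m, 0, noise_sd))
    }
    intens[, d$ref_channel] <- pooled * 2^rnorm(m, 0, noise_sd)
    tab <- data.frame(psm_id = sprintf("%s_psm%06d", d$set_id, seq_len(m)),
                      gene = gene_vec,
                      unique = runif(m) >= shared_frac,
                      set_id = d$set_id, stringsAsFactors = FALSE)
    tab[chans] <- intens
    # guarantee >=1 unique PSM per gene so every gene is quantifiable
    first <- !duplicated(tab$gene)
    tab$unique[first] <- TRUE
    sets[[si]] <- tab
  }
  truth <- structure(list(de_genes = effects, synergist_compounds = NULL,
                          consensus_genes = NULL, seed = seed),
                     class = "SimTruth")
  list(sets = sets, truth = truth)
}

#' Simulate an RNA count matrix with planted fold changes
#'
#' Counts are negative-binomial with mean `lib_size * baseline *
#' 2^lfc` and gene-wise dispersion `alpha` (`alpha = 0` gives Poisson
#' draws).
#'
#' @param n_genes Number of genes.
#' @param conditions Condition labels (first is the reference).
#' @param n_reps Replicates per condition (default 3).
#' @param dispersion NB dispersion alpha: scalar or per-gene vector
#'   (>= 0).
#' @param lfc_spec Named list: condition -> named numeric vector (gene ->
#'   planted log2 fold change vs the reference condition).
#' @param lib_sizes Named numeric vector of per-sample library sizes;
#'   default 2e6 for every sample.
#' @param seed Integer seed.
#' @return List with `counts` (integer matrix, genes x samples, sample
#'   names `<condition>_r<i>`), `groups` (named condition labels) and
#'   `truth`.
#' @export
simulate_count_matrix <- function(n_genes = 5000L,
                                  conditions = c("ctrl", "gef24"),
                                  n_reps = 3L, dispersion = 0.1,
                                  lfc_spec = list(), lib_sizes = NULL,
                                  seed = 1L) {
  if (any(dispersion < 0)) abort("dispersion must be >= 0")
  set.seed(seed)
  genes <- sim_gene_names(n_genes)
  alpha <- rep_len(dispersion, n_genes)
  samples <- paste(rep(conditions, each = n_reps),
                   rep(seq_len(n_reps), times = length(conditions)), sep = "_r")
  groups <- stats::setNames(rep(conditions, each = n_reps), samples)
  if (is.null(lib_sizes)) lib_sizes <- stats::setNames(rep(2e6, length(samples)), samples)
  if (!all(samples %in% names(lib_sizes))) abort("lib_sizes must cover all samples")
  if (any(lib_sizes != round(lib_sizes))) abort("library sizes must be integers")
  rel <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1.5)
  rel <- rel / sum(rel)
  counts <- matrix(0L, n_genes, length(samples),
                   dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    cond <- groups[[j]]
    lfc <- rep(0, n_genes)
    e <- lfc_spec[[cond]]
    if (!is.null(e)) {
      idx <- match(names(e), genes)
      if (anyNA(idx)) abort("lfc_spec names must be generated gene names")
      lfc[idx] <- as.numeric(e)
    }
    mu <- lib_sizes[[samples[j]]] * rel * 2^lfc
    if (any(mu < 0)) abort("negative means")
    counts[, j] <- as.integer(
      ifelse(alpha == 0, rpois(n_genes, mu),
             rnbinom(n_genes, mu = mu, size = 1 / pmax(alpha, 1e-12))))
  }
  truth <- structure(list(de_genes = lfc_spec, synergist_compounds = NULL,
                          consensus_genes = NULL, seed = seed),
                     class = "SimTruth")
  list(counts = counts, groups = groups, truth = truth)
}

#' Simulate a mono/combination drug-screen plate table
#'
#' Each compound is tested in two arms (monotherapy and combination with
#' a fixed anchor drug) at `n_doses` concentrations on a 10-fold
#' dilution ladder. True responses follow a 4PL curve with bottom 0,
#' slope in \[0.5, 3\] and inflection uniform in the tested log10 dose
#' window; tops are uniform in \[0, 100\]. Planted synergists receive a
#' potency shift (inflection lowered by `synergy_shift` log10 units) in
#' the combination arm; to represent pharmacologically meaningful
#' synergy they are drawn with tops in \[60, 100\] and inflections in
#' the upper half of the window. Raw well signals interpolate between
#' the plate's negative (DMSO) and positive (kill) control levels;
#' measurement noise is multiplicative with a constant coefficient of
#' variation (`noise_sd` percent of each well's own signal), the
#' characteristic error structure of luminescence viability readouts.
#'
#' @param n_compounds Number of library compounds (default 528).
#' @param n_doses Doses per arm (default 5).
#' @param dilution Fold dilution between doses (default 10).
#' @param top_dose Highest tested concentration, molar (default 1e-5;
#'   with 5 doses and 10-fold dilution the window spans a 10,000-fold
#'   range).
#' @param n_synergists Number of planted synergists (default 17).
#' @param synergy_shift Potency shift of the combo arm for synergists,
#'   log10 units (default 1.5).
#' @param noise_sd Measurement coefficient of variation, percent of the
#'   well signal (default 10).
#' @param compounds_per_plate Compounds per 384-well plate (default 35;
#'   both arms of a compound share a plate).
#' @param seed Integer seed.
#' @return List with `plates` (well-level data frame in the
#'   [normalize_plate()] schema), `truth` (a `SimTruth` whose
#'   `synergist_compounds` are the planted compound ids) and
#'   `truth_curves` (per compound-arm true 4PL parameters and
#'   closed-form DSS/sDSS at threshold 10).
#' @export
simulate_screen_plates <- function(n_compounds = 528L, n_doses = 5L,
                                   dilution = 10, top_dose = 1e-5,
                                   n_synergists = 17L, synergy_shift = 1.5,
                                   noise_sd = 10, compounds_per_plate = 35L,
                                   seed = 1L) {
  if (n_doses < 2L) abort("n_doses must be >= 2")
  if (dilution <= 1) abort("dilution must be > 1")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (n_synergists > n_compounds) {
    abort("n_synergists (%d) cannot exceed n_compounds (%d)",
          n_synergists, n_compounds)
  }
  set.seed(seed)
  compounds <- sprintf("CPD%04d", seq_len(n_compounds))
  synergists <- sort(sample(compounds, n_synergists))
  doses <- top_dose / dilution^((n_doses - 1L):0)
  x_min <- log10(min(doses)); x_max <- log10(max(doses))

  top <- runif(n_compounds, 0, 100)
  slope <- runif(n_compounds, 0.5, 3)
  infl <- runif(n_compounds, x_min, x_max)
  is_syn <- compounds %in% synergists
  top[is_syn] <- runif(sum(is_syn), 60, 100)
  infl[is_syn] <- runif(sum(is_syn), (x_min + x_max) / 2, x_max)
  infl_combo <- ifelse(is_syn, infl - synergy_shift, infl)

  t_act <- 10
  true_dss <- function(tt, bb, ss, cc) {
    a <- dss_area(tt, bb, ss, cc, x_min, x_max, t_act)
    100 * a / ((100 - t_act) * (x_max - x_min))
  }
  dss_mono <- mapply(true_dss, top, 0, slope, infl)
  dss_combo <- mapply(true_dss, top, 0, slope, infl_combo)

  # luminescence-style readout: noise is multiplicative with constant
  # coefficient of variation (noise_sd percent of the well's own signal)
  neg_mean <- 1000; pos_mean <- 10
  cv <- noise_sd / 100
  noisy <- function(clean) clean * (1 + rnorm(length(clean), 0, cv))
  plate_of <- ceiling(seq_len(n_compounds) / compounds_per_plate)
  rows <- vector("list", 0L)
  for (pl in unique(plate_of)) {
    plate_id <- sprintf("P%03d", pl)
    cps <- which(plate_of == pl)
    well <- 0L
    add <- function(compound, arm, conc, control, signal) {
      well <<- well + 1L
      data.frame(plate_id = plate_id, well = sprintf("w%03d", well),
                 compound = compound, arm = arm, conc_molar = conc,
                 signal = signal, control = control,
                 stringsAsFactors = FALSE)
    }
    plate_rows <- list()
    for (i in cps) {
      for (arm in c("mono", "combo")) {
        cc <- if (arm == "mono") infl[i] else infl_combo[i]
        inhib <- four_pl(log10(doses), top[i], 0, slope[i], cc)
        sig <- noisy(pos_mean + (neg_mean - pos_mean) * (100 - inhib) / 100)
        for (k in seq_len(n_doses)) {
          plate_rows[[length(plate_rows) + 1L]] <-
            add(compounds[i], arm, doses[k], "none", sig[k])
        }
      }
    }
    for (j in seq_len(16L)) {
      plate_rows[[length(plate_rows) + 1L]] <-
        add("DMSO", "control", NA_real_, "neg", noisy(neg_mean))
    }
    for (j in seq_len(8L)) {
      plate_rows[[length(plate_rows) + 1L]] <-
        add("BzCl", "control", NA_real_, "pos", noisy(pos_mean))
    }
    rows[[length(rows) + 1L]] <- do.call(rbind, plate_rows)
  }
  plates <- do.call(rbind, rows)
  rownames(plates) <- NULL
  truth_curves <- data.frame(
    compound = compounds, synergist = is_syn, top = top, bottom = 0,
    slope = slope, inflection_mono = infl, inflection_combo = infl_combo,
    dss_mono = dss_mono, dss_combo = dss_combo,
    sdss = dss_combo - dss_mono, stringsAsFactors = FALSE)
  truth <- structure(list(de_genes = NULL, synergist_compounds = synergists,
                          consensus_genes = NULL, seed = seed),
                     class = "SimTruth")
  list(plates = plates, truth = truth, truth_curves = truth_curves)
}

#' Simulate ChIP-experiment target evidence with planted consensus genes
#'
#' Every planted consensus gene is observed in at least
#' `min_experiments` of the experiments; every other universe gene
#' enters each experiment independently with probability
#' `background_rate`.
#'
#' @param universe Character vector of candidate target genes.
#' @param consensus_genes Planted consensus genes (subset of `universe`);
#'   if `NULL`, `n_consensus` genes are sampled.
#' @param n_consensus Number of consensus genes to sample when
#'   `consensus_genes` is `NULL` (default 50).
#' @param n_experiments Number of ChIP experiments (default 7).
#' @param min_experiments Minimum experiments per consensus gene
#'   (default 4).
#' @param background_rate Per-experiment membership probability for
#'   non-consensus genes, in \[0, 1\].
#' @param seed Integer seed.
#' @return List with `evidence` (data frame `gene`, `experiment`) and
#'   `truth` (a `SimTruth` with `consensus_genes`).
#' @export
simulate_chip_experiments <- function(universe, consensus_genes = NULL,
                                      n_consensus = 50L, n_experiments = 7L,
                                      min_experiments = 4L,
                                      background_rate = 0.1, seed = 1L) {
  if (background_rate < 0 || background_rate > 1) {
    abort("background_rate must lie in [0, 1]")
  }
  set.seed(seed)
  universe <- unique(canon_gene(universe))
  if (is.null(consensus_genes)) {
    consensus_genes <- sort(sample(universe, min(n_consensus, length(universe))))
  }
  consensus_genes <- unique(canon_gene(consensus_genes))
  if (!all(consensus_genes %in% universe)) {
    abort("consensus genes must be a subset of the universe")
  }
  exps <- sprintf("chip%d", seq_len(n_experiments))
  rows <- list()
  for (g in consensus_genes) {
    k <- sample(min_experiments:n_experiments, 1L)
    for (e in sample(exps, k)) {
      rows[[length(rows) + 1L]] <- data.frame(gene = g, experiment = e,
                                              stringsAsFactors = FALSE)
    }
  }
  bg <- setdiff(universe, consensus_genes)
  for (e in exps) {
    hit <- bg[runif(length(bg)) < background_rate]
    if (length(hit) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(gene = hit, experiment = e,
                                              stringsAsFactors = FALSE)
    }
  }
  evidence <- do.call(rbind, rows)
  if (is.null(evidence)) {
    evidence <- data.frame(gene = character(0), experiment = character(0))
  }
  evidence <- evidence[order(evidence$gene, evidence$experiment), , drop = FALSE]
  rownames(evidence) <- NULL
  truth <- structure(list(de_genes = NULL, synergist_compounds = NULL,
                          consensus_genes = consensus_genes, seed = seed),
                     class = "SimTruth")
  list(evidence = evidence, truth = truth)
}

#' Simulate target/decoy protein scores
#'
#' One target and one decoy entry per gene symbol, with normal scores.
#' Equal target and decoy means give exchangeable (null) scores.
#'
#' @param n_genes Number of gene symbols.
#' @param target_mean,decoy_mean,score_sd Normal score parameters
#'   (defaults 2, 0, 1).
#' @param seed Integer seed.
#' @return Data frame `gene`, `is_decoy`, `score` in the
#'   [picked_protein_fdr()] schema.
#' @export
simulate_decoy_scores <- function(n_genes = 1000L, target_mean = 2,
                                  decoy_mean = 0, score_sd = 1, seed = 1L) {
  set.seed(seed)
  genes <- sim_gene_names(n_genes)
  data.frame(
    gene = rep(genes, 2L),
    is_decoy = rep(c(FALSE, TRUE), each = n_genes),
    score = c(rnorm(n_genes, target_mean, score_sd),
              rnorm(n_genes, decoy_mean, score_sd)),
    stringsAsFactors = FALSE)
}

#' @export
print.SimTruth <- function(x, ...) {
  cat("SimTruth (seed", x$seed, ")\n")
  if (!is.null(x$de_genes)) {
    cat("  planted DE conditions:", paste(names(x$de_genes), collapse = ", "), "\n")
  }
  if (!is.null(x$synergist_compounds)) {
    cat("  planted synergists:", length(x$synergist_compounds), "\n")
  }
  if (!is.null(x$consensus_genes)) {
    cat("  planted consensus genes:", length(x$consensus_genes), "\n")
  }
  invisible(x)
}
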