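# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no stored data files.

# minimal PSM table: one row per (gene, psm), intensities supplied as a
# list of 10-vectors
make_psm_table <- function(genes, intensities, unique = TRUE,
                           set_id = "set1") {
  stopifnot(length(genes) == length(intensities))
  df <- data.frame(psm_id = sprintf("psm%03d", seq_along(genes)),
                   gene = genes,
                   unique = rep_len(unique, length(genes)),
                   set_id = set_id, stringsAsFactors = FALSE)
  m <- do.call(rbind, intensities)
  colnames(m) <- tmt10_channels()
  cbind(df, m)
}

# random PSM table for brute-force oracle comparisons
random_psm_table <- function(n_genes, max_psms = 4, seed) {
  set.seed(seed)
  genes <- rep(sprintf("g%02d", seq_len(n_genes)),
               sample(max_psms, n_genes, replace = TRUE))
  ints <- lapply(seq_along(genes), function(i) 2^rnorm(10, 16, 2))
  make_psm_table(genes, ints)
}

# protein ratio matrix with two triplicate groups and per-gene noise
# scaled by 1/sqrt(n_psms); planted lfc on the first n_de genes
make_group_prm <- function(n_genes, noise, lfc = 0, n_de = 0, seed) {
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  npsm <- 1L + stats::rpois(n_genes, 2)
  eff <- rep(0, n_genes)
  if (n_de > 0) eff[seq_len(n_de)] <- lfc
  m <- matrix(stats::rnorm(n_genes * 6, 0, noise / sqrt(rep(npsm, 6))),
              n_genes, 6)
  m[, 1:3] <- m[, 1:3] + eff
  dimnames(m) <- list(genes, c(paste0("a", 1:3), paste0("b", 1:3)))
  protein_ratio_matrix(m, npsm, "s")
}

two_group_labels <- stats::setNames(rep(c("A", "B"), each = 3),
                                    c(paste0("a", 1:3), paste0("b", 1:3)))

# independent step-up BH oracle (literal textbook construction)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  run <- Inf
  for (i in n:1) {
    run <- min(run, p[o[i]] * n / i)
    adj[o[i]] <- min(run, 1)
  }
  adj
}

# numerical-quadrature DSS oracle. The integrand max(y - t, 0) has a
# kink where the curve crosses the threshold; the crossing is located by
# independent root-finding so the quadrature only sees a smooth segment.
dss_quadrature <- function(top, bottom, slope, infl, x_min, x_max, t = 10) {
  y_of <- function(x) bottom + (top - bottom) / (1 + 10^(slope * (infl - x)))
  if (top <= t) return(0)
  x1 <- if (y_of(x_min) >= t) {
    x_min
  } else if (y_of(x_max) <= t) {
    x_max
  } else {
    stats::uniroot(function(x) y_of(x) - t, c(x_min, x_max),
                   tol = 1e-13)$root
  }
  a <- if (x1 >= x_max) {
    0
  } else {
    stats::integrate(function(x) y_of(x) - t, x1, x_max, rel.tol = 1e-11,
                     subdivisions = 1000L)$value
  }
  100 * a / ((100 - t) * (x_max - x_min))
}

# noise-free dose-response series from known 4PL parameters
series_from_curve <- function(top, bottom, slope, infl,
                              doses = 10^seq(-9, -5)) {
  x <- log10(doses)
  y <- bottom + (top - bottom) / (1 + 10^(slope * (infl - x)))
  list(doses = doses, responses = y)
}
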