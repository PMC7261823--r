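# Drug sensitivity and resistance testing (DSRT) analysis: plate
# normalization, 4PL dose-response fitting, drug sensitivity score (DSS),
# synergy score (sDSS) with QC-aware hit calling, and screen summaries.

#' Normalize raw plate signals to percent inhibition
#'
#' Per plate, cell-viability signals (e.g. CellTiterGlo luminescence) are
#' rescaled between the negative control (DMSO, 100% viability) and the
#' positive kill control (e.g. 100 uM benzethonium chloride, 0%
#' viability): `viability = 100 * (signal - mean_pos) / (mean_neg -
#' mean_pos)` and `inhibition = 100 - viability`.
#'
#' @param wells Data frame with columns `plate_id`, `well`, `compound`,
#'   `arm`, `conc_molar`, `signal`, `control` (one of `"none"`, `"neg"`,
#'   `"pos"`).
#' @return Data frame of the non-control wells with an added
#'   `inhibition` column (% inhibition).
#' @export
normalize_plate <- function(wells) {
  assert_columns(wells, c("plate_id", "well", "compound", "arm",
                          "conc_molar", "signal", "control"), "plate table")
  out <- lapply(split(wells, wells$plate_id), function(pl) {
    neg <- pl$signal[pl$control == "neg"]
    pos <- pl$signal[pl$control == "pos"]
    if (length(neg) < 2L || length(pos) < 2L) {
      abort("plate '%s': need >=2 wells per control", pl$plate_id[1L])
    }
    if (mean(neg) <= mean(pos)) {
      abort("plate '%s': negative-control mean <= positive-control mean",
            pl$plate_id[1L])
    }
    dose <- pl[pl$control == "none", , drop = FALSE]
    viability <- 100 * (dose$signal - mean(pos)) / (mean(neg) - mean(pos))
    dose$inhibition <- 100 - viability
    dose
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split normalized wells into per-compound-arm dose-response series
#'
#' @param normalized Output of [normalize_plate()].
#' @return Named list of data frames (one per `compound|arm`) with
#'   columns `conc_molar` (increasing) and `inhibition`.
#' @export
as_dose_response_series <- function(normalized) {
  assert_columns(normalized, c("compound", "arm", "conc_molar", "inhibition"),
                 "normalized wells")
  key <- paste(normalized$compound, normalized$arm, sep = "|")
  lapply(split(normalized, key), function(d) {
    d <- d[order(d$conc_molar), , drop = FALSE]
    if (any(diff(d$conc_molar) <= 0)) {
      abort("compound '%s' (%s): doses must be strictly increasing",
            d$compound[1L], d$arm[1L])
    }
    rownames(d) <- NULL
    d
  })
}

# log-logistic response at log10 dose x for a fitted curve
four_pl <- function(x, top, bottom, slope, inflection) {
  bottom + (top - bottom) / (1 + 10^(slope * (inflection - x)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Bounded least-squares fit of `y(x) = d + (a - d) / (1 + 10^(b(c -
#' x)))` with `x = log10(dose)`: top asymptote `a` in \[0, 100\], bottom
#' `d` in \[0, a\], slope `b` in (0, 10\], inflection `c` within +/- 2
#' log10 units of the tested dose window. Responses are % inhibition;
#' by default they are clamped to \[0, 100\] before fitting, the usual
#' preprocessing of normalized screen responses whose noise carries them
#' outside the physically meaningful range. If the optimizer fails, a
#' flat curve at the mean response is returned with `converged = FALSE`.
#'
#' @param doses Molar concentrations (>= 4 distinct values).
#' @param responses Percent inhibition at each dose.
#' @param clamp Two-element range responses are clamped to before
#'   fitting (default `c(0, 100)`); `NULL` fits the raw responses.
#' @return A `FittedCurve` list: `top`, `bottom`, `slope`, `inflection`,
#'   `converged`, `residual_se` (`sqrt(SSR / max(n - 4, 1))`, % units)
#'   and `n`.
#' @export
fit_4pl <- function(doses, responses, clamp = c(0, 100)) {
  stopifnot(length(doses) == length(responses))
  if (length(unique(doses)) < 4L) abort("need >= 4 distinct doses")
  if (any(doses <= 0)) abort("doses must be positive molar concentrations")
  x <- log10(doses)
  y <- if (is.null(clamp)) responses else pmin(pmax(responses, clamp[1L]), clamp[2L])
  n <- length(y)
  flat <- function() {
    a <- mean(y)
    list(top = a, bottom = a, slope = 1, inflection = mean(range(x)),
         converged = FALSE,
         residual_se = sqrt(sum((y - a)^2) / max(n - 4L, 1L)), n = n)
  }
  # bottom parametrized as frac * top so the d <= a constraint is a box
  a0 <- min(max(max(y), 1), 99)
  f0 <- min(max(min(y) / a0, 0), 0.9)
  half <- a0 / 2
  c_half <- if (any(y >= half) && any(y < half)) x[which(y >= half)[1L]] else mean(x)
  # deterministic multi-start: bounded nonlinear fits on few points are
  # sensitive to the starting point. A small primary grid is tried
  # first; the extended grid only runs if no primary start converges.
  primary <- expand.grid(a = a0, frac = f0, b = c(1, 2.5),
                         cc = unique(c(c_half, mean(x))))
  extended <- expand.grid(a = c(a0, min(a0 + 5, 100)),
                          frac = c(f0, 0.05),
                          b = c(0.6, 1, 2, 4),
                          cc = unique(c(c_half, mean(x), mean(x) - 1,
                                        mean(x) + 1)))
  try_starts <- function(starts, fit, best_ssr) {
    for (i in seq_len(nrow(starts))) {
      cand <- tryCatch(
        minpack.lm::nlsLM(
          y ~ frac * a + a * (1 - frac) / (1 + 10^(b * (cc - x))),
          start = as.list(starts[i, ]),
          lower = c(0, 0, 1e-3, min(x) - 2),
          upper = c(100, 1, 10, max(x) + 2),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(cand)) {
        ssr <- sum(stats::residuals(cand)^2)
        if (ssr < best_ssr) {
          fit <- cand
          best_ssr <- ssr
        }
        # an essentially perfect fit cannot improve; stop early
        if (ssr < 1e-10 * max(1, sum(y^2))) break
      }
    }
    list(fit = fit, ssr = best_ssr)
  }
  res <- try_starts(primary, NULL, Inf)
  if (is.null(res$fit)) res <- try_starts(extended, res$fit, res$ssr)
  fit <- res$fit
  if (is.null(fit)) return(flat())
  cf <- coef(fit)
  ssr <- sum(residuals(fit)^2)
  list(top = unname(cf["a"]), bottom = unname(cf["a"] * cf["frac"]),
       slope = unname(cf["b"]), inflection = unname(cf["cc"]),
       converged = fit$convInfo$isConv,
       residual_se = sqrt(ssr / max(n - 4L, 1L)), n = n)
}

# closed-form area above the activity threshold t under the 4PL curve on
# [x_min, x_max]; antiderivative of (y - t) is
#   (d - t) x + (a - d)/(b ln 10) * ln(1 + 10^(b(x - c)))
dss_area <- function(top, bottom, slope, inflection, x_min, x_max, t) {
  if (top <= t) return(0)
  x1 <- if (bottom >= t) {
    x_min
  } else {
    # y(x1) = t  =>  x1 = c - (1/b) log10((a - t)/(t - d))
    inflection - log10((top - t) / (t - bottom)) / slope
  }
  x1 <- min(max(x1, x_min), x_max)
  antider <- function(x) {
    (bottom - t) * x +
      (top - bottom) / (slope * log(10)) * log1p(10^(slope * (x - inflection)))
  }
  max(antider(x_max) - antider(x1), 0)
}

#' Drug sensitivity score from a fitted dose-response curve
#'
#' DSS1 is the area between the curve and the activity threshold `t`,
#' integrated in closed form from the dose where the curve first exceeds
#' `t` to the top of the tested window, normalized by the maximal
#' attainable area: `DSS1 = 100 * A / ((100 - t) * (x_max - x_min))`. A
#' curve whose top asymptote does not exceed `t` scores 0. Variants:
#' `DSS2 = DSS1 * 100 / top` penalizes partial-efficacy compounds;
#' `DSS3 = DSS2 * (x_max - x1) / (x_max - x_min)` additionally weights by
#' the fraction of the dose window with above-threshold activity. The
#' variant normalizations beyond DSS1 are conventions, configurable
#' rather than canonical.
#'
#' @param curve A `FittedCurve` from [fit_4pl()].
#' @param x_min,x_max Log10 molar bounds of the tested dose window.
#' @param t Activity threshold in % inhibition (default 10).
#' @param variant `"DSS1"` (default), `"DSS2"` or `"DSS3"`.
#' @param compound,arm Optional identifiers carried into the result.
#' @return A `DssResult` list: `compound`, `arm`, `dss`, `variant`,
#'   `excluded` (initialized `FALSE`; see [qc_filter()]),
#'   `activity_threshold`, `residual_se`.
#' @export
compute_dss <- function(curve, x_min, x_max, t = 10,
                        variant = c("DSS1", "DSS2", "DSS3"),
                        compound = NA_character_, arm = NA_character_) {
  variant <- match.arg(variant)
  if (!is.finite(x_min) || !is.finite(x_max) || x_min >= x_max) {
    abort("invalid dose window [%s, %s]", x_min, x_max)
  }
  a <- curve$top; d <- curve$bottom; b <- curve$slope; cc <- curve$inflection
  area <- dss_area(a, d, b, cc, x_min, x_max, t)
  dss <- 100 * area / ((100 - t) * (x_max - x_min))
  if (variant %in% c("DSS2", "DSS3") && dss > 0) {
    dss <- dss * 100 / a
    if (variant == "DSS3") {
      x1 <- if (d >= t) x_min else cc - log10((a - t) / (t - d)) / b
      x1 <- min(max(x1, x_min), x_max)
      dss <- dss * (x_max - x1) / (x_max - x_min)
    }
  }
  list(compound = compound, arm = arm, dss = dss, variant = variant,
       excluded = FALSE, activity_threshold = t,
       residual_se = curve$residual_se %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag DSS values whose curve fit is unreliable
#'
#' A DSS value is excluded from downstream hit calling when the standard
#' error of estimate of its curve exceeds 19 (strictly greater, % units),
#' or when the fit did not converge.
#'
#' @param dss A `DssResult` from [compute_dss()].
#' @param curve The `FittedCurve` the DSS was computed from.
#' @param se_cutoff Exclusion threshold on `residual_se` (default 19).
#' @return The `DssResult` with its `excluded` flag set.
#' @export
qc_filter <- function(dss, curve, se_cutoff = 19) {
  if (is.null(curve$residual_se)) abort("curve carries no residual_se")
  dss$residual_se <- curve$residual_se
  dss$excluded <- curve$residual_se > se_cutoff || !isTRUE(curve$converged)
  dss
}

#' Synergy score of a combination arm over monotherapy
#'
#' `sDSS = DSS_combo - DSS_mono`; a compound is a combination hit when
#' its sDSS exceeds the cutoff (default 5) and neither arm was excluded
#' by QC.
#'
#' @param mono,combo `DssResult` objects for the same compound and DSS
#'   variant.
#' @param hit_cutoff sDSS threshold for hit calling (default 5).
#' @return A `SynergyCall` list: `compound`, `sdss`, `is_hit`,
#'   `mono_dss`, `combo_dss`, `any_excluded`.
#' @export
compute_sdss <- function(mono, combo, hit_cutoff = 5) {
  if (!identical(mono$variant, combo$variant)) {
    abort("DSS variant mismatch: %s vs %s", mono$variant, combo$variant)
  }
  if (!identical(mono$compound, combo$compound)) {
    abort("compound mismatch: %s vs %s", mono$compound, combo$compound)
  }
  sdss <- combo$dss - mono$dss
  any_excl <- isTRUE(mono$excluded) || isTRUE(combo$excluded)
  list(compound = mono$compound, sdss = sdss,
       is_hit = sdss > hit_cutoff && !any_excl,
       mono_dss = mono$dss, combo_dss = combo$dss,
       any_excluded = any_excl)
}

#' Score a full combination screen
#'
#' Runs normalization, per-arm 4PL fitting, DSS, QC and sDSS for every
#' compound with both a mono and a combo arm.
#'
#' @param plates Raw plate table (see [normalize_plate()]).
#' @param t Activity threshold (%) for DSS (default 10).
#' @param hit_cutoff sDSS hit threshold (default 5).
#' @param se_cutoff QC threshold on curve standard error (default 19).
#' @param variant DSS variant (default `"DSS1"`).
#' @return Data frame, one row per compound: `compound`, `mono_dss`,
#'   `combo_dss`, `sdss`, `mono_se`, `combo_se`, `any_excluded`,
#'   `is_hit`.
#' @export
score_screen <- function(plates, t = 10, hit_cutoff = 5, se_cutoff = 19,
                         variant = "DSS1") {
  series <- as_dose_response_series(normalize_plate(plates))
  meta <- do.call(rbind, lapply(series, function(d) {
    data.frame(compound = d$compound[1L], arm = d$arm[1L],
               stringsAsFactors = FALSE)
  }))
  compounds <- sort(unique(meta$compound))
  rows <- lapply(compounds, function(cp) {
    one_arm <- function(arm) {
      d <- series[[paste(cp, arm, sep = "|")]]
      if (is.null(d)) return(NULL)
      x <- log10(d$conc_molar)
      curve <- fit_4pl(d$conc_molar, d$inhibition)
      dss <- compute_dss(curve, x_min = min(x), x_max = max(x), t = t,
                         variant = variant, compound = cp, arm = arm)
      qc_filter(dss, curve, se_cutoff = se_cutoff)
    }
    mono <- one_arm("mono"); combo <- one_arm("combo")
    if (is.null(mono) || is.null(combo)) return(NULL)
    call <- compute_sdss(mono, combo, hit_cutoff = hit_cutoff)
    data.frame(compound = cp, mono_dss = mono$dss, combo_dss = combo$dss,
               sdss = call$sdss, mono_se = mono$residual_se,
               combo_se = combo$residual_se,
               any_excluded = call$any_excluded, is_hit = call$is_hit,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(compound = character(0), mono_dss = numeric(0),
                      combo_dss = numeric(0), sdss = numeric(0),
                      mono_se = numeric(0), combo_se = numeric(0),
                      any_excluded = logical(0), is_hit = logical(0))
  }
  rownames(res) <- NULL
  res
}

#' Summarize combination-screen hits with target annotation
#'
#' @param scored Output of [score_screen()] (or a data frame of
#'   `SynergyCall`s with `compound`, `sdss`, `is_hit`).
#' @param targets Data frame `compound`, `target` (optionally `source`);
#'   multiple annotation sources are unioned and deduplicated.
#' @param classes Optional data frame `compound`, `class` (e.g. kinase
#'   inhibitor).
#' @return List with `hits` (one row per hit, sorted by decreasing sdss,
#'   with a `targets` column of `;`-collapsed unique target symbols and
#'   optional `class`) and `class_counts` (table over hit classes, empty
#'   when `classes` is `NULL`).
#' @export
screen_summary <- function(scored, targets = NULL, classes = NULL) {
  assert_columns(scored, c("compound", "sdss", "is_hit"), "scored screen")
  hits <- scored[scored$is_hit, , drop = FALSE]
  hits <- hits[order(-hits$sdss, hits$compound), , drop = FALSE]
  target_list <- function(cp) {
    if (is.null(targets)) return("")
    tg <- sort(unique(canon_gene(targets$target[targets$compound == cp])))
    if (length(tg) == 0L) {
      log_stage("screen", "hit compound '%s' has no target annotation", cp)
    }
    paste(tg, collapse = ";")
  }
  hits$targets <- vapply(hits$compound, target_list, character(1))
  if (!is.null(classes)) {
    assert_columns(classes, c("compound", "class"), "class annotation")
    idx <- match(hits$compound, classes$compound)
    hits$class <- classes$class[idx]
  }
  class_counts <- if (!is.null(classes) && nrow(hits) > 0L) {
    table(hits$class, useNA = "ifany")
  } else {
    table(character(0))
  }
  rownames(hits) <- NULL
  list(hits = hits, class_counts = class_counts)
}
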