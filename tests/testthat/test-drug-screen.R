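# Plate normalization, 4PL fitting, DSS, QC, sDSS and screen summaries.

make_plate <- function(signals, concs = 10^seq(-9, -5)) {
  data.frame(plate_id = "P1",
             well = sprintf("w%02d", seq_len(length(signals) + 4)),
             compound = c(rep("CPD", length(signals)), rep("DMSO", 2),
                          rep("BzCl", 2)),
             arm = c(rep("mono", length(signals)), rep("control", 4)),
             conc_molar = c(concs, rep(NA, 4)),
             signal = c(signals, 1000, 1000, 0, 0),
             control = c(rep("none", length(signals)), "neg", "neg",
                         "pos", "pos"),
             stringsAsFactors = FALSE)
}

test_that("plate normalization maps controls to 0 and 100% inhibition", {
  norm <- normalize_plate(make_plate(c(1000, 500, 0, 250, 750)))
  expect_equal(norm$inhibition, c(0, 50, 100, 75, 25))
})

test_that("degenerate control plates are rejected", {
  pl <- make_plate(c(500, 500, 500, 500, 500))
  pl$signal[pl$control == "neg"] <- 0
  pl$signal[pl$control == "pos"] <- 1000
  expect_error(normalize_plate(pl), "negative-control mean")
  pl2 <- make_plate(rep(500, 5))
  pl2 <- pl2[pl2$control != "pos" | seq_len(nrow(pl2)) %in% 8, ]
  expect_error(normalize_plate(pl2), ">=2 wells")
})

test_that("4PL fitting recovers noise-free generating parameters", {
  s <- series_from_curve(100, 0, 1, -7)
  fit <- fit_4pl(s$doses, s$responses)
  expect_true(fit$converged)
  expect_equal(fit$top, 100, tolerance = 1e-3)
  expect_equal(fit$bottom, 0, tolerance = 1e-3)
  expect_equal(fit$slope, 1, tolerance = 1e-3)
  expect_equal(fit$inflection, -7, tolerance = 1e-3)
  expect_lt(fit$residual_se, 1e-3)
})

test_that("a zero response series gives a flat near-zero fit", {
  fit <- fit_4pl(10^seq(-9, -5), rep(0, 5))
  expect_lt(fit$top, 1e-3)
  expect_equal(fit$residual_se, 0, tolerance = 1e-6)
})

test_that("residual_se equals the hand-computed root mean square", {
  # 6 points on a known curve plus fixed residuals
  doses <- 10^seq(-10, -5)
  y <- series_from_curve(80, 0, 1.5, -7.5, doses)$responses
  resid <- c(1, 2, 1.5, -1, 0.5, 0)   # keeps responses inside [0, 100]
  fit <- fit_4pl(doses, y + resid)
  ssr_hat <- sum((y + resid -
                    (fit$bottom + (fit$top - fit$bottom) /
                       (1 + 10^(fit$slope * (fit$inflection - log10(doses))))))^2)
  expect_equal(fit$residual_se, sqrt(ssr_hat / 2), tolerance = 1e-9)
})

test_that("closed-form DSS matches adaptive quadrature on random curves", {
  set.seed(20)
  worst <- 0
  for (i in 1:200) {
    a <- runif(1, 0, 100); b <- runif(1, 0.5, 3)
    cc <- runif(1, -9, -5); d <- runif(1, 0, min(a, 30))
    curve <- list(top = a, bottom = d, slope = b, inflection = cc,
                  converged = TRUE, residual_se = 0)
    dss <- compute_dss(curve, -9, -5)$dss
    oracle <- dss_quadrature(a, d, b, cc, -9, -5)
    if (oracle > 1e-3) worst <- max(worst, abs(dss - oracle) / oracle)
    expect_lt(abs(dss - oracle), max(1e-6 * max(oracle, 1), 1e-9))
  }
  expect_lt(worst, 1e-6)
})

test_that("DSS limit cases behave", {
  flat0 <- list(top = 0, bottom = 0, slope = 1, inflection = -7,
                converged = TRUE, residual_se = 0)
  expect_equal(compute_dss(flat0, -9, -5)$dss, 0)
  # top below the activity threshold scores zero
  low <- list(top = 9.99, bottom = 0, slope = 1, inflection = -7,
              converged = TRUE, residual_se = 0)
  expect_equal(compute_dss(low, -9, -5)$dss, 0)
  # saturated inhibition across the whole window scores 100
  sat <- list(top = 100, bottom = 100, slope = 1, inflection = -7,
              converged = TRUE, residual_se = 0)
  expect_equal(compute_dss(sat, -9, -5)$dss, 100, tolerance = 1e-9)
  expect_error(compute_dss(sat, -5, -9), "invalid dose window")
})

test_that("DSS is monotone in efficacy and potency", {
  tops <- seq(15, 100, by = 5)
  dss_a <- vapply(tops, function(a) {
    compute_dss(list(top = a, bottom = 0, slope = 1, inflection = -7,
                     converged = TRUE, residual_se = 0), -9, -5)$dss
  }, numeric(1))
  expect_true(all(diff(dss_a) >= 0))
  infls <- seq(-9, -5, by = 0.25)
  dss_c <- vapply(infls, function(cc) {
    compute_dss(list(top = 80, bottom = 0, slope = 1, inflection = cc,
                     converged = TRUE, residual_se = 0), -9, -5)$dss
  }, numeric(1))
  expect_true(all(diff(dss_c) <= 0))
})

test_that("QC excludes curves with standard error above 19, strictly", {
  base <- list(top = 50, bottom = 0, slope = 1, inflection = -7,
               converged = TRUE)
  dss <- compute_dss(c(base, residual_se = 0), -9, -5)
  expect_true(qc_filter(dss, c(base, residual_se = 25))$excluded)
  expect_false(qc_filter(dss, c(base, residual_se = 0))$excluded)
  expect_false(qc_filter(dss, c(base, residual_se = 19))$excluded)
  # non-converged fits are excluded regardless of SE
  nc <- c(list(top = 50, bottom = 0, slope = 1, inflection = -7,
               converged = FALSE), residual_se = 0)
  expect_true(qc_filter(dss, nc)$excluded)
})

test_that("sDSS arithmetic, antisymmetry and QC propagation", {
  mk <- function(dss, excluded = FALSE) {
    list(compound = "X", arm = "mono", dss = dss, variant = "DSS1",
         excluded = excluded, activity_threshold = 10, residual_se = 0)
  }
  call <- compute_sdss(mk(4), mk(12))
  expect_equal(call$sdss, 8)
  expect_true(call$is_hit)
  expect_equal(compute_sdss(mk(7), mk(7))$sdss, 0)
  # swapping arms negates the score
  expect_equal(compute_sdss(mk(12), mk(4))$sdss, -8)
  # exclusion vetoes the hit regardless of sdss
  call2 <- compute_sdss(mk(2), mk(30, excluded = TRUE))
  expect_false(call2$is_hit)
  expect_equal(call2$sdss, 28)
  bad <- mk(4); bad$variant <- "DSS2"
  expect_error(compute_sdss(bad, mk(12)), "variant mismatch")
})

test_that("noise-free screens recover exactly the planted synergists", {
  scr <- simulate_screen_plates(n_compounds = 40, n_synergists = 5,
                                noise_sd = 0, seed = 7)
  scored <- score_screen(scr$plates)
  expect_identical(sort(scored$compound[scored$is_hit]),
                   scr$truth$synergist_compounds)
  # scored sdss tracks the closed-form truth on the generating curves.
  # Curves whose response only rises at the last tested dose are weakly
  # identified from 5 points (several parameter sets interpolate the
  # data), so agreement is to DSS-unit precision, not machine precision.
  m <- merge(scored, scr$truth_curves, by = "compound")
  expect_lt(max(abs(m$sdss.x - m$sdss.y)), 2.5)
  # mid-window curves are fully identified and recovered tightly
  mid <- m$inflection_mono > -8 & m$inflection_mono < -6 & m$top > 30 &
    !m$synergist
  if (any(mid)) expect_lt(max(abs(m$sdss.x[mid] - m$sdss.y[mid])), 1e-3)
})

test_that("screen summary unions targets and handles empty results", {
  scored <- data.frame(compound = c("c1", "c2", "c3"),
                       sdss = c(9, 7, 1), is_hit = c(TRUE, TRUE, FALSE))
  targets <- data.frame(compound = c("c1", "c1", "c1", "c2"),
                        target = c("egfr", "EGFR", "MET", "BRAF"),
                        source = c("vendor", "db", "db", "vendor"))
  classes <- data.frame(compound = c("c1", "c2", "c3"),
                        class = c("kinase inhibitor", "kinase inhibitor",
                                  "other"))
  s <- screen_summary(scored, targets, classes)
  expect_equal(s$hits$compound, c("c1", "c2"))
  expect_equal(s$hits$targets[1], "EGFR;MET")   # deduplicated union
  expect_equal(unname(s$class_counts["kinase inhibitor"]), 2L)
  none <- screen_summary(scored[scored$sdss > 100, ], targets)
  expect_equal(nrow(none$hits), 0L)
})
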