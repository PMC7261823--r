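# Median sweeping, aggregation, centering, bridging and picked FDR.

test_that("sweeping centres each PSM's log2 ratios at zero", {
  psm <- make_psm_table("g1", list(c(2, 4, 8, rep(4, 7))))
  sw <- sweep_psm_ratios(psm)
  r <- as.numeric(sw[1, tmt10_channels()])
  expect_equal(r[1:3], c(-1, 0, 1))
  expect_equal(median(r), 0)

  # all channels equal -> all ratios zero
  psm2 <- make_psm_table("g1", list(rep(7, 10)))
  expect_true(all(as.numeric(sweep_psm_ratios(psm2)[1, tmt10_channels()]) == 0))
})

test_that("sweeping is invariant to scaling a PSM's intensities", {
  psm <- random_psm_table(5, seed = 11)
  sw1 <- sweep_psm_ratios(psm)
  psm2 <- psm
  psm2[3, tmt10_channels()] <- psm2[3, tmt10_channels()] * 17.3
  sw2 <- sweep_psm_ratios(psm2)
  expect_equal(as.matrix(sw1[, tmt10_channels()]),
               as.matrix(sw2[, tmt10_channels()]), tolerance = 1e-12)
})

test_that("PSMs with fewer than two channels are dropped with a warning", {
  ints <- list(rep(4, 10), c(4, rep(NA, 9)))
  psm <- make_psm_table(c("g1", "g1"), ints)
  expect_warning(sw <- sweep_psm_ratios(psm), "<2 quantified")
  expect_equal(nrow(sw), 1L)
})

test_that("aggregation takes per-channel medians over unique PSMs only", {
  # two mirrored PSMs cancel to zero
  i1 <- 2^c(-1, 0, 1, rep(0, 7))
  i2 <- 2^c(1, 0, -1, rep(0, 7))
  psm <- make_psm_table(c("g1", "g1"), list(16 * i1, 16 * i2))
  prm <- aggregate_protein_ratios(sweep_psm_ratios(psm))
  expect_equal(unname(prm$mat["G1", ]), rep(0, 10))
  expect_equal(unname(prm$n_psms["G1"]), 2L)

  # a single-PSM gene keeps that PSM's ratios
  psm1 <- make_psm_table("g2", list(16 * i1))
  sw <- sweep_psm_ratios(psm1)
  prm1 <- aggregate_protein_ratios(sw)
  expect_equal(unname(prm1$mat["G2", ]),
               as.numeric(sw[1, tmt10_channels()]))
})

test_that("aggregation equals a brute-force median oracle on random tables", {
  for (seed in 1:20) {
    psm <- random_psm_table(n_genes = 8, seed = seed)
    sw <- sweep_psm_ratios(psm)
    prm <- aggregate_protein_ratios(sw)
    # independent oracle: explicit loop over genes and channels
    for (g in unique(toupper(sw$gene))) {
      rows <- sw[toupper(sw$gene) == g & sw$unique, tmt10_channels(),
                 drop = FALSE]
      expected <- apply(as.matrix(rows), 2, median)
      expect_equal(unname(prm$mat[g, ]), unname(expected), tolerance = 1e-12)
    }
  }
})

test_that("non-unique PSMs are excluded and empty genes reported", {
  i <- rep(16, 10)
  psm <- make_psm_table(c("g1", "g1", "g2"), list(i, 2 * i, 4 * i),
                        unique = c(TRUE, FALSE, FALSE))
  sw <- sweep_psm_ratios(psm)
  expect_message(prm <- aggregate_protein_ratios(sw), "no unique PSMs")
  expect_equal(rownames(prm$mat), "G1")
  expect_equal(unname(prm$n_psms), 1L)
})

test_that("column centering zeroes medians and is idempotent", {
  set.seed(3)
  m <- matrix(rnorm(40, 1, 2), 4, 10,
              dimnames = list(paste0("g", 1:4), tmt10_channels()))
  prm <- center_columns(protein_ratio_matrix(m, rep(1L, 4), "s"))
  expect_true(all(abs(apply(prm$mat, 2, median)) < 1e-12))
  prm2 <- center_columns(prm)
  expect_equal(prm2$mat, prm$mat)
  # row differences between columns preserved up to a per-column shift
  shift <- m - prm$mat
  expect_true(all(abs(shift - rep(shift[1, ], each = 4)) < 1e-12))
})

test_that("bridging is invariant to set-level shifts and intersects genes", {
  set.seed(4)
  mk <- function(genes, offset, set_id) {
    m <- matrix(rnorm(length(genes) * 10), length(genes), 10,
                dimnames = list(genes, tmt10_channels())) + offset
    protein_ratio_matrix(m, rep(2L, length(genes)), set_id)
  }
  s1 <- mk(c("A", "B", "C"), 0, "set1")
  s2 <- mk(c("B", "C", "D"), 0, "set2")
  b <- bridge_sets(s1, s2)
  expect_setequal(rownames(b$mat), c("B", "C"))
  expect_equal(ncol(b$mat), 18L)

  # adding a constant to every column of set2 leaves the bridge unchanged
  s2_shift <- s2
  s2_shift$mat <- s2_shift$mat + 3.14
  b2 <- bridge_sets(s1, s2_shift)
  expect_equal(b2$mat, b$mat, tolerance = 1e-12)

  # identical measurements relative to reference agree across sets
  s3 <- mk(c("A", "B"), 0, "set2")
  s3$mat <- s1$mat[c("A", "B"), ]
  b3 <- bridge_sets(s1, s3)
  expect_equal(unname(b3$mat[, 1:9]), unname(b3$mat[, 10:18]))
})

test_that("bridging requires the reference column", {
  m <- matrix(0, 2, 9, dimnames = list(c("A", "B"), tmt10_channels()[1:9]))
  s <- protein_ratio_matrix(m, c(1L, 1L), "set1")
  full <- protein_ratio_matrix(cbind(m, tmt_131 = c(0, 0)), c(1L, 1L), "set2")
  expect_error(bridge_sets(s, full), "reference column")
})

test_that("picked FDR matches hand enumeration on the worked example", {
  scored <- data.frame(gene = c("A", "A", "B", "B"),
                       is_decoy = c(FALSE, TRUE, FALSE, TRUE),
                       score = c(9, 4, 3, 7))
  pf <- picked_protein_fdr(scored)
  expect_equal(pf$gene, c("A", "B"))
  expect_equal(pf$is_decoy, c(FALSE, TRUE))
  expect_equal(pf$score, c(9, 7))
  expect_equal(pf$fdr, c(0, 1))
  expect_equal(pf$q_value, c(0, 1))
  expect_equal(pf$passed, c(TRUE, FALSE))
})

test_that("picked FDR edge conventions hold", {
  # all decoys outscore all targets -> every target q = 1
  sc <- data.frame(gene = rep(c("A", "B", "C"), each = 2),
                   is_decoy = rep(c(FALSE, TRUE), 3),
                   score = c(1, 10, 2, 11, 3, 12))
  pf <- picked_protein_fdr(sc)
  expect_true(all(pf$q_value[!pf$is_decoy] == 1))

  # no decoys -> all q = 0
  sc2 <- data.frame(gene = c("A", "B"), is_decoy = FALSE, score = c(5, 1))
  expect_true(all(picked_protein_fdr(sc2)$q_value == 0))

  # score tie within a gene keeps the target
  sc3 <- data.frame(gene = c("A", "A"), is_decoy = c(FALSE, TRUE),
                    score = c(5, 5))
  expect_false(picked_protein_fdr(sc3)$is_decoy[1])
})

test_that("picked FDR equals brute-force rank enumeration", {
  for (seed in 1:10) {
    sc <- simulate_decoy_scores(n_genes = 200, target_mean = 0.5, seed = seed)
    pf <- picked_protein_fdr(sc)
    # oracle: pick per gene by max score, then enumerate every rank
    picks <- do.call(rbind, lapply(split(sc, sc$gene), function(g) {
      g[order(-g$score, g$is_decoy), ][1, ]
    }))
    picks <- picks[order(-picks$score, !picks$is_decoy), ]
    n <- nrow(picks)
    fdr <- numeric(n)
    for (k in seq_len(n)) {
      nd <- sum(picks$is_decoy[1:k]); nt <- k - nd
      fdr[k] <- if (nt == 0) {
        if (nd == 0) 0 else 1
      } else {
        min(nd / nt, 1)
      }
    }
    q <- numeric(n)
    run <- Inf
    for (k in n:1) {
      run <- min(run, fdr[k]); q[k] <- run
    }
    expect_equal(pf$q_value, q, tolerance = 1e-12)
  }
})

test_that("empirical FDR on exchangeable scores stays near the cutoff", {
  frac <- vapply(1:60, function(s) {
    sc <- simulate_decoy_scores(n_genes = 400, target_mean = 0,
                                decoy_mean = 0, seed = 4000 + s)
    pf <- picked_protein_fdr(sc)
    sum(pf$passed) / sum(!pf$is_decoy)
  }, numeric(1))
  expect_lt(mean(frac), 0.02)
})
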