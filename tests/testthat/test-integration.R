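# Omics merging, annotation counting, consensus ChIP filtering,
# candidate derivation and hit-target lookup.

mk_dea <- function(genes, sig = FALSE, lfc = 0) {
  data.frame(gene = genes, log2fc = rep_len(lfc, length(genes)),
             p_raw = 0.5, p_adj = rep_len(ifelse(sig, 0.001, 0.5),
                                          length(genes)),
             significant = rep_len(sig, length(genes)),
             stringsAsFactors = FALSE)
}

test_that("merge_omics counts identification and regulation overlaps", {
  m <- mk_dea(c("A", "B", "C"), sig = c(TRUE, TRUE, FALSE), lfc = 2)
  p <- mk_dea(c("B", "C", "D"), sig = c(TRUE, FALSE, TRUE), lfc = 1)
  res <- merge_omics(m, p)
  expect_equal(res$counts$n_both, 2L)
  expect_equal(res$counts$n_mrna_only, 1L)
  expect_equal(res$counts$n_protein_only, 1L)
  expect_equal(res$counts$n_regulated_both, 1L)   # only B

  # disjoint sets
  res2 <- merge_omics(mk_dea(c("A", "B")), mk_dea(c("C", "D")))
  expect_equal(res2$counts$n_both, 0L)

  # identical sets with identical calls
  res3 <- merge_omics(mk_dea(c("A", "B"), sig = TRUE, lfc = 2),
                      mk_dea(c("A", "B"), sig = TRUE, lfc = 2))
  expect_equal(res3$counts$n_both, 2L)
  expect_equal(res3$counts$n_regulated_both, 2L)

  expect_error(merge_omics(mk_dea(c("A", "A")), mk_dea("B")),
               "duplicate gene")
})

test_that("merge_omics counts are invariant to row order", {
  m <- mk_dea(c("A", "B", "C", "D"), sig = c(TRUE, FALSE, TRUE, FALSE))
  p <- mk_dea(c("C", "A", "E"), sig = c(TRUE, TRUE, FALSE))
  r1 <- merge_omics(m, p)$counts
  r2 <- merge_omics(m[c(3, 1, 4, 2), ], p[c(2, 3, 1), ])$counts
  expect_identical(r1, r2)
})

test_that("annotate_genes counts category membership by brute force", {
  cats <- data.frame(gene = c("A", "B", "C", "A"),
                     category = c("kinase", "kinase", "TF", "TF"))
  empty <- annotate_genes(character(0), cats)
  expect_equal(empty[c("kinase", "TF")], c(kinase = 0L, TF = 0L))
  expect_equal(annotate_genes("B", cats)[c("kinase", "TF")],
               c(kinase = 1L, TF = 0L))
  # multi-label gene counts in both categories
  expect_equal(annotate_genes(c("A", "C"), cats)[c("kinase", "TF")],
               c(kinase = 1L, TF = 2L))
  set.seed(30)
  universe <- sprintf("G%03d", 1:50)
  cats2 <- data.frame(gene = sample(universe, 40, replace = TRUE),
                      category = sample(c("x", "y", "z"), 40, replace = TRUE))
  subset <- sample(universe, 20)
  got <- annotate_genes(subset, cats2)
  for (ct in names(got)) {
    expect_equal(unname(got[ct]),
                 length(intersect(toupper(subset),
                                  unique(toupper(cats2$gene[cats2$category == ct])))))
  }
})

test_that("consensus filter applies the >= min_experiments rule", {
  ev <- data.frame(gene = c(rep("A", 4), rep("B", 3), rep("C", 7)),
                   experiment = c(paste0("chip", 1:4), paste0("chip", 1:3),
                                  paste0("chip", 1:7)))
  expect_equal(consensus_chip_targets(ev, 4), c("A", "C"))
  expect_equal(consensus_chip_targets(ev, 1), c("A", "B", "C"))
  # duplicated observations of the same experiment do not inflate counts
  ev2 <- rbind(ev, data.frame(gene = "B", experiment = "chip1"))
  expect_equal(consensus_chip_targets(ev2, 4), c("A", "C"))
  expect_error(consensus_chip_targets(ev, 99), "min_experiments")
})

test_that("generated ChIP evidence respects background-rate limits", {
  universe <- sprintf("G%03d", 1:100)
  planted <- universe[1:10]
  zero <- simulate_chip_experiments(universe, planted, background_rate = 0,
                                    seed = 31)
  expect_identical(consensus_chip_targets(zero$evidence, 4), sort(planted))
  one <- simulate_chip_experiments(universe, planted, background_rate = 1,
                                   seed = 32)
  expect_identical(consensus_chip_targets(one$evidence, 4), sort(universe))
  mid <- simulate_chip_experiments(universe, planted, background_rate = 0.3,
                                   seed = 33)
  expect_true(all(planted %in% consensus_chip_targets(mid$evidence, 4)))
})

test_that("candidate derivation intersects consensus with regulated genes", {
  consensus <- c("A", "B", "C", "D")
  dea1 <- mk_dea(c("A", "B", "E"), sig = c(TRUE, FALSE, TRUE), lfc = 1)
  dea2 <- mk_dea(c("B", "C", "F"), sig = c(TRUE, FALSE, TRUE), lfc = 1)
  cand <- candidate_targets(consensus, list(c1 = dea1, c2 = dea2))
  expect_equal(cand$genes, c("A", "B"))   # up in >= 1 condition
  # direction = down uses the down calls
  dea3 <- mk_dea(c("A", "C"), sig = TRUE, lfc = -2)
  cand_dn <- candidate_targets(consensus, list(c1 = dea3),
                               direction = "down")
  expect_equal(cand_dn$genes, c("A", "C"))
  # empty consensus is allowed
  expect_equal(candidate_targets(character(0), list(c1 = dea1))$genes,
               character(0))
})

test_that("candidate set shrinks as min_experiments grows", {
  universe <- sprintf("G%03d", 1:200)
  sim <- simulate_chip_experiments(universe, universe[1:20],
                                   background_rate = 0.4, seed = 34)
  dea <- mk_dea(universe, sig = TRUE, lfc = 1)
  sizes <- vapply(1:7, function(k) {
    cons <- consensus_chip_targets(sim$evidence, k)
    length(candidate_targets(cons, list(x = dea))$genes)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("hit targets are flagged for regulation at each level", {
  hits <- data.frame(compound = c("c1", "c2", "c3"),
                     is_hit = c(TRUE, TRUE, FALSE))
  targets <- data.frame(compound = c("c1", "c2", "c2", "c3"),
                        target = c("EGFR", "MET", "EGFR", "BRAF"))
  mrna <- mk_dea(c("EGFR", "MET"), sig = c(TRUE, FALSE), lfc = 2)
  protein <- mk_dea(c("EGFR", "MET"), sig = c(TRUE, TRUE), lfc = 1)
  tab <- map_hit_targets(hits, targets, mrna, protein)
  expect_equal(tab$target, c("EGFR", "MET"))       # c3 not a hit
  expect_equal(tab$compounds, c("c1;c2", "c2"))
  expect_equal(tab$up_mrna, c(TRUE, FALSE))
  expect_equal(tab$up_protein, c(TRUE, TRUE))
  # hit with no regulated targets stays listed with false flags
  tab2 <- map_hit_targets(hits, targets, mk_dea("KRAS"), mk_dea("KRAS"))
  expect_true(all(!tab2$up_mrna & !tab2$up_protein))
  # no hits -> empty table
  none <- map_hit_targets(transform(hits, is_hit = FALSE), targets,
                          mrna, protein)
  expect_equal(nrow(none), 0L)
})
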