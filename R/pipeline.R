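# Pipeline configuration and the end-to-end driver chaining simulation,
# quantification, differential expression, screen scoring, integration
# and enrichment.

config_defaults <- function() {
  list(
    seed = 1L,
    # significance cutoffs
    mrna_lfc_cutoff = 1.0,
    protein_lfc_cutoff = 0.5,
    padj_cutoff = 0.01,
    protein_fdr_cutoff = 0.01,
    # screen scoring
    activity_threshold = 10,
    sdss_cutoff = 5,
    se_cutoff = 19,
    dss_variant = "DSS1",
    # integration / enrichment
    min_experiments = 4L,
    ora_fdr_cutoff = 0.05,
    ora_min_size = 5L,
    ora_max_size = 2000L,
    # synthetic-data problem sizes
    sim_n_genes_protein = 800L,
    sim_n_genes_mrna = 3000L,
    sim_n_compounds = 120L,
    sim_n_synergists = 8L,
    sim_screen_noise_sd = 10,
    sim_psm_noise_sd = 0.1,
    sim_mrna_dispersion = 0.1,
    sim_chip_background_rate = 0.1,
    sim_n_consensus = 80L
  )
}

#' Build a validated pipeline configuration
#'
#' All defaults are the study's analysis settings: mRNA |log2FC| > 1 and
#' protein |log2FC| > 0.5 at adjusted p < 0.01, picked protein FDR 1%,
#' DSS activity threshold 10%, curve-SE exclusion above 19, sDSS hit
#' cutoff 5, ChIP consensus in >= 4 experiments, ORA FDR < 0.05. Unknown
#' keys are rejected.
#'
#' @param ... Named overrides of the defaults (see
#'   `adaptomics:::config_defaults()`).
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  cfg <- config_defaults()
  over <- list(...)
  if (length(over) > 0L && (is.null(names(over)) || any(names(over) == ""))) {
    abort("configuration overrides must be named")
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    abort("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "PipelineConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' Configurations round-trip unchanged; unknown keys in a file are
#' rejected on read.
#'
#' @param path YAML file path.
#' @return A `PipelineConfig`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config A `PipelineConfig` to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

# Deterministic planted truth for the simulation-driven pipeline run:
# which genes are regulated where, which compounds synergize, which genes
# are consensus ChIP targets.
plan_truth <- function(cfg) {
  genes_p <- sim_gene_names(cfg$sim_n_genes_protein)
  genes_m <- sim_gene_names(cfg$sim_n_genes_mrna)
  up <- genes_p[1:60]                       # up on silencing (de-repressed)
  down <- genes_p[61:100]
  protein_effects <- list(
    siBCL6_untreated = c(stats::setNames(rep(1, 20), up[1:20]),
                         stats::setNames(rep(-1, 20), down[1:20])),
    siBCL6_gef24 = c(stats::setNames(rep(1, 20), up[21:40]),
                     stats::setNames(rep(-1, 20), down[21:40])),
    siBCL6_gef48 = c(stats::setNames(rep(1, 40), up[21:60]),
                     stats::setNames(rep(-1, 0), character(0))))
  mrna_up <- genes_m[1:60]
  mrna_down <- genes_m[61:120]
  mrna_effects <- list(gef24 = c(stats::setNames(rep(2, 60), mrna_up),
                                 stats::setNames(rep(-2, 60), mrna_down)))
  # consensus ChIP set: half overlaps the planted-up proteins
  consensus <- c(up[1:30], genes_p[201:(200 + cfg$sim_n_consensus - 30)])
  list(protein_effects = protein_effects, protein_up = up,
       protein_down = down, mrna_effects = mrna_effects,
       mrna_up = mrna_up, mrna_down = mrna_down,
       consensus = sort(consensus), genes_p = genes_p, genes_m = genes_m)
}

# simulated auxiliary annotations: drug targets, compound classes,
# functional gene categories and a gene-set collection
plan_annotations <- function(cfg, truth, scored_compounds, seed) {
  set.seed(seed)
  compounds <- scored_compounds
  targets <- do.call(rbind, lapply(compounds, function(cp) {
    tg <- sample(truth$genes_m, sample(1:3, 1L))
    data.frame(compound = cp, target = tg,
               source = sample(c("vendor", "kinobeads", "db"), length(tg),
                               replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  classes <- data.frame(
    compound = compounds,
    class = sample(c("kinase inhibitor", "other"), length(compounds),
                   replace = TRUE, prob = c(0.48, 0.52)),
    stringsAsFactors = FALSE)
  # gene sets over the mRNA universe; one set is loaded with planted
  # up-regulated genes so enrichment has signal to find
  sets <- lapply(seq_len(19L), function(i) sample(truth$genes_m, 60L))
  names(sets) <- sprintf("RANDOM_SET_%02d", seq_len(19L))
  sets[["PLANTED_RESPONSE_SET"]] <- unique(c(truth$mrna_up,
                                             sample(truth$genes_m, 20L)))
  list(targets = targets, classes = classes, gene_sets = sets)
}

#' Run the full analysis pipeline on simulated data
#'
#' Chains every stage end-to-end: simulate inputs with planted truth,
#' quantify the two-set proteome (sweep, aggregate, centre, bridge) and
#' the picked protein FDR, run protein and mRNA differential expression,
#' score the mono/combination drug screen, derive consensus ChIP
#' candidates, map hit targets and run over-representation analysis. All
#' randomness flows from `config$seed`; outputs are deterministic given
#' the configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; created if missing. All result
#'   tables are written there along with `run_info.yaml` (seed, config
#'   hash, package version and per-stage row counts).
#' @return Invisibly, a list of the in-memory results: `protein_matrix`,
#'   `picked_fdr`, `protein_dea` (per condition), `mrna_dea`, `screen`,
#'   `hits`, `consensus`, `candidates`, `hit_targets`, `enrichment`,
#'   `truth`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- as.integer(config$seed)
  truth <- plan_truth(config)

  # --- simulate -------------------------------------------------------
  log_stage("simulate", "seed=%d hash=%s", seed, hash)
  psm <- simulate_psm_tables(n_genes = config$sim_n_genes_protein,
                             effects = truth$protein_effects,
                             noise_sd = config$sim_psm_noise_sd,
                             seed = seed + 1001L)
  cnt <- simulate_count_matrix(n_genes = config$sim_n_genes_mrna,
                               conditions = c("ctrl", "gef24"),
                               dispersion = config$sim_mrna_dispersion,
                               lfc_spec = truth$mrna_effects,
                               seed = seed + 1002L)
  scr <- simulate_screen_plates(n_compounds = config$sim_n_compounds,
                                n_synergists = config$sim_n_synergists,
                                noise_sd = config$sim_screen_noise_sd,
                                seed = seed + 1003L)
  chip <- simulate_chip_experiments(universe = truth$genes_p,
                                    consensus_genes = truth$consensus,
                                    min_experiments = config$min_experiments,
                                    background_rate = config$sim_chip_background_rate,
                                    seed = seed + 1004L)
  decoys <- simulate_decoy_scores(n_genes = config$sim_n_genes_protein,
                                  seed = seed + 1005L)
  ann <- plan_annotations(config, truth,
                          sort(unique(scr$plates$compound[scr$plates$control == "none"])),
                          seed = seed + 1006L)

  # --- proteome quantification ---------------------------------------
  quant_one <- function(tab) {
    center_columns(aggregate_protein_ratios(sweep_psm_ratios(tab)))
  }
  prm1 <- quant_one(psm$sets$set1)
  prm2 <- quant_one(psm$sets$set2)
  bridged <- bridge_sets(prm1, prm2, reference_label = "tmt_131")
  log_stage("quant", "set1 %d genes, set2 %d genes, bridged %d genes",
            nrow(prm1$mat), nrow(prm2$mat), nrow(bridged$mat))
  picked <- picked_protein_fdr(decoys, fdr_cutoff = config$protein_fdr_cutoff)

  # sample labels: <set>.<channel> -> condition from the design
  design <- default_tmt_design()
  groups <- unlist(lapply(design, function(d) {
    chans <- tmt10_channels()[setdiff(1:10, d$ref_channel)]
    stats::setNames(d$condition, paste(d$set_id, chans, sep = "."))
  }))
  names(groups) <- unlist(lapply(design, function(d) {
    paste(d$set_id, tmt10_channels()[setdiff(1:10, d$ref_channel)], sep = ".")
  }))

  # --- differential expression ---------------------------------------
  conditions <- c("untreated", "gef24", "gef48")
  protein_dea <- lapply(stats::setNames(conditions, conditions), function(cond) {
    moderated_protein_dea(bridged, groups,
                          contrast = paste0(c("siBCL6_", "siCtrl_"), cond))
  })
  for (cond in conditions) {
    cs <- call_significant(protein_dea[[cond]], "protein")
    log_stage("dea", "protein %s: %d up / %d down of %d genes", cond,
              cs$n_up, cs$n_down, nrow(protein_dea[[cond]]))
  }
  mrna_dea <- nb_count_dea(cnt$counts, cnt$groups,
                           contrast = c("gef24", "ctrl"))
  cs <- call_significant(mrna_dea, "mrna")
  log_stage("dea", "mrna gef24: %d up / %d down of %d genes",
            cs$n_up, cs$n_down, nrow(mrna_dea))

  # --- drug screen ----------------------------------------------------
  scored <- score_screen(scr$plates, t = config$activity_threshold,
                         hit_cutoff = config$sdss_cutoff,
                         se_cutoff = config$se_cutoff,
                         variant = config$dss_variant)
  summ <- screen_summary(scored, targets = ann$targets, classes = ann$classes)
  log_stage("screen", "%d compounds scored, %d hits (sDSS > %s)",
            nrow(scored), nrow(summ$hits), format(config$sdss_cutoff))

  # --- integration ----------------------------------------------------
  consensus <- consensus_chip_targets(chip$evidence,
                                      min_experiments = config$min_experiments)
  candidates <- candidate_targets(consensus, protein_dea, direction = "up")
  log_stage("integrate", "%d consensus targets, %d candidates",
            length(consensus), length(candidates$genes))
  merged <- merge_omics(mrna_dea, protein_dea$gef24)
  hit_targets <- map_hit_targets(scored, ann$targets, mrna_dea,
                                 protein_dea$gef24)

  # --- enrichment -----------------------------------------------------
  up_mrna <- mrna_dea$gene[mrna_dea$significant & mrna_dea$log2fc > 0]
  enr <- ora(up_mrna, ann$gene_sets, background = mrna_dea$gene,
             fdr_cutoff = config$ora_fdr_cutoff,
             min_size = config$ora_min_size, max_size = config$ora_max_size)
  log_stage("enrich", "%d sets tested, %d enriched at FDR < %s",
            nrow(enr), sum(enr$enriched), format(config$ora_fdr_cutoff))

  # --- write outputs --------------------------------------------------
  out <- function(...) file.path(out_dir, ...)
  write_protein_matrix(bridged, out("protein_matrix.tsv"))
  write_table_generic(picked, out("picked_fdr.tsv"))
  for (cond in conditions) {
    write_dea_results(protein_dea[[cond]],
                      out(sprintf("dea_protein_%s.tsv", cond)))
  }
  write_dea_results(mrna_dea, out("dea_mrna_gef24.tsv"))
  write_table_generic(scored, out("screen_scores.tsv"))
  write_table_generic(summ$hits, out("screen_hits.tsv"))
  writeLines(consensus, out("chip_consensus.txt"))
  writeLines(candidates$genes, out("candidates.txt"))
  write_table_generic(hit_targets, out("hit_targets.tsv"))
  write_table_generic(enr, out("enrichment.tsv"))
  yaml::write_yaml(list(
    seed = seed, config_hash = hash,
    package_version = as.character(utils::packageVersion("adaptomics")),
    tables = list(protein_matrix = nrow(bridged$mat),
                  picked_fdr = nrow(picked),
                  mrna_dea = nrow(mrna_dea),
                  screen = nrow(scored), hits = nrow(summ$hits),
                  consensus = length(consensus),
                  candidates = length(candidates$genes),
                  enrichment = nrow(enr))),
    out("run_info.yaml"))

  invisible(list(protein_matrix = bridged, picked_fdr = picked,
                 protein_dea = protein_dea, mrna_dea = mrna_dea,
                 screen = scored, hits = summ$hits, consensus = consensus,
                 candidates = candidates, hit_targets = hit_targets,
                 enrichment = enr, merged = merged,
                 truth = list(protein = truth, screen = scr$truth,
                              chip = chip$truth),
                 config_hash = hash))
}
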