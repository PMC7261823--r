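# Set-logic integration of the omics layers: identification/regulation
# overlaps, category annotation, consensus ChIP-target filtering,
# candidate derivation, and hit-target regulation lookup.

#' Merge mRNA- and protein-level DEA results by gene
#'
#' Full outer join keyed on uppercased gene symbol, with identification
#' and regulation overlap counts.
#'
#' @param mrna,protein `DeaResult` data frames (one row per gene).
#' @return List with `table` (joined table; mRNA columns suffixed
#'   `.mrna`, protein columns `.protein`) and `counts`: `n_mrna_only`,
#'   `n_protein_only`, `n_both` (identified at both levels),
#'   `n_regulated_both` (significant at both levels).
#' @export
merge_omics <- function(mrna, protein) {
  for (nm in c("mrna", "protein")) {
    df <- if (nm == "mrna") mrna else protein
    assert_columns(df, c("gene", "log2fc", "p_adj", "significant"),
                   paste(nm, "DEA results"))
    dup <- unique(df$gene[duplicated(canon_gene(df$gene))])
    if (length(dup) > 0L) {
      abort("duplicate gene row(s) in %s results: %s", nm,
            paste(head(dup, 5L), collapse = ", "))
    }
  }
  mrna$gene <- canon_gene(mrna$gene)
  protein$gene <- canon_gene(protein$gene)
  joined <- merge(mrna, protein, by = "gene", all = TRUE,
                  suffixes = c(".mrna", ".protein"))
  in_m <- joined$gene %in% mrna$gene
  in_p <- joined$gene %in% protein$gene
  reg_both <- joined$significant.mrna & joined$significant.protein
  list(table = joined,
       counts = list(
         n_mrna_only = sum(in_m & !in_p),
         n_protein_only = sum(!in_m & in_p),
         n_both = sum(in_m & in_p),
         n_regulated_both = sum(reg_both, na.rm = TRUE)))
}

#' Count functional-category membership within a gene subset
#'
#' @param genes Character vector of gene symbols (the subset of
#'   interest, e.g. regulated genes).
#' @param categories Data frame `gene`, `category`; a gene may carry
#'   several category labels and counts in each.
#' @return Named integer vector of per-category counts within `genes`.
#' @export
annotate_genes <- function(genes, categories) {
  assert_columns(categories, c("gene", "category"), "category table")
  genes <- unique(canon_gene(genes))
  categories$gene <- canon_gene(categories$gene)
  cats <- sort(unique(as.character(categories$category)))
  counts <- vapply(cats, function(ct) {
    length(intersect(genes, categories$gene[categories$category == ct]))
  }, integer(1))
  setNames(as.integer(counts), cats)
}

#' Consensus ChIP targets across independent experiments
#'
#' Keeps genes identified as targets in at least `min_experiments` of the
#' available ChIP experiments, removing low-confidence single-experiment
#' targets.
#'
#' @param evidence Data frame `gene`, `experiment` (one row per
#'   gene-experiment observation; duplicates are collapsed).
#' @param min_experiments Minimum number of distinct experiments
#'   supporting a gene (default 4).
#' @return Sorted character vector of consensus target genes.
#' @export
consensus_chip_targets <- function(evidence, min_experiments = 4L) {
  assert_columns(evidence, c("gene", "experiment"), "ChIP evidence")
  n_exp <- length(unique(evidence$experiment))
  if (min_experiments < 1L || min_experiments > max(n_exp, 1L)) {
    abort("min_experiments must lie in [1, %d]", n_exp)
  }
  ev <- unique(data.frame(gene = canon_gene(evidence$gene),
                          experiment = as.character(evidence$experiment),
                          stringsAsFactors = FALSE))
  tab <- table(ev$gene)
  sort(names(tab)[tab >= min_experiments])
}

#' Derive regulated candidate target genes of a transcriptional repressor
#'
#' Intersects consensus ChIP targets with genes significantly regulated
#' (by default: up, consistent with loss of a repressor) in at least one
#' of the tested conditions.
#'
#' @param consensus Character vector of consensus ChIP target genes.
#' @param dea_by_condition Named list of `DeaResult` data frames, one per
#'   condition, each carrying `significant` flags and `log2fc`.
#' @param direction `"up"` (default) or `"down"`.
#' @return A `CandidateSet` list: `genes` (sorted), `provenance` (rule
#'   string), `n_consensus`, `n_regulated`.
#' @export
candidate_targets <- function(consensus, dea_by_condition, direction = c("up", "down")) {
  direction <- match.arg(direction)
  sgn <- if (direction == "up") 1 else -1
  regulated <- unique(unlist(lapply(dea_by_condition, function(dea) {
    assert_columns(dea, c("gene", "log2fc", "significant"), "DEA results")
    canon_gene(dea$gene[dea$significant & sgn * dea$log2fc > 0])
  })))
  genes <- sort(intersect(canon_gene(consensus), regulated))
  structure(list(genes = genes,
                 provenance = sprintf("chip-consensus & %s-in->=1-of-%d-conditions",
                                      direction, length(dea_by_condition)),
                 n_consensus = length(unique(canon_gene(consensus))),
                 n_regulated = length(regulated)),
            class = "CandidateSet")
}

#' @export
print.CandidateSet <- function(x, ...) {
  cat(sprintf("CandidateSet: %d gene(s) [%s]\n", length(x$genes), x$provenance))
  invisible(x)
}

#' Regulation status of combination-screen hit targets
#'
#' Takes the union of annotated targets across all hit compounds and
#' flags each target for significant up-regulation at the mRNA and
#' protein level.
#'
#' @param hits Data frame with `compound` and `is_hit` (e.g. the output
#'   of [score_screen()]).
#' @param targets Annotation data frame `compound`, `target`.
#' @param mrna,protein `DeaResult` data frames.
#' @return Data frame `target`, `compounds` (`;`-collapsed hit compounds
#'   annotated with the target), `up_mrna`, `up_protein`.
#' @export
map_hit_targets <- function(hits, targets, mrna, protein) {
  assert_columns(hits, c("compound", "is_hit"), "hit table")
  assert_columns(targets, c("compound", "target"), "target annotation")
  hit_cp <- unique(hits$compound[hits$is_hit])
  ann <- targets[targets$compound %in% hit_cp, , drop = FALSE]
  if (nrow(ann) == 0L) {
    return(data.frame(target = character(0), compounds = character(0),
                      up_mrna = logical(0), up_protein = logical(0)))
  }
  ann$target <- canon_gene(ann$target)
  up_set <- function(dea) {
    canon_gene(dea$gene[dea$significant & dea$log2fc > 0])
  }
  up_m <- up_set(mrna); up_p <- up_set(protein)
  tg <- sort(unique(ann$target))
  data.frame(
    target = tg,
    compounds = vapply(tg, function(g) {
      paste(sort(unique(ann$compound[ann$target == g])), collapse = ";")
    }, character(1)),
    up_mrna = tg %in% up_m,
    up_protein = tg %in% up_p,
    row.names = NULL, stringsAsFactors = FALSE)
}
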