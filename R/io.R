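# Readers and writers for the pipeline's plain-text table schemas.
# All tables are TSV (plates: CSV) with a header row, UTF-8, '.' decimal;
# floating point values are written at 9 significant digits so outputs
# are diff-stable.

format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 9L, format = "g"))
}

write_table_generic <- function(df, path, sep = "\t") {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_num(out[[j]])
  }
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

read_table_generic <- function(path, required, numeric_cols = character(0),
                               sep = "\t") {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = "NA")
  assert_columns(df, required, sprintf("file '%s'", path))
  for (cl in numeric_cols) {
    raw <- df[[cl]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & raw != "NA")
    if (length(bad) > 0L) {
      abort("file '%s': non-numeric value in column '%s' at data line(s) %s",
            path, cl, paste(head(bad, 5L), collapse = ", "))
    }
    df[[cl]] <- val
  }
  df
}

#' Read / write a PSM reporter-intensity table
#'
#' Columns: `psm_id`, `gene`, `unique`, `set_id` and the ten reporter
#' channels of [tmt10_channels()].
#'
#' @param path File path (TSV).
#' @return Data frame in the [sweep_psm_ratios()] schema.
#' @export
read_psm_table <- function(path) {
  df <- read_table_generic(path, c("psm_id", "gene", "unique", "set_id",
                                   tmt10_channels()),
                           numeric_cols = tmt10_channels())
  if (any(duplicated(df$psm_id))) {
    abort("file '%s': duplicate psm_id values", path)
  }
  df$unique <- as.logical(df$unique)
  df
}

#' @rdname read_psm_table
#' @param psm PSM data frame to write.
#' @export
write_psm_table <- function(psm, path) {
  assert_columns(psm, c("psm_id", "gene", "unique", "set_id", tmt10_channels()),
                 "PSM table")
  write_table_generic(psm, path)
}

#' Read / write a gene x sample count matrix
#'
#' TSV with a leading `gene` column; remaining columns are samples.
#'
#' @param path File path (TSV).
#' @return Integer matrix with gene rownames.
#' @export
read_count_matrix <- function(path) {
  df <- read_table_generic(path, "gene")
  if (any(duplicated(df$gene))) abort("file '%s': duplicate gene rows", path)
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  storage.mode(m) <- "numeric"
  if (any(is.na(m)) || any(m != round(m)) || any(m < 0)) {
    abort("file '%s': counts must be non-negative integers", path)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene
  m
}

#' @rdname read_count_matrix
#' @param counts Integer matrix (genes x samples) to write.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_generic(df, path)
}

#' Read / write a drug-screen plate table (CSV)
#'
#' Columns: `plate_id`, `well`, `compound`, `arm`, `conc_molar`,
#' `signal`, `control` (`none`/`neg`/`pos`).
#'
#' @param path File path (CSV).
#' @return Data frame in the [normalize_plate()] schema.
#' @export
read_plate_table <- function(path) {
  df <- read_table_generic(path, c("plate_id", "well", "compound", "arm",
                                   "conc_molar", "signal", "control"),
                           numeric_cols = c("conc_molar", "signal"),
                           sep = ",")
  bad <- setdiff(unique(df$control), c("none", "neg", "pos"))
  if (length(bad) > 0L) {
    abort("file '%s': invalid control flag(s): %s", path,
          paste(bad, collapse = ", "))
  }
  df
}

#' @rdname read_plate_table
#' @param plates Plate data frame to write.
#' @export
write_plate_table <- function(plates, path) {
  assert_columns(plates, c("plate_id", "well", "compound", "arm",
                           "conc_molar", "signal", "control"), "plate table")
  write_table_generic(plates, path, sep = ",")
}

#' Read / write ChIP target evidence
#'
#' TSV with columns `gene`, `experiment`.
#'
#' @param path File path (TSV).
#' @return Data frame `gene`, `experiment`.
#' @export
read_chip_table <- function(path) {
  read_table_generic(path, c("gene", "experiment"))
}

#' @rdname read_chip_table
#' @param evidence ChIP evidence data frame to write.
#' @export
write_chip_table <- function(evidence, path) {
  assert_columns(evidence, c("gene", "experiment"), "ChIP evidence")
  write_table_generic(evidence, path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. Lines with fewer than three fields are parse
#' errors.
#'
#' @param path File path (GMT).
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      abort("file '%s': GMT line %d has %d field(s); need >= 3",
            path, i, length(fields))
    }
    sets[[fields[1L]]] <- unique(fields[-c(1L, 2L)])
  }
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an annotation table with required columns
#'
#' Generic TSV reader for gene-category (`gene`, `category`) and
#' drug-target (`compound`, `target`, optional `source`) annotations.
#'
#' @param path File path (TSV).
#' @param required Required column names.
#' @return Data frame.
#' @export
read_annotation <- function(path, required) {
  read_table_generic(path, required)
}

#' Read / write DEA result tables
#'
#' TSV with columns `gene`, `log2fc`, `p_raw`, `p_adj`, `significant`,
#' `evidence_n`, `level`, `contrast`.
#'
#' @param path File path (TSV).
#' @return `DeaResult` data frame.
#' @export
read_dea_results <- function(path) {
  df <- read_table_generic(path, c("gene", "log2fc", "p_raw", "p_adj",
                                   "significant", "evidence_n", "level",
                                   "contrast"),
                           numeric_cols = c("log2fc", "p_raw", "p_adj",
                                            "evidence_n"))
  df$significant <- as.logical(df$significant)
  df
}

#' @rdname read_dea_results
#' @param dea `DeaResult` data frame to write.
#' @export
write_dea_results <- function(dea, path) {
  assert_columns(dea, c("gene", "log2fc", "p_raw", "p_adj", "significant",
                        "evidence_n", "level", "contrast"), "DEA results")
  write_table_generic(dea, path)
}

#' Write a protein ratio matrix with its PSM-count sidecar column
#'
#' @param prm A [protein_ratio_matrix()].
#' @param path Output path (TSV); columns `gene`, `n_psms`, then one
#'   column per sample.
#' @export
write_protein_matrix <- function(prm, path) {
  stopifnot(inherits(prm, "ProteinRatioMatrix"))
  df <- data.frame(gene = rownames(prm$mat),
                   n_psms = as.integer(prm$n_psms),
                   prm$mat, check.names = FALSE, stringsAsFactors = FALSE)
  write_table_generic(df, path)
}

#' @rdname write_protein_matrix
#' @param set_id Set identifier to attach on read.
#' @export
read_protein_matrix <- function(path, set_id = NA_character_) {
  df <- read_table_generic(path, c("gene", "n_psms"))
  samp <- setdiff(names(df), c("gene", "n_psms"))
  m <- as.matrix(df[, samp, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- df$gene
  protein_ratio_matrix(m, as.integer(df$n_psms), set_id = set_id)
}

#' Read a newline-delimited gene list
#'
#' @param path File path; one gene symbol per line.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  x <- trimws(readLines(path, encoding = "UTF-8"))
  x[nzchar(x)]
}
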