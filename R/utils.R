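# Internal helpers shared across modules.

#' Reporter channel column names for a TMT 10-plex table
#'
#' @return Character vector of the ten reporter-intensity column names, in
#'   mass order (126, 127N, 127C, ..., 131).
#' @export
tmt10_channels <- function() {
  c("tmt_126", "tmt_127n", "tmt_127c", "tmt_128n", "tmt_128c",
    "tmt_129n", "tmt_129c", "tmt_130n", "tmt_130c", "tmt_131")
}

# stop() with call. = FALSE and sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# one structured log line per pipeline stage
log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Newton iteration for the inverse of trigamma(); used when estimating the
# prior degrees of freedom of the variance model by method of moments.
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in seq_len(50)) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-8) break
    }
    y
  }, numeric(1))
}

# uppercase gene symbols: the package's gene identity convention
canon_gene <- function(x) toupper(trimws(as.character(x)))
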