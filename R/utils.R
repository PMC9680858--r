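# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# stop() wrapper giving consistent condition classes for testing
coex_abort <- function(msg, class = "coexnet_error", ...) {
  rlang::abort(msg, class = c(class, "coexnet_error"), ...)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (is.finite(x) || allow_inf) && x >= lower && x <= upper
  if (!ok) {
    coex_abort(sprintf("`%s` must be a single number in [%s, %s].",
                       name, format(lower), format(upper)))
  }
  invisible(x)
}

# suggest near matches for a mistyped gene identifier
near_matches <- function(x, candidates, n = 5L) {
  hits <- agrep(x, candidates, max.distance = 0.25, value = TRUE)
  if (length(hits) == 0L) hits <- head(candidates, n)
  head(hits, n)
}

# delimiter from file extension; gzip suffix is transparent
infer_delim <- function(path) {
  base <- sub("\\.gz$", "", path)
  if (grepl("\\.csv$", base, ignore.case = TRUE)) "," else "\t"
}
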