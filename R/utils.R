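#' @keywords internal
"_PACKAGE"

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

#' Derive a named RNG substream seed from a master seed
#'
#' Each simulation stage consumes its own substream so that, e.g., adding
#' methylation sites never perturbs behaviour draws. The substream seed is a
#' deterministic hash of the master seed and the stream name, kept below
#' 2^31 - 1.
#'
#' @param seed master integer seed
#' @param stream character stream name
#' @return an integer seed
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  # (seed * 48271 + h) stays below 2^53, so the modulus is computed exactly
  as.integer(((abs(seed) %% 2147483629) * 48271 + h) %% 2147483629 + 1)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_config(field, "must be a single strictly positive number")
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_config(field, "must be a single non-negative number")
  invisible(x)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(field, "must lie in [0, 1]")
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`; the single
#' multiple-testing path used by every stage of the package.
#'
#' @param p numeric vector of p-values
#' @return q-values, same length and order as `p`
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
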