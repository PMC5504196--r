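#' Configuration for trimodal latency simulations
#'
#' Bundles everything a simulator needs: a common counter threshold `shape`,
#' one Poisson intensity rate per modality, the number of trials, a master
#' seed, and (for the race model) the target Pearson correlation matrix of
#' the three channel latencies. The threshold is shared across modalities;
#' only the rates differ.
#'
#' @param shape Positive integer counter threshold, common to all modalities.
#' @param rates Named numeric vector `c(A = , V = , S = )` of intensity rates
#'   (events/ms).
#' @param n Number of trials per condition.
#' @param seed Master integer seed; per-condition and per-architecture
#'   substreams are derived from it deterministically.
#' @param correlation 3x3 symmetric unit-diagonal matrix of target Pearson
#'   correlations between channel latencies (rows/cols A, V, S), or a named
#'   list/vector with entries `r_AV`, `r_AS`, `r_VS`. Default: independence.
#'
#' @return An object of class `trimodal_config`.
#' @examples
#' trimodal_config(shape = 2, rates = c(A = 0.01, V = 0.01, S = 0.01), n = 2000)
#' @export
trimodal_config <- function(shape = 2,
                            rates = c(A = 0.01, V = 0.01, S = 0.01),
                            n = 2000,
                            seed = 1,
                            correlation = diag(3)) {
  if (is.null(names(rates))) names(rates) <- MODALITIES
  if (!setequal(names(rates), MODALITIES)) {
    abort("`rates` must be named with modalities A, V, S.")
  }
  rates <- rates[MODALITIES]
  if (any(rates <= 0)) abort("All rates must be positive (events/ms).")
  specs <- lapply(rates, function(r) erlang_spec(shape, r))
  if (length(n) != 1L || n < 1 || n != round(n)) {
    abort("`n` must be a single positive integer.")
  }
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed)) {
    abort("`seed` must be a single integer.")
  }
  if (!is.matrix(correlation)) {
    cl <- as.list(correlation)
    correlation <- correlation_matrix(cl$r_AV %||% 0, cl$r_AS %||% 0,
                                      cl$r_VS %||% 0)
  }
  dimnames(correlation) <- list(MODALITIES, MODALITIES)
  check_correlation_matrix(correlation)
  structure(
    list(shape = as.integer(shape), rates = rates, specs = specs,
         n = as.integer(n), seed = as.integer(seed), correlation = correlation),
    class = "trimodal_config")
}

#' @export
print.trimodal_config <- function(x, ...) {
  cat(sprintf("<trimodal_config> shape = %d, n = %d, seed = %d\n",
              x$shape, x$n, x$seed))
  cat(sprintf("  rates (/ms): A = %g, V = %g, S = %g\n",
              x$rates["A"], x$rates["V"], x$rates["S"]))
  cat(sprintf("  target correlations: r_AV = %.3f, r_AS = %.3f, r_VS = %.3f\n",
              x$correlation["A", "V"], x$correlation["A", "S"],
              x$correlation["V", "S"]))
  invisible(x)
}

# Deterministic substream seed below 2^31, derived from the master seed and a
# stream label, so that mixed-architecture compositions are reproducible
# stream by stream.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((abs(as.numeric(seed)) * 48271 + h * 69621 + 11) %% 2147483629)
}

# Which unimodal channels feed each condition.
condition_members <- list(
  A = "A", V = "V", S = "S",
  AV = c("A", "V"), VS = c("V", "S"), AS = c("A", "S"),
  AVS = c("A", "V", "S")
)
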