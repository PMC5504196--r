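#' Empirical distribution functions for reaction times
#'
#' `fit_ecdf()` builds the right-continuous empirical CDF of a latency sample:
#' a step function putting mass 1/n on each observation ("P(RT <= t)"
#' convention, ties accumulate). `eval_cdf()` evaluates a CDF -- an ECDF from
#' `fit_ecdf()`, any function of t, or an [erlang_spec()] -- on a sorted time
#' grid.
#'
#' @param x Non-empty numeric vector of non-negative latencies (ms).
#' @param cdf A function (e.g. from `fit_ecdf()`), an [erlang_spec()], or a
#'   numeric vector already evaluated on `grid`.
#' @param grid Numeric vector of times (ms), sorted ascending.
#'
#' @return `fit_ecdf()` returns a function of class `c("rt_ecdf", "ecdf", ...)`
#'   with attributes `n` and `sorted_values`; `eval_cdf()` returns a numeric
#'   vector of probabilities, monotone non-decreasing along `grid`.
#' @examples
#' F <- fit_ecdf(c(5, 10, 10, 20))
#' eval_cdf(F, c(0, 10, 25)) # 0, 0.75, 1
#' @export
fit_ecdf <- function(x) {
  if (length(x) == 0L) abort("Cannot fit an ECDF to an empty sample.")
  if (!is.numeric(x) || any(!is.finite(x))) abort("Latencies must be finite numbers.")
  if (any(x < 0)) abort("Latencies must be non-negative (ms).")
  f <- stats::ecdf(x)
  class(f) <- c("rt_ecdf", class(f))
  attr(f, "n") <- length(x)
  attr(f, "sorted_values") <- sort(x)
  f
}

#' @rdname fit_ecdf
#' @export
eval_cdf <- function(cdf, grid) {
  if (is.unsorted(grid)) abort("`grid` must be sorted ascending.")
  if (is.numeric(cdf)) {
    if (length(cdf) != length(grid)) {
      abort("A numeric `cdf` must have one value per grid point.")
    }
    return(cdf)
  }
  if (inherits(cdf, "erlang_spec")) return(erlang_cdf(cdf, grid))
  if (!is.function(cdf)) abort("`cdf` must be a function, numeric vector, or erlang_spec.")
  cdf(grid)
}

#' @export
print.rt_ecdf <- function(x, ...) {
  v <- attr(x, "sorted_values")
  cat(sprintf("<rt_ecdf> n = %d, range [%.4g, %.4g] ms\n",
              attr(x, "n"), v[1], v[length(v)]))
  invisible(x)
}

# One-sample Dvoretzky-Kiefer-Wolfowitz band half-width at level 1 - alpha.
dkw_epsilon <- function(n, alpha = 0.05) sqrt(log(2 / alpha) / (2 * n))

# Two-sample sup-distance tolerance for comparing two ECDFs.
dkw_two_sample <- function(n1, n2, alpha = 0.01) {
  sqrt(log(2 / alpha) / 2) * sqrt(1 / n1 + 1 / n2)
}

# Sup distance between two CDFs evaluated on a grid.
sup_distance <- function(f, g, grid) max(abs(eval_cdf(f, grid) - eval_cdf(g, grid)))
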