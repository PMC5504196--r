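#' Erlang channel-latency specification
#'
#' Detection latency of a single modality is modelled as the waiting time for
#' the `shape`-th event of a Poisson process with intensity `rate`, i.e. an
#' Erlang (integer-shape gamma) random variable. Times are in milliseconds,
#' rates in events per millisecond.
#'
#' @param shape Positive integer event-count threshold (the counter criterion).
#' @param rate Positive intensity rate, events/ms.
#'
#' @return An object of class `erlang_spec`: a list with fields `shape` and
#'   `rate`.
#' @examples
#' spec <- erlang_spec(2, 0.01)
#' erlang_mean(spec) # 200 ms
#' @export
erlang_spec <- function(shape, rate) {
  if (length(shape) != 1L || !is.numeric(shape) || is.na(shape) ||
      shape < 1 || shape != round(shape)) {
    abort("`shape` must be a single integer >= 1.")
  }
  if (length(rate) != 1L || !is.numeric(rate) || is.na(rate) || rate <= 0) {
    abort("`rate` must be a single positive number (events/ms).")
  }
  structure(list(shape = as.integer(shape), rate = as.numeric(rate)),
            class = "erlang_spec")
}

#' @export
print.erlang_spec <- function(x, ...) {
  cat(sprintf("<erlang_spec> shape = %d, rate = %g /ms (mean %.4g ms)\n",
              x$shape, x$rate, erlang_mean(x)))
  invisible(x)
}

as_erlang_spec <- function(x) {
  if (inherits(x, "erlang_spec")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(erlang_spec(x[[1]], x[[2]]))
  abort("Expected an `erlang_spec` (see `erlang_spec()`).")
}

#' Erlang distribution function, quantiles, mean and draws
#'
#' `erlang_cdf()` evaluates P(D <= t) for the latency D of an
#' [erlang_spec()] channel; `erlang_quantile()` is its inverse;
#' `erlang_mean()` returns E D = shape/rate; `erlang_draw()` samples.
#'
#' @param spec An [erlang_spec()].
#' @param t Vector of non-negative times (ms).
#' @param p Vector of probabilities in \[0, 1\].
#' @param n Number of draws.
#'
#' @return `erlang_cdf()` and `erlang_quantile()` return numeric vectors the
#'   length of their input; `erlang_mean()` a scalar (ms); `erlang_draw()` a
#'   numeric vector of latencies (ms).
#' @examples
#' erlang_cdf(erlang_spec(2, 0.03), c(0, 66.667, 500))
#' @export
erlang_cdf <- function(spec, t) {
  spec <- as_erlang_spec(spec)
  if (any(!is.finite(t) & !is.infinite(t)) || any(t < 0, na.rm = TRUE)) {
    abort("`t` must be non-negative times (ms).")
  }
  pgamma(t, shape = spec$shape, rate = spec$rate)
}

#' @rdname erlang_cdf
#' @export
erlang_quantile <- function(spec, p) {
  spec <- as_erlang_spec(spec)
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("`p` must lie in [0, 1].")
  qgamma(p, shape = spec$shape, rate = spec$rate)
}

#' @rdname erlang_cdf
#' @export
erlang_mean <- function(spec) {
  spec <- as_erlang_spec(spec)
  spec$shape / spec$rate
}

#' @rdname erlang_cdf
#' @export
erlang_draw <- function(spec, n) {
  spec <- as_erlang_spec(spec)
  rgamma(n, shape = spec$shape, rate = spec$rate)
}

#' Method-of-moments rate recovery for Erlang samples
#'
#' Given latencies from a single modality and a known counter threshold
#' `shape`, estimates the Poisson intensity rate by the method of moments,
#' `rate = shape / mean(rt)`. The standard error follows from the delta
#' method: `sd(rate_hat) ~= rate / sqrt(shape * n)`.
#'
#' @param data A data frame with an `rt_ms` column, or a numeric vector of
#'   latencies (ms).
#' @param shape Known integer shape of the Erlang family.
#'
#' @return A one-row tibble with columns `shape`, `rate`, `se` and `n`.
#' @examples
#' x <- erlang_draw(erlang_spec(2, 0.01), 500)
#' estimate_erlang_rate(x, shape = 2)
#' @export
estimate_erlang_rate <- function(data, shape) {
  x <- if (is.data.frame(data)) data$rt_ms else data
  if (is.null(x) || !is.numeric(x) || length(x) == 0L) {
    abort("`data` must be a numeric vector or a data frame with an `rt_ms` column.")
  }
  if (any(x < 0)) abort("Latencies must be non-negative.")
  rate_hat <- shape / mean(x)
  tibble::tibble(
    shape = as.integer(shape),
    rate = rate_hat,
    se = rate_hat / sqrt(shape * length(x)),
    n = length(x)
  )
}
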