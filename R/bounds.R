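# The bound family. Names follow the inputs: e.g. bonf_AV_AS_A is the
# Bonferroni-type curve F_AV + F_AS - F_A bounding F_AVS.

clip01 <- function(x) pmin(pmax(x, 0), 1)

new_bound_curve <- function(name, grid, values, assumes = NULL) {
  out <- tibble::tibble(bound = name, time = grid, value = clip01(values))
  if (!is.null(assumes)) attr(out, "assumes") <- assumes
  class(out) <- c("bound_curve", class(out))
  out
}

#' Race-model bound curves
#'
#' Upper bounds on a redundant-condition distribution function implied by the
#' race architecture under context invariance, each evaluated on a common
#' time grid and clipped to \[0, 1\]:
#'
#' * `bimodal_bound()`: the classical bimodal bound
#'   `F_xy(t) <= F_x(t) + F_y(t)`.
#' * `boole3_bound()`: the Boole bound
#'   `F_AVS(t) <= F_A(t) + F_V(t) + F_S(t)`.
#' * `bonferroni_bounds()`: the three Bonferroni-type trimodal bounds
#'   `F_AVS <= F_AV + F_AS - F_A`, `F_AVS <= F_VS + F_AS - F_S`,
#'   `F_AVS <= F_AV + F_VS - F_V` (raw values additionally floored at 0).
#' * `sharp_bound()`: their pointwise minimum -- the sharpest bound the
#'   complete trimodal family provides; whenever the bimodal bounds hold,
#'   each Bonferroni curve, hence the sharp curve, lies below the Boole curve.
#' * `restricted_bound()`: `F_AVS <= F_pair + F_single` (e.g.
#'   `F_AV + F_S`), the bound available when a bimodal condition stands in
#'   for a combined "unimodal" channel and context invariance is assumed
#'   only for that bivariate pairing.
#'
#' CDF arguments may be functions (e.g. [fit_ecdf()] output or an
#' [erlang_spec()] closure), [erlang_spec()] objects, or numeric vectors
#' already evaluated on `grid`.
#'
#' @param F_x,F_y,F_A,F_V,F_S,F_AV,F_VS,F_AS,F_pair,F_single CDFs as above.
#' @param grid Sorted time grid (ms).
#' @param name Bound identifier for the output.
#' @param bonferroni The tibble returned by `bonferroni_bounds()` (all three
#'   curves, one shared grid).
#' @param pair,single Condition labels recorded as metadata on the restricted
#'   bound (which restricted context-invariance identity it presumes).
#'
#' @return A tibble with columns `bound`, `time`, `value` (probabilities in
#'   \[0, 1\]); `bonferroni_bounds()` stacks three such curves;
#'   `sharp_bound()` adds an `argmin` column naming the active curve(s) at
#'   each time.
#' @examples
#' g <- seq(0, 600, by = 5)
#' FA <- erlang_spec(2, 0.01)
#' b <- boole3_bound(FA, FA, FA, g)
#' head(b)
#' @export
bimodal_bound <- function(F_x, F_y, grid, name = "bimodal") {
  new_bound_curve(name, grid, eval_cdf(F_x, grid) + eval_cdf(F_y, grid))
}

#' @rdname bimodal_bound
#' @export
boole3_bound <- function(F_A, F_V, F_S, grid) {
  new_bound_curve(
    "boole3", grid,
    eval_cdf(F_A, grid) + eval_cdf(F_V, grid) + eval_cdf(F_S, grid))
}

#' @rdname bimodal_bound
#' @export
bonferroni_bounds <- function(F_AV, F_VS, F_AS, F_A, F_V, F_S, grid) {
  fav <- eval_cdf(F_AV, grid); fvs <- eval_cdf(F_VS, grid)
  fas <- eval_cdf(F_AS, grid)
  fa <- eval_cdf(F_A, grid); fv <- eval_cdf(F_V, grid); fs <- eval_cdf(F_S, grid)
  dplyr::bind_rows(
    new_bound_curve("bonf_AV_AS_A", grid, fav + fas - fa),
    new_bound_curve("bonf_VS_AS_S", grid, fvs + fas - fs),
    new_bound_curve("bonf_AV_VS_V", grid, fav + fvs - fv)
  )
}

#' @rdname bimodal_bound
#' @export
sharp_bound <- function(bonferroni) {
  stopifnot(is.data.frame(bonferroni),
            all(c("bound", "time", "value") %in% names(bonferroni)))
  wide <- tidyr::pivot_wider(bonferroni, id_cols = "time",
                             names_from = "bound", values_from = "value")
  curves <- setdiff(names(wide), "time")
  if (length(curves) != 3L || anyNA(wide)) {
    abort("sharp_bound() needs all three Bonferroni curves on one common grid.")
  }
  m <- as.matrix(wide[curves])
  vmin <- do.call(pmin, as.data.frame(m))
  argmin <- apply(m <= vmin + 1e-12, 1L,
                  function(is_min) paste(curves[is_min], collapse = ","))
  out <- new_bound_curve("sharp", wide$time, vmin)
  out$argmin <- argmin
  out
}

#' @rdname bimodal_bound
#' @export
restricted_bound <- function(F_pair, F_single, grid, pair = "AV", single = "S") {
  new_bound_curve(
    sprintf("restricted_(%s)%s", pair, single), grid,
    eval_cdf(F_pair, grid) + eval_cdf(F_single, grid),
    assumes = sprintf(
      "bivariate context invariance for the combined channel %s raced against %s",
      pair, single))
}

#' Where does an observed CDF exceed a bound?
#'
#' Compares a redundant-condition CDF with a bound curve on the bound's grid.
#' The bound counts as violated if the CDF exceeds it by more than
#' `tolerance` at some grid point; the violated region is reported both in
#' time and in percentiles of the redundant-condition distribution itself
#' (the percentile p is violated when the CDF exceeds the bound where it
#' equals p), matching the convention of reading violations off the CDF's own
#' y-axis.
#'
#' @param F_redundant CDF of the redundant condition (function,
#'   [erlang_spec()], or numeric vector on the bound's grid).
#' @param bound A bound-curve tibble (single curve) from the bound
#'   constructors.
#' @param tolerance Allowed exceedance before flagging; use 0 for analytic
#'   CDFs, a DKW-style band for ECDFs ([rmi_report()] sets this
#'   automatically).
#'
#' @return A one-row tibble: `bound`, `violated`, `max_violation`,
#'   `t_first`, `t_last` (ms), `pct_first`, `pct_last` (percent), `tolerance`.
#'   `max_violation` is the largest raw exceedance over the violated region,
#'   0 when not violated.
#' @examples
#' g <- seq(0, 600, by = 2)
#' bound <- sharp_bound(bonferroni_bounds(
#'   function(t) pmin(2 * pgamma(t, 2, rate = 0.01), 1),
#'   function(t) pmin(2 * pgamma(t, 2, rate = 0.01), 1),
#'   function(t) pmin(2 * pgamma(t, 2, rate = 0.01), 1),
#'   erlang_spec(2, 0.01), erlang_spec(2, 0.01), erlang_spec(2, 0.01), g))
#' assess_violation(erlang_spec(2, 0.03), bound)
#' @export
assess_violation <- function(F_redundant, bound, tolerance = 0) {
  stopifnot(is.data.frame(bound), all(c("bound", "time", "value") %in% names(bound)))
  if (length(unique(bound$bound)) != 1L) {
    abort("`bound` must contain a single bound curve; see rmi_report() for batches.")
  }
  name <- bound$bound[1]
  times <- bound$time
  fr <- eval_cdf(F_redundant, times)
  excess <- fr - bound$value
  # strict exceedance only: exact ties (e.g. ECDF sums sharing float terms)
  # are not violations, so guard with machine-precision slack
  hit <- excess > tolerance + 1e-12
  if (!any(hit)) {
    return(tibble::tibble(
      bound = name, violated = FALSE, max_violation = 0,
      t_first = NA_real_, t_last = NA_real_,
      pct_first = NA_real_, pct_last = NA_real_, tolerance = tolerance))
  }
  idx <- which(hit)
  tibble::tibble(
    bound = name, violated = TRUE,
    max_violation = max(excess[idx]),
    t_first = times[min(idx)], t_last = times[max(idx)],
    pct_first = 100 * min(fr[idx]), pct_last = 100 * max(fr[idx]),
    tolerance = tolerance)
}
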