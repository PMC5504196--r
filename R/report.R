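# Orchestration: compute every applicable bound for a condition table and
# assess violations. Each bound has a target (the redundant condition it
# bounds) and required input conditions; bounds whose conditions are missing
# are skipped with a reason, per the incomplete-design use case.

bound_catalog <- function() {
  tibble::tribble(
    ~name,               ~target, ~inputs,
    "bimodal_AV",        "AV",    list(c("A", "V")),
    "bimodal_VS",        "VS",    list(c("V", "S")),
    "bimodal_AS",        "AS",    list(c("A", "S")),
    "boole3",            "AVS",   list(c("A", "V", "S")),
    "bonf_AV_AS_A",      "AVS",   list(c("AV", "AS", "A")),
    "bonf_VS_AS_S",      "AVS",   list(c("VS", "AS", "S")),
    "bonf_AV_VS_V",      "AVS",   list(c("AV", "VS", "V")),
    "sharp",             "AVS",   list(c("AV", "VS", "AS", "A", "V", "S")),
    "restricted_(AV)S",  "AVS",   list(c("AV", "S")),
    "restricted_(VS)A",  "AVS",   list(c("VS", "A")),
    "restricted_(AS)V",  "AVS",   list(c("AS", "V")),
  ) |> tidyr::unnest_wider("inputs", names_sep = "") |>
    dplyr::rename(inputs = "inputs1")
}

compute_bound <- function(name, F, grid) {
  switch(name,
    bimodal_AV = bimodal_bound(F$A, F$V, grid, "bimodal_AV"),
    bimodal_VS = bimodal_bound(F$V, F$S, grid, "bimodal_VS"),
    bimodal_AS = bimodal_bound(F$A, F$S, grid, "bimodal_AS"),
    boole3 = boole3_bound(F$A, F$V, F$S, grid),
    bonf_AV_AS_A = ,
    bonf_VS_AS_S = ,
    bonf_AV_VS_V = dplyr::filter(
      bonferroni_bounds(F$AV, F$VS, F$AS, F$A, F$V, F$S, grid),
      .data$bound == name),
    sharp = sharp_bound(
      bonferroni_bounds(F$AV, F$VS, F$AS, F$A, F$V, F$S, grid)),
    `restricted_(AV)S` = restricted_bound(F$AV, F$S, grid, "AV", "S"),
    `restricted_(VS)A` = restricted_bound(F$VS, F$A, grid, "VS", "A"),
    `restricted_(AS)V` = restricted_bound(F$AS, F$V, grid, "AS", "V"),
    abort(sprintf("Unknown bound '%s'.", name))
  )
}

#' Full race-model-inequality report for a condition table
#'
#' Computes every bound in the family whose input conditions are present --
#' the three bimodal bounds, the Boole and Bonferroni-type trimodal bounds,
#' their sharp pointwise minimum, and the three restricted bounds for
#' incomplete designs -- evaluates each against the ECDF of its target
#' redundant condition, and reports where the target exceeds the bound.
#' Bounds whose inputs or target are missing are listed as skipped, so
#' partial designs (e.g. only AVS, AV and S observed) are handled gracefully.
#'
#' The default violation tolerance for a bound is the sum of one-sample DKW
#' band half-widths at level `alpha` over the target and every input
#' condition, which suppresses pure sampling artifacts; set `tolerance = 0`
#' to read raw curve exceedance as in a plotted-figure comparison.
#'
#' @param data Long-format condition table (columns `condition`, `rt_ms`);
#'   condition labels are canonicalized (e.g. "VA" to "AV").
#' @param tolerance Either `NULL` (per-bound DKW default), or a single
#'   number applied to every bound.
#' @param alpha Level of the default DKW bands (0.05).
#' @param grid Time grid; default is the union of all observed values plus 0
#'   (bounds and ECDFs are step functions changing only there).
#'
#' @return An object of class `rmi_report`: a list with elements `curves`
#'   (long tibble `bound`, `time`, `value`), `violations` (one row per
#'   computed bound, see [assess_violation()], plus the `target` condition
#'   and its sample size), `skipped` (bound, reason), `ecdf` (long tibble of
#'   condition ECDFs on the grid), `conditions` (condition, n), and `grid`.
#'   Methods: [tidy()] (violation table), [glance()] (one-row summary),
#'   [autoplot()] (CDF-versus-bounds figure), `print()`.
#' @examples
#' rep <- rmi_report(generate_fixture("mixed_fig1", trimodal_config(n = 300)))
#' tidy(rep)
#' @export
rmi_report <- function(data, tolerance = NULL, alpha = 0.05, grid = NULL) {
  data <- validate_study_table(data)
  counts <- dplyr::count(data, .data$condition)
  present <- counts$condition
  n_of <- setNames(counts$n, counts$condition)
  grid <- grid %||% sort(unique(c(0, data$rt_ms)))
  if (is.unsorted(grid)) abort("`grid` must be sorted ascending.")
  F <- lapply(setNames(present, present),
              function(cond) fit_ecdf(data$rt_ms[data$condition == cond]))

  catalog <- bound_catalog()
  doable <- purrr::map_lgl(seq_len(nrow(catalog)), function(i) {
    catalog$target[i] %in% present && all(catalog$inputs[[i]] %in% present)
  })
  if (!any(doable)) {
    abort(paste0(
      "No bound is computable: need at least one redundant condition ",
      "together with the sub-conditions its bounds require."))
  }
  skipped <- purrr::map_dfr(which(!doable), function(i) {
    missing <- setdiff(c(catalog$target[i], catalog$inputs[[i]]), present)
    tibble::tibble(bound = catalog$name[i],
                   reason = paste0("missing conditions: ",
                                   paste(missing, collapse = ", ")))
  })

  curves <- purrr::map(which(doable),
                       function(i) compute_bound(catalog$name[i], F, grid))
  violations <- purrr::map_dfr(seq_along(curves), function(k) {
    i <- which(doable)[k]
    target <- catalog$target[i]
    tol <- tolerance %||%
      (dkw_epsilon(n_of[[target]], alpha) +
         sum(dkw_epsilon(unname(n_of[catalog$inputs[[i]]]), alpha)))
    dplyr::mutate(
      assess_violation(F[[target]], curves[[k]][c("bound", "time", "value")],
                       tolerance = tol),
      target = target, n_target = n_of[[target]], .after = "bound")
  })

  ecdf_tbl <- purrr::map_dfr(present, function(cond) {
    tibble::tibble(condition = cond, time = grid,
                   value = eval_cdf(F[[cond]], grid))
  })

  structure(
    list(curves = dplyr::bind_rows(curves), violations = violations,
         skipped = skipped, ecdf = ecdf_tbl,
         conditions = counts, grid = grid, alpha = alpha),
    class = "rmi_report")
}

#' @export
print.rmi_report <- function(x, ...) {
  cat(sprintf("<rmi_report> %d conditions, %d bounds computed, %d skipped\n",
              nrow(x$conditions), nrow(x$violations), nrow(x$skipped)))
  v <- x$violations
  if (any(v$violated)) {
    vv <- v[v$violated, ]
    cat("Violated bounds:\n")
    for (i in seq_len(nrow(vv))) {
      cat(sprintf(
        "  %s (target %s): max excess %.3f over t in [%.1f, %.1f] ms, percentiles %.1f-%.1f%%\n",
        vv$bound[i], vv$target[i], vv$max_violation[i],
        vv$t_first[i], vv$t_last[i], vv$pct_first[i], vv$pct_last[i]))
    }
  } else {
    cat("No bound violated at the working tolerance.\n")
  }
  if (nrow(x$skipped) > 0) {
    cat(sprintf("Skipped: %s\n", paste(x$skipped$bound, collapse = ", ")))
  }
  invisible(x)
}

#' Tidy and summary methods for rmi_report
#'
#' `tidy()` returns the violation table (one row per computed bound);
#' `glance()` a one-row summary.
#'
#' @param x An [rmi_report()] object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rmi_report <- function(x, ...) x$violations

#' @rdname tidy.rmi_report
#' @export
glance.rmi_report <- function(x, ...) {
  tibble::tibble(
    n_conditions = nrow(x$conditions),
    n_trials = sum(x$conditions$n),
    n_bounds = nrow(x$violations),
    n_skipped = nrow(x$skipped),
    n_violated = sum(x$violations$violated),
    max_violation = max(c(0, x$violations$max_violation))
  )
}

#' Plot observed CDFs against their race-model bounds
#'
#' One panel per redundant (target) condition: the target's empirical CDF as
#' a black step function, each computed bound as a coloured curve. Regions
#' where the step function rises above a bound are the violations reported
#' by [tidy()].
#'
#' @param object An [rmi_report()] object.
#' @param bounds Optional character vector restricting which bound curves to
#'   draw (default: all computed).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rmi_report <- function(object, bounds = NULL, ...) {
  v <- object$violations
  curves <- dplyr::left_join(object$curves,
                             v[c("bound", "target")], by = "bound")
  if (!is.null(bounds)) curves <- curves[curves$bound %in% bounds, ]
  obs <- dplyr::rename(object$ecdf, target = "condition")
  obs <- obs[obs$target %in% unique(curves$target), ]
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_step(data = obs, colour = "black", linewidth = 0.7) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$bound), linewidth = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$target)) +
    ggplot2::labs(x = "time (ms)", y = "P(RT <= t)",
                  colour = "bound",
                  title = "Observed CDFs vs race-model bounds") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
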