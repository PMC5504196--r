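#' Simulate the race architecture
#'
#' Draws joint channel latencies (D_A, D_V, D_S) with Erlang marginals and the
#' requested Pearson dependence (via a calibrated Gaussian copula), then
#' derives all seven condition samples from the *same* joint draws: unimodal
#' conditions are the marginal columns, redundant conditions the per-trial
#' minima. Sharing trials realizes complete context invariance by
#' construction, so the output is a true-positive control for
#' [check_context_invariance()] and satisfies every race-model bound up to
#' sampling error.
#'
#' The requested correlation matrix must be positive semidefinite (the
#' Stanley-Wang admissibility constraint); targets below the copula's
#' countermonotone floor, or whose latent matrix leaves the admissible set,
#' are clamped with a warning. Both requested and achieved correlations are
#' attached to the result.
#'
#' @param config A [trimodal_config()].
#'
#' @return A tibble with columns `condition`, `rt_ms`, `trial`,
#'   `architecture`, one block of `config$n` rows per condition, with
#'   attributes `joint` (tibble of per-trial `trial`, `A`, `V`, `S`
#'   latencies), `correlation_requested`, `correlation_latent`,
#'   `correlation_achieved`, and `config`.
#' @examples
#' cfg <- trimodal_config(n = 200, seed = 7)
#' race <- simulate_race(cfg)
#' dplyr::count(race, condition)
#' @export
simulate_race <- function(config) {
  stopifnot(inherits(config, "trimodal_config"))
  identity_corr <- max(abs(config$correlation - diag(3))) == 0
  if (identity_corr) {
    latent <- diag(3)
    dimnames(latent) <- list(MODALITIES, MODALITIES)
    achieved <- latent
  } else {
    res <- resolve_copula_correlation(config$correlation, config$shape)
    latent <- res$latent
    achieved <- res$achieved
  }
  set.seed(substream_seed(config$seed, "race"))
  z <- matrix(rnorm(3L * config$n), ncol = 3L) %*% psd_sqrt(latent)
  x <- vapply(seq_along(MODALITIES), function(j) {
    qgamma(pnorm(z[, j], lower.tail = FALSE),
           shape = config$shape, rate = config$rates[[MODALITIES[j]]],
           lower.tail = FALSE)
  }, numeric(config$n))
  x <- matrix(x, nrow = config$n, dimnames = list(NULL, MODALITIES))
  joint <- tibble::as_tibble(x)
  joint$trial <- seq_len(config$n)
  joint <- joint[, c("trial", MODALITIES)]

  out <- purrr::map_dfr(CONDITIONS, function(cond) {
    cols <- condition_members[[cond]]
    tibble::tibble(
      condition = cond,
      rt_ms = as.numeric(
        if (length(cols) == 1L) x[, cols]
        else do.call(pmin, as.data.frame(x[, cols, drop = FALSE]))),
      trial = seq_len(config$n),
      architecture = "race"
    )
  })
  attr(out, "joint") <- joint
  attr(out, "correlation_requested") <- config$correlation
  attr(out, "correlation_latent") <- latent
  attr(out, "correlation_achieved") <- achieved
  attr(out, "config") <- config
  out
}

#' Simulate the superposition (coactivation) architecture
#'
#' Under the Poisson superposition model the channel counting processes add,
#' so the latency for any stimulus combination is again Erlang with the same
#' threshold and rate equal to the *sum* of the member channel rates:
#' unimodal conditions are Gamma(shape, rate_x), bimodal Gamma(shape,
#' rate_x + rate_y), trimodal Gamma(shape, rate_A + rate_V + rate_S). Each
#' condition is drawn from its own deterministic substream of the master
#' seed. The correlation matrix in `config` plays no role here and is noted
#' as ignored when non-trivial.
#'
#' @param config A [trimodal_config()].
#'
#' @return A tibble with columns `condition`, `rt_ms`, `trial`,
#'   `architecture` (= "superposition"), `config$n` rows per condition.
#' @examples
#' sup <- simulate_superposition(trimodal_config(n = 200, seed = 7))
#' mean(sup$rt_ms[sup$condition == "AVS"]) # about 2 / 0.03 = 66.7 ms
#' @export
simulate_superposition <- function(config) {
  stopifnot(inherits(config, "trimodal_config"))
  if (max(abs(config$correlation - diag(3))) > 0) {
    inform("simulate_superposition(): the correlation matrix is ignored (channel counts pool into one process).")
  }
  out <- purrr::map_dfr(CONDITIONS, function(cond) {
    rate <- sum(config$rates[condition_members[[cond]]])
    set.seed(substream_seed(config$seed, paste0("superposition_", cond)))
    tibble::tibble(
      condition = cond,
      rt_ms = rgamma(config$n, shape = config$shape, rate = rate),
      trial = seq_len(config$n),
      architecture = "superposition"
    )
  })
  attr(out, "config") <- config
  out
}

#' Context-invariance diagnostic
#'
#' Complete context invariance -- the core assumption behind every race-model
#' bound -- requires each unimodal and bimodal condition distribution to equal
#' the corresponding marginal of the trivariate joint latency distribution.
#' Given joint draws and observed condition samples, this reports, identity
#' by identity, the sup-distance between the condition's ECDF and the ECDF of
#' the matching joint-derived latency (marginal column for unimodal
#' conditions, per-trial minimum for redundant ones), with a pass/fail at a
#' two-sample DKW-style tolerance. Conditions sharing the joint's trials pass
#' with distance 0; conditions absent from `data` are reported as not
#' checkable rather than failed.
#'
#' @param joint Either the tibble of per-trial `A`, `V`, `S` latencies or the
#'   output of [simulate_race()] (its `joint` attribute is used).
#' @param data A long-format condition table (columns `condition`, `rt_ms`).
#' @param tolerance Sup-distance threshold; default is the two-sample DKW
#'   band `sqrt(log(2/alpha)/2) * sqrt(1/n1 + 1/n2)`.
#' @param alpha Level for the default tolerance (0.01).
#'
#' @return A tibble of class `invariance_check` with one row per identity:
#'   `condition`, `identity`, `n_data`, `n_joint`, `sup_distance`,
#'   `tolerance`, `status` ("pass", "fail", or "not checkable").
#' @examples
#' race <- simulate_race(trimodal_config(n = 300, seed = 2))
#' check_context_invariance(race, race) # shared trials: all distances 0
#' @export
check_context_invariance <- function(joint, data, tolerance = NULL, alpha = 0.01) {
  if (is.data.frame(joint) && !is.null(attr(joint, "joint"))) {
    joint <- attr(joint, "joint")
  }
  if (!all(MODALITIES %in% names(joint))) {
    abort("`joint` must contain per-trial latency columns A, V, S.")
  }
  data <- validate_study_table(data)
  out <- purrr::map_dfr(CONDITIONS, function(cond) {
    cols <- condition_members[[cond]]
    derived <- if (length(cols) == 1L) joint[[cols]] else
      do.call(pmin, as.list(joint[cols]))
    identity <- sprintf("F_%s = %s marginal of the joint", cond,
                        if (length(cols) == 1L) "univariate"
                        else if (length(cols) == 2L) "bivariate (min)"
                        else "trivariate (min)")
    obs <- data$rt_ms[data$condition == cond]
    if (length(obs) == 0L) {
      return(tibble::tibble(condition = cond, identity = identity,
                            n_data = 0L, n_joint = length(derived),
                            sup_distance = NA_real_, tolerance = NA_real_,
                            status = "not checkable"))
    }
    grid <- sort(unique(c(obs, derived)))
    d <- sup_distance(fit_ecdf(obs), fit_ecdf(derived), grid)
    tol <- tolerance %||% dkw_two_sample(length(obs), length(derived), alpha)
    tibble::tibble(condition = cond, identity = identity,
                   n_data = length(obs), n_joint = length(derived),
                   sup_distance = d, tolerance = tol,
                   status = if (d <= tol) "pass" else "fail")
  })
  class(out) <- c("invariance_check", class(out))
  out
}

#' Redundant signals effect magnitudes
#'
#' For each redundant condition present, the mean reaction-time gain over the
#' fastest of its sub-conditions: `gain = min over sub-conditions of
#' mean(sub) - mean(redundant)`. Under a race with identical independent
#' channels the gain is strictly positive (statistical facilitation); a gain
#' of zero arises only for degenerate latencies.
#'
#' @param data Long-format condition table (columns `condition`, `rt_ms`).
#'
#' @return A tibble with one row per assessable redundant condition:
#'   `condition`, `gain_ms`, `fastest_subcondition`, `mean_redundant_ms`,
#'   `mean_fastest_ms`. Redundant conditions whose sub-conditions are all
#'   missing are omitted with a warning.
#' @examples
#' race <- simulate_race(trimodal_config(n = 500, seed = 3))
#' rse_magnitude(race)
#' @export
rse_magnitude <- function(data) {
  data <- validate_study_table(data)
  means <- vapply(split(data$rt_ms, data$condition), mean, numeric(1))
  redundant <- intersect(c("AV", "VS", "AS", "AVS"), names(means))
  skipped <- character()
  rows <- purrr::map_dfr(redundant, function(cond) {
    subs <- setdiff(names(condition_members)[
      vapply(condition_members,
             function(m) all(m %in% condition_members[[cond]]), logical(1))],
      cond)
    subs <- intersect(subs, names(means))
    if (length(subs) == 0L) {
      skipped <<- c(skipped, cond)
      return(NULL)
    }
    fastest <- subs[which.min(means[subs])]
    tibble::tibble(
      condition = cond,
      gain_ms = means[[fastest]] - means[[cond]],
      fastest_subcondition = fastest,
      mean_redundant_ms = means[[cond]],
      mean_fastest_ms = means[[fastest]]
    )
  })
  if (length(skipped) > 0L) {
    warn(sprintf("No sub-conditions available for: %s; omitted.",
                 paste(skipped, collapse = ", ")))
  }
  rows
}
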