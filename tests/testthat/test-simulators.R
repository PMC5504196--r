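test_that("seeded runs are bit-reproducible and substreams differ by architecture", {
  cfg <- ref_config(n = 200, seed = 9)
  expect_identical(simulate_race(cfg), simulate_race(cfg))
  expect_identical(simulate_superposition(cfg), simulate_superposition(cfg))
  expect_false(identical(condition_rt(simulate_race(cfg), "A"),
                         condition_rt(simulate_superposition(cfg), "A")))
  cfg2 <- ref_config(n = 200, seed = 10)
  expect_false(identical(simulate_race(cfg), simulate_race(cfg2)))
})

test_that("race unimodal marginals follow their Erlang specs (DKW band)", {
  cfg <- ref_config(n = 4000, seed = 21)
  race <- simulate_race(cfg)
  for (m in c("A", "V", "S")) {
    x <- condition_rt(race, m)
    grid <- sort(x)
    d <- max(abs(eval_cdf(fit_ecdf(x), grid) -
                   erlang_cdf(erlang_spec(2, 0.01), grid)))
    expect_lt(d, trirace:::dkw_epsilon(4000, 0.01))
  }
})

test_that("with shape 1 the race trimodal minimum is exponential with summed rate", {
  cfg <- ref_config(n = 8000, seed = 22, shape = 1)
  avs <- condition_rt(simulate_race(cfg), "AVS")
  grid <- sort(avs)
  d <- max(abs(eval_cdf(fit_ecdf(avs), grid) - (1 - exp(-0.03 * grid))))
  expect_lt(d, trirace:::dkw_epsilon(8000, 0.01))
  # and coincides with the superposition trimodal draw (same distribution)
  sup <- condition_rt(simulate_superposition(cfg), "AVS")
  both <- sort(c(avs, sup))
  d2 <- max(abs(eval_cdf(fit_ecdf(avs), both) - eval_cdf(fit_ecdf(sup), both)))
  expect_lt(d2, trirace:::dkw_two_sample(8000, 8000, 0.01))
})

test_that("independent race trimodal mean matches a brute-force independent-draw oracle", {
  cfg <- ref_config(n = 10000, seed = 23)
  avs <- condition_rt(simulate_race(cfg), "AVS")
  set.seed(991)
  oracle <- pmin(rgamma(10000, 2, rate = 0.01),
                 rgamma(10000, 2, rate = 0.01),
                 rgamma(10000, 2, rate = 0.01))
  se <- sqrt(var(avs) / 10000 + var(oracle) / 10000)
  expect_lt(abs(mean(avs) - mean(oracle)), 4 * se)
})

test_that("superposition redundant conditions are Erlang with summed rates", {
  cfg <- ref_config(n = 8000, seed = 24)
  sup <- simulate_superposition(cfg)
  for (case in list(list("AVS", 0.03), list("AV", 0.02), list("A", 0.01))) {
    x <- condition_rt(sup, case[[1]])
    grid <- sort(x)
    d <- max(abs(eval_cdf(fit_ecdf(x), grid) -
                   erlang_cdf(erlang_spec(2, case[[2]]), grid)))
    expect_lt(d, trirace:::dkw_epsilon(8000, 0.01))
  }
})

test_that("achieved pairwise correlations match the calibrated targets", {
  target <- trirace:::correlation_matrix(-0.3, 0.25, -0.2)
  cfg <- ref_config(n = 20000, seed = 25, correlation = target)
  race <- simulate_race(cfg)
  ach <- attr(race, "correlation_achieved")
  expect_equal(ach[upper.tri(ach)], target[upper.tri(target)], tolerance = 0.02)
  j <- attr(race, "joint")
  emp <- cor(as.matrix(j[c("A", "V", "S")]))
  expect_equal(emp[upper.tri(emp)], target[upper.tri(target)], tolerance = 0.03)
})

test_that("negative dependence speeds up redundant minima relative to independence", {
  ind <- simulate_race(ref_config(n = 10000, seed = 26))
  neg <- suppressWarnings(simulate_race(
    ref_config(n = 10000, seed = 27,
               correlation = trirace:::correlation_matrix(-0.5, -0.5, -0.5))))
  for (cond in c("AV", "AVS")) {
    a <- condition_rt(neg, cond); b <- condition_rt(ind, cond)
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    expect_lt(mean(a), mean(b) - 2 * se)
  }
})

test_that("context invariance holds by construction and perturbations are localized", {
  cfg <- ref_config(n = 2000, seed = 28)
  race <- simulate_race(cfg)
  shared <- check_context_invariance(race, race)
  expect_true(all(shared$status == "pass"))
  expect_true(all(shared$sup_distance == 0))

  # unimodal A resampled independently at the same spec: within tolerance
  resampled <- race
  set.seed(5150)
  resampled$rt_ms[resampled$condition == "A"] <- rgamma(2000, 2, rate = 0.01)
  fresh <- check_context_invariance(race, resampled)
  expect_true(all(fresh$status == "pass"))

  # halving the A rate is flagged on the A identity only
  perturbed <- race
  set.seed(5151)
  perturbed$rt_ms[perturbed$condition == "A"] <- rgamma(2000, 2, rate = 0.005)
  flagged <- check_context_invariance(race, perturbed)
  expect_identical(flagged$status[flagged$condition == "A"], "fail")
  expect_true(all(flagged$status[flagged$condition != "A"] == "pass"))

  # missing conditions are reported as not checkable, not failed
  partial <- dplyr::filter(race, condition %in% c("A", "AVS"))
  part <- check_context_invariance(race, partial)
  expect_identical(sort(part$condition[part$status == "not checkable"]),
                   sort(c("V", "S", "AV", "VS", "AS")))
})

test_that("rse_magnitude: degenerate zero gain, race facilitation, superposition closed form", {
  flat <- tibble::tibble(condition = rep(c("A", "V", "S", "AV", "VS", "AS", "AVS"), each = 5),
                         rt_ms = 100)
  expect_true(all(rse_magnitude(flat)$gain_ms == 0))

  race <- simulate_race(ref_config(n = 4000, seed = 29))
  expect_true(all(rse_magnitude(race)$gain_ms > 0))

  sup <- simulate_superposition(ref_config(n = 20000, seed = 30))
  g <- rse_magnitude(sup)
  avs <- g$gain_ms[g$condition == "AVS"]
  # trimodal mean 2/(3 lambda), fastest sub-condition is a bimodal with mean 2/(2 lambda)
  expect_equal(avs, 2 / 0.02 - 2 / 0.03, tolerance = 0.05)

  missing_subs <- tibble::tibble(condition = rep(c("AV", "VS"), each = 3),
                                 rt_ms = c(90, 95, 100, 80, 85, 90))
  expect_warning(out <- rse_magnitude(missing_subs), "omitted")
  expect_equal(nrow(out), 0)
})
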