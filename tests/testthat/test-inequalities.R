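test_that("bound arithmetic: sums, Bonferroni differences, clipping and flooring", {
  g <- 0
  expect_equal(bimodal_bound(0.7, 0.6, g)$value, 1)   # capped at 1
  expect_equal(bimodal_bound(0.2, 0.3, g)$value, 0.5)
  expect_equal(bimodal_bound(0, 0, g)$value, 0)
  expect_equal(boole3_bound(0.1, 0.1, 0.1, g)$value, 0.3)
  expect_equal(boole3_bound(0.5, 0.4, 0.3, g)$value, 1)
  b <- bonferroni_bounds(F_AV = 0.4, F_VS = 0.6, F_AS = 0.4,
                         F_A = 0.4, F_V = 0.2, F_S = 0.1, grid = g)
  expect_equal(b$value[b$bound == "bonf_AV_AS_A"], 0.4)
  expect_equal(b$value[b$bound == "bonf_AV_VS_V"], 0.8)
  floor_case <- bonferroni_bounds(0.1, 0.5, 0.1, 0.9, 0.1, 0.1, g)
  expect_equal(floor_case$value[floor_case$bound == "bonf_AV_AS_A"], 0) # floored
  r <- restricted_bound(0.3, 0.4, g)
  expect_equal(r$value, 0.7)
  expect_match(attr(r, "assumes"), "bivariate context invariance")
  expect_equal(restricted_bound(1, 0.2, g)$value, 1)
})

test_that("sharp_bound is the pointwise minimum and names all argmin curves", {
  g <- c(10, 20)
  b <- dplyr::bind_rows(
    tibble::tibble(bound = "bonf_AV_AS_A", time = g, value = c(0.3, 0.5)),
    tibble::tibble(bound = "bonf_VS_AS_S", time = g, value = c(0.5, 0.5)),
    tibble::tibble(bound = "bonf_AV_VS_V", time = g, value = c(0.4, 0.7)))
  s <- sharp_bound(b)
  expect_equal(s$value, c(0.3, 0.5))
  expect_equal(s$argmin, c("bonf_AV_AS_A", "bonf_AV_AS_A,bonf_VS_AS_S"))
  # symmetric inputs: sharp equals each input curve
  sym <- dplyr::mutate(b, value = rep(c(0.2, 0.6), 3))
  expect_equal(sharp_bound(sym)$value, c(0.2, 0.6))
  # mismatched grids are an error
  bad <- b
  bad$time[1] <- 11
  expect_error(sharp_bound(bad), "common grid")
})

test_that("bound curves are monotone when their inputs are", {
  grid <- seq(0, 700, by = 7)
  FA <- erlang_spec(2, 0.012); FV <- erlang_spec(2, 0.01); FS <- erlang_spec(2, 0.008)
  pair_cdf <- function(r1, r2) function(t) race_min_cdf(t, 2, c(r1, r2))
  curves <- dplyr::bind_rows(
    boole3_bound(FA, FV, FS, grid),
    bonferroni_bounds(pair_cdf(0.012, 0.01), pair_cdf(0.01, 0.008),
                      pair_cdf(0.012, 0.008), FA, FV, FS, grid),
    restricted_bound(pair_cdf(0.012, 0.01), FS, grid))
  for (nm in unique(curves$bound)) {
    v <- curves$value[curves$bound == nm]
    expect_true(all(diff(v) >= -1e-12), info = nm)
    expect_true(all(v >= 0 & v <= 1), info = nm)
  }
})

test_that("every bound holds exactly on a fully enumerated discrete joint", {
  joint <- toy_joint()
  times <- c(5, 10, 15, 20, 25, 30, 35, 40, 45)
  F <- list(A = toy_cdf(joint, "A", times), V = toy_cdf(joint, "V", times),
            S = toy_cdf(joint, "S", times),
            AV = toy_cdf(joint, c("A", "V"), times),
            VS = toy_cdf(joint, c("V", "S"), times),
            AS = toy_cdf(joint, c("A", "S"), times))
  favs <- toy_cdf(joint, c("A", "V", "S"), times)
  bonf <- bonferroni_bounds(F$AV, F$VS, F$AS, F$A, F$V, F$S, times)
  curves <- dplyr::bind_rows(
    bimodal_bound(F$A, F$V, times, "bimodal_AV"),
    bimodal_bound(F$V, F$S, times, "bimodal_VS"),
    bimodal_bound(F$A, F$S, times, "bimodal_AS"),
    boole3_bound(F$A, F$V, F$S, times),
    bonf, sharp_bound(bonf)[c("bound", "time", "value")],
    restricted_bound(F$AV, F$S, times, "AV", "S"),
    restricted_bound(F$VS, F$A, times, "VS", "A"),
    restricted_bound(F$AS, F$V, times, "AS", "V"))
  targets <- list(bimodal_AV = toy_cdf(joint, c("A", "V"), times),
                  bimodal_VS = toy_cdf(joint, c("V", "S"), times),
                  bimodal_AS = toy_cdf(joint, c("A", "S"), times))
  for (nm in unique(curves$bound)) {
    bound_v <- curves$value[curves$bound == nm]
    target_v <- if (nm %in% names(targets)) targets[[nm]] else favs
    expect_true(all(target_v <= bound_v + 1e-12), info = nm)
  }
})

test_that("given the bimodal bounds, Bonferroni curves dominate Boole and sharp dominates all", {
  fix <- generate_fixture("mixed_fig1", ref_config(n = 1500, seed = 31))
  rep <- rmi_report(fix, tolerance = 0)
  wide <- tidyr::pivot_wider(rep$curves[c("bound", "time", "value")],
                             names_from = "bound", values_from = "value")
  F <- lapply(split(fix$rt_ms, fix$condition), fit_ecdf)
  bimodal_ok <- eval_cdf(F$AV, wide$time) <= eval_cdf(F$A, wide$time) + eval_cdf(F$V, wide$time) &
    eval_cdf(F$VS, wide$time) <= eval_cdf(F$V, wide$time) + eval_cdf(F$S, wide$time) &
    eval_cdf(F$AS, wide$time) <= eval_cdf(F$A, wide$time) + eval_cdf(F$S, wide$time)
  expect_gt(sum(bimodal_ok), 0)
  w <- wide[bimodal_ok, ]
  for (nm in c("bonf_AV_AS_A", "bonf_VS_AS_S", "bonf_AV_VS_V")) {
    expect_true(all(w[[nm]] <= w$boole3 + 1e-12), info = nm)
    expect_true(all(w$sharp <= w[[nm]] + 1e-12), info = nm)
  }
})

test_that("assess_violation reports the violated region in time and percentiles", {
  g <- seq(0, 800, by = 1)
  ok <- assess_violation(erlang_spec(2, 0.01),
                         boole3_bound(erlang_spec(2, 0.01), erlang_spec(2, 0.01),
                                      erlang_spec(2, 0.01), g))
  expect_false(ok$violated)
  expect_identical(ok$max_violation, 0)

  # superposition trimodal CDF against the sharp race bound: analytic curves
  pair <- function(t) race_min_cdf(t, 2, c(0.01, 0.01))
  sharp <- sharp_bound(bonferroni_bounds(pair, pair, pair,
                                         erlang_spec(2, 0.01), erlang_spec(2, 0.01),
                                         erlang_spec(2, 0.01), g))
  v <- assess_violation(erlang_spec(2, 0.03), sharp[c("bound", "time", "value")])
  expect_true(v$violated)
  expect_gt(v$pct_last, 80)
  expect_gt(v$max_violation, 0.1)
  expect_lt(v$t_first, v$t_last)
})

test_that("rmi_report computes exactly the bounds the design supports", {
  fix <- generate_fixture("mixed_fig1", ref_config(n = 400, seed = 32))
  full <- rmi_report(fix)
  expect_equal(nrow(full$violations), 11)
  expect_equal(nrow(full$skipped), 0)
  expect_setequal(
    full$violations$bound,
    c("bimodal_AV", "bimodal_VS", "bimodal_AS", "boole3", "bonf_AV_AS_A",
      "bonf_VS_AS_S", "bonf_AV_VS_V", "sharp",
      "restricted_(AV)S", "restricted_(VS)A", "restricted_(AS)V"))

  partial <- dplyr::filter(fix, condition %in% c("AVS", "AV", "S"))
  pr <- rmi_report(partial)
  expect_identical(pr$violations$bound, "restricted_(AV)S")
  expect_equal(nrow(pr$skipped), 10)
  expect_match(pr$skipped$reason[pr$skipped$bound == "boole3"], "missing conditions")

  expect_error(rmi_report(dplyr::filter(fix, condition == "AVS")),
               "No bound is computable")
})

test_that("report methods: tidy, glance, autoplot, print", {
  fix <- generate_fixture("mixed_fig1", ref_config(n = 400, seed = 33))
  rep <- rmi_report(fix)
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("bound", "target", "violated", "max_violation",
                    "pct_first", "pct_last", "tolerance") %in% names(td)))
  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_bounds, 11)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
  expect_output(print(rep), "rmi_report")
})
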