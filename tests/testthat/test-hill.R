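hill_curve <- function(x, K_H, h, mode, y_max = 1, baseline = 0) {
  u <- x^h / (x^h + K_H^h)
  if (mode == "inhibition") u <- 1 - u
  baseline + y_max * u
}

test_that("mode selection follows the sign of the linear correlation", {
  x <- seq(1, 100, length.out = 20)
  expect_equal(select_mode(x, 2 * x + 1)$mode, "activation")
  expect_equal(select_mode(x, -2 * x)$mode, "inhibition")
  const <- select_mode(x, rep(1, 20))
  expect_true(const$degenerate)
})

test_that("noiseless Hill data are recovered to high precision in both modes", {
  x <- exp(seq(log(2), log(500), length.out = 29))
  cases <- list(list(mode = "activation", K_H = 39, h = 2),
                list(mode = "inhibition", K_H = 355, h = 3))
  for (cs in cases) {
    y <- hill_curve(x, cs$K_H, cs$h, cs$mode, y_max = 2.5, baseline = -1)
    fit <- fit_hill_pair(x, y, n_starts = 50, seed = 1, try_lag = FALSE)
    expect_equal(fit$mode, cs$mode)
    expect_lt(abs(fit$K_H - cs$K_H) / cs$K_H, 0.01)
    expect_lt(abs(fit$h - cs$h) / cs$h, 0.01)
    expect_gt(fit$r_squared, 0.999)
    expect_equal(fit$r_squared, fit$pearson_r2, tolerance = 1e-9)
  }
})

test_that("parameters are recovered within 10% under 5% measurement noise", {
  x <- exp(seq(log(2), log(500), length.out = 29))
  y <- hill_curve(x, 39, 2, "activation", y_max = 2, baseline = 0.3)
  for (seed in 1:3) {
    x_noisy <- x * exp(with_seed(seed, rnorm(29, 0, 0.05)))
    fit <- fit_hill_pair(x_noisy, y, n_starts = 50, seed = 1,
                         try_lag = FALSE)
    expect_lt(abs(fit$K_H - 39) / 39, 0.10)
    expect_lt(abs(fit$h - 2) / 2, 0.10)
  }
})

test_that("the Hill coefficient bound is active for step-like data", {
  x <- exp(seq(log(5), log(500), length.out = 25))
  y <- as.numeric(x > 50)
  fit <- fit_hill_pair(x, y, n_starts = 40, seed = 1, try_lag = FALSE)
  expect_identical(fit$h, 10)
})

test_that("lagged data prefer the one-point time-shifted fit", {
  scn_t <- seq(0, 20, length.out = 25)
  a <- 1 / (1 + exp(-(scn_t - 10)))      # smooth activity profile
  x <- 50 * (pmin(pmax(c(a[-1], a[25]), 0.05), 0.95) /
               (1 - pmin(pmax(c(a[-1], a[25]), 0.05), 0.95)))^(1 / 2)
  # x at time t encodes the activity one step later
  fit <- fit_hill_pair(x, a, n_starts = 40, seed = 3, try_lag = TRUE)
  expect_identical(fit$lag, -1L)
  expect_gt(fit$r_squared, 0.999)

  fit0 <- fit_hill_pair(x, a, n_starts = 40, seed = 3, try_lag = FALSE)
  expect_gt(fit$r_squared, fit0$r_squared)
})

test_that("R-squared is invariant under affine rescaling of the activity", {
  x <- exp(seq(log(1), log(300), length.out = 20))
  y <- hill_curve(x, 60, 1.5, "activation")
  y_noisy <- y + with_seed(5, rnorm(20, 0, 0.05))
  f1 <- fit_hill_pair(x, y_noisy, n_starts = 30, seed = 2, try_lag = FALSE)
  f2 <- fit_hill_pair(x, 7 * y_noisy - 3, n_starts = 30, seed = 2,
                      try_lag = FALSE)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-6)
  expect_equal(f2$y_max, 7 * f1$y_max, tolerance = 1e-4)
})

test_that("an activation fit never beats the inhibition fit on inhibition data", {
  x <- exp(seq(log(1), log(300), length.out = 15))
  y <- hill_curve(x, 45, 2, "inhibition", y_max = 1.8, baseline = 0.1)
  act <- alloscreen:::fit_hill_core(x, y, "activation", n_starts = 30, seed = 4)
  inh <- alloscreen:::fit_hill_core(x, y, "inhibition", n_starts = 30, seed = 4)
  expect_lte(act$r_squared, inh$r_squared + 1e-9)
  expect_equal(fit_hill_pair(x, y, n_starts = 30, seed = 4,
                             try_lag = FALSE)$mode, "inhibition")
})

test_that("the multistart fit matches an exhaustive grid-search oracle on short series", {
  for (seed in 1:3) {
    set.seed(seed + 100)
    x <- sort(exp(runif(8, log(1), log(200))))
    y <- hill_curve(x, exp(runif(1, log(5), log(100))), runif(1, 0.5, 6),
                    sample(c("activation", "inhibition"), 1)) +
      rnorm(8, 0, 0.08)
    fit <- fit_hill_pair(x, y, n_starts = 50, seed = seed, try_lag = FALSE)
    oracle <- hill_grid_r2(x, y)
    expect_gte(fit$r_squared, oracle - 0.01)
  }
})

test_that("multistart fitting is deterministic under a fixed seed", {
  x <- exp(seq(log(1), log(300), length.out = 18))
  y <- hill_curve(x, 70, 2, "activation") + with_seed(9, rnorm(18, 0, 0.1))
  f1 <- fit_hill_pair(x, y, n_starts = 25, seed = 6)
  f2 <- fit_hill_pair(x, y, n_starts = 25, seed = 6)
  expect_identical(f1, f2)
})

test_that("series alignment handles identical, denser and disjoint grids", {
  act <- tibble::tibble(regulator = "TF1", time = 0:9,
                        activity = sin(0:9))
  met_same <- tidyr::expand_grid(metabolite = "m1", time = 0:9,
                                 replicate = 1:2) %>%
    dplyr::mutate(concentration = 10 + time + (replicate - 1) * 0.2)
  al <- align_series(met_same, act)
  expect_equal(al$time, as.numeric(0:9))
  expect_equal(al$met_time, as.numeric(0:9))
  expect_equal(al$concentration, 10.1 + 0:9)   # replicate mean

  # denser metabolome grid: every activity point matches exactly
  met_dense <- tibble::tibble(metabolite = "m1",
                              time = seq(0, 9, by = 0.5), replicate = 1L) %>%
    dplyr::mutate(concentration = time)
  al2 <- align_series(met_dense, act)
  expect_equal(al2$met_time, as.numeric(0:9))

  # disjoint grids beyond the window: everything dropped
  met_far <- tibble::tibble(metabolite = "m1", time = 100 + 0:9,
                            replicate = 1L, concentration = 1)
  al3 <- align_series(met_far, act)
  expect_equal(nrow(al3), 0)
})

test_that("the all-pairs screen enumerates pairs, skips short series and is order-invariant", {
  act <- tidyr::expand_grid(regulator = c("TFa", "TFb"), time = 0:12) %>%
    dplyr::mutate(activity = ifelse(regulator == "TFa",
                                    hill_curve(2 + time, 5, 2, "activation"),
                                    cos(time / 2)))
  met <- tidyr::expand_grid(metabolite = c("m1", "m2", "m3"), time = 0:12,
                            replicate = 1L) %>%
    dplyr::mutate(concentration = dplyr::case_when(
      metabolite == "m1" ~ 2 + time,
      metabolite == "m2" ~ 30 - 2 * time,
      TRUE ~ 10 + sin(time)))
  scr <- screen_hill(met, act, n_starts = 10, seed = 3)
  expect_equal(nrow(scr), 6)
  expect_true(all(diff(scr$r_squared) <= 1e-12))

  # permuting input rows leaves the results identical
  scr2 <- screen_hill(met[sample(nrow(met)), ],
                      act[rev(seq_len(nrow(act))), ],
                      n_starts = 10, seed = 3)
  expect_equal(as.data.frame(scr), as.data.frame(scr2))

  # a metabolite observed at too few matching times is skipped with a reason
  met_short <- dplyr::bind_rows(
    met, tibble::tibble(metabolite = "m4", time = c(0, 1, 2),
                        replicate = 1L, concentration = 1:3))
  scr3 <- screen_hill(met_short, act, n_starts = 5, seed = 3)
  skipped <- scr3[scr3$metabolite == "m4", ]
  expect_true(all(!is.na(skipped$skip_reason)))
  expect_true(all(skipped$r_squared == -Inf))
  expect_error(screen_hill(met[0, ], act), "empty")
})
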