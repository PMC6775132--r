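# Hill-type screening of metabolite-TF pairs. The activity y is modeled as
# an affine map of the Hill transform of the metabolite concentration x:
#   activation: u = x^h / (x^h + K_H^h)
#   inhibition: u = K_H^h / (x^h + K_H^h)
# with y ~ baseline + y_max * u. Given (K_H, h) the affine parameters have a
# closed-form ordinary-least-squares solution, so the nonlinear search runs
# over (log K_H, h) only, from 50 random starts, with the Hill coefficient
# bounded above by 10. Each pair is fitted at lag 0 and with the TF activity
# shifted back by one time point; the better R-squared wins.

hill_u <- function(x, K_H, h, mode) {
  xh <- x^h
  kh <- K_H^h
  u <- xh / (xh + kh)
  if (mode == "inhibition") u <- 1 - u
  u
}

# closed-form affine fit of y on u; returns SSE and coefficients
affine_fit <- function(u, y) {
  vu <- stats::var(u)
  if (!is.finite(vu) || vu < 1e-14) {
    b1 <- 0; b0 <- mean(y)
  } else {
    b1 <- stats::cov(u, y) / vu
    b0 <- mean(y) - b1 * mean(u)
  }
  r <- y - b0 - b1 * u
  list(sse = sum(r^2), y_max = b1, baseline = b0)
}

#' Select activation or inhibition kinetics for a pair
#'
#' The mode is chosen from the sign of the Pearson correlation between
#' metabolite concentration and TF activity: positive correlations are fitted
#' with activating kinetics, negative ones with inhibition kinetics. A
#' numerically zero correlation (or a degenerate constant series) defaults to
#' activation and is flagged.
#'
#' @param x Metabolite concentrations.
#' @param y TF activities.
#' @return List with `mode`, `r` (Pearson correlation) and `degenerate`.
#' @export
select_mode <- function(x, y) {
  r <- suppressWarnings(cor(x, y))
  degenerate <- !is.finite(r) || abs(r) < 1e-12
  list(mode = if (!degenerate && r < 0) "inhibition" else "activation",
       r = if (is.finite(r)) r else NA_real_, degenerate = degenerate)
}

# multistart bounded fit over (log K_H, h) for a fixed mode
fit_hill_core <- function(x, y, mode, n_starts = 50, h_max = 10, seed = 1) {
  xp <- x[x > 0]
  if (!length(xp)) return(NULL)
  lk_lo <- log(min(xp) / 10)
  lk_hi <- log(10 * max(x))
  obj <- function(par) affine_fit(hill_u(x, exp(par[1]), par[2], mode), y)$sse
  starts <- with_seed(seed, cbind(runif(n_starts, lk_lo, lk_hi),
                                  pmax(runif(n_starts, 0, h_max), 1e-3)))
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      optim(starts[s, ], obj, method = "L-BFGS-B",
            lower = c(lk_lo, 1e-3), upper = c(lk_hi, h_max)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12) {
      best <- fit
      best$start <- s
    }
  }
  if (is.null(best)) return(NULL)
  ab <- affine_fit(hill_u(x, exp(best$par[1]), best$par[2], mode), y)
  sst <- sum((y - mean(y))^2)
  yhat <- ab$baseline + ab$y_max * hill_u(x, exp(best$par[1]), best$par[2], mode)
  pr <- suppressWarnings(cor(y, yhat))
  list(K_H = exp(best$par[1]), h = best$par[2], y_max = ab$y_max,
       baseline = ab$baseline,
       r_squared = if (sst > 0) 1 - ab$sse / sst else NA_real_,
       pearson_r2 = if (is.finite(pr)) pr^2 else NA_real_,
       sse = ab$sse, best_start = best$start)
}

#' Fit Hill kinetics to one metabolite-TF pair
#'
#' Runs the multistart nonlinear fit for the pair at lag 0 and, when
#' `try_lag` is TRUE, with the TF activity shifted back by one time point
#' (activity at time t+1 paired with the metabolite at time t, accounting for
#' gene expression responding after the metabolite changes). Starting values
#' draw `K_H` log-uniformly between a tenth of the smallest positive
#' concentration and ten times the largest, and `h` uniformly on (0, 10].
#' The variant with the higher R-squared is returned. R-squared is
#' `1 - SS_res/SS_tot` between the measured TF activity and the affine-mapped
#' Hill transform of the metabolite levels; because the affine map is fitted
#' by ordinary least squares this coincides with the squared Pearson
#' correlation between activity and transformed metabolite levels (both are
#' reported).
#'
#' @param x Metabolite concentrations (uM, >= 0) on the common grid.
#' @param y TF activities on the same grid.
#' @param n_starts Random starts per variant (default 50).
#' @param seed Seed for the start draws.
#' @param try_lag Also fit the one-point-lag variant (default TRUE).
#' @param h_max Upper bound on the Hill coefficient (default 10).
#' @param min_points Minimum usable points (default 6).
#' @return One-row tibble: `mode`, `K_H`, `h`, `y_max`, `baseline`, `lag`,
#'   `r_squared`, `pearson_r2`, `linear_r`, `degenerate`, `n_points`.
#' @examples
#' x <- seq(1, 200, length.out = 20)
#' y <- 2 * x^2 / (x^2 + 50^2) - 1
#' fit_hill_pair(x, y, n_starts = 10, seed = 1)
#' @export
fit_hill_pair <- function(x, y, n_starts = 50, seed = 1, try_lag = TRUE,
                          h_max = 10, min_points = 6) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (any(x < 0)) stopf("metabolite concentrations must be non-negative")
  failed <- tibble(mode = NA_character_, K_H = NA_real_, h = NA_real_,
                   y_max = NA_real_, baseline = NA_real_, lag = 0L,
                   r_squared = -Inf, pearson_r2 = NA_real_,
                   linear_r = NA_real_, degenerate = TRUE,
                   n_points = length(x))
  if (length(x) < min_points) return(failed)

  variants <- list(list(x = x, y = y, lag = 0L))
  if (try_lag && length(x) > min_points)
    variants <- c(variants,
                  list(list(x = x[-length(x)], y = y[-1], lag = -1L)))
  best <- NULL
  for (v in variants) {
    ms <- select_mode(v$x, v$y)
    if (ms$degenerate && !is.finite(ms$r)) next
    core <- fit_hill_core(v$x, v$y, ms$mode, n_starts = n_starts,
                          h_max = h_max, seed = seed)
    if (is.null(core)) next
    row <- tibble(mode = ms$mode, K_H = core$K_H, h = core$h,
                  y_max = core$y_max, baseline = core$baseline,
                  lag = v$lag, r_squared = core$r_squared,
                  pearson_r2 = core$pearson_r2, linear_r = ms$r,
                  degenerate = ms$degenerate, n_points = length(v$x))
    if (is.null(best) || isTRUE(row$r_squared > best$r_squared + 1e-12))
      best <- row
  }
  if (is.null(best)) return(failed)
  best
}

#' Pair metabolite and activity series on a common time grid
#'
#' The transcriptome grid (of the activities) is the reference: for each
#' activity time point the metabolite value is the replicate mean at the
#' nearest metabolome time point within `window` hours. Unmatched activity
#' points are dropped and counted per metabolite.
#'
#' @param metabolites Tibble `metabolite`, `time`, `replicate`,
#'   `concentration`.
#' @param activities Tibble `regulator`, `time`, `activity` (e.g. from
#'   [nca_activities()] or [simulate_tf_activities()]).
#' @param window Maximum match distance in hours; defaults to half the median
#'   spacing of the activity grid.
#' @return Tibble `metabolite`, `time`, `met_time`, `concentration` covering
#'   every matched activity time point, with attribute `"dropped"` counting
#'   unmatched points per metabolite.
#' @export
align_series <- function(metabolites, activities, window = NULL) {
  t_act <- sort(unique(activities$time))
  if (is.null(window)) window <- stats::median(diff(t_act)) / 2
  met_mean <- metabolites %>%
    group_by(.data$metabolite, .data$time) %>%
    summarise(concentration = mean(.data$concentration), .groups = "drop")
  out <- met_mean %>%
    group_by(.data$metabolite) %>%
    dplyr::group_modify(function(d, key) {
      idx <- vapply(t_act, function(t) which.min(abs(d$time - t)), integer(1))
      dist <- abs(d$time[idx] - t_act)
      ok <- dist <= window
      tibble(time = t_act[ok], met_time = d$time[idx][ok],
             concentration = d$concentration[idx][ok])
    }) %>% ungroup()
  dropped <- out %>%
    group_by(.data$metabolite) %>%
    summarise(n_matched = n(), .groups = "drop") %>%
    mutate(n_dropped = length(t_act) - .data$n_matched)
  attr(out, "dropped") <- dropped
  out
}

#' Screen all metabolite-TF pairs for Hill-type relationships
#'
#' Fits every combination of a measured metabolite and a supplied regulator
#' activity profile with [fit_hill_pair()] after aligning the two time grids
#' with [align_series()]. Per-pair fitting seeds are a deterministic hash of
#' the pair ids and the master seed, so results do not depend on input order.
#' Pairs with fewer than `min_points` common time points are skipped with a
#' recorded reason.
#'
#' @param metabolites Tibble `metabolite`, `time`, `replicate`,
#'   `concentration`.
#' @param activities Tibble `regulator`, `time`, `activity`.
#' @param n_starts Random starts per pair and lag variant (default 50).
#' @param seed Master seed (default 1).
#' @param r2_threshold Hill-relationship threshold on R-squared (default
#'   0.75).
#' @param window,min_points Passed to the alignment and per-pair fit.
#' @param try_lag Also fit the one-point-lag variant (default TRUE).
#' @return Tibble of class `hill_screen`, one row per pair, sorted by
#'   decreasing R-squared, with `passed = r_squared > r2_threshold` and
#'   skipped pairs carrying a `skip_reason`.
#' @export
screen_hill <- function(metabolites, activities, n_starts = 50, seed = 1,
                        r2_threshold = 0.75, window = NULL, try_lag = TRUE,
                        min_points = 6) {
  if (!nrow(metabolites) || !nrow(activities))
    stopf("empty metabolite or activity input")
  paired <- align_series(metabolites, activities, window = window)
  mets <- sort(unique(metabolites$metabolite))
  regs <- sort(unique(activities$regulator))
  act_wide <- activities %>%
    group_by(.data$regulator, .data$time) %>%
    summarise(activity = mean(.data$activity), .groups = "drop")

  grid <- tidyr::expand_grid(metabolite = mets, regulator = regs)
  res <- purrr::pmap_dfr(grid, function(metabolite, regulator) {
    xm <- paired %>% filter(.data$metabolite == !!metabolite)
    ya <- act_wide %>% filter(.data$regulator == !!regulator)
    common <- inner_join(xm, ya, by = "time")
    base <- tibble(metabolite = metabolite, regulator = regulator)
    if (nrow(common) < min_points) {
      return(dplyr::bind_cols(base,
        tibble(mode = NA_character_, K_H = NA_real_, h = NA_real_,
               y_max = NA_real_, baseline = NA_real_, lag = 0L,
               r_squared = -Inf, pearson_r2 = NA_real_, linear_r = NA_real_,
               degenerate = TRUE, n_points = nrow(common),
               skip_reason = "fewer than min_points common time points")))
    }
    fit <- fit_hill_pair(common$concentration, common$activity,
                         n_starts = n_starts,
                         seed = hash_seed(metabolite, regulator, master = seed),
                         try_lag = try_lag, min_points = min_points)
    dplyr::bind_cols(base, fit, tibble(skip_reason = NA_character_))
  })
  res <- res %>%
    mutate(passed = is.finite(.data$r_squared) &
             .data$r_squared > r2_threshold) %>%
    arrange(desc(.data$r_squared))
  attr(res, "r2_threshold") <- r2_threshold
  attr(res, "seed") <- seed
  class(res) <- c("hill_screen", class(res))
  res
}
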