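make_noiseless_fit <- function(seed = 2, n_restarts = 10, ...) {
  scn <- scenario(n_genes = 60, n_regulators = 6, n_metabolites = 6,
                  n_planted = 3, noise_sd = 0, met_noise_sdlog = 0,
                  seed = seed)
  study <- suppressMessages(simulate_study(scn))
  list(scn = scn, study = study,
       fit = nca(study$expression, study$network, n_restarts = n_restarts,
                 seed = 1, ...))
}

test_that("noiseless expression is refactored to numerically zero residual", {
  w <- make_noiseless_fit()
  best <- alloscreen:::best_restart(w$fit)
  expect_lte(best$residual, 1e-8 * sum(w$fit$E^2))
  expect_equal(glance(w$fit)$variance_explained, 1, tolerance = 1e-6)
})

test_that("the ALS residual trace is monotone non-increasing on noisy data", {
  scn <- scenario(n_genes = 50, n_regulators = 5, n_metabolites = 4,
                  n_planted = 2, noise_sd = 0.1, seed = 4)
  study <- suppressMessages(simulate_study(scn))
  fit <- nca(study$expression, study$network, n_restarts = 5, seed = 2)
  for (f in fit$fits) {
    tr <- f$residual_trace
    if (length(tr) > 1)
      expect_true(all(diff(tr) <= 1e-12 * (1 + tr[-length(tr)])))
  }
})

test_that("the fixed zero pattern of the connectivity matrix is preserved", {
  w <- make_noiseless_fit(seed = 6, n_restarts = 3)
  for (f in w$fit$fits)
    expect_true(all(f$A[!w$fit$mask] == 0))
})

test_that("the single-regulator limit matches the closed-form least-squares oracle", {
  scn <- scenario(n_genes = 30, n_regulators = 0, n_metabolites = 2,
                  n_planted = 0, noise_sd = 0.05, seed = 3)
  net <- simulate_regulatory_network(scn)
  act <- simulate_tf_activities(scn) %>% dplyr::filter(regulator == "global")
  expr <- simulate_expression(act, net, scn)
  fit <- nca(expr, net, n_restarts = 3, seed = 1, tol = 1e-8,
             max_iter = 2000)
  best <- alloscreen:::best_restart(fit)
  # given the final A, P must be the least-squares projection of E onto its
  # row space
  P_oracle <- qr.coef(qr(best$A), fit$E)
  expect_equal(unname(best$P), unname(P_oracle), tolerance = 1e-8)
  # and the rank-1 factorization residual cannot beat the truncated SVD
  sv <- svd(fit$E)
  svd_res <- sum(fit$E^2) - sv$d[1]^2
  expect_equal(best$residual, svd_res, tolerance = 1e-6)
})

test_that("ensemble alignment collapses scale and sign ambiguity", {
  # restarts that are exact +/- scalings of one solution must collapse to a
  # zero-width band after z-scoring and sign alignment
  set.seed(31)
  P0 <- matrix(rnorm(3 * 10), 3, 10)
  A0 <- matrix(rnorm(5 * 3), 5, 3)
  mask <- matrix(TRUE, 5, 3)
  fits <- lapply(c(1, -2, 0.5, -0.1), function(s)
    list(A = A0 / s, P = P0 * s, converged = TRUE, residual = 0))
  s <- alloscreen:::summarize_restarts(fits, mask, signs = NULL,
                                       regs = paste0("R", 1:3),
                                       times = 1:10)
  expect_lt(max(s$hi - s$lo), 1e-12)
  expect_true(all(s$lo <= s$mean + 1e-12 & s$mean <= s$hi + 1e-12))

  # a single restart gives a degenerate band equal to the mean
  w <- make_noiseless_fit(seed = 8, n_restarts = 1)
  expect_equal(w$fit$summary$lo, w$fit$summary$mean, tolerance = 1e-12)
  expect_equal(w$fit$summary$hi, w$fit$summary$mean, tolerance = 1e-12)
})

test_that("aligned mean activities recover planted truth under mild noise", {
  scn <- scenario(n_genes = 60, n_regulators = 6, n_metabolites = 6,
                  n_planted = 3, noise_sd = 0.05, met_noise_sdlog = 0,
                  seed = 11)
  study <- suppressMessages(simulate_study(scn))
  fit <- nca(study$expression, study$network, n_restarts = 20, seed = 2)
  truth <- profile_matrix(dplyr::mutate(study$activities, replicate = 1L),
                          "regulator", "activity")
  cors <- vapply(fit$regulators,
                 function(r) cor(fit$summary$mean[r, ], truth[r, ]),
                 numeric(1))
  expect_gte(mean(cors >= 0.95), 0.9)
})

test_that("variance explained behaves at its extremes and at a planted 3:1 ratio", {
  w <- make_noiseless_fit(seed = 12, n_restarts = 2)
  best <- alloscreen:::best_restart(w$fit)
  expect_equal(variance_explained(w$fit$E, best$A, best$P), 1,
               tolerance = 1e-9)
  # zero activities explain nothing of per-gene-centered data
  E_cent <- w$fit$E - rowMeans(w$fit$E)
  P0 <- matrix(0, ncol(best$A), ncol(w$fit$E))
  expect_equal(variance_explained(E_cent, best$A, P0), 0)

  # noise_sd set so that signal variance is three times noise variance
  scn <- scenario(n_genes = 80, n_regulators = 6, n_metabolites = 4,
                  n_planted = 2, noise_sd = 0, replicate_count = 1,
                  seed = 21)
  net <- simulate_regulatory_network(scn)
  act <- simulate_tf_activities(scn)
  clean <- simulate_expression(act, net, scn)
  Ec <- profile_matrix(clean, "gene", "value")
  sig_var <- mean((Ec - rowMeans(Ec))^2)
  scn$noise_sd <- sqrt(sig_var / 3)
  noisy <- simulate_expression(act, net, scn)
  En <- profile_matrix(noisy, "gene", "value")
  w_true <- attr(clean, "weights")
  genes <- rownames(En)
  A_true <- matrix(0, length(genes), 7,
                   dimnames = list(genes, sort(unique(net$regulator))))
  A_true[cbind(match(w_true$gene, genes),
               match(w_true$regulator, colnames(A_true)))] <- w_true$weight
  P_true <- profile_matrix(dplyr::mutate(act, replicate = 1L),
                           "regulator", "activity")[colnames(A_true), ]
  expect_equal(variance_explained(En, A_true, P_true), 0.75,
               tolerance = 0.05 / 0.75)
})

test_that("identifiability diagnostics flag duplicates and coverage", {
  net <- tibble::tibble(
    regulator = c("TF1", "TF1", "TF2", "TF2", "TF3"),
    gene = c("g1", "g2", "g1", "g2", "g3"))
  rep <- check_identifiability(net)
  expect_equal(rep$duplicate_of[rep$regulator == "TF2"], "TF1")
  expect_true(rep$covered_by_others[rep$regulator == "TF1"])
  expect_false(rep$covered_by_others[rep$regulator == "TF3"])

  diag_net <- tibble::tibble(regulator = paste0("TF", 1:3),
                             gene = paste0("g", 1:3))
  clean <- check_identifiability(diag_net)
  expect_true(all(is.na(clean$duplicate_of)))
  expect_false(any(clean$covered_by_others))

  expect_error(check_identifiability(tibble::tibble(regulator = character(),
                                                    gene = character())),
               "empty")
})

test_that("tidy and autoplot expose the ensemble summary", {
  w <- make_noiseless_fit(seed = 2, n_restarts = 3)
  td <- tidy(w$fit)
  expect_setequal(names(td),
                  c("regulator", "time", "activity", "ci_lo", "ci_hi"))
  expect_equal(nrow(td), 7 * length(w$fit$times))
  p <- ggplot2::autoplot(w$fit, regulators = c("TF1", "TF2"))
  expect_s3_class(p, "ggplot")
})
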