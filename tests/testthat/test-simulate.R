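test_that("regulatory network construction covers every gene and is reproducible", {
  scn <- scenario(n_genes = 50, n_regulators = 5, n_metabolites = 6,
                  n_planted = 3, seed = 1)
  net <- simulate_regulatory_network(scn)
  expect_setequal(unique(net$regulator), c(paste0("TF", 1:5), "global"))
  expect_setequal(unique(net$gene[net$is_global]), scn$genes)
  # every gene regulated (global guarantees it), signs well-formed
  expect_setequal(unique(net$gene), scn$genes)
  expect_true(all(net$sign %in% c(-1L, 1L)))
  expect_identical(net, simulate_regulatory_network(scn))

  # identifiability by construction: distinct target sets per TF
  tf_sets <- split(net$gene[!net$is_global], net$regulator[!net$is_global])
  keys <- vapply(tf_sets, function(s) paste(sort(s), collapse = "|"), "")
  expect_false(any(duplicated(keys)))
})

test_that("degenerate and infeasible network requests are handled", {
  scn0 <- scenario(n_genes = 10, n_regulators = 0, n_metabolites = 2,
                   n_planted = 0, seed = 1)
  net0 <- simulate_regulatory_network(scn0)
  expect_identical(unique(net0$regulator), "global")
  expect_equal(nrow(net0), 10)

  scn_bad <- scenario(n_genes = 7, n_regulators = 6, n_metabolites = 2,
                      n_planted = 0, seed = 1)
  expect_error(simulate_regulatory_network(scn_bad), "infeasible")
})

test_that("the designated on-off-on profile saturates in the right phases", {
  scn <- quick_scenario()
  act <- simulate_tf_activities(scn)
  a1 <- act[act$regulator == "TF1", ]
  growth <- phase_indicator(a1$time, scn$phase_times)
  rng <- range(a1$activity)
  hi <- rng[1] + 0.75 * diff(rng)
  lo <- rng[1] + 0.25 * diff(rng)
  expect_true(all(a1$activity[growth] >= hi))
  expect_true(all(a1$activity[!growth] <= lo))
  expect_identical(act, simulate_tf_activities(scn))
})

test_that("expression equals connectivity times activities at zero noise", {
  scn <- quick_scenario()
  net <- simulate_regulatory_network(scn)
  act <- simulate_tf_activities(scn)
  expr <- simulate_expression(act, net, scn)
  w <- attr(expr, "weights")

  P <- profile_matrix(dplyr::mutate(act, replicate = 1L),
                      "regulator", "activity")
  genes <- sort(unique(net$gene))
  A <- matrix(0, length(genes), nrow(P), dimnames = list(genes, rownames(P)))
  A[cbind(match(w$gene, genes), match(w$regulator, rownames(P)))] <- w$weight
  E_expect <- A %*% P

  E_got <- profile_matrix(expr, "gene", "value")
  expect_equal(E_got, E_expect[rownames(E_got), colnames(E_got)],
               tolerance = 1e-12)
  # replicate columns share the same noiseless mean
  by_rep <- tidyr::pivot_wider(expr, names_from = "replicate",
                               values_from = "value")
  expect_equal(by_rep$`1`, by_rep$`2`, tolerance = 1e-12)
})

test_that("log-scale expression noise matches the declared standard deviation", {
  scn <- scenario(n_genes = 60, n_regulators = 5, n_metabolites = 5,
                  n_planted = 2, noise_sd = 0.1, met_noise_sdlog = 0,
                  n_timepoints = 20, n_met_timepoints = 20, seed = 3)
  net <- simulate_regulatory_network(scn)
  act <- simulate_tf_activities(scn)
  noisy <- simulate_expression(act, net, scn)
  scn0 <- scn; scn0$noise_sd <- 0
  clean <- simulate_expression(act, net, scn0)
  resid <- noisy$value - clean$value
  expect_gte(length(resid), 1000)
  expect_lt(abs(sd(resid) - 0.1) / 0.1, 0.2)
})

test_that("the factorization is bilinear: scaling activities and weights cancels", {
  scn <- quick_scenario()
  net <- simulate_regulatory_network(scn)
  act <- simulate_tf_activities(scn)
  e1 <- simulate_expression(act, net, scn)
  w <- attr(e1, "weights")
  act2 <- dplyr::mutate(act, activity = 2 * activity)
  w2 <- dplyr::mutate(w, weight = weight / 2)
  e2 <- simulate_expression(act2, net, scn, weights = w2)
  expect_equal(e1$value, e2$value, tolerance = 1e-12)
})

test_that("expression generation rejects missing regulators", {
  scn <- quick_scenario()
  net <- simulate_regulatory_network(scn)
  act <- simulate_tf_activities(scn)
  expect_error(
    simulate_expression(act[act$regulator != "TF2", ], net, scn), "TF2")
})

test_that("Hill inversion hits the half-saturation point and preserves mode sign", {
  expect_equal(hill_invert(0.5, K_H = 50, h = 1, mode = "activation"), 50)
  expect_equal(hill_invert(0.5, K_H = 50, h = 3, mode = "inhibition"), 50)

  scn <- scenario(n_genes = 40, n_regulators = 4, n_metabolites = 6,
                  noise_sd = 0, met_noise_sdlog = 0, seed = 2,
                  planted = tibble::tibble(
                    metabolite = c("met01", "met02"),
                    regulator = c("TF2", "TF3"),
                    mode = c("activation", "inhibition"),
                    K_H = c(50, 80), h = c(2, 2), lag = c(0L, 0L)))
  act <- simulate_tf_activities(scn)
  mets <- simulate_metabolites(act, scn)
  for (i in 1:2) {
    m <- mets[mets$metabolite == scn$planted$metabolite[i], ]
    a <- act[act$regulator == scn$planted$regulator[i], ]
    joint <- dplyr::inner_join(
      dplyr::summarise(dplyr::group_by(m, time),
                       conc = mean(concentration), .groups = "drop"),
      a, by = "time")
    r <- cor(joint$conc, joint$activity)
    rs <- cor(joint$conc, joint$activity, method = "spearman")
    if (scn$planted$mode[i] == "activation") {
      expect_gt(r, 0)
      expect_equal(rs, 1)
    } else {
      expect_lt(r, 0)
      expect_equal(rs, -1)
    }
  }
})

test_that("noiseless planted metabolites are recovered by the Hill fit", {
  scn <- scenario(n_genes = 40, n_regulators = 4, n_metabolites = 5,
                  noise_sd = 0, met_noise_sdlog = 0, seed = 5,
                  planted = tibble::tibble(
                    metabolite = "met01", regulator = "TF2",
                    mode = "activation", K_H = 50, h = 2, lag = 0L))
  act <- simulate_tf_activities(scn)
  mets <- simulate_metabolites(act, scn)
  paired <- align_series(mets, act)
  joint <- dplyr::inner_join(
    paired[paired$metabolite == "met01", ],
    act[act$regulator == "TF2", ], by = "time")
  fit <- fit_hill_pair(joint$concentration, joint$activity,
                       n_starts = 30, seed = 1)
  expect_equal(fit$mode, "activation")
  expect_lt(abs(fit$K_H - 50) / 50, 0.01)
  expect_lt(abs(fit$h - 2) / 2, 0.01)
  expect_gt(fit$r_squared, 0.999)
})

test_that("toy metabolic model links planted effectors to their TF regulons", {
  scn <- quick_scenario()
  study <- suppressMessages(simulate_study(scn))
  model <- study$model
  expect_s3_class(model, "metabolic_model")
  expect_gte(dplyr::n_distinct(model$reactions$subsystem), 3)
  expect_true(all(c("p", "e") %in% model$metabolites$compartment))
  expect_true(all(model$cofactors %in% model$metabolites$id))

  adj <- build_adjacency(model)
  D <- metabolite_gene_distances(adj)
  regulon <- study$network[!study$network$is_global, ]
  for (i in seq_len(nrow(scn$planted))) {
    d <- tf_min_distance(D, scn$planted$metabolite[i],
                         regulon$gene[regulon$regulator == scn$planted$regulator[i]])
    expect_equal(d, 1)
  }
  # cofactors are pruned from the bipartite graph
  expect_length(intersect(model$cofactors, adj$metabolites), 0)
})

test_that("identical scenarios and seeds give bit-identical studies", {
  s1 <- suppressMessages(simulate_study(quick_scenario(seed = 9)))
  s2 <- suppressMessages(simulate_study(quick_scenario(seed = 9)))
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$metabolites, s2$metabolites)
  expect_identical(s1$network, s2$network)
})
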