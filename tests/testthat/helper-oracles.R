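# Independent oracles and small fixture builders used across tests.

# Floyd-Warshall all-pairs shortest paths on an undirected graph given an
# edge list of node names; independent of the igraph-based implementation.
fw_distances <- function(nodes, edges) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- match(edges[[1]][i], nodes)
    b <- match(edges[[2]][i], nodes)
    D[a, b] <- D[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# exhaustive grid-search oracle for the Hill fit: best achievable R^2 over a
# 200 x 200 (log K_H, h) grid with the affine map fitted by least squares;
# with an intercept, activation and inhibition transforms give identical R^2,
# so a single transform suffices
hill_grid_r2 <- function(x, y, n_grid = 200, h_max = 10) {
  xp <- x[x > 0]
  lk <- seq(log(min(xp) / 10), log(10 * max(x)), length.out = n_grid)
  hs <- seq(h_max / n_grid, h_max, length.out = n_grid)
  best <- -Inf
  for (K in exp(lk)) {
    for (h in hs) {
      u <- x^h / (x^h + K^h)
      r <- suppressWarnings(stats::cor(u, y))
      if (is.finite(r) && r^2 > best) best <- r^2
    }
  }
  best
}

# linear pathway model m1 -g1- m2 -g2- m3 -g3- m4 -g4- m5 used by the
# distance tests
linear_pathway_model <- function() {
  mets <- tibble::tibble(id = paste0("m", 1:5), compartment = "c")
  rxns <- tibble::tibble(id = paste0("r", 1:4),
                         subsystem = c("sA", "sA", "sB", "sB"),
                         gene_rule = paste0("gene", 1:4))
  stoich <- purrr::map_dfr(1:4, function(i)
    tibble::tibble(reaction = paste0("r", i),
                   metabolite = paste0("m", c(i, i + 1)),
                   coef = c(-1, 1)))
  alloscreen::metabolic_model(mets, rxns, stoich, cofactors = character())
}

# random bipartite metabolite-gene model for property tests
random_bipartite_model <- function(n_met, n_rxn, seed) {
  set.seed(seed)
  mets <- tibble::tibble(id = paste0("m", seq_len(n_met)), compartment = "c")
  rxns <- tibble::tibble(id = paste0("r", seq_len(n_rxn)),
                         subsystem = NA_character_,
                         gene_rule = paste0("gene", seq_len(n_rxn)))
  stoich <- purrr::map_dfr(seq_len(n_rxn), function(i) {
    k <- sample(1:3, 1)
    tibble::tibble(reaction = paste0("r", i),
                   metabolite = sample(mets$id, k),
                   coef = sample(c(-2, -1, 1, 2), k, replace = TRUE))
  })
  alloscreen::metabolic_model(mets, rxns, stoich, cofactors = character())
}

# small default-ish scenario used by several tests
quick_scenario <- function(..., seed = 1) {
  alloscreen::scenario(n_genes = 40, n_regulators = 4, n_metabolites = 8,
                       n_planted = 3, noise_sd = 0, met_noise_sdlog = 0,
                       seed = seed, ...)
}
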