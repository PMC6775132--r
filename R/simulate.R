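# Synthetic-data generators: planted regulatory network, TF activity
# profiles, expression and metabolite time courses, and a toy metabolic
# model, all deterministic in the scenario seed.

# ---- activity profiles -------------------------------------------------

# per-regulator piecewise exponential-relaxation parameters: a level and a
# rate per phase, plus a starting value. Drawn once per scenario seed.
activity_params <- function(scn) {
  regs <- c(scn$regulators, "global")
  ind <- as.numeric(phase_indicator(scn$time_trans, scn$phase_times))
  with_seed(hash_seed("activities", master = scn$seed), {
    prm <- lapply(regs, function(r) {
      # relaxation toward a per-phase level plus a transient excursion at
      # each phase entry; the two time scales decorrelate regulators. Only
      # the designated control TF is allowed on-off-on dynamics, so draws
      # that track the growth-phase indicator too closely are rejected.
      for (try in 1:50) {
        p <- list(levels = runif(3, -1.5, 1.5), rates = runif(3, 0.3, 2.5),
                  v0 = runif(1, -1.5, 1.5),
                  bumps = runif(3, -2, 2), bump_rates = runif(3, 0.5, 3))
        pc <- suppressWarnings(
          cor(eval_relaxation(p, scn$time_trans, scn$phase_times), ind))
        if (!is.finite(pc) || abs(pc) <= 0.8) break
      }
      p
    })
    names(prm) <- regs
    # first TF follows on-off-on dynamics: high in both growth phases, low in
    # starvation, with fast relaxation so phase values saturate
    if (length(scn$regulators) >= 1)
      prm[[scn$regulators[1]]] <- list(levels = c(1.2, -1.2, 1.2),
                                       rates = c(6, 6, 6), v0 = 1.2,
                                       bumps = c(0, 0, 0),
                                       bump_rates = c(1, 1, 1))
    # the global basal regulator varies only mildly around its baseline
    prm[["global"]] <- list(levels = c(1, 0.8, 1.05), rates = c(0.8, 0.8, 0.8),
                            v0 = 1, bumps = c(0.1, -0.1, 0.1),
                            bump_rates = c(1.5, 1.5, 1.5))
    prm
  })
}

# evaluate one relaxation profile at arbitrary times; the optional bump term
# b*(e^-k dt - e^-2k dt) is zero at phase entry and relaxes away, preserving
# continuity across phase boundaries
eval_relaxation <- function(prm, times, phase_times) {
  if (is.null(prm$bumps)) prm$bumps <- c(0, 0, 0)
  if (is.null(prm$bump_rates)) prm$bump_rates <- c(1, 1, 1)
  starts <- c(0, phase_times)
  val_at <- function(p, dt) {
    prm$levels[p] + (vstart[p] - prm$levels[p]) * exp(-prm$rates[p] * dt) +
      prm$bumps[p] * (exp(-prm$bump_rates[p] * dt) -
                        exp(-2 * prm$bump_rates[p] * dt))
  }
  v <- prm$v0
  vstart <- numeric(3)
  for (p in 1:3) {
    vstart[p] <- v
    if (p < 3) v <- val_at(p, starts[p + 1] - starts[p])
  }
  phase <- findInterval(times, starts)
  vapply(seq_along(times),
         function(i) val_at(phase[i], times[i] - starts[phase[i]]),
         numeric(1))
}

# all regulator profiles (incl. global) evaluated at `times`
activity_profiles <- function(scn, times) {
  prm <- activity_params(scn)
  purrr::map_dfr(names(prm), function(r) {
    tibble(regulator = r, time = times,
           activity = eval_relaxation(prm[[r]], times, scn$phase_times))
  })
}

#' Generate ground-truth transcription-factor activity profiles
#'
#' Produces one smooth activity profile per regulator (plus the global basal
#' regulator) over the transcriptome time grid. Profiles are phase-wise
#' exponential relaxations toward per-phase levels, which resembles the
#' relaxation dynamics of regulators entering and exiting carbon starvation.
#' The first TF is always given on-off-on dynamics (high during both growth
#' phases, low during starvation) so that the downstream TF filter has a
#' positive control.
#'
#' @param scn An [scenario()] object.
#' @return A tibble with columns `regulator`, `time` (hours) and `activity`
#'   (arbitrary units).
#' @export
simulate_tf_activities <- function(scn) {
  activity_profiles(scn, scn$time_trans)
}

# ---- regulatory network ------------------------------------------------

#' Generate a planted transcription-regulation network
#'
#' Builds a sparse signed regulator-gene topology satisfying the
#' identifiability requirements of network component analysis: every gene has
#' at least one regulator, each TF owns two exclusive target genes (so no two
#' regulators share a target set and no regulator's targets are fully covered
#' by the others), and a global basal regulator is connected to every gene.
#'
#' @param scn An [scenario()] object.
#' @return A tibble with columns `regulator`, `gene`, `sign` (+1/-1) and
#'   `is_global`.
#' @export
simulate_regulatory_network <- function(scn) {
  R <- scn$n_regulators
  if (R > 0 && scn$n_genes < 2 * R)
    stopf("infeasible sparsity: %d regulators need at least %d genes for exclusive targets",
          R, 2 * R)
  edges <- with_seed(hash_seed("network", master = scn$seed), {
    out <- list()
    if (R > 0) {
      # two exclusive genes per TF guarantee distinct, non-covered target sets
      excl <- tibble(regulator = rep(scn$regulators, each = 2),
                     gene = scn$genes[seq_len(2 * R)])
      rest <- scn$genes[-seq_len(2 * R)]
      extra <- purrr::map_dfr(rest, function(g) {
        k <- sample(1:3, 1)
        tibble(regulator = sample(scn$regulators, min(k, R)), gene = g)
      })
      out <- bind_rows(excl, extra)
      out$sign <- ifelse(runif(nrow(out)) < 0.6, 1L, -1L)
    } else {
      out <- tibble(regulator = character(), gene = character(),
                    sign = integer())
    }
    out
  })
  edges$is_global <- FALSE
  global <- tibble(regulator = "global", gene = scn$genes, sign = 1L,
                   is_global = TRUE)
  bind_rows(edges, global) %>% arrange(.data$regulator, .data$gene)
}

# ---- expression --------------------------------------------------------

#' Generate a log-scale expression time course from planted activities
#'
#' Implements the generative counterpart of the NCA model: the noiseless
#' log10 expression matrix is the product of the signed connectivity weights
#' and the regulator activity profiles, and i.i.d. Gaussian noise is added on
#' the log10 scale independently per replicate. Replicate columns therefore
#' share the same noiseless mean.
#'
#' @param activities Tibble of `regulator`, `time`, `activity` (all network
#'   regulators must be present).
#' @param network Tibble of `regulator`, `gene`, `sign` edges, e.g. from
#'   [simulate_regulatory_network()].
#' @param scn An [scenario()] object (supplies noise level, replicate count
#'   and seed).
#' @param weights Optional tibble `regulator`, `gene`, `weight` overriding the
#'   seed-drawn connectivity weights.
#' @return A tibble `gene`, `time`, `replicate`, `value` (log10 scale) with
#'   the weight table attached as attribute `"weights"`.
#' @export
simulate_expression <- function(activities, network, scn, weights = NULL) {
  P <- profile_matrix(dplyr::mutate(activities, replicate = 1L),
                      "regulator", "activity")
  missing <- setdiff(unique(network$regulator), rownames(P))
  if (length(missing))
    stopf("activities missing for regulator(s): %s",
          paste(missing, collapse = ", "))
  if (is.null(weights)) {
    weights <- with_seed(hash_seed("weights", master = scn$seed), {
      network %>% mutate(weight = .data$sign * runif(n(), 0.5, 1.5))
    })
  }
  genes <- sort(unique(network$gene))
  A <- matrix(0, length(genes), nrow(P),
              dimnames = list(genes, rownames(P)))
  A[cbind(match(weights$gene, genes), match(weights$regulator, rownames(P)))] <-
    weights$weight
  E0 <- A %*% P
  times <- as.numeric(colnames(P))
  out <- tidyr::expand_grid(gene = genes, time = times,
                            replicate = seq_len(scn$replicate_count)) %>%
    arrange(.data$gene, .data$time, .data$replicate)
  mu <- E0[cbind(match(out$gene, genes), match(out$time, times))]
  eps <- if (scn$noise_sd > 0) {
    with_seed(hash_seed("exprnoise", master = scn$seed),
              rnorm(nrow(out), 0, scn$noise_sd))
  } else 0
  out$value <- mu + eps
  attr(out, "weights") <- weights %>% select("regulator", "gene", "weight")
  out
}

# ---- metabolites -------------------------------------------------------

# invert a Hill law so that the transformed concentration reproduces r
hill_invert <- function(r, K_H, h, mode) {
  if (mode == "activation") K_H * (r / (1 - r))^(1 / h)
  else K_H * ((1 - r) / r)^(1 / h)
}

#' Generate metabolite concentration time courses
#'
#' For each planted interaction the metabolite trajectory is obtained by
#' inverting the corresponding Hill law: the planted TF activity is rescaled
#' affinely into `[0.05, 0.95]` (Hill saturation is asymptotic, so the open
#' interval avoids infinite concentrations) and mapped through the inverse
#' activation or inhibition kinetics with the planted `K_H` and `h`. A planted
#' lag of one time point makes the metabolite lead the TF activity by one
#' transcriptome sampling step. Non-planted metabolites follow smooth random
#' log-scale trajectories independent of all activities. Lognormal measurement
#' noise is applied per replicate.
#'
#' @param activities Tibble `regulator`, `time`, `activity` on the
#'   transcriptome grid (interpolated linearly where the metabolome grid is
#'   denser).
#' @param scn An [scenario()] object.
#' @return A tibble `metabolite`, `time`, `replicate`, `concentration` (uM).
#' @export
simulate_metabolites <- function(activities, scn) {
  dt <- diff(scn$time_trans[1:2])
  planted <- scn$planted
  profiles <- list()
  for (m in scn$metabolites) {
    row <- planted[planted$metabolite == m, ]
    if (nrow(row) == 1) {
      act <- activities[activities$regulator == row$regulator, ]
      eval_t <- scn$time_met + row$lag * dt
      a <- approx(act$time, act$activity, xout = eval_t, rule = 2)$y
      rng <- range(a)
      if (diff(rng) < 1e-12) {
        warn(sprintf("constant activity for %s: %s generated as a decoy",
                     row$regulator, m))
        profiles[[m]] <- NULL
        next
      }
      r <- 0.05 + 0.9 * (a - rng[1]) / diff(rng)
      profiles[[m]] <- hill_invert(r, row$K_H, row$h, row$mode)
    }
  }
  # decoys are smooth random log-scale trajectories statistically
  # independent of the phase structure and of all regulator activities
  decoys <- setdiff(scn$metabolites, names(profiles))
  decoy_prof <- with_seed(hash_seed("decoys", master = scn$seed), {
    lapply(setNames(decoys, decoys), function(m) {
      mu <- runif(1, log(5), log(500))
      a <- runif(2, 0.2, 0.8)
      per <- c(runif(1, 7, 30), runif(1, 3, 8))
      ph <- runif(2, 0, 2 * pi)
      exp(mu + a[1] * sin(2 * pi * scn$time_met / per[1] + ph[1]) +
            a[2] * sin(2 * pi * scn$time_met / per[2] + ph[2]))
    })
  })
  profiles <- c(profiles, decoy_prof)[scn$metabolites]
  profiles <- profiles[!vapply(profiles, is.null, logical(1))]

  rc <- scn$replicate_count
  out <- purrr::map_dfr(names(profiles), function(m) {
    tidyr::expand_grid(time = scn$time_met, replicate = seq_len(rc)) %>%
      mutate(metabolite = m, mu = rep(profiles[[m]], each = rc)) %>%
      select("metabolite", "time", "replicate", "mu")
  })
  fac <- if (scn$met_noise_sdlog > 0) {
    with_seed(hash_seed("metnoise", master = scn$seed),
              exp(rnorm(nrow(out), 0, scn$met_noise_sdlog)))
  } else 1
  out$concentration <- out$mu * fac
  out$mu <- NULL
  out
}

# ---- toy metabolic model ----------------------------------------------

#' Generate a toy genome-scale metabolic model
#'
#' Builds a small stoichiometric model that links the scenario's metabolites
#' to the planted regulatory network: each planted effector metabolite is a
#' product of a reaction encoded by an exclusive target gene of its TF (so the
#' substrate/product distance criterion holds by construction), while decoy
#' metabolites attach to genes outside the planted regulons and to separate
#' subsystems. The model carries a cofactor list (ATP/ADP/AMP, NAD(H)) and
#' periplasmic/extracellular glucose species so that graph pruning is
#' exercised.
#'
#' @param scn An [scenario()] object.
#' @param network Regulatory network tibble; regenerated from `scn` when
#'   omitted.
#' @return A `metabolic_model` object; see [metabolic_model()].
#' @export
simulate_toy_metabolic_model <- function(scn, network = NULL) {
  if (is.null(network)) network <- simulate_regulatory_network(scn)
  planted <- scn$planted
  tf_edges <- network[!network$is_global, ]

  exclusive_gene <- function(tf) {
    mine <- tf_edges$gene[tf_edges$regulator == tf]
    others <- tf_edges$gene[tf_edges$regulator != tf]
    excl <- setdiff(mine, others)
    if (length(excl)) excl[1] else mine[1]
  }
  # decoy reactions attach to genes exclusive to one round-robin TF: a decoy
  # can then satisfy the distance criterion for at most that single TF
  all_tfs <- unique(tf_edges$regulator)
  decoy_hosts <- if (length(all_tfs)) all_tfs else "none"

  mets <- tibble(id = scn$metabolites, compartment = "c")
  cofactors <- c("atp_c", "adp_c", "amp_c", "nad_c", "nadh_c")
  species <- bind_rows(
    mets,
    tibble(id = cofactors, compartment = "c"),
    tibble(id = c("glc_e", "glc_p", "glc_c"), compartment = c("e", "p", "c"))
  )

  rxns <- list(); stoich <- list()
  for (i in seq_len(nrow(planted))) {
    m <- planted$metabolite[i]; tf <- planted$regulator[i]
    rid <- paste0("R_", m)
    rxns[[rid]] <- tibble(id = rid, subsystem = paste0("sub_", tf),
                          gene_rule = exclusive_gene(tf))
    stoich[[rid]] <- tibble(reaction = rid,
                            metabolite = c(m, "atp_c", "adp_c"),
                            coef = c(1, -1, 1))
  }
  decoys <- setdiff(scn$metabolites, planted$metabolite)
  for (j in seq_along(decoys)) {
    m <- decoys[j]
    rid <- paste0("R_", m)
    host <- decoy_hosts[(j - 1) %% length(decoy_hosts) + 1]
    g <- if (host == "none") "" else exclusive_gene(host)
    mine <- tf_edges$gene[tf_edges$regulator == host]
    excl <- setdiff(mine, tf_edges$gene[tf_edges$regulator != host])
    rule <- if (j == 1 && length(excl) >= 2)
      paste(excl[1], "and", excl[2]) else g
    rxns[[rid]] <- tibble(id = rid,
                          subsystem = paste0("decoy_sub_", m),
                          gene_rule = rule)
    stoich[[rid]] <- tibble(reaction = rid,
                            metabolite = c(m, "nad_c", "nadh_c"),
                            coef = c(1, -1, 1))
  }
  rxns[["R_glc_transport"]] <- tibble(id = "R_glc_transport",
                                      subsystem = "transport", gene_rule = "")
  stoich[["R_glc_transport"]] <- tibble(reaction = "R_glc_transport",
                                        metabolite = c("glc_e", "glc_p"),
                                        coef = c(-1, 1))
  upt_gene <- if (length(all_tfs)) exclusive_gene(all_tfs[1]) else ""
  rxns[["R_glc_uptake"]] <- tibble(id = "R_glc_uptake",
                                   subsystem = "transport",
                                   gene_rule = upt_gene)
  stoich[["R_glc_uptake"]] <- tibble(reaction = "R_glc_uptake",
                                     metabolite = c("glc_p", "glc_c"),
                                     coef = c(-1, 1))

  metabolic_model(metabolites = species, reactions = bind_rows(rxns),
                  stoich = bind_rows(stoich), cofactors = cofactors)
}

# ---- one-stop study ----------------------------------------------------

#' Simulate a complete synthetic study
#'
#' Runs all generators for one scenario and bundles their outputs together
#' with the planted ground truth, giving a full set of inputs for the
#' NCA -> Hill screen -> distance pipeline.
#'
#' @param scn An [scenario()] object.
#' @return A list of class `alloscreen_study` with elements `scenario`,
#'   `network`, `activities` (ground truth), `expression`, `metabolites`,
#'   `model`, `truth` (planted interactions) and `literature` (the truth
#'   formatted as a literature metabolite-TF network).
#' @examples
#' study <- simulate_study(scenario(n_genes = 40, n_regulators = 4,
#'                                  n_metabolites = 8, n_planted = 2, seed = 1))
#' names(study)
#' @export
simulate_study <- function(scn) {
  network <- simulate_regulatory_network(scn)
  activities <- simulate_tf_activities(scn)
  expression <- simulate_expression(activities, network, scn)
  metabolites <- simulate_metabolites(activities, scn)
  model <- simulate_toy_metabolic_model(scn, network)
  structure(list(
    scenario = scn, network = network, activities = activities,
    expression = expression, metabolites = metabolites, model = model,
    truth = scn$planted,
    literature = scn$planted %>% select("metabolite", "regulator", "mode")
  ), class = "alloscreen_study")
}
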