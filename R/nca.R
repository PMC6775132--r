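# Network component analysis: topology-constrained alternating least
# squares. The expression matrix E (genes x time, log10) is factored as
# E ~ A P where the zero pattern of A is fixed by the regulatory network and
# P holds the latent regulator activity profiles. The factorization is only
# defined up to a per-regulator scale and sign, which the ensemble summary
# removes.

# solve min ||E - A P|| over P with ridge fallback for ill-conditioned A
solve_P <- function(A, E, ridge = 1e-6) {
  AtA <- crossprod(A)
  ok <- tryCatch({
    R <- chol(AtA)
    kappa_est <- (max(diag(R)) / max(min(diag(R)), .Machine$double.eps))^2
    if (kappa_est > 1e8) stop("ill-conditioned")
    backsolve(R, backsolve(R, crossprod(A, E), transpose = TRUE))
  }, error = function(e) NULL)
  if (is.null(ok))
    ok <- solve(AtA + ridge * diag(ncol(A)), crossprod(A, E))
  ok
}

# update the nonzero entries of A row-wise: each gene's coefficients are the
# least-squares regression of its expression profile on its regulators'
# activity profiles
solve_A <- function(A, E, P, mask, ridge = 1e-6) {
  for (i in seq_len(nrow(A))) {
    idx <- which(mask[i, ])
    Ps <- P[idx, , drop = FALSE]
    M <- tcrossprod(Ps)
    rhs <- Ps %*% E[i, ]
    coefs <- tryCatch({
      R <- chol(M)
      kappa_est <- (max(diag(R)) / max(min(diag(R)), .Machine$double.eps))^2
      if (kappa_est > 1e8) stop("ill-conditioned")
      backsolve(R, backsolve(R, rhs, transpose = TRUE))
    }, error = function(e) solve(M + ridge * diag(length(idx)), rhs))
    A[i, idx] <- coefs
  }
  A
}

# one ALS run from one random initialization; where prior edge signs are
# known the starting weight is drawn in the prior orthant, otherwise
# uniformly on (-1, 1)
nca_single <- function(E, mask, signs, tol = 0.01, max_iter = 500,
                       ridge = 1e-6, init_seed = 1) {
  A <- matrix(0, nrow(E), ncol(mask), dimnames = dimnames(mask))
  nz <- which(mask)
  A[nz] <- with_seed(init_seed, {
    w <- runif(length(nz), -1, 1)
    if (!is.null(signs)) {
      pr <- signs[nz]
      known <- !is.na(pr) & pr != 0
      w[known] <- pr[known] * abs(w[known])
    }
    w
  })
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- solve_P(A, E, ridge)
    A <- solve_A(A, E, P, mask, ridge)
    res <- sum((E - A %*% P)^2)
    trace <- c(trace, res)
    if (it > 1) {
      prev <- trace[it - 1]
      if (prev <= .Machine$double.eps ||
          abs(prev - res) / max(prev, .Machine$double.eps) <= tol) {
        converged <- TRUE
        break
      }
    }
  }
  P <- solve_P(A, E, ridge)
  list(A = A, P = P, residual_trace = trace, converged = converged,
       residual = sum((E - A %*% P)^2))
}

# orient one restart's (A, P): flip regulator k when the fitted signs of its
# connectivity column disagree with the prior signs; fall back to correlation
# with a reference profile when no prior is available
orient_restart <- function(fit, mask, signs, reference = NULL) {
  for (k in seq_len(ncol(fit$A))) {
    idx <- which(mask[, k])
    s <- 0
    if (!is.null(signs)) {
      pr <- signs[idx, k]
      known <- !is.na(pr) & pr != 0
      if (any(known)) s <- sum(sign(fit$A[idx, k][known]) * pr[known])
    }
    if (s == 0 && !is.null(reference)) {
      cc <- suppressWarnings(cor(fit$P[k, ], reference[k, ]))
      if (is.finite(cc)) s <- cc
    }
    if (s < 0) {
      fit$A[, k] <- -fit$A[, k]
      fit$P[k, ] <- -fit$P[k, ]
    }
  }
  fit
}

#' Infer regulator activities by network component analysis
#'
#' Factors a log10 expression time course into fixed-topology connectivity
#' weights and latent regulator activity profiles by alternating least
#' squares: given the connectivity weights, activities are the least-squares
#' solution; given activities, each gene's weights are re-estimated by least
#' squares restricted to that gene's regulators, preserving the zero pattern
#' exactly. Each restart starts from connectivity weights drawn uniformly on
#' (-1, 1) and stops when the summed squared residual changes by at most
#' `tol` (relative) between iterations. The restart ensemble yields
#' per-regulator mean activity profiles with percentile 95% confidence bands
#' after z-score normalization and sign alignment (see Details).
#'
#' @details NCA is invariant to rescaling a regulator's activity row while
#' inversely rescaling its connectivity column, so raw restarts are not
#' comparable. Each restart's profiles are z-scored per regulator over time,
#' then sign-oriented: against the signed connectivity prior where edge signs
#' are supplied (flip when the majority of fitted weights disagree), else by
#' correlation with the first converged restart. Means and pointwise
#' 2.5/97.5 percentile bands are computed over converged restarts only.
#'
#' @param expression Tibble `gene`, `time`, `replicate`, `value` (log10
#'   scale); replicates are averaged per time point.
#' @param network Connectivity tibble `regulator`, `gene`(, `sign`), e.g.
#'   from [assemble_connectivity()] or [simulate_regulatory_network()].
#' @param n_restarts Number of randomized restarts (default 100).
#' @param tol Relative residual-change convergence threshold (default 0.01).
#' @param max_iter Iteration cap per restart (default 500).
#' @param seed Master seed for the restart initializations.
#' @param ridge Ridge penalty used as fallback for ill-conditioned
#'   subproblems (condition number > 1e8).
#' @return An object of class `nca_fit`; see [tidy.nca_fit()],
#'   [glance.nca_fit()] and [autoplot.nca_fit()].
#' @examples
#' scn <- scenario(n_genes = 30, n_regulators = 3, n_metabolites = 4,
#'                 n_timepoints = 9, n_met_timepoints = 9, noise_sd = 0,
#'                 n_planted = 2, seed = 1)
#' study <- simulate_study(scn)
#' fit <- nca(study$expression, study$network, n_restarts = 5, seed = 1)
#' glance(fit)
#' @export
nca <- function(expression, network, n_restarts = 100, tol = 0.01,
                max_iter = 500, seed = 1, ridge = 1e-6) {
  if (n_restarts < 1) stopf("n_restarts must be >= 1")
  if (tol <= 0 || tol >= 1) stopf("tol must be in (0, 1)")
  E <- profile_matrix(expression, "gene", "value")
  regs <- sort(unique(network$regulator))
  genes_net <- unique(network$gene)
  keep <- intersect(rownames(E), genes_net)
  if (!length(keep)) stopf("no genes shared between expression data and network")
  missing <- setdiff(rownames(E), genes_net)
  if (length(missing))
    inform(sprintf("%d gene(s) without regulators excluded from NCA",
                   length(missing)))
  E <- E[keep, , drop = FALSE]
  net <- network %>% filter(.data$gene %in% keep)
  regs <- sort(unique(net$regulator))
  if (nrow(E) <= length(regs))
    stopf("NCA needs more genes (%d) than regulators (%d)", nrow(E), length(regs))

  mask <- matrix(FALSE, nrow(E), length(regs),
                 dimnames = list(rownames(E), regs))
  mask[cbind(match(net$gene, rownames(E)), match(net$regulator, regs))] <- TRUE
  signs <- NULL
  if ("sign" %in% names(net) && any(!is.na(net$sign))) {
    signs <- matrix(NA_real_, nrow(E), length(regs),
                    dimnames = dimnames(mask))
    signs[cbind(match(net$gene, rownames(E)), match(net$regulator, regs))] <-
      as.numeric(net$sign)
  }

  restart_seeds <- with_seed(seed, sample.int(2147483646L, n_restarts))
  fits <- lapply(restart_seeds, function(s)
    nca_single(E, mask, signs, tol = tol, max_iter = max_iter,
               ridge = ridge, init_seed = s))

  structure(list(
    E = E, mask = mask, signs = signs, regulators = regs,
    times = as.numeric(colnames(E)), fits = fits,
    settings = list(n_restarts = n_restarts, tol = tol,
                    max_iter = max_iter, seed = seed, ridge = ridge),
    summary = summarize_restarts(fits, mask, signs, regs,
                                 as.numeric(colnames(E)))
  ), class = "nca_fit")
}

# align converged restarts and compute the ensemble summary
summarize_restarts <- function(fits, mask, signs, regs, times) {
  conv <- which(vapply(fits, `[[`, logical(1), "converged"))
  if (!length(conv)) stopf("no NCA restart converged; raise max_iter or tol")
  ref <- NULL
  aligned <- array(NA_real_, c(length(regs), length(times), length(conv)),
                   dimnames = list(regs, NULL, NULL))
  for (j in seq_along(conv)) {
    f <- orient_restart(fits[[conv[j]]], mask, signs, reference = ref)
    Pz <- t(apply(f$P, 1, zscore))
    if (is.null(ref)) ref <- Pz
    aligned[, , j] <- Pz
  }
  mean_p <- apply(aligned, c(1, 2), mean)
  lo <- apply(aligned, c(1, 2), quantile, probs = 0.025, names = FALSE)
  hi <- apply(aligned, c(1, 2), quantile, probs = 0.975, names = FALSE)
  # the percentile band is widened minimally so it always contains the mean
  lo <- pmin(lo, mean_p)
  hi <- pmax(hi, mean_p)
  rng <- apply(mean_p, 1, function(x) diff(range(x)))
  rel_ci <- rowMeans(hi - lo) / ifelse(rng > 0, rng, NA_real_)
  list(aligned = aligned, mean = mean_p, lo = lo, hi = hi,
       rel_ci_width = setNames(rel_ci, regs), n_converged = length(conv),
       converged_idx = conv)
}

#' Fraction of expression variance explained by an NCA factorization
#'
#' Computes `1 - ||E - AP||^2 / ||E - rowmeans(E)||^2`, clamped to `[0, 1]`
#' for reporting, i.e. the share of per-gene-centered transcript dynamics
#' reproduced by the regulator activities.
#'
#' @param E Expression matrix (genes x time) or an `nca_fit` (then `A`, `P`
#'   are taken from its best converged restart).
#' @param A,P Connectivity and activity matrices.
#' @return A single fraction in `[0, 1]`.
#' @export
variance_explained <- function(E, A = NULL, P = NULL) {
  if (inherits(E, "nca_fit")) {
    best <- best_restart(E)
    return(variance_explained(E$E, best$A, best$P))
  }
  stopifnot(!is.null(A), !is.null(P))
  resid <- sum((E - A %*% P)^2)
  tot <- sum((E - rowMeans(E))^2)
  if (tot <= .Machine$double.eps) return(if (resid <= .Machine$double.eps) 1 else 0)
  min(max(1 - resid / tot, 0), 1)
}

best_restart <- function(fit) {
  conv <- fit$summary$converged_idx
  fit$fits[[conv[which.min(vapply(fit$fits[conv], `[[`, numeric(1), "residual"))]]]
}

#' Check NCA identifiability of a connectivity topology
#'
#' Advisory diagnostics: flags pairs of regulators with identical target
#' sets and regulators whose target set is fully covered by the union of the
#' other regulators' targets. Either situation leaves the factorization
#' under-determined, but the check never blocks a run.
#'
#' @param network Connectivity tibble `regulator`, `gene`.
#' @return Tibble `regulator`, `duplicate_of`, `covered_by_others`.
#' @export
check_identifiability <- function(network) {
  if (!nrow(network)) stopf("empty connectivity matrix")
  sets <- split(network$gene, network$regulator)
  sets <- lapply(sets, unique)
  regs <- names(sets)
  key <- vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1))
  dup_of <- vapply(seq_along(regs), function(i) {
    j <- which(key == key[i])
    j <- j[j != i]
    if (length(j)) regs[min(j)] else NA_character_
  }, character(1))
  covered <- vapply(seq_along(regs), function(i) {
    others <- unique(unlist(sets[-i]))
    all(sets[[i]] %in% others)
  }, logical(1))
  tibble(regulator = regs, duplicate_of = dup_of,
         covered_by_others = covered)
}

#' @export
print.nca_fit <- function(x, ...) {
  cat(sprintf("<nca_fit> %d genes x %d time points, %d regulators\n",
              nrow(x$E), length(x$times), length(x$regulators)))
  cat(sprintf("  %d/%d restarts converged; variance explained %.3f\n",
              x$summary$n_converged, x$settings$n_restarts,
              variance_explained(x)))
  invisible(x)
}

#' Tidy an NCA fit
#'
#' @param x An `nca_fit`.
#' @param ... Unused.
#' @return Tibble `regulator`, `time`, `activity` (ensemble mean, z-scored),
#'   `ci_lo`, `ci_hi`.
#' @export
tidy.nca_fit <- function(x, ...) {
  s <- x$summary
  purrr::map_dfr(seq_along(x$regulators), function(k)
    tibble(regulator = x$regulators[k], time = x$times,
           activity = s$mean[k, ], ci_lo = s$lo[k, ], ci_hi = s$hi[k, ]))
}

#' One-row summary of an NCA fit
#'
#' @param x An `nca_fit`.
#' @param ... Unused.
#' @return Tibble with the number of regulators, converged restarts, the best
#'   restart residual and the variance explained.
#' @export
glance.nca_fit <- function(x, ...) {
  best <- best_restart(x)
  tibble(n_genes = nrow(x$E), n_regulators = length(x$regulators),
         n_timepoints = length(x$times),
         n_restarts = x$settings$n_restarts,
         n_converged = x$summary$n_converged,
         best_residual = best$residual,
         variance_explained = variance_explained(x$E, best$A, best$P))
}

#' Extract ensemble mean activities from an NCA fit
#'
#' Convenience accessor returning the activity table the downstream Hill
#' screen consumes, optionally excluding the global basal regulator.
#'
#' @param fit An `nca_fit`.
#' @param drop_global Drop the regulator named "global" (default TRUE).
#' @return Tibble `regulator`, `time`, `activity`.
#' @export
nca_activities <- function(fit, drop_global = TRUE) {
  out <- tidy(fit) %>% select("regulator", "time", "activity")
  if (drop_global) out <- out %>% filter(.data$regulator != "global")
  out
}
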