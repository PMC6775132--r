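# End-to-end orchestration: TF filtering, known-network recovery, candidate
# prediction, per-TF effector statistics, and the light time-course
# utilities (hierarchical clustering of dynamics, adenylate energy charge).

#' Filter transcription factors before the all-pairs screen
#'
#' Excludes regulators that are unsuitable for the metabolite screen:
#' (i) on-off-on dynamics, detected when the absolute correlation of the mean
#' activity profile with the binary growth-phase indicator exceeds
#' `onoff_threshold` (such profiles track the growth phase itself rather than
#' any single metabolite); (ii) poorly estimated profiles whose mean 95%
#' confidence-interval width exceeds `ci_threshold` times the regulator's
#' activity range; (iii) members of a supplied two-component-system list
#' (these respond to external signals rather than internal metabolites). The
#' global basal regulator is always excluded.
#'
#' @param fit An `nca_fit`.
#' @param two_component Character vector of regulators in two-component
#'   systems.
#' @param phase_times Length-2 numeric, growth-to-starvation and
#'   starvation-to-regrowth times (hours); required when the on-off-on filter
#'   is enabled.
#' @param onoff_threshold Phase-indicator correlation threshold (default
#'   0.9).
#' @param ci_threshold Relative confidence-width threshold (default 1,
#'   i.e. 100% of the activity range).
#' @return Tibble `regulator`, `excluded`, `reasons` (comma-separated,
#'   subset of `on_off_on`, `wide_confidence`, `two_component`),
#'   `phase_correlation`, `rel_ci_width`.
#' @export
filter_tfs <- function(fit, two_component = character(),
                       phase_times = NULL, onoff_threshold = 0.9,
                       ci_threshold = 1) {
  if (is.null(phase_times))
    stopf("phase_times is required for the on-off-on filter")
  ind <- as.numeric(phase_indicator(fit$times, phase_times))
  s <- fit$summary
  purrr::map_dfr(seq_along(fit$regulators), function(k) {
    r <- fit$regulators[k]
    pc <- suppressWarnings(cor(s$mean[k, ], ind))
    rel <- s$rel_ci_width[[r]]
    reasons <- c(
      if (is.finite(pc) && abs(pc) > onoff_threshold) "on_off_on",
      if (is.finite(rel) && rel > ci_threshold) "wide_confidence",
      if (r %in% two_component) "two_component")
    if (r == "global") reasons <- union(reasons, "global_regulator")
    tibble(regulator = r, excluded = length(reasons) > 0,
           reasons = paste(reasons, collapse = ","),
           phase_correlation = pc, rel_ci_width = rel)
  })
}

#' Retained regulators after TF filtering
#' @param filter_report Output of [filter_tfs()].
#' @return Character vector of retained regulator ids.
#' @export
retained_tfs <- function(filter_report) {
  filter_report$regulator[!filter_report$excluded]
}

#' Score recovery of a literature metabolite-TF network
#'
#' For every literature TF covered by the data (at least one known effector
#' measured and a fitted activity profile), reports whether any known
#' effector shows a Hill-type relationship (`r_squared > r2_threshold`) and
#' whether the fitted mode (activation/inhibition) matches the annotated one.
#' Literature edges whose metabolite was not measured count as not covered,
#' not as failures.
#'
#' @param literature Tibble `metabolite`, `regulator`, `mode`.
#' @param fits A `hill_screen` tibble from [screen_hill()].
#' @param r2_threshold R-squared threshold (default 0.75).
#' @return Tibble per literature TF: `regulator`, `covered`, `recovered`,
#'   `n_known`, `n_measured`, `best_known_r2`, `mode_match` (NA when the
#'   annotation is "unknown" or the TF was not recovered).
#' @export
recover_known_network <- function(literature, fits, r2_threshold = 0.75) {
  fitted_pairs <- fits %>%
    filter(is.na(.data$skip_reason) | !nzchar(.data$skip_reason))
  purrr::map_dfr(split(literature, literature$regulator), function(lit) {
    r <- lit$regulator[1]
    f <- fitted_pairs %>% filter(.data$regulator == r)
    measured <- lit %>% filter(.data$metabolite %in% f$metabolite)
    covered <- nrow(measured) > 0 && nrow(f) > 0
    if (!covered) {
      return(tibble(regulator = r, covered = FALSE, recovered = NA,
                    n_known = nrow(lit), n_measured = nrow(measured),
                    best_known_r2 = NA_real_, mode_match = NA))
    }
    known_fits <- f %>%
      semi_join(measured, by = c("metabolite", "regulator")) %>%
      left_join(measured %>% select("metabolite", lit_mode = "mode"),
                by = "metabolite")
    hits <- known_fits %>%
      filter(is.finite(.data$r_squared), .data$r_squared > r2_threshold)
    recovered <- nrow(hits) > 0
    mode_match <- if (!recovered) NA else {
      annotated <- hits %>% filter(.data$lit_mode %in% c("activation", "inhibition"))
      if (!nrow(annotated)) NA else all(annotated$mode == annotated$lit_mode)
    }
    tibble(regulator = r, covered = TRUE, recovered = recovered,
           n_known = nrow(lit), n_measured = nrow(measured),
           best_known_r2 = max(known_fits$r_squared, -Inf),
           mode_match = mode_match)
  })
}

#' Predict candidate metabolite-TF interactions
#'
#' Intersects the three evidence layers: a Hill-type relationship
#' (`r_squared > r2_threshold`), a passing metabolic-network distance
#' criterion, and a retained TF. Candidates of TFs that correlate with at
#' most two metabolites are flagged (`few_effectors`), since sparse effector
#' sets are the most specific predictions.
#'
#' @param fits A `hill_screen` tibble.
#' @param verdicts Tibble from [distance_criterion()].
#' @param filter_report Optional tibble from [filter_tfs()]; when supplied,
#'   excluded TFs are removed.
#' @param r2_threshold R-squared threshold (default 0.75).
#' @return Tibble of candidates: `metabolite`, `regulator`, `mode`, `K_H`,
#'   `h`, `lag`, `r_squared`, `satisfied_by`, `witness_gene`,
#'   `n_effectors_tf`, `few_effectors`, sorted by TF then R-squared.
#' @export
predict_interactions <- function(fits, verdicts, filter_report = NULL,
                                 r2_threshold = 0.75) {
  cand <- fits %>%
    filter(is.finite(.data$r_squared), .data$r_squared > r2_threshold)
  if (!is.null(filter_report))
    cand <- cand %>% filter(.data$regulator %in% retained_tfs(filter_report))
  cand <- cand %>%
    inner_join(verdicts %>%
                 select("metabolite", "regulator", "passes",
                        "satisfied_by", "witness_gene"),
               by = c("metabolite", "regulator")) %>%
    filter(!is.na(.data$passes), .data$passes)
  cand <- cand %>%
    group_by(.data$regulator) %>%
    mutate(n_effectors_tf = n(), few_effectors = n() <= 2) %>%
    ungroup() %>%
    select("metabolite", "regulator", "mode", "K_H", "h", "lag",
           "r_squared", "satisfied_by", "witness_gene",
           "n_effectors_tf", "few_effectors") %>%
    arrange(.data$regulator, desc(.data$r_squared), .data$metabolite)
  cand
}

#' Average effector counts per TF before and after the distance criterion
#'
#' Mean number of metabolites with a Hill-type relationship per TF, before
#' and after applying the distance criterion. Two denominators are reported:
#' all TFs with at least one passing metabolite before the criterion, and
#' the subset that still has one after it.
#'
#' @param fits A `hill_screen` tibble.
#' @param verdicts Tibble from [distance_criterion()].
#' @param r2_threshold R-squared threshold (default 0.75).
#' @return One-row tibble: `n_tfs_before`, `mean_before`, `mean_after`
#'   (over TFs with >= 1 passing metabolite before the criterion),
#'   `n_tfs_after`, `mean_after_surviving` (over TFs with >= 1 candidate
#'   after it). All `NA` when no pair passes.
#' @export
per_tf_effector_stats <- function(fits, verdicts, r2_threshold = 0.75) {
  passing <- fits %>%
    filter(is.finite(.data$r_squared), .data$r_squared > r2_threshold)
  if (!nrow(passing))
    return(tibble(n_tfs_before = 0L, mean_before = NA_real_,
                  mean_after = NA_real_, n_tfs_after = 0L,
                  mean_after_surviving = NA_real_))
  after <- passing %>%
    inner_join(verdicts %>% select("metabolite", "regulator", "passes"),
               by = c("metabolite", "regulator")) %>%
    filter(!is.na(.data$passes), .data$passes)
  before_counts <- passing %>% dplyr::count(.data$regulator)
  after_counts <- after %>% dplyr::count(.data$regulator)
  merged <- before_counts %>%
    left_join(after_counts, by = "regulator",
              suffix = c("_before", "_after")) %>%
    mutate(n_after = dplyr::coalesce(.data$n_after, 0L))
  tibble(n_tfs_before = nrow(merged),
         mean_before = mean(merged$n_before),
         mean_after = mean(merged$n_after),
         n_tfs_after = sum(merged$n_after > 0),
         mean_after_surviving = if (any(merged$n_after > 0))
           mean(merged$n_after[merged$n_after > 0]) else NA_real_)
}

#' Summary counts of an end-to-end screen
#'
#' @param fits A `hill_screen` tibble.
#' @param verdicts Tibble from [distance_criterion()].
#' @param filter_report Tibble from [filter_tfs()].
#' @param r2_threshold R-squared threshold (default 0.75).
#' @return One-row tibble: pairs tested, pairs passing the R-squared
#'   threshold, candidates after the distance criterion, TFs retained.
#' @export
screen_summary <- function(fits, verdicts, filter_report,
                           r2_threshold = 0.75) {
  cand <- predict_interactions(fits, verdicts, filter_report, r2_threshold)
  tibble(
    n_pairs_tested = sum(is.na(fits$skip_reason)),
    n_pairs_skipped = sum(!is.na(fits$skip_reason)),
    n_pairs_passing_r2 = sum(fits$passed, na.rm = TRUE),
    n_candidates = nrow(cand),
    n_tfs_retained = length(retained_tfs(filter_report)),
    n_tfs_with_candidates = dplyr::n_distinct(cand$regulator)
  )
}

#' Cluster time-course dynamics
#'
#' Z-scores each series over time (constant series map to all zeros),
#' clusters with agglomerative hierarchical clustering (Euclidean distance,
#' average linkage by default) and cuts the tree into `k` groups.
#'
#' @param tbl Long tibble with columns `id`, `time`, `value` (replicates, if
#'   any, are averaged per time point).
#' @param k Number of clusters (default 4).
#' @param linkage Linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return List with `labels` (tibble `id`, `cluster`) and `profiles`
#'   (tibble `cluster`, `time`, `mean_value`, `n_members`).
#' @export
cluster_dynamics <- function(tbl, k = 4, linkage = "average") {
  m <- tbl %>%
    group_by(.data$id, .data$time) %>%
    summarise(value = mean(.data$value), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "time", values_from = "value") %>%
    arrange(.data$id)
  ids <- m$id
  mat <- as.matrix(m[, -1])
  z <- t(apply(mat, 1, zscore))
  hc <- hclust(dist(z), method = linkage)
  cl <- cutree(hc, k = min(k, nrow(z)))
  labels <- tibble(id = ids, cluster = unname(cl))
  times <- as.numeric(colnames(mat))
  profiles <- purrr::map_dfr(sort(unique(cl)), function(g)
    tibble(cluster = g, time = times,
           mean_value = colMeans(z[cl == g, , drop = FALSE]),
           n_members = sum(cl == g)))
  list(labels = labels, profiles = profiles)
}

#' Adenylate energy charge
#'
#' Atkinson's index `(ATP + 0.5 ADP) / (ATP + ADP + AMP)`, a value in
#' `[0, 1]` summarizing the cellular energetic state.
#'
#' @param atp,adp,amp Concentrations (same units), vectorized.
#' @return Numeric vector in `[0, 1]`; `NA` where the total adenylate pool
#'   is zero.
#' @examples
#' energy_charge(1, 0, 0)   # 1
#' energy_charge(1, 1, 1)   # 0.5
#' @export
energy_charge <- function(atp, adp, amp) {
  if (any(c(atp, adp, amp) < 0, na.rm = TRUE))
    stopf("concentrations must be non-negative")
  tot <- atp + adp + amp
  ifelse(tot > 0, (atp + 0.5 * adp) / tot, NA_real_)
}

#' Run the full screen on a study
#'
#' Convenience driver chaining NCA, TF filtering, the all-pairs Hill screen,
#' the distance criterion and candidate prediction, mirroring the
#' simulate -> nca -> hillscreen -> distance -> predict pipeline.
#'
#' @param study An `alloscreen_study` from [simulate_study()], or a list with
#'   the same elements built from user data (`expression`, `metabolites`,
#'   `network`, `model`, and optionally `literature` and `scenario`).
#' @param n_restarts,nca_seed NCA ensemble settings.
#' @param n_starts,screen_seed Hill-screen settings.
#' @param r2_threshold R-squared threshold (default 0.75).
#' @param two_component Two-component-system regulators to exclude.
#' @param phase_times Phase switch times; defaults to the study scenario's.
#' @return List with `nca`, `filter_report`, `fits`, `verdicts`,
#'   `candidates`, `summary`, `effector_stats` and (when the study has a
#'   literature network) `recovery`.
#' @export
run_screen <- function(study, n_restarts = 100, nca_seed = 1,
                       n_starts = 50, screen_seed = 1, r2_threshold = 0.75,
                       two_component = character(), phase_times = NULL) {
  phase_times <- phase_times %||% study$scenario$phase_times
  fit <- nca(study$expression, study$network, n_restarts = n_restarts,
             seed = nca_seed)
  report <- filter_tfs(fit, two_component = two_component,
                       phase_times = phase_times)
  acts <- nca_activities(fit) %>%
    filter(.data$regulator %in% retained_tfs(report))
  fits <- screen_hill(study$metabolites, acts, n_starts = n_starts,
                      seed = screen_seed, r2_threshold = r2_threshold)
  regulon <- study$network %>% filter(!.data$is_global)
  verdicts <- distance_criterion(
    fits %>% distinct(.data$metabolite, .data$regulator),
    study$model, regulon)
  candidates <- predict_interactions(fits, verdicts, report, r2_threshold)
  out <- list(nca = fit, filter_report = report, fits = fits,
              verdicts = verdicts, candidates = candidates,
              summary = screen_summary(fits, verdicts, report, r2_threshold),
              effector_stats = per_tf_effector_stats(fits, verdicts,
                                                     r2_threshold))
  if (!is.null(study$literature))
    out$recovery <- recover_known_network(study$literature, fits,
                                          r2_threshold)
  out
}
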