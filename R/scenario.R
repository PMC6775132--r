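#' Define a synthetic study scenario
#'
#' A scenario fixes everything the synthetic-data generators need: the size of
#' the planted regulatory network, the sampling grids of the transcriptome and
#' metabolome time courses, the growth--starvation--regrowth phase structure,
#' the measurement-noise levels, and the set of planted metabolite--TF
#' interactions that downstream recovery tests try to rediscover.
#'
#' Defaults emulate a 20 h batch experiment: 6 h growth, 12 h carbon
#' starvation and 2 h growth resumption, sampled at 29 transcriptome and 35
#' metabolome time points in duplicate. Expression noise is additive on the
#' log10 scale (default 0.064, i.e. roughly a 16% multiplicative error on
#' transcript abundances); metabolite measurements get lognormal noise with
#' roughly an 18% coefficient of variation.
#'
#' @param n_genes Number of genes in the planted network.
#' @param n_regulators Number of transcription factors (a global basal
#'   regulator is always added on top of these).
#' @param n_metabolites Number of measured metabolites (planted effectors plus
#'   decoys).
#' @param n_timepoints Transcriptome time points, evenly spaced on
#'   `[0, t_max]`.
#' @param n_met_timepoints Metabolome time points; the metabolome grid is the
#'   transcriptome grid plus interval midpoints until this count is reached.
#' @param t_max Duration of the experiment in hours.
#' @param phase_times Times (hours) of the growth-to-starvation and
#'   starvation-to-regrowth switches.
#' @param noise_sd Standard deviation of additive log10-scale expression
#'   noise; must be >= 0.
#' @param met_noise_sdlog Lognormal sdlog of metabolite measurement noise.
#' @param replicate_count Replicates per time point.
#' @param planted Optional tibble of planted interactions with columns
#'   `metabolite`, `regulator`, `mode` ("activation"/"inhibition"), `K_H`
#'   (uM, > 0), `h` (in (0, 10]), `lag` (0 or 1 transcriptome steps). When
#'   `NULL`, `n_planted` interactions are drawn deterministically from `seed`.
#' @param n_planted Number of auto-planted interactions when `planted` is
#'   `NULL`.
#' @param seed Integer seed; the same scenario and seed give bit-identical
#'   synthetic data.
#'
#' @return An object of class `alloscreen_scenario`.
#' @examples
#' scn <- scenario(n_genes = 40, n_regulators = 4, n_metabolites = 8,
#'                 n_planted = 3, seed = 1)
#' scn$planted
#' @export
scenario <- function(n_genes = 120, n_regulators = 10, n_metabolites = 30,
                     n_timepoints = 29, n_met_timepoints = 35, t_max = 20,
                     phase_times = c(6, 18), noise_sd = 0.064,
                     met_noise_sdlog = 0.178, replicate_count = 2,
                     planted = NULL, n_planted = 5, seed = 1) {
  if (n_regulators >= n_genes)
    stopf("need more genes than regulators (%d regulators, %d genes)",
          n_regulators, n_genes)
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (replicate_count < 1) stopf("replicate_count must be >= 1")
  if (n_met_timepoints < n_timepoints)
    stopf("metabolome grid must be at least as dense as the transcriptome grid")
  if (length(phase_times) != 2 || diff(phase_times) <= 0 ||
      phase_times[1] <= 0 || phase_times[2] >= t_max)
    stopf("phase_times must be strictly increasing and inside (0, t_max)")

  time_trans <- seq(0, t_max, length.out = n_timepoints)
  phase_boundaries <- vapply(phase_times,
                             function(p) min(which(time_trans >= p)),
                             integer(1))
  if (phase_boundaries[1] <= 1 || phase_boundaries[2] >= n_timepoints ||
      diff(phase_boundaries) < 1)
    stopf("phase boundaries fall outside the interior of the time grid")

  # metabolome grid: transcriptome grid plus midpoints of the widest-spread
  # early intervals until the requested density is reached
  extra <- n_met_timepoints - n_timepoints
  mids <- (time_trans[-1] + time_trans[-n_timepoints]) / 2
  time_met <- sort(c(time_trans, mids[seq_len(extra)]))

  regulators <- if (n_regulators > 0) paste0("TF", seq_len(n_regulators)) else character()
  genes <- sprintf("g%03d", seq_len(n_genes))
  metabolites <- sprintf("met%02d", seq_len(n_metabolites))

  if (is.null(planted)) {
    # the first TF is reserved as the on-off-on filter control, so planted
    # interactions go to the remaining regulators when there are enough
    hosts <- if (n_regulators > n_planted) regulators[-1] else regulators
    n_planted <- min(n_planted, n_metabolites, length(hosts))
    planted <- with_seed(hash_seed("plant", master = seed), {
      tibble(
        metabolite = metabolites[seq_len(n_planted)],
        regulator = hosts[seq_len(n_planted)],
        mode = sample(c("activation", "inhibition"), n_planted, replace = TRUE),
        K_H = exp(runif(n_planted, log(10), log(500))),
        h = sample(c(1, 2, 4), n_planted, replace = TRUE),
        lag = rep(c(0L, 1L), length.out = n_planted)
      )
    })
  } else {
    planted <- as_tibble(planted)
    if (!"lag" %in% names(planted)) planted$lag <- 0L
  }
  stopifnot(all(planted$K_H > 0), all(planted$h > 0), all(planted$h <= 10),
            all(planted$lag %in% c(0L, 1L)),
            all(planted$mode %in% c("activation", "inhibition")),
            all(planted$metabolite %in% metabolites),
            all(planted$regulator %in% regulators))

  structure(list(
    n_genes = n_genes, n_regulators = n_regulators,
    n_metabolites = n_metabolites,
    n_timepoints = n_timepoints, n_met_timepoints = n_met_timepoints,
    t_max = t_max, phase_times = phase_times,
    phase_boundaries = phase_boundaries,
    time_trans = time_trans, time_met = time_met,
    noise_sd = noise_sd, met_noise_sdlog = met_noise_sdlog,
    replicate_count = replicate_count,
    regulators = regulators, genes = genes, metabolites = metabolites,
    planted = planted, seed = as.integer(seed)
  ), class = "alloscreen_scenario")
}

#' @export
print.alloscreen_scenario <- function(x, ...) {
  cat(sprintf(
    "<alloscreen_scenario> %d genes, %d TFs (+global), %d metabolites\n",
    x$n_genes, x$n_regulators, x$n_metabolites))
  cat(sprintf("  %d/%d transcriptome/metabolome time points over %g h, phases at %g h and %g h\n",
              x$n_timepoints, x$n_met_timepoints, x$t_max,
              x$phase_times[1], x$phase_times[2]))
  cat(sprintf("  noise_sd = %g (log10), %d replicates, %d planted interactions, seed %d\n",
              x$noise_sd, x$replicate_count, nrow(x$planted), x$seed))
  invisible(x)
}

# growth-phase indicator on an arbitrary time vector: TRUE during the two
# growth phases, FALSE during starvation
phase_indicator <- function(times, phase_times) {
  times < phase_times[1] | times >= phase_times[2]
}
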