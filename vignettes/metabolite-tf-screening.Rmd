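---
title: "Screening metabolite–transcription-factor interactions from paired time-course omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening metabolite–transcription-factor interactions from paired time-course omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alloscreen)
library(dplyr)
```

## The problem

Many small metabolites regulate gene expression by binding transcription
factors (TFs) allosterically: cyclic AMP activates CRP, tryptophan arms the
TrpR repressor, and so on. Most such interactions are unknown, because
in vitro binding assays do not scale to all pairs of metabolites and TFs.
`alloscreen` implements an in vivo screening strategy: perturb a culture
through a dynamic transition (here, growth → carbon starvation → growth
resumption), measure metabolite concentrations and transcript abundances
over time, infer the latent activity of every TF from the transcriptome,
and ask which metabolite's concentration profile explains which TF's
activity profile through saturable Hill-type kinetics. Because co-varying
metabolites create many coincidental matches, candidates are finally pruned
with a metabolic-network distance criterion.

The pipeline has three computational stages, each exposed as ordinary
tibble-in/tibble-out functions:

1. **TF activity inference (NCA)** — `nca()`
2. **All-pairs Hill screening** — `screen_hill()`
3. **Distance pruning and prediction** — `distance_criterion()`,
   `predict_interactions()`

A fourth component, the synthetic-data generator (`scenario()`,
`simulate_study()`), plants known interactions into simulated data so that
every stage has a recovery test.

## Network component analysis

Let $E$ be the $n_g \times n_t$ matrix of log$_{10}$ expression values
(genes × time points, TPM units, replicates averaged). Given a known
regulatory topology, NCA seeks

$$\min_{A,P} \lVert E - A P \rVert^2,$$

where $A$ ($n_g \times n_r$) holds connectivity weights with a **fixed zero
pattern** — gene $i$ may only load on its annotated regulators — and $P$
($n_r \times n_t$) holds the latent activity profiles. A global basal
regulator connected to every gene absorbs baseline expression by RNA
polymerase; it is appended automatically by `assemble_connectivity()` and
the synthetic generator.

`nca()` solves this by alternating least squares: given $A$, the activity
update $P = (A^\top A)^{-1} A^\top E$ is the exact least-squares solution;
given $P$, each gene's nonzero weights are re-estimated by a small per-gene
regression restricted to that gene's regulators, so the zero pattern is
preserved exactly. Both half-steps solve their subproblem exactly, which
makes the summed squared residual monotone non-increasing. Iteration stops
when the residual changes by no more than `tol` (default 1%, i.e. 0.01
relative) between sweeps, with a `max_iter = 500` safety cap.

The factorization is invariant to rescaling any activity row while
inversely rescaling the matching connectivity column, so a single run's
scale and sign are arbitrary. `nca()` therefore runs an ensemble of
restarts (default 100), each initialized with weights drawn uniformly on
$(-1, 1)$ — in the prior sign's orthant where edge signs are annotated,
which empirically steers nearly every restart into the global basin on
identifiable problems. Each converged restart is z-scored per regulator
over time, sign-oriented (against the annotated edge signs when available,
else by correlation with the first converged restart), and summarized by
the pointwise mean and the 2.5/97.5 percentile band. The percentile band is
widened minimally where needed so it always contains the mean. The fraction
of per-gene-centered transcript dynamics reproduced by the factorization is
reported by `variance_explained()`.

Degenerate subproblems (condition number above $10^8$, e.g. duplicated
regulator target sets) fall back to a small ridge penalty ($10^{-6}$) so
ALS stays defined; `check_identifiability()` reports, without blocking,
regulators with duplicated target sets or targets fully covered by other
regulators.

## Hill-type screening

For a metabolite concentration $x$ and TF activity $y$, activation and
inhibition kinetics are

$$y = y_{\max}\frac{x^h}{x^h + K_H^h}, \qquad
  y = y_{\max}\frac{K_H^h}{x^h + K_H^h},$$

with activation constant $K_H$ (µM) and Hill coefficient $h$, constrained
to $h \le 10$ (steeper curves are indistinguishable from steps at this
sampling density). The mode is chosen from the sign of the linear Pearson
correlation: positive → activation, negative → inhibition. With a fitted
intercept the two transforms give identical goodness of fit (they differ by
an affine map), so the correlation sign is the only principled mode
selector.

NCA activities are z-scored and can be negative while the Hill forms are
nonnegative, so the package fits an affine output map: given $(K_H, h)$,
the transform $u(x)$ is computed and the scale $y_{\max}$ and an offset are
obtained in closed form by ordinary least squares. The nonlinear search
then runs only over $(\log K_H, h)$, bounded (`L-BFGS-B`) with $K_H$
between a tenth of the smallest positive and ten times the largest observed
concentration, from 50 random starts per pair ($K_H$ log-uniform, $h$
uniform on $(0, 10]$). Because the metabolome and transcriptome were
sampled on different grids (35 vs 29 time points), `align_series()` first
pairs each activity time point with the replicate-mean metabolite value at
the nearest metabolome time point within half a grid step; pairs with fewer
than six common points are skipped with a recorded reason.

Each pair is fitted twice: at lag 0, and with the TF activity shifted back
by one time point (activity at $t_{i+1}$ against metabolite at $t_i$),
because expression responds after the metabolite changes; the variant with
the better $R^2$ wins. $R^2 = 1 - SS_{res}/SS_{tot}$ between the measured
activity and the affine-mapped Hill transform of the metabolite levels —
which, at the least-squares optimum, equals the squared Pearson correlation
between the two (both are reported). A pair "shows a Hill-type
relationship" when $R^2 > 0.75$.

Per-pair fitting seeds are a deterministic hash of the pair ids and the
master seed, so screen results are independent of input row order.

## TF filtering

Before the all-pairs screen, three classes of regulators are excluded by
`filter_tfs()`:

* **on-off-on dynamics** — activity tracks the growth-phase indicator
  itself (absolute correlation above 0.9 by default); such profiles match
  every phase-locked metabolite and carry no pair-specific information;
* **wide confidence** — the mean 95% ensemble band exceeds 100% of the
  regulator's activity range, i.e. the activity profile is not actually
  determined by the data;
* **two-component systems** — supplied as a list; these respond to
  extracellular signals rather than internal metabolites.

The "confidence interval > 100%" rule is interpreted relative to each
regulator's activity range; the global basal regulator is always excluded.

## The distance criterion

From a stoichiometric model, cofactors (a configurable list shipping with
ATP/ADP/AMP, NAD(P)(H), CoA, etc.) and all non-cytosolic species are
removed from the stoichiometric matrix $N$; the metabolite–gene adjacency
is $F = |N| \cdot G$ with $G$ the reaction–gene matrix (absolute values so
substrates and products both count), its boolean $F'$ defines an undirected
bipartite graph, and breadth-first search gives all metabolite–gene
distances (odd by bipartite alternation; `Inf` when unreachable). Any gene
mentioned in a reaction's boolean gene rule is associated with that
reaction — distances need reachability, not enzyme logic.

A metabolite–TF pair passes when the metabolite is a substrate or product
of a reaction encoded by one of the TF's target genes (equivalently,
bipartite distance 1), **or** when it shares a metabolic subsystem with
such a reaction — the biological rationale being that metabolites tend to
regulate genes of their own biosynthesis or consumption pathways.
Metabolite subsystem annotations come from a user table when available and
default to the subsystems of adjacent reactions otherwise; a metabolite
absent from the model with no annotation yields a "not computable" verdict
rather than a rejection. `predict_interactions()` intersects the three
evidence layers (Hill fit, criterion, retained TF).

## The synthetic-data generator

`scenario()` fixes the study conditions; its defaults emulate the
experimental design the method targets: a 20 h batch culture with phase
switches at 6 h and 18 h, 29 transcriptome and 35 metabolome time points
(the metabolome grid is the transcriptome grid plus interval midpoints,
forcing downstream code to handle misaligned sampling), duplicate samples,
additive log$_{10}$ expression noise of 0.064 (≈ 16% multiplicative
transcript error) and lognormal metabolite noise with sdlog 0.178 (≈ 18%
coefficient of variation) — measurement-error levels typical of RNA-seq
and LC-MS/MS time courses.

TF activities are phase-wise exponential relaxations toward per-phase
levels plus a transient excursion at each phase entry; the two time scales
keep the profile family well-conditioned, which matters because NCA can
only separate regulators whose profiles are linearly independent. The
first TF is always a deliberately on-off-on control (high–low–high with
fast saturation) to exercise the TF filter, and draws for the remaining
regulators that would track the phase indicator almost perfectly
(|correlation| > 0.8) are rejected and redrawn — only the designated
control should trip the filter. Expression is generated exactly under the
NCA model ($E = AP + \varepsilon$), with weights of magnitude 0.5–1.5 and
the annotated sign.

Planted metabolite trajectories invert the Hill law: the host TF's
activity is mapped affinely into $[0.05, 0.95]$ (Hill saturation is
asymptotic, so the open interval avoids infinite concentrations) and pushed
through the inverse activation or inhibition transform with the planted
$(K_H, h)$; a planted lag of one point makes the metabolite lead the
activity by one transcriptome step. By default planted interactions are
hosted by regulators 2…k, since the first TF is the filter control. Decoy
metabolites follow smooth random log-scale trajectories (two sinusoids
with random periods of 3–8 h and 7–30 h) that are statistically independent
of the phase structure and of every activity profile.

The toy metabolic model places each planted effector as the product of a
reaction encoded by a gene exclusive to its host TF (so the
substrate/product criterion holds by construction), attaches each decoy to
a gene exclusive to a single round-robin TF with a private subsystem (so a
decoy can pass the criterion for at most one TF), declares a cofactor list,
and includes periplasmic and extracellular species to exercise pruning.

What the generator does **not** emulate: mechanistic metabolism (no
ODE/FBA dynamics), the heavy co-variation of real metabolite pools (real
decoys are phase-locked and correlate with many TFs — this is exactly why
the distance criterion exists, and synthetic precision figures are
optimistic relative to real data), combinatorial regulation beyond linear
superposition on the log scale, and raw-read or spectrum level noise.

## Numerical choices and degenerate inputs

* Zero TPM values are floored at a configurable pseudocount (default
  0.01 TPM) before log$_{10}$.
* ALS subproblems with condition number above $10^8$ use ridge $10^{-6}$.
* A zero linear correlation (|r| < $10^{-12}$) between a metabolite and an
  activity tie-breaks to activation and is flagged; constant series are
  flagged degenerate and skipped.
* Constant profiles z-score to all zeros rather than NaN.
* Hill fits where every start fails return an $R^2 = -\infty$ sentinel.
* A planted interaction on a constant activity profile cannot be inverted
  and is demoted to a decoy with a warning.

## Problem sizes used in the tests

The bundled tests and the acceptance script run desk-scale versions of the
study: 40–120 genes, 4–12 regulators, up to 25 metabolites with 10 planted
interactions, 29/35 time points, 10–50 NCA restarts and 30–50 Hill starts
per pair. These sizes were chosen so that the full suite exercises every
code path, including the end-to-end planted-recovery run, while remaining
comfortable to run locally; the algorithms scale to regulon-database-sized
inputs (thousands of genes, hundreds of regulators) without modification.

## Known limitations

* Correlation-based screening cannot distinguish direct allosteric binding
  from indirect co-regulation; candidates are hypotheses for in vitro
  validation, not confirmed interactions.
* The Hill fit assumes a single effector per TF; multi-effector logic is
  out of scope.
* The distance criterion needs the metabolite to be present (or annotated)
  in the metabolic reconstruction; unmapped metabolites are reported as
  not computable.
* The NCA ensemble summarizes converged restarts only; with few restarts
  the percentile band is a coarse uncertainty estimate.

## A worked example

```{r example, eval = FALSE}
study <- simulate_study(scenario(seed = 1))
res <- run_screen(study, n_restarts = 50)
res$summary
res$candidates
autoplot(res$nca, regulators = c("TF2", "TF3"))
```
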