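---
title: "Inferring and characterizing functional connectivity among spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and characterizing functional connectivity among spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikegraph)
```

## The problem

Multielectrode recordings yield tens of simultaneously observed spike
trains.  *Functional connectivity* asks which trains statistically
influence which others: the answer is a binary **directed** graph, with an
edge $i \to j$ meaning that recent spiking of train $i$ modulates the
firing hazard of train $j$ over and above what $j$'s own renewal dynamics
and all *other* trains explain.  spikegraph implements the full analysis
chain for this setting: per-stimulus trial extraction, Cox
modulated-renewal inference of the connectivity graph, graph-theoretic
characterization (density, path length, efficiency, clustering, degree,
betweenness, hubs), a 3-node motif census against degree-preserving null
ensembles, Holland–Leinhardt P1 expansiveness/attractiveness coefficients,
and activity summaries across stimuli.  A synthetic generator with known
ground truth makes every stage testable by parameter recovery.

## The Cox modulated-renewal model

For a chosen *target* train, let $u(t)$ be its backward recurrence time
(time since its last spike).  Each *reference* train $j$ contributes an
influence covariate

$$Z_j(t) = \exp\{-(t - s_j(t))/\tau\},$$

where $s_j(t)$ is $j$'s most recent spike at or before $t$ and $\tau$ is
the kernel time constant ($Z_j = 0$ before $j$'s first spike; $Z_j \in
[0,1]$, equal to 1 exactly at a reference spike).  The target's conditional
intensity is modelled as

$$\lambda(t) = \lambda_0(u(t)) \, \exp\Big\{\sum_j \beta_j Z_j(t)\Big\},$$

a Cox proportional-hazards model on the renewal age axis with
time-varying covariates and an unspecified baseline hazard $\lambda_0$.
All references enter **one joint fit**, so each $\beta_j$ is the influence
of train $j$ conditional on every other recorded train — the property that
distinguishes this estimator from pairwise cross-correlation.  A pairwise
mode is provided for comparison (`estimate_connectivity(..., mode =
"pairwise")`).

Estimation uses the partial likelihood.  Each inter-spike interval of the
target is one observation whose "survival time" is the interval length,
with an event at its end; the leading interval (session start to first
spike) and the trailing interval are right-censored because the renewal
age at their open end is not observed.  The risk set of an event at
elapsed time $u$ contains every observation of length $\ge u$, and the
covariates of observation $k$ at that moment are evaluated at the
*absolute* session time $\mathrm{start}_k + u$, honouring the concatenated
timeline:

$$\ell(\beta) = \sum_{\text{events } e}\Big[\beta^\top Z_e -
  \log \!\!\sum_{k \in R(u_e)}\!\! \exp\{\beta^\top Z_k(\mathrm{start}_k + u_e)\}\Big].$$

The partial likelihood is concave; it is maximized by Newton–Raphson with
step halving from $\beta = 0$ (convergence when the largest step falls
below $10^{-8}$, cap 100 iterations), implemented in C++ with the
covariates cached per (observation, event-time) pair and each risk set's
linear predictors max-centred before exponentiation.  Ties in interval
lengths use the Breslow approximation — adequate at continuous time
resolution where exact ties are rare.  Standard errors come from the
inverse observed information; an edge $i \to j$ is called when the
two-sided Wald interval for $\beta_i$ in target $j$'s fit excludes zero.

Choices a user can change, with defaults and reasons:

* `tau_s = 0.01` s — the influence kernel memory.  Fast synaptic
  time-scales motivate a 10 ms default; the kernel form is pluggable in
  principle and `tau_s` is a config knob everywhere.
* `alpha_level = 0.05` — the edge-call level.  No multiple-testing
  correction is applied by default; Bonferroni and Benjamini–Hochberg are
  available (`correction =`), applied to the pooled Wald p-values of all
  reference–target tests.
* `min_events = 30` — minimum target spikes for a fit; below this the
  information is too weak for Wald calibration.
* References with no spikes are dropped with a warning; a singular
  information matrix (e.g. duplicated or constant covariates) drops the
  reference dominating the null direction and refits.  A non-converged
  target contributes an empty column, never fabricated edges.

### Trial concatenation

Recordings are organized as randomized trials per stimulus.  All trials of
one stimulus are concatenated onto a continuous clock and analysed as one
session; inter-spike intervals spanning trial boundaries are kept as-is,
following the convention that the per-stimulus record is treated as
continuous despite the gaps.  Because such boundary-spanning intervals are
statistically suspect, `split_isis_at_boundaries` (default off) lets the
Cox stage censor each interval at the first boundary it crosses instead.

## The synthetic generator

`simulate_spike_trains()` draws from exactly the model the estimator
assumes — a multivariate modulated renewal process

$$\lambda_i(t) = \lambda_{0,i}(u_i(t))\,
  \exp\Big\{\sum_{j:\,(j,i)\in E} w_{ji} Z_j(t)\Big\}$$

— so that parameter recovery is a well-posed test: the generator validates
the estimator, not itself.  Baselines are renewal processes with
exponential (`poisson`) or gamma inter-spike intervals; the gamma shape
defaults to 2 (a mildly regular train) with the rate parametrized so the
mean ISI equals `1/rate_hz`.  Default rates sit in the 2–20 Hz band that
characterizes medium cortical firing; shapes below 1 are rejected because
their hazard is unbounded at zero age.

Simulation is exact Ogata thinning, with no time discretization.  Because
the gamma hazard increases to its asymptote (shape × rate) and every
$Z_j$ decays between spikes, the per-node intensity bound

$$B_i = \lambda_{0,i}^{\max} \exp\Big\{\sum_j \max(0, w_{ji}) Z_j(t_0)\Big\}$$

evaluated at the last accepted event time $t_0$ remains valid until the
next accepted spike; rejected candidates advance time without touching the
bounds.  This is a strict refinement of bounding every $Z_j$ by 1 —
identical output law, far fewer rejections.  A bound above $10^6$ Hz
raises an error naming the offending node (weights too large for
thinning).

`simulate_stimulus_session()` simulates each stimulus's network
*continuously* for `n_trials * trial_s` seconds, cuts the realization into
trials and interleaves them (randomized order, silent gaps, default
`gap_s = 1` s — inter-trial gaps are generic since nothing downstream uses
their content).  Re-concatenating the trials with
`extract_stimulus_segments()` therefore recovers the continuous
realization exactly, which makes the extract-after-simulate identity a
sharp test rather than an approximate one.

What the generator deliberately does **not** emulate: bursting and
refractory structure beyond the renewal baseline, slow non-stationarities,
common-input latent drive, electrode cross-talk, and spike-sorting errors.
Passing recovery tests on this generator shows the estimator is correct
under its own assumptions, not that real cortical data satisfy those
assumptions.

## Graph measures

All measures operate on the binary directed adjacency matrix (rows =
source, columns = target; the diagonal is structurally zero).

* **Density** $= m / (n(n-1))$.
* **Characteristic path length**: mean breadth-first directed distance
  over *reachable* ordered pairs.  Real connectivity graphs contain
  unreachable pairs (a train that nothing influences has no incoming
  paths), so averaging finite distances only is the convention that keeps
  the measure defined; a graph with no reachable pair reports `NA` with a
  warning.
* **Global efficiency**: mean of $1/d$ over all ordered pairs with
  $1/\infty = 0$; unreachable pairs legitimately pull efficiency down.
* **Clustering**: the Fagiolo directed coefficient,
  $C_i = [(A + A^\top)^3]_{ii} \big/ \{2[d_i(d_i-1) - 2d_i^{\leftrightarrow}]\}$,
  which counts all orientations of triangles through $i$.  It was chosen
  over the undirected projection because the graphs are directed and the
  directed variant attains 1 exactly on fully reciprocated triangles;
  which directed variant produced historical tables is generally
  unstated, so the definition is documented here and isolated in one
  function.  Nodes with a zero denominator are undefined and excluded
  from the global mean.
* **Degrees and high-degree nodes**: total degree = in + out; a node is
  high-degree when its total degree exceeds the mean plus one standard
  deviation.  The SD is the *population* SD (divide by $n$) — an arbitrary
  but fixed, documented convention.
* **Betweenness**: Brandes shortest-path betweenness with fractional
  counting, normalized by $(n-1)(n-2)$ (igraph supplies the traversal;
  tests pin it to a brute-force path-enumeration oracle).
* **Hubs**: the high-degree nodes ordered by total degree then
  betweenness, ties by label; the head of the list is "the hub".

## Motif census and null ensemble

A triad (3-node induced subgraph) falls in one of 64 edge configurations,
which collapse to 13 weakly connected isomorphism classes.  Motif IDs 1–13
follow the standard triad-census ordering of those classes (021D, 021U,
021C, 111D, 111U, 030T, 030C, 201, 120D, 120U, 120C, 210, 300), which
sorts by edge count with the conventional D/U/C sub-order; the fully
reciprocated triangle is ID 13.  The published figure keys of older motif
work are not always reprinted, so this mapping is frozen, documented, and
exhaustively verified against hand-coded exemplars in the tests —
cross-study comparisons of a specific ID should check the key first.

Counting is **structural** by default: each weakly connected triple is
classified by its induced subgraph and counted once (equivalently, the
connected part of the 16-slot triad census).  A **functional** mode also
counts every connected spanning sub-triad contained in each induced
configuration, for comparison with subgraph-counting conventions.
Triples are enumerated via centre nodes (every connected triple has a node
adjacent to the other two), not by scanning all $\binom{n}{3}$ blindly.

Significance uses 1000 degree-preserving random graphs (edge switching:
`swap_factor * m` attempted swaps, default 100 per edge, a standard mixing
heuristic; self-loops and duplicate edges are rejected so in- and
out-degree sequences are preserved exactly).  For each class the z-score
against the null mean/SD is reported, together with the add-one empirical
enrichment p-value $p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{null}} + 1)$;
"significant" means $p < 0.05$ one-sided.  The empirical p was chosen over
a z-threshold because null census distributions are discrete and often
skewed; a class whose null has zero variance and whose count merely equals
it gets $p = 1$ and an undefined z.

## The P1 model

The Holland–Leinhardt P1 model treats unordered node pairs as independent
dyads with four states whose log-weights are: null $= 0$; $i \to j$
$= \theta + \alpha_i + \beta_j$; $j \to i$ symmetric; mutual
$= 2\theta + \rho + \alpha_i + \alpha_j + \beta_i + \beta_j$.  Fitted
$\alpha_i$ (*expansiveness*) measures node $i$'s propensity to send edges
— to influence other trains — and $\beta_j$ (*attractiveness*) its
propensity to receive them, with $\theta$ the overall density and $\rho$
reciprocity.  The reciprocity term is included by default because the full
dyad-independent model is the natural maximum-likelihood target; a
`reciprocity = FALSE` switch drops it.

The likelihood is a concave exponential family, maximized here by damped
Newton–Raphson on the dyad log-likelihood with a quadratic penalty on
$\sum\alpha$ and $\sum\beta$.  The penalty selects the centred
representative along the likelihood's translation-invariant directions, so
the fit satisfies the identification $\sum\alpha = \sum\beta = 0$ and, at
convergence, the MLE moment conditions: fitted expected out-/in-degrees
equal the observed degrees and the expected mutual count equals the dyad
census.  (Classical treatments fit the same MLE by iterative proportional
scaling; Newton on the same concave objective reaches the identical
optimum in far fewer passes and makes the monotone-likelihood property
explicit through its line search.)

Degenerate degrees produce infinite MLEs: a node with out-degree 0 has
$\hat\alpha = -\infty$, one that every other node points at has
$\hat\beta = +\infty$, and a graph without mutual dyads has
$\hat\rho = -\infty$.  These are reported as signed-infinity sentinels,
their forced edge states are removed from the affected dyads' state
spaces, and they are excluded from the centring and from coefficient
rankings — so a train that nothing influences cannot derail the fit, while
the remaining coefficients stay finite and interpretable.

`sample_p1_network()` draws from the same four-state dyad distribution and
closes the recovery loop: on 60-node networks with unit-scale coefficient
spread, fitted $\alpha, \beta$ correlate with the truth at $r > 0.9$ and
$\theta, \rho$ are recovered without systematic bias (the acceptance suite
measures exactly this).

## Activity summaries

Firing rate = spike count / effective (concatenated) duration, per channel
and stimulus.  The outlier screen flags a channel when its rate exceeds a
ceiling under *any* stimulus (default 20 Hz, the upper edge of the medium
cortical band) or stays below a floor under *all* stimuli (default 0, i.e.
off); the verbal criterion in the source recordings is reconstructed by
this rule, which reproduces the documented exclusion set {4, 5, 29} on the
bundled rate table.  Cross-stimulus similarity is the Pearson correlation
between per-channel mean-rate vectors over retained channels.  Whether the
original tables used rate vectors or time-binned activity is not stated;
the rate-vector reading reproduces the published correlations to within
the precision the printed rates support (the table is printed at 0.1 Hz
resolution, which propagates to roughly ±0.01 in a correlation), and a
binned-count alternative can be computed from the same segments if raw
recordings are available.

## Numerical and design notes

* **Determinism.** Every stochastic stage takes an explicit seed;
  sub-seeds for multi-stage runs are derived from the master seed, and the
  RNG state of the caller is never clobbered.  Identical (config, seed)
  gives byte-identical outputs.
* **Overflow.** Risk-set sums and dyad weights are max-centred before
  exponentiation; the gamma hazard is evaluated on the log scale with its
  asymptote substituted where the survival function underflows.
* **Ties.** Breslow for the partial likelihood; ranking ties broken by
  label everywhere so output ordering is total and stable.
* **Problem sizes in the shipped checks.** The statistical suites run at
  deliberately moderate scale chosen to give sharp binomial bounds while
  keeping the whole suite interactive: type-I calibration uses 200
  sessions of 6 independent 8 Hz trains × 60 s (1000 Wald tests);
  coverage uses 200 sessions of a planted unit coupling over 80 s;
  connectivity recovery runs one 29-train, density-0.10 network over
  120 s — the scale of the motivating recordings; P1 recovery uses 20
  networks of 60 nodes.
* **Known limitations.** The influence kernel form is fixed to
  exponential decay (the time constant, not the shape, is configurable);
  delays/latencies are not modelled; the Wald edge rule ignores the joint
  dependence among the 28 × 29 tests unless a correction is switched on;
  the P1 fit reports point coefficients without standard errors, matching
  its descriptive use; and all validation rests on the generator's renewal
  assumptions, as discussed above.

## A compact end-to-end example

```{r example, eval = FALSE}
cfg <- list(
  synthetic = list(n_nodes = 12, n_stimuli = 2, density = 0.12,
                   weight_range = c(1.0, 1.5), rate_hz = 8,
                   n_trials = 10, trial_s = 6, gap_s = 1),
  motifs = list(n_null = 500),
  seed = 42, out_dir = tempfile("spikegraph_run_"))
report <- run_pipeline(cfg)
report                         # per-stimulus density, CPL, hubs
report$per_stimulus[["1"]]$p1  # expansiveness / attractiveness
report$correlations            # cross-stimulus activity similarity
```
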