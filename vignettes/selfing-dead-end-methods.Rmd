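---
title: "Testing the selfing dead-end hypothesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the selfing dead-end hypothesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

The "selfing as an evolutionary dead end" (SEDE) hypothesis makes two
macroevolutionary predictions about lineages that shift from outcrossing to
self-fertilisation: transitions are effectively irreversible, and selfing
lineages suffer reduced net diversification (elevated extinction and/or
suppressed speciation). `selfsse` implements the complete analysis tool-chain
used to test these predictions on a dated phylogeny with a binary
mating-system character — the motivating system being a clade of 30
Madagascan *Bulbophyllum* orchid species of which eight contain
auto-pollinating (rostellum-less) morphs — together with seeded forward
simulators so every stage can be validated on data with known truth.

Throughout, trees are rooted, ultrametric `ape::phylo` objects with branch
lengths in million years (Myr); node ages are measured backward from the
present (tips at age 0) and all rates are in events · lineage⁻¹ · Myr⁻¹.
State 0 is the ancestral condition (outcrossing, "O"), state 1 the derived
condition (selfing, "S").

## Character coding

Mating type is recorded per species as `Outcrossing`, `Dimorphic`,
`Trimorphic` or `Unknown`. `code_any_instance()` applies the *any-instance*
rule: a species is scored derived (1) if the derived condition occurs in any
sampled individual — dimorphic and trimorphic species alike — while fixation
of the ancestral condition scores 0 and unknown species are coded missing
(`NA`). Missing species are never dropped: the likelihood machinery treats
them as contributing both states (partial likelihood `(1, 1)`), and
reconstructions can impute their modal state. On the bundled study table
this yields 20 outcrossing, 8 selfing and 2 missing species.

## Diversification models on branching times

The trait-independent stage works from the branching times
$t_2 \ge t_3 \ge \dots \ge t_N$ of the reconstructed tree ($t_2$ = crown
age). All six models share one additive likelihood constant — the
crown-conditioned form with no $(N-1)!$ term — so AIC values are comparable
across models:

* **PB** (pure birth): $\ln L = (N-2)\ln\lambda - \lambda G$ with total
  lineage-time $G = 2t_2 + \sum_{i\ge3} t_i$; the MLE is closed-form,
  $\hat\lambda = (N-2)/G$.
* **BD** (constant-rate birth–death, reconstructed process conditioned on
  crown age and survival), parameterised by net rate $r = \lambda-\mu$ and
  extinction fraction $a = \mu/\lambda \in [0,1)$, so the boundary fit
  $a = 0$ is representable and reproduces PB exactly.
* **DDL / DDX** (diversity-dependent): per-lineage speciation
  $\lambda_k = \lambda_0(1-k/K)$ or $\lambda_k = \lambda_0 k^{-x}$ while $k$
  lineages exist; both collapse onto PB at their null parameter.
* **Y2R / Y3R** (multi-rate Yule): piecewise-constant pure birth with one or
  two shift ages. Because the likelihood is piecewise-constant in a shift
  between consecutive events, shifts are searched exhaustively over the
  observed branching times (an event exactly at a shift belongs to the older
  regime) and the per-regime rates are closed-form (events / lineage-time),
  which makes the fit exact and deterministic. Shift ages count as free
  parameters (Y2R: 3 d.f., Y3R: 5 d.f.).

`fit_diversification()` returns the six fits as one tibble;
`daicrc_test()` computes $\Delta\mathrm{AIC}_{RC}$ — the AIC of the best
rate-constant model minus that of the best rate-variable model — and
calibrates it against a null distribution obtained by re-simulating
pure-birth trees of the same size at $\hat\lambda_{PB}$ and refitting all
six models per replicate. Under a constant-rate truth the rejection rate at
the simulated 95th percentile sits at the nominal 5%.

## The two-rate Markov (Mk2) stage

`mk2_loglik()` is the exact pruning likelihood of the two-state
continuous-time Markov chain with forward rate $q_{01}$ and backward rate
$q_{10}$, using the closed-form transition probabilities (for
$s = q_{01}+q_{10} > 0$, $P(0\to0) = (q_{10} + q_{01}e^{-st})/s$). The root
is combined under an equal prior by default ("stationary" and fixed priors
are available); the equal default was chosen because the source analysis
does not state its root treatment. `mk2_asr_marginal()` runs the standard
up-down (inside-outside) pass for per-node marginal state probabilities and
additionally reports marginals for missing tips so transition counting can
impute them.

`mk2_mcmc()` mirrors a BayesTraits-style analysis: Metropolis–Hastings over
$(q_{01}, q_{10})$ with uniform sliding-window proposals, drawing a tree
uniformly from a posterior sample at every generation so the chain
integrates over topology and branch-length uncertainty. The published
reversible-jump "hyperprior with an exponential prior (mean seeded from a
uniform on 0–30)" is implemented as the hierarchical prior it describes —
each rate is exponential with a mean that is itself a sampled parameter,
uniform on (0, 30) — without trans-model jumps, which the description
under-determines; a one-rate constraint is available separately through the
ML interface. The `ratedev` tuning parameter maps to the proposal half-width
in rate units; the default (3) was tuned so that acceptance sits mid-way in
the 0.1–0.6 band on 30-tip, Myr-scale problems (the published value of 110
belongs to a different branch-length scale). The sampler's correctness is
tested two ways: a prior-only chain must reproduce the hierarchical prior
exactly, and for truths drawn from that prior the nominal 90% credible
intervals must cover at close to the nominal rate.

A practical warning documented by the tests: a single binary character on a
30-tip, ~5 Myr tree carries only a few log-units of likelihood information
about the rates, so with this deliberately vague prior the posterior is
prior-dominated and credible intervals for any particular low "true" rate
can miss it. This is the same small-tree power limitation that applies to
the original analysis, and it is why the package's recovery tests for fixed
truths use larger trees.

## The BiSSE stage

`bisse_loglik()` implements the Binary State Speciation and Extinction
likelihood: along every branch (rootward time $t$) the extinction
probabilities $E_i$ and data densities $D_i$ of each state satisfy

$$\frac{dE_i}{dt} = \mu_i - (\lambda_i+\mu_i+q_i)E_i + \lambda_i E_i^2 + q_i E_j,
\qquad
\frac{dD_i}{dt} = -(\lambda_i+\mu_i+q_i)D_i + q_i D_j + 2\lambda_i E_i D_i,$$

with $q_i$ the away-rate from state $i$. Tips start at $D$ = the state
indicator (both 1 if missing; scaled by per-state sampling fractions if
given, default complete sampling) and $E = 1 - f$; at nodes
$D_i \leftarrow \lambda_i D_i^{(L)} D_i^{(R)}$. Integration uses an adaptive
Cash–Karp Runge–Kutta stepper in compiled code with relative tolerance
1e-8.

Two numerical choices matter and were made after measuring their failure
modes:

* **Per-branch renormalisation.** $D$ scales linearly, so after every branch
  the pair is divided by its sum and the log accumulated exactly. Combined
  with an effectively zero *absolute* tolerance (1e-200), integration is
  controlled in relative terms. With a conventional absolute tolerance
  (1e-10) the high-transition-rate "stationary shuffle" ridge of the
  likelihood surface — where branch factors decay below the absolute floor —
  integrates as noise and can surface spurious optima inflated by tens of
  log-units, which breaks the nesting inequality between constrained and
  full models.
* **Root treatment.** Default: weights proportional to the root $D$ values
  ("observed" weighting) with survival conditioning ON (divide by
  $\sum_i w_i \lambda_i (1-E_i)^2$); both are togglable because the source
  analysis relied on a package default it does not state. With no
  extinction, no transitions and flat weighting, the survival-conditioned
  likelihood equals the PB branching-time likelihood up to a constant — the
  conditioning removes the crown node's $\lambda$ factor, so the identity
  requires conditioning ON.

`bisse_fit()` fits one (possibly constrained) model per tree of a posterior
sample by bounded quasi-Newton optimisation on log rates, starting from a
state-independent birth–death heuristic with deterministic jittered
restarts, then reports across-tree medians and 95% ranges. Matching the
published construction, AIC is computed per tree and then summarised, so
the median-AIC column is a median of per-tree AICs rather than
$2k - 2\,\mathrm{median}(\ln L)$.

`bisse_model_suite()` fits the thirteen canonical models (full; three
equality ties; six single zero-fixes; three multi-zero "dead end" models)
with *start chaining*: every constrained model also starts from the full
model's optimum projected onto its constraint, and the full model is refit
from any constrained optimum that beats it. The BiSSE surface is multimodal
and without chaining independently-started fits can violate the nesting
inequality. Likelihood-ratio tests pair each constrained fit with the
full-model fit on the same tree ($2\Delta\ln L \sim \chi^2_{\Delta df}$),
and the suite reports the percentage of trees rejecting each constraint at
$P < 0.05$.

`bisse_asr_marginal()` obtains marginal ancestral states by constraining
each node to each state in turn and renormalising the two constrained
likelihoods; `asr_average()` matches nodes across a tree sample by tip-set
bipartition and averages onto a reference topology. Nodes absent from a
given tree are skipped by default (the average runs over supporting trees,
with the support count reported); the alternative reading — counting absent
trees as zero weight, so probabilities sum to the node's support fraction —
is available via `absent = "zero"`, since the source figure caption does
not fix the convention.

## Bayes factors and transition counts

`bf_statistic()` evaluates monophyly hypotheses from supplied marginal tree
log-likelihoods (estimating those marginal likelihoods is out of scope —
they are consumed as printed inputs). The default arithmetic is the plain
difference of log marginal likelihoods, which is the rule that reproduces
the published statistic column (484.1, 513.2); the literal "2 ×" reading is
available behind `rule = "twice"`. Bands: ≤ 2 none, (2, 6] positive,
(6, 10] strong, > 10 very strong. Note the published first row prints 676.0
where the difference rule gives 675.9 — rounding of unprinted precision; no
single arithmetic reproduces all printed digits exactly.

`count_transitions()` assigns every node and tip its modal state
(probability > 0.5; an exact 0.5 tie resolves to the ancestral state and is
flagged) and counts direction-split parent→child state changes. Missing
tips take their reconstruction-imputed modal state by default
(`missing = "strict"` excludes their pendant edges), which is the rule under
which a reconstruction with all internal nodes ancestral and eight derived
tips yields exactly eight independent gains on terminal branches.

## The synthetic-data generator

`sim_yule()`, `sim_bd()` and `sim_bisse()` are crown-conditioned forward
Gillespie simulators; waiting times are exponential in the total event
rate. For pure birth the lineage count is monotone, so the size-stopped run
ends when the count reaches `n` with the final interval drawn as the
waiting time to the next unobserved event (`Exponential(n λ)`), keeping
simulated branching-time likelihoods coherent with the crown-conditioned
fitting likelihoods (stopping exactly at the n-th birth is available via
`final_segment = "at_birth"`). With extinction the count can revisit `n`,
and stopping at first passage demonstrably clusters events against the
stopping boundary (it inflated the recovered extinction fraction in pilot
runs), so `sim_bd()`/`sim_bisse()` use the general sampling approach
instead: the process runs until it dies out or safely exceeds `n`, the
"present" is drawn among all time intervals during which exactly `n`
lineages were alive, and realisations are importance-resampled in batches
of 16 with weight equal to their total time at `n`. Realisations that
never reach `n` are rejected, with a 10,000-retry cap.
Extinct lineages are pruned, and the true state at every surviving node is
recorded so recovery can be scored. `sim_mk2()` evolves the binary chain
down a fixed tree, returning tip and node truth.

`sim_clade_c_like()` packages the study conditions: a 30-tip history
simulated under the irreversible two-parameter regime
($\lambda_O = 0.68$, $q_{OS} = 0.21$, all other rates 0), redrawn until
exactly 8 of 30 tips are derived; the crown rescaled to 5.3 Myr; a sample of
trees sharing that topology with log-normal, rank-preserving age jitter
(crown log-SD 0.29, matching a 95% interval of roughly 2.7–8.5 Myr; node
log-SD 0.1); and 2 of the 22 ancestral-state tips recoded missing so the
observed composition is 20/8/2. What the generator does *not* emulate:
topological uncertainty across the tree sample (the topology is shared),
gene-tree/alignment error, non-ultrametric dating error, and any violation
of the BiSSE process itself — so green recovery tests certify the
implementation under the model, not the model's adequacy for real data.

Randomness is routed through explicit `seed` arguments using R's standard
generator (restored on exit, so simulations never disturb the caller's RNG
state); a fixed seed gives byte-identical output.

## Problem sizes used by the test-suite and acceptance script

The packaged checks run at reduced but statistically meaningful sizes,
chosen as the smallest scales at which each property is expected to hold
with comfortable margin: oracle equivalences on ≤ 6-tip trees; estimator
recovery at 500 (pure birth), 200 (birth–death) and 50 (BiSSE model
selection) replicates of 30-tip trees; state-symmetric BiSSE rate recovery
on 120-tip trees, where extinction is actually estimable; the
rate-constancy calibration at 200 × 200 replicates; and the acceptance
script's synthetic study on a 25-tree sample. Extinction-fraction
estimates on 30-tip trees are individually very noisy (the recovery
criterion is a wide median bracket, not a tight tolerance), which is itself
one of the power caveats the original analysis acknowledges.

## Known limitations

* BiSSE power on 30-tip trees with 8/30 derived tips is low, particularly
  for extinction rates; model-selection outcomes should be read with the
  same caution the source analysis applies.
* The MCMC stage implements the hierarchical prior but not reversible-jump
  moves between one- and two-rate models.
* Marginal likelihood estimation for the monophyly tests, tree inference
  and divergence dating are out of scope; their outputs are inputs here.
* Terminally-unresolved clades, sampling fractions per clade, and
  time-varying extensions (fossilised birth–death, MuSSE/HiSSE) are not
  implemented.
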