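---
title: "Models and methods: sex-determining mechanisms, transition rates, and diversification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: sex-determining mechanisms, transition rates, and diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`sdmdiv` implements a macro-evolutionary analysis of a binary sex-determining
mechanism (SDM) — genotypic (GSD, coded 0) versus temperature-dependent (TSD,
coded 1) sex determination — on dated phylogenies, of the kind used to ask
whether SDM is associated with diversification in turtles and lizards, and
whether transition-rate asymmetry plus lifespan evolution better explains the
prevalence of each mechanism. The package provides the four statistical
engines such a study needs, a parametric-bootstrap harness tying them
together, and simulators that generate synthetic data with the statistical
structure of the empirical systems, so every method can be validated
end-to-end without the original data compilations.

This vignette documents the models, their assumptions, the tunable
parameters, the numerical choices, and the known limitations. Every
empirical statement here is computed by the package's test suite or the
reproduction script (`scripts/acceptance.R`); nothing is quoted from elsewhere.

# The discrete-character model (Mk2)

A two-state continuous-time Markov chain with instantaneous rates
$q_{GT}$ (GSD $\to$ TSD) and $q_{TG}$ (TSD $\to$ GSD) runs along each branch.
For two states the branch transition matrix has the closed form
$P(t) = \Pi + (I - \Pi)e^{-(q_{GT}+q_{TG})t}$, where $\Pi$ has rows equal to
the stationary distribution, so the pruning likelihood needs no numerical
matrix exponential. `mk2_loglik()` combines tip partials root-ward with
per-node rescaling (log scalers accumulated), which keeps 1000-tip
likelihoods exact in floating point.

**Root treatment.** The root state can be handled four ways: `"obs"`
(default; weights proportional to each state's root partial likelihood, the
FitzJohn weighting used by the software family this analysis descends from),
`"flat"`, `"stationary"`, or `"fixed"`. The original study never states its
ML root prior, so the choice is exposed everywhere and recorded by the
pipeline; results on strongly informative data are insensitive to it, and
all cross-validation tests pin it explicitly.

**ML fitting.** `fit_mk2()` maximizes over $\log q$ with L-BFGS-B, bounds
$[10^{-9}, 10]$, from a deterministic set of starts: a log-spaced grid
$\{10^{-4},\dots,1\}$ plus a parsimony-informed start (Fitch change count
divided by total branch length). A deterministic grid rather than random
draws means fitting consumes no random numbers, which keeps bootstrap
replicate streams and pipeline reruns byte-for-byte reproducible.

**A known pathology: the saturation ridge.** When the number of informative
tips is small (a few dozen), the global maximum of the Mk2 likelihood
sometimes sits at very large, nearly proportional rate pairs: there
$P(t)$ is effectively stationary on every branch and the likelihood equals
that of i.i.d. draws from the tip-frequency distribution, which can exceed
the likelihood near the generating rates. With 1000-tip trees this never
matters, and with 250 known tips it is rare, but when 95% of states are
masked (50 known tips) roughly a quarter of replicates maximize on the
ridge. The consequence, demonstrated in the test suite, is that the *mean*
of the global ML estimate under heavy masking is biased upward even though
the *median* stays on the generating value; estimator variance grows
sharply, as expected. A local optimizer started near interior values does
not show this, because it never finds the ridge — which is worth knowing
when comparing against analyses done with single-start optimizers. We keep
the honest global search.

**MCMC.** `mk2_mcmc()` samples the posterior over $(q_{GT}, q_{TG})$ under
independent exponential priors (mean 0.1 by default) with a univariate
slice sampler on the log-rate scale (step-out width 1.0, fixed scan order
$q_{GT}$ then $q_{TG}$, the log-scale Jacobian included in the target).
Default chain settings mirror the reference analysis: 2000 steps with the
first 25% discarded. The asymmetry summary is the posterior probability
PP $= \Pr(q_{TG} > q_{GT})$, significant outside $[0.025, 0.975]$.

**Ancestral states.** `marginal_asr_mk2()` computes each internal node's
marginal state probability by clamping the node to each state and re-running
the pruning pass — algebraically identical to the down-pass/up-pass
formulation and exact; the test suite checks it against exhaustive
enumeration over all joint ancestral assignments on small trees at
$10^{-10}$.

# The BiSSE model

The binary-state speciation and extinction model gives each state its own
speciation rate $\lambda_i$, extinction rate $\mu_i$, and the transition
rates $q_{GT}, q_{TG}$, and computes the joint likelihood of tree shape and
tip states. Along each branch the standard coupled ODEs for the extinction
probability $E_i(t)$ and data likelihood $D_i(t)$ are integrated tip-to-root
(initial conditions $E_i(0) = 1 - f_i$, $D_i(0) = f_i$ for the observed
state, where $f_i$ is the sampling fraction of the "skeletal tree"
correction); at each speciation node the daughter $D$s multiply together
with $\lambda_i$.

Numerical choices: an embedded Dormand–Prince 5(4) adaptive Runge–Kutta
(rtol $10^{-8}$, atol $10^{-10}$, tightenable per call) implemented in C++,
$E$ clamped to $[0,1]$ and $D$ to $[0,\infty)$ against round-off, and
per-node rescaling of $D$ with accumulated log scalers. The root combines
states with the same prior options as Mk2; survival conditioning (on by
default) divides by $\sum_i w_i \lambda_i (1-E_i)^2$ with the weights
computed from the unconditioned partials. These conventions reduce, for a
single observed state with $\mu = 0$, $q = 0$, $f = 1$, to the Yule kernel
$\lambda^{n-2} e^{-\lambda X}$ ($X$ = total branch length), which the tests
verify against the closed form at $10^{-8}$; the original study's
root/conditioning choices are unstated, so only this internal consistency —
not table-level numeric identity with the original — is claimed.

Two tests are built on the likelihood:

* `fit_bisse_transition_test()` — transition-rate asymmetry with
  $\lambda_G = \lambda_T$ and $\mu_G = \mu_T$ constrained (1-df LRT), the
  design used to check that rate asymmetry survives accounting for
  diversification and incomplete sampling (one shared sampling fraction,
  per-state fractions available but off by default).
* `fit_bisse_diversification_test()` — state-independent null against
  state-dependent speciation (optionally also extinction); its
  log-likelihood difference is the statistic the bootstrap harness nulls.

Fits optimize log-rates with deterministic data-driven starts (Yule
$\hat\lambda$, parsimony-scaled $q$); the constrained fit runs first and
warm-starts the free fit, which enforces nesting monotonicity up to
optimizer jitter. At $\mu = 0$ the constrained-BiSSE transition-rate MLEs
coincide with the Mk2 MLEs; the validation suite checks agreement within 5%
on 300-tip simulations.

# MacroCAIC: species richness against a binary predictor

For each internal node whose daughter clades differ in (reconstructed)
predictor value, the response contrast is $\ln(N_{hi}/N_{lo})$ — summed
clade richness, oriented toward the daughter with the higher predictor
value — and the predictor contrast is the standard Felsenstein contrast
(differences scaled by $\sqrt{v_1+v_2}$, internal values and branch-length
adjustments from the contrasts down-pass). Richness defaults to one species
per tip; a per-tip richness table lets pruned trees carry full-clade counts
— the original analysis does not state which mapping it used, so both are
supported and neither is claimed to reproduce its table exactly.

The regression of response on predictor contrasts is ordinary least squares
*through the origin* (contrast orientation is arbitrary, so the fit must be
sign-flip invariant), restricted to contrasts whose clade holds at least MNS
species (cutoffs 10, 20, 30, 40 by convention); with $k$ contrasts the $F$
test has $(1, k-1)$ degrees of freedom, and the reported $r^2$ is the
adjusted value (hence occasionally negative). Fewer than two surviving
contrasts is reported as not-computable rather than an error, since high
MNS cutoffs routinely empty the table on small clades.

# The parametric bootstrap harness

`parametric_bootstrap()` makes any statistic's null distribution under
neutral character evolution: fit Mk2 to the observed states, simulate
`n_reps` characters on the *fixed* tree with the root fixed to the
reconstructed ancestral state (not resampled), recompute the statistic per
replicate, and report $p$ = proportion of simulated values $\geq$ the
observed one. Two presets mirror the two described uses: free two-rate MLEs
for diversification-test nulls, constrained equal-rate MLEs for
transition-rate nulls. The plain proportion rule is the default to match
the reference procedure; the $(k+1)/(n+1)$ correction is available (and
recommended — the plain rule can return exactly 0). Replicate $i$ draws its
character from stream `seed + i`, so results are independent of evaluation
order; replicates where the statistic is undefined (e.g. no informative
contrasts) are dropped and counted, and more than 20% undefined aborts.
The harness is statistic-agnostic: MacroCAIC $F$, BiSSE $\Delta$LL, Mk2
$\Delta$LL and MCMC PP all plug in. Calibration (bootstrap $p$ uniform on
data generated under the null) is verified in the validation suite by
Kolmogorov–Smirnov tests at reduced problem sizes (40 data sets × 100
replicates for MacroCAIC $F$; 18 × 50 for BiSSE $\Delta$LL, whose fits
dominate the runtime).

# Regime-dependent lifespan models

Lifespans (years) are natural-log transformed — the reference analysis says
"log-transformed" without a base; base $e$ is used and optima are
back-transformed to years for reporting. The tree is partitioned into GSD
and TSD regimes by `paint_regimes()`: each node takes its argmax marginal
state, ties inherit the parent's regime (a root tie goes to TSD, the
reconstructed ancestral state in the target systems), and each branch
carries its child node's regime.

Four Gaussian models are fitted by exact GLS likelihoods over the painted
tree, all parameters profiled analytically except one scalar optimized on a
log grid with local refinement:

* **BM1** — Brownian motion, one rate $\sigma^2$, free root value (2
  parameters);
* **BM2** — one rate per regime, via the regime-split shared-path matrices
  $V_G, V_T$ with $\Sigma = \sigma^2_G V_G + \sigma^2_T V_T$ (3);
* **OU1** — single-optimum Ornstein–Uhlenbeck with the fixed-root
  covariance $\mathrm{Cov}(i,j) = \tfrac{\sigma^2}{2\alpha} e^{-\alpha
  d_{ij}} (1 - e^{-2\alpha t_{a}})$, $t_a$ the depth of the pair's most
  recent common ancestor (3);
* **OUM** — distinct optimum per regime with shared $\alpha, \sigma^2$; the
  expectation of tip $i$ weights each optimum by the exponential-decay
  regime history along its root-to-tip path, with the root's weight
  $e^{-\alpha T}$ assigned to the root regime's optimum (4).

The fixed-root covariance (rather than the stationary form) is used so that
OU1 converges to BM1 continuously as $\alpha \to 0^+$ — verified numerically
at $10^{-3}$ — and the root value is tied to the root regime's optimum under
OU (free under BM); an estimable-root variant was considered and rejected to
keep OU1/OUM nested with a single-df difference. $\alpha$ is searched in
$[10^{-3}, 50]/T$ ($T$ = tree height). Nesting identities
(BM2 $=$ BM1 at equal rates, OUM $=$ OU1 at equal optima) hold exactly by
construction and are asserted in the tests. Model comparison uses 1-df LRTs
for the two nested pairs and AIC $= 2k - 2\log L$ across all four.

# Synthetic data: what it emulates, and what it does not

`simulate_bd_tree()` grows constant-rate birth–death trees forward in time,
stops when the target tip count is alive, extends by the waiting time to
the next event (so pendant branches are positive and the last inter-node
interval keeps its exponential law), prunes extinct lineages, and retries
on total extinction. No tree-height conditioning is applied — adequate for
the pure-birth ($\mu = 0$) designs all the validation simulations use.
Internode waiting times at $k$ lineages are verified exponential with rate
$k\lambda$ by KS test. `simulate_binary_character()` is an exact CTMC
simulation (exponential waiting times between flips) retaining the full
change history, so ancestral reconstructions and the pruning likelihood can
be validated against the generating process; its tip-pattern distribution
on a fixed 4-tip tree matches the pruning probabilities by chi-square.
`simulate_regime_trait()` draws BM/OU values branch-by-branch from the
exact conditional transition laws.

`make_fixture()` packages these into two profiles whose defaults are fixed
study conditions, chosen analytically before any test was run:

* **turtle-like** (default $n = 87$): equal slow rates
  $q_{GT} = q_{TG} = 0.006$, TSD root. With the expected crown age of a
  pure-birth tree at $\lambda = 0.1$ ($T \approx \ln(n)/\lambda$), the
  two-state transition probability gives an expected TSD tip share of
  $0.5 + 0.5e^{-2qT} \approx 0.78$, the empirical turtle frequency.
  Lifespan optima are the reference values 22.6 (GSD) and 35.9 (TSD) years
  on the log scale, with $\alpha = 0.1$ (phylogenetic half-life about a
  sixth of tree height) and $\sigma^2 = 0.03$, giving a stationary spread
  of roughly $\pm$0.4 log-years — lifespans spanning about 10–90 years.
* **lizard-like** (default $n = 300$): strongly asymmetric rates
  $q_{GT} = 0.002$, $q_{TG} = 0.04$, TSD root; the stationary GSD share
  (0.95) times the expected approach to stationarity over the crown age
  yields an expected GSD tip share near 0.86, the empirical lizard
  frequency; optima 7.9 and 10.1 years.

Per-tip richness counts are drawn as $1 + \mathrm{NegBin}(\mathrm{size} =
0.7, \mu = 9)$ — skewed clade sizes of order 1–60, a realistic shape for
genus-level richness. Missing states are masked uniformly at random; real
missing data cluster taxonomically, so passing tests under uniform masking
say nothing about taxonomically structured gaps. The simulators also do not
generate state-dependent diversification (no BiSSE-style trees): all null
calibrations are neutral characters on fixed trees, matching the validation
design, and the power check for the diversification test uses a constructed
two-clade tree instead. Fixture trees are in arbitrary time units with
$\lambda = 0.1$; empirical trees in millions of years have rates on other
scales, so fixture rate magnitudes should not be read as calibrated values.

# Problem sizes and reproducibility

The validation suite runs at reduced but statistically meaningful sizes,
chosen so the full suite completes in minutes while each check retains
power: 50 replicates per rate combination for the recovery design (the
reference used 100; the reproduction script uses 100), 40 × 100 and 18 × 50
data-set/replicate pairs for the two bootstrap calibrations, 20 × 300-tip
data sets for the Mk2–BiSSE agreement, 50 fixtures for the optimum-ordering
recovery. All simulators are seed-reproducible bit-for-bit; the pipeline
embeds its seed and settings in every output table and rerunning with the
same configuration reproduces outputs byte-identically.

# Known limitations

* Only two states, one binary regime partition: no hidden-rate or
  multi-state generalizations, no per-regime OU $\alpha$ or $\sigma^2$
  variants, no measurement-error term.
* The BiSSE machinery assumes time-homogeneous rates across the whole tree,
  as does everything downstream of it.
* Under heavy missing data the global ML transition-rate estimator is
  mean-biased by the saturation ridge (see above); medians, and estimates on
  well-sampled trees, are unaffected.
* The bootstrap harness fixes the tree: no accounting for topological or
  dating uncertainty.
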