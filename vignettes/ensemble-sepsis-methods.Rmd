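---
title: "Ensemble modeling of neutrophil trafficking in CLP sepsis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble modeling of neutrophil trafficking in CLP sepsis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsisflow)
```

# Scope

`sepsisflow` studies the acute inflammatory response to cecal ligation and
puncture (CLP) induced sepsis in rats as a *population of models*: a single
compartmental ODE structure whose parameter distribution — not a single
best fit — represents cohort heterogeneity. The workflow is: generate (or
load) two-cohort time-course data, calibrate a Metropolis MCMC parameter
ensemble per cohort, diagnose convergence, contrast the ensembles through
the inverse correlation matrix, and run in-silico hemoadsorption (HA)
treatment experiments on virtual cohorts.

This vignette is the package's methods reference: the model equations and
their assumptions, the parameter registry and priors, the synthetic-data
generator, the sampler and its tuning, the multivariate analysis, and the
numerical and design decisions taken where several choices were defensible.

# The compartmental model

Nineteen states in three well-mixed compartments (peritoneum, blood,
lung). Two Hill forms are used throughout, both with Hill coefficient
$n = 3$:

* plain Hill $H(x; \kappa) = x^n/(x^n + \kappa^n)$ for concentration-valued
  regulators (bacteria, neutrophil counts, the activation flux);
* normalized HillCube $h(x;\kappa) = H(x;\kappa)/H(1;\kappa)$ for
  unit-interval regulators ($PI$, $AI$, $D$), so that a regulator at its
  maximal value 1 drives its target at exactly 1. This keeps the
  unit-interval states closed in $[0,1]$ under the dynamics.

Parameters are named $\kappa$ (activation/inhibition thresholds), $\tau$
(time constants, hours) and $r$ (mass-action rates); numbers refer to
registry ids (`parameter_registry()`).

## Bacteria (peritoneum)

$$\dot B = (r_{33}\,g + r_{51} B)\Big(1 - \frac{B}{B_\infty}\Big)
  - r_{34}\, f(B)\, N_t - r_{52} \min(B, B_{mac})$$

The CLP operation seeds bacteria at a constant rate $r_{33}$ scaled by the
severity grade $g \in [0,1]$; both the source and intrinsic growth
($r_{51} = 0.1$/hr) saturate logistically at the carrying capacity
$B_\infty = 10^9$ CFU/ml. Tissue neutrophils kill on encounter at rate
$r_{34}$ per cell, with $f(B) = \min(B, B_\infty)$ capturing the saturation
of per-neutrophil killing capacity at extreme bacterial densities.
Resident peritoneal macrophages remove bacteria at $r_{52} = 0.1$/hr up to
the level $B_{mac} = 10^5$ CFU/ml they can control unaided; above it the
term is a constant capacity.

## Neutrophil pools

With $B_n = B/B_\infty$, the transition fluxes are

* release: $(r_8 + r_{10} H(B_n;\kappa_9))\,N_{bm}$,
* priming: $H(B;\kappa_{12})\, N_r/\tau_{13}$,
* systemic activation: $h(PI;\kappa_{14})\,N_r/\tau_{15}$ and
  $h(PI;\kappa_{17})\,N_p/\tau_{18}$,
* migration to tissue:
  $H(B;\kappa_{25})\,\big(1 - h(PI;\kappa_{26})\big)\,N_p/\tau_{19}$,
* sequestration: $h(PI;\kappa_{21})\,N_a/\tau_{22}$,
* lung migration: $h(PI;\kappa_{28})\,N_s/\tau_{24}$,

with first-order death terms $N_x/\tau$ on every blood/tissue pool, the
blood-to-tissue and blood-to-lung fluxes scaled by the volume ratios
$V_{bt} = 34.4/25$ and $V_{bl} = 34.4/48$, and tissue influx crowded out by
$(1 - N_t/N_t^{max})$, $N_t^{max} = 2\times10^7$ cells/ml. The factor
$1 - h(PI;\kappa_{26})$ is the migration-impairment term: systemically
activated inflammation downregulates chemotactic competence, a lumped
representation of receptor loss and adhesion failure. Systemically
activated neutrophils cannot enter the infected tissue at all — their only
exit routes are death and lung sequestration.

The bone-marrow reserve loses only the infection-driven surge
($\dot N_{bm} = -r_{10} H(B_n;\kappa_9) N_{bm}$); basal release is balanced
by granulopoiesis. This makes the pre-CLP homeostatic state an exact fixed
point — with basal depletion no self-consistent resting state exists and
the "healthy animal" would drift over a 200 h simulation, which we consider
the less defensible behavior. The reserve is initialized at
$10^{11}$ cells/ml-equivalent, chosen so that the printed basal release
rate $r_8 = 3.22\times10^{-6}$/hr sustains a resting blood pool of
$\approx 2.6\times10^6$ cells/ml, a normal rat neutrophil count.

## Inflammation and damage

$$\dot{PI} = \frac{1}{\tau_4}\Big[\mathrm{OR}\big(H(B_n;\kappa_1),
  h(D;\kappa_2)\big)\,\Big(1 - h(AI;\kappa_3)\big(1 - h(PI;\kappa_6)\big)\Big)
  - PI\Big]$$
$$\dot{AI} = \frac{1}{\tau_7}\big[h(PI;\kappa_5) - AI\big], \qquad
\dot D = \frac{1}{\tau_{32}}\Big[\mathrm{OR}\big(H(N_s/N_t^{max};\kappa_{30}),
  H(N_l/N_t^{max};\kappa_{31})\big) - D\Big]$$

where $\mathrm{OR}(a,b) = 1-(1-a)(1-b)$ is the continuous OR gate.
Pro-inflammation is driven by bacteria or damage and inhibited by
anti-inflammation — but only partially: the escape factor
$1 - h(PI;\kappa_6)$ moderates the inhibition at high $PI$, reflecting the
observation that anti-inflammatory activity coexists with, and cannot fully
counteract, strong systemic inflammation. Damage integrates the injury
inflicted by sequestered and lung neutrophils and resolves with time
constant $\tau_{32}$.

## Observables

Each plasma marker relaxes sigmoidally toward a Hill read-out of its
upstream state: TNFα, IL-1β and IL-6 read $PI$; IL-10 reads $AI$ (it is the
canonical anti-inflammatory cytokine); HMGB1, creatinine and ALT read $D$
(the single damage state cannot resolve their individual kinetics beyond
separate thresholds and time constants, a deliberate coarse-graining);
L-selectin reads the neutrophil activation flux
$\Phi = h(PI;\kappa_{14})N_r/\tau_{15} + h(PI;\kappa_{17})N_p/\tau_{18} +
h(PI;\kappa_{21})N_a/\tau_{22}$, normalized by $N_t^{max}$ per hour — the
summed rate of the three PI-gated transitions out of the resting, primed
and activated pools. No direct cytokine–cytokine interactions are modeled.

## Initial conditions and survival

All simulations start from the homeostatic fixed point
(`homeostatic_state()`): no bacteria, inflammation, damage or observables;
the resting pool at its release/death balance. Identical initial conditions
across cohorts place all phenotype differences in the parameters. A virtual
animal *survives* when at the 200 h horizon both $B < B_{crit}$ and
$PI < 0.5$. The bacterial threshold defaults to
$B_{crit} = 5\times10^8$ CFU/ml, midway between the model's
neutrophil-controlled equilibrium ($\approx 2\times10^8$ under a persistent
CLP source) and the carrying capacity; it is a configuration value of
`survival_criteria()`, not a constant of the model.

# Parameters and priors

`parameter_registry()` carries all 57 parameters: 34 dynamic parameters
(sampled by MCMC), 16 observation-mapping parameters (fitted once by a
bounded optimizer minimizing the summed two-cohort cost, then frozen, so
the mapping is identical for both cohorts) and 7 constants. Four rates come
from the literature values printed for this system (basal and maximal
bone-marrow release, the CLP source rate $9.40\times10^7$ CFU/ml/hr and the
killing rate $6.61\times10^{-8}$ ml/cell/hr), as do all seven constants;
the remaining baselines were chosen once so the model exhibits the
qualitative two-phenotype behavior described below, and are documented per
parameter in the registry.

Priors are uniform on the log10 scale, per group: unit-interval thresholds
$[10^{-2}, 2]$, bacterial thresholds $[10^4, 10^8]$ CFU/ml, time constants
$[0.5, 500]$ h, rates two decades around their baselines. The wide ranges
deliberately include all plausible values; the data, not the prior, should
constrain the stiff directions.

The survivor ground truth (the registry baseline) primes and migrates
quickly ($\tau_{13} = 3$ h, $\tau_{19} = 2$ h) and resists systemic
activation ($\kappa_{14} = 0.7$, $\kappa_{26} = 0.9$): tissue neutrophils
reach $\approx 7\times10^6$/ml, the infection is forced down to the
controlled equilibrium, and inflammation resolves ($PI(200) \approx 0.06$).
The non-survivor truth slows priming, migration and damage resolution and
lowers the activation and impairment thresholds: neutrophils activate in
the blood, sequester, and accumulate in the lung; bacteria stay near
carrying capacity, $PI$ hovers above 0.5 and damage approaches 0.9 — the
dysregulated-trafficking phenotype.

# Synthetic cohorts

`generate_cohort()` emulates the experimental design: 23 virtual animals
(7 survivors / 16 non-survivors), eight plasma markers at 18, 22, 48, 72,
120, 144, 168 h post-CLP at severity $g = 1$. Per animal, the 34 sampled
parameters receive lognormal inter-animal jitter (sd 0.1 in log10 space,
clamped to the prior); the simulated observables receive multiplicative
lognormal measurement noise (sd 0.2) on the raw scale. Cytokine raw values
are $e^{\alpha O}$ with $\alpha = \ln 1000$ (three decades of dynamic
range), then natural-log transformed and divided by their maximum across
all animals and time points — both cohorts pooled, as in a single assay
batch; other markers are max-normalized directly. Per-point standard
deviations are floored at 0.05 on the normalized scale so the cost weights
stay finite.

A detection floor of 0.1% of each observable's dynamic range is applied to
the normalization reference: a marker whose signal never rises above the
floor (e.g. damage markers in a resolving survivor) is reported relative to
the floor rather than rescaled to peak 1. Without it, max-normalization
amplifies numerically vanishing trajectories into arbitrary unit-scale
shapes, which no assay would report. The model prediction entering the cost
is normalized with the same rule, so in the noiseless limit the cohort
means equal the predictions exactly — the oracle used by the
parameter-recovery tests.

What the generator does *not* emulate: assay censoring/detection-limit
truncation beyond the floor, correlated multi-plex measurement errors,
animal dropout (early deaths are measured to the end), and any real-data
accession — the synthetic cohorts share the experiment's structure, not its
numbers. Passing tests therefore demonstrate the machinery's correctness
and the model's qualitative fidelity, not quantitative agreement with any
animal measurement.

# Calibration

The cost is the weighted sum of squared residuals
$C(\theta) = \sum_s \sum_t \big((m_{st} - \hat y_{st})/\sigma_{st}\big)^2$
over all observables and measurement times; solver failures map to
$C = \infty$ (the proposal is rejected). The target is the Boltzmann
density $\pi(\theta) \propto e^{-C(\theta)/T}$, sampled by random-walk
Metropolis in log10 parameter space: componentwise normal proposals,
out-of-bounds proposals rejected (preserving the truncated uniform prior),
acceptance $\min(1, e^{-\Delta C/T})$.

Tuning (`tune_chain()`) runs entirely during burn-in and is then frozen:
after a settle phase, a global proposal scale follows a diminishing-gain
stochastic approximation toward the target acceptance ratio 0.25 while
per-parameter relative scales track the recent sample spread; finally the
acceptance is probed at frozen scales and corrected (the chain keeps
descending during adaptation, which would otherwise bias the frozen ratio).
The temperature, if not given, is set once to $\max(8, C_0/25)$: the floor
keeps the energy landscape smooth relative to $T$, which stabilizes the
acceptance ratio while the chain traverses basins of varying local
roughness; for schedule-sensitive work (e.g. parameter recovery on
noiseless data) a fixed low temperature can be passed instead.

Scales: the desk preset (default, used by the test-suite and the worked
examples) runs 2–3 chains of a few thousand proposals over a reduced
8-parameter mask covering the phenotype-defining parameters; the full
preset (5 chains × 10⁶ proposals per cohort over all 34 parameters,
ensembles of 10⁴) reproduces the production study scale and is
cluster-scale — it is configured but never run by the tests. Convergence is
monitored with the Gelman–Rubin potential scale reduction factor, computed
per parameter as $\sqrt{\hat V/W}$ with $W$ the mean within-chain variance,
$B/n$ the variance of chain means and $\hat V = \frac{n-1}{n}W + B/n$ —
the classic multi-chain estimator without chain splitting.

# Ensemble analysis

On an ensemble of $n$ samples × $p$ parameters (log10 scale), the sample
correlation matrix $C$ is inverted to $K = C^{-1}$, the approximate Hessian
of the cost surface near its minimum. The eigendecomposition of $K$
(descending) gives the stiffness spectrum: stiff directions are parameter
combinations the data constrain well. The diagonal gives multiple
correlations $R_i = \sqrt{1 - 1/K_{ii}}$ — how strongly parameter $i$ is
tied to the best linear combination of all others — and the off-diagonal
elements give partial correlations $P_{ij} = -K_{ij}/\sqrt{K_{ii}K_{jj}}$,
the pairwise association after regressing out all other parameters. Both
formulas are validated in the test suite against brute-force regression
oracles.

To contrast two cohorts, every parameter pair is tested for a change in
partial correlation with a two-sample Fisher z test (controlling $p-2$
covariates), Benjamini–Hochberg corrected across all $p(p-1)/2$ pairs at
$\alpha = 0.05$, combined with an absolute-difference filter
$|\Delta r| \ge 0.1$; significant pairs are categorized as *lose* (weaker
in the second ensemble), *gain* (stronger) or *flip* (significant sign
reversal with both magnitudes individually significant). MCMC samples are
autocorrelated, so the tests should be fed effective sample sizes
(`effective_sample_size()`, integrated-autocorrelation estimate with an
initial-positive-sequence cutoff) rather than raw row counts; with raw
counts the tests overstate significance badly. The choice of test and
thresholds is ours — the analysis tradition this follows reports
"significant changes" without fixing a procedure — so categorized pair
lists should be compared across studies only qualitatively.

# Hemoadsorption experiments

The hypothetical HA device eliminates exactly three circulating components
— activated neutrophils, $PI$ and $AI$ — during a treatment window
(default 18–22 h post-CLP, matching a 4 h treatment started at 18 h). Each
elimination is a Hill function (coefficient 3, like every other
interaction) of the target's own level times a maximal rate, subtracted
from the $N_a$, $PI$ and $AI$ equations, and exactly zero outside the
window; the solver is restarted at both window boundaries so the
discontinuity never straddles an internal step.

The device rate constants are configuration values with no measured
counterpart. The defaults (`ha_config()`: $PI$ elimination 1/hr with
half-max 0.05, $N_a$ elimination $2\times10^6$ cells/ml/hr with half-max
$10^5$, $AI$ elimination 0.02/hr) were fixed once at the saturating effect
size — during the window they pin $PI$ near zero, which fully releases the
migration-impairment brake. Treating a jittered synthetic non-survivor
ensemble (log10 jitter 0.15 around the non-survivor truth, filtered to sham
non-survivors) rescues roughly 7% of members. The fraction saturates there:
with a persistent CLP source, bacteria sit near carrying capacity by 18 h,
and four hours of unimpaired migration can only tip members already close
to the survival basin — the treatable shell is thin. We report this as a
property of the model geometry rather than widening the window or the
jitter to manufacture a larger effect. Rescued members reproduce the
characteristic trafficking signature: higher tissue-neutrophil and lower
sequestered/lung-neutrophil trajectories than treated non-survivors.
Conversely, a misdirected device (high $AI$ elimination, no $PI$
elimination) can kill borderline survivors by removing the brake on
systemic inflammation — treatment harm is representable, not just benefit.

# Numerical choices

* Solver: `lsoda` (stiff multistep with automatic switching), relative
  tolerance $10^{-6}$, absolute tolerance 1 for count-valued states and
  $10^{-9}$ for unit-interval states — the state magnitudes span nine
  orders. The right-hand side is compiled C; a pure-R reference
  implementation is kept in exact agreement (tested to $10^{-6}$ relative
  along trajectories).
* Undershoot guard: regulator levels entering Hill terms are clamped at 0
  (and unit-interval regulators at 1) inside the right-hand side, so
  transient trial-step undershoot cannot produce NaNs; after integration,
  counts below $-1$ CFU/ml (beyond any roundoff) or unit states outside
  $[-10^{-6}, 1+10^{-6}]$ abort with an error rather than being silently
  clamped.
* Degenerate inputs: zero-rate HA configurations are treated as sham and
  integrated without restarts, making sham runs bit-identical to untreated
  runs; all-zero observables normalize against the detection floor; rank
  deficiency or condition numbers beyond $10^{12}$ in the ensemble
  correlation matrix raise a singular-ensemble error naming the offending
  columns.
* Determinism: every stochastic function takes an explicit integer seed;
  the pipeline derives fixed per-stage seeds from one master seed and
  caches stage artifacts by configuration hash and file checksum, so an
  identical configuration reproduces byte-identical artifacts.
* Problem sizes: the shipped tests run the desk scale throughout — 200-member
  invariant sweeps, 10,000-step acceptance-ratio chains, a 50,000-step
  recovery chain on an 8-parameter mask, and ~150-member treatment cohorts;
  these sizes were chosen as the smallest at which the respective statistics
  are stable.

# Known limitations

* The ODE structure is a phenomenological reconstruction: the interaction
  terms encode the described biology (which pools interact, what gates
  what) with standardized Hill/HillCube forms; alternative algebraic forms
  with the same qualitative structure would fit synthetic data equally
  well. No claim is made that individual rate constants are biologically
  identifiable — that is precisely why the package works with ensembles and
  stiffness spectra rather than point estimates.
* The persistent CLP source makes full bacterial clearance impossible;
  survival means *control*, not sterilization. Scenarios with
  self-resolving sources (abscess walling-off) are out of scope.
* Compartments are well-mixed; there is no spatial transport, and the lung
  is the only distant organ represented.
* The HA device model is a lumped elimination kinetics, not device physics
  (no flow rates or adsorption isotherms), and its rate constants are
  assumptions.
* Desk-scale chains are far from converged posteriors; they exercise the
  machinery and the qualitative phenotypes. Quantitative ensemble
  statements (pair-change tables, stiffness spectra) require the full-scale
  preset.
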