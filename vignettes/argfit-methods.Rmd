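---
title: "Methods: estimating ARG fitness costs and simulating strain-ARG communities"
author: "argfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating ARG fitness costs and simulating strain-ARG communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argfit)
```

# The problem

Antibiotic resistance genes (ARGs) carried on plasmids protect their host
bacteria when the cognate antibiotic is present, but most of a bacterium's
life is spent in environments where it is not. Whether an ARG then persists
depends on its *direct* fitness effect on the host — and that effect can
differ between host strains. A strain in which an ARG is neutral or
beneficial acts as a *selective refuge* that can keep the gene in a
community with no antibiotic selection at all. `argfit` implements the
quantitative machinery for this question: estimating per-strain ARG fitness
effects from competition assays, testing whether those effects track the
host phylogeny, and simulating what the measured effects imply for the
joint fate of strains and ARGs in a community.

# Relative fitness from competition counts

The basic measurement is a head-to-head competition over one 24 h serial
batch cycle between a *test* competitor (a strain carrying either an
ARG-plasmid or the empty vector) and a GFP-tagged *reference*, scored by
flow cytometry at day 0 and day 1. With $p_{t,0}, p_{t,1}$ the test
proportions, $p_{r,\cdot} = 1 - p_{t,\cdot}$ the reference proportions, and
$d$ the net fold-growth over the cycle (100-fold under 1:100 daily
transfer), the relative fitness is the ratio of realized log fold-changes:

$$W \;=\; \frac{\ln(d\,p_{t,1}/p_{t,0})}{\ln(d\,p_{r,1}/p_{r,0})}.$$

The growth multiplier $d$ is applied to **both** competitors: it accounts
for growth occurring during the competition, which both competitors
experience. The effect of an ARG in a strain is then the fitness of the
ARG carrier relative to the same strain carrying the empty vector,

$$e \;=\; \frac{\overline{W}_\mathrm{ARG}}{\overline{W}_\mathrm{Vec}},
\qquad \text{cost\%} = (1 - e)\cdot 100,$$

using the ratio of replicate means (aggregation per strain before
comparison). The difference of means is co-reported for analyses that work
on the additive scale. Records whose proportions hit 0 or 1 have no finite
log fold-change; they are excluded with a logged reason rather than
pseudocounted, mirroring how the assay data are filtered rather than
smoothed.

## The start-frequency filter

Natural-isolate cells clump, and clumps passing the cytometer flow cell
distort event counts. The defence is a quality filter that uses *only*
day-0 information: a record is excluded when the measured day-0 frequency
of either competitor deviates from the 50:50 target by more than 15
absolute percentage points (retain $[0.35, 0.65]$, boundary inclusive).
"15%" is read as absolute percentage points; a relative reading
(`relative = TRUE`) is available as an option. Because the filter never
looks at the day-1 change, it cannot bias the fitness estimates
themselves.

## Bias diagnostics

Two known biases of the assay are quantified analytically:

* **Plasmid loss.** Reference cells that lose their GFP plasmid during the
  competition day are miscounted as test cells. For a loss fraction $f$
  per day in a 50:50 neutral competition, counting the lost cells on the
  test side inflates $W$ by $\ln(1+f)/\ln d$ (the conservative,
  test-side-only estimand; `two_sided = TRUE` also books the reference-side
  depletion, $\ln(d(1+f))/\ln(d(1-f)) - 1$, roughly twice as large). At
  the measured $f = 0.004$ and $d = 100$ the one-sided inflation is
  $8.7\times10^{-4}$ — less than 0.1% of the true value, which is why
  plasmid loss cannot explain percent-scale ARG costs.
* **Compensatory mutations.** A mutant with per-generation advantage $s$
  starting at frequency $p_0$ follows
  $p_t = p_0 e^{st}/(1 - p_0 + p_0 e^{st})$ under deterministic selection.
  Even a 15% beneficial mutation starting from ~10 cells stays near
  $10^{-4}$ over the ~60 generations an assay spans, so within-assay
  evolution cannot meaningfully perturb the estimates.

## Many-against-one testing

Every ARG is compared against the *same* vector control, so per-ARG tests
are not independent and a family-wise correction specific to
many-against-one designs is needed. `many_to_one_test()` implements a
resampling (max-$|t|$) version: pooled-variance $t$ statistics of each ARG
group against the vector group; a null built by bootstrap-resampling
within-group centred residuals; and an adjusted p-value equal to the
add-one-corrected fraction of null $\max|t|$ values at least as large as
the group's observed $|t|$. Two structural guarantees hold by
construction: adjusted p-values never fall below unadjusted ones, and —
because each group's resampling stream is seeded from its own label —
adding comparison groups can only increase adjusted p-values. A parametric
Dunnett test (multivariate-$t$ quantiles) gives the same calls on
clear-cut data; the resampling route avoids distributional assumptions at
replicate sizes of 5–10.

`fit_arg_effects()` wires these pieces together and returns a classed
model object; `coef()`, `summary()`, `plot()` and `simulate()` behave as
for other fitted models. Crossed random-effects mixed models (strain and
ARG as crossed random effects, block effects) are deliberately out of
scope: `as.data.frame()` exports the tidy replicate-level table for lme4
or similar tooling.

## qPCR copy number

Plasmid copy number per chromosome is computed by the comparative-Ct
method: $2^{-(Ct_p - Ct_{ch})}$ from the plasmid and single-copy
chromosomal amplicons, normalized to a reference strain (ΔΔCt). This is a
one-line calculation, implemented exactly so that a noise-free synthetic
Ct table round-trips input copy numbers without error.

# Phylogenetic signal

If ARG effects were predictable from host relatedness, refuge strains
could be identified from a phylogeny. Two standard statistics are
implemented against that hypothesis, both accepting non-ultrametric trees
(an accessory-genome tree need not be clock-like):

* **Pagel's λ** multiplies the off-diagonal entries of the Brownian
  shared-path covariance by $\lambda \in [0,1]$ and maximizes the
  multivariate-normal likelihood, with the ancestral mean and Brownian
  rate profiled out by GLS. The search is a 21-point grid pre-scan
  followed by bounded scalar optimization (the profile can be multimodal),
  and boundary candidates 0 and 1 are always evaluated. Because
  $\lambda = 0$ lies on the parameter boundary, the likelihood-ratio
  p-value uses the halved $\chi^2_1$ tail.
* **Blomberg's K** is the ratio of the observed $MSE_0/MSE$ (tip variance
  about the GLS mean over the generalized MSE under the tree covariance
  $V$) to its Brownian expectation $(\mathrm{tr}(V) - n/\mathbf{1}'V^{-1}
  \mathbf{1})/(n-1)$; K ≈ 1 under Brownian motion. Its p-value is an
  add-one-corrected tip-permutation test (default 999 permutations,
  seeded).

Both statistics are invariant to affine trait transformations, and both
agree with the independent `phytools::phylosig` implementation to
numerical precision on shared inputs (pinned in tests). With ~11 strains
the power of any single test is modest; the recovery tests therefore
operate at 100–200 tips where the sampling behaviour of the estimators is
unambiguous.

# The community simulator

## Baseline fitness from growth curves

Direct competitions between divergent natural isolates can be distorted by
interference (colicins, phage), so baseline fitness of the progenitor
strains is reconstructed from resource use alone. Each strain is described
by a lag (h), a maximum growth rate (per h) and a yield (density per unit
resource). `baseline_fitness()` simulates a 50:50 in-silico batch
competition of each strain against the reference under one shared limiting
resource, sized so that a reference-vs-reference pairing realizes exactly
the configured dilution (100-fold) within the 24 h cycle; growth stops
when the resource is exhausted. Baseline fitness is the ratio of realized
log fold-changes, so the reference is exactly 1. This growth model is a
deliberate reconstruction — it is isolated behind a single function so an
alternative model can be substituted without touching the simulator. A
strain that cannot double within a cycle triggers a warning but is still
scored.

## Wright–Fisher dynamics

The community is every strain × ARG combination (vector included).
`combine_fitness()` multiplies each strain's baseline by the ARG's effect
ratio in that strain; the vector column therefore equals the baseline
exactly. `wright_fisher()` then iterates discrete generations (one
generation = one whole 24 h cycle, matching fitness estimates integrated
over a complete competition cycle): initial counts as equal as integer
rounding allows (floor division, remainder to the first types in label
order — deterministic, so runs are exactly reproducible), and each next
generation a multinomial draw of $N$ individuals with probabilities
proportional to frequency × fitness.

Fitness values are drawn once per replicate from
$\mathcal{N}(\text{mean}, \text{se})$ — the uncertainty of the *estimate*,
not the replicate scatter — because the draws exist to propagate
measurement error of the fitness estimates into the prediction, not to
model generation-scale environmental noise. A consequence worth noting:
a combination with a slightly worse mean but wider uncertainty can win
more replicates than a better-measured rival. A `per-generation` redraw
mode and a `fixed-mean` mode are available. Draws must be positive to be
Wright–Fisher weights; non-positive draws are redrawn (truncated normal)
and counted in the result.

The model contains no horizontal transfer, no frequency dependence and no
direct inter-strain interactions, so in the long run a single combination
must win each replicate; the scientific content is *which* one, and how
that depends on the starting cast.

## Persistence and the dropout grid

A strain (or ARG) persists when its summed final frequency exceeds a
threshold in enough replicate simulations. Two conventions are preserved
as presets because both are in use for this assay design: threshold 0.02
in at least 5 of 10 replicates (`"strict"`), and 0.01 in at least 2 of 10
(`"lenient"`); neither is privileged, and explicit values override both.
`dropout_grid()` repeats the simulation for every condition in (no
omission + each strain) × (no omission + each ARG) — 84 conditions for 11
strains and 6 ARGs — with per-condition seeds derived deterministically
from the master seed and the condition label, so any sub-grid reproduces
the corresponding conditions of the full grid exactly. The vector control
is never droppable: it is the baseline every ARG is compared against.

# The synthetic-data generator

The generator exists so that every stage has a test surface with known
truth. It emulates, with defaults chosen to match the assay it mimics:

* **Effect structure**: effects are additive on the ratio scale
  (grand mean 0.98 — an overall ~2% cost — plus strain, ARG and
  interaction deviations with sds 0.01/0.01/0.015, making interaction
  variance comparable to the main effects, the regime where refuges
  matter; pairwise combination differences then average ~2.3%, in the
  percent-scale range the assays report). The vector column is exactly 1.
* **Start mixes**: day-0 test frequency jittered around 0.5 (sd 0.08), so
  a realistic minority of records falls outside the ±15-point window and
  the filter is genuinely exercised.
* **Counts**: both days drawn beta-binomially with intraclass correlation
  ρ (default 0.02) at 10,000 events — clumping makes effective sample
  sizes far smaller than event counts; ρ = 0 reduces exactly to binomial.
  The event count itself is a free parameter, not an empirical value.
  Together the jitter and count overdispersion remove roughly a sixth of
  records at the default filter, and give per-record fitness estimates a
  scatter of several percent, both matching the reported behaviour of the
  real assay.
* **Plasmid loss**: a fraction 0.004 of day-1 reference events is
  reassigned to the test side, reproducing the misclassification bias at
  its measured size.
* **Truth recoverability**: the expected day-1 frequency is the root of
  $\ln(d p_1/p_0) = W \ln(d(1-p_1)/(1-p_0))$, i.e. exactly the mixture for
  which the estimator returns the true $W$ — so with noise switched off
  the pipeline recovers truth to counting resolution, and estimator bias
  can be attributed to noise, not to the generator.

What the generator does *not* emulate: per-event fluorescence
distributions, gating artifacts, day-to-day block effects, or correlated
noise between day 0 and day 1 of a record. Passing recovery tests on
synthetic data therefore validates the estimation logic under the stated
noise model, not the cytometry pipeline upstream of event counts.

# Numerical choices and degenerate inputs

* Proportions of exactly 0 or 1 make $W$ undefined: flagged and excluded,
  never pseudocounted.
* The filter boundary is inclusive, with a $10^{-12}$ allowance so that
  count ratios representing exactly 0.35 or 0.65 are retained despite
  floating-point representation.
* Cells with one replicate report a mean but no interval (flagged), and
  contribute no uncertainty to the simulator (se treated as 0, reported).
* Permutation and resampling p-values use the add-one correction, so they
  are never 0 and are exactly uniform on their support under the null.
* All generators and simulators take explicit seeds; per-group and
  per-condition streams are derived from label hashes so results are
  invariant to the composition of the rest of the run.
* λ optimization evaluates boundary candidates explicitly; a singular
  λ-covariance (can arise with duplicated tips at λ = 1) is reported as an
  error rather than silently regularized.

# Problem sizes used in the validation suite

The package's own checks run at deliberately chosen scales: estimator
recovery at 500 replicates per combination; neutral fixation at population
100 over 2000 replicates; the deterministic-limit check at population
10^4 (compared while the deterministic map is inside [0.005, 0.995] —
near fixation, absorbed replicates necessarily sit above the map while
the Monte-Carlo SE collapses, so the transit phase is where the
deterministic limit is a meaningful claim); signal recovery at 100–200
tips over 20 simulations; family-wise error over 1000 simulated null
families; and the full dropout grid at population 10^3, 100 generations,
10 replicates. These sizes keep every check's Monte-Carlo error well
inside its assertion bands while completing in seconds.

# Known limitations

* Per-strain aggregation uses t-intervals on replicate effects;
  model-based intervals from a crossed mixed model may differ and are out
  of scope (the replicate table is exported instead).
* The ±15-point filter's outlier diagnostic for whole experimental blocks
  (estimates far above all other blocks of the same strain) is reported,
  never auto-removed: removing data on the basis of estimates is a
  judgement call that should stay with the analyst.
* The baseline growth model ignores interactions between strains other
  than shared resource depletion, by design.
* The simulator's normal fitness draws are truncated at zero; with
  percent-scale uncertainties truncation is essentially never triggered,
  but with very wide uncertainties the drawn distribution is no longer
  exactly the stated normal.
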