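---
title: "Modelling MITF-STAT3 crosstalk through their shared inhibitor PIAS3"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MITF-STAT3 crosstalk through their shared inhibitor PIAS3}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system and the model

In melanocytes the transcription factors MITF (master regulator of the
melanocyte program, activated through the MAPK arm) and STAT3 (cytokine
signalling, activated through JAK) are co-regulated by a single shared
inhibitor, PIAS3. PIAS3 binds *non-activated* MITF but *activated*
(tyrosine-phosphorylated) STAT3; abundance of one factor can sequester
PIAS3 away from the other. `pias3net` implements a deterministic
mass-action model of this module with 15 dynamical quantities:

* four free MITF phosphoforms — unphosphorylated, S73-phosphorylated
  (by ERK and by auto-phosphorylation), S409-phosphorylated (by RSK1),
  and doubly phosphorylated — plus their four PIAS3 complexes;
* free PIAS3;
* the RSK1/RSK1p cycle (fixed total pool, 500 au by default);
* STAT3, phospho-STAT3 and the PIAS3–STAT3p complex;
* `R`, the fraction of S73-phosphorylated MITF that is
  ubiquitin-tagged for degradation.

The two inputs, `ERKp` and `JAKp`, are held piecewise constant; a
signalling event is a step in one or both levels (resting level 10 au,
full activation ~1000 au). Amounts are in arbitrary units (au), time in
minutes. MITF, PIAS3 and STAT3 are produced at constant rates and
degrade linearly; proteins in complex are stabilized, degrading at 20%
of the mean of their constituents' free rates
(`complex_degradation_rate()`). S73-phosphorylated MITF — free or
complexed — degrades only in its ubiquitinated share, i.e. its
degradation rate is multiplied by `R`.

### Ubiquitination as a single shared fraction

Tracking ubiquitination as a separate modification would double the
MITF state space. Instead one fraction `R` is shared by all
S73-phosphorylated MITF and evolves through three processes
(`ubiquitination_terms()`): tagging of the un-tagged share, catalysed
by ERKp (`(1-R)·ERKp·k_u`); depletion of the tagged share by its faster
degradation; and dilution by newly produced, un-tagged protein. The
depletion term is implemented in a singularity-free algebraic form that
agrees with the one-minute-turnover derivation for `R > 0` and is
regular at `R = 0` — the equivalence is a unit test, not an assumption.
The dilution ratio `A` is clamped into `[0, 1]` and set to 1 when its
denominator is non-positive; without the clamp, states in which
S409-driven degradation outpaces production would push `R` above 1.

### Activity readouts

Experiments measure transcriptional activity (luciferase reporters or
target-gene mRNA), not protein amounts. For MITF the package maps the
four *free* phosphoforms to a score
`f = 10 - 0.11·[MITF] + 0.44·[MITFp73] + 0.11·[MITFp409] + 0.56·[MITFpp]`
(`mitf_activity()`); complexed MITF cannot bind DNA and is excluded.
The offset keeps the score positive in the regimes studied; ratios
between conditions are taken on the raw score, offset included, since
that is the quantity standing in for a luciferase measurement. STAT3
activity is simply free phospho-STAT3 (`stat3_activity()`): PIAS3-bound
STAT3p is inert.

## Parameters

`default_parameters()` returns the 30 core constants (plus the RSK1
pool size). The published parameter table and the accompanying prose
disagree on one value: the PIAS3 production rate is printed once as
0.262 au/min and, consistently throughout the modelling text and every
experiment protocol, as 1.262 au/min. Both readings are exposed as
*dialects* (`"methods"`, the default, and `"table1"`). The methods
dialect is the default because the experiment catalog is anchored to it
— transfections are described as elevations *from 1.262* — and because
it reproduces more of the catalog (24 versus 20 experiments).

At the resting steady state (`steady_state()`, inputs 10/10) the three
protein totals are within one order of magnitude of each other
(roughly 800, 670 and 110 au for MITF, PIAS3 and STAT3 under the
methods dialect) — the near-equimolar regime the module needs to
function as a crosstalk hub. The printed "steady state amount of
approximately 100 au" is treated as this order-of-magnitude property,
not a hard target, given the production-rate inconsistency above.

```{r}
library(pias3net)
p <- default_parameters()
ss <- steady_state(p)
tr <- simulate_model(p, initial = ss, duration = 120,
                     erkp = 1000, jakp = 1000)
head(as.data.frame(tr))
```

## The virtual-experiment catalog

`experiment_catalog()` encodes 28 published wet-lab experiments as
data: per-condition phase lists (duration, parameter overrides, input
levels), initial-state edits, readouts, and a success criterion — a
conjunction of interval, ratio and ordering clauses with the published
bounds. Transfections are modelled as elevated production rates; for
RSK1, whose total is not dynamic, as an enlarged pool (500 → 5000 au,
phosphorylated fraction preserved). Point mutants edit the affected
rate constants (S409A: S409 phosphorylation zeroed; S73D: S73
de-phosphorylation zeroed and auto-phosphorylation raised; S409D: the
RSK1 cycle and S409 rates shifted toward the phosphorylated state;
STAT3-Y705F: STAT3 phosphorylation zeroed; STAT3-C: phosphorylation
raised, de-phosphorylation zeroed). Unless a protocol says otherwise, a
condition starts from the resting steady state at baseline inputs;
host-cell lines lacking endogenous MITF start with the MITF pools
zeroed (complexed PIAS3 is then released to the free pool, conserving
PIAS3).

Design choices where the protocols left room:

* "Activation level elevated from 10 to 20" in the reporter series
  (#9–#12) is read as `ERKp = 20`, `JAKp = 10`: these experiments probe
  only the MAPK arm. (The JAK reading changes the outcomes by well
  under a percent either way.)
* Ordering clauses ("higher than", "at least 25% higher") are strict
  inequalities, so degenerate all-zero readouts — e.g. when all
  association constants are zeroed and no complex can form — fail
  rather than pass on `0 = 0`.
* The STAT3-reporter series (#19–#24) measures fold-change over a
  background condition (STAT3 transfection only, no activation, 3240
  min), exactly as printed.
* Replicated series share one perturbation record in the catalog
  builder, so an edit to the shared base propagates to every member.

`run_experiment()` simulates each condition phase by phase (state
carried across phases), extracts readouts at the stated times by
linear interpolation, and evaluates the clauses;
`run_all_experiments()` runs the catalog with steady-state memoization
and returns the 28 pass/fail verdicts. Solver failures are reported as
*errored*, distinct from a criterion failure.

```{r}
batch <- run_all_experiments()
batch
batch$results[["26"]]$clauses
```

With default parameters the batch passes 24 of the 28 experiments.
Experiment #26 — activation response of cells whose MITF cannot bind
PIAS3 — fails on its STAT3 clauses: in the simulation STAT3 activity
rises on activation regardless of the MITF mutation, because MITF
degradation frees similar amounts of PIAS3 in both genotypes. This is a
genuine limit of the model topology, not a numerical artifact. Three
further entries miss their quantitative windows narrowly while
matching the qualitative behaviour: #7 (the MITF–PIAS3 complex peaks at
~3–4 minutes after activation and is back at baseline by the 10-minute
readout, so the "higher at 10 min" clause fails by 0.014%), #9 (PIAS3
co-transfection leaves 48% of MITF activity where the window ends at
42%) and #11 (the S409A series lands at 11.8% against a 15–55% window).
Notably #11 and #12 are mechanically identical once S409
phosphorylation is zeroed — RSK1 has no remaining target — yet their
published windows differ ([15,55]% vs [10,50]%), so no single simulated
value can sit comfortably in both; ours satisfies #12 only. These
boundary cases are also the entries whose verdicts can flip under
otherwise negligible (<2% readout drift) perturbations of the STAT3-arm
parameters, which is why the "MITF-only experiments ignore the STAT3
arm" property is asserted on outcomes for the robust entries and on
readout drift for the boundary ones.

## Global sensitivity analysis

`sample_parameters()` draws core-parameter sets log-uniformly within
one half to double each default (30 dimensions; the RSK1 pool size and
all experiment-specific settings stay fixed). `outcome_matrix()`
re-runs the whole catalog per draw, giving an n × 28 boolean matrix.
For experiment *i* and parameter *j*, `sensitivity_measure()` sorts
the draws by parameter *j*, splits them into 100 equal rank-bins and
sums `|f_i^k - f_i|` over bins — a rank-based statistic, invariant
under monotone transforms of the parameter, bounded by
`n_bins · max(f_i, 1 - f_i)`. Entries that do not exceed the maximum
statistic observed under random permutations of the parameter values
are zeroed (`sensitivity_analysis()`); one seeded permutation stream
is shared across parameters, which is exact here because a permuted
column induces a uniformly random row ordering whatever the column's
values, and reusing the draws removes between-parameter Monte-Carlo
variance from the thresholds. Rows are finally normalized to their
maximum for display.

Scale: the package's test suite and examples run the scan at n = 2000
samples with 1000 permutations and 100 bins (bins of 20 draws), which
resolves effects on bin success rates of roughly ±0.1 and completes in
a few minutes; larger scans improve resolution as `sqrt(n)` and can be
run through the same functions (the CLI writes all matrices as CSV).
At the 2000-sample scale the S409-phosphoform binding constants
(`k_Mp409ass`, `k_Mp409diss`) and the MITF production rate (`p_MITF`)
show no detectable effect on any experiment — the S409-bound complex is
rare at its default affinity, and the criteria are ratio-based, so the
absolute MITF supply cancels. Parameters with genuinely weak effects
(the STAT3 production/degradation rates and the ubiquitination
constant) may also fall below the permutation threshold at this scale,
whereas a finer scan separates them from the truly inert trio.

## Numerical choices

* Integration: `lsoda` (stiff-capable) via deSolve, with the
  right-hand side compiled in C; absolute tolerance 1e-8 au, relative
  1e-6 by default, configurable everywhere. The reference R
  implementation `model_rhs()` is exported and tested against the C
  version and against an independently assembled
  stoichiometry-matrix oracle (relative error < 1e-9).
* Reported states are floored at 0 (and `R` clamped to `[0,1]`) only
  for reporting and phase hand-off; amounts more negative than 1e-4 au
  abort the run instead of being hidden.
* Steady states are found by long integration (50,000 min per attempt,
  up to five attempts) and verified by a residual criterion:
  `max |dx/dt| / max(|x|, eps)` below 1e-6 per minute.
* Rank ties in the sensitivity sort are broken by sample index
  (stable); with continuous sampling they have probability zero.
* Readout times are interpolated linearly from the reporting grid, and
  every protocol-stated time is a grid point, so criterion outcomes do
  not depend on the reporting step.

## What the harness does and does not show

The catalog is both the validation suite and the package's synthetic
fixture generator: every test input is constructed programmatically
from published protocol numbers. Passing it shows that the printed
equation system, under the printed perturbations, reproduces the
published qualitative behaviours (kinase kinetics, phosphoform
balance, degradation kinetics, sequestration-driven crosstalk and its
asymmetry — within the activation windows the protocols use, stepping
ERKp perturbs STAT3 activity more than stepping JAKp perturbs MITF
activity, although both effects largely wash out at the new steady
state). It does not calibrate the model
to absolute protein amounts (none are published; units are arbitrary),
does not model transcription/translation delays of the transfected
genes (production steps on instantaneously), and cannot adjudicate
details of the original authors' unpublished implementation — the
three near-boundary window misses above are exactly the cases where
such details matter.
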