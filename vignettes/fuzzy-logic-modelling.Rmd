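---
title: "Constrained fuzzy logic modelling of perturbation expression data"
author: "fuzzyhep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained fuzzy logic modelling of perturbation expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyhep)
```

## The problem and the model

Proinflammatory cytokines such as IL-6 downregulate a broad panel of
hepatic drug-metabolizing enzyme and transporter (DMET) genes. Which of
the three signalling branches IL-6 activates — JAK/STAT3, PI3K/AKT/NF-κB,
MAPK/ERK — carries this repression, and through which transcriptional
regulators, can be asked quantitatively with perturbation data: gene
expression fold changes measured with and without chemical inhibition of
each branch in primary hepatocytes from several donors.

`fuzzyhep` answers it with constrained fuzzy logic (cFL). A prior
knowledge network (PKN) of signed, directed influences is the hypothesis
space; the calibrated model is a selection of logic gates over that
network. A species' state lives in [0, 1]. Every gate input passes
through a normalized Hill transfer function

$$f(x) = \frac{x^{n}\,(1 + k^{n})}{x^{n} + k^{n}},$$

which is strictly increasing with $f(0)=0$ and $f(1)=1$; $k \in (0,1]$ is
the half-activation gain in state units and $n \ge 1$ the steepness
(dimensionless). An inhibiting input contributes $1-f(x)$. A gate's
output is the minimum over its input contributions (fuzzy AND); a
species' state is the maximum over its active gates (fuzzy OR), or a
constitutive baseline (1 for species flagged `constitutive`, 0
otherwise) if no gate is active. Stimuli and inhibitors are clamps that
override gates; inhibitor clamps are total (level 0), since the chemical
inhibitions being emulated are near-complete. The normalization $f(1)=1$
makes Boolean inputs propagate exactly, so with the stimulus off the
model produces crisp 0/1 states — the behaviour the data normalization
is anchored to (below).

Two modelling assumptions matter. First, steady state only: species are
evaluated once in topological order, so the PKN must be acyclic and
feedback loops (e.g. SOCS-mediated receptor inhibition) are removed
before modelling — feedback needs a time scale this formalism does not
have, and `removeFeedback()` either applies a curated deletion list or
automatically cuts the transition participating in most simple cycles
(ties broken lexicographically, so the result is deterministic). Second,
inhibition-after-transfer: an inhibitory gate contributes $1-f(x)$, which
gives state 1 to a target whose only input is an inhibiting transition
from an inactive pathway. That is exactly the control-condition behaviour
of a downregulated DMET gene, and it is why such genes need no explicit
basal activator in the model.

## Network preprocessing

`compressNetwork()` removes species that are neither measured nor
perturbable (and are not stimuli or constitutive regulators) by
pass-through rewiring, multiplying signs along the bridged path. A
species is kept when removal could change the logic: in-degree and
out-degree both above 1, a rewire that would create a contradictory
duplicate transition, or — decisive in all cases — when an exhaustive
Boolean simulation over every 0/1 clamp pattern of the stimuli and
perturbable species shows any measured species changing state. The
simulation check is the operational definition of "necessary for logical
consistency": the rule-based retention criteria are a fast screen, the
equivalence oracle is the guarantee. Note that an unmeasured species with
several inputs and one *inhibiting* output is not removable (negating an
OR is not the OR of negations); the oracle catches this class
automatically.

`expandGates()` then enumerates the gate hypothesis space: every incoming
transition as a one-input gate plus all AND combinations of 2..`maxAndSize`
inputs with distinct sources. The default `maxAndSize = 2` keeps the
space near the scale the calibration is designed for (tens of gates, of
order a hundred transfer parameters); the count per target with $d$
inputs is $d + \sum_{j} \binom{d}{j}$ and is verified against brute-force
enumeration in the tests.

## Data normalization

qPCR Ct tables become linear fold changes by ΔΔCt
(`deltaDeltaCt()`: $\Delta Ct$ against the reference gene,
$\Delta\Delta Ct$ against the calibrator sample, $FC = 2^{-\Delta\Delta Ct}$;
a missing reference Ct marks the sample missing rather than imputing).
Fold changes are mapped to [0, 1] with $v = fc^h/(m^h + fc^h)$, $h = 4$
for all genes. The midpoint $m$ is class-specific
(`assignMidpoints()`, classifying on the mean IL-6-alone fold change
across donors):

* mean < 1 (downregulated): $m = 0.5$ — the control fold change 1 maps
  to $1/1.0625 \approx 0.94$, anchoring the untreated state near the ON
  state the model produces there;
* 1 ≤ mean < `strongUpCutoff` (weakly induced, CYP2E1-like): $m = 2$ —
  control maps to $1/17 \approx 0.06$;
* mean ≥ `strongUpCutoff` (strongly induced acute-phase genes): $m$ =
  half the mean IL-6 fold change, so the induced level maps to ≈ 0.94.

`strongUpCutoff` defaults to 4 on the linear fold-change scale; the
hand-assigned midpoints of specific genes are reproducible through the
`overrides` argument. The 0.94 control anchor is deliberate: it spreads
the data across [0, 1] while pinning each gene class to the Boolean
extreme the simulation reaches without stimulus. It also sets a fit
floor — a model whose gene state is exactly 1 at control differs from the
0.94 anchor by $0.059^2 \approx 0.0035$ per control cell — which is the
dominant term of the noise-free family MSE (~6×10⁻⁴ on the bundled
benchmark).

## Calibration, reduction, families

`gaOptimize()` runs a genetic algorithm over genomes that assign each
candidate gate either "off" or one cell of the discrete grid
$k \in \{0.2, \dots, 1.0\}$, $n \in \{1,2,3,4,6\}$ (45 cells; both grids
configurable). Defaults: population 50, at most 500 generations, stop
after 100 without improvement, tournament selection of size 2, uniform
crossover, per-locus mutation 0.05, elitism 1. Fitness is the negative
MSE over all non-missing (gene, condition, donor) cells, donors pooled
with equal weight per cell — one "mean" model over all donors. Control
conditions are included as data points; their anchored values are what
tie the baseline down. The MSE over genome populations is evaluated in
C++ from per-(gene, condition) sufficient statistics, which is what makes
families of runs cheap. Identical seed and settings give identical
results; on genome spaces small enough to enumerate, the GA's optimum is
tested to coincide with exhaustive search.

`reduceModel()` greedily switches off the active gate whose removal
increases the MSE least, while the cumulative increase over the unreduced
model stays within the selection threshold (default 0.01 MSE units;
ties broken by lowest gate index). Transfer parameters are frozen during
reduction — removal only ever deletes, so the bound
$MSE_{reduced} \le MSE_{optimized} + threshold$ holds by construction and
is asserted on every run. One consequence worth knowing: the reduction
budget is real. On noise-free data the optimizer reaches the anchor
floor, and reduction may still legitimately spend up to the full
threshold on removing a cheap gate (for example a gene that is ON in only
two conditions). Claims about fit quality therefore refer to the
optimized models; claims about parsimony to the reduced ones.

`fitModelFamily()` repeats optimize + reduce `nRuns` times (run $r$ seeds
the GA with `seed + r`) and records, for every transition and gate, the
fraction of reduced models containing it. `consensusNetwork()` keeps
transitions at or above a display cutoff (default 30%) with the frequency
as edge weight; `reductionCurve()` re-reduces one set of GA runs at a
ladder of thresholds, giving the monotone trade-off between mean
parameter count (two scalars per active gate — the counting convention
used everywhere here) and mean MSE.

## The synthetic benchmark

No donor-level expression tables exist publicly for this system, so the
package generates its own ground truth. `makeBenchmarkPKN("paper")`
builds a network with the reference architecture: IL-6 into three
signalling branches; a transcription-factor layer in which a
nuclear-receptor-complex hub (RXRNR) is repressed by MAPK and NF-κB and a
GR-like factor by MAPK; and 35 measured genes, 27 of them reached through
the hub, three strongly induced STAT3 targets (CRP/SAA/SOCS3-like), plus
GR-activated and NF-κB-repressed genes. `makeBenchmarkDesign()` supplies
the seven conditions: control, IL-6, three single inhibitions
(STAT3i, PI3Ki, MAPKi) and the two tolerated double inhibitions
(STAT3i+MAPKi, PI3Ki+MAPKi); the third double inhibition is deliberately
absent, mirroring a co-inhibition the cells do not survive.

`sampleTruth()` draws one gate per target from the expanded space and
(k, n) from the training grids — the fitter's space always covers the
truth — and `emitDataset()` inverts the Hill normalization to turn
clipped steady states (clip $\varepsilon = 10^{-3}$, avoiding the
infinities of exact Boolean states) into fold changes, forces the control
column to 1, and then applies, in order: a fixed per-gene log2
effect-size offset (sd 0.5) so genes differ in regulation magnitude as
real panels do; a per-(donor, gene) log2 random effect (sd 0.25); a
lognormal measurement error with CV 0.2
($\sigma = \sqrt{\log(1+CV^2)}$); and independent missingness
(probability 0.02). These defaults are the package's definition of the
study conditions and are used unchanged by the tests and the acceptance
script.

Two structural choices keep the benchmark honest rather than easy.
First, identifiability: genes with two regulators pair influences whose
candidate gates (both singles and the AND) have distinct steady-state
signatures under the seven conditions, and every candidate leaves the
gene ON at control — otherwise a randomly sampled truth could be
observationally indistinguishable from an alternative gate, and no
fitter could be expected to recover it. Constitutive-regulator targets
are excluded from the panel for the same reason (AND with a constant-1
input is invisible), though the constitutive mechanism itself is part of
the engine and of the bundled hepatic example network. Second, class
consistency: because emission inverts the normalization per gene class,
a gene whose control state contradicts its class anchor would carry an
irreducible artifact; the panel design rules this out by construction.

What the generator does *not* emulate: time courses and feedback
(excluded by the steady-state formalism), partial inhibitor efficacy,
amplification-efficiency artefacts in the qPCR step, correlated
missingness (whole failed assays), and graded intermediate expression
states — with binary clamps the truth's states are exactly 0/1, so
recovering transfer-function *shapes* is not tested by the benchmark,
only gate structure. Passing the pipeline tests therefore demonstrates
topology recovery under realistic noise, not parameter identification on
real, graded data.

## Numerical choices and problem sizes

* Steady-state evaluation visits species in one fixed topological order;
  any valid order gives the same result on a DAG, and the C++ kernel is
  cross-checked against an independent recursive evaluator.
* MSE pooling skips missing cells in numerator and denominator; an
  all-missing dataset is an error, never a zero.
* Spearman validation (`spearmanValidation()`) uses midranks, the exact
  null distribution for tie-free n ≤ 10 and the t-approximation
  otherwise; clustering (`clusterLog2FC()`) is average-linkage on
  pairwise-complete Euclidean distances scaled by
  $\sqrt{p/\#shared}$; the grouped t-test pools variances by default
  (Welch by flag) and refuses zero-variance input.
* Tests run the full-scale recovery at 20 family runs, 5 donors, seed 7
  (about 10 s with the compiled kernel), exhaustive GA checks on a
  46²-genome space, and 200-network oracle sweeps; the whole suite is
  about a minute on one CPU. These sizes are the package's chosen
  regression points, scaled to make the properties sharp rather than the
  runtime long.

## Known limitations

Reduction order is greedy and parameters are not re-optimized after
removals; a different removal order could reach a smaller model at equal
MSE. Consensus frequencies conflate structural ambiguity with GA
stochasticity — a gate at 50% may be genuinely undecidable from the
design rather than half-supported. The benchmark's binary truth states
mean transfer-parameter grids are exercised but not stressed. And the
automatic feedback-removal policy optimizes cycle count, not biological
plausibility; for curated networks, pass an explicit removal list, as the
bundled hepatic example does.
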