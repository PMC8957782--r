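---
title: "Methods: rare-variant screening and Cav3.2 channel biophysics"
author: "cavscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant screening and Cav3.2 channel biophysics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavscreen)
```

# Overview

`cavscreen` couples two analyses that in practice meet in studies of
calcium-channel variants in neurodevelopmental disorders:

1. a **family-based rare-variant screen** over the 18 genes encoding
   voltage-gated calcium-channel (VGCC) subunits, classifying inheritance
   models in affected children — including compound heterozygotes in trios
   and quads — from an annotated multi-sample VCF and a PED pedigree; and
2. a **whole-cell voltage-clamp analysis** of T-type (Cav3.2) currents:
   peak current–voltage relations, modified-Boltzmann activation fits,
   steady-state inactivation fits, activation kinetics and charge transfer,
   with per-genotype summaries and one-way ANOVA contrasts.

Because raw sequencing and patch-clamp data of such studies are typically
not depositable, the package ships its own synthetic data layer: a
Hodgkin–Huxley-style current simulator with built-in per-genotype gating
parameters, and a toy-cohort generator that emits an annotated VCF/PED pair
whose expected screening outcome is known exactly. The simulator and
generator are first-class, tested code: every analysis routine is validated
by round trips through them.

# The variant screen

## Filter cascade

Variants are decomposed to one record per ALT allele and then pass, in
order:

| Step | Rule | Default |
|------|------|---------|
| Genotype quality | remove genotypes with DP below or GQ below threshold (equality passes) | DP ≥ 10, GQ ≥ 20 |
| Frequency | effective MAF = max over configured sources, missing = 0 | rare ≤ 1%, ultra-rare ≤ 0.1% |
| Deleteriousness | LGD (stop-gain, stop-loss, frameshift, splice) always; missense by CADD | CADD ≥ 15 |

Boundary semantics matter: strictly sub-threshold genotypes are removed, so
DP = 10 and GQ = 20 pass; MAF equal to a ceiling passes; CADD equal to the
threshold is damaging. Taking the **maximum** over frequency sources is the
conservative resolution when releases disagree; a variant absent from every
source is treated as novel (MAF 0). A genotype that fails the quality
filter is treated as missing rather than reference, so a low-quality parent
degrades a call to `inherited_ambiguous` instead of fabricating a de novo.

## Inheritance models

For each affected child carrying the ALT allele: heterozygous calls are
assigned a parental origin when exactly one genotyped parent carries the
allele; both parents carrying gives `inherited_ambiguous`; neither gives
`de_novo` (reported but flagged, since the screen targets inherited
variation). Homozygous children are `homozygous`, with a Mendelian-error
flag (never an exception) when a genotyped parent carries no ALT. Male
children with the ALT on chrX outside the GRCh38 pseudoautosomal regions
are `hemizygous`, with maternal origin recorded when the mother carries;
female X calls are handled as autosomal.

**Compound heterozygotes** pair two heterozygous calls in the same gene and
proband with distinct parental origins. Because the parents are unaffected,
a cis configuration cannot be causal under a recessive model, so pairs in
which any single parent carries both alleles are excluded. A variant may
appear in several pairs; a sibling carrying only one member of a pair is
never called.

The dominant-model candidate list keeps ultra-rare damaging heterozygous
inherited/de novo calls; the recessive-model list keeps rare damaging
homozygous, hemizygous and compound-het calls. Family-level counts count
each distinct variant once per family, so monozygotic twins (both reported
as carriers) do not double-count their family.

## The toy cohort

`make_toy_cohort()` writes four families — a quad with affected monozygotic
twins and an unaffected sibling who carries only the paternal variant, a
trio with a compound-het proband, and two trios with male probands carrying
maternally transmitted hemizygous chrX variants — using the published
coordinates, CADD scores, dbSNP identifiers and gnomAD v3.0 frequencies of
the six recessive-acting variants. Ten decoy records each exercise exactly
one rejection path (common, synonymous, sub-threshold CADD, low DP/GQ,
off-panel gene, carriers without affected status, a same-parent cis pair,
an LGD variant in a parent only). gnomAD v2 non-neuro frequencies are not
printed for the six true variants, so the toy VCF carries only the v3
field for them; under the max rule a missing source contributes 0. The
expected call set is written to a JSON manifest so tests never re-derive
it from the code under test.

# The channel model and simulator

## Gating model

The simulator uses a two-gate Hodgkin–Huxley-style scheme,

$$I(t) = C \, \bar g \, m(t) \, h(t) \, (V - E_{rev}),$$

with first-order kinetics $\dot m = (m_\infty - m)/\tau_m$,
$\dot h = (h_\infty - h)/\tau_h$ and steady states

$$m_\infty(V) = \frac{1}{1 + e^{(V_h - V)/S}}, \qquad
  h_\infty(V) = \frac{1}{1 + e^{z (V - V_i)/25.6}},$$

the 25.6 mV thermal scale entering the inactivation curve exactly as in the
analysis equations. The activation gate is first order (exponent 1, not
$m^2$ or $m^3$): peak-based analyses fit a single Boltzmann to the peak
conductance, and a first-order gate makes that fit well-posed, so this is a
simulator convention, not a biophysical claim. Units are mV, ms, pA, pF;
conductance density $\bar g$ is in nS/pF; inward current is negative.

Command voltages are piecewise constant, so within each epoch the gate
trajectories are exact exponentials toward their steady states; the
simulator evaluates that closed form at the 0.2 ms sample grid (5 kHz
digitization). This is exact for this protocol class — the test suite still
cross-checks peak currents against an independent fine-step `deSolve`
integration to 0.5%. The 10 s inter-sweep interval at holding is modeled as
exact re-equilibration to the holding steady state. Noise is additive white
Gaussian per sample; leak is assumed perfectly subtracted, and no
series-resistance or capacitive-transient artifacts are simulated.

## Protocols

* **Activation**: holding −120 mV; 20 ms baseline; 100 ms test pulses from
  −110 to +20 mV in 10 mV steps (14 sweeps).
* **Inactivation**: holding −120 mV; 20 ms baseline; 1 s conditioning from
  −120 to −60 mV in 10 mV steps (7 sweeps); 100 ms test pulse at −40 mV.

## Built-in parameter sets

The five built-in genotypes place their activation and inactivation
midpoints at the fitted values reported for the wild-type channel and the
four characterized variants (Vh −45.5/−50.1/−49.5/−49.3/−43.4 mV and Vi
−78.9/−77.1/−75.3/−79.5/−78.2 mV for WT / Lys785Met / Pro849Ser /
Pro2124Leu / Ser2338Phe). Everything those reports do not print is a
documented fixture convention, chosen once:

* $E_{rev}$ = +30 mV, $S$ = 5 mV, $z$ = 4 (slope 25.6/4 = 6.4 mV) —
  typical T-type values;
* WT conductance density 1.0 nS/pF; Lys785Met 1.6 nS/pF, encoding its
  gain-of-function direction at a magnitude detectable at the reported
  cell counts;
* time constants are positive bell-shaped functions of voltage,
  $\tau(V) = b + a\,e^{-((V-\mu)/w)^2}$, calibrated so WT time-to-peak at
  −40 mV is ≈ 12 ms and decay ≈ 25 ms (plausible T-type range).

One deliberate design constraint: per genotype, $\tau_h(V)$ is a **fixed
multiple** of $\tau_m(V)$ (identical bell shape). For a rising gate times a
decaying gate, the peak of $m(t)h(t)$ then attenuates $m_\infty(V)$ by a
voltage-independent factor, so the peak-conductance curve remains exactly
proportional to the generating Boltzmann and the round-trip recovery of
$V_h$ is unbiased. Mutant kinetics scale $\tau_m$ (1.5× for Lys785Met and
Ser2338Phe; 3× for Pro849Ser, whose $\tau_h$ is also 0.72× WT): the 3× was
sized by a power analysis so the slower time-to-peak direction remains
detectable at the reported group sizes despite Pro849Ser's faster decay
cutting its peak amplitude.

## Cohort variability

`cohort_spec()` defaults encode the simulated study conditions: capacitance
log-normal with median 15 pF and CV 0.25 (typical HEK-293 cells),
a log-normal per-cell conductance multiplier with mean 1 and CV 0.15
(transfection variability), and 5 pA recording noise. Per-cell noise seeds
derive deterministically from the master seed; the same spec and seed give
bit-identical recordings.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real recordings: seal/leak drift, capacitive
transients, series-resistance error, endogenous HEK currents, run-down,
cell-to-cell scatter in the midpoints themselves, or auxiliary-subunit
effects. The round-trip results validate the analysis code, not the
biology.

# Recording analysis

## Peaks and I–V relations

The peak of each sweep is the most negative baseline-subtracted sample in
the test epoch; the baseline is the mean over the 10 ms before step onset,
and the first two post-onset samples are skipped (capacitive-transient
convention — the simulator has none, real data would). Before the search
the trace is smoothed with a centered 5-sample (1 ms) running mean:
picking the extremum of a noisy trace biases small peaks upward, and a
1 ms window is negligible against tens-of-ms T-type peaks while
suppressing most of that bias. Densities divide by the cell capacitance;
mean curves average densities across cells per voltage with SEM.

For the **inactivation protocol** the peaks are referenced to the
holding-epoch baseline instead of the 10 ms before the test pulse: at
depolarized conditioning potentials the channel passes a steady window
current, and a pre-test baseline would subtract genuine current from the
peak, biasing $V_i$ negative by up to ~0.6 mV in simulation.

## Fits

The activation fit is four-parameter nonlinear least squares of
$$I_{peak}(V) = (V - E_{rev})\, G_{max} \big/ \big(1 + e^{(V_h - V)/S}\big)$$
via Levenberg–Marquardt, with deterministic initialization ($E_{rev,0}$ =
+30 mV, $V_{h,0}$ at half-maximal chord conductance, $S_0$ = 5 mV,
$G_{max,0}$ from the maximal chord conductance) and bounds $E_{rev} \in
[0, 80]$, $V_h \in [-90, 0]$, $S \in [1, 15]$ mV, $G_{max} > 0$. A fit is
flagged unconverged when the optimizer fails or a parameter sits at a
bound; no exception is raised. A lattice-search oracle (grid over
$E_{rev} \times V_h \times S$ with the conditionally linear $G_{max}$
solved exactly) bounds the optimizer's RSS in the tests. The inactivation
fit is the two-parameter analogue with the 25.6 mV scale fixed. Both the
mean-curve fit (the reported headline) and per-cell fits (for group
statistics) are provided.

Kinetics at the −40 mV test potential: time to peak from step onset, and a
single-exponential fit $A e^{-(t-t_{peak})/\tau} + C$ from the peak sample
to the end of the epoch, with the offset free; a trace whose peak falls at
the epoch end gets no $\tau$, flagged. Charge transfer integrates the
magnitude of the baseline-subtracted inward current by the trapezoidal rule
at native sampling to 2, 10 and 100 ms, in pC and pC/pF. Conductance
density is exposed under both plausible definitions — chord conductance at
−40 mV, density(−40)/(−40 − $E_{rev}$), and fitted $G_{max}$ — because
published "conductance density at −40 mV" wording does not distinguish
them; group contrasts hold under either here.

# Group statistics

Parameters are summarized as mean ± SEM per genotype. Group differences use
the classical equal-variance one-way ANOVA F test; pairwise contrasts
against WT are two-sided Welch t-tests, uncorrected by default — mirroring
the per-contrast reporting style of the source analyses, which state only
"one-way ANOVA" yet print per-mutant p-values — with Holm correction
available by flag. Degenerate inputs (zero between- and within-group
variance) return p = 1, flagged.

# Numerical and validation choices

* All randomness flows from explicit integer seeds; cohort generation,
  simulation and the pipeline are bit-reproducible.
* Noise-free fits recover generating parameters to 1e-6 relative; the
  simulator matches a 100×-finer independent ODE integration to well
  under 0.5%.
* The screen is validated against a brute-force enumeration over all
  (variant, proband) pairs and all variant pairs per gene on randomized
  small cohorts, and obeys monotonicity (tightening any threshold never
  adds calls) and idempotence.
* ANOVA p-values are checked against a permutation oracle and a 2000-run
  null simulation of the type-I error rate.
* Problem sizes in the test-suite round trips (16-cell cohorts, 200
  Monte-Carlo replicates for directional contrasts, 2000 null ANOVA
  simulations) were chosen as the smallest sizes at which the checked
  properties are statistically meaningful at the published group sizes.

# Known limitations

* The simulator's first-order activation gate makes peak-conductance
  Boltzmann fits exactly well-posed; real Cav3.2 activation is sigmoidal
  in time, and fits to real data carry model mismatch this package does
  not exhibit.
* Phase of compound-het pairs is inferred purely from parental genotypes;
  without phased reads, pairs in genes where a parent is ungenotyped
  remain ambiguous and are not called.
* The screen consumes annotations (gene, consequence, CADD, frequencies)
  as given; it neither recomputes nor lifts over anything.
* Printed per-contrast p-values from small patch-clamp groups depend on an
  unstated post-hoc procedure; only directions and the reported midpoints
  are treated as reproducible targets here.
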