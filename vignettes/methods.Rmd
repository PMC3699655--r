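---
title: "Methods: perturbation-based attribution of airway gene expression to eosinophils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perturbation-based attribution of airway gene expression to eosinophils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eosid)
```

## The attribution problem

Bulk expression of airway samples is a cell mixture. After an allergen
challenge, eosinophils (EOS) can go from under 1% to roughly three
quarters of bronchoalveolar lavage (BAL) cells, so genes whose bulk signal
tracks that influx are candidates for EOS expression — but challenge also
activates resident cells, and a gene induced in macrophages post-challenge
is indistinguishable from an EOS gene on a single contrast. `eosid`
implements a three-perturbation design that breaks this confound:

* **segmental challenge (BAL V2 vs V1)** raises the EOS fraction
  massively: EOS and challenge-induced genes both rise;
* **EOS depletion with mepolizumab (V3/V4 vs V1/V2)** halves the
  challenge-driven eosinophilia while leaving non-EOS induction intact:
  only genes carried by EOS lose signal;
* **whole-lung challenge in sputum (V2 vs V1)** replicates the influx in
  an anatomically and technically independent compartment, gated on
  subjects whose canonical EOS markers (IL5RA, RNASE2, RNASE3, SIGLEC8)
  actually responded.

A gene surviving all three filters is attributed to airway EOS. The
filters are deliberately simple consensus fold-change rules — no variance
model and no multiple-testing correction — reproducing the published
analysis style; their statistical behaviour is characterized below rather
than "improved".

## Selection rules and their parameters

All rules act on per-subject linear fold changes; log2 input is
exponentiated first. Defaults (all configurable via
`selection_thresholds()`):

| parameter | default | role |
|---|---|---|
| `bal_up_fc` | 2.0 | BAL V2/V1 up-regulation, required in **every** subject |
| `mepo_down_fc` | 1.5 | both depletion criteria, every subject |
| `sputum_marker_fc` | 2.0 | marker gating of sputum subjects |
| `sputum_up_fc` | 1.5 | sputum V2/V1, every gated subject |
| `mode` | strict `>` | boundary rule; `gte` available |
| `mepo_combine` | `and` | how the two depletion criteria combine |
| `min_markers` | 4 | markers required to gate a subject |

The depletion threshold is 1.5 rather than 2 because mepolizumab reduces
BAL eosinophilia by about half, so even a perfectly EOS-restricted gene is
expected to drop only about 2-fold.

Three design points were genuinely open and are resolved as follows:

* **The two depletion criteria combine with AND.** "Using both" criteria
  most plausibly means both must indicate a decrease; an OR mode is
  provided (`mepo_combine = "or"`) for sensitivity analysis.
* **Marker gating demands all four markers.** A subject with three of
  four markers above threshold is not gated by default (`min_markers`
  relaxes this for exploration only).
* **Per-subject evaluation everywhere.** The all-of-n consensus mirrors
  the "both subjects" rule of the BAL branch; a pooled mode
  (`compute_fold_change(per_subject = FALSE)`, geometric means per visit)
  exists but is not the default.

Numerical details: near-zero linear denominators are floored at
`1e-6 × median positive value` of the matrix, so fold changes stay finite
without perturbing realistic intensities; every flooring event is
messaged. Branch outputs are returned in canonical alphabetical order,
making all results invariant to gene and subject ordering. The seven Venn
regions are computed over the union of the three branch outputs (the
published analysis intersects gene lists, not platform universes).

## The synthetic study generator

`simulate_study()` emulates the study design so that every pipeline stage
is testable without external data. Bulk intensity of gene $g$ in sample
$s$ is

$$x_{gs} = \left[ f_s E_g a_g(s) + (1 - f_s) B_g b_g(s) \right]
  \cdot e^{\varepsilon},\qquad \varepsilon \sim N(0, \sigma^2),$$

with $f_s$ the EOS fraction, $E_g, B_g$ the EOS/non-EOS compartment
baselines (log-uniform over $[2^4, 2^{12}]$, spanning a typical
normalized-intensity dynamic range without modelling a platform), and
$a_g, b_g$ post-challenge multipliers active at V2/V4 and sputum V2.
Noise is multiplicative log-normal — the standard microarray error model,
which keeps fold changes scale-free. Defaults follow the documented study
conditions:

* EOS-fraction means: BAL 0.005 (V1, V3), 0.739 (V2), 0.34 (V4); sputum
  0.020 (V1), 0.082 (V2). The reported BAL dispersions (±4.2 and ±9
  percentage points at n = 8) are interpreted as standard errors and
  converted to per-subject standard deviations (sd = SEM·√8 ≈ 0.119 and
  0.255), truncating draws to [0, 1]. Sputum dispersions are not reported;
  0.008 and 0.035 are chosen once as a realistic between-subject spread
  wide enough that marker gating genuinely splits the six-subject arm.
* Gene classes (1000 genes): 50 `eos_specific` ($E = 50B$, constitutive;
  the four marker genes are the first four), 50 `eos_activated`
  ($E = 50B$ plus 3× EOS activation post-challenge), 50
  `noneos_challenge_induced` (3× induction post-challenge), 850 `null`.
  The EOS/non-EOS ratio of 50 and both 3× multipliers are stipulated
  effect sizes, not estimates.
* One purified-EOS sample per BAL subject at V2 with $f = 0.995$
  (purity below the 99% exclusion bound used for purified preparations).
* Cytospin differentials: multinomial counts of 400 cells, EOS
  probability $f_s$, remainder split with compartment-typical
  proportions.
* qPCR plate: marker genes against the constitutive reference GUSB
  (whose expected expression is constant across samples by construction),
  triplicate wells, Ct noise sd 0.15 cycles (typical plate precision),
  per-primer efficiencies drawn from 91–96%.

One modelling choice deserves emphasis: **challenge-induced non-EOS genes
apply their induction in both compartments** ($a = b = 3$ with $E = B$).
This encodes a gene whose induction is independent of the EOS influx —
exactly the confounder the depletion branch exists to remove. Its bulk
signal is then $3\times$ at every post-challenge visit regardless of $f$,
so it passes the BAL (FC 3 > 2) and sputum (3 > 1.5) branches, while both
depletion criteria equal exactly 1 and fail — at any noise level the
exclusion is structural, and in the noise-free limit it is exact. Had the
induction been confined to the non-EOS compartment, dilution by the
post-challenge EOS influx (non-EOS fraction ≈ 0.26 at V2) would cap its
bulk fold change near 1.5 and the gene would never reach the BAL branch
in the first place; the two-compartment confounder worth simulating is
the one the design has to work to exclude.

Mepolizumab is modelled purely as the reduction of $f$ at V3/V4; the
possibility that post-depletion EOS are phenotypically distinct is
deliberately not modelled.

### What the generator does not emulate

Probe-level effects, batch and platform differences (Affymetrix vs
Agilent), background/saturation, cross-hybridization, dropout, and any
correlation structure between genes. Passing recovery tests therefore
demonstrates the logic and calibration of the selection rules under an
idealized error model, not robustness to real microarray artefacts.

## Power of the consensus rule under noise

With $\sigma = 0.25$ (natural-log units) each fold change carries
log-scale noise of sd $\sigma\sqrt{2} \approx 0.354$; the four-sample
depletion ratio carries $2\sigma = 0.5$. The depletion branch's available
signal is bounded by the fraction ratio $f_{V2}/f_{V4} = 0.739/0.34
\approx 2.17$, a log margin over the 1.5 threshold of only
$\ln(2.17/1.5) \approx 0.37$ — about one noise standard deviation. A
true EOS gene therefore passes each per-subject depletion test with
probability ~0.7–0.85, and the all-of-8 AND rule with probability well
under 0.1; between-subject spread in $f_{V4}$ (per-subject sd 0.255)
makes whole subjects fail for *every* gene when their post-mepolizumab
eosinophilia happens to stay high. Consequently, under the default noisy
conditions the pipeline's sensitivity is low (0.25 at the pinned
regression seed; often lower) while its false discovery rate stays at
zero — strict consensus fold-change filtering buys specificity with
sensitivity. This is a property of the published selection design itself,
worth knowing when interpreting such gene lists: with only two array
subjects, the original BAL consensus was far less punishing than an
eight-subject consensus, and genuinely low-noise platforms are required
for the depletion contrast's narrow margin. The deterministic limit
(σ = 0 and zero fraction spread) recovers the EOS program exactly, which
is the correctness statement the tests pin down; the noisy-sensitivity
behaviour is characterized, not hidden.

## qPCR quantification

Relative quantification uses the comparative threshold-cycle method:
replicate Cts are averaged per (sample, gene); $\Delta Ct$ subtracts the
reference gene (GUSB); $\Delta\Delta Ct$ subtracts the calibrator
sample's $\Delta Ct$; fold change $= 2^{-\Delta\Delta Ct}$. Conventions:

* **Efficiency** is estimated from a dilution-series standard curve as
  $E = 10^{-1/\text{slope}} - 1$ (slope in cycles per log10 unit; −3.3219
  ⇒ 100%). Curves outside the 91–96% band are flagged, not rejected.
* **Base 2 is kept even when measured efficiency is below 100%** — no
  Pfaffl-type correction — matching conventional reporting. The resulting
  bias is quantifiable (a true ratio $R$ reports as
  $R^{\ln 2/\ln(1+E)}$) and is covered by a test, not corrected.
* **Calibration is per subject** (each subject's own pre-challenge BAL
  sample), via `qpcr_relative_expression()`; whether the original
  analysis calibrated per subject or on a pooled baseline is not
  determinable from the published description, and per-subject is the
  default here.
* **Paired comparisons** use Student's paired t-test on log-transformed
  fold changes (any log base gives identical t and p). All-zero paired
  differences return t = 0, p = 1 with a warning, avoiding NaN on
  degenerate inputs.

## Problem sizes and determinism

The test suite and the reproduction script run entirely on synthetic data
and packaged text fixtures: 1000-gene studies with 8 BAL + 6 sputum
subjects for end-to-end checks, ≤50-gene matrices for the 200 randomized
brute-force oracle comparisons, 10⁴ draws for moment checks, and 10³
replicates for the type-I-error calibration — a few seconds each on one
CPU. Every stochastic result is pinned by an explicit seed; the
simulator's regression values are frozen at seed 20130702.

## Known limitations

* Symbol-level gene identity only (uppercase/trim normalization); no
  alias or ortholog resolution, so platform-specific symbols survive
  as-is.
* The simulator's independence assumptions (gene-wise noise, shared
  fraction per sample) understate the correlation of real array errors.
* The depletion branch inherits the narrow signal margin discussed above;
  users with more subjects should consider the pooled fold-change mode or
  relaxed consensus explicitly, as a stated analysis choice.
* Hierarchical clustering of the selected genes and functional-annotation
  enrichment are out of scope; gene lists are ordered alphabetically (or
  by fold change in user code), not by cluster.
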