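---
title: "Quantifying preclinical drug response and building expression-based response classifiers"
author: "PreclinRx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying preclinical drug response and building expression-based response classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PreclinRx)
```

# Scope and model systems

Patient-derived organoids (PDO) and xenografts (PDX) are the two standard
preclinical model systems for testing drug sensitivity of an individual
tumour. `PreclinRx` covers the complete quantitative chain for both: raw
assay readings to sensitivity summaries, sensitivity plus expression to
drug-response gene signatures, and signatures to a small ("mini")
expression classifier of treatment response, with resampling-based
evaluation throughout. A seeded synthetic-cohort generator stands in for
access-controlled patient data, so every stage is exercised end to end by
the test suite.

# In-vitro dose-response (PDO)

Viability screens are luminescence readouts on 384-well plates with
vehicle (DMSO) wells as the maximum-signal control and a cytotoxic
staurosporine control as the minimum. `percentInhibition()` maps a reading
linearly onto the 0–100 % inhibition scale defined by these controls;
values outside [0, 100] are deliberately retained (overshoot carries
information). Dilution series follow `serialDilutionSeries()`; the default
screen geometry is ten 1:3 steps from 60 µM (down to 3.05 nM), or from
5 µg/ml (to 0.25 ng/ml) for antibodies.

`fitFourParameterLogistic()` fits

$$y(c) = \text{bottom} + \frac{\text{top} - \text{bottom}}
        {1 + (\mathrm{IC}_{50}/c)^{\text{hill}}}$$

to replicate-mean inhibition by least squares, with the inflection
parameterised on the log10-concentration scale. Two summary statistics are
kept deliberately distinct: the **relative IC50** is the fitted inflection
(not the absolute 50 %-crossing), and **Emax** is the *observed* mean
inhibition at the top tested concentration, independent of the fit.

Numerical choices: the optimiser starts from a heuristic (bottom = min,
top = max, IC50 at the geometric mid-concentration, hill = 1) plus five
jittered restarts, keeps the best residual sum of squares, and polishes
with a gradient step. Curves with an observed response span under 10
percentage points are declared unconverged and censored `above_range` —
downstream they are categorised resistant rather than dropped, because
every screened model receives a category. A fitted inflection outside the
tested range is likewise flagged censored.

Recovery behaviour: on noise-free curves the inflection is recovered to
well under 0.1 % relative error across IC50 0.01–10 µM and hill 0.5–2.
With 5 % additive noise and two replicates the IC50 of ordinary slopes
(hill ≥ 1) is typically recovered within 25 % relative (median over
seeds), but shallow curves (hill = 0.5) spread the transition over so many
decades of concentration that the inflection is intrinsically
ill-determined at this noise level — an independent Levenberg–Marquardt
fit shows the same dispersion, so this is estimator variance, not an
optimiser artefact. Tests therefore assert the noisy-recovery bound for
hill ≥ 1 only.

Category boundaries on the micromolar scale are 0.0361 / 0.4277 / 5.0656
µM; each boundary value is assigned to the more sensitive category,
matching the one inclusively printed anchor ("≤ 0.0361"). The antibody
(cetuximab) scale uses boundaries −5.777 / −4.703 / −3.63 / −1.483 on
log10(IC50). As printed, those four values leave the interval
(−5.777, −4.703] without a class; we assign it to *moderate* (the
neighbouring class on the sensitive side) and treat the log-scale
boundaries as descriptive rather than authoritative.

# In-vivo response (PDX)

Tumour volume is computed from calliper length and width as
$V = l\,w^2/2$ (inputs are swap-normalised so $l \ge w$). The primary
endpoint is **T/C**: 100 × mean treated volume over mean control volume at
the last day present in both arms (±2-day alignment tolerance, nearest
match — the endpoint-alignment rule is our choice, as is summarising arms
by the arithmetic mean with a median option; cohorts of 5–6 animals per
arm make the mean adequate). Categories: strong ≤ 10 < moderate ≤ 25 <
minor ≤ 50 < resistant, reconciling integer-phrased boundaries with
continuous T/C. A model is a **responder** iff its category is strong or
moderate (T/C ≤ 25), the binarization used for classifier training.

In parallel, the RECIST-adapted call uses the relative tumour volume
RTV = end/start: CR at exactly 0, PR below 0.7, SD in [0.7, 1.2], PD
above 1.2 — a complete partition of [0, ∞). Arm-level RTV averages
per-animal RTVs; an arm-level CR additionally requires every end volume to
be zero. PDO/PDX sibling pairs are called concordant when their
four-level calls differ by at most one rank.

# Signature discovery

Variable-gene selection uses the quantile absolute deviation
$\mathrm{QAD} = P_{75}(|x_i - \mathrm{median}(x)|)$, computed on both raw
and log2-transformed RPKM, keeping the intersection of the two top
rankings after an expression floor (> 0.5 RPKM in more than three
samples).

Differential expression runs in four setups per drug and model system:
(a) strong+moderate vs minor+resistant, (b) strong+moderate+minor vs
resistant, (c) the 20 most vs 20 least sensitive PDX (10 vs 10 for PDO),
and (d) a per-gene regression of log2 expression on the continuous
phenotype (IC50 or T/C). Setups a–c filter at FDR ≤ 0.01 (Benjamini–
Hochberg), |log2FC| ≥ 1 (fold changes use a 0.1-RPKM pseudocount to avoid
division by zero) and an absolute RPKM group-mean difference ≥ 1; setup d
filters at FDR ≤ 0.01 and per-gene dispersion < 4. The signature is the
union across setups, intersected with a low-expression filter (≥ 1 RPKM
in ≥ 5 PDX or ≥ 3 PDO samples, mean ≥ 0.8 RPKM), with per-gene provenance
recording which setups selected it and a deterministic order (descending
best |log2FC|, ties by gene id).

Two reinterpretations were unavoidable and are worth stating plainly.
First, the default two-group statistic is a Welch t-test on log2(RPKM+1):
the original analyses used a count-model package, but count-level inference
is not reproducible from RPKM values alone, so the test is pluggable (any
`function(a, b) -> p` can be substituted) while every filter threshold is
implemented exactly. Second, "dispersion" in setup d is taken as the
per-gene RPKM variance/mean ratio. Under a log-normal expression model the
variance grows with the square of the mean, so this filter mostly excludes
high-expression genes, and setup d contributes mainly low-to-moderate
expression genes; the two-group setups carry the high expressors.

Mean-pattern matrices z-score each gene's log2 expression across samples
(or against stored reference-cohort means/sds) and summarise each
signature per sample by a trimmed mean (default trim 0.25; a plain mean at
trim 0). The PDX/PDO pair ranking score combines the pseudocounted log2
fold change *f* and the log-scale difference *d* as
$r = \mathrm{sign}(f)\sqrt{|f|\,|d|}$ when *f* and *d* agree in sign and 0
otherwise; the zero-on-discordance rule is our reading of a geometric mean
of two signed quantities (a signed-product alternative is available), and
the output is a complete descending ranking suitable as pre-ranked
enrichment input.

# The mini-classifier

Features are log2(RPKM+1) values z-scored per gene on the training cohort;
the scaler is stored with the model. Highly correlated gene pairs
(Pearson r ≥ 0.8) are pruned in two deterministic passes, dropping the
member with the lower pre-scaling mean expression — in the synthetic
generator the lower-mean partner of each planted pair is known, so the
pruning direction is testable.

The classifier is a soft-margin linear SVM minimising
$\tfrac12\lVert w\rVert^2 + \sum_i C_{class(i)} \xi_i$ with separate costs
for the resistant and responder classes (the training sets are imbalanced,
typically ~14 responders vs ~34 resistant). Costs are tuned by grid search
under a stratified bootstrap, scoring out-of-bag F1 with responder as the
positive class — response is the clinically scarce call. One set of
bootstrap draws is shared across the grid within a tuning call (a
variance-reduction choice; it also keeps the comparison between grid
points paired).

Feature ranking is an adapted SVM-RFE: per recursive step, tune the costs,
fit the SVM on stratified leave-n-out training subsets (default: leave
out 20 % of each class; the "n" is our declared default, 200 resamples at
full strength), and score each remaining gene by the mean of |w| over
resamples — the weight vector itself, not w², is the ranking basis, and
the absolute value prevents sign flips across resamples from cancelling
informative weights (a signed-mean alternative exists behind the same
interface). The bottom 10 % of features is dropped while more than 50
remain, then one at a time; elimination order is the ranking.

Feature-size selection evaluates each (cost pair, size k) candidate by
resampled F1 and sensitivity of the SVM on the top-k genes, ranks
candidates by F1, and among the top *m* picks the highest sensitivity
(ties: higher F1, smaller k, smaller costs). The default *m* is 3; the
"5fu" preset uses *m* = 11, reading the corresponding selection phrase as
"among the top eleven F1 scores" — the grammatically possible
"eleventh-highest" reading would pick a single arbitrary candidate and
contradict the stated highest-sensitivity rationale. The cost grid spans
0.001–5 per class and contains the tuned optima of both reference
classifiers (0.05/0.3 and 0.007/0.02; the 5-FU preset adds 0.007).
Decision values of exactly zero predict resistant — conservative for
treatment selection. The winning configuration is refit on the full
training cohort and stored with its scaler.

Mutation-status prediction is the comparator: a sample is called resistant
iff it carries KRAS codon 12/13 mutations (`kras_codon12_13` mode, for
cohorts genotyped only there) or KRAS/NRAS G12, G13, Q22, Q61, A146 or
BRAF V600E (`all_ras_raf` mode).

# Evaluation protocol

`confusionAndMetrics()` reports TP/FP/TN/FN with sensitivity, specificity,
balanced accuracy = (sensitivity + specificity)/2 and F1; undefined
metrics are NA, never silently zero. Repeated stratified k-fold
cross-validation (default 100 × 10-fold) refits *everything the trainer
does* — scaling, pruning, cost tuning, RFE, size selection — inside each
training fold, pools each repeat's held-out predictions into one confusion
table and averages metric values (not counts) over repeats.

External validation mimics cohort transfer: expression is
log2-transformed if needed and **z-scored within the new cohort**,
replacing the training scaler — this removes global location/scale batch
offsets by construction (a property the tests verify with a planted +2
log2 shift) and is the only batch handling in scope. RECIST-style truth
maps CR/PR to responder and PD to non-responder; SD samples are either
counted as non-responders (default — the clinical non-benefit reading) or
excluded, and both variants are reported where it matters. Strata restrict
evaluation to KRAS or all-RAS/RAF wild-type samples via the mutation
rules. Gene identifiers can be translated through a user-supplied
two-column mapping; prediction requires ≥ 80 % of model genes to map and
proceeds on the mapped subset.

# The synthetic cohort generator

The generator emulates exactly the statistical structure the analysis
assumes. Gene baselines are uniform on log2(RPKM+1) in [1, 8] with
Gaussian log-scale noise (sd 1 by default); the cohort default is 14
responders vs 34 resistant with 200 genes, 10 of them shifted by a log2
fold change of 2 in responders; 5 planted gene pairs share a latent signal
with the partner's extra noise solved so the population correlation equals
the 0.9 target and the partner's baseline set one log2 unit lower (so
pruning has a known truth); 10 % of genes are forced below 1 RPKM mean to
exercise the expression filters. Dose-response curves are 4PL with the top
asymptote chosen to pass through the requested Emax at the top
concentration; growth series are exponential with multiplicative
log-normal noise, emitted as calliper pairs under a fixed length = 1.2 ×
width convention so volumes round-trip exactly. Labels are assigned first
(class sizes exactly as configured) and molecular structure is planted
conditional on them — this way a zero-effect configuration has labels
genuinely independent of the data, the correct null for permutation and
chance-level controls. T/C values are drawn uniformly on (0, 25] for
responders and (25, 100] for resistant, consistent with the responder
binarization.

What the generator does **not** model: count-level sequencing noise
(log-normal RPKM stands in for it, which is adequate because every
downstream computation operates on log2 RPKM), tumour purity and stromal
admixture, batch structure beyond global shifts, correlated gene modules
beyond the planted pairs, and realistic linkage disequilibrium between
mutations and expression. Passing tests therefore demonstrate that the
implementation does what the methods specify under their own assumptions —
not that those methods will reach the same accuracy on real cohorts.

# Problem sizes and reproducibility

The package's own validation runs on deliberately compact designs: the
classifier recovery check uses the 14-vs-34 cohort with 25 bootstrap and
50 leave-n-out iterations and a 3 × 3 cost grid; cross-validation of the
full pipeline uses 10 × 10-fold with a further reduced in-fold search
(2 × 2 grid, 4 bootstrap, 8 ranking resamples, 30 % elimination steps);
chance-level controls use a 30-vs-30 cohort with 100 noise genes and
10 × 10-fold CV, where the cross-validated balanced accuracy of a
chance-level predictor is estimated stably. These sizes are the package's
validation choices; the full-strength defaults (100 bootstrap, 200
resamples, 13-value grid, 100 repeats) remain the function defaults for
real analyses.

Every stochastic operation takes an explicit seed and routes through one
RNG helper that restores the caller's RNG state, so identical inputs and
seeds give bit-identical outputs — the test suite asserts this for the
generator, the pipeline and cross-validation, and `runPipeline()` writes a
manifest (seeds, settings, checksums) alongside its artifacts.

# Known limitations

- The two-group statistic is a Welch t-test, not a count-model test; with
  RPKM-only input this is a deliberate substitution and the filters, not
  the test, carry the method's identity.
- The log-scale antibody category boundaries are implemented as printed
  but contain a gap; micromolar categories should be preferred where both
  apply.
- Shallow dose-response curves (hill « 1) yield wide IC50 uncertainty at
  realistic noise; Emax is the more stable summary there.
- `glmAssociation()`'s dispersion filter (variance/mean < 4 on RPKM)
  suppresses high-expression genes under log-normal noise; rely on setups
  a–c for those.
- External validation corrects only global location/scale differences (by
  per-cohort z-scoring); platform effects that reorder samples within a
  gene are out of scope.
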