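---
title: "Models and methods behind meltshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meltshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltshift)
```

meltshift re-implements, as one tested pipeline, the computational analyses
used to dissect drug resistance in melanoma cell lines from multi-layer
proteomics data: thermal proteome profiling (TPP) with melting-point shift
calling, subtractive differential (phospho)proteomics with kinase triage,
kinase-substrate and transcription-factor over-representation, zero
interaction potency (ZIP) drug-synergy scoring, and grouped gene–gene
co-expression ranking. Because the original raw mass-spectrometry data are
not reproducible at desk scale, every stage is exercised against a seeded
synthetic-data generator whose planted structure acts as ground truth. This
vignette explains each model, its assumptions, the tunable parameters, and
the design choices made where the methodology left them open.

## The melting-curve model

TPP heats aliquots of a lysate or of intact cells across a ten-temperature
gradient; soluble protein at each temperature is quantified through one
TMT10 reporter channel. Profiles are expressed relative to the lowest
temperature (`normalize_profile`), so a well-behaved melter starts at 1 and
decays towards a plateau. The fitted model is the three-parameter sigmoid

$$f(T) = \frac{1 - p}{1 + e^{-(a/T - b)}} + p,$$

where $p \in [0, 1)$ is the fraction remaining soluble at high temperature
and $a$ (°C units) and $b$ (unitless) shape the transition. The melting
point solves $f(T_m) = 1/2$ in closed form,

$$T_m = \frac{a}{\,b - \ln\!\frac{0.5}{0.5 - p}\,},$$

which reduces to $T_m = a/b$ when $p = 0$ and is undefined when
$p \ge 0.5$ (the curve never crosses one half).

Numerical choices:

* **Optimizer.** Bounded Levenberg–Marquardt least squares with
  deterministic multi-start initialization: the $T_m$ seed comes from the
  observed half-decay crossing, and nine fixed start variants perturb the
  slope parameter ($b_0 \in \{10, 6, 15\}$) and the $T_m$ seed
  ($\times\{1, 0.95, 1.05\}$). No random jitter is used, so identical
  profiles always produce identical fits — a property the peptide/protein
  mode-equivalence test relies on. Remaining starts are skipped once the
  residual is indistinguishable from measurement noise (relative SSE
  below $10^{-8}$).
* **Bounds.** $p \in [0, 0.4]$ during fitting (quality control later
  applies the stricter $p < 0.3$), $a > 0$, $b \in (0, 100]$; this keeps
  the curve physically meaningful without clipping genuinely poor fits.
* **Extrapolation guard.** A fitted $T_m$ is reported only inside
  $[T_{\min} - 5, T_{\max} + 5]$ °C; roots far outside the measured
  gradient are fit artifacts, not measurements.
* **Missing channels** are omitted from the loss (no imputation); profiles
  with fewer than 8 of 10 observed channels, or with an absent or zero
  reference channel, are flagged unusable. Flat profiles (no decay
  variance) are reported as non-melters with no fabricated parameters.
* **Levels.** The peptide-level mode fits each row as stored — the choice
  used for phospho-TPP, where aggregating sites to proteins would average
  away site-specific stability. The protein-level mode takes the
  channel-wise median of peptide profiles before fitting.

Cross-experiment normalization (`median_normalize`) corrects channel-level
systematic differences between the experiments of one run. A jointly
observed feature subset defines per-experiment median profiles; the
correction factor at each temperature is the across-experiment median of
those medians divided by the experiment's own median. Defining the target
as a median of medians (rather than a fitted value) makes identical
experiments receive exactly identity factors; the sigmoid fitted to the
target profile is returned as a QC summary. Below 50 jointly observed
features (configurable) normalization is skipped with identity factors —
a small joint subset would let a few features steer every profile.

## Melting-point shift calling

`compare_conditions` tests features between two condition sets (drug vs
vehicle within a line, or line vs line at matched treatment) across
replicate pairs. Because published TPP criteria are specified only as a
family, the hit rules are codified as explicit, configurable defaults
(`tpp_params`):

1. per-pair p-value below 0.05 for the replicate pair with the larger
   $|\Delta T_m|$ and below 0.1 for the other;
2. the same sign of $\Delta T_m$ in every pair (replicate concordance);
3. the smallest $|\Delta T_m|$ across pairs exceeding the reference-side
   replicate instability $|T_m(B,\mathrm{rep 1}) - T_m(B,\mathrm{rep 2})|$;
4. curve QC: $R^2 \ge 0.8$ on both sides, vehicle plateau $< 0.3$,
   steepest slope $\le -0.06$ /°C on both sides.

Per-pair p-values come from a robust z-score of a feature's $\Delta T_m$
against the empirical distribution of all QC-passing features in that
pair. The spread is estimated separately on each side of the median from
the 15.87/84.13 percentiles (the $\pm 1$ SD quantiles of a Gaussian), so a
heavy tail of true shifters on one side does not mask the other.
Benjamini–Hochberg adjusted p-values are reported per pair for
transparency but the hit rules use raw p-values, matching the published
criteria's structure. Every feature appears in the output with reason
codes (`NOMELT`, `R2`, `PLATEAU`, `SLOPE`, `SIGN`, `PVALUE`, `STABILITY`,
`UNPAIRED`); nothing is silently dropped. Cross-cell-line comparisons
reuse the identical machinery with cell lines as sides; the stability term
is then the reference line's replicate $\Delta T_m$. The summary
(`count_significant`) reports replicate-concordant hits per comparison, and
a union count (any pair passing p and QC) as a secondary column, since it
is not knowable whether published per-setting counts were concordant or
union counts.

Adjustment is performed within each comparison, not across layouts — each
comparison asks its own question, and pooling layouts would couple their
null distributions.

## Differential expression and subtractive kinase triage

`ttest_differential` follows the Perseus convention: Student's two-sample
equal-variance t-test on log2 intensities (Welch by option), fold change
as the linear ratio of group means with the signed convention (a ratio of
0.5 reported as −2), and regulation flags from raw p < 0.05 combined with
|fold change| ≥ 1.5. No multiple-testing correction enters the flags —
fidelity to the stated criteria wins over statistical preference — but a
BH-adjusted p is reported alongside. Features with fewer than two valid
values in a group are listed as untested with a reason, never imputed.
Phosphopeptides are pre-filtered by localization probability ≥ 0.75
(inclusive boundary); the filter refuses protein rows, which have no
localization concept.

Because the two cell lines are not isogenic, resistant-unique candidates
are isolated by set subtraction (`subtractive_unique`): regulated entries
of the sensitive line are removed from those of the resistant line within
the same treatment/direction. `intersect_settings` then intersects
resistant-unique sets across treatments, and `annotate_kinases`
cross-references the result with user-supplied kinome and druggable-kinome
GMT libraries. The shipped `kinome_example.gmt` is an illustrative
synthetic fixture, not a curated kinome — freezing a real database version
inside the package would misrepresent its provenance. The pipeline reports
both sizes of the input sets along with the difference so Venn-style
figures can be reconstructed; whether features untested in one line should
be excluded first is left to the caller, who can subset the differential
tables before extracting regulated sets.

## Over-representation

`overrepresentation` computes, per library term, the hypergeometric
upper-tail probability of the observed overlap between a query set and the
term's members, both intersected with a declared universe. The universe
defaults to what was quantified in the experiment rather than the genome,
because that is the sampling frame the query was actually drawn from. The
exact statistic used by the original kinase-substrate enrichment web tool
is not specified; the hypergeometric upper tail is this package's declared
definition, verified against exhaustive enumeration on small universes.
One engine serves both kinase-substrate queries (phosphosite sets
collapsed to one entry per substrate protein via
`phosphosite_to_substrate_query`) and TF-target queries. The
kinase-reporting filter keeps terms with raw p < 0.05 and strictly more
than 7 intersected genes. Ties in the output ranking break by
(p, −overlap, term id) so results are deterministic. Depletion testing is
out of scope: only over-representation is reported.

## ZIP synergy scoring

Dose–response matrices are converted to inhibition (1 − viability,
clipped to [0, 1] with clip flags; overgrowth wells keep weight 1 in fits
by default). Monotherapy rows are fit with a four-parameter logistic
$y(x) = y_{\min} + (y_{\max} - y_{\min})/(1 + (m/x)^\lambda)$ with
$m > 0$, $\lambda \in [0.1, 10]$, $0 \le y_{\min} \le y_{\max} \le 1$;
doses enter on the log scale internally and the zero dose anchors the
baseline rather than entering a logarithm.

The zero-interaction expectation for two inhibitions is the
multiplicative-survival null $y_1 + y_2 - y_1 y_2$. For each combination
dose the response is re-fit conditionally along each drug with the
baseline anchored at the other drug's fitted monotherapy effect (the
potency-shift construction of the ZIP framework); the fitted combination
effect is the average of the two conditional predictions, and
$\delta = \hat{y}_{\mathrm{fit}} - \hat{y}_{\mathrm{ZIP}}$. Positive
$\delta$ means synergy, negative antagonism. The summary score is the
unweighted mean of $\delta$ over all combination wells — the canonical ZIP
summary; a most-synergistic-area variant can be computed from the returned
surface. Replicates are scored individually and then summarized
(`replicate_summary`) with well-wise mean and SD; scoring before averaging
keeps replicate dispersion visible. On noiseless surfaces constructed
exactly from the null, the pipeline returns $\delta \approx 0$: the ZIP
null is a fixed point of the construction, which the test suite verifies
on random logistic surfaces.

## Grouped co-expression

`grouped_correlation` computes Pearson's r between two genes within each
sample group on the log2 scale (a `log2(x + 1)` transform is available for
raw TPM input), with two-sided p-values, BH adjustment across groups, and
ranking by (adjusted p, −r). Groups below `min_n = 10` samples are
excluded with a notice — below that, r is too unstable to rank — and
zero-variance genes flag the group rather than erroring. Adjustment spans
groups (cancer types), mirroring how the motivating analysis reports
adjusted correlations per cancer type.

## The synthetic-data generator

`sim_config` fixes every study condition; one seed determines every output
through named substreams per stage, so any stage can be regenerated
independently and byte-identically. The generator emulates:

* **TPP geometry**: ten temperatures (default 37–67 °C on the conventional
  TMT10 gradient 37, 41, 44, 47, 50, 53, 56, 59, 63, 67 — the emulated
  study names ten temperatures but not their values), two biological
  replicates, two cell lines × {vehicle, drug} × layouts. Intensities are
  sampled around the melting sigmoid scaled by a log-normal feature
  abundance with multiplicative log-normal noise (`noise_sd = 0.02`
  relative, a typical reporter-level CV). True plateaus are drawn from
  [0, 0.25] and slope parameters from [26, 40] so that planted curves pass
  the codified QC gates — the planted biology is meant to be recoverable,
  and curves that fail their own QC would conflate generator and caller
  effects. True Tm spans [42, 60] °C, inside the gradient. Shifted
  features move Tm by `shift_magnitude` under drug in both replicates,
  holding plateau and slope — the biology the concordance rule assumes —
  and optional discordant decoys flip the sign in replicate 2 to exercise
  that rule. A separate planted set carries baseline Tm offsets between
  the cell lines, giving the cross-line comparisons their own signal.
* **Expression studies**: two cell lines × four treatments (DMSO, BRAFi,
  Hsp90i, combo) × three replicates, log-normal intensities, fold-change
  effects planted per (line, treatment, direction) in disjoint
  shared / resistant-only / sensitive-only strata so that the subtractive
  structure exists by construction, plus an `n_core` resistant-only
  upregulated set shared across all three treatments (the three-way
  intersection signal). Phosphopeptide mode plants a configurable fraction
  of rows below the 0.75 localization threshold.
* **Dose matrices**: logistic monotherapies with configured EC50 and Hill
  slopes; combination wells equal the ZIP expectation plus
  `planted_delta`, with additive Gaussian viability noise (sd 0.02).
  Default EC50s sit near the top of the dose ranges so that planted
  offsets are not truncated by the [0, 1] inhibition bounds.
* **Co-expression panels**: per-group bivariate Gaussians on the log2
  scale with target correlations (exactly collinear at |r| = 1).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: peptide sequences and digestion, missing-value
mechanisms that correlate with abundance, batch effects and
label-efficiency drift between TMT channels, heteroscedastic noise at low
intensity, co-regulated feature blocks, or annotation libraries with
realistic overlap structure. Results on real data will be noisier than the
planted-recovery figures in the test suite, which quantify correctness of
the implementation, not expected field performance.

One caveat specific to first-channel normalization: dividing a sigmoid by
its value at the lowest temperature leaves the sigmoid family slightly
(the reference channel is itself below 1 for early melters), so fitted Tm
on normalized data carries a small systematic offset relative to the
generating parameters. Paired comparisons are unaffected — both sides are
distorted identically — and the oracle-equivalence tests therefore feed
the fitter raw sigmoid values where exact recovery is the property under
test.

## Problem sizes and interfaces

The test suite and acceptance script use 2,000 features for shift-recovery
and subtractive-recovery runs, 500 for the global null, 400 phosphopeptides
for the enrichment wiring, 50 random surfaces for the ZIP null, and 100
repetitions of the n = 500 co-expression panel — sizes chosen so each
property is measured with comfortable margins while a full run stays
convenient on a laptop. The package's interface is its functions together
with `scripts/acceptance.R` and `run_study`, which composes the whole
synthetic study (simulate → fit → compare → differential → subtractive →
enrichment → synergy → co-expression) into one deterministic, manifest-
carrying bundle; no separate command-line wrapper is provided, since the
intended use is programmatic.

## Known limitations

* Only the three-parameter sigmoid is supported; thermodynamic two-state
  models, spline fits and isothermal dose–response TPP are out of scope.
* The robust-z p-values are calibrated against the empirical shift
  distribution and assume most features are unshifted; runs where a large
  fraction of the proteome genuinely shifts will lose power.
* The differential stage tests features independently; no variance
  moderation across features is applied, by design fidelity to the
  emulated workflow.
* Loewe- and HSA-based synergy models are not implemented; the Bliss
  expectation exists only as the internal ZIP reference.
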