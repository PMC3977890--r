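---
title: "Validating ordinal IHC scoring: agreement, tolerance intervals and operator bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating ordinal IHC scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcval)
```

## The validation problem

Immunohistochemistry (IHC) read by eye is an ordinal qualitative assay: an
operator assigns each object — here a candidate circulating tumour cell
(CTC) on a filter spot — a staining-intensity grade on the scale
0 (negative), 1 (weak), 2 (moderate), 3 (strong).  For such an assay the
performance characteristic that matters is reproducibility, and the
dominant error source is the reader, not the chemistry.  `ihcval`
implements a validation workflow for this setting built on two
complementary statistics:

* **Cohen's kappa** measures chance-corrected categorical agreement
  between two sets of calls, but compresses all structure into one
  number.
* **β-content γ-confidence tolerance intervals (BCTI)** on the paired
  score *differences*, computed per reported category, separate the two
  components kappa mixes together: a systematic offset of the interval
  centre is *bias*, the interval width is *imprecision*.  The per-category
  plot of these intervals is the assay's *accuracy profile*.

The pairing design is a modified form of incurred sample reanalysis
(ISR): instead of one operator reading the same samples twice, two
operators each read the same samples once and their calls are substituted
into the repeat-analysis calculations.  When the same samples really are
read twice (two runs), the conventional ISR comparison applies unchanged,
with the repeat differences judged against the ±30 % total-error
benchmark used for quantitative biomarker assays.

## Data model

A scoring sheet is a CSV with columns `patient_id`, `spot_id`,
`object_id`, `operator_id`, `run_id`, `score`; one row per candidate cell
per operator per run.  Two states that look similar are kept distinct on
purpose: an **empty score** means the operator did not detect or did not
score the object, while **score 0** is a real negative call.  The binary
positive/negative evaluation needs the 0 as data; the missing state only
enters as pairing bookkeeping (and, optionally, as a negative call via
`collapse_to_binary(..., missing_as = "negative")` when detection
discrepancies should count as disagreements).

Matching of objects across operators uses the shared
(`patient_id`, `spot_id`, `object_id`) key.  Matching is treated as an
upstream problem: scanner image frames give both readers a natural common
coordinate key, and guessing an image-registration procedure inside a
statistics package would be out of place.

## Agreement: kappa and its interpretation

For a K×K contingency table of paired calls with observed agreement
Pr(a) (the diagonal mass) and chance agreement
Pr(e) = Σ_k (row_k/n)(col_k/n),

$$\kappa = \frac{\Pr(a) - \Pr(e)}{1 - \Pr(e)}.$$

`cohens_kappa()` refuses the degenerate case Pr(e) = 1 (both raters stuck
on one category) rather than returning 0/0.  Verbal interpretation uses
the Landis–Koch bands (`interpret_kappa()`), with boundaries closed on
the upper end so that 0.80 is still "substantial" and 0.81 "almost
perfect".  Kappa confidence intervals and weighted or multi-rater kappas
are deliberately out of scope: the workflow uses plain unweighted kappa
as a summary, not a significance test.

Pairs with a missing side are excluded from agreement tables by default
(`complete_only = TRUE`); the alternative keeps them as an explicit "ND"
category so that detection mismatches count as disagreement.  Both counts
are always logged in the paired object and the report — unmatched objects
are the silent data-loss channel of agreement studies.

## Tolerance intervals

For a set of n paired differences with mean m and sample standard
deviation s (n − 1 denominator), the BCTI is m ± k·s, with k the
two-sided normal-theory tolerance factor.  The default `method = "howe"`
uses Howe's closed-form approximation

$$k = z_{(1+\beta)/2}\,\sqrt{\frac{\nu\,(1 + 1/n)}{\chi^2_{1-\gamma,\nu}}},
\qquad \nu = n - 1,$$

with the lower-tail 1 − γ chi-square quantile.  A Monte-Carlo calibration
(`method = "montecarlo"`) solves, for each of many simulated normal
samples, the smallest factor whose interval reaches content β, and takes
the γ quantile of those factors; it serves as an independent oracle for
the closed form (they agree within about 1 % for n ≥ 10 at the default
levels) and as the route for coverage checks.

Parameter defaults, with reasoning:

* **β = 0.67 and 0.95**: the two content levels at which accuracy
  profiles are conventionally drawn — roughly "two thirds of repeats" and
  "19 out of 20 repeats".
* **γ = 0.90**: the confidence level is a package choice (the assay
  validation literature rarely prints it); 90 % is the conventional value
  in tolerance-interval work.  It is exposed everywhere and stamped into
  every output.
* **Difference scale**: accuracy profiles default to the *absolute* scale
  (score units), where a centre of +0.35 reads directly as "side B scores
  a third of a grade higher".  The ISR benchmark requires the *percent*
  scale, d = 100 (B − A) / pair mean, because the ±30 % acceptance bound
  is a relative criterion.  A pair of two zero scores is defined to have
  difference 0 on both scales — two negative calls are perfect agreement,
  not an indeterminate 0/0.
* **Grouping**: profile groups use the reference (side A) score by
  default; `group_by = "pair_mean"` is available since either convention
  is defensible.
* **Bias threshold 0.25 score units**: a quarter of a category is a
  conservative, interpretable default for flagging a systematic offset on
  an ordinal scale with unit steps; it is configurable and the flag is a
  result, never an error.
* **ISR rule**: at least 2/3 of percent-scale repeat differences within
  ±30 %, the conventional acceptance criterion for repeat analysis of
  ligand-binding-type quantitative assays; both numbers are arguments of
  `isr_pass_rate()`.

A caveat the package states in its own provenance output: score
differences are discrete, while the tolerance factor is normal-theory.
The interval contents are therefore approximate; this inherits the
practice of applying BCTI machinery directly to ordinal scoring data.
Degenerate difference sets (zero dispersion) return a zero-width interval
flagged `degenerate` instead of failing, and categories with fewer than
two complete pairs are reported as `insufficient` rather than silently
dropped.

## The simulator

`simulate_study()` generates two-operator studies with known structure.
Each object carries a latent true grade; an operator is a 4×4
row-stochastic confusion matrix (truth → reported score) plus a detection
probability.  Real studies have no ground truth — the latent category
exists so that the analysis pipeline can be tested against a known
generator, e.g. by checking that empirical confusion matrices recover the
generating ones.

The default design mirrors a realistic CTC reproducibility experiment:
8 patients × 4 filter spots, per-spot object counts uniform on 0..30 (the
reported range of CTC yields per ml of blood in prostate-cancer
patients), and a flat distribution over true grades.  A flat truth
distribution is a deliberate simplification: it exercises all four
categories equally, which is what a validation of the *scale* needs,
though clinical samples are usually skewed towards negatives.

Two presets encode the canonical before/after-training scenarios:

* `pre_training`: both operators carry small symmetric adjacent-category
  noise (0.05 to each neighbouring grade), and in addition operator A
  moves probability mass 0.35 from true strong (3) to reported
  moderate (2) while operator B moves the same mass from true moderate to
  reported strong — opposing pulls at the moderate/strong boundary.
* `post_training`: the same residual noise with both biases removed.

The bias mass 0.35 and noise 0.05 are package choices, fixed once: they
were picked so that the pre-training scenario lands in the "moderate"
kappa band while its binary collapse stays "almost perfect", and training
lifts intensity kappa into the "almost perfect" band — the qualitative
transition a successful reader-training programme produces.  Runs reuse
the same objects and truths with fresh operator noise, so a two-run
simulation supports conventional ISR on identical samples.

What the simulator does **not** model, and what passing tests therefore
cannot show about real data: reader correlation beyond the shared truth
(real operators disagree non-independently, e.g. on faint cells),
false-positive non-tumour objects captured by filtration, staining or
scanning batch effects, and any image-level content.  The simulator
validates the statistical machinery, not the assay.

## Workflow and determinism

`run_validation()` executes, for each run: pairing → binary and intensity
agreement (tables archived alongside the kappas) → absolute-scale
accuracy profile → bias report; and for two runs additionally the
per-operator conventional ISR on the percent scale.  `render_tables()`
writes the report as CSV plus a YAML provenance block (configuration
echo, seed, versions — no timestamps).  The whole path from seed to
rendered bytes is deterministic: the simulator seeds a private RNG stream
and restores the caller's, and rendering is a pure function of the
report, so identical configurations reproduce identical files.

The package's statistical checks run at sizes chosen to keep Monte-Carlo
error well inside the asserted bounds while remaining quick: 5 000
simulated samples for coverage checks, 50 000 samples per Monte-Carlo
factor calibration, and 5 000-object studies for confusion-matrix
recovery (per-entry standard error below 0.01).

## A worked run

```{r example}
cfg <- validation_config(simulate = list(scenario = "pre_training"),
                         seed = 42L)
report <- run_validation(cfg)
report
```

The intensity kappa sits two bands below the binary kappa, and the bias
report localises the reason: the side-B operator reads objects the
reference operator called moderate (2) about a third of a grade higher,
with the opposite sign at strong (3).  After the `post_training` preset
the same seed yields no bias flags and an intensity kappa in the "almost
perfect" band:

```{r example-post}
post <- run_validation(validation_config(
  simulate = list(scenario = "post_training"), seed = 42L))
post$agreement[, c("run", "evaluation", "kappa", "band")]
```

```{r example-plot, fig.width = 6, fig.height = 4}
plot(report$profiles$R1)
```

## Known limitations

* Normal-theory tolerance factors on discrete, bounded differences:
  contents are approximate, and extreme categories (0 and 3) can only be
  missed in one direction, which the symmetric interval ignores.
* Unweighted kappa treats a 0-vs-3 disagreement the same as 2-vs-3; the
  accuracy profile, not kappa, carries the ordinal information here.
* Pooling: differences are pooled per category across patients; with few
  objects per patient a per-patient analysis is underpowered, but strong
  patient effects would widen the pooled intervals without being
  attributed.
* The ±30 % rule and the 2/3 fraction are conventions imported from
  quantitative assay validation; on a four-point scale the percent
  difference of a single-grade disagreement depends strongly on the pair
  mean (40 % at 2 vs 3, 67 % at 1 vs 2), so the percent scale is most
  meaningful for the pooled repeat-analysis check, not per category.
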