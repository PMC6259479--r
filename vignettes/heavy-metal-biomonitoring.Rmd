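---
title: "Heavy-metal biomonitoring with phytoscreen: models, conventions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heavy-metal biomonitoring with phytoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoscreen)
library(dplyr)
```

## The study design phytoscreen models

The package targets the common biomonitoring design in which several
polluted sites (here, automobile workshops) and one control site are
sampled for soil and for the tissues (root, leaf, fruit, stem) of a
resident plant, and concentrations of a panel of metals — by default Pb,
Hg, Cd, Cu and Zn, in mg/kg dry weight — plus pH and electrical
conductivity (µS/cm) are measured. All downstream quantities are ratios or
summaries of these concentrations:

* **Contamination factor** CF = C~sample~ / C~background~ per metal, with the
  background conventionally the control-plot mean (`control_background()`);
  any user-supplied background table may be substituted.
* **Pollution load index** PLI = geometric mean of a site's CFs, computed on
  the log scale (`exp(mean(log(cf)))`) for stability; a zero CF forces
  PLI = 0 by definition.
* **Aerial portion** = leaf + fruit + stem mean concentrations;
  **translocation factor** TF = aerial / root;
  **plant/soil ratio** = mean of the four tissue means / soil mean.
* **Regulatory screening**: group means against WHO (tissue) and DPR/USEPA
  (soil) limits; verdicts are `exceeds` (mean above the upper limit),
  `below` (under the lower limit) or `within-range` (inside a ranged limit
  such as WHO's 0.05–0.5 mg/kg for Hg in plants).
* **Inference**: paired t-tests between test and control series and Pearson
  correlation between soil and tissue parameters across sites.

Assumptions worth stating: tissue and soil values entering the accumulation
metrics are *means over sites*, so the TF and ratio are ratios of means,
not means of per-site ratios; screening uses the *mean*, not the maximum,
so it answers "does the typical site exceed the limit"; and all units are
fixed per parameter (dry-weight mg/kg for metals), never stored per row.

## Conventions chosen where the field literature is loose

Several published conventions are ambiguous; phytoscreen fixes them as
follows, and these choices are deliberate package policy:

* **TF denominator is the root concentration.** Narrative definitions of
  the translocation factor sometimes say "concentration in the soil", but
  published TF tables in this literature are numerically consistent only
  with aerial/root (e.g. 128.4 / 51.4 = 2.498). phytoscreen implements
  aerial/root; the plant/soil ratio is the separate soil-denominated
  quantity.
* **Aerial portion is a sum of tissue means,** reverse-engineered exactly
  from reference tables (43.4 + 41.8 + 43.2 = 128.4), and the plant/soil
  ratio averages the four tissue means. These reconstructions are verified
  in the test suite against the bundled printed tables.
* **Sample SD (n − 1).** "Mean ± SD" summaries use the sample standard
  deviation; population SD is never used. Groups of one report SD as
  missing rather than zero.
* **Classification follows the interval table, not prose.** A PLI of 8.3
  falls in the 4.1–9.0 "Severe pollution" interval and is labelled so,
  even where a source narrative calls such a site "very severe".
* **Paired-test pairing is by site index** across matched test/control
  composites; this is a configuration choice, since published tables report
  n = 7 without stating the pairing. For per-parameter tissue tests the
  package exposes the series; it does not claim to reproduce any published
  t values (the underlying replicate data are unpublished), so the
  statistical stages are validated by oracle equivalence and null
  simulation instead (see the test suite).
* **No multiple-testing correction by default,** matching field practice;
  `soil_tissue_correlation_matrix(..., adjust = "holm")` is available.

## The Lacatusu interval scheme and its normalization

The published contamination/pollution interval table is internally
inconsistent: its first row reads "< 1" although the following rows begin
at 0.10, and consecutive bins leave gaps (0.25→0.26, 1.00→1.10, 2.0→2.1,
4.0→4.1, 9.0→9.1). Used verbatim, the bins would overlap and leak.
phytoscreen ships a normalized scheme (`lacatusu_scheme()`): the first
interval is read as [0, 0.10], each upper bound is extended to the next
interval's lower bound, the last interval is unbounded, and interior
boundaries are **closed on the right** (a value equal to an upper bound
takes the lower interval's label; a `closed-left` flag is available in
`read_scheme()`). Under this normalization every non-negative value maps
to exactly one label and the mapping is monotone in the class rank — both
are property-tested.

```{r}
sch <- lacatusu_scheme()
sch
classify_index(3.4, sch)
classify_index(7.6, sch)
```

## Numerical and reporting precision

Full precision is kept internally everywhere; rounding happens only in
report rendering (`format_mean_sd()`: 1 decimal place at ≥ 10, 2 below).
When comparing against printed tables, the test suite uses tolerances that
absorb the tables' own rounding: ±0.05 on 1-dp contamination factors,
±0.1 on PLIs recomputed from 1-dp CFs, ±0.01 on 2-dp translocation
factors (printed tables mix rounding and truncation — 2.498 may be printed
2.49). Two residual discrepancies in the bundled reference tables cannot
be closed from the printed precision alone and are left as documented
failures rather than papered over: one site's printed PLI differs by 0.108
from the value its own 1-dp CFs imply, and the Cd plant/soil ratio
reconstructs to 0.6071 where 0.605 is printed. The bundled tissue table
also contains one inverted min/max pair (control fruit Cd, 9.0 > 4.0);
`validate_records()` flags it as a warning and the loaders never silently
swap it.

Degenerate inputs are resolved, not left to chance: a paired test with
identically zero differences returns t = 0, p = 1; constant nonzero
differences return an infinite t with p = 0; correlation of a constant
series is an error; a zero CF is legal (PLI 0) but a zero or negative
background is not.

## The synthetic-data generator

`generate_study()` draws a study-shaped dataset with known ground truth.
Per metal *m* and stand:

* soil = median~m~ · enrichment~m~ · exp(σ~s~ Z), a **median-parameterized
  lognormal** — changing σ~s~ does not move the median, so enrichment
  targets stay put. Arithmetic means of such draws carry the factor
  e^(σ²/2); tests that compare arithmetic means against design medians
  apply this correction explicitly.
* tissue~t~ = soil · slope~m~ · w~t~ · exp(σ~n~ Z − σ~n~²/2), with
  **mean-one** residual noise, so the expected tissue/soil ratio is exactly
  slope~m~ · w~t~ with no correction term.

`ground_truth()` returns the implied expectations: CF = enrichment (the
control and test soils share the lognormal mean factor, which cancels),
TF = (w~leaf~ + w~fruit~ + w~stem~) / w~root~, ratio = slope.

Defaults state a definite world: 7 test sites + 1 control, 3 stands per
site; control soil medians (Pb 21.9, Hg 17.1, Cd 4.7, Cu 5.4, Zn 3.2
mg/kg) at the magnitudes of an uncontaminated rainforest soil; enrichments
(3.4, 2.2, 4.3, 10.4, 14.9) chosen so test-plot soil means resemble a
workshop survey (soil Pb ≈ 74 mg/kg); transfer slopes 0.48–0.78 matching
observed whole-plant/soil ratios; tissue partition (root 1.1, leaf 1.0,
fruit 0.95, stem 0.95) giving a ground-truth TF of 2.64; σ~s~ = 0.3 and
σ~n~ = 0.15, set once to roughly match published SD/mean ratios and
documented here as arbitrary. pH is normal (sd 0.4, clamped to [0, 14])
and EC lognormal (σ 0.25) around test/control offsets.

What the generator emulates: polluted-site enrichment over a shared
control baseline, positive soil→tissue dependence, right-skewed positive
concentrations, seeded determinism. What it does not: spatial
autocorrelation among neighbouring workshops, temporal dynamics,
detection-limit censoring, inter-metal correlation from shared sources,
and per-metal tissue-partition differences (one partition vector serves
all metals). A green parameter-recovery test therefore establishes that
the pipeline's estimators are consistent under the stated lognormal world
— not that field data meet these assumptions.

```{r}
d <- study_design(seed = 7)
rec <- generate_study(d)
summarize_concentrations(rec) |>
  filter(parameter == "Pb", medium == "soil")
ground_truth(d)
```

## The pipeline runner

`run_pipeline(config)` orchestrates all stages from a flat key=value file:
records are read (or simulated from the default design), validated
(errors stop the run before any output), summarized, turned into
contamination profiles (background = control-site soil means), the
accumulation table, the soil–tissue correlation matrix and the exceedance
report, each written as CSV next to a JSON manifest (inputs, config MD5,
seed, package and R versions, timestamp). All randomness flows through
one seed; identical config + seed gives byte-identical CSVs, which is
tested. A `FAILED` marker file is left if the run stops after output
began.

## Known limitations

* Pre-aggregated summary tables cannot feed the correlation stage (it
  needs per-site values) and fix n as given — per-tissue n in published
  tables is often ambiguous and is never inferred.
* Screening compares means only; a `within-range` verdict on a ranged
  limit is not a compliance statement.
* The indices are ratio summaries; no uptake kinetics, geo-accumulation
  index, enrichment factor or health-risk quotients are computed.
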