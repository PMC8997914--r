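---
title: "Scoring chemosensitivity assays and testing mutation-resistance association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring chemosensitivity assays and testing mutation-resistance association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csra)
```

## The assay and its score

The chemosensitivity/chemoresistance assay (CSRA) exposes primary tumour
cells on a 96-well plate to a drug at six fixed fractions of a reference
test drug concentration (TDC): 6.25, 12.5, 25, 50, 100 and 200%. The
reference TDCs for the drugs this package handles by default are
Doxorubicin 1.0, Ifosfamide (its activated 4-hydroperoxy metabolite) 3.0,
Docetaxel 11.3 and Gemcitabine 25.0, with the two clinical combinations at
the summed doses. The unit string ("mg/mL") is carried verbatim from the
assay configuration and never converted: the numbers function only as
labels for the ladder, and the printed unit is pharmacologically doubtful
(the Gemcitabine value is plausible in µg/mL), so silently "fixing" it
would be worse than passing it through opaquely.

Viability is read out by a resazurin-based fluorescence signal. Per
fraction $c$, percent inhibition is anchored by the two plate controls —
vehicle wells (untreated cells, 0% inhibition) and blank wells (medium
only, 100% inhibition):

$$I(c) = 100\,\Bigl(1 - \frac{\bar T_c - \bar B}{\bar V - \bar B}\Bigr).$$

Replicates are aggregated by arithmetic mean (the assay runs triplicates,
but any replicate count $\ge 1$ per fraction is accepted). The score is
the **sensitivity index**

$$\mathrm{SI} = 600 - \sum_{c} I(c),$$

summed over the six fractions, and the call is **sensitive** for
$\mathrm{SI} < 250$, **resistant** otherwise.

Three numerical choices here were genuinely open:

* **Clamping.** Raw inhibition can leave $[0, 100]$ — growth stimulation
  at low dose, or signal below blank. By default each $I(c)$ is clamped
  to $[0, 100]$ before summation, which keeps SI on the $[0, 600]$ scale
  the formula's construction implies; the unclamped sum is always reported
  alongside (`si_raw`) for audit, and `use_clamped = FALSE` switches the
  reported score.
* **The tie at 250.** The published rule defines sensitive as $< 250$ and
  resistant as $> 250$, leaving equality unassigned. We call
  $\mathrm{SI} = 250$ resistant: for treatment selection the conservative
  error is to withhold a drug, not to recommend an inactive one.
* **Positive controls.** Reference-sensitive cultures run on each batch
  are ordinary specimens to the scorer; `qc_positive_controls()` checks
  their calls against a user-supplied expectation table rather than
  hard-coding specimen IDs.

The scorer deliberately fits nothing: no IC50, no four-parameter logistic.
The SI is a sum of sampled inhibitions, and its useful invariants — SI is
bounded, weakly decreasing in every inhibition value, and invariant under
common rescaling of all well signals — are exactly what the test suite
checks by property testing.

## Panel filtering

Upstream variant calling and annotation are out of scope; the package
ingests an annotated variant table (simplified MAF-like TSV, or an
annotated VCF via vcfR) and restricts it to a user-supplied
apoptosis-pathway gene panel. A variant qualifies when its consequence is
protein-altering: missense, nonsense, frameshift or splice. Synonymous and
"other" classes never qualify. We deliberately do not reimplement a
database pathogenicity filter: the published analysis leaned on COSMIC
narratives with no algorithmic rule, and reproducibility without database
access matters more; `require_cosmic = TRUE` offers a crude proxy (keep
only variants with a COSMIC identifier). Gene symbols are matched
case-insensitively with no alias resolution.

The result is a binary specimen × gene matrix over the *whole* cohort —
all-zero rows are kept, so Mut− is an explicit observation, and a
specimen is Mut+ when any panel gene carries a qualifying variant.

## The association test

Per drug and stratum (UPS, SS, pooled STS) the package builds the 2×2
table of mutation status against the call and computes a one-sided Fisher
exact p-value. The kernel is the hypergeometric pmf evaluated in log space
(`lchoose`), authored here rather than delegated, because the tail
conventions are the substance of the analysis: with $X$ = resistant count
among Mut+ specimens under fixed margins, the upper tail
$P(X \ge x_\mathrm{obs})$ captures resistance *enrichment* among mutated
specimens and the lower tail *depletion*.

The published analysis says "one-sided" without fixing the side. The
default `tail = "auto"` reports the smaller tail, labelled with its
direction; both fixed tails remain available. Auto is adopted because it
reproduces the full published pooled grid (p = 0.036, 0.56, 0.24, 0.36,
0.14, 0.21 across the six drug rows — upper-tailed for the first four,
lower-tailed for the Gemcitabine rows). Note the auto rule is *not* a
two-sided test and its null rejection rate can exceed a single fixed
tail's; the acceptance suite therefore measures its empirical type-I rate
directly (see below).

Missing calls are handled by pairwise deletion: each drug's tables use
only specimens with a call for that drug, so table totals vary by drug.
Degenerate margins (no Mut+ or no Mut− specimens) return p = 1 with a
flag rather than an error. No multiplicity correction is applied across
the drug × stratum grid, matching the analysis this package reproduces; a
Benjamini–Hochberg column is available via `bh_adjust = TRUE` but off by
default.

Two follow-up tests reuse the same kernel:

* `reassignment_analysis()` — specimens whose only qualifying variants
  are annotated partial loss-of-function are moved to Mut− (default) or
  excluded. Reassignment is the default because partial function is an
  observation about the *specimen's pathway status*, not a reason to
  discard the specimen; both policies are computed in the acceptance
  script (0.0066 vs 0.0087 on the reference cohort).
* `gene_class_distribution_test()` — among mutated specimens, a 2×2 of
  histotype against TP53-vs-other-gene mutation class.

## The reference cohort

`ref_cohort()` reconstructs the 37-specimen study cohort from its
published summaries: the 11-variant panel table (10 Mut+ specimens; one
carries both an ATM and an NTRK1 variant), histotype labels, and
per-specimen calls chosen deterministically so that every stratified count
is reproduced. Two caveats are built in as data, not hidden:

* Only the 10 Mut+ specimens have published identifiers; Mut− specimens
  carry synthetic placeholder IDs (`UPS-01` …, `SS-01` …).
* The published Dox+Ifo row is internally inconsistent — its UPS and SS
  cells do not sum to its pooled STS cells. The fixture reproduces the
  pooled cells (which carry the headline p-value) and the UPS cells; the
  SS cells for that one row absorb the discrepancy.

Two further published values are *not* reproducible from the printed
counts and are treated as documented discrepancies rather than forced: the
SS Doxorubicin p-value (printed 0.38; no standard Fisher tail on the
printed SS counts gives it — upper 0.091, two-sided 0.18) and the UPS
Ifosfamide p-value (printed 0.52 where the min-tail gives 0.5257, i.e.
0.53 rounded; likely truncation).

## The synthetic generator

`gen_cohort()` draws a cohort with known ground truth, used for
round-trip and operating-characteristic tests. Its defaults *are* the
study conditions: 25 UPS + 12 SS specimens; mutation prevalence 10/37;
Mut− Doxorubicin resistance probability 14/27 with the mutation
multiplying the resistance odds by $(9/1)/(14/13) \approx 8.36$ (the
reference cohort's observed odds ratio); the other drugs resist at their
observed cohort rates, independent of mutation (0.64, 0.43, 0.68, 0.61,
0.45 for Ifo, Dox+Ifo, Doc, Gem, Doc+Gem).

The resistance *phenotype* is drawn first and dose response follows a
Hill curve per phenotype, $I(c) = I_{\max} c^h / (\mathrm{ec50}^h + c^h)$:
sensitive cultures use $I_{\max} = 100$, $\mathrm{ec50} = 12.5$ (% TDC),
$h = 2$ (noiseless SI ≈ 158); resistant cultures $I_{\max} = 40$,
$\mathrm{ec50} = 100$, $h = 1.5$ (noiseless SI ≈ 533). This puts the two
SI modes on opposite sides of the 250 threshold, emulating the strongly
bimodal SI distributions seen in real cohorts, and keeps planted truth
unambiguous — thresholding a continuous SI would make "true phenotype"
a matter of the same cut-off being tested. Well signals are vehicle mean
10 000, blank mean 500 (arbitrary fluorescence units), triplicate wells,
additive Gaussian noise (SD 150) truncated at zero because plate readers
report non-negative signals. At these settings the SI noise (a few SI
units) is far from the 150-unit gap to the threshold, so classification
error is zero in practice — which is the point: the generator validates
the pipeline's bookkeeping and statistics, not assay noise robustness.
What it does *not* emulate: inter-specimen Hill-parameter variation,
intermediate phenotypes near SI 250, spatial plate effects, or any
association between histotype and resistance. Passing round-trip tests
therefore demonstrate correctness of scoring, filtering and testing, not
that real assay data are this clean.

Everything is a deterministic function of `(config, seed)`; written
cohorts are byte-identical across runs.

## Operating characteristics checked by the suite

The acceptance tests recompute, at desk scale on one CPU:

* the published pooled p-values and prevalence from the reference cohort;
* kernel correctness: agreement with a brute-force enumeration oracle on
  1 000 random tables ($N \le 40$) and pmf normalisation over the full
  support for every margin combination up to $N = 200$;
* SI invariants under randomised inputs;
* a zero-error noiseless round trip, and the empirical type-I rate of the
  auto-tail test at $\alpha = 0.05$ over 2 000 truth-level null
  replicates (OR = 1), which stays below $0.05$ plus three Monte-Carlo
  standard errors thanks to the discreteness of the exact test at
  $n = 37$.

Problem sizes (1 000 oracle tables, 2 000 null replicates, truth-level
rather than plate-level simulation for the null) were chosen so the whole
suite runs in a few minutes while keeping Monte-Carlo error well inside
the asserted tolerances.

## Known limitations

* The SI weights all six doses equally; a culture inhibited only at high
  dose and one inhibited uniformly at moderate dose can share an SI.
* The auto-tail rule is data-dependent; confirmatory use should fix the
  tail a priori (both fixed tails are exposed).
* Panel membership is a user input; the package ships only the minimal
  six-gene panel needed for the reference analysis, not a full
  apoptosis-pathway list.
* VCF ingestion reads the first ANN/CSQ annotation block per record and
  does not re-normalise indels; heavily multi-allelic records should be
  split upstream.
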