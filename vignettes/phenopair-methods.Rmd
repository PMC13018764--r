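---
title: "Comparing parent- and clinician-reported phenotype sets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing parent- and clinician-reported phenotype sets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenopair)
```

## The problem

Deep-phenotyping cohorts of children with monogenic neurodevelopmental
disorders increasingly collect phenotype data from two parallel sources:
structured parent questionnaires curated into Human Phenotype Ontology
(HPO) terms (parent-reported data, PRD) and clinician proformas
(clinician-reported data, CRD). The two sources disagree in
characteristic ways — parents volunteer common childhood phenotypes such
as asthma or dental caries, clinicians contribute specialised descriptors
such as seizure semiology — and quantifying that disagreement per
participant matters for anyone deciding which source to trust for what.

phenopair implements the per-participant comparison machinery: three
scores (quantity, detail, semantic similarity), paired categorical tests,
descendant-closure phenotype queries, comparison against a
gene-to-phenotype (G2P) reference, and a synthetic cohort generator that
makes every stage testable without access to any real cohort.

## Scores

**Quantity** is the number of distinct HPO terms a source provided for a
participant in a scope (one body system, or "combined" across systems).
Within-source duplicates are collapsed first.

**Detail** credits the source holding the more *specific* term. For every
PRD x CRD term pair where one term is a proper ancestor of the other, the
source holding the descendant gains the minimum number of `is_a` edges
separating the pair (minimum over multiple-parentage paths — the
conservative reading). Unrelated pairs and identical terms contribute
nothing. All qualifying pairs accumulate; a `best_pair_only` flag caps
each term at its largest single increment for sensitivity analysis. One
consequence worth knowing: if both sources report the *same* set and that
set contains an ancestor-descendant pair, both totals rise by the same
amount — the scores stay balanced (category "Equal"), but they are not
zero. The zero-on-identical property holds exactly for antichain sets.

**Similarity** uses Lin's information-theoretic term similarity,
`2 IC(MICA) / (IC(a) + IC(b))`, where the most informative common
ancestor search includes the two terms themselves, so identical terms
score exactly 1 and terms whose only shared ancestor is the root score 0.
Term sets are combined by the symmetric best-match average (each term's
best partner in the opposite set, averaged, in both directions, then
averaged) — the common default of ontology-similarity toolkits; the exact
set combination used by upstream R packages is not documented, so this is
an explicit assumption of the package.

### Information content

Two IC estimators are provided. The default is *intrinsic* IC,
`-log(n_desc(t) / n_desc(root))`: it needs no annotation corpus and is
stable on small cohorts. *Corpus* IC (annotation counts propagated to
ancestors, `-log(freq(t)/freq(root))`) is available for sensitivity
analysis; terms never annotated get infinite IC there, and any similarity
involving an infinite-IC term is defined as 0 (identical terms still 1).
Natural log throughout; Lin similarity is a ratio, so the base cancels.

## Statistics

Per scope, participants are cross-classified as "Parent more", "Doctor
more" or "Equal" by strict inequality on quantity or detail. McNemar's
chi-square on the two discordant counts tests for a systematic direction;
"Equal" participants drop out of the test by construction. The continuity
correction is on by default (matching `stats::mcnemar.test`, including
its clamping of the corrected difference at zero); raw p values are
adjusted by Benjamini-Hochberg within one family per analysis block
(systems; gene groups; genes) — never pooled across blocks.

For the G2P comparison, per-participant best-match similarities of the
PRD, CRD and combined (plain-union) sets against a gene's reference list
are compared by Welch's heteroscedastic one-way ANOVA; when the global
test is significant at 0.05 (configurable), all pairwise Welch t tests
follow with Holm adjustment. Tests are two-sided throughout. A caveat
operationalised in the test suite: best-match similarity against a
*larger* reference list is never expected to decrease, so reference-list
size must be kept in mind when comparing genes.

## Pairing rules

Participants with data from only one source are excluded per scope. For a
single system this is unambiguous. For the combined scope the default is
the strict rule — both sources present in *every* system where either
reported anything — with a lenient alternative (both sources present
anywhere). On real data the two rules differ modestly; on synthetic data
they differ enormously, see below.

## The synthetic cohort generator

`simulate_cohort()` states a world with the qualitative structure the
analysis assumes: per participant, a causal gene is drawn; the latent
phenotype set is a random subset (inclusion probability 0.8) of the
gene's profile pool; each source detects each latent term independently
with a per-system probability; a detected term is reported exactly with
the source's *specificity*, otherwise replaced by an ancestor `k` levels
up (`k = 1 + Geometric(0.5)`, truncated at the body-system branch head);
and a Poisson number of unrelated common-childhood-phenotype terms is
appended per source.

Default parameters encode the reporting asymmetries seen in real paired
cohorts: CRD specificity 0.9 vs PRD 0.6 (clinicians report more
precisely), PRD detection 0.85 vs CRD 0.5 in dental, gastroenterology,
immunology and respiratory (parents report more there), CRD 0.85 vs PRD
0.6 in neurology, and noise rates 1.0 (PRD) vs 0.3 (CRD). These were
chosen once as plausible magnitudes and are not fitted to any dataset.

Profile pools contain only *leaf* terms of the bundled mini-ontology:
latent phenotypes are maximally specific, and sources can only coarsen
them. This keeps the blur model interpretable (with one-sided blurring,
only the exact-reporting source can ever earn detail credit).

Two deliberate departures from realism: systems are drawn independently
per participant, and the mini-ontology is ~47 terms rather than ~19,000.
The independence artifact means the strict combined pairing rule —
requiring both sources in every active system — excludes almost everyone
(probability about 0.5 per active system, compounded), which is why
`recovery_experiment()` defaults to the lenient rule. A green recovery
test therefore establishes that the pipeline detects planted asymmetries
of stated size at stated n; it does not establish anything about
real-cohort effect sizes, which come from a far deeper ontology and
correlated reporting.

## Numerical and degenerate-input choices

* Ties in any score comparison are "Equal" (strict inequality defines the
  directional categories).
* Similarity of two identical sets is exactly 1 by construction, not by
  tolerance; computed values are clamped to [0, 1] against floating-point
  overshoot.
* Either term set empty: similarity is `NA` and the participant is
  excluded by pairing; zero discordant pairs: the McNemar test for that
  scope is reported as `NA` rather than failing the family.
* Welch tests refuse groups with fewer than two observations or zero
  variance, naming the group.
* Obsolete ontology terms are kept only in a replacement map; alternate
  ids resolve to their primary term; unresolvable ids are dropped with
  counts in the load report (or fail the load, per `on_unknown`).
* Term frequency counts participants, not records: a term reported by
  both sources counts once in the combined tabulation.
* "Child code" in phenotype queries means any proper descendant at any
  depth, since clinically meaningful subtypes sit several levels down.

## Calibration and what the tests establish

The acceptance suite verifies, among other things, that the null
generator (both sources statistically identical) yields a McNemar
rejection rate of 5% +/- 2% over 2000 replicate cohorts. That check runs
the *uncorrected* chi-square: the continuity-corrected variant is
deliberately conservative (measured ~4-4.5% at ~100 discordant pairs) and
remains the user-facing default; the calibration validates the nominal
chi-square approximation itself.

## Known limitations

* Only `is_a` edges build the graph; other OBO relationship types and
  OWL semantics are out of scope.
* Body-system labels are data (the survey's binning), not inferred from
  the ontology; no term-to-system mapping is computed for user cohorts.
* The set-similarity combination (symmetric best-match average) is an
  assumption; figures-style visualisation is out of scope.
* Corpus IC on small cohorts is unstable — that is precisely why
  intrinsic IC is the default.
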