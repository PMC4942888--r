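---
title: "Detecting cognitive conflicts in repertory grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cognitive conflicts in repertory grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridconflict)
```

## The data: a repertory grid

The repertory grid technique elicits, in a semi-structured interview, a
person's own bipolar constructs ("shy–sociable", "generous–selfish") and
has them rate a roster of significant people — the *elements* — on every
construct, on a 7-point Likert scale. The roster always includes the
current self ("self now") and the ideal self ("the way I would like to
be"). The result is a C×E integer matrix: rows are constructs, columns
elements. `gridconflict` consumes such matrices, either built in code
with `repgrid()` or read from a small delimited text format with
`read_grid()`.

```{r}
g <- example_grid()
g
```

The scale is configurable but must be symmetric: the analysis hinges on
the scale midpoint (4 on a 1–7 scale), and a midpoint that is not an
attainable rating would make the dilemmatic rule vacuous. Grids with
missing cells are rejected rather than imputed; the downstream
procedure assumes a complete matrix, and silent imputation would
manufacture conflict structure that the person never expressed.

## Construct classification

Each construct is classified from the self and ideal ratings alone:

* **dilemmatic** — the ideal self is rated exactly at the midpoint.
  Neither pole is preferable; the construct offers no clear course of
  action. This rule is checked first and takes precedence.
* **congruent** — self and ideal are rated similarly
  (gap `|self − ideal| ≤ 1` by default): the person does not wish to
  change here.
* **discrepant** — self and ideal sit at opposite poles
  (gap `≥ 4` by default): a desired change.
* **neutral** — anything in between (gap 2–3). Neutral constructs take
  no part in dilemma detection.

The verbal definitions behind "similarly" and "opposite poles" do not
come with numbers attached, so the gap bands are this package's
operationalization, chosen as the simplest faithful reading of a 1–7
scale: a gap of 4 or more forces self and ideal onto opposite sides of
the midpoint, and a gap of at most 1 is the tightest notion of
"similar" that still tolerates one scale point of noise. Both bands are
exposed in `detection_parameters()` so a user can explore other
readings; the defaults are used everywhere in this package.

## Implicative dilemmas

An implicative dilemma is a congruent–discrepant construct pair whose
ratings co-vary so strongly that the desired change (on the discrepant
construct) implies an undesired change (on the congruent one): "if I
became happy, I would become selfish". The rule: the pair is flagged
when the **oriented correlation** strictly exceeds 0.35.

`oriented_correlation()` computes a plain Pearson product–moment
correlation between the two construct rows, after fixing each row's
direction so the sign of *r* carries the dilemma's meaning:

* the congruent construct is oriented with the **ideal element's pole**
  at the low end of the scale (the desired pole, which the self
  shares);
* the discrepant construct is oriented with the **self element's
  pole** (the present/symptom pole) at the low end.

A row is oriented by reflection about the scale midpoint
(`x → min + max − x`) when its reference rating lies above the
midpoint. The reference choices guarantee a defined orientation in
every reachable case: a congruent construct's ideal can never sit at
the midpoint (it would be dilemmatic instead), and a discrepant
construct's self cannot sit at the midpoint on a 1–7 scale (the gap
would be at most 3). Orientation makes the whole analysis invariant
under construct reflection — a grid and its reflection describe the
same person, and the test suite asserts this invariance on hundreds of
randomized grids.

Two decisions here were genuinely open:

* **Element set.** Whether the correlation should run over all elements
  or exclude self and ideal is not fixed by the tradition this
  procedure comes from. The default includes all elements — the whole
  score matrix is what is "subjected to statistical analysis" — and
  `detection_parameters(include_self_ideal = FALSE)` switches to
  others-only, so the ambiguity is explorable rather than buried.
* **Strictness.** The threshold comparison is strict (`r > 0.35`, not
  `≥`), matching the rule's usual statement. `bracket_threshold()`
  makes this testable: it searches integer rating rows for a pair whose
  correlation is *exactly* 7/20 — exactness proved by the integer
  identity `400·cov²ₙ = 49·v₁·v₂`, no floating point involved — and
  confirms the detector leaves it unflagged.

Pairs with zero rating variance have no defined correlation; they are
skipped with a warning rather than treated as r = 0, because a silent
zero would mask a degenerate grid.

Detected dilemmas are returned sorted by descending correlation with
index-pair tie-breaks, so reports and JSON exports are diffable.

## Prototypical figures

For each dilemma the significant others split into the "two kinds of
people" the dilemma describes: those rated on the congruent construct's
self pole *and* the discrepant construct's present pole (the current
position — "generous but depressed"), and those on the undesired and
desired poles respectively (the implication of change — "happy but
selfish"). Membership requires the rating to sit strictly off the
midpoint by at least `pole_membership_margin` (default 1 point);
midpoint ratings belong to neither side, and self and ideal are never
listed.

For a dilemmatic construct the prototypes are the others rated at each
pole with the most extreme score the person actually used on that side
— the used range, not the theoretical 1/7 — with ties kept.

## Summary indices

Four grid-level indices accompany the conflict analysis. The tradition
names these indices without publishing formulas, so the definitions
below are this package's own operationalizations — deliberately the
simplest defensible ones, and **not** certified equivalents of any
legacy grid program's internals:

* **self-ideal discrepancy** — mean `|self − ideal|` over constructs,
  divided by the scale span; in [0, 1].
* **self-perceived social isolation** — mean normalized city-block
  distance between the self column and each other's column; in [0, 1].
* **perceived adequacy of others** — one minus the mean normalized
  city-block distance between the ideal column and each other's
  column, so higher = others seen closer to the ideal; in [0, 1].
* **polarization** — percentage of all ratings at either scale
  extreme; in [0, 100].

City-block distance was preferred over Euclidean because ratings are
ordinal Likert steps: a two-point disagreement on one construct and
one-point disagreements on two constructs are treated as the same
amount of difference. Each index is a small pure function, so an
alternative definition can be added without touching the API.

## Pre/post comparison

Dilemmas resolve through two pathways: the self moves towards the ideal
(the discrepant construct stops being discrepant), or the association
between the two constructs weakens below threshold.
`compare_pre_post()` takes two grids with identical constructs (matched
by index, verbatim pole-label equality — fuzzy label matching would be
guesswork) and reports, per pre-grid dilemma, the change in self-ideal
discrepancy, the change in the pair's oriented correlation, and whether
the pair is still flagged. The post correlation is computed with the
post grid's own orientation anchors; if a pair's classification breaks
in the post grid the correlation is still reported (the association may
persist even when eligibility ends).

## The synthetic generator

`generate_grid()` exists so every detector and index is testable
without patient data. A pair plant draws the two rows over the other
elements from a shared latent factor mixed with independent noise
(`z₂ = r·z₁ + √(1−r²)·ε`), maps latent values to ratings by
`round(midpoint + (span/4)·z)` with clamping to the scale, and sets the
self/ideal cells from the plant (defaults: congruent 2/1, discrepant
2/7). Discretization attenuates the latent correlation, so the
generator reports the *realized* correlation of the discretized rows
per grid; tests assert against realized values, never against the
target. Plant specs verify their classification intent at construction
time — a plant that would not classify as intended is a hard error, not
a silently misleading fixture.

What the generator emulates: controlled inter-construct correlation,
designated self/ideal elements with controlled gaps, a realistic roster
size (default 12 significant others, in the 10–15 range typical of
clinical grids). What it does not emulate: the lumpy, skewed rating
distributions of real patients, construct elicitation effects,
rater-specific response styles, or the empirical prevalence of dilemmas
in clinical versus control samples. Passing tests therefore demonstrate
that the *procedure* behaves as specified on grids with known planted
structure — they say nothing about prevalence in any population.

Determinism: one integer seed per spec; replicate streams in
`null_detection_rate()` use `seed + i`, a documented counter scheme, so
runs are reproducible and extensible. The generator saves and restores
the caller's RNG state.

## Numerical choices

* Correlations are computed from exact integer sums (ratings are small
  integers, so all accumulations are exact in double precision; one
  correctly-rounded square root and one division remain). This makes
  every correlation bit-reproducible across element orderings — which
  is why permutation invariance holds *exactly* in the tests — and
  makes behavior at the decision boundary deterministic.
* `bracket_threshold()` rationalizes the threshold (denominators up to
  1000), hill-climbs an integer objective to find an exactly-at-threshold
  pair, and returns the supremum of unflagged correlations found. On
  the default parameters it returns exactly 0.35.
* Degenerate inputs: zero-variance rows give NA-plus-warning;
  out-of-range or missing ratings are rejected at validation with
  cell-accurate diagnostics; asymmetric scales are rejected at
  construction.
* Output ordering is deterministic everywhere (descending r with index
  tie-breaks; ascending indices for dilemmatic constructs).

## Problem sizes used by the test suite

The shipped tests run on sizes chosen to exercise the mathematics
rather than to mimic a clinic: random grids up to 12 elements × 10
constructs (1,000 replicates for the correlation-oracle comparison, 500
for the invariance suite), recovery curves at 15 total elements with
200 replicates per planted correlation in {0, 0.2, 0.4, 0.6, 0.8,
0.95}, and a 2,000-replicate null-rate comparison against an
independent Monte-Carlo sampler. The recovery regression bound (≥ 95 %
detection at latent r = 0.9 with 30 others) was calibrated once with a
pilot run of the implemented pipeline and then frozen.

## Known limitations

* The index formulas are this package's operationalizations of named
  measures; comparisons with numbers produced by legacy grid software
  are qualitative, not exact.
* Only the four indices above are provided; the broader battery of
  grid measures (intensity/PVEFF, cognitive differentiation, triadic
  conflict metrics) is out of scope.
* Grids must be complete; there is no imputation.
* No significance testing of correlations is performed: the 0.35 rule
  is a fixed operational criterion, not an inferential test, and at
  small element counts the sample correlation is noisy — the recovery
  and null-rate curves quantify exactly how noisy.
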