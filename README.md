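# gridconflict

Cognitive-conflict assessment for repertory grids from personal
construct psychology.

Practitioners and researchers working with the repertory grid technique
rate a roster of significant people (the *elements*, always including
the current self and the ideal self) on the interviewee's own bipolar
constructs (e.g. "generous–selfish"), on a 7-point Likert scale.
`gridconflict` analyses the resulting C×E rating matrix for the
conflict structures that matter in case formulation:

* **Construct classification.** From the self and ideal ratings of each
  construct: *congruent* (gap |self − ideal| ≤ 1, no change wished),
  *discrepant* (gap ≥ 4, change wished), *dilemmatic* (ideal at the
  scale midpoint — neither pole is a clear course of action), else
  *neutral*.
* **Implicative dilemmas.** A congruent–discrepant pair is flagged
  whenever the oriented Pearson correlation between the two rating
  rows strictly exceeds 0.35 — the desired change on the discrepant
  construct ("depressed → happy") is associated with an undesired
  change on a construct the person does not want to move on
  ("generous → selfish"). Rows are oriented so the congruent
  construct's desired pole and the discrepant construct's present pole
  sit at the low end of the scale, which is what gives the sign of *r*
  its meaning.
* **Prototypical figures.** For each dilemma, the "two kinds of
  people" among the significant others: those exemplifying the current
  position and those exemplifying what change would imply.
* **Grid indices.** Self-ideal discrepancy, self-perceived social
  isolation, perceived adequacy of others (normalized city-block
  distances) and polarization (percentage of extreme ratings).
* **Pre/post comparison** along the two dilemma-resolution pathways:
  reduced self-ideal discrepancy, or weakened pair association.
* **Synthetic grids** with planted conflict structure and controlled
  latent correlation, for method evaluation without patient data.

## Worked example

```r
library(gridconflict)
g <- example_grid()
g
#> <repgrid: 2 constructs x 5 elements, scale 1-7>
#>                    Self* Ideal** Mother Father Friend
#> generous - selfish     2       1      2      6      5
#> depressed - happy      2       7      1      6      6
#> (* self, ** ideal)

detect_implicative_dilemmas(g)
#>   congruent_index discrepant_index oriented_r self_pole_congruent
#> 1               1                2  0.3670524            generous
#>   undesired_pole_congruent present_pole_discrepant desired_pole_discrepant
#> 1                  selfish               depressed                   happy
```

The person sees herself as generous (self 2, ideal 1: congruent — she
wants to stay that way) and as depressed while wanting to be happy
(self 2, ideal 7: discrepant). The two rating rows correlate at
r = 0.367 > 0.35 in the dilemma orientation, so the desired change is
entangled with an undesired one: becoming happy reads as becoming
selfish. The prototypical figures make the two positions concrete —
`find_prototypical_figures()` returns Mother (rated 2, 1: generous and
depressed, the current position) against Father and Friend (rated 6, 6
and 5, 6: happy but selfish, the implication of change). The summary
indices for this grid: self-ideal discrepancy 0.50, self isolation
0.44, adequacy of others 0.50, polarization 30 %.

`analyze_grid()` runs the whole pipeline; `write_results()` exports it
as schema-validated JSON and `render_report()` as a plain-text case
report. Grid files use a small documented text dialect
(`read_grid()` / `write_grid()`; see `inst/extdata/example_grid.tsv`).
A command-line interface wrapping these functions is installed at
`system.file("cli", "gridconflict", package = "gridconflict")` with
`analyze`, `simulate` and `report` subcommands.

## Scope

The package consumes already-elicited grids; construct elicitation,
rating collection and any therapeutic protocol built on top of the
assessment are out of scope, as are importers for legacy grid-program
file formats and grid measures beyond the four indices named above.
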