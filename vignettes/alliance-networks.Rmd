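---
title: "Quantifying multi-level alliances from group-composition surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multi-level alliances from group-composition surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alliancenet)
```

## The problem

Male Indo-Pacific bottlenose dolphins in some populations cooperate at three
nested levels: first-order alliances (pairs or trios that jointly consort a
female), second-order alliances (stable teams of roughly 4--14 males, the
core social unit), and third-order alliances (cooperative relationships
between two second-order alliances). The raw evidence for this structure is
a pile of *surveys* -- timestamped snapshots of group composition with a
predominant activity -- plus video-coded behavioral records taken when
groups of different alliances fuse. `alliancenet` turns those inputs into
the quantities used to describe such societies: dyadic half-weight
association indices, community assignments with fit diagnostics,
within/between-alliance strength metrics, temporal snapshots, and
unique-pair tallies of affiliative behavior, with inter-coder reliability.

## Association: the half-weight index

For a dyad $(A, B)$ the half-weight index is

$$\mathrm{HWI} = \frac{x}{x + y_{AB} + \tfrac{1}{2}(y_A + y_B)}$$

where $x$ counts sampling periods with both individuals in the same group,
$y_{AB}$ periods where both were seen but apart, and $y_A, y_B$ periods
where only one was seen. The index lies in $[0, 1]$ and corrects for the
chance of sighting one but not both members of a dyad, which keeps it
comparable across individuals with different sighting effort.

One survey is treated as one sampling period. Because same-day resights of
the same group are excluded upstream and a survey records a single group,
$y_{AB}$ is identically zero and the index reduces to $2x/(n_A + n_B)$.
The $y_{AB}$ term is nevertheless kept as an explicit component of
`count_sightings()` so that day-based sampling periods can be configured
later without touching the index code.

Filtering defaults (`survey_filter_config()`) restrict association data to
surveys whose predominant activity is resting, travelling or socialising
(co-occurrence at a shared food patch is not association), to the
August--December window where mating and field seasons overlap, and drop
same-day resights and flagged inter-group conflicts. The operational
definition of a "same-day resight" is not fully standardised in the
literature we follow; here a later survey on the same date counts as a
resight when its Jaccard membership overlap with an earlier retained survey
exceeds a configurable threshold (default 0.5). The rule never removes the
first survey of a date, and filtering is idempotent.

## Community detection and its diagnostics

Alliance membership is confirmed, not assumed: `average_linkage()` runs
agglomerative clustering directly on the similarity (HWI) scale, merging at
each step the two clusters with maximal average pairwise HWI. Average
linkage is reducible, so merge heights are monotone non-increasing. Ties
are broken deterministically (the pair whose lexicographically smallest
member id sorts first), so results are identical across platforms. The
dendrogram is equivalent to UPGMA on the distance $1 - \mathrm{HWI}$, which
the test suite uses as an independent oracle.

Two diagnostics decide whether and where to cut the tree:

* **Cophenetic correlation (CCC)** -- the Pearson correlation between the
  dyadic HWI values and the height at which each dyad is joined. It is
  computed on the similarity scale directly (so reported values are
  positive when the tree fits), and values above 0.8 are taken, by
  convention, to mean the hierarchical model represents the network well.
* **Modularity (Q)** -- for each candidate cut,
  $Q = \sum_c \left[ W_c/W - (S_c/2W)^2 \right]$ on the HWI-weighted
  complete graph, where $W$ is total edge weight, $W_c$ within-cluster
  weight and $S_c$ summed node strength. Zero dyads contribute nothing. A
  single cluster gives $Q = 0$. An `"unweighted"` variant evaluates the
  same formula on the binarised graph, since association software differs
  in which null model it uses; the weighted form is the default.

`best_partition()` cuts just below every distinct merge height (plus the
all-singleton cut), evaluates Q at each induced partition, and returns the
maximiser. A cut at level $h$ groups all pairs joined at height $\geq h$.
Because "the HWI level of a cut" is quoted in two conventions -- the merge
height itself or the midpoint between adjacent heights -- both are
reported (`cut_at_qmax`, `cut_midpoint`). Ties in Q resolve towards the
higher cut level. Degenerate inputs are reported rather than guessed at: an
all-zero matrix has undefined Q, and a zero-variance dyad vector (including
the 2-individual case) has undefined CCC.

## Strength within and between alliances

`strength_table()` computes, per individual, `wStrength` (summed HWI to
own-alliance members) and `bStrength` (summed HWI to members of third-order
partner alliances). Raw strength scales with alliance size, so each measure
is normalised by the maximum of that measure *within the individual's own
second-order alliance*; `wStrength_N` and `bStrength_N` then lie in
$[0, 1]$ with exactly one individual per alliance at 1, barring ties. The
normalisation group was a genuine design choice: normalising over the whole
network is also defensible and is available via
`normalization = "network"`, but the within-alliance reading matches how
the metric is used to compare males *to other members of their alliance*.
When an alliance has several third-order partners, `bStrength` defaults to
the union of all partner alliances and a per-partner breakdown is attached
as an attribute, since either framing may be wanted. An alliance with no
partner in a period has `bStrength = 0` and an undefined (`NA`)
`bStrength_N`, with a warning rather than a silent 0/0.

`temporal_snapshots()` recomputes the entire chain (HWI, diagnostics,
strengths) over discrete multi-year windows with per-period rosters, the
standard way of tracking network change when membership turns over through
mortality. A period in which fewer than two rostered individuals are
sighted is skipped with a warning.

## Fusion-event behavior coding

During inter-alliance fusions, affiliative records are coded as petting
(`PET`), rubbing (`RUB`), touching distance without discernible contact
(`D0`), and synchronous surfacing (`SYNCH`, two or three actors).
`tally_event()` reduces records to *unique pairs per event and category*:
"PR pairs" have at least one petting/rubbing record, "PR + D0" additionally
admits `D0`, and a 3-actor synch contributes its three constituent pairs
(the published pair counts are defined over synchs of two *or three*
males; an option disables the decomposition). Pairs are classified
second-order / third-order / non-allied against the registry.
`summarize_tallies()` reports both per-event column totals and cross-event
deduplicated unique-pair counts. The two framings genuinely differ --
published text totals sometimes mix them -- so both are emitted rather
than reconciled. Aggression and consort-directed behaviors are validated
and carried through but not tallied into the affiliative categories.

Coder reliability uses Cohen's kappa,
$\kappa = (p_o - p_e)/(1 - p_e)$; with more than two coders the unweighted
mean of pairwise kappas is reported, the simplest convention when no
coder is privileged. The degenerate case $p_e = 1$ (a single label used
throughout, in full agreement) is reported as $\kappa = 1$ with a warning.

## The permutation null

Preferential association is tested by comparing the coefficient of
variation of the off-diagonal HWI values against a null generated by
sequential 2x2 checkerboard swaps of the individual-by-survey incidence
matrix. Every swap preserves each survey's group size and each
individual's sighting count, the standard degree-preserving null for group
data. Defaults are 1000 burn-in swap attempts and 100 attempts between
samples; data admitting no valid swap (e.g. identical membership in every
survey) raise an error naming the condition. One-sided and doubled
two-sided p-values are reported with the $+1$ correction. The group-swap
variant is implemented; data-stream designs differ mainly in what is held
fixed, and the statistic (`cv_hwi`, `mean_hwi`, `sd_hwi`) is selectable.

## What the synthetic society emulates

`society_config()` plants a known three-level society so every stage is
testable without field data. First-order units are the behavioral atoms:
each survey is seeded by one unit (members join with cohesion probability
0.95), every other unit of the same alliance joins independently with
probability `p2 = 0.35`, and for each third-order pair involving the
seed's alliance one partner-alliance unit joins with probability
`p3 = 0.12`, chosen with weight `bridge_bias = 3` for that alliance's
designated bridge unit. Letting same-alliance units join *independently*
(rather than attaching at most one) is deliberate: fission--fusion groups
frequently contain several units of an alliance, and it is what gives
cross-unit within-alliance HWI values around 0.4 -- the regime in which a
modularity-maximised cut separates second-order alliances rather than
first-order units, as observed in real societies. `p3 = 0.12` mirrors the
order of magnitude of the fraction of field surveys that capture
third-order associations. The presets `"T1"` and `"T3"` reproduce the
*structure* of the studied society (alliances of 12/7/5 and 10/5/5 males
built from pairs/trios; one vs two third-order pairs) with synthetic ids;
no field parameter values are claimed.

`expected_hwi()` gives the closed-form expectation of the index per dyad
class under this model (combining per-survey presence probabilities as
$2E[x]/(E[n_A]+E[n_B])$, a consistent large-sample approximation), and is
the oracle against which Monte-Carlo output is checked. The generator does
not emulate: spatial structure or ranging, observation effort bias,
female/consort dynamics, gregariousness differences between individuals of
the same class, or demographic turnover beyond scripted mortality dates.
Passing the planted-recovery tests therefore shows the pipeline is correct
under the stated grouping model, not that real data will be as clean;
field matrices have more heterogeneous within-alliance structure and much
sparser between-alliance sampling.

`generate_fusion_log()` similarly plants fusion events (one unit per side
of a third-order pair, bridge-weighted) whose per-pair behavior records are
emitted independently at configurable rates, and records its own true
unique-pair tally by direct set construction so the coding module can be
checked against it exactly.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds; no global RNG state
leaks (the previous state is restored on exit). The test suite runs the
planted-recovery and bridge-detection checks over 20 seeds of 2000 surveys
each, the closed-form-vs-Monte-Carlo check at 20,000 surveys, and the
permutation type-I calibration over 200 null societies with 100 null
samples each -- sizes chosen to give stable pass/fail behavior at around a
minute of total runtime. Re-running any pipeline stage with the same
configuration and seed reproduces byte-identical outputs.

This package is a library plus scripts rather than a shell tool:
`alliance_report()` chains filter, association, clustering, strength and
snapshots end-to-end and writes CSV/JSON/GraphML/newick artifacts, which
is the intended batch entry point.

## Known limitations

* The published supplementary HWI matrices are not redistributable here;
  the checks that reproduce the published diagnostics (pooled
  $Q$, CCC, and the per-period values) run only after those tables are
  transcribed into `inst/extdata/supplementary/` (see `?supplementary_dir`).
* Gregariousness-corrected modularity variants beyond the
  weighted/unweighted switch are not implemented.
* The permutation null mixes by sequential swaps from the observed matrix;
  for very sparse incidence matrices mixing can be slow and the defaults
  should be raised.
* Lagged association rates, other association indices (simple ratio,
  twice-weight) and network bootstrap confidence are out of scope.
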