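# alliancenet

Tools for quantifying **multi-level male alliances** in fission–fusion
animal societies — the kind of social system found in Indo-Pacific
bottlenose dolphins, where pairs/trios of males (first-order alliances)
nest inside stable teams of 4–14 males (second-order alliances), some of
which maintain cooperative relationships with another team (third-order
alliances). The package takes the field's raw inputs — group-composition
surveys, an alliance registry, and video-coded behavior logs from
inter-alliance fusion events — and produces the standard quantitative
description of such a society.

## What it computes

* **Half-weight association index (HWI)** per dyad:
  `HWI = x / (x + y_AB + (y_A + y_B)/2)`, the sighting-effort–corrected
  association measure (reduces to `2x/(n_A + n_B)` with one group per
  sampling period). Surveys are filtered first: rest/travel/social
  activity only, an August–December window, same-day resights and
  inter-group conflicts dropped.
* **Alliance communities** by average-linkage agglomerative clustering on
  the HWI matrix, validated by the cophenetic correlation coefficient
  (CCC > 0.8 means the hierarchy fits) and cut where Newman's weighted
  modularity `Q = Σ_c [W_c/W − (S_c/2W)²]` is maximised.
* **Strength metrics**: per-individual summed HWI within the own alliance
  (`wStrength`) and to third-order partner alliances (`bStrength`), each
  normalised by the maximum within the individual's alliance, plus
  temporal snapshots over multi-year windows and mean association between
  first-order units.
* **Fusion-event tallies**: unique petting/rubbing pairs (with and without
  touching-distance `D0` records) and synchrony pairs per event, split
  second- vs third-order, with Cohen's kappa for coder reliability.
* **A permutation test** for preferential association (checkerboard swaps
  preserving group sizes and individual sighting counts).
* **A planted-society simulator** (`society_config()`, presets `"T1"` and
  `"T3"`) with a closed-form expected-HWI oracle, so the entire pipeline
  is testable without field data.

## Worked example

Simulate a three-alliance society (12/7/5 males, one third-order pair,
2000 surveys), then run the full chain:

```r
library(alliancenet)
cfg <- society_preset("T1")
reg <- registry_from_config(cfg, "T1")
sim <- generate_surveys(cfg, n_surveys = 2000, seed = 7)
kept <- filter_surveys(sim$surveys)
m   <- half_weight_index(count_sightings(kept, names(reg$second_order)))
best_partition(m)
#> Cluster diagnostics: 3 communities, max Q = 0.4156 at HWI = 0.3681 (midpoint 0.2186), CCC = 0.9984
#>   KS01: KS01 KS02 KS03 KS04 KS05 KS06 KS07 KS08 KS09 KS10 KS11 KS12
#>   PD01: PD01 PD02 PD03 PD04 PD05 PD06 PD07
#>   RR01: RR01 RR02 RR03 RR04 RR05
```

The cut at maximal modularity recovers the three planted second-order
alliances exactly (Q = 0.42 at an HWI cut of 0.37), and the near-1 CCC
says the dendrogram faithfully represents the dyadic associations. The
strength table then identifies the planted "bridge" trios — the
first-order units that carry the third-order relationship:

```r
st <- strength_table(m, reg, "T1")
head(st[order(-st$bStrength_N), c("id","alliance","wStrength","bStrength","bStrength_N")], 6)
#>      id alliance wStrength bStrength bStrength_N
#> 1  KS01       KS      5.47     0.743       1.000
#> 13 PD01       PD      3.35     1.057       1.000
#> 15 PD03       PD      3.35     1.053       0.996
#> 3  KS03       KS      5.42     0.720       0.969
#> 14 PD02       PD      3.32     0.998       0.944
#> 2  KS02       KS      5.46     0.701       0.943
```

Members of the designated bridge units (KS01–KS03, PD01–PD03) hold the
top `bStrength_N` ranks in their alliances. Surveys classify as
within-alliance or third-order against the registry:

```r
table(classify_surveys(kept, reg, "T1"))
#>     third_order within_alliance
#>             139            1195
```

`alliance_report()` chains all of the above (plus temporal snapshots) and
writes CSV/JSON/GraphML/newick outputs to a directory. Fusion-event logs
are tallied with `read_behavior_log()` + `summarize_tallies()`; a packaged
fixture (`inst/extdata/table1_synthetic_records.csv`, synthetic pair
identities reproducing the published per-event counts) shows the format.

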