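# sgascreen

Analysis of synthetic genetic array (SGA) colony-size screens in R: from raw
plate grids to normalized fitness, multiplicative-model genetic-interaction
scores, filtered hit lists and screen summaries, for both synthetic
sick/lethal (SL, double-deletion) and synthetic dosage lethal (SDL,
overexpression × deletion) screens.

## Who this is for

Groups running arrayed genetic-interaction screens in yeast — robotic
pinning at 384/768/1536 colony density, border-control strains at the plate
edge, replicate colonies per strain, replicate biological screens — who need
a scriptable, testable pipeline for turning colony-size tables into scored
interactions. Because raw plate data from such screens is rarely deposited,
the package ships a synthetic-screen generator that emulates the full data
structure (planted single-mutant fitness defects, planted pairwise
interaction effects, multiplicative spatial biases, lognormal colony noise),
so every stage of the analysis is validated against a known ground truth.

## The model

Colony size reports fitness. For a query strain *q* crossed into an array
strain *a*, the null expectation under the **multiplicative model** is

```
E[f_qa] = f_q × f_a
```

where `f_q` and `f_a` are the single-mutant fitness values (wild type ≈ 1),
estimated from a control-query cross. The **interaction score** is the
observed deviation

```
ε = f_qa (observed) − f_q × f_a (expected)
```

with negative ε the sick/lethal direction. SL screens call negative hits at
a derived threshold, mean − 2 SD of the screen's score distribution; SDL
screens use a conservative fixed cutoff of −0.5 (−0.3 is the conventional
"strong negative interaction" reference), with pairs already sick on the
promoter-repressed (+thiamin) control condition set aside. Pairs whose genes
lie within 200,000 bp on the same chromosome are excluded, since meiotic
linkage rather than epistasis depletes those double mutants.

Normalization corrects each plate for spatial bias: sizes are scaled by the
plate reference (median array strain, which the array design keeps
wild-type-like) and multiplicative row/column effects are removed by an
alternating median polish. See the methods vignette
(`vignettes/sga-screen-analysis.Rmd`) for assumptions and numerical details.

## Worked example

Simulate an SL screen in the classic design — 91 array strains at 768
density with 6 replicate colonies each, duplicate-pinned to 1536 (12
colonies), 3 replicate screens, 4 queries drawn from the array, noise CV
0.10, spatial gradients and edge enhancement on, a −0.4 interaction planted
on 5% of pairs — then score it:

```r
library(sgascreen)

cfg <- screen_config("sl", query_ids = sprintf("tf%02d", 1:4),
                     array_ids = sprintf("tf%02d", 1:91))
sim <- simulate_screen(cfg, seed = 1, interaction_frac = 0.05,
                       interaction_effect = -0.4)
res <- score_screen(sim$plates, sim$layout, sim$screens, sim$annotations, cfg)
res
#> SGA SL screen result
#>   generated pairs: 364 | scored: 354 | reciprocal collapsed: 6
#>   excluded - self: 4 linked: 0 low replicates: 0 control defect: 0
#>   threshold: -0.2077 | negative hits: 18 (5.08%) | positive hits: 0
```

The 4 × 91 cross generates 364 ordered combinations; 6 pairs screened in
both directions collapse into single records, 4 self-crosses are excluded,
and the remaining 354 pairs are scored. The derived threshold (mean − 2 SD
of the scores) lands at −0.208, and the 18 planted interactions are exactly
the 18 negative calls (5.08% hit frequency). Results are tibbles throughout:

```r
library(dplyr)
tidy(res) |> filter(hit == "negative") |> arrange(score) |>
  select(query_id, array_id, observed, expected, score, n) |> head(5)
#> # A tibble: 5 × 6
#>   query_id array_id observed expected  score     n
#>   <chr>    <chr>       <dbl>    <dbl>  <dbl> <int>
#> 1 tf01     tf14        0.180    0.683 -0.503    35
#> 2 tf04     tf68        0.136    0.633 -0.498    35
#> 3 tf03     tf76        0.351    0.828 -0.477    36
#> 4 tf01     tf85        0.480    0.953 -0.473    35
#> 5 tf01     tf30        0.553    1.01  -0.458    34
```

`glance(res)` gives the one-row accounting summary, `autoplot(res)` the
score heatmap (arrays × queries, excluded cells blank), and
`autoplot(res, type = "scores")` the score distribution with the threshold.
`score_matrix()`, `write_interactions()`, `summarize_screen()` and
`compare_screens()` cover matrix export, the machine-readable hit table,
accounting summaries and overlap partitions against other screens. SDL
screens work the same way with `screen_config("sdl", ...)`, which adds the
+thiamin control condition and the empty-vector control query.

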