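---
title: "Scoring genetic-interaction screens from colony-size arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genetic-interaction screens from colony-size arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgascreen)
```

## The measurement and the model

In an arrayed genetic-interaction screen, a query mutation is crossed into
a plated collection of array mutants by robotic pinning, and the colony
size of each double mutant reports its fitness. The analysis rests on the
multiplicative null model: if the single mutants grow at fitness $f_q$ and
$f_a$ (wild type $\approx 1$), a non-interacting double mutant is expected
at $f_q f_a$, and the interaction score is the deviation

$$\varepsilon = f_{qa} - f_q f_a,$$

negative for synthetic sick/lethal (SL) pairs. Synthetic dosage lethality
(SDL) screens use the same arithmetic with an overexpression query: the
"single-mutant fitness" of the query is the toxicity of overexpression in
an otherwise wild-type background, estimated against an empty-vector
control cross, and each query cross is accompanied by plates grown under
promoter repression (+thiamin for an *nmt1*-driven construct) as a control
condition.

The pipeline runs, in order: plate parsing → per-plate spatial
normalization → replicate-outlier flagging → single-mutant fitness from the
control cross → query fitness → per-pair double-mutant fitness →
reciprocal-cross merging (SL) → multiplicative scores → linkage filtering →
threshold derivation and hit calling (plus control-condition filtering in
SDL mode) → screen summary. `score_screen()` wires the stages together and
attaches a manifest of per-stage counts; every stage is also exported on
its own.

## Plate geometry and layouts

The three standard densities are 384 (16 × 24), 768 (24 × 32) and 1536
(32 × 48); coordinates are 1-based from the top-left, matching
robotic-pinning convention. Layouts place every boundary position as a
border control (a neutral strain that absorbs the enhanced growth at the
plate edge and is excluded from all statistics), each array strain at a
fixed number of interior positions, and at least one blank. Since the
true plate coordinates of such screens are rarely published, the layout
engine uses a deterministic reconstruction honouring the published counts:
occupied positions are spread evenly across the interior (blanks
interleaved) and the strain list is strided across replicate passes, so no
strain is confined to one plate region — dispersion is what makes replicate
averaging robust to residual spatial structure.

`duplicate_pin()` models pinning the whole 768 array twice onto one 1536
plate, doubling every multiplicity (6 → 12 colonies per strain). The
geometric dialect is fixed so fixtures are stable: source cell $(r, c)$ of
the 24 × 32 grid maps to target cells $(c, 2r-1)$ and $(c, 2r)$ of the
32 × 48 grid, a bijection onto the full target grid that keeps every
boundary cell a border control.

## Normalization

Raw colony sizes carry plate-level and spatial artifacts: overall plate
scale, smooth row/column gradients from media and incubation geometry, and
enhanced growth within about two positions of the border. `normalize_plate()`
converts sizes to dimensionless relative fitness in three steps.

1. **Plate scaling.** All sizes are divided by the plate reference: the
   configured statistic (median by default) over the *per-strain medians*
   of eligible colonies. Eligible means interior array positions with a
   present, growing colony — border controls, blanks, missing positions
   and zero-size colonies never define the reference. Taking one vote per
   strain matters: a per-colony median drifts into the lower tail of the
   wild-type size distribution as soon as a sizeable minority of colonies
   is sick, whereas the strain-level reference is exact whenever more than
   half the strains on the plate are wild-type-like — which is precisely
   the assumption the array design is built on.
2. **Row/column correction.** Multiplicative row and column effects are
   fitted by alternating median polish and divided out. The fit iterates
   to a fixed point (tolerance $10^{-12}$, at most 25 cycles; in practice a
   handful) rather than stopping after one pass: at the fixed point the
   row and column medians of the corrected plate are all 1, which makes
   the correction exact for separable bias fields and idempotent —
   renormalizing a normalized plate changes nothing, a property the test
   suite asserts at $10^{-9}$.
3. **Rescaling.** The plate reference of the corrected values is pinned
   back to exactly 1.

Zero-size colonies are biology (no growth), kept as observations; missing
colonies (failed pinning) stay missing — the parser and the normalizer
preserve the distinction, and the `min_colony_size` parameter (default 0 =
off) can demote sub-threshold specks to zero.

Two caveats are deliberate. The row/column model cannot represent the edge
ring exactly (edge enhancement is not row × column separable), so cells in
the four ring-intersection corners are over-corrected by roughly the edge
factor; with dispersed replicates this contributes at most a few percent
to a strain's mean. And on *sparse* plates — a handful of strains on a
large grid, so each row holds only a few colonies — line medians reflect
strain composition rather than spatial bias and the polish can absorb real
signal; the correction assumes dense plates (the real 546/768 or 1092/1536
designs) and should be disabled for small pilot layouts. No per-cell
smoothing surface is fitted: it would add free parameters that nothing in
a synthetic validation can pin down.

**Outlier flagging.** Within each plate, a colony deviating from its
strain's replicate median by more than `outlier_mad_multiplier` (default 5)
times the raw median absolute deviation is flagged; with fewer than three
replicate colonies the rule is off, and with a zero MAD any deviant is
flagged. Flags propagate — colonies are excluded from aggregation but
never silently dropped.

## Fitness estimation and the query-rescaling step

Array single-mutant fitness is the mean of a strain's usable normalized
colonies across the control-cross plates and replicate screens. Colonies
are pooled with equal weight (the default; `aggregate = "screen_mean"`
averages per-screen means instead, for designs with unbalanced replicate
counts). Pairs or strains with no usable colony are kept with $n = 0$ and
flagged, so downstream accounting stays exact; pairs with fewer than
`min_replicates` (default 6, half the 12-colony design) usable colonies
are flagged `low_replicates` and excluded from calling.

Per-plate normalization pins each plate's reference to 1 — including the
query-cross plates, where the query's own fitness defect scales *every*
colony. The plate reference therefore absorbs $f_q$, and plate-relative
double-mutant fitness estimates $f_{qa}/f_q$, not $f_{qa}$. The scorer
reattaches the factor: observed double fitness is the plate-relative mean
times the independently estimated query fitness. For SL screens the query
deletions are members of the array (as in a design whose 38 queries are
drawn from its 91 array strains), so $f_q$ comes from the control cross;
for SDL screens, where the query is an overexpression strain not on the
array, $f_q$ is estimated as the ratio of raw plate references, query
cross over empty-vector cross. Both estimators are exact on noise-free
screens, and the construction makes the multiplicative null exact as well:
with no planted effects, query and control plates differ by the factor
$f_q$ alone, normalization maps them to identical values, and every score
is zero to machine precision even with spatial bias planted — a property
the acceptance suite asserts at $10^{-12}$.

Reciprocal crosses — $(A, B)$ screened with $A$ as query and $(B, A)$ with
$B$ — measure the same double mutant and are pooled at the colony level
(counts add, means are colony-weighted, dispersions combine through the
pooled sum of squares) into one unordered record. Self-crosses measure a
marker artifact and are flagged, never scored.

## Filtering, thresholds and calls

**Linkage.** Pairs on the same chromosome with an interval gap strictly
below `linkage_window_bp` (default 200,000 bp) are flagged and excluded
from threshold derivation and hit lists. The gap is the minimum distance
between the two gene intervals (0 when overlapping); the boundary is
strict, so a gap of exactly 200 kb is retained — the two conventions
differ only at equality and the choice is asserted in the tests. Distances
could alternatively be measured start-to-start; interval gap was chosen as
the more conservative reading and the difference is one gene length.

**SL threshold.** Negative hits are scores at or below
$\mathrm{mean} - k \cdot \mathrm{SD}$ of the unflagged scores (sample SD,
$n - 1$; default $k = 2$). A score sample with mean 0.015 and SD 0.100 —
the regime a screen of mostly non-interacting transcription-factor pairs
produces — gives the familiar −0.185. The threshold is derived after
linkage and self-cross exclusion, before calling; scores of exactly 0 are
never called negative, which only matters in the degenerate zero-spread
case. **SDL cutoffs.** Fixed at ±`sdl_cutoff` (default 0.5): below −0.5
negative (conservative relative to the −0.3 "strong interaction"
reference), above +0.5 positive, reported for display. SDL combinations
whose fitness on the +thiamin control plates falls below
`control_fitness_floor` (default 0.5) are flagged `control_defect` — their
sickness cannot be attributed to overexpression (leaky expression is the
usual culprit) — and are reported but excluded from the confirmed list.

**Accounting.** Every ordered query × array combination is accounted for
exactly once: reciprocal merging collapses two ordered combinations into
one record, and each record is either scored or excluded by exactly one
flag with precedence self-cross → linked → low-replicates →
control-defect. `summarize_screen()` asserts the identity
$n_\text{scored} + \sum \text{exclusions} + n_\text{collapsed} =
n_\text{generated}$, and reported frequencies are rounded half-even to two
decimals, the printed precision of screen reports. Scores are rounded to
two decimals only at the reporting layer (`write_interactions()`,
`score_matrix()`); internal values keep full precision.

## The synthetic-screen generator

`simulate_screen()` produces the complete data a real screen would: the
control-query cross and one screen per query, each with
`n_screen_replicates` (default 3) replicate plates, plus paired +thiamin
control plates in SDL mode. Expected colony size at an interior position
is `reference_size` (1000 area units; immaterial, as a scale-invariance
test asserts) times planted fitness — $f_a$ on the control cross,
$\max(0, f_q f_a + \varepsilon)$ on a query cross, with the interaction
planted additively on the fitness scale to match the difference-score
convention — multiplied by the spatial bias field and per-colony noise.
Border cells grow at fitness 1, blanks are size 0.

The bias field is `plate_scale` × linear row and column gradients (default
slope 0.01 per position, about ±15% across a 1536 plate) × `edge_factor`
(default 1.1) within two positions of the border; noise is multiplicative
lognormal with mean 1 and CV `noise_cv` (default 0.10) — colony areas are
positive and right-skewed, and no published noise model exists for these
screens, so a lognormal is the standard minimal choice. Planted truth
defaults emulate a transcription-factor deletion array: 30% of strains
carry a uniform fitness defect on [0.5, 0.9] (keeping the median array
strain wild-type-like, the anchor normalization relies on), SDL query
toxicity uniform on [0.4, 0.9], and interactions of −0.4 on 5% of pairs.
Synthetic annotations place genes 250 kb apart round-robin over three
chromosomes, so nothing is linked unless linkage is planted explicitly.
Everything derives from one integer seed; identical seeds give
byte-identical plate tables.

What the generator does *not* emulate — and what passing tests therefore
cannot certify about real data: mating/sporulation efficiency differences,
selection-marker escape, pinning carry-over between rounds, agar defects
and plate-to-plate incubator gradients beyond the parametric field,
competition between neighbouring colonies, and image-segmentation error.
The validation shows the *analysis* is correct under its stated model, not
that the model exhausts real plates.

## Validation sizes and numerical choices

The test suite validates end to end on synthetic screens sized to run in
seconds while matching the real designs where it matters: the
multiplicative-null and exact-recovery checks use 10-strain arrays
(noise-free, machine tolerance); parameter recovery uses the full
12 × 3-colony replication at noise CV 0.10 on a 12-strain array with 9
wild-type strains, asserting every planted ε within ±0.05; planted-hit
recall/precision (≥ 0.9 / ≥ 0.8 asserted) and the acceptance script use
the full 91-strain array with 4 queries under default bias and noise; the
brute-force oracle cross-check uses a 5 × 5 screen recomputed by a
straight-line base-R script. Degenerate inputs fail loudly by design: a
plate with no growing eligible colony has no reference and is an error, as
are dimension mismatches, duplicated positions, unknown strains, missing
annotations, and threshold derivation from fewer than two scores.

## Known limitations

Beyond the normalization caveats above: query fitness estimated by plate
ratio (SDL) is confounded with any plate-scale drift between query and
control screens, so replicate screens are what make it usable; the
linkage rule uses a single symmetric window rather than a recombination
map; and the multiplicative model itself saturates near zero fitness —
planted effects that drive $f_q f_a + \varepsilon$ below 0 are clipped,
so very strong interactions on already-sick backgrounds are reported at
the boundary rather than at their planted magnitude.
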