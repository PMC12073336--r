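---
title: "Scoring beverages under the original and updated Nutri-Score algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring beverages under the original and updated Nutri-Score algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bevscore)
```

## The scoring model

Nutri-Score grades a product from its per-100 mL composition by summing
points for unfavorable components and subtracting points for favorable
ones. Each component's points come from an ordered band table; the boundary
convention throughout is *value ≤ threshold earns that band's points*, with
points increasing strictly above each threshold, which matches how every
step of the official tables is stated (e.g. "0 points for ≤40 %, 2 points
for >40 %"). Totals are exact integers: label values are taken at face
precision and nothing is rounded in between.

Two algorithm generations are implemented.

**Original (2015).** Unfavorable: energy (kJ), sugars, saturated fat and
sodium, 0–10 points each; favorable: protein and fiber (0–5 each) and the
fruit/vegetable/legume percentage (0/2/4/10). The theoretical beverage
total therefore spans −20 to 40. Plant-based drinks (cereal-, legume-,
nut-based and mixes), milk and milkshakes were not treated as beverages:
they are routed to the general-food band tables (much looser energy and
sugar bands, FVL steps 0/1/2/5) and the general-food letter cut-offs.

**Updated (2023).** All twelve categories are beverages. Salt is scored
directly on a 0–20 point ladder (0.2 g steps), protein deepens to 0–7,
fiber bands move to 3–7.4 g, the FVL component flattens to 0/2/4/6, and
products whose ingredient list contains non-nutritive sweeteners incur a
flat 4-point penalty. The total spans −18 to 54. Letter cut-offs move to
B ≤ 2 / C 3–6 / D 7–9 / E ≥ 10; A remains reserved for plain water on both
beverage scales.

The point-band tables are shipped as versioned JSON under
`inst/extdata/scales/` and validated at load (`load_scale()`): thresholds
strictly increasing, points non-decreasing, letter cut-offs partitioning
the score line. Only the endpoint spans and point ranges of each component
are externally anchored; the interior thresholds are the official published
tables, carried as configuration so that a future revision is a data edit,
not a code edit.

### Decisions where the rules are underdetermined

* **Salt vs sodium.** EU labels declare salt, but the 2015 component is
  sodium. The conversion sodium (mg) = salt (g) × 1000 / 2.5 is applied
  internally.
* **Protein-counting exception.** The official 2015 algorithm withholds
  protein points when the unfavorable total reaches 11 and the FVL
  component is below its maximum. The default here is plain subtraction —
  the straightforward reading of the published description — with the
  official exception available via `official_protein_rule = TRUE`
  (`score_2015()`, `score_products()`).
* **Saturated fat in 2023.** The headline changes to the updated beverage
  algorithm concern salt, sweeteners, protein and the re-cut bands, but the
  printed maximum (54 = 10 + 10 + 10 + 20 + 4) is only reachable with a
  0–10 saturated-fat component, so it is retained.
* **Lower bound of B (2015).** Since A is reserved for water, B is taken as
  *all* scores ≤ 1; there is no lower letter for a non-water beverage.
* **2015 food-scale letters.** Milk, milkshakes and plant-based drinks use
  the official general-food cut-offs (A ≤ −1, B 0–2, C 3–10, D 11–18,
  E ≥ 19), which reproduce the expected category assignments (a legume
  drink at −1 is A, milk at 0 is B, a milkshake at 6 is C). The food scale
  ignores the water flag.

## Reading composition tables

`read_products()` accepts UTF-8 CSV with `.` or `,` decimals (Spanish label
transcriptions vary). Energy may be declared in kJ, kcal or both: kcal is
converted at 4.184 kJ/kcal when kJ is absent, and when both are present but
disagree by more than 2 % the regulated unit (kJ) wins with a warning.
Undeclared fiber is imputed to zero — the conservative choice, since fiber
declaration is optional and assuming zero can only understate a product's
favorable side — and the imputations are counted and reported. A missing
FVL percentage defaults to 0 on the same conservative logic. Rows that
violate the composition invariants (negative nutrients, saturated fat above
total fat, unknown category, FVL outside 0–100, duplicate ids) are rejected
with row-level reasons, never silently dropped. `derive_flags()` detects
non-nutritive sweeteners in free-text ingredient lists by case- and
diacritic-insensitive keyword matching (Spanish/English spellings and EU
E-numbers, configurable) and parses an explicitly declared juice
percentage.

## The synthetic market generator

No public per-product database covers the Spanish beverage market, so the
package ships a seeded generator (`simulate_market()`) whose *per-category
marginals* emulate published category summaries: twelve categories with
median and min–max per 100 mL for energy, sugars, total and saturated fat,
salt, protein, fiber and FVL, and category sizes totalling 3432 products.

* **Distribution family.** Each summary gives exactly three numbers, so the
  sampler is the minimal-assumption distribution honoring all three: a
  two-piece triangular — a 50/50 mixture of a rising triangle on
  [min, median] and a falling triangle on [median, max] — whose population
  median equals the stated median exactly and whose support is the stated
  range. This is an emulation choice, not a claim about the real market.
* **Physical coherence.** Marginals are sampled independently, which can
  produce impossible rows, so saturated fat is clamped to total fat and
  energy is reconciled with the macronutrients: the sampled energy is
  blended 50/50 with the Atwater estimate (4 kcal/g sugars and protein,
  9 kcal/g fat, 2 kcal/g fiber), kept within ±15 % of the draw, and
  re-truncated to the category range.
* **Label precision.** Values are emitted as a label would declare them
  (two decimals; FVL one), which also makes CSV round-trips exact.
* **Sweetener prevalence** is 1 in the artificially sweetened category and
  0 elsewhere, mirroring the categorization rule that a product with
  non-nutritive sweeteners *is* an artificially sweetened beverage. No
  category carries a water flag (plain water is outside the twelve).
* **Bimodal FVL.** Juice categories mix near-pure juices with juice drinks,
  so their FVL is drawn as a mixture: weight 0.8 on the triangular
  component, 0.2 at zero. The weight is configurable per category in the
  JSON specification.
* **A transcription reconciliation.** The legume-based saturated-fat
  summary as published has its median above its maximum (0.3 vs 0.27); the
  maximum is taken as 2.7 g, consistent with the category's total-fat range.
  The unusually high legume-based salt range (max 2.9 g/100 mL) is carried
  as printed.

What passing tests on this generator show — and what they do not: the
scorer and pipeline behave correctly on data with realistic *marginal*
structure, but the generator knows nothing of the real market's joint
distribution (sugar–FVL correlation in nectars, protein–fat coupling in
dairy), brand clustering, or reformulation waves. Category-level summary
statistics computed on synthetic data are therefore illustrative, not
estimates of the real market's values.

## The comparison pipeline

`compare_scores()` pairs both versions per product;
`build_summary()` aggregates per category.

* **Relative variation** is per product,
  ((score₂₀₂₃ − score₂₀₁₅)/score₂₀₁₅) × 100. It is undefined when the 2015
  score is 0 — a common case (milk's median 2015 score is 0) — and how such
  products should enter a category aggregate is genuinely open. The default
  excludes them and averages the rest, reporting the excluded count;
  `relvar = "median-excluding-zeros"` and `relvar = "of-medians"` (the
  variation of the category medians) are available. None of the three is
  asserted to be how any particular published figure was aggregated.
* **Wilcoxon signed-rank** (via `stats::wilcox.test` on the non-zero
  differences): zeros dropped by Wilcoxon's convention, ties mid-ranked,
  exact distribution for ≤ 25 non-zero distinct differences, otherwise the
  normal approximation with continuity and tie correction; the two branches
  agree to well under 0.01 at the switchover in the test suite. An
  all-zero-difference sample is flagged degenerate with p = 1.
* **Spearman** rank consistency is the product-moment correlation of
  mid-ranks (`stats::cor(method = "spearman")`); ties are the norm since
  totals are small integers. A zero-variance margin yields `NA` with a
  warning.
* **Kappa agreement** between the two letter assignments is unweighted
  Cohen's kappa on the five-letter scale by default (also reported × 100,
  the style agreement percentages are usually quoted in); linear weights
  are available since letters are ordinal. The degenerate single-cell
  table is defined as kappa 1 when observed agreement is perfect.
* **Chi-square** compares the two versions' letter distributions (pooled
  expected counts, no continuity correction, letters absent from both
  dropped), with a low-expected-count flag below 5. It is computed per
  category in `build_summary()` and can be pooled by calling
  `chi_square_letters()` on the market-wide counts.
* **Discrimination** is the number of distinct letters (colors) each
  version uses within a category, 1–5.
* Raw p-values are reported per category with no multiplicity correction
  (α = 0.05 is a labeling convention here, never a filter); apply
  `p.adjust` downstream if families of tests are being compared.

## Problem sizes and numerical choices

The test suite exercises the full pipeline at one tenth of the market
(344 products) and the generator-distribution checks at n = 10,000 draws;
band-lookup equivalence against a linear-scan oracle uses 10,000 random
values per component table. The acceptance script's quantities are analytic
properties of the band tables (range sums, component maxima, letter
boundaries) and are seed-independent by construction. All scoring is
integer arithmetic; the only floating-point care needed is at band
boundaries, where thresholds are carried as short decimal literals so that
declared label values compare exactly.

## Limitations

Alcohol scoring, per-portion scoring, the 2022/2023 general-food algorithm
(beyond the 2015 food scale needed for the original routing) and the
red-meat rule are out of scope. The generator reproduces marginals only,
so cross-version agreement statistics on synthetic data reflect the
algorithms and the marginal structure, not the real market's joint
composition.
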