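# metabmatrix

A declarative, fully traceable engine for classifying consumer packaged-food
products into progressive **metabolic-health tiers**. It is aimed at food
scientists, reformulation teams and nutrition informaticians who need to
evaluate a product portfolio against layered, explainable criteria rather
than a single front-of-pack score.

## The model

Most nutrient-profiling schemes assign points for good and bad attributes and
sum them, so "poison A + antidote B = neutral". This engine deliberately does
the opposite. Products are evaluated against a configuration of declarative
criteria organized into five progressive levels that gate six ordered tier
labels:

```
III  <  II-C  <  II-B  <  II-A  <  I-B  <  I-A
```

Tier III is the unconditional floor (conventional foods); each ascent is
gated by one criterion level. A product's label is the highest tier `L` such
that **every** criterion at levels `1..L` passes (out-of-scope criteria count
as vacuous passes). Formally, with per-level pass indicators
`P(l) = ∧ᵢ [criterion i at level l does not fail]`,

```
label = max { L : P(1) ∧ … ∧ P(L) },    L ∈ {0,…,5}
```

so failures can never be averaged away by fortification: positive attributes
at higher levels are recorded but cannot compensate a level-1 failure.
Criteria are evaluated **per realistic serving**, not per 100 g, and span
three pillars — *feed the gut* (fiber, stabilizer replacement), *protect the
liver* (added sugar, trans fat, additives, heavy metals, pesticides) and
*support the brain* (omega-6 cap, omega-6:omega-3 ≤ 4:1, EPA/DHA,
micronutrient minimums) — plus transparency and sustainability attributes.

The shipped default configuration holds 38 criteria across the five levels
(12/5/9/8/4), anchored by four normative thresholds: added sugar ≤ 1 teaspoon
(4.2 g) per serving, omega-6 ≤ 5 g per serving, omega-6:omega-3 ≤ 4:1, and
vitamin D ≥ 400 IU per serving for dairy. The remaining criteria are
reconstructions flagged `non-normative` in the configuration file.

Around the rule engine the package provides:

* a hierarchical **product model** (one JSON document per product, nested
  components with mass fractions) with a total validator and an
  assumption-tracked rollup to a per-serving nutrient profile;
* an **ingredient lexicon** resolving synonyms, chemical/Latin names,
  E-numbers and bounded-distance misspellings — whole-term matching only, so
  a *peanut* is never a *nut* — with modifier handling (`organic`,
  `non-GMO`, `cold-pressed`, `partially hydrogenated`, …), concern
  neutralization and Big 8/9 **allergen detection**;
* per-product **reports** (JSON + Markdown) and a portfolio **overview CSV**;
* per-criterion **recommendations** with numeric targets and strategy texts
  (the juice sugar-mitigation strategy set among them);
* a seeded **synthetic portfolio generator** and named before/after
  re-engineering scenarios, since the original industrial portfolio is
  proprietary.

## Worked example

```r
library(metabmatrix)

sc <- named_scenarios()                      # synthetic re-engineering pairs
p  <- load_product(jsonlite::toJSON(sc$chocolate_milk_v1,
                                    auto_unbox = TRUE, digits = NA))
ev <- evaluate_product(p)                    # default 38-criterion matrix
ev$tier
#> <tier III: levels passed [2], blocked by L1-SUG-ADDED>

rec <- ev$recommendations[[1]]
sprintf("current %.1f g -> target %.1f g added sugar per serving",
        rec$current_value, rec$target_value)
#> "current 11.0 g -> target 4.2 g added sugar per serving"
head(rec$strategy_texts, 3)
#> [1] "No added sugars: do not add sugar to products already containing high amounts of sugar"
#> [2] "Microbial technology: use of organisms to consume the sugar"
#> [3] "Nanofiltration: filtering out sugar"
```

The original chocolate milk carries 11 g added sugar per 240 mL serving, so
it fails the level-1 added-sugar criterion and stays at Tier III no matter
what else it contains; the recommendation targets the 4.2 g boundary and
lists the sugar-mitigation strategies. `render_report()` turns the
evaluation into a one-page report:

```
# Product report: chocolate milk (original) (chocolate_milk_v1)

- Category: dairy
- Serving: 240 mL
- Tier: **III**
- Engine 0.9.0, configuration mm-2022.1
- Allergens (big8): milk

| Criterion | Level | Status | Measured | Threshold | Explanation |
|---|---|---|---|---|---|
| L1-SUG-ADDED | 1 | fail | 11 | 4.2 | sugar_added = 11 g per-serving; allowed at most 4.2 g -> fail |
| ...
```

A shell front end lives at `inst/cli/metabmatrix`
(`validate | evaluate | probe | synth | scenarios`).

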