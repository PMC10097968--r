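---
title: "The layered tier engine: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The layered tier engine: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabmatrix)
```

## The evaluation model

`metabmatrix` classifies packaged-food products into six ordered tiers,
`III < II-C < II-B < II-A < I-B < I-A`, using criteria grouped into five
progressive levels. Tier III is an unconditional floor carrying no criteria
of its own; each criterion level gates one ascent. The assigned label is the
highest tier whose gating levels *all* pass, where a level passes when none
of its criteria fails (a criterion scoped to other product categories is
`not-applicable` and counts as a vacuous pass).

Two modelling commitments follow from the scheme's critique of conventional
nutrient profiling:

* **No score averaging.** There is no numeric score anywhere in the engine.
  Fortification recorded at level 4 cannot offset an excess recorded at
  level 1; a product failing any level-1 criterion is Tier III regardless of
  every other outcome. This is enforced by construction and fuzz-tested over
  random outcome vectors.
* **Serving-size basis.** Criteria are evaluated per realistic serving, not
  per 100 g. A per-100g basis remains available for density-style criteria
  (used by the culinary oil criterion) and for the demonstration rating
  systems.

Nutrients are handled as fine-grained species (glucose, fructose and
galactose rather than "sugars"; ALA/EPA/DHA rather than "unsaturated fat")
through a controlled vocabulary that fixes one canonical unit per nutrient.
Evaluation goes beyond nutrients to ingredients: prohibitions are expressed
against canonical ingredient ids or additive groups, qualified by a concern
category, a confidence floor and neutralization rules.

## Criterion semantics and numerical choices

Boundary inclusivity follows the framework's own phrasing: a *max* threshold
("no more than 5 g omega-6 per serving") passes at the boundary and fails
strictly above it; a *min* threshold ("at least 400 IU vitamin D") passes at
the boundary. Where a reconstructed criterion has no published phrasing, max
thresholds are inclusive-pass at the boundary. The ratio predicate passes at
`num/den <= cap`, passes vacuously when both terms are zero, and fails when
only the denominator is zero.

A nutrient with no measurement **fails** its criterion with the explanation
"value unavailable". The alternative readings (pass, or not-applicable)
would let data gaps launder a product upward; the assumption-tracking
machinery exists precisely to keep gaps visible, so the conservative rule is
the only consistent one.

Every outcome carries a non-empty explanation tracing measured value, rule
and verdict; reports are fully reproducible from their JSON form. The
`probe_threshold()` instrument verifies configured boundaries independently
of the configuration file by bisecting the pass/fail transition of a single
criterion over a template product (default tolerance `1e-6`; a flat
interval is an error, not a zero).

## The product model and rollup

Products are single JSON documents with a nested component tree. Rollup to a
per-serving profile is mass-fraction-weighted and linear; per-100g (or
per-100mL) component panels are rescaled by the serving size. Volume bases
are treated like mass bases with no density model: component densities are
not available in label data, and inventing them would silently distort every
volume product. Numerical tolerances:

* species sums may exceed their parent total by at most 5 % relative
  (`fructose + glucose + ... <= sugar_total * 1.05`), loose enough for label
  rounding, tight enough to catch construction errors;
* sibling mass fractions must sum to 1 within 0.01;
* component nesting is capped at depth 8 so malformed (cyclic) input
  terminates with a validation error;
* declared label panels win over component rollups when both exist — the
  declared panel is the regulated artifact — with a consistency warning
  whenever the two disagree by more than 20 % relative on a shared nutrient.
  How the original programme reconciled assay data with declared panels is
  not published; this rule is the package's own choice.

Components without a panel fall back to a reference registry; every
substitution emits an assumption record that reports must surface. The
bundled registry entries are synthetic, label-plausible stand-ins and are
named as such.

A validator warning (not an error) flags multi-serve packs whose implied
portion falls below 30 g/mL — the pint-declaring-sixteen-servings problem —
via the optional `package_size` field.

## Ingredient normalization

Matching is whole-term against whole-alias after folding (case, punctuation,
E-number spacing). Misspellings are handled by a bounded
Damerau–Levenshtein match: distance ≤ 1 for folded terms of up to 8
characters, ≤ 2 for longer terms, accepted only when a single canonical id
attains the minimum. Two guards keep the matcher conservative:

* an ingredient is excluded from fuzzy candidacy when any of its aliases
  occurs inside the term as a strict substring with a word character
  adjacent (so neither "citric acidx" nor "eggx" resolves, and a *peanut*
  can never match *nut*-containing aliases);
* anything beyond the distance bound returns the unknown marker — never a
  best guess. Unknown ingredients are listed in reports and treated as
  benign for concern criteria, keeping the coverage gap explicit.

The modifier lexicon is a closed, versioned list (`organic`, the non-GMO
family, `cold-pressed`, `extra-virgin`, `unrefined`, `hydrogenated`,
`partially hydrogenated`). Modifiers can neutralize *potentially-offending*
concerns (as can a product whitelist); *offending* concerns are never
neutralizable. The hydrogenation modifiers additionally place any oil into
the corresponding hydrogenated-oil groups, so "partially hydrogenated X"
is caught without enumerating every oil. A consequence is that the
partially-hydrogenated prohibition is logically entailed by the broader
hydrogenated-oils prohibition; `coverage_fixtures()` therefore records a
documented skip for it rather than pretending to isolate it.

The confidence scale (`suspected < probable < established`) is a three-point
reconstruction — the original publication names a confidence mechanism
without enumerating it. Prohibitions default to a `probable` floor, which
lets suspected-only concerns (e.g. some non-nutritive sweeteners) pass while
staying visible in the registry.

## The default configuration

The default matrix holds 38 criteria in five levels (12/5/9/8/4). Four
thresholds are normative to the framework: added sugar ≤ 4.2 g (one
teaspoon, using the USDA household-measure convention of 4.2 g per teaspoon)
per serving; omega-6 ≤ 5 g per serving; omega-6:omega-3 ≤ 4:1; vitamin D ≥
400 IU per serving for dairy. Everything else is a reconstruction guided by
the published level themes — level 1 covers healthy fats, sugars, additives,
salt (the FDA low-sodium definition of 140 mg/serving), heavy metals,
pesticides and antibiotics; level 2 vegetable oils; level 3 vitamin,
mineral, fatty-acid and fiber minimums (a MENA-focused selection: vitamin D,
calcium, zinc, magnesium, iron); level 4 further targets, allergen
informatics, independent testing and cold-pressed oils; level 5
sustainability and traceability — and is marked `non-normative` in the
configuration file. Population retargeting is a configuration swap, not a
code change. Vitamin D conversions use the standard 40 IU = 1 µg.

The additive-concern registry is a seed set covering the substances the
framework names (carboxymethylcellulose, carrageenan, BHA, parabens,
bisphenol-A, chlorpyrifos, partially hydrogenated oils, the accepted
sweeteners erythritol/stevia/monk fruit and the pending allulose/tagatose);
the full industrial review it mirrors spans hundreds of substances and is
not reconstructable, so the registry is explicitly user-extensible.

## The synthetic portfolio

No portfolio data are published, so testing rests on a seeded generator.
Distributions are uniform within per-category ranges — deliberately, with no
claim of statistical realism. The defaults emulate a mixed
dairy/juice/ice-cream/culinary portfolio (180 products, mirroring the scale
of the original application) whose ranges were chosen once so that roughly
half of a default draw lands at Tier III, which keeps the recommendation
path exercised; about a third of products carry component trees (some two
levels deep) instead of flat declared panels. Generation is
integer-seeded and byte-deterministic; values are rounded to four decimals
at the per-serving level and rescaled without re-rounding so species-sum
invariants hold by construction.

What passing tests on synthetic data do show: the engine's rule semantics,
ladder logic, explanation plumbing, determinism and report formats. What
they cannot show: that real ingredient statements (multilingual, free-text,
OCR-derived) resolve at the seed lexicon's coverage, or that real nutrient
panels satisfy the species-sum tolerances as cleanly. The unknown-ingredient
listing and the validator's full-violation reports are the operational
mitigations.

Named scenarios (`chocolate_milk_v1/v2`, `chocolate_ice_cream_v1/v2`) mirror
the published before/after re-engineering pairs; their numeric contents are
invented fixtures, constructed so that v1 fails the level-1 sugar (and, for
the ice cream, stabilizer) criteria and v2 passes level 1.

## Problem sizes and verification

The test suite verifies, among others: boundary recovery of all four
normative thresholds by bisection; ladder agreement with a brute-force scan
over all 2^5 level-pass patterns; no-compensation over 10,000 random outcome
vectors; rollup linearity to 1e-9 relative; generator legality on a
2,000-product sample (the generator contract is zero validator errors at any
scale); and byte-identical reruns of a seeded 180-product end-to-end
evaluation. `scripts/acceptance.R` recomputes the three headline rule
constants from scratch at tolerance 1e-6.

## Known limitations

* No density or moisture modelling; per-100mL is treated as per-100g.
* No regulatory rounding rules for printed labels, no OCR, no multilingual
  statements, and no ML-based matching — the framework explicitly requires
  fully traceable results, which rules out non-inspectable matchers.
* The 34 non-normative criteria are plausible reconstructions, not the
  original rule set; the configuration format exists so that users can
  replace them wholesale.
* The seed lexicon (~75 entries) covers every substance the default
  configuration references, not general retail ingredient statements.
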