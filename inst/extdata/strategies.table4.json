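{
  "version": "1.0",
  "note": "Recommendation strategy templates. The sugar list seeds the mitigation strategies for sugars in juice; pillar lists are generic fallbacks.",
  "nutrient_families": {
    "sugar": [
      "No added sugars: do not add sugar to products already containing high amounts of sugar",
      "Microbial technology: use of organisms to consume the sugar",
      "Nanofiltration: filtering out sugar",
      "Fiber: mitigating the impact of fructose with whole fiber",
      "Modify juice to water ratio: less juice or juice concentrate, more water",
      "Replace sugar with non-caloric sweeteners",
      "Investigate new sugars and sweetener solutions (allulose, tagatose, protein-based sweeteners, sweetener combinations)",
      "Modifying ingredients: modulators, enhancers, texturizing agents",
      "Portion control: use smaller containers"
    ]
  },
  "pillars": {
    "feed-gut": [
      "Add soluble fiber (e.g., pectin, inulin) to reach the fiber target",
      "Replace offending stabilizers or emulsifiers with alternative soluble fibers",
      "Preserve the whole-food matrix where processing allows"
    ],
    "protect-liver": [
      "Reduce or remove the offending ingredient or contaminant at the source",
      "Audit supplier specifications for contaminant and additive loads",
      "Replace the offending additive with a benign alternative from the accepted list"
    ],
    "support-brain": [
      "Fortify with algal or marine oils to raise EPA/DHA",
      "Replace refined seed oils with cold-pressed or unrefined oils (e.g., extra-virgin olive oil)",
      "Fortify with the missing vitamin or mineral to the stated per-serving target"
    ],
    "transparency": [
      "Document the attribute and have it independently verified",
      "Publish allergen and sourcing information beyond minimum labeling requirements"
    ],
    "sustainability": [
      "Obtain certification for the named sustainability attribute",
      "Trace sourcing through supplier attestations and audits"
    ]
  }
}
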