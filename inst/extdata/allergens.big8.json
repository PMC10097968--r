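{
  "mode": "big8",
  "note": "FDA mandatory-disclosure allergen categories (pre-2023). Triggers are canonical lexicon ids. Highly refined soybean oil is deliberately absent from the soybeans triggers (FDA exemption).",
  "categories": {
    "milk": ["milk", "skim-milk", "cream", "butter", "whey", "casein", "milk-powder"],
    "eggs": ["egg"],
    "fish": ["salmon", "cod", "tuna", "fish-oil"],
    "shellfish": ["shrimp", "crab", "lobster"],
    "tree-nuts": ["almond", "walnut", "cashew", "hazelnut"],
    "peanuts": ["peanut", "peanut-butter"],
    "wheat": ["wheat"],
    "soybeans": ["soy", "soy-lecithin"]
  }
}
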