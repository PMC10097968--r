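{
  "mode": "big9",
  "note": "FDA mandatory-disclosure allergen categories including sesame (effective 2023).",
  "categories": {
    "milk": ["milk", "skim-milk", "cream", "butter", "whey", "casein", "milk-powder"],
    "eggs": ["egg"],
    "fish": ["salmon", "cod", "tuna", "fish-oil"],
    "shellfish": ["shrimp", "crab", "lobster"],
    "tree-nuts": ["almond", "walnut", "cashew", "hazelnut"],
    "peanuts": ["peanut", "peanut-butter"],
    "wheat": ["wheat"],
    "soybeans": ["soy", "soy-lecithin"],
    "sesame": ["sesame"]
  }
}
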