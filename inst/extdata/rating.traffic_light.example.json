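{
  "name": "traffic-light-demo",
  "note": "NON-NORMATIVE demonstration of the calculated-ratings capability in the style of UK front-of-pack traffic lights. Cut points are illustrative only and play no role in tier assignment.",
  "basis": "per-100g",
  "bands": ["green", "amber", "red"],
  "nutrients": {
    "sugar_total": {"cuts": [5, 22.5]},
    "fat_total": {"cuts": [3, 17.5]},
    "fat_saturated": {"cuts": [1.5, 5]},
    "sodium": {"cuts": [120, 600]}
  }
}
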