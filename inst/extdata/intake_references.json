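{
  "version": "1.0",
  "references": [
    {"nutrient": "epa_dha", "population": "adult", "lower": 250, "upper": 500, "unit": "mg", "note": "combined EPA+DHA daily intake for adults"},
    {"nutrient": "fiber_total", "population": "adult", "lower": 25, "upper": 38, "unit": "g", "note": "daily dietary fiber (non-normative reference)"},
    {"nutrient": "vitamin_d", "population": "adult", "lower": 600, "upper": 4000, "unit": "IU", "note": "daily vitamin D (non-normative reference)"},
    {"nutrient": "sodium", "population": "adult", "lower": 1500, "upper": 2300, "unit": "mg", "note": "daily sodium (non-normative reference)"}
  ]
}
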