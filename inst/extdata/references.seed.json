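{
  "version": "1.0",
  "note": "Reference nutrient registry: per-100g profiles substituted for untested components. Values are synthetic, label-plausible stand-ins (no deposited composition data exists for the original portfolio); every substitution is surfaced as an assumption record.",
  "entries": {
    "grape-juice": {
      "name": "grape juice (reference)",
      "match_names": ["grape juice", "white grape juice"],
      "basis": "per-100g",
      "quantities": {"sugar_total": 14.8, "glucose": 7.2, "fructose": 7.4, "sucrose": 0.2, "sugar_added": 0, "fiber_total": 0.2, "protein": 0.4, "sodium": 5, "potassium": 104, "vitamin_c": 0.1, "fat_total": 0.1}
    },
    "whole-milk": {
      "name": "whole milk (reference)",
      "match_names": ["whole milk", "milk", "fresh milk"],
      "basis": "per-100g",
      "quantities": {"sugar_total": 5.0, "lactose": 5.0, "sugar_added": 0, "fat_total": 3.6, "fat_saturated": 2.3, "fat_mufa": 0.9, "fat_pufa": 0.2, "omega6_total": 0.12, "omega3_total": 0.05, "protein": 3.3, "sodium": 40, "calcium": 120, "potassium": 150, "vitamin_d": 2, "vitamin_a": 130, "vitamin_b12": 0.45, "vitamin_b6": 0.04, "riboflavin": 0.17, "phosphorus": 95, "zinc": 0.4, "magnesium": 11}
    },
    "skim-milk": {
      "name": "skim milk (reference)",
      "match_names": ["skim milk", "skimmed milk", "nonfat milk"],
      "basis": "per-100g",
      "quantities": {"sugar_total": 5.1, "lactose": 5.1, "sugar_added": 0, "fat_total": 0.1, "fat_saturated": 0.1, "protein": 3.4, "sodium": 42, "calcium": 125, "potassium": 156, "vitamin_b12": 0.5, "phosphorus": 100, "zinc": 0.4, "magnesium": 11}
    },
    "cocoa-powder": {
      "name": "cocoa powder (reference)",
      "match_names": ["cocoa powder", "cocoa", "cacao powder"],
      "basis": "per-100g",
      "quantities": {"sugar_total": 1.8, "sugar_added": 0, "fat_total": 13.7, "fat_saturated": 8.1, "fat_mufa": 4.6, "fat_pufa": 0.4, "omega6_total": 0.38, "omega3_total": 0.02, "fiber_total": 33.2, "fiber_soluble": 8.0, "fiber_insoluble": 25.2, "protein": 19.6, "sodium": 21, "iron": 13.9, "magnesium": 499, "zinc": 6.8, "potassium": 1524}
    },
    "strawberry": {
      "name": "strawberry (reference)",
      "match_names": ["strawberry", "strawberries", "strawberry puree"],
      "basis": "per-100g",
      "quantities": {"sugar_total": 4.9, "glucose": 2.0, "fructose": 2.4, "sucrose": 0.5, "sugar_added": 0, "fiber_total": 2.0, "fiber_soluble": 0.6, "fiber_insoluble": 1.4, "protein": 0.7, "sodium": 1, "vitamin_c": 59, "folate": 24, "potassium": 153}
    },
    "cream": {
      "name": "cream (reference)",
      "match_names": ["cream", "heavy cream"],
      "basis": "per-100g",
      "quantities": {"sugar_total": 2.9, "lactose": 2.9, "sugar_added": 0, "fat_total": 36.1, "fat_saturated": 23.0, "fat_mufa": 9.1, "fat_pufa": 1.4, "omega6_total": 0.9, "omega3_total": 0.3, "protein": 2.1, "sodium": 27, "calcium": 66, "vitamin_a": 1470, "vitamin_d": 2.4}
    },
    "water": {
      "name": "water (reference)",
      "match_names": ["water", "purified water"],
      "basis": "per-100g",
      "quantities": {}
    }
  }
}
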