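{
  "version": "1.0",
  "note": "Controlled nutrient vocabulary. Each nutrient has one canonical unit; all profile quantities are stored in that unit.",
  "nutrients": [
    {"id": "sugar_total", "label": "Total sugar", "unit": "g", "class": "macronutrient"},
    {"id": "sugar_added", "label": "Added sugar", "unit": "g", "class": "macronutrient"},
    {"id": "sucrose", "label": "Sucrose", "unit": "g", "class": "sugar-species"},
    {"id": "glucose", "label": "Glucose", "unit": "g", "class": "sugar-species"},
    {"id": "fructose", "label": "Fructose", "unit": "g", "class": "sugar-species"},
    {"id": "galactose", "label": "Galactose", "unit": "g", "class": "sugar-species"},
    {"id": "lactose", "label": "Lactose", "unit": "g", "class": "sugar-species"},
    {"id": "fat_total", "label": "Total fat", "unit": "g", "class": "macronutrient"},
    {"id": "fat_saturated", "label": "Saturated fat", "unit": "g", "class": "fat-species"},
    {"id": "fat_trans", "label": "Trans fat", "unit": "g", "class": "fat-species"},
    {"id": "fat_mufa", "label": "Monounsaturated fat", "unit": "g", "class": "fat-species"},
    {"id": "fat_pufa", "label": "Polyunsaturated fat", "unit": "g", "class": "fat-species"},
    {"id": "omega6_total", "label": "Omega-6 fatty acids, total", "unit": "g", "class": "fat-species"},
    {"id": "omega3_total", "label": "Omega-3 fatty acids, total", "unit": "g", "class": "fat-species"},
    {"id": "ala", "label": "Alpha-linolenic acid (ALA)", "unit": "g", "class": "fat-species"},
    {"id": "epa", "label": "Eicosapentaenoic acid (EPA)", "unit": "mg", "class": "fat-species"},
    {"id": "dha", "label": "Docosahexaenoic acid (DHA)", "unit": "mg", "class": "fat-species"},
    {"id": "fiber_total", "label": "Total dietary fiber", "unit": "g", "class": "macronutrient"},
    {"id": "fiber_soluble", "label": "Soluble fiber", "unit": "g", "class": "fiber-species"},
    {"id": "fiber_insoluble", "label": "Insoluble fiber", "unit": "g", "class": "fiber-species"},
    {"id": "protein", "label": "Protein", "unit": "g", "class": "macronutrient"},
    {"id": "sodium", "label": "Sodium", "unit": "mg", "class": "mineral"},
    {"id": "choline", "label": "Choline", "unit": "mg", "class": "micronutrient"},
    {"id": "copper", "label": "Copper", "unit": "mg", "class": "mineral"},
    {"id": "magnesium", "label": "Magnesium", "unit": "mg", "class": "mineral"},
    {"id": "manganese", "label": "Manganese", "unit": "mg", "class": "mineral"},
    {"id": "iodine", "label": "Iodine", "unit": "ug", "class": "mineral"},
    {"id": "iron", "label": "Iron", "unit": "mg", "class": "mineral"},
    {"id": "phosphorus", "label": "Phosphorus", "unit": "mg", "class": "mineral"},
    {"id": "potassium", "label": "Potassium", "unit": "mg", "class": "mineral"},
    {"id": "selenium", "label": "Selenium", "unit": "ug", "class": "mineral"},
    {"id": "zinc", "label": "Zinc", "unit": "mg", "class": "mineral"},
    {"id": "calcium", "label": "Calcium", "unit": "mg", "class": "mineral"},
    {"id": "vitamin_a", "label": "Vitamin A", "unit": "IU", "class": "vitamin"},
    {"id": "vitamin_d", "label": "Vitamin D", "unit": "IU", "class": "vitamin"},
    {"id": "vitamin_e", "label": "Vitamin E (tocopherols)", "unit": "mg", "class": "vitamin"},
    {"id": "vitamin_c", "label": "Vitamin C (ascorbic acid)", "unit": "mg", "class": "vitamin"},
    {"id": "thiamine", "label": "Vitamin B1 (thiamine)", "unit": "mg", "class": "vitamin"},
    {"id": "riboflavin", "label": "Vitamin B2 (riboflavin)", "unit": "mg", "class": "vitamin"},
    {"id": "niacin", "label": "Niacin", "unit": "mg", "class": "vitamin"},
    {"id": "pantothenic_acid", "label": "Vitamin B5 (pantothenic acid)", "unit": "mg", "class": "vitamin"},
    {"id": "vitamin_b6", "label": "Vitamin B6 (pyridoxine)", "unit": "mg", "class": "vitamin"},
    {"id": "vitamin_b12", "label": "Vitamin B12", "unit": "ug", "class": "vitamin"},
    {"id": "folate", "label": "Total folate", "unit": "ug", "class": "vitamin"},
    {"id": "lead", "label": "Lead", "unit": "ug", "class": "heavy-metal"},
    {"id": "arsenic", "label": "Arsenic", "unit": "ug", "class": "heavy-metal"},
    {"id": "cadmium", "label": "Cadmium", "unit": "ug", "class": "heavy-metal"},
    {"id": "mercury", "label": "Mercury", "unit": "ug", "class": "heavy-metal"},
    {"id": "glyphosate", "label": "Glyphosate", "unit": "ug", "class": "contaminant"}
  ],
  "sum_rules": [
    {"total": "sugar_total", "parts": ["sucrose", "glucose", "fructose", "galactose", "lactose"]},
    {"total": "sugar_total", "parts": ["sugar_added"]},
    {"total": "fat_total", "parts": ["fat_saturated", "fat_trans", "fat_mufa", "fat_pufa"]},
    {"total": "fiber_total", "parts": ["fiber_soluble", "fiber_insoluble"]}
  ]
}
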