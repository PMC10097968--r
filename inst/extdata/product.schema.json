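{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Product document",
  "description": "One JSON file per product. The in-package validator implements these rules (plus cross-field consistency checks such as species-sum tolerances and sibling mass-fraction sums) and reports every violation, not just the first. Nutrient ids and canonical units come from nutrients.vocab.json.",
  "type": "object",
  "required": ["id", "name", "category", "serving_size"],
  "properties": {
    "id": {"type": "string", "minLength": 1},
    "name": {"type": "string", "minLength": 1},
    "category": {"enum": ["dairy", "juice", "ice-cream", "culinary", "beverage", "other"]},
    "serving_size": {
      "type": "object",
      "required": ["value", "unit"],
      "properties": {
        "value": {"type": "number", "exclusiveMinimum": 0},
        "unit": {"enum": ["g", "mL"]}
      }
    },
    "package_size": {
      "type": "object",
      "properties": {
        "value": {"type": "number", "exclusiveMinimum": 0},
        "unit": {"enum": ["g", "mL"]}
      }
    },
    "servings_per_package": {"type": "number", "exclusiveMinimum": 0},
    "ingredient_statement": {"type": "string"},
    "claims": {"type": "array", "items": {"type": "string"}},
    "whitelist_ids": {"type": "array", "items": {"type": "string"}},
    "declared_profile": {"$ref": "#/definitions/profile"},
    "components": {"type": "array", "items": {"$ref": "#/definitions/component"}}
  },
  "definitions": {
    "profile": {
      "type": "object",
      "required": ["basis", "quantities"],
      "properties": {
        "basis": {"enum": ["per-serving", "per-100g", "per-100mL"]},
        "quantities": {
          "type": "object",
          "additionalProperties": {"type": "number", "minimum": 0},
          "description": "Keys are nutrient ids from the controlled vocabulary; values are amounts in each nutrient's canonical unit."
        }
      }
    },
    "component": {
      "type": "object",
      "required": ["id", "name", "mass_fraction"],
      "properties": {
        "id": {"type": "string", "minLength": 1},
        "name": {"type": "string", "minLength": 1},
        "mass_fraction": {"type": "number", "minimum": 0, "maximum": 1},
        "ingredient_statement": {"type": "string"},
        "profile": {"$ref": "#/definitions/profile"},
        "provenance": {"enum": ["assayed", "declared", "reference-substituted"]},
        "components": {"type": "array", "items": {"$ref": "#/definitions/component"}}
      }
    }
  }
}
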