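{
  "version": "1.0",
  "note": "Additive-concern seed registry. Entries are keyed by canonical lexicon ids and overlay the lexicon's own concern lists (registry wins on the same category). A seed set only: the full additive review this schema is built for covers hundreds of substances and is maintained separately by users.",
  "entries": {
    "carboxymethylcellulose": [
      {"concern_category": "gut-inflammation", "status": "offending", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "commercial emulsifier associated with intestinal inflammation"},
      {"concern_category": "metabolic-harm", "status": "offending", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "emulsifier with documented adverse gut/metabolic effects"}
    ],
    "polysorbate-80": [
      {"concern_category": "gut-inflammation", "status": "offending", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "synthetic emulsifier associated with intestinal inflammation"},
      {"concern_category": "metabolic-harm", "status": "offending", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "synthetic emulsifier with documented adverse gut/metabolic effects"}
    ],
    "carrageenan": [
      {"concern_category": "gut-inflammation", "status": "potentially-offending", "confidence": "probable", "neutralizing_modifiers": [], "citation_note": "stabilizer under replacement by alternative soluble fibers"},
      {"concern_category": "metabolic-harm", "status": "potentially-offending", "confidence": "probable", "neutralizing_modifiers": [], "citation_note": "stabilizer under replacement by alternative soluble fibers"}
    ],
    "bha": [
      {"concern_category": "obesogen", "status": "offending", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "antioxidant preservative and candidate obesogen"},
      {"concern_category": "metabolic-harm", "status": "offending", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "antioxidant preservative and candidate obesogen"}
    ],
    "methylparaben": [
      {"concern_category": "obesogen", "status": "offending", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "paraben preservative and candidate obesogen"},
      {"concern_category": "metabolic-harm", "status": "offending", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "paraben preservative and candidate obesogen"}
    ],
    "propylparaben": [
      {"concern_category": "obesogen", "status": "offending", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "paraben preservative and candidate obesogen"},
      {"concern_category": "metabolic-harm", "status": "offending", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "paraben preservative and candidate obesogen"}
    ],
    "bisphenol-a": [
      {"concern_category": "obesogen", "status": "offending", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "packaging-contact chemical activating PPAR-gamma"},
      {"concern_category": "metabolic-harm", "status": "offending", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "packaging-contact chemical activating PPAR-gamma"}
    ],
    "chlorpyrifos": [
      {"concern_category": "obesogen", "status": "offending", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "organophosphate insecticide and candidate obesogen"},
      {"concern_category": "metabolic-harm", "status": "offending", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "organophosphate insecticide and candidate obesogen"}
    ],
    "hfcs": [
      {"concern_category": "metabolic-harm", "status": "offending", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "concentrated fructose source driving hepatic de novo lipogenesis"}
    ],
    "sodium-benzoate": [
      {"concern_category": "metabolic-harm", "status": "potentially-offending", "confidence": "probable", "neutralizing_modifiers": [], "citation_note": "preservative under review; replace where feasible"}
    ],
    "aspartame": [
      {"concern_category": "metabolic-harm", "status": "potentially-offending", "confidence": "suspected", "neutralizing_modifiers": [], "citation_note": "non-nutritive sweetener; microbiome and insulin-secretion signals under study"}
    ],
    "sucralose": [
      {"concern_category": "metabolic-harm", "status": "potentially-offending", "confidence": "suspected", "neutralizing_modifiers": [], "citation_note": "non-nutritive sweetener; microbiome signals under study"}
    ],
    "erythritol": [
      {"concern_category": "regulatory-status", "status": "benign", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "accepted sweetener on the shortlist"}
    ],
    "stevia": [
      {"concern_category": "regulatory-status", "status": "benign", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "accepted sweetener on the shortlist"}
    ],
    "monk-fruit": [
      {"concern_category": "regulatory-status", "status": "benign", "confidence": "established", "neutralizing_modifiers": [], "citation_note": "accepted sweetener on the shortlist"}
    ],
    "allulose": [
      {"concern_category": "regulatory-status", "status": "benign", "confidence": "probable", "neutralizing_modifiers": [], "citation_note": "preferred sweetener pending GSO/EFSA approval (as of the 2022 review)"}
    ],
    "tagatose": [
      {"concern_category": "regulatory-status", "status": "benign", "confidence": "probable", "neutralizing_modifiers": [], "citation_note": "candidate sweetener pending wider regulatory adoption"}
    ]
  }
}
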