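# shared fixtures: built once per test run, entirely in code

mm_json <- function(doc) {
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
}

load_doc <- function(doc) load_product(mm_json(doc))

fx_matrix <- load_default_matrix()
fx_lexicon <- load_lexicon()
fx_refs <- load_reference_registry()

# minimal valid dairy product with a declared per-serving panel
minimal_doc <- function(id = "p1", category = "dairy",
                        quantities = list(sugar_total = 5, sugar_added = 2)) {
  list(id = id, name = paste0("product ", id), category = category,
       serving_size = list(value = 240, unit = "mL"),
       declared_profile = list(basis = "per-serving", quantities = quantities))
}

# a resolved evaluation subject with an arbitrary per-serving panel
make_resolved <- function(quantities, category = "dairy",
                          serving = list(value = 240, unit = "mL"),
                          statement = "", claims = character(),
                          product_id = "t1", whitelist = character()) {
  structure(list(
    product_id = product_id, name = "test subject", category = category,
    serving_size = serving,
    profile = structure(list(basis = "per-serving",
                             quantities = unlist(quantities) %||% stats::setNames(numeric(0), character(0))),
                        class = "mm_profile"),
    parsed = resolve_statement(statement, fx_lexicon),
    unknown_ingredients = character(),
    claims = vapply(claims, fold_term, character(1), USE.NAMES = FALSE),
    whitelist_ids = whitelist,
    assumptions = list(), warnings = character(),
    allergens = character(), allergen_mode = "big8"
  ), class = "mm_resolved")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# synthetic criterion/outcome builders for ladder tests (no product needed)
fake_criterion <- function(id, level, type = "threshold") {
  list(id = id, label = id, level = level, pillar = "protect-liver", scope = list(),
       predicate = list(type = "threshold", nutrient = "sugar_added",
                        direction = "max", value = 1, unit = "g",
                        basis = "per-serving", inclusive = TRUE))
}

fake_outcome <- function(id, level, status) {
  structure(list(criterion_id = id, level = level, pillar = "protect-liver",
                 status = status, measured_value = NA_real_, unit = NA_character_,
                 threshold = NA_real_, explanation = "synthetic outcome"),
            class = "mm_outcome")
}

# outcome sets following a per-level pass pattern (5 levels, 2 criteria each)
outcomes_for_pattern <- function(pattern) {
  crits <- list(); outs <- list()
  for (l in 1:5) {
    for (k in 1:2) {
      id <- sprintf("C%d-%d", l, k)
      crits[[length(crits) + 1]] <- fake_criterion(id, l)
      status <- if (pattern[l] || k == 1) "pass" else "fail"
      outs[[length(outs) + 1]] <- fake_outcome(id, l, status)
    }
  }
  list(criteria = crits, outcomes = outs)
}

# independent ladder oracle: scan ascents directly from the pattern
ladder_oracle <- function(pattern) {
  ascent <- 0L
  for (l in 1:5) if (pattern[l]) ascent <- l else break
  tier_labels()[ascent + 1L]
}
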