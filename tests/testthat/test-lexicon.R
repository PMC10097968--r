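test_that("statements parse into entries, sub-ingredients and modifiers", {
  ps <- parse_statement("water, non-GMO citric acid, stabilizer (carrageenan, guar gum)")
  expect_length(ps, 3)
  expect_identical(ps[[2]]$modifiers, "non-gmo")
  expect_length(ps[[3]]$sub_ingredients, 2)
  expect_identical(ps[[3]]$sub_ingredients[[1]]$term, "carrageenan")

  expect_length(parse_statement(""), 0)

  one <- parse_statement("organic milk")
  expect_length(one, 1)
  expect_identical(one[[1]]$modifiers, "organic")
  expect_identical(one[[1]]$term, "milk")

  # offsets index into the original statement
  st <- "water, organic milk"
  ps <- parse_statement(st)
  expect_identical(substr(st, ps[[2]]$start, ps[[2]]$end), " organic milk")

  expect_warning(parse_statement("water, stabilizer (carrageenan"), "unbalanced")
})

test_that("synonyms, chemical names, Latin names and E-numbers all resolve", {
  for (term in c("E330", "e-330", "E 330", "acidum citricum",
                 "2-hydroxypropane-1,2,3-tricarboxylic acid", "Citric Acid")) {
    expect_identical(normalize_term(term, fx_lexicon), "citric-acid", label = term)
  }
})

test_that("bounded fuzzy matching catches misspellings but never guesses", {
  # oracle: exhaustive Damerau-Levenshtein scan over every alias confirms the
  # unique nearest alias for "citirc acid" is citric acid at distance 1
  tab <- fx_lexicon$alias_tab
  d <- vapply(tab$alias, function(a) metabmatrix:::osa_distance("citirc acid", a),
              numeric(1))
  expect_identical(unique(tab$id[d == min(d)]), "citric-acid")
  expect_identical(min(d), 1)
  expect_identical(normalize_term("citirc acid", fx_lexicon), "citric-acid")

  expect_identical(normalize_term("carageenan", fx_lexicon), "carrageenan")
  expect_identical(normalize_term("completely unknown stuff", fx_lexicon),
                   UNKNOWN_INGREDIENT)
})

test_that("a peanut is never a (tree) nut: whole-term matching only", {
  expect_identical(normalize_term("peanut", fx_lexicon), "peanut")
  expect_false("tree-nuts" %in% classify_groups(normalize_term("peanut", fx_lexicon),
                                                fx_lexicon))
  reg <- load_allergen_registry("big8")
  expect_identical(detect_allergens(resolve_statement("peanut", fx_lexicon), reg),
                   "peanuts")
})

test_that("aliases embedded in longer terms with adjacent word characters never match", {
  set.seed(7)
  idx <- sample(nrow(fx_lexicon$alias_tab), 40)
  for (i in idx) {
    a <- fx_lexicon$alias_tab$alias[i]
    aid <- fx_lexicon$alias_tab$id[i]
    for (term in c(paste0("x", a), paste0(a, "x"), paste0("zq", a, "zq"))) {
      if (term %in% fx_lexicon$alias_tab$alias) next
      got <- normalize_term(term, fx_lexicon)
      expect_false(identical(got, aid), info = paste(term, "->", got))
    }
  }
})

test_that("normalization is idempotent over every resolvable alias", {
  tab <- fx_lexicon$alias_tab
  for (i in seq_len(nrow(tab))) {
    id <- normalize_term(tab$alias[i], fx_lexicon)
    expect_identical(normalize_term(fx_lexicon$entries[[id]]$preferred_name, fx_lexicon),
                     id, label = tab$alias[i])
  }
})

test_that("group classification follows the lexicon", {
  monolaurin <- normalize_term("glycerol monolaurate", fx_lexicon)
  expect_true("mono-and-diglycerides" %in% classify_groups(monolaurin, fx_lexicon))
  expect_true("emulsifiers" %in% classify_groups("carboxymethylcellulose", fx_lexicon))
  expect_identical(classify_groups("cocoa-powder", fx_lexicon), character(0))
  expect_error(classify_groups("no-such-id", fx_lexicon), class = "mm_lookup_error")
})

test_that("modifier-derived hydrogenation enters the effective groups", {
  ps <- resolve_statement("partially hydrogenated soybean oil", fx_lexicon)[[1]]
  expect_identical(ps$canonical_id, "soybean-oil")
  g <- metabmatrix:::effective_groups(ps$canonical_id, ps$modifiers, fx_lexicon)
  expect_true(all(c("partially-hydrogenated-oils", "hydrogenated-oils") %in% g))
  ps2 <- resolve_statement("hydrogenated coconut oil", fx_lexicon)[[1]]
  g2 <- metabmatrix:::effective_groups(ps2$canonical_id, ps2$modifiers, fx_lexicon)
  expect_true("hydrogenated-oils" %in% g2)
  expect_false("partially-hydrogenated-oils" %in% g2)
})

test_that("concern neutralization follows modifier and whitelist rules", {
  entry <- resolve_statement("non-GMO citric acid", fx_lexicon)[[1]]
  expect_identical(resolve_concern(entry, "GMO-status", lexicon = fx_lexicon)$status,
                   "benign")

  plain <- resolve_statement("citric acid", fx_lexicon)[[1]]
  expect_identical(resolve_concern(plain, "GMO-status", lexicon = fx_lexicon)$status,
                   "potentially-offending")
  expect_identical(
    resolve_concern(plain, "GMO-status", whitelist = c("prod-9"),
                    product_id = "prod-9", lexicon = fx_lexicon)$status,
    "benign")

  # offending is never neutralizable
  cmc <- resolve_statement("organic carboxymethylcellulose", fx_lexicon)[[1]]
  expect_identical(cmc$canonical_id, "carboxymethylcellulose")
  expect_identical(
    resolve_concern(cmc, "gut-inflammation", whitelist = "prod-9",
                    product_id = "prod-9", lexicon = fx_lexicon)$status,
    "offending")

  expect_error(resolve_concern(plain, "", lexicon = fx_lexicon),
               class = "mm_argument_error")
})

test_that("neutralization is monotone: modifiers never worsen a status", {
  rank <- c(`benign-unknown` = 0, benign = 0, `potentially-offending` = 1, offending = 2)
  cats <- c("GMO-status", "gut-inflammation", "metabolic-harm", "refined-seed-oil")
  terms <- c("citric acid", "carrageenan", "soybean oil", "carboxymethylcellulose",
             "guar gum", "palm oil")
  mods <- c("non-GMO", "organic", "cold-pressed", "unrefined")
  for (term in terms) {
    for (cat in cats) {
      base <- resolve_concern(resolve_statement(term, fx_lexicon)[[1]], cat,
                              lexicon = fx_lexicon)
      for (m in mods) {
        with_mod <- resolve_concern(
          resolve_statement(paste(m, term), fx_lexicon)[[1]], cat, lexicon = fx_lexicon)
        expect_lte(rank[[with_mod$status]], rank[[base$status]],
                   label = paste(m, term, cat))
      }
    }
  }
})

test_that("allergen detection finds every category exactly once", {
  st8 <- "milk, egg, cod, shrimp, almond, peanut, wheat, soy, water, salt"
  got8 <- detect_allergens(resolve_statement(st8, fx_lexicon),
                           load_allergen_registry("big8"))
  expect_length(got8, 8)
  got9 <- detect_allergens(resolve_statement(paste0(st8, ", sesame"), fx_lexicon),
                           load_allergen_registry("big9"))
  expect_length(got9, 9)
  expect_identical(setdiff(got9, got8), "sesame")
  expect_length(detect_allergens(resolve_statement("water, salt", fx_lexicon),
                                 load_allergen_registry("big8")), 0)
  # sub-ingredients contribute too
  nested <- resolve_statement("chocolate coating (milk powder, soy lecithin)", fx_lexicon)
  expect_setequal(detect_allergens(nested, load_allergen_registry("big8")),
                  c("milk", "soybeans"))
})

test_that("allergen detection is a union over statement parts", {
  reg <- load_allergen_registry("big9")
  a <- resolve_statement("milk, almond", fx_lexicon)
  b <- resolve_statement("shrimp, sesame", fx_lexicon)
  expect_setequal(detect_allergens(c(a, b), reg),
                  union(detect_allergens(a, reg), detect_allergens(b, reg)))
})

test_that("big9 is big8 plus sesame", {
  r8 <- load_allergen_registry("big8")
  r9 <- load_allergen_registry("big9")
  expect_setequal(names(r9$categories), c(names(r8$categories), "sesame"))
})
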