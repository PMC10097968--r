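test_that("a minimal document loads into a product with empty components", {
  p <- load_doc(minimal_doc())
  expect_s3_class(p, "mm_product")
  expect_length(p$components, 0)
  expect_identical(p$category, "dairy")
})

test_that("malformed JSON raises a parse error naming a byte offset", {
  err <- expect_error(load_product('{"id": "x", }'), class = "mm_parse_error")
  expect_match(conditionMessage(err), "byte offset")
})

test_that("sibling mass fractions summing to 0.80 fail naming the parent", {
  doc <- minimal_doc()
  doc$declared_profile <- NULL
  doc$components <- list(
    list(id = "a", name = "part a", mass_fraction = 0.5,
         profile = list(basis = "per-100mL", quantities = list(sugar_total = 4))),
    list(id = "b", name = "part b", mass_fraction = 0.3,
         profile = list(basis = "per-100mL", quantities = list(sugar_total = 1)))
  )
  err <- expect_error(load_doc(doc), class = "mm_validation_error")
  expect_match(conditionMessage(err), "mass-fraction-sum")
  expect_match(conditionMessage(err), "components")
})

test_that("validation lists every violation, not just the first", {
  doc <- minimal_doc(category = "snacks",
                     quantities = list(sugar_total = 5, fructose = 4, glucose = 3,
                                       caffeine = 1))
  err <- expect_error(load_doc(doc), class = "mm_validation_error")
  msg <- conditionMessage(err)
  expect_match(msg, "category-enum")
  expect_match(msg, "sum-rule:sugar_total")
  expect_match(msg, "caffeine")
})

test_that("nested component trees load with depth >= 2", {
  doc <- minimal_doc(id = "juice1", category = "juice")
  doc$declared_profile <- NULL
  doc$components <- list(
    list(id = "blend", name = "juice blend", mass_fraction = 1,
         components = list(
           list(id = "gjc", name = "grape juice concentrate", mass_fraction = 0.3,
                profile = list(basis = "per-100mL", quantities = list(sugar_total = 40))),
           list(id = "w", name = "water", mass_fraction = 0.7,
                profile = list(basis = "per-100mL", quantities = list()))
         ))
  )
  p <- load_doc(doc)
  expect_length(p$components[[1]]$components, 2)
})

test_that("validate_product is total and flags constructed breaches", {
  p <- load_doc(minimal_doc())
  expect_identical(nrow(validate_product(p)), 0L)

  # fructose + glucose > total sugar x 1.05
  broken <- minimal_doc(quantities = list(sugar_total = 5, fructose = 3, glucose = 2.5))
  bp <- build_product(jsonlite::fromJSON(mm_json(broken), simplifyVector = FALSE))
  v <- validate_product(bp)
  expect_identical(sum(v$rule == "sum-rule:sugar_total"), 1L)

  # a corpus of deliberately broken fixtures: every breach reported
  fixtures <- list(
    list(doc = minimal_doc(category = "nope"), rule = "category-enum"),
    list(doc = modifyList(minimal_doc(), list(serving_size = list(value = -1, unit = "g"))),
         rule = "serving-positive"),
    list(doc = minimal_doc(quantities = list(sugar_total = -2)), rule = "non-negative"),
    list(doc = minimal_doc(quantities = list(fat_total = 1, fat_saturated = 0.9,
                                             fat_mufa = 0.3)), rule = "sum-rule:fat_total")
  )
  for (fx in fixtures) {
    bp <- build_product(jsonlite::fromJSON(mm_json(fx$doc), simplifyVector = FALSE))
    expect_true(fx$rule %in% validate_product(bp)$rule, info = fx$rule)
  }
})

test_that("implausibly small implied portions warn but do not error", {
  doc <- minimal_doc(id = "pint", category = "ice-cream")
  doc$serving_size <- list(value = 29.5, unit = "mL")
  doc$package_size <- list(value = 473, unit = "mL")
  doc$servings_per_package <- 16
  bp <- build_product(jsonlite::fromJSON(mm_json(doc), simplifyVector = FALSE))
  v <- validate_product(bp)
  expect_identical(v$rule[v$severity == "warning"], "portion-plausibility")
  expect_false(any(v$severity == "error"))

  # the same pack declaring 4 servings (118 mL portions) is plausible
  doc$servings_per_package <- 4
  doc$serving_size <- list(value = 118, unit = "mL")
  bp <- build_product(jsonlite::fromJSON(mm_json(doc), simplifyVector = FALSE))
  expect_false("portion-plausibility" %in% validate_product(bp)$rule)
})

test_that("rollup mixes components linearly and rescales to the serving", {
  doc <- minimal_doc(id = "mix")
  doc$serving_size <- list(value = 200, unit = "g")
  doc$declared_profile <- NULL
  doc$components <- list(
    list(id = "a", name = "sweet part", mass_fraction = 0.5,
         profile = list(basis = "per-100g", quantities = list(sugar_total = 10))),
    list(id = "b", name = "plain part", mass_fraction = 0.5,
         profile = list(basis = "per-100g", quantities = list(sugar_total = 0)))
  )
  res <- resolve_profile(load_doc(doc))
  expect_equal(unname(res$profile$quantities[["sugar_total"]]), 10)
  expect_length(res$assumptions, 0)
})

test_that("rollup is linear in mass fractions to 1e-9 relative", {
  qa <- list(sugar_total = 12, protein = 3, sodium = 80)
  qb <- list(sugar_total = 2, protein = 9, sodium = 10)
  for (p in c(0.13, 0.5, 0.87)) {
    doc <- minimal_doc(id = "lin")
    doc$serving_size <- list(value = 100, unit = "g")
    doc$declared_profile <- NULL
    doc$components <- list(
      list(id = "a", name = "a", mass_fraction = p,
           profile = list(basis = "per-100g", quantities = qa)),
      list(id = "b", name = "b", mass_fraction = 1 - p,
           profile = list(basis = "per-100g", quantities = qb))
    )
    got <- resolve_profile(load_doc(doc))$profile$quantities
    for (n in names(qa)) {
      expect_equal(unname(got[[n]]), p * qa[[n]] + (1 - p) * qb[[n]],
                   tolerance = 1e-9)
    }
  }
})

test_that("a single full-fraction component resolves to exactly its profile", {
  doc <- minimal_doc(id = "one")
  doc$serving_size <- list(value = 250, unit = "g")
  doc$declared_profile <- NULL
  q <- list(sugar_total = 4.4, protein = 3.3, sodium = 44)
  doc$components <- list(list(id = "only", name = "only", mass_fraction = 1,
                              profile = list(basis = "per-100g", quantities = q)))
  got <- resolve_profile(load_doc(doc))$profile$quantities
  for (n in names(q)) expect_equal(unname(got[[n]]), q[[n]] * 2.5)
})

test_that("reference substitution fills missing profiles and logs assumptions", {
  doc <- minimal_doc(id = "gj", category = "juice")
  doc$serving_size <- list(value = 100, unit = "mL")
  doc$declared_profile <- NULL
  doc$components <- list(
    list(id = "c1", name = "grape juice", mass_fraction = 0.5),
    list(id = "c2", name = "water", mass_fraction = 0.5)
  )
  res <- resolve_profile(load_doc(doc))
  expect_length(res$assumptions, 2)  # one per reference-substituted component
  expect_identical(res$assumptions[[1]]$reference_entry_id, "grape-juice")
  expect_true(length(res$assumptions[[1]]$substituted_fields) > 0)
  expect_equal(unname(res$profile$quantities[["sugar_total"]]), 14.8 * 0.5)
})

test_that("components without profile or reference entry are unresolvable", {
  doc <- minimal_doc(id = "mys")
  doc$declared_profile <- NULL
  doc$components <- list(list(id = "m", name = "mystery paste", mass_fraction = 1))
  err <- expect_error(resolve_profile(load_doc(doc)), class = "mm_unresolvable_component")
  expect_match(conditionMessage(err), "mystery paste")
})

test_that("declared panel wins over rollup with a consistency warning", {
  doc <- minimal_doc(id = "conf",
                     quantities = list(sugar_total = 10))
  doc$serving_size <- list(value = 100, unit = "g")
  doc$components <- list(list(id = "a", name = "a", mass_fraction = 1,
                              profile = list(basis = "per-100g",
                                             quantities = list(sugar_total = 20))))
  res <- resolve_profile(load_doc(doc))
  expect_equal(unname(res$profile$quantities[["sugar_total"]]), 10)
  expect_match(res$warnings, "differ by more than 20%", all = FALSE)
})
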