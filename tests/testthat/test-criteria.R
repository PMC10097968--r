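crit_by_id <- function(id) {
  ids <- vapply(fx_matrix$criteria, `[[`, character(1), "id")
  fx_matrix$criteria[[match(id, ids)]]
}

test_that("max thresholds fail strictly above the boundary, pass at it", {
  cr <- crit_by_id("L1-FAT-OMEGA6")
  base <- list(omega6_total = 0)
  base$omega6_total <- 5.5
  expect_identical(evaluate(make_resolved(base), cr, fx_lexicon)$status, "fail")
  base$omega6_total <- 5.0
  expect_identical(evaluate(make_resolved(base), cr, fx_lexicon)$status, "pass")

  # boundary contract: threshold +/- epsilon flips exactly at the boundary
  eps <- 1e-9
  for (cr2 in list(crit_by_id("L1-SUG-ADDED"), crit_by_id("L1-NA-SODIUM"))) {
    n <- cr2$predicate$nutrient
    thr <- cr2$predicate$value
    at <- setNames(list(thr), n)
    above <- setNames(list(thr + eps), n)
    below <- setNames(list(max(0, thr - eps)), n)
    expect_identical(evaluate(make_resolved(at), cr2, fx_lexicon)$status, "pass")
    expect_identical(evaluate(make_resolved(above), cr2, fx_lexicon)$status, "fail")
    expect_identical(evaluate(make_resolved(below), cr2, fx_lexicon)$status, "pass")
  }
})

test_that("min thresholds pass at the boundary ('at least 400 IU')", {
  cr <- crit_by_id("L3-VIT-D")
  expect_identical(
    evaluate(make_resolved(list(vitamin_d = 400)), cr, fx_lexicon)$status, "pass")
  expect_identical(
    evaluate(make_resolved(list(vitamin_d = 399.999)), cr, fx_lexicon)$status, "fail")
})

test_that("the omega-6:3 ratio passes at 4:1 and handles zero denominators", {
  cr <- crit_by_id("L2-RATIO-O6O3")
  ev <- function(o6, o3) {
    evaluate(make_resolved(list(omega6_total = o6, omega3_total = o3)),
             cr, fx_lexicon)$status
  }
  expect_identical(ev(20, 4), "fail")  # 5:1
  expect_identical(ev(20, 5), "pass")  # exactly 4:1
  expect_identical(ev(20, 3), "fail")
  expect_identical(ev(1, 0), "fail")   # unbounded ratio
  expect_identical(ev(0, 0), "pass")   # vacuous
})

test_that("an all-zero profile passes every max-threshold criterion", {
  zeros <- setNames(as.list(rep(0, length(nutrient_vocabulary()$id))),
                    nutrient_vocabulary()$id)
  subject <- make_resolved(zeros)
  for (cr in fx_matrix$criteria) {
    p <- cr$predicate
    if (p$type == "threshold" && p$direction == "max") {
      oc <- evaluate(subject, cr, fx_lexicon)
      expect_true(oc$status %in% c("pass", "not-applicable"), label = cr$id)
    }
  }
})

test_that("missing measurements fail conservatively and visibly", {
  cr <- crit_by_id("L1-FAT-OMEGA6")
  oc <- evaluate(make_resolved(list(sugar_added = 1)), cr, fx_lexicon)
  expect_identical(oc$status, "fail")
  expect_match(oc$explanation, "value unavailable")

  # conservatism: removing a measurement never flips fail -> pass
  full <- list(omega6_total = 9, omega3_total = 1, sugar_added = 9)
  for (cr2 in fx_matrix$criteria) {
    if (!cr2$predicate$type %in% c("threshold", "ratio")) next
    before <- evaluate(make_resolved(full), cr2, fx_lexicon)$status
    if (before != "fail") next
    for (drop in names(full)) {
      reduced <- full[setdiff(names(full), drop)]
      after <- evaluate(make_resolved(reduced), cr2, fx_lexicon)$status
      expect_identical(after, "fail", label = paste(cr2$id, "without", drop))
    }
  }
})

test_that("ingredient prohibitions respect neutralization and confidence floors", {
  cr <- crit_by_id("L2-ING-SEED-OILS")
  fails <- function(st) {
    evaluate(make_resolved(list(sugar_added = 0), statement = st),
             cr, fx_lexicon)$status
  }
  expect_identical(fails("soybean oil"), "fail")
  expect_identical(fails("cold-pressed soybean oil"), "pass")
  expect_identical(fails("olive oil"), "pass")

  # suspected-confidence concerns stay below the probable floor
  additives <- crit_by_id("L1-ING-ADDITIVES")
  expect_identical(
    evaluate(make_resolved(list(), statement = "aspartame"), additives, fx_lexicon)$status,
    "pass")
  expect_identical(
    evaluate(make_resolved(list(), statement = "carrageenan"), additives, fx_lexicon)$status,
    "fail")
  # whitelist neutralizes the potentially-offending stabilizer
  wl <- make_resolved(list(), statement = "carrageenan", product_id = "wl-1",
                      whitelist = "wl-1")
  expect_identical(evaluate(wl, additives, fx_lexicon)$status, "pass")
})

test_that("out-of-scope criteria are not applicable and never block", {
  cr <- crit_by_id("L3-VIT-D")  # dairy-scoped
  oc <- evaluate(make_resolved(list(vitamin_d = 0), category = "juice"), cr, fx_lexicon)
  expect_identical(oc$status, "not-applicable")
  expect_match(oc$explanation, "scoped")
})

test_that("evaluate_all returns one explained outcome per criterion in order", {
  subject <- make_resolved(list(sugar_added = 1), statement = "water",
                           claims = metabmatrix:::.mm_attributes)
  outs <- evaluate_all(subject, fx_matrix, fx_lexicon)
  expect_length(outs, length(fx_matrix$criteria))
  expect_identical(vapply(outs, `[[`, character(1), "criterion_id"),
                   vapply(fx_matrix$criteria, `[[`, character(1), "id"))
  expect_true(all(nzchar(vapply(outs, `[[`, character(1), "explanation"))))

  expect_length(evaluate_all(subject, list(), fx_lexicon), 0)
  dup <- list(crit_by_id("L1-SUG-ADDED"), crit_by_id("L1-SUG-ADDED"))
  expect_error(evaluate_all(subject, dup, fx_lexicon), class = "mm_config_error")
})

test_that("numeric outcomes cite their measured value and threshold", {
  subject <- make_resolved(list(omega6_total = 6.25, omega3_total = 1))
  for (id in c("L1-FAT-OMEGA6", "L2-RATIO-O6O3")) {
    oc <- evaluate(subject, crit_by_id(id), fx_lexicon)
    expect_match(oc$explanation, format(oc$measured_value, digits = 6), fixed = TRUE)
    expect_match(oc$explanation, format(oc$threshold, digits = 6), fixed = TRUE)
  }
})

test_that("evaluation is a pure function of resolved product and criterion", {
  subject <- make_resolved(list(omega6_total = 2, omega3_total = 1),
                           statement = "soybean oil, carrageenan")
  for (cr in fx_matrix$criteria) {
    a <- evaluate(subject, cr, fx_lexicon, fx_matrix$lists)
    b <- evaluate(subject, cr, fx_lexicon, fx_matrix$lists)
    expect_identical(a, b, label = cr$id)
  }
})

test_that("criteria referencing unknown nutrients are configuration errors", {
  cr <- crit_by_id("L1-SUG-ADDED")
  cr$predicate$nutrient <- "caffeine"
  expect_error(evaluate(make_resolved(list(sugar_added = 0)), cr, fx_lexicon),
               class = "mm_config_error")
  expect_match(paste(validate_criteria(list(cr)), collapse = " "), "caffeine")
})

test_that("calculated ratings band by left-closed interval lookup", {
  cfg <- load_rating_config()
  sub <- function(v) {
    make_resolved(list(sugar_total = v), serving = list(value = 100, unit = "g"))
  }
  expect_identical(unname(compute_rating(sub(2), cfg)["sugar_total"]), "green")
  expect_identical(unname(compute_rating(sub(5), cfg)["sugar_total"]), "green")   # at cut: lower band
  expect_identical(unname(compute_rating(sub(5.01), cfg)["sugar_total"]), "amber")
  expect_identical(unname(compute_rating(sub(40), cfg)["sugar_total"]), "red")
  expect_identical(unname(compute_rating(sub(1), cfg)["sodium"]), "unrated")

  # monotone: increasing a nutrient never lowers its band
  set.seed(11)
  bands <- c(green = 1, amber = 2, red = 3)
  for (i in 1:25) {
    v <- sort(runif(2, 0, 30))
    expect_lte(bands[[compute_rating(sub(v[1]), cfg)["sugar_total"]]],
               bands[[compute_rating(sub(v[2]), cfg)["sugar_total"]]])
  }
})
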