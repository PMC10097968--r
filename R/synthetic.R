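#' @title Synthetic portfolio generator and named scenarios
#' @description The portfolio this framework was originally applied to is
#'   proprietary, so the package ships a seeded generator that emulates a
#'   packaged-food portfolio across dairy, juice, ice-cream and culinary
#'   categories: per-serving nutrient panels covering the full analyte
#'   vocabulary, optional nested component trees with mass fractions, and
#'   ingredient statements exercising every criterion. Distributions are
#'   uniform within configured ranges -- the generator makes no claim of
#'   statistical realism; it exists so that every criterion, the tier
#'   ladder and the reports are testable with no external data.
#' @name synthetic-portfolio
NULL

.mm_attributes <- c("antibiotic-free", "allergen-disclosure", "independently-tested",
                    "science-backed-claims", "cold-pressed-oils", "sustainable-packaging",
                    "traceable-sourcing", "animal-welfare-certified")

mm_with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Construct a generator specification
#'
#' @param seed Integer seed; the same spec always yields identical output.
#' @param n Number of products.
#' @param mix Named category proportions (must sum to 1).
#' @param nesting_prob Probability that a product carries a component tree
#'   (possibly two levels deep) instead of a flat declared panel.
#' @param additive_prob Per-category probability of including a
#'   concern-carrying additive in the ingredient statement.
#' @return An `mm_generator_spec`.
#' @export
generator_spec <- function(seed = 1L, n = 180L,
                           mix = c(dairy = 0.35, juice = 0.25,
                                   `ice-cream` = 0.20, culinary = 0.20),
                           nesting_prob = 0.3,
                           additive_prob = c(dairy = 0.15, juice = 0.15,
                                             `ice-cream` = 0.25, culinary = 0.30)) {
  if (abs(sum(mix) - 1) > 1e-9) {
    mm_error("mm_argument_error", "category mix proportions must sum to 1")
  }
  if (any(mix < 0) || n < 1 || nesting_prob < 0 || nesting_prob > 1) {
    mm_error("mm_argument_error", "invalid generator specification")
  }
  structure(list(seed = as.integer(seed), n = as.integer(n), mix = mix,
                 nesting_prob = nesting_prob, additive_prob = additive_prob),
            class = "mm_generator_spec")
}

r4 <- function(x) round(x, 4)

mm_gen_profile <- function(category) {
  u <- function(a, b) r4(runif(1, a, b))
  q <- list()
  if (category == "dairy") {
    lactose <- u(3, 6)
    added <- u(0, 7)
    q$sugar_added <- added; q$lactose <- lactose; q$sucrose <- added
    q$sugar_total <- r4(added + lactose)
    ft <- u(3, 9)
    q$fat_total <- ft
    q$fat_saturated <- r4(ft * 0.6); q$fat_mufa <- r4(ft * 0.25); q$fat_pufa <- r4(ft * 0.1)
    q$fat_trans <- if (runif(1) < 0.97) 0 else u(0.1, 0.4)
    q$fat_total <- r4(ft + q$fat_trans)
    q$omega6_total <- u(0, 2); q$omega3_total <- u(0.1, 0.8)
    q$epa <- u(0, 60); q$dha <- u(0, 60)
    q$protein <- u(6, 10); q$sodium <- u(40, 140)
    fib <- u(0, 4)
    q$fiber_soluble <- r4(fib * 0.6); q$fiber_insoluble <- r4(fib * 0.4)
    q$fiber_total <- q$fiber_soluble + q$fiber_insoluble
    q$vitamin_d <- u(0, 600); q$vitamin_a <- u(200, 900)
    q$calcium <- u(120, 420); q$zinc <- u(0.3, 2.2); q$magnesium <- u(8, 45)
    q$vitamin_b12 <- u(0.1, 1.6); q$vitamin_b6 <- u(0.02, 0.5)
  } else if (category == "juice") {
    total <- u(6, 22)
    added <- min(total, u(0, 8))
    q$sugar_total <- total; q$sugar_added <- r4(added)
    q$fructose <- r4(total * 0.45); q$glucose <- r4(total * 0.42); q$sucrose <- r4(total * 0.1)
    q$fat_total <- u(0, 0.4)
    q$fat_trans <- 0
    q$omega6_total <- u(0, 0.3); q$omega3_total <- u(0, 0.2)
    q$protein <- u(0.2, 1.5); q$sodium <- u(2, 60)
    fib <- u(0, 4)
    q$fiber_soluble <- r4(fib * 0.7); q$fiber_insoluble <- r4(fib * 0.3)
    q$fiber_total <- q$fiber_soluble + q$fiber_insoluble
    q$iron <- u(0.2, 2.2); q$magnesium <- u(6, 45); q$folate <- u(5, 90)
    q$vitamin_c <- u(10, 90)
  } else if (category == "ice-cream") {
    lactose <- u(3, 6)
    added <- u(0.5, 6.5)
    q$sugar_added <- added; q$lactose <- lactose; q$sucrose <- added
    q$sugar_total <- r4(added + lactose)
    ft <- u(6, 16)
    q$fat_total <- ft
    q$fat_saturated <- r4(ft * 0.65); q$fat_mufa <- r4(ft * 0.22); q$fat_pufa <- r4(ft * 0.08)
    q$fat_trans <- if (runif(1) < 0.95) 0 else u(0.1, 0.5)
    q$fat_total <- r4(ft + q$fat_trans)
    q$omega6_total <- u(0, 1.5); q$omega3_total <- u(0, 0.6)
    q$epa <- u(0, 50); q$dha <- u(0, 50)
    q$protein <- u(2, 6); q$sodium <- u(30, 160)
    fib <- u(0, 3.5)
    q$fiber_soluble <- r4(fib * 0.6); q$fiber_insoluble <- r4(fib * 0.4)
    q$fiber_total <- q$fiber_soluble + q$fiber_insoluble
    q$calcium <- u(80, 380)
  } else { # culinary
    added <- u(0, 5)
    q$sugar_added <- added; q$sucrose <- added; q$sugar_total <- r4(added + u(0, 2))
    ft <- u(2, 14)
    q$fat_total <- ft
    q$fat_saturated <- r4(ft * 0.3); q$fat_mufa <- r4(ft * 0.4); q$fat_pufa <- r4(ft * 0.25)
    q$fat_trans <- if (runif(1) < 0.9) 0 else u(0.1, 0.4)
    q$fat_total <- r4(ft + q$fat_trans)
    q$omega6_total <- u(0, 4); q$omega3_total <- u(0.05, 1.2)
    q$protein <- u(0.5, 5); q$sodium <- u(30, 160)
    fib <- u(0, 3)
    q$fiber_soluble <- r4(fib * 0.5); q$fiber_insoluble <- r4(fib * 0.5)
    q$fiber_total <- q$fiber_soluble + q$fiber_insoluble
    q$iron <- u(0.2, 2)
  }
  # occasional contaminant loads, mostly zero
  q$lead <- if (runif(1) < 0.06) u(0.5, 8) else 0
  q$cadmium <- if (runif(1) < 0.05) u(0.5, 8) else 0
  q$mercury <- if (runif(1) < 0.03) u(0.2, 3) else 0
  q$arsenic <- if (runif(1) < 0.05) u(0.5, 14) else 0
  q$glyphosate <- if (runif(1) < 0.06) u(0.5, 16) else 0
  q
}

.mm_base_statements <- list(
  dairy = "whole milk, cream, cocoa powder, pectin, natural flavors",
  juice = "water, grape juice concentrate, strawberry puree, natural flavors",
  `ice-cream` = "whole milk, cream, sugar, cocoa powder, locust bean gum",
  culinary = "water, extra virgin olive oil, salt, citric acid"
)
.mm_additive_pool <- list(
  dairy = c("carrageenan", "sodium benzoate"),
  juice = c("sodium benzoate", "high fructose corn syrup"),
  `ice-cream` = c("carrageenan", "carboxymethylcellulose", "mono- and diglycerides"),
  culinary = c("soybean oil", "palm oil", "BHA")
)

mm_gen_product <- function(i, category, spec) {
  serving <- switch(category, dairy = list(value = 240, unit = "mL"),
                    juice = list(value = 240, unit = "mL"),
                    `ice-cream` = list(value = 100, unit = "g"),
                    list(value = 15, unit = "g"))
  q <- mm_gen_profile(category)
  statement <- .mm_base_statements[[category]]
  if (runif(1) < spec$additive_prob[[category]]) {
    pool <- .mm_additive_pool[[category]]
    statement <- paste(statement, sample(pool, 1), sep = ", ")
  }
  claims <- if (runif(1) < 0.35) {
    .mm_attributes
  } else {
    keep <- .mm_attributes[runif(length(.mm_attributes)) < 0.55]
    if (runif(1) < 0.95) keep <- union("antibiotic-free", keep)
    keep
  }
  doc <- list(
    id = sprintf("syn-%04d", i),
    name = sprintf("synthetic %s %04d", category, i),
    category = category,
    serving_size = serving,
    servings_per_package = sample(c(1, 1, 1, 4), 1),
    ingredient_statement = statement,
    claims = as.list(claims),
    whitelist_ids = list()
  )
  if (runif(1) < spec$nesting_prob) {
    # component tree whose mass-weighted rollup reproduces the target panel
    # uniform rescale (no re-rounding: that could break species sums)
    per100 <- lapply(q, function(v) v / serving$value * 100)
    base_comp <- list(id = sprintf("c%04d-1", i), name = "base blend",
                      mass_fraction = 0.6, provenance = "assayed",
                      profile = list(basis = if (serving$unit == "mL") "per-100mL" else "per-100g",
                                     quantities = per100))
    if (runif(1) < 0.5) {
      # push the profile one level deeper: two sub-blends of the same panel
      base_comp$profile <- NULL
      base_comp$components <- list(
        list(id = sprintf("c%04d-1a", i), name = "sub-blend A", mass_fraction = 0.5,
             provenance = "assayed",
             profile = list(basis = if (serving$unit == "mL") "per-100mL" else "per-100g",
                            quantities = per100)),
        list(id = sprintf("c%04d-1b", i), name = "sub-blend B", mass_fraction = 0.5,
             provenance = "assayed",
             profile = list(basis = if (serving$unit == "mL") "per-100mL" else "per-100g",
                            quantities = per100))
      )
    }
    doc$components <- list(
      base_comp,
      list(id = sprintf("c%04d-2", i), name = "carrier", mass_fraction = 0.4,
           provenance = "assayed",
           profile = list(basis = if (serving$unit == "mL") "per-100mL" else "per-100g",
                          quantities = per100))
    )
  } else {
    doc$declared_profile <- list(basis = "per-serving", quantities = q)
  }
  doc
}

#' Generate a synthetic product portfolio
#'
#' Deterministic given the spec: the same seed and spec produce byte-identical
#' JSON documents. Every generated product passes [load_product()] and
#' [validate_product()] with zero errors by construction.
#'
#' @param spec An `mm_generator_spec`.
#' @param as_json Return JSON strings instead of document lists.
#' @return A list of product documents (or JSON strings).
#' @export
generate_portfolio <- function(spec = generator_spec(), as_json = FALSE) {
  stopifnot(inherits(spec, "mm_generator_spec"))
  docs <- mm_with_seed(spec$seed, {
    cats <- sample(names(spec$mix), spec$n, replace = TRUE, prob = spec$mix)
    lapply(seq_len(spec$n), function(i) mm_gen_product(i, cats[i], spec))
  })
  if (as_json) {
    lapply(docs, function(d) {
      as.character(jsonlite::toJSON(d, auto_unbox = TRUE, digits = NA, pretty = TRUE))
    })
  } else {
    docs
  }
}

#' Write a generated portfolio to disk
#'
#' One JSON file per product plus a `manifest.json`.
#'
#' @param docs Output of [generate_portfolio()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_portfolio <- function(docs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(docs, function(d) {
    f <- file.path(dir, paste0(d$id, ".json"))
    writeLines(as.character(jsonlite::toJSON(d, auto_unbox = TRUE, digits = NA,
                                             pretty = TRUE)), f)
    basename(f)
  }, character(1))
  jsonlite::write_json(list(count = length(docs), files = files),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Template product passing every default criterion
#'
#' Deterministic (no randomness): a fortified product of the requested
#' category whose panel, statement and claims satisfy all 38 default
#' criteria in scope, used as the base for coverage fixtures and threshold
#' probing.
#'
#' @param category Product category.
#' @param id Product id for the document.
#' @return A product document list.
#' @export
all_pass_product <- function(category = "dairy", id = paste0("fix-all-pass-", category)) {
  serving <- switch(category, dairy = list(value = 240, unit = "mL"),
                    juice = list(value = 240, unit = "mL"),
                    `ice-cream` = list(value = 100, unit = "g"),
                    culinary = list(value = 15, unit = "g"),
                    list(value = 100, unit = "g"))
  q <- list(
    sugar_added = 3, sucrose = 3, sugar_total = 8,
    fat_total = 6, fat_saturated = 3.5, fat_trans = 0, fat_mufa = 1.5, fat_pufa = 0.8,
    omega6_total = 0.5, omega3_total = 0.5, ala = 0.2, epa = 30, dha = 30,
    fiber_total = 2.5, fiber_soluble = 1.5, fiber_insoluble = 1,
    protein = 8, sodium = 100,
    vitamin_d = 450, vitamin_a = 550, calcium = 300, zinc = 1.5, magnesium = 30,
    iron = 1.5, vitamin_b12 = 1.2, vitamin_b6 = 0.3, folate = 60,
    lead = 0, cadmium = 0, mercury = 0, arsenic = 0, glyphosate = 0
  )
  if (category == "dairy" || category == "ice-cream") q$lactose <- 5
  if (category == "juice") {
    q$fructose <- 2.5; q$glucose <- 2.5
    q$protein <- 0.8; q$fat_total <- 0.2
    q$fat_saturated <- 0; q$fat_mufa <- 0; q$fat_pufa <- 0.1
    q$omega6_total <- 0; q$omega3_total <- 0; q$ala <- 0; q$epa <- 0; q$dha <- 0
  }
  if (category == "culinary") q$protein <- 3.5
  statement <- switch(category,
    dairy = "whole milk, cream, cocoa powder, pectin, algal oil, stevia",
    juice = "water, grape juice concentrate, natural flavors, pectin",
    `ice-cream` = "whole milk, cream, cocoa powder, pectin, locust bean gum",
    culinary = "water, extra virgin olive oil, salt, pectin",
    "water, pectin")
  list(id = id, name = paste0("all-pass ", category, " template"),
       category = category, serving_size = serving, servings_per_package = 1,
       ingredient_statement = statement,
       claims = as.list(.mm_attributes), whitelist_ids = list(),
       declared_profile = list(basis = "per-serving", quantities = q))
}

# keep a mutated panel consistent with the species-sum rules
mm_set_nutrient <- function(doc, nutrient, value) {
  q <- doc$declared_profile$quantities
  q[[nutrient]] <- value
  for (rule in nutrient_sum_rules()) {
    if (nutrient %in% rule$parts && !is.null(q[[rule$total]])) {
      s <- sum(unlist(q[intersect(rule$parts, names(q))]))
      if (s > q[[rule$total]]) q[[rule$total]] <- s
    }
    if (nutrient == rule$total) {
      parts <- intersect(rule$parts, names(q))
      s <- sum(unlist(q[parts]))
      if (s > value) for (p in parts) q[[p]] <- value * q[[p]] / s
    }
  }
  doc$declared_profile$quantities <- q
  doc
}

#' Coverage fixtures: one product failing exactly one criterion
#'
#' For every configured criterion, emits (when constructible) a product that
#' fails exactly that criterion while passing all others in scope, plus one
#' all-pass product. Criteria that cannot be isolated -- a prohibition
#' logically entailed by a broader one, or an exclusion list that is empty
#' in the default configuration -- are returned as documented skip records
#' instead.
#'
#' @param matrix An `mm_matrix`.
#' @return A list with `products` (named list of product documents, the
#'   intended single failing criterion in `attr(doc, "fails")`) and `skips`
#'   (data frame `criterion_id`, `reason`).
#' @export
coverage_fixtures <- function(matrix = load_default_matrix()) {
  products <- list()
  skips <- list()
  add_skip <- function(id, reason) {
    skips[[length(skips) + 1]] <<- data.frame(criterion_id = id, reason = reason,
                                              stringsAsFactors = FALSE)
  }
  for (cr in matrix$criteria) {
    scope <- cr$scope %||% character()
    category <- if (length(scope) > 0) scope[[1]] else "dairy"
    doc <- all_pass_product(category, id = paste0("fix-", tolower(cr$id)))
    doc$name <- paste0("isolator for ", cr$id)
    p <- cr$predicate
    if (p$type == "threshold") {
      unit <- canonical_unit(p$nutrient)
      thr <- convert(p$value, p$unit %||% unit, unit, p$nutrient)
      if (p$direction == "max") {
        bump <- if (thr == 0) 0.5 else thr * 1.5
        if (identical(p$basis, "per-100g")) {
          bump <- bump * doc$serving_size$value / 100
        }
        doc <- mm_set_nutrient(doc, p$nutrient, bump)
        if (p$nutrient == "omega6_total") {
          # keep the omega-6:3 ratio inside its own cap
          doc <- mm_set_nutrient(doc, "omega3_total", bump / 4 * 1.05)
        }
        if (identical(p$basis, "per-100g") && p$nutrient == "omega6_total") {
          # per-100g density isolator must stay under the per-serving cap
          doc <- mm_set_nutrient(doc, "omega6_total", min(bump, 4))
          doc <- mm_set_nutrient(doc, "omega3_total", 1.05)
        }
      } else {
        doc <- mm_set_nutrient(doc, p$nutrient, 0)
      }
    } else if (p$type == "ratio") {
      doc <- mm_set_nutrient(doc, p$numerator, 3)
      doc <- mm_set_nutrient(doc, p$denominator, 3 / p$max * 0.8)
    } else if (p$type == "forbid_ingredient") {
      trigger <- switch(cr$id,
        "L1-ING-ADDITIVES" = "carrageenan",
        "L2-ING-SEED-OILS" = "soybean oil",
        "L2-ING-HYDROGENATED" = "hydrogenated coconut oil",
        "L2-ING-REFINED-TROPICAL" = "palm oil",
        NULL)
      if (is.null(trigger)) {
        add_skip(cr$id, "not isolable: every trigger also offends a broader prohibition")
        next
      }
      doc$ingredient_statement <- paste(doc$ingredient_statement, trigger, sep = ", ")
    } else if (p$type == "require_attribute") {
      doc$claims <- as.list(setdiff(unlist(doc$claims), p$attribute))
    } else if (p$type == "list_membership") {
      members <- matrix$lists[[p$list]] %||% character()
      if (identical(p$mode, "exclude") && length(members) == 0) {
        add_skip(cr$id, "not isolable: exclusion list is empty in this configuration")
        next
      }
      if (identical(p$mode, "exclude")) {
        doc$id <- members[[1]]
      } # include-mode: the all-pass id is simply absent from the list
    }
    attr(doc, "fails") <- cr$id
    products[[doc$id]] <- doc
  }
  all_pass <- all_pass_product("dairy", id = "fix-all-pass")
  attr(all_pass, "fails") <- NA_character_
  products[["fix-all-pass"]] <- all_pass
  list(products = products,
       skips = if (length(skips) > 0) do.call(rbind, skips) else
         data.frame(criterion_id = character(), reason = character(),
                    stringsAsFactors = FALSE))
}

#' Named before/after re-engineering scenarios
#'
#' Paired fixtures modeled on the published chocolate-milk and
#' chocolate-ice-cream re-engineering examples: the v1 products fail
#' level-1 sugar (and, for the ice cream, stabilizer/emulsifier) criteria;
#' the v2 reformulations pass level 1. All numeric contents are synthetic
#' stand-ins -- the original compositions are not published.
#'
#' @return A named list of product documents: `chocolate_milk_v1`/`_v2`,
#'   `chocolate_ice_cream_v1`/`_v2`.
#' @export
named_scenarios <- function() {
  milk_q <- list(sugar_added = 11, sucrose = 11, lactose = 5, sugar_total = 16,
                 fat_total = 6, fat_saturated = 3.6, fat_trans = 0, fat_mufa = 1.5,
                 fat_pufa = 0.5, omega6_total = 0.3, omega3_total = 0.2,
                 epa = 0, dha = 0, fiber_total = 1, fiber_soluble = 0.7,
                 fiber_insoluble = 0.3, protein = 8, sodium = 120,
                 vitamin_d = 100, vitamin_a = 300, calcium = 280, zinc = 0.9,
                 magnesium = 25, vitamin_b12 = 0.9, vitamin_b6 = 0.1,
                 lead = 0, cadmium = 0, mercury = 0, arsenic = 0, glyphosate = 0)
  milk_v1 <- list(
    id = "chocolate_milk_v1", name = "chocolate milk (original)",
    category = "dairy", serving_size = list(value = 240, unit = "mL"),
    servings_per_package = 1,
    ingredient_statement = "whole milk, sugar, cocoa powder, natural flavors",
    claims = list("antibiotic-free"), whitelist_ids = list(),
    declared_profile = list(basis = "per-serving", quantities = milk_q))
  milk_v2 <- milk_v1
  milk_v2$id <- "chocolate_milk_v2"
  milk_v2$name <- "chocolate milk (re-engineered)"
  milk_v2$ingredient_statement <-
    "whole milk, cocoa powder, stevia, pectin, algal oil, natural flavors"
  q2 <- milk_q
  q2$sugar_added <- 3; q2$sucrose <- 3; q2$sugar_total <- 8
  q2$omega3_total <- 0.4; q2$epa <- 40; q2$dha <- 40
  q2$fiber_total <- 2.5; q2$fiber_soluble <- 1.8; q2$fiber_insoluble <- 0.7
  milk_v2$declared_profile$quantities <- q2

  ice_q <- list(sugar_added = 14, sucrose = 14, lactose = 5, sugar_total = 19,
                fat_total = 11, fat_saturated = 7, fat_trans = 0, fat_mufa = 2.5,
                fat_pufa = 0.9, omega6_total = 0.6, omega3_total = 0.2,
                epa = 0, dha = 0, fiber_total = 0.8, fiber_soluble = 0.5,
                fiber_insoluble = 0.3, protein = 3.5, sodium = 90,
                calcium = 160, lead = 0, cadmium = 0, mercury = 0,
                arsenic = 0, glyphosate = 0)
  ice_v1 <- list(
    id = "chocolate_ice_cream_v1", name = "chocolate ice cream (original)",
    category = "ice-cream", serving_size = list(value = 100, unit = "g"),
    servings_per_package = 4,
    package_size = list(value = 400, unit = "g"),
    ingredient_statement = "whole milk, cream, sugar, cocoa powder, carrageenan, mono- and diglycerides",
    claims = list("antibiotic-free"), whitelist_ids = list(),
    declared_profile = list(basis = "per-serving", quantities = ice_q))
  ice_v2 <- ice_v1
  ice_v2$id <- "chocolate_ice_cream_v2"
  ice_v2$name <- "chocolate ice cream (re-engineered)"
  ice_v2$ingredient_statement <-
    "whole milk, cream, cocoa powder, allulose, pectin, locust bean gum, algal oil"
  qi2 <- ice_q
  qi2$sugar_added <- 4; qi2$sucrose <- 4; qi2$sugar_total <- 9
  qi2$omega3_total <- 0.3; qi2$epa <- 30; qi2$dha <- 30
  qi2$fiber_total <- 2.2; qi2$fiber_soluble <- 1.6; qi2$fiber_insoluble <- 0.6
  qi2$calcium <- 240
  ice_v2$declared_profile$quantities <- qi2

  list(chocolate_milk_v1 = milk_v1, chocolate_milk_v2 = milk_v2,
       chocolate_ice_cream_v1 = ice_v1, chocolate_ice_cream_v2 = ice_v2)
}
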