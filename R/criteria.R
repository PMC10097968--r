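#' @title Declarative criterion model and evaluator
#' @description One criterion is one declarative rule -- a nutrient threshold
#'   on a stated basis, a nutrient ratio cap, an ingredient prohibition with
#'   concern category and confidence floor, a required product attribute, or
#'   membership on a named list -- and every evaluation returns an explained
#'   outcome tracing value, rule and verdict. There is deliberately no
#'   numeric scoring or averaging anywhere: criteria pass or fail
#'   individually and the tier ladder consumes them as such.
#' @name criteria
NULL

.mm_pillars <- c("feed-gut", "protect-liver", "support-brain", "transparency",
                 "sustainability")
.mm_predicate_types <- c("threshold", "ratio", "forbid_ingredient",
                         "require_attribute", "list_membership")

#' Validate a list of criterion records
#'
#' Checks every criterion and returns all violations (not just the first):
#' unique ids, level in 1..5, known pillar, categories drawn from the closed
#' enum, exactly one well-formed predicate, non-negative thresholds, nutrient
#' ids from the controlled vocabulary, strictly positive ratio caps.
#'
#' @param criteria List of criterion records.
#' @return Character vector of violation messages (empty when valid).
#' @export
validate_criteria <- function(criteria) {
  msgs <- character()
  ids <- vapply(criteria, function(cr) cr$id %||% NA_character_, character(1))
  if (anyDuplicated(ids)) {
    msgs <- c(msgs, paste0("duplicate criterion ids: ",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (cr in criteria) {
    where <- cr$id %||% "<missing id>"
    lvl <- cr$level %||% NA
    if (!is.numeric(lvl) || is.na(lvl) || lvl < 1 || lvl > 5) {
      msgs <- c(msgs, sprintf("%s: level must be an integer in 1..5", where))
    }
    if (!(cr$pillar %||% "") %in% .mm_pillars) {
      msgs <- c(msgs, sprintf("%s: unknown pillar '%s'", where, cr$pillar %||% ""))
    }
    bad_scope <- setdiff(cr$scope %||% character(), .mm_categories)
    if (length(bad_scope) > 0) {
      msgs <- c(msgs, sprintf("%s: scope categories not in the closed enum: %s",
                              where, paste(bad_scope, collapse = ", ")))
    }
    p <- cr$predicate
    if (is.null(p) || !(p$type %||% "") %in% .mm_predicate_types) {
      msgs <- c(msgs, sprintf("%s: predicate type must be one of {%s}", where,
                              paste(.mm_predicate_types, collapse = ", ")))
      next
    }
    if (p$type == "threshold") {
      if (!(p$nutrient %||% "") %in% nutrient_ids()) {
        msgs <- c(msgs, sprintf("%s: nutrient '%s' not in the controlled vocabulary",
                                where, p$nutrient %||% ""))
      }
      if (!(p$direction %||% "") %in% c("max", "min")) {
        msgs <- c(msgs, sprintf("%s: threshold direction must be max or min", where))
      }
      if (!is.numeric(p$value %||% NA) || is.na(p$value) || p$value < 0) {
        msgs <- c(msgs, sprintf("%s: threshold value must be >= 0", where))
      }
      if (!(p$basis %||% "per-serving") %in% c("per-serving", "per-100g")) {
        msgs <- c(msgs, sprintf("%s: threshold basis must be per-serving or per-100g", where))
      }
    } else if (p$type == "ratio") {
      for (n in c(p$numerator, p$denominator)) {
        if (!(n %||% "") %in% nutrient_ids()) {
          msgs <- c(msgs, sprintf("%s: nutrient '%s' not in the controlled vocabulary",
                                  where, n %||% ""))
        }
      }
      if (!is.numeric(p$max %||% NA) || is.na(p$max) || p$max <= 0) {
        msgs <- c(msgs, sprintf("%s: ratio cap must be > 0", where))
      }
    } else if (p$type == "forbid_ingredient") {
      if (!nzchar(p$target %||% "")) {
        msgs <- c(msgs, sprintf("%s: forbid_ingredient needs a target", where))
      }
      if (!(p$min_confidence %||% "probable") %in% names(.mm_confidence_rank)) {
        msgs <- c(msgs, sprintf("%s: unknown min_confidence", where))
      }
    } else if (p$type == "require_attribute") {
      if (!nzchar(p$attribute %||% "")) {
        msgs <- c(msgs, sprintf("%s: require_attribute needs an attribute id", where))
      }
    } else if (p$type == "list_membership") {
      if (!nzchar(p$list %||% "")) {
        msgs <- c(msgs, sprintf("%s: list_membership needs a list id", where))
      }
      if (!(p$mode %||% "") %in% c("include", "exclude")) {
        msgs <- c(msgs, sprintf("%s: list_membership mode must be include or exclude", where))
      }
    }
  }
  msgs
}

#' Resolve a product for evaluation
#'
#' One-stop preparation of everything the evaluator needs: the per-serving
#' nutrient profile (with assumption records), the canonicalized ingredient
#' entries from the product statement and every component statement, folded
#' claims and detected allergens.
#'
#' @param product An `mm_product`.
#' @param lexicon An `mm_lexicon`.
#' @param references Reference registry.
#' @param allergens An `mm_allergen_registry` (or `NULL` to skip detection).
#' @return An `mm_resolved` object.
#' @export
resolve_product <- function(product, lexicon = load_lexicon(),
                            references = load_reference_registry(),
                            allergens = load_allergen_registry("big8")) {
  rp <- resolve_profile(product, references)
  statements <- c(product$ingredient_statement, mm_component_statements(product$components))
  statements <- statements[nzchar(trimws(statements))]
  parsed <- do.call(c, c(list(list()), lapply(statements, resolve_statement, lexicon = lexicon)))
  flat <- flatten_parsed(parsed)
  unknown <- unique(vapply(
    Filter(function(e) identical(e$canonical_id, UNKNOWN_INGREDIENT), flat),
    function(e) e$raw, character(1)))
  structure(list(
    product_id = product$id,
    name = product$name,
    category = product$category,
    serving_size = product$serving_size,
    profile = rp$profile,
    parsed = parsed,
    unknown_ingredients = unknown,
    claims = vapply(product$claims, fold_term, character(1), USE.NAMES = FALSE),
    whitelist_ids = product$whitelist_ids,
    assumptions = rp$assumptions,
    warnings = rp$warnings,
    allergens = if (!is.null(allergens)) {
      detect_allergens(parsed, allergens)
    } else character(),
    allergen_mode = if (!is.null(allergens)) allergens$mode else NA_character_
  ), class = "mm_resolved")
}

mm_component_statements <- function(comps) {
  unlist(lapply(comps, function(cm) {
    c(cm$ingredient_statement %||% "", mm_component_statements(cm$components))
  })) %||% character()
}

mm_outcome <- function(criterion, status, measured = NA_real_, unit = NA_character_,
                       threshold = NA_real_, explanation) {
  structure(list(criterion_id = criterion$id, level = criterion$level,
                 pillar = criterion$pillar, status = status,
                 measured_value = measured, unit = unit, threshold = threshold,
                 explanation = explanation), class = "mm_outcome")
}

#' Evaluate one criterion against a resolved product
#'
#' Pure function of (resolved product, criterion). Boundary semantics follow
#' the framework's own phrasing: a max threshold passes at the boundary and
#' fails strictly above it ("no more than"); a min threshold passes at the
#' boundary ("at least"). A ratio passes vacuously when numerator and
#' denominator are both zero and fails when only the denominator is zero. A
#' nutrient with no measurement fails conservatively with the explanation
#' "value unavailable" -- data gaps must stay visible, never silently pass.
#' Criteria scoped to other product categories return `not-applicable`.
#'
#' @param resolved An `mm_resolved` product.
#' @param criterion A criterion record.
#' @param lexicon An `mm_lexicon` (used by ingredient predicates).
#' @param lists Named lists for `list_membership` predicates.
#' @return An `mm_outcome` with a non-empty explanation.
#' @export
evaluate <- function(resolved, criterion, lexicon = load_lexicon(), lists = list()) {
  p <- criterion$predicate
  scope <- criterion$scope %||% character()
  if (length(scope) > 0 && !resolved$category %in% scope) {
    return(mm_outcome(criterion, "not-applicable",
                      explanation = sprintf(
                        "criterion is scoped to {%s}; product category is %s",
                        paste(scope, collapse = ", "), resolved$category)))
  }
  switch(p$type,
    threshold = mm_eval_threshold(resolved, criterion),
    ratio = mm_eval_ratio(resolved, criterion),
    forbid_ingredient = mm_eval_forbid(resolved, criterion, lexicon),
    require_attribute = mm_eval_attribute(resolved, criterion),
    list_membership = mm_eval_list(resolved, criterion, lists),
    mm_error("mm_config_error", paste0("unknown predicate type: ", p$type))
  )
}

mm_eval_threshold <- function(resolved, criterion) {
  p <- criterion$predicate
  if (!p$nutrient %in% nutrient_ids()) {
    mm_error("mm_config_error",
             sprintf("criterion %s references unknown nutrient '%s'", criterion$id, p$nutrient))
  }
  unit <- canonical_unit(p$nutrient)
  thr <- convert(p$value, p$unit %||% unit, unit, p$nutrient)
  q <- resolved$profile$quantities
  basis <- p$basis %||% "per-serving"
  if (!p$nutrient %in% names(q) || is.na(q[[p$nutrient]])) {
    return(mm_outcome(criterion, "fail", measured = NA_real_, unit = unit, threshold = thr,
                      explanation = sprintf(
                        "value unavailable: no measurement for %s; threshold %s %.6g %s %s fails conservatively",
                        p$nutrient, if (p$direction == "max") "max" else "min", thr, unit, basis)))
  }
  value <- q[[p$nutrient]]
  if (basis == "per-100g") value <- value / resolved$serving_size$value * 100
  inclusive <- !identical(p$inclusive, FALSE)
  pass <- if (p$direction == "max") {
    if (inclusive) value <= thr else value < thr
  } else {
    if (inclusive) value >= thr else value > thr
  }
  mm_outcome(criterion, if (pass) "pass" else "fail",
             measured = value, unit = unit, threshold = thr,
             explanation = sprintf(
               "%s = %.6g %s %s; %s %.6g %s -> %s",
               p$nutrient, value, unit, basis,
               if (p$direction == "max") "allowed at most" else "required at least",
               thr, unit, if (pass) "pass" else "fail"))
}

mm_eval_ratio <- function(resolved, criterion) {
  p <- criterion$predicate
  q <- resolved$profile$quantities
  num_name <- p$numerator; den_name <- p$denominator
  if (!num_name %in% names(q) || !den_name %in% names(q)) {
    missing <- setdiff(c(num_name, den_name), names(q))
    return(mm_outcome(criterion, "fail", threshold = p$max,
                      explanation = sprintf(
                        "value unavailable: no measurement for %s; ratio cap %.6g fails conservatively",
                        paste(missing, collapse = ", "), p$max)))
  }
  num <- q[[num_name]]; den <- q[[den_name]]
  if (den == 0 && num == 0) {
    return(mm_outcome(criterion, "pass", measured = 0, threshold = p$max,
                      explanation = sprintf("%s and %s both absent; ratio cap %.6g passes vacuously",
                                            num_name, den_name, p$max)))
  }
  if (den == 0) {
    return(mm_outcome(criterion, "fail", measured = Inf, threshold = p$max,
                      explanation = sprintf(
                        "%s = %.6g with %s = 0: ratio unbounded, cap %.6g -> fail",
                        num_name, num, den_name, p$max)))
  }
  ratio <- num / den
  pass <- ratio <= p$max
  mm_outcome(criterion, if (pass) "pass" else "fail",
             measured = ratio, threshold = p$max,
             explanation = sprintf("%s/%s = %.6g/%.6g = %.6g; allowed at most %.6g -> %s",
                                   num_name, den_name, num, den, ratio, p$max,
                                   if (pass) "pass" else "fail"))
}

mm_eval_forbid <- function(resolved, criterion, lexicon) {
  p <- criterion$predicate
  min_rank <- .mm_confidence_rank[[p$min_confidence %||% "probable"]]
  target <- p$target
  kind <- p$target_kind %||% if (identical(target, "*")) "any" else "group"
  offenders <- character()
  for (e in flatten_parsed(resolved$parsed)) {
    cid <- e$canonical_id %||% UNKNOWN_INGREDIENT
    if (identical(cid, UNKNOWN_INGREDIENT)) next
    matched <- switch(kind,
      any = TRUE,
      ingredient = identical(cid, target),
      group = target %in% effective_groups(cid, e$modifiers, lexicon),
      identical(cid, target) || target %in% effective_groups(cid, e$modifiers, lexicon)
    )
    if (!matched) next
    st <- resolve_concern(e, p$concern_category, resolved$whitelist_ids,
                          resolved$product_id, lexicon)
    offending <- st$status %in% c("offending", "potentially-offending") &&
      !is.na(st$confidence) && .mm_confidence_rank[[st$confidence]] >= min_rank
    if (!offending && kind != "any" && identical(st$status, "benign") &&
        is.na(st$confidence)) {
      # membership in an explicitly banned group/id with no recorded concern:
      # the presence itself is the concern, and it is not neutralizable
      offending <- TRUE
      st$status <- "offending"; st$confidence <- "established"
    }
    if (offending) {
      offenders <- c(offenders, sprintf("%s (%s, %s/%s)", e$raw, cid, st$status, st$confidence))
    }
  }
  if (length(offenders) == 0) {
    mm_outcome(criterion, "pass",
               explanation = sprintf(
                 "no ingredient matching target '%s' is %s-or-worse for %s at confidence >= %s",
                 target, "potentially-offending", p$concern_category,
                 p$min_confidence %||% "probable"))
  } else {
    mm_outcome(criterion, "fail",
               explanation = sprintf("offending for %s (min confidence %s): %s",
                                     p$concern_category, p$min_confidence %||% "probable",
                                     paste(offenders, collapse = "; ")))
  }
}

mm_eval_attribute <- function(resolved, criterion) {
  attr_id <- fold_term(criterion$predicate$attribute)
  present <- attr_id %in% resolved$claims
  mm_outcome(criterion, if (present) "pass" else "fail",
             explanation = sprintf("attribute '%s' %s among product claims -> %s",
                                   criterion$predicate$attribute,
                                   if (present) "present" else "absent",
                                   if (present) "pass" else "fail"))
}

mm_eval_list <- function(resolved, criterion, lists) {
  p <- criterion$predicate
  members <- lists[[p$list]] %||% character()
  on_list <- resolved$product_id %in% members
  pass <- if (identical(p$mode, "include")) on_list else !on_list
  mm_outcome(criterion, if (pass) "pass" else "fail",
             explanation = sprintf("product %s is %s list '%s' (%s mode) -> %s",
                                   resolved$product_id,
                                   if (on_list) "on" else "not on", p$list, p$mode,
                                   if (pass) "pass" else "fail"))
}

#' Evaluate every criterion of a configuration
#'
#' @param resolved An `mm_resolved` product.
#' @param criteria_set List of criterion records (must have unique ids) or an
#'   `mm_matrix` configuration.
#' @param lexicon An `mm_lexicon`.
#' @param lists Named lists for `list_membership` predicates; defaults to the
#'   matrix's own lists when `criteria_set` is an `mm_matrix`.
#' @return A list of `mm_outcome`, one per criterion, order preserved.
#' @export
evaluate_all <- function(resolved, criteria_set, lexicon = load_lexicon(), lists = NULL) {
  if (inherits(criteria_set, "mm_matrix")) {
    lists <- lists %||% criteria_set$lists
    criteria_set <- criteria_set$criteria
  }
  ids <- vapply(criteria_set, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    mm_error("mm_config_error",
             paste0("duplicate criterion ids: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  lapply(criteria_set, function(cr) evaluate(resolved, cr, lexicon, lists %||% list()))
}

#' Compute calculated ratings for a rating-system configuration
#'
#' Demonstration of the pluggable calculated-ratings capability (front-of-
#' pack schemes such as traffic lights). Each configured nutrient is rated
#' by interval lookup of its value on the configured basis; intervals are
#' left-closed downward, i.e. a value equal to a cut point falls in the
#' lower band. Entirely independent of tier logic.
#'
#' @param resolved An `mm_resolved` product.
#' @param config A rating config (see `rating.traffic_light.example.json`):
#'   `bands` (low to high), `basis`, and per-nutrient strictly increasing
#'   `cuts`.
#' @return Named character vector: nutrient id to band (or `"unrated"`).
#' @export
compute_rating <- function(resolved, config) {
  q <- resolved$profile$quantities
  out <- character()
  for (nid in names(config$nutrients)) {
    cuts <- unlist(config$nutrients[[nid]]$cuts)
    if (is.unsorted(cuts, strictly = TRUE)) {
      mm_error("mm_config_error",
               sprintf("rating cut points for %s must be strictly increasing", nid))
    }
    if (!nid %in% names(q)) {
      out[nid] <- "unrated"
      next
    }
    value <- q[[nid]]
    if (identical(config$basis, "per-100g")) {
      value <- value / resolved$serving_size$value * 100
    }
    band <- findInterval(value, cuts, left.open = TRUE) + 1L
    out[nid] <- unlist(config$bands)[band]
  }
  out
}

#' Load a rating-system configuration file
#'
#' @param path JSON path; default = the bundled traffic-light demonstration.
#' @return The parsed config list.
#' @export
load_rating_config <- function(path = mm_extdata("rating.traffic_light.example.json")) {
  jsonlite::read_json(path)
}
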