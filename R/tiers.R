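#' @title Layered tier assignment, recommendations, threshold probing
#' @description Tier assignment is layered, never averaged: level-1
#'   (harm-reduction) criteria gate the first ascent out of the
#'   conventional-food floor, and a product's label is the highest tier
#'   whose gating levels *all* pass. Positive attributes at higher levels
#'   can never compensate a failure below -- a product with cold-pressed
#'   olive oil and added B vitamins but excess omega-6 stays at the bottom.
#' @name tiers
NULL

#' Ordered tier labels
#'
#' Six labels, five gated ascents: `III` (conventional foods and beverages,
#' the unconditional floor with no criteria of its own) then `II-C`, `II-B`,
#' `II-A`, `I-B`, `I-A`, gated by criterion levels 1..5 respectively.
#'
#' @return Character vector of the six labels in ascending order.
#' @export
tier_labels <- function() c("III", "II-C", "II-B", "II-A", "I-B", "I-A")

#' Assign a tier from criterion outcomes
#'
#' The label is the highest tier whose gating levels 1..L all pass, where a
#' level passes when none of its outcomes is a failure (`not-applicable`
#' counts as a pass: scoped criteria must not trap out-of-scope categories).
#' Failures above the first blocked level are still recorded but cannot
#' affect the label, and there is no score averaging of any kind.
#'
#' @param outcomes List of `mm_outcome` covering the criteria set.
#' @param criteria_set List of criterion records or an `mm_matrix`.
#' @return An `mm_tier` with `label`, `level_index` (0..5 ascents gained),
#'   `per_level_pass`, and `blocking` (failed outcomes at the lowest
#'   non-passed level; empty iff the label is `I-A`).
#' @export
assign_tier <- function(outcomes, criteria_set) {
  if (inherits(criteria_set, "mm_matrix")) criteria_set <- criteria_set$criteria
  ids <- vapply(criteria_set, `[[`, character(1), "id")
  out_ids <- vapply(outcomes, `[[`, character(1), "criterion_id")
  missing <- setdiff(ids, out_ids)
  if (length(missing) > 0) {
    mm_error("mm_incomplete_evaluation",
             paste0("outcomes missing for configured criteria: ",
                    paste(missing, collapse = ", ")))
  }
  levels <- vapply(outcomes, `[[`, numeric(1), "level")
  status <- vapply(outcomes, `[[`, character(1), "status")
  per_level_pass <- vapply(1:5, function(l) {
    idx <- levels == l
    !any(status[idx] == "fail")
  }, logical(1))
  names(per_level_pass) <- as.character(1:5)
  ascent <- 0L
  for (l in 1:5) {
    if (per_level_pass[l]) ascent <- l else break
  }
  label <- tier_labels()[ascent + 1L]
  blocking <- list()
  if (ascent < 5L) {
    block_level <- ascent + 1L
    blocking <- outcomes[levels == block_level & status == "fail"]
  }
  structure(list(label = label, level_index = ascent,
                 per_level_pass = per_level_pass, blocking = blocking),
            class = "mm_tier")
}

#' @export
print.mm_tier <- function(x, ...) {
  cat(sprintf("<tier %s: levels passed [%s]%s>\n", x$label,
              paste(which(x$per_level_pass), collapse = ","),
              if (length(x$blocking) > 0) {
                paste0(", blocked by ",
                       paste(vapply(x$blocking, `[[`, character(1), "criterion_id"),
                             collapse = ", "))
              } else ""))
  invisible(x)
}

#' Load the strategy template registry
#'
#' @param path JSON path; default = the bundled registry whose sugar list
#'   seeds the juice sugar-mitigation strategies.
#' @return The parsed template registry.
#' @export
load_strategy_templates <- function(path = NULL) {
  if (is.null(path)) {
    return(mm_cached("strategies", function() {
      jsonlite::read_json(mm_extdata("strategies.table4.json"))
    }))
  }
  jsonlite::read_json(path)
}

.mm_sugar_nutrients <- c("sugar_total", "sugar_added", "sucrose", "glucose",
                         "fructose", "galactose", "lactose")

#' Recommend modifications to reach the next tier
#'
#' Emits exactly one recommendation per blocking outcome at the next gated
#' level: numeric criteria get the criterion boundary as the target value,
#' ingredient prohibitions a removal/replacement action, required attributes
#' a documentation action. Strategy texts are selected by nutrient family
#' (sugar criteria draw the juice sugar-mitigation strategy set) or by
#' criterion pillar.
#'
#' @param resolved The `mm_resolved` product.
#' @param tier_result An `mm_tier` from [assign_tier()].
#' @param criteria_set List of criterion records or an `mm_matrix`.
#' @param templates Strategy registry from [load_strategy_templates()].
#' @return A list of recommendation records; empty when the label is `I-A`.
#' @export
recommend <- function(resolved, tier_result, criteria_set,
                      templates = load_strategy_templates()) {
  if (inherits(criteria_set, "mm_matrix")) criteria_set <- criteria_set$criteria
  if (length(tier_result$blocking) == 0) return(list())
  by_id <- setNames(criteria_set, vapply(criteria_set, `[[`, character(1), "id"))
  lapply(tier_result$blocking, function(oc) {
    cr <- by_id[[oc$criterion_id]]
    p <- cr$predicate
    target <- NA_real_
    action <- NULL
    if (p$type == "threshold") {
      target <- convert(p$value, p$unit %||% canonical_unit(p$nutrient),
                        canonical_unit(p$nutrient), p$nutrient)
      action <- sprintf("%s %s to %s %.6g %s %s",
                        if (p$direction == "max") "Reduce" else "Raise",
                        p$nutrient,
                        if (p$direction == "max") "at most" else "at least",
                        target, canonical_unit(p$nutrient), p$basis %||% "per-serving")
    } else if (p$type == "ratio") {
      target <- p$max
      action <- sprintf("Bring the %s:%s ratio to at most %.6g (raise %s or reduce %s)",
                        p$numerator, p$denominator, p$max, p$denominator, p$numerator)
    } else if (p$type == "forbid_ingredient") {
      action <- sprintf("Remove or replace ingredients offending for %s (target: %s)",
                        p$concern_category, p$target)
    } else if (p$type == "require_attribute") {
      action <- sprintf("Document and certify the '%s' attribute", p$attribute)
    } else if (p$type == "list_membership") {
      action <- sprintf("Resolve the product's status on list '%s'", p$list)
    }
    strategies <- if (p$type %in% c("threshold", "ratio") &&
                      any(c(p$nutrient, p$numerator) %in% .mm_sugar_nutrients)) {
      unlist(templates$nutrient_families$sugar)
    } else {
      unlist(templates$pillars[[cr$pillar]] %||% list())
    }
    list(criterion_id = cr$id, level = cr$level,
         current_value = oc$measured_value, target_value = target,
         unit = oc$unit, action = action,
         strategy_texts = as.character(strategies))
  })
}

#' Probe a criterion's pass/fail boundary by bisection
#'
#' A verification instrument: vary one nutrient of a template product across
#' `[low, high]`, evaluate only the named criterion, and bisect the pass/fail
#' boundary to within `tolerance`. The template must flip verdict exactly
#' once across the interval; a flat interval raises an `mm_probe_error`.
#'
#' @param criteria_set List of criterion records or an `mm_matrix`.
#' @param criterion_id Id of the criterion to probe.
#' @param template An `mm_resolved` product used as the probing template.
#' @param nutrient Nutrient id to vary (per-serving).
#' @param low,high Interval endpoints.
#' @param tolerance Bisection tolerance (default `1e-6`).
#' @param lexicon An `mm_lexicon`.
#' @return The boundary value (midpoint of the final bracket).
#' @export
probe_threshold <- function(criteria_set, criterion_id, template, nutrient,
                            low, high, tolerance = 1e-6,
                            lexicon = load_lexicon()) {
  lists <- list()
  if (inherits(criteria_set, "mm_matrix")) {
    lists <- criteria_set$lists
    criteria_set <- criteria_set$criteria
  }
  ids <- vapply(criteria_set, `[[`, character(1), "id")
  idx <- match(criterion_id, ids)
  if (is.na(idx)) mm_error("mm_lookup_error", paste0("unknown criterion id: ", criterion_id))
  cr <- criteria_set[[idx]]
  passes <- function(v) {
    template$profile$quantities[[nutrient]] <- v
    oc <- evaluate(template, cr, lexicon, lists)
    if (oc$status == "not-applicable") {
      mm_error("mm_probe_error",
               sprintf("criterion %s is not applicable to the template's category (%s)",
                       criterion_id, template$category))
    }
    oc$status == "pass"
  }
  p_low <- passes(low)
  p_high <- passes(high)
  if (identical(p_low, p_high)) {
    mm_error("mm_probe_error",
             sprintf("no pass/fail sign change for %s over [%g, %g] when varying %s",
                     criterion_id, low, high, nutrient))
  }
  while (high - low > tolerance) {
    mid <- (low + high) / 2
    if (identical(passes(mid), p_low)) low <- mid else high <- mid
  }
  (low + high) / 2
}
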