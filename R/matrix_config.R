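#' @title Default matrix configuration and intake references
#' @description The shipped default configuration holds 38 criteria in five
#'   progressive levels (allocation 12/5/9/8/4). Four thresholds are
#'   normative to the framework -- added sugar at most one teaspoon (4.2 g)
#'   per serving, omega-6 at most 5 g per serving, an omega-6:omega-3 ratio
#'   of at most 4:1, and at least 400 IU vitamin D per serving for dairy --
#'   while the remaining criteria are reconstructions guided by the level
#'   themes (healthy fats, sugars, additives, salt, heavy metals, pesticides
#'   and antibiotics at level 1; vegetable oils at level 2; vitamin, mineral,
#'   fatty-acid and fiber minimums at level 3; further targets, allergen
#'   informatics, testing and cold-pressed oils at level 4; sustainability
#'   and traceable sourcing at level 5) and flagged non-normative.
#' @name matrix-config
NULL

.mm_default_allocation <- c(`1` = 12L, `2` = 5L, `3` = 9L, `4` = 8L, `5` = 4L)

#' Load a matrix configuration file
#'
#' Parses and validates a criteria configuration; load fails loudly with a
#' full violation listing on any breach.
#'
#' @param path Configuration JSON path.
#' @param expect_default When `TRUE`, additionally enforce the default-
#'   configuration invariants: exactly 38 criteria across 5 levels and the
#'   four normative thresholds present with their stated values.
#' @return An `mm_matrix` with `version`, `criteria`, `lists`,
#'   `intake_references`.
#' @export
load_matrix <- function(path, expect_default = FALSE) {
  doc <- jsonlite::read_json(path)
  criteria <- doc$criteria %||% list()
  criteria <- lapply(criteria, function(cr) {
    cr$scope <- as.character(unlist(cr$scope %||% list()))
    cr$level <- as.integer(cr$level)
    cr
  })
  msgs <- validate_criteria(criteria)
  levels <- vapply(criteria, `[[`, integer(1), "level")
  if (!all(1:5 %in% levels)) {
    msgs <- c(msgs, "every level 1..5 must contain at least one criterion")
  }
  if (expect_default) {
    if (length(criteria) != 38) {
      msgs <- c(msgs, sprintf("default configuration must hold 38 criteria, found %d",
                              length(criteria)))
    }
    msgs <- c(msgs, mm_check_normative(criteria))
  }
  if (length(msgs) > 0) {
    mm_error("mm_config_error",
             paste0("invalid matrix configuration (", path, "):\n",
                    paste0("  - ", msgs, collapse = "\n")))
  }
  structure(list(
    version = doc$version %||% "unversioned",
    criteria = criteria,
    lists = lapply(doc$lists %||% list(), function(x) as.character(unlist(x))),
    intake_references = load_intake_references()
  ), class = "mm_matrix")
}

mm_check_normative <- function(criteria) {
  msgs <- character()
  by_id <- setNames(criteria, vapply(criteria, `[[`, character(1), "id"))
  want <- list(
    list(id = "L1-SUG-ADDED", level = 1L,
         chk = function(p) p$type == "threshold" && p$nutrient == "sugar_added" &&
           p$direction == "max" && isTRUE(all.equal(p$value, 4.2))),
    list(id = "L1-FAT-OMEGA6", level = 1L,
         chk = function(p) p$type == "threshold" && p$nutrient == "omega6_total" &&
           p$direction == "max" && isTRUE(all.equal(p$value, 5))),
    list(id = "L2-RATIO-O6O3", level = 2L,
         chk = function(p) p$type == "ratio" && isTRUE(all.equal(p$max, 4))),
    list(id = "L3-VIT-D", level = 3L,
         chk = function(p) p$type == "threshold" && p$nutrient == "vitamin_d" &&
           p$direction == "min" && isTRUE(all.equal(p$value, 400)))
  )
  for (w in want) {
    cr <- by_id[[w$id]]
    if (is.null(cr)) {
      msgs <- c(msgs, sprintf("normative criterion %s is missing", w$id))
    } else if (cr$level != w$level || !isTRUE(w$chk(cr$predicate))) {
      msgs <- c(msgs, sprintf("normative criterion %s has been altered", w$id))
    }
  }
  msgs
}

#' Load the bundled default matrix configuration
#'
#' Pure and deterministic: repeated loads return identical configurations.
#'
#' @return An `mm_matrix` with the validated 38-criterion default set.
#' @export
#' @examples
#' m <- load_default_matrix()
#' length(m$criteria)  # 38
load_default_matrix <- function() {
  mm_cached("default_matrix", function() {
    load_matrix(mm_extdata("matrix.default.json"), expect_default = TRUE)
  })
}

load_intake_references <- function(path = NULL) {
  loader <- function(p) {
    doc <- jsonlite::read_json(p)
    refs <- lapply(doc$references, function(r) {
      if (r$lower > r$upper) {
        mm_error("mm_config_error",
                 sprintf("intake reference %s/%s: lower %g exceeds upper %g",
                         r$nutrient, r$population, r$lower, r$upper))
      }
      r
    })
    refs
  }
  if (is.null(path)) {
    return(mm_cached("intake_refs", function() loader(mm_extdata("intake_references.json"))))
  }
  loader(path)
}

#' Look up a daily intake reference range
#'
#' @param nutrient Nutrient key (e.g. `"epa_dha"` for the combined EPA+DHA
#'   adult range of 250--500 mg/day).
#' @param population Population tag (default `"adult"`).
#' @param references Parsed reference list (default: bundled).
#' @return The reference record (`nutrient`, `population`, `lower`, `upper`,
#'   `unit`, `note`).
#' @export
#' @examples
#' lookup_intake_reference("epa_dha")$lower  # 250
lookup_intake_reference <- function(nutrient, population = "adult",
                                    references = load_intake_references()) {
  for (r in references) {
    if (identical(r$nutrient, nutrient) && identical(r$population, population)) {
      return(r)
    }
  }
  mm_error("mm_lookup_error",
           sprintf("no intake reference for %s (%s)", nutrient, population))
}

#' Evaluate a product end to end
#'
#' Convenience pipeline: resolve, evaluate every configured criterion,
#' assign the tier, and generate recommendations.
#'
#' @param product An `mm_product`.
#' @param matrix An `mm_matrix` (default: the bundled default).
#' @param lexicon,references,allergens,templates Supporting registries.
#' @return A list with `resolved`, `outcomes`, `tier`, `recommendations`.
#' @export
evaluate_product <- function(product, matrix = load_default_matrix(),
                             lexicon = load_lexicon(),
                             references = load_reference_registry(),
                             allergens = load_allergen_registry("big8"),
                             templates = load_strategy_templates()) {
  resolved <- resolve_product(product, lexicon, references, allergens)
  outcomes <- evaluate_all(resolved, matrix, lexicon)
  tier <- assign_tier(outcomes, matrix)
  recs <- recommend(resolved, tier, matrix, templates)
  list(resolved = resolved, outcomes = outcomes, tier = tier, recommendations = recs)
}
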