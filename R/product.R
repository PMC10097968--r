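#' @title Hierarchical product model: ingestion, validation, nutrient rollup
#' @description Products are JSON documents (one file per product) holding a
#'   nested component tree with mass fractions, ingredient statements and
#'   nutrient profiles. These functions load such documents, check every
#'   structural invariant, and aggregate component profiles into a single
#'   per-serving nutrient profile while logging every reference substitution
#'   as an assumption record.
#' @name product-model
NULL

.mm_categories <- c("dairy", "juice", "ice-cream", "culinary", "beverage", "other")
.mm_bases <- c("per-serving", "per-100g", "per-100mL")
.mm_provenance <- c("assayed", "declared", "reference-substituted")
.mm_max_depth <- 8L       # recursion guard: deeper trees are treated as malformed
.mm_eps_sum <- 0.05       # relative tolerance for species-sum rules
.mm_eps_mass <- 0.01      # absolute tolerance for sibling mass-fraction sums
.mm_conflict_rel <- 0.20  # declared vs rolled-up disagreement threshold

new_profile <- function(basis, quantities) {
  q <- vapply(quantities, function(x) as.numeric(x)[1], numeric(1))
  structure(list(basis = basis, quantities = q), class = "mm_profile")
}

#' Load a product JSON document
#'
#' Parses and validates a single-product JSON document. Malformed JSON raises
#' an `mm_parse_error` naming the byte offset of the failure; a structurally
#' valid document that breaches any invariant raises an
#' `mm_validation_error` whose message lists *every* violated field path.
#' Unknown top-level keys are preserved under `$extra` but otherwise ignored.
#'
#' @param x Path to a JSON file, or a JSON string.
#' @return A validated `mm_product` object.
#' @seealso [validate_product()], [resolve_profile()]
#' @export
load_product <- function(x) {
  txt <- if (length(x) == 1 && !grepl("[{\\[]", substr(x, 1, 1)) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  ok <- jsonlite::validate(txt)
  if (!isTRUE(ok)) {
    offset <- mm_json_error_offset(txt, attr(ok, "err"))
    mm_error("mm_parse_error",
             sprintf("malformed JSON near byte offset %s: %s", offset,
                     trimws(strsplit(attr(ok, "err") %||% "parse error", "\n")[[1]][1])))
  }
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  product <- build_product(doc)
  findings <- validate_product(product)
  errors <- findings[findings$severity == "error", , drop = FALSE]
  if (nrow(errors) > 0) {
    mm_error("mm_validation_error",
             paste0("invalid product document:\n",
                    paste(sprintf("  - %s [%s]: %s", errors$path, errors$rule,
                                  errors$message), collapse = "\n")),
             findings = findings)
  }
  product
}

# locate the failing byte in a malformed document: yajl reports a short text
# context ending at the failure point; fall back to scanning prefixes.
mm_json_error_offset <- function(txt, err) {
  if (!is.null(err)) {
    ctx <- regmatches(err, regexpr("\n +[^\n]+\n", err))
    if (length(ctx) == 1) {
      frag <- trimws(gsub("\\(right here\\).*", "", ctx))
      if (nzchar(frag)) {
        pos <- regexpr(frag, txt, fixed = TRUE)
        if (pos > 0) return(pos + attr(pos, "match.length") - 1L)
      }
    }
  }
  "(unknown)"
}

build_product <- function(doc) {
  known <- c("id", "name", "category", "serving_size", "package_size",
             "servings_per_package", "ingredient_statement", "claims",
             "whitelist_ids", "declared_profile", "components")
  serving <- doc$serving_size %||% list(value = NA_real_, unit = "g")
  structure(list(
    id = doc$id %||% NA_character_,
    name = doc$name %||% NA_character_,
    category = doc$category %||% NA_character_,
    serving_size = list(value = as.numeric(serving$value %||% NA_real_),
                        unit = serving$unit %||% "g"),
    package_size = if (!is.null(doc$package_size)) {
      list(value = as.numeric(doc$package_size$value), unit = doc$package_size$unit %||% "g")
    },
    servings_per_package = as.numeric(doc$servings_per_package %||% 1),
    ingredient_statement = doc$ingredient_statement %||% "",
    claims = as.character(unlist(doc$claims %||% list())),
    whitelist_ids = as.character(unlist(doc$whitelist_ids %||% list())),
    declared_profile = if (!is.null(doc$declared_profile)) {
      new_profile(doc$declared_profile$basis %||% "per-serving",
                  doc$declared_profile$quantities %||% list())
    },
    components = lapply(doc$components %||% list(), build_component),
    extra = doc[setdiff(names(doc), known)]
  ), class = "mm_product")
}

build_component <- function(doc) {
  structure(list(
    id = doc$id %||% NA_character_,
    name = doc$name %||% NA_character_,
    mass_fraction = as.numeric(doc$mass_fraction %||% NA_real_),
    ingredient_statement = doc$ingredient_statement %||% "",
    profile = if (!is.null(doc$profile)) {
      new_profile(doc$profile$basis %||% "per-100g", doc$profile$quantities %||% list())
    },
    provenance = doc$provenance %||% "declared",
    components = lapply(doc$components %||% list(), build_component)
  ), class = "mm_component")
}

#' @export
print.mm_product <- function(x, ...) {
  cat(sprintf("<product %s: %s [%s], serving %g %s, %d component(s)>\n",
              x$id, x$name, x$category, x$serving_size$value,
              x$serving_size$unit, length(x$components)))
  invisible(x)
}

finding <- function(severity, path, rule, message) {
  data.frame(severity = severity, path = path, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a product against all model invariants
#'
#' A total validator: it never raises, and returns one row per finding.
#' Errors cover the closed category enum, serving size positivity, profile
#' presence, unknown nutrient ids, negative quantities, species-sum
#' tolerances (sugar, fat and fiber species may not exceed their parent
#' total by more than 5\% relative), sibling mass fractions (must sum to
#' 1 within 0.01), provenance values and excessive component nesting.
#' A portion-plausibility *warning* is emitted for multi-serve packs that
#' imply a per-serving portion below 30 g or mL.
#'
#' @param product An `mm_product` (from [load_product()] or built in code).
#' @return A data frame with columns `severity` (`"error"`/`"warning"`),
#'   `path`, `rule`, `message`; zero rows when fully consistent.
#' @export
validate_product <- function(product) {
  f <- list()
  add <- function(...) f[[length(f) + 1]] <<- finding(...)

  if (is.na(product$category) || !product$category %in% .mm_categories) {
    add("error", "category", "category-enum",
        sprintf("category %s not in {%s}", product$category %||% "<missing>",
                paste(.mm_categories, collapse = ", ")))
  }
  sv <- product$serving_size$value
  if (is.na(sv) || sv <= 0) {
    add("error", "serving_size.value", "serving-positive", "serving_size must be > 0")
  }
  if (!product$serving_size$unit %in% c("g", "mL")) {
    add("error", "serving_size.unit", "serving-unit", "serving unit must be g or mL")
  }

  # profiles may also come from the reference registry at resolve time, so a
  # component tree without explicit profiles is still loadable
  if (is.null(product$declared_profile) && length(product$components) == 0) {
    add("error", "declared_profile", "profile-presence",
        "product needs a declared_profile or components to resolve a profile from")
  }

  check_profile <- function(profile, path) {
    if (!profile$basis %in% .mm_bases) {
      add("error", paste0(path, ".basis"), "basis-enum",
          sprintf("basis %s not in {%s}", profile$basis, paste(.mm_bases, collapse = ", ")))
    }
    q <- profile$quantities
    unknown <- setdiff(names(q), nutrient_ids())
    for (u in unknown) {
      add("error", paste0(path, ".quantities.", u), "nutrient-vocabulary",
          sprintf("unknown nutrient id '%s'", u))
    }
    neg <- names(q)[!is.na(q) & q < 0]
    for (n in neg) {
      add("error", paste0(path, ".quantities.", n), "non-negative",
          sprintf("%s is negative (%g)", n, q[[n]]))
    }
    for (rule in nutrient_sum_rules()) {
      if (!rule$total %in% names(q)) next
      parts <- intersect(rule$parts, names(q))
      if (length(parts) == 0) next
      total <- q[[rule$total]]
      s <- sum(q[parts])
      if (s > total * (1 + .mm_eps_sum) + 1e-12) {
        add("error", path, paste0("sum-rule:", rule$total),
            sprintf("%s species sum %.4g exceeds %s %.4g by more than %d%%",
                    rule$total, s, rule$total, total, round(100 * .mm_eps_sum)))
      }
    }
  }
  if (!is.null(product$declared_profile)) {
    check_profile(product$declared_profile, "declared_profile")
  }

  check_components <- function(comps, path, depth) {
    if (length(comps) == 0) return(invisible())
    if (depth > .mm_max_depth) {
      add("error", path, "max-depth",
          sprintf("component nesting exceeds depth %d (malformed or cyclic input)", .mm_max_depth))
      return(invisible())
    }
    fr <- vapply(comps, function(cm) cm$mass_fraction, numeric(1))
    if (any(is.na(fr) | fr < 0 | fr > 1)) {
      add("error", path, "mass-fraction-range",
          "every mass_fraction must be a number in [0, 1]")
    } else if (abs(sum(fr) - 1) > .mm_eps_mass) {
      add("error", path, "mass-fraction-sum",
          sprintf("sibling mass fractions under %s sum to %.4g, not 1 +/- %.2g",
                  path, sum(fr), .mm_eps_mass))
    }
    for (cm in comps) {
      cpath <- paste0(path, ".", cm$id %||% "?")
      if (!cm$provenance %in% .mm_provenance) {
        add("error", paste0(cpath, ".provenance"), "provenance-enum",
            sprintf("provenance %s not in {%s}", cm$provenance,
                    paste(.mm_provenance, collapse = ", ")))
      }
      if (!is.null(cm$profile)) check_profile(cm$profile, paste0(cpath, ".profile"))
      check_components(cm$components, cpath, depth + 1L)
    }
  }
  check_components(product$components, "components", 1L)

  spp <- product$servings_per_package
  if (!is.na(spp) && spp > 1) {
    portion <- if (!is.null(product$package_size)) product$package_size$value / spp else sv
    if (!is.na(portion) && portion < 30) {
      add("warning", "servings_per_package", "portion-plausibility",
          sprintf("multi-serve pack implies a portion of %.3g %s (< 30); check serving realism",
                  portion, product$serving_size$unit))
    }
  }

  if (length(f) == 0) {
    return(data.frame(severity = character(), path = character(),
                      rule = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, f)
}

#' Reference nutrient registry
#'
#' Loads the bundled per-100g reference registry (or a user file of the same
#' shape) used to substitute a reference profile for components that carry
#' no profile of their own.
#'
#' @param path Optional path to a registry JSON file; default = bundled seed.
#' @return A named list of reference entries.
#' @export
load_reference_registry <- function(path = NULL) {
  if (is.null(path)) {
    return(mm_cached("references", function() mm_read_references(mm_extdata("references.seed.json"))))
  }
  mm_read_references(path)
}

mm_read_references <- function(path) {
  doc <- jsonlite::read_json(path)
  entries <- lapply(doc$entries, function(e) {
    list(name = e$name, match_names = unlist(e$match_names %||% list()),
         profile = new_profile(e$basis %||% "per-100g", e$quantities %||% list()))
  })
  entries
}

mm_reference_lookup <- function(name, references) {
  key <- fold_term(name %||% "")
  for (id in names(references)) {
    if (key == id || key %in% vapply(references[[id]]$match_names, fold_term, character(1))) {
      return(id)
    }
  }
  NULL
}

#' Resolve a product to a per-serving nutrient profile
#'
#' Aggregates the component tree by mass-fraction weighting into a per-100g
#' profile and rescales it to the serving size; components without a profile
#' fall back first to their own subcomponents and then to the reference
#' registry, with every reference substitution logged as an assumption
#' record. When a declared (label) profile is present it wins over the
#' component rollup -- declared panels are the regulated artifact -- and a
#' consistency warning is attached when the two disagree by more than 20\%
#' relative on any shared nutrient.
#'
#' @param product A validated `mm_product`.
#' @param references Reference registry from [load_reference_registry()].
#' @return A list with elements `profile` (per-serving `mm_profile`),
#'   `assumptions` (list of assumption records) and `warnings` (character).
#' @export
resolve_profile <- function(product, references = load_reference_registry()) {
  assumptions <- list()
  warnings <- character()

  resolve_component <- function(cm, path) {
    if (!is.null(cm$profile)) {
      if (cm$profile$basis == "per-serving") {
        mm_error("mm_validation_error",
                 sprintf("component %s: component profiles must be per-100g or per-100mL", path))
      }
      return(cm$profile$quantities)
    }
    if (length(cm$components) > 0) {
      return(mm_weighted_sum(lapply(cm$components, function(k) {
        resolve_component(k, paste0(path, ".", k$id))
      }), vapply(cm$components, function(k) k$mass_fraction, numeric(1))))
    }
    ref_id <- mm_reference_lookup(cm$name, references)
    if (is.null(ref_id)) {
      mm_error("mm_unresolvable_component",
               sprintf("component %s ('%s') has no profile, no subcomponents and no reference entry",
                       path, cm$name))
    }
    q <- references[[ref_id]]$profile$quantities
    assumptions[[length(assumptions) + 1]] <<- list(
      component_id = cm$id,
      reference_entry_id = ref_id,
      substituted_fields = names(q),
      note = sprintf("profile for component '%s' substituted from reference entry '%s'",
                     cm$name, ref_id)
    )
    q
  }

  serving <- product$serving_size$value
  rolled <- NULL
  if (length(product$components) > 0) {
    per100 <- mm_weighted_sum(
      lapply(product$components, function(cm) resolve_component(cm, cm$id)),
      vapply(product$components, function(cm) cm$mass_fraction, numeric(1))
    )
    rolled <- per100 * serving / 100
  }

  declared <- NULL
  if (!is.null(product$declared_profile)) {
    dp <- product$declared_profile
    declared <- if (dp$basis == "per-serving") dp$quantities else dp$quantities * serving / 100
  }

  if (!is.null(declared) && !is.null(rolled)) {
    shared <- intersect(names(declared), names(rolled))
    for (n in shared) {
      d <- declared[[n]]; r <- rolled[[n]]
      if (max(abs(d), abs(r)) > 0 && abs(d - r) / max(abs(d), abs(r)) > .mm_conflict_rel) {
        warnings <- c(warnings, sprintf(
          "declared %s (%.4g) and component rollup (%.4g) differ by more than %d%%; declared value used",
          n, d, r, round(100 * .mm_conflict_rel)))
      }
    }
  }

  q <- declared %||% rolled
  if (is.null(q)) {
    mm_error("mm_unresolvable_component",
             sprintf("product %s has neither a declared profile nor resolvable components", product$id))
  }
  list(profile = structure(list(basis = "per-serving", quantities = q), class = "mm_profile"),
       assumptions = assumptions, warnings = warnings)
}

mm_weighted_sum <- function(qlist, weights) {
  all_names <- unique(unlist(lapply(qlist, names)))
  out <- setNames(numeric(length(all_names)), all_names)
  for (i in seq_along(qlist)) {
    q <- qlist[[i]]
    if (length(q) > 0) out[names(q)] <- out[names(q)] + weights[i] * q
  }
  out
}
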