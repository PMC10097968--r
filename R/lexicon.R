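#' @title Ingredient lexicon: parsing, normalization, concerns, allergens
#' @description Ingredient statements appear in many forms and levels of
#'   detail. This module parses a statement into entries (with parenthesized
#'   sub-ingredients and leading modifiers such as "organic" or "non-GMO"),
#'   resolves each term against a canonical lexicon -- exact alias matching
#'   after case/punctuation folding, E-number codes, and a bounded
#'   Damerau-Levenshtein match for common misspellings that never matches on
#'   substring containment (a "peanut" is never a "nut") -- classifies
#'   canonical ingredients into additive groups, resolves concern status with
#'   modifier/whitelist neutralization, and detects Big 8/9 allergens.
#' @name lexicon
NULL

# Closed, versioned modifier lexicon (tag = canonical tag, forms = folded
# surface forms stripped from the head of an ingredient term).
.mm_modifiers <- list(
  list(tag = "partially-hydrogenated", forms = c("partially hydrogenated")),
  list(tag = "hydrogenated",           forms = c("hydrogenated")),
  list(tag = "non-gmo", forms = c("non gmo", "gmo free", "without gmos", "without gmo s",
                                  "non genetically engineered", "naturally derived")),
  list(tag = "organic",       forms = c("organic")),
  list(tag = "cold-pressed",  forms = c("cold pressed")),
  list(tag = "extra-virgin",  forms = c("extra virgin")),
  list(tag = "unrefined",     forms = c("unrefined"))
)

UNKNOWN_INGREDIENT <- "<unknown>"

#' Fold an ingredient term for matching
#'
#' Lowercases, maps punctuation to spaces, squeezes whitespace, and collapses
#' E-number spellings ("E 330", "e-330") to the canonical `e330` form.
#'
#' @param term Character scalar.
#' @return The folded term.
#' @export
fold_term <- function(term) {
  x <- tolower(trimws(term))
  x <- gsub("[^a-z0-9]+", " ", x)
  x <- trimws(gsub(" +", " ", x))
  # E-number canonical form: "e 330a" -> "e330a"
  if (grepl("^e ?[0-9]{3,4}[a-z]?$", x)) x <- gsub(" ", "", x)
  x
}

#' Load the ingredient lexicon and additive-concern registry
#'
#' Reads the canonical-ingredient lexicon and overlays the additive-concern
#' registry (registry entries win over lexicon concerns for the same
#' category). Checks that aliases are globally unique after folding and that
#' every registry id resolves in the lexicon.
#'
#' @param path Lexicon JSON path (default: bundled seed lexicon).
#' @param additives_path Concern-registry JSON path (default: bundled seed).
#' @return An `mm_lexicon` object.
#' @export
load_lexicon <- function(path = NULL, additives_path = NULL) {
  if (is.null(path) && is.null(additives_path)) {
    return(mm_cached("lexicon", function() {
      mm_build_lexicon(mm_extdata("lexicon.seed.json"), mm_extdata("additives.seed.json"))
    }))
  }
  mm_build_lexicon(path %||% mm_extdata("lexicon.seed.json"),
                   additives_path %||% mm_extdata("additives.seed.json"))
}

mm_build_lexicon <- function(path, additives_path) {
  doc <- jsonlite::read_json(path)
  entries <- list()
  for (e in doc$entries) {
    entries[[e$id]] <- list(
      id = e$id,
      preferred_name = e$preferred_name,
      aliases = unique(c(e$preferred_name, unlist(e$aliases %||% list()))),
      groups = as.character(unlist(e$groups %||% list())),
      concerns = lapply(e$concerns %||% list(), mm_build_concern),
      allergen_category = e$allergen_category %||% NA_character_
    )
  }
  reg <- jsonlite::read_json(additives_path)
  for (id in names(reg$entries)) {
    if (is.null(entries[[id]])) {
      mm_error("mm_config_error",
               sprintf("additive registry id '%s' does not resolve in the lexicon", id))
    }
    overlay <- lapply(reg$entries[[id]], mm_build_concern)
    kept <- Filter(function(cn) {
      !cn$concern_category %in% vapply(overlay, `[[`, character(1), "concern_category")
    }, entries[[id]]$concerns)
    entries[[id]]$concerns <- c(kept, overlay)
  }

  ids <- names(entries)
  alias_tab <- do.call(rbind, lapply(entries, function(e) {
    data.frame(alias = vapply(e$aliases, fold_term, character(1)),
               id = e$id, stringsAsFactors = FALSE)
  }))
  alias_tab <- alias_tab[nzchar(alias_tab$alias), , drop = FALSE]
  dup <- alias_tab$alias[duplicated(alias_tab$alias)]
  conflicting <- unique(dup[vapply(dup, function(a) {
    length(unique(alias_tab$id[alias_tab$alias == a])) > 1
  }, logical(1))])
  if (length(conflicting) > 0) {
    mm_error("mm_config_error",
             paste0("lexicon aliases not unique after folding: ",
                    paste(conflicting, collapse = ", ")))
  }
  alias_tab <- alias_tab[!duplicated(alias_tab$alias), , drop = FALSE]
  alias_tab$nchar <- nchar(alias_tab$alias)

  structure(list(entries = entries, alias_tab = alias_tab,
                 version = doc$version %||% "unversioned"),
            class = "mm_lexicon")
}

mm_build_concern <- function(cn) {
  out <- list(
    concern_category = cn$concern_category,
    status = cn$status,
    confidence = cn$confidence %||% "probable",
    neutralizing_modifiers = as.character(unlist(cn$neutralizing_modifiers %||% list())),
    citation_note = cn$citation_note %||% ""
  )
  if (length(out$neutralizing_modifiers) > 0 && out$status != "potentially-offending") {
    mm_error("mm_config_error", sprintf(
      "concern '%s': neutralizing modifiers are only meaningful for potentially-offending status",
      out$concern_category))
  }
  out
}

# Damerau-Levenshtein (optimal string alignment) distance, used only on the
# few candidates that survive a C-level plain-Levenshtein prefilter.
osa_distance <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0) return(nb)
  if (nb == 0) return(na)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  d <- matrix(0L, na + 1, nb + 1)
  d[, 1] <- 0:na; d[1, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      cost <- if (av[i] == bv[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
      if (i > 1 && j > 1 && av[i] == bv[j - 1] && av[i - 1] == bv[j]) {
        d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
      }
    }
  }
  d[na + 1, nb + 1]
}

#' Resolve one term to a canonical ingredient id
#'
#' Exact alias match after folding; failing that, a bounded fuzzy match for
#' misspellings: Damerau-Levenshtein distance at most 1 for folded terms of
#' up to 8 characters, at most 2 for longer terms, accepted only when a
#' single canonical id attains the minimal distance. Matching is whole-term
#' against whole-alias -- an alias embedded in a longer term with adjacent
#' word characters never matches. Unresolvable terms return the unknown
#' marker, never a guess beyond the bound.
#'
#' @param term Raw ingredient term.
#' @param lexicon An `mm_lexicon`.
#' @return A canonical id, or `UNKNOWN_INGREDIENT`.
#' @export
normalize_term <- function(term, lexicon = load_lexicon()) {
  folded <- fold_term(term)
  if (!nzchar(folded)) mm_error("mm_argument_error", "empty term after folding")
  tab <- lexicon$alias_tab
  hit <- match(folded, tab$alias)
  if (!is.na(hit)) return(tab$id[hit])

  bound <- if (nchar(folded) <= 8) 1L else 2L
  cand <- tab[abs(tab$nchar - nchar(folded)) <= bound, , drop = FALSE]
  if (nrow(cand) == 0) return(UNKNOWN_INGREDIENT)
  # plain Levenshtein lower-bounds transposition-aware distance within +1
  lev <- utils::adist(folded, cand$alias)[1, ]
  cand <- cand[lev <= bound + 1L, , drop = FALSE]
  if (nrow(cand) == 0) return(UNKNOWN_INGREDIENT)
  # substring guard: an ingredient whose alias sits inside the term with a
  # word character adjacent is not a candidate ("citric acidx" or "eggx"
  # must not resolve to citric acid or egg through any of their aliases)
  embedded <- vapply(tab$alias, function(a) {
    if (nchar(folded) <= nchar(a)) return(FALSE)
    pos <- regexpr(a, folded, fixed = TRUE)
    if (pos < 0) return(FALSE)
    before <- if (pos > 1) substr(folded, pos - 1, pos - 1) else ""
    after_i <- pos + nchar(a)
    after <- if (after_i <= nchar(folded)) substr(folded, after_i, after_i) else ""
    grepl("[a-z0-9]", before) || grepl("[a-z0-9]", after)
  }, logical(1))
  cand <- cand[!cand$id %in% unique(tab$id[embedded]), , drop = FALSE]
  if (nrow(cand) == 0) return(UNKNOWN_INGREDIENT)
  d <- vapply(cand$alias, function(a) osa_distance(folded, a), numeric(1))
  dmin <- min(d)
  if (dmin > bound) return(UNKNOWN_INGREDIENT)
  best <- cand[d == dmin, , drop = FALSE]
  if (length(unique(best$id)) == 1) best$id[1] else UNKNOWN_INGREDIENT
}

#' Parse an ingredient statement
#'
#' Splits on commas/semicolons outside parentheses; a parenthesized list
#' becomes nested `sub_ingredients`; leading tokens from the closed modifier
#' lexicon (organic, non-GMO and variants, cold-pressed, extra-virgin,
#' unrefined, hydrogenated, partially hydrogenated) are stripped into
#' `modifiers`. Order is preserved, and each entry retains its raw span with
#' character offsets into the original statement. Unbalanced parentheses
#' yield a warning and a best-effort flat split.
#'
#' @param statement Ingredient statement text (may be empty).
#' @return A list of parsed-ingredient entries, each with `raw`, `start`,
#'   `end`, `term`, `modifiers` and `sub_ingredients`.
#' @export
parse_statement <- function(statement) {
  if (is.null(statement) || !nzchar(trimws(statement))) return(list())
  chars <- strsplit(statement, "")[[1]]
  # depth *at* a character: a separator directly after ")" is top-level
  depth <- cumsum((chars == "(") - c(0, (chars == ")")[-length(chars)]))
  net <- cumsum((chars == "(") - (chars == ")"))
  if (net[length(net)] != 0 || any(net < 0)) {
    warning("unbalanced parentheses in ingredient statement; using flat split",
            call. = FALSE)
    statement <- gsub("[()]", " ", statement)
    chars <- strsplit(statement, "")[[1]]
    depth <- rep(0L, length(chars))
  }
  breaks <- which(chars %in% c(",", ";") & depth == 0)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks - 1L, length(chars))
  out <- list()
  for (k in seq_along(starts)) {
    if (starts[k] > ends[k]) next
    raw <- substr(statement, starts[k], ends[k])
    if (!nzchar(trimws(raw))) next
    out[[length(out) + 1]] <- mm_parse_entry(raw, starts[k])
  }
  out
}

mm_parse_entry <- function(raw, offset) {
  sub_ingredients <- list()
  open <- regexpr("(", raw, fixed = TRUE)
  head_txt <- raw
  if (open > 0) {
    close <- max(gregexpr(")", raw, fixed = TRUE)[[1]])
    inner <- substr(raw, open + 1, close - 1)
    head_txt <- paste(substr(raw, 1, open - 1), substring(raw, close + 1))
    sub_parsed <- parse_statement(inner)
    # re-anchor sub-entry offsets into the full statement
    sub_ingredients <- lapply(sub_parsed, function(s) {
      s$start <- s$start + offset + open - 1L
      s$end <- s$end + offset + open - 1L
      s
    })
  }
  folded <- fold_term(head_txt)
  modifiers <- character()
  repeat {
    matched <- FALSE
    for (m in .mm_modifiers) {
      for (form in m$forms) {
        if (folded == form || startsWith(folded, paste0(form, " "))) {
          modifiers <- unique(c(modifiers, m$tag))
          folded <- trimws(substring(folded, nchar(form) + 1))
          matched <- TRUE
          break
        }
      }
      if (matched) break
    }
    if (!matched || !nzchar(folded)) break
  }
  list(raw = trimws(raw), start = offset,
       end = offset + nchar(raw) - 1L,
       term = folded, modifiers = modifiers,
       sub_ingredients = sub_ingredients)
}

#' Parse and canonicalize an ingredient statement
#'
#' Runs [parse_statement()] and annotates every entry (including nested
#' sub-ingredients) with its canonical id. The full raw span is tried first
#' as an exact alias (so multi-word entries like "extra virgin olive oil"
#' resolve even though a modifier is stripped), then the modifier-stripped
#' term is resolved with fuzzy matching.
#'
#' @inheritParams parse_statement
#' @param lexicon An `mm_lexicon`.
#' @return Parsed entries with a `canonical_id` field (`UNKNOWN_INGREDIENT`
#'   when unresolvable).
#' @export
resolve_statement <- function(statement, lexicon = load_lexicon()) {
  annotate <- function(entries) {
    lapply(entries, function(e) {
      raw_folded <- fold_term(e$raw)
      hit <- match(raw_folded, lexicon$alias_tab$alias)
      e$canonical_id <- if (!is.na(hit)) {
        lexicon$alias_tab$id[hit]
      } else if (nzchar(e$term)) {
        normalize_term(e$term, lexicon)
      } else {
        UNKNOWN_INGREDIENT
      }
      e$sub_ingredients <- annotate(e$sub_ingredients)
      e
    })
  }
  annotate(parse_statement(statement))
}

flatten_parsed <- function(parsed) {
  out <- list()
  walk <- function(entries) {
    for (e in entries) {
      out[[length(out) + 1]] <<- e
      walk(e$sub_ingredients)
    }
  }
  walk(parsed)
  out
}

#' Group memberships of a canonical ingredient
#'
#' @param canonical_id A lexicon id.
#' @param lexicon An `mm_lexicon`.
#' @return Character vector of group ids (possibly empty).
#' @export
classify_groups <- function(canonical_id, lexicon = load_lexicon()) {
  e <- lexicon$entries[[canonical_id]]
  if (is.null(e)) mm_error("mm_lookup_error", paste0("unknown canonical id: ", canonical_id))
  e$groups
}

# Groups including modifier-derived ones: an oil carrying the
# "(partially) hydrogenated" modifier belongs to the corresponding
# hydrogenated-oil groups even if the lexicon entry itself does not.
effective_groups <- function(canonical_id, modifiers, lexicon = load_lexicon()) {
  g <- classify_groups(canonical_id, lexicon)
  if ("vegetable-oils" %in% g || "omega3-sources" %in% g) {
    if ("partially-hydrogenated" %in% modifiers) {
      g <- union(g, c("partially-hydrogenated-oils", "hydrogenated-oils"))
    } else if ("hydrogenated" %in% modifiers) {
      g <- union(g, "hydrogenated-oils")
    }
  }
  g
}

.mm_confidence_rank <- c(suspected = 1L, probable = 2L, established = 3L)

#' Effective concern status of a parsed entry
#'
#' Looks up the ingredient's concern record for `concern_category` and
#' applies neutralization: a potentially-offending status is downgraded to
#' benign when the entry carries one of the concern's neutralizing modifiers
#' or when the product id is on the product whitelist. An offending status
#' is never neutralizable. Unknown ingredients are benign for concern
#' purposes (they are surfaced separately in reports).
#'
#' @param entry A parsed entry with `canonical_id` and `modifiers`.
#' @param concern_category Concern category id (e.g. `"GMO-status"`).
#' @param whitelist Product ids whitelisted for this concern.
#' @param product_id The product under evaluation.
#' @param lexicon An `mm_lexicon`.
#' @return A list with `status` (`"offending"`, `"potentially-offending"`,
#'   `"benign"`, or `"benign-unknown"`), `confidence`, and `neutralized_by`.
#' @export
resolve_concern <- function(entry, concern_category, whitelist = character(),
                            product_id = NULL, lexicon = load_lexicon()) {
  if (is.null(concern_category) || !nzchar(concern_category)) {
    mm_error("mm_argument_error", "concern_category must be a non-empty string")
  }
  cid <- entry$canonical_id %||% UNKNOWN_INGREDIENT
  if (identical(cid, UNKNOWN_INGREDIENT)) {
    return(list(status = "benign-unknown", confidence = NA_character_, neutralized_by = NULL))
  }
  e <- lexicon$entries[[cid]]
  if (is.null(e)) mm_error("mm_lookup_error", paste0("unknown canonical id: ", cid))
  cn <- Filter(function(x) identical(x$concern_category, concern_category), e$concerns)
  if (length(cn) == 0) {
    return(list(status = "benign", confidence = NA_character_, neutralized_by = NULL))
  }
  cn <- cn[[1]]
  status <- cn$status
  neutralized_by <- NULL
  if (identical(status, "potentially-offending")) {
    mods <- intersect(entry$modifiers %||% character(), cn$neutralizing_modifiers)
    if (length(mods) > 0) {
      status <- "benign"
      neutralized_by <- paste0("modifier:", mods[1])
    } else if (!is.null(product_id) && product_id %in% whitelist) {
      status <- "benign"
      neutralized_by <- "whitelist"
    }
  }
  list(status = status, confidence = cn$confidence, neutralized_by = neutralized_by)
}

#' Load an allergen registry
#'
#' @param mode `"big8"` or `"big9"`, selecting the bundled registry; or
#'   supply `path` to load a custom registry file.
#' @param path Optional path to a registry JSON file.
#' @return An `mm_allergen_registry` with `mode` and `categories`.
#' @export
load_allergen_registry <- function(mode = c("big8", "big9"), path = NULL) {
  if (is.null(path)) {
    mode <- match.arg(mode)
    path <- mm_extdata(paste0("allergens.", mode, ".json"))
  }
  doc <- jsonlite::read_json(path)
  reg <- structure(list(mode = doc$mode,
                        categories = lapply(doc$categories, unlist)),
                   class = "mm_allergen_registry")
  n <- length(reg$categories)
  expected <- if (identical(reg$mode, "big9")) 9L else 8L
  if (n != expected) {
    mm_error("mm_config_error",
             sprintf("allergen registry mode %s must define %d categories, found %d",
                     reg$mode, expected, n))
  }
  reg
}

#' Detect allergen categories in a parsed statement
#'
#' Union over all entries (including nested sub-ingredients) of the allergen
#' categories whose trigger sets contain the entry's canonical id. Unknown
#' ingredients contribute nothing.
#'
#' @param parsed Output of [resolve_statement()].
#' @param registry An `mm_allergen_registry`.
#' @return Sorted character vector of detected category ids.
#' @export
detect_allergens <- function(parsed, registry = load_allergen_registry("big8")) {
  ids <- vapply(flatten_parsed(parsed), function(e) e$canonical_id %||% UNKNOWN_INGREDIENT,
                character(1))
  ids <- setdiff(unique(ids), UNKNOWN_INGREDIENT)
  hit <- vapply(registry$categories, function(triggers) any(ids %in% triggers), logical(1))
  sort(names(registry$categories)[hit])
}
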