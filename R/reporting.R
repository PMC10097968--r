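#' @title Per-product reports and the portfolio overview
#' @description Evaluation results are reported in two forms: a per-product
#'   report documenting how the product did on every criterion, its tier,
#'   the recommended modifications to reach the next tier and the
#'   assumptions made during rollup (JSON is the canonical serialization,
#'   Markdown the human-readable one, both carrying identical information);
#'   and an overview spreadsheet combining input data and all per-product
#'   results minus recommendations and assumptions.
#' @name reporting
NULL

#' Render a per-product report
#'
#' @param evaluation Result of [evaluate_product()] (elements `resolved`,
#'   `outcomes`, `tier`, `recommendations`).
#' @param config_version Version stamp of the criteria configuration.
#' @return An `mm_report`: a fully serializable list with the product
#'   identity, engine and configuration version stamps, one outcome row per
#'   configured criterion (blocking criteria listed first), the tier label,
#'   recommendations and assumptions.
#' @export
render_report <- function(evaluation, config_version) {
  resolved <- evaluation$resolved
  outcomes <- evaluation$outcomes
  tier <- evaluation$tier
  if (length(outcomes) == 0) mm_error("mm_argument_error", "no outcomes to report")
  blocking_ids <- vapply(tier$blocking, `[[`, character(1), "criterion_id")
  ord <- order(!vapply(outcomes, function(o) o$criterion_id %in% blocking_ids, logical(1)))
  rows <- lapply(outcomes[ord], function(o) {
    list(criterion_id = o$criterion_id, level = o$level, status = o$status,
         measured_value = if (is.na(o$measured_value)) NULL else o$measured_value,
         unit = if (is.na(o$unit)) NULL else o$unit,
         threshold = if (is.na(o$threshold)) NULL else o$threshold,
         explanation = o$explanation)
  })
  structure(list(
    product = list(id = resolved$product_id, name = resolved$name,
                   category = resolved$category,
                   serving_size = resolved$serving_size),
    engine_version = as.character(utils::packageVersion("metabmatrix")),
    config_version = config_version,
    tier = list(label = tier$label,
                per_level_pass = as.list(tier$per_level_pass)),
    outcomes = rows,
    recommendations = evaluation$recommendations,
    assumptions = resolved$assumptions,
    allergens = as.list(resolved$allergens),
    allergen_mode = resolved$allergen_mode,
    unknown_ingredients = as.list(resolved$unknown_ingredients),
    warnings = as.list(resolved$warnings)
  ), class = "mm_report")
}

#' Serialize a report to canonical JSON
#'
#' @param report An `mm_report`.
#' @return A JSON string (pretty-printed, stable key order).
#' @export
report_to_json <- function(report) {
  # canonical form: serialize, reparse, reserialize -- this makes the output
  # a fixed point, so parse -> re-render is byte-identical
  j <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE,
                        digits = NA, null = "null")
  as.character(jsonlite::toJSON(jsonlite::fromJSON(j, simplifyVector = FALSE),
                                auto_unbox = TRUE, pretty = TRUE, digits = NA,
                                null = "null"))
}

#' Parse a report back from its JSON form
#'
#' @param json A JSON string produced by [report_to_json()] (or a file path).
#' @return An `mm_report`.
#' @export
report_from_json <- function(json) {
  if (length(json) == 1 && !grepl("^\\s*\\{", json) && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  structure(jsonlite::fromJSON(json, simplifyVector = FALSE), class = "mm_report")
}

#' Render the human-readable (Markdown) form of a report
#'
#' Deterministic given the report; carries the same information as the JSON
#' form.
#'
#' @param report An `mm_report`.
#' @return A single Markdown string.
#' @export
report_to_markdown <- function(report) {
  fmt_num <- function(x) {
    if (is.null(x) || length(x) == 0 || is.na(x)) "-" else format(x, digits = 6)
  }
  lines <- c(
    sprintf("# Product report: %s (%s)", report$product$name, report$product$id),
    "",
    sprintf("- Category: %s", report$product$category),
    sprintf("- Serving: %s %s", fmt_num(report$product$serving_size$value),
            report$product$serving_size$unit),
    sprintf("- Tier: **%s**", report$tier$label),
    sprintf("- Engine %s, configuration %s", report$engine_version, report$config_version),
    sprintf("- Allergens (%s): %s", report$allergen_mode %||% "-",
            if (length(report$allergens) > 0) {
              paste(unlist(report$allergens), collapse = ", ")
            } else "none detected"),
    "",
    "## Criteria",
    "",
    "| Criterion | Level | Status | Measured | Threshold | Explanation |",
    "|---|---|---|---|---|---|"
  )
  for (o in report$outcomes) {
    lines <- c(lines, sprintf("| %s | %d | %s | %s | %s | %s |",
                              o$criterion_id, as.integer(o$level), o$status,
                              fmt_num(o$measured_value %||% NA),
                              fmt_num(o$threshold %||% NA),
                              gsub("\\|", "/", o$explanation)))
  }
  lines <- c(lines, "", "## Recommendations", "")
  if (length(report$recommendations) == 0) {
    lines <- c(lines, "None: the product meets every configured criterion.")
  } else {
    for (r in report$recommendations) {
      lines <- c(lines, sprintf("- **%s**: %s", r$criterion_id, r$action))
      for (s in unlist(r$strategy_texts)) lines <- c(lines, sprintf("  - %s", s))
    }
  }
  lines <- c(lines, "", "## Assumptions", "")
  if (length(report$assumptions) == 0) {
    lines <- c(lines, "None: no reference substitutions were needed.")
  } else {
    for (a in report$assumptions) {
      lines <- c(lines, sprintf("- %s", a$note))
    }
  }
  if (length(report$unknown_ingredients) > 0) {
    lines <- c(lines, "", "## Unrecognized ingredients", "",
               sprintf("- %s", unlist(report$unknown_ingredients)))
  }
  if (length(report$warnings) > 0) {
    lines <- c(lines, "", "## Warnings", "", sprintf("- %s", unlist(report$warnings)))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Build the portfolio overview table
#'
#' One row per product combining input summary, every criterion status and
#' measured value, and the tier label -- explicitly excluding
#' recommendations and assumptions. All reports must come from the same
#' configuration version, otherwise rows would not be comparable.
#'
#' @param reports List of `mm_report` objects (at least one).
#' @return A data frame with a stable column order.
#' @export
render_overview <- function(reports) {
  if (length(reports) == 0) mm_error("mm_argument_error", "need at least one report")
  versions <- unique(vapply(reports, `[[`, character(1), "config_version"))
  if (length(versions) > 1) {
    mm_error("mm_config_error",
             paste0("reports from mixed configuration versions: ",
                    paste(versions, collapse = ", ")))
  }
  crit_ids <- sort(unique(unlist(lapply(reports, function(r) {
    vapply(r$outcomes, `[[`, character(1), "criterion_id")
  }))))
  rows <- lapply(reports, function(r) {
    base <- data.frame(
      product_id = r$product$id, name = r$product$name,
      category = r$product$category,
      serving_size = r$product$serving_size$value,
      serving_unit = r$product$serving_size$unit,
      tier = r$tier$label,
      allergens = paste(unlist(r$allergens), collapse = ";"),
      stringsAsFactors = FALSE)
    oc <- setNames(r$outcomes, vapply(r$outcomes, `[[`, character(1), "criterion_id"))
    for (id in crit_ids) {
      o <- oc[[id]]
      base[[paste0(id, ".status")]] <- o$status %||% NA_character_
      mv <- o$measured_value %||% NA_real_
      base[[paste0(id, ".value")]] <- if (is.null(mv)) NA_real_ else as.numeric(mv)
    }
    base
  })
  do.call(rbind, rows)
}

#' Write the overview as RFC 4180 CSV
#'
#' @param overview Data frame from [render_overview()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overview <- function(overview, path) {
  utils::write.csv(overview, path, row.names = FALSE, fileEncoding = "UTF-8",
                   eol = "\n", na = "")
  invisible(path)
}
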