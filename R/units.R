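#' Controlled nutrient vocabulary
#'
#' Returns the controlled nutrient vocabulary shipped with the package: one
#' row per nutrient with its stable id, display label, canonical unit and
#' coarse class. Every nutrient quantity handled by the engine is stored in
#' the canonical unit of this table; profile documents using other ids are
#' rejected at validation.
#'
#' @return A data frame with columns `id`, `label`, `unit`, `class`.
#' @export
#' @examples
#' head(nutrient_vocabulary())
nutrient_vocabulary <- function() {
  mm_cached("vocab", function() {
    doc <- jsonlite::read_json(mm_extdata("nutrients.vocab.json"))
    do.call(rbind, lapply(doc$nutrients, function(n) {
      data.frame(id = n$id, label = n$label, unit = n$unit, class = n$class,
                 stringsAsFactors = FALSE)
    }))
  })
}

nutrient_sum_rules <- function() {
  mm_cached("sum_rules", function() {
    doc <- jsonlite::read_json(mm_extdata("nutrients.vocab.json"))
    lapply(doc$sum_rules, function(r) {
      list(total = r$total, parts = unlist(r$parts))
    })
  })
}

nutrient_ids <- function() nutrient_vocabulary()$id

#' Canonical unit of a nutrient
#'
#' @param nutrient A nutrient id from [nutrient_vocabulary()].
#' @return The canonical unit string (`"g"`, `"mg"`, `"ug"` or `"IU"`).
#' @export
canonical_unit <- function(nutrient) {
  vocab <- nutrient_vocabulary()
  i <- match(nutrient, vocab$id)
  if (is.na(i)) mm_error("mm_lookup_error", paste0("unknown nutrient id: ", nutrient))
  vocab$unit[i]
}

# Fixed design constants: 40 IU vitamin D per ug; 4.2 g granulated sugar per
# household teaspoon; salt mass = sodium mass x 2.5.
.mm_conversions <- list(
  list(nutrients = "vitamin_d", from = "IU", to = "ug", factor = 1 / 40),
  list(nutrients = c("sugar_total", "sugar_added", "sucrose", "glucose",
                     "fructose", "galactose", "lactose"),
       from = "tsp", to = "g", factor = 4.2),
  list(nutrients = "sodium", from = "mg", to = "g-salt", factor = 2.5 / 1000),
  list(nutrients = NULL, from = "g", to = "mg", factor = 1000),
  list(nutrients = NULL, from = "mg", to = "ug", factor = 1000)
)

#' Convert a nutrient quantity between units
#'
#' Exact arithmetic conversion between a nutrient's supported units:
#' vitamin D IU/ug (40 IU = 1 ug), sugars teaspoon/gram (1 tsp = 4.2 g),
#' sodium mg to salt-equivalent grams (salt = sodium x 2.5), and metric
#' mass prefixes. Identity conversions are always supported; undefined
#' pairs raise an `mm_conversion_error`.
#'
#' @param amount Numeric quantity.
#' @param from,to Unit strings.
#' @param nutrient Nutrient id the conversion applies to.
#' @return The converted numeric quantity.
#' @export
#' @examples
#' convert(400, "IU", "ug", "vitamin_d")  # 10
#' convert(1, "tsp", "g", "sugar_added")  # 4.2
convert <- function(amount, from, to, nutrient) {
  stopifnot(is.numeric(amount), length(from) == 1, length(to) == 1)
  if (identical(from, to)) return(amount)
  for (cv in .mm_conversions) {
    applies <- is.null(cv$nutrients) || nutrient %in% cv$nutrients
    if (!applies) next
    if (identical(from, cv$from) && identical(to, cv$to)) return(amount * cv$factor)
    if (identical(from, cv$to) && identical(to, cv$from)) return(amount / cv$factor)
  }
  mm_error("mm_conversion_error",
           sprintf("unsupported conversion for %s: %s -> %s", nutrient, from, to))
}
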