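# ---------------------------------------------------------------------------
# Per-100 g composition -> served-mass scaling -> dish-level totals.
# ---------------------------------------------------------------------------

#' Scale a per-100 g composition to a served mass
#'
#' @param composition named numeric component vector per 100 g (a finalized
#'   item: no NA), or an [fcdb()] plus `food_id`.
#' @param grams served mass in g (>= 0).
#' @param food_id when `composition` is an fcdb, the item to scale.
#' @export
scale_to_mass <- function(composition, grams, food_id = NULL) {
  if (inherits(composition, "fcdb")) {
    composition <- composition$amounts[food_id, ]
  }
  if (anyNA(composition)) {
    stop("unresolved component state(s): ",
         paste(names(composition)[is.na(composition)], collapse = ", "),
         call. = FALSE)
  }
  if (grams < 0) stop("grams must be >= 0", call. = FALSE)
  composition * grams / 100
}

#' Dish-level nutrient totals under one FCDB
#'
#' Sums, per dish, each ingredient use's composition scaled to its mass.
#'
#' @param uses long use table (`dish_id`, `ingr_name`, `ingr_grams`).
#' @param compositions matrix from [ingredient_compositions()], rows keyed by
#'   ingredient name.
#' @param source_fcdb tag recorded in the output.
#' @return data.frame: `dish_id`, `mass`, one column per component,
#'   `source_fcdb`.
#' @export
dish_totals <- function(uses, compositions, source_fcdb = "target") {
  unmatched <- setdiff(unique(uses$ingr_name), rownames(compositions))
  if (length(unmatched)) {
    stop("unmatched ingredient(s): ", paste(unmatched, collapse = ", "),
         call. = FALSE)
  }
  comp <- compositions[uses$ingr_name, , drop = FALSE]
  if (anyNA(comp)) stop("compositions contain unresolved values", call. = FALSE)
  scaled <- comp * (uses$ingr_grams / 100)
  dish <- factor(uses$dish_id, levels = unique(uses$dish_id))
  totals <- rowsum(scaled, dish)
  mass <- rowsum(uses$ingr_grams, dish)[, 1]
  out <- data.frame(dish_id = levels(dish), mass = mass,
                    totals, source_fcdb = source_fcdb,
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  out
}

#' Seven-number corpus summary (type-7 quantiles)
#'
#' @param totals a [dish_totals()] table (or any data.frame of dishes).
#' @param fields columns to summarize.
#' @return data.frame: one row per field with min/Q1/median/Q3/max/mean/SD.
#' @export
corpus_summary <- function(totals, fields) {
  if (!nrow(totals)) stop("empty corpus", call. = FALSE)
  out <- do.call(rbind, lapply(fields, function(f) {
    data.frame(field = f, t(seven_number(totals[[f]])),
               stringsAsFactors = FALSE)
  }))
  out
}
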