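# ---------------------------------------------------------------------------
# Dataset-level cleaning and the five missing-value imputation strategies.
# All curation judgments enter as explicit tables; nothing is automatic
# except the reproducible outlier *detector* (flagging only).
# ---------------------------------------------------------------------------

#' Remove plate-only dishes
#' @param dishes a `dish_set`.
#' @param plate_only_ids character vector of dish ids to drop.
#' @return the filtered `dish_set`; the number removed is attached as
#'   attribute `"removed"`.
#' @export
remove_plate_only <- function(dishes, plate_only_ids) {
  stopifnot(inherits(dishes, "dish_set"))
  absent <- setdiff(plate_only_ids, dishes$dishes$dish_id)
  if (length(absent)) {
    warning("plate-only id(s) not present: ", paste(absent, collapse = ", "))
  }
  keep <- !(dishes$dishes$dish_id %in% plate_only_ids)
  out <- dishes
  out$dishes <- dishes$dishes[keep, , drop = FALSE]
  out$uses <- dishes$uses[!(dishes$uses$dish_id %in% plate_only_ids), ,
                          drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Recover missing ingredient names
#'
#' Empty ingredient names in the long use table are resolved first from the
#' ingredient catalogue, then from a manual map (the image-derived judgments,
#' supplied as data). Ids resolvable by neither are an error.
#'
#' @param uses long use table ([wide_to_long()]).
#' @param catalog [parse_ingredient_catalog()] output; deprecated entries do
#'   not resolve names.
#' @param manual_map data.frame `ingr_id`, `ingr_name`.
#' @return list(uses = repaired table, report = counts by recovery route).
#' @export
recover_missing_names <- function(uses, catalog,
                                  manual_map = data.frame(ingr_id = character(),
                                                          ingr_name = character())) {
  nameless <- is.na(uses$ingr_name) | trimws(uses$ingr_name) == ""
  via_catalog <- 0L; via_manual <- 0L
  if (any(nameless)) {
    cat_ok <- catalog[!catalog$deprecated, , drop = FALSE]
    cat_names <- stats::setNames(cat_ok$canonical_name, cat_ok$ingr_id)
    man_names <- stats::setNames(as.character(manual_map$ingr_name),
                                 manual_map$ingr_id)
    ids <- uses$ingr_id[nameless]
    from_cat <- unname(cat_names[ids])
    from_man <- unname(man_names[ids])
    resolved <- ifelse(!is.na(from_cat), from_cat, from_man)
    if (anyNA(resolved)) {
      stop("ingredient id(s) unresolvable by catalogue or manual map: ",
           paste(unique(ids[is.na(resolved)]), collapse = ", "), call. = FALSE)
    }
    via_catalog <- sum(!is.na(from_cat))
    via_manual <- sum(is.na(from_cat))
    uses$ingr_name[nameless] <- resolved
  }
  list(uses = uses,
       report = c(recovered_via_catalog = via_catalog,
                  recovered_via_manual_map = via_manual))
}

#' Per-ingredient mass summary and outlier candidates
#'
#' Computes the seven-number mass summary per ingredient and flags uses whose
#' mass exceeds `factor` times that ingredient's median. Ingredients with
#' fewer than `min_uses` uses are never flagged (their median is not robust).
#' Detection only: corrections are separate, explicit table entries.
#'
#' @param uses long use table.
#' @param factor flag threshold as a multiple of the ingredient median.
#' @param min_uses minimum number of uses before flagging applies.
#' @return list(summary = per-ingredient statistics, flagged = offending rows).
#' @export
detect_mass_outliers <- function(uses, factor = 100, min_uses = 3L) {
  by_ing <- split(uses$ingr_grams, uses$ingr_name)
  summ <- do.call(rbind, lapply(names(by_ing), function(nm) {
    s <- seven_number(by_ing[[nm]])
    data.frame(ingr_name = nm, n = length(by_ing[[nm]]), t(s),
               stringsAsFactors = FALSE)
  }))
  med <- stats::setNames(summ$median, summ$ingr_name)
  n_uses <- stats::setNames(summ$n, summ$ingr_name)
  flag <- uses$ingr_grams > factor * med[uses$ingr_name] &
    n_uses[uses$ingr_name] >= min_uses
  list(summary = summ, flagged = uses[which(flag), , drop = FALSE])
}

#' Mass correction table constructor
#' @param ingr_id,wrong_mass,corrected_mass,rationale vectors of equal length
#' @export
mass_corrections <- function(ingr_id, wrong_mass, corrected_mass,
                             rationale = "") {
  stopifnot(all(corrected_mass > 0))
  if (any(corrected_mass >= wrong_mass)) {
    stop("corrections must reduce the mass (order-of-magnitude errors)",
         call. = FALSE)
  }
  data.frame(ingr_id = as.character(ingr_id), wrong_mass = wrong_mass,
             corrected_mass = corrected_mass, rationale = rationale,
             stringsAsFactors = FALSE)
}

#' Apply an explicit mass-correction table
#'
#' Each correction targets every use of `ingr_id` whose recorded mass equals
#' `wrong_mass`; matching rows get `corrected_mass`. Corrections matching
#' nothing raise a warning. Only targeted rows change.
#'
#' Declared per-use nutrient columns (`declared_*`), when present, are
#' rescaled by `corrected_mass / wrong_mass` so the declared side of the
#' comparison also reflects the fix (a material mass error must not inflate
#' the between-FCDB difference).
#'
#' @param uses long use table.
#' @param corrections a [mass_corrections()] table (or CSV-read equivalent).
#' @export
apply_mass_corrections <- function(uses, corrections) {
  decl_cols <- grep("^declared_", names(uses), value = TRUE)
  for (i in seq_len(nrow(corrections))) {
    cr <- corrections[i, ]
    hit <- uses$ingr_id == cr$ingr_id & uses$ingr_grams == cr$wrong_mass
    if (!any(hit)) {
      warning("correction for ", cr$ingr_id, " @ ", cr$wrong_mass,
              " g matched no use")
    }
    uses$ingr_grams[hit] <- cr$corrected_mass
    for (dc in decl_cols) {
      uses[[dc]][hit] <- uses[[dc]][hit] * cr$corrected_mass / cr$wrong_mass
    }
  }
  uses
}

# built-in by-calculation rules: value from the rest of the item's profile
.calculators <- list(
  # carbohydrate by difference: 100 - water - protein - fat - ash - alcohol
  carb_by_difference = function(amounts) {
    need <- c("water", "protein", "fat", "ash", "alcohol")
    vals <- amounts[need]
    vals[is.na(vals)] <- 0
    max(0, 100 - sum(vals))
  },
  # chloride from sodium via the Cl/Na molar mass ratio 35.453/22.990
  chloride_from_sodium = function(amounts) {
    na <- amounts[["sodium"]]
    if (is.na(na)) return(NA_real_)
    na * 35.453 / 22.990
  }
)

#' Imputation plan constructor
#'
#' A plan is an ordered rule table mapping (component, item class) to one of
#' the five strategies; the first applicable rule wins. `item_class = "*"`
#' matches any class. `param` names the strategy's argument: the calculator
#' for `by_calculation`, the recipe id for `recipe_calculation`; donors for
#' `similar_item` / `borrowed` come from the helper tables.
#'
#' @param component,item_class,strategy,param equal-length vectors; strategy
#'   in similar_item / by_calculation / assumed_zero / recipe_calculation /
#'   borrowed.
#' @export
imputation_plan <- function(component, item_class = "*", strategy,
                            param = NA_character_) {
  ok <- c("similar_item", "by_calculation", "assumed_zero",
          "recipe_calculation", "borrowed")
  stopifnot(all(strategy %in% ok))
  data.frame(component = component, item_class = item_class,
             strategy = strategy, param = param, stringsAsFactors = FALSE)
}

#' Resolve every missing value in an FCDB
#'
#' Walks all (item, component) cells with state "missing" and applies the
#' first plan rule matching the component and the item's class. Measured
#' values are never touched. Strategies:
#' \describe{
#'   \item{similar_item}{copy the resolved value of the donor item named in
#'     `helpers$donor_map` (columns `food_id`, `donor_food_id`).}
#'   \item{by_calculation}{apply the named calculator (built-ins:
#'     `carb_by_difference`, `chloride_from_sodium`) to the item's profile.}
#'   \item{assumed_zero}{logical zero (e.g. vitamin B12 in plant foods).}
#'   \item{recipe_calculation}{value from composing the recipe named in
#'     `param` over `helpers$recipes` and the FCDB itself.}
#'   \item{borrowed}{value for the same component from `helpers$borrowed`,
#'     another FCDB carrying the same food_id (or mapped via
#'     `helpers$borrow_map`).}
#' }
#'
#' @param x an [fcdb()]; trace flags should be resolved first
#'   ([resolve_traces()]).
#' @param plan an [imputation_plan()].
#' @param helpers list with optional `donor_map`, `recipes`, `borrowed`,
#'   `borrow_map`, `calculators` (named list extending the built-ins).
#' @return list(fcdb = resolved FCDB, audit = counts per strategy + total).
#' @export
impute_missing <- function(x, plan, helpers = list()) {
  stopifnot(inherits(x, "fcdb"))
  calcs <- utils::modifyList(.calculators, helpers$calculators %||% list())
  counts <- c(similar_item = 0L, by_calculation = 0L, assumed_zero = 0L,
              recipe_calculation = 0L, borrowed = 0L)
  cells <- which(x$state == "missing", arr.ind = TRUE)
  for (k in seq_len(nrow(cells))) {
    i <- cells[k, 1]; j <- cells[k, 2]
    comp <- colnames(x$state)[j]
    cls <- x$items$item_class[i]
    rule <- plan[plan$component == comp &
                   (plan$item_class == "*" | plan$item_class == cls), ,
                 drop = FALSE]
    if (!nrow(rule)) {
      stop("no imputation rule for item '", x$items$food_id[i],
           "', component '", comp, "'", call. = FALSE)
    }
    rule <- rule[1L, ]
    val <- switch(rule$strategy,
      assumed_zero = 0,
      by_calculation = {
        f <- calcs[[rule$param]]
        if (is.null(f)) stop("unknown calculator: ", rule$param, call. = FALSE)
        f(x$amounts[i, ])
      },
      similar_item = {
        dm <- helpers$donor_map
        donor <- dm$donor_food_id[dm$food_id == x$items$food_id[i]]
        if (!length(donor)) {
          stop("no donor for item '", x$items$food_id[i], "'", call. = FALSE)
        }
        x$amounts[donor[1L], comp]
      },
      recipe_calculation = {
        comp_vec <- compose_recipe(helpers$recipes[
          helpers$recipes$recipe_id == rule$param, , drop = FALSE], x)
        comp_vec$amounts[comp]
      },
      borrowed = {
        b <- helpers$borrowed
        if (is.null(b)) stop("no borrowed FCDB supplied", call. = FALSE)
        fid <- x$items$food_id[i]
        if (!is.null(helpers$borrow_map)) {
          m <- helpers$borrow_map
          mapped <- m$source_food_id[m$food_id == fid]
          if (length(mapped)) fid <- mapped[1L]
        }
        b$amounts[fid, comp]
      })
    if (is.na(val)) {
      stop("strategy '", rule$strategy, "' produced NA for item '",
           x$items$food_id[i], "', component '", comp, "'", call. = FALSE)
    }
    x$amounts[i, j] <- val
    x$state[i, j] <- "imputed"
    x$method[i, j] <- rule$strategy
    counts[rule$strategy] <- counts[rule$strategy] + 1L
  }
  list(fcdb = x, audit = list(counts = counts, total = sum(counts)))
}
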