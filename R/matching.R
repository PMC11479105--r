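# ---------------------------------------------------------------------------
# Linking each distinct ingredient to target-FCDB composition through five
# expert-curated, table-driven strategies: exact, similar, generic_mean,
# recipe, borrowed. No fuzzy string matching: every link comes from a table.
# ---------------------------------------------------------------------------

.no_match <- function(name) {
  data.frame(ingr_name = name, strategy = NA_character_, target = NA_character_,
             cooked_raw_discrepancy = FALSE, note = "no match",
             stringsAsFactors = FALSE)
}

#' Exact (name-map) matching
#'
#' @param ingredient_name ingredient name as used in the dish files.
#' @param name_map curated two-column table `ingr_name`, `food_id`.
#' @return a one-row MatchRecord data.frame (`strategy == "exact"`), or a
#'   no-match sentinel (`strategy` NA) when the name is absent from the map.
#' @export
exact_match <- function(ingredient_name, name_map) {
  hit <- name_map$food_id[name_map$ingr_name == ingredient_name]
  if (length(hit) > 1L) {
    stop("ambiguous name map for '", ingredient_name, "'", call. = FALSE)
  }
  if (!length(hit)) return(.no_match(ingredient_name))
  data.frame(ingr_name = ingredient_name, strategy = "exact", target = hit,
             cooked_raw_discrepancy = FALSE, note = "",
             stringsAsFactors = FALSE)
}

# per-component scale used by the similarity metric: SD over the candidate
# pool (degenerate SDs fall back to 1 so a constant axis cannot divide by 0)
.profile_components <- c("energy_kcal", "protein", "fat", "carb_avail", "water")

#' Similarity matching on the 5-component profile
#'
#' Selects, among an expert-curated candidate set, the item whose
#' (energy, protein, fat, carbohydrate, water) per-100 g profile is closest
#' to the ingredient's. Distance is Euclidean after dividing each axis by the
#' candidate-pool SD of that component (so kcal cannot dominate grams);
#' exact ties break to the lexicographically smallest food_id.
#'
#' @param ingredient_profile named numeric vector with entries
#'   `energy_kcal`, `protein`, `fat`, `carb_avail`, `water` (per 100 g).
#' @param candidates an [fcdb()] restricted to the candidate items, or a full
#'   fcdb plus `candidate_ids`.
#' @param candidate_ids optional food_ids selecting candidates within `candidates`.
#' @param ingr_name label carried into the MatchRecord.
#' @export
similarity_match <- function(ingredient_profile, candidates,
                             candidate_ids = NULL, ingr_name = "") {
  stopifnot(inherits(candidates, "fcdb"))
  ids <- candidate_ids %||% candidates$items$food_id
  if (!length(ids)) stop("empty candidate list", call. = FALSE)
  prof <- candidates$amounts[ids, .profile_components, drop = FALSE]
  if (anyNA(prof)) {
    stop("candidate profiles incomplete on the 5 similarity components",
         call. = FALSE)
  }
  target <- ingredient_profile[.profile_components]
  if (anyNA(target)) stop("ingredient profile incomplete", call. = FALSE)
  sds <- apply(prof, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  z <- sweep(prof, 2, target, "-")
  z <- sweep(z, 2, sds, "/")
  d <- sqrt(rowSums(z^2))
  best <- ids[order(d, ids)][1L]
  data.frame(ingr_name = ingr_name, strategy = "similar", target = best,
             cooked_raw_discrepancy = FALSE,
             note = sprintf("distance=%.6g", min(d)),
             stringsAsFactors = FALSE)
}

#' Generic-ingredient mean composition
#'
#' Per-component arithmetic mean over the candidate items' resolvable values;
#' a component missing in every candidate stays missing (NA), one missing in
#' some candidates averages the rest and is flagged.
#'
#' @param candidates an [fcdb()]; @param candidate_ids food_ids to average.
#' @return list(food_id, amounts = named mean vector, flagged = components
#'   averaged over a strict subset of candidates).
#' @export
generic_mean <- function(candidates, candidate_ids = NULL) {
  stopifnot(inherits(candidates, "fcdb"))
  ids <- candidate_ids %||% candidates$items$food_id
  if (!length(ids)) stop("empty candidate list", call. = FALSE)
  a <- candidates$amounts[ids, , drop = FALSE]
  means <- colMeans(a, na.rm = TRUE)
  means[is.nan(means)] <- NA_real_
  n_present <- colSums(!is.na(a))
  list(food_id = paste0("mean(", paste(sort(ids), collapse = "+"), ")"),
       amounts = means,
       flagged = names(means)[n_present > 0 & n_present < length(ids)])
}

#' Compose a recipe into a per-100 g food item
#'
#' A recipe lists (food_id, grams) components summing to 100 g of finished
#' recipe; the composition is the grams/100-weighted sum of the component
#' items' per-100 g values. No yield or retention correction is applied
#' (a documented limitation of the whole pipeline). The result is flagged
#' cooked when any component item is cooked.
#'
#' @param recipe data.frame `recipe_id`, `food_id`, `grams` (one recipe).
#' @param fcdb_obj an [fcdb()] resolving every component food_id.
#' @export
compose_recipe <- function(recipe, fcdb_obj) {
  stopifnot(inherits(fcdb_obj, "fcdb"), nrow(recipe) >= 1L)
  if (length(unique(recipe$recipe_id)) != 1L) {
    stop("compose_recipe expects a single recipe", call. = FALSE)
  }
  if (any(recipe$grams <= 0)) stop("component grams must be > 0", call. = FALSE)
  if (abs(sum(recipe$grams) - 100) > 1e-6) {
    stop("recipe '", recipe$recipe_id[1], "' grams sum to ",
         sum(recipe$grams), ", not 100", call. = FALSE)
  }
  missing_ids <- setdiff(recipe$food_id, fcdb_obj$items$food_id)
  if (length(missing_ids)) {
    stop("unresolvable recipe component(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  w <- recipe$grams / 100
  a <- fcdb_obj$amounts[recipe$food_id, , drop = FALSE]
  amounts <- colSums(sweep(a, 1, w, "*"))
  cooked <- any(fcdb_obj$items$cooked[match(recipe$food_id,
                                            fcdb_obj$items$food_id)])
  list(food_id = recipe$recipe_id[1], amounts = amounts, cooked = cooked)
}

#' Resolve all distinct ingredients through the strategy cascade
#'
#' Tries each strategy in `cascade` order per ingredient: `exact` consults
#' `tables$name_map`; `similar` consults `tables$similar_candidates`
#' (`ingr_name`, `food_id`, several rows per name) plus the ingredient's
#' declared profile; `generic_mean` consults `tables$generic_sets`; `recipe`
#' consults `tables$recipe_map` (`ingr_name`, `recipe_id`); `borrowed`
#' consults `tables$borrowed` (`ingr_name`, `source_food_id`). Ingredients
#' unresolved after the cascade are an error. `tables$cooked_raw`
#' (`ingr_name`, `discrepancy`) sets the cooked/raw-discrepancy flag feeding
#' the difference-determinants regression.
#'
#' @param ingredients data.frame with `ingr_name`, optional profile columns
#'   `energy_kcal`, `protein`, `fat`, `carb_avail`, `water` (per 100 g) and
#'   `n_uses` (weighting the audit).
#' @param fcdb_obj the target [fcdb()].
#' @param tables named list of curation tables (see above).
#' @param cascade strategy order; default exact, similar, generic_mean,
#'   recipe, borrowed.
#' @return list(matches = one MatchRecord per ingredient,
#'   audit = list(counts, weighted_counts)).
#' @export
resolve_all <- function(ingredients, fcdb_obj, tables,
                        cascade = c("exact", "similar", "generic_mean",
                                    "recipe", "borrowed")) {
  recs <- vector("list", nrow(ingredients))
  for (i in seq_len(nrow(ingredients))) {
    nm <- ingredients$ingr_name[i]
    rec <- NULL
    for (strategy in cascade) {
      rec <- switch(strategy,
        exact = {
          r <- exact_match(nm, tables$name_map %||%
                             data.frame(ingr_name = character(),
                                        food_id = character()))
          if (is.na(r$strategy)) NULL else r
        },
        similar = {
          cand <- tables$similar_candidates
          ids <- if (is.null(cand)) character() else
            cand$food_id[cand$ingr_name == nm]
          if (!length(ids)) NULL else {
            have <- intersect(.profile_components, names(ingredients))
            prof <- stats::setNames(rep(NA_real_, 5), .profile_components)
            prof[have] <- unlist(ingredients[i, have])
            if (is.na(prof["water"])) {
              # dish files carry no water; close the per-100 g budget instead
              prof["water"] <- max(0, 100 - sum(prof[c("protein", "fat",
                                                       "carb_avail")]))
            }
            similarity_match(prof, fcdb_obj, ids, ingr_name = nm)
          }
        },
        generic_mean = {
          gs <- tables$generic_sets
          ids <- if (is.null(gs)) character() else gs$food_id[gs$ingr_name == nm]
          if (!length(ids)) NULL else
            data.frame(ingr_name = nm, strategy = "generic_mean",
                       target = paste(sort(ids), collapse = "|"),
                       cooked_raw_discrepancy = FALSE, note = "",
                       stringsAsFactors = FALSE)
        },
        recipe = {
          rm_ <- tables$recipe_map
          rid <- if (is.null(rm_)) character() else
            rm_$recipe_id[rm_$ingr_name == nm]
          if (!length(rid)) NULL else
            data.frame(ingr_name = nm, strategy = "recipe", target = rid[1L],
                       cooked_raw_discrepancy = FALSE, note = "",
                       stringsAsFactors = FALSE)
        },
        borrowed = {
          bw <- tables$borrowed
          fid <- if (is.null(bw)) character() else
            bw$source_food_id[bw$ingr_name == nm]
          if (!length(fid)) NULL else
            data.frame(ingr_name = nm, strategy = "borrowed", target = fid[1L],
                       cooked_raw_discrepancy = FALSE, note = "",
                       stringsAsFactors = FALSE)
        })
      if (!is.null(rec)) break
    }
    if (is.null(rec)) recs[[i]] <- .no_match(nm) else recs[[i]] <- rec
  }
  matches <- do.call(rbind, recs)
  unresolved <- matches$ingr_name[is.na(matches$strategy)]
  if (length(unresolved)) {
    stop("unresolved ingredient(s) after cascade: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  cr <- tables$cooked_raw
  if (!is.null(cr)) {
    flag <- cr$discrepancy[match(matches$ingr_name, cr$ingr_name)]
    matches$cooked_raw_discrepancy <- !is.na(flag) & as.logical(flag)
  }
  counts <- table(factor(matches$strategy,
                         levels = c("exact", "similar", "generic_mean",
                                    "recipe", "borrowed")))
  w <- ingredients$n_uses %||% rep(1L, nrow(ingredients))
  weighted <- tapply(w, factor(matches$strategy,
                               levels = names(counts)), sum)
  weighted[is.na(weighted)] <- 0
  list(matches = matches,
       audit = list(counts = c(counts), weighted_counts = c(weighted)))
}

#' Per-ingredient composition matrix implied by a match table
#'
#' Materializes each matched ingredient's per-100 g component vector from its
#' MatchRecord: direct lookup for exact/similar, candidate means for
#' generic_mean, [compose_recipe()] for recipe, and a lookup in the borrowed
#' FCDB for borrowed.
#'
#' @param matches `resolve_all()$matches`.
#' @param fcdb_obj target [fcdb()] (must be fully resolved for use in totals).
#' @param recipes recipe definition table (`recipe_id`, `food_id`, `grams`).
#' @param borrowed_fcdb the source FCDB for borrowed values.
#' @return numeric matrix, one row per ingredient name.
#' @export
ingredient_compositions <- function(matches, fcdb_obj, recipes = NULL,
                                    borrowed_fcdb = NULL) {
  out <- matrix(NA_real_, nrow(matches), nrow(fcdb_obj$registry),
                dimnames = list(matches$ingr_name, fcdb_obj$registry$code))
  for (i in seq_len(nrow(matches))) {
    m <- matches[i, ]
    out[i, ] <- switch(m$strategy,
      exact = ,
      similar = fcdb_obj$amounts[m$target, ],
      generic_mean = generic_mean(fcdb_obj,
                                  strsplit(m$target, "|", fixed = TRUE)[[1]])$amounts,
      recipe = compose_recipe(recipes[recipes$recipe_id == m$target, ,
                                      drop = FALSE], fcdb_obj)$amounts,
      borrowed = {
        if (is.null(borrowed_fcdb)) stop("borrowed FCDB missing", call. = FALSE)
        borrowed_fcdb$amounts[m$target, ]
      },
      stop("unknown strategy: ", m$strategy, call. = FALSE))
  }
  out
}
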