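# ---------------------------------------------------------------------------
# Seeded synthetic world: paired FCDBs sharing items but differing by the
# fiber-in-carbohydrate definitional offset plus per-component noise, and
# dish files in the public ragged-wide dialect with planted curation work
# (plate-only dishes, missing names, a mass outlier) and known ground truth.
#
# The generator computes every dish total itself, by direct arithmetic over
# the compositions it planted; that independent computation is the oracle the
# pipeline is tested against.
# ---------------------------------------------------------------------------

#' Synthetic-world configuration
#'
#' Defaults state the emulated world once: dish scale echoes the real corpus
#' (right-skewed masses with median ~150 g, median 3 ingredients), the
#' definitional carbohydrate offset is on (source B's carbohydrate includes
#' fiber, source A's does not), the strategy mix roughly follows the observed
#' ~70% exact share, and the planted regression betas are the published
#' carbohydrate-model coefficients.
#'
#' @param n_items food items in each FCDB.
#' @param n_ingredients distinct dish ingredients.
#' @param n_dishes dishes generated (plus 2 planted plate-only dishes).
#' @param max_ingredients per-dish cap; counts are 1 + Poisson(2.5) truncated.
#' @param mass_meanlog,mass_sdlog lognormal per-use mass (g).
#' @param carb_definition_offset logical; B's carbohydrate includes fiber.
#' @param noise_sd lognormal SD of B's per-component noise around A.
#' @param missing_rate planted missing rate on the imputable components
#'   (chloride, vitamin B12 in plant items, vitamin D, retinol).
#' @param trace_rate planted trace rate on alpha-tocopherol.
#' @param strategy_fractions named fractions over
#'   exact/similar/generic_mean/recipe/borrowed (sum 1).
#' @param rawcooked_rate fraction of distinct ingredients whose match carries
#'   a cooked/raw discrepancy.
#' @param rawcooked_effect multiplicative bump applied to the A-side
#'   macronutrients of discrepant ingredients (0 disables).
#' @param plant_curation logical; plant plate-only dishes, missing names and
#'   one mass outlier with its correction row.
#' @param betas named planted regression coefficients (see
#'   [simulate_regression()]).
#' @param resid_sd,outlier_rate,outlier_shift regression noise geometry.
#' @param seed mandatory RNG seed.
#' @export
synth_config <- function(n_items = 60L, n_ingredients = 40L, n_dishes = 400L,
                         max_ingredients = 12L,
                         mass_meanlog = log(40), mass_sdlog = 0.8,
                         carb_definition_offset = TRUE,
                         noise_sd = 0.05,
                         missing_rate = 0.05, trace_rate = 0.05,
                         strategy_fractions = c(exact = 0.70, similar = 0.10,
                                                generic_mean = 0.05,
                                                recipe = 0.10, borrowed = 0.05),
                         rawcooked_rate = 0.25, rawcooked_effect = 0.10,
                         plant_curation = TRUE,
                         betas = c(`(Intercept)` = -1.50, mass_25 = -0.37,
                                   n_ingredients = 0.11, rawcookedone = 0.51,
                                   rawcookedmore = 1.54, recreatedyes = 0.52,
                                   `rawcookedone:recreatedyes` = -0.49,
                                   `rawcookedmore:recreatedyes` = -0.69),
                         resid_sd = 3, outlier_rate = 0.10,
                         outlier_shift = 40, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  rates <- c(missing_rate, trace_rate, rawcooked_rate, outlier_rate,
             strategy_fractions)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0,1]", call. = FALSE)
  if (abs(sum(strategy_fractions) - 1) > 1e-8) {
    stop("strategy_fractions must sum to 1", call. = FALSE)
  }
  cfg <- as.list(environment())
  n_needed <- ceiling(n_ingredients * (1 + strategy_fractions[["generic_mean"]] +
                                         strategy_fractions[["recipe"]])) + 2
  if (n_items < n_needed) {
    stop("infeasible config: n_items too small for the strategy mix",
         call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

# plausible per-100 g item compositions on the packaged registry
.gen_items <- function(n, registry) {
  protein <- round(stats::rgamma(n, 2, rate = 0.15), 2)    # ~0-40 g
  fat <- round(stats::rgamma(n, 1.5, rate = 0.15), 2)
  sugar <- round(stats::rgamma(n, 1.2, rate = 0.12), 2)
  starch <- round(stats::rgamma(n, 1.2, rate = 0.10), 2)
  fiber <- round(stats::rgamma(n, 1.5, rate = 0.6), 2)     # ~0-8 g
  carb <- sugar + starch
  macro <- protein + fat + carb + fiber
  scale_down <- pmin(1, 95 / (macro + 1e-9))
  protein <- protein * scale_down; fat <- fat * scale_down
  sugar <- sugar * scale_down; starch <- starch * scale_down
  fiber <- fiber * scale_down; carb <- sugar + starch
  ash <- round(stats::runif(n, 0.3, 2.5), 2)
  water <- pmax(0, 100 - (protein + fat + carb + fiber + ash))
  alcohol <- rep(0, n)
  energy <- 4 * protein + 9 * fat + 4 * carb + 2 * fiber
  sodium <- round(stats::rgamma(n, 1.2, rate = 0.005), 1)   # mg
  m <- cbind(energy_kcal = energy, energy_kj = 4.184 * energy,
             water = water, protein = protein, fat = fat,
             carb_avail = carb, fiber = fiber, sugar = sugar,
             starch = starch, ash = ash, alcohol = alcohol,
             sodium = sodium,
             chloride = round(sodium * 35.453 / 22.990, 2),
             potassium = round(stats::rgamma(n, 2, rate = 0.008), 1),
             retinol = round(stats::rgamma(n, 1, rate = 0.02), 1),
             vitamin_d = round(stats::rgamma(n, 1, rate = 0.8), 2),
             alpha_tocopherol = round(stats::rgamma(n, 1.5, rate = 1), 3),
             vitamin_b12 = round(stats::rgamma(n, 1, rate = 1.2), 2),
             sfa_short = round(stats::rgamma(n, 1, rate = 3), 3),
             pufa_other = round(stats::rgamma(n, 1, rate = 2), 3))
  m[, registry$code, drop = FALSE]
}

#' Generate the synthetic bundle
#'
#' Writes to `dir`: `registry.csv`, `fcdb_A.csv` (harmonization target, with
#' planted trace/missing sentinels), `fcdb_B.csv` (complete source FCDB),
#' `dish_metadata_cafe1.csv` (public dialect), `ingredients_metadata.csv`,
#' curation tables (`name_map.csv`, `similar_candidates.csv`,
#' `generic_sets.csv`, `recipes.csv`, `recipe_map.csv`, `borrowed.csv`,
#' `cooked_raw.csv`, `plate_only.csv`, `mass_corrections.csv`,
#' `manual_names.csv`, `donor_map.csv`, `imputation_plan.csv`) and
#' `ground_truth.json`. Regeneration with the same seed is byte-identical.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @return the ground-truth list, invisibly.
#' @export
generate_synthetic <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  registry <- default_registry()
  gt <- with_seed(config$seed, .generate_impl(config, dir, registry))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(gt)
}

.generate_impl <- function(cfg, dir, registry) {
  codes <- registry$code
  n_items <- cfg$n_items

  ## ---- FCDB A (true, fully resolved) and B (noisy + carb definition) -----
  comp_A <- .gen_items(n_items, registry)
  food_ids <- sprintf("food_%03d", seq_len(n_items))
  rownames(comp_A) <- food_ids
  item_class <- sample(c("plant", "animal"), n_items, replace = TRUE,
                       prob = c(0.6, 0.4))
  cooked <- sample(c(TRUE, FALSE), n_items, replace = TRUE, prob = c(0.4, 0.6))
  comp_A[item_class == "plant", "vitamin_b12"] <- 0

  noise <- matrix(exp(stats::rnorm(n_items * length(codes), 0, cfg$noise_sd)),
                  n_items, length(codes), dimnames = list(food_ids, codes))
  comp_B <- comp_A * noise
  if (cfg$carb_definition_offset) {
    # source B reports carbohydrate by difference: fiber included
    comp_B[, "carb_avail"] <- comp_A[, "carb_avail"] * noise[, "carb_avail"] +
      comp_A[, "fiber"] * noise[, "fiber"]
  }
  comp_B[, "energy_kcal"] <- 4 * comp_B[, "protein"] + 9 * comp_B[, "fat"] +
    4 * comp_B[, "carb_avail"]
  comp_B[, "energy_kj"] <- 4.184 * comp_B[, "energy_kcal"]

  ## ---- plant trace and missing states in A, keeping comp_A the truth -----
  state_A <- matrix("measured", n_items, length(codes),
                    dimnames = list(food_ids, codes))
  tr_cells <- which(stats::runif(n_items) < cfg$trace_rate)
  state_A[tr_cells, "alpha_tocopherol"] <- "trace"
  comp_A[tr_cells, "alpha_tocopherol"] <- 0.005   # the trace-rule constant

  plant_missing <- function(comp, truth) {
    cells <- which(stats::runif(n_items) < cfg$missing_rate)
    cells <- cells[state_A[cells, comp] == "measured"]
    state_A[cells, comp] <<- "missing"
    comp_A[cells, comp] <<- truth(cells)
    cells
  }
  miss_cl <- plant_missing("chloride",
                           function(i) comp_A[i, "sodium"] * 35.453 / 22.990)
  miss_b12 <- {
    cells <- which(stats::runif(n_items) < cfg$missing_rate &
                     item_class == "plant")
    state_A[cells, "vitamin_b12"] <- "missing"
    comp_A[cells, "vitamin_b12"] <- 0
    cells
  }
  # vitamin D: missing cells imputed from a donor item; pick donors among
  # items that stay measured, and make the donor's value the planted truth
  miss_vd <- which(stats::runif(n_items) < cfg$missing_rate)
  donor_pool <- setdiff(seq_len(n_items), miss_vd)
  donor_map <- data.frame(food_id = character(), donor_food_id = character(),
                          stringsAsFactors = FALSE)
  if (length(miss_vd) && length(donor_pool)) {
    donors <- sample(donor_pool, length(miss_vd), replace = TRUE)
    state_A[miss_vd, "vitamin_d"] <- "missing"
    comp_A[miss_vd, "vitamin_d"] <- comp_A[donors, "vitamin_d"]
    donor_map <- data.frame(food_id = food_ids[miss_vd],
                            donor_food_id = food_ids[donors],
                            stringsAsFactors = FALSE)
  } else {
    miss_vd <- integer()
  }
  miss_ret <- plant_missing("retinol", function(i) comp_B[i, "retinol"])

  ## ---- distinct ingredients and their strategies -------------------------
  n_ing <- cfg$n_ingredients
  strategies <- rep(names(cfg$strategy_fractions),
                    times = round(cfg$strategy_fractions * n_ing))
  strategies <- c(strategies, rep("exact", n_ing - length(strategies)))[1:n_ing]
  strategies <- sample(strategies)
  ingr_ids <- sprintf("ingr_%03d", seq_len(n_ing))
  ingr_names <- sprintf("ingredient_%03d", seq_len(n_ing))

  # true item assignment: one per ingredient, without replacement
  true_item <- sample.int(n_items, n_ing)
  used <- true_item

  name_map <- similar_cand <- generic_sets <- recipe_map <- borrowed <- NULL
  recipes <- NULL
  comp_A_ing <- matrix(NA_real_, n_ing, length(codes),
                       dimnames = list(ingr_names, codes))
  comp_B_ing <- comp_A_ing
  raw_dist <- function(i, j) {
    sqrt(sum((comp_A[i, c("energy_kcal", "protein", "fat", "carb_avail",
                          "water")] -
                comp_A[j, c("energy_kcal", "protein", "fat", "carb_avail",
                            "water")])^2))
  }
  for (k in seq_len(n_ing)) {
    it <- true_item[k]
    switch(strategies[k],
      exact = {
        name_map <- rbind(name_map,
                          data.frame(ingr_name = ingr_names[k],
                                     food_id = food_ids[it]))
        comp_A_ing[k, ] <- comp_A[it, ]
        comp_B_ing[k, ] <- comp_B[it, ]
      },
      similar = {
        # decoy = the available item farthest from the true one in raw
        # profile space, so declared-profile noise cannot flip the argmin
        pool <- setdiff(seq_len(n_items), it)
        d <- vapply(pool, function(j) raw_dist(it, j), numeric(1))
        decoy <- pool[which.max(d)]
        similar_cand <- rbind(similar_cand,
                              data.frame(ingr_name = ingr_names[k],
                                         food_id = c(food_ids[it],
                                                     food_ids[decoy])))
        comp_A_ing[k, ] <- comp_A[it, ]
        comp_B_ing[k, ] <- comp_B[it, ]
      },
      generic_mean = {
        pool <- setdiff(seq_len(n_items), used)
        other <- pool[1L]
        used <- c(used, other)
        ids <- c(it, other)
        generic_sets <- rbind(generic_sets,
                              data.frame(ingr_name = ingr_names[k],
                                         food_id = food_ids[ids]))
        comp_A_ing[k, ] <- colMeans(comp_A[ids, , drop = FALSE])
        comp_B_ing[k, ] <- colMeans(comp_B[ids, , drop = FALSE])
      },
      recipe = {
        pool <- setdiff(seq_len(n_items), used)
        other <- pool[1L]
        used <- c(used, other)
        rid <- paste0("recipe_", ingr_ids[k])
        g1 <- round(stats::runif(1, 30, 70), 1)
        recipes <- rbind(recipes,
                         data.frame(recipe_id = rid,
                                    food_id = food_ids[c(it, other)],
                                    grams = c(g1, 100 - g1)))
        recipe_map <- rbind(recipe_map,
                            data.frame(ingr_name = ingr_names[k],
                                       recipe_id = rid))
        w <- c(g1, 100 - g1) / 100
        comp_A_ing[k, ] <- colSums(comp_A[c(it, other), , drop = FALSE] * w)
        comp_B_ing[k, ] <- colSums(comp_B[c(it, other), , drop = FALSE] * w)
      },
      borrowed = {
        borrowed <- rbind(borrowed,
                          data.frame(ingr_name = ingr_names[k],
                                     source_food_id = food_ids[it]))
        comp_A_ing[k, ] <- comp_B[it, ]   # borrowed values come from B
        comp_B_ing[k, ] <- comp_B[it, ]
      })
  }

  ## ---- cooked/raw discrepancy flags and their A-side effect --------------
  disc <- stats::runif(n_ing) < cfg$rawcooked_rate
  cooked_raw <- data.frame(ingr_name = ingr_names, discrepancy = disc,
                           stringsAsFactors = FALSE)
  # The cooked/raw mismatch shifts the *declared* (B) side: the source FCDB
  # described a differently prepared item, so its macronutrients are deflated
  # by the effect. The A side is untouched, which keeps fcdb_A a faithful
  # input for the exact/similar/recipe resolution paths.
  if (cfg$rawcooked_effect > 0 && any(disc)) {
    macro <- c("protein", "fat", "carb_avail")
    comp_B_ing[disc, macro] <- comp_B_ing[disc, macro] /
      (1 + cfg$rawcooked_effect)
    comp_B_ing[disc, "energy_kcal"] <- 4 * comp_B_ing[disc, "protein"] +
      9 * comp_B_ing[disc, "fat"] + 4 * comp_B_ing[disc, "carb_avail"]
    comp_B_ing[disc, "energy_kj"] <- 4.184 * comp_B_ing[disc, "energy_kcal"]
  }

  ## ---- dishes -------------------------------------------------------------
  n_dish <- cfg$n_dishes
  dish_ids <- sprintf("dish_%05d", seq_len(n_dish))
  uses <- vector("list", n_dish)
  for (d in seq_len(n_dish)) {
    k <- min(1L + stats::rpois(1, 2.5), cfg$max_ingredients)
    sel <- sample.int(n_ing, k)
    grams <- round(stats::rlnorm(k, cfg$mass_meanlog, cfg$mass_sdlog), 1)
    uses[[d]] <- data.frame(dish_id = dish_ids[d], position = seq_len(k),
                            ingr_idx = sel, ingr_grams = grams,
                            stringsAsFactors = FALSE)
  }
  uses <- do.call(rbind, uses)

  ## ---- planted curation work ---------------------------------------------
  plate_ids <- character()
  corrections <- data.frame()
  manual_names <- data.frame(ingr_id = character(), ingr_name = character(),
                             stringsAsFactors = FALSE)
  blank_name_rows <- integer()
  deprecated_ing <- NA_integer_
  if (cfg$plant_curation) {
    # one mass outlier (x1000) on an ingredient with >= 3 uses
    tab <- table(uses$ingr_idx)
    cand <- as.integer(names(tab)[tab >= 3])
    if (length(cand)) {
      tgt <- which(uses$ingr_idx == cand[1L])[1L]
      right <- uses$ingr_grams[tgt]
      uses$ingr_grams[tgt] <- right * 1000
      corrections <- data.frame(ingr_id = ingr_ids[cand[1L]],
                                wrong_mass = right * 1000,
                                corrected_mass = right,
                                rationale = "order-of-magnitude error",
                                stringsAsFactors = FALSE)
    }
    # missing names: some uses of two ingredients lose their name in the
    # dish file; the first is recoverable from the catalogue, the second is
    # catalogued as "deprecated" and needs the manual map
    freq <- table(uses$ingr_idx)
    multi <- as.integer(names(freq)[freq >= 2])
    multi <- setdiff(multi, if (nrow(corrections)) cand[1L] else integer())
    if (length(multi) >= 2) {
      blank_name_rows <- c(which(uses$ingr_idx == multi[1L])[1L],
                           which(uses$ingr_idx == multi[2L])[1L])
      deprecated_ing <- multi[2L]
      manual_names <- data.frame(ingr_id = ingr_ids[multi[2L]],
                                 ingr_name = ingr_names[multi[2L]],
                                 stringsAsFactors = FALSE)
    }
    plate_ids <- c("dish_plate_a", "dish_plate_b")
  }

  ## ---- write the dish metadata file (public dialect) ---------------------
  scale <- uses$ingr_grams / 100
  decl <- comp_B_ing[uses$ingr_idx, c("energy_kcal", "fat", "carb_avail",
                                      "protein"), drop = FALSE] * scale
  uses_out <- data.frame(dish_id = uses$dish_id, position = uses$position,
                         ingr_id = ingr_ids[uses$ingr_idx],
                         ingr_name = ingr_names[uses$ingr_idx],
                         ingr_grams = uses$ingr_grams,
                         declared_energy = decl[, "energy_kcal"],
                         declared_fat = decl[, "fat"],
                         declared_carb = decl[, "carb_avail"],
                         declared_protein = decl[, "protein"],
                         stringsAsFactors = FALSE)
  if (length(blank_name_rows)) uses_out$ingr_name[blank_name_rows] <- ""
  dish_hdr <- data.frame(
    dish_id = dish_ids,
    total_mass = as.numeric(rowsum(uses_out$ingr_grams, uses$dish_id)[dish_ids, ]),
    total_calories = as.numeric(rowsum(uses_out$declared_energy,
                                       uses$dish_id)[dish_ids, ]),
    total_fat = as.numeric(rowsum(uses_out$declared_fat, uses$dish_id)[dish_ids, ]),
    total_carb = as.numeric(rowsum(uses_out$declared_carb,
                                   uses$dish_id)[dish_ids, ]),
    total_protein = as.numeric(rowsum(uses_out$declared_protein,
                                      uses$dish_id)[dish_ids, ]),
    num_ingrs = as.integer(table(uses$dish_id)[dish_ids]),
    stringsAsFactors = FALSE)
  if (length(plate_ids)) {
    plate_uses <- data.frame(dish_id = plate_ids, position = 1L,
                             ingr_id = "ingr_plate", ingr_name = "plate",
                             ingr_grams = 0, declared_energy = 0,
                             declared_fat = 0, declared_carb = 0,
                             declared_protein = 0, stringsAsFactors = FALSE)
    uses_out <- rbind(uses_out, plate_uses)
    dish_hdr <- rbind(dish_hdr,
                      data.frame(dish_id = plate_ids, total_mass = 0,
                                 total_calories = 0, total_fat = 0,
                                 total_carb = 0, total_protein = 0,
                                 num_ingrs = 1L, stringsAsFactors = FALSE))
  }
  ds <- structure(list(dishes = dish_hdr, uses = uses_out,
                       dialect = n5k_dialect("public")),
                  class = "dish_set")
  write_dish_metadata(ds, file.path(dir, "dish_metadata_cafe1.csv"))

  ## ---- catalogue and curation tables -------------------------------------
  catalog <- data.frame(id = c(ingr_ids, "ingr_plate"),
                        ingr = c(ingr_names, "plate"),
                        stringsAsFactors = FALSE)
  if (!is.na(deprecated_ing)) {
    catalog$ingr[deprecated_ing] <- "deprecated"
  }
  utils::write.csv(catalog, file.path(dir, "ingredients_metadata.csv"),
                   row.names = FALSE)

  wt <- function(df, f) if (!is.null(df) && nrow(df)) {
    utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  } else {
    utils::write.csv(df %||% data.frame(), file.path(dir, f), row.names = FALSE)
  }
  wt(name_map, "name_map.csv")
  wt(similar_cand, "similar_candidates.csv")
  wt(generic_sets, "generic_sets.csv")
  wt(recipes, "recipes.csv")
  wt(recipe_map, "recipe_map.csv")
  wt(borrowed, "borrowed.csv")
  wt(cooked_raw, "cooked_raw.csv")
  wt(data.frame(dish_id = plate_ids), "plate_only.csv")
  wt(corrections, "mass_corrections.csv")
  wt(manual_names, "manual_names.csv")
  wt(donor_map, "donor_map.csv")
  plan <- imputation_plan(
    component = c("chloride", "vitamin_b12", "vitamin_d", "retinol"),
    item_class = c("*", "plant", "*", "*"),
    strategy = c("by_calculation", "assumed_zero", "similar_item", "borrowed"),
    param = c("chloride_from_sodium", NA, NA, NA))
  utils::write.csv(plan, file.path(dir, "imputation_plan.csv"),
                   row.names = FALSE)

  ## ---- write the FCDB files ----------------------------------------------
  utils::write.csv(as.data.frame(registry),
                   file.path(dir, "registry.csv"), row.names = FALSE)
  items_A <- data.frame(food_id = food_ids, name = food_ids, cooked = cooked,
                        item_class = item_class, stringsAsFactors = FALSE)
  amounts_A_file <- comp_A
  amounts_A_file[state_A != "measured"] <- NA
  fa <- fcdb(items_A, amounts_A_file,
             ifelse(state_A == "measured", "measured", state_A), registry)
  write_fcdb(fa, file.path(dir, "fcdb_A.csv"))
  fb <- fcdb(items_A, comp_B,
             matrix("measured", n_items, length(codes),
                    dimnames = dimnames(comp_B)), registry)
  write_fcdb(fb, file.path(dir, "fcdb_B.csv"))

  ## ---- independent ground-truth totals (post-curation corpus) ------------
  grams_fixed <- uses$ingr_grams
  if (nrow(corrections)) {
    hit <- ingr_ids[uses$ingr_idx] == corrections$ingr_id &
      grams_fixed == corrections$wrong_mass
    grams_fixed[hit] <- corrections$corrected_mass
  }
  totals_A <- totals_B <- matrix(0, n_dish, length(codes),
                                 dimnames = list(dish_ids, codes))
  fiber_mass <- stats::setNames(numeric(n_dish), dish_ids)
  mass_tot <- stats::setNames(numeric(n_dish), dish_ids)
  for (r in seq_len(nrow(uses))) {
    d <- uses$dish_id[r]; k <- uses$ingr_idx[r]; g <- grams_fixed[r]
    totals_A[d, ] <- totals_A[d, ] + comp_A_ing[k, ] * g / 100
    totals_B[d, ] <- totals_B[d, ] + comp_B_ing[k, ] * g / 100
    mass_tot[d] <- mass_tot[d] + g
    if (strategies[k] != "borrowed") {
      fiber_mass[d] <- fiber_mass[d] + comp_A_ing[k, "fiber"] * g / 100
    }
  }
  disc_count <- stats::setNames(integer(n_dish), dish_ids)
  has_recipe <- stats::setNames(logical(n_dish), dish_ids)
  for (r in seq_len(nrow(uses))) {
    d <- uses$dish_id[r]; k <- uses$ingr_idx[r]
    disc_count[d] <- disc_count[d] + as.integer(disc[k])
    has_recipe[d] <- has_recipe[d] || strategies[k] == "recipe"
  }

  list(
    config = unclass(cfg),
    strategy_counts = as.list(table(factor(strategies,
      levels = c("exact", "similar", "generic_mean", "recipe", "borrowed")))),
    dish_ids = dish_ids,
    mass = as.numeric(mass_tot),
    totals_A = as.data.frame(totals_A),
    totals_B = as.data.frame(totals_B),
    fiber_mass = as.numeric(fiber_mass),
    rawcooked_count = as.integer(disc_count),
    recreated = as.logical(has_recipe),
    plate_only = plate_ids,
    n_missing_planted = length(miss_cl) + length(miss_b12) +
      length(miss_vd) + length(miss_ret),
    n_trace_planted = length(tr_cells),
    planted_betas = as.list(cfg$betas)
  )
}

#' Simulate the difference-determinants regression world
#'
#' Draws a design shaped like the published model (mass in 25 g units,
#' ingredient count, rawcooked none/one/more, recreated no/yes, and their
#' interaction), a response `X beta + e` with Gaussian errors, and an
#' `outlier_rate` fraction of gross response outliers shifted by
#' `outlier_shift`. Ground truth (`betas`, outlier rows) is returned.
#'
#' @param n dishes; @param betas named length-8 coefficient vector in
#'   model-matrix order; @param resid_sd Gaussian error SD;
#'   @param outlier_rate,outlier_shift contamination geometry;
#'   @param seed RNG seed.
#' @export
simulate_regression <- function(n, betas, resid_sd = 3, outlier_rate = 0,
                                outlier_shift = 40, seed) {
  stopifnot(!missing(seed))
  with_seed(seed, {
    frame <- data.frame(
      mass_25 = stats::rgamma(n, 2, rate = 0.3),
      n_ingredients = 1L + stats::rpois(n, 2.5),
      rawcooked = factor(sample(c("none", "one", "more"), n, TRUE,
                                prob = c(0.35, 0.30, 0.35)),
                         levels = c("none", "one", "more")),
      recreated = factor(sample(c("no", "yes"), n, TRUE, prob = c(0.7, 0.3)),
                         levels = c("no", "yes")))
    X <- stats::model.matrix(
      ~ mass_25 + n_ingredients + rawcooked + recreated + rawcooked:recreated,
      data = frame)
    stopifnot(identical(colnames(X), names(betas)))
    e <- stats::rnorm(n, 0, resid_sd)
    out_rows <- which(stats::runif(n) < outlier_rate)
    e[out_rows] <- outlier_shift + abs(stats::rnorm(length(out_rows), 0,
                                                    resid_sd))
    y <- as.vector(X %*% betas + e)
    list(X = X, y = y, frame = frame, betas = betas, outliers = out_rows)
  })
}

#' End-to-end pipeline check against the generator's ground truth
#'
#' Generates a bundle, runs the full pipeline on its files, and compares the
#' recovered dish totals, strategy audit, and concordance quantities to the
#' planted truth.
#'
#' @param config a [synth_config()]; @param dir working directory.
#' @return report list with `max_abs_total_error`, `audit_matches`,
#'   per-nutrient delta medians, and the pipeline artifacts.
#' @export
end_to_end_check <- function(config, dir = tempfile("synthworld")) {
  gt <- generate_synthetic(config, dir)
  res <- harmonize_bundle(dir)
  tot <- res$totals
  gt_tot <- as.matrix(gt$totals_A)
  common <- intersect(tot$dish_id, rownames(gt_tot))
  comp <- as.matrix(tot[match(common, tot$dish_id),
                        colnames(gt_tot), drop = FALSE])
  err <- max(abs(comp - gt_tot[common, , drop = FALSE]))
  audit_ok <- identical(
    as.integer(res$match_audit$counts),
    as.integer(unlist(gt$strategy_counts)))
  decl <- res$declared_totals
  dd <- decl[match(common, decl$dish_id), ]
  deltas <- list(
    carb = stats::median(comp[, "carb_avail"] - dd$carb_avail),
    protein = stats::median(comp[, "protein"] - dd$protein),
    fat = stats::median(comp[, "fat"] - dd$fat))
  list(max_abs_total_error = err, audit_matches = audit_ok,
       median_delta = deltas, ground_truth = gt, pipeline = res)
}
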