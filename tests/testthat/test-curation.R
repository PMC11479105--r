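make_uses <- function() {
  data.frame(dish_id = c("d1", "d1", "d2", "d2", "d3"),
             position = c(1L, 2L, 1L, 2L, 1L),
             ingr_id = c("i1", "i2", "i1", "i3", "i1"),
             ingr_name = c("olives", "asparagus", "olives", "rice", "olives"),
             ingr_grams = c(5, 3324, 5, 50, 7974),
             declared_energy = c(10, 60, 10, 65, 15948),
             declared_fat = c(1, 0.1, 1, 0.1, 1595),
             declared_carb = c(0.2, 6, 0.2, 14, 319),
             declared_protein = c(0.1, 7, 0.1, 1.3, 160),
             stringsAsFactors = FALSE)
}

test_that("plate-only removal drops exactly the listed dishes", {
  f <- write_dish_lines(c(
    "d1,52,100,0.2,14,0.3,i,apple,100,52,0.2,14,0.3",
    "plate_1,0,0,0,0,0,ip,plate,0,0,0,0,0",
    "d2,52,100,0.2,14,0.3,i,apple,100,52,0.2,14,0.3",
    "plate_2,0,0,0,0,0,ip,plate,0,0,0,0,0"))
  ds <- parse_dish_metadata(f)
  out <- remove_plate_only(ds, c("plate_1", "plate_2"))
  expect_equal(out$dishes$dish_id, c("d1", "d2"))
  expect_equal(attr(out, "removed"), 2L)
  expect_equal(remove_plate_only(ds, character())$dishes, ds$dishes)
  expect_warning(remove_plate_only(ds, "ghost"), "not present")
  all_gone <- remove_plate_only(ds, ds$dishes$dish_id)
  expect_equal(nrow(all_gone$dishes), 0L)
})

test_that("missing names recover via catalogue then manual map", {
  uses <- make_uses()
  uses$ingr_name[c(1, 4)] <- ""
  catalog <- data.frame(ingr_id = c("i1", "i3"),
                        canonical_name = c("olives", "deprecated"),
                        deprecated = c(FALSE, TRUE), stringsAsFactors = FALSE)
  manual <- data.frame(ingr_id = "i3", ingr_name = "rice")
  out <- recover_missing_names(uses, catalog, manual)
  expect_equal(out$uses$ingr_name[1], "olives")
  expect_equal(out$uses$ingr_name[4], "rice")
  expect_equal(unname(out$report), c(1L, 1L))
  expect_error(recover_missing_names(uses, catalog), "i3")
})

test_that("mass outlier detection flags extreme uses only", {
  uses <- data.frame(ingr_id = "i1", ingr_name = "olives",
                     ingr_grams = c(5, 5, 7974), stringsAsFactors = FALSE)
  det <- detect_mass_outliers(uses)
  expect_equal(det$flagged$ingr_grams, 7974)
  expect_equal(det$summary$median, 5)
  uniform <- data.frame(ingr_id = "i1", ingr_name = "x",
                        ingr_grams = rep(10, 5), stringsAsFactors = FALSE)
  expect_equal(nrow(detect_mass_outliers(uniform)$flagged), 0L)
  single <- data.frame(ingr_id = "i1", ingr_name = "y", ingr_grams = 9999,
                       stringsAsFactors = FALSE)
  expect_equal(nrow(detect_mass_outliers(single)$flagged), 0L)
})

test_that("mass corrections rewrite only targeted rows, conserving the ledger", {
  uses <- make_uses()
  corr <- mass_corrections(c("i1", "i2"), c(7974, 3324), c(7.974, 3.324),
                           "order-of-magnitude error")
  out <- apply_mass_corrections(uses, corr)
  expect_equal(out$ingr_grams[5], 7.974)
  expect_equal(out$ingr_grams[2], 3.324)
  expect_equal(out$ingr_grams[c(1, 3, 4)], uses$ingr_grams[c(1, 3, 4)])
  expect_equal(sum(uses$ingr_grams) - sum(out$ingr_grams),
               sum(corr$wrong_mass - corr$corrected_mass))
  # declared values rescale with the mass
  expect_equal(out$declared_energy[5], 15948 * 7.974 / 7974)
  expect_equal(apply_mass_corrections(uses, corr[0, ]), uses)
  expect_warning(apply_mass_corrections(uses,
    mass_corrections("i9", 1000, 1)), "matched no use")
  expect_error(mass_corrections("i1", 5, 7), "reduce")
})

test_that("missing-value imputation follows the plan with a faithful audit", {
  reg <- component_registry(data.frame(
    code = c("water", "protein", "fat", "ash", "alcohol", "carb_avail",
             "sodium", "chloride", "vitamin_b12"),
    name = letters[1:9],
    unit = c(rep("g", 6), "mg", "mg", "ug"),
    trace_threshold = NA_real_, stringsAsFactors = FALSE))
  a <- rbind(it_a = c(60, 10, 5, 2, 0, NA, 1000, NA, NA),
             it_b = c(70, 5, 2, 1, 0, 15, 200, 300, 1))
  colnames(a) <- reg$code
  s <- matrix("measured", 2, 9, dimnames = dimnames(a))
  s[is.na(a)] <- "missing"
  x <- fcdb(data.frame(food_id = c("it_a", "it_b"),
                       name = c("veg", "fish"),
                       item_class = c("plant", "animal"),
                       stringsAsFactors = FALSE), a, s, reg)
  plan <- imputation_plan(
    component = c("carb_avail", "chloride", "vitamin_b12"),
    item_class = c("*", "*", "plant"),
    strategy = c("by_calculation", "by_calculation", "assumed_zero"),
    param = c("carb_by_difference", "chloride_from_sodium", NA))
  out <- impute_missing(x, plan)
  expect_equal(unname(out$fcdb$amounts["it_a", "carb_avail"]), 23)
  expect_equal(unname(out$fcdb$amounts["it_a", "chloride"]),
               1000 * 35.453 / 22.990)
  expect_equal(round(unname(out$fcdb$amounts["it_a", "chloride"])), 1542)
  expect_equal(unname(out$fcdb$amounts["it_a", "vitamin_b12"]), 0)
  expect_equal(out$fcdb$method["it_a", "vitamin_b12"], "assumed_zero")
  # audit total equals the number of originally missing cells
  expect_equal(out$audit$total, sum(s == "missing"))
  expect_equal(unname(out$audit$counts["by_calculation"]), 2L)
  expect_equal(unname(out$audit$counts["assumed_zero"]), 1L)
  # measured values never overwritten
  meas <- s == "measured"
  expect_equal(out$fcdb$amounts[meas], a[meas])
  expect_false(any(out$fcdb$state == "missing"))
  # a missing cell with no applicable rule is an error naming the pair
  x2 <- x
  x2$state["it_b", "fat"] <- "missing"
  x2$amounts["it_b", "fat"] <- NA
  expect_error(impute_missing(x2, plan), "fat")
})

test_that("similar-item and borrowed strategies pull donor values", {
  x <- tiny_fcdb(3)
  x$state["it_a", "retinol"] <- "missing"
  x$amounts["it_a", "retinol"] <- NA
  x$state["it_c", "sodium"] <- "missing"
  x$amounts["it_c", "sodium"] <- NA
  plan <- imputation_plan(component = c("retinol", "sodium"),
                          strategy = c("similar_item", "borrowed"))
  donor <- tiny_fcdb(3)
  out <- impute_missing(x, plan,
                        helpers = list(
                          donor_map = data.frame(food_id = "it_a",
                                                 donor_food_id = "it_b"),
                          borrowed = donor))
  expect_equal(unname(out$fcdb$amounts["it_a", "retinol"]),
               unname(donor$amounts["it_b", "retinol"]))
  expect_equal(unname(out$fcdb$amounts["it_c", "sodium"]),
               unname(donor$amounts["it_c", "sodium"]))
  expect_equal(out$audit$total, 2L)
})
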