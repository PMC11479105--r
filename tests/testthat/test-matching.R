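test_that("exact matching is map-driven with ambiguity errors", {
  map <- data.frame(ingr_name = c("eggplant", "salmon"),
                    food_id = c("IT_melanzane", "IT_salmone"))
  m <- exact_match("eggplant", map)
  expect_equal(m$strategy, "exact")
  expect_equal(m$target, "IT_melanzane")
  expect_true(is.na(exact_match("kale", map)$strategy))
  dup <- rbind(map, data.frame(ingr_name = "eggplant", food_id = "IT_other"))
  expect_error(exact_match("eggplant", dup), "ambiguous")
})

test_that("similarity matching minimizes the scaled distance with id tie-break", {
  x <- tiny_fcdb(4)
  target <- x$amounts["it_b", c("energy_kcal", "protein", "fat",
                                "carb_avail", "water")]
  m <- similarity_match(target, x)
  expect_equal(m$target, "it_b")
  expect_match(m$note, "distance=0")
  # two candidates differing from the target only in water, by 5 vs 10
  y <- tiny_fcdb(2)
  y$amounts["it_a", ] <- y$amounts["it_b", ]
  y$amounts["it_a", "water"] <- y$amounts["it_b", "water"] + 5
  prof <- y$amounts["it_b", c("energy_kcal", "protein", "fat",
                              "carb_avail", "water")]
  prof["water"] <- prof["water"] + 10  # it_a is 5 away, it_b is 10 away
  expect_equal(similarity_match(prof, y)$target, "it_a")
  # exact tie -> lexicographically smallest food_id
  y$amounts["it_a", ] <- y$amounts["it_b", ]
  expect_equal(similarity_match(y$amounts["it_b", c("energy_kcal", "protein",
                                                    "fat", "carb_avail",
                                                    "water")], y)$target,
               "it_a")
  expect_error(similarity_match(target, x, candidate_ids = character()),
               "empty candidate")
})

test_that("generic_mean averages resolvable values per component", {
  x <- tiny_fcdb(3)
  x$amounts["it_a", "protein"] <- 10
  x$amounts["it_b", "protein"] <- 20
  gm <- generic_mean(x, c("it_a", "it_b"))
  expect_equal(unname(gm$amounts["protein"]), 15)
  # one of three missing a component: mean of the two present, flagged
  x$state["it_c", "retinol"] <- "missing"
  x$amounts["it_c", "retinol"] <- NA
  gm3 <- generic_mean(x)
  expect_equal(unname(gm3$amounts["retinol"]),
               mean(x$amounts[c("it_a", "it_b"), "retinol"]))
  expect_true("retinol" %in% gm3$flagged)
  # single candidate is the identity; k copies likewise
  expect_equal(generic_mean(x, "it_a")$amounts, x$amounts["it_a", ])
  expect_equal(generic_mean(x, rep("it_a", 4))$amounts, x$amounts["it_a", ])
  expect_error(generic_mean(x, character()), "empty")
})

test_that("compose_recipe is the grams-weighted mean, no yield correction", {
  x <- tiny_fcdb(3)
  x$amounts["it_a", "energy_kcal"] <- 100
  x$amounts["it_b", "energy_kcal"] <- 300
  rec <- data.frame(recipe_id = "r1", food_id = c("it_a", "it_b"),
                    grams = c(50, 50))
  out <- compose_recipe(rec, x)
  expect_equal(unname(out$amounts["energy_kcal"]), 200)
  # single component at 100 g is that item
  one <- data.frame(recipe_id = "r2", food_id = "it_c", grams = 100)
  expect_equal(compose_recipe(one, x)$amounts, x$amounts["it_c", ])
  # all-zero component stays zero
  x0 <- x; x0$amounts[, "protein"] <- 0
  expect_equal(unname(compose_recipe(rec, x0)$amounts["protein"]), 0)
  # contract violations
  bad <- rec; bad$grams <- c(50, 40)
  expect_error(compose_recipe(bad, x), "not 100")
  ghost <- rec; ghost$food_id[2] <- "it_zz"
  expect_error(compose_recipe(ghost, x), "it_zz")
  # linearity + permutation invariance
  withr::with_seed(5, {
    for (i in 1:10) {
      g1 <- round(stats::runif(1, 10, 90), 4)
      r <- data.frame(recipe_id = "rp", food_id = c("it_a", "it_b"),
                      grams = c(g1, 100 - g1))
      a1 <- compose_recipe(r, x)$amounts
      a2 <- compose_recipe(r[2:1, ], x)$amounts
      expect_equal(a1, a2)
      manual <- (g1 * x$amounts["it_a", ] + (100 - g1) * x$amounts["it_b", ]) / 100
      expect_equal(a1, manual)
    }
  })
})

test_that("resolve_all walks the cascade and audits a strategy partition", {
  x <- tiny_fcdb(4)
  ing <- data.frame(ingr_name = c("alpha", "beta", "gamma", "delta"),
                    n_uses = c(5L, 2L, 1L, 1L),
                    stringsAsFactors = FALSE)
  tables <- list(
    name_map = data.frame(ingr_name = c("alpha", "beta"),
                          food_id = c("it_a", "it_b")),
    generic_sets = data.frame(ingr_name = "gamma",
                              food_id = c("it_a", "it_c")),
    recipe_map = data.frame(ingr_name = "delta", recipe_id = "r1"),
    cooked_raw = data.frame(ingr_name = "beta", discrepancy = TRUE))
  res <- resolve_all(ing, x, tables)
  expect_equal(unname(res$audit$counts[c("exact", "generic_mean", "recipe")]),
               c(2L, 1L, 1L))
  expect_equal(sum(res$audit$counts), nrow(ing))
  expect_equal(sum(res$audit$weighted_counts), sum(ing$n_uses))
  expect_true(res$matches$cooked_raw_discrepancy[res$matches$ingr_name == "beta"])
  expect_false(any(res$matches$cooked_raw_discrepancy[
    res$matches$ingr_name != "beta"]))
  # unresolved ingredient is an error listing it
  ing2 <- rbind(ing, data.frame(ingr_name = "mystery", n_uses = 1L))
  expect_error(resolve_all(ing2, x, tables), "mystery")
})

test_that("ingredient_compositions materializes every strategy", {
  x <- tiny_fcdb(4)
  recipes <- data.frame(recipe_id = "r1", food_id = c("it_a", "it_d"),
                        grams = c(40, 60))
  matches <- data.frame(
    ingr_name = c("a", "b", "c", "d"),
    strategy = c("exact", "generic_mean", "recipe", "borrowed"),
    target = c("it_a", "it_b|it_c", "r1", "it_d"),
    cooked_raw_discrepancy = FALSE, note = "", stringsAsFactors = FALSE)
  comp <- ingredient_compositions(matches, x, recipes, borrowed_fcdb = x)
  expect_equal(comp["a", ], x$amounts["it_a", ])
  expect_equal(comp["b", ], colMeans(x$amounts[c("it_b", "it_c"), ]))
  expect_equal(comp["c", ],
               (40 * x$amounts["it_a", ] + 60 * x$amounts["it_d", ]) / 100)
  expect_equal(comp["d", ], x$amounts["it_d", ])
})
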