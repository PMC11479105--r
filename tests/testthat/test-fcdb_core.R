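test_that("trace rule resolves to the threshold-specific constant", {
  cases <- list(list(def = component_def("retinol", unit = "ug",
                                         trace_threshold = 0.6), out = 0.5),
                list(def = component_def("vitamin_d", unit = "ug",
                                         trace_threshold = 0.06), out = 0.05),
                list(def = component_def("alpha_tocopherol", unit = "mg",
                                         trace_threshold = 0.006), out = 0.005))
  for (cs in cases) {
    v <- impute_trace(nutrient_value(state = "trace"), cs$def)
    expect_equal(v$amount, cs$out)
    expect_equal(v$state, "imputed")
    expect_equal(v$method, "trace-rule")
  }
  expect_error(impute_trace(nutrient_value(state = "trace"),
                            component_def("protein")), "no trace criterion")
  expect_error(impute_trace(nutrient_value(10, "measured"),
                            component_def("retinol", trace_threshold = 0.6)),
               "trace-state")
})

test_that("nutrient_value enforces its state/amount invariants", {
  expect_error(nutrient_value(state = "measured"), "requires an amount")
  expect_error(nutrient_value(1, state = "trace"), "carries no amount")
  expect_error(nutrient_value(1, state = "imputed"), "method")
})

test_that("resolve_traces leaves no trace state and keeps measured cells", {
  x <- tiny_fcdb()
  x$state["it_a", "retinol"] <- "trace"
  x$amounts["it_a", "retinol"] <- NA
  y <- resolve_traces(x)
  expect_false(any(y$state == "trace"))
  expect_equal(y$amounts["it_a", "retinol"], 0.5)
  expect_equal(y$method["it_a", "retinol"], "trace-rule")
  untouched <- y$state == "measured"
  expect_equal(y$amounts[untouched], x$amounts[untouched])
})

test_that("available carbohydrates subtracts fiber and floors at zero", {
  expect_equal(available_carbohydrates(50, 10), 40)
  expect_equal(available_carbohydrates(10, 10), 0)
  expect_warning(out <- available_carbohydrates(5, 8), "floored")
  expect_equal(out, 0)
})

test_that("equivalents formulas match their worked values", {
  expect_equal(as.numeric(beta_carotene_equivalents(10, 4, 2)), 13)
  expect_equal(as.numeric(beta_carotene_equivalents(0, 0, 0)), 0)
  bce1 <- beta_carotene_equivalents(1, NA, 0)
  expect_equal(as.numeric(bce1), 1)
  expect_true(attr(bce1, "flagged"))
  expect_equal(as.numeric(retinol_equivalent(0, 60)), 10)
  expect_equal(as.numeric(retinol_equivalent(100, 0)), 100)
  expect_equal(as.numeric(retinol_equivalent(10, 12)), 12)
  expect_equal(as.numeric(alpha_tocopherol_equivalents(1, 1, 1, 1, 0, 0, 0)), 1.51)
  expect_equal(as.numeric(alpha_tocopherol_equivalents(0, 0, 0, 0, 0, 0, 0)), 0)
  expect_equal(as.numeric(alpha_tocopherol_equivalents(0, 0, 0, 0, 1, 1, 1)), 0.36)
  expect_equal(as.numeric(short_chain_sfa(1, 1, 1, 1)), 4)
  expect_equal(as.numeric(short_chain_sfa(0, 0, 0, 0)), 0)
  sc <- short_chain_sfa(1, NA, 1, 1)
  expect_equal(as.numeric(sc), 3)
  expect_true(attr(sc, "flagged"))
  expect_equal(as.numeric(other_pufas(list(x = 0.2, y = 0.3))), 0.5)
  expect_equal(as.numeric(other_pufas(list())), 0)
  op <- other_pufas(list(x = NA_real_))
  expect_equal(as.numeric(op), 0)
  expect_true(attr(op, "flagged"))
  # all-missing equivalents propagate missing
  expect_true(is.na(beta_carotene_equivalents(NA, NA, NA)))
  expect_true(is.na(retinol_equivalent(NA, NA, missing_policy = "propagate")))
})

test_that("derivation formulas are linear in their inputs", {
  withr::with_seed(11, {
    for (rep in 1:25) {
      lam <- stats::runif(1, 0, 5)
      v <- stats::runif(7, 0, 20)
      expect_equal(
        as.numeric(beta_carotene_equivalents(lam * v[1], lam * v[2], lam * v[3])),
        lam * as.numeric(beta_carotene_equivalents(v[1], v[2], v[3])))
      expect_equal(
        as.numeric(retinol_equivalent(lam * v[1], lam * v[2])),
        lam * as.numeric(retinol_equivalent(v[1], v[2])))
      expect_equal(
        as.numeric(do.call(alpha_tocopherol_equivalents, as.list(lam * v))),
        lam * as.numeric(do.call(alpha_tocopherol_equivalents, as.list(v))))
      expect_equal(
        as.numeric(short_chain_sfa(lam * v[1], lam * v[2], lam * v[3], lam * v[4])),
        lam * as.numeric(short_chain_sfa(v[1], v[2], v[3], v[4])))
    }
  })
})

test_that("fcdb CSV round-trips through sentinel tokens", {
  x <- tiny_fcdb()
  x$state["it_a", "retinol"] <- "trace"
  x$amounts["it_a", "retinol"] <- NA
  x$state["it_b", "sodium"] <- "missing"
  x$amounts["it_b", "sodium"] <- NA
  f <- tempfile(fileext = ".csv")
  write_fcdb(x, f)
  y <- read_fcdb(f, x$registry)
  expect_equal(y$state, x$state)
  expect_equal(y$amounts, x$amounts, tolerance = 1e-9)
  expect_equal(y$items$cooked, x$items$cooked)
})

test_that("fcdb constructor enforces the amount/state invariant", {
  x <- tiny_fcdb()
  a <- x$amounts; s <- x$state
  s["it_a", "protein"] <- "missing"   # amount still present
  expect_error(fcdb(x$items, a, s, x$registry), "iff")
})

test_that("energy converts at 4.184 kJ per kcal", {
  expect_equal(kcal_to_kj(100), 418.4)
  expect_equal(kj_to_kcal(kcal_to_kj(162.7)), 162.7)
})
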