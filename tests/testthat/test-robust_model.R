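planted_betas <- c(`(Intercept)` = -1.50, mass_25 = -0.37,
                   n_ingredients = 0.11, rawcookedone = 0.51,
                   rawcookedmore = 1.54, recreatedyes = 0.52,
                   `rawcookedone:recreatedyes` = -0.49,
                   `rawcookedmore:recreatedyes` = -0.69)

fast_ctrl <- function(seed) mm_control(n_subsamples = 50L, seed = seed)

test_that("noiseless linear data is recovered exactly", {
  sim <- simulate_regression(300, planted_betas, resid_sd = 0, seed = 1)
  fit <- fit_mm(sim$X, sim$y, fast_ctrl(2))
  expect_equal(unname(fit$coefficients), unname(planted_betas),
               tolerance = 1e-8)
  expect_equal(fit$scale, 0)
  expect_true(fit$converged)
})

test_that("clean Gaussian data: MM agrees with the OLS oracle", {
  sim <- simulate_regression(2000, planted_betas, resid_sd = 3,
                             outlier_rate = 0, seed = 5)
  fit <- fit_mm(sim$X, sim$y, fast_ctrl(6))
  ols <- stats::lm.fit(sim$X, sim$y)
  ols_se <- sqrt(diag(chol2inv(chol(crossprod(sim$X))) *
                        sum(ols$residuals^2) / (2000 - 8)))
  expect_true(all(abs(fit$coefficients - ols$coefficients) < 2 * ols_se))
  expect_true(fit$converged)
  expect_true(all(fit$weights >= 0 & fit$weights <= 1))
})

test_that("MM is affine equivariant in the response", {
  sim <- simulate_regression(400, planted_betas, resid_sd = 2,
                             outlier_rate = 0.05, seed = 9)
  f1 <- fit_mm(sim$X, sim$y, fast_ctrl(10))
  f2 <- fit_mm(sim$X, 3.5 * sim$y, fast_ctrl(10))
  expect_equal(f2$coefficients, 3.5 * f1$coefficients, tolerance = 1e-4)
  expect_equal(f2$scale, 3.5 * f1$scale, tolerance = 1e-4)
})

test_that("gross outliers get near-zero weight and bounded influence", {
  sim <- simulate_regression(600, planted_betas, resid_sd = 3,
                             outlier_rate = 0.1, outlier_shift = 60, seed = 13)
  fit <- fit_mm(sim$X, sim$y, fast_ctrl(14))
  expect_lt(mean(fit$weights[sim$outliers]), 0.05)
  expect_gt(mean(fit$weights[-sim$outliers]), 0.8)
  ols <- stats::lm.fit(sim$X, sim$y)$coefficients
  expect_lt(sum(abs(fit$coefficients - planted_betas)),
            sum(abs(ols - planted_betas)))
})

test_that("robust_wald on one coefficient squares the t-ratio", {
  sim <- simulate_regression(500, planted_betas, resid_sd = 3, seed = 17)
  fit <- fit_mm(sim$X, sim$y, fast_ctrl(18))
  w <- robust_wald(fit, "mass_25")
  expect_equal(w$statistic, (fit$coefficients["mass_25"] / fit$se["mass_25"])^2,
               ignore_attr = TRUE)
  expect_equal(w$df, 1L)
  # zero coefficient vector -> statistic 0, p = 1 (synthetic fit object)
  fake <- structure(list(coefficients = c(a = 0, b = 0),
                         cov = diag(2), n = 100L, p = 2L), class = "mmfit")
  w0 <- robust_wald(fake, 1:2)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_chisq, 1)
  expect_equal(w0$p_f, 1)
  sing <- structure(list(coefficients = c(a = 1, b = 1),
                         cov = matrix(1, 2, 2), n = 100L, p = 2L),
                    class = "mmfit")
  expect_error(robust_wald(sing, 1:2), "singular")
})

test_that("degenerate designs are rejected", {
  X <- cbind(1, 1:10, 2 * (1:10))
  expect_error(fit_mm(X, rnorm(10), fast_ctrl(1)), "rank deficient")
  expect_error(fit_mm(cbind(1, 1:2), rnorm(2), fast_ctrl(1)), "n >")
})

test_that("model frame encodes the published design", {
  uses <- data.frame(dish_id = c("d1", "d2", "d2", "d3", "d3", "d3"),
                     ingr_name = c("a", "a", "b", "a", "b", "c"),
                     ingr_grams = c(250, 100, 50, 30, 30, 40),
                     stringsAsFactors = FALSE)
  matches <- data.frame(ingr_name = c("a", "b", "c"),
                        strategy = c("exact", "recipe", "exact"),
                        target = c("f1", "r1", "f2"),
                        cooked_raw_discrepancy = c(FALSE, TRUE, TRUE),
                        note = "", stringsAsFactors = FALSE)
  fl <- dish_flags(uses, matches)
  expect_equal(fl$rawcooked[fl$dish_id == "d1"], factor("none",
               levels = c("none", "one", "more")))
  expect_equal(as.character(fl$rawcooked[fl$dish_id == "d2"]), "one")
  expect_equal(as.character(fl$rawcooked[fl$dish_id == "d3"]), "more")
  expect_equal(as.character(fl$recreated[fl$dish_id == "d1"]), "no")
  expect_equal(as.character(fl$recreated[fl$dish_id == "d3"]), "yes")
  comp <- c("energy_kcal", "protein")
  ta <- data.frame(dish_id = c("d1", "d2", "d3"), mass = c(250, 150, 100),
                   energy_kcal = c(10, 20, 30), protein = c(1, 2, 3))
  tb <- ta; tb$energy_kcal <- tb$energy_kcal - 2
  mf <- build_model_frame(ta, tb, "energy_kcal", fl)
  expect_equal(mf$y, rep(2, 3))
  expect_equal(mf$frame$mass_25, c(10, 6, 4))
  expect_equal(ncol(mf$X), 8L)
  # reference row (none, no) has all-zero dummies
  ref <- mf$X[mf$frame$dish_id == "d1", ]
  expect_equal(unname(ref[-(1:3)]), rep(0, 5))
  # (more, yes) switches the main and interaction dummies together
  d3 <- mf$X[mf$frame$dish_id == "d3", ]
  expect_equal(unname(d3[c("rawcookedmore", "recreatedyes",
                           "rawcookedmore:recreatedyes")]), rep(1, 3))
})
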