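# ---------------------------------------------------------------------------
# Robust MM regression for the difference-determinants model.
#
# Two-stage estimator: (i) a high-breakdown S-estimate of scale found by
# fast-S subsampling with a 50%-breakdown Tukey bisquare (c0 = 1.5476,
# E_Phi[rho] = 0.5); (ii) a high-efficiency bisquare M-step (c = 4.685, 95%
# Gaussian efficiency) by IRLS with the S scale held fixed.
# ---------------------------------------------------------------------------

# bisquare rho standardized to max 1
.rho_bisq <- function(u, c) {
  v <- pmin(abs(u) / c, 1)
  1 - (1 - v^2)^3
}

# psi (derivative up to the 6/c^2 constant) and its derivative; both vanish
# beyond |u| > c
.psi_bisq <- function(u, c) {
  out <- u * (1 - (u / c)^2)^2
  out[abs(u) > c] <- 0
  out
}

.psip_bisq <- function(u, c) {
  v <- (u / c)^2
  out <- (1 - v) * (1 - 5 * v)
  out[abs(u) > c] <- 0
  out
}

# IRLS weights w(u) = psi(u)/u
.w_bisq <- function(u, c) {
  out <- (1 - (u / c)^2)^2
  out[abs(u) > c] <- 0
  out
}

# M-estimate of scale: solve mean(rho(r/s, c)) = b by fixed-point iteration
.mscale <- function(r, c = 1.5476, b = 0.5, tol = 1e-10, max_it = 200L) {
  s <- stats::median(abs(r)) / 0.6745
  if (s <= 0) {
    # more than half the residuals are exactly zero: scale collapses
    s <- mean(abs(r)) / 0.6745
    if (s <= 0) return(0)
  }
  for (it in seq_len(max_it)) {
    s_new <- s * sqrt(mean(.rho_bisq(r / s, c)) / b)
    if (abs(s_new - s) <= tol * s) return(s_new)
    s <- s_new
  }
  s
}

.wls <- function(X, y, w) {
  Xw <- X * sqrt(w)
  yw <- y * sqrt(w)
  qr_ <- qr(Xw)
  if (qr_$rank < ncol(X)) return(NULL)
  qr.coef(qr_, yw)
}

# one IRLS step toward the S objective at the current scale
.istep <- function(X, y, beta, c0, b) {
  r <- as.vector(y - X %*% beta)
  s <- .mscale(r, c0, b)
  if (s <= 0) return(list(beta = beta, s = 0))
  w <- .w_bisq(r / s, c0)
  if (sum(w > 0) < ncol(X)) return(NULL)
  beta_new <- .wls(X, y, w)
  if (is.null(beta_new)) return(NULL)
  list(beta = beta_new, s = s)
}

#' Tuning configuration for [fit_mm()]
#'
#' @param n_subsamples fast-S elemental subsamples (default 500).
#' @param n_best candidates refined to convergence (default 5).
#' @param k_fast cheap I-steps applied to every candidate (default 2).
#' @param c0 bisquare constant of the S stage; 1.5476 gives 50% breakdown.
#' @param b right-hand side of the M-scale equation (0.5 for 50% breakdown).
#' @param c_eff bisquare constant of the M step; 4.685 gives 95% efficiency.
#' @param tol convergence: max absolute coefficient change (default 1e-8).
#' @param max_it IRLS iteration cap (default 200).
#' @param seed RNG seed for the fast-S subsampling (required; default
#'   20240101).
#' @export
mm_control <- function(n_subsamples = 500L, n_best = 5L, k_fast = 2L,
                       c0 = 1.5476, b = 0.5, c_eff = 4.685,
                       tol = 1e-8, max_it = 200L, seed = 20240101L) {
  stopifnot(n_subsamples >= 1, n_best >= 1, !is.null(seed))
  list(n_subsamples = as.integer(n_subsamples), n_best = as.integer(n_best),
       k_fast = as.integer(k_fast), c0 = c0, b = b, c_eff = c_eff,
       tol = tol, max_it = as.integer(max_it), seed = as.integer(seed))
}

# fast-S stage: elemental subsamples -> k_fast I-steps -> full refinement of
# the best candidates by M-scale
.fast_s <- function(X, y, ctrl) {
  n <- nrow(X); p <- ncol(X)
  best <- vector("list", ctrl$n_best)
  best_s <- rep(Inf, ctrl$n_best)
  with_seed(ctrl$seed, {
    for (i in seq_len(ctrl$n_subsamples)) {
      beta <- NULL
      for (try_ in 1:30) {
        idx <- sample.int(n, p)
        qr_ <- qr(X[idx, , drop = FALSE])
        if (qr_$rank == p) {
          beta <- qr.coef(qr_, y[idx])
          break
        }
      }
      if (is.null(beta)) next
      st <- list(beta = beta)
      ok <- TRUE
      for (k in seq_len(ctrl$k_fast)) {
        st2 <- .istep(X, y, st$beta, ctrl$c0, ctrl$b)
        if (is.null(st2)) { ok <- FALSE; break }
        st <- st2
        if (st$s == 0) break
      }
      if (!ok) next
      s_i <- .mscale(y - X %*% st$beta, ctrl$c0, ctrl$b)
      jmax <- which.max(best_s)
      if (s_i < best_s[jmax]) {
        best_s[jmax] <- s_i
        best[[jmax]] <- st$beta
      }
    }
  })
  if (all(!is.finite(best_s))) stop("fast-S found no candidate", call. = FALSE)
  # full refinement of the surviving candidates
  out_beta <- NULL; out_s <- Inf
  for (j in which(is.finite(best_s))) {
    beta <- best[[j]]
    s_prev <- Inf
    for (it in 1:100) {
      st <- .istep(X, y, beta, ctrl$c0, ctrl$b)
      if (is.null(st)) break
      beta <- st$beta
      if (st$s == 0 || abs(s_prev - st$s) <= 1e-9 * st$s) break
      s_prev <- st$s
    }
    s_fin <- .mscale(y - X %*% beta, ctrl$c0, ctrl$b)
    if (s_fin < out_s) { out_s <- s_fin; out_beta <- beta }
  }
  list(beta = out_beta, scale = out_s)
}

#' Fit a robust MM regression
#'
#' @param X design matrix (including the intercept column), full rank, with
#'   more rows than columns; or a formula.
#' @param y numeric response.
#' @param control an [mm_control()].
#' @param data when `X` is a formula, the model frame.
#' @return an object of class `mmfit`: coefficients, robust `scale`,
#'   asymptotic covariance `cov`, standard errors, symmetric 95% `ci`,
#'   IRLS `weights`, `converged`, `iterations`, residuals, fitted values.
#' @export
fit_mm <- function(X, y = NULL, control = mm_control(), data = NULL) {
  if (inherits(X, "formula")) {
    mf <- stats::model.frame(X, data = data)
    y <- stats::model.response(mf)
    X <- stats::model.matrix(attr(mf, "terms"), mf)
  }
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need n > number of columns", call. = FALSE)
  if (qr(X)$rank < p) stop("design matrix is rank deficient", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  s_stage <- .fast_s(X, y, control)
  s <- s_stage$scale
  beta <- s_stage$beta
  if (s <= 0) {
    # exact fit (noiseless data): S scale collapses; keep the S coefficients
    r <- as.vector(y - X %*% beta)
    fit <- list(coefficients = stats::setNames(as.vector(beta), colnames(X)),
                scale = 0, cov = matrix(0, p, p), se = rep(0, p),
                ci = cbind(lower = as.vector(beta), upper = as.vector(beta)),
                weights = rep(1, n), converged = TRUE, iterations = 0L,
                residuals = r, fitted = as.vector(X %*% beta), n = n, p = p,
                control = control)
    class(fit) <- "mmfit"
    return(fit)
  }

  # M step at fixed scale
  converged <- FALSE
  it <- 0L
  while (it < control$max_it) {
    it <- it + 1L
    r <- as.vector(y - X %*% beta)
    w <- .w_bisq(r / s, control$c_eff)
    if (sum(w > 0) < p) break
    beta_new <- .wls(X, y, w)
    if (is.null(beta_new)) break
    if (max(abs(beta_new - beta)) < control$tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  if (!converged) {
    warning("MM IRLS did not converge in ", control$max_it, " iterations")
  }

  r <- as.vector(y - X %*% beta)
  u <- r / s
  psi <- .psi_bisq(u, control$c_eff)
  psip <- .psip_bisq(u, control$c_eff)
  # asymptotic covariance: s^2 * E[psi^2]/E[psi']^2 * (X'X)^-1
  denom <- mean(psip)
  xtx_inv <- solve(crossprod(X))
  cov <- s^2 * mean(psi^2) / denom^2 * xtx_inv
  se <- sqrt(diag(cov))
  est <- as.vector(beta)
  fit <- list(coefficients = stats::setNames(est, colnames(X)),
              scale = s, cov = cov,
              se = stats::setNames(se, colnames(X)),
              ci = cbind(lower = est - 1.96 * se, upper = est + 1.96 * se),
              weights = .w_bisq(u, control$c_eff),
              converged = converged, iterations = it,
              residuals = r, fitted = as.vector(X %*% beta),
              n = n, p = p, control = control)
  class(fit) <- "mmfit"
  fit
}

#' @export
print.mmfit <- function(x, ...) {
  cat("Robust MM regression (bisquare S + M), scale =",
      format(x$scale, digits = 5), if (!x$converged) "[NOT CONVERGED]", "\n")
  tab <- cbind(beta = x$coefficients, se = x$se, x$ci)
  print(round(tab, 4))
  invisible(x)
}

#' Robust Wald test on one or several coefficients
#'
#' Quadratic form beta' V^-1 beta on the selected coefficients. Reports the
#' chi-square reference (df = set size) and the F reference
#' (df1 = set size, df2 = n - p). A Wald test on all dummies of one factor is
#' the "robust ANOVA" for that variable.
#'
#' @param fit an `mmfit`.
#' @param coefficient_set integer indices or coefficient names.
#' @export
robust_wald <- function(fit, coefficient_set) {
  stopifnot(inherits(fit, "mmfit"))
  idx <- if (is.character(coefficient_set)) {
    match(coefficient_set, names(fit$coefficients))
  } else as.integer(coefficient_set)
  if (anyNA(idx)) stop("unknown coefficient(s)", call. = FALSE)
  b <- fit$coefficients[idx]
  V <- fit$cov[idx, idx, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular sub-covariance", call. = FALSE))
  stat <- as.numeric(t(b) %*% Vi %*% b)
  q <- length(idx)
  list(statistic = stat, df = q,
       p_chisq = stats::pchisq(stat, df = q, lower.tail = FALSE),
       df2 = fit$n - fit$p,
       p_f = stats::pf(stat / q, q, fit$n - fit$p, lower.tail = FALSE))
}

# ---------------------------------------------------------------------------
# Model frame for the difference-determinants regression
# ---------------------------------------------------------------------------

#' Per-dish covariate flags from a match table
#'
#' rawcooked = none/one/more by the count of uses whose matched ingredient
#' carries a cooked/raw discrepancy; recreated = yes iff any use resolves to
#' a recipe-strategy match.
#'
#' @param uses long use table; @param matches `resolve_all()$matches`.
#' @return data.frame `dish_id`, `n_ingredients`, `rawcooked`, `recreated`.
#' @export
dish_flags <- function(uses, matches) {
  m <- matches[match(uses$ingr_name, matches$ingr_name), ]
  if (anyNA(m$strategy)) stop("uses contain unmatched ingredients", call. = FALSE)
  disc <- tapply(m$cooked_raw_discrepancy, uses$dish_id, sum)
  rec <- tapply(m$strategy == "recipe", uses$dish_id, any)
  n_ing <- tapply(uses$ingr_name, uses$dish_id, length)
  ids <- names(disc)
  data.frame(dish_id = ids,
             n_ingredients = as.integer(n_ing[ids]),
             rawcooked = factor(ifelse(disc[ids] == 0, "none",
                                       ifelse(disc[ids] == 1, "one", "more")),
                                levels = c("none", "one", "more")),
             recreated = factor(ifelse(rec[ids], "yes", "no"),
                                levels = c("no", "yes")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the difference-determinants model frame for one nutrient
#'
#' Response: delta = A - B for `nutrient`. Covariates: total mass in 25 g
#' units, number of ingredients, rawcooked (none/one/more), recreated
#' (no/yes), and the rawcooked x recreated interaction. Reference levels
#' (none, no) yield all-zero dummies; the design has 8 columns including the
#' intercept.
#'
#' @param totals_a,totals_b [dish_totals()] tables sharing dish_ids.
#' @param nutrient component column to difference.
#' @param flags [dish_flags()] output.
#' @return list(frame = data.frame, X = model matrix, y = response).
#' @export
build_model_frame <- function(totals_a, totals_b, nutrient, flags) {
  common <- intersect(totals_a$dish_id, totals_b$dish_id)
  a <- totals_a[match(common, totals_a$dish_id), ]
  b <- totals_b[match(common, totals_b$dish_id), ]
  f <- flags[match(common, flags$dish_id), ]
  if (anyNA(f$rawcooked) || anyNA(f$recreated)) {
    stop("missing covariate flags for some dishes", call. = FALSE)
  }
  frame <- data.frame(dish_id = common,
                      delta = a[[nutrient]] - b[[nutrient]],
                      mass_25 = a$mass / 25,
                      n_ingredients = f$n_ingredients,
                      rawcooked = f$rawcooked,
                      recreated = f$recreated,
                      stringsAsFactors = FALSE)
  X <- stats::model.matrix(
    ~ mass_25 + n_ingredients + rawcooked + recreated + rawcooked:recreated,
    data = frame)
  list(frame = frame, X = X, y = frame$delta)
}
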