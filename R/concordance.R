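# ---------------------------------------------------------------------------
# Paired-comparison battery between per-dish nutrient tables computed under
# two FCDBs. Sign convention throughout: diff = value_A - value_B with A the
# harmonized (target-FCDB) side and B the declared/source side.
# ---------------------------------------------------------------------------

#' Pearson correlation with the t-transform test
#' @param x,y paired numeric vectors, n >= 3, finite, non-constant.
#' @return list(r, p) with a two-sided p-value.
#' @export
pearson_with_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the vectors", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

# quintile class under a vector's own type-7 cutoffs; values equal to a
# cutoff go to the lower quintile (breaks right-closed)
.quintile_class <- function(v) {
  cuts <- stats::quantile(v, probs = c(0.2, 0.4, 0.6, 0.8), type = 7,
                          names = FALSE)
  breaks <- c(-Inf, unique(cuts), Inf)
  as.integer(cut(v, breaks = breaks, labels = FALSE, right = TRUE))
}

#' Quintile cross-classification of two paired vectors
#'
#' Each vector is classified by its own quintile cutoffs; the joint 5x5
#' distribution is expressed in cell percentages of n. Heavy ties can leave
#' fewer than 5 distinct classes; this is recorded (and warned about), not
#' resampled.
#'
#' @param x,y paired numeric vectors, n >= 5.
#' @return object of class `crosstab`: list(cells = 5x5 percentage matrix
#'   (x rows, y columns), n, cutoffs_x, cutoffs_y, degenerate).
#' @export
quintile_crosstab <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  cx <- .quintile_class(x)
  cy <- .quintile_class(y)
  degenerate <- max(cx) < 5L || max(cy) < 5L
  if (degenerate) {
    warning("ties produced fewer than 5 distinct quintile classes")
  }
  tab <- table(factor(cx, levels = 1:5), factor(cy, levels = 1:5))
  cells <- 100 * as.matrix(tab) / length(x)
  dimnames(cells) <- list(A = paste0("Q", 1:5), B = paste0("Q", 1:5))
  structure(list(cells = cells, n = length(x),
                 cutoffs_x = stats::quantile(x, c(0.2, 0.4, 0.6, 0.8), type = 7),
                 cutoffs_y = stats::quantile(y, c(0.2, 0.4, 0.6, 0.8), type = 7),
                 degenerate = degenerate),
            class = "crosstab")
}

#' Percent perfect agreement (diagonal sum) of a crosstab
#' @param ct a `crosstab` or a 5x5 percentage matrix.
#' @export
pct_agreement <- function(ct) {
  cells <- if (inherits(ct, "crosstab")) ct$cells else as.matrix(ct)
  sum(diag(cells))
}

#' Unweighted Cohen's kappa from a cross-classification
#'
#' kappa = (po - pe) / (1 - pe) with po the diagonal proportion and pe the
#' chance agreement from the marginals. Accepts a `crosstab`, a percentage
#' matrix (cells summing to ~100) or a count matrix.
#'
#' @param ct square matrix or `crosstab`.
#' @return kappa (numeric scalar).
#' @export
cohen_kappa_unweighted <- function(ct) {
  cells <- if (inherits(ct, "crosstab")) ct$cells else as.matrix(ct)
  stopifnot(nrow(cells) == ncol(cells))
  p <- cells / sum(cells)
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  if (isTRUE(all.equal(pe, 1))) stop("chance agreement pe == 1", call. = FALSE)
  (po - pe) / (1 - pe)
}

#' Interpretation band for a kappa value
#' @param kappa numeric scalar
#' @export
kappa_band <- function(kappa) {
  if (kappa >= 0.80) "strong to very strong"
  else if (kappa >= 0.60) "moderate"
  else if (kappa >= 0.40) "weak"
  else "none to slight"
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' diff = x - y; bias = mean(diff); limits = bias +/- 1.96 * sample SD(diff).
#' Returned per-dish means/diffs feed the conventional plot (x = pairwise
#' mean, y = difference).
#'
#' @param x,y paired numeric vectors, n >= 2.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       mean = (x + y) / 2, diff = d, sd = s)
}

#' Seven-number summary of a difference vector (+ optional kernel density)
#'
#' @param diffs numeric vector (n >= 1).
#' @param density logical; when TRUE a Gaussian-kernel density (Silverman
#'   bandwidth, plot-only) is attached.
#' @export
difference_summary <- function(diffs, density = FALSE) {
  stopifnot(length(diffs) >= 1)
  out <- list(summary = seven_number(diffs))
  if (density && length(diffs) >= 2 && stats::sd(diffs) > 0) {
    out$density <- stats::density(diffs, bw = "nrd0", kernel = "gaussian")
  }
  out
}

#' Kolmogorov-Smirnov normality and Wilcoxon signed-rank location tests
#'
#' KS compares the differences against a Normal with their own mean and SD
#' (no small-sample Lilliefors correction). The Wilcoxon signed-rank test is
#' two-sided against location 0: exact for n <= 25 without ties/zeros, normal
#' approximation with continuity correction otherwise.
#'
#' @param diffs numeric difference vector, n >= 3; not all zero.
#' @return list(ks_p, wilcoxon_p).
#' @export
normality_and_location_tests <- function(diffs) {
  stopifnot(length(diffs) >= 3)
  if (all(diffs == 0)) {
    stop("all differences zero: signed-rank test undefined", call. = FALSE)
  }
  ks <- suppressWarnings(
    stats::ks.test(diffs, "pnorm", mean = mean(diffs), sd = stats::sd(diffs)))
  nonzero <- diffs[diffs != 0]
  exact <- length(nonzero) <= 25 && !anyDuplicated(abs(nonzero)) &&
    length(nonzero) == length(diffs)
  wt <- suppressWarnings(
    stats::wilcox.test(diffs, mu = 0, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(ks_p = ks$p.value, wilcoxon_p = wt$p.value)
}

#' Top-k dishes by absolute difference
#'
#' Ranks dishes by |delta| of `nutrient`, ties broken by dish_id, and reports
#' for each selected dish the percentile of its |delta| in every other
#' nutrient's distribution.
#'
#' @param diff_table data.frame: `dish_id` plus one delta column per nutrient.
#' @param nutrient column to rank on.
#' @param k rows to return (k <= n).
#' @export
top_extreme <- function(diff_table, nutrient, k = 25L) {
  stopifnot(k <= nrow(diff_table))
  adiff <- abs(diff_table[[nutrient]])
  ord <- order(-adiff, diff_table$dish_id)
  sel <- diff_table[ord[seq_len(k)], , drop = FALSE]
  others <- setdiff(names(diff_table), c("dish_id", nutrient))
  for (o in others) {
    ecdf_o <- stats::ecdf(abs(diff_table[[o]]))
    sel[[paste0("pctile_", o)]] <- 100 * ecdf_o(abs(sel[[o]]))
  }
  sel$rank <- seq_len(k)
  rownames(sel) <- NULL
  sel
}

#' Full agreement report for one nutrient
#'
#' Assembles the whole battery: Pearson r + test, quintile cross-tab with
#' percent agreement and unweighted kappa, Bland-Altman bias and limits,
#' difference summary, KS and Wilcoxon tests.
#'
#' @param x,y paired per-dish values (A = harmonized, B = declared).
#' @export
agreement_report <- function(x, y) {
  ct <- quintile_crosstab(x, y)
  ba <- bland_altman(x, y)
  tests <- normality_and_location_tests(x - y)
  pr <- pearson_with_test(x, y)
  list(pearson_r = pr$r, pearson_p = pr$p,
       crosstab = ct,
       pct_agree = pct_agreement(ct),
       kappa = cohen_kappa_unweighted(ct),
       kappa_band = kappa_band(cohen_kappa_unweighted(ct)),
       bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
       diff_summary = difference_summary(x - y)$summary,
       ks_p = tests$ks_p, wilcoxon_p = tests$wilcoxon_p)
}
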