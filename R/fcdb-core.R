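#' Component registry
#'
#' A component registry defines the nutrient components an FCDB carries: a
#' unique code, a display name, a unit, and the analytical trace threshold
#' under which the component may be flagged "trace" (one of 0.6, 0.06, 0.006
#' in the component's unit, or none).
#'
#' @param x data.frame with columns `code`, `name`, `unit`, `trace_threshold`
#'   (numeric; `NA` means the component has no trace criterion).
#' @return a validated `component_registry` data.frame.
#' @export
component_registry <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("code", "name", "unit", "trace_threshold") %in% names(x)))
  if (anyDuplicated(x$code)) stop("duplicate component codes", call. = FALSE)
  units_ok <- x$unit %in% c("g", "mg", "ug", "kcal", "kJ")
  if (!all(units_ok)) {
    stop("unknown unit(s): ", paste(unique(x$unit[!units_ok]), collapse = ", "),
         call. = FALSE)
  }
  thr <- x$trace_threshold
  if (!all(is.na(thr) | thr %in% c(0.6, 0.06, 0.006))) {
    stop("trace_threshold must be 0.6, 0.06, 0.006 or NA", call. = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  class(x) <- c("component_registry", "data.frame")
  x
}

#' Read a component registry from CSV
#' @param path CSV with columns code,name,unit,trace_threshold (blank = none)
#' @export
read_component_registry <- function(path) {
  df <- read_csv_strict(path)
  df$trace_threshold <- suppressWarnings(as.numeric(df$trace_threshold))
  component_registry(df)
}

#' The packaged default 20-component registry
#'
#' A compact synthetic registry (energy in kcal and kJ, water, macronutrients,
#' fiber, a handful of micronutrients with trace thresholds). It is data, not
#' a reproduction of any national FCDB's component list.
#' @export
default_registry <- function() {
  read_component_registry(
    system.file("extdata", "component_registry.csv", package = "fcdblink",
                mustWork = TRUE))
}

#' A single nutrient value with its state
#'
#' @param amount numeric amount per 100 g edible part, or `NA` when the state
#'   carries no amount (trace, missing).
#' @param state one of `"measured"`, `"trace"`, `"missing"`, `"imputed"`.
#' @param method imputation strategy tag, required when `state == "imputed"`.
#' @export
nutrient_value <- function(amount = NA_real_, state = "measured",
                           method = NA_character_) {
  stopifnot(state %in% c("measured", "trace", "missing", "imputed"))
  if (state %in% c("measured", "imputed") && is.na(amount)) {
    stop("state '", state, "' requires an amount", call. = FALSE)
  }
  if (state %in% c("trace", "missing") && !is.na(amount)) {
    stop("state '", state, "' carries no amount", call. = FALSE)
  }
  if (state == "imputed" && is.na(method)) {
    stop("imputed values must record their method", call. = FALSE)
  }
  structure(list(amount = as.numeric(amount), state = state, method = method),
            class = "nutrient_value")
}

#' A component definition
#' @param code,name,unit,trace_threshold see [component_registry()]
#' @export
component_def <- function(code, name = code, unit = "g",
                          trace_threshold = NA_real_) {
  df <- component_registry(data.frame(
    code = code, name = name, unit = unit,
    trace_threshold = as.numeric(trace_threshold),
    stringsAsFactors = FALSE))
  as.list(df[1L, ])
}

# the trace imputation constants keyed by analytical threshold
.trace_constants <- c("0.6" = 0.5, "0.06" = 0.05, "0.006" = 0.005)

#' Resolve a trace flag to its conventional imputed amount
#'
#' Components flagged "trace" (present below the analytical quantification
#' criterion of 0.6, 0.06 or 0.006 in the component's unit) are imputed with
#' the conventional constants 0.5, 0.05 and 0.005 respectively.
#'
#' @param value a [nutrient_value()] with `state == "trace"`.
#' @param def a [component_def()] (or registry row) with a trace threshold.
#' @return the resolved [nutrient_value()]: `state == "imputed"`,
#'   `method == "trace-rule"`, amount set to the threshold-specific constant.
#' @export
impute_trace <- function(value, def) {
  stopifnot(inherits(value, "nutrient_value"))
  if (value$state != "trace") {
    stop("impute_trace expects a trace-state value", call. = FALSE)
  }
  thr <- def$trace_threshold
  if (is.na(thr)) {
    stop("component '", def$code, "' has no trace criterion", call. = FALSE)
  }
  key <- format(thr, scientific = FALSE, trim = TRUE)
  if (!key %in% names(.trace_constants)) {
    stop("unknown trace threshold: ", thr, call. = FALSE)
  }
  nutrient_value(unname(.trace_constants[key]), "imputed", "trace-rule")
}

# ---------------------------------------------------------------------------
# FCDB container: items x components, with parallel amount / state / method
# matrices. Vectorized; one row per food item, one column per component code.
# ---------------------------------------------------------------------------

#' Construct an FCDB object
#'
#' @param items data.frame with columns `food_id`, `name`, `cooked` (logical),
#'   and optionally `item_class` (e.g. "plant", "animal"; used by
#'   imputation plans).
#' @param amounts numeric matrix (items x components), per 100 g edible part;
#'   `NA` wherever the state carries no amount.
#' @param state character matrix of the same shape, entries in
#'   measured/trace/missing/imputed.
#' @param registry a [component_registry()].
#' @param method optional character matrix recording imputation methods.
#' @export
fcdb <- function(items, amounts, state, registry, method = NULL) {
  stopifnot(is.data.frame(items), all(c("food_id", "name") %in% names(items)))
  if (anyDuplicated(items$food_id)) stop("duplicate food_id", call. = FALSE)
  if (is.null(items$cooked)) items$cooked <- FALSE
  if (is.null(items$item_class)) items$item_class <- "generic"
  amounts <- as.matrix(amounts)
  state <- as.matrix(state)
  stopifnot(identical(dim(amounts), dim(state)),
            nrow(amounts) == nrow(items))
  if (!setequal(colnames(amounts), registry$code)) {
    stop("amount columns must be exactly the registry's component codes",
         call. = FALSE)
  }
  amounts <- amounts[, registry$code, drop = FALSE]
  state <- state[, registry$code, drop = FALSE]
  rownames(amounts) <- rownames(state) <- items$food_id
  if (is.null(method)) {
    method <- matrix(NA_character_, nrow(amounts), ncol(amounts),
                     dimnames = dimnames(amounts))
  } else {
    method <- as.matrix(method)[, registry$code, drop = FALSE]
    rownames(method) <- items$food_id
  }
  bad <- (state %in% c("measured", "imputed")) != !is.na(amounts)
  if (any(bad)) {
    stop("amount present iff state is measured/imputed violated in ",
         sum(bad), " cell(s)", call. = FALSE)
  }
  structure(list(items = items, amounts = amounts, state = state,
                 method = method, registry = registry),
            class = "fcdb")
}

#' @export
print.fcdb <- function(x, ...) {
  cat("<fcdb> ", nrow(x$items), " items x ", nrow(x$registry),
      " components; states: ",
      paste(names(table(x$state)), table(x$state), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read an FCDB from CSV
#'
#' One row per food item; columns `food_id`, `name`, `cooked`, optionally
#' `item_class`, then one column per registry component code. Sentinel tokens
#' mark trace and missing cells.
#'
#' @param path CSV file.
#' @param registry a [component_registry()].
#' @param trace_token,missing_token sentinels used in the file.
#' @export
read_fcdb <- function(path, registry, trace_token = "tr", missing_token = "") {
  df <- read_csv_strict(path, colClasses = "character")
  meta_cols <- intersect(c("food_id", "name", "cooked", "item_class"), names(df))
  missing_comp <- setdiff(registry$code, names(df))
  if (length(missing_comp)) {
    stop("FCDB file lacks component column(s): ",
         paste(missing_comp, collapse = ", "), call. = FALSE)
  }
  items <- df[meta_cols]
  items$cooked <- if ("cooked" %in% meta_cols) {
    tolower(items$cooked) %in% c("true", "1", "yes")
  } else FALSE
  raw <- as.matrix(df[registry$code])
  state <- matrix("measured", nrow(raw), ncol(raw), dimnames = dimnames(raw))
  state[raw == trace_token] <- "trace"
  state[is.na(raw) | trimws(raw) == missing_token] <- "missing"
  amounts <- suppressWarnings(matrix(NA_real_, nrow(raw), ncol(raw),
                                     dimnames = dimnames(raw)))
  meas <- state == "measured"
  amounts[meas] <- parse_num(raw[meas])
  fcdb(items, amounts, state, registry)
}

#' Write an FCDB to CSV (inverse of [read_fcdb()]; imputed written as numbers)
#' @export
write_fcdb <- function(x, path, trace_token = "tr", missing_token = "") {
  stopifnot(inherits(x, "fcdb"))
  out <- matrix("", nrow(x$amounts), ncol(x$amounts),
                dimnames = dimnames(x$amounts))
  num <- x$state %in% c("measured", "imputed")
  out[num] <- format(x$amounts[num], scientific = FALSE, trim = TRUE, digits = 10)
  out[x$state == "trace"] <- trace_token
  out[x$state == "missing"] <- missing_token
  df <- cbind(x$items[c("food_id", "name", "cooked", "item_class")],
              as.data.frame(out, stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Resolve every trace flag in an FCDB
#'
#' Applies [impute_trace()] cell-wise; after this no cell has state "trace".
#' @param x an [fcdb()].
#' @export
resolve_traces <- function(x) {
  stopifnot(inherits(x, "fcdb"))
  for (code in x$registry$code) {
    idx <- which(x$state[, code] == "trace")
    if (!length(idx)) next
    thr <- x$registry$trace_threshold[x$registry$code == code]
    if (is.na(thr)) {
      stop("trace flag on component '", code, "' which has no trace criterion",
           call. = FALSE)
    }
    const <- unname(.trace_constants[format(thr, scientific = FALSE, trim = TRUE)])
    x$amounts[idx, code] <- const
    x$state[idx, code] <- "imputed"
    x$method[idx, code] <- "trace-rule"
  }
  x
}

# ---------------------------------------------------------------------------
# Component-harmonization formulas. All are linear; missing summands follow a
# policy: "zero" treats them as 0 and flags the result, "propagate" returns
# NA when any (or for the equivalents, all) inputs are missing.
# ---------------------------------------------------------------------------

.sum_with_policy <- function(terms, weights, policy, all_missing_na = TRUE) {
  m <- mapply(function(t, w) w * t, terms, weights, SIMPLIFY = TRUE)
  m <- matrix(m, ncol = length(terms))
  miss <- is.na(m)
  if (policy == "propagate") {
    out <- rowSums(m)
    out[rowSums(!miss) == 0L] <- NA_real_
  } else {
    out <- rowSums(m, na.rm = TRUE)
    if (all_missing_na) out[rowSums(!miss) == 0L & ncol(m) > 0L] <- NA_real_
  }
  attr(out, "flagged") <- rowSums(miss) > 0L
  out
}

#' Available carbohydrates from carbohydrate-by-difference and fiber
#'
#' The "available carbohydrates" definition (soluble carbohydrates + starch)
#' excludes fiber, whereas carbohydrate-by-difference includes it; the
#' harmonized value is their difference, floored at 0 with a warning since a
#' negative nutrient mass is meaningless.
#' @param carb_by_difference,total_fiber g per 100 g; vectors recycle.
#' @export
available_carbohydrates <- function(carb_by_difference, total_fiber) {
  out <- carb_by_difference - total_fiber
  neg <- !is.na(out) & out < 0
  if (any(neg)) {
    warning(sum(neg), " negative available-carbohydrate value(s) floored at 0")
    out[neg] <- 0
  }
  out
}

#' Beta-carotene equivalents
#' @param beta,alpha,crypto micrograms per 100 g
#' @param missing_policy "zero" (default, flags) or "propagate"
#' @export
beta_carotene_equivalents <- function(beta, alpha, crypto,
                                      missing_policy = c("zero", "propagate")) {
  missing_policy <- match.arg(missing_policy)
  .sum_with_policy(list(beta, alpha, crypto), c(1, 0.5, 0.5), missing_policy)
}

#' Retinol equivalent (vitamin A activity)
#' @param retinol,bce micrograms per 100 g (bce = beta-carotene equivalents)
#' @inheritParams beta_carotene_equivalents
#' @export
retinol_equivalent <- function(retinol, bce,
                               missing_policy = c("zero", "propagate")) {
  missing_policy <- match.arg(missing_policy)
  .sum_with_policy(list(retinol, bce), c(1, 1 / 6), missing_policy)
}

#' Alpha-tocopherol equivalents (vitamin E activity)
#' @param a,b,g,d tocopherols, mg per 100 g
#' @param at3,bt3,gt3 tocotrienols, mg per 100 g
#' @inheritParams beta_carotene_equivalents
#' @export
alpha_tocopherol_equivalents <- function(a, b, g, d, at3, bt3, gt3,
                                         missing_policy = c("zero", "propagate")) {
  missing_policy <- match.arg(missing_policy)
  .sum_with_policy(list(a, b, g, d, at3, bt3, gt3),
                   c(1, 0.4, 0.1, 0.01, 0.3, 0.05, 0.01), missing_policy)
}

#' Short-chain saturated fatty acids (C4:0 + C6:0 + C8:0 + C10:0)
#' @param c4,c6,c8,c10 g per 100 g
#' @inheritParams beta_carotene_equivalents
#' @export
short_chain_sfa <- function(c4, c6, c8, c10,
                            missing_policy = c("zero", "propagate")) {
  missing_policy <- match.arg(missing_policy)
  .sum_with_policy(list(c4, c6, c8, c10), c(1, 1, 1, 1), missing_policy)
}

#' Other PUFAs: sum of source-FCDB-only polyunsaturated fatty acid columns
#' @param pufa_components named list/data.frame of numeric vectors (g/100 g)
#' @export
other_pufas <- function(pufa_components) {
  if (!length(pufa_components)) {
    out <- 0
    attr(out, "flagged") <- FALSE
    return(out)
  }
  .sum_with_policy(as.list(pufa_components),
                   rep(1, length(pufa_components)), "zero",
                   all_missing_na = FALSE)
}

#' Energy unit conversion (4.184 kJ per kcal; kcal is primary in reports)
#' @param kcal numeric vector
#' @export
kcal_to_kj <- function(kcal) 4.184 * kcal

#' @rdname kcal_to_kj
#' @param kj numeric vector
#' @export
kj_to_kcal <- function(kj) kj / 4.184
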