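# ---------------------------------------------------------------------------
# Nutrition5k-dialect metadata: each dish is one CSV row, a dish-level header
# block followed by one 7-field block per ingredient. Two column-order
# presets exist in the wild; both are supported via a dialect object.
# ---------------------------------------------------------------------------

#' Nutrition5k CSV dialect
#'
#' The public cafeteria files order the dish header as
#' `dish_id, total_calories, total_mass, total_fat, total_carb, total_protein`
#' with no ingredient-count column (the count is inferred from the number of
#' trailing 7-field blocks); an alternative "mass_first" layout puts
#' `total_mass` before `total_calories` and carries an explicit `num_ingrs`
#' column. Ingredient blocks are always
#' `ingr_id, ingr_name, ingr_grams, ingr_calories, ingr_fat, ingr_carb,
#' ingr_protein`.
#'
#' @param preset `"public"` (default) or `"mass_first"`.
#' @export
n5k_dialect <- function(preset = c("public", "mass_first")) {
  preset <- match.arg(preset)
  header <- switch(preset,
    public = c("dish_id", "total_calories", "total_mass", "total_fat",
               "total_carb", "total_protein"),
    mass_first = c("dish_id", "total_mass", "total_calories", "total_fat",
                   "total_carb", "total_protein", "num_ingrs"))
  structure(list(preset = preset, header = header,
                 has_num_ingrs = "num_ingrs" %in% header,
                 block = c("ingr_id", "ingr_name", "ingr_grams",
                           "ingr_calories", "ingr_fat", "ingr_carb",
                           "ingr_protein")),
            class = "n5k_dialect")
}

#' Parse a Nutrition5k dish metadata file
#'
#' Reads the ragged-wide dish file and validates every row: numeric fields
#' must parse, the trailing fields must divide into whole 7-field ingredient
#' blocks, and (when the dialect declares `num_ingrs`) the block count must
#' equal it. Declared dish totals are cross-checked against the sum of the
#' ingredient masses with relative tolerance `mass_tol`; violations are
#' warnings, not errors (mass errors are expected in the raw data and fixed
#' by curation).
#'
#' @param path CSV file (no header row; UTF-8; "." decimal separator).
#' @param dialect an [n5k_dialect()].
#' @param mass_tol relative tolerance for the declared-total-vs-sum check.
#' @return a `dish_set`: list with `dishes` (one row per dish) and `uses`
#'   (long table, one row per ingredient use, ordered as in the file).
#' @export
parse_dish_metadata <- function(path, dialect = n5k_dialect(),
                                mass_tol = 1e-3) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  nh <- length(dialect$header)
  dishes <- vector("list", length(lines))
  uses <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    # tolerate a single trailing comma
    if (length(f) > nh && f[length(f)] == "") f <- f[-length(f)]
    if (length(f) < nh) {
      stop("row ", i, ": fewer fields than the dish header block", call. = FALSE)
    }
    hd <- as.list(f[seq_len(nh)])
    names(hd) <- dialect$header
    rest <- f[-seq_len(nh)]
    if (length(rest) %% 7L != 0L) {
      stop("row ", i, " (dish ", hd$dish_id,
           "): ingredient fields not a multiple of 7", call. = FALSE)
    }
    nblocks <- length(rest) %/% 7L
    if (dialect$has_num_ingrs) {
      declared_n <- as.integer(parse_num(hd$num_ingrs))
      if (declared_n != nblocks) {
        stop("dish ", hd$dish_id, ": num_ingrs=", declared_n, " but ",
             nblocks, " ingredient block(s) present", call. = FALSE)
      }
    }
    num_fields <- setdiff(dialect$header, c("dish_id", "num_ingrs"))
    hd[num_fields] <- tryCatch(lapply(hd[num_fields], parse_num),
      error = function(e) stop("dish ", hd$dish_id, ": ", conditionMessage(e),
                               call. = FALSE))
    blk <- matrix(rest, ncol = 7L, byrow = TRUE,
                  dimnames = list(NULL, dialect$block))
    grams <- tryCatch(
      parse_num(blk[, "ingr_grams"]),
      error = function(e) stop("dish ", hd$dish_id, ": non-numeric mass",
                               call. = FALSE))
    if (any(grams < 0, na.rm = TRUE)) {
      stop("dish ", hd$dish_id, ": negative ingredient mass", call. = FALSE)
    }
    u <- data.frame(
      dish_id = hd$dish_id,
      position = seq_len(nblocks),
      ingr_id = blk[, "ingr_id"],
      ingr_name = blk[, "ingr_name"],
      ingr_grams = grams,
      declared_energy = parse_num(blk[, "ingr_calories"]),
      declared_fat = parse_num(blk[, "ingr_fat"]),
      declared_carb = parse_num(blk[, "ingr_carb"]),
      declared_protein = parse_num(blk[, "ingr_protein"]),
      stringsAsFactors = FALSE)
    dishes[[i]] <- data.frame(
      dish_id = hd$dish_id,
      total_mass = hd$total_mass,
      total_calories = hd$total_calories,
      total_fat = hd$total_fat,
      total_carb = hd$total_carb,
      total_protein = hd$total_protein,
      num_ingrs = nblocks,
      stringsAsFactors = FALSE)
    uses[[i]] <- u
  }
  dishes <- if (length(dishes)) do.call(rbind, dishes) else
    data.frame(dish_id = character(), total_mass = numeric(),
               total_calories = numeric(), total_fat = numeric(),
               total_carb = numeric(), total_protein = numeric(),
               num_ingrs = integer(), stringsAsFactors = FALSE)
  uses <- if (length(uses)) do.call(rbind, uses) else
    data.frame(dish_id = character(), position = integer(),
               ingr_id = character(), ingr_name = character(),
               ingr_grams = numeric(), declared_energy = numeric(),
               declared_fat = numeric(), declared_carb = numeric(),
               declared_protein = numeric(), stringsAsFactors = FALSE)
  if (nrow(dishes)) {
    if (anyDuplicated(dishes$dish_id)) {
      warning("duplicate dish_id(s): ",
              paste(unique(dishes$dish_id[duplicated(dishes$dish_id)]),
                    collapse = ", "))
    }
    mass_sum <- tapply(uses$ingr_grams, uses$dish_id, sum)[dishes$dish_id]
    off <- abs(dishes$total_mass - mass_sum) >
      mass_tol * pmax(1, abs(dishes$total_mass))
    if (any(off, na.rm = TRUE)) {
      warning(sum(off, na.rm = TRUE),
              " dish(es) whose declared total mass disagrees with the sum of ",
              "ingredient masses (checked at relative tolerance ", mass_tol, ")")
    }
  }
  structure(list(dishes = dishes, uses = uses, dialect = dialect),
            class = "dish_set")
}

#' @export
print.dish_set <- function(x, ...) {
  cat("<dish_set> ", nrow(x$dishes), " dishes, ", nrow(x$uses),
      " ingredient uses (dialect: ", x$dialect$preset, ")\n", sep = "")
  invisible(x)
}

#' Write a dish_set back to the ragged-wide dialect (inverse of the parser)
#' @param x a `dish_set`; @param path output CSV; @param dialect layout
#' @export
write_dish_metadata <- function(x, path, dialect = x$dialect) {
  stopifnot(inherits(x, "dish_set"))
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE, digits = 10)
  rows <- vapply(seq_len(nrow(x$dishes)), function(i) {
    d <- x$dishes[i, ]
    u <- x$uses[x$uses$dish_id == d$dish_id, , drop = FALSE]
    u <- u[order(u$position), , drop = FALSE]
    hd <- vapply(dialect$header, function(col) {
      if (col == "dish_id") d$dish_id
      else if (col == "num_ingrs") as.character(d$num_ingrs)
      else fmt(d[[col]])
    }, character(1))
    blocks <- apply(u, 1L, function(r) {
      paste(r[["ingr_id"]], r[["ingr_name"]], fmt(as.numeric(r[["ingr_grams"]])),
            fmt(as.numeric(r[["declared_energy"]])),
            fmt(as.numeric(r[["declared_fat"]])),
            fmt(as.numeric(r[["declared_carb"]])),
            fmt(as.numeric(r[["declared_protein"]])), sep = ",")
    })
    paste(c(paste(hd, collapse = ","), blocks), collapse = ",")
  }, character(1))
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Parse the ingredient catalogue
#'
#' @param path CSV with (at least) id and name columns.
#' @param id_col,name_col column names in the file.
#' @param deprecated_token names equal to this token (or empty) are flagged
#'   `deprecated = TRUE`.
#' @return data.frame with `ingr_id`, `canonical_name`, `deprecated`.
#' @export
parse_ingredient_catalog <- function(path, id_col = "id", name_col = "ingr",
                                     deprecated_token = "deprecated") {
  df <- read_csv_strict(path)
  if (!all(c(id_col, name_col) %in% names(df))) {
    # fall back to first two columns
    id_col <- names(df)[1]; name_col <- names(df)[2]
  }
  out <- data.frame(ingr_id = as.character(df[[id_col]]),
                    canonical_name = as.character(df[[name_col]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$ingr_id)) {
    stop("duplicate ingr_id in catalogue: ",
         paste(unique(out$ingr_id[duplicated(out$ingr_id)]), collapse = ", "),
         call. = FALSE)
  }
  out$deprecated <- is.na(out$canonical_name) |
    trimws(out$canonical_name) == "" |
    out$canonical_name == deprecated_token
  out
}

#' Reshape a dish_set from wide to long
#'
#' Returns the long ingredient-use table (one row per use). The reshape
#' conserves per-dish mass by construction; the inverse is
#' [long_to_wide()].
#' @param dishes a `dish_set`.
#' @export
wide_to_long <- function(dishes) {
  stopifnot(inherits(dishes, "dish_set"))
  u <- dishes$uses
  n_expected <- sum(dishes$dishes$num_ingrs)
  if (nrow(u) != n_expected) {
    stop("long row count ", nrow(u), " != sum(num_ingrs) ", n_expected,
         call. = FALSE)
  }
  if (anyDuplicated(u[c("dish_id", "position")])) {
    stop("(dish_id, position) not unique", call. = FALSE)
  }
  u
}

#' Reassemble a dish_set from a long use table and a dish header table
#' @param uses long table as produced by [wide_to_long()]
#' @param dishes dish header table (a `dish_set$dishes`)
#' @param dialect layout for later writing
#' @export
long_to_wide <- function(uses, dishes, dialect = n5k_dialect()) {
  dishes$num_ingrs <- as.integer(table(uses$dish_id)[dishes$dish_id])
  dishes$num_ingrs[is.na(dishes$num_ingrs)] <- 0L
  structure(list(dishes = dishes, uses = uses, dialect = dialect),
            class = "dish_set")
}
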