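#' @keywords internal
"_PACKAGE"

# numeric parser that refuses locale surprises: "." decimal point only,
# no thousands separators, empty string -> NA
parse_num <- function(x) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  bad <- !is.na(x) & !grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x)
  if (any(bad)) {
    stop("non-numeric value(s): ", paste(utils::head(unique(x[bad]), 5L), collapse = ", "),
         call. = FALSE)
  }
  as.numeric(x)
}

# type-7 quantile summary used everywhere a seven-number summary is reported
seven_number <- function(x) {
  q <- stats::quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
    mean = mean(x), sd = stats::sd(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 12345) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

read_csv_strict <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8", ...)
}
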