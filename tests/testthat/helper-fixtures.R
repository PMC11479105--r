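# fixtures are built in code; nothing binary ships with the tests

tiny_registry <- function() {
  component_registry(data.frame(
    code = c("energy_kcal", "protein", "fat", "carb_avail", "water",
             "fiber", "sodium", "retinol"),
    name = c("Energy", "Protein", "Fat", "Carb", "Water", "Fiber",
             "Sodium", "Retinol"),
    unit = c("kcal", "g", "g", "g", "g", "g", "mg", "ug"),
    trace_threshold = c(NA, NA, NA, NA, NA, NA, NA, 0.6),
    stringsAsFactors = FALSE))
}

# small fully measured fcdb on the tiny registry
tiny_fcdb <- function(n = 4) {
  reg <- tiny_registry()
  set.seed(1234)
  a <- cbind(energy_kcal = c(100, 300, 52, 250)[1:n],
             protein = c(10, 20, 0.3, 5)[1:n],
             fat = c(1, 15, 0.2, 10)[1:n],
             carb_avail = c(12, 20, 12, 30)[1:n],
             water = c(70, 40, 85, 50)[1:n],
             fiber = c(2, 1, 2.4, 3)[1:n],
             sodium = c(10, 500, 1, 300)[1:n],
             retinol = c(0, 50, 0, 20)[1:n])
  items <- data.frame(food_id = paste0("it_", letters[1:n]),
                      name = paste0("item ", letters[1:n]),
                      cooked = c(FALSE, TRUE, FALSE, TRUE)[1:n],
                      item_class = c("plant", "animal", "plant", "animal")[1:n],
                      stringsAsFactors = FALSE)
  rownames(a) <- items$food_id
  fcdb(items, a, matrix("measured", n, ncol(a), dimnames = dimnames(a)), reg)
}

# write a mass_first-dialect dish file from raw lines
write_dish_lines <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# default small synthetic config used by several suites
test_synth_config <- function(seed, ...) {
  synth_config(n_items = 40L, n_ingredients = 25L, n_dishes = 120L,
               seed = seed, ...)
}
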