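#' FFQ schema: questionnaire structure, frequency maps and composition matrix
#'
#' An `ffq_schema` bundles everything needed to turn raw food-frequency
#' questionnaire (FFQ) answers into daily intakes: the 108 item questions and
#' their assignment to 30 food groups, the 9-level frequency-to-intakes/day
#' map, the portion-photo multipliers and sex/age-specific reference portion
#' sizes, the 6 taste-liking items, and a per-gram item-by-nutrient
#' composition matrix used for energy and nutrient estimation.
#'
#' The packaged default schema is synthetic but dimensionally faithful to the
#' instrument it emulates: exactly 108 items, 30 food groups, a 9-level
#' frequency scale spanning 0-4 intakes/day, 3 portion-photo questions
#' (staple, protein, vegetable plates) with 4 levels each, 6 taste items (2
#' each for bitter, sweet, sour), and ~40 nutrients. Its composition matrix
#' is generated deterministically and calibrated so that a typical simulated
#' respondent reports close to 2000 kcal/day. Every element can be replaced
#' via [ffq_schema()] or a schema directory read with [read_ffq_schema()].
#'
#' @param items Tibble with columns `item`, `food_group`, `portion_class`.
#' @param freq_map Numeric length 9, monotone nondecreasing, in `[0, 4]`:
#'   intakes/day for frequency levels 1..9.
#' @param level_probs Numeric length 9 summing to 1: marginal probabilities of
#'   each frequency level used by the cohort simulator's latent thresholds.
#' @param portion_multipliers Numeric length 4: multiplier applied to the
#'   reference portion for portion-photo answers 1..4.
#' @param portion_grams Tibble with columns `sex`, `age_band`,
#'   `portion_class`, `grams`: reference portion weight in grams.
#' @param taste_items Tibble with columns `item`, `taste_class`; exactly 6
#'   rows, 2 per class in bitter/sweet/sour.
#' @param taste_level_probs Numeric length 6 summing to 1.
#' @param composition Tibble: column `item` plus one numeric column per
#'   nutrient, amounts per gram of food.
#' @param bmr_coefficients Tibble with columns `sex`, `age_band`, `slope`,
#'   `intercept`: basal metabolic rate (kcal/day) = slope * weight_kg +
#'   intercept, used for the physical-activity-level (PAL) plausibility
#'   screen.
#' @return An object of class `ffq_schema`.
#' @export
ffq_schema <- function(items, freq_map, level_probs, portion_multipliers,
                       portion_grams, taste_items, taste_level_probs,
                       composition, bmr_coefficients) {
  items <- tibble::as_tibble(items)
  if (!"gram_scale" %in% names(items)) items$gram_scale <- 1
  schema <- structure(
    list(
      items = items,
      food_groups = unique(items$food_group),
      freq_map = freq_map,
      level_probs = level_probs,
      portion_multipliers = portion_multipliers,
      portion_grams = tibble::as_tibble(portion_grams),
      taste_items = tibble::as_tibble(taste_items),
      taste_level_probs = taste_level_probs,
      composition = tibble::as_tibble(composition),
      nutrients = setdiff(names(composition), "item"),
      bmr_coefficients = tibble::as_tibble(bmr_coefficients)
    ),
    class = "ffq_schema"
  )
  validate_ffq_schema(schema)
}

#' Validate an FFQ schema
#'
#' Checks the structural invariants of the questionnaire definition: 108
#' items each assigned to one of 30 food groups, a monotone frequency map
#' bounded in `[0, 4]` intakes/day, 6 taste items (2 per taste class), and a
#' composition matrix covering every item.
#'
#' @param schema An `ffq_schema`.
#' @return The schema, invisibly-checked (returned unchanged).
#' @export
validate_ffq_schema <- function(schema) {
  items <- schema$items
  if (nrow(items) != 108L) {
    abort(sprintf("FFQ schema must define exactly 108 items, got %d.", nrow(items)))
  }
  if (anyDuplicated(items$item) > 0L) abort("FFQ item names must be unique.")
  if (length(unique(items$food_group)) != 30L) {
    abort(sprintf(
      "FFQ items must map onto exactly 30 food groups, got %d.",
      length(unique(items$food_group))
    ))
  }
  if (any(is.na(items$food_group))) abort("Every item needs a food-group assignment.")
  fm <- schema$freq_map
  if (length(fm) != 9L || is.unsorted(fm) || any(fm < 0) || any(fm > 4)) {
    abort("Frequency map must be 9 monotone nondecreasing values in [0, 4] intakes/day.")
  }
  if (length(schema$level_probs) != 9L ||
      abs(sum(schema$level_probs) - 1) > 1e-8 || any(schema$level_probs <= 0)) {
    abort("level_probs must be 9 positive probabilities summing to 1.")
  }
  if (length(schema$portion_multipliers) != 4L || any(schema$portion_multipliers <= 0)) {
    abort("portion_multipliers must be 4 positive values.")
  }
  ti <- schema$taste_items
  if (nrow(ti) != 6L || !all(sort(ti$taste_class) == rep(c("bitter", "sour", "sweet"), each = 2))) {
    abort("Taste items must be exactly 6: two per class bitter/sweet/sour.")
  }
  if (!setequal(schema$composition$item, items$item)) {
    abort("Composition matrix must cover exactly the 108 schema items.")
  }
  if (!"energy_kcal" %in% schema$nutrients) {
    abort("Composition matrix must include an `energy_kcal` column (kcal per gram).")
  }
  classes <- unique(items$portion_class)
  missing_pg <- setdiff(classes, unique(schema$portion_grams$portion_class))
  if (length(missing_pg) > 0) {
    abort(paste0("portion_grams lacks classes: ", paste(missing_pg, collapse = ", ")))
  }
  invisible(schema)
}

# Food groups of the default schema: number of items, the portion plate
# (photo question) used to weight them, and a per-group scale on the class
# reference portion (a pat of butter is not a plate of stew).
# 18 * 4 + 12 * 3 = 108 items.
default_food_groups <- function() {
  tibble::tribble(
    ~food_group,                  ~portion_class, ~n_items, ~gram_scale,
    "vegetables",                 "vegetable",    4L, 1.0,
    "potatoes",                   "vegetable",    4L, 1.0,
    "fruits_berries",             "none",         4L, 0.8,
    "fruit_juice",                "none",         3L, 1.3,
    "legumes",                    "vegetable",    4L, 1.0,
    "nuts_seeds",                 "none",         4L, 0.2,
    "whole_grains",               "staple",       4L, 1.0,
    "refined_grains",             "staple",       4L, 1.0,
    "breakfast_cereals",          "staple",       3L, 0.5,
    "fish_shellfish",             "protein",      4L, 1.0,
    "red_meat",                   "protein",      4L, 1.0,
    "processed_meat",             "protein",      4L, 0.6,
    "poultry",                    "protein",      4L, 1.0,
    "venison",                    "protein",      3L, 1.0,
    "eggs",                       "protein",      3L, 0.45,
    "dairy_products",             "none",         4L, 1.3,
    "cheese",                     "none",         3L, 0.15,
    "plant_milk_substitutes",     "none",         3L, 1.3,
    "vegetable_oils",             "none",         3L, 0.07,
    "butter_margarine",           "none",         3L, 0.07,
    "sweets_chocolate",           "none",         4L, 0.25,
    "desserts",                   "none",         4L, 0.6,
    "ice_cream",                  "none",         3L, 0.5,
    "snacks",                     "none",         4L, 0.25,
    "sugar_sweetened_beverages",  "none",         4L, 2.2,
    "coffee",                     "none",         3L, 1.3,
    "tea",                        "none",         3L, 1.3,
    "water",                      "none",         3L, 1.7,
    "alcoholic_beverages",        "none",         4L, 2.2,
    "ready_meals",                "staple",       4L, 1.0
  )
}

# Per-gram macronutrient profile by food group: water, protein, fat,
# carbohydrate, fiber fractions, share of carbohydrate that is sugar, share of
# sugar that is added, and alcohol fraction. Synthetic but order-of-magnitude
# realistic; energy follows by Atwater factors.
default_group_macros <- function() {
  tibble::tribble(
    ~food_group, ~water, ~protein, ~fat, ~carb, ~fiber, ~sugar_frac, ~added_frac, ~alcohol,
    "vegetables",                0.92, 0.020, 0.003, 0.040, 0.020, 0.50, 0.00, 0,
    "potatoes",                  0.78, 0.020, 0.001, 0.170, 0.020, 0.05, 0.00, 0,
    "fruits_berries",            0.85, 0.010, 0.003, 0.120, 0.020, 0.90, 0.00, 0,
    "fruit_juice",               0.89, 0.005, 0.001, 0.100, 0.002, 1.00, 0.00, 0,
    "legumes",                   0.70, 0.080, 0.010, 0.150, 0.060, 0.10, 0.00, 0,
    "nuts_seeds",                0.05, 0.200, 0.500, 0.150, 0.080, 0.30, 0.00, 0,
    "whole_grains",              0.35, 0.090, 0.020, 0.450, 0.080, 0.05, 0.50, 0,
    "refined_grains",            0.35, 0.080, 0.020, 0.500, 0.030, 0.08, 0.70, 0,
    "breakfast_cereals",         0.10, 0.100, 0.050, 0.650, 0.070, 0.25, 0.80, 0,
    "fish_shellfish",            0.70, 0.200, 0.080, 0.000, 0.000, 0.00, 0.00, 0,
    "red_meat",                  0.65, 0.220, 0.120, 0.000, 0.000, 0.00, 0.00, 0,
    "processed_meat",            0.55, 0.150, 0.250, 0.020, 0.000, 0.20, 0.80, 0,
    "poultry",                   0.68, 0.230, 0.080, 0.000, 0.000, 0.00, 0.00, 0,
    "venison",                   0.72, 0.230, 0.030, 0.000, 0.000, 0.00, 0.00, 0,
    "eggs",                      0.75, 0.130, 0.100, 0.010, 0.000, 0.10, 0.00, 0,
    "dairy_products",            0.87, 0.035, 0.035, 0.050, 0.000, 0.90, 0.00, 0,
    "cheese",                    0.40, 0.250, 0.300, 0.010, 0.000, 0.50, 0.00, 0,
    "plant_milk_substitutes",    0.90, 0.010, 0.015, 0.060, 0.005, 0.60, 0.40, 0,
    "vegetable_oils",            0.00, 0.000, 0.990, 0.000, 0.000, 0.00, 0.00, 0,
    "butter_margarine",          0.15, 0.005, 0.800, 0.005, 0.000, 0.10, 0.00, 0,
    "sweets_chocolate",          0.05, 0.050, 0.300, 0.550, 0.020, 0.80, 0.95, 0,
    "desserts",                  0.40, 0.040, 0.150, 0.350, 0.010, 0.60, 0.90, 0,
    "ice_cream",                 0.60, 0.035, 0.100, 0.250, 0.000, 0.80, 0.85, 0,
    "snacks",                    0.03, 0.060, 0.300, 0.550, 0.040, 0.05, 0.50, 0,
    "sugar_sweetened_beverages", 0.89, 0.000, 0.000, 0.100, 0.000, 1.00, 0.95, 0,
    "coffee",                    0.99, 0.001, 0.000, 0.003, 0.000, 0.30, 0.30, 0,
    "tea",                       0.995, 0.000, 0.000, 0.002, 0.000, 0.30, 0.30, 0,
    "water",                     1.00, 0.000, 0.000, 0.000, 0.000, 0.00, 0.00, 0,
    "alcoholic_beverages",       0.90, 0.003, 0.000, 0.030, 0.000, 0.40, 0.20, 0.05,
    "ready_meals",               0.65, 0.080, 0.100, 0.150, 0.010, 0.10, 0.50, 0
  )
}

# Deterministic synthetic composition matrix (per-gram nutrient amounts) for
# the 108 default items. Micronutrient densities are random within plausible
# per-gram ranges, boosted for group/nutrient affinities (vitamin C in
# fruit/vegetables, B12 and cholesterol in animal foods, ...).
build_default_composition <- function(items) {
  macros <- default_group_macros()
  df <- dplyr::left_join(items, macros, by = "food_group")
  n <- nrow(df)
  jit <- function(lo = 0.8, hi = 1.25) runif(n, lo, hi)
  protein_g <- df$protein * jit()
  fat_g <- df$fat * jit()
  carbohydrate_g <- df$carb * jit()
  fiber_g <- df$fiber * jit()
  alcohol_g <- df$alcohol * jit()
  water_g <- pmin(df$water * jit(0.95, 1.02), 1)
  total_sugar_g <- carbohydrate_g * df$sugar_frac
  monosaccharides_g <- 0.4 * total_sugar_g
  disaccharides_g <- 0.6 * total_sugar_g
  added_sucrose_g <- total_sugar_g * df$added_frac
  free_saccharides_g <- monosaccharides_g + added_sucrose_g * 0.5
  energy_kcal <- 4 * (protein_g + carbohydrate_g) + 9 * fat_g +
    7 * alcohol_g + 2 * fiber_g
  animal <- df$food_group %in% c(
    "fish_shellfish", "red_meat", "processed_meat", "poultry", "venison",
    "eggs", "dairy_products", "cheese", "ice_cream", "butter_margarine"
  )
  plantfresh <- df$food_group %in% c(
    "vegetables", "fruits_berries", "fruit_juice", "legumes", "potatoes"
  )
  fishoil <- df$food_group %in% c("fish_shellfish", "vegetable_oils", "nuts_seeds")
  solid <- water_g < 0.85
  retinol_ug <- runif(n, 0, 0.3) + ifelse(animal, runif(n, 0.2, 1.5), 0)
  beta_carotene_ug <- runif(n, 0, 1) + ifelse(plantfresh, runif(n, 2, 20), 0)
  comp <- tibble::tibble(
    item = df$item,
    energy_kcal = energy_kcal,
    protein_g = protein_g,
    fat_g = fat_g,
    saturated_fat_g = fat_g * runif(n, 0.2, 0.5),
    monounsaturated_fat_g = fat_g * runif(n, 0.2, 0.4),
    polyunsaturated_fat_g = fat_g * runif(n, 0.1, 0.3),
    trans_fat_g = fat_g * runif(n, 0, 0.03),
    cholesterol_mg = ifelse(animal, runif(n, 0.2, 3), 0),
    carbohydrate_g = carbohydrate_g,
    monosaccharides_g = monosaccharides_g,
    disaccharides_g = disaccharides_g,
    added_sucrose_g = added_sucrose_g,
    free_saccharides_g = free_saccharides_g,
    total_sugar_g = total_sugar_g,
    fiber_g = fiber_g,
    alcohol_g = alcohol_g,
    water_g = water_g,
    sodium_mg = ifelse(solid, runif(n, 0.5, 8), runif(n, 0.01, 0.5)),
    potassium_mg = runif(n, 0.3, 4),
    calcium_mg = runif(n, 0.1, 1.5) +
      ifelse(df$food_group %in% c("dairy_products", "cheese"), runif(n, 2, 8), 0),
    magnesium_mg = runif(n, 0.05, 1),
    iron_mg = runif(n, 0.002, 0.05),
    zinc_mg = runif(n, 0.002, 0.05),
    iodine_ug = runif(n, 0.01, 0.5) + ifelse(animal, runif(n, 0.1, 1), 0),
    selenium_ug = runif(n, 0.01, 0.5),
    phosphorus_mg = runif(n, 0.2, 3),
    retinol_ug = retinol_ug,
    beta_carotene_ug = beta_carotene_ug,
    vitamin_a_re = retinol_ug + beta_carotene_ug / 12,
    vitamin_d_ug = ifelse(fishoil, runif(n, 0.01, 0.1), runif(n, 0, 0.01)),
    vitamin_e_mg = ifelse(fishoil, runif(n, 0.05, 0.5), runif(n, 0.001, 0.05)),
    vitamin_k_ug = runif(n, 0.01, 3) + ifelse(plantfresh, runif(n, 0.5, 3), 0),
    thiamin_mg = runif(n, 0.0005, 0.01),
    riboflavin_mg = runif(n, 0.0005, 0.01),
    niacin_mg = runif(n, 0.001, 0.1),
    vitamin_b6_mg = runif(n, 0.0005, 0.01),
    folate_ug = runif(n, 0.05, 2) + ifelse(plantfresh, runif(n, 0.5, 3), 0),
    vitamin_b12_ug = ifelse(animal, runif(n, 0.002, 0.03), 0),
    vitamin_c_mg = ifelse(plantfresh, runif(n, 0.1, 1), runif(n, 0, 0.05)),
    omega3_g = ifelse(fishoil, runif(n, 0.002, 0.03), runif(n, 0, 0.002))
  )
  comp
}

#' The packaged default FFQ schema
#'
#' Builds the default synthetic schema: 108 items across 30 food groups, the
#' default 9-level frequency map `{0, 0.03, 0.1, 0.14, 0.43, 0.79, 1, 2, 4}`
#' intakes/day (endpoints pinned to the instrument's printed 0-4 intakes/day
#' range, interior values conventional frequency midpoints), portion-photo
#' multipliers `{0.7, 1.0, 1.3, 1.6}`, sex- and age-band-specific reference
#' portions, 6 taste items, Schofield-type BMR coefficients for the PAL
#' screen, and a deterministic synthetic composition matrix calibrated so a
#' typical simulated diet yields roughly 2000 kcal/day.
#'
#' The build is deterministic: repeated calls return identical schemas and do
#' not disturb the caller's random-number state.
#'
#' @return An `ffq_schema` object.
#' @export
#' @examples
#' schema <- default_ffq_schema()
#' nrow(schema$items)              # 108
#' length(schema$food_groups)      # 30
default_ffq_schema <- function() {
  groups <- default_food_groups()
  items <- tibble::tibble(
    food_group = rep(groups$food_group, groups$n_items),
    portion_class = rep(groups$portion_class, groups$n_items),
    gram_scale = rep(groups$gram_scale, groups$n_items)
  )
  items <- items |>
    dplyr::group_by(.data$food_group) |>
    dplyr::mutate(item = paste0(.data$food_group, "_", dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::select("item", "food_group", "portion_class", "gram_scale")
  # keep schema order aligned with the group table, not alphabetical
  items <- items[order(match(items$food_group, groups$food_group)), ]

  freq_map <- c(0, 0.03, 0.1, 0.14, 0.43, 0.79, 1, 2, 4)
  level_probs <- c(0.45, 0.18, 0.12, 0.08, 0.07, 0.05, 0.03, 0.015, 0.005)
  portion_multipliers <- c(0.7, 1.0, 1.3, 1.6)

  portion_grams <- tidyr::expand_grid(
    sex = c("F", "M"),
    age_band = c("18-30", "31-60"),
    portion_class = c("staple", "protein", "vegetable", "none")
  ) |>
    dplyr::mutate(
      base = dplyr::case_when(
        .data$portion_class == "staple" ~ 180,
        .data$portion_class == "protein" ~ 130,
        .data$portion_class == "vegetable" ~ 75,
        TRUE ~ 150
      ),
      grams = .data$base *
        ifelse(.data$sex == "M", 1.15, 0.9) *
        ifelse(.data$age_band == "31-60", 0.97, 1)
    ) |>
    dplyr::select("sex", "age_band", "portion_class", "grams")

  taste_items <- tibble::tribble(
    ~item, ~taste_class,
    "black_coffee", "bitter",
    "grapefruit", "bitter",
    "sweets", "sweet",
    "jam_marmalade", "sweet",
    "juice", "sour",
    "lemon", "sour"
  )
  taste_level_probs <- c(0.05, 0.10, 0.20, 0.30, 0.20, 0.15)

  # Schofield-type BMR (kcal/day) = slope * weight_kg + intercept
  bmr <- tibble::tribble(
    ~sex, ~age_band, ~slope, ~intercept,
    "M", "18-30", 15.057, 692.2,
    "M", "31-60", 11.472, 873.1,
    "F", "18-30", 14.818, 486.6,
    "F", "31-60", 8.126, 845.6
  )

  composition <- with_preserved_seed(190841, build_default_composition(items))

  # Calibrate reference portions so the expected energy of a typical
  # respondent (default level probabilities, average portion photo) is close
  # to 2000 kcal/day.
  mean_intake <- sum(level_probs * freq_map)
  mean_mult <- sum(c(0.2, 0.4, 0.3, 0.1) * portion_multipliers)
  grams_m <- portion_grams |>
    dplyr::filter(.data$sex == "M", .data$age_band == "18-30")
  # calibrate against the sex-averaged reference portion, not the male one
  g_lookup <- setNames(grams_m$grams / 1.15, grams_m$portion_class)
  e_density <- composition$energy_kcal[match(items$item, composition$item)]
  e0 <- sum(
    mean_intake * mean_mult * g_lookup[items$portion_class] *
      items$gram_scale * e_density
  )
  k <- 2013 / e0
  portion_grams$grams <- round(portion_grams$grams * k, 1)

  ffq_schema(
    items = items,
    freq_map = freq_map,
    level_probs = level_probs,
    portion_multipliers = portion_multipliers,
    portion_grams = portion_grams,
    taste_items = taste_items,
    taste_level_probs = taste_level_probs,
    composition = composition,
    bmr_coefficients = bmr
  )
}

#' Write / read an FFQ schema as plain-text config
#'
#' The schema is stored as a directory: `schema.yaml` holding the item table,
#' frequency map, portion definitions and taste items, plus
#' `composition.csv` holding the item-by-nutrient matrix.
#'
#' @param schema An `ffq_schema`.
#' @param dir Directory to write to (created if needed).
#' @return `write_ffq_schema()` returns `dir` invisibly; `read_ffq_schema()`
#'   returns the reconstructed `ffq_schema`.
#' @export
write_ffq_schema <- function(schema, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    items = lapply(seq_len(nrow(schema$items)), function(i) as.list(schema$items[i, ])),
    freq_map = as.numeric(schema$freq_map),
    level_probs = as.numeric(schema$level_probs),
    portion_multipliers = as.numeric(schema$portion_multipliers),
    portion_grams = lapply(
      seq_len(nrow(schema$portion_grams)),
      function(i) as.list(schema$portion_grams[i, ])
    ),
    taste_items = lapply(
      seq_len(nrow(schema$taste_items)),
      function(i) as.list(schema$taste_items[i, ])
    ),
    taste_level_probs = as.numeric(schema$taste_level_probs),
    bmr_coefficients = lapply(
      seq_len(nrow(schema$bmr_coefficients)),
      function(i) as.list(schema$bmr_coefficients[i, ])
    )
  )
  yaml::write_yaml(meta, file.path(dir, "schema.yaml"))
  readr::write_csv(schema$composition, file.path(dir, "composition.csv"))
  invisible(dir)
}

#' @rdname write_ffq_schema
#' @export
read_ffq_schema <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "schema.yaml"))
  bind_rows_of_lists <- function(x) dplyr::bind_rows(lapply(x, tibble::as_tibble))
  composition <- readr::read_csv(
    file.path(dir, "composition.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  ffq_schema(
    items = bind_rows_of_lists(meta$items),
    freq_map = as.numeric(meta$freq_map),
    level_probs = as.numeric(meta$level_probs),
    portion_multipliers = as.numeric(meta$portion_multipliers),
    portion_grams = bind_rows_of_lists(meta$portion_grams),
    taste_items = bind_rows_of_lists(meta$taste_items),
    taste_level_probs = as.numeric(meta$taste_level_probs),
    composition = composition,
    bmr_coefficients = bind_rows_of_lists(meta$bmr_coefficients)
  )
}

#' @export
print.ffq_schema <- function(x, ...) {
  cat("<ffq_schema>\n")
  cat(sprintf("  items: %d across %d food groups\n", nrow(x$items), length(x$food_groups)))
  cat(sprintf(
    "  frequency map: %s intakes/day\n",
    paste(format(x$freq_map, trim = TRUE), collapse = ", ")
  ))
  cat(sprintf("  nutrients: %d (incl. energy_kcal)\n", length(x$nutrients)))
  cat(sprintf("  taste items: %s\n", paste(x$taste_items$item, collapse = ", ")))
  invisible(x)
}
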