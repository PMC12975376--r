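#' @keywords internal
ffq_item_cols <- function(schema) schema$items$item

taste_cols <- function(schema) paste0("taste_", schema$taste_items$item)

portion_cols <- function() paste0("portion_", c("staple", "protein", "vegetable"))

#' Validate FFQ answers against a schema
#'
#' Checks that the answer table has a `participant_id` column plus every
#' item, portion and taste column the schema declares, and that all present
#' (non-missing) answers lie within their declared ordinal ranges
#' (frequencies 1-9, portions 1-4, taste likings 1-6).
#'
#' @param ffq Tibble of raw answers, one row per participant.
#' @param schema An [ffq_schema()].
#' @return `ffq`, invisibly.
#' @export
validate_ffq <- function(ffq, schema) {
  needed <- c("participant_id", ffq_item_cols(schema), portion_cols(), taste_cols(schema))
  miss <- setdiff(needed, names(ffq))
  if (length(miss) > 0) {
    abort(paste0("FFQ table lacks columns: ", paste(head(miss, 5), collapse = ", ")))
  }
  rng_ok <- function(cols, lo, hi, what) {
    m <- as.matrix(ffq[cols])
    bad <- m < lo | m > hi
    if (any(bad, na.rm = TRUE)) {
      abort(sprintf("%s answers outside %d..%d found.", what, lo, hi))
    }
  }
  rng_ok(ffq_item_cols(schema), 1L, 9L, "Frequency")
  rng_ok(portion_cols(), 1L, 4L, "Portion")
  rng_ok(taste_cols(schema), 1L, 6L, "Taste")
  invisible(ffq)
}

#' Per-participant missing-answer fraction
#'
#' Fraction of the 108 frequency questions left unanswered. This is the
#' quantity the quality-control stage compares against its 10% threshold;
#' it is computed on the raw answers, before any imputation.
#'
#' @inheritParams validate_ffq
#' @return Tibble with `participant_id` and `missing_fraction`.
#' @export
missingness_fraction <- function(ffq, schema) {
  m <- as.matrix(ffq[ffq_item_cols(schema)])
  tibble::tibble(
    participant_id = ffq$participant_id,
    missing_fraction = rowMeans(is.na(m))
  )
}

#' Median-impute missing FFQ answers
#'
#' Replaces every missing frequency or taste answer with the per-question
#' median over the non-missing respondents. Medians falling between two
#' ordinal levels (even split) round down to the nearer valid level, so the
#' imputed value is always an observed answer category. Portion-photo
#' answers are never imputed: a missing portion indication is a
#' quality-control exclusion, not a gap to fill. Imputation is meant to run
#' after the missingness fractions have been recorded, so it cannot rescue a
#' record from the >=10%-missing exclusion.
#'
#' @inheritParams validate_ffq
#' @return The answer table with item and taste gaps filled.
#' @export
#' @examples
#' schema <- default_ffq_schema()
#' coh <- simulate_ffq_cohort(
#'   simulation_spec(0.4, 0.1, 0.5, 20, 20, missing_rate = 0.05, seed = 7),
#'   schema
#' )
#' imputed <- impute_missing(coh$ffq, schema)
#' anyNA(imputed[schema$items$item])  # FALSE
impute_missing <- function(ffq, schema) {
  cols <- c(ffq_item_cols(schema), taste_cols(schema))
  out <- ffq
  for (cl in cols) {
    v <- out[[cl]]
    if (anyNA(v)) {
      obs <- v[!is.na(v)]
      if (length(obs) == 0L) {
        abort(sprintf("Question `%s` is missing for every respondent; cannot impute.", cl))
      }
      v[is.na(v)] <- as.integer(floor(median(obs)))
      out[[cl]] <- v
    }
  }
  out
}

#' Convert frequency levels to daily intakes
#'
#' Maps each item's 9-level ordinal frequency answer through the schema's
#' monotone frequency map into intakes/day on the instrument's 0-4
#' intakes/day scale.
#'
#' @param ffq Imputed answer table (no missing frequency answers).
#' @param schema An [ffq_schema()].
#' @return Tibble: `participant_id` plus one intakes/day column per item.
#' @export
frequencies_to_daily <- function(ffq, schema) {
  cols <- ffq_item_cols(schema)
  m <- as.matrix(ffq[cols])
  if (anyNA(m)) abort("Frequency answers contain missing values; impute first.")
  if (any(m < 1 | m > 9)) abort("Frequency levels outside 1..9.")
  intakes <- matrix(schema$freq_map[m], nrow(m), ncol(m), dimnames = list(NULL, cols))
  dplyr::bind_cols(
    tibble::tibble(participant_id = ffq$participant_id),
    tibble::as_tibble(intakes)
  )
}

#' Aggregate item intakes to the 30 food groups
#'
#' Food-group intake is the plain sum of the member items' intakes/day.
#' Exactly 30 group columns are emitted, prefixed `fg_`, in the schema's
#' fixed group order.
#'
#' @param item_intakes Output of [frequencies_to_daily()].
#' @param schema An [ffq_schema()].
#' @return Tibble: `participant_id` plus 30 `fg_*` columns (intakes/day).
#' @export
aggregate_food_groups <- function(item_intakes, schema) {
  m <- as.matrix(item_intakes[ffq_item_cols(schema)])
  groups <- schema$food_groups
  agg <- vapply(
    groups,
    function(g) {
      members <- schema$items$item[schema$items$food_group == g]
      rowSums(m[, members, drop = FALSE])
    },
    numeric(nrow(m))
  )
  if (nrow(m) == 1L) agg <- matrix(agg, nrow = 1, dimnames = list(NULL, groups))
  colnames(agg) <- paste0("fg_", groups)
  dplyr::bind_cols(
    tibble::tibble(participant_id = item_intakes$participant_id),
    tibble::as_tibble(agg)
  )
}

age_band_of <- function(age) ifelse(age <= 30, "18-30", "31-60")

# n x 108 matrix of grams per intake for each participant x item:
# reference portion (sex, age band, item's plate class) x the participant's
# portion-photo multiplier for that class (classes without a photo get 1).
portion_grams_matrix <- function(ffq, participants, schema) {
  pp <- participants[match(ffq$participant_id, participants$participant_id), ]
  band <- age_band_of(pp$age)
  pg <- schema$portion_grams
  key <- paste(pg$sex, pg$age_band, pg$portion_class)
  g_lookup <- setNames(pg$grams, key)
  classes <- schema$items$portion_class
  n <- nrow(ffq)
  base <- matrix(0, n, 108)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    base[, idx] <- g_lookup[paste(pp$sex, band, cl)]
  }
  mult <- matrix(1, n, 108)
  for (cl in c("staple", "protein", "vegetable")) {
    ans <- ffq[[paste0("portion_", cl)]]
    idx <- which(classes == cl)
    if (length(idx) > 0) {
      mult[, idx] <- schema$portion_multipliers[ans]
    }
  }
  scale_m <- matrix(schema$items$gram_scale, n, 108, byrow = TRUE)
  base * mult * scale_m
}

#' Estimate daily energy and nutrient intakes
#'
#' Nutrient intake is the composition-weighted sum over items:
#' intakes/day x portion grams (sex- and age-band-specific reference portion
#' scaled by the participant's portion-photo multiplier) x per-gram nutrient
#' content. Energy is returned in kcal/day; other nutrients in the units of
#' the schema's composition columns (g, mg or ug per day).
#'
#' @param item_intakes Output of [frequencies_to_daily()].
#' @param ffq Answer table (for the portion-photo answers).
#' @param participants Participant table with `sex` and `age`.
#' @param schema An [ffq_schema()].
#' @return Tibble: `participant_id` plus one column per nutrient.
#' @export
estimate_nutrients <- function(item_intakes, ffq, participants, schema) {
  missing_p <- setdiff(ffq$participant_id, participants$participant_id)
  if (length(missing_p) > 0) {
    abort(paste0(
      "FFQ rows without a participant record: ",
      paste(head(missing_p, 5), collapse = ", ")
    ))
  }
  if (anyNA(as.matrix(ffq[portion_cols()]))) {
    abort("Portion-photo answers contain missing values; such records fail QC and must be removed first.")
  }
  intake <- as.matrix(item_intakes[ffq_item_cols(schema)])
  grams <- portion_grams_matrix(ffq, participants, schema)
  comp <- as.matrix(
    schema$composition[
      match(ffq_item_cols(schema), schema$composition$item),
      schema$nutrients
    ]
  )
  out <- (intake * grams) %*% comp
  dplyr::bind_cols(
    tibble::tibble(participant_id = item_intakes$participant_id),
    tibble::as_tibble(out)
  )
}

#' Impute missing body weight by sex-specific median
#'
#' @param participants Participant table with `sex` and `weight_kg`.
#' @return The table with `weight_kg` gaps filled by the median weight of
#'   the participant's sex.
#' @export
impute_weight <- function(participants) {
  participants |>
    dplyr::group_by(.data$sex) |>
    dplyr::mutate(
      weight_kg = ifelse(
        is.na(.data$weight_kg),
        median(.data$weight_kg, na.rm = TRUE),
        .data$weight_kg
      )
    ) |>
    dplyr::ungroup()
}

#' Compute intake profiles for a cohort
#'
#' Runs the full FFQ-to-intake chain: median imputation of item/taste
#' answers, frequency-to-daily conversion, food-group aggregation, nutrient
#' and energy estimation, BMI (weight / height^2, height in meters) and the
#' physical-activity-level proxy PAL = energy intake / Schofield-type basal
#' metabolic rate. Records with missing portion answers are carried through
#' with `NA` nutrient columns (they cannot be portion-weighted) and are
#' rejected by [apply_qc()].
#'
#' @param ffq Raw answer table.
#' @param participants Participant table.
#' @param schema An [ffq_schema()].
#' @return Tibble: `participant_id`, 30 `fg_*` food-group columns,
#'   nutrient columns (incl. `energy_kcal`), `pal`, `bmi`.
#' @export
intake_profiles <- function(ffq, participants, schema = default_ffq_schema()) {
  validate_ffq(ffq, schema)
  participants <- impute_weight(participants)
  imputed <- impute_missing(ffq, schema)
  daily <- frequencies_to_daily(imputed, schema)
  groups <- aggregate_food_groups(daily, schema)

  has_portions <- !apply(is.na(as.matrix(imputed[portion_cols()])), 1, any)
  nutr_cols <- schema$nutrients
  nutr <- tibble::as_tibble(
    matrix(
      NA_real_, nrow(ffq), length(nutr_cols),
      dimnames = list(NULL, nutr_cols)
    )
  )
  if (any(has_portions)) {
    sub <- estimate_nutrients(
      daily[has_portions, , drop = FALSE],
      imputed[has_portions, , drop = FALSE],
      participants, schema
    )
    nutr[has_portions, ] <- sub[nutr_cols]
  }

  pp <- participants[match(ffq$participant_id, participants$participant_id), ]
  bmr <- schema$bmr_coefficients
  bkey <- paste(bmr$sex, bmr$age_band)
  slope <- setNames(bmr$slope, bkey)[paste(pp$sex, age_band_of(pp$age))]
  icept <- setNames(bmr$intercept, bkey)[paste(pp$sex, age_band_of(pp$age))]
  bmr_kcal <- slope * pp$weight_kg + icept

  dplyr::bind_cols(
    groups,
    nutr,
    tibble::tibble(
      pal = unname(nutr$energy_kcal / bmr_kcal),
      bmi = pp$weight_kg / (pp$height_cm / 100)^2
    )
  )
}

#' Quality-control thresholds
#'
#' Plausibility bounds for dietary records: exclusion for >=10% missing
#' frequency answers, any missing portion indication, energy below 500 or
#' above 6000 kcal/day, PAL below 0.3 or above 4, or BMI below 15 or above
#' 140 kg/m^2. All bounds are strict: a record at exactly 500 kcal is
#' retained.
#'
#' @param energy_min,energy_max Energy bounds, kcal/day.
#' @param pal_min,pal_max PAL bounds.
#' @param bmi_min,bmi_max BMI bounds, kg/m^2.
#' @param missing_max Missing-answer fraction at or above which a record is
#'   excluded.
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(energy_min = 500, energy_max = 6000,
                          pal_min = 0.3, pal_max = 4,
                          bmi_min = 15, bmi_max = 140,
                          missing_max = 0.10) {
  list(
    energy_min = energy_min, energy_max = energy_max,
    pal_min = pal_min, pal_max = pal_max,
    bmi_min = bmi_min, bmi_max = bmi_max,
    missing_max = missing_max
  )
}

#' Apply quality control to a cohort
#'
#' Flags each participant against the plausibility screen and then removes
#' both members of any twin pair left incomplete by the individual-level
#' exclusions. Reason codes: `missingness` (>= 10% of the 108 frequency
#' questions unanswered), `portion_incomplete` (any missing portion-photo
#' answer), `energy` (< 500 or > 6000 kcal/day), `pal` (< 0.3 or > 4),
#' `bmi` (< 15 or > 140), `incomplete_pair`.
#'
#' @param ffq Raw answer table (pre-imputation: missingness is judged on the
#'   answers as given).
#' @param participants Participant table with `pair_id`.
#' @param profiles Output of [intake_profiles()].
#' @param thresholds A [qc_thresholds()] list.
#' @return An object of class `qc_report`: tibble with `participant_id`,
#'   `pass`, and `reasons` (semicolon-joined codes, `""` when passing),
#'   carrying the reason tally and threshold set as attributes.
#' @export
apply_qc <- function(ffq, participants, profiles, thresholds = qc_thresholds()) {
  missing_p <- setdiff(ffq$participant_id, participants$participant_id)
  if (length(missing_p) > 0) {
    abort(paste0(
      "FFQ rows without a participant record: ",
      paste(head(missing_p, 5), collapse = ", ")
    ))
  }
  mf <- missingness_fraction(ffq, default_schema_like(ffq, profiles))
  # missingness judged on the item columns present in `ffq`; use profiles for
  # derived quantities
  prof <- profiles[match(ffq$participant_id, profiles$participant_id), ]
  reasons <- vector("list", nrow(ffq))
  add <- function(reasons, flag, code) {
    idx <- which(flag)
    for (i in idx) reasons[[i]] <- c(reasons[[i]], code)
    reasons
  }
  th <- thresholds
  portion_missing <- apply(is.na(as.matrix(ffq[portion_cols()])), 1, any)
  energy <- prof$energy_kcal
  reasons <- add(reasons, mf$missing_fraction >= th$missing_max, "missingness")
  reasons <- add(reasons, portion_missing, "portion_incomplete")
  reasons <- add(
    reasons,
    !is.na(energy) & (energy < th$energy_min | energy > th$energy_max),
    "energy"
  )
  reasons <- add(
    reasons,
    !is.na(prof$pal) & (prof$pal < th$pal_min | prof$pal > th$pal_max),
    "pal"
  )
  reasons <- add(
    reasons,
    !is.na(prof$bmi) & (prof$bmi < th$bmi_min | prof$bmi > th$bmi_max),
    "bmi"
  )
  indiv_pass <- vapply(reasons, is.null, logical(1))

  # pair completion: both co-twins must individually pass
  pp <- participants[match(ffq$participant_id, participants$participant_id), ]
  pass_by_pair <- tapply(indiv_pass, pp$pair_id, sum)
  pair_n <- tapply(rep(1L, nrow(pp)), pp$pair_id, sum)
  complete <- names(pass_by_pair)[pass_by_pair == 2 & pair_n == 2]
  pair_ok <- pp$pair_id %in% complete
  reasons <- add(reasons, indiv_pass & !pair_ok, "incomplete_pair")
  pass <- indiv_pass & pair_ok

  report <- tibble::tibble(
    participant_id = ffq$participant_id,
    pass = pass,
    reasons = vapply(
      reasons,
      function(r) paste(r, collapse = ";"),
      character(1)
    )
  )
  all_codes <- c(
    "missingness", "portion_incomplete", "energy", "pal", "bmi",
    "incomplete_pair"
  )
  tally <- vapply(
    all_codes,
    function(code) sum(vapply(reasons, function(r) code %in% r, logical(1))),
    integer(1)
  )
  structure(
    report,
    class = c("qc_report", class(report)),
    reason_counts = tally,
    thresholds = th,
    n_individual_fail = sum(!indiv_pass)
  )
}

# apply_qc only needs the item columns; reconstruct a minimal schema-like
# object for missingness_fraction from the ffq columns themselves.
default_schema_like <- function(ffq, profiles) {
  item_cols <- setdiff(
    names(ffq),
    c("participant_id", portion_cols(), grep("^taste_", names(ffq), value = TRUE))
  )
  list(items = tibble::tibble(item = item_cols))
}

#' QC waterfall summary
#'
#' Reconciling count table for a [apply_qc()] report: input records, counts
#' per exclusion reason (a record can carry several), records excluded, and
#' records retained. `input = retained + excluded` always holds.
#'
#' @param report A `qc_report`.
#' @return A tibble of labelled counts.
#' @export
qc_waterfall <- function(report) {
  counts <- attr(report, "reason_counts")
  tibble::tibble(
    step = c("input", names(counts), "excluded", "retained"),
    n = c(
      nrow(report),
      as.integer(counts),
      sum(!report$pass),
      sum(report$pass)
    )
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  print(qc_waterfall(x), n = Inf)
  invisible(x)
}
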