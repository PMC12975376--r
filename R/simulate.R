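#' Specify a synthetic twin-cohort simulation
#'
#' A `simulation_spec` fixes the generating conditions of a synthetic twin
#' cohort: the ACE variance fractions of the latent dietary traits, the
#' number of monozygotic (MZ) and dizygotic (DZ) complete pairs, covariate
#' effects on the latent healthy-diet trait, the item-level missingness rate,
#' and the fraction of records made deliberately implausible so the
#' quality-control stage has something to reject.
#'
#' Under the classical twin model MZ co-twins share all additive-genetic
#' variance while DZ co-twins share half of it (genetic correlation fixed at
#' 0.5); both share the common-environment component fully. The generator
#' follows that path construction exactly.
#'
#' @param a2,c2,e2 Additive-genetic, shared-environment and
#'   nonshared-environment variance fractions; must be nonnegative and sum
#'   to 1.
#' @param n_mz_pairs,n_dz_pairs Number of complete MZ / DZ pairs.
#' @param covariate_effects Named list of linear effects on the latent
#'   healthy-diet trait; supported names: `sex` (added for females) and
#'   `weight` (per standardized kg).
#' @param missing_rate Fraction of item/taste answers blanked at random, in
#'   `[0, 1)`.
#' @param implausible_fraction Fraction of participants whose FFQ answers are
#'   replaced by extreme patterns that fail the energy plausibility bounds
#'   (half report essentially nothing, half report everything at maximum).
#' @param bmi_outlier_fraction Fraction of participants given height/weight
#'   that put their BMI outside the plausible 15-140 kg/m^2 window.
#' @param prop_female Proportion of female individuals (default 0.595, the
#'   cohort composition the generator emulates). MZ pairs are always
#'   same-sex; DZ pairs mix same- and opposite-sex.
#' @param seed Integer seed; every simulation is a pure function of the spec.
#' @return An object of class `simulation_spec`.
#' @export
#' @examples
#' spec <- simulation_spec(a2 = 0.5, c2 = 0, e2 = 0.5,
#'                         n_mz_pairs = 100, n_dz_pairs = 200, seed = 1)
simulation_spec <- function(a2, c2, e2, n_mz_pairs, n_dz_pairs,
                            covariate_effects = list(),
                            missing_rate = 0,
                            implausible_fraction = 0,
                            bmi_outlier_fraction = 0,
                            prop_female = 0.595,
                            seed = 1L) {
  for (nm in c("a2", "c2", "e2")) stopifnot_scalar_number(get(nm), nm)
  if (a2 < 0 || c2 < 0 || e2 < 0 || abs(a2 + c2 + e2 - 1) > 1e-12) {
    abort("Variance fractions a2, c2, e2 must be nonnegative and sum to 1 (within 1e-12).")
  }
  if (n_mz_pairs < 0 || n_dz_pairs < 0) abort("Pair counts must be nonnegative.")
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate must be in [0, 1).")
  if (implausible_fraction < 0 || implausible_fraction > 1 ||
      bmi_outlier_fraction < 0 || bmi_outlier_fraction > 1) {
    abort("Implausible fractions must be in [0, 1].")
  }
  bad <- setdiff(names(covariate_effects), c("sex", "weight"))
  if (length(bad) > 0) {
    abort(paste0("Unsupported covariate effects: ", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      a2 = a2, c2 = c2, e2 = e2,
      n_mz_pairs = as.integer(n_mz_pairs),
      n_dz_pairs = as.integer(n_dz_pairs),
      covariate_effects = covariate_effects,
      missing_rate = missing_rate,
      implausible_fraction = implausible_fraction,
      bmi_outlier_fraction = bmi_outlier_fraction,
      prop_female = prop_female,
      seed = as.integer(seed)
    ),
    class = "simulation_spec"
  )
}

# Draw one ACE-structured latent trait for a cohort laid out as complete
# pairs. MZ co-twins share the full additive-genetic deviate; DZ co-twins'
# genetic deviates correlate 0.5, built as sqrt(.5) * shared + sqrt(.5) *
# unique. Values are in pair-major order (twin 1, twin 2 alternating).
draw_ace_trait <- function(a2, c2, e2, n_mz, n_dz) {
  sa <- sqrt(a2); sc <- sqrt(c2); se <- sqrt(e2)
  mz_a <- rnorm(n_mz); mz_c <- rnorm(n_mz)
  mz1 <- sa * mz_a + sc * mz_c + se * rnorm(n_mz)
  mz2 <- sa * mz_a + sc * mz_c + se * rnorm(n_mz)
  dz_as <- rnorm(n_dz); dz_c <- rnorm(n_dz)
  s5 <- sqrt(0.5)
  dz1 <- sa * (s5 * dz_as + s5 * rnorm(n_dz)) + sc * dz_c + se * rnorm(n_dz)
  dz2 <- sa * (s5 * dz_as + s5 * rnorm(n_dz)) + sc * dz_c + se * rnorm(n_dz)
  list(mz1 = mz1, mz2 = mz2, dz1 = dz1, dz2 = dz2)
}

#' Simulate paired latent trait values under an ACE model
#'
#' Draws one standardized quantitative trait for a cohort of complete twin
#' pairs with the ACE structure fixed by the spec: within-pair covariance
#' `a2 + c2` for MZ pairs and `0.5 * a2 + c2` for DZ pairs, unit marginal
#' variance in expectation. Deterministic given `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return A tibble with columns `pair_id`, `zygosity` (`"MZ"`/`"DZ"`),
#'   `twin1`, `twin2`.
#' @export
#' @examples
#' spec <- simulation_spec(0.6, 0.2, 0.2, 500, 500, seed = 42)
#' pairs <- simulate_trait_pairs(spec)
#' cor(pairs$twin1[pairs$zygosity == "MZ"], pairs$twin2[pairs$zygosity == "MZ"])
simulate_trait_pairs <- function(spec) {
  if (!inherits(spec, "simulation_spec")) abort("`spec` must be a simulation_spec.")
  with_preserved_seed(spec$seed, {
    tr <- draw_ace_trait(spec$a2, spec$c2, spec$e2, spec$n_mz_pairs, spec$n_dz_pairs)
    tibble::tibble(
      pair_id = c(
        sprintf("MZ%05d", seq_len(spec$n_mz_pairs)),
        sprintf("DZ%05d", seq_len(spec$n_dz_pairs))
      ),
      zygosity = rep(c("MZ", "DZ"), c(spec$n_mz_pairs, spec$n_dz_pairs)),
      twin1 = c(tr$mz1, tr$dz1),
      twin2 = c(tr$mz2, tr$dz2)
    )
  })
}

# Matrix of k iid ACE-structured latent columns for a pair-major cohort:
# every column has the spec's variance fractions; co-twin sharing follows the
# MZ/DZ relatedness (1.0 / 0.5 genetic correlation, full C sharing).
draw_ace_matrix <- function(a2, c2, e2, n_mz, n_dz, k) {
  sa <- sqrt(a2); sc <- sqrt(c2); se <- sqrt(e2); s5 <- sqrt(0.5)
  rm_ <- function(nr) matrix(rnorm(nr * k), nr, k)
  mz_a <- rm_(n_mz); mz_c <- rm_(n_mz)
  mz1 <- sa * mz_a + sc * mz_c + se * rm_(n_mz)
  mz2 <- sa * mz_a + sc * mz_c + se * rm_(n_mz)
  dz_a <- rm_(n_dz); dz_c <- rm_(n_dz)
  dz1 <- sa * (s5 * dz_a + s5 * rm_(n_dz)) + sc * dz_c + se * rm_(n_dz)
  dz2 <- sa * (s5 * dz_a + s5 * rm_(n_dz)) + sc * dz_c + se * rm_(n_dz)
  interleave <- function(m1, m2) {
    out <- matrix(0, 2 * nrow(m1), k)
    if (nrow(m1) > 0) {
      out[seq(1, 2 * nrow(m1), by = 2), ] <- m1
      out[seq(2, 2 * nrow(m1), by = 2), ] <- m2
    }
    out
  }
  rbind(interleave(mz1, mz2), interleave(dz1, dz2))
}

# Latent loading of the healthy-diet trait on each food group: positive for
# groups a health-conscious eater reports more of, negative for groups they
# report less of, small for neutral groups. Drives realistic cross-item
# correlation; item-level residual noise tops the latent variance up to 1.
diet_group_loadings <- function() {
  c(
    vegetables = 0.55, potatoes = 0.10, fruits_berries = 0.55,
    fruit_juice = 0.15, legumes = 0.50, nuts_seeds = 0.45,
    whole_grains = 0.50, refined_grains = -0.25, breakfast_cereals = 0.20,
    fish_shellfish = 0.40, red_meat = -0.35, processed_meat = -0.45,
    poultry = 0.10, venison = 0.15, eggs = 0.10, dairy_products = 0.05,
    cheese = -0.05, plant_milk_substitutes = 0.30, vegetable_oils = 0.35,
    butter_margarine = -0.20, sweets_chocolate = -0.50, desserts = -0.45,
    ice_cream = -0.35, snacks = -0.50, sugar_sweetened_beverages = -0.55,
    coffee = 0.05, tea = 0.15, water = 0.25, alcoholic_beverages = -0.15,
    ready_meals = -0.40
  )
}

#' Simulate a full synthetic FFQ twin cohort
#'
#' Generates a complete-pair twin cohort with participant records (sex, age,
#' height, weight), latent ACE-structured healthy-diet and taste traits, and
#' item-level FFQ responses: each item's 9-level ordinal frequency comes from
#' cutting a latent Gaussian (loading on the healthy-diet trait per food
#' group, plus item noise and covariate shifts) at the schema's marginal
#' level thresholds. Taste-liking answers are generated the same way from
#' bitter/sweet/sour latent traits on a 6-level scale. A configurable
#' fraction of records is made implausible (to exercise the energy QC
#' bounds) or given an out-of-bounds BMI, and answers are blanked at the
#' spec's missing rate. Ground-truth labels for every manipulated record are
#' returned in `truth` so tests can assert QC decisions exactly.
#'
#' @param spec A [simulation_spec()].
#' @param schema An [ffq_schema()]; defaults to the packaged schema.
#' @return An object of class `twin_cohort`: a list with `participants`
#'   (tibble), `ffq` (tibble of ordinal answers, one row per participant),
#'   `latent_traits` (tibble of the generating trait values) and `truth`
#'   (spec plus ground-truth label sets).
#' @export
simulate_ffq_cohort <- function(spec, schema = default_ffq_schema()) {
  if (!inherits(spec, "simulation_spec")) abort("`spec` must be a simulation_spec.")
  validate_ffq_schema(schema)
  with_preserved_seed(spec$seed + 1L, {
    n_mz <- spec$n_mz_pairs
    n_dz <- spec$n_dz_pairs
    n_pairs <- n_mz + n_dz
    n <- 2L * n_pairs
    pair_id <- c(
      rep(sprintf("MZ%05d", seq_len(n_mz)), each = 2),
      rep(sprintf("DZ%05d", seq_len(n_dz)), each = 2)
    )
    zygosity <- rep(c("MZ", "DZ"), c(2 * n_mz, 2 * n_dz))
    # MZ: sex assigned at pair level (always same-sex); DZ: per individual,
    # yielding a mix of same- and opposite-sex pairs.
    sex_mz <- rep(ifelse(runif(n_mz) < spec$prop_female, "F", "M"), each = 2)
    sex_dz <- ifelse(runif(2 * n_dz) < spec$prop_female, "F", "M")
    sex <- c(sex_mz, sex_dz)
    age <- pmax(18, pmin(30, round(rnorm(n, 24, 1.2))))
    height_cm <- ifelse(sex == "M", rnorm(n, 180, 7), rnorm(n, 167, 6.5))
    weight_kg <- ifelse(sex == "M", rnorm(n, 80, 12), rnorm(n, 66, 11))
    # keep unflagged records safely inside the plausible BMI window
    weight_kg <- pmin(pmax(weight_kg, 17 * (height_cm / 100)^2),
                      40 * (height_cm / 100)^2)
    participants <- tibble::tibble(
      participant_id = sprintf("P%05d", seq_len(n)),
      pair_id = pair_id,
      zygosity = zygosity,
      sex = sex,
      age = age,
      height_cm = round(height_cm, 1),
      weight_kg = round(weight_kg, 1)
    )

    # Latent ACE traits in the same pair-major order as `participants`
    pairwise <- function() {
      tr <- draw_ace_trait(spec$a2, spec$c2, spec$e2, n_mz, n_dz)
      c(rbind(tr$mz1, tr$mz2), rbind(tr$dz1, tr$dz2))
    }
    z_diet <- pairwise()
    z_bitter <- pairwise()
    z_sweet <- pairwise()
    z_sour <- pairwise()

    eff <- spec$covariate_effects
    eta <- z_diet +
      (eff$sex %||% 0) * (sex == "F") +
      (eff$weight %||% 0) * as.numeric(scale(weight_kg))
    # winsorize the latent diet propensity so unmanipulated records cannot
    # drift past the energy plausibility bounds by chance
    eta <- pmin(pmax(eta, -1.6), 1.9)

    # FFQ item levels: latent x_ij = lambda_g * eta_i + sqrt(1-lambda^2) eps,
    # cut at the schema's marginal thresholds.
    thresholds <- qnorm(cumsum(schema$level_probs))[1:8]
    loadings <- diet_group_loadings()[schema$items$food_group]
    lam <- matrix(loadings, nrow = n, ncol = 108, byrow = TRUE)
    # item-specific propensities carry the same ACE structure as the shared
    # trait, so every item (and any aggregate of items) has the spec's
    # variance fractions; the loading only controls cross-item correlation
    eps_items <- draw_ace_matrix(spec$a2, spec$c2, spec$e2, n_mz, n_dz, 108)
    x <- lam * eta + sqrt(1 - lam^2) * eps_items
    levels_mat <- matrix(
      findInterval(x, thresholds) + 1L,
      n, 108
    )
    colnames(levels_mat) <- schema$items$item

    # Portion-photo answers per plate class
    portion_classes <- c("staple", "protein", "vegetable")
    portions <- vapply(
      portion_classes,
      function(cl) sample(1:4, n, replace = TRUE, prob = c(0.2, 0.4, 0.3, 0.1)),
      integer(n)
    )
    colnames(portions) <- paste0("portion_", portion_classes)

    # Taste ratings: 2 items per class on a 6-level scale
    t_thresholds <- qnorm(cumsum(schema$taste_level_probs))[1:5]
    taste_latent <- list(
      bitter = z_bitter, sweet = z_sweet, sour = z_sour
    )
    taste_mat <- matrix(
      NA_integer_, n, 6,
      dimnames = list(NULL, paste0("taste_", schema$taste_items$item))
    )
    eps_taste <- draw_ace_matrix(spec$a2, spec$c2, spec$e2, n_mz, n_dz, 6)
    for (k in seq_len(6)) {
      cls <- schema$taste_items$taste_class[k]
      lt <- 0.7 * taste_latent[[cls]] + sqrt(1 - 0.49) * eps_taste[, k]
      taste_mat[, k] <- findInterval(lt, t_thresholds) + 1L
    }

    # Implausible records: half report (almost) nothing -> energy < 500 kcal,
    # half report everything at the top level -> energy > 6000 kcal.
    n_impl <- floor(spec$implausible_fraction * n)
    impl_idx <- if (n_impl > 0) sort(sample.int(n, n_impl)) else integer(0)
    low_idx <- impl_idx[seq_len(ceiling(length(impl_idx) / 2))]
    high_idx <- setdiff(impl_idx, low_idx)
    if (length(low_idx) > 0) levels_mat[low_idx, ] <- 1L
    if (length(high_idx) > 0) {
      levels_mat[high_idx, ] <- 9L
      portions[high_idx, ] <- 4L
    }

    # BMI outliers: grossly inconsistent height/weight
    n_bmi <- floor(spec$bmi_outlier_fraction * n)
    bmi_idx <- if (n_bmi > 0) {
      sort(sample(setdiff(seq_len(n), impl_idx), n_bmi))
    } else {
      integer(0)
    }
    if (length(bmi_idx) > 0) {
      participants$height_cm[bmi_idx] <- 100
      participants$weight_kg[bmi_idx] <- 200
    }

    # Item-level missingness (frequency + taste answers; portion answers are
    # left intact so missingness and portion-completeness QC stay separable)
    high_missing_idx <- integer(0)
    if (spec$missing_rate > 0) {
      miss_f <- matrix(runif(n * 108) < spec$missing_rate, n, 108)
      levels_mat[miss_f] <- NA_integer_
      miss_t <- matrix(runif(n * 6) < spec$missing_rate, n, 6)
      taste_mat[miss_t] <- NA_integer_
      # records that crossed the 10%-missing QC threshold are ground truth too
      high_missing_idx <- which(rowMeans(miss_f) >= 0.10)
    }

    # Nudge unmanipulated records back inside the plausibility window: item
    # noise and portion multipliers can otherwise push a legitimate record
    # across the energy/PAL screening bounds, which would make the QC
    # ground-truth labels ambiguous. Energy is evaluated exactly as the
    # processing stage will see it (median-imputed answers); offending
    # records have their observed item levels shifted one step at a time
    # until energy sits in a margin well inside the bounds (620-5400 kcal,
    # tightened per person so PAL stays inside 0.3-4 too).
    pg <- schema$portion_grams
    g_lookup <- setNames(pg$grams, paste(pg$sex, pg$age_band, pg$portion_class))
    band <- ifelse(age <= 30, "18-30", "31-60")
    item_classes <- schema$items$portion_class
    base_g <- matrix(0, n, 108)
    for (cl in unique(item_classes)) {
      idx <- which(item_classes == cl)
      base_g[, idx] <- g_lookup[paste(sex, band, cl)]
    }
    mult_g <- matrix(1, n, 108)
    for (cl in c("staple", "protein", "vegetable")) {
      idx <- which(item_classes == cl)
      mult_g[, idx] <- schema$portion_multipliers[portions[, paste0("portion_", cl)]]
    }
    e_density <- schema$composition$energy_kcal[
      match(schema$items$item, schema$composition$item)
    ]
    g2 <- base_g * mult_g *
      matrix(schema$items$gram_scale * e_density, n, 108, byrow = TRUE)
    bmrc <- schema$bmr_coefficients
    bkey <- paste(bmrc$sex, bmrc$age_band)
    wt <- participants$weight_kg
    bmr <- setNames(bmrc$slope, bkey)[paste(sex, band)] * wt +
      setNames(bmrc$intercept, bkey)[paste(sex, band)]
    lo_e <- pmax(620, 0.33 * bmr)
    hi_e <- pmin(5400, 3.8 * bmr)
    clean <- setdiff(seq_len(n), c(impl_idx, high_missing_idx))
    impute_levels <- function(m) {
      for (j in seq_len(ncol(m))) {
        v <- m[, j]
        if (anyNA(v)) m[is.na(v), j] <- as.integer(floor(median(v, na.rm = TRUE)))
      }
      m
    }
    for (iter in 1:12) {
      energy <- rowSums(
        matrix(schema$freq_map[impute_levels(levels_mat)], n, 108) * g2
      )
      high <- intersect(clean, which(energy > hi_e))
      low <- intersect(clean, which(energy < lo_e))
      if (length(high) == 0 && length(low) == 0) break
      levels_mat[high, ] <- pmax(levels_mat[high, , drop = FALSE] - 1L, 1L)
      levels_mat[low, ] <- pmin(levels_mat[low, , drop = FALSE] + 1L, 9L)
    }

    ffq <- dplyr::bind_cols(
      tibble::tibble(participant_id = participants$participant_id),
      tibble::as_tibble(levels_mat),
      tibble::as_tibble(portions),
      tibble::as_tibble(taste_mat)
    )

    structure(
      list(
        participants = participants,
        ffq = ffq,
        latent_traits = tibble::tibble(
          participant_id = participants$participant_id,
          diet = z_diet, bitter = z_bitter, sweet = z_sweet, sour = z_sour
        ),
        truth = list(
          spec = spec,
          implausible_low_ids = participants$participant_id[low_idx],
          implausible_high_ids = participants$participant_id[high_idx],
          bmi_outlier_ids = participants$participant_id[bmi_idx],
          high_missing_ids = participants$participant_id[high_missing_idx],
          qc_expected_fail_ids = participants$participant_id[
            sort(unique(c(impl_idx, bmi_idx, high_missing_idx)))
          ]
        )
      ),
      class = "twin_cohort"
    )
  })
}

#' @export
print.twin_cohort <- function(x, ...) {
  n <- nrow(x$participants)
  cat("<twin_cohort>\n")
  cat(sprintf(
    "  %d participants in %d pairs (%d MZ, %d DZ); %.1f%% female\n",
    n, n / 2,
    sum(x$participants$zygosity == "MZ") / 2,
    sum(x$participants$zygosity == "DZ") / 2,
    100 * mean(x$participants$sex == "F")
  ))
  cat(sprintf(
    "  truth: a2=%.2f c2=%.2f e2=%.2f, %d flagged implausible\n",
    x$truth$spec$a2, x$truth$spec$c2, x$truth$spec$e2,
    length(x$truth$qc_expected_fail_ids)
  ))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Persists the participant table and FFQ answer table as CSV, plus a
#' `truth.yaml` sidecar recording the generating spec and ground-truth label
#' sets.
#'
#' @param cohort A `twin_cohort` from [simulate_ffq_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$participants, file.path(dir, "participants.csv"))
  readr::write_csv(cohort$ffq, file.path(dir, "ffq.csv"))
  spec <- cohort$truth$spec
  yaml::write_yaml(
    list(
      spec = list(
        a2 = spec$a2, c2 = spec$c2, e2 = spec$e2,
        n_mz_pairs = spec$n_mz_pairs, n_dz_pairs = spec$n_dz_pairs,
        missing_rate = spec$missing_rate,
        implausible_fraction = spec$implausible_fraction,
        bmi_outlier_fraction = spec$bmi_outlier_fraction,
        prop_female = spec$prop_female,
        seed = spec$seed
      ),
      implausible_low_ids = as.list(cohort$truth$implausible_low_ids),
      implausible_high_ids = as.list(cohort$truth$implausible_high_ids),
      bmi_outlier_ids = as.list(cohort$truth$bmi_outlier_ids)
    ),
    file.path(dir, "truth.yaml")
  )
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `participants.csv` and `ffq.csv`.
#' @return A list with tibbles `participants` and `ffq`.
#' @export
read_cohort <- function(dir) {
  list(
    participants = readr::read_csv(
      file.path(dir, "participants.csv"),
      show_col_types = FALSE, progress = FALSE
    ),
    ffq = readr::read_csv(
      file.path(dir, "ffq.csv"),
      show_col_types = FALSE, progress = FALSE
    )
  )
}
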