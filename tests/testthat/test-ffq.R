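schema <- default_ffq_schema()

small_cohort <- function(seed = 21, n_mz = 30, n_dz = 30, ...) {
  simulate_ffq_cohort(simulation_spec(0.5, 0.1, 0.4, n_mz, n_dz, seed = seed, ...), schema)
}

test_that("default schema satisfies the questionnaire structure", {
  expect_equal(nrow(schema$items), 108L)
  expect_equal(length(unique(schema$items$food_group)), 30L)
  expect_equal(length(schema$freq_map), 9L)
  expect_equal(schema$freq_map[1], 0)   # "never" level
  expect_equal(schema$freq_map[9], 4)   # printed ceiling, intakes/day
  expect_false(is.unsorted(schema$freq_map))
  expect_equal(nrow(schema$taste_items), 6L)
  expect_equal(
    sort(as.integer(table(schema$taste_items$taste_class))),
    c(2L, 2L, 2L)
  )
  expect_gte(length(schema$nutrients), 40L)
})

test_that("schema round-trips through its plain-text format", {
  d <- withr::local_tempdir()
  write_ffq_schema(schema, d)
  back <- read_ffq_schema(d)
  expect_equal(back$items, schema$items)
  expect_equal(back$freq_map, schema$freq_map)
  expect_equal(as.data.frame(back$composition), as.data.frame(schema$composition),
               tolerance = 1e-12)
})

test_that("median imputation matches a sort-based oracle and is identity on complete data", {
  coh <- small_cohort(seed = 22, n_mz = 51, n_dz = 0)  # 102 respondents
  ffq <- coh$ffq
  # blank one question for 51 respondents, leaving an odd 51 observed
  item <- schema$items$item[17]
  ffq[[item]][1:51] <- NA_integer_
  observed <- ffq[[item]][52:nrow(ffq)]
  oracle <- sort(observed)[(length(observed) + 1) / 2]  # middle of a sorted odd set
  imp <- impute_missing(ffq, schema)
  expect_true(all(imp[[item]][1:51] == oracle))
  # identity when nothing is missing
  coh2 <- small_cohort(seed = 23)
  expect_identical(impute_missing(coh2$ffq, schema), coh2$ffq)
})

test_that("imputation rounds half-level medians down and errors on all-missing questions", {
  coh <- small_cohort(seed = 24, n_mz = 2, n_dz = 0)
  ffq <- coh$ffq
  item <- schema$items$item[1]
  # even split {2, 2, 4, missing} -> median 2 ; {2, 4, ...} half-level cases
  ffq[[item]] <- c(2L, 3L, NA_integer_, NA_integer_)[seq_len(nrow(ffq))]
  imp <- impute_missing(ffq, schema)
  expect_equal(imp[[item]][is.na(ffq[[item]])], rep(2L, sum(is.na(ffq[[item]]))))
  ffq[[item]] <- NA_integer_
  expect_error(impute_missing(ffq, schema), "missing for every respondent")
})

test_that("frequency-to-daily conversion is a table lookup with range checks", {
  coh <- small_cohort(seed = 25, n_mz = 2, n_dz = 2)
  ffq <- impute_missing(coh$ffq, schema)
  daily <- frequencies_to_daily(ffq, schema)
  # table-lookup oracle on the full record
  for (i in 1:2) {
    expect_equal(
      as.numeric(daily[i, schema$items$item]),
      schema$freq_map[as.integer(ffq[i, schema$items$item])]
    )
  }
  bad <- ffq
  bad[[schema$items$item[5]]][1] <- 12L
  expect_error(frequencies_to_daily(bad, schema), "1..9")
})

test_that("food-group aggregation conserves mass and sums member items", {
  coh <- small_cohort(seed = 26)
  daily <- frequencies_to_daily(impute_missing(coh$ffq, schema), schema)
  groups <- aggregate_food_groups(daily, schema)
  expect_equal(sum(grepl("^fg_", names(groups))), 30L)
  # mass conservation for every record
  expect_equal(
    rowSums(as.matrix(groups[paste0("fg_", schema$food_groups)])),
    rowSums(as.matrix(daily[schema$items$item])),
    tolerance = 1e-12
  )
  # hand sum: first three items of one group
  g <- schema$food_groups[1]
  members <- schema$items$item[schema$items$food_group == g]
  expect_equal(
    groups[[paste0("fg_", g)]],
    rowSums(as.matrix(daily[members])),
    tolerance = 1e-12
  )
})

test_that("nutrient estimation equals an independent per-item product sum", {
  coh <- small_cohort(seed = 27, n_mz = 3, n_dz = 3)
  ffq <- impute_missing(coh$ffq, schema)
  daily <- frequencies_to_daily(ffq, schema)
  nutr <- estimate_nutrients(daily, ffq, coh$participants, schema)
  # loop-based oracle for two participants and three nutrients
  pg <- schema$portion_grams
  for (i in c(1, 4)) {
    p <- coh$participants[coh$participants$participant_id == ffq$participant_id[i], ]
    band <- if (p$age <= 30) "18-30" else "31-60"
    for (nut in c("energy_kcal", "protein_g", "calcium_mg")) {
      total <- 0
      for (j in seq_len(108)) {
        it <- schema$items[j, ]
        grams <- pg$grams[pg$sex == p$sex & pg$age_band == band &
                            pg$portion_class == it$portion_class]
        mult <- if (it$portion_class %in% c("staple", "protein", "vegetable")) {
          schema$portion_multipliers[ffq[[paste0("portion_", it$portion_class)]][i]]
        } else {
          1
        }
        dens <- schema$composition[[nut]][schema$composition$item == it$item]
        total <- total + daily[[it$item]][i] * grams * mult * it$gram_scale * dens
      }
      expect_equal(nutr[[nut]][i], total, tolerance = 1e-9)
    }
  }
  # zero intakes give zero everything
  zero <- daily
  zero[schema$items$item] <- 0
  nz <- estimate_nutrients(zero, ffq, coh$participants, schema)
  expect_true(all(as.matrix(nz[schema$nutrients]) == 0))
})

test_that("raising a frequency level never decreases group or nutrient intakes", {
  coh <- small_cohort(seed = 28, n_mz = 2, n_dz = 2)
  ffq <- impute_missing(coh$ffq, schema)
  item <- schema$items$item[40]
  lower <- ffq; lower[[item]][1] <- 3L
  higher <- ffq; higher[[item]][1] <- 8L
  d_lo <- frequencies_to_daily(lower, schema)
  d_hi <- frequencies_to_daily(higher, schema)
  g_lo <- aggregate_food_groups(d_lo, schema)
  g_hi <- aggregate_food_groups(d_hi, schema)
  n_lo <- estimate_nutrients(d_lo, lower, coh$participants, schema)
  n_hi <- estimate_nutrients(d_hi, higher, coh$participants, schema)
  expect_true(all(as.matrix(g_hi[-1]) - as.matrix(g_lo[-1]) >= -1e-12))
  expect_true(all(as.matrix(n_hi[-1]) - as.matrix(n_lo[-1]) >= -1e-12))
})

test_that("QC applies the printed plausibility bounds with strict inequalities", {
  coh <- small_cohort(seed = 29, n_mz = 10, n_dz = 10)
  prof <- intake_profiles(coh$ffq, coh$participants, schema)
  # energy exactly at the lower bound is retained; just below is excluded
  prof_edge <- prof
  prof_edge$energy_kcal[1] <- 500
  prof_edge$pal[1] <- 0.5
  qc <- apply_qc(coh$ffq, coh$participants, prof_edge)
  expect_false(grepl("energy", qc$reasons[1]))
  prof_edge$energy_kcal[1] <- 499.99
  qc2 <- apply_qc(coh$ffq, coh$participants, prof_edge)
  expect_true(grepl("energy", qc2$reasons[1]))
  # a record with 11 of 108 items missing (10.2%) fails the missingness rule
  ffq_miss <- coh$ffq
  ffq_miss[1, schema$items$item[1:11]] <- NA_integer_
  qc3 <- apply_qc(ffq_miss, coh$participants, prof)
  expect_true(grepl("missingness", qc3$reasons[1]))
  # 10 of 108 (9.3%) does not
  ffq_miss2 <- coh$ffq
  ffq_miss2[1, schema$items$item[1:10]] <- NA_integer_
  qc4 <- apply_qc(ffq_miss2, coh$participants, prof)
  expect_false(grepl("missingness", qc4$reasons[1]))
})

test_that("QC excludes exactly the generator-labelled records and their co-twins", {
  coh <- small_cohort(
    seed = 30, n_mz = 150, n_dz = 150,
    implausible_fraction = 0.02, bmi_outlier_fraction = 0.01,
    missing_rate = 0.02
  )
  prof <- intake_profiles(coh$ffq, coh$participants, schema)
  qc <- apply_qc(coh$ffq, coh$participants, prof)
  indiv_fail <- qc$participant_id[!qc$pass & qc$reasons != "incomplete_pair"]
  expect_setequal(indiv_fail, coh$truth$qc_expected_fail_ids)
  # pair completion: every excluded id's co-twin is gone too
  pp <- coh$participants
  retained_pairs <- pp$pair_id[pp$participant_id %in% qc$participant_id[qc$pass]]
  expect_true(all(table(retained_pairs) == 2))
  # waterfall reconciles
  wf <- qc_waterfall(qc)
  expect_equal(
    wf$n[wf$step == "input"],
    wf$n[wf$step == "retained"] + wf$n[wf$step == "excluded"]
  )
})

test_that("clean cohorts pass QC completely and QC is idempotent", {
  coh <- small_cohort(seed = 31, n_mz = 50, n_dz = 50)
  prof <- intake_profiles(coh$ffq, coh$participants, schema)
  qc <- apply_qc(coh$ffq, coh$participants, prof)
  expect_true(all(qc$pass))
  # idempotence: re-running on the retained set excludes no one
  keep <- qc$participant_id[qc$pass]
  i <- coh$ffq$participant_id %in% keep
  qc2 <- apply_qc(
    coh$ffq[i, ],
    coh$participants[coh$participants$participant_id %in% keep, ],
    prof[prof$participant_id %in% keep, ]
  )
  expect_true(all(qc2$pass))
})

test_that("profiles compute BMI from height and weight and PAL from energy", {
  coh <- small_cohort(seed = 32, n_mz = 5, n_dz = 5)
  prof <- intake_profiles(coh$ffq, coh$participants, schema)
  pp <- coh$participants
  expect_equal(
    prof$bmi,
    pp$weight_kg[match(prof$participant_id, pp$participant_id)] /
      (pp$height_cm[match(prof$participant_id, pp$participant_id)] / 100)^2,
    tolerance = 1e-12
  )
  # PAL oracle for one male participant
  i <- which(pp$sex == "M")[1]
  b <- schema$bmr_coefficients
  slope <- b$slope[b$sex == "M" & b$age_band == "18-30"]
  icept <- b$intercept[b$sex == "M" & b$age_band == "18-30"]
  j <- match(pp$participant_id[i], prof$participant_id)
  expect_equal(
    prof$pal[j],
    prof$energy_kcal[j] / (slope * pp$weight_kg[i] + icept),
    tolerance = 1e-12
  )
})

test_that("sex-specific median weight imputation fills gaps", {
  coh <- small_cohort(seed = 33, n_mz = 10, n_dz = 10)
  pp <- coh$participants
  pp$weight_kg[c(1, 2)] <- NA
  imp <- impute_weight(pp)
  for (k in 1:2) {
    s <- pp$sex[k]
    expect_equal(
      imp$weight_kg[k],
      median(pp$weight_kg[pp$sex == s], na.rm = TRUE)
    )
  }
})
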