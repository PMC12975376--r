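# Hand-computed expected scores for the rank fixture (participant i has
# intake i in every component, energy 1000 kcal, all female, alcohol 15 g/d
# for i = 1..3):
#   rMED tertile cutpoints of 1..9 are (3.67, 6.33): positives score 0/1/2
#   for i in 1-3 / 4-6 / 7-9, meat and dairy reverse to 2/1/0, alcohol
#   favourable (5-25 g/d for women) only for i = 1..3.
#   -> scores 6,6,6, 8,8,8, 12,12,12
#   HNFI: median of 1..9 is 5, strictly-above scores 1 per component
#   -> 0,0,0,0,0,6,6,6,6
#   PDI quintile cutpoints (2.6, 4.2, 5.8, 7.4) give quintiles
#   1,1,2,2,3,4,4,5,5; 12 plant ascending + 6 animal reversed
#   -> total = 36 + 6 * quintile = 42,42,48,48,54,60,60,66,66
test_that("index scorers reproduce hand-computed rank fixture scores", {
  fx <- rank_profiles_fixture(9)
  r <- score_rmed(fx$profiles, fx$participants)
  expect_equal(r$score, c(6L, 6L, 6L, 8L, 8L, 8L, 12L, 12L, 12L))
  h <- score_hnfi(fx$profiles, fx$participants)
  expect_equal(h$score, c(0L, 0L, 0L, 0L, 0L, 6L, 6L, 6L, 6L))
  p <- score_pdi(fx$profiles, fx$participants)
  expect_equal(p$score, c(42L, 42L, 48L, 48L, 54L, 60L, 60L, 66L, 66L))
  # component sums equal totals
  for (sc in list(r, h, p)) {
    pts <- as.matrix(sc[grep("_pts$", names(sc))])
    expect_equal(as.integer(rowSums(pts)), sc$score)
  }
})

test_that("maximal and minimal adherence hit the printed score extrema", {
  fx <- rank_profiles_fixture(9)
  defs <- diet_index_definitions()
  # maximal rMED adherence: top of all positives, zero on meat/dairy,
  # alcohol inside the favourable female range
  pos_groups <- unique(unlist(
    defs$rmed$groups[!defs$rmed$component %in% c("meat", "dairy", "alcohol")]
  ))
  overrides <- c(
    setNames(as.list(rep(50, length(pos_groups))), pos_groups),
    list(
      red_meat = 0, processed_meat = 0, poultry = 0, venison = 0,
      dairy_products = 0, cheese = 0
    )
  )
  prof_max <- add_profile(fx$profiles, "MAX", 0, alcohol = 15, overrides = overrides)
  parts <- dplyr::bind_rows(
    fx$participants,
    dplyr::mutate(fx$participants[1, ], participant_id = "MAX")
  )
  cuts <- index_cutpoints(fx$profiles, fx$participants)
  r <- score_rmed(prof_max, parts, cutpoints = cuts)
  expect_equal(r$score[r$participant_id == "MAX"], 18L)
  # minimal rMED adherence: zero positives, heavy meat/dairy, no alcohol
  prof_min <- add_profile(
    fx$profiles, "MIN", 0, alcohol = 0,
    overrides = list(
      red_meat = 50, processed_meat = 50, poultry = 50, venison = 50,
      dairy_products = 50, cheese = 50
    )
  )
  parts_min <- dplyr::bind_rows(
    fx$participants,
    dplyr::mutate(fx$participants[1, ], participant_id = "MIN")
  )
  r0 <- score_rmed(prof_min, parts_min, cutpoints = cuts)
  expect_equal(r0$score[r0$participant_id == "MIN"], 0L)
  # HNFI extremes
  h_max <- score_hnfi(add_profile(fx$profiles, "MAX", 50), parts, cutpoints = cuts)
  expect_equal(h_max$score[h_max$participant_id == "MAX"], 6L)
  h_min <- score_hnfi(add_profile(fx$profiles, "MIN", 0), parts_min, cutpoints = cuts)
  expect_equal(h_min$score[h_min$participant_id == "MIN"], 0L)
  # PDI extremes: top quintile of all plant, bottom of all animal, and mirror
  plant_groups <- unique(unlist(defs$pdi$groups[defs$pdi$direction == "plant"]))
  animal_groups <- unique(unlist(defs$pdi$groups[defs$pdi$direction == "animal"]))
  p_max <- score_pdi(
    add_profile(
      fx$profiles, "MAX", 0,
      overrides = c(
        setNames(as.list(rep(50, length(plant_groups))), plant_groups),
        setNames(as.list(rep(0, length(animal_groups))), animal_groups)
      )
    ),
    parts, cutpoints = cuts
  )
  expect_equal(p_max$score[p_max$participant_id == "MAX"], 90L)
  p_min <- score_pdi(
    add_profile(
      fx$profiles, "MIN", 0,
      overrides = c(
        setNames(as.list(rep(0, length(plant_groups))), plant_groups),
        setNames(as.list(rep(50, length(animal_groups))), animal_groups)
      )
    ),
    parts_min, cutpoints = cuts
  )
  expect_equal(p_min$score[p_min$participant_id == "MIN"], 18L)
})

test_that("index definitions have the documented component counts and ranges", {
  defs <- diet_index_definitions()
  expect_equal(nrow(defs$rmed), 9L)
  expect_equal(nrow(defs$hnfi), 6L)
  expect_equal(nrow(defs$pdi), 18L)
  expect_equal(sum(defs$pdi$direction == "plant"), 12L)
  expect_equal(sum(defs$pdi$direction == "animal"), 6L)
})

test_that("scores stay inside their ranges on random cohorts", {
  for (seed in c(41, 42)) {
    coh <- simulate_ffq_cohort(
      simulation_spec(0.5, 0.1, 0.4, 40, 40, seed = seed)
    )
    prof <- intake_profiles(coh$ffq, coh$participants)
    sc <- score_diet_indices(prof, coh$participants)
    expect_true(all(sc$rmed >= 0 & sc$rmed <= 18))
    expect_true(all(sc$hnfi >= 0 & sc$hnfi <= 6))
    expect_true(all(sc$pdi >= 18 & sc$pdi <= 90))
  }
})

test_that("reordering participants permutes scores identically", {
  coh <- simulate_ffq_cohort(simulation_spec(0.5, 0.1, 0.4, 25, 25, seed = 43))
  prof <- intake_profiles(coh$ffq, coh$participants)
  sc <- score_diet_indices(prof, coh$participants)
  perm <- sample(nrow(prof))
  sc_perm <- score_diet_indices(prof[perm, ], coh$participants)
  expect_equal(
    sc_perm,
    sc[match(sc_perm$participant_id, sc$participant_id), ],
    ignore_attr = TRUE
  )
})

test_that("raising a positively scored component never lowers the index", {
  fx <- rank_profiles_fixture(9)
  cuts <- index_cutpoints(fx$profiles, fx$participants)
  base <- score_pdi(fx$profiles, fx$participants, cutpoints = cuts)
  bumped_prof <- fx$profiles
  bumped_prof$fg_vegetables[2] <- bumped_prof$fg_vegetables[2] + 10
  bumped <- score_pdi(bumped_prof, fx$participants, cutpoints = cuts)
  expect_gte(bumped$score[2], base$score[2])
})

test_that("tiny cohorts are rejected with advice to supply cutpoints", {
  fx <- rank_profiles_fixture(9)
  expect_error(
    index_cutpoints(fx$profiles[1:2, ], fx$participants[1:2, ]),
    "cutpoints"
  )
})
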