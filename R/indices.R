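#' Default a priori diet-index definitions
#'
#' Component-to-food-group mappings for the three scored diet-quality
#' indices, following the original index publications with one modification:
#' the Mediterranean index's olive-oil component is computed from total
#' vegetable oil use, since the questionnaire does not separate olive oil
#' from other cooking oils.
#'
#' * **rMED** (relative Mediterranean Diet Index, range 0-18): 9 components;
#'   6 beneficial components scored 0/1/2 by sex-specific tertiles of
#'   energy-adjusted intake (per 1000 kcal), 2 detrimental components (meat,
#'   dairy) reverse-scored 2/1/0, and alcohol scored 2 inside a sex-specific
#'   moderate range (5-25 g/day for women, 10-50 g/day for men), else 0.
#' * **HNFI** (Healthy Nordic Food Index, range 0-6): 6 components, 1 point
#'   each for intake strictly above the cohort median.
#' * **PDI** (overall Plant-Based Diet Index, range 18-90): 18 components
#'   quintile-scored; 12 plant groups ascending 1-5, 6 animal groups
#'   reversed 5-1.
#'
#' Every mapping is a plain tibble and can be replaced wholesale; cutpoints
#' can be computed in-cohort with [index_cutpoints()] or supplied externally.
#'
#' @return A named list with elements `rmed`, `hnfi`, `pdi` and the alcohol
#'   ranges used by the rMED alcohol component.
#' @export
diet_index_definitions <- function() {
  rmed <- tibble::tribble(
    ~component, ~groups, ~rule,
    "fruit", list(c("fruits_berries", "nuts_seeds")), "tertile_0_1_2",
    "vegetables", list("vegetables"), "tertile_0_1_2",
    "legumes", list("legumes"), "tertile_0_1_2",
    "cereals", list(c("whole_grains", "refined_grains", "breakfast_cereals")), "tertile_0_1_2",
    "fish", list("fish_shellfish"), "tertile_0_1_2",
    "olive_oil", list("vegetable_oils"), "tertile_0_1_2",
    "meat", list(c("red_meat", "processed_meat", "poultry", "venison")), "reverse_tertile",
    "dairy", list(c("dairy_products", "cheese")), "reverse_tertile",
    "alcohol", list(character(0)), "alcohol_range_0_2"
  ) |>
    dplyr::mutate(groups = lapply(.data$groups, unlist))
  hnfi <- tibble::tribble(
    ~component, ~groups,
    "fish", "fish_shellfish",
    "cabbages_roots", "vegetables",
    "rye_bread", "whole_grains",
    "oatmeal", "breakfast_cereals",
    "apples_pears", "fruits_berries",
    "root_vegetables", "potatoes"
  ) |>
    dplyr::mutate(groups = as.list(.data$groups))
  pdi <- tibble::tribble(
    ~component, ~groups, ~direction,
    "whole_grains", list("whole_grains"), "plant",
    "fruits", list("fruits_berries"), "plant",
    "vegetables", list("vegetables"), "plant",
    "nuts", list("nuts_seeds"), "plant",
    "legumes", list(c("legumes", "plant_milk_substitutes")), "plant",
    "vegetable_oils", list("vegetable_oils"), "plant",
    "tea_coffee", list(c("coffee", "tea")), "plant",
    "fruit_juices", list("fruit_juice"), "plant",
    "refined_grains", list("refined_grains"), "plant",
    "potatoes", list("potatoes"), "plant",
    "sugar_sweetened_beverages", list("sugar_sweetened_beverages"), "plant",
    "sweets_desserts", list(c("sweets_chocolate", "desserts", "ice_cream", "snacks")), "plant",
    "animal_fat", list("butter_margarine"), "animal",
    "dairy", list(c("dairy_products", "cheese")), "animal",
    "eggs", list("eggs"), "animal",
    "fish_shellfish", list("fish_shellfish"), "animal",
    "meat", list(c("red_meat", "processed_meat", "poultry", "venison")), "animal",
    "misc_animal_foods", list("ready_meals"), "animal"
  ) |>
    dplyr::mutate(groups = lapply(.data$groups, unlist))
  list(
    rmed = rmed,
    hnfi = hnfi,
    pdi = pdi,
    alcohol_range = list(F = c(5, 25), M = c(10, 50))
  )
}

# intake per participant for each component = sum of its fg_ columns
component_intakes <- function(profiles, def) {
  n <- nrow(profiles)
  m <- vapply(
    seq_len(nrow(def)),
    function(i) {
      gs <- def$groups[[i]]
      if (length(gs) == 0) return(rep(0, n))
      rowSums(as.matrix(profiles[paste0("fg_", gs)]))
    },
    numeric(n)
  )
  if (n == 1L) m <- matrix(m, nrow = 1)
  colnames(m) <- def$component
  m
}

# category of x given ascending cutpoints, ties scoring into the lower
# category: category = number of cutpoints strictly exceeded
cut_category <- function(x, cuts) {
  rowSums(outer(x, cuts, FUN = ">"))
}

#' Compute in-cohort index cutpoints
#'
#' Tertile cutpoints (sex-specific, on energy-adjusted intake per 1000
#' kcal) for rMED, whole-cohort medians for HNFI and whole-cohort quintile
#' cutpoints for PDI. Exporting these and passing them back to the scorers
#' lets small or external cohorts be scored against fixed reference
#' cutpoints.
#'
#' @param profiles Intake profiles ([intake_profiles()] output, retained
#'   records only).
#' @param participants Participant table (for sex).
#' @param definitions Index definitions, see [diet_index_definitions()].
#' @return A named list of cutpoint tables (`rmed`, `hnfi`, `pdi`).
#' @export
index_cutpoints <- function(profiles, participants,
                            definitions = diet_index_definitions()) {
  if (nrow(profiles) < 3) {
    abort(paste0(
      "Cohort too small to compute tertile cutpoints (need >= 3 profiles); ",
      "supply externally derived cutpoints via the `cutpoints` argument."
    ))
  }
  sex <- participants$sex[match(profiles$participant_id, participants$participant_id)]
  rdef <- definitions$rmed[definitions$rmed$rule != "alcohol_range_0_2", ]
  dens <- component_intakes(profiles, rdef) / profiles$energy_kcal * 1000
  rmed_cuts <- purrr::map_dfr(c("F", "M"), function(s) {
    idx <- which(sex == s)
    purrr::map_dfr(seq_len(nrow(rdef)), function(i) {
      q <- quantile(dens[idx, i], c(1 / 3, 2 / 3), names = FALSE, na.rm = TRUE)
      tibble::tibble(component = rdef$component[i], sex = s, t1 = q[1], t2 = q[2])
    })
  })
  hm <- component_intakes(profiles, definitions$hnfi)
  hnfi_cuts <- tibble::tibble(
    component = definitions$hnfi$component,
    med = apply(hm, 2, median)
  )
  pm <- component_intakes(profiles, definitions$pdi)
  qs <- t(apply(pm, 2, quantile, probs = c(0.2, 0.4, 0.6, 0.8), names = FALSE))
  pdi_cuts <- tibble::tibble(
    component = definitions$pdi$component,
    q1 = qs[, 1], q2 = qs[, 2], q3 = qs[, 3], q4 = qs[, 4]
  )
  list(rmed = rmed_cuts, hnfi = hnfi_cuts, pdi = pdi_cuts)
}

#' Score the relative Mediterranean Diet Index (rMED)
#'
#' Intakes are energy-adjusted to densities per 1000 kcal, then the 6
#' beneficial components score 0/1/2 by sex-specific tertiles, meat and
#' dairy reverse-score 2/1/0, and alcohol (g/day, from the nutrient
#' estimate) scores 2 inside the sex-specific moderate range. Ties at a
#' cutpoint fall into the lower category. Totals lie in 0-18.
#'
#' @param profiles Intake profiles of the analyzed (QC-passed) cohort.
#' @param participants Participant table (for sex).
#' @param definitions See [diet_index_definitions()].
#' @param cutpoints Optional externally supplied cutpoints
#'   ([index_cutpoints()] structure); computed in-cohort when `NULL`.
#' @return Tibble with `participant_id`, one `<component>_pts` column per
#'   component, and the total `score`.
#' @export
score_rmed <- function(profiles, participants,
                       definitions = diet_index_definitions(),
                       cutpoints = NULL) {
  cuts <- cutpoints %||% index_cutpoints(profiles, participants, definitions)
  sex <- participants$sex[match(profiles$participant_id, participants$participant_id)]
  rdef <- definitions$rmed[definitions$rmed$rule != "alcohol_range_0_2", ]
  dens <- component_intakes(profiles, rdef) / profiles$energy_kcal * 1000
  pts <- matrix(
    0L, nrow(profiles), nrow(definitions$rmed),
    dimnames = list(NULL, definitions$rmed$component)
  )
  for (i in seq_len(nrow(rdef))) {
    comp <- rdef$component[i]
    for (s in c("F", "M")) {
      row <- cuts$rmed[cuts$rmed$component == comp & cuts$rmed$sex == s, ]
      idx <- which(sex == s)
      if (length(idx) == 0) next
      cat3 <- cut_category(dens[idx, i], c(row$t1, row$t2))
      pts[idx, comp] <- if (rdef$rule[i] == "reverse_tertile") 2L - cat3 else cat3
    }
  }
  alc <- profiles$alcohol_g
  rng <- definitions$alcohol_range
  fav <- ifelse(
    sex == "F",
    alc >= rng$F[1] & alc <= rng$F[2],
    alc >= rng$M[1] & alc <= rng$M[2]
  )
  pts[, "alcohol"] <- ifelse(fav, 2L, 0L)
  out <- tibble::as_tibble(pts)
  names(out) <- paste0(names(out), "_pts")
  dplyr::bind_cols(
    tibble::tibble(participant_id = profiles$participant_id),
    out,
    tibble::tibble(score = as.integer(rowSums(pts)))
  )
}

#' Score the Healthy Nordic Food Index (HNFI)
#'
#' Each of 6 components contributes 1 point when intake is strictly above
#' the cohort median (intake at the median scores 0). Totals lie in 0-6.
#'
#' @inheritParams score_rmed
#' @return Tibble with `participant_id`, component point columns and
#'   `score`.
#' @export
score_hnfi <- function(profiles, participants,
                       definitions = diet_index_definitions(),
                       cutpoints = NULL) {
  cuts <- cutpoints %||% index_cutpoints(profiles, participants, definitions)
  m <- component_intakes(profiles, definitions$hnfi)
  med <- setNames(cuts$hnfi$med, cuts$hnfi$component)
  pts <- vapply(
    colnames(m),
    function(comp) as.integer(m[, comp] > med[comp]),
    integer(nrow(m))
  )
  if (nrow(m) == 1L) pts <- matrix(pts, nrow = 1, dimnames = list(NULL, colnames(m)))
  out <- tibble::as_tibble(pts)
  names(out) <- paste0(names(out), "_pts")
  dplyr::bind_cols(
    tibble::tibble(participant_id = profiles$participant_id),
    out,
    tibble::tibble(score = as.integer(rowSums(pts)))
  )
}

#' Score the overall Plant-Based Diet Index (PDI)
#'
#' The 18 components are quintile-scored on the whole-cohort distribution:
#' plant groups ascending 1-5, animal groups reversed 5-1, ties at a
#' cutpoint falling into the lower quintile. Totals lie in 18-90.
#'
#' @inheritParams score_rmed
#' @return Tibble with `participant_id`, component point columns and
#'   `score`.
#' @export
score_pdi <- function(profiles, participants,
                      definitions = diet_index_definitions(),
                      cutpoints = NULL) {
  cuts <- cutpoints %||% index_cutpoints(profiles, participants, definitions)
  pdef <- definitions$pdi
  m <- component_intakes(profiles, pdef)
  pts <- matrix(
    0L, nrow(profiles), nrow(pdef),
    dimnames = list(NULL, pdef$component)
  )
  for (i in seq_len(nrow(pdef))) {
    row <- cuts$pdi[cuts$pdi$component == pdef$component[i], ]
    quint <- 1L + cut_category(m[, i], c(row$q1, row$q2, row$q3, row$q4))
    pts[, i] <- if (pdef$direction[i] == "animal") 6L - quint else quint
  }
  out <- tibble::as_tibble(pts)
  names(out) <- paste0(names(out), "_pts")
  dplyr::bind_cols(
    tibble::tibble(participant_id = profiles$participant_id),
    out,
    tibble::tibble(score = as.integer(rowSums(pts)))
  )
}

#' Score all three diet indices
#'
#' Convenience wrapper running [score_rmed()], [score_hnfi()] and
#' [score_pdi()] on the same cohort.
#'
#' @inheritParams score_rmed
#' @return Tibble with `participant_id`, `rmed`, `hnfi`, `pdi`.
#' @export
#' @examples
#' coh <- simulate_ffq_cohort(simulation_spec(0.4, 0.1, 0.5, 30, 30, seed = 3))
#' prof <- intake_profiles(coh$ffq, coh$participants)
#' scores <- score_diet_indices(prof, coh$participants)
#' range(scores$rmed)
score_diet_indices <- function(profiles, participants,
                               definitions = diet_index_definitions(),
                               cutpoints = NULL) {
  cuts <- cutpoints %||% index_cutpoints(profiles, participants, definitions)
  tibble::tibble(
    participant_id = profiles$participant_id,
    rmed = score_rmed(profiles, participants, definitions, cuts)$score,
    hnfi = score_hnfi(profiles, participants, definitions, cuts)$score,
    pdi = score_pdi(profiles, participants, definitions, cuts)$score
  )
}
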