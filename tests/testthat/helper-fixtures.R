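# Shared fixtures, built in code at test time.

# A small profiles table with controlled component intakes: participant i has
# intake i (intakes/day) in every food group, energy 1000 kcal/day so
# energy densities equal raw intakes, and alcohol 15 g/day for the first
# three participants. All female, so sex-specific cutpoints coincide with
# the whole-cohort ones.
rank_profiles_fixture <- function(n = 9) {
  schema <- default_ffq_schema()
  prof <- tibble::tibble(participant_id = sprintf("R%02d", seq_len(n)))
  for (g in schema$food_groups) prof[[paste0("fg_", g)]] <- as.numeric(seq_len(n))
  prof$energy_kcal <- 1000
  prof$alcohol_g <- c(rep(15, 3), rep(0, n - 3))[seq_len(n)]
  prof$pal <- 1.5
  prof$bmi <- 22
  participants <- tibble::tibble(
    participant_id = prof$participant_id,
    pair_id = sprintf("PAIR%02d", ceiling(seq_len(n) / 2)),
    zygosity = "DZ",
    sex = "F",
    age = 24,
    height_cm = 167,
    weight_kg = 65
  )
  list(profiles = prof, participants = participants, schema = schema)
}

# Append a profile with given intake in every food group (and optional
# per-group overrides), energy 1000 kcal, given alcohol g/day.
add_profile <- function(profiles, id, value, alcohol = 0, overrides = list()) {
  schema_groups <- sub("^fg_", "", grep("^fg_", names(profiles), value = TRUE))
  row <- tibble::tibble(participant_id = id)
  for (g in schema_groups) {
    row[[paste0("fg_", g)]] <- if (g %in% names(overrides)) overrides[[g]] else value
  }
  row$energy_kcal <- 1000
  row$alcohol_g <- alcohol
  row$pal <- 1.5
  row$bmi <- 22
  dplyr::bind_rows(profiles, row)
}

# Independent oracle: sample twin pairs directly from the bivariate normal
# with the model covariance (off-diagonal a2 + c2 for MZ, 0.5 a2 + c2 for
# DZ) through a Cholesky factor.
mvn_pairs_oracle <- function(a2, c2, e2, n_mz, n_dz, seed) {
  draw <- function(n, r) {
    z <- matrix(rnorm(2 * n), n, 2)
    L <- chol(matrix(c(1, r, r, 1), 2))
    z %*% L
  }
  set.seed(seed)
  mz <- draw(n_mz, a2 + c2)
  dz <- draw(n_dz, 0.5 * a2 + c2)
  tibble::tibble(
    pair_id = c(sprintf("MZ%05d", seq_len(n_mz)), sprintf("DZ%05d", seq_len(n_dz))),
    zygosity = rep(c("MZ", "DZ"), c(n_mz, n_dz)),
    twin1 = c(mz[, 1], dz[, 1]),
    twin2 = c(mz[, 2], dz[, 2])
  )
}

# Brute-force Benjamini-Hochberg step-up: q_i = min over j with p_j >= p_i
# of m * p_j / rank_j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Standardize pair values within zygosity (what the equal-means/variances
# gate guarantees in expectation), for the ML-vs-moment comparison.
standardize_within_zygosity <- function(pairs) {
  for (z in c("MZ", "DZ")) {
    i <- pairs$zygosity == z
    v <- c(pairs$twin1[i], pairs$twin2[i])
    pairs$twin1[i] <- (pairs$twin1[i] - mean(v)) / sd(v)
    pairs$twin2[i] <- (pairs$twin2[i] - mean(v)) / sd(v)
  }
  pairs
}

ace_model_names <- function() setNames(c("ACE", "AE", "CE", "E"), c("ACE", "AE", "CE", "E"))

fit_all_models <- function(pairs) {
  lapply(ace_model_names(), function(m) fit_ace(pairs, m, ci = FALSE))
}
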