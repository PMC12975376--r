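test_that("pair correlations match a textbook computation and set the flags", {
  # 5 hand-written MZ pairs plus 5 DZ pairs
  pairs <- tibble::tibble(
    pair_id = sprintf("P%d", 1:10),
    zygosity = rep(c("MZ", "DZ"), each = 5),
    twin1 = c(1, 2, 3, 4, 5, 2, 1, 4, 3, 5),
    twin2 = c(1.2, 1.9, 3.4, 3.8, 5.1, 5, 2, 1, 4, 3)
  )
  hand_r <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  co <- pair_correlations(pairs)
  expect_equal(co$r_mz, hand_r(pairs$twin1[1:5], pairs$twin2[1:5]), tolerance = 1e-12)
  expect_equal(co$r_dz, hand_r(pairs$twin1[6:10], pairs$twin2[6:10]), tolerance = 1e-12)
  expect_true(co$genetic_signal)
  # identical twins give r = 1; degenerate columns error
  same <- pairs; same$twin2 <- same$twin1
  expect_equal(pair_correlations(same)$r_mz, 1)
  flat <- pairs; flat$twin1[1:5] <- 3
  expect_error(pair_correlations(flat), "Zero variance")
})

test_that("Falconer's formula is 2 (rMZ - rDZ) with range notes", {
  expect_equal(falconer_h2(list(r_mz = 0.40, r_dz = 0.15))$h2, 0.5)
  expect_equal(falconer_h2(list(r_mz = 0.3, r_dz = 0.3))$h2, 0)
  expect_equal(falconer_h2(list(r_mz = 0.5, r_dz = 0.25))$h2, 0.5)
  out <- falconer_h2(list(r_mz = 0.9, r_dz = 0.1))
  expect_match(out$note, "outside")
})

test_that("assumption tests match the Welch-Satterthwaite hand formula", {
  set.seed(61)
  pairs <- tibble::tibble(
    pair_id = sprintf("P%d", 1:40),
    zygosity = rep(c("MZ", "DZ"), each = 20),
    twin1 = rnorm(40), twin2 = rnorm(40)
  )
  mz <- c(pairs$twin1[1:20], pairs$twin2[1:20])
  dz <- c(pairs$twin1[21:40], pairs$twin2[21:40])
  s1 <- var(mz) / 40; s2 <- var(dz) / 40
  t_stat <- (mean(mz) - mean(dz)) / sqrt(s1 + s2)
  df <- (s1 + s2)^2 / (s1^2 / 39 + s2^2 / 39)
  p_hand <- 2 * pt(-abs(t_stat), df)
  out <- assumption_tests(pairs, n_traits = 10)
  expect_equal(out$welch_p, p_hand, tolerance = 1e-12)
  expect_equal(out$bonferroni_alpha, 0.005)
  expect_true(out$passed)
  # a 5 SD mean shift fails decisively
  shifted <- pairs
  shifted$twin1[1:20] <- shifted$twin1[1:20] + 5
  shifted$twin2[1:20] <- shifted$twin2[1:20] + 5
  out2 <- assumption_tests(shifted, n_traits = 10)
  expect_lt(out2$welch_p, 1e-10)
  expect_false(out2$passed)
})

test_that("E-model likelihood equals the closed-form independence limit", {
  spec <- simulation_spec(0, 0, 1, 200, 200, seed = 62)
  pairs <- simulate_trait_pairs(spec)
  fit <- fit_ace(pairs, "E", ci = FALSE)
  v <- c(pairs$twin1, pairs$twin2)
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  ll_closed <- sum(dnorm(v, mu, sqrt(s2), log = TRUE))
  expect_equal(fit$loglik, ll_closed, tolerance = 1e-6)
  expect_equal(fit$mu, mu, tolerance = 1e-4)
  expect_equal(fit$e2, 1)
  expect_equal(fit$n_params, 2L)
})

test_that("AE fits recover a simulated heritability and match the moment form", {
  spec <- simulation_spec(0.6, 0, 0.4, 5000, 5000, seed = 63)
  pairs <- simulate_trait_pairs(spec)
  fit <- fit_ace(pairs, "AE", ci = FALSE)
  expect_lt(abs(fit$a2 - 0.6), 0.03)
  ace <- fit_ace(standardize_within_zygosity(pairs), "ACE", ci = FALSE)
  mom <- with(
    pair_correlations(standardize_within_zygosity(pairs)),
    c(2 * (r_mz - r_dz), 2 * r_dz - r_mz, 1 - r_mz)
  )
  expect_lt(max(abs(mom - c(ace$a2, ace$c2, ace$e2))), 0.02)
})

test_that("a shared-environment truth drives the A estimate to the boundary", {
  spec <- simulation_spec(0, 0.5, 0.5, 1500, 1500, seed = 64)
  pairs <- simulate_trait_pairs(spec)
  fit <- fit_ace(pairs, "ACE", ci = FALSE)
  expect_lt(fit$a2, 0.06)
  expect_lt(abs(fit$c2 - 0.5), 0.05)
})

test_that("model invariants hold: parameter counts, AIC identity, nesting monotonicity", {
  spec <- simulation_spec(0.4, 0.2, 0.4, 300, 300, seed = 65)
  pairs <- simulate_trait_pairs(spec)
  fits <- fit_all_models(pairs)
  ks <- c(ACE = 4L, AE = 3L, CE = 3L, E = 2L)
  for (m in names(fits)) {
    f <- fits[[m]]
    expect_equal(f$n_params, ks[[m]])
    expect_equal(f$aic, -2 * f$loglik + 2 * f$n_params, tolerance = 1e-9)
    expect_equal(f$a2 + f$c2 + f$e2, 1, tolerance = 1e-6)
    expect_gt(f$e2, 0)
    # stored loglik is reproducible from stored parameters
    expect_equal(ace_loglik(f, pairs), f$loglik, tolerance = 1e-8)
  }
  expect_gte(fits$ACE$loglik, fits$AE$loglik - 1e-8)
  expect_gte(fits$AE$loglik, fits$E$loglik - 1e-8)
  expect_gte(fits$ACE$loglik, fits$CE$loglik - 1e-8)
  expect_gte(fits$CE$loglik, fits$E$loglik - 1e-8)
})

test_that("swapping twin order within pairs leaves estimates unchanged", {
  spec <- simulation_spec(0.5, 0.1, 0.4, 400, 400, seed = 66)
  pairs <- simulate_trait_pairs(spec)
  swapped <- pairs
  swap <- seq(1, nrow(pairs), by = 2)
  tmp <- swapped$twin1[swap]
  swapped$twin1[swap] <- swapped$twin2[swap]
  swapped$twin2[swap] <- tmp
  f1 <- fit_ace(pairs, "ACE", ci = FALSE)
  f2 <- fit_ace(swapped, "ACE", ci = FALSE)
  expect_lt(abs(f1$a2 - f2$a2), 1e-6)
  expect_lt(abs(f1$c2 - f2$c2), 1e-6)
  expect_lt(abs(f1$e2 - f2$e2), 1e-6)
})

test_that("profile-likelihood CIs behave: coverage-style sanity on one draw", {
  spec <- simulation_spec(0.5, 0, 0.5, 429, 987, seed = 67)
  fit <- fit_ace(simulate_trait_pairs(spec), "AE")
  ci <- fit$ci
  a2 <- ci[ci$component == "a2", ]
  expect_lt(a2$lower, fit$a2)
  expect_gt(a2$upper, fit$a2)
  expect_true(all(ci$lower >= 0 & ci$upper <= 1))
  # e2 interval mirrors a2 under AE (two free fractions summing to 1)
  e2 <- ci[ci$component == "e2", ]
  expect_equal(e2$lower, 1 - a2$upper, tolerance = 1e-4)
  expect_equal(e2$upper, 1 - a2$lower, tolerance = 1e-4)
})

test_that("likelihood-ratio tests follow the chi-square reference", {
  spec <- simulation_spec(0.4, 0.1, 0.5, 300, 300, seed = 68)
  pairs <- simulate_trait_pairs(spec)
  fits <- fit_all_models(pairs)
  # identical fits give statistic 0 and p = 1
  self <- likelihood_ratio_test(fits$ACE, fits$ACE |> (\(f) {
    f$model <- "AE"; f$n_params <- 3L; f
  })())
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  # chi-square quantile identity at the 5% critical value
  expect_equal(pchisq(3.841459, df = 1, lower.tail = FALSE), 0.05, tolerance = 1e-6)
  lrt <- likelihood_ratio_test(fits$ACE, fits$E)
  expect_equal(lrt$df, 2L)
  expect_equal(
    lrt$p_value,
    pchisq(lrt$statistic, 2, lower.tail = FALSE),
    tolerance = 1e-12
  )
  expect_error(likelihood_ratio_test(fits$AE, fits$CE), "not nested")
})

fabricate_fit <- function(model, loglik) {
  structure(
    list(
      model = model, loglik = loglik,
      n_params = c(ACE = 4L, AE = 3L, CE = 3L, E = 2L)[[model]],
      aic = -2 * loglik + 2 * c(ACE = 4L, AE = 3L, CE = 3L, E = 2L)[[model]]
    ),
    class = "ace_fit"
  )
}

test_that("parsimony rules: equal fit prefers the smaller model, AE before CE", {
  fits <- list(
    ACE = fabricate_fit("ACE", -100),
    AE = fabricate_fit("AE", -100),
    CE = fabricate_fit("CE", -100),
    E = fabricate_fit("E", -110)
  )
  sel <- select_ace_model(fits)
  expect_equal(sel$chosen, "AE")  # ties on AIC and df break toward AE
  # a strongly worse CE is ineligible even with low AIC arithmetic
  fits2 <- list(
    ACE = fabricate_fit("ACE", -100),
    AE = fabricate_fit("AE", -100.5),
    CE = fabricate_fit("CE", -115),
    E = fabricate_fit("E", -130)
  )
  sel2 <- select_ace_model(fits2)
  expect_false("CE" %in% c(sel2$chosen))
  expect_equal(sel2$chosen, "AE")
})

test_that("selection picks the generating model on simulated data", {
  # strong C signal, no A -> CE
  pairs_ce <- simulate_trait_pairs(simulation_spec(0, 0.5, 0.5, 429, 987, seed = 69))
  sel_ce <- select_ace_model(fit_all_models(pairs_ce))
  expect_equal(sel_ce$chosen, "CE")
  # no familial resemblance -> E
  pairs_e <- simulate_trait_pairs(simulation_spec(0, 0, 1, 429, 987, seed = 70))
  sel_e <- select_ace_model(fit_all_models(pairs_e))
  expect_equal(sel_e$chosen, "E")
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(71)
  for (i in 1:5) {
    p <- runif(sample(3:50, 1))
    expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_adjust(numeric(0)), "at least one")
})

test_that("tidy and glance methods expose broom-style summaries", {
  spec <- simulation_spec(0.5, 0, 0.5, 100, 100, seed = 72)
  fit <- fit_ace(simulate_trait_pairs(spec), "AE")
  td <- tidy(fit)
  expect_equal(td$term, c("a2", "c2", "e2"))
  expect_equal(td$estimate, c(fit$a2, fit$c2, fit$e2))
  expect_true(all(c("conf.low", "conf.high") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$AIC, fit$aic)
  expect_equal(gl$df, 3L)
})

test_that("the per-trait analysis table assembles correlations, fits and FDR", {
  spec <- simulation_spec(0.5, 0, 0.5, 60, 90, seed = 73)
  coh <- simulate_ffq_cohort(spec)
  traits <- coh$latent_traits[c("participant_id", "diet", "bitter")]
  res <- twin_ace(traits, coh$participants, ci = TRUE)
  tab <- tidy(res)
  expect_equal(tab$trait, c("diet", "bitter"))
  expect_true(all(tab$assumptions_passed))
  expect_true(all(!is.na(tab$fdr_q)))
  expect_equal(tab$fdr_q, fdr_adjust(tab$lrt_ace_vs_ce_p))
  expect_true(all(tab$a2_lower <= tab$a2 & tab$a2 <= tab$a2_upper, na.rm = TRUE))
  gl <- glance(res)
  expect_equal(gl$n_traits, 2L)
})
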