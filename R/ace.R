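#' Build twin-pair sets from individual trait values
#'
#' Pivots a per-participant trait vector into complete (twin1, twin2) pairs
#' split by zygosity, the unit of twin modeling. Twin order within a pair is
#' the order of appearance in the participant table. Pairs with any missing
#' value are dropped.
#'
#' @param values Tibble with `participant_id` and a `value` column, or a
#'   named numeric vector keyed by participant id.
#' @param participants Participant table with `participant_id`, `pair_id`,
#'   `zygosity`.
#' @return A tibble with columns `pair_id`, `zygosity`, `twin1`, `twin2`.
#' @export
make_twin_pairs <- function(values, participants) {
  if (is.numeric(values) && !is.null(names(values))) {
    values <- tibble::tibble(participant_id = names(values), value = unname(values))
  }
  df <- participants |>
    dplyr::select("participant_id", "pair_id", "zygosity") |>
    dplyr::inner_join(values, by = "participant_id") |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::mutate(member = dplyr::row_number()) |>
    dplyr::ungroup()
  wide <- df |>
    dplyr::select("pair_id", "zygosity", "member", "value") |>
    tidyr::pivot_wider(
      names_from = "member", values_from = "value", names_prefix = "twin"
    )
  if (!"twin2" %in% names(wide)) wide$twin2 <- NA_real_
  wide |>
    dplyr::filter(!is.na(.data$twin1), !is.na(.data$twin2)) |>
    dplyr::select("pair_id", "zygosity", "twin1", "twin2")
}

#' Within-pair Pearson correlations by zygosity
#'
#' Pearson correlation between twin 1 and twin 2 in the as-given ordering,
#' separately for MZ and DZ pairs. A higher MZ than DZ correlation is the
#' classical indication of additive-genetic influence and is returned as the
#' `genetic_signal` flag.
#'
#' @param pairs Tibble from [make_twin_pairs()].
#' @return A one-row tibble: `r_mz`, `r_dz`, `n_mz_pairs`, `n_dz_pairs`,
#'   `genetic_signal`.
#' @export
pair_correlations <- function(pairs) {
  one <- function(z) {
    d <- pairs[pairs$zygosity == z, ]
    if (nrow(d) < 2) abort(sprintf("Need >= 2 %s pairs for a correlation.", z))
    if (sd(d$twin1) == 0 || sd(d$twin2) == 0) {
      abort(sprintf("Zero variance in a %s twin column; correlation undefined.", z))
    }
    list(r = cor(d$twin1, d$twin2), n = nrow(d))
  }
  mz <- one("MZ")
  dz <- one("DZ")
  tibble::tibble(
    r_mz = mz$r, r_dz = dz$r,
    n_mz_pairs = mz$n, n_dz_pairs = dz$n,
    genetic_signal = mz$r > dz$r
  )
}

#' Falconer's heritability estimate
#'
#' The rough moment estimate h2 = 2 (rMZ - rDZ) from zygosity-specific twin
#' correlations. Values outside `[0, 1]` are reported as-is with a note,
#' since the formula can exceed the admissible range in small samples.
#'
#' @param corrs Output of [pair_correlations()] (or any list with `r_mz`,
#'   `r_dz`).
#' @return A one-row tibble: `h2`, `note` (`""` when h2 is inside [0, 1]).
#' @export
#' @examples
#' falconer_h2(list(r_mz = 0.40, r_dz = 0.15))$h2  # 0.5
falconer_h2 <- function(corrs) {
  h2 <- 2 * (corrs$r_mz - corrs$r_dz)
  tibble::tibble(
    h2 = h2,
    note = if (h2 < 0 || h2 > 1) "outside [0, 1]; interpret qualitatively" else ""
  )
}

#' Equal-means and equal-variances assumption tests
#'
#' The classical twin model requires MZ and DZ individuals to share the same
#' trait mean and variance. Tested with a Welch two-sample t-test (means)
#' and a two-sided F-test on the variance ratio, both on individual-level
#' values, against a Bonferroni-corrected threshold 0.05 / n_traits. Traits
#' failing either test are flagged for exclusion from model fitting.
#'
#' @param pairs Tibble from [make_twin_pairs()].
#' @param n_traits Number of traits tested in the analysis (Bonferroni
#'   denominator).
#' @param alpha Familywise level before correction; default 0.05.
#' @return A one-row tibble: `welch_p`, `f_p`, `bonferroni_alpha`, `passed`.
#' @export
assumption_tests <- function(pairs, n_traits = 1, alpha = 0.05) {
  mz <- c(pairs$twin1[pairs$zygosity == "MZ"], pairs$twin2[pairs$zygosity == "MZ"])
  dz <- c(pairs$twin1[pairs$zygosity == "DZ"], pairs$twin2[pairs$zygosity == "DZ"])
  if (sd(mz) == 0 || sd(dz) == 0) abort("Degenerate variance in a zygosity group.")
  wp <- t.test(mz, dz)$p.value
  fp <- var.test(mz, dz)$p.value
  thr <- alpha / n_traits
  tibble::tibble(
    welch_p = wp, f_p = fp, bonferroni_alpha = thr,
    passed = wp >= thr & fp >= thr
  )
}

# Sufficient statistics of pair vectors per zygosity: with equal means and
# variances across twins, the bivariate-normal log-likelihood depends on the
# data only through n, S = sum(t1 + t2), SS = sum(t1^2 + t2^2),
# SP = sum(t1 * t2).
pair_suffstats <- function(pairs) {
  one <- function(z) {
    d <- pairs[pairs$zygosity == z, ]
    list(
      n = nrow(d),
      S = sum(d$twin1 + d$twin2),
      SS = sum(d$twin1^2 + d$twin2^2),
      SP = sum(d$twin1 * d$twin2)
    )
  }
  list(MZ = one("MZ"), DZ = one("DZ"))
}

# Log-likelihood of all pairs given mean mu, total variance sigma2 and
# within-pair correlations r_mz, r_dz, from sufficient statistics.
loglik_from_stats <- function(st, mu, sigma2, r_mz, r_dz) {
  ll_z <- function(s, r) {
    if (s$n == 0) return(0)
    q <- s$SS - 2 * mu * s$S + 2 * s$n * mu^2 -
      2 * r * (s$SP - mu * s$S + s$n * mu^2)
    -s$n * log(2 * pi) - s$n * log(sigma2) - s$n / 2 * log(1 - r^2) -
      q / (2 * sigma2 * (1 - r^2))
  }
  ll_z(st$MZ, r_mz) + ll_z(st$DZ, r_dz)
}

ace_free_params <- c(ACE = 4L, AE = 3L, CE = 3L, E = 2L)

# Map an unconstrained parameter vector to (mu, a2, c2, e2) on the raw
# variance scale. Path coefficients are squared, so components are
# nonnegative by construction.
ace_unpack <- function(theta, model) {
  mu <- theta[1]
  i <- 2
  a2 <- c2 <- 0
  if (model %in% c("ACE", "AE")) { a2 <- theta[i]^2; i <- i + 1 }
  if (model %in% c("ACE", "CE")) { c2 <- theta[i]^2; i <- i + 1 }
  e2 <- theta[i]^2
  list(mu = mu, a2 = a2, c2 = c2, e2 = e2)
}

ace_negll <- function(theta, st, model) {
  p <- ace_unpack(theta, model)
  sigma2 <- p$a2 + p$c2 + p$e2
  if (!is.finite(sigma2) || sigma2 <= 1e-12 || p$e2 <= 1e-12) return(1e10)
  r_mz <- (p$a2 + p$c2) / sigma2
  r_dz <- (0.5 * p$a2 + p$c2) / sigma2
  if (r_mz >= 1 - 1e-12 || r_dz >= 1 - 1e-12) return(1e10)
  -loglik_from_stats(st, p$mu, sigma2, r_mz, r_dz)
}

# Method-of-moments closed form on pair data: a2 = 2(rMZ - rDZ),
# c2 = 2 rDZ - rMZ, e2 = 1 - rMZ (standardized scale).
moment_estimates <- function(pairs) {
  co <- pair_correlations(pairs)
  tibble::tibble(
    a2 = 2 * (co$r_mz - co$r_dz),
    c2 = 2 * co$r_dz - co$r_mz,
    e2 = 1 - co$r_mz
  )
}

#' Fit a twin variance-components model by maximum likelihood
#'
#' Maximizes the joint bivariate-normal log-likelihood of the (twin1, twin2)
#' pair vectors with a common mean and total variance across twins and
#' zygosity groups, and within-pair covariance `a2 + c2` for MZ pairs and
#' `0.5 a2 + c2` for DZ pairs. The model label fixes absent paths to zero:
#' `"ACE"` frees all three components, `"AE"`, `"CE"` and `"E"` are its
#' nested submodels. Parameters are path coefficients (squared into
#' components), so components are nonnegative by construction; optimization
#' is multi-start BFGS from a moment-informed point plus random
#' perturbations. Reported components are standardized fractions of total
#' variance; 95% confidence intervals come from the profile likelihood on
#' each standardized component (delta-method fallback, flagged in the `ci`
#' table's `method` column).
#'
#' @param pairs Tibble from [make_twin_pairs()]; needs >= 10 pairs per
#'   zygosity.
#' @param model One of `"ACE"`, `"AE"`, `"CE"`, `"E"`.
#' @param ci Compute 95% CIs (profile likelihood); disable for speed in
#'   large screens.
#' @param conf_level CI coverage; default 0.95.
#' @param n_starts Number of optimizer starts (first is moment-informed).
#' @return An object of class `ace_fit`: model label, `mu`, `sigma2`,
#'   standardized `a2`, `c2`, `e2`, `loglik`, `n_params`, `aic`, `ci`
#'   (tibble), pair counts and convergence info.
#' @export
#' @examples
#' spec <- simulation_spec(0.6, 0, 0.4, 400, 400, seed = 11)
#' fit <- fit_ace(simulate_trait_pairs(spec), "AE", ci = FALSE)
#' fit$a2
fit_ace <- function(pairs, model = c("ACE", "AE", "CE", "E"),
                    ci = TRUE, conf_level = 0.95, n_starts = 5) {
  model <- match.arg(model)
  n_mz <- sum(pairs$zygosity == "MZ")
  n_dz <- sum(pairs$zygosity == "DZ")
  if (n_mz < 10 || n_dz < 10) {
    abort("Model fitting needs at least 10 pairs per zygosity.")
  }
  st <- pair_suffstats(pairs)
  all_v <- c(pairs$twin1, pairs$twin2)
  v <- var(all_v)
  m0 <- mean(all_v)
  mom <- moment_estimates(pairs)
  clip <- function(x) pmin(pmax(x, 0.05), 0.9)
  a2s <- clip(mom$a2) * v
  c2s <- clip(mom$c2) * v
  e2s <- max(v - switch(model,
    ACE = a2s + c2s, AE = a2s, CE = c2s, E = 0
  ), 0.05 * v)
  start0 <- switch(model,
    ACE = c(m0, sqrt(a2s), sqrt(c2s), sqrt(e2s)),
    AE = c(m0, sqrt(a2s), sqrt(e2s)),
    CE = c(m0, sqrt(c2s), sqrt(e2s)),
    E = c(m0, sqrt(v))
  )
  starts <- list(start0)
  if (n_starts > 1) {
    # deterministic perturbations: no RNG so fits are reproducible anywhere
    scales <- seq(0.5, 1.5, length.out = n_starts - 1)
    for (k in seq_len(n_starts - 1)) {
      s <- start0
      s[-1] <- s[-1] * scales[k] + 0.01 * k
      starts[[k + 1]] <- s
    }
  }
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      optim(s, ace_negll, st = st, model = model, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best) || best$value >= 1e9) {
    abort(sprintf("Optimizer failed to converge for the %s model.", model))
  }
  p <- ace_unpack(best$par, model)
  sigma2 <- p$a2 + p$c2 + p$e2
  comps <- c(a2 = p$a2, c2 = p$c2, e2 = p$e2) / sigma2
  loglik <- -best$value
  k <- ace_free_params[[model]]
  fit <- structure(
    list(
      model = model,
      mu = p$mu,
      sigma2 = sigma2,
      a2 = unname(comps["a2"]),
      c2 = unname(comps["c2"]),
      e2 = unname(comps["e2"]),
      loglik = loglik,
      n_params = k,
      aic = -2 * loglik + 2 * k,
      n_mz_pairs = n_mz,
      n_dz_pairs = n_dz,
      convergence = best$convergence,
      suffstats = st,
      ci = NULL
    ),
    class = "ace_fit"
  )
  if (ci) fit$ci <- ace_profile_ci(fit, conf_level)
  fit
}

# Profile log-likelihood for one standardized component fixed at `h`,
# maximized over the mean, the total variance and (for ACE) the remaining
# free fraction. For fixed fractions the inner maximum over mu and sigma2 is
# closed-form: mu is the 1/(1+r)-weighted grand mean and sigma2 the averaged
# quadratic form.
profile_ll_fixed_fracs <- function(st, fa, fc) {
  r_mz <- fa + fc
  r_dz <- 0.5 * fa + fc
  if (r_mz >= 1 - 1e-10 || r_dz >= 1 - 1e-10) return(-1e10)
  w_mz <- st$MZ$n / (1 + r_mz)
  w_dz <- st$DZ$n / (1 + r_dz)
  mu <- (st$MZ$S / (1 + r_mz) + st$DZ$S / (1 + r_dz)) / (2 * (w_mz + w_dz))
  qf <- function(s, r) {
    (s$SS - 2 * mu * s$S + 2 * s$n * mu^2 -
       2 * r * (s$SP - mu * s$S + s$n * mu^2)) / (1 - r^2)
  }
  n_tot <- st$MZ$n + st$DZ$n
  sigma2 <- (qf(st$MZ, r_mz) + qf(st$DZ, r_dz)) / (2 * n_tot)
  if (!is.finite(sigma2) || sigma2 <= 0) return(-1e10)
  loglik_from_stats(st, mu, sigma2, r_mz, r_dz)
}

# Profile over the component named `comp` at standardized value h, for a
# given model: remaining free fraction (ACE only) maximized numerically.
profile_ll_component <- function(st, model, comp, h) {
  h <- min(max(h, 0), 1)
  if (model == "ACE") {
    other_max <- 1 - h - 1e-9
    if (other_max <= 0) {
      fa <- if (comp == "a2") h else if (comp == "e2") 0 else 0
      fc <- if (comp == "c2") h else 0
      if (comp == "e2") return(profile_ll_fixed_fracs(st, 0, 0))
      return(profile_ll_fixed_fracs(st, fa, fc))
    }
    f <- function(t) {
      if (comp == "a2") profile_ll_fixed_fracs(st, h, t)
      else if (comp == "c2") profile_ll_fixed_fracs(st, t, h)
      else profile_ll_fixed_fracs(st, t, 1 - h - t)
    }
    opt <- optimize(f, c(0, other_max), maximum = TRUE, tol = 1e-9)
    opt$objective
  } else if (model == "AE") {
    fa <- if (comp == "a2") h else 1 - h
    profile_ll_fixed_fracs(st, fa, 0)
  } else if (model == "CE") {
    fc <- if (comp == "c2") h else 1 - h
    profile_ll_fixed_fracs(st, 0, fc)
  } else {
    profile_ll_fixed_fracs(st, 0, 0)
  }
}

# 95% profile-likelihood confidence intervals on the standardized variance
# fractions, by inverting the likelihood-ratio statistic against chi^2(1).
ace_profile_ci <- function(fit, conf_level = 0.95) {
  st <- fit$suffstats
  model <- fit$model
  comps <- switch(model,
    ACE = c("a2", "c2", "e2"),
    AE = c("a2", "e2"),
    CE = c("c2", "e2"),
    E = "e2"
  )
  crit <- qchisq(conf_level, df = 1) / 2
  llmax <- fit$loglik
  rows <- lapply(comps, function(comp) {
    est <- fit[[comp]]
    if (model == "E") {
      return(tibble::tibble(
        component = comp, estimate = est, lower = 1, upper = 1,
        method = "degenerate"
      ))
    }
    drop_at <- function(h) llmax - profile_ll_component(st, model, comp, h) - crit
    bound <- function(side) {
      lim <- if (side == "lower") 0 else 1
      f_lim <- tryCatch(drop_at(lim), error = function(e) NA_real_)
      if (is.na(f_lim)) return(NA_real_)
      if (f_lim <= 0) return(lim)  # interval reaches the boundary
      interval <- if (side == "lower") c(lim, est) else c(est, lim)
      if (abs(diff(interval)) < 1e-10) return(est)
      tryCatch(
        uniroot(drop_at, interval = interval, tol = 1e-6)$root,
        error = function(e) NA_real_
      )
    }
    lo <- bound("lower")
    hi <- bound("upper")
    method <- "profile"
    if (is.na(lo) || is.na(hi)) {
      # delta-method fallback from the curvature of the profile likelihood
      hstep <- 1e-3
      ll2 <- vapply(
        c(est - hstep, est, est + hstep),
        function(h) profile_ll_component(st, model, comp, min(max(h, 0), 1)),
        numeric(1)
      )
      d2 <- (ll2[1] - 2 * ll2[2] + ll2[3]) / hstep^2
      se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
      zc <- qnorm(1 - (1 - conf_level) / 2)
      lo <- max(0, est - zc * se)
      hi <- min(1, est + zc * se)
      method <- "delta"
    }
    tibble::tibble(
      component = comp, estimate = est, lower = lo, upper = hi, method = method
    )
  })
  dplyr::bind_rows(rows)
}

#' Recompute the log-likelihood of a fitted model from its parameters
#'
#' Consistency check: evaluates the pair log-likelihood at the stored
#' parameter values; equals `fit$loglik` up to optimizer tolerance.
#'
#' @param fit An `ace_fit`.
#' @param pairs The pair tibble the model was fitted to.
#' @return The log-likelihood as a number.
#' @export
ace_loglik <- function(fit, pairs) {
  st <- pair_suffstats(pairs)
  r_mz <- fit$a2 + fit$c2
  r_dz <- 0.5 * fit$a2 + fit$c2
  loglik_from_stats(st, fit$mu, fit$sigma2, r_mz, r_dz)
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf(
    "<ace_fit %s>  a2=%.3f c2=%.3f e2=%.3f  loglik=%.2f AIC=%.2f (%d MZ + %d DZ pairs)\n",
    x$model, x$a2, x$c2, x$e2, x$loglik, x$aic, x$n_mz_pairs, x$n_dz_pairs
  ))
  if (!is.null(x$ci)) print(x$ci)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ACE model fit
#'
#' @param x An `ace_fit`.
#' @param ... Unused.
#' @return A tibble with one row per variance component: `term`,
#'   `estimate`, and, when CIs were computed, `conf.low`, `conf.high`.
#' @export
#' @exportS3Method generics::tidy
tidy.ace_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c("a2", "c2", "e2"),
    estimate = c(x$a2, x$c2, x$e2)
  )
  if (!is.null(x$ci)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(
        x$ci,
        term = "component", conf.low = "lower", conf.high = "upper"
      ),
      by = "term"
    )
  }
  out
}

#' One-row model summary of an ACE fit
#'
#' @param x An `ace_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model label, `logLik`, `AIC`, `df`
#'   (free parameters), pair counts.
#' @export
#' @exportS3Method generics::glance
glance.ace_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, logLik = x$loglik, AIC = x$aic, df = x$n_params,
    n_mz_pairs = x$n_mz_pairs, n_dz_pairs = x$n_dz_pairs
  )
}

#' Likelihood-ratio test between nested twin models
#'
#' Statistic 2 (loglik_full - loglik_nested), clamped at zero, referred to a
#' chi-square with df equal to the difference in free parameters. The naive
#' chi-square reference is used (no boundary mixture), which is conservative
#' for variance components.
#'
#' @param full,nested `ace_fit` objects; `nested`'s free paths must be a
#'   subset of `full`'s.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, nested) {
  nesting <- list(
    ACE = c("AE", "CE", "E"), AE = "E", CE = "E", E = character(0)
  )
  if (!nested$model %in% nesting[[full$model]]) {
    abort(sprintf("%s is not nested in %s.", nested$model, full$model))
  }
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  df <- full$n_params - nested$n_params
  tibble::tibble(
    statistic = stat, df = df,
    p_value = pchisq(stat, df = df, lower.tail = FALSE)
  )
}

#' Select the most parsimonious twin model
#'
#' Implements the nested-model selection rule: fit ACE and its submodels,
#' keep every submodel whose likelihood-ratio test against ACE is
#' nonsignificant (p > alpha, ACE itself always eligible), and choose the
#' eligible model with the lowest AIC. Ties break toward fewer parameters,
#' then AE before CE.
#'
#' @param fits Named list of `ace_fit`s for `ACE`, `AE`, `CE`, `E`.
#' @param alpha Significance level for the LRT gate; default 0.05.
#' @return An object of class `ace_selection`: the fits, the LRT table, the
#'   chosen label, and the ACE-vs-CE test (the significance test of the
#'   additive-genetic component).
#' @export
select_ace_model <- function(fits, alpha = 0.05) {
  needed <- c("ACE", "AE", "CE", "E")
  if (!all(needed %in% names(fits))) {
    abort("`fits` must contain models ACE, AE, CE and E.")
  }
  lrt <- dplyr::bind_rows(lapply(c("AE", "CE", "E"), function(m) {
    dplyr::bind_cols(
      tibble::tibble(model = m),
      likelihood_ratio_test(fits$ACE, fits[[m]])
    )
  }))
  eligible <- c("ACE", lrt$model[lrt$p_value > alpha])
  cand <- tibble::tibble(
    model = eligible,
    aic = vapply(eligible, function(m) fits[[m]]$aic, numeric(1)),
    k = vapply(eligible, function(m) fits[[m]]$n_params, numeric(1)),
    pref = match(eligible, c("AE", "CE", "ACE", "E"))
  )
  cand <- cand[order(cand$aic, cand$k, cand$pref), ]
  chosen <- cand$model[1]
  structure(
    list(
      fits = fits,
      lrt = lrt,
      chosen = chosen,
      lrt_ace_vs_ce = lrt[lrt$model == "CE", c("statistic", "df", "p_value")],
      alpha = alpha
    ),
    class = "ace_selection"
  )
}

#' @export
print.ace_selection <- function(x, ...) {
  cat(sprintf("<ace_selection> chosen: %s\n", x$chosen))
  tab <- dplyr::bind_rows(lapply(x$fits, glance))
  print(dplyr::left_join(tab, x$lrt[c("model", "p_value")], by = "model"))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up false-discovery-rate adjustment across traits, with the
#' usual monotonicity enforcement (cumulative minimum from the largest
#' rank).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) < 1) abort("Need at least one p-value.")
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Full per-trait twin analysis
#'
#' Runs the complete variance-decomposition workflow for every trait column:
#' pair construction, zygosity correlations and Falconer's estimate,
#' equal-means/equal-variances assumption tests with Bonferroni gating,
#' maximum-likelihood fits of ACE and its nested submodels, parsimonious
#' model selection, profile-likelihood CIs on the chosen model, and
#' Benjamini-Hochberg FDR adjustment of the ACE-vs-CE p-values across all
#' analyzed traits.
#'
#' @param traits Tibble: `participant_id` plus one standardized trait column
#'   per trait (see [prepare_traits()]).
#' @param participants Participant table with `pair_id`, `zygosity`.
#' @param alpha Significance level for LRT gating; default 0.05.
#' @param ci Compute profile-likelihood CIs for the chosen model of each
#'   trait.
#' @return An object of class `twin_ace_result` wrapping a per-trait tibble
#'   (`$table`) with correlations, Falconer h2, assumption p-values, chosen
#'   model, standardized components with CIs, ACE-vs-CE LRT p and FDR q,
#'   plus the full fit objects in `$selections`.
#' @export
twin_ace <- function(traits, participants, alpha = 0.05, ci = TRUE) {
  trait_names <- setdiff(names(traits), "participant_id")
  n_traits <- length(trait_names)
  if (n_traits == 0) abort("No trait columns to analyze.")
  selections <- list()
  rows <- vector("list", n_traits)
  for (i in seq_along(trait_names)) {
    tn <- trait_names[i]
    pairs <- make_twin_pairs(
      tibble::tibble(participant_id = traits$participant_id, value = traits[[tn]]),
      participants
    )
    co <- pair_correlations(pairs)
    fal <- falconer_h2(co)
    as_ <- assumption_tests(pairs, n_traits = n_traits)
    base <- tibble::tibble(
      trait = tn,
      n_mz_pairs = co$n_mz_pairs, n_dz_pairs = co$n_dz_pairs,
      r_mz = co$r_mz, r_dz = co$r_dz, genetic_signal = co$genetic_signal,
      falconer_h2 = fal$h2,
      welch_p = as_$welch_p, f_p = as_$f_p, assumptions_passed = as_$passed
    )
    if (!as_$passed) {
      rows[[i]] <- dplyr::bind_cols(base, tibble::tibble(
        chosen = NA_character_, a2 = NA_real_, c2 = NA_real_, e2 = NA_real_,
        a2_lower = NA_real_, a2_upper = NA_real_,
        lrt_ace_vs_ce_p = NA_real_
      ))
      next
    }
    fits <- lapply(
      setNames(c("ACE", "AE", "CE", "E"), c("ACE", "AE", "CE", "E")),
      function(m) fit_ace(pairs, m, ci = FALSE)
    )
    sel <- select_ace_model(fits, alpha = alpha)
    chosen_fit <- fits[[sel$chosen]]
    if (ci) chosen_fit$ci <- ace_profile_ci(chosen_fit)
    sel$fits[[sel$chosen]] <- chosen_fit
    selections[[tn]] <- sel
    a2ci <- if (ci && "a2" %in% chosen_fit$ci$component) {
      chosen_fit$ci[chosen_fit$ci$component == "a2", ]
    } else {
      tibble::tibble(lower = NA_real_, upper = NA_real_)
    }
    rows[[i]] <- dplyr::bind_cols(base, tibble::tibble(
      chosen = sel$chosen,
      a2 = chosen_fit$a2, c2 = chosen_fit$c2, e2 = chosen_fit$e2,
      a2_lower = a2ci$lower, a2_upper = a2ci$upper,
      lrt_ace_vs_ce_p = sel$lrt_ace_vs_ce$p_value
    ))
  }
  table <- dplyr::bind_rows(rows)
  analyzed <- !is.na(table$lrt_ace_vs_ce_p)
  table$fdr_q <- NA_real_
  if (any(analyzed)) {
    table$fdr_q[analyzed] <- fdr_adjust(table$lrt_ace_vs_ce_p[analyzed])
  }
  structure(
    list(table = table, selections = selections, alpha = alpha),
    class = "twin_ace_result"
  )
}

#' @export
print.twin_ace_result <- function(x, ...) {
  cat(sprintf(
    "<twin_ace_result> %d traits (%d passed assumptions)\n",
    nrow(x$table), sum(x$table$assumptions_passed)
  ))
  print(dplyr::select(
    x$table, "trait", "r_mz", "r_dz", "chosen", "a2", "a2_lower",
    "a2_upper", "fdr_q"
  ))
  invisible(x)
}

#' @rdname twin_ace
#' @param x A `twin_ace_result`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.twin_ace_result <- function(x, ...) x$table

#' @rdname twin_ace
#' @export
#' @exportS3Method generics::glance
glance.twin_ace_result <- function(x, ...) {
  tab <- x$table
  tibble::tibble(
    n_traits = nrow(tab),
    n_passed_assumptions = sum(tab$assumptions_passed),
    n_ae = sum(tab$chosen == "AE", na.rm = TRUE),
    n_ace = sum(tab$chosen == "ACE", na.rm = TRUE),
    n_ce = sum(tab$chosen == "CE", na.rm = TRUE),
    n_e = sum(tab$chosen == "E", na.rm = TRUE),
    mean_a2 = mean(tab$a2, na.rm = TRUE),
    mean_r_mz = mean(tab$r_mz),
    mean_r_dz = mean(tab$r_dz)
  )
}
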