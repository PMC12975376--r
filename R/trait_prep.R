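#' Moment-based sample skewness
#'
#' Fisher-Pearson g1 skewness, m3 / m2^(3/2) with central moments using the
#' plain 1/n denominator (no small-sample correction). This is the statistic
#' compared against the +/-1 screening threshold.
#'
#' @param x Numeric vector, at least 3 finite values.
#' @return Skewness as a single number.
#' @export
skewness_g1 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) abort("Skewness needs at least 3 finite values.")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' Screen a trait for skewness and log-transform if needed
#'
#' Computes the g1 skewness of the raw values; when its absolute value is
#' strictly above the threshold (default 1), applies `log10(x + offset)`
#' (default offset 1, keeping zero intakes at zero) and records the
#' post-transform skewness. Already-transformed input (flagged) is never
#' transformed twice.
#'
#' @param x Nonnegative trait values.
#' @param threshold Absolute skewness above which to transform; default 1.
#' @param offset Offset inside the log; default 1.
#' @param already_transformed Set `TRUE` to make the call a no-op beyond
#'   recording skewness (idempotence guard).
#' @return A list: `values`, `log_transformed`, `skewness_raw`,
#'   `skewness_final`.
#' @export
#' @examples
#' screen_and_transform(c(0, 0, 0, 0, 0, 0, 0, 100))$log_transformed  # TRUE
screen_and_transform <- function(x, threshold = 1, offset = 1,
                                 already_transformed = FALSE) {
  if (any(x < 0, na.rm = TRUE)) {
    abort("Negative trait values: intakes are nonnegative by construction.")
  }
  if (length(x[is.finite(x)]) < 8) {
    abort("Skewness screening needs at least 8 finite values.")
  }
  sk <- skewness_g1(x)
  if (already_transformed || abs(sk) <= threshold) {
    return(list(
      values = x, log_transformed = already_transformed,
      skewness_raw = sk, skewness_final = sk
    ))
  }
  y <- log10(x + offset)
  list(
    values = y, log_transformed = TRUE,
    skewness_raw = sk, skewness_final = skewness_g1(y)
  )
}

#' Covariate sets per trait class
#'
#' The fixed default adjustment sets: food groups and nutrients are adjusted
#' for sex, body weight, total energy and a sex-energy interaction; total
#' energy for sex and body weight; diet indices for sex, body weight and
#' total energy; taste preferences for sex only.
#'
#' @return Named list mapping trait class to covariate term vector.
#' @export
trait_covariate_sets <- function() {
  list(
    food_group = c("sex", "weight", "energy", "sex:energy"),
    nutrient = c("sex", "weight", "energy", "sex:energy"),
    energy = c("sex", "weight"),
    index = c("sex", "weight", "energy"),
    taste = c("sex")
  )
}

#' Residualize a trait on its class-specific covariates
#'
#' Ordinary least-squares adjustment of the (possibly log-transformed) trait
#' on the covariate set of its class, followed by standardization of the
#' residuals to mean 0, SD 1 (sample SD, n-1 denominator). Sex enters as a
#' binary indicator (female = 1); the interaction term is the product of
#' that indicator with energy.
#'
#' @param values Trait values, one per participant row of `covariates`.
#' @param covariates Tibble with columns `sex` ("F"/"M"), `weight_kg` and
#'   `energy_kcal` (complete; impute weight first with [impute_weight()]).
#' @param trait_class One of `"food_group"`, `"nutrient"`, `"energy"`,
#'   `"index"`, `"taste"`.
#' @param covariate_terms Optional override of the class default terms.
#' @return A list: `values` (standardized residuals), `coefficients` (the
#'   OLS fit), `terms`.
#' @export
residualize <- function(values, covariates, trait_class,
                        covariate_terms = NULL) {
  terms <- covariate_terms %||% trait_covariate_sets()[[trait_class]]
  if (is.null(terms)) abort(sprintf("Unknown trait class `%s`.", trait_class))
  df <- tibble::tibble(
    y = values,
    sex = as.numeric(covariates$sex == "F"),
    weight = covariates$weight_kg,
    energy = covariates$energy_kcal
  )
  if (anyNA(df)) abort("Covariate columns must be complete before residualization.")
  fml <- stats::reformulate(terms, response = "y")
  fit <- lm(fml, data = df)
  if (any(is.na(coef(fit)))) {
    abort(paste0(
      "Rank-deficient adjustment design; collinear terms: ",
      paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")
    ))
  }
  r <- residuals(fit)
  s <- sd(r)
  if (s == 0) abort("Residuals are constant; cannot standardize.")
  list(values = as.numeric((r - mean(r)) / s), coefficients = coef(fit), terms = terms)
}

#' Prepare traits for twin modeling
#'
#' Full preparation of a trait table: for every trait column, screen for
#' skewness and log10-transform when |g1| > 1, residualize on the
#' class-specific covariate set, and standardize to mean 0, SD 1. The
#' pipeline order is fixed: transform, then residualize, then standardize.
#'
#' @param traits Tibble: `participant_id` plus one column per trait.
#' @param trait_classes Named character vector mapping every trait column to
#'   its class (see [trait_covariate_sets()]).
#' @param participants Participant table (sex, weight; weight gaps are
#'   median-imputed by sex).
#' @param energy Numeric vector of total energy intake (kcal/day) aligned
#'   with `traits` rows; used as covariate.
#' @return A list of class `prepared_traits`: `values` (tibble,
#'   `participant_id` + standardized trait columns) and `log` (tibble of
#'   per-trait provenance: class, skewness before/after, transform flag,
#'   covariate terms).
#' @export
prepare_traits <- function(traits, trait_classes, participants, energy) {
  trait_names <- setdiff(names(traits), "participant_id")
  missing_cls <- setdiff(trait_names, names(trait_classes))
  if (length(missing_cls) > 0) {
    abort(paste0(
      "No trait class declared for: ", paste(head(missing_cls, 5), collapse = ", ")
    ))
  }
  participants <- impute_weight(participants)
  pp <- participants[match(traits$participant_id, participants$participant_id), ]
  covs <- tibble::tibble(
    sex = pp$sex, weight_kg = pp$weight_kg, energy_kcal = energy
  )
  out <- list()
  logs <- vector("list", length(trait_names))
  for (i in seq_along(trait_names)) {
    tn <- trait_names[i]
    cls <- trait_classes[[tn]]
    st <- screen_and_transform(traits[[tn]])
    rs <- residualize(st$values, covs, cls)
    out[[tn]] <- rs$values
    logs[[i]] <- tibble::tibble(
      trait = tn, trait_class = cls,
      skewness_raw = st$skewness_raw,
      log_transformed = st$log_transformed,
      skewness_final = st$skewness_final,
      covariates = paste(rs$terms, collapse = " + ")
    )
  }
  structure(
    list(
      values = tibble::as_tibble(
        c(list(participant_id = traits$participant_id), out[trait_names])
      ),
      log = dplyr::bind_rows(logs)
    ),
    class = "prepared_traits"
  )
}

#' @export
print.prepared_traits <- function(x, ...) {
  cat("<prepared_traits>\n")
  cat(sprintf(
    "  %d traits x %d participants; %d log10-transformed\n",
    nrow(x$log), nrow(x$values), sum(x$log$log_transformed)
  ))
  invisible(x)
}
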