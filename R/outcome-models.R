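#' Standardize numeric columns to mean 0, sd 1
#'
#' Uses the sample standard deviation (denominator `n - 1`). Idempotent on
#' already-standardized columns.
#'
#' @param data A data frame.
#' @param columns Character vector of column names to standardize.
#' @return The data frame with the named columns standardized.
#' @export
standardize_columns <- function(data, columns) {
  for (cn in columns) {
    x <- data[[cn]]
    if (!is.numeric(x))
      ms_abort(sprintf("column %s is not numeric", cn), "ms_parameter_error")
    s <- sd(x)
    if (!is.finite(s) || s == 0)
      ms_abort(sprintf("column %s has zero variance", cn),
               "ms_standardization_error")
    data[[cn]] <- (x - mean(x)) / s
  }
  data
}

#' Fit the city fixed-effects outcome regression
#'
#' Ordinary least squares of an outcome on the behavior weights, the four
#' area demographics, and a city fixed effect (dummy encoding, first level
#' dropped): `y_i ~ sum_j beta_j w_ij + sum_l gamma_l d_il + city_i + eps_i`.
#' Regressors enter on their raw scale, so coefficients recover generating
#' values directly; standardized coefficients (`estimate * sd(x) / sd(y)`)
#' are reported alongside for comparability across terms.
#'
#' Behavior weights recovered by a converged KL factorization are exactly
#' compositional: each user's weights sum to the (constant) total mass of
#' their activity vector, so the weight block spans the constant and an
#' explicit intercept would make the design singular. When the weight block
#' is detected as compositional the intercept is dropped and absorbed by the
#' weights; the reference level of the city factor is still dropped, and the
#' R-squared is always computed centered (`1 - RSS/TSS`), which remains
#' valid because the constant stays inside the model span.
#'
#' @param data Data frame holding the outcome, regressors, and fixed-effect
#'   factor.
#' @param outcome Name of the outcome column.
#' @param behavior_cols Character vector of behavior-weight columns (may be
#'   empty for a demographics-only model).
#' @param demo_cols Character vector of demographic columns (may be empty).
#' @param fe_col Name of the city factor column, or `NULL` for no fixed
#'   effect.
#' @param robust Use HC1 heteroskedasticity-robust standard errors instead
#'   of classical ones (default `FALSE`).
#' @return A list of class `fe_fit`: `coefficients` (tibble of term,
#'   estimate, se, std_estimate, term class), `r_squared`, `n`,
#'   `variant`, and the underlying `lm` fit.
#' @export
fit_fixed_effects <- function(data, outcome, behavior_cols, demo_cols,
                              fe_col = "city_id", robust = FALSE) {
  terms <- c(behavior_cols, demo_cols)
  if (length(terms) == 0)
    ms_abort("no regressors supplied", "ms_parameter_error")
  compositional <- FALSE
  if (length(behavior_cols) > 1) {
    rs <- rowSums(data[, behavior_cols, drop = FALSE])
    compositional <- sd(rs) < 1e-4 * max(mean(abs(rs)), 1e-12)
  }
  # build the design explicitly: optional intercept, regressors, and city
  # dummies with the reference level dropped
  df <- data.frame(.outcome = data[[outcome]], check.names = FALSE)
  cols <- character(0)
  if (!compositional) {
    df[["(Intercept)"]] <- 1
    cols <- "(Intercept)"
  }
  for (cn in terms) df[[cn]] <- data[[cn]]
  cols <- c(cols, terms)
  if (!is.null(fe_col)) {
    f <- factor(data[[fe_col]])
    if (nlevels(f) >= 2) {
      for (lv in levels(f)[-1]) {
        nm <- paste0(fe_col, lv)
        df[[nm]] <- as.numeric(f == lv)
        cols <- c(cols, nm)
      }
    }
  }
  if (nrow(df) <= length(cols))
    ms_abort("more regressors than observations", "ms_parameter_error")
  fml <- stats::as.formula(
    paste("`.outcome` ~ 0 +", paste(sprintf("`%s`", cols), collapse = " + ")))
  fit <- lm(fml, data = df)
  if (anyNA(coef(fit)))
    ms_abort(paste("collinear design; offending terms:",
                   paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
             "ms_collinearity_error")
  sm <- summary(fit)
  ses <- if (robust) sqrt(diag(hc1_vcov(fit))) else sm$coefficients[, "Std. Error"]
  est <- coef(fit)
  y <- data[[outcome]]
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  sy <- sd(y)
  std <- vapply(names(est), function(tn) {
    raw <- gsub("`", "", tn)
    if (raw %in% terms) est[[tn]] * sd(data[[raw]]) / sy else NA_real_
  }, numeric(1))
  term_names <- gsub("`", "", names(est))
  coefs <- tibble::tibble(
    term = term_names,
    estimate = unname(est),
    se = unname(ses),
    std_estimate = unname(std),
    class = ifelse(term_names %in% behavior_cols, "behavior",
                   ifelse(term_names %in% demo_cols, "demographic",
                          "fixed_effect")))
  structure(list(coefficients = coefs, r_squared = r2,
                 n = nrow(df),
                 variant = paste(c(if (length(behavior_cols)) "M",
                                   if (length(demo_cols)) "D"), collapse = "+"),
                 compositional = compositional,
                 fit = fit),
            class = "fe_fit")
}

# HC1 sandwich covariance for lm
hc1_vcov <- function(fit) {
  Xm <- stats::model.matrix(fit)
  u <- stats::residuals(fit)
  n <- nrow(Xm); p <- ncol(Xm)
  bread <- solve(crossprod(Xm))
  meat <- crossprod(Xm * u)
  n / (n - p) * bread %*% meat %*% bread
}

#' R-squared decomposition across model variants
#'
#' Fits three nested models on the same observations -- demographics only
#' (D), behavior weights only (M), and both (M+D) -- all including the city
#' fixed effect, mirroring the variance-decomposition comparison of census
#' features against latent behaviors.
#'
#' @inheritParams fit_fixed_effects
#' @return A named list of `fe_fit` objects `D`, `M`, `MD`.
#' @export
r2_decomposition <- function(data, outcome, behavior_cols, demo_cols,
                             fe_col = "city_id") {
  keep <- complete.cases(data[, c(outcome, behavior_cols, demo_cols,
                                  fe_col), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  list(D = fit_fixed_effects(d, outcome, character(0), demo_cols, fe_col),
       M = fit_fixed_effects(d, outcome, behavior_cols, character(0), fe_col),
       MD = fit_fixed_effects(d, outcome, behavior_cols, demo_cols, fe_col))
}

#' Aggregate user weights to tract-level means
#'
#' @param W User-by-behavior weight matrix with user ids as rownames.
#' @param tract_map Tibble with `user_id` and `tract_id` (e.g. the home
#'   area) for every user in `W`.
#' @return A tibble with `tract_id`, `n_users`, and one mean-weight column
#'   per behavior.
#' @export
aggregate_tract_weights <- function(W, tract_map) {
  stopifnot(!is.null(rownames(W)))
  idx <- match(rownames(W), tract_map$user_id)
  if (anyNA(idx))
    ms_abort("every user in W must be mapped to a tract", "ms_consistency_error")
  tract <- tract_map$tract_id[idx]
  beh <- colnames(W)
  if (is.null(beh)) beh <- sprintf("behavior_%02d", seq_len(ncol(W)))
  agg <- rowsum(W, tract) / as.vector(table(tract)[sort(unique(tract))])
  out <- tibble::tibble(tract_id = rownames(agg),
                        n_users = as.integer(table(tract)[rownames(agg)]))
  for (j in seq_along(beh)) out[[beh[j]]] <- unname(agg[, j])
  out
}

#' Correlation screen of behavior weights against demographics
#'
#' Pearson correlations between every behavior weight and every demographic
#' feature of the user's home area, plus the R-squared of each behavior
#' weight regressed on all four features jointly -- the screen for whether
#' latent behaviors are explainable by census-type traits.
#'
#' @param W User-by-behavior weight matrix with user ids as rownames.
#' @param users Tibble with `user_id`, `home_area`.
#' @param demographics Area table with `area_id` and the feature columns.
#' @param features Demographic columns to use (default the four used in the
#'   outcome models).
#' @return A list with `correlations` (behaviors x features matrix) and
#'   `r_squared` (named vector per behavior); attribute `n_dropped` counts
#'   users without a demographics join.
#' @export
weight_demographics_correlation <- function(W, users, demographics,
                                            features = c("median_income", "density",
                                                         "frac_black", "frac_transit")) {
  stopifnot(!is.null(rownames(W)))
  d <- dplyr::left_join(tibble::tibble(user_id = rownames(W)),
                        users[, c("user_id", "home_area")], by = "user_id")
  d <- dplyr::left_join(d, demographics, by = c(home_area = "area_id"))
  ok <- complete.cases(d[, features])
  n_dropped <- sum(!ok)
  Wok <- W[ok, , drop = FALSE]
  Fm <- as.matrix(d[ok, features])
  beh <- colnames(W)
  if (is.null(beh)) beh <- sprintf("behavior_%02d", seq_len(ncol(W)))
  cors <- cor(Wok, Fm)
  dimnames(cors) <- list(beh, features)
  r2 <- vapply(seq_len(ncol(Wok)), function(j) {
    summary(lm(Wok[, j] ~ Fm))$r.squared
  }, numeric(1))
  names(r2) <- beh
  out <- list(correlations = cors, r_squared = r2)
  attr(out, "n_dropped") <- n_dropped
  out
}
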