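make_regression_data <- function(n = 600, seed = 1, n_cities = 3) {
  model <- generate_planted_behaviors(4, 20, seed = seed)
  W <- generate_user_weights(n, model, 0.5, seed = seed + 1)
  demo <- generate_demographics(8, n_cities, seed = seed + 2)
  users <- tibble::tibble(
    user_id = rownames(W),
    city_id = rep(sprintf("city_%02d", seq_len(n_cities)), length.out = n))
  users$home_area <- withr::with_seed(seed + 3, vapply(users$city_id, function(ct)
    sample(demo$area_id[demo$city_id == ct], 1), character(1)))
  dat <- dplyr::left_join(users, demo, by = c(home_area = "area_id", "city_id"))
  dat <- dplyr::bind_cols(dat, tibble::as_tibble(W))
  list(W = W, users = users, demo = demo, dat = dat,
       demo_cols = c("median_income", "density", "frac_black", "frac_transit"))
}

test_that("column standardization matches the sample-sd convention", {
  d <- tibble::tibble(a = c(1, 2, 3), b = c(10, 10, 40))
  s <- standardize_columns(d, "a")
  expect_equal(s$a, c(-1, 0, 1))
  # idempotent
  expect_equal(standardize_columns(s, "a")$a, s$a, tolerance = 1e-12)
  expect_error(standardize_columns(tibble::tibble(x = rep(2, 5)), "x"),
               class = "ms_standardization_error")
})

test_that("fixed-effects fits recover generating coefficients exactly at zero noise", {
  md <- make_regression_data(n = 600, seed = 111)
  beta <- c(2, -1, 0.5, 3)
  gamma <- c(1e-5, 2e-4, -1.5, 0.8)
  ce <- c(city_01 = 0, city_02 = 1.5, city_03 = -2)
  y <- generate_outcomes(md$W, md$users, md$demo, beta, gamma, ce, noise_sd = 0)
  dat <- md$dat
  dat$outcome <- y$outcome
  f <- fit_fixed_effects(dat, "outcome", paste0("w0", 1:4), md$demo_cols)
  cf <- f$coefficients
  expect_true(f$compositional)
  expect_lt(max(abs(cf$estimate[cf$class == "behavior"] - beta)), 1e-8)
  expect_lt(max(abs(cf$estimate[cf$class == "demographic"] - gamma)), 1e-8)
  expect_gt(f$r_squared, 1 - 1e-8)
  expect_equal(cf$estimate[cf$term == "city_idcity_02"], 1.5, tolerance = 1e-8)
})

test_that("standardized coefficients are invariant to regressor units", {
  md <- make_regression_data(n = 400, seed = 112)
  dat <- md$dat
  dat$outcome <- withr::with_seed(9, 2 * dat$median_income * 1e-5 +
                                    0.5 * dat$w01 + rnorm(nrow(dat)))
  f1 <- fit_fixed_effects(dat, "outcome", paste0("w0", 1:4), md$demo_cols)
  dat2 <- dat
  dat2$median_income <- dat2$median_income / 1000  # change units
  f2 <- fit_fixed_effects(dat2, "outcome", paste0("w0", 1:4), md$demo_cols)
  s1 <- f1$coefficients$std_estimate[f1$coefficients$term == "median_income"]
  s2 <- f2$coefficients$std_estimate[f2$coefficients$term == "median_income"]
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("a collinear design raises an error naming the offending column", {
  md <- make_regression_data(n = 200, seed = 113)
  dat <- md$dat
  dat$dup <- dat$median_income
  dat$outcome <- dat$w01
  expect_error(
    fit_fixed_effects(dat, "outcome", paste0("w0", 1:4),
                      c(md$demo_cols, "dup")),
    class = "ms_collinearity_error")
})

test_that("the R-squared decomposition is nested-monotone", {
  md <- make_regression_data(n = 500, seed = 114)
  dat <- md$dat
  # outcome driven by behaviors only
  dat$outcome <- withr::with_seed(10, as.numeric(md$W %*% c(3, -2, 1, 0.5)) +
                                    rnorm(nrow(dat), 0, 0.1))
  tri <- r2_decomposition(dat, "outcome", paste0("w0", 1:4), md$demo_cols)
  expect_gte(tri$MD$r_squared, max(tri$M$r_squared, tri$D$r_squared) - 1e-10)
  expect_gt(tri$M$r_squared, tri$D$r_squared)
  expect_identical(tri$M$variant, "M")
  expect_identical(tri$D$variant, "D")
  expect_identical(tri$MD$variant, "M+D")

  # pure-noise outcome: all three R-squared near zero
  dat$noiseout <- withr::with_seed(11, rnorm(nrow(dat)))
  tri0 <- r2_decomposition(dat, "noiseout", paste0("w0", 1:4), md$demo_cols)
  expect_lt(tri0$MD$r_squared, 0.05)
  expect_gte(tri0$MD$r_squared, max(tri0$M$r_squared, tri0$D$r_squared) - 1e-10)
})

test_that("tract aggregation averages user weights", {
  W <- rbind(c(1, 0), c(0, 1), c(0.4, 0.6))
  rownames(W) <- c("u1", "u2", "u3")
  colnames(W) <- c("w01", "w02")
  tm <- tibble::tibble(user_id = c("u1", "u2", "u3"),
                       tract_id = c("t1", "t1", "t2"))
  agg <- aggregate_tract_weights(W, tm)
  expect_equal(agg$w01[agg$tract_id == "t1"], 0.5)
  expect_equal(agg$w01[agg$tract_id == "t2"], 0.4)  # single user passthrough
  expect_equal(agg$n_users, c(2L, 1L))
  # row order of W does not matter
  agg2 <- aggregate_tract_weights(W[c(3, 1, 2), ], tm)
  expect_equal(agg2$w01, agg$w01)
  expect_error(aggregate_tract_weights(W, tm[1:2, ]),
               class = "ms_consistency_error")
})

test_that("the weight-demographics screen detects planted and null relations", {
  md <- make_regression_data(n = 5000, seed = 115)
  W <- md$W
  # behavior 1 exactly linear in home income
  W[, 1] <- md$dat$median_income * 1e-5
  screen <- weight_demographics_correlation(W, md$users, md$demo)
  expect_equal(unname(screen$correlations["w01", "median_income"]), 1,
               tolerance = 1e-10)
  # independent weights stay near zero correlation
  W2 <- withr::with_seed(12, matrix(rgamma(5000 * 4, 1), 5000, 4))
  W2 <- W2 / rowSums(W2)
  rownames(W2) <- rownames(md$W); colnames(W2) <- colnames(md$W)
  screen2 <- weight_demographics_correlation(W2, md$users, md$demo)
  expect_lt(max(abs(screen2$correlations)), 0.05)
  # joint R^2 dominates any single squared correlation
  expect_true(all(screen2$r_squared + 1e-12 >=
                    apply(screen2$correlations^2, 1, max)))
})
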