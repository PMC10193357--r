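test_that("planted behavior bases are row-stochastic, sparse, and distinct", {
  m1 <- generate_planted_behaviors(1, 4, sparsity = 0, seed = 1)
  expect_equal(nrow(m1$B_true), 1)
  expect_equal(sum(m1$B_true), 1, tolerance = 1e-9)

  m <- generate_planted_behaviors(3, 248, sparsity = 0.8, seed = 7)
  expect_equal(dim(m$B_true), c(3, 253))
  expect_true(all(abs(rowSums(m$B_true) - 1) < 1e-9))
  expect_true(all(m$B_true >= 0))
  # at sparsity 0.8 at least 20% of category entries stay nonzero per row
  nz <- rowSums(m$B_true[, 1:248] > 0)
  expect_true(all(nz >= 0.2 * 248))
  # temporal block carries the configured share of each row's mass
  expect_equal(unname(rowSums(m$B_true[, 249:253])), rep(0.2, 3),
               tolerance = 1e-9)

  expect_error(generate_planted_behaviors(5, 4, seed = 1),
               class = "ms_infeasible_rank_error")
})

test_that("user weights are Dirichlet rows with entropy governed by alpha", {
  m <- generate_planted_behaviors(12, 40, seed = 2)

  W_conc <- generate_user_weights(200, m, 100, seed = 3)
  expect_true(all(abs(rowSums(W_conc) - 1) < 1e-9))
  expect_true(all(apply(W_conc, 1, weight_entropy) > 0.99))

  # Monte-Carlo: sparse alpha drives the mean normalized entropy below 0.5
  W_sparse <- generate_user_weights(10000, m, 0.05, seed = 4)
  expect_lt(mean(apply(W_sparse, 1, weight_entropy)), 0.5)

  expect_identical(dim(generate_user_weights(0, m, 0.5, seed = 5)), c(0L, 12L))
  expect_error(generate_user_weights(10, m, -1, seed = 6),
               class = "ms_parameter_error")
})

test_that("visit draws follow the planted category distribution", {
  m <- generate_planted_behaviors(3, 25, sparsity = 0.6, seed = 9)
  # one user, one-hot on behavior 2, many visits, no noise
  W <- matrix(c(0, 1, 0), 1, 3, dimnames = list("u00001", NULL))
  cfg <- synthetic_config(n_users_per_city = 1, n_cities = 1,
                          n_areas_per_city = 4, visits_per_user = 10000,
                          noise_rate = 0, seed = 10)
  sim <- generate_visit_records(m, W, cfg)
  expect_gt(nrow(sim$visits), 50)  # passes the visit-count filter by construction
  emp <- table(factor(sim$visits$category, levels = m$category_labels)) /
    nrow(sim$visits)
  truth <- planted_basis_features(m)[2, seq_len(25)]
  expect_lt(sum(abs(as.numeric(emp) - truth)) / 2, 0.05)  # total variation
})

test_that("full-noise visits are uniform over categories", {
  m <- generate_planted_behaviors(3, 20, sparsity = 0.6, seed = 11)
  W <- generate_user_weights(2, m, 0.5, seed = 12)
  cfg <- synthetic_config(n_users_per_city = 2, n_cities = 1,
                          n_areas_per_city = 4, visits_per_user = 5000,
                          noise_rate = 1, seed = 13)
  sim <- generate_visit_records(m, W, cfg)
  counts <- table(factor(sim$visits$category, levels = m$category_labels))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("empirical activity vectors approach the planted mixture as visits grow", {
  m <- generate_planted_behaviors(3, 20, sparsity = 0.6, seed = 21)
  W <- generate_user_weights(1, m, 0.5, seed = 22)
  truth <- as.numeric(W %*% planted_basis_features(m)[, seq_len(20)])
  tv <- sapply(c(100, 5000), function(nv) {
    cfg <- synthetic_config(1, 1, 4, visits_per_user = nv, noise_rate = 0,
                            seed = 23)
    sim <- generate_visit_records(m, W, cfg)
    emp <- as.numeric(table(factor(sim$visits$category,
                                   levels = m$category_labels))) / nv
    sum(abs(emp - truth)) / 2
  })
  expect_lt(tv[2], tv[1])
})

test_that("synthetic tables are deterministic in the seed", {
  m <- generate_planted_behaviors(3, 15, seed = 31)
  W <- generate_user_weights(10, m, 0.5, seed = 32)
  cfg <- synthetic_config(10, 1, 5, visits_per_user = 20, seed = 33)
  demo <- generate_demographics(5, 1, seed = 34)
  s1 <- generate_visit_records(m, W, cfg, demo)
  s2 <- generate_visit_records(m, W, cfg, demo)
  expect_identical(s1$visits, s2$visits)
  expect_identical(s1$night_pings, s2$night_pings)
  cfg2 <- synthetic_config(10, 1, 5, visits_per_user = 20, seed = 99)
  s3 <- generate_visit_records(m, W, cfg2, demo)
  expect_false(identical(s1$visits$venue_id, s3$visits$venue_id))

  expect_identical(generate_demographics(6, 2, seed = 1),
                   generate_demographics(6, 2, seed = 1))
  expect_false(identical(generate_demographics(6, 2, seed = 1),
                         generate_demographics(6, 2, seed = 2)))
})

test_that("demographics tables have distinct incomes and valid fractions", {
  d <- generate_demographics(4, 1, seed = 41)
  expect_equal(nrow(d), 4)
  expect_equal(length(unique(d$median_income)), 4)
  for (cn in c("frac_black", "frac_transit", "frac_long_commute"))
    expect_true(all(d[[cn]] >= 0 & d[[cn]] <= 1))
  expect_error(generate_demographics(3, 1, seed = 42),
               class = "ms_quartile_infeasible_error")
})

test_that("generated outcomes follow the stated linear model", {
  m <- generate_planted_behaviors(4, 15, seed = 51)
  W <- generate_user_weights(40, m, 0.5, seed = 52)
  demo <- generate_demographics(5, 1, seed = 53)
  users <- tibble::tibble(user_id = rownames(W), city_id = "city_01",
                          home_area = rep(demo$area_id, length.out = 40))
  y0 <- generate_outcomes(W, users, demo, beta = rep(0, 4), gamma = rep(0, 4),
                          city_effects = 0, noise_sd = 0)
  expect_true(all(y0$outcome == 0))
  # linear in the regressors when noise-free
  y1 <- generate_outcomes(W, users, demo, beta = 1:4, gamma = c(0, 0, 0, 0),
                          city_effects = 0, noise_sd = 0)
  expect_equal(y1$outcome, as.numeric(W %*% (1:4)), tolerance = 1e-12)
  expect_error(generate_outcomes(W, users, demo, beta = 1:4, gamma = rep(0, 4),
                                 noise_sd = -1),
               class = "ms_parameter_error")
})

test_that("synthetic data round-trips through CSV", {
  m <- generate_planted_behaviors(2, 10, seed = 61)
  W <- generate_user_weights(5, m, 0.5, seed = 62)
  cfg <- synthetic_config(5, 1, 4, visits_per_user = 10, seed = 63)
  sim <- generate_visit_records(m, W, cfg)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_data(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["visits"]], stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(sim$visits))
  expect_match(back$start_time[1], "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}\\+00:00$")
})
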