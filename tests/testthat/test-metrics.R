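test_that("normalized weight entropy matches its closed forms", {
  one_hot <- c(1, rep(0, 11))
  expect_equal(weight_entropy(one_hot), 0)
  expect_equal(weight_entropy(rep(1 / 12, 12)), 1, tolerance = 1e-12)
  # two equal behaviors out of 12: log 2 / log 12
  expect_equal(weight_entropy(c(0.5, 0.5, rep(0, 10))), log(2) / log(12),
               tolerance = 1e-12)
  # scale and permutation invariance
  w <- c(4, 1, 3, 0, 2, rep(0, 7))
  expect_equal(weight_entropy(w), weight_entropy(10 * w), tolerance = 1e-12)
  expect_equal(weight_entropy(w), weight_entropy(rev(w)), tolerance = 1e-12)
  expect_error(weight_entropy(c(1)), class = "ms_parameter_error")
  expect_error(weight_entropy(rep(0, 12)), class = "ms_undefined_entropy_error")
})

test_that("income quartiles split per city with ties to the lower quartile", {
  demo <- tibble::tibble(area_id = sprintf("a%02d", 1:8), city_id = "c1",
                         median_income = 1:8)
  users <- tibble::tibble(user_id = sprintf("u%d", 1:8),
                          home_area = sprintf("a%02d", 1:8), city_id = "c1")
  q <- assign_income_quartiles(users, demo)
  expect_equal(q$income_quartile, c(1, 1, 2, 2, 3, 3, 4, 4))

  # two cities quartile independently
  demo2 <- dplyr::bind_rows(demo,
                            tibble::tibble(area_id = sprintf("b%02d", 1:8),
                                           city_id = "c2",
                                           median_income = 101:108))
  users2 <- dplyr::bind_rows(users,
                             tibble::tibble(user_id = sprintf("v%d", 1:8),
                                            home_area = sprintf("b%02d", 1:8),
                                            city_id = "c2"))
  q2 <- assign_income_quartiles(users2, demo2)
  expect_equal(q2$income_quartile[q2$city_id == "c2"], c(1, 1, 2, 2, 3, 3, 4, 4))

  # income exactly at the 25th percentile goes to the lower quartile
  demo3 <- tibble::tibble(area_id = sprintf("a%d", 1:5), city_id = "c1",
                          median_income = c(10, 20, 30, 40, 50))
  users3 <- tibble::tibble(user_id = sprintf("u%d", 1:5),
                           home_area = sprintf("a%d", 1:5), city_id = "c1")
  q3 <- assign_income_quartiles(users3, demo3)
  # quantile(10..50, .25) = 20 exactly; the income-20 user stays in q1
  expect_equal(q3$income_quartile[q3$home_area == "a2"], 1)

  expect_error(assign_income_quartiles(
    tibble::tibble(user_id = "u1", home_area = "zz", city_id = "c1"), demo),
    class = "ms_consistency_error")
})

test_that("place and group time shares match hand counts", {
  visits <- tibble::tibble(
    user_id = c("u1", "u1", "u2", "u3"),
    venue_id = c("alpha", "beta", "alpha", "alpha"),
    dwell_min = c(60, 60, 10, 20))
  # u1 and u2 in quartile 1 and 1, u3 in quartile 3
  quart <- tibble::tibble(user_id = c("u1", "u2", "u3"),
                          income_quartile = c(1L, 1L, 3L))
  sh <- place_time_shares(visits, quart)
  t1 <- sh$tau_ialpha[sh$tau_ialpha$user_id == "u1", ]
  expect_equal(sort(t1$share), c(0.5, 0.5))
  # alpha: q1 gets 60+10 = 70 of 90, q3 gets 20 of 90
  ta <- sh$tau_qalpha[sh$tau_qalpha$venue_id == "alpha", ]
  expect_equal(unname(unlist(ta[, c("q1", "q2", "q3", "q4")])),
               c(70 / 90, 0, 20 / 90, 0), tolerance = 1e-12)
  # beta visited only by a q1 user
  tb <- sh$tau_qalpha[sh$tau_qalpha$venue_id == "beta", ]
  expect_equal(unname(unlist(tb[, c("q1", "q2", "q3", "q4")])), c(1, 0, 0, 0))

  # spec hand count: 3 users (q 1, 1, 3) spending 10/10/20 at one place
  v2 <- tibble::tibble(user_id = c("a", "b", "c"), venue_id = "p",
                       dwell_min = c(10, 10, 20))
  q2 <- tibble::tibble(user_id = c("a", "b", "c"), income_quartile = c(1L, 1L, 3L))
  sh2 <- place_time_shares(v2, q2)
  expect_equal(unname(unlist(sh2$tau_qalpha[1, c("q1", "q2", "q3", "q4")])),
               c(0.5, 0, 0.5, 0), tolerance = 1e-12)
})

test_that("group exposure is the stochastic product of the share maps", {
  # one place dominated by q2
  sh <- list(
    tau_ialpha = tibble::tibble(user_id = "u1", venue_id = "p1", share = 1),
    tau_qalpha = tibble::tibble(venue_id = "p1", q1 = 0, q2 = 1, q3 = 0, q4 = 0))
  tau <- group_exposure(sh)
  expect_equal(unname(unlist(tau[1, -1])), c(0, 1, 0, 0))

  # two places, half time each, one-hot on different groups
  sh2 <- list(
    tau_ialpha = tibble::tibble(user_id = "u1", venue_id = c("p1", "p2"),
                                share = c(0.5, 0.5)),
    tau_qalpha = tibble::tibble(venue_id = c("p1", "p2"),
                                q1 = c(1, 0), q2 = c(0, 1), q3 = 0, q4 = 0))
  expect_equal(unname(unlist(group_exposure(sh2)[1, -1])), c(0.5, 0.5, 0, 0))

  # uniform composition everywhere gives uniform exposure
  sh3 <- list(
    tau_ialpha = tibble::tibble(user_id = "u1", venue_id = c("p1", "p2"),
                                share = c(0.3, 0.7)),
    tau_qalpha = tibble::tibble(venue_id = c("p1", "p2"), q1 = 0.25, q2 = 0.25,
                                q3 = 0.25, q4 = 0.25))
  expect_equal(unname(unlist(group_exposure(sh3)[1, -1])), rep(0.25, 4))

  # place missing from the composition map is a consistency error
  sh4 <- sh2
  sh4$tau_qalpha <- sh4$tau_qalpha[1, ]
  expect_error(group_exposure(sh4), class = "ms_consistency_error")
})

test_that("integration matches the closed form with exact extremes", {
  expect_equal(integration(c(0.25, 0.25, 0.25, 0.25)), 1)
  expect_equal(integration(c(1, 0, 0, 0)), 0)
  expect_equal(integration(c(0, 0, 1, 0)), 0)
  expect_equal(integration(c(0.5, 0.5, 0, 0)), 1 / 3, tolerance = 1e-12)
  # maximized only at the uniform vector
  set.seed(101)
  for (i in 1:50) {
    g <- rgamma(4, 1); tau <- g / sum(g)
    if (max(abs(tau - 0.25)) > 1e-6) expect_lt(integration(tau), 1)
  }
  expect_error(integration(c(0.5, 0.5, 0.5, 0.5)), class = "ms_contract_error")
})

test_that("exploration is the unique-place ratio", {
  expect_equal(exploration(letters[1:10]), 1)
  expect_equal(exploration(rep("p", 50)), 0.02)
  expect_equal(exploration(c("a", "a", "b", "c")), 0.75)
  expect_error(exploration(character(0)), class = "ms_contract_error")
})

test_that("exposure rows sum to one on generated data", {
  p <- small_planted_matrix(seed = 102, n_users = 40, m_cat = 12, k_true = 2,
                            visits_per_user = 60)
  users <- dplyr::inner_join(p$ingest$homes,
                             p$sim$users[, c("user_id", "city_id")],
                             by = "user_id")
  users <- assign_income_quartiles(users, p$sim$demographics)
  tau <- group_exposure(place_time_shares(p$ingest$visits, users))
  expect_true(all(abs(rowSums(as.matrix(tau[, -1])) - 1) < 1e-9))
  W <- matrix(rgamma(nrow(tau) * 3, 1), nrow(tau), 3)
  W <- W / rowSums(W)
  rownames(W) <- tau$user_id
  stats <- user_behavior_stats(W, p$ingest$visits, tau)
  expect_true(all(stats$integration >= 0 & stats$integration <= 1))
  expect_true(all(stats$exploration > 0 & stats$exploration <= 1))
})

test_that("behavior summaries report per-city and overall means", {
  W <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5), c(0.5, 0.5))
  colnames(W) <- c("w01", "w02")
  s <- summarize_behaviors(W, c("c1", "c1", "c2", "c2"))
  expect_equal(s$mean_weight[s$city == "all" & s$behavior == "w01"], 0.5)
  expect_equal(s$se[s$city == "c2" & s$behavior == "w01"], 0)  # constant rows
  # single city: overall equals the city block
  s1 <- summarize_behaviors(W, rep("c1", 4))
  expect_equal(s1$mean_weight[s1$city == "all"], s1$mean_weight[s1$city == "c1"])
})
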