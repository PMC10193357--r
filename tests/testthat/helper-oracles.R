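# Independent oracles used across tests.

# exhaustive minimum-cost assignment (feasible for n <= 6)
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  best_perm <- NULL
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  for (p in perms(seq_len(n))) {
    cst <- sum(cost[cbind(seq_len(n), p)])
    if (cst < best) { best <- cst; best_perm <- p }
  }
  list(cost = best, perm = best_perm)
}

# cosine between matrix rows, used to check match_factors independently
cos_rows <- function(A, B) {
  (A / sqrt(rowSums(A^2))) %*% t(B / sqrt(rowSums(B^2)))
}

# quick tibble of visits at given times/categories for one or more users
make_visits <- function(user_id, category, time, venue_id = NULL,
                        dwell_min = 30, city_id = "city_01",
                        area_id = "city_01_a001") {
  n <- max(length(user_id), length(category), length(time), length(dwell_min))
  tibble::tibble(
    user_id = rep_len(user_id, n),
    venue_id = rep_len(if (is.null(venue_id)) sprintf("v%03d", seq_len(n)) else venue_id, n),
    category = rep_len(category, n),
    start_time = rep_len(as.POSIXct(time, tz = "UTC"), n),
    dwell_min = rep_len(dwell_min, n),
    area_id = rep_len(area_id, n),
    city_id = rep_len(city_id, n))
}

# small planted dataset run through generation + ingest + features
small_planted_matrix <- function(seed, n_users = 240, m_cat = 30,
                                 k_true = 4, visits_per_user = 80,
                                 noise_rate = 0.05) {
  model <- generate_planted_behaviors(k_true, m_cat, sparsity = 0.8, seed = seed)
  W <- generate_user_weights(n_users, model, 0.5, seed = seed + 1)
  cfg <- synthetic_config(n_users_per_city = n_users, n_cities = 1,
                          n_areas_per_city = 6,
                          visits_per_user = visits_per_user,
                          noise_rate = noise_rate, seed = seed + 2)
  sim <- generate_visit_records(model, W, cfg)
  ing <- suppressWarnings(ingest_visits(sim$visits, sim$night_pings, n_top = m_cat))
  X <- build_activity_matrix(ing$visits, ing$categories)
  list(model = model, W_true = W, sim = sim, ingest = ing, X = X)
}
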