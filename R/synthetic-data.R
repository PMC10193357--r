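#' Generate a planted set of latent activity behaviors
#'
#' Creates the ground-truth behavior basis used by the synthetic mobility
#' generator: a `k_true x (m_cat + 5)` row-stochastic matrix whose first
#' `m_cat` columns are venue-category propensities and whose last 5 columns
#' are temporal propensities (morning, afternoon, evening, weekday, weekend).
#' Each row allocates a fixed share of its mass (`temporal_share`, default
#' 20\%) to the temporal block so both blocks influence the factorization.
#'
#' @param k_true Number of planted behaviors (rank), `>= 1`.
#' @param m_cat Number of venue categories; must be `>= k_true`.
#' @param sparsity Fraction of category entries zeroed per row before
#'   renormalization, in `[0, 1)`. Higher sparsity gives better-separated
#'   behaviors.
#' @param seed Integer seed; fixes the basis exactly.
#' @param temporal_share Share of each row's mass carried by the 5 temporal
#'   features (default 0.2).
#' @return An object of class `planted_model`: a list with `B_true`
#'   (row-stochastic matrix with named columns), `category_labels`, `k_true`,
#'   `temporal_share`, and `seed`.
#' @export
generate_planted_behaviors <- function(k_true, m_cat, sparsity = 0.8, seed = 1L,
                                       temporal_share = 0.2) {
  if (k_true < 1) ms_abort("k_true must be >= 1", "ms_parameter_error")
  if (k_true > m_cat)
    ms_abort("infeasible rank: k_true exceeds the number of categories",
             "ms_infeasible_rank_error")
  if (sparsity < 0 || sparsity >= 1)
    ms_abort("sparsity must be in [0, 1)", "ms_parameter_error")
  if (temporal_share <= 0 || temporal_share >= 1)
    ms_abort("temporal_share must be in (0, 1)", "ms_parameter_error")
  category_labels <- sprintf("cat_%03d", seq_len(m_cat))
  n_zero <- floor(sparsity * m_cat)
  for (attempt in 0:99) {
    B <- withr::with_seed(seed + attempt, {
      cat_block <- matrix(rgamma(k_true * m_cat, shape = 1), k_true, m_cat)
      if (n_zero > 0) {
        for (r in seq_len(k_true)) {
          cat_block[r, sample.int(m_cat, n_zero)] <- 0
        }
      }
      # guard against a fully-zeroed row
      dead <- rowSums(cat_block) == 0
      if (any(dead)) cat_block[dead, 1] <- 1
      cat_block <- cat_block / rowSums(cat_block) * (1 - temporal_share)
      tmp_block <- matrix(rgamma(k_true * 5, shape = 2), k_true, 5)
      tmp_block <- tmp_block / rowSums(tmp_block) * temporal_share
      cbind(cat_block, tmp_block)
    })
    # rows must be pairwise distinct (cosine strictly below 1)
    if (k_true == 1L || max_pairwise_cosine(B) < 1 - 1e-6) {
      colnames(B) <- c(category_labels, temporal_feature_names())
      model <- list(B_true = B, category_labels = category_labels,
                    k_true = k_true, temporal_share = temporal_share,
                    seed = seed)
      class(model) <- "planted_model"
      return(model)
    }
  }
  ms_abort("could not generate pairwise-distinct behaviors in 100 attempts",
           "ms_degenerate_basis_error")
}

temporal_feature_names <- function() {
  c("time_morning", "time_afternoon", "time_evening",
    "time_weekday", "time_weekend")
}

max_pairwise_cosine <- function(B) {
  Bn <- B / sqrt(rowSums(B^2))
  G <- Bn %*% t(Bn)
  max(G[upper.tri(G)])
}

#' Planted behaviors expressed on the activity-feature scale
#'
#' The activity vector built from visits normalizes each block separately:
#' category fractions sum to 1, time-of-day fractions sum to 1, and
#' weekday/weekend fractions sum to 1. A user following planted behavior `j`
#' therefore produces, in expectation, the row of `B_true` with each block
#' renormalized to unit mass. This helper returns that block-renormalized
#' basis, the natural target when comparing a recovered basis to the truth.
#'
#' @param model A `planted_model`.
#' @return A `k_true x (m_cat + 5)` matrix whose category block, time-of-day
#'   block, and week block each sum to 1 per row.
#' @export
planted_basis_features <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  B <- model$B_true
  m_cat <- length(model$category_labels)
  cat_idx <- seq_len(m_cat)
  tod_idx <- m_cat + 1:3
  wk_idx <- m_cat + 4:5
  B[, cat_idx] <- B[, cat_idx, drop = FALSE] / rowSums(B[, cat_idx, drop = FALSE])
  B[, tod_idx] <- B[, tod_idx, drop = FALSE] / rowSums(B[, tod_idx, drop = FALSE])
  B[, wk_idx] <- B[, wk_idx, drop = FALSE] / rowSums(B[, wk_idx, drop = FALSE])
  B
}

#' Generate per-user behavior weights
#'
#' Draws each user's normalized behavior-weight vector from a Dirichlet
#' distribution. Small concentration parameters yield users dominated by a
#' single behavior (low weight entropy); large ones yield near-uniform
#' mixtures (entropy near 1).
#'
#' @param n_users Number of users (rows); may be 0.
#' @param model A `planted_model` (fixes the number of behaviors).
#' @param dirichlet_alpha Positive concentration vector of length `k_true`,
#'   or a single value recycled.
#' @param seed Integer seed.
#' @return An `n_users x k_true` matrix with non-negative rows summing to 1.
#' @export
generate_user_weights <- function(n_users, model, dirichlet_alpha = 0.5, seed = 1L) {
  stopifnot(inherits(model, "planted_model"))
  k <- model$k_true
  if (length(dirichlet_alpha) == 1L) dirichlet_alpha <- rep(dirichlet_alpha, k)
  if (length(dirichlet_alpha) != k)
    ms_abort("dirichlet_alpha must have length k_true", "ms_parameter_error")
  if (any(dirichlet_alpha <= 0))
    ms_abort("dirichlet_alpha entries must be positive", "ms_parameter_error")
  if (n_users == 0L) return(matrix(numeric(0), 0L, k))
  W <- withr::with_seed(seed, {
    g <- matrix(rgamma(n_users * k, shape = rep(dirichlet_alpha, each = n_users)),
                n_users, k)
    # a numerically all-zero row can occur for tiny alpha; resample cheaply
    zero <- rowSums(g) == 0
    while (any(zero)) {
      g[zero, ] <- rgamma(sum(zero) * k, shape = rep(dirichlet_alpha, each = sum(zero)))
      zero <- rowSums(g) == 0
    }
    g / rowSums(g)
  })
  dimnames(W) <- list(sprintf("u%05d", seq_len(n_users)),
                      sprintf("w%02d", seq_len(k)))
  W
}

#' Build a synthetic-data configuration
#'
#' @param n_users_per_city Users simulated in each city.
#' @param n_cities Number of cities.
#' @param n_areas_per_city Census-like areas per city (`>= 4` so income
#'   quartiles are well defined).
#' @param visits_per_user Visits drawn per user (single count, recycled).
#' @param dirichlet_alpha Concentration for user weights (see
#'   [generate_user_weights()]).
#' @param noise_rate Fraction of visits drawn uniformly at random over
#'   categories and time windows instead of from the planted mixture, in
#'   `[0, 1]`.
#' @param n_night_pings Nighttime anchor pings emitted per user at their home
#'   area (makes home inference testable).
#' @param seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_users_per_city = 2000L, n_cities = 3L,
                             n_areas_per_city = 20L, visits_per_user = 60L,
                             dirichlet_alpha = 0.5, noise_rate = 0,
                             n_night_pings = 10L, seed = 1L) {
  if (noise_rate < 0 || noise_rate > 1)
    ms_abort("noise_rate must be in [0, 1]", "ms_parameter_error")
  if (any(c(n_users_per_city, n_cities, n_areas_per_city, visits_per_user) < 1))
    ms_abort("counts must be >= 1", "ms_parameter_error")
  structure(list(n_users_per_city = as.integer(n_users_per_city),
                 n_cities = as.integer(n_cities),
                 n_areas_per_city = as.integer(n_areas_per_city),
                 visits_per_user = as.integer(visits_per_user),
                 dirichlet_alpha = dirichlet_alpha,
                 noise_rate = noise_rate,
                 n_night_pings = as.integer(n_night_pings),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate area-level demographics
#'
#' Emits one row per area with a strictly distinct log-normal median household
#' income within each city (so per-city income quartiles are non-degenerate),
#' a log-normal population density, and Beta-distributed fractions of Black
#' population, public-transport use, and long (>45 min) commutes.
#'
#' @param n_areas_per_city Areas per city, `>= 4`.
#' @param n_cities Number of cities.
#' @param seed Integer seed.
#' @return A tibble with columns `area_id`, `city_id`, `median_income`,
#'   `density`, `frac_black`, `frac_transit`, `frac_long_commute`.
#' @export
generate_demographics <- function(n_areas_per_city, n_cities = 1L, seed = 1L) {
  if (n_areas_per_city < 4)
    ms_abort("need at least 4 areas per city for income quartiles",
             "ms_quartile_infeasible_error")
  withr::with_seed(seed, {
    n <- n_areas_per_city * n_cities
    city_id <- rep(sprintf("city_%02d", seq_len(n_cities)), each = n_areas_per_city)
    income <- exp(rnorm(n, mean = log(60000), sd = 0.5))
    # enforce strict distinctness within city (ties are measure-zero but the
    # quartile contract requires it)
    for (ct in unique(city_id)) {
      idx <- which(city_id == ct)
      while (anyDuplicated(income[idx]))
        income[idx] <- income[idx] + runif(length(idx), 0, 1e-6)
    }
    tibble::tibble(
      area_id = sprintf("%s_a%03d", city_id,
                        rep(seq_len(n_areas_per_city), times = n_cities)),
      city_id = city_id,
      median_income = income,
      density = exp(rnorm(n, mean = log(3000), sd = 0.8)),
      frac_black = rbeta(n, 1.5, 6),
      frac_transit = rbeta(n, 1.2, 8),
      frac_long_commute = rbeta(n, 2, 5))
  })
}

#' Generate synthetic visit records
#'
#' Simulates the raw input of the pipeline. Each user is assigned a home area
#' in their city; each visit draws a behavior from the user's weight vector,
#' then a venue category, a time-of-day window, and a weekday/weekend flag
#' from that behavior's planted propensities (or uniformly at random with
#' probability `noise_rate`). Venues are planted per (area, category) with a
#' Poisson(3) count (minimum 1), and each venue carries a Dirichlet-planted
#' income-group composition that biases which venues users of each income
#' quartile pick, so co-visitation and income-exposure metrics are
#' non-trivial. Nighttime anchor pings (10 pm - 6 am) at the home area are
#' emitted alongside the visits so home inference is testable. All timestamps
#' are ISO-8601 UTC within a six-month window.
#'
#' @param model A `planted_model`.
#' @param weights Row-stochastic user weight matrix from
#'   [generate_user_weights()]; `nrow(weights)` must equal
#'   `n_users_per_city * n_cities`.
#' @param config A `synthetic_config`.
#' @param demographics Area table from [generate_demographics()]; if `NULL`,
#'   one is generated from the config.
#' @return A list of class `synthetic_mobility` with tibbles `visits`
#'   (`user_id`, `venue_id`, `category`, `start_time`, `dwell_min`,
#'   `area_id`, `city_id`), `night_pings` (`user_id`, `area_id`, `city_id`,
#'   `timestamp`), `users` (`user_id`, `home_area`, `city_id`,
#'   `income_quartile`), and `venues`.
#' @export
generate_visit_records <- function(model, weights, config, demographics = NULL) {
  stopifnot(inherits(model, "planted_model"), inherits(config, "synthetic_config"))
  n_users <- nrow(weights)
  if (n_users != config$n_users_per_city * config$n_cities)
    ms_abort("nrow(weights) must equal n_users_per_city * n_cities",
             "ms_parameter_error")
  if (is.null(demographics))
    demographics <- generate_demographics(config$n_areas_per_city,
                                          config$n_cities,
                                          seed = config$seed + 1L)
  m_cat <- length(model$category_labels)
  cat_idx <- seq_len(m_cat)
  Bf <- planted_basis_features(model)
  cat_probs <- Bf[, cat_idx, drop = FALSE]
  tod_probs <- Bf[, m_cat + 1:3, drop = FALSE]
  wk_probs <- Bf[, m_cat + 4:5, drop = FALSE]

  withr::with_seed(config$seed, {
    cities <- sprintf("city_%02d", seq_len(config$n_cities))
    users <- tibble::tibble(
      user_id = sprintf("u%05d", seq_len(n_users)),
      city_id = rep(cities, each = config$n_users_per_city))
    # home area uniform among the city's areas
    users$home_area <- vapply(users$city_id, function(ct) {
      a <- demographics$area_id[demographics$city_id == ct]
      a[sample.int(length(a), 1L)]
    }, character(1))
    # income quartile of the home area within the city (ties to the lower
    # quartile, matching the metrics module)
    users$income_quartile <- NA_integer_
    for (ct in cities) {
      idx <- users$city_id == ct
      inc_map <- setNames(demographics$median_income, demographics$area_id)
      inc <- inc_map[users$home_area[idx]]
      qs <- quantile(demographics$median_income[demographics$city_id == ct],
                     c(0.25, 0.5, 0.75))
      users$income_quartile[idx] <- 1L + (inc > qs[1]) + (inc > qs[2]) + (inc > qs[3])
    }

    # venues: Poisson(3), min 1, per (area, category); planted income-group mix
    grid_area <- rep(demographics$area_id, each = m_cat)
    grid_city <- rep(demographics$city_id, each = m_cat)
    grid_cat <- rep(model$category_labels, times = nrow(demographics))
    n_per <- pmax(1L, rpois(length(grid_area), lambda = 3))
    venues <- tibble::tibble(
      area_id = rep(grid_area, n_per),
      city_id = rep(grid_city, n_per),
      category = rep(grid_cat, n_per))
    venues$venue_id <- sprintf("v%06d", seq_len(nrow(venues)))
    comp <- matrix(rgamma(nrow(venues) * 4, shape = 0.5), ncol = 4)
    comp <- comp / rowSums(comp)
    colnames(comp) <- paste0("comp_q", 1:4)
    venues <- dplyr::bind_cols(venues, tibble::as_tibble(comp))

    # per-visit draws
    v_per_user <- rep(config$visits_per_user, n_users)
    total <- sum(v_per_user)
    vis_user <- rep(seq_len(n_users), v_per_user)
    # behavior per visit: inverse-CDF against each user's cumulative weights
    cw <- t(apply(weights, 1, cumsum))
    u01 <- runif(total)
    beh <- integer(total)
    for (j in seq_len(ncol(weights))) {
      lo <- if (j == 1L) 0 else cw[vis_user, j - 1L]
      beh[u01 >= lo & u01 < cw[vis_user, j]] <- j
    }
    beh[beh == 0L] <- ncol(weights)
    is_noise <- runif(total) < config$noise_rate
    cat_draw <- integer(total); tod_draw <- integer(total); wk_draw <- integer(total)
    for (j in seq_len(model$k_true)) {
      sel <- which(beh == j & !is_noise)
      if (length(sel)) {
        cat_draw[sel] <- sample.int(m_cat, length(sel), replace = TRUE,
                                    prob = cat_probs[j, ])
        tod_draw[sel] <- sample.int(3L, length(sel), replace = TRUE,
                                    prob = tod_probs[j, ])
        wk_draw[sel] <- sample.int(2L, length(sel), replace = TRUE,
                                   prob = wk_probs[j, ])
      }
    }
    if (any(is_noise)) {
      sel <- which(is_noise)
      cat_draw[sel] <- sample.int(m_cat, length(sel), replace = TRUE)
      tod_draw[sel] <- sample.int(3L, length(sel), replace = TRUE)
      wk_draw[sel] <- sample.int(2L, length(sel), replace = TRUE)
    }

    # venue choice: within (city, category), weighted by the venue's planted
    # share of the visitor's income group
    vis_city <- users$city_id[vis_user]
    vis_q <- users$income_quartile[vis_user]
    vis_cat <- model$category_labels[cat_draw]
    venue_pick <- character(total)
    area_pick <- character(total)
    key <- paste(vis_city, vis_cat, vis_q, sep = "|")
    for (k in unique(key)) {
      sel <- which(key == k)
      parts <- strsplit(k, "|", fixed = TRUE)[[1]]
      cand <- which(venues$city_id == parts[1] & venues$category == parts[2])
      w <- comp[cand, as.integer(parts[3])]
      if (sum(w) <= 0) w <- rep(1, length(cand))
      pick <- cand[sample.int(length(cand), length(sel), replace = TRUE, prob = w)]
      venue_pick[sel] <- venues$venue_id[pick]
      area_pick[sel] <- venues$area_id[pick]
    }

    # timestamps: six months in 2017, date consistent with the weekday /
    # weekend draw, uniform time inside the drawn window
    dates <- seq(as.Date("2017-01-01"), as.Date("2017-06-30"), by = "day")
    is_wknd <- format(dates, "%u") %in% c("6", "7")
    wkday_dates <- dates[!is_wknd]; wknd_dates <- dates[is_wknd]
    date_pick <- as.Date(ifelse(wk_draw == 1L,
      wkday_dates[sample.int(length(wkday_dates), total, replace = TRUE)],
      wknd_dates[sample.int(length(wknd_dates), total, replace = TRUE)]),
      origin = "1970-01-01")
    win_lo <- c(5, 12, 18)[tod_draw]
    win_hi <- c(12, 18, 24)[tod_draw]
    secs <- (win_lo + runif(total) * (win_hi - win_lo)) * 3600
    start_time <- as.POSIXct(date_pick, tz = "UTC") + secs

    visits <- tibble::tibble(
      user_id = users$user_id[vis_user],
      venue_id = venue_pick,
      category = vis_cat,
      start_time = start_time,
      dwell_min = runif(total, 6, 180),
      area_id = area_pick,
      city_id = vis_city)

    # night anchor pings at the home area
    np <- config$n_night_pings
    ping_user <- rep(seq_len(n_users), each = np)
    pdates <- dates[sample.int(length(dates), n_users * np, replace = TRUE)]
    # hour uniform over [22, 24) U [0, 6): draw in [0, 8) then shift
    ph <- runif(n_users * np, 0, 8)
    psec <- ifelse(ph < 2, (22 + ph) * 3600, (ph - 2) * 3600)
    night_pings <- tibble::tibble(
      user_id = users$user_id[ping_user],
      area_id = users$home_area[ping_user],
      city_id = users$city_id[ping_user],
      timestamp = as.POSIXct(pdates, tz = "UTC") + psec)

    structure(list(visits = visits, night_pings = night_pings,
                   users = users, venues = venues,
                   demographics = demographics, config = config),
              class = "synthetic_mobility")
  })
}

#' Generate outcomes from a linear model with city fixed effects
#'
#' Builds a per-user outcome as a linear combination of the user's behavior
#' weights and their home area's demographics, plus a city fixed effect and
#' Gaussian noise: `y_i = sum_j beta_j w_ij + sum_l gamma_l d_il + city_i +
#' eps_i`. With `noise_sd = 0` the outcome is an exact linear function of the
#' regressors, so a correctly specified fit recovers `beta` and `gamma`
#' exactly.
#'
#' @param weights User weight matrix (rows aligned with `users`).
#' @param users Tibble with `user_id`, `home_area`, `city_id`.
#' @param demographics Area demographics table.
#' @param beta Coefficient vector, length `ncol(weights)`.
#' @param gamma Length-4 coefficient vector for (`median_income`, `density`,
#'   `frac_black`, `frac_transit`).
#' @param city_effects Named vector of city intercepts (or single value
#'   recycled over cities).
#' @param noise_sd Gaussian noise standard deviation, `>= 0`.
#' @param seed Integer seed for the noise.
#' @return A tibble `user_id`, `outcome`.
#' @export
generate_outcomes <- function(weights, users, demographics, beta, gamma,
                              city_effects = 0, noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) ms_abort("noise_sd must be >= 0", "ms_parameter_error")
  if (length(beta) != ncol(weights))
    ms_abort("beta must have length ncol(weights)", "ms_parameter_error")
  if (length(gamma) != 4L)
    ms_abort("gamma must have length 4", "ms_parameter_error")
  stopifnot(nrow(weights) == nrow(users))
  d <- dplyr::left_join(users, demographics,
                        by = c(home_area = "area_id", "city_id"))
  D <- as.matrix(d[, c("median_income", "density", "frac_black", "frac_transit")])
  cities <- sort(unique(users$city_id))
  if (length(city_effects) == 1L) city_effects <- setNames(rep(city_effects, length(cities)), cities)
  eps <- if (noise_sd > 0) withr::with_seed(seed, rnorm(nrow(users), 0, noise_sd)) else 0
  y <- as.numeric(weights %*% beta) + as.numeric(D %*% gamma) +
    unname(city_effects[users$city_id]) + eps
  tibble::tibble(user_id = users$user_id, outcome = y)
}

#' Write a synthetic dataset to plain CSV files with a JSON sidecar
#'
#' @param sim A `synthetic_mobility` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_data <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_mobility"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(visits = file.path(dir, "visits.csv"),
             night_pings = file.path(dir, "night_pings.csv"),
             users = file.path(dir, "users.csv"),
             venues = file.path(dir, "venues.csv"),
             demographics = file.path(dir, "demographics.csv"))
  iso <- function(x) format(x, "%Y-%m-%dT%H:%M:%S+00:00")
  v <- sim$visits; v$start_time <- iso(v$start_time)
  np <- sim$night_pings; np$timestamp <- iso(np$timestamp)
  write.csv(v, paths["visits"], row.names = FALSE)
  write.csv(np, paths["night_pings"], row.names = FALSE)
  write.csv(sim$users, paths["users"], row.names = FALSE)
  write.csv(sim$venues, paths["venues"], row.names = FALSE)
  write.csv(sim$demographics, paths["demographics"], row.names = FALSE)
  side <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(sim$config), side, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, config = side))
}
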