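#' Normalized entropy of a behavior-weight vector
#'
#' `S = -sum(w_hat log w_hat) / log k` on the normalized weights
#' `w_hat = w / sum(w)`, with `0 log 0 = 0`. `S = 0` when a single behavior
#' strictly dominates; `S = 1` when all `k` behaviors carry equal weight.
#'
#' @param w Non-negative weight vector with at least one positive entry and
#'   `k = length(w) >= 2`.
#' @return A number in `[0, 1]`.
#' @export
weight_entropy <- function(w) {
  if (length(w) < 2)
    ms_abort("entropy needs k >= 2 (log k = 0 at k = 1)", "ms_parameter_error")
  if (any(w < 0) || sum(w) == 0)
    ms_abort("weights must be non-negative with a positive sum",
             "ms_undefined_entropy_error")
  wh <- w / sum(w)
  pos <- wh > 0
  -sum(wh[pos] * log(wh[pos])) / log(length(w)) + 0  # "+ 0" avoids IEEE -0
}

#' Assign users to within-city income quartiles
#'
#' Users are quartiled within each city on the median household income of
#' their home area. Boundaries are the 25/50/75th percentiles of the
#' area-level income distribution of the city; incomes exactly at a boundary
#' go to the lower quartile.
#'
#' @param users Tibble with `user_id`, `home_area`, `city_id`.
#' @param demographics Area table with `area_id`, `city_id`, `median_income`.
#' @return The `users` tibble with an added integer `income_quartile` column
#'   in `{1, 2, 3, 4}`.
#' @export
assign_income_quartiles <- function(users, demographics) {
  inc_map <- setNames(demographics$median_income, demographics$area_id)
  users$home_income <- unname(inc_map[users$home_area])
  if (anyNA(users$home_income))
    ms_abort("some home areas are missing from the demographics table",
             "ms_consistency_error")
  users$income_quartile <- NA_integer_
  for (ct in unique(users$city_id)) {
    idx <- users$city_id == ct
    inc <- users$home_income[idx]
    if (length(unique(inc)) < 4)
      ms_abort(sprintf("degenerate income distribution in %s", ct),
               "ms_quartile_error")
    qs <- quantile(inc, c(0.25, 0.5, 0.75))
    users$income_quartile[idx] <-
      1L + (inc > qs[1]) + (inc > qs[2]) + (inc > qs[3])
  }
  users
}

#' Dwell-time shares of users at places and of income groups at places
#'
#' `tau_ialpha` is the fraction of user `i`'s total dwell time spent at place
#' (venue) `alpha`; `tau_qalpha` is the fraction of all dwell time at `alpha`
#' contributed by users of income quartile `q`. Exposure is dwell-time
#' weighted by default; `weighting = "count"` uses visit counts instead.
#'
#' @param visits Visit table with `user_id`, `venue_id`, `dwell_min`.
#' @param quartiles Tibble with `user_id`, `income_quartile` for every user
#'   in `visits`.
#' @param weighting `"time"` (default) or `"count"`.
#' @return A list with `tau_ialpha` (tibble `user_id`, `venue_id`, `share`)
#'   and `tau_qalpha` (tibble `venue_id`, `q1`..`q4`).
#' @export
place_time_shares <- function(visits, quartiles, weighting = c("time", "count")) {
  weighting <- match.arg(weighting)
  v <- dplyr::inner_join(visits, quartiles[, c("user_id", "income_quartile")],
                         by = "user_id")
  if (nrow(v) < nrow(visits))
    message(sprintf("%d visits dropped: user without an income quartile",
                    nrow(visits) - nrow(v)))
  v$wt <- if (weighting == "time") v$dwell_min else 1
  v <- v[v$wt > 0, , drop = FALSE]
  tau_ialpha <- v |>
    dplyr::group_by(.data$user_id, .data$venue_id) |>
    dplyr::summarise(minutes = sum(.data$wt), .groups = "drop_last") |>
    dplyr::mutate(share = .data$minutes / sum(.data$minutes)) |>
    dplyr::ungroup() |>
    dplyr::select("user_id", "venue_id", "share")
  tau_qalpha <- v |>
    dplyr::group_by(.data$venue_id, .data$income_quartile) |>
    dplyr::summarise(minutes = sum(.data$wt), .groups = "drop_last") |>
    dplyr::mutate(share = .data$minutes / sum(.data$minutes)) |>
    dplyr::ungroup() |>
    dplyr::select("venue_id", "income_quartile", "share") |>
    tidyr::pivot_wider(names_from = "income_quartile", values_from = "share",
                       names_prefix = "q", values_fill = 0)
  for (qn in paste0("q", 1:4)) if (!qn %in% names(tau_qalpha)) tau_qalpha[[qn]] <- 0
  tau_qalpha <- tau_qalpha[, c("venue_id", paste0("q", 1:4))]
  list(tau_ialpha = tau_ialpha, tau_qalpha = tau_qalpha)
}

#' Per-user exposure to the four income groups
#'
#' `tau_iq = sum_alpha tau_ialpha * tau_qalpha`: the share of user `i`'s
#' time spent exposed to income group `q`, obtained by weighting each visited
#' place's group composition by the user's time share there. Rows sum to 1
#' (product of stochastic vectors).
#'
#' @param shares The list returned by [place_time_shares()].
#' @return A tibble `user_id`, `q1`..`q4`.
#' @export
group_exposure <- function(shares) {
  ti <- shares$tau_ialpha
  tq <- shares$tau_qalpha
  missing_places <- setdiff(unique(ti$venue_id), tq$venue_id)
  if (length(missing_places))
    ms_abort("places present in tau_ialpha but missing from tau_qalpha",
             "ms_consistency_error")
  j <- dplyr::inner_join(ti, tq, by = "venue_id", relationship = "many-to-one")
  j |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(q1 = sum(.data$share * .data$q1),
                     q2 = sum(.data$share * .data$q2),
                     q3 = sum(.data$share * .data$q3),
                     q4 = sum(.data$share * .data$q4),
                     .groups = "drop")
}

#' Experienced income integration
#'
#' `I = 1 - (2/3) * sum_q |tau_iq - 1/4|`. Equals 1 iff exposure is uniform
#' over the four income groups and 0 iff it is concentrated on a single
#' group (the 2/3 prefactor exactly normalizes the maximal deviation sum of
#' 3/2 to 1).
#'
#' @param tau_iq A stochastic 4-vector, or a matrix / data frame of such rows.
#' @return A number (or vector) in `[0, 1]`.
#' @export
integration <- function(tau_iq) {
  m <- if (is.data.frame(tau_iq)) as.matrix(tau_iq) else
    if (is.matrix(tau_iq)) tau_iq else matrix(tau_iq, nrow = 1)
  if (ncol(m) != 4 || any(m < -1e-9) || any(abs(rowSums(m) - 1) > 1e-6))
    ms_abort("tau_iq rows must be non-negative and sum to 1 over 4 groups",
             "ms_contract_error")
  out <- 1 - (2 / 3) * rowSums(abs(m - 0.25))
  if (length(out) == 1L && !is.matrix(tau_iq) && !is.data.frame(tau_iq))
    out <- unname(out[1])
  out
}

#' Place exploration of a user
#'
#' The number of unique places (venues) visited divided by the total number
#' of visits: close to 1 for explorers (almost every visit is to a new
#' place), close to 0 for returners.
#'
#' @param venue_ids Vector of the venues of one user's visits, one entry per
#'   visit (at least one).
#' @return A number in `(0, 1]`.
#' @export
exploration <- function(venue_ids) {
  if (length(venue_ids) == 0)
    ms_abort("exploration is undefined for a user with zero visits",
             "ms_contract_error")
  length(unique(venue_ids)) / length(venue_ids)
}

#' Per-user behavior statistics
#'
#' Combines the behavior weights and the visit table into one row per user:
#' the normalized-entropy of the weights, the exploration ratio, the visit
#' and unique-place counts, and (when exposure shares are supplied) the
#' income-group exposure vector and the integration metric.
#'
#' @param W User-by-behavior weight matrix with user ids as rownames.
#' @param visits Visit table (`user_id`, `venue_id`).
#' @param tau_iq Optional exposure tibble from [group_exposure()].
#' @return A tibble with one row per user of `W`.
#' @export
user_behavior_stats <- function(W, visits, tau_iq = NULL) {
  stopifnot(!is.null(rownames(W)))
  ent <- apply(W, 1, weight_entropy)
  vis <- visits |>
    dplyr::filter(.data$user_id %in% rownames(W)) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(n_visits = dplyr::n(),
                     n_unique_places = dplyr::n_distinct(.data$venue_id),
                     .groups = "drop") |>
    dplyr::mutate(exploration = .data$n_unique_places / .data$n_visits)
  out <- tibble::tibble(user_id = rownames(W), entropy = unname(ent)) |>
    dplyr::left_join(vis, by = "user_id")
  if (!is.null(tau_iq)) {
    out <- dplyr::left_join(out, tau_iq, by = "user_id")
    ok <- complete.cases(out[, paste0("q", 1:4)])
    out$integration <- NA_real_
    out$integration[ok] <- integration(out[ok, paste0("q", 1:4)])
  }
  out
}

#' Mean behavior weights overall and by city
#'
#' @param W User-by-behavior weight matrix.
#' @param city_ids City label per row of `W`.
#' @return A tibble `city`, `behavior`, `mean_weight`, `se`, `n`; the row
#'   block with `city == "all"` is the overall mean.
#' @export
summarize_behaviors <- function(W, city_ids) {
  stopifnot(nrow(W) == length(city_ids))
  k <- ncol(W)
  beh <- colnames(W)
  if (is.null(beh)) beh <- sprintf("behavior_%02d", seq_len(k))
  one <- function(sub, label) {
    tibble::tibble(
      city = label, behavior = beh,
      mean_weight = unname(colMeans(sub)),
      se = unname(apply(sub, 2, sd)) / sqrt(nrow(sub)),
      n = nrow(sub))
  }
  dplyr::bind_rows(
    one(W, "all"),
    dplyr::bind_rows(lapply(sort(unique(city_ids)), function(ct)
      one(W[city_ids == ct, , drop = FALSE], ct))))
}
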