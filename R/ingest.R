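#' Filter candidate stays to valid visits
#'
#' Keeps exactly the stays lasting more than 5 minutes and less than 4 hours;
#' rows with a missing dwell are rejected and counted. Both bounds are
#' strict. All other columns pass through unchanged.
#'
#' @param stays Data frame with at least a `dwell_min` column.
#' @param min_dwell,max_dwell Exclusive dwell bounds in minutes (defaults 5
#'   and 240).
#' @return The filtered tibble, with attribute `n_dropped` giving counts
#'   dropped per rule (`missing_dwell`, `too_short`, `too_long`).
#' @export
extract_visits <- function(stays, min_dwell = 5, max_dwell = 240) {
  stopifnot("dwell_min" %in% names(stays))
  missing_dwell <- is.na(stays$dwell_min)
  too_short <- !missing_dwell & stays$dwell_min <= min_dwell
  too_long <- !missing_dwell & stays$dwell_min >= max_dwell
  out <- tibble::as_tibble(stays[!(missing_dwell | too_short | too_long), , drop = FALSE])
  attr(out, "n_dropped") <- c(missing_dwell = sum(missing_dwell),
                              too_short = sum(too_short),
                              too_long = sum(too_long))
  out
}

#' Infer each user's home area from nighttime pings
#'
#' The home area is the modal area among pings between 10 pm and 6 am local
#' time (the window `[22:00, 24:00) U [00:00, 06:00)`). Ties break to the
#' lexicographically smallest area id. Users without any night ping are
#' excluded and reported.
#'
#' @param night_pings Data frame with `user_id`, `area_id`, `timestamp`
#'   (POSIXct; the stored timezone/offset supplies local time).
#' @return A tibble `user_id`, `home_area`, with attribute `no_home` listing
#'   user ids that had no ping inside the window.
#' @export
infer_home_area <- function(night_pings) {
  stopifnot(all(c("user_id", "area_id", "timestamp") %in% names(night_pings)))
  hr <- as.numeric(format(night_pings$timestamp, "%H")) +
    as.numeric(format(night_pings$timestamp, "%M")) / 60
  in_window <- hr >= 22 | hr < 6
  np <- night_pings[in_window, , drop = FALSE]
  homes <- np |>
    dplyr::count(.data$user_id, .data$area_id) |>
    dplyr::arrange(.data$user_id, dplyr::desc(.data$n), .data$area_id) |>
    dplyr::distinct(.data$user_id, .keep_all = TRUE) |>
    dplyr::select("user_id", home_area = "area_id")
  no_home <- setdiff(unique(night_pings$user_id), homes$user_id)
  attr(homes, "no_home") <- no_home
  homes
}

#' Select users meeting the activity thresholds
#'
#' A user qualifies with strictly more than `min_visits` visits and at least
#' `min_categories` distinct categories among their visits.
#'
#' @param visits Visit table with `user_id` and `category`.
#' @param min_visits Strict lower bound on the visit count (default 50).
#' @param min_categories Inclusive lower bound on distinct categories
#'   (default 5).
#' @return Character vector of qualifying user ids (sorted).
#' @export
filter_users <- function(visits, min_visits = 50, min_categories = 5) {
  tab <- visits |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(n_visits = dplyr::n(),
                     n_categories = dplyr::n_distinct(.data$category),
                     .groups = "drop")
  sort(tab$user_id[tab$n_visits > min_visits & tab$n_categories >= min_categories])
}

#' Restrict visits to the globally most-visited categories
#'
#' Ranks categories by total visit count over the whole dataset and keeps
#' only visits to the top `n_top`. Ties at the cutoff break by lexicographic
#' category name. The returned category list fixes the column order of the
#' activity matrix.
#'
#' @param visits Visit table with a `category` column.
#' @param n_top Number of categories to keep (default 248).
#' @return A list with `visits` (restricted tibble) and `categories` (the
#'   ordered kept-category vector, most-visited first).
#' @export
restrict_top_categories <- function(visits, n_top = 248) {
  counts <- visits |>
    dplyr::count(.data$category) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$category)
  if (nrow(counts) <= n_top) {
    if (nrow(counts) < n_top)
      warning(sprintf("only %d distinct categories (< n_top = %d); keeping all",
                      nrow(counts), n_top))
    keep <- counts$category
  } else {
    keep <- counts$category[seq_len(n_top)]
  }
  list(visits = tibble::as_tibble(visits[visits$category %in% keep, , drop = FALSE]),
       categories = keep)
}

#' Run the full ingest stage
#'
#' Applies, in order: visit extraction (dwell bounds), restriction to the top
#' categories computed on the extracted set, and the user activity filter on
#' the restricted set (so every retained user meets the thresholds on the
#' final category set). Home areas are inferred from the night pings.
#'
#' @param stays Candidate stay table.
#' @param night_pings Night ping table for home inference.
#' @param n_top,min_visits,min_categories Filter parameters (defaults 248,
#'   50, 5).
#' @return A list with `visits` (filtered, restricted, qualifying users
#'   only), `categories`, `homes`, and `report` (counts dropped per rule).
#' @export
ingest_visits <- function(stays, night_pings, n_top = 248,
                          min_visits = 50, min_categories = 5) {
  ext <- extract_visits(stays)
  top <- restrict_top_categories(ext, n_top = n_top)
  keep_users <- filter_users(top$visits, min_visits, min_categories)
  visits <- top$visits[top$visits$user_id %in% keep_users, , drop = FALSE]
  homes <- infer_home_area(night_pings)
  report <- list(dropped_stays = as.list(attr(ext, "n_dropped")),
                 n_categories_kept = length(top$categories),
                 n_users_in = dplyr::n_distinct(stays$user_id),
                 n_users_kept = length(keep_users),
                 n_no_home = length(attr(homes, "no_home")))
  list(visits = tibble::as_tibble(visits), categories = top$categories,
       homes = homes, report = report)
}
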