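#' Classify a timestamp into a time-of-day window
#'
#' Windows: morning `[05:00, 12:00)`, afternoon `[12:00, 18:00)`,
#' evening/nighttime `[18:00, 24:00)`. Times in `[00:00, 05:00)` fall in no
#' window and are labelled `"unclassified"`; they still count toward
#' weekday/weekend and category fractions downstream.
#'
#' @param start_time POSIXct vector.
#' @return Character vector in `{"morning", "afternoon", "evening",
#'   "unclassified"}`.
#' @export
time_window <- function(start_time) {
  hr <- as.numeric(format(start_time, "%H")) +
    as.numeric(format(start_time, "%M")) / 60 +
    as.numeric(format(start_time, "%S")) / 3600
  out <- rep("unclassified", length(hr))
  out[hr >= 5 & hr < 12] <- "morning"
  out[hr >= 12 & hr < 18] <- "afternoon"
  out[hr >= 18] <- "evening"
  out
}

#' Build one user's activity vector
#'
#' The M-dimensional description of a user: the fraction of visits in each
#' indexed category (summing to 1), the fractions of visits in the morning /
#' afternoon / evening windows (over classified visits), and the weekday /
#' weekend fractions (over all visits; Saturday and Sunday are weekend). A
#' visit's window and day are determined by its start time.
#'
#' @param visits Visit table for a single user (`category`, `start_time`).
#' @param category_index Ordered category vector fixing the column order.
#' @return Named numeric vector of length `length(category_index) + 5`.
#' @export
build_activity_vector <- function(visits, category_index) {
  visits <- visits[visits$category %in% category_index, , drop = FALSE]
  if (nrow(visits) == 0L)
    ms_abort("user has no visits in the indexed categories", "ms_contract_error")
  cat_counts <- table(factor(visits$category, levels = category_index))
  cat_block <- as.numeric(cat_counts) / nrow(visits)
  tw <- time_window(visits$start_time)
  classified <- tw[tw != "unclassified"]
  tod <- if (length(classified)) {
    as.numeric(table(factor(classified,
                            levels = c("morning", "afternoon", "evening")))) /
      length(classified)
  } else c(0, 0, 0)
  wknd <- format(visits$start_time, "%u") %in% c("6", "7")
  wk <- c(mean(!wknd), mean(wknd))
  setNames(c(cat_block, tod, wk), c(category_index, temporal_feature_names()))
}

#' Assemble the user-by-feature activity matrix
#'
#' Stacks per-user activity vectors into the `N x M` matrix factorized by the
#' NMF stage. Rows are ordered by sorted user id, columns by the category
#' index followed by the five temporal features, so the result is fully
#' deterministic.
#'
#' @param visits Filtered visit table (`user_id`, `category`, `start_time`).
#' @param category_index Ordered category vector (e.g. from
#'   [restrict_top_categories()]).
#' @return A numeric matrix with `rownames` = sorted user ids and `colnames`
#'   = categories plus temporal features.
#' @export
build_activity_matrix <- function(visits, category_index) {
  users <- sort(unique(visits$user_id))
  M <- length(category_index) + 5L
  X <- matrix(0, nrow = length(users), ncol = M,
              dimnames = list(users, c(category_index, temporal_feature_names())))
  if (length(users) == 0L) return(X)
  # vectorized blocks: category fractions
  vis <- visits[visits$category %in% category_index, , drop = FALSE]
  uf <- factor(vis$user_id, levels = users)
  cf <- factor(vis$category, levels = category_index)
  counts <- table(uf, cf)
  totals <- rowSums(counts)
  if (any(totals == 0))
    ms_abort("user with zero indexed visits reached matrix assembly",
             "ms_contract_error")
  X[, seq_along(category_index)] <- counts / totals
  tw <- time_window(vis$start_time)
  twf <- factor(tw, levels = c("morning", "afternoon", "evening"))
  tod_counts <- table(uf, twf)
  tod_tot <- rowSums(tod_counts)
  tod_frac <- tod_counts / ifelse(tod_tot == 0, 1, tod_tot)
  X[, length(category_index) + 1:3] <- tod_frac
  wknd <- factor(ifelse(format(vis$start_time, "%u") %in% c("6", "7"),
                        "weekend", "weekday"), levels = c("weekday", "weekend"))
  wk_counts <- table(uf, wknd)
  X[, length(category_index) + 4:5] <- wk_counts / totals
  X
}
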