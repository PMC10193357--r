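#' Optimally match the rows of two behavior bases
#'
#' Factorization restarts recover the same behaviors up to row permutation
#' and scale. This finds the one-to-one row assignment between two bases
#' maximizing total cosine similarity (solved exactly by the Hungarian
#' algorithm) and reports the mean matched cosine.
#'
#' @param B1,B2 Bases of identical dimensions (`k x M`).
#' @return A list with `permutation` (`permutation[i]` is the row of `B2`
#'   matched to row `i` of `B1`) and `mean_cosine`.
#' @export
match_factors <- function(B1, B2) {
  if (!all(dim(B1) == dim(B2)))
    ms_abort("bases must have identical dimensions", "ms_parameter_error")
  C <- cosine_rows(B1, B2)
  perm <- solve_assignment(1 - C)
  list(permutation = perm,
       mean_cosine = mean(C[cbind(seq_len(nrow(C)), perm)]))
}

cosine_rows <- function(B1, B2) {
  n1 <- sqrt(rowSums(B1^2)); n2 <- sqrt(rowSums(B2^2))
  n1[n1 == 0] <- 1; n2[n2 == 0] <- 1
  (B1 / n1) %*% t(B2 / n2)
}

#' Restart stability of the recovered factors
#'
#' The mean, over all pairs of restarts, of the mean matched cosine between
#' their bases. 1 means every restart recovers the same behaviors (up to
#' permutation and scale); values well below 1 signal an unstable rank.
#'
#' @param bases A list of `k x M` bases (e.g. `fit$runs_B` from
#'   [multi_restart()]), length `>= 2`.
#' @return A number in `[0, 1]`.
#' @export
stability_score <- function(bases) {
  n <- length(bases)
  if (n < 2) ms_abort("stability needs at least 2 restarts", "ms_parameter_error")
  pairs <- utils::combn(n, 2)
  mean(apply(pairs, 2, function(p)
    match_factors(bases[[p[1]]], bases[[p[2]]])$mean_cosine))
}

#' Bi-cross-validation error of a factorization rank
#'
#' Owen-Perry held-out-block validation: rows and columns are partitioned
#' into folds; for each (row-fold, column-fold) pair the corresponding block
#' `A` is held out, a rank-`k` factorization is fitted on the complementary
#' submatrix, the held-out rows and columns are attached by one-sided
#' projection, and `A` is predicted as the product of the projected factors.
#' The returned error is the mean per-entry generalized KL divergence between
#' held-out blocks and their predictions.
#'
#' @param X Non-negative matrix.
#' @param k Candidate rank.
#' @param n_row_folds,n_col_folds Number of folds (default 3 each).
#' @param seed Integer seed for the fold assignment and inner fits.
#' @param n_restarts Restarts for each inner factorization (default 2).
#' @param max_iter,tol Inner factorization controls.
#' @return Mean held-out per-entry KL error (non-negative scalar).
#' @export
bicross_validate <- function(X, k, n_row_folds = 3L, n_col_folds = 3L, seed = 1L,
                             n_restarts = 2L, max_iter = 300L, tol = 1e-7) {
  if (n_row_folds < 2 || n_col_folds < 2)
    ms_abort("need at least 2 folds in each direction", "ms_fold_scheme_error")
  N <- nrow(X); M <- ncol(X)
  folds <- withr::with_seed(seed, list(
    row = sample(rep_len(seq_len(n_row_folds), N)),
    col = sample(rep_len(seq_len(n_col_folds), M))))
  if (any(tabulate(folds$row, n_row_folds) == 0) ||
      any(tabulate(folds$col, n_col_folds) == 0))
    ms_abort("empty fold: X too small for the fold scheme", "ms_fold_scheme_error")
  eps <- .kl_eps
  errs <- numeric(0)
  for (r in seq_len(n_row_folds)) {
    for (cc in seq_len(n_col_folds)) {
      ri <- folds$row == r; ci <- folds$col == cc
      A <- X[ri, ci, drop = FALSE]
      D <- X[!ri, !ci, drop = FALSE]
      fit <- multi_restart(D, k, n_runs = n_restarts,
                           base_seed = seed + 1000L * r + cc,
                           max_iter = max_iter, tol = tol)
      # attach held-out rows to the trained basis, held-out columns to the
      # trained weights (transposed one-sided problem)
      W_r <- suppressWarnings(project_weights(X[ri, !ci, drop = FALSE], fit$B,
                                              max_iter = max_iter))
      B_c <- t(suppressWarnings(project_weights(t(X[!ri, ci, drop = FALSE]),
                                                t(fit$W), max_iter = max_iter)))
      A_hat <- pmax(W_r %*% B_c, eps)
      pos <- A > 0
      err <- sum(A[pos] * log(A[pos] / A_hat[pos])) - sum(A) + sum(A_hat)
      errs <- c(errs, max(err, 0) / length(A))  # clamp float round-off
    }
  }
  mean(errs)
}

#' Rank diagnostics over a candidate grid
#'
#' For each candidate rank: a multi-restart factorization (best and mean KL
#' loss), the restart stability of the bases, and the bi-cross-validation
#' error.
#'
#' @param X Non-negative matrix.
#' @param k_grid Integer vector of candidate ranks (default `2:20`).
#' @param n_restarts Restarts per rank for loss and stability (default 20).
#' @param n_row_folds,n_col_folds Bi-cross-validation fold scheme.
#' @param bcv_restarts Restarts for each inner bi-cross-validation fit.
#' @param seed Integer seed.
#' @param max_iter,tol Factorization controls.
#' @return A tibble with columns `k`, `mean_loss`, `best_loss`, `stability`,
#'   `bcv_error`, `n_runs`.
#' @export
rank_diagnostics <- function(X, k_grid = 2:20, n_restarts = 20L,
                             n_row_folds = 3L, n_col_folds = 3L,
                             bcv_restarts = 2L, seed = 1L,
                             max_iter = 300L, tol = 1e-7) {
  rows <- lapply(k_grid, function(k) {
    fit <- multi_restart(X, k, n_runs = n_restarts,
                         base_seed = derive_seed(seed, paste0("restarts", k)),
                         max_iter = max_iter, tol = tol)
    tibble::tibble(
      k = k,
      mean_loss = mean(fit$runs$kl_loss),
      best_loss = min(fit$runs$kl_loss),
      stability = stability_score(fit$runs_B),
      bcv_error = bicross_validate(X, k, n_row_folds, n_col_folds,
                                   seed = derive_seed(seed, paste0("bcv", k)),
                                   n_restarts = bcv_restarts,
                                   max_iter = max_iter, tol = tol),
      n_runs = n_restarts)
  })
  dplyr::bind_rows(rows)
}

#' Select the factorization rank
#'
#' Chooses the rank minimizing the bi-cross-validation error among candidates
#' whose restart stability meets the floor; ties go to the smaller rank. If
#' no candidate meets the floor, the unconstrained bi-cross-validation
#' minimizer is returned with a prominent warning.
#'
#' @param diagnostics Tibble from [rank_diagnostics()] (needs `k`,
#'   `bcv_error`, `stability`).
#' @param stability_floor Minimum acceptable stability (default 0.8).
#' @return A list with `k` (the chosen rank) and `decision` (the diagnostics
#'   ordered as considered, with an `eligible` flag).
#' @export
select_rank <- function(diagnostics, stability_floor = 0.8) {
  if (nrow(diagnostics) < 2)
    ms_abort("need at least 2 candidate ranks", "ms_parameter_error")
  d <- diagnostics[order(diagnostics$bcv_error, diagnostics$k), ]
  d$eligible <- d$stability >= stability_floor
  if (any(d$eligible)) {
    k <- d$k[d$eligible][1]
  } else {
    warning("no candidate rank meets the stability floor; ",
            "returning the unconstrained bi-cross-validation minimizer")
    k <- d$k[1]
  }
  list(k = k, decision = d)
}
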