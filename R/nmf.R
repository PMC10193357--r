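#' Generalized Kullback-Leibler divergence between non-negative matrices
#'
#' `D(X || Y) = sum_ij [ x log(x/y) - x + y ]` with the convention
#' `0 log 0 = 0`. This is the objective minimized by the factorization. With
#' `normalize = TRUE` the sum is divided by the number of matrix entries,
#' giving an average per-entry distance.
#'
#' @param X Non-negative matrix.
#' @param Y Matrix of the same shape, positive wherever `X` is positive.
#' @param normalize Divide by the number of entries? (default `FALSE`).
#' @return A single non-negative number.
#' @export
kl_divergence <- function(X, Y, normalize = FALSE) {
  if (!all(dim(X) == dim(Y)))
    ms_abort("X and Y must have the same shape", "ms_parameter_error")
  if (any(X > 0 & Y <= 0))
    ms_abort("infinite divergence: X > 0 where Y = 0", "ms_infinite_divergence_error")
  pos <- X > 0
  d <- sum(X[pos] * log(X[pos] / Y[pos])) - sum(X) + sum(Y)
  if (normalize) d <- d / length(X)
  d
}

#' Frobenius distance between matrices
#'
#' `sqrt(sum (x - y)^2)`, optionally divided by the number of entries.
#'
#' @inheritParams kl_divergence
#' @return A single non-negative number.
#' @export
frobenius_distance <- function(X, Y, normalize = FALSE) {
  if (!all(dim(X) == dim(Y)))
    ms_abort("X and Y must have the same shape", "ms_parameter_error")
  d <- sqrt(sum((X - Y)^2))
  if (normalize) d <- d / length(X)
  d
}

# numerical floor inside logs and denominators of the KL updates
.kl_eps <- 1e-12

#' Non-negative matrix factorization under generalized KL divergence
#'
#' Factorizes a non-negative activity matrix as `X ~ W B` with `W (N x k)`
#' and `B (k x M)` non-negative, minimizing the generalized KL divergence by
#' multiplicative updates. Each full sweep (one `W` update and one `B`
#' update) is guaranteed not to increase the objective; the per-sweep loss
#' trace is stored so the contract can be asserted. On return `B` rows are
#' rescaled to sum to 1 with the compensating rescale absorbed into `W`
#' columns, fixing the scale ambiguity of the product.
#'
#' @param X Non-negative numeric matrix with no all-zero rows.
#' @param k Rank, `1 <= k <= min(dim(X))`.
#' @param max_iter Maximum number of sweeps (default 500).
#' @param tol Relative loss-change convergence threshold (default 1e-6).
#' @param seed Integer seed for the random initialization. Entries of `W`
#'   and `B` are drawn i.i.d. uniform(0.1, 1.1) and rescaled so the initial
#'   product matches `mean(X)`; strictly positive starts avoid KL
#'   singularities.
#' @param allow_zero_rows Internal switch used by bi-cross-validation, where
#'   submatrices may legitimately contain empty rows.
#' @return A list of class `kl_nmf`: `W`, `B`, `kl_loss`, `frob_dist`
#'   (both unnormalized and per-entry as `kl_loss_mean`, `frob_dist_mean`),
#'   `k`, `seed`, `n_iter`, `converged`, and `loss_trace`.
#' @export
kl_nmf <- function(X, k, max_iter = 500L, tol = 1e-6, seed = 1L,
                   allow_zero_rows = FALSE) {
  check_nonneg_matrix(X)
  N <- nrow(X); M <- ncol(X)
  if (k < 1 || k > min(N, M))
    ms_abort("k must satisfy 1 <= k <= min(dim(X))", "ms_parameter_error")
  if (!allow_zero_rows && any(rowSums(X) == 0))
    ms_abort("X has all-zero rows; filter users upstream", "ms_input_error")
  eps <- .kl_eps
  init <- withr::with_seed(seed, {
    W <- matrix(runif(N * k, 0.1, 1.1), N, k)
    B <- matrix(runif(k * M, 0.1, 1.1), k, M)
    list(W = W, B = B)
  })
  W <- init$W; B <- init$B
  s <- sqrt(mean(X) / mean(W %*% B))
  W <- W * s; B <- B * s

  loss_of <- function(Y) {
    pos <- X > 0
    sum(X[pos] * log(X[pos] / pmax(Y[pos], eps))) - sum(X) + sum(Y)
  }
  Y <- W %*% B
  trace <- numeric(max_iter)
  prev <- loss_of(Y)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    R <- X / pmax(Y, eps)
    W <- W * (R %*% t(B)) / pmax(matrix(rowSums(B), N, k, byrow = TRUE), eps)
    Y <- W %*% B
    R <- X / pmax(Y, eps)
    B <- B * (t(W) %*% R) / pmax(matrix(colSums(W), k, M), eps)
    Y <- W %*% B
    cur <- loss_of(Y)
    trace[it] <- cur
    if (prev - cur < tol * max(abs(prev), eps)) {
      converged <- TRUE
      prev <- cur
      break
    }
    prev <- cur
  }
  # canonical scale: B rows sum to 1, W columns compensate
  rs <- pmax(rowSums(B), eps)
  B <- B / rs
  W <- W * matrix(rs, nrow(W), k, byrow = TRUE)
  Y <- W %*% B
  kl <- loss_of(Y)
  fr <- sqrt(sum((X - Y)^2))
  rownames(W) <- rownames(X)
  colnames(B) <- colnames(X)
  structure(list(W = W, B = B,
                 kl_loss = kl, frob_dist = fr,
                 kl_loss_mean = kl / length(X),
                 frob_dist_mean = fr / length(X),
                 k = k, seed = seed, n_iter = it, converged = converged,
                 loss_trace = trace[seq_len(it)]),
            class = "kl_nmf")
}

#' Multi-restart KL-NMF
#'
#' Runs [kl_nmf()] from `n_runs` random initializations and returns the run
#' with the smallest KL loss; all runs' seeds, losses, and bases are retained
#' for the restart-stability diagnostic.
#'
#' @inheritParams kl_nmf
#' @param n_runs Number of restarts (default 200).
#' @param base_seed Seed of the first restart; restart `r` uses
#'   `base_seed + r - 1`.
#' @param keep_W Also retain every restart's `W` (memory-heavy for large N;
#'   default `FALSE`).
#' @return The best `kl_nmf` fit, with extra fields `runs` (a tibble of
#'   seed, kl_loss, n_iter, converged per restart), `runs_B` (list of bases),
#'   and optionally `runs_W`.
#' @export
multi_restart <- function(X, k, n_runs = 200L, base_seed = 1L,
                          max_iter = 500L, tol = 1e-6, keep_W = FALSE) {
  if (n_runs < 1) ms_abort("n_runs must be >= 1", "ms_parameter_error")
  fits <- lapply(seq_len(n_runs), function(r)
    kl_nmf(X, k, max_iter = max_iter, tol = tol, seed = base_seed + r - 1L))
  losses <- vapply(fits, `[[`, numeric(1), "kl_loss")
  best <- fits[[which.min(losses)]]
  best$runs <- tibble::tibble(
    seed = vapply(fits, `[[`, numeric(1), "seed"),
    kl_loss = losses,
    n_iter = vapply(fits, `[[`, numeric(1), "n_iter"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  best$runs_B <- lapply(fits, `[[`, "B")
  if (keep_W) best$runs_W <- lapply(fits, `[[`, "W")
  best
}

#' Sample users uniformly per city
#'
#' Draws up to `n_per_city` users without replacement from each city so no
#' city dominates the factorization sample. Cities with fewer users
#' contribute all of them.
#'
#' @param user_ids Character vector of user ids.
#' @param city_ids City label for each user.
#' @param n_per_city Sample size per city (default 10000).
#' @param seed Integer seed.
#' @return Character vector of sampled user ids (sorted).
#' @export
sample_users_per_city <- function(user_ids, city_ids, n_per_city = 10000L, seed = 1L) {
  stopifnot(length(user_ids) == length(city_ids))
  withr::with_seed(seed, {
    out <- unlist(lapply(split(user_ids, city_ids), function(u) {
      if (length(u) <= n_per_city) u else u[sample.int(length(u), n_per_city)]
    }), use.names = FALSE)
    sort(out)
  })
}

#' Project activity rows onto a fixed behavior basis
#'
#' Solves the one-sided non-negative regression `X_new ~ W B_fixed` holding
#' the basis fixed, so users outside the factorization sample get behavior
#' weights on the common basis. By default the generalized KL objective (the
#' factorization loss) is minimized by one-sided multiplicative updates from
#' a deterministic positive start; a least-squares variant is available via
#' `loss = "ls"`. All-zero input rows map to all-zero weights with a
#' warning.
#'
#' @param X_new Non-negative matrix whose columns match `B_fixed`.
#' @param B_fixed Basis matrix (`k x M`).
#' @param loss `"kl"` (default) or `"ls"`.
#' @param max_iter,tol Update controls.
#' @return A non-negative `nrow(X_new) x k` weight matrix.
#' @export
project_weights <- function(X_new, B_fixed, loss = c("kl", "ls"),
                            max_iter = 500L, tol = 1e-9) {
  loss <- match.arg(loss)
  check_nonneg_matrix(X_new, "X_new")
  if (ncol(X_new) != ncol(B_fixed))
    ms_abort("column dimension of X_new must match B_fixed", "ms_parameter_error")
  eps <- .kl_eps
  k <- nrow(B_fixed)
  zero_rows <- rowSums(X_new) == 0
  if (any(zero_rows)) warning(sprintf("%d all-zero rows mapped to zero weights",
                                      sum(zero_rows)))
  # deterministic init: flat weights scaled so row masses match
  W <- matrix(rep(pmax(rowSums(X_new), eps) / max(sum(B_fixed), eps), k),
              ncol = k)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    Y <- W %*% B_fixed
    if (loss == "kl") {
      R <- X_new / pmax(Y, eps)
      W <- W * (R %*% t(B_fixed)) /
        pmax(matrix(rowSums(B_fixed), nrow(W), k, byrow = TRUE), eps)
      pos <- X_new > 0
      cur <- sum(X_new[pos] * log(X_new[pos] / pmax(Y[pos], eps))) -
        sum(X_new) + sum(Y)
    } else {
      W <- W * (X_new %*% t(B_fixed)) / pmax(W %*% (B_fixed %*% t(B_fixed)), eps)
      cur <- sum((X_new - Y)^2)
    }
    if (is.finite(prev) && prev - cur < tol * max(abs(prev), eps)) break
    prev <- cur
  }
  W[zero_rows, ] <- 0
  W
}
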