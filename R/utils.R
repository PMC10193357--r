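#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from a single master seed and a stage label, so that one integer fixes an
#' entire run while stages stay statistically decoupled.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage label (e.g. `"simulate"`, `"factorize"`).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master_seed) %% 65011 * 104729 + h * 7919) %% (2^31 - 1))
}

# internal: consistent error helper
ms_abort <- function(msg, class) {
  stop(structure(class = c(class, "mobstyle_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# internal: check a numeric matrix is non-negative and finite
check_nonneg_matrix <- function(X, name = "X") {
  if (!is.matrix(X) || !is.numeric(X))
    ms_abort(sprintf("%s must be a numeric matrix", name), "ms_input_error")
  if (anyNA(X) || any(!is.finite(X)))
    ms_abort(sprintf("%s contains NA or non-finite entries", name), "ms_input_error")
  if (any(X < 0))
    ms_abort(sprintf("%s contains negative entries", name), "ms_input_error")
  invisible(X)
}
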