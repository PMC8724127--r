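# Internal helpers: validation and seeded evaluation.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_bad_arg <- function(arg, must, class = "hubrank_error_validation") {
  rlang::abort(sprintf("`%s` must %s.", arg, must), class = class)
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded package operations do
#' not disturb the session's random stream.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

check_count <- function(x, arg, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort_bad_arg(arg, sprintf("be a single integer >= %s", min))
  }
  as.integer(x)
}

check_fraction <- function(x, arg, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort_bad_arg(arg, sprintf(
      "be a single number in %s%s, %s%s",
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"
    ))
  }
  as.numeric(x)
}

#' Validate a connectivity matrix
#'
#' A valid connectivity matrix is square, numeric, symmetric, hollow (zero
#' diagonal) and non-negative. Errors name the first offending entries.
#' @noRd
validate_matrix <- function(W, arg = "matrix", tol = 1e-8) {
  if (!is.matrix(W) || !is.numeric(W) || nrow(W) != ncol(W)) {
    abort_bad_arg(arg, "be a square numeric matrix")
  }
  if (anyNA(W)) abort_bad_arg(arg, "not contain missing values")
  bad <- which(W < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    rlang::abort(
      sprintf(
        "`%s` has negative weights, e.g. at [%d, %d].",
        arg, bad[1, 1], bad[1, 2]
      ),
      class = "hubrank_error_validation"
    )
  }
  asym <- abs(W - t(W))
  if (max(asym) > tol * max(1, max(abs(W)))) {
    bad <- which(asym == max(asym), arr.ind = TRUE)
    rlang::abort(
      sprintf(
        "`%s` is not symmetric, e.g. at [%d, %d] vs [%d, %d].",
        arg, bad[1, 1], bad[1, 2], bad[1, 2], bad[1, 1]
      ),
      class = "hubrank_error_validation"
    )
  }
  if (any(diag(W) != 0)) {
    i <- which(diag(W) != 0)[1]
    rlang::abort(
      sprintf("`%s` has a nonzero diagonal entry at node %d.", arg, i),
      class = "hubrank_error_validation"
    )
  }
  invisible(W)
}

node_ids <- function(W) rownames(W) %||% paste0("roi_", seq_len(nrow(W)))

#' Derive a stream of sub-seeds from one master seed
#'
#' Deterministic per index, bounded below 2^31 so they remain valid R seeds.
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
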