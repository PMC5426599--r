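#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous RNG state, so seeded package functions never
#' disturb the session RNG.
#'
#' @param seed Integer scalar, or `NULL` to use the current RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (abs(seed) >= 2^31) stop("seed must be a 32-bit integer", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a deterministic 32-bit sub-seed from a master seed and a stage label.
# Keeps every derived seed in [0, 2^31): required because R integers are 32-bit.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000000L) * 2011L + (h %% 100003L)
}

#' Monte-Carlo pseudo p-value
#'
#' The permutation convention used throughout the package:
#' `(1 + #exceedances) / (1 + n_sim)`, which can never be zero.
#'
#' @param stat_obs Observed statistic.
#' @param stat_sim Vector of simulated statistics.
#' @param alternative `"greater"`, `"less"`, or `"two_sided"` (on absolute
#'   values).
#' @return Pseudo p-value in (0, 1].
#' @export
pseudo_p <- function(stat_obs, stat_sim,
                     alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  n <- length(stat_sim)
  exc <- switch(alternative,
    greater   = sum(stat_sim >= stat_obs),
    less      = sum(stat_sim <= stat_obs),
    two_sided = sum(abs(stat_sim) >= abs(stat_obs))
  )
  (1 + exc) / (1 + n)
}

# Half-up decimal rounding (Table-style reporting). R's round() is banker's.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Largest-remainder apportionment of `total` into integer parts proportional
# to non-negative weights `w`; parts sum to `total` exactly.
largest_remainder <- function(total, w) {
  stopifnot(total >= 0, all(w >= 0), sum(w) > 0)
  q <- total * w / sum(w)
  base <- floor(q)
  rem <- as.integer(round(total - sum(base)))
  out <- base
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1
  }
  as.integer(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
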