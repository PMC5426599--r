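#' Geographical-detector q-statistic
#'
#' Measures how much a stratification (for example zone membership) explains a
#' child-level variable: `q = 1 - SSW/SST` where
#' `SSW = sum_h sum_{i in h} (y_hi - mean_h)^2` and
#' `SST = sum_i (y_i - mean)^2`. Equivalently `q = SSB/SST`, the between-strata
#' share of the variance, so `q` lies in `[0, 1]`: 0 when all stratum means are
#' equal, 1 when every stratum is internally constant. Single-member strata
#' contribute 0 to SSW.
#'
#' @param values Numeric child-level variable (district prevalence).
#' @param strata Stratum label per child (zone id); at least 2 strata.
#' @return Object of class `qstat`: `q`, `n`, `L`, `N_h`, `sigma2_h`
#'   (population variances), `ssw`, `sst`, `pseudo_p` (`NA` until
#'   [q_significance()]).
#' @export
q_statistic <- function(values, strata) {
  stopifnot(length(values) == length(strata))
  ok <- !is.na(values) & !is.na(strata)
  y <- values[ok]; h <- as.character(strata[ok])
  n <- length(y)
  lev <- sort(unique(h))
  if (length(lev) < 2) stop_invalid("need >= 2 strata")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop_invalid("zero total variance")
  N_h <- vapply(lev, function(l) sum(h == l), numeric(1))
  sigma2_h <- vapply(lev, function(l) {
    v <- y[h == l]
    sum((v - mean(v))^2) / length(v)  # population variance
  }, numeric(1))
  ssw <- sum(N_h * sigma2_h)
  structure(list(q = 1 - ssw / sst, n = n, L = length(lev), N_h = N_h,
                 sigma2_h = sigma2_h, ssw = ssw, sst = sst,
                 pseudo_p = NA_real_, n_perm = NA_integer_),
            class = "qstat")
}

#' @rdname q_statistic
#' @param n_perm Number of stratum-label permutations (default 999).
#' @param seed Integer seed.
#' @details [q_significance()] assesses the statistic by permutation: stratum
#'   labels are shuffled over the units `n_perm` times and the one-sided
#'   pseudo-p is `(1 + #{q_perm >= q_obs}) / (1 + n_perm)`. (The
#'   noncentral-F approximation used by the original geographical-detector
#'   software is a possible extension; permutation is assumption-free and
#'   consistent with the rest of the pipeline's inference.)
#' @export
q_significance <- function(values, strata, n_perm = 999, seed = 1L) {
  obs <- q_statistic(values, strata)
  ok <- !is.na(values) & !is.na(strata)
  y <- values[ok]; h <- as.character(strata[ok])
  qperm <- with_seed(seed, vapply(seq_len(n_perm), function(p)
    q_statistic(y, h[sample.int(length(h))])$q, numeric(1)))
  obs$pseudo_p <- pseudo_p(obs$q, qperm, "greater")
  obs$n_perm <- as.integer(n_perm)
  obs$perm_q <- qperm
  obs
}

#' @export
print.qstat <- function(x, ...) {
  cat(sprintf("q-statistic = %.4g (n = %d, L = %d strata)", x$q, x$n, x$L))
  if (!is.na(x$pseudo_p))
    cat(sprintf(", pseudo-p = %.4g (%d permutations)", x$pseudo_p, x$n_perm))
  cat("\n")
  invisible(x)
}
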