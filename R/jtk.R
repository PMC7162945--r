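#' JTK rhythmicity test configuration
#'
#' The test scans a grid of candidate periods and phase lags.  With 14
#' samples spanning a single 26-h window only the 24-h period is resolvable,
#' so the default period set is `{24}`; the lag grid steps by the sampling
#' interval and covers the full period, so anti-phase patterns are captured
#' by lags in the second half of the cycle.  The minimum per-combination
#' exact P is Bonferroni-adjusted by the number of (period, lag)
#' combinations.
#'
#' @param periods_h candidate periods in hours (all > 0).
#' @param lag_step_h lag grid step in hours; `NULL` uses the design's
#'   sampling interval.
#' @param p_adjust adjustment across combinations (only `"bonferroni"`).
#' @param exact_n_max largest series length for which the exact null is
#'   computed (guardrail for the dynamic program).
#' @return a `jtk_config` list.
#' @export
jtk_config <- function(periods_h = 24, lag_step_h = NULL,
                       p_adjust = "bonferroni", exact_n_max = 25) {
  if (any(periods_h <= 0)) rhythmod_stop("jtk", "periods must be positive")
  if (!identical(p_adjust, "bonferroni")) {
    rhythmod_stop("jtk", "only bonferroni adjustment is supported")
  }
  structure(list(periods_h = periods_h, lag_step_h = lag_step_h,
                 p_adjust = p_adjust, exact_n_max = exact_n_max),
            class = "jtk_config")
}

#' Cosine reference rank pattern
#'
#' Midranks of `cos(2*pi*(t - lag)/period)` at the sample times.  Sampling
#' symmetry produces ties (e.g. ZT2 and ZT22 share a cosine value at lag 0),
#' which the exact null conditions on.
#'
#' @param period_h reference period (> 0).
#' @param lag_h ZT position of the reference maximum.
#' @param sample_times_zt sample times, hours ZT.
#' @return numeric vector of midranks (ties averaged).
#' @export
reference_rank_pattern <- function(period_h, lag_h, sample_times_zt) {
  if (period_h <= 0) rhythmod_stop("jtk", "period must be positive")
  ref <- cos(2 * pi * (sample_times_zt - lag_h) / period_h)
  rank(round(ref, 9), ties.method = "average")
}

#' Kendall-type S statistic against a reference ranking
#'
#' `S = sum_{i<j} sign(x_j - x_i) * sign(ref_j - ref_i)`; pairs tied in
#' either vector contribute 0.
#'
#' @param x observed series.
#' @param ref_ranks reference ranks of the same length (>= 3).
#' @return list with `S`, concordant/discordant pair counts, and `max_S`
#'   (pairs untied in the reference).
#' @export
kendall_S <- function(x, ref_ranks) {
  n <- length(x)
  if (n != length(ref_ranks)) rhythmod_stop("jtk", "length mismatch")
  if (n < 3) rhythmod_stop("jtk", "need at least 3 points")
  ij <- utils::combn(n, 2)
  sx <- sign(x[ij[2, ]] - x[ij[1, ]])
  sr <- sign(ref_ranks[ij[2, ]] - ref_ranks[ij[1, ]])
  prod <- sx * sr
  list(S = sum(prod),
       concordant = sum(prod > 0),
       discordant = sum(prod < 0),
       max_S = sum(sr != 0))
}

# Gaussian binomial coefficient [a choose b]_q as a coefficient vector
# (exponents 0 .. b*(a-b)), via [a b] = [a-1 b-1] + q^b [a-1 b].
gaussian_binomial <- function(a, b) {
  if (b == 0 || b == a) return(1)
  prev <- vector("list", a + 1)  # prev[[k+1]] = [a' choose k]_q at a' = row
  prev[[1]] <- 1
  for (row in 1:a) {
    cur <- vector("list", a + 1)
    cur[[1]] <- 1
    kmax <- min(row, b)
    for (k in 1:kmax) {
      if (k == row) { cur[[k + 1]] <- 1; next }
      p1 <- prev[[k]]            # [row-1 choose k-1]
      p2 <- prev[[k + 1]]        # [row-1 choose k]
      shifted <- c(rep(0, k), p2)
      len <- max(length(p1), length(shifted))
      cur[[k + 1]] <- c(p1, rep(0, len - length(p1))) +
        c(shifted, rep(0, len - length(shifted)))
    }
    prev <- cur
  }
  prev[[b + 1]]
}

# plain O(nm) polynomial product of coefficient vectors (exponents from 0)
poly_mult <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1)
  for (i in seq_along(p)) {
    out[i:(i + length(q) - 1)] <- out[i:(i + length(q) - 1)] + p[i] * q
  }
  out
}

#' Exact null distribution of the Kendall-type S statistic
#'
#' Distribution of `S` when the data are a uniformly random permutation of
#' distinct values, conditioned on the reference tie pattern.  With reference
#' tie-group sizes `t_1..t_g`, the concordant-pair count follows the
#' Jonckheere-Terpstra permutation null, whose generating function is the
#' Gaussian (q-)multinomial coefficient; it is built here by convolving
#' Gaussian binomials group by group (Harding's algorithm).  The
#' distribution is symmetric about 0 and `S` steps by 2 over
#' `[-max_S, max_S]`.
#'
#' @param ref_ranks reference rank vector (ties allowed).
#' @param n_max guardrail on the series length (default 25).
#' @return list with `S` (achievable values), `prob` (their probabilities)
#'   and `max_S`.
#' @export
exact_null_distribution <- function(ref_ranks, n_max = 25) {
  n <- length(ref_ranks)
  if (n > n_max) rhythmod_stop("jtk", sprintf("n = %d exceeds limit %d", n, n_max))
  sizes <- as.integer(table(ref_ranks))
  max_S <- (n^2 - sum(sizes^2)) / 2  # pairs untied in the reference
  poly <- 1
  m <- 0
  for (t in sizes) {
    poly <- poly_mult(poly, gaussian_binomial(m + t, t))
    poly <- poly / sum(poly)  # keep coefficients O(1): pmf convolution
    m <- m + t
  }
  u <- seq_along(poly) - 1
  list(S = 2 * u - max_S, prob = poly, max_S = max_S)
}

# upper-tail exact P(S >= s_obs) from a null distribution object
null_upper_tail <- function(null, s_obs) {
  sum(null$prob[null$S >= s_obs - 1e-9])
}

#' Exact JTK rhythmicity test of one series
#'
#' For every (period, lag) combination the observed series is scored against
#' the cosine reference rank pattern with the Kendall-type S statistic, and
#' the one-sided upper-tail exact P is computed from the permutation null.
#' The result takes the minimising combination (ties broken toward the
#' smaller lag, then the earlier period); the adjusted P is
#' `min(1, p_min * n_combinations)`.  The phase is the ZT position of the
#' winning reference maximum, in `[0, period)`.
#'
#' @param series numeric series.
#' @param times sample times (hours ZT), same length as `series`.
#' @param config a [jtk_config()].
#' @return object of class `jtk_result`: list with `best_period_h`,
#'   `best_lag_h`, `phase_zt`, `tau`, `p_exact`, `p_adjusted`,
#'   `amplitude_est`, `n_combinations`, `degenerate`.
#' @examples
#' d <- diel_design()
#' s <- simulate_series(d, amplitude = 1, phase_zt = 4)
#' jtk_test(s, d$sample_times_zt)$phase_zt  # 4
#' @export
jtk_test <- function(series, times, config = jtk_config()) {
  if (length(series) != length(times)) rhythmod_stop("jtk", "length mismatch")
  if (stats::sd(series) == 0) {
    return(structure(list(best_period_h = NA_real_, best_lag_h = NA_real_,
                          phase_zt = NA_real_, tau = 0, p_exact = 1,
                          p_adjusted = 1, amplitude_est = 0,
                          n_combinations = NA_integer_, degenerate = TRUE),
                     class = "jtk_result"))
  }
  step0 <- config$lag_step_h
  null_cache <- new.env(parent = emptyenv())
  best <- NULL
  n_comb <- 0L
  for (period in config$periods_h) {
    step <- if (is.null(step0)) min(diff(sort(unique(times)))) else step0
    lags <- seq(0, period - step, by = step)
    for (lag in lags) {
      n_comb <- n_comb + 1L
      ref <- reference_rank_pattern(period, lag, times)
      key <- paste(sort(table(ref)), collapse = ",")
      null <- get0(key, envir = null_cache)
      if (is.null(null)) {
        null <- exact_null_distribution(ref, config$exact_n_max)
        assign(key, null, envir = null_cache)
      }
      ks <- kendall_S(series, ref)
      p <- null_upper_tail(null, ks$S)
      if (is.null(best) || p < best$p - 1e-12) {
        best <- list(period = period, lag = lag, p = p, S = ks$S,
                     max_S = ks$max_S)
      }
    }
  }
  ref_best <- cos(2 * pi * (times - best$lag) / best$period)
  fit <- stats::lm(series ~ ref_best)
  fitted_range <- range(stats::fitted(fit))
  structure(list(
    best_period_h = best$period,
    best_lag_h = best$lag,
    phase_zt = best$lag %% best$period,
    tau = if (best$max_S > 0) best$S / best$max_S else 0,
    p_exact = best$p,
    p_adjusted = min(1, best$p * n_comb),
    amplitude_est = (fitted_range[2] - fitted_range[1]) / 2,
    n_combinations = n_comb,
    degenerate = FALSE
  ), class = "jtk_result")
}

#' @export
print.jtk_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("jtk_result: degenerate (constant) series; p = 1\n")
  } else {
    cat(sprintf(
      "jtk_result: period %g h, phase ZT%g, tau %.3f, p_exact %.3g, p_adjusted %.3g\n",
      x$best_period_h, x$phase_zt, x$tau, x$p_exact, x$p_adjusted))
  }
  invisible(x)
}

#' Run the JTK test on every row of a matrix
#'
#' @param mat series x time points matrix with rownames.
#' @param times sample times (hours ZT).
#' @param config a [jtk_config()].
#' @return data frame with one row per series: `series_id`, `period`,
#'   `phase_zt`, `tau`, `p_exact`, `p_adjusted`, `degenerate`.
#' @export
jtk_batch <- function(mat, times, config = jtk_config()) {
  rows <- lapply(rownames(mat), function(id) {
    r <- jtk_test(mat[id, ], times, config)
    data.frame(series_id = id, period = r$best_period_h,
               phase_zt = r$phase_zt, tau = r$tau, p_exact = r$p_exact,
               p_adjusted = r$p_adjusted, degenerate = r$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# all permutations of 1..n as an (n! x n) matrix, lexicographic
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    block <- (k - 1) * nrow(sub) + seq_len(nrow(sub))
    rest <- setdiff(seq_len(n), k)
    out[block, 1] <- k
    out[block, -1] <- matrix(rest[sub], nrow(sub), n - 1)
  }
  out
}

#' Brute-force permutation P-value (test oracle)
#'
#' Exact upper-tail probability of the observed S by enumerating all `n!`
#' permutations of the observed values.  A validation oracle for
#' [exact_null_distribution()], not part of the pipeline; limited to
#' `n <= 8`.
#'
#' @param x observed series (length <= 8).
#' @param ref_ranks reference ranks.
#' @return exact upper-tail probability `P(S_perm >= S_obs)`.
#' @export
permutation_oracle_p <- function(x, ref_ranks) {
  n <- length(x)
  if (n > 8) rhythmod_stop("jtk", "oracle limited to n <= 8")
  s_obs <- kendall_S(x, ref_ranks)$S
  perms <- all_permutations(n)
  ij <- utils::combn(n, 2)
  sr <- sign(ref_ranks[ij[2, ]] - ref_ranks[ij[1, ]])
  xs <- matrix(x[perms], nrow(perms), n)
  sx <- sign(xs[, ij[2, ], drop = FALSE] - xs[, ij[1, ], drop = FALSE])
  s_all <- as.vector(sx %*% sr)
  mean(s_all >= s_obs - 1e-9)
}
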