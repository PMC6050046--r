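#' Configuration of the Z-ring incorporation model
#'
#' The model considers `n_protofilaments` protofilaments, each `L` subunits
#' long, in a cell where a proportion `f` of FtsZ carries a laterally
#' disruptive mutation.  The number of disruptive subunits in protofilament
#' i is `x_i ~ Binomial(L, f)` (stochastic copolymerization).  A
#' protofilament with more disruptive subunits than the threshold `T`
#' incorporates into the Z-ring with probability `p_incorp_above`
#' (default 0.01); one at or below the threshold incorporates with
#' probability `p_incorp_below` (default 0.99).  The critical fraction is
#' `f_c = T / L`.  The summary statistic of one replicate is the fraction
#' of disruptive subunits that ended up inside the ring,
#' `sum(x * V) / sum(x)`, where `V` is the 0/1 incorporation vector;
#' replicates with `sum(x) = 0` leave the statistic undefined.
#'
#' @param n_protofilaments number of protofilaments (default 200).
#' @param subunits_per_protofilament protofilament length L (default 50).
#' @param f proportion of disruptive subunits in the cell, in `[0, 1]`.
#' @param threshold integer tolerance threshold T, `0 <= T <= L`.
#' @param p_incorp_above,p_incorp_below incorporation probabilities above /
#'   at-or-below the threshold (defaults 0.01 and 0.99).
#' @param n_reps number of independent replicates (default 10000).
#' @param seed optional integer seed; the run is fully reproducible given
#'   the seed (replicates consume one binomial block then one uniform
#'   block, in replicate-major order).
#' @param tie_below logical; treat `x_i == T` as tolerated (incorporation
#'   probability `p_incorp_below`).  Default `TRUE`, reading the critical
#'   fraction as the highest tolerated fraction.
#' @return object of class `zring_config`.
#' @export
zring_config <- function(f, threshold, n_protofilaments = 200L,
                         subunits_per_protofilament = 50L,
                         p_incorp_above = 0.01, p_incorp_below = 0.99,
                         n_reps = 10000L, seed = NULL, tie_below = TRUE) {
  if (!is_prob(f)) stopf("`f` must be a probability in [0, 1]")
  if (!is_count(n_protofilaments)) stopf("`n_protofilaments` must be a positive integer")
  if (!is_count(subunits_per_protofilament))
    stopf("`subunits_per_protofilament` must be a positive integer")
  L <- as.integer(subunits_per_protofilament)
  if (!is.numeric(threshold) || threshold != round(threshold) ||
      threshold < 0 || threshold > L)
    stopf("`threshold` must be an integer in [0, L]")
  if (!is_prob(p_incorp_above) || !is_prob(p_incorp_below))
    stopf("incorporation probabilities must lie in [0, 1]")
  if (!is_count(n_reps)) stopf("`n_reps` must be a positive integer")
  structure(list(n_protofilaments = as.integer(n_protofilaments),
                 subunits_per_protofilament = L,
                 f = f, threshold = as.integer(threshold),
                 p_incorp_above = p_incorp_above,
                 p_incorp_below = p_incorp_below,
                 n_reps = as.integer(n_reps), seed = seed,
                 tie_below = isTRUE(tie_below)),
            class = "zring_config")
}

#' @export
print.zring_config <- function(x, ...) {
  cat(sprintf("zring_config: %d protofilaments x %d subunits, f = %.3f, T = %d (f_c = %.3f)\n",
              x$n_protofilaments, x$subunits_per_protofilament, x$f,
              x$threshold, critical_fraction(x)))
  cat(sprintf("  p_incorp: %.2f above threshold, %.2f at/below; %d reps\n",
              x$p_incorp_above, x$p_incorp_below, x$n_reps))
  invisible(x)
}

#' @rdname zring_config
#' @param config a `zring_config`.
#' @export
critical_fraction <- function(config) {
  config$threshold / config$subunits_per_protofilament
}

#' Sample protofilament compositions
#'
#' Draws one replicate of disruptive-subunit counts,
#' `x_i ~ Binomial(L, f)` i.i.d. over protofilaments, using the current
#' RNG stream.
#'
#' @param config a [zring_config()].
#' @return integer vector of length `n_protofilaments`.
#' @export
sample_compositions <- function(config) {
  stats::rbinom(config$n_protofilaments, config$subunits_per_protofilament,
                config$f)
}

#' Sample incorporation states
#'
#' Given compositions `x`, draws the Boolean incorporation vector `V`:
#' `V_i = 1` with probability `p_incorp_above` when `x_i` exceeds the
#' threshold, else with probability `p_incorp_below` (ties at the threshold
#' follow `config$tie_below`).
#'
#' @param x integer vector of compositions, entries in `[0, L]`.
#' @param config a [zring_config()].
#' @return integer 0/1 vector of the same length.
#' @export
incorporation_states <- function(x, config) {
  if (any(x < 0 | x > config$subunits_per_protofilament))
    stopf("compositions must lie in [0, L]")
  above <- if (config$tie_below) x > config$threshold else x >= config$threshold
  p <- ifelse(above, config$p_incorp_above, config$p_incorp_below)
  as.integer(stats::runif(length(x)) < p)
}

#' Fraction of disruptive subunits inside the ring
#'
#' The per-replicate statistic `sum(x * V) / sum(x)`; `NA` when
#' `sum(x) = 0` (no disruptive subunit exists, statistic undefined).
#'
#' @param x integer compositions.
#' @param V 0/1 incorporation states.
#' @return numeric scalar in `[0, 1]`, or `NA`.
#' @export
disruptive_fraction_in_ring <- function(x, V) {
  if (length(x) != length(V)) stopf("`x` and `V` must have equal length")
  s <- sum(x)
  if (s == 0) return(NA_real_)
  sum(x * V) / s
}

#' Run the Z-ring incorporation simulation
#'
#' Runs `n_reps` independent replicates (sample compositions, sample
#' incorporation states, compute the statistic) and aggregates the mean and
#' standard error over the replicates where the statistic is defined.
#' Fully reproducible given `config$seed`; the caller's RNG state is
#' preserved.
#'
#' @param config a [zring_config()].
#' @return object of class `zring_sim`: `per_rep_statistic` (length
#'   `n_reps`, `NA` where undefined), `mean`, `se`, `n_undefined`,
#'   `config`.
#' @export
run_simulation <- function(config) {
  n <- config$n_protofilaments
  L <- config$subunits_per_protofilament
  reps <- config$n_reps
  stats_vec <- with_preserved_seed(config$seed, {
    X <- matrix(stats::rbinom(reps * n, L, config$f), nrow = reps, byrow = TRUE)
    above <- if (config$tie_below) X > config$threshold else X >= config$threshold
    P <- ifelse(above, config$p_incorp_above, config$p_incorp_below)
    V <- matrix(stats::runif(reps * n), nrow = reps, byrow = TRUE) < P
    num <- rowSums(X * V)
    den <- rowSums(X)
    ifelse(den > 0, num / den, NA_real_)
  })
  defined <- stats_vec[!is.na(stats_vec)]
  structure(list(per_rep_statistic = stats_vec,
                 mean = mean(defined),
                 se = if (length(defined) > 1L)
                   stats::sd(defined) / sqrt(length(defined)) else NA_real_,
                 n_undefined = sum(is.na(stats_vec)),
                 config = config),
            class = "zring_sim")
}

#' @export
print.zring_sim <- function(x, ...) {
  cat(sprintf("zring_sim: f = %.3f, T = %d, %d reps\n", x$config$f,
              x$config$threshold, x$config$n_reps))
  cat(sprintf("  mean fraction of disruptive subunits in ring: %.4f (se %.2g)\n",
              x$mean, x$se))
  if (x$n_undefined > 0)
    cat(sprintf("  %d replicate(s) undefined (no disruptive subunits)\n",
                x$n_undefined))
  invisible(x)
}

#' @export
summary.zring_sim <- function(object, ...) {
  q <- stats::quantile(object$per_rep_statistic, c(0.025, 0.5, 0.975),
                       na.rm = TRUE)
  out <- c(mean = object$mean, se = object$se, lo95 = unname(q[1]),
           median = unname(q[2]), hi95 = unname(q[3]),
           p_undefined = object$n_undefined / object$config$n_reps)
  class(out) <- "summary.zring_sim"
  out
}

#' @export
print.summary.zring_sim <- function(x, ...) {
  print(unclass(x)); invisible(x)
}

#' Exact expectation of the statistic by enumeration (small instances)
#'
#' Enumerates every composition vector `x` in `{0..L}^n` and every
#' incorporation vector `V` in `{0,1}^n`, weighting by binomial and
#' Bernoulli probabilities, and returns the exact conditional expectation
#' `E[sum(xV)/sum(x) | sum(x) > 0]` together with `P(sum(x) = 0)`.  The
#' state space has `(L+1)^n * 2^n` outcomes, so `n` and `L` are capped at 4.
#'
#' @param n number of protofilaments (<= 4).
#' @param L protofilament length (<= 4).
#' @param f,threshold,p_above,p_below model parameters as in
#'   [zring_config()].
#' @param tie_below tie rule at `x == threshold` (default below).
#' @return list with `expectation`, `p_undefined`, `variance` (conditional
#'   variance of the statistic).
#' @export
exact_statistic_small <- function(n, L, f, threshold, p_above = 0.01,
                                  p_below = 0.99, tie_below = TRUE) {
  if (!is_count(n) || n > 4) stopf("`n` must be an integer in 1..4")
  if (!is_count(L) || L > 4) stopf("`L` must be an integer in 1..4")
  x_grid <- as.matrix(expand.grid(rep(list(0:L), n)))
  v_grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  px <- matrix(stats::dbinom(x_grid, L, f), nrow = nrow(x_grid))
  wx <- apply(px, 1, prod)
  e1 <- 0; e2 <- 0; p0 <- 0
  for (i in seq_len(nrow(x_grid))) {
    x <- x_grid[i, ]
    sx <- sum(x)
    if (sx == 0) { p0 <- p0 + wx[i]; next }
    above <- if (tie_below) x > threshold else x >= threshold
    p <- ifelse(above, p_above, p_below)
    for (k in seq_len(nrow(v_grid))) {
      v <- v_grid[k, ]
      wv <- prod(ifelse(v == 1, p, 1 - p))
      s <- sum(x * v) / sx
      w <- wx[i] * wv
      e1 <- e1 + w * s
      e2 <- e2 + w * s^2
    }
  }
  pd <- 1 - p0
  if (pd <= 0) return(list(expectation = NA_real_, p_undefined = 1,
                           variance = NA_real_))
  m <- e1 / pd
  list(expectation = m, p_undefined = p0, variance = e2 / pd - m^2)
}

#' Exact mean of the statistic for arbitrary size (semi-analytic)
#'
#' Marginalizing the incorporation states analytically, the statistic's
#' conditional mean given compositions is
#' `p_above + (p_below - p_above) * sum(x_i b_i) / sum(x_i)` with
#' `b_i = 1` when protofilament i is at or below threshold.  Taking the
#' expectation over i.i.d. binomial compositions and exploiting exchange-
#' ability reduces the mean to one-dimensional integrals
#' `E[1/(k + S)] = integral_0^1 t^(k-1) (1 - f + f t)^((n-1) L) dt`,
#' accumulated in log space so that the tiny excess over `p_above` at
#' large `f` retains its ordering.  Used by [zring_sweep()] as the
#' noise-free reference curve.
#'
#' @inheritParams exact_statistic_small
#' @return list with `mean`, `log_excess` (log of `mean - p_above`;
#'   `-Inf` when the excess underflows), `p_undefined`.
#' @export
zring_exact_mean <- function(n, L, f, threshold, p_above = 0.01,
                             p_below = 0.99, tie_below = TRUE) {
  if (f <= 0) {
    return(list(mean = NA_real_, log_excess = NA_real_, p_undefined = 1))
  }
  kmax <- if (tie_below) threshold else threshold - 1L
  log_p0 <- n * L * log1p(-f)
  log_pdef <- log1p(-exp(log_p0))
  if (kmax < 1L) {
    # only x_i = 0 can be "below"; such terms contribute 0 to the numerator
    return(list(mean = p_above, log_excess = -Inf,
                p_undefined = exp(log_p0)))
  }
  M <- (n - 1) * L
  log_terms <- vapply(1:kmax, function(k) {
    I <- stats::integrate(function(t) t^(k - 1) * (1 - f + f * t)^M,
                          0, 1, rel.tol = 1e-12)$value
    stats::dbinom(k, L, f, log = TRUE) + log(k) + log(I)
  }, numeric(1))
  log_g <- log(n) + logsumexp(log_terms)
  log_excess <- log(p_below - p_above) + log_g - log_pdef
  list(mean = p_above + exp(log_excess), log_excess = log_excess,
       p_undefined = exp(log_p0))
}

#' Sweep the incorporation model over (f, T) grids
#'
#' Runs [run_simulation()] for every combination of `f_grid` and `T_grid`
#' and attaches the semi-analytic reference mean from [zring_exact_mean()]
#' as monotonicity diagnostics.
#'
#' @param f_grid numeric vector of disruptive proportions.
#' @param T_grid integer vector of thresholds.
#' @param config a template [zring_config()] supplying all remaining
#'   parameters (its `f`/`threshold` are overridden per grid point; seeds
#'   are derived per point from `config$seed`).
#' @return data frame of class `zring_sweep` with columns `f`, `threshold`,
#'   `mean`, `se`, `p_undefined`, `mean_exact`, `log_excess_exact`.
#' @export
zring_sweep <- function(f_grid, T_grid, config) {
  if (!length(f_grid) || !length(T_grid)) stopf("grids must be non-empty")
  grid <- expand.grid(f = f_grid, threshold = T_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$f <- grid$f[i]
    cfg$threshold <- as.integer(grid$threshold[i])
    if (!is.null(config$seed)) cfg$seed <- config$seed + i
    sim <- run_simulation(cfg)
    ex <- zring_exact_mean(cfg$n_protofilaments, cfg$subunits_per_protofilament,
                           cfg$f, cfg$threshold, cfg$p_incorp_above,
                           cfg$p_incorp_below, cfg$tie_below)
    data.frame(f = cfg$f, threshold = cfg$threshold, mean = sim$mean,
               se = sim$se, p_undefined = sim$n_undefined / cfg$n_reps,
               mean_exact = ex$mean, log_excess_exact = ex$log_excess)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("zring_sweep", class(out))
  out
}

#' @export
plot.zring_sweep <- function(x, ...) {
  ts <- sort(unique(x$threshold))
  cols <- grDevices::hcl.colors(max(length(ts), 2L), "Dark 3")
  graphics::plot(NULL, xlim = range(x$f), ylim = c(0, 1),
                 xlab = "cellular proportion f of disruptive subunits",
                 ylab = "fraction of disruptive subunits in Z-ring", ...)
  for (i in seq_along(ts)) {
    d <- x[x$threshold == ts[i], ]
    d <- d[order(d$f), ]
    graphics::lines(d$f, d$mean, col = cols[i], lwd = 2)
    graphics::points(d$f, d$mean, col = cols[i], pch = 16)
  }
  graphics::legend("topright", legend = sprintf("T = %d", ts), col = cols,
                   lwd = 2, bty = "n")
  invisible(x)
}
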