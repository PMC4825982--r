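#' Symmetric Dirichlet model specification
#'
#' Bundles the two parameters of the symmetric Dirichlet density over an
#' `n`-category probability vector: the number of categories `n` (for
#' English phonemes conventionally 44) and the concentration `beta`
#' shared by all categories. Larger `beta` produces a more homogeneous
#' probability vector; as `beta` shrinks below 1 a few categories take
#' most of the mass.
#'
#' @param n Number of categories (integer, >= 1).
#' @param beta Concentration parameter (> 0).
#' @return An object of class `"dirichlet_spec"`.
#' @examples
#' dirichlet_spec(44, 0.8)
#' @export
dirichlet_spec <- function(n, beta) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != floor(n))
    stop("'n' must be a single integer >= 1")
  if (length(beta) != 1L || is.na(beta) || beta <= 0)
    stop("'beta' must be a single positive number")
  structure(list(n = as.integer(n), beta = as.numeric(beta)),
            class = "dirichlet_spec")
}

#' @export
print.dirichlet_spec <- function(x, ...) {
  cat(sprintf("Symmetric Dirichlet: n = %d categories, beta = %g\n",
              x$n, x$beta))
  invisible(x)
}

#' Regularized lower incomplete gamma function
#'
#' Computes `phi(y) = P(beta, y)`, the CDF of a unit-scale gamma variate
#' with shape `beta`. This is the building block of the order-statistic
#' density of the symmetric Dirichlet: the Dirichlet vector can be
#' realized as independent gamma(beta) variates divided by their sum, so
#' ranking Dirichlet components reduces to ranking gamma variates.
#'
#' @param y Non-negative numeric vector of evaluation points.
#' @param beta Gamma shape parameter (> 0).
#' @param log.p If `TRUE` return log of the value.
#' @return Values in \[0, 1\] (or their logs), same length as `y`.
#' @examples
#' incomplete_gamma_phi(1, 1)  # 1 - exp(-1)
#' @export
incomplete_gamma_phi <- function(y, beta, log.p = FALSE) {
  if (length(beta) != 1L || is.na(beta) || beta <= 0)
    stop("'beta' must be a single positive number")
  if (any(y < 0, na.rm = TRUE))
    stop("'y' must be non-negative")
  stats::pgamma(y, shape = beta, log.p = log.p)
}

# Log of the moment-generating kernel chi_r(y; m): the density of the
# r-th LARGEST of n iid gamma(beta) variates, times
# Gamma(n beta) / Gamma(n beta + m). All factors are assembled on the
# log scale; binomial-type coefficients overflow in direct form already
# around n = 44.
chi_log_kernel <- function(y, r, m, n, beta) {
  log_phi  <- stats::pgamma(y, shape = beta, log.p = TRUE)
  log_1mphi <- stats::pgamma(y, shape = beta, lower.tail = FALSE,
                             log.p = TRUE)
  lgamma(n * beta) - lgamma(n * beta + m) +
    lgamma(n + 1) - lgamma(n - r + 1) - lgamma(r) +
    (beta - 1) * log(y) - y - lgamma(beta) +
    (n - r) * log_phi + (r - 1) * log_1mphi
}

#' Order-statistic moment kernel of the symmetric Dirichlet
#'
#' Density-like kernel `chi_r(y; m)` whose `m`-th moment integral
#' `int_0^Inf y^m chi_r(y; m) dy` equals the `m`-th moment of the `r`-th
#' largest component of a symmetric Dirichlet(`n`, `beta`) vector. For
#' `m = 0` it is exactly the density of the `r`-th largest of `n`
#' independent gamma(`beta`) variates.
#'
#' @param y Non-negative numeric vector.
#' @param r Rank, `1 <= r <= n` (1 = largest component).
#' @param m Moment order (non-negative integer).
#' @param spec A [dirichlet_spec()].
#' @param log If `TRUE` return the log kernel.
#' @return Kernel values (>= 0), same length as `y`.
#' @export
chi_density <- function(y, r, m, spec, log = FALSE) {
  stopifnot(inherits(spec, "dirichlet_spec"))
  if (length(r) != 1L || r < 1 || r > spec$n || r != floor(r))
    stop(sprintf("rank 'r' must be an integer in [1, %d]", spec$n))
  if (length(m) != 1L || m < 0)
    stop("'m' must be a non-negative integer")
  out <- rep(-Inf, length(y))
  pos <- !is.na(y) & y > 0
  out[pos] <- chi_log_kernel(y[pos], r, m, spec$n, spec$beta)
  out[is.na(y)] <- NA_real_
  if (log) out else exp(out)
}

#' Moment of an ordered Dirichlet component
#'
#' Computes `<theta_(r)^m>`, the `m`-th moment of the `r`-th largest
#' component of a symmetric Dirichlet vector, by adaptive quadrature of
#' the kernel returned by [chi_density()] over the semi-infinite gamma
#' scale.
#'
#' @param r Rank (1 = largest).
#' @param m Moment order; the fitting path uses only 1 and 2 but any
#'   positive integer is accepted.
#' @param spec A [dirichlet_spec()].
#' @param tol Absolute quadrature tolerance (default `1e-10`).
#' @return The moment, a single number.
#' @examples
#' ordered_moment(1, 1, dirichlet_spec(2, 1))  # 0.75
#' @export
ordered_moment <- function(r, m, spec, tol = 1e-10) {
  stopifnot(inherits(spec, "dirichlet_spec"))
  if (length(r) != 1L || r < 1 || r > spec$n || r != floor(r))
    stop(sprintf("rank 'r' must be an integer in [1, %d]", spec$n))
  # Integrate in u = y^beta: the Jacobian cancels the y^(beta-1)
  # factor exactly (their log-exponents sum to -log(beta)), removing
  # the power singularity at the origin for beta < 1 and keeping the
  # integrand smooth for beta > 1.
  n <- spec$n; beta <- spec$beta
  const <- lgamma(n * beta) - lgamma(n * beta + m) +
    lgamma(n + 1) - lgamma(n - r + 1) - lgamma(r) -
    lgamma(beta) - log(beta)
  integrand <- function(u) {
    out <- numeric(length(u))
    pos <- u > 0
    log_y <- log(u[pos]) / beta
    y <- exp(log_y)
    log_phi <- stats::pgamma(y, shape = beta, log.p = TRUE)
    log_1mphi <- stats::pgamma(y, shape = beta, lower.tail = FALSE,
                               log.p = TRUE)
    out[pos] <- exp(const + m * log_y - y +
                      (n - r) * log_phi + (r - 1) * log_1mphi)
    out
  }
  res <- tryCatch(
    stats::integrate(integrand, lower = 0, upper = Inf,
                     abs.tol = tol, rel.tol = tol,
                     subdivisions = 1000L),
    error = function(e) stop(sprintf(
      "quadrature failed for r = %d, m = %d (n = %d, beta = %g): %s",
      r, m, spec$n, spec$beta, conditionMessage(e)), call. = FALSE))
  if (res$abs.error > max(tol * 100, 1e-8))
    stop(sprintf(
      "quadrature did not reach tol = %g (achieved abs error %g)",
      tol, res$abs.error))
  res$value
}

#' Expected ranked frequency curve
#'
#' The model's predicted rank-frequency relation: the vector of expected
#' ordered components `<theta_(r)>`, r = 1..n, of a symmetric Dirichlet
#' vector. This is the curve that observed ranked phoneme frequencies
#' are fitted against.
#'
#' @param spec A [dirichlet_spec()].
#' @param tol Absolute quadrature tolerance per rank.
#' @return Numeric vector of length `spec$n`, non-increasing, summing
#'   to 1 (within quadrature tolerance).
#' @examples
#' expected_curve(dirichlet_spec(3, 1))  # (11, 5, 2) / 18
#' @export
expected_curve <- function(spec, tol = 1e-10) {
  stopifnot(inherits(spec, "dirichlet_spec"))
  vapply(seq_len(spec$n), ordered_moment, numeric(1),
         m = 1, spec = spec, tol = tol)
}

#' Order-statistic summary table
#'
#' Per-rank expected value, second moment, and relative fluctuation
#' `eps_r = (<theta_(r)^2> - <theta_(r)>^2) / <theta_(r)>^2` of the
#' ordered symmetric-Dirichlet components. `eps_r` measures how tightly
#' a single realized ranked profile hugs the expected curve; it is
#' non-monotonic in rank, smallest at moderate ranks and largest for the
#' very rarest categories.
#'
#' @inheritParams expected_curve
#' @return A data frame of class `"order_stat_table"` with columns
#'   `rank`, `mean`, `second_moment`, `rel_fluctuation`; the spec and
#'   tolerance are attached as attributes.
#' @export
order_stat_table <- function(spec, tol = 1e-10) {
  stopifnot(inherits(spec, "dirichlet_spec"))
  m1 <- expected_curve(spec, tol)
  m2 <- vapply(seq_len(spec$n), ordered_moment, numeric(1),
               m = 2, spec = spec, tol = tol)
  out <- data.frame(rank = seq_len(spec$n), mean = m1,
                    second_moment = m2,
                    rel_fluctuation = (m2 - m1^2) / m1^2)
  attr(out, "spec") <- spec
  attr(out, "tol") <- tol
  class(out) <- c("order_stat_table", "data.frame")
  out
}

#' Approximate ranked frequency curve
#'
#' Closed-form approximation to [expected_curve()] obtained by inverting
#' the tail relation `r/n = 1 - phi(f_r * n * beta)`:
#' `f_r = phi^{-1}(1 - r/n) / (n beta)`, with `phi^{-1}` the gamma
#' quantile function. Exact limit `f_n = 0` at the last rank. For
#' `beta = 1` this reduces to `log(n / r) / n`. The approximation nearly
#' overlaps the exact curve except at the first few ranks.
#'
#' @param spec A [dirichlet_spec()].
#' @return Numeric vector of length `spec$n`.
#' @export
approx_curve <- function(spec) {
  stopifnot(inherits(spec, "dirichlet_spec"))
  r <- seq_len(spec$n)
  stats::qgamma(1 - r / spec$n, shape = spec$beta) / (spec$n * spec$beta)
}

#' Relative fluctuation of an ordered component
#'
#' `eps_r = (<theta_(r)^2> - <theta_(r)>^2) / <theta_(r)>^2`, the
#' normalized variance of the `r`-th largest Dirichlet component.
#'
#' @inheritParams ordered_moment
#' @return A single non-negative number.
#' @export
relative_fluctuation <- function(r, spec, tol = 1e-10) {
  m1 <- ordered_moment(r, 1, spec, tol)
  m2 <- ordered_moment(r, 2, spec, tol)
  (m2 - m1^2) / m1^2
}

#' Flat-case (beta = 1) closed form for the expected ranked curve
#'
#' For the uniform density on the simplex the expected `r`-th largest
#' component is `(1/n) * sum_{k=r}^{n} 1/k` (spacings of exponential
#' order statistics). Serves as an independent oracle for the quadrature
#' route at `beta = 1`.
#'
#' @param n Number of categories.
#' @param r Rank or vector of ranks.
#' @return Expected value(s) of the ordered component(s).
#' @export
flat_closed_form <- function(n, r = seq_len(n)) {
  if (any(r < 1 | r > n | r != floor(r)))
    stop(sprintf("ranks must be integers in [1, %d]", n))
  tail_sums <- rev(cumsum(1 / rev(seq_len(n))))  # sum_{k=r}^n 1/k
  tail_sums[r] / n
}

# Evaluate an expression with a temporary RNG state seeded by `seed`,
# restoring the caller's RNG state afterwards. Keeps all samplers pure
# functions of (arguments, seed).
with_seed <- function(seed, expr) {
  if (length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  has_seed <- exists(".Random.seed", envir = globalenv(),
                     inherits = FALSE)
  if (has_seed)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_seed)
      assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Sample sorted symmetric-Dirichlet vectors
#'
#' Draws probability vectors from the symmetric Dirichlet by normalizing
#' independent gamma(`beta`) variates, then sorts each vector in
#' non-increasing order. The Monte-Carlo counterpart of
#' [expected_curve()].
#'
#' @param spec A [dirichlet_spec()].
#' @param draws Number of vectors to draw.
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return A `draws x n` matrix; each row is non-increasing and sums
#'   to 1.
#' @export
sample_ordered <- function(spec, draws, seed) {
  stopifnot(inherits(spec, "dirichlet_spec"))
  if (length(draws) != 1L || draws < 1 || draws != floor(draws))
    stop("'draws' must be a positive integer")
  if (spec$n == 1L)
    return(matrix(1, nrow = draws, ncol = 1L))
  with_seed(seed, {
    g <- matrix(stats::rgamma(draws * spec$n, shape = spec$beta),
                nrow = draws, ncol = spec$n)
    g <- g / rowSums(g)
    t(apply(g, 1L, sort, decreasing = TRUE))
  })
}
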