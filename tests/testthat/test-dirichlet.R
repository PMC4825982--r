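test_that("incomplete_gamma_phi is the regularized lower incomplete gamma", {
  expect_equal(incomplete_gamma_phi(0, 0.7), 0)
  expect_equal(incomplete_gamma_phi(1, 1), 1 - exp(-1),
               tolerance = 1e-12)
  # direct adaptive quadrature of the defining integrand
  oracle <- integrate(function(x) x^(0.8 - 1) * exp(-x) / gamma(0.8),
                      0, 0.5, rel.tol = 1e-12)$value
  expect_equal(incomplete_gamma_phi(0.5, 0.8), oracle,
               tolerance = 1e-10)
  y <- seq(0, 10, length.out = 50)
  expect_true(all(diff(incomplete_gamma_phi(y, 0.6)) >= 0))
  expect_error(incomplete_gamma_phi(1, -1), "positive")
})

test_that("chi kernel integrates to the right mass", {
  # single category: theta = 1 identically, all moments 1
  s1 <- dirichlet_spec(1, 0.9)
  for (m in c(0, 1, 3)) {
    v <- integrate(function(y) chi_density(y, 1, m, s1) * y^m,
                   0, Inf, rel.tol = 1e-10)$value
    expect_equal(v, 1, tolerance = 1e-8)
  }
  # first moments over ranks sum to one
  s5 <- dirichlet_spec(5, 0.7)
  tot <- sum(vapply(1:5, function(r)
    integrate(function(y) y * chi_density(y, r, 1, s5),
              0, Inf, rel.tol = 1e-10)$value, numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-8)
  expect_error(chi_density(1, 7, 1, s5), "rank")
})

test_that("chi kernel (m = 0) matches the Monte-Carlo law of sorted gamma draws", {
  # P(2nd largest of 5 gamma(0.7) draws <= 1) via quadrature vs
  # simulation
  s5 <- dirichlet_spec(5, 0.7)
  p_quad <- integrate(function(y) chi_density(y, 2, 0, s5), 0, 1,
                      rel.tol = 1e-10)$value
  set.seed(301)
  draws <- 2e5
  g <- matrix(rgamma(draws * 5, 0.7), draws, 5)
  x2 <- apply(g, 1, function(z) sort(z, decreasing = TRUE)[2])
  p_mc <- mean(x2 <= 1)
  se <- sqrt(p_mc * (1 - p_mc) / draws)
  expect_lt(abs(p_quad - p_mc), 4 * se)
})

test_that("ordered moments reproduce closed-form simplex integrals", {
  expect_equal(ordered_moment(1, 1, dirichlet_spec(2, 1)), 0.75,
               tolerance = 1e-9)
  expect_equal(ordered_moment(1, 1, dirichlet_spec(3, 1)), 11 / 18,
               tolerance = 1e-9)
  s2 <- dirichlet_spec(2, 1)
  expect_equal(ordered_moment(1, 2, s2) + ordered_moment(2, 2, s2),
               2 / 3, tolerance = 1e-9)
})

test_that("expected curve is a normalized, strictly decreasing probability profile", {
  expect_equal(expected_curve(dirichlet_spec(3, 1)),
               c(11, 5, 2) / 18, tolerance = 1e-9)
  expect_equal(expected_curve(dirichlet_spec(1, 0.8)), 1,
               tolerance = 1e-10)
  for (n in c(2, 10, 44)) {
    for (beta in c(0.3, 0.8, 1.5)) {
      f <- expected_curve(dirichlet_spec(n, beta), tol = 1e-10)
      expect_equal(sum(f), 1, tolerance = 1e-8)
      expect_true(all(diff(f) < 0) || n == 1)
      expect_true(all(f > 0))
    }
  }
  # larger beta -> more homogeneous -> smaller top frequency
  tops <- vapply(c(0.4, 0.8, 1.2), function(b)
    ordered_moment(1, 1, dirichlet_spec(15, b)), numeric(1))
  expect_true(all(diff(tops) < 0))
})

test_that("second moments satisfy the Beta-marginal sum rule", {
  for (n in c(2, 10, 44)) {
    for (beta in c(0.3, 0.8, 1.5)) {
      tab <- order_stat_table(dirichlet_spec(n, beta), tol = 1e-10)
      expect_equal(sum(tab$second_moment),
                   (beta + 1) / (n * beta + 1), tolerance = 1e-8)
      expect_true(all(tab$rel_fluctuation >= 0))
    }
  }
})

test_that("beta = 1 quadrature equals the harmonic-tail closed form", {
  for (n in c(13, 50)) {
    quad <- expected_curve(dirichlet_spec(n, 1), tol = 1e-11)
    expect_lt(max(abs(quad - flat_closed_form(n))), 1e-8)
  }
  expect_equal(flat_closed_form(2, 1), 0.75)
  expect_equal(flat_closed_form(3, 3), 1 / 9)
  for (n in c(2, 7, 30))
    expect_equal(sum(flat_closed_form(n)), 1, tolerance = 1e-12)
})

test_that("approximate curve inverts the tail relation", {
  # beta = 1: exponential quantiles give log(n / r) / n
  n <- 30
  ap <- approx_curve(dirichlet_spec(n, 1))
  expect_equal(ap, log(n / (1:n)) / n, tolerance = 1e-10)
  expect_equal(ap[n], 0)
  # near-overlap with the exact curve at the study's parameters:
  # discrepancy is visible only at the very top ranks
  s <- dirichlet_spec(44, 0.8)
  exact <- expected_curve(s)
  d <- abs(approx_curve(s) - exact)
  expect_lt(d[1] / exact[1], 0.2)
  expect_lt(max(d[-1]) / exact[1], 0.08)
  expect_lt(median(d) / exact[1], 0.01)
})

test_that("relative fluctuation matches closed forms and degenerate limits", {
  expect_equal(relative_fluctuation(1, dirichlet_spec(2, 1)), 1 / 27,
               tolerance = 1e-8)
  expect_equal(relative_fluctuation(1, dirichlet_spec(1, 0.5)), 0,
               tolerance = 1e-10)
})

test_that("sampled sorted vectors agree with quadrature and are reproducible", {
  s <- dirichlet_spec(3, 1)
  m <- sample_ordered(s, 1e5, seed = 11)
  expect_equal(rowSums(m), rep(1, nrow(m)), tolerance = 1e-12)
  expect_true(all(m[, 1] >= m[, 2] & m[, 2] >= m[, 3]))
  cm <- colMeans(m)
  se <- apply(m, 2, sd) / sqrt(nrow(m))
  expect_true(all(abs(cm - c(11, 5, 2) / 18) <= 3 * se))
  expect_identical(m, sample_ordered(s, 1e5, seed = 11))
  expect_false(identical(m[1, ], sample_ordered(s, 1, seed = 12)[1, ]))
})

test_that("sampling does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(sample_ordered(dirichlet_spec(4, 0.7), 10, seed = 5))
  expect_identical(runif(1), a)
})

test_that("neutrality: dropped-and-renormalized components stay Dirichlet with the same beta", {
  # drop 4 of 8 components of raw Dirichlet draws, renormalize, sort;
  # the first two ordered moments must match the 4-category curve
  n <- 8; keep <- 4; beta <- 0.7; draws <- 4e4
  set.seed(17)
  g <- matrix(rgamma(draws * n, beta), draws, n)
  th <- g / rowSums(g)
  sub <- th[, seq_len(keep)]
  sub <- sub / rowSums(sub)
  sub <- t(apply(sub, 1, sort, decreasing = TRUE))
  s4 <- dirichlet_spec(keep, beta)
  m1 <- expected_curve(s4)
  m2 <- vapply(seq_len(keep), ordered_moment, numeric(1), m = 2,
               spec = s4)
  se1 <- apply(sub, 2, sd) / sqrt(draws)
  expect_true(all(abs(colMeans(sub) - m1) <= 4 * se1))
  se2 <- apply(sub^2, 2, sd) / sqrt(draws)
  expect_true(all(abs(colMeans(sub^2) - m2) <= 4 * se2))
})
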