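test_that("goodness of fit matches hand-computed projections", {
  # perfect fit
  L <- matrix(stats::rnorm(12), 4, 3)
  m <- c(1, -2, 0.5)
  fit <- goodness_of_fit(L %*% m, L)
  expect_lt(abs(fit$gof - 1), 1e-12)
  expect_equal(fit$moment, m, tolerance = 1e-9)
  # orthogonal measurement
  l <- matrix(c(1, 0, 0), 3, 1)
  expect_equal(goodness_of_fit(c(0, 1, 1), l)$gof, 0)
  # hand-computed: u = (1,1,0), column (1,0,0): projection (1,0,0)
  fit2 <- goodness_of_fit(c(1, 1, 0), l)
  expect_equal(fit2$gof, 0.5)
  expect_equal(fit2$moment, 1)
  expect_error(goodness_of_fit(c(0, 0, 0), l), "zero measurement")
  expect_error(goodness_of_fit(c(1, 1), l), "mismatch")
})

test_that("moving scan equals a brute-force per-node oracle and recovers a grid source", {
  sc <- get_small_scenario()
  sh <- sc$head$shells
  lf <- sc$leadfield_std
  k_true <- sc$reference$index
  m_true <- c(4e-9, 2e-9, -7e-9)
  u <- as.vector(lf$gain[, (3 * k_true - 2):(3 * k_true)] %*% m_true)
  res <- scan_moving(u, lf, shells = sh)
  expect_equal(res$best_index, k_true)
  expect_gte(res$gof, 1 - 1e-9)
  expect_equal(res$moment, m_true, tolerance = 1e-6)
  # brute-force oracle: explicit normal-equation projection per node
  gof_oracle <- vapply(seq_len(nrow(lf$source_positions)), function(k) {
    L <- lf$gain[, (3 * k - 2):(3 * k)]
    p <- L %*% solve(crossprod(L), crossprod(L, u))
    1 - sum((u - p)^2) / sum(u^2)
  }, numeric(1))
  expect_equal(res$gof_per_position, gof_oracle, tolerance = 1e-9)
})

test_that("exact GoF ties break to the lowest index with a warning", {
  lf <- structure(
    list(gain = cbind(matrix(c(1, 0, -1, 0, 1, -1, 1, 1, -2), 3, 3),
                      matrix(c(1, 0, -1, 0, 1, -1, 1, 1, -2), 3, 3)),
         source_positions = rbind(c(0, 0, 0.05), c(0, 0, 0.06)),
         electrode_labels = c("a", "b", "c"),
         conductivities = NULL, reference = "average"),
    class = "leadfield")
  expect_warning(res <- scan_moving(c(1, 0, -1), lf), "tie")
  expect_equal(res$best_index, 1L)
})

test_that("rotating scan recovers moments and dominates the fixed scan", {
  sc <- get_small_scenario()
  lf <- sc$leadfield_std
  k <- sc$reference$index
  L3 <- lf$gain[, (3 * k - 2):(3 * k)]
  m <- c(-2e-9, 5e-9, 3e-9)
  u <- as.vector(L3 %*% m)
  rot <- scan_rotating(u, L3)
  expect_lt(sqrt(sum((rot$moment - m)^2)) / sqrt(sum(m^2)), 1e-9)
  # strength scales linearly with the measurement
  rot3 <- scan_rotating(3 * u, L3)
  expect_equal(rot3$strength, 3 * rot$strength, tolerance = 1e-9)
  # nested models: fixed <= rotating at the same position, any measurement
  set.seed(12)
  for (i in 1:20) {
    u_r <- stats::rnorm(nrow(L3), sd = 1e-7)
    u_r <- u_r - mean(u_r)
    ori <- stats::rnorm(3)
    ori <- ori / sqrt(sum(ori^2))
    fx <- scan_fixed(u_r, L3 %*% ori)
    rt <- scan_rotating(u_r, L3)
    expect_lte(fx$gof, rt$gof + 1e-12)
  }
})

test_that("fixed scan matches the least-squares slope of a 1-D oracle", {
  set.seed(3)
  l <- stats::rnorm(15)
  u <- 2.5 * l
  fx <- scan_fixed(u, l)
  expect_equal(fx$strength, 2.5, tolerance = 1e-12)
  expect_equal(fx$gof, 1, tolerance = 1e-12)
  # orthogonal measurement: zero amplitude, zero fit
  u_perp <- stats::rnorm(15)
  u_perp <- u_perp - sum(u_perp * l) / sum(l^2) * l
  fx0 <- scan_fixed(u_perp, l)
  expect_lt(abs(fx0$strength), 1e-12 * max(abs(u_perp)) / max(abs(l)))
  expect_lt(fx0$gof, 1e-12)
  # brute-force 1-D minimisation oracle
  u2 <- u + u_perp
  slope <- stats::optimize(function(s) sum((u2 - s * l)^2),
                           c(-100, 100), tol = 1e-12)$minimum
  expect_equal(scan_fixed(u2, l)$strength, slope, tolerance = 1e-6)
})

test_that("orientation frames reproduce a hand-computed Gram-Schmidt triple", {
  fr <- build_orientation_frame(c(2, 2, 0), c(0, 0, 0.07), c(0, 1, 0))
  expect_equal(fr$e1, c(1, 1, 0) / sqrt(2))
  expect_equal(fr$e2, c(0, 0, 1))
  expect_equal(fr$e3, c(-1, 1, 0) / sqrt(2))
  # orthonormality on random inputs
  set.seed(8)
  for (i in 1:10) {
    f <- build_orientation_frame(stats::rnorm(3), stats::rnorm(3), stats::rnorm(3))
    G <- rbind(f$e1, f$e2, f$e3)
    expect_lt(max(abs(G %*% t(G) - diag(3))), 1e-12)
  }
  expect_error(build_orientation_frame(c(0, 0, 1), c(0, 0, 0.07), c(0, 1, 0)),
               "parallel to the radial")
})

test_that("orientation angles follow their closed forms", {
  fr <- build_orientation_frame(c(1, 0, 0), c(0, 0, 0.07), c(0, 1, 0))
  expect_equal(orientation_angles(5 * fr$e1, fr), c(phi = 0, theta = 0))
  expect_equal(orientation_angles(fr$e2, fr)[["theta"]], 90)
  ang <- orientation_angles((fr$e1 + fr$e3) / sqrt(2), fr)
  expect_equal(ang[["phi"]], 45)
  expect_equal(ang[["theta"]], 0, tolerance = 1e-12)
  expect_error(orientation_angles(c(0, 0, 0), fr), "zero moment")
})

test_that("source depth is the distance to the inner skull", {
  sh <- default_head()$shells
  expect_equal(source_depth(c(0, 0, 0.072), sh), 0.008)
  expect_equal(source_depth(c(0, 0.08, 0), sh), 0)
  expect_equal(source_depth(c(0, 0, 0), sh), 0.08)
  expect_error(source_depth(c(0, 0, 0.085), sh), "outside the inner skull")
})

test_that("scan variants are monotone in their degrees of freedom", {
  sc <- get_small_scenario()
  lf <- sc$leadfield_std
  k <- sc$reference$index
  L3 <- lf$gain[, (3 * k - 2):(3 * k)]
  ori <- sc$reference$orientation
  set.seed(99)
  for (i in 1:25) {
    u <- stats::rnorm(nrow(lf$gain), sd = 1e-7)
    u <- u - mean(u)
    g_f <- scan_fixed(u, L3 %*% ori)$gof
    g_r <- scan_rotating(u, L3)$gof
    g_m <- suppressWarnings(scan_moving(u, lf)$gof)
    expect_lte(g_f, g_r + 1e-12)
    expect_lte(g_r, g_m + 1e-12)
  }
})
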