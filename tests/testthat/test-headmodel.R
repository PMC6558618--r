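test_that("shell model validates its geometry invariants", {
  expect_error(shell_model(c(0.08, 0.07), c(1, 1), c("a", "b")),
               "strictly increasing")
  expect_error(shell_model(c(0.07, 0.08), c(1, -1), c("a", "b")), "positive")
  expect_error(shell_model(c(0.07, 0.08), c(1, 1), c("a", "a")), "unique")
  sh <- default_head()$shells
  expect_equal(length(sh$radii), 5L)
  expect_equal(tissue_at_radius(c(0.05, 0.075, 0.078, 0.079, 0.085, 0.09, 0.1), sh),
               c("wm", "gm", "gm", "csf", "skull", "skin", NA))
})

test_that("zero moment gives zero potential and negation flips the sign", {
  sh <- default_head()$shells
  pts <- random_surface_points(12, scalp_radius(sh), seed = 11)
  expect_equal(potential_layered_sphere(dipole(c(0, 0, 0.05), c(0, 0, 0)),
                                        pts, sh),
               rep(0, 12))
  m <- c(3e-9, -2e-9, 1e-9)
  u1 <- potential_layered_sphere(dipole(c(0, 0.01, 0.06), m), pts, sh)
  u2 <- potential_layered_sphere(dipole(c(0, 0.01, 0.06), -m), pts, sh)
  expect_equal(u2, -u1)
})

test_that("central dipole in a homogeneous sphere matches the closed form", {
  R <- 0.092
  sigma <- 0.33
  sh <- homogeneous_shells(R, sigma)
  pts <- random_surface_points(15, R, seed = 5)
  q <- c(2e-9, -4e-9, 1e-9)
  u <- potential_layered_sphere(dipole(c(0, 0, 0), q), pts, sh)
  u_exact <- 3 * as.vector((pts / R) %*% q) / (4 * pi * sigma * R^2)
  expect_lt(max(abs(u - u_exact)) / max(abs(u_exact)), 1e-8)
})

test_that("equal-conductivity multishell models collapse to the homogeneous sphere", {
  R <- 0.092
  sigma <- 0.4
  pts <- random_surface_points(10, R, seed = 21)
  dip <- dipole(c(0.01, -0.02, 0.05), c(5e-9, 2e-9, -1e-9))
  u1 <- potential_layered_sphere(dip, pts, homogeneous_shells(R, sigma))
  set.seed(31)
  for (n_shell in 2:6) {
    radii <- sort(stats::runif(n_shell - 1L, 0.062, 0.09))
    sh <- shell_model(c(radii, R), rep(sigma, n_shell),
                      sprintf("t%d", seq_len(n_shell)))
    u <- potential_layered_sphere(dip, pts, sh)
    expect_lt(max(abs(u - u1)) / max(abs(u1)), 1e-8)
  }
})

test_that("series truncation is converged at the default tolerance", {
  sh <- default_head()$shells
  pts <- random_surface_points(20, scalp_radius(sh), seed = 41)
  dip <- dipole(c(0, 0.02, 0.071), c(1e-8, 5e-9, 0))  # superficial source
  u8 <- potential_layered_sphere(dip, pts, sh, rtol = 1e-8)
  u12 <- potential_layered_sphere(dip, pts, sh, rtol = 1e-12)
  expect_lt(max(abs(u8 - u12)) / max(abs(u12)), 1e-6)
  expect_error(potential_layered_sphere(dip, pts, sh, rtol = 1e-13,
                                        n_max = 10L),
               "not converged")
})

test_that("dipoles outside the allowed region raise domain errors", {
  sh <- default_head()$shells
  pts <- random_surface_points(8, scalp_radius(sh), seed = 3)
  expect_error(potential_layered_sphere(dipole(c(0, 0, 0.083), c(1e-9, 0, 0)),
                                        pts, sh),
               "innermost two shells")
  expect_error(potential_layered_sphere(dipole(c(0, 0, 0.1), c(1e-9, 0, 0)),
                                        pts, sh),
               "outside the scalp")
})

test_that("radial current vanishes at the scalp surface", {
  sh <- default_head()$shells
  R <- scalp_radius(sh)
  dirs <- random_surface_points(10, 1, seed = 17)
  dip <- dipole(c(0, 0.01, 0.06), c(4e-9, -2e-9, 3e-9))
  delta <- 1e-6
  u_out <- potential_layered_sphere(dip, dirs * R, sh)
  u_in <- potential_layered_sphere(dip, dirs * (R - delta), sh)
  # exterior-facing finite difference of V along r: O(delta) curvature only
  expect_lt(max(abs(u_out - u_in)), 1e-3 * max(abs(u_out)))
})

test_that("swapping two electrodes permutes the output identically", {
  sh <- default_head()$shells
  pts <- random_surface_points(9, scalp_radius(sh), seed = 53)
  dip <- dipole(c(0.01, 0, 0.065), c(1e-9, 1e-9, 1e-9))
  u <- potential_layered_sphere(dip, pts, sh)
  perm <- c(2L, 1L, seq(3L, 9L))
  u_perm <- potential_layered_sphere(dip, pts[perm, ], sh)
  expect_equal(u_perm, u[perm])
})

test_that("average referencing subtracts the channel mean and is idempotent", {
  expect_equal(apply_average_reference(c(1, 2, 3)), c(-1, 0, 1))
  x <- matrix(c(1, 2, 3, 4, 6, 8), 3, 2)
  y <- apply_average_reference(x)
  expect_equal(colMeans(y), c(0, 0))
  expect_equal(apply_average_reference(y), y)
  expect_error(apply_average_reference(5), "at least 2 channels")
})

test_that("GoF is unchanged by re-applying the shared average reference", {
  # the average reference is idempotent, so re-referencing measurement and
  # gain together cannot move the GoF; this is what makes a canonical
  # shared reference necessary (non-orthogonal reference changes, e.g. to
  # a single electrode, do alter the L2 residual).
  sh <- default_head()$shells
  el <- generate_electrodes(20, seed = 2, radius = sh)
  pos <- rbind(c(0, 0, 0.06), c(0.01, 0.01, 0.055))
  lf <- compute_leadfield(pos, el, sh)
  set.seed(7)
  u <- apply_average_reference(
    as.vector(lf$gain %*% stats::rnorm(6, sd = 1e-9)) +
      1e-8 * stats::rnorm(20))
  g <- goodness_of_fit(u, lf$gain[, 1:3])$gof
  expect_identical(goodness_of_fit(apply_average_reference(u),
                                   apply_average_reference(lf$gain[, 1:3]))$gof,
                   g)
  # global scaling of the measurement leaves the GoF unchanged
  expect_equal(goodness_of_fit(5.5 * u, lf$gain[, 1:3])$gof, g)
})

test_that("leadfield assembly honours its shape and reference contracts", {
  sh <- default_head()$shells
  el <- generate_electrodes(12, seed = 4, radius = sh)
  grid <- build_cubic_grid(c(0, 0, 0.055), 0.006, 0.003)
  lf <- compute_leadfield(grid, el, sh)
  expect_equal(dim(lf$gain), c(12L, 3L * 27L))
  expect_lt(max(abs(colSums(lf$gain))),
            1e-12 * max(sqrt(colSums(lf$gain^2))))
  # column 3(k-1)+a is the average-referenced unit forward along axis a
  k <- 14L
  dip <- dipole(grid$positions[k, ], c(0, 1, 0))
  u <- apply_average_reference(potential_layered_sphere(dip, el, sh))
  # batch and per-dipole paths truncate the series adaptively and
  # independently, so they agree to the series tolerance, not bitwise
  expect_equal(lf$gain[, 3L * (k - 1L) + 2L], u, tolerance = 1e-7)
  expect_error(compute_leadfield(rbind(c(0, 0, 0.085)), el, sh),
               "invalid source positions")
})

test_that("leadfield text container round-trips", {
  sh <- default_head()$shells
  el <- generate_electrodes(8, seed = 6, radius = sh)
  lf <- compute_leadfield(rbind(c(0, 0, 0.05)), el, sh)
  path <- withr::local_tempdir()
  write_leadfield(lf, file.path(path, "lf"))
  lf2 <- read_leadfield(file.path(path, "lf"))
  expect_equal(lf2$gain, lf$gain, tolerance = 1e-15)
  expect_equal(lf2$electrode_labels, lf$electrode_labels)
  expect_equal(lf2$conductivities, lf$conductivities)
  expect_equal(lf2$reference, "average")
})

test_that("electrode TSV files round-trip with projection on read", {
  sh <- default_head()$shells
  el <- generate_electrodes(10, seed = 9, radius = sh)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_electrodes_tsv(el, path)
  el2 <- read_electrodes_tsv(path, radius = sh)
  expect_equal(el2$labels, el$labels)
  expect_equal(el2$positions, el$positions, tolerance = 1e-9)
  expect_true(all(abs(sqrt(rowSums(el2$positions^2)) - scalp_radius(sh)) < 1e-9))
})
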