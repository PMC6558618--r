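test_that("the default prior carries the study's conductivity intervals", {
  p <- default_prior()
  expect_equal(p$lower[p$tissue == "skull"], 1.6e-3)
  expect_equal(p$upper[p$tissue == "skull"], 33.0e-3)
  expect_equal(p$standard[p$tissue == "csf"], 1.790)
  expect_equal(p$standard[p$tissue == "skin"], 0.430)
  expect_error(conductivity_prior("a", 2, 1, 1.5), "exceeds")
  expect_error(conductivity_prior("a", 1, 2, 3), "outside")
})

test_that("conductivity rescaling is the affine Legendre-domain map", {
  p <- default_prior()
  expect_equal(rescale_conductivity(c(skull = 1.6e-3), p, "skull")[["skull"]], -1)
  expect_equal(rescale_conductivity(c(skull = 33e-3), p, "skull")[["skull"]], 1)
  expect_equal(rescale_conductivity(c(skull = 17.3e-3), p, "skull")[["skull"]],
               0, tolerance = 1e-12)
  expect_equal(rescale_conductivity(c(skull = 10e-3), p, "skull")[["skull"]],
               (10 - 17.3) / 15.7, tolerance = 1e-12)
  # round trip to 1e-14 on random interior points
  set.seed(4)
  sig <- sample_prior(p, 50, seed = 9)
  xi <- rescale_conductivity(sig, p)
  back <- unrescale_conductivity(xi, p)
  expect_lt(max(abs(back - sig[, p$tissue]) / (p$upper - p$lower)[col(back)]),
            1e-14)
  expect_error(rescale_conductivity(c(skull = 0.05), p, "skull"), "bounds")
  degenerate <- conductivity_prior("x", 1, 1, 1)
  expect_error(rescale_conductivity(c(x = 1), degenerate, "x"), "degenerate")
})

test_that("prior sampling is uniform, bounded and seed-deterministic", {
  p <- default_prior()
  s1 <- sample_prior(p, 500, seed = 42, uncertain = "skull")
  s2 <- sample_prior(p, 500, seed = 42, uncertain = "skull")
  expect_identical(s1, s2)
  expect_true(all(s1[, "skull"] >= 1.6e-3 & s1[, "skull"] <= 33e-3))
  # untouched tissues pinned at the standard value
  expect_true(all(s1[, "gm"] == 0.330))
  # sample mean within 3 standard errors of the interval midpoint
  mid <- (1.6e-3 + 33e-3) / 2
  se <- (33e-3 - 1.6e-3) / sqrt(12 * 500)
  expect_lt(abs(mean(s1[, "skull"]) - mid), 3 * se)
  s3 <- sample_prior(p, 5, seed = 43, uncertain = "skull")
  expect_false(all(s3[, "skull"] == s1[1:5, "skull"]))
})

test_that("multi-index sets have the closed-form count with alpha = 0 first", {
  for (d in 1:4) for (p in 0:4) {
    idx <- multi_index_set(d, p)
    expect_equal(nrow(idx), choose(d + p, p))
    expect_equal(idx[1, ], rep(0L, d))
    expect_true(all(rowSums(idx) <= p))
    expect_equal(anyDuplicated(idx), 0L)
  }
})

test_that("1-D sparse grid is the Gauss-Legendre rule, exact to degree 9", {
  sg <- sparse_grid_nodes(1, 4)
  expect_equal(sg$n_nodes, 5L)
  expect_equal(sum(sg$weights), 1, tolerance = 1e-14)
  for (k in 0:9) {
    est <- sum(sg$weights * sg$nodes[, 1]^k)
    exact <- if (k %% 2 == 0) 1 / (k + 1) else 0
    expect_equal(est, exact, tolerance = 1e-13)
  }
  # degree 10 is the first the 5-point rule cannot integrate
  expect_gt(abs(sum(sg$weights * sg$nodes[, 1]^10) - 1 / 11), 1e-4)
})

test_that("2-D Smolyak grid equals a brute-force union of tensor rules", {
  sg <- sparse_grid_nodes(2, 4)
  # independent enumeration: same combination formula built from scratch
  gl <- function(m) {
    if (m == 1) return(list(x = 0, w = 1))
    g <- pracma::gaussLegendre(m, -1, 1)
    list(x = g$x, w = g$w / 2)
  }
  L <- 6
  nodes <- NULL; wts <- NULL
  for (l1 in 1:L) for (l2 in 1:L) {
    s <- l1 + l2
    if (s < L - 1 || s > L) next
    coef <- (-1)^(L - s) * choose(1, L - s)
    r1 <- gl(l1); r2 <- gl(l2)
    g <- expand.grid(x1 = r1$x, x2 = r2$x)
    w <- apply(expand.grid(w1 = r1$w, w2 = r2$w), 1, prod)
    nodes <- rbind(nodes, as.matrix(g)); wts <- c(wts, coef * w)
  }
  key <- apply(round(nodes, 12), 1, paste, collapse = ",")
  ref_nodes <- nodes[!duplicated(key), ]
  expect_equal(sg$n_nodes, nrow(ref_nodes))
  key_pkg <- apply(round(sg$nodes, 12), 1, paste, collapse = ",")
  expect_setequal(key_pkg, unique(key))
  # integration agreement with the brute-force weights on random smooth f
  f <- function(x) exp(0.3 * x[, 1]) * cos(x[, 2])
  expect_equal(sum(sg$weights * f(sg$nodes)),
               sum(tapply(wts, key, sum)[key[!duplicated(key)]] *
                     f(ref_nodes)),
               tolerance = 1e-12)
  expect_equal(sum(sg$weights), 1, tolerance = 1e-12)
})

test_that("sparse grids integrate all total-degree <= 2p+1 monomials in d = 4", {
  sg <- sparse_grid_nodes(4, 4)
  set.seed(10)
  for (rep in 1:40) {
    td <- sample(0:9, 1)
    k <- tabulate(sample(1:4, td, replace = TRUE), nbins = 4)
    est <- sum(sg$weights * apply(sweep(sg$nodes, 2, k, `^`), 1, prod))
    exact <- prod(ifelse(k %% 2 == 0, 1 / (k + 1), 0))
    expect_equal(est, exact, tolerance = 1e-12)
  }
})

test_that("projection coefficients match analytic Legendre expansions", {
  sg <- sparse_grid_nodes(1, 4)
  # constant
  m0 <- fit_pce(rep(3.5, 5), sg$nodes, sg$weights, 4)
  expect_equal(m0$coefficients[1, 1], 3.5, tolerance = 1e-13)
  expect_lt(max(abs(m0$coefficients[-1, 1])), 1e-12)
  # f(xi) = xi^2 = 1/3 + (2/3) P_2 -> orthonormal coefficient 2/(3 sqrt(5))
  m2 <- fit_pce(sg$nodes[, 1]^2, sg$nodes, sg$weights, 4)
  expect_equal(m2$coefficients[1, 1], 1 / 3, tolerance = 1e-13)
  expect_equal(m2$coefficients[3, 1], 2 / (3 * sqrt(5)), tolerance = 1e-13)
  expect_lt(max(abs(m2$coefficients[c(2, 4, 5), 1])), 1e-13)
})

test_that("degree <= 4 polynomials are reproduced exactly by both fit methods", {
  set.seed(6)
  for (d in c(2L, 4L)) {
    idx <- multi_index_set(d, 4L)
    coef_true <- stats::rnorm(nrow(idx))
    truth <- function(x) {
      drop(eeguq:::.basis_matrix(x, idx) %*% coef_true)
    }
    sg <- sparse_grid_nodes(d, 4)
    for (method in c("projection", "regression")) {
      model <- fit_pce(truth(sg$nodes), sg$nodes, sg$weights, 4,
                       method = method)
      x_test <- matrix(stats::runif(1000 * d, -1, 1), ncol = d)
      expect_lt(max(abs(evaluate_pce(model, x_test) - truth(x_test))), 1e-10)
    }
  }
})

test_that("surrogate evaluation honours bounds and the degenerate constant model", {
  p <- default_prior()
  sg <- sparse_grid_nodes(1, 0)
  m <- fit_pce(2.25, sg$nodes, sg$weights, 0, tissues = "skull")
  expect_equal(evaluate_pce(m, c(skull = 10e-3), prior = p), 2.25)
  m4 <- fit_pce(sparse_grid_nodes(1, 4)$nodes[, 1],
                sparse_grid_nodes(1, 4)$nodes,
                sparse_grid_nodes(1, 4)$weights, 4, tissues = "skull")
  expect_error(evaluate_pce(m4, matrix(1.5, 1, 1)), "extrapolate")
  expect_error(evaluate_pce(m4, c(skull = 50e-3), prior = p), "bounds")
  expect_error(fit_pce(c(1, NaN, 1, 1, 1), sparse_grid_nodes(1, 4)$nodes,
                       sparse_grid_nodes(1, 4)$weights, 4),
               "non-finite")
})

test_that("Sobol indices recover analytic variance decompositions", {
  sg <- sparse_grid_nodes(2, 4)
  # f = xi1: everything on subset {1}
  m1 <- fit_pce(sg$nodes[, 1], sg$nodes, sg$weights, 4)
  st1 <- sobol_indices(m1, max_order = 2)
  expect_equal(st1$S[st1$subsets == "1", 1], 1, tolerance = 1e-12)
  expect_equal(st1$S[st1$subsets == "2", 1], 0, tolerance = 1e-12)
  expect_equal(st1$S[st1$subsets == "1:2", 1], 0, tolerance = 1e-12)
  # f = xi1 + xi2 + xi1 xi2: S1 = S2 = 3/7, S12 = 1/7
  f <- sg$nodes[, 1] + sg$nodes[, 2] + sg$nodes[, 1] * sg$nodes[, 2]
  st <- sobol_indices(fit_pce(f, sg$nodes, sg$weights, 4), max_order = 2)
  expect_equal(st$S[st$subsets == "1", 1], 3 / 7, tolerance = 1e-10)
  expect_equal(st$S[st$subsets == "2", 1], 3 / 7, tolerance = 1e-10)
  expect_equal(st$S[st$subsets == "1:2", 1], 1 / 7, tolerance = 1e-10)
  expect_equal(sum(st$S[, 1]), 1, tolerance = 1e-12)
  expect_equal(st$total_variance[1], 7 / 9, tolerance = 1e-12)
  # zero-variance outputs are flagged, not divided
  st0 <- sobol_indices(fit_pce(rep(2, sg$n_nodes), sg$nodes, sg$weights, 4))
  expect_true(st0$zero_variance[1])
  expect_true(all(is.na(st0$S[, 1])))
})

test_that("Parseval: sampled surrogate variance matches the coefficient sum", {
  set.seed(13)
  sg <- sparse_grid_nodes(3, 4)
  idx <- multi_index_set(3L, 4L)
  coef_true <- stats::rnorm(nrow(idx), sd = 0.3)
  model <- fit_pce(drop(eeguq:::.basis_matrix(sg$nodes, idx) %*% coef_true),
                   sg$nodes, sg$weights, 4)
  x <- matrix(stats::runif(3 * 20000, -1, 1), ncol = 3)
  v_mc <- stats::var(evaluate_pce(model, x))
  v_coef <- sum(model$coefficients[-1, 1]^2)
  expect_lt(abs(v_mc - v_coef) / v_coef, 0.05)
})

test_that("coefficient-based Sobol indices agree with a Saltelli Monte Carlo oracle", {
  # analytic, non-additive test function on [-1, 1]^3
  f <- function(x) x[, 1] + 0.5 * x[, 2]^2 + x[, 1] * x[, 3] + 0.2 * x[, 3]^3
  sg <- sparse_grid_nodes(3, 4)
  st <- sobol_indices(fit_pce(f(sg$nodes), sg$nodes, sg$weights, 4),
                      max_order = 3)
  mc <- saltelli_first_order(f, d = 3, n = 2e4, seed = 77)
  for (i in 1:3) {
    s_pce <- st$S[st$subsets == as.character(i), 1]
    expect_lt(abs(s_pce - mc$S[i]), 3 * mc$se[i] + 1e-6)
  }
})

test_that("PCE text container round-trips", {
  sg <- sparse_grid_nodes(2, 2)
  f <- sg$nodes[, 1]^2 + sg$nodes[, 2]
  m <- fit_pce(f, sg$nodes, sg$weights, 2, tissues = c("skin", "skull"),
               bounds = rbind(lower = c(0.28, 0.0016),
                              upper = c(0.87, 0.033)))
  path <- withr::local_tempdir()
  write_pce(m, file.path(path, "pce"))
  m2 <- read_pce(file.path(path, "pce"))
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-15)
  expect_equal(m2$multi_indices, m$multi_indices)
  expect_equal(m2$tissues, m$tissues)
  x <- matrix(stats::runif(10, -1, 1), 5, 2)
  expect_equal(evaluate_pce(m2, x), evaluate_pce(m, x), tolerance = 1e-14)
})
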