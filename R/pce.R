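#' Total-degree multi-index set
#'
#' All multi-indices `alpha` in `N_0^d` with `|alpha|_1 <= p`, ordered by
#' total degree then lexicographically. The count is `choose(d + p, p)` and
#' `alpha = 0` is always the first row.
#'
#' @param d Number of dimensions (>= 1).
#' @param p Maximum total degree (>= 0).
#' @return Integer matrix `n_terms x d`.
#' @export
multi_index_set <- function(d, p) {
  if (d < 1L || p < 0L) stop("require d >= 1 and p >= 0")
  grid <- as.matrix(expand.grid(rep(list(0:p), d)))
  grid <- grid[rowSums(grid) <= p, , drop = FALSE]
  ord <- order(rowSums(grid), apply(grid, 1L, paste, collapse = ","))
  m <- grid[ord, , drop = FALSE]
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# Legendre polynomial values P_0..P_pmax at x (vector), via the three-term
# recursion; returns length(x) x (pmax+1).
.legendre_values <- function(x, pmax) {
  out <- matrix(0, length(x), pmax + 1L)
  out[, 1L] <- 1
  if (pmax >= 1L) out[, 2L] <- x
  if (pmax >= 2L) {
    for (n in 1L:(pmax - 1L)) {
      out[, n + 2L] <- ((2 * n + 1) * x * out[, n + 1L] - n * out[, n]) / (n + 1)
    }
  }
  out
}

# Orthonormal-Legendre tensor basis matrix: rows are points in [-1,1]^d,
# columns the multi-indices. Orthonormal under the uniform probability
# measure on [-1,1]^d: psi_k(x) = sqrt(2k+1) P_k(x).
.basis_matrix <- function(points, indices) {
  points <- as.matrix(points)
  d <- ncol(points)
  pmax <- max(indices)
  uni <- lapply(seq_len(d), function(j) {
    v <- .legendre_values(points[, j], pmax)
    sweep(v, 2L, sqrt(2 * (0:pmax) + 1), "*")
  })
  out <- matrix(1, nrow(points), nrow(indices))
  for (j in seq_len(d)) {
    out <- out * uni[[j]][, indices[, j] + 1L, drop = FALSE]
  }
  out
}

# 1-D Gauss-Legendre rule on [-1, 1] under the uniform probability measure
# (weights sum to 1). Exact for polynomials of degree 2m - 1.
.gauss_rule <- function(m) {
  if (m == 1L) return(list(x = 0, w = 1))
  g <- pracma::gaussLegendre(m, -1, 1)
  list(x = g$x, w = g$w / 2)
}

#' Smolyak sparse-grid collocation nodes
#'
#' Smolyak combination of 1-D Gauss-Legendre rules with linear growth
#' (level-l rule = l-point Gauss-Legendre), at the minimum Smolyak level
#' `L = d + degree` whose sparse rule integrates all polynomials of total
#' degree `2 (L - d) + 1 >= 2 * degree` exactly — sufficient for the
#' pseudo-spectral projection of a degree-`degree` expansion. Weights sum
#' to 1 under the uniform probability measure. Deterministic.
#'
#' In one dimension this reduces to the plain `degree + 1`-point
#' Gauss-Legendre rule.
#'
#' @param d Number of dimensions (>= 1).
#' @param degree Target total polynomial degree `p >= 0` of the expansion.
#' @return List with `nodes` (unique, n x d matrix in `[-1, 1]^d`),
#'   `weights` (combined Smolyak weights, summing to 1), `level` and
#'   `n_nodes`.
#' @export
sparse_grid_nodes <- function(d, degree) {
  if (d < 1L || degree < 0L) stop("require d >= 1 and degree >= 0")
  L <- d + degree
  combos <- as.matrix(expand.grid(rep(list(seq_len(L)), d)))
  s <- rowSums(combos)
  combos <- combos[s >= L - d + 1L & s <= L, , drop = FALSE]
  nodes <- NULL
  wts <- NULL
  for (i in seq_len(nrow(combos))) {
    l <- combos[i, ]
    coef <- (-1)^(L - sum(l)) * choose(d - 1L, L - sum(l))
    rules <- lapply(l, .gauss_rule)
    xg <- as.matrix(expand.grid(lapply(rules, `[[`, "x")))
    wg <- apply(as.matrix(expand.grid(lapply(rules, `[[`, "w"))), 1L, prod)
    nodes <- rbind(nodes, xg)
    wts <- c(wts, coef * wg)
  }
  key <- apply(round(nodes, 12L), 1L, paste, collapse = ",")
  agg <- tapply(wts, key, sum)
  keep <- !duplicated(key)
  ux <- nodes[keep, , drop = FALSE]
  uw <- as.numeric(agg[key[keep]])
  dimnames(ux) <- NULL
  list(nodes = ux, weights = uw, level = L, n_nodes = nrow(ux))
}

#' Fit a polynomial chaos expansion by pseudo-spectral projection
#'
#' Coefficients are computed as `c_alpha = sum_k w_k f(node_k)
#' Psi_alpha(node_k)` with the orthonormal Legendre tensor basis; all
#' outputs are fitted against the shared node set in one pass. Given the
#' quadrature exactness of [sparse_grid_nodes()], any output that is itself
#' a polynomial of total degree `<= degree` is reproduced exactly.
#'
#' @param evaluations Numeric matrix `n_nodes x n_outputs` (a vector is
#'   treated as a single output), row-aligned with `nodes`.
#' @param nodes,weights Collocation nodes in `[-1, 1]^d` and weights, e.g.
#'   from [sparse_grid_nodes()].
#' @param degree Maximum total degree of the expansion.
#' @param bounds Optional 2 x d matrix (rows: lower, upper) of the physical
#'   intervals each dimension was rescaled from.
#' @param tissues Optional dimension (tissue) names.
#' @param output_meta Optional metadata describing how to reshape outputs
#'   (used to rebuild leadfield objects).
#' @param method `"projection"` (the pseudo-spectral quadrature formula
#'   above, the default) or `"regression"`: unweighted least squares of the
#'   same basis on the same nodes. The two coincide for polynomial outputs
#'   of total degree `<= degree`; for outputs with strong higher-degree
#'   content, regression avoids quadrature aliasing of that content into
#'   the retained coefficients.
#' @return An object of class `pce_model` with fields `dims`, `degree`,
#'   `multi_indices`, `coefficients` (`n_terms x n_outputs`), `bounds`,
#'   `tissues`, `basis = "legendre-orthonormal"`, `n_nodes`.
#' @export
fit_pce <- function(evaluations, nodes, weights, degree,
                    bounds = NULL, tissues = NULL, output_meta = NULL,
                    method = c("projection", "regression")) {
  method <- match.arg(method)
  nodes <- as.matrix(nodes)
  ev <- if (is.matrix(evaluations)) evaluations else matrix(evaluations, ncol = 1L)
  if (nrow(ev) != nrow(nodes)) stop("evaluations must be row-aligned with nodes")
  if (any(!is.finite(ev))) {
    stop(sprintf("non-finite evaluation at node id(s): %s",
                 paste(utils::head(which(rowSums(!is.finite(ev)) > 0), 10L),
                       collapse = ", ")))
  }
  d <- ncol(nodes)
  idx <- multi_index_set(d, degree)
  psi <- .basis_matrix(nodes, idx)
  coef <- if (method == "projection") {
    crossprod(psi, weights * ev)         # n_terms x n_outputs
  } else {
    if (nrow(psi) < ncol(psi)) {
      stop("regression fit needs at least as many nodes as basis terms")
    }
    qr.solve(psi, ev)
  }
  structure(
    list(dims = d, degree = as.integer(degree), multi_indices = idx,
         coefficients = coef, bounds = bounds, tissues = tissues,
         basis = "legendre-orthonormal", n_nodes = nrow(nodes),
         fit_method = method, output_meta = output_meta),
    class = "pce_model"
  )
}

#' @export
print.pce_model <- function(x, ...) {
  cat(sprintf("<pce_model> d = %d, degree = %d, %d terms, %d outputs (%d collocation nodes)\n",
              x$dims, x$degree, nrow(x$multi_indices), ncol(x$coefficients),
              x$n_nodes))
  if (!is.null(x$tissues)) cat("  uncertain:", paste(x$tissues, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a polynomial chaos surrogate
#'
#' @param model A [fit_pce()] result.
#' @param xi Evaluation point(s): either rescaled coordinates in
#'   `[-1, 1]^d` (vector or n x d matrix), or — when `prior` is given — a
#'   named conductivity vector/matrix (S/m) which is rescaled first. No
#'   extrapolation: out-of-bounds inputs raise an error.
#' @param prior Optional [conductivity_prior()] used to rescale `sigma`
#'   inputs (the model's `tissues` select the dimensions).
#' @return Numeric vector of outputs (or n x n_outputs matrix for multiple
#'   points).
#' @export
evaluate_pce <- function(model, xi, prior = NULL) {
  if (!is.null(prior)) {
    xi <- rescale_conductivity(xi, prior, tissues = model$tissues)
    if (!is.matrix(xi)) xi <- matrix(xi, 1L)
  }
  x <- if (is.matrix(xi)) xi else matrix(xi, 1L)
  if (ncol(x) != model$dims) stop("evaluation point has wrong dimension")
  if (any(x < -1 - 1e-12) || any(x > 1 + 1e-12)) {
    stop("evaluation point outside [-1, 1]^d; surrogate does not extrapolate")
  }
  psi <- .basis_matrix(x, model$multi_indices)
  out <- psi %*% model$coefficients
  if (nrow(out) == 1L) as.numeric(out) else out
}

#' Reconstruct a leadfield from a surrogate evaluation
#'
#' Reshapes the flattened output of a leadfield-valued surrogate back into
#' a [compute_leadfield()]-style object.
#'
#' @param model A leadfield-valued [fit_pce()] model (with `output_meta`).
#' @param sigma Named conductivity vector (S/m).
#' @param prior The [conductivity_prior()] the model was built from.
#' @return A `leadfield` object.
#' @export
evaluate_pce_leadfield <- function(model, sigma, prior) {
  meta <- model$output_meta
  if (is.null(meta)) stop("model has no leadfield output metadata")
  vals <- evaluate_pce(model, sigma, prior = prior)
  gain <- matrix(vals, nrow = length(meta$electrode_labels))
  structure(
    list(gain = gain, source_positions = meta$source_positions,
         electrode_labels = meta$electrode_labels,
         conductivities = sigma, reference = meta$reference),
    class = "leadfield"
  )
}

#' Sobol sensitivity indices from polynomial chaos coefficients
#'
#' With an orthonormal basis, the output variance is the sum of squared
#' non-constant coefficients, and the conditional variance attributable to
#' a variable subset is the sum over multi-indices supported exactly on
#' that subset: `S(i,...,j) = V(i,...,j) / V`. Indices of all orders up to
#' `max_order` are reported; outputs with zero variance are flagged and
#' excluded from the ratios rather than divided.
#'
#' @param model A [fit_pce()] result.
#' @param max_order Highest interaction order to report (default 2; at
#'   most `model$dims`).
#' @return An object of class `sobol_table`: list with
#'   `total_variance` (per output), `subsets` (character, e.g. `"1"` or
#'   `"1:3"`, or tissue names when available), `S` (n_subsets x n_outputs
#'   matrix of indices, `NA` for zero-variance outputs), `order` (per
#'   subset) and `zero_variance` (logical per output).
#' @export
sobol_indices <- function(model, max_order = 2L) {
  d <- model$dims
  max_order <- min(max_order, d)
  idx <- model$multi_indices
  coef <- model$coefficients
  nz <- rowSums(idx) > 0L
  var_total <- colSums(coef[nz, , drop = FALSE]^2)
  # zero variance up to roundoff of the projection/regression arithmetic
  zero <- var_total <= 1e-24 * colSums(coef^2)
  support <- (idx > 0L)
  ord <- rowSums(support)
  subsets <- list()
  orders <- integer(0)
  for (o in seq_len(max_order)) {
    cmb <- utils::combn(d, o)
    for (c_i in seq_len(ncol(cmb))) {
      subsets[[length(subsets) + 1L]] <- cmb[, c_i]
      orders <- c(orders, o)
    }
  }
  S <- matrix(NA_real_, length(subsets), ncol(coef))
  Vcond <- matrix(0, length(subsets), ncol(coef))
  for (i in seq_along(subsets)) {
    sset <- subsets[[i]]
    in_sub <- rep(FALSE, d)
    in_sub[sset] <- TRUE
    match_rows <- apply(support, 1L, function(s) all(s == in_sub))
    Vcond[i, ] <- colSums(coef[match_rows, , drop = FALSE]^2)
    S[i, !zero] <- Vcond[i, !zero] / var_total[!zero]
  }
  labels <- vapply(subsets, function(s) {
    if (!is.null(model$tissues)) paste(model$tissues[s], collapse = ":")
    else paste(s, collapse = ":")
  }, character(1))
  structure(
    list(total_variance = var_total, subsets = labels, subset_dims = subsets,
         S = S, conditional_variance = Vcond, order = orders,
         zero_variance = zero, max_order = max_order),
    class = "sobol_table"
  )
}

#' @export
print.sobol_table <- function(x, ...) {
  cat(sprintf("<sobol_table> %d subsets (orders 1..%d), %d outputs, %d zero-variance\n",
              length(x$subsets), x$max_order, length(x$total_variance),
              sum(x$zero_variance)))
  invisible(x)
}
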