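#' Uniform conductivity prior
#'
#' Per-tissue uniform bounds and standard (literature) values. The default
#' prior uses the study intervals, in mS/m: skin [280, 870] (standard 430),
#' skull [1.6, 33.0] (10.0), CSF [1769.6, 1810.4] (1790.0), gray matter
#' [220, 670] (330), white matter [90, 290] (140). Values are stored in S/m.
#'
#' @param tissues Character vector of tissue names.
#' @param lower,upper,standard Numeric vectors (S/m) with
#'   `lower <= standard <= upper` (equality allowed for degenerate test
#'   priors).
#' @return An object of class `conductivity_prior`: a data frame with
#'   columns `tissue`, `lower`, `upper`, `standard`.
#' @examples
#' default_prior()
#' @export
conductivity_prior <- function(tissues, lower, upper, standard) {
  tissues <- as.character(tissues)
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  standard <- as.numeric(standard)
  n <- length(tissues)
  if (length(lower) != n || length(upper) != n || length(standard) != n) {
    stop("tissues, lower, upper and standard must have equal length")
  }
  if (anyDuplicated(tissues)) stop("tissue names must be unique")
  if (any(lower > upper)) stop("lower bound exceeds upper bound")
  if (any(standard < lower | standard > upper)) {
    stop("standard value outside [lower, upper]")
  }
  structure(data.frame(tissue = tissues, lower = lower, upper = upper,
                       standard = standard, stringsAsFactors = FALSE),
            class = c("conductivity_prior", "data.frame"))
}

#' @rdname conductivity_prior
#' @export
default_prior <- function() {
  conductivity_prior(
    tissues = c("wm", "gm", "csf", "skull", "skin"),
    lower = c(90, 220, 1769.6, 1.6, 280) / 1000,
    upper = c(290, 670, 1810.4, 33.0, 870) / 1000,
    standard = c(140, 330, 1790.0, 10.0, 430) / 1000
  )
}

.prior_row <- function(prior, tissue) {
  i <- match(tissue, prior$tissue)
  if (any(is.na(i))) {
    stop(sprintf("tissue(s) not in prior: %s",
                 paste(tissue[is.na(i)], collapse = ", ")))
  }
  i
}

#' Standard conductivity set of a prior
#'
#' @param prior A [conductivity_prior()].
#' @return Named numeric vector of standard conductivities (S/m).
#' @export
standard_conductivities <- function(prior) {
  stats::setNames(prior$standard, prior$tissue)
}

#' Map conductivities to the Legendre domain and back
#'
#' Affine map of each uncertain conductivity from its uniform interval
#' `[lower, upper]` to `[-1, 1]` (and inverse). Degenerate intervals
#' (`lower == upper`) cannot be rescaled and raise an error.
#'
#' @param sigma Named numeric vector of conductivities (S/m) or a matrix
#'   with named columns; must contain the `tissues` and lie within bounds.
#' @param prior A [conductivity_prior()].
#' @param tissues Tissues (order defines the dimensions of the result);
#'   default: all tissues in the prior.
#' @return Numeric vector (or matrix) of rescaled coordinates in
#'   `[-1, 1]^d`.
#' @examples
#' p <- default_prior()
#' rescale_conductivity(c(skull = 0.010), p, "skull")  # (10 - 17.3)/15.7
#' @export
rescale_conductivity <- function(sigma, prior, tissues = prior$tissue) {
  i <- .prior_row(prior, tissues)
  lo <- prior$lower[i]
  hi <- prior$upper[i]
  if (any(hi - lo <= 0)) {
    stop(sprintf("degenerate prior interval for tissue(s): %s",
                 paste(tissues[hi - lo <= 0], collapse = ", ")))
  }
  sig <- if (is.matrix(sigma)) sigma[, tissues, drop = FALSE] else {
    matrix(sigma[tissues], 1L, dimnames = list(NULL, tissues))
  }
  for (k in seq_along(tissues)) {
    bad <- sig[, k] < lo[k] - 1e-12 * (hi[k] - lo[k]) |
      sig[, k] > hi[k] + 1e-12 * (hi[k] - lo[k])
    if (any(bad)) {
      stop(sprintf("conductivity for '%s' outside prior bounds [%g, %g] S/m",
                   tissues[k], lo[k], hi[k]))
    }
  }
  xi <- sweep(sweep(sig, 2L, (lo + hi) / 2), 2L, (hi - lo) / 2, "/")
  xi <- pmin(pmax(xi, -1), 1)  # argument order preserves the matrix shape
  if (is.matrix(sigma)) xi else stats::setNames(as.numeric(xi), tissues)
}

#' @rdname rescale_conductivity
#' @param xi Rescaled coordinates in `[-1, 1]^d` (vector or matrix with one
#'   column per tissue).
#' @export
unrescale_conductivity <- function(xi, prior, tissues = prior$tissue) {
  i <- .prior_row(prior, tissues)
  lo <- prior$lower[i]
  hi <- prior$upper[i]
  x <- if (is.matrix(xi)) xi else matrix(xi, 1L)
  if (ncol(x) != length(tissues)) stop("xi has wrong dimension")
  sig <- sweep(sweep(x, 2L, (hi - lo) / 2, "*"), 2L, (lo + hi) / 2, "+")
  colnames(sig) <- tissues
  if (is.matrix(xi)) sig else stats::setNames(as.numeric(sig), tissues)
}

#' Draw conductivity sets from the prior
#'
#' Draws `n` i.i.d. sets: each uncertain tissue uniform on its interval,
#' all other tissues fixed at their standard value. Identical seeds give
#' identical samples.
#'
#' @param prior A [conductivity_prior()].
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param uncertain Tissues drawn from their priors (default: all).
#' @return An n x n_tissue matrix (S/m) with tissue column names.
#' @export
sample_prior <- function(prior, n, seed, uncertain = prior$tissue) {
  if (n < 1L) stop("n must be at least 1")
  .prior_row(prior, uncertain)
  out <- matrix(rep(prior$standard, each = n), n, nrow(prior),
                dimnames = list(NULL, prior$tissue))
  rs <- .with_seed(seed, {
    vapply(uncertain, function(t) {
      i <- match(t, prior$tissue)
      stats::runif(n, prior$lower[i], prior$upper[i])
    }, numeric(n))
  })
  out[, uncertain] <- rs
  out
}

# Evaluate an expression with a local RNG state seeded by `seed`,
# restoring the caller's state afterwards.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
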