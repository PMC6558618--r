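#' Relative difference measure (topography error)
#'
#' `rdm(u1, u2) = || u1/||u1|| - u2/||u2|| ||_2`: the Euclidean distance
#' between the unit-normalised topographies. Ranges from 0 (identical
#' topography up to positive scaling) to 2 (opposite topography);
#' symmetric and scale-invariant.
#'
#' @param u1,u2 Nonzero numeric vectors of equal length.
#' @return Scalar in `[0, 2]`.
#' @examples
#' rdm(c(1, 2, 3), c(2, 4, 6))  # 0
#' @export
rdm <- function(u1, u2) {
  n1 <- sqrt(sum(u1^2))
  n2 <- sqrt(sum(u2^2))
  if (n1 == 0 || n2 == 0) stop("RDM is undefined for a zero vector")
  if (length(u1) != length(u2)) stop("vectors must have equal length")
  min(2, sqrt(sum((u1 / n1 - u2 / n2)^2)))
}

#' Logarithmic magnitude error
#'
#' `lnmag(u1, u2) = ln(||u1|| / ||u2||)`: 0 for equal magnitude,
#' antisymmetric under swapping, additive under chained comparisons.
#'
#' @param u1,u2 Nonzero numeric vectors.
#' @return Scalar in `(-Inf, Inf)`.
#' @export
lnmag <- function(u1, u2) {
  n1 <- sqrt(sum(u1^2))
  n2 <- sqrt(sum(u2^2))
  if (n1 == 0 || n2 == 0) stop("lnMAG is undefined for a zero vector")
  log(n1 / n2)
}

#' Per-electrode standard deviation over potential samples
#'
#' @param samples Numeric matrix, one sample topography per row.
#' @return Numeric vector of unbiased (n - 1) standard deviations, one per
#'   electrode; order-invariant in the samples.
#' @export
electrodewise_std <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L) stop("at least 2 samples are required")
  apply(samples, 2L, stats::sd)
}

#' Validate a leadfield surrogate against the exact forward model
#'
#' Draws `n_test` conductivity sets from the prior, computes the exact and
#' surrogate leadfields for each, and compares them per source topography:
#' for every source position and unit-moment direction, the RDM and lnMAG
#' between the surrogate and exact columns.
#'
#' @param model A leadfield-valued [fit_pce()] model (with `output_meta`).
#' @param prior The [conductivity_prior()] the model was built over.
#' @param shells_template A [shell_model()] giving geometry and tissue
#'   order; per-draw conductivities are substituted into it.
#' @param electrodes The [electrode_array()] the model was built with.
#' @param n_test Number of test draws (default 10).
#' @param seed Integer seed for the draws.
#' @return List with `summary` (max/mean RDM, max/mean `|lnMAG|`) and
#'   `table` (data frame `draw, source_index, direction, rdm, lnmag`).
#' @export
validate_surrogate <- function(model, prior, shells_template, electrodes,
                               n_test = 10L, seed = 1L) {
  meta <- model$output_meta
  if (is.null(meta)) stop("model has no leadfield output metadata")
  if (!identical(meta$electrode_labels, electrodes$labels)) {
    stop("electrode geometry mismatch between model and electrodes")
  }
  sig_draws <- sample_prior(prior, n_test, seed, uncertain = model$tissues)
  rows <- vector("list", n_test)
  for (t in seq_len(n_test)) {
    sig <- sig_draws[t, ]
    sh <- shell_model(shells_template$radii,
                      sig[shells_template$tissue_labels],
                      shells_template$tissue_labels)
    exact <- compute_leadfield(meta$source_positions, electrodes, sh)
    surr <- evaluate_pce_leadfield(model, sig, prior)
    K <- nrow(meta$source_positions)
    df <- expand.grid(direction = 1:3, source_index = seq_len(K))
    df$draw <- t
    df$rdm <- NA_real_
    df$lnmag <- NA_real_
    for (i in seq_len(nrow(df))) {
      col <- 3L * (df$source_index[i] - 1L) + df$direction[i]
      df$rdm[i] <- rdm(surr$gain[, col], exact$gain[, col])
      df$lnmag[i] <- lnmag(surr$gain[, col], exact$gain[, col])
    }
    rows[[t]] <- df[, c("draw", "source_index", "direction", "rdm", "lnmag")]
  }
  tab <- do.call(rbind, rows)
  list(summary = c(max_rdm = max(tab$rdm), mean_rdm = mean(tab$rdm),
                   max_abs_lnmag = max(abs(tab$lnmag)),
                   mean_abs_lnmag = mean(abs(tab$lnmag))),
       table = tab)
}
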