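#' Goodness of fit of a single dipole gain block
#'
#' For a referenced measurement `u` and an n x k gain block `L` (k = 1 for a
#' fixed-orientation source, k = 3 for a free-orientation source), the
#' goodness of fit is
#' \deqn{GoF = 1 - (||u - L L^+ u||_2 / ||u||_2)^2,}
#' the fraction of measurement power explained by the orthogonal projection
#' onto the column space of `L`. The Moore-Penrose pseudoinverse is computed
#' by singular-value decomposition with a relative cutoff of
#' `1e-10 * sigma_max`, so rank-deficient (near-silent) blocks are handled
#' gracefully.
#'
#' @param u_meas Referenced potential vector (nonzero).
#' @param L n x k gain block sharing channel count and reference with
#'   `u_meas`.
#' @return List with `gof` (in `[0, 1]`) and `moment` (`L^+ u`, the fitted
#'   moment for k = 3 or signed amplitude for k = 1).
#' @examples
#' goodness_of_fit(c(1, 1, 0), matrix(c(1, 0, 0), 3, 1))  # gof 0.5
#' @export
goodness_of_fit <- function(u_meas, L) {
  L <- as.matrix(L)
  u_meas <- as.numeric(u_meas)
  if (length(u_meas) != nrow(L)) stop("channel count mismatch between u_meas and L")
  nu2 <- sum(u_meas^2)
  if (nu2 == 0) stop("GoF is undefined for a zero measurement")
  sv <- svd(L)
  keep <- sv$d > 1e-10 * max(sv$d, 0)
  if (!any(keep)) {
    return(list(gof = 0, moment = rep(0, ncol(L))))
  }
  Ut_u <- crossprod(sv$u[, keep, drop = FALSE], u_meas)
  moment <- sv$v[, keep, drop = FALSE] %*% (Ut_u / sv$d[keep])
  proj <- sv$u[, keep, drop = FALSE] %*% Ut_u
  gof <- 1 - sum((u_meas - proj)^2) / nu2
  list(gof = max(0, min(1, gof)), moment = as.numeric(moment))
}

#' Moving goal-function scan (free position, orientation and strength)
#'
#' Evaluates the goodness of fit at every retained source position and
#' returns the position with the overall maximum. Ties (GoF within 1e-12 of
#' the maximum) are broken by the lowest index, with a warning.
#'
#' @param u_meas Referenced potential vector.
#' @param leadfield A [leadfield()] sharing the measurement's reference.
#' @param shells Optional [shell_model()]; when given, the source depth
#'   below the inner skull is reported.
#' @param frame Optional [build_orientation_frame()] result; when given,
#'   the fitted moment's azimuth/elevation angles are reported.
#' @return An object of class `scan_result`: list with `best_index`,
#'   `position`, `moment`, `strength`, `gof`, `gof_per_position`, and (when
#'   available) `depth`, `phi`, `theta`.
#' @export
scan_moving <- function(u_meas, leadfield, shells = NULL, frame = NULL) {
  K <- nrow(leadfield$source_positions)
  if (K == 0L) stop("cannot scan an empty source space")
  gofs <- numeric(K)
  moments <- matrix(0, K, 3L)
  for (k in seq_len(K)) {
    fit <- goodness_of_fit(u_meas, .gain_block(leadfield, k))
    gofs[k] <- fit$gof
    moments[k, ] <- fit$moment
  }
  top <- max(gofs)
  tied <- which(gofs > top - 1e-12)
  if (length(tied) > 1L) {
    warning(sprintf("GoF tie among %d positions (delta < 1e-12); returning lowest index %d",
                    length(tied), tied[1L]))
  }
  best <- tied[1L]
  moment <- moments[best, ]
  strength <- sqrt(sum(moment^2))
  res <- list(best_index = best,
              position = as.numeric(leadfield$source_positions[best, ]),
              moment = moment,
              strength = strength,
              gof = gofs[best],
              gof_per_position = gofs)
  if (!is.null(shells)) res$depth <- source_depth(res$position, shells)
  if (!is.null(frame) && strength > 0) {
    ang <- orientation_angles(moment, frame)
    res$phi <- ang[["phi"]]
    res$theta <- ang[["theta"]]
  }
  structure(res, class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> best index %d, GoF %.6f, strength %.3g A m\n",
              x$best_index, x$gof, x$strength))
  if (!is.null(x$depth)) cat(sprintf("  depth %.2f mm\n", 1000 * x$depth))
  invisible(x)
}

#' Rotating goal-function scan (fixed position, free orientation)
#'
#' @param u_meas Referenced potential vector.
#' @param L3 n x 3 gain block at the fixed position.
#' @param frame Optional orientation frame for angle reporting.
#' @return List with `moment`, `strength`, `gof` and, when a frame is given,
#'   `phi` and `theta` (degrees).
#' @export
scan_rotating <- function(u_meas, L3, frame = NULL) {
  L3 <- as.matrix(L3)
  if (ncol(L3) != 3L) stop("L3 must have exactly 3 columns")
  fit <- goodness_of_fit(u_meas, L3)
  res <- list(moment = fit$moment,
              strength = sqrt(sum(fit$moment^2)),
              gof = fit$gof)
  if (!is.null(frame) && res$strength > 0) {
    ang <- orientation_angles(fit$moment, frame)
    res$phi <- ang[["phi"]]
    res$theta <- ang[["theta"]]
  }
  res
}

#' Fixed goal-function scan (fixed position and orientation, free strength)
#'
#' @param u_meas Referenced potential vector.
#' @param l n x 1 gain column for the fixed position and orientation.
#' @return List with `strength` (signed least-squares amplitude),
#'   `magnitude` (`|strength|`) and `gof`.
#' @export
scan_fixed <- function(u_meas, l) {
  l <- as.matrix(l)
  if (ncol(l) != 1L) stop("l must be a single gain column")
  fit <- goodness_of_fit(u_meas, l)
  list(strength = fit$moment[1L], magnitude = abs(fit$moment[1L]),
       gof = fit$gof)
}

#' Orientation frame at a source position
#'
#' Orthonormal triad built by Gram-Schmidt from, in order: the reference
#' source orientation (`e1`), the radial direction from the source toward
#' the inner skull (`e2`, outward `+position/||position||` in the sphere
#' model), and a configured direction toward the interhemispheric fissure
#' (`e3`, default `+y`).
#'
#' @param reference_orientation Length-3 vector, not parallel to the radial
#'   direction at `position`.
#' @param position Length-3 source position (m), nonzero.
#' @param fissure_direction Length-3 vector, linearly independent of the
#'   first two.
#' @return An object of class `orientation_frame` with unit fields `e1`,
#'   `e2`, `e3`.
#' @export
build_orientation_frame <- function(reference_orientation, position,
                                    fissure_direction = c(0, 1, 0)) {
  v1 <- as.numeric(reference_orientation)
  r <- sqrt(sum(position^2))
  if (r == 0) stop("orientation frame undefined at the origin")
  v2 <- as.numeric(position) / r
  v3 <- as.numeric(fissure_direction)
  n1 <- sqrt(sum(v1^2))
  if (n1 == 0) stop("reference orientation must be nonzero")
  e1 <- v1 / n1
  w2 <- v2 - sum(v2 * e1) * e1
  n2 <- sqrt(sum(w2^2))
  if (n2 < 1e-10) stop("degenerate frame: reference orientation is parallel to the radial direction")
  e2 <- w2 / n2
  w3 <- v3 - sum(v3 * e1) * e1 - sum(v3 * e2) * e2
  n3 <- sqrt(sum(w3^2))
  if (n3 < 1e-10) stop("degenerate frame: fissure direction is coplanar with the first two axes")
  e3 <- w3 / n3
  structure(list(e1 = e1, e2 = e2, e3 = e3), class = "orientation_frame")
}

#' Azimuth and elevation of a moment in an orientation frame
#'
#' Elevation `theta = asin(m_hat . e2)` grows as the source turns more
#' radial; azimuth `phi = atan2(m_hat . e3, m_hat . e1)` is positive for a
#' tangential rotation toward the fissure direction.
#'
#' @param moment Nonzero length-3 vector.
#' @param frame An [build_orientation_frame()] result.
#' @return Named numeric vector `c(phi = , theta = )` in degrees, with
#'   `-180 < phi <= 180` and `-90 <= theta <= 90`.
#' @export
orientation_angles <- function(moment, frame) {
  m <- as.numeric(moment)
  nm <- sqrt(sum(m^2))
  if (nm == 0) stop("orientation angles are undefined for a zero moment")
  mh <- m / nm
  s2 <- max(-1, min(1, sum(mh * frame$e2)))
  theta <- asin(s2) * 180 / pi
  phi <- atan2(sum(mh * frame$e3), sum(mh * frame$e1)) * 180 / pi
  if (phi <= -180) phi <- phi + 360
  c(phi = phi, theta = theta)
}

#' Source depth below the inner skull surface
#'
#' @param position Length-3 source position (m), strictly inside the inner
#'   skull.
#' @param shells A [shell_model()] with a `csf` shell.
#' @return Depth in metres, `r_inner_skull - ||position||`.
#' @examples
#' head <- default_head()
#' source_depth(c(0, 0, 0.072), head$shells)  # 8 mm
#' @export
source_depth <- function(position, shells) {
  r <- sqrt(sum(position^2))
  r_is <- inner_skull_radius(shells)
  if (r > r_is) {
    stop(sprintf("position at radius %.2f mm lies outside the inner skull (%.2f mm)",
                 1000 * r, 1000 * r_is))
  }
  r_is - r
}
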