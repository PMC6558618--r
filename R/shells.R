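#' Concentric-shell volume conductor model
#'
#' A `shell_model` describes a head as nested concentric spherical shells,
#' each with a homogeneous isotropic conductivity. It is the desk-scale
#' volume conductor used throughout the package: shell boundaries are given
#' by their outer radii (strictly increasing, outermost = scalp surface) and
#' conductivities are listed innermost to outermost.
#'
#' All quantities are SI internally: radii in metres, conductivities in S/m.
#' Millimetres and mS/m appear only at file and configuration boundaries.
#'
#' @param radii Numeric vector of shell outer radii in metres, strictly
#'   increasing and positive.
#' @param conductivities Numeric vector of shell conductivities in S/m,
#'   ordered innermost to outermost, strictly positive.
#' @param tissue_labels Character vector of unique tissue labels per shell.
#' @return An object of class `shell_model` with fields `radii`,
#'   `conductivities` and `tissue_labels`.
#' @examples
#' head <- default_head()
#' head$shells
#' @export
shell_model <- function(radii, conductivities,
                        tissue_labels = c("wm", "gm", "csf", "skull", "skin")) {
  radii <- as.numeric(radii)
  conductivities <- as.numeric(conductivities)
  tissue_labels <- as.character(tissue_labels)
  if (length(radii) < 1L) stop("at least one shell is required")
  if (length(radii) != length(conductivities) ||
      length(radii) != length(tissue_labels)) {
    stop("radii, conductivities and tissue_labels must have equal length")
  }
  if (any(!is.finite(radii)) || any(radii <= 0) ||
      any(diff(radii) <= 0)) {
    stop("radii must be positive, finite and strictly increasing")
  }
  if (any(!is.finite(conductivities)) || any(conductivities <= 0)) {
    stop("conductivities must be positive and finite")
  }
  if (anyDuplicated(tissue_labels)) stop("tissue labels must be unique")
  structure(
    list(radii = radii, conductivities = conductivities,
         tissue_labels = tissue_labels),
    class = "shell_model"
  )
}

#' @export
print.shell_model <- function(x, ...) {
  cat(sprintf("<shell_model> %d shells, scalp radius %.1f mm\n",
              length(x$radii), 1000 * max(x$radii)))
  df <- data.frame(tissue = x$tissue_labels,
                   outer_radius_mm = 1000 * x$radii,
                   conductivity_mS_per_m = 1000 * x$conductivities)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @return Scalp (outermost) radius in metres.
#' @rdname shell_model
#' @export
scalp_radius <- function(shells) max(shells$radii)

#' Outer radius of the brain (gray + white matter) region
#'
#' The brain/CSF boundary radius: the largest outer radius among shells
#' labelled as brain tissue.
#'
#' @param shells A [shell_model()].
#' @param brain_tissues Labels counted as brain (default `c("wm", "gm")`).
#' @return Radius in metres.
#' @export
brain_radius <- function(shells, brain_tissues = c("wm", "gm")) {
  idx <- which(shells$tissue_labels %in% brain_tissues)
  if (length(idx) == 0L) stop("no shell labelled as brain tissue")
  max(shells$radii[idx])
}

#' Inner-skull radius (outer radius of the CSF shell)
#'
#' Source depth is measured from this surface inward.
#'
#' @param shells A [shell_model()].
#' @return Radius in metres.
#' @export
inner_skull_radius <- function(shells) {
  idx <- match("csf", shells$tissue_labels)
  if (is.na(idx)) stop("shell model has no 'csf' shell; inner skull undefined")
  shells$radii[idx]
}

#' Tissue label at a given radius
#'
#' Radial intervals are half-open and inner-closed: a position exactly on a
#' shell boundary belongs to the inner shell, so tissue assignment is
#' deterministic.
#'
#' @param r Numeric vector of radii (m).
#' @param shells A [shell_model()].
#' @return Character vector of tissue labels; `NA` outside the scalp.
#' @export
tissue_at_radius <- function(r, shells) {
  idx <- findInterval(r, shells$radii, left.open = TRUE) + 1L
  out <- rep(NA_character_, length(r))
  ok <- idx <= length(shells$radii) & r >= 0
  out[ok] <- shells$tissue_labels[idx[ok]]
  out
}

#' Electrode array on the scalp sphere
#'
#' Electrode positions are projected radially onto the outermost shell
#' surface; a warning is emitted when the projection displaces a sensor by
#' more than `warn_displacement`.
#'
#' @param positions Numeric n x 3 matrix of sensor positions (m).
#' @param labels Character vector of unique sensor labels (default
#'   `E001, E002, ...`).
#' @param radius Scalp radius (m) to project onto; may also be given as a
#'   [shell_model()].
#' @param warn_displacement Displacement (m) above which a warning is issued
#'   (default 2 mm).
#' @return An object of class `electrode_array` with fields `labels` and
#'   `positions` (rows on the sphere of radius `radius`).
#' @export
electrode_array <- function(positions, labels = NULL, radius,
                            warn_displacement = 2e-3) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an n x 3 matrix")
  n <- nrow(positions)
  if (n < 4L) stop("at least 4 electrodes are required")
  if (inherits(radius, "shell_model")) radius <- scalp_radius(radius)
  if (is.null(labels)) labels <- sprintf("E%03d", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must match the number of positions")
  if (anyDuplicated(labels)) stop("electrode labels must be unique")
  nrm <- sqrt(rowSums(positions^2))
  if (any(nrm == 0)) stop("electrode at the origin cannot be projected")
  proj <- positions * (radius / nrm)
  disp <- abs(nrm - radius)
  if (any(disp > warn_displacement)) {
    warning(sprintf("%d electrode(s) displaced by more than %.1f mm during projection (max %.2f mm)",
                    sum(disp > warn_displacement), 1000 * warn_displacement,
                    1000 * max(disp)))
  }
  dimnames(proj) <- list(labels, c("x", "y", "z"))
  structure(list(labels = labels, positions = proj, radius = radius),
            class = "electrode_array")
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("<electrode_array> %d sensors on sphere of radius %.1f mm\n",
              length(x$labels), 1000 * x$radius))
  invisible(x)
}

#' Current dipole source
#'
#' @param position Length-3 numeric, source position (m).
#' @param moment Length-3 numeric, dipole moment (A m).
#' @return An object of class `dipole` with accessors `strength` (A m,
#'   `= ||moment||`) and `orientation` (unit vector, `NA` for a silent
#'   dipole).
#' @export
dipole <- function(position, moment) {
  position <- as.numeric(position)
  moment <- as.numeric(moment)
  if (length(position) != 3L || length(moment) != 3L) {
    stop("position and moment must be length-3 numeric vectors")
  }
  if (any(!is.finite(position)) || any(!is.finite(moment))) {
    stop("position and moment must be finite")
  }
  strength <- sqrt(sum(moment^2))
  orientation <- if (strength > 0) moment / strength else rep(NA_real_, 3L)
  structure(list(position = position, moment = moment,
                 strength = strength, orientation = orientation),
            class = "dipole")
}

#' Check that a dipole position lies in the allowed source region
#'
#' Sources must lie strictly inside the brain region (gray or white matter)
#' with a configurable safety margin to the brain/CSF boundary.
#'
#' @param position Length-3 numeric position (m).
#' @param shells A [shell_model()].
#' @param margin Minimum distance (m) below the brain/CSF boundary
#'   (default 1 mm).
#' @param brain_tissues Labels counted as brain.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_dipole_position <- function(position, shells, margin = 1e-3,
                                     brain_tissues = c("wm", "gm")) {
  r <- sqrt(sum(position^2))
  r_brain <- brain_radius(shells, brain_tissues)
  if (r >= r_brain - margin) {
    stop(sprintf("dipole at radius %.2f mm is outside the allowed source region (brain radius %.2f mm, margin %.2f mm)",
                 1000 * r, 1000 * r_brain, 1000 * margin))
  }
  invisible(TRUE)
}
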