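#' Candidate source spaces
#'
#' A `source_space` holds candidate dipole positions together with a
#' per-position validity mask. Grid-born spaces record their lattice
#' metadata so that retained + masked counts always account for the full
#' lattice.
#'
#' @param positions Numeric n x 3 matrix of retained positions (m).
#' @param mask Data frame with columns `x`, `y`, `z`, `reason` covering the
#'   full candidate set (`reason == "ok"` for retained positions).
#' @param grid_meta Optional list with `center`, `extent`, `spacing` (m).
#' @return An object of class `source_space`.
#' @export
source_space <- function(positions, mask = NULL, grid_meta = NULL) {
  positions <- as.matrix(positions)
  if (nrow(positions) > 0L && ncol(positions) != 3L) {
    stop("positions must be an n x 3 matrix")
  }
  if (nrow(positions) > 0L &&
      anyDuplicated(apply(round(positions, 12L), 1L, paste, collapse = ","))) {
    stop("source positions must be unique")
  }
  if (is.null(mask)) {
    mask <- data.frame(x = positions[, 1], y = positions[, 2],
                       z = positions[, 3],
                       reason = rep("ok", nrow(positions)))
  }
  structure(list(positions = positions, mask = mask, grid_meta = grid_meta),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %d retained / %d candidate positions\n",
              nrow(x$positions), nrow(x$mask)))
  if (!is.null(x$grid_meta)) {
    cat(sprintf("  grid: extent %.1f mm, spacing %.2f mm, center (%.1f, %.1f, %.1f) mm\n",
                1000 * x$grid_meta$extent, 1000 * x$grid_meta$spacing,
                1000 * x$grid_meta$center[1], 1000 * x$grid_meta$center[2],
                1000 * x$grid_meta$center[3]))
  }
  invisible(x)
}

#' Build a regular cubic source grid
#'
#' Regular lattice spanning `extent` along each axis (endpoints inclusive,
#' `center +- extent/2`), yielding `(extent/spacing + 1)^3` positions. This
#' is the fine second-step scan grid placed around an initial dipole fit;
#' at the full study scale (extent 30 mm, spacing 1.5 mm) it has
#' 21^3 = 9,261 positions.
#'
#' @param center Length-3 numeric grid center (m).
#' @param extent Total extent per axis (m), a non-negative integer multiple
#'   of `spacing`.
#' @param spacing Lattice spacing (m), positive.
#' @return A [source_space()] with all mask reasons `"ok"`.
#' @examples
#' g <- build_cubic_grid(c(0, 0, 0.07), extent = 0.003, spacing = 0.0015)
#' nrow(g$positions)  # 27
#' @export
build_cubic_grid <- function(center, extent, spacing) {
  center <- as.numeric(center)
  if (length(center) != 3L) stop("center must be a length-3 point")
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be positive")
  if (!is.finite(extent) || extent < 0) stop("extent must be non-negative")
  k <- extent / spacing
  if (abs(k - round(k)) > 1e-9) {
    stop("extent must be an integer multiple of spacing")
  }
  k <- as.integer(round(k))
  offs <- if (k == 0L) 0 else seq(-extent / 2, extent / 2, length.out = k + 1L)
  lat <- as.matrix(expand.grid(x = offs + center[1],
                               y = offs + center[2],
                               z = offs + center[3]))
  colnames(lat) <- c("x", "y", "z")
  source_space(lat,
               grid_meta = list(center = center, extent = extent,
                                spacing = spacing))
}

#' Mask source positions by tissue and distance to the CSF boundary
#'
#' Retains positions whose radius lies in an allowed brain shell and at
#' least `min_csf_distance` below the brain/CSF boundary radius. Positions
#' too close to the brain/CSF interface are removed because the large
#' conductivity jump there degrades forward-solution accuracy; deeper
#' non-brain positions are flagged `outside_brain`.
#'
#' @param space A [source_space()].
#' @param shells A [shell_model()].
#' @param allowed_tissues Labels of shells in which sources may lie.
#' @param min_csf_distance Minimum distance (m) below the brain/CSF
#'   boundary (default 2 mm).
#' @return A [source_space()] whose mask records a reason
#'   (`ok | outside_brain | too_close_to_csf`) for every candidate.
#' @export
mask_positions <- function(space, shells, allowed_tissues = c("wm", "gm"),
                           min_csf_distance = 2e-3) {
  if (!all(allowed_tissues %in% shells$tissue_labels)) {
    stop("shells do not contain all allowed tissue labels")
  }
  cand <- as.matrix(space$mask[, c("x", "y", "z")])
  r <- sqrt(rowSums(cand^2))
  tissue <- tissue_at_radius(r, shells)
  r_brain <- brain_radius(shells, allowed_tissues)
  reason <- rep("ok", nrow(cand))
  reason[is.na(tissue) | !(tissue %in% allowed_tissues)] <- "outside_brain"
  reason[reason == "ok" & r > r_brain - min_csf_distance] <- "too_close_to_csf"
  mask <- data.frame(x = cand[, 1], y = cand[, 2], z = cand[, 3],
                     reason = reason)
  kept <- cand[reason == "ok", , drop = FALSE]
  out <- source_space(kept, mask = mask, grid_meta = space$grid_meta)
  if (nrow(kept) == 0L) attr(out, "empty") <- TRUE
  out
}

#' Coarse whole-brain source space
#'
#' First-step scan grid: a lattice over the bounding cube of the brain
#' region, masked to the allowed tissues with the default margin to the
#' brain/CSF boundary. Deterministic.
#'
#' @param shells A [shell_model()].
#' @param spacing Lattice spacing (m).
#' @param allowed_tissues,min_csf_distance Passed to [mask_positions()].
#' @return A masked [source_space()].
#' @export
coarse_brain_space <- function(shells, spacing,
                               allowed_tissues = c("wm", "gm"),
                               min_csf_distance = 2e-3) {
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be positive")
  r_brain <- brain_radius(shells, allowed_tissues)
  if (spacing > r_brain) stop("spacing exceeds the brain radius")
  k <- floor(r_brain / spacing)
  extent <- 2 * k * spacing
  grid <- build_cubic_grid(c(0, 0, 0), extent, spacing)
  mask_positions(grid, shells, allowed_tissues = allowed_tissues,
                 min_csf_distance = min_csf_distance)
}

#' Export a source space to CSV
#'
#' Writes the full candidate set with mask reasons, coordinates in mm.
#'
#' @param space A [source_space()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_source_space_csv <- function(space, path) {
  df <- data.frame(x_mm = 1000 * space$mask$x,
                   y_mm = 1000 * space$mask$y,
                   z_mm = 1000 * space$mask$z,
                   mask_reason = space$mask$reason)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
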