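#' Read and write electrode layouts (TSV, mm)
#'
#' The file format is tab-separated with one header line and columns
#' `label x y z`, coordinates in millimetres. On read, positions are
#' projected onto the scalp sphere (warning if displaced by more than
#' 2 mm).
#'
#' @param path File path.
#' @param radius Scalp radius (m) or a [shell_model()] to project onto.
#' @return [read_electrodes_tsv()]: an [electrode_array()];
#'   [write_electrodes_tsv()]: `path`, invisibly.
#' @export
read_electrodes_tsv <- function(path, radius) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("electrode file must have columns: label x y z")
  }
  electrode_array(as.matrix(df[, c("x", "y", "z")]) / 1000,
                  labels = df$label, radius = radius)
}

#' @rdname read_electrodes_tsv
#' @param electrodes An [electrode_array()].
#' @export
write_electrodes_tsv <- function(electrodes, path) {
  df <- data.frame(label = electrodes$labels,
                   x = 1000 * electrodes$positions[, 1],
                   y = 1000 * electrodes$positions[, 2],
                   z = 1000 * electrodes$positions[, 3])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save and load a leadfield as a plain-text container
#'
#' A directory holding `gain.tsv` (the gain matrix),
#' `source_positions.tsv` and `meta.json` (electrode labels,
#' conductivities, reference, units). Round-trips exactly up to text
#' precision (17 significant digits).
#'
#' @param lf A `leadfield`.
#' @param path Directory path (created if absent).
#' @return [write_leadfield()]: `path`, invisibly; [read_leadfield()]: a
#'   `leadfield`.
#' @export
write_leadfield <- function(lf, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(format(lf$gain, digits = 17, trim = TRUE),
                     file.path(path, "gain.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(format(lf$source_positions, digits = 17, trim = TRUE),
                     file.path(path, "source_positions.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(electrode_labels = lf$electrode_labels,
               conductivities = as.list(lf$conductivities),
               reference = lf$reference,
               units = list(gain = "V per A*m", positions = "m",
                            conductivities = "S/m"))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_leadfield
#' @export
read_leadfield <- function(path) {
  gain <- as.matrix(utils::read.table(file.path(path, "gain.tsv"), sep = "\t"))
  dimnames(gain) <- NULL
  pos <- as.matrix(utils::read.table(file.path(path, "source_positions.tsv"),
                                     sep = "\t"))
  dimnames(pos) <- NULL
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  structure(
    list(gain = gain, source_positions = pos,
         electrode_labels = meta$electrode_labels,
         conductivities = unlist(meta$conductivities),
         reference = meta$reference),
    class = "leadfield"
  )
}

#' Save and load a polynomial chaos model as a plain-text container
#'
#' A directory holding `coefficients.tsv`, `multi_indices.tsv` and
#' `meta.json` (bounds, tissues, basis, degree, output metadata).
#'
#' @param model A [fit_pce()] result.
#' @param path Directory path.
#' @return [write_pce()]: `path`, invisibly; [read_pce()]: a `pce_model`.
#' @export
write_pce <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(format(model$coefficients, digits = 17, trim = TRUE),
                     file.path(path, "coefficients.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(model$multi_indices,
                     file.path(path, "multi_indices.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(dims = model$dims, degree = model$degree,
               basis = model$basis, n_nodes = model$n_nodes,
               tissues = model$tissues,
               bounds = if (is.null(model$bounds)) NULL else
                 list(lower = as.numeric(model$bounds["lower", ]),
                      upper = as.numeric(model$bounds["upper", ])),
               output_meta = if (is.null(model$output_meta)) NULL else
                 list(electrode_labels = model$output_meta$electrode_labels,
                      source_positions = apply(model$output_meta$source_positions,
                                               1L, as.numeric,
                                               simplify = FALSE),
                      reference = model$output_meta$reference))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pce
#' @export
read_pce <- function(path) {
  coef <- as.matrix(utils::read.table(file.path(path, "coefficients.tsv"),
                                      sep = "\t"))
  dimnames(coef) <- NULL
  idx <- as.matrix(utils::read.table(file.path(path, "multi_indices.tsv"),
                                     sep = "\t"))
  dimnames(idx) <- NULL
  storage.mode(idx) <- "integer"
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  bounds <- NULL
  if (!is.null(meta$bounds)) {
    bounds <- rbind(lower = meta$bounds$lower, upper = meta$bounds$upper)
    colnames(bounds) <- meta$tissues
  }
  om <- NULL
  if (length(meta$output_meta) > 0L) {
    sp <- meta$output_meta$source_positions
    if (!is.matrix(sp)) sp <- do.call(rbind, sp)
    om <- list(electrode_labels = meta$output_meta$electrode_labels,
               source_positions = sp,
               reference = meta$output_meta$reference)
  }
  structure(
    list(dims = meta$dims, degree = meta$degree, multi_indices = idx,
         coefficients = coef, bounds = bounds, tissues = meta$tissues,
         basis = meta$basis, n_nodes = meta$n_nodes, output_meta = om),
    class = "pce_model"
  )
}

#' Write a Sobol table to CSV
#'
#' Long format: one row per (subset, output) with the index value.
#'
#' @param st A [sobol_indices()] result.
#' @param path Output file path.
#' @param output_labels Optional labels for the outputs (e.g. electrode
#'   names).
#' @return `path`, invisibly.
#' @export
write_sobol_csv <- function(st, path, output_labels = NULL) {
  n_out <- length(st$total_variance)
  if (is.null(output_labels)) output_labels <- as.character(seq_len(n_out))
  df <- expand.grid(electrode = output_labels, subset = st$subsets,
                    stringsAsFactors = FALSE)[, c("subset", "electrode")]
  df$S <- as.vector(t(st$S))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic measurement to CSV
#'
#' Columns `label,u_volts`.
#'
#' @param meas A [generate_measurement()] result.
#' @param electrodes The matching [electrode_array()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurement_csv <- function(meas, electrodes, path) {
  utils::write.csv(data.frame(label = electrodes$labels,
                              u_volts = meas$u_meas),
                   path, row.names = FALSE)
  invisible(path)
}
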