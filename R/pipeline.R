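#' Build the synthetic study scenario
#'
#' Mirrors the study's two-step source-analysis construction on the
#' synthetic head: (1) a coarse whole-brain goal-function scan of the
#' noisy measurement with standard conductivities fixes the reference
#' position, orientation and orientation frame; (2) a fine cubic grid is
#' centred on that reference position and masked to the brain compartments
#' away from the CSF boundary. Per-sample scans later reuse this fine grid.
#'
#' @param seed Master seed; the measurement noise and any derived draws
#'   use seeds derived deterministically from it.
#' @param snr Measurement signal-to-noise ratio (default 7.5).
#' @param n_electrodes Number of scalp sensors (default 70).
#' @param coarse_spacing Coarse grid spacing (m, default 8 mm).
#' @param fine_extent,fine_spacing Fine grid total extent and spacing
#'   (m; defaults 16 mm and 4 mm, a 5^3 = 125-node desk-scale stand-in for
#'   the full-scale 21^3 grid).
#' @param truth Optional ground-truth [dipole()] (default
#'   [default_truth_dipole()]).
#' @param min_csf_distance Source masking margin (m, default 2 mm).
#' @return An object of class `uq_scenario`: list with `head`,
#'   `electrodes`, `truth`, `measurement`, `reference` (position,
#'   orientation, fine-grid index, frame, coarse GoF), `fine_space`,
#'   `leadfield_std` (exact fine-grid leadfield at standard
#'   conductivities), `params` and `hash`.
#' @export
build_scenario <- function(seed = 1L, snr = 7.5, n_electrodes = 70L,
                           coarse_spacing = 8e-3,
                           fine_extent = 16e-3, fine_spacing = 4e-3,
                           truth = NULL, min_csf_distance = 2e-3) {
  head <- default_head()
  electrodes <- generate_electrodes(n_electrodes,
                                    seed = .child_seed(seed, 1L),
                                    radius = head$shells)
  if (is.null(truth)) truth <- default_truth_dipole(head$shells)
  validate_dipole_position(truth$position, head$shells)
  meas <- generate_measurement(truth, head$shells, electrodes, snr = snr,
                               seed = .child_seed(seed, 2L))

  # step 1: coarse whole-brain scan with standard conductivities
  coarse <- coarse_brain_space(head$shells, coarse_spacing,
                               min_csf_distance = min_csf_distance)
  lf_coarse <- compute_leadfield(coarse, electrodes, head$shells)
  fit_coarse <- scan_moving(meas$u_meas, lf_coarse, shells = head$shells)
  ref_pos <- fit_coarse$position

  # step 2: fine cubic grid around the initial reconstruction
  fine <- build_cubic_grid(ref_pos, fine_extent, fine_spacing)
  fine <- mask_positions(fine, head$shells,
                         min_csf_distance = min_csf_distance)
  if (nrow(fine$positions) == 0L) stop("fine source grid is empty after masking")
  lf_fine <- compute_leadfield(fine, electrodes, head$shells)
  d2 <- rowSums(sweep(fine$positions, 2L, ref_pos)^2)
  ref_index <- which.min(d2)
  rot <- scan_rotating(meas$u_meas, .gain_block(lf_fine, ref_index))
  ref_ori <- rot$moment / sqrt(sum(rot$moment^2))
  frame <- build_orientation_frame(ref_ori, fine$positions[ref_index, ],
                                   head$fissure_direction)

  params <- list(seed = seed, snr = snr, n_electrodes = n_electrodes,
                 coarse_spacing = coarse_spacing, fine_extent = fine_extent,
                 fine_spacing = fine_spacing,
                 min_csf_distance = min_csf_distance)
  hash <- sprintf("%08x",
                  sum(utf8ToInt(paste(unlist(params), collapse = "|")) *
                        seq_along(utf8ToInt(paste(unlist(params),
                                                  collapse = "|")))) %% 2147483647)
  structure(
    list(head = head, electrodes = electrodes, truth = truth,
         measurement = meas,
         reference = list(position = as.numeric(fine$positions[ref_index, ]),
                          orientation = ref_ori, index = ref_index,
                          frame = frame, coarse_gof = fit_coarse$gof,
                          moment = rot$moment),
         fine_space = fine, leadfield_std = lf_fine,
         params = params, hash = hash),
    class = "uq_scenario"
  )
}

#' @export
print.uq_scenario <- function(x, ...) {
  cat(sprintf("<uq_scenario> %d electrodes, SNR %.2f, fine grid %d nodes, reference depth %.1f mm (hash %s)\n",
              length(x$electrodes$labels), x$params$snr,
              nrow(x$fine_space$positions),
              1000 * source_depth(x$reference$position, x$head$shells),
              x$hash))
  invisible(x)
}

.child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483629)
}

#' Build a polynomial chaos surrogate of the fine-grid leadfield
#'
#' Computes the exact forward leadfield at every Smolyak collocation node
#' (conductivity set) and projects onto the orthonormal Legendre basis of
#' total degree `degree`. All flattened leadfield entries share one node
#' set.
#'
#' @param scenario A [build_scenario()] result.
#' @param uncertain Tissues treated as uncertain (order defines the
#'   surrogate dimensions).
#' @param degree Maximum total polynomial degree (default 4).
#' @param method Coefficient fit, see [fit_pce()]. The default here is
#'   `"regression"`: the leadfield's amplitude varies steeply near the
#'   lower skull-conductivity bound, and least squares on the same nodes
#'   keeps that higher-degree content from aliasing into the retained
#'   coefficients.
#' @return A leadfield-valued [fit_pce()] model.
#' @export
build_leadfield_pce <- function(scenario, uncertain, degree = 4L,
                                method = "regression") {
  prior <- scenario$head$prior
  shells0 <- scenario$head$shells
  d <- length(uncertain)
  sg <- sparse_grid_nodes(d, degree)
  sig_nodes <- .nodes_to_sigma(sg$nodes, prior, uncertain)
  pos <- scenario$fine_space$positions
  E <- length(scenario$electrodes$labels)
  evals <- matrix(0, sg$n_nodes, E * 3L * nrow(pos))
  for (i in seq_len(sg$n_nodes)) {
    sh <- shell_model(shells0$radii,
                      sig_nodes[i, shells0$tissue_labels],
                      shells0$tissue_labels)
    lf <- compute_leadfield(pos, scenario$electrodes, sh)
    evals[i, ] <- as.vector(lf$gain)
  }
  bounds <- rbind(lower = prior$lower[.prior_row(prior, uncertain)],
                  upper = prior$upper[.prior_row(prior, uncertain)])
  colnames(bounds) <- uncertain
  fit_pce(evals, sg$nodes, sg$weights, degree,
          bounds = bounds, tissues = uncertain, method = method,
          output_meta = list(electrode_labels = scenario$electrodes$labels,
                             source_positions = pos,
                             reference = "average"))
}

# Map rescaled collocation nodes to full conductivity sets (uncertain
# tissues from the nodes, all others at their standard value).
.nodes_to_sigma <- function(nodes, prior, uncertain) {
  n <- nrow(nodes)
  out <- matrix(rep(prior$standard, each = n), n, nrow(prior),
                dimnames = list(NULL, prior$tissue))
  out[, uncertain] <- unrescale_conductivity(nodes, prior, uncertain)
  out
}

#' Collocation-node budget of the full experiment design
#'
#' Enumerates the conductivity sets at which an exact forward leadfield
#' must be computed to fit all expansions of the study design (by default:
#' five univariate expansions plus one four-variate expansion over skin,
#' skull, gray and white matter, all at total degree 4) and counts the
#' distinct sets.
#'
#' @param prior A [conductivity_prior()].
#' @param degree Expansion degree (default 4).
#' @param univariate Tissues receiving univariate expansions (default all
#'   five).
#' @param multivariate Tissue set of the joint expansion (default skin,
#'   skull, gm, wm — CSF dropped).
#' @return List with `total` (distinct conductivity sets), `per_expansion`
#'   (named node counts) and `sigma_sets` (the deduplicated matrix).
#' @export
forward_evaluation_budget <- function(prior = default_prior(), degree = 4L,
                                      univariate = prior$tissue,
                                      multivariate = c("skin", "skull", "gm", "wm")) {
  sets <- list()
  counts <- integer(0)
  for (t in univariate) {
    sg <- sparse_grid_nodes(1L, degree)
    sets[[t]] <- .nodes_to_sigma(sg$nodes, prior, t)
    counts[t] <- sg$n_nodes
  }
  sg <- sparse_grid_nodes(length(multivariate), degree)
  key_m <- paste(multivariate, collapse = "+")
  sets[[key_m]] <- .nodes_to_sigma(sg$nodes, prior, multivariate)
  counts[key_m] <- sg$n_nodes
  all_sets <- do.call(rbind, sets)
  keys <- apply(signif(all_sets, 12L), 1L, paste, collapse = ",")
  uniq <- all_sets[!duplicated(keys), , drop = FALSE]
  list(total = nrow(uniq), per_expansion = counts, sigma_sets = uniq)
}

# Shared sampling loop behind the univariate and multivariate experiments.
.run_experiment <- function(scenario, uncertain, n, seed, model = NULL,
                            degree = 4L) {
  prior <- scenario$head$prior
  if (is.null(model)) {
    model <- build_leadfield_pce(scenario, uncertain, degree = degree)
  }
  samples <- sample_prior(prior, n, .child_seed(seed, 3L),
                          uncertain = uncertain)
  u <- scenario$measurement$u_meas
  shells <- scenario$head$shells
  frame <- scenario$reference$frame
  ref_idx <- scenario$reference$index
  ref_ori <- scenario$reference$orientation
  E <- length(scenario$electrodes$labels)
  K <- nrow(scenario$fine_space$positions)

  # one basis row per sample, evaluated in a single matrix product
  xi <- rescale_conductivity(samples, prior, tissues = model$tissues)
  psi <- .basis_matrix(xi, model$multi_indices)

  cols_ref <- (3L * (ref_idx - 1L) + 1L):(3L * ref_idx)
  out <- data.frame(sample_id = seq_len(n))
  for (t in prior$tissue) out[[paste0("sigma_", t, "_mS")]] <- 1000 * samples[, t]
  num0 <- numeric(n)
  out$fixed_strength_nAm <- num0; out$fixed_gof <- num0
  out$rot_phi_deg <- num0; out$rot_theta_deg <- num0; out$rot_gof <- num0
  out$mov_index <- integer(n)
  out$mov_x_mm <- num0; out$mov_y_mm <- num0; out$mov_z_mm <- num0
  out$mov_depth_mm <- num0; out$mov_strength_nAm <- num0; out$mov_gof <- num0

  for (i in seq_len(n)) {
    gain <- matrix(psi[i, ] %*% model$coefficients, nrow = E)
    lf <- structure(list(gain = gain,
                         source_positions = scenario$fine_space$positions,
                         electrode_labels = scenario$electrodes$labels,
                         conductivities = samples[i, ],
                         reference = "average"),
                    class = "leadfield")
    L3 <- gain[, cols_ref, drop = FALSE]
    fx <- scan_fixed(u, L3 %*% ref_ori)
    rt <- scan_rotating(u, L3, frame = frame)
    mv <- suppressWarnings(scan_moving(u, lf, shells = shells, frame = frame))
    out$fixed_strength_nAm[i] <- 1e9 * fx$strength
    out$fixed_gof[i] <- fx$gof
    out$rot_phi_deg[i] <- if (is.null(rt$phi)) NA_real_ else rt$phi
    out$rot_theta_deg[i] <- if (is.null(rt$theta)) NA_real_ else rt$theta
    out$rot_gof[i] <- rt$gof
    out$mov_index[i] <- mv$best_index
    out$mov_x_mm[i] <- 1000 * mv$position[1]
    out$mov_y_mm[i] <- 1000 * mv$position[2]
    out$mov_z_mm[i] <- 1000 * mv$position[3]
    out$mov_depth_mm[i] <- 1000 * mv$depth
    out$mov_strength_nAm[i] <- 1e9 * mv$strength
    out$mov_gof[i] <- mv$gof
  }
  structure(out,
            class = c("experiment_table", "data.frame"),
            uncertain = uncertain, n = n, seed = seed,
            scenario_hash = scenario$hash, model = model,
            prior = prior)
}

#' Univariate uncertainty-quantification experiment
#'
#' Varies one tissue conductivity over its uniform prior while all other
#' tissues stay at their standard value: builds (or reuses) the univariate
#' degree-4 leadfield surrogate, draws `n` conductivity samples, and runs
#' the fixed, rotating and moving goal-function scans for each sampled
#' leadfield. Deterministic given the seed.
#'
#' @param tissue Tissue whose conductivity is uncertain.
#' @param scenario A [build_scenario()] result.
#' @param n Number of prior samples (study scale: 10,000).
#' @param seed Integer seed.
#' @param model Optional prebuilt surrogate (from
#'   [build_leadfield_pce()]).
#' @param degree Surrogate degree (default 4).
#' @return An `experiment_table` data frame, one row per sample:
#'   conductivities (mS/m), fixed-scan strength/GoF, rotating-scan
#'   phi/theta/GoF, moving-scan position/depth/strength/GoF. Metadata in
#'   attributes `uncertain`, `n`, `seed`, `scenario_hash`, `model`.
#' @export
run_univariate <- function(tissue, scenario, n = 10000L, seed = 1L,
                           model = NULL, degree = 4L) {
  stopifnot(length(tissue) == 1L)
  .prior_row(scenario$head$prior, tissue)
  .run_experiment(scenario, tissue, n, seed, model = model, degree = degree)
}

#' Multivariate uncertainty-quantification experiment
#'
#' Joint uncertainty over skin, skull, gray- and white-matter
#' conductivities (CSF is dropped: its prior interval is too narrow to
#' matter), using a four-variate degree-4 surrogate.
#'
#' @inheritParams run_univariate
#' @param uncertain Tissue set (default `c("skin", "skull", "gm", "wm")`).
#' @return An `experiment_table`, as for [run_univariate()].
#' @export
run_multivariate <- function(scenario, n = 10000L, seed = 1L,
                             uncertain = c("skin", "skull", "gm", "wm"),
                             model = NULL, degree = 4L) {
  .run_experiment(scenario, uncertain, n, seed, model = model,
                  degree = degree)
}

#' Best-fitting conductivity set of an experiment
#'
#' The maximal moving-scan GoF over all samples, the conductivity set that
#' attains it (ties: lowest sample id), and the standard deviation of the
#' GoF across samples.
#'
#' @param table An `experiment_table`.
#' @return List with `gof_max`, `sigma_mS` (named, mS/m), `sample_id` and
#'   `sd_gof`.
#' @export
best_fit <- function(table) {
  if (nrow(table) == 0L) stop("empty experiment table")
  best <- which.max(table$mov_gof)  # which.max returns the first maximum
  sig_cols <- grep("^sigma_.*_mS$", names(table), value = TRUE)
  sig <- as.numeric(table[best, sig_cols])
  names(sig) <- sub("^sigma_(.*)_mS$", "\\1", sig_cols)
  list(gof_max = table$mov_gof[best], sigma_mS = sig,
       sample_id = table$sample_id[best],
       sd_gof = stats::sd(table$mov_gof))
}

#' Binned median source depth over two conductivities
#'
#' 2-D binning of the samples over the prior intervals of two uncertain
#' tissues; the median moving-scan depth is reported per nonempty bin
#' (empty bins are `NA`-flagged).
#'
#' @param table An `experiment_table` in which both tissues were uncertain.
#' @param tissue_x,tissue_y Tissue names.
#' @param bins Number of equal-width bins per axis (default 8).
#' @return List with `x_mid`, `y_mid` (bin midpoints, mS/m), `median_depth`
#'   (bins x bins matrix, mm), `count` (occupancy, sums to `nrow(table)`).
#' @export
depth_surface <- function(table, tissue_x, tissue_y, bins = 8L) {
  unc <- attr(table, "uncertain")
  if (!all(c(tissue_x, tissue_y) %in% unc)) {
    stop("both tissues must be uncertain in the experiment")
  }
  prior <- attr(table, "prior")
  get_edges <- function(t) {
    i <- .prior_row(prior, t)
    seq(1000 * prior$lower[i], 1000 * prior$upper[i], length.out = bins + 1L)
  }
  ex <- get_edges(tissue_x)
  ey <- get_edges(tissue_y)
  x <- table[[paste0("sigma_", tissue_x, "_mS")]]
  y <- table[[paste0("sigma_", tissue_y, "_mS")]]
  ix <- pmin(bins, pmax(1L, findInterval(x, ex, rightmost.closed = TRUE)))
  iy <- pmin(bins, pmax(1L, findInterval(y, ey, rightmost.closed = TRUE)))
  med <- matrix(NA_real_, bins, bins)
  cnt <- matrix(0L, bins, bins)
  for (a in seq_len(bins)) for (b in seq_len(bins)) {
    sel <- ix == a & iy == b
    cnt[a, b] <- sum(sel)
    if (any(sel)) med[a, b] <- stats::median(table$mov_depth_mm[sel])
  }
  list(x_mid = (ex[-1] + ex[-(bins + 1L)]) / 2,
       y_mid = (ey[-1] + ey[-(bins + 1L)]) / 2,
       median_depth = med, count = cnt)
}

#' Per-electrode sensitivity report for the reference source
#'
#' Derives the polynomial chaos expansion of the electrode potentials of
#' the fixed reference dipole from a leadfield-valued surrogate (the
#' potentials are linear in the leadfield entries, so their coefficients
#' are linear combinations of the leadfield coefficients), then reports
#' first- and second-order Sobol indices per electrode, the residual
#' `1 - sum(reported orders)`, the mean voltage, and the per-electrode
#' standard deviation over sampled surrogate potentials.
#'
#' @param model A leadfield-valued [fit_pce()] model over >= 2 tissues.
#' @param scenario The [build_scenario()] result the model belongs to.
#' @param n_samples Monte Carlo sample count for the per-electrode standard
#'   deviation (default 1000).
#' @param seed Integer seed for those samples.
#' @return List with `table` (data frame, one row per electrode, sorted by
#'   voltage: label, voltage_uV, std_uV, `S_<subset>` columns in %, and
#'   `residual_pct`) and `sobol` (the underlying [sobol_indices()] result).
#' @export
sensitivity_report <- function(model, scenario, n_samples = 1000L,
                               seed = 1L) {
  if (length(model$tissues) < 2L) {
    stop("sensitivity report requires a model over at least 2 uncertain tissues")
  }
  E <- length(model$output_meta$electrode_labels)
  ref_idx <- scenario$reference$index
  m <- scenario$reference$moment
  cols <- 3L * (ref_idx - 1L) + (1:3)
  cu <- matrix(0, nrow(model$multi_indices), E)
  for (a in 1:3) {
    block <- model$coefficients[, (cols[a] - 1L) * E + seq_len(E), drop = FALSE]
    cu <- cu + m[a] * block
  }
  pot_model <- structure(
    list(dims = model$dims, degree = model$degree,
         multi_indices = model$multi_indices, coefficients = cu,
         bounds = model$bounds, tissues = model$tissues,
         basis = model$basis, n_nodes = model$n_nodes, output_meta = NULL),
    class = "pce_model")
  st <- sobol_indices(pot_model, max_order = 2L)
  sig <- sample_prior(scenario$head$prior, n_samples,
                      .child_seed(seed, 4L), uncertain = model$tissues)
  xi <- rescale_conductivity(sig, scenario$head$prior, model$tissues)
  draws <- .basis_matrix(xi, model$multi_indices) %*% cu
  df <- data.frame(label = model$output_meta$electrode_labels,
                   voltage_uV = 1e6 * cu[1L, ],
                   std_uV = 1e6 * electrodewise_std(draws))
  ssum <- rep(0, E)
  for (i in seq_along(st$subsets)) {
    col <- paste0("S_", gsub(":", "_", st$subsets[i]), "_pct")
    df[[col]] <- 100 * st$S[i, ]
    ssum <- ssum + ifelse(is.na(st$S[i, ]), 0, st$S[i, ])
  }
  df$residual_pct <- ifelse(st$zero_variance, NA_real_, 100 * (1 - ssum))
  df <- df[order(df$voltage_uV, decreasing = TRUE), ]
  rownames(df) <- NULL
  list(table = df, sobol = st)
}

#' Write an experiment table to CSV
#'
#' @param table An `experiment_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_experiment_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
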