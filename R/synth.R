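#' Default synthetic head model
#'
#' Five concentric shells (white matter, gray matter, CSF, skull, skin)
#' with boundaries at 70, 78, 80, 86 and 92 mm — conventional placeholder
#' radii, not subject-specific measurements — and the standard literature
#' conductivities of [default_prior()]. The fissure direction used for
#' orientation frames defaults to `+y`.
#'
#' @return List with `shells` ([shell_model()]), `prior`
#'   ([conductivity_prior()]) and `fissure_direction`.
#' @export
default_head <- function() {
  prior <- default_prior()
  labels <- c("wm", "gm", "csf", "skull", "skin")
  sig <- standard_conductivities(prior)[labels]
  shells <- shell_model(radii = c(70, 78, 80, 86, 92) / 1000,
                        conductivities = as.numeric(sig),
                        tissue_labels = labels)
  list(shells = shells, prior = prior, fissure_direction = c(0, 1, 0))
}

#' Quasi-uniform electrode layout on the upper scalp
#'
#' Places `n` sensors on a spherical cap covering `cap_fraction` of the
#' sphere surface (measured from the vertex down), using a Fibonacci
#' lattice for quasi-uniform coverage. The seed only rotates the lattice
#' about the vertical axis; layouts are deterministic given the seed.
#'
#' @param n Number of electrodes (>= 4; default 70, the study's channel
#'   count after exclusions).
#' @param cap_fraction Fraction of the sphere covered, in `(0, 1]`
#'   (default 0.5: the upper hemisphere).
#' @param seed Integer seed (default 1).
#' @param radius Scalp radius (m) or a [shell_model()].
#' @return An [electrode_array()].
#' @export
generate_electrodes <- function(n = 70L, cap_fraction = 0.5, seed = 1L,
                                radius = default_head()$shells) {
  if (n < 4L) stop("at least 4 electrodes are required")
  if (!is.finite(cap_fraction) || cap_fraction <= 0 || cap_fraction > 1) {
    stop("cap_fraction must be in (0, 1]")
  }
  if (inherits(radius, "shell_model")) radius <- scalp_radius(radius)
  golden <- pi * (3 - sqrt(5))
  offset <- .with_seed(seed, stats::runif(1, 0, 2 * pi))
  i <- seq_len(n)
  z <- 1 - 2 * cap_fraction * (i - 0.5) / n
  az <- golden * i + offset
  s <- sqrt(pmax(0, 1 - z^2))
  pts <- radius * cbind(s * cos(az), s * sin(az), z)
  electrode_array(pts, labels = sprintf("E%03d", i), radius = radius)
}

#' Default ground-truth dipole of the synthetic scenario
#'
#' A gray-matter source at 8 mm depth below the inner skull, oriented
#' mostly tangentially with a small radial component, strength 10 nAm —
#' scenario defaults emulating a superficial somatosensory source, not
#' subject-specific values.
#'
#' @param shells A [shell_model()].
#' @param depth Source depth below the inner skull (m, default 8 mm).
#' @param strength Dipole strength (A m, default 1e-8).
#' @return A [dipole()].
#' @export
default_truth_dipole <- function(shells = default_head()$shells,
                                 depth = 8e-3, strength = 1e-8) {
  r <- inner_skull_radius(shells) - depth
  dir <- c(0.35, 0.25, 0.90)
  dir <- dir / sqrt(sum(dir^2))
  pos <- r * dir
  # tangential direction: component of +y orthogonal to the radial
  tang <- c(0, 1, 0) - sum(c(0, 1, 0) * dir) * dir
  tang <- tang / sqrt(sum(tang^2))
  ori <- 0.97 * tang + 0.243 * dir
  ori <- ori / sqrt(sum(ori^2))
  dipole(pos, strength * ori)
}

#' Generate a synthetic scalp topography at a target SNR
#'
#' Computes the average-referenced forward solution of the ground-truth
#' dipole and adds i.i.d. Gaussian noise per channel with variance
#' `mean(signal^2) / snr`. The study's SNR is a temporal power ratio; with
#' no time dimension here it is reinterpreted as mean squared signal over
#' noise variance across channels, preserving the single number the
#' analysis conditions on.
#'
#' @param truth A [dipole()] (nonzero moment).
#' @param shells A [shell_model()].
#' @param electrodes An [electrode_array()].
#' @param snr Target signal-to-noise ratio (> 0, or `Inf` for noiseless;
#'   default 7.5).
#' @param seed Integer seed for the noise draw.
#' @return An object of class `synthetic_sep`: list with `u_meas`
#'   (referenced potentials, V), `u_clean`, `truth`, `noise_sd`,
#'   `snr_target`, `snr_realized` and `seed`.
#' @export
generate_measurement <- function(truth, shells, electrodes, snr = 7.5,
                                 seed = 1L) {
  if (!is.infinite(snr) && snr <= 0) stop("snr must be positive or Inf")
  u_clean <- apply_average_reference(
    potential_layered_sphere(truth, electrodes, shells))
  if (all(u_clean == 0)) stop("silent configuration: the truth dipole produces no signal")
  if (is.infinite(snr)) {
    return(structure(list(u_meas = u_clean, u_clean = u_clean, truth = truth,
                          noise_sd = 0, snr_target = Inf, snr_realized = Inf,
                          seed = seed),
                     class = "synthetic_sep"))
  }
  noise_sd <- sqrt(mean(u_clean^2) / snr)
  eps <- .with_seed(seed, stats::rnorm(length(u_clean), sd = noise_sd))
  u <- u_clean + eps
  structure(list(u_meas = u, u_clean = u_clean, truth = truth,
                 noise_sd = noise_sd, snr_target = snr,
                 snr_realized = mean(u_clean^2) / mean(eps^2), seed = seed),
            class = "synthetic_sep")
}

#' @export
print.synthetic_sep <- function(x, ...) {
  cat(sprintf("<synthetic_sep> %d channels, target SNR %.2f (realized %.2f), noise sd %.3g V\n",
              length(x$u_meas), x$snr_target, x$snr_realized, x$noise_sd))
  invisible(x)
}
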