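# Per-degree radial boundary-value system for the concentric-shell conductor.
#
# For spherical-harmonic degree n the potential in shell j is
#   V_j(r) = A_j (r / r_j)^n + B_j (r_{j-1} / r)^(n+1)  (+ primary in the
# source shell), with B_1 = 0 by regularity at the origin. The per-shell
# scaling keeps every matrix entry in [0, 1] up to the n/r derivative
# factors, so the system stays well conditioned at high degree.
#
# Unknown ordering: A_1, A_2, B_2, ..., A_J, B_J (2J - 1 unknowns).
.degree_matrix <- function(n, shells) {
  r <- shells$radii
  sig <- shells$conductivities
  J <- length(r)
  m <- matrix(0, 2L * J - 1L, 2L * J - 1L)
  a_idx <- function(j) if (j == 1L) 1L else 2L * j - 2L
  b_idx <- function(j) 2L * j - 1L  # only for j >= 2
  r_in <- c(0, r[-J])               # inner radius of each shell
  if (J > 1L) {
    for (i in seq_len(J - 1L)) {
      ri <- r[i]
      # shell i side, evaluated at its own outer radius
      phi_i <- 1
      dphi_i <- n / ri
      psi_i <- (r_in[i] / ri)^(n + 1)
      dpsi_i <- -(n + 1) / ri * psi_i
      # shell i+1 side, evaluated at its inner radius
      phi_o <- (ri / r[i + 1L])^n
      dphi_o <- n / ri * phi_o
      psi_o <- 1
      dpsi_o <- -(n + 1) / ri
      rowV <- 2L * i - 1L
      rowF <- 2L * i
      m[rowV, a_idx(i)] <- phi_i
      m[rowF, a_idx(i)] <- sig[i] * dphi_i
      if (i >= 2L) {
        m[rowV, b_idx(i)] <- psi_i
        m[rowF, b_idx(i)] <- sig[i] * dpsi_i
      }
      m[rowV, a_idx(i + 1L)] <- -phi_o
      m[rowF, a_idx(i + 1L)] <- -sig[i + 1L] * dphi_o
      m[rowV, b_idx(i + 1L)] <- -psi_o
      m[rowF, b_idx(i + 1L)] <- -sig[i + 1L] * dpsi_o
    }
  }
  # insulating exterior: radial current vanishes at the scalp
  R <- r[J]
  row <- 2L * J - 1L
  m[row, a_idx(J)] <- n / R
  if (J >= 2L) m[row, b_idx(J)] <- -(n + 1) / R * (r_in[J] / R)^(n + 1)
  m
}

# Primary (infinite-medium) dipole potential coefficients of degree n at
# radius rr, for a source at radius b0 in a medium of conductivity sig_s.
# Returns c(value, derivative) for the radial and tangential unit sources.
# branch ">" is valid for rr >= b0, "<" for rr <= b0.
.primary_terms <- function(n, b0, sig_s, rr, branch) {
  if (branch == ">") {
    base <- (if (n == 1L) 1 else (b0 / rr)^(n - 1)) / (4 * pi * sig_s * rr^2)
    v_rad <- n * base
    v_tan <- base
    d_rad <- -(n + 1) / rr * v_rad
    d_tan <- -(n + 1) / rr * v_tan
  } else {
    base <- (rr / b0)^n / (4 * pi * sig_s * b0^2)
    v_rad <- -(n + 1) * base
    v_tan <- base
    d_rad <- n / rr * v_rad
    d_tan <- n / rr * v_tan
  }
  list(rad = c(v_rad, d_rad), tan = c(v_tan, d_tan))
}

# Right-hand side (2 columns: radial, tangential unit source) of the
# degree-n system for a dipole at radius b0 in source shell s.
.degree_rhs <- function(n, shells, s, b0) {
  r <- shells$radii
  sig <- shells$conductivities
  J <- length(r)
  rhs <- matrix(0, 2L * J - 1L, 2L)
  # interface below the source shell: use the r < b0 expansion
  if (s >= 2L) {
    pt <- .primary_terms(n, b0, sig[s], r[s - 1L], "<")
    rowV <- 2L * (s - 1L) - 1L
    rowF <- 2L * (s - 1L)
    rhs[rowV, ] <- rhs[rowV, ] + c(pt$rad[1], pt$tan[1])
    rhs[rowF, ] <- rhs[rowF, ] + sig[s] * c(pt$rad[2], pt$tan[2])
  }
  # interface above the source shell: use the r > b0 expansion
  if (s <= J - 1L) {
    pt <- .primary_terms(n, b0, sig[s], r[s], ">")
    rowV <- 2L * s - 1L
    rowF <- 2L * s
    rhs[rowV, ] <- rhs[rowV, ] - c(pt$rad[1], pt$tan[1])
    rhs[rowF, ] <- rhs[rowF, ] - sig[s] * c(pt$rad[2], pt$tan[2])
  }
  if (s == J) {  # source in the outermost shell: primary enters the outer BC
    pt <- .primary_terms(n, b0, sig[s], r[J], ">")
    rhs[2L * J - 1L, ] <- rhs[2L * J - 1L, ] - c(pt$rad[2], pt$tan[2])
  }
  rhs
}

.source_shell <- function(b0, shells) {
  s <- findInterval(b0, shells$radii, left.open = TRUE) + 1L
  if (s > length(shells$radii)) {
    stop(sprintf("dipole at radius %.2f mm lies outside the scalp (%.2f mm)",
                 1000 * b0, 1000 * max(shells$radii)))
  }
  if (s > 2L) {
    stop(sprintf("dipole at radius %.2f mm is not inside the innermost two shells",
                 1000 * b0))
  }
  s
}

#' Scalp potential of a dipole in a multilayer sphere
#'
#' Quasi-static series solution for the electric potential of a current
#' dipole inside a concentric multi-shell conductor with insulating
#' exterior. The spherical-harmonic series is truncated adaptively: degrees
#' are added until the relative contribution stays below `rtol` for three
#' consecutive degrees.
#'
#' @param dip A [dipole()].
#' @param electrodes An [electrode_array()] (or an n x 3 matrix of field
#'   points inside or on the scalp sphere).
#' @param shells A [shell_model()].
#' @param rtol Relative series tolerance (default `1e-8`).
#' @param n_max Maximum spherical-harmonic degree (default 200).
#' @return Numeric vector of unreferenced potentials (V), one per electrode.
#'   Linear in the dipole moment.
#' @examples
#' head <- default_head()
#' el <- generate_electrodes(16, radius = scalp_radius(head$shells))
#' dip <- dipole(c(0, 0, 0.05), c(1e-8, 0, 0))
#' u <- potential_layered_sphere(dip, el, head$shells)
#' @export
potential_layered_sphere <- function(dip, electrodes, shells,
                                     rtol = 1e-8, n_max = 200L) {
  pts <- if (inherits(electrodes, "electrode_array")) {
    electrodes$positions
  } else {
    as.matrix(electrodes)
  }
  if (ncol(pts) != 3L) stop("field points must be an n x 3 matrix")
  b <- dip$position
  b0 <- sqrt(sum(b^2))
  s <- .source_shell(b0, shells)
  if (dip$strength == 0) return(rep(0, nrow(pts)))

  r_pts <- sqrt(rowSums(pts^2))
  if (any(r_pts <= 0)) stop("field point at the origin is not supported")
  R <- max(shells$radii)
  if (any(r_pts > R * (1 + 1e-9))) stop("field points must lie inside or on the scalp sphere")
  r_pts <- pmin(r_pts, R)
  # shell containing each field point (boundary -> inner shell)
  j_pts <- findInterval(r_pts, shells$radii, left.open = TRUE) + 1L
  j_pts <- pmin(j_pts, length(shells$radii))

  bhat <- if (b0 > 0) b / b0 else c(0, 0, 1)
  ehat <- pts / r_pts
  cosg <- pmin(1, pmax(-1, as.vector(ehat %*% bhat)))
  m_r <- sum(dip$moment * bhat)
  m_e <- as.vector(ehat %*% dip$moment)  # m . r_hat per point

  r_in <- c(0, shells$radii[-length(shells$radii)])
  a_idx <- function(j) if (j == 1L) 1L else 2L * j - 2L
  b_idx <- function(j) 2L * j - 1L

  n_pts <- nrow(pts)
  u <- numeric(n_pts)
  P_prev <- rep(1, n_pts)   # P_0
  P_cur <- cosg             # P_1
  dP_prev <- rep(0, n_pts)  # P_0'
  dP_cur <- rep(1, n_pts)   # P_1'
  below <- 0L
  achieved <- Inf
  for (n in seq_len(n_max)) {
    if (n > 1L) {
      P_new <- ((2 * n - 1) * cosg * P_cur - (n - 1) * P_prev) / n
      dP_new <- n * P_cur + cosg * dP_cur
      P_prev <- P_cur; P_cur <- P_new
      dP_prev <- dP_cur; dP_cur <- dP_new
    }
    M <- .degree_matrix(n, shells)
    rhs <- .degree_rhs(n, shells, s, b0)
    X <- solve(M, rhs)
    # radial profile at each field point
    v_rad <- numeric(n_pts)
    v_tan <- numeric(n_pts)
    for (j in unique(j_pts)) {
      sel <- j_pts == j
      rr <- r_pts[sel]
      phi <- (rr / shells$radii[j])^n
      psi <- if (j >= 2L) (r_in[j] / rr)^(n + 1) else 0
      A <- X[a_idx(j), ]
      B <- if (j >= 2L) X[b_idx(j), ] else c(0, 0)
      vr <- A[1] * phi + B[1] * psi
      vt <- A[2] * phi + B[2] * psi
      if (j == s) {
        br <- ifelse(rr >= b0, ">", "<")
        for (w in which(sel)) {
          pt <- .primary_terms(n, b0, shells$conductivities[s], r_pts[w],
                               if (r_pts[w] >= b0) ">" else "<")
          v_rad[w] <- pt$rad[1]
          v_tan[w] <- pt$tan[1]
        }
        v_rad[sel] <- v_rad[sel] + vr
        v_tan[sel] <- v_tan[sel] + vt
      } else {
        v_rad[sel] <- vr
        v_tan[sel] <- vt
      }
    }
    inc <- v_rad * P_cur * m_r + v_tan * dP_cur * (m_e - cosg * m_r)
    u <- u + inc
    scale <- max(abs(u))
    achieved <- if (scale > 0) max(abs(inc)) / scale else Inf
    if (is.finite(achieved) && achieved < rtol) {
      below <- below + 1L
      if (below >= 3L) return(u)
    } else {
      below <- 0L
    }
  }
  stop(sprintf("series not converged at n_max = %d (achieved relative residual %.3e, requested %.3e)",
               n_max, achieved, rtol))
}

# Batched forward solution for many source positions, field points on the
# scalp surface. Returns the unreferenced gain matrix (n_electrodes x 3K):
# column 3(k-1)+a is the potential of a unit dipole along axis a at source k.
.forward_batch <- function(src_pos, elec_pos, shells,
                           rtol = 1e-8, n_max = 200L) {
  src_pos <- as.matrix(src_pos)
  K <- nrow(src_pos)
  E <- nrow(elec_pos)
  R <- max(shells$radii)
  b0 <- sqrt(rowSums(src_pos^2))
  s_k <- vapply(b0, .source_shell, integer(1), shells = shells)
  bhat <- src_pos / ifelse(b0 > 0, b0, 1)
  if (any(b0 == 0)) {
    bhat[b0 == 0, ] <- matrix(c(0, 0, 1), sum(b0 == 0), 3, byrow = TRUE)
  }
  ehat <- elec_pos / sqrt(rowSums(elec_pos^2))
  cosg <- ehat %*% t(bhat)              # E x K
  cosg <- pmin(1, pmax(-1, cosg))

  J <- length(shells$radii)
  r_in <- c(0, shells$radii[-J])
  iAJ <- if (J == 1L) 1L else 2L * J - 2L
  iBJ <- 2L * J - 1L
  psi_R <- if (J >= 2L) (r_in[J] / R)^(n_max + 1) else 0  # placeholder, set per degree

  S1 <- matrix(0, E, K)
  S2 <- matrix(0, E, K)
  P_prev <- matrix(1, E, K)
  P_cur <- cosg
  dP_cur <- matrix(1, E, K)
  below <- 0L
  achieved <- Inf
  for (n in seq_len(n_max)) {
    if (n > 1L) {
      P_new <- ((2 * n - 1) * cosg * P_cur - (n - 1) * P_prev) / n
      dP_new <- n * P_cur + cosg * dP_cur
      P_prev <- P_cur; P_cur <- P_new
      dP_cur <- dP_new
    }
    M <- .degree_matrix(n, shells)
    rhs <- matrix(0, nrow(M), 2L * K)
    for (k in seq_len(K)) {
      rhs[, c(2L * k - 1L, 2L * k)] <- .degree_rhs(n, shells, s_k[k], b0[k])
    }
    X <- solve(M, rhs)
    psiR <- if (J >= 2L) (r_in[J] / R)^(n + 1) else 0
    AJ <- X[iAJ, ]
    BJ <- if (J >= 2L) X[iBJ, ] else numeric(2L * K)
    v_scalp <- AJ + BJ * psiR           # length 2K, at r = R (phi_J(R) = 1)
    # sources in the outermost shell contribute their primary field at R
    outerJ <- which(s_k == J)
    for (k in outerJ) {
      pt <- .primary_terms(n, b0[k], shells$conductivities[J], R, ">")
      v_scalp[2L * k - 1L] <- v_scalp[2L * k - 1L] + pt$rad[1]
      v_scalp[2L * k] <- v_scalp[2L * k] + pt$tan[1]
    }
    Rrad <- v_scalp[seq(1L, 2L * K, by = 2L)]
    Rtan <- v_scalp[seq(2L, 2L * K, by = 2L)]
    inc1 <- P_cur * matrix(Rrad, E, K, byrow = TRUE)
    inc2 <- dP_cur * matrix(Rtan, E, K, byrow = TRUE)
    S1 <- S1 + inc1
    S2 <- S2 + inc2
    scale <- max(abs(S1)) + 2 * max(abs(S2))
    achieved <- if (scale > 0) (max(abs(inc1)) + 2 * max(abs(inc2))) / scale else Inf
    if (is.finite(achieved) && achieved < rtol) {
      below <- below + 1L
      if (below >= 3L) break
    } else {
      below <- 0L
    }
    if (n == n_max && below < 3L) {
      stop(sprintf("series not converged at n_max = %d (achieved relative residual %.3e, requested %.3e)",
                   n_max, achieved, rtol))
    }
  }
  gain <- matrix(0, E, 3L * K)
  for (a in 1:3) {
    # V[e, k] for unit moment along axis a:
    #   S1 * bhat_a + S2 * (ehat_a - cosg * bhat_a)
    bh <- matrix(bhat[, a], E, K, byrow = TRUE)
    eh <- matrix(ehat[, a], E, K)
    gain[, seq(a, 3L * K, by = 3L)] <- S1 * bh + S2 * (eh - cosg * bh)
  }
  gain
}

#' Average reference
#'
#' Subtracts the mean over channels. For a matrix, channels are rows and the
#' per-column (per-source) channel mean is removed. Idempotent.
#'
#' @param potentials Numeric vector (one value per channel) or matrix
#'   (channels x sources).
#' @return Same shape as the input, re-referenced to the average.
#' @examples
#' apply_average_reference(c(1, 2, 3))
#' @export
apply_average_reference <- function(potentials) {
  if (is.matrix(potentials)) {
    if (nrow(potentials) < 2L) stop("average reference needs at least 2 channels")
    sweep(potentials, 2L, colMeans(potentials))
  } else {
    if (length(potentials) < 2L) stop("average reference needs at least 2 channels")
    potentials - mean(potentials)
  }
}

#' Compute a leadfield for a source space
#'
#' Assembles the electrodes x (3 x sources) gain matrix of the multilayer
#' sphere model: column `3(k-1)+a` is the average-referenced potential of a
#' unit dipole (1 A m) along Cartesian axis `a` at source position `k`.
#'
#' @param space A [source_space()] (or an n x 3 matrix of positions, m).
#' @param electrodes An [electrode_array()].
#' @param shells A [shell_model()].
#' @param rtol,n_max Series truncation controls, see
#'   [potential_layered_sphere()].
#' @return An object of class `leadfield`: list with `gain`,
#'   `source_positions`, `electrode_labels`, `conductivities` (named, S/m)
#'   and `reference = "average"`.
#' @export
compute_leadfield <- function(space, electrodes, shells,
                              rtol = 1e-8, n_max = 200L) {
  pos <- if (inherits(space, "source_space")) space$positions else as.matrix(space)
  if (ncol(pos) != 3L) stop("source positions must be an n x 3 matrix")
  if (nrow(pos) == 0L) stop("source space is empty")
  b0 <- sqrt(rowSums(pos^2))
  bad <- which(vapply(b0, function(r) {
    tryCatch({ .source_shell(r, shells); FALSE }, error = function(e) TRUE)
  }, logical(1)))
  if (length(bad) > 0L) {
    stop(sprintf("invalid source positions at indices: %s",
                 paste(utils::head(bad, 20L), collapse = ", ")))
  }
  gain <- .forward_batch(pos, electrodes$positions, shells,
                         rtol = rtol, n_max = n_max)
  gain <- apply_average_reference(gain)
  sig <- shells$conductivities
  names(sig) <- shells$tissue_labels
  structure(
    list(gain = gain,
         source_positions = pos,
         electrode_labels = electrodes$labels,
         conductivities = sig,
         reference = "average"),
    class = "leadfield"
  )
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d electrodes x %d sources (%s reference)\n",
              nrow(x$gain), nrow(x$source_positions), x$reference))
  invisible(x)
}

# 3-column gain block of source k
.gain_block <- function(lf, k) {
  lf$gain[, (3L * (k - 1L) + 1L):(3L * k), drop = FALSE]
}
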