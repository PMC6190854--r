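#' Resolved force state at the focal rim cell
#'
#' Bundles the in-plane (xz-plane) force magnitudes and angles at the focal
#' marginal-crypt-epithelium cell C_e: the pull from the dividing column
#' (`F_C_xz`), the adhesion forces from its right and left rim neighbours
#' (`F_R_xz`, `F_L_xz`) with their angles to the pull axis (`theta1`,
#' `theta2`), and the chain-straightening angle `theta3` at the right
#' neighbour together with the forces it balances (`F_R1_xz`, `F_R2_xz`).
#' Angles are radians. Vertical (y-axis) angles may be supplied for the
#' out-of-plane balance check but are not inverted.
#'
#' @param F_C_xz,F_R_xz,F_L_xz Non-negative in-plane force magnitudes.
#' @param theta1,theta2 Angles in `[0, pi/2]` between the neighbour adhesion
#'   forces and the pull axis.
#' @param theta3 Angle in `[0, pi]` between the two adhesion bonds at the
#'   right neighbour (`pi` = straight chain). Optional.
#' @param F_pulling Extra axial pull recruited once the rim cell column
#'   inclines (default 0).
#' @param F_R1_xz,F_R2_xz Forces balanced across the right neighbour.
#' @param theta_R_y,theta_L_y,theta_C_y Optional angles to the vertical axis.
#' @return An object of class `force_state` (a validated list).
#' @export
force_state <- function(F_C_xz, F_R_xz, F_L_xz, theta1, theta2,
                        theta3 = NA_real_, F_pulling = 0,
                        F_R1_xz = NA_real_, F_R2_xz = NA_real_,
                        theta_R_y = NA_real_, theta_L_y = NA_real_,
                        theta_C_y = NA_real_) {
  mags <- c(F_C_xz = F_C_xz, F_R_xz = F_R_xz, F_L_xz = F_L_xz, F_pulling = F_pulling)
  if (any(!is.finite(mags)) || any(mags < 0))
    stop("force magnitudes must be finite and >= 0", call. = FALSE)
  eps <- 1e-12
  if (!is.finite(theta1) || !is.finite(theta2) ||
      theta1 < -eps || theta1 > pi / 2 + eps || theta2 < -eps || theta2 > pi / 2 + eps)
    stop("theta1 and theta2 must lie in [0, pi/2]", call. = FALSE)
  if (!is.na(theta3) && (theta3 < -eps || theta3 > pi + eps))
    stop("theta3 must lie in [0, pi]", call. = FALSE)
  structure(list(F_C_xz = F_C_xz, F_R_xz = F_R_xz, F_L_xz = F_L_xz,
                 theta1 = theta1, theta2 = theta2, theta3 = theta3,
                 F_pulling = F_pulling, F_R1_xz = F_R1_xz, F_R2_xz = F_R2_xz,
                 theta_R_y = theta_R_y, theta_L_y = theta_L_y,
                 theta_C_y = theta_C_y),
            class = "force_state")
}

#' @export
print.force_state <- function(x, ...) {
  cat(sprintf("<force_state> F_C=%.4g F_R=%.4g F_L=%.4g | theta1=%.2f deg theta2=%.2f deg theta3=%s\n",
              x$F_C_xz, x$F_R_xz, x$F_L_xz, x$theta1 * 180 / pi, x$theta2 * 180 / pi,
              if (is.na(x$theta3)) "NA" else sprintf("%.2f deg", x$theta3 * 180 / pi)))
  invisible(x)
}

#' In-plane force balance residual at the focal rim cell
#'
#' The x-axis equilibrium of the focal cell requires the pull from the
#' dividing column to be matched by the axial components of the two
#' neighbouring adhesion forces: residual
#' `F_C_xz - (F_R_xz*cos(theta1) + F_L_xz*cos(theta2))`, zero at equilibrium.
#'
#' @param state A [force_state()].
#' @return Signed residual force (zero at equilibrium).
#' @export
x_balance_residual <- function(state) {
  stopifnot(inherits(state, "force_state"))
  state$F_C_xz - (state$F_R_xz * cos(state$theta1) + state$F_L_xz * cos(state$theta2))
}

#' Vertical force balance residual
#'
#' Checks the y-axis equilibrium at the focal cell: the extrusion force from
#' the dividing column against the vertical components of the three pulls,
#' each projected with its own angle to the y-axis. The vertical balance is
#' verified, never inverted; it does not drive displacement in the simulator.
#'
#' @param F_ext Extrusion force along y from the dividing column.
#' @param F_R,F_L,F_C Pull magnitudes from the right, left, and crypt-side
#'   neighbours.
#' @param theta_R_y,theta_L_y,theta_C_y Angles of those pulls to the y-axis.
#' @return Signed residual force.
#' @export
y_balance_residual <- function(F_ext, F_R, F_L, F_C, theta_R_y, theta_L_y, theta_C_y) {
  F_ext - (F_R * cos(theta_R_y) + F_L * cos(theta_L_y) + F_C * cos(theta_C_y))
}

#' Symmetric opening angles at a given pull
#'
#' Inverts the x-axis balance under left/right symmetry
#' (`F_R_xz = F_L_xz = F_side`): both neighbour forces make the same angle
#' `theta = acos(F_C / (2 F_side))` with the pull axis. Equal force
#' magnitudes (`F_C = F_side`) give the 120-degree opening,
#' `theta1 + theta2 = 2*pi/3`; the angles close monotonically as the pull
#' grows and no solution exists beyond `F_C = 2 F_side`, where the chain must
#' recruit additional straightening / `F_pulling`.
#'
#' @param F_C Pull magnitude, `0 <= F_C <= 2*F_side`.
#' @param F_side Common neighbour force magnitude (> 0).
#' @return Named numeric vector `c(theta1, theta2)` in radians.
#' @export
solve_symmetric_angles <- function(F_C, F_side) {
  if (!is.finite(F_side) || F_side <= 0) stop("F_side must be > 0", call. = FALSE)
  if (!is.finite(F_C) || F_C < 0) stop("F_C must be >= 0", call. = FALSE)
  if (F_C > 2 * F_side)
    stop("no symmetric solution: F_C exceeds 2*F_side (straightening regime)", call. = FALSE)
  th <- acos(F_C / (2 * F_side))
  c(theta1 = th, theta2 = th)
}

#' Chain-straightening angle at the right neighbour
#'
#' Balances the counterforce transmitted through the right rim neighbour:
#' `F_R1 = F_R2 * cos(pi - theta3)` gives
#' `theta3 = pi - acos(F_R1 / F_R2)`. As the transmitted forces equalize
#' (`F_R1 -> F_R2`) the bond angle straightens, `theta3 -> pi`, which is the
#' mechanism that stretches the opening toward a line.
#'
#' @param F_R1 Transmitted force, `0 <= F_R1 <= F_R2`.
#' @param F_R2 Force along the next bond (> 0).
#' @return `theta3` in radians, in `[pi/2, pi]`.
#' @export
straightening_angle <- function(F_R1, F_R2) {
  if (!is.finite(F_R2) || F_R2 <= 0) stop("F_R2 must be > 0", call. = FALSE)
  if (!is.finite(F_R1) || F_R1 < 0) stop("F_R1 must be >= 0", call. = FALSE)
  if (F_R1 > F_R2) stop("no solution: F_R1 exceeds F_R2", call. = FALSE)
  pi - acos(F_R1 / F_R2)
}

validate_cells <- function(cells) {
  req <- c("cell_id", "x", "y")
  if (!is.data.frame(cells) || !all(req %in% names(cells)))
    stop("`cells` must be a data frame with columns cell_id, x, y", call. = FALSE)
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell_id", call. = FALSE)
  cells
}

validate_junctions <- function(junctions, ids) {
  req <- c("cell_a", "cell_b", "rest_length", "stiffness")
  if (!is.data.frame(junctions) || !all(req %in% names(junctions)))
    stop("`junctions` must have columns cell_a, cell_b, rest_length, stiffness", call. = FALSE)
  if (any(junctions$rest_length <= 0) || any(junctions$stiffness <= 0))
    stop("junction rest_length and stiffness must be > 0", call. = FALSE)
  if (!all(junctions$cell_a %in% ids) || !all(junctions$cell_b %in% ids))
    stop("junction endpoints must be cell ids", call. = FALSE)
  if (any(junctions$cell_a == junctions$cell_b))
    stop("junction endpoints must differ", call. = FALSE)
  junctions
}

# internal: spring + anchor + applied forces and total energy for a
# configuration P (n x 2). A is the m x n signed incidence matrix.
net_forces <- function(P, A, L0, k, Fapp, P0, anchor_k) {
  dvec <- -(A %*% P)                       # P[b,] - P[a,]
  len <- sqrt(rowSums(dvec^2))
  len <- pmax(len, 1e-300)
  coef <- k * (len - L0) / len
  Fspring <- crossprod(A, dvec * coef)     # + on a toward b when stretched
  Fspring + Fapp - anchor_k * (P - P0)
}

total_energy <- function(P, A, L0, k, Fapp, P0, anchor_k) {
  dvec <- -(A %*% P)
  len <- sqrt(rowSums(dvec^2))
  0.5 * sum(k * (len - L0)^2) + 0.5 * anchor_k * sum((P - P0)^2) - sum(Fapp * P)
}

#' Quasi-static relaxation of an adhesion spring network
#'
#' Relaxes a network of point cells joined by Hookean adhesion springs to
#' mechanical equilibrium under applied pulls, by overdamped fixed-point
#' iteration on the net forces with a backtracking line search on the total
#' elastic energy (energy is non-increasing across accepted iterations).
#' Convergence is declared when every free cell's net-force magnitude falls
#' below `tol`. Cells are centres only; the only internal forces are the
#' junction springs (plus optional anchor tethers standing for attachment of
#' the rim to the underlying gland, which also make the equilibrium isolated).
#'
#' @param cells Data frame with columns `cell_id`, `x`, `y` (and optionally
#'   `role`, `column_index`).
#' @param junctions Data frame with columns `cell_a`, `cell_b`,
#'   `rest_length`, `stiffness`.
#' @param applied Optional data frame `cell_id`, `fx`, `fy` of lumped applied
#'   forces (cell-division pulls).
#' @param pinned Optional vector of cell ids held fixed.
#' @param anchor_stiffness Optional tether stiffness to each cell's anchor
#'   position (0 disables anchors).
#' @param anchor_ref Optional anchor positions: a data frame with `cell_id`,
#'   `x`, `y` (or an n x 2 matrix in cell order). Defaults to the starting
#'   positions in `cells`.
#' @param tol Force-residual tolerance for convergence.
#' @param max_iter Iteration cap; exceeding it raises a convergence error
#'   carrying the final residual.
#' @param ce Cell id of the focal rim cell for force resolution; defaults to
#'   the cell with the largest applied force, if any.
#' @return An object of class `ring_equilibrium`: list with the relaxed
#'   `cells`, `iterations`, `residual`, `energy`, per-cell `forces`, and
#'   `force_state` (a [force_state()] at `ce`, or `NULL`).
#' @export
relax_ring <- function(cells, junctions, applied = NULL, pinned = integer(),
                       anchor_stiffness = 0, anchor_ref = NULL,
                       tol = 1e-8, max_iter = 1e5, ce = NULL) {
  cells <- validate_cells(cells)
  junctions <- validate_junctions(junctions, cells$cell_id)
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0", call. = FALSE)
  n <- nrow(cells)
  ids <- cells$cell_id
  ia <- match(junctions$cell_a, ids)
  ib <- match(junctions$cell_b, ids)
  m <- length(ia)

  # connectivity of the junction graph
  comp <- seq_len(n)
  repeat {
    new <- comp
    new[ia] <- pmin(new[ia], comp[ib]); new[ib] <- pmin(new[ib], comp[ia])
    new <- new[new]  # path halving
    if (identical(new, comp)) break
    comp <- new
  }
  if (length(unique(comp)) > 1L)
    stop("junction graph is not connected", call. = FALSE)

  A <- matrix(0, m, n)
  A[cbind(seq_len(m), ia)] <- 1
  A[cbind(seq_len(m), ib)] <- -1
  L0 <- junctions$rest_length
  k <- junctions$stiffness

  P <- cbind(cells$x, cells$y)
  if (is.null(anchor_ref)) {
    P0 <- P
  } else if (is.data.frame(anchor_ref)) {
    idx <- match(ids, anchor_ref$cell_id)
    if (anyNA(idx)) stop("anchor_ref must cover every cell id", call. = FALSE)
    P0 <- cbind(anchor_ref$x[idx], anchor_ref$y[idx])
  } else {
    P0 <- as.matrix(anchor_ref)
    if (!identical(dim(P0), dim(P))) stop("anchor_ref has wrong dimensions", call. = FALSE)
  }
  Fapp <- matrix(0, n, 2)
  if (!is.null(applied) && nrow(as.data.frame(applied)) > 0L) {
    applied <- as.data.frame(applied)
    idx <- match(applied$cell_id, ids)
    if (anyNA(idx)) stop("applied forces reference unknown cell ids", call. = FALSE)
    Fapp[idx, ] <- Fapp[idx, ] + cbind(applied$fx, applied$fy)
  }
  free <- !(ids %in% pinned)

  # overdamped inertial relaxation (FIRE-style adaptive damping) with a
  # monotone-energy safeguard: any step that would raise the total energy is
  # rejected, the pseudo-velocity reset, and the step size halved
  dt <- 0.1 / sqrt(max(k))
  dt_max <- 2 / sqrt(max(k))
  alpha <- alpha0 <- 0.1
  n_pos <- 0L
  V <- matrix(0, n, 2)
  energy <- total_energy(P, A, L0, k, Fapp, P0, anchor_stiffness)
  Fnet <- net_forces(P, A, L0, k, Fapp, P0, anchor_stiffness)
  Fnet[!free, ] <- 0
  res <- if (any(free)) max(sqrt(rowSums(Fnet^2))) else 0
  iter <- 0L
  while (res >= tol) {
    if (iter >= max_iter) {
      cond <- structure(
        class = c("cryptmech_convergence_error", "error", "condition"),
        list(message = sprintf("relax_ring did not converge in %d iterations (residual %.3e)",
                               as.integer(max_iter), res),
             call = sys.call(-1), residual = res))
      stop(cond)
    }
    power <- sum(Fnet * V)
    if (power > 0) {
      n_pos <- n_pos + 1L
      nv <- sqrt(sum(V^2)); nf <- sqrt(sum(Fnet^2))
      if (nf > 0) V <- (1 - alpha) * V + alpha * (nv / nf) * Fnet
      if (n_pos > 5L) {
        dt <- min(dt * 1.1, dt_max)
        alpha <- alpha * 0.99
      }
    } else {
      V[] <- 0
      dt <- dt * 0.5
      alpha <- alpha0
      n_pos <- 0L
    }
    V <- V + dt * Fnet
    V[!free, ] <- 0
    trial <- P + dt * V
    e_trial <- total_energy(trial, A, L0, k, Fapp, P0, anchor_stiffness)
    # non-increase up to rounding noise in the energy evaluation itself
    slack <- 16 * .Machine$double.eps * (abs(energy) + abs(e_trial) + 1)
    if (e_trial <= energy + slack) {
      P <- trial
      energy <- e_trial
    } else {
      V[] <- 0
      dt <- max(dt * 0.5, 1e-12)
      alpha <- alpha0
      n_pos <- 0L
    }
    Fnet <- net_forces(P, A, L0, k, Fapp, P0, anchor_stiffness)
    Fnet[!free, ] <- 0
    res <- max(sqrt(rowSums(Fnet^2)))
    iter <- iter + 1L
  }

  out_cells <- cells
  out_cells$x <- P[, 1L]
  out_cells$y <- P[, 2L]

  # resolve the force state at the focal rim cell
  fs <- NULL
  if (is.null(ce) && any(Fapp != 0)) {
    ce <- ids[which.max(sqrt(rowSums(Fapp^2)))]
  }
  if (!is.null(ce)) {
    fs <- resolve_force_state(P, ids, ia, ib, L0, k, Fapp, ce)
  }

  structure(list(cells = out_cells, iterations = iter, residual = res,
                 energy = energy, forces = Fnet, force_state = fs,
                 converged = TRUE),
            class = "ring_equilibrium")
}

#' @export
print.ring_equilibrium <- function(x, ...) {
  cat(sprintf("<ring_equilibrium> %d cells, %d iterations, residual %.3e, energy %.6g\n",
              nrow(x$cells), x$iterations, x$residual, x$energy))
  if (!is.null(x$force_state)) print(x$force_state)
  invisible(x)
}

# internal: resolved forces and angles at the focal rim cell.
resolve_force_state <- function(P, ids, ia, ib, L0, k, Fapp, ce) {
  i <- match(ce, ids)
  if (is.na(i)) stop("`ce` is not a cell id", call. = FALSE)
  fa <- Fapp[i, ]
  F_C <- sqrt(sum(fa^2))
  u <- if (F_C > 0) fa / F_C else c(1, 0)    # pull axis

  on_e <- which(ia == i | ib == i)
  if (length(on_e) < 2L) return(NULL)
  # junction force on ce from each incident bond
  bond_force <- function(e) {
    j <- if (ia[e] == i) ib[e] else ia[e]
    d <- P[j, ] - P[i, ]
    len <- sqrt(sum(d^2))
    list(other = j, vec = k[e] * (len - L0[e]) * d / len, dir = d / len, edge = e)
  }
  bf <- lapply(on_e, bond_force)
  # right neighbour: positive side of the pull axis (left-handed otherwise)
  side <- vapply(bf, function(b) u[1L] * b$dir[2L] - u[2L] * b$dir[1L], 0)
  ord <- order(side)
  bR <- bf[[ord[1L]]]; bL <- bf[[ord[length(ord)]]]

  ang_to <- function(v, ref) {
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(NA_real_)
    acos(max(-1, min(1, sum(v * ref) / nv)))
  }
  th1 <- ang_to(bR$vec, -u)
  th2 <- ang_to(bL$vec, -u)
  F_R <- sqrt(sum(bR$vec^2)); F_L <- sqrt(sum(bL$vec^2))

  # straightening angle at the right neighbour C_R: angle between its bond
  # back to ce and its bond onward to C_s-R
  jR <- bR$other
  on_r <- setdiff(which(ia == jR | ib == jR), bR$edge)
  th3 <- NA_real_; F_R1 <- NA_real_; F_R2 <- NA_real_
  if (length(on_r) >= 1L) {
    e2 <- on_r[1L]
    j2 <- if (ia[e2] == jR) ib[e2] else ia[e2]
    v1 <- P[i, ] - P[jR, ]
    v2 <- P[j2, ] - P[jR, ]
    th3 <- ang_to(v1, v2 / sqrt(sum(v2^2)))
    F_R1 <- F_R
    len2 <- sqrt(sum(v2^2))
    F_R2 <- abs(k[e2] * (len2 - L0[e2]))
  }
  force_state(F_C_xz = F_C, F_R_xz = F_R, F_L_xz = F_L,
              theta1 = min(th1, pi / 2), theta2 = min(th2, pi / 2),
              theta3 = th3, F_pulling = F_C, F_R1_xz = F_R1, F_R2_xz = F_R2)
}

#' Opening angle sum at the focal cell of a relaxed ring
#'
#' Convenience accessor: `theta1 + theta2` (radians) from a relaxed ring's
#' force state, the quantity that closes from ~pi toward 0 as the pull grows.
#'
#' @param eq A `ring_equilibrium` from [relax_ring()].
#' @return Numeric angle sum in radians (or `NA` if no focal cell resolved).
#' @export
opening_angle_sum <- function(eq) {
  stopifnot(inherits(eq, "ring_equilibrium"))
  if (is.null(eq$force_state)) return(NA_real_)
  eq$force_state$theta1 + eq$force_state$theta2
}
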