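# Independent oracles used across the suite. The equilibrium oracle minimizes
# the total spring energy directly with stats::optim (BFGS, analytic
# gradient) and shares no code with the package's damped fixed-point
# relaxation.

oracle_equilibrium <- function(cells, junctions, applied = NULL,
                               pinned = integer(), anchor_stiffness = 0,
                               anchor_ref = NULL) {
  ids <- cells$cell_id
  n <- nrow(cells)
  ia <- match(junctions$cell_a, ids)
  ib <- match(junctions$cell_b, ids)
  L0 <- junctions$rest_length
  k <- junctions$stiffness
  Pstart <- cbind(cells$x, cells$y)
  Pref <- if (is.null(anchor_ref)) Pstart else {
    idx <- match(ids, anchor_ref$cell_id)
    cbind(anchor_ref$x[idx], anchor_ref$y[idx])
  }
  Fapp <- matrix(0, n, 2)
  if (!is.null(applied)) {
    idx <- match(applied$cell_id, ids)
    Fapp[idx, ] <- cbind(applied$fx, applied$fy)
  }
  free <- which(!(ids %in% pinned))

  unpack <- function(theta) {
    P <- Pstart
    P[free, ] <- matrix(theta, ncol = 2)
    P
  }
  energy <- function(theta) {
    P <- unpack(theta)
    d <- P[ib, , drop = FALSE] - P[ia, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    0.5 * sum(k * (len - L0)^2) +
      0.5 * anchor_stiffness * sum((P - Pref)^2) - sum(Fapp * P)
  }
  grad <- function(theta) {
    P <- unpack(theta)
    d <- P[ib, , drop = FALSE] - P[ia, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    coef <- k * (len - L0) / len
    G <- matrix(0, n, 2)
    for (e in seq_along(ia)) {
      G[ia[e], ] <- G[ia[e], ] - coef[e] * d[e, ]
      G[ib[e], ] <- G[ib[e], ] + coef[e] * d[e, ]
    }
    G <- G + anchor_stiffness * (P - Pref) - Fapp
    as.vector(G[free, ])
  }
  fit <- stats::optim(as.vector(Pstart[free, ]), energy, grad, method = "BFGS",
                      control = list(maxit = 10000, reltol = 1e-16))
  # polish with a second start from the BFGS solution
  fit <- stats::optim(fit$par, energy, grad, method = "BFGS",
                      control = list(maxit = 10000, reltol = 1e-16))
  P <- unpack(fit$par)
  out <- cells
  out$x <- P[, 1L]
  out$y <- P[, 2L]
  out
}

# random convex (hence simple) polygon rescaled to a fixed perimeter
random_simple_polygon <- function(n_vertices, perimeter = 2 * pi) {
  th <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, 0.5, 1.5)
  pts <- cbind(r * cos(th), r * sin(th))
  ct <- contour_xy(pts)
  p <- sum(sqrt(rowSums((ct$points[c(2:nrow(ct$points), 1L), ] - ct$points)^2)))
  contour_xy(ct$points * (perimeter / p))
}

max_position_diff <- function(a, b) {
  max(sqrt((a$x - b$x)^2 + (a$y - b$y)^2))
}
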