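#' Bending strain at height y above the neutral surface
#'
#' For a thin epithelial sheet bent to radius of curvature `R`, material at
#' signed height `y` from the neutral surface carries longitudinal strain
#' `y / R`: positive on the stretched (basal) side, negative on the
#' compressed (luminal) side, zero on the neutral surface itself.
#'
#' @param y Signed height above the neutral surface.
#' @param R Radius of curvature (nonzero).
#' @return Dimensionless strain `y / R`.
#' @export
bending_strain <- function(y, R) {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R == 0)
    stop("R must be a nonzero finite radius", call. = FALSE)
  y / R
}

#' Second moment of area about the neutral (centroidal) axis
#'
#' Numerically integrates `I = integral of y^2 dA` for a planar section
#' described by its width profile `w(y)`, using midpoint quadrature with grid
#' doubling and Richardson extrapolation until the relative change is below
#' `tol`. By default the axis is placed at the section centroid (the neutral
#' surface of a small bend); passing a numeric `axis` evaluates the second
#' moment about that line instead (parallel-axis shifts can only increase I).
#'
#' @param width Either a function of `y` returning the section width, or a
#'   data frame / matrix with columns `y` and `width` to be interpolated
#'   linearly.
#' @param lower,upper Integration limits in `y` (required when `width` is a
#'   function; inferred from the data otherwise).
#' @param axis `NULL` for the centroidal axis, or a numeric `y` position.
#' @param tol Relative convergence tolerance of the refinement loop.
#' @return Second moment of area (length^4).
#' @examples
#' moment_of_inertia(function(y) rep(1, length(y)), -0.5, 0.5)  # ~ 1/12
#' @export
moment_of_inertia <- function(width, lower = NULL, upper = NULL, axis = NULL,
                              tol = 1e-8) {
  if (is.data.frame(width) || is.matrix(width)) {
    tab <- as.data.frame(width)
    if (!all(c("y", "width") %in% names(tab)))
      stop("sampled profile needs columns `y` and `width`", call. = FALSE)
    if (is.null(lower)) lower <- min(tab$y)
    if (is.null(upper)) upper <- max(tab$y)
    wf <- stats::approxfun(tab$y, tab$width, rule = 2)
  } else if (is.function(width)) {
    if (is.null(lower) || is.null(upper))
      stop("`lower` and `upper` are required with a width function", call. = FALSE)
    wf <- width
  } else stop("`width` must be a function or a sampled profile", call. = FALSE)
  if (!is.finite(lower) || !is.finite(upper) || upper <= lower)
    stop("invalid integration limits", call. = FALSE)

  quad <- function(f, n) {
    h <- (upper - lower) / n
    y <- lower + (seq_len(n) - 0.5) * h
    sum(f(y)) * h
  }
  refine <- function(f) {
    n <- 64L
    prev <- quad(f, n)
    repeat {
      n <- n * 2L
      cur <- quad(f, n)
      rich <- cur + (cur - prev) / 3   # midpoint rule is O(h^2)
      if (abs(cur - prev) <= tol * max(abs(rich), 1e-300) || n >= 2^21) return(rich)
      prev <- cur
    }
  }

  area <- refine(function(y) wf(y))
  if (!is.finite(area) || area <= 0)
    stop("section has zero or negative area", call. = FALSE)
  y0 <- if (is.null(axis)) refine(function(y) y * wf(y)) / area else axis
  refine(function(y) (y - y0)^2 * wf(y))
}

#' Bending moment of a sheet of flexural rigidity E*I at curvature 1/R
#'
#' `tau = E * I / R`, the resultant of the Hookean stress distribution
#' `E*y/R` integrated over the section (consistent with integrating
#' `E/R * y^2 dA` directly).
#'
#' @param E Young's modulus (> 0).
#' @param I Second moment of area (> 0).
#' @param R Radius of curvature (nonzero).
#' @return Bending moment.
#' @export
bending_moment <- function(E, I, R) {
  if (!is.finite(E) || E <= 0 || !is.finite(I) || I <= 0)
    stop("E and I must be positive", call. = FALSE)
  if (!is.finite(R) || R == 0) stop("R must be a nonzero radius", call. = FALSE)
  E * I / R
}

#' Euler critical load of a pinned epithelial segment
#'
#' The axial load above which a pinned-pinned elastic column of flexural
#' rigidity `E*I` and end-to-end length `Lc` buckles:
#' `F_crit = pi^2 * E * I / Lc^2`. In the crypt model this is the force scale
#' at which the epithelial sheet would bend toward rupture, and therefore the
#' threshold at which the EMT feedback engages. The critical load is
#' independent of the (small) deflection amplitude.
#'
#' @param E Young's modulus (> 0).
#' @param I Second moment of area (> 0).
#' @param Lc End-to-end connecting length (> 0); the buckle wavelength equals
#'   `Lc`, taken as twice the segment length `l`.
#' @return Critical axial force.
#' @export
euler_critical_force <- function(E, I, Lc) {
  vals <- c(E = E, I = I, Lc = Lc)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("E, I and Lc must be positive", call. = FALSE)
  pi^2 * E * I / Lc^2
}

#' First buckling mode shape of the pinned segment
#'
#' `y_p = K_mode * sin(pi * x_p / Lc)`: zero at both pinned ends, maximal
#' (`K_mode`) at midspan, and satisfying the small-deflection beam equation
#' `y'' = -(pi/Lc)^2 * y` at the critical load.
#'
#' @param K_mode Mode amplitude.
#' @param Lc Segment end-to-end length (> 0).
#' @param x_p Axial positions in `[0, Lc]` (vectorized).
#' @return Deflections `y_p` at `x_p`.
#' @export
mode_shape <- function(K_mode, Lc, x_p) {
  if (!is.finite(Lc) || Lc <= 0) stop("Lc must be positive", call. = FALSE)
  if (any(!is.finite(x_p)) || any(x_p < 0) || any(x_p > Lc))
    stop("x_p must lie in [0, Lc]", call. = FALSE)
  K_mode * sin(pi * x_p / Lc)
}

#' Finite-difference residual of the mode shape in the beam equation
#'
#' Samples the sine mode on a regular grid and returns the maximum absolute
#' residual of the centred second difference against `-(pi/Lc)^2 * y_p`.
#' Small residuals confirm the sine profile solves the linearized
#' beam-buckling equation at the Euler load.
#'
#' @param K_mode Mode amplitude.
#' @param Lc Segment length (> 0).
#' @param n_samples Number of grid points (>= 5).
#' @return Maximum absolute residual over interior grid points.
#' @export
mode_ode_residual <- function(K_mode, Lc, n_samples = 1000L) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 5L) stop("n_samples must be >= 5", call. = FALSE)
  x <- seq(0, Lc, length.out = n_samples)
  h <- x[2L] - x[1L]
  y <- mode_shape(K_mode, Lc, x)
  i <- 2:(n_samples - 1L)
  d2 <- (y[i - 1L] - 2 * y[i] + y[i + 1L]) / h^2
  max(abs(d2 + (pi / Lc)^2 * y[i]))
}

#' Critical load of a discrete pinned chain (stiffness-matrix route)
#'
#' Independent discrete route to the Euler load: an `n_segments`-link pinned
#' chain with bending stiffness `E*I` has quadratic bending energy
#' `K_b = E*I*h * C'C` (C the second-difference operator at interior nodes)
#' and geometric softening `G = h * D'D` under axial load; the critical load
#' is the smallest generalized eigenvalue of `K_b v = F G v`, i.e. the load
#' at which the transverse stiffness `K_b - F*G` loses positive-definiteness.
#' Converges to [euler_critical_force()] at rate O(1/n^2).
#'
#' @param n_segments Number of links (>= 3).
#' @param E,I,Lc As in [euler_critical_force()].
#' @return Discrete critical load.
#' @export
discrete_chain_critical_load <- function(n_segments, E, I, Lc) {
  n_segments <- as.integer(n_segments)
  if (n_segments < 3L) stop("n_segments must be >= 3", call. = FALSE)
  vals <- c(E = E, I = I, Lc = Lc)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("E, I and Lc must be positive", call. = FALSE)
  h <- Lc / n_segments
  ni <- n_segments - 1L                      # interior nodes; ends pinned at 0
  # second differences at interior nodes (pinned ends contribute zeros)
  C <- matrix(0, ni, ni)
  diag(C) <- -2
  if (ni > 1L) {
    C[cbind(1:(ni - 1L), 2:ni)] <- 1
    C[cbind(2:ni, 1:(ni - 1L))] <- 1
  }
  C <- C / h^2
  # first differences over the n segments
  D <- matrix(0, n_segments, ni)
  D[cbind(1:ni, 1:ni)] <- 1
  D[cbind(2:(ni + 1L), 1:ni)] <- D[cbind(2:(ni + 1L), 1:ni)] - 1
  D <- D / h
  Kb <- E * I * h * crossprod(C)
  G <- h * crossprod(D)
  # generalized symmetric eigenproblem via Cholesky of G
  L <- chol(G)
  M <- backsolve(L, t(backsolve(L, Kb, transpose = TRUE)), transpose = TRUE)
  M <- (M + t(M)) / 2
  min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
}

#' Critical load detected from a finite-amplitude buckle
#'
#' Energy-balance detection of the critical load from a deflected profile of
#' finite amplitude: the profile `K_mode * sin(pi*x/Lc)` is evaluated with
#' the exact (nonlinear) curvature and arc length, giving bending energy
#' `U = E*I/2 * integral(kappa^2 ds)` and end shortening
#' `delta = integral(sqrt(1 + y'^2) - 1) dx` of an inextensible sheet; the
#' load at which axial work matches bending energy is `U / delta`. As
#' `K_mode -> 0` this tends to the Euler load; for small amplitudes the
#' detected load is amplitude-independent to O((K_mode*pi/Lc)^2).
#'
#' @param K_mode Finite mode amplitude (> 0).
#' @param Lc Segment length (> 0).
#' @param E,I Material parameters (> 0).
#' @param n_samples Quadrature points (midpoint rule).
#' @return Detected critical load.
#' @export
critical_load_from_amplitude <- function(K_mode, Lc, E, I, n_samples = 4000L) {
  if (!is.finite(K_mode) || K_mode <= 0) stop("K_mode must be > 0", call. = FALSE)
  vals <- c(E = E, I = I, Lc = Lc)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("E, I and Lc must be positive", call. = FALSE)
  n <- as.integer(n_samples)
  h <- Lc / n
  x <- (seq_len(n) - 0.5) * h
  b <- K_mode * pi / Lc
  yp <- b * cos(pi * x / Lc)                   # y'
  ypp <- -K_mode * (pi / Lc)^2 * sin(pi * x / Lc)  # y''
  U <- 0.5 * E * I * sum(ypp^2 / (1 + yp^2)^(5 / 2)) * h
  delta <- sum(sqrt(1 + yp^2) - 1) * h
  U / delta
}
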