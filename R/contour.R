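#' Closed planar contour
#'
#' Constructs a closed 2D contour from an ordered set of vertices. Contours
#' represent crypt-opening outlines in the plane of the mucosal surface.
#' Vertices are stored counter-clockwise (the input is reoriented if its
#' signed shoelace area is negative); a duplicated closing vertex is dropped.
#'
#' @param x Numeric vector of x coordinates, or a two-column matrix /
#'   data frame of coordinates.
#' @param y Numeric vector of y coordinates (ignored when `x` is two-column).
#' @param closed Logical; open contours are accepted by the constructor but
#'   rejected by the shape metrics.
#' @return An object of class `crypt_contour`: a list with elements `points`
#'   (an n x 2 matrix) and `closed`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 64 + 1)[-1]
#' circ <- contour_xy(cos(th), sin(th))
#' isoperimetric_ratio(circ)
#' @export
contour_xy <- function(x, y = NULL, closed = TRUE) {
  if (is.null(y)) {
    m <- as.matrix(x)
    if (ncol(m) != 2L) stop("contour input must have two coordinate columns", call. = FALSE)
    x <- as.numeric(m[, 1L]); y <- as.numeric(m[, 2L])
  }
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  pts <- cbind(x = as.numeric(x), y = as.numeric(y))
  if (!all(is.finite(pts))) stop("contour coordinates must be finite", call. = FALSE)
  n <- nrow(pts)
  # drop an explicit closing vertex
  if (closed && n > 1L && all(pts[1L, ] == pts[n, ])) {
    pts <- pts[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (closed && n < 3L) stop("a closed contour needs at least 3 distinct points", call. = FALSE)
  nxt <- c(seq_len(n)[-1L], 1L)
  dup <- rowSums((pts - pts[nxt, , drop = FALSE])^2) == 0
  if (!closed) dup[n] <- FALSE
  if (any(dup)) stop("contour has consecutive duplicate points", call. = FALSE)
  if (closed && shoelace_area(pts) < 0) pts <- pts[rev(seq_len(n)), , drop = FALSE]
  structure(list(points = pts, closed = isTRUE(closed)), class = "crypt_contour")
}

#' @export
print.crypt_contour <- function(x, ...) {
  cat(sprintf("<crypt_contour> %d vertices, %s\n", nrow(x$points),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

as_contour <- function(x) {
  if (inherits(x, "crypt_contour")) return(x)
  contour_xy(x)
}

# signed area by the shoelace formula (positive = counter-clockwise)
shoelace_area <- function(pts) {
  n <- nrow(pts)
  nxt <- c(seq_len(n)[-1L], 1L)
  sum(pts[, 1L] * pts[nxt, 2L] - pts[nxt, 1L] * pts[, 2L]) / 2
}

# centroid of the enclosed region (shoelace moments)
area_centroid <- function(pts) {
  n <- nrow(pts)
  nxt <- c(seq_len(n)[-1L], 1L)
  cr <- pts[, 1L] * pts[nxt, 2L] - pts[nxt, 1L] * pts[, 2L]
  a <- sum(cr) / 2
  if (a == 0) return(colMeans(pts))
  cx <- sum((pts[, 1L] + pts[nxt, 1L]) * cr) / (6 * a)
  cy <- sum((pts[, 2L] + pts[nxt, 2L]) * cr) / (6 * a)
  c(cx, cy)
}

contour_perimeter <- function(pts) {
  n <- nrow(pts)
  nxt <- c(seq_len(n)[-1L], 1L)
  sum(sqrt(rowSums((pts[nxt, , drop = FALSE] - pts)^2)))
}

#' Isoperimetric ratio of a closed contour
#'
#' Computes 4*pi*A / P^2, the classical circularity measure. By the
#' isoperimetric inequality the ratio lies in (0, 1] and equals 1 only for a
#' circle; it decreases as the crypt opening stretches toward a line.
#'
#' @param contour A [contour_xy()] object (or coordinates coercible to one).
#' @return Dimensionless ratio in (0, 1].
#' @export
isoperimetric_ratio <- function(contour) {
  contour <- as_contour(contour)
  if (!contour$closed) stop("isoperimetric ratio is defined for closed contours only", call. = FALSE)
  a <- abs(shoelace_area(contour$points))
  p <- contour_perimeter(contour$points)
  if (a <= 0 || p <= 0) stop("degenerate contour: zero area or perimeter", call. = FALSE)
  4 * pi * a / p^2
}

#' Shape descriptors of a closed contour
#'
#' Returns the metrics used to grade crypt-opening morphology: the
#' isoperimetric ratio, the aspect ratio of the extents along the principal
#' axes of the vertex second-moment matrix, the maximal extent, and a
#' dimensionless asymmetry (offset of the enclosed-area centroid from the
#' midpoint of the major-axis extent, relative to that extent), which
#' separates teardrop outlines from symmetric ovals.
#'
#' When the two second-moment eigenvalues tie, the principal axis closer to
#' the x-axis is taken, so the metrics are deterministic. Both ratio metrics
#' are invariant to rigid motion and uniform scaling.
#'
#' @param contour A [contour_xy()] object (or coordinates coercible to one).
#' @return A list with `isoperimetric_ratio`, `aspect_ratio` (>= 1),
#'   `max_width`, and `asymmetry`.
#' @export
shape_metrics <- function(contour) {
  contour <- as_contour(contour)
  if (!contour$closed) stop("shape metrics are defined for closed contours only", call. = FALSE)
  pts <- contour$points
  ctr <- colMeans(pts)
  d <- sweep(pts, 2L, ctr)
  M <- crossprod(d) / nrow(d)
  if (!all(is.finite(M)) || sum(diag(M)) <= 0)
    stop("degenerate contour: vertices coincide", call. = FALSE)
  eg <- eigen(M, symmetric = TRUE)
  if (abs(eg$values[1L] - eg$values[2L]) <= 1e-12 * sum(abs(eg$values))) {
    # tie: choose the axis closer to x
    ax <- if (abs(eg$vectors[1L, 1L]) >= abs(eg$vectors[1L, 2L])) eg$vectors[, 1L] else eg$vectors[, 2L]
    major <- ax
  } else {
    major <- eg$vectors[, 1L]
  }
  minor <- c(-major[2L], major[1L])
  pr_major <- d %*% major
  pr_minor <- d %*% minor
  e1 <- diff(range(pr_major))
  e2 <- diff(range(pr_minor))
  if (min(e1, e2) <= 0) stop("degenerate contour: zero extent", call. = FALSE)
  if (e2 > e1) { tmp <- pr_major; pr_major <- pr_minor; pr_minor <- tmp }
  # offset of the enclosed-area centroid from the midpoint of the major extent
  ac <- area_centroid(pts)
  c_major <- sum((ac - ctr) * (if (e1 >= e2) major else minor))
  mid <- mean(range(pr_major))
  asym <- 2 * abs(c_major - mid) / max(e1, e2)
  list(
    isoperimetric_ratio = isoperimetric_ratio(contour),
    aspect_ratio = max(e1, e2) / min(e1, e2),
    max_width = max(e1, e2),
    asymmetry = asym
  )
}

#' Idealized L-shaped tubular gland
#'
#' Builds the centerline-plus-circular-sections model of a gastric gland in
#' the ideal state: a vertical pit of depth `pit_depth` perpendicular to the
#' mucosal surface, joined at a sharp right angle to a horizontal gland
#' segment of length `gland_length` running parallel to the surface. Every
#' cross-section is a sampled circle of the segment's radius, so its
#' isoperimetric ratio is 1 up to discretization.
#'
#' @param pit_radius,gland_radius Positive radii of the pit and gland tubes.
#' @param pit_depth,gland_length Positive axial lengths of the two segments.
#' @param n_circumference Number of vertices per cross-section circle (>= 3).
#' @param n_axial Number of cross-sections along the centerline (>= 3).
#' @return An object of class `l_tube`: list with `sections` (each holding
#'   `center` and `axis` in 3D, `radius`, `arclength`, and a planar
#'   `contour`), the input geometry, and `turn_angle` (radians) between the
#'   first and last axis directions.
#' @export
build_l_tube <- function(pit_radius, gland_radius, pit_depth, gland_length,
                         n_circumference = 36L, n_axial = 30L) {
  for (nm in c("pit_radius", "gland_radius", "pit_depth", "gland_length")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a positive length", nm), call. = FALSE)
  }
  n_circumference <- as.integer(n_circumference)
  n_axial <- as.integer(n_axial)
  if (n_circumference < 3L || n_axial < 3L)
    stop("sampling counts must be >= 3", call. = FALSE)

  total <- pit_depth + gland_length
  s <- (seq_len(n_axial) - 0.5) / n_axial * total   # midpoints along the axis
  th <- (seq_len(n_circumference) - 1L) / n_circumference * 2 * pi
  circ <- function(r) contour_xy(r * cos(th), r * sin(th))

  sections <- lapply(s, function(si) {
    if (si <= pit_depth) {
      list(center = c(0, -si, 0), axis = c(0, -1, 0), radius = pit_radius,
           segment = "pit", arclength = si, contour = circ(pit_radius))
    } else {
      list(center = c(si - pit_depth, -pit_depth, 0), axis = c(1, 0, 0),
           radius = gland_radius, segment = "gland", arclength = si,
           contour = circ(gland_radius))
    }
  })
  a1 <- sections[[1L]]$axis
  a2 <- sections[[length(sections)]]$axis
  turn <- acos(max(-1, min(1, sum(a1 * a2))))
  structure(list(sections = sections,
                 pit_radius = pit_radius, gland_radius = gland_radius,
                 pit_depth = pit_depth, gland_length = gland_length,
                 n_circumference = n_circumference, n_axial = n_axial,
                 turn_angle = turn),
            class = "l_tube")
}

#' @export
print.l_tube <- function(x, ...) {
  cat(sprintf("<l_tube> pit %.3g (r=%.3g) + gland %.3g (r=%.3g), %d sections, turn %.1f deg\n",
              x$pit_depth, x$pit_radius, x$gland_length, x$gland_radius,
              length(x$sections), x$turn_angle * 180 / pi))
  invisible(x)
}
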