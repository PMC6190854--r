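#' Simulation configuration
#'
#' Assembles and validates the configuration of a crypt-opening run. The
#' defaults are the package's reference study conditions: dimensionless
#' mechanics with all unit scales at 1, a 24-cell marginal-crypt-epithelium
#' ring with unit adhesion springs, flexural parameters `E = 1`, `I = 1`,
#' `Lc = 2` (the buckle wavelength equals `Lc`, twice the one-cell segment
#' length), a per-division force increment of 5% of the Euler load, a viscous
#' drag `F_v = 0.5` per division, and exponential depth attenuation with rate
#' 0.5 over 5 cross-sections.
#'
#' @param n_divisions Number of stem-cell divisions to simulate (>= 0).
#' @param delta_F_per_division Force added to the rim-cell pull per division;
#'   default `0.05 * euler_critical_force(E, I, Lc)`.
#' @param ring_size Number of cells on the marginal crypt epithelium ring.
#' @param K_spring Hooke constant of the hysteresis ledger spring.
#' @param F_v Constant viscous force per division event (>= 0).
#' @param E,I,Lc Flexural parameters of the epithelial sheet (see
#'   [euler_critical_force()]).
#' @param n_cross_sections Number of depth cross-sections `m`.
#' @param attenuation_lambda Exponential decay rate of displacement per depth
#'   index (> 0).
#' @param emt_tolerance_band Fractional band `epsilon` above the Euler load
#'   that the EMT feedback tolerates, in (0, 1).
#' @param seed Integer seed (fixture generation; the mechanics core is
#'   deterministic).
#' @param A_L_schedule Numeric vector of added-cell lengths per depth
#'   cross-section (recycled defaults to zeros).
#' @param emt_enabled Logical; cap the pull at the Euler load via EMT.
#' @param anchor_stiffness Tether stiffness of each rim cell to its reference
#'   position (attachment to the underlying gland).
#' @param relax_tol Force residual tolerance of the per-step relaxation.
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_divisions = 200L,
                       delta_F_per_division = NULL,
                       ring_size = 24L,
                       K_spring = 1,
                       F_v = 0.5,
                       E = 1,
                       I = 1,
                       Lc = 2,
                       n_cross_sections = 5L,
                       attenuation_lambda = 0.5,
                       emt_tolerance_band = 0.05,
                       seed = 1L,
                       A_L_schedule = NULL,
                       emt_enabled = TRUE,
                       anchor_stiffness = 0.02,
                       relax_tol = 1e-6) {
  chk_pos <- function(v, nm, strict = TRUE) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || (strict && v <= 0) || (!strict && v < 0))
      stop(sprintf("invalid config value for `%s`", nm), call. = FALSE)
    v
  }
  n_divisions <- as.integer(n_divisions)
  if (is.na(n_divisions) || n_divisions < 0) stop("invalid config value for `n_divisions`", call. = FALSE)
  ring_size <- as.integer(ring_size)
  if (is.na(ring_size) || ring_size < 4L) stop("invalid config value for `ring_size`", call. = FALSE)
  K_spring <- chk_pos(K_spring, "K_spring")
  F_v <- chk_pos(F_v, "F_v", strict = FALSE)
  E <- chk_pos(E, "E"); I <- chk_pos(I, "I"); Lc <- chk_pos(Lc, "Lc")
  n_cross_sections <- as.integer(n_cross_sections)
  if (is.na(n_cross_sections) || n_cross_sections < 1L)
    stop("invalid config value for `n_cross_sections`", call. = FALSE)
  attenuation_lambda <- chk_pos(attenuation_lambda, "attenuation_lambda")
  if (!is.numeric(emt_tolerance_band) || emt_tolerance_band <= 0 || emt_tolerance_band >= 1)
    stop("invalid config value for `emt_tolerance_band`", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("invalid config value for `seed`", call. = FALSE)
  F_crit <- euler_critical_force(E, I, Lc)
  if (is.null(delta_F_per_division)) delta_F_per_division <- 0.05 * F_crit
  delta_F_per_division <- chk_pos(delta_F_per_division, "delta_F_per_division")
  if (is.null(A_L_schedule)) A_L_schedule <- rep(0, n_cross_sections)
  if (!is.numeric(A_L_schedule) || any(!is.finite(A_L_schedule)) || any(A_L_schedule < 0))
    stop("invalid config value for `A_L_schedule`", call. = FALSE)
  A_L_schedule <- rep_len(A_L_schedule, n_cross_sections)
  anchor_stiffness <- chk_pos(anchor_stiffness, "anchor_stiffness", strict = FALSE)
  relax_tol <- chk_pos(relax_tol, "relax_tol")
  structure(list(n_divisions = n_divisions,
                 delta_F_per_division = delta_F_per_division,
                 ring_size = ring_size, K_spring = K_spring, F_v = F_v,
                 E = E, I = I, Lc = Lc,
                 n_cross_sections = n_cross_sections,
                 attenuation_lambda = attenuation_lambda,
                 emt_tolerance_band = emt_tolerance_band,
                 seed = seed, A_L_schedule = A_L_schedule,
                 emt_enabled = isTRUE(emt_enabled),
                 anchor_stiffness = anchor_stiffness,
                 relax_tol = relax_tol,
                 F_crit = F_crit),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  divisions: %d, delta_F: %.4g (F_crit = %.4g), EMT %s (band %.2g)\n",
              x$n_divisions, x$delta_F_per_division, x$F_crit,
              if (x$emt_enabled) "on" else "off", x$emt_tolerance_band))
  cat(sprintf("  ring: %d cells, K_spring %.3g, F_v %.3g, anchors %.3g\n",
              x$ring_size, x$K_spring, x$F_v, x$anchor_stiffness))
  cat(sprintf("  depth: %d sections, lambda %.3g\n", x$n_cross_sections,
              x$attenuation_lambda))
  invisible(x)
}

#' Fresh simulation state
#'
#' Builds the initial state of a run: the MCE ring at rest (unit cell
#' spacing), the focal rim cell `C_e` on the +x axis, the antipodal cell
#' pinned (gland-side attachment), zero pull and empty ledgers.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_state`.
#' @export
new_sim_state <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fx <- make_fixture("ring", params = list(n = config$ring_size, spacing = 1),
                     seed = config$seed)
  n <- config$ring_size
  structure(list(step = 0L,
                 F_C_xz = 0,
                 y_p = 0,
                 cells = fx$cells,
                 junctions = fx$junctions,
                 ce = fx$cells$cell_id[1L],
                 pinned = fx$cells$cell_id[n %/% 2L + 1L],
                 ref_cells = fx$cells,
                 ledger_events = list(),
                 emt_events = list(),
                 n_emt_last_step = 0L,
                 force_state = NULL,
                 residual = 0,
                 forces = NULL),
            class = "sim_state")
}

#' EMT force-limiting feedback
#'
#' The phenomenological epithelial-mesenchymal-transition rule: whenever the
#' rim-cell pull exceeds the Euler critical load, an EMT event fires, the
#' buckle deflection `y_p` is reduced in proportion to the required force
#' drop, and the pull is brought back to the critical load — so after
#' burn-in the pull always stays within `F_crit * (1 + epsilon)`. With the
#' feedback disabled the state passes through unchanged.
#'
#' @param state A `sim_state`.
#' @param config A [sim_config()].
#' @return The state with capped `F_C_xz`, reduced `y_p`, and any new events
#'   appended to `state$emt_events`.
#' @export
emt_feedback <- function(state, config) {
  stopifnot(inherits(state, "sim_state"), inherits(config, "sim_config"))
  state$n_emt_last_step <- 0L
  if (!config$emt_enabled) return(state)
  F_crit <- config$F_crit
  if (state$F_C_xz > F_crit) {
    y_before <- state$y_p
    y_after <- y_before * F_crit / state$F_C_xz
    ev <- data.frame(step = state$step, cell_id = state$ce,
                     force_at_trigger = state$F_C_xz,
                     y_p_before = y_before, y_p_after = y_after)
    state$emt_events <- c(state$emt_events, list(ev))
    state$n_emt_last_step <- 1L
    state$y_p <- y_after
    state$F_C_xz <- F_crit
  }
  state
}

#' One division step of the crypt simulator
#'
#' A single stem-cell division at the focal column: the pull on the rim cell
#' grows by `delta_F_per_division` and the buckle deflection by a small
#' increment, the EMT feedback caps the pull at the Euler load (if enabled),
#' the ring is relaxed to the new equilibrium, and the viscoelastic ledger
#' records the stretch/recovery pair for this division.
#'
#' @param state A `sim_state` (from [new_sim_state()] or a previous step).
#' @param config A [sim_config()].
#' @return The advanced `sim_state`.
#' @export
sim_step <- function(state, config) {
  stopifnot(inherits(state, "sim_state"), inherits(config, "sim_config"))
  state$step <- state$step + 1L
  state$F_C_xz <- state$F_C_xz + config$delta_F_per_division
  state$y_p <- state$y_p + 0.01 * config$Lc
  state <- emt_feedback(state, config)

  applied <- data.frame(cell_id = state$ce, fx = state$F_C_xz, fy = 0)
  # warm start from the previous equilibrium; anchors stay tied to the
  # reference (initial) ring so equilibria do not depend on the path taken
  eq <- relax_ring(state$cells, state$junctions, applied = applied,
                   pinned = state$pinned,
                   anchor_stiffness = config$anchor_stiffness,
                   anchor_ref = state$ref_cells,
                   tol = config$relax_tol, max_iter = 2e5, ce = state$ce)
  state$cells <- eq$cells
  state$force_state <- eq$force_state
  state$residual <- eq$residual
  state$forces <- eq$forces

  state$ledger_events <- c(state$ledger_events,
                           list(c(F = state$F_C_xz, K_spring = config$K_spring,
                                  F_v = config$F_v)))
  state
}

state_contour <- function(state) {
  contour_xy(state$cells$x, state$cells$y)
}

#' Default shape-classification thresholds
#'
#' The documented threshold table used by [classify_opening()]. A contour is
#' `round` while nearly circular, `oval` once visibly elongated, `droplet`
#' past aspect 1.6, and `linear` past aspect 8 (the stretched-line regime);
#' `groove` is reserved for lattice compositions of neighbouring linear
#' openings (see [compose_groove()]).
#'
#' @param round_aspect Aspect ratio below which (with high circularity) the
#'   opening is `round`.
#' @param round_iso Minimum isoperimetric ratio of a `round` opening.
#' @param droplet_aspect Aspect ratio at which an elongated opening becomes a
#'   `droplet`.
#' @param linear_aspect Aspect ratio of the `linear` (stretched-line) class.
#' @return Named list of thresholds.
#' @export
opening_thresholds <- function(round_aspect = 1.15, round_iso = 0.9,
                               droplet_aspect = 1.6, linear_aspect = 8) {
  list(round_aspect = round_aspect, round_iso = round_iso,
       droplet_aspect = droplet_aspect, linear_aspect = linear_aspect)
}

#' Ordered opening-shape classes
#'
#' The morphological sequence the model traverses as the pull grows; labels
#' only ever move forward along this ordering in a run with monotone force
#' growth.
#'
#' @return Character vector of class labels, least to most deformed.
#' @export
opening_class_order <- function() c("round", "oval", "droplet", "linear", "groove")

#' Classify an opening contour
#'
#' Deterministic thresholding of the shape metrics onto the morphological
#' classes seen under magnifying endoscopy: `round`/`oval` (fundic),
#' `droplet` (transitional), `linear` (pyloric-type stretched line).
#'
#' @param metrics A list from [shape_metrics()] (fields `isoperimetric_ratio`
#'   and `aspect_ratio`; `asymmetry` is reported but the classes are ordered
#'   by elongation alone so a run's label sequence is monotone).
#' @param thresholds Threshold table from [opening_thresholds()].
#' @return A single label (see [opening_class_order()]).
#' @export
classify_opening <- function(metrics, thresholds = opening_thresholds()) {
  a <- metrics$aspect_ratio
  iso <- metrics$isoperimetric_ratio
  if (!is.finite(a) || a < 1) stop("invalid metrics: aspect_ratio must be >= 1", call. = FALSE)
  if (a >= thresholds$linear_aspect) return("linear")
  if (a >= thresholds$droplet_aspect) return("droplet")
  if (a >= thresholds$round_aspect || iso < thresholds$round_iso) return("oval")
  "round"
}

#' Compose neighbouring linear openings into a reticular groove
#'
#' A single pit can at most reach the `linear` class; the reticular groove of
#' the antral mucosa arises when the linear openings of neighbouring gland
#' columns line up on the mucosal lattice. This rendering convention labels a
#' composition of two or more `linear` openings as `groove` and otherwise
#' returns the most deformed member label.
#'
#' @param labels Character vector of opening labels of the composed pits.
#' @return A single composite label.
#' @export
compose_groove <- function(labels) {
  ord <- opening_class_order()
  if (!all(labels %in% ord)) stop("unknown opening label", call. = FALSE)
  if (length(labels) >= 2L && all(labels == "linear")) return("groove")
  ord[max(match(labels, ord))]
}

#' Depth attenuation profile of the accumulated displacement
#'
#' Distributes the surface net displacement `S_x` over the `m`-indexed depth
#' cross-sections of the pit. Deformation decays with distance from the
#' marginal crypt epithelium (Saint-Venant attenuation), modelled as
#' `S_x_m = S_x * exp(-lambda * m) + A_L[m]`, where `A_L` is the length of
#' cells added near the replication zone at each depth by stress-induced
#' differentiation of neighbouring columns. The profile must be strictly
#' decreasing in `m`; an `A_L` schedule that breaks monotonicity is a
#' configuration error. `D_L` is an opaque strictly increasing per-depth
#' auxiliary length (depth index plus cumulative added-cell length).
#'
#' @param ledger A `displacement_ledger` (its accumulated `S_x` is used) or a
#'   single positive number `S_x`.
#' @param config A [sim_config()] supplying `n_cross_sections`,
#'   `attenuation_lambda` and `A_L_schedule`.
#' @return Data frame with columns `m` (0-based depth index), `S_x_m`, `A_L`,
#'   `D_L`.
#' @export
depth_profile <- function(ledger, config) {
  stopifnot(inherits(config, "sim_config"))
  S_x <- if (inherits(ledger, "displacement_ledger")) attr(ledger, "S_x") else as.numeric(ledger)
  if (length(S_x) != 1L || !is.finite(S_x) || S_x <= 0)
    stop("depth profile requires a positive accumulated displacement S_x", call. = FALSE)
  lambda <- config$attenuation_lambda
  if (!is.finite(lambda) || lambda <= 0)
    stop("attenuation_lambda must be > 0", call. = FALSE)
  m <- 0:(config$n_cross_sections - 1L)
  A_L <- config$A_L_schedule
  S_x_m <- S_x * exp(-lambda * m) + A_L
  if (any(diff(S_x_m) >= 0))
    stop("config error: A_L_schedule breaks the strict depth decrease of S_x", call. = FALSE)
  D_L <- m + cumsum(A_L)
  data.frame(m = m, S_x_m = S_x_m, A_L = A_L, D_L = D_L)
}

#' Run the crypt-opening simulator
#'
#' Drives the full model: repeated stem-cell divisions load the focal rim
#' cell, the ring relaxes quasi-statically after each division, the EMT
#' feedback caps the pull at the Euler critical load, the viscoelastic ledger
#' accumulates the irreversible displacement, and the depth profile spreads
#' it down the pit. The trajectory records force, net displacement, shape
#' metrics, and the morphological class at every step; with monotone force
#' growth the class sequence moves one way along
#' round -> oval -> droplet -> linear.
#'
#' @param config A [sim_config()].
#' @param thresholds Classification thresholds ([opening_thresholds()]).
#' @param n_checkpoints Number of steps at which the full contour is kept.
#' @return An object of class `crypt_sim`: list with `trajectory` (one row
#'   per step, including step 0), `ledger` (a `displacement_ledger`),
#'   `emt_events`, `depth` (or `NULL` when no net displacement accumulated),
#'   `contours` (named by step), `final_state`, `F_crit`, `config`, and
#'   `thresholds`.
#' @examples
#' \donttest{
#' fit <- run_crypt_sim(sim_config(n_divisions = 20))
#' summary(fit)
#' }
#' @export
run_crypt_sim <- function(config = sim_config(), thresholds = opening_thresholds(),
                          n_checkpoints = 20L) {
  stopifnot(inherits(config, "sim_config"))
  state <- new_sim_state(config)
  keep <- unique(round(seq(0, config$n_divisions, length.out = min(n_checkpoints + 1L, config$n_divisions + 1L))))

  rows <- vector("list", config$n_divisions + 1L)
  contours <- list()
  record <- function(state, s_x) {
    ct <- state_contour(state)
    met <- shape_metrics(ct)
    data.frame(step = state$step, F_C_xz = state$F_C_xz, S_x = s_x,
               label = classify_opening(met, thresholds),
               iso_ratio = met$isoperimetric_ratio,
               aspect_ratio = met$aspect_ratio,
               n_emt_events = state$n_emt_last_step)
  }
  rows[[1L]] <- record(state, 0)
  if (0 %in% keep) contours[["0"]] <- state_contour(state)

  for (i in seq_len(config$n_divisions)) {
    state <- sim_step(state, config)
    rows[[i + 1L]] <- record(state, NA_real_)
    if (i %in% keep) contours[[as.character(i)]] <- state_contour(state)
  }

  trajectory <- do.call(rbind, rows)
  ev <- if (length(state$ledger_events)) {
    as.data.frame(do.call(rbind, state$ledger_events))
  } else data.frame(F = numeric(), K_spring = numeric(), F_v = numeric())
  ledger <- accumulate_displacement(ev)
  # the trajectory's displacement column *is* the ledger's running sum
  trajectory$S_x <- c(0, ledger$S_x_cumulative)
  emt <- if (length(state$emt_events)) do.call(rbind, state$emt_events) else
    data.frame(step = integer(), cell_id = integer(), force_at_trigger = numeric(),
               y_p_before = numeric(), y_p_after = numeric())
  depth <- if (attr(ledger, "S_x") > 0) depth_profile(ledger, config) else NULL

  structure(list(trajectory = trajectory, ledger = ledger, emt_events = emt,
                 depth = depth, contours = contours, final_state = state,
                 F_crit = config$F_crit, config = config,
                 thresholds = thresholds),
            class = "crypt_sim")
}

#' @export
print.crypt_sim <- function(x, ...) {
  tr <- x$trajectory
  last <- tr[nrow(tr), ]
  cat("Crypt-opening elastic simulation\n")
  cat(sprintf("  %d divisions | F_C_xz: %.4g (F_crit %.4g) | EMT events: %d\n",
              x$config$n_divisions, last$F_C_xz, x$F_crit, nrow(x$emt_events)))
  cat(sprintf("  opening: %s (iso %.4g, aspect %.4g) | net displacement S_x = %.4g\n",
              last$label, last$iso_ratio, last$aspect_ratio, attr(x$ledger, "S_x")))
  invisible(x)
}

#' @export
summary.crypt_sim <- function(object, ...) {
  tr <- object$trajectory
  labs <- factor(tr$label, levels = opening_class_order())
  out <- list(
    n_divisions = object$config$n_divisions,
    F_crit = object$F_crit,
    final_force = tr$F_C_xz[nrow(tr)],
    max_force = max(tr$F_C_xz),
    final_label = tr$label[nrow(tr)],
    label_counts = table(labs),
    first_step_of_label = vapply(levels(labs), function(l) {
      w <- which(tr$label == l)
      if (length(w)) tr$step[w[1L]] else NA_integer_
    }, integer(1)),
    S_x = attr(object$ledger, "S_x"),
    n_emt_events = nrow(object$emt_events),
    final_iso = tr$iso_ratio[nrow(tr)],
    final_aspect = tr$aspect_ratio[nrow(tr)],
    depth = object$depth
  )
  class(out) <- "summary.crypt_sim"
  out
}

#' @export
print.summary.crypt_sim <- function(x, ...) {
  cat("Crypt-opening simulation summary\n")
  cat(sprintf("  divisions: %d | Euler load F_crit = %.6g | max force = %.6g\n",
              x$n_divisions, x$F_crit, x$max_force))
  cat(sprintf("  EMT events: %d | accumulated net displacement S_x = %.6g\n",
              x$n_emt_events, x$S_x))
  cat(sprintf("  final opening: %s (iso ratio %.4g, aspect ratio %.4g)\n",
              x$final_label, x$final_iso, x$final_aspect))
  cat("  first step reaching each class:\n")
  fs <- x$first_step_of_label
  for (l in names(fs)) if (!is.na(fs[[l]])) cat(sprintf("    %-8s step %d\n", l, fs[[l]]))
  if (!is.null(x$depth)) {
    cat("  depth profile (S_x by cross-section):\n")
    print(x$depth, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.crypt_sim <- function(object, ...) {
  cfg <- object$config
  c(F_crit = object$F_crit,
    delta_F_per_division = cfg$delta_F_per_division,
    K_spring = cfg$K_spring, F_v = cfg$F_v,
    E = cfg$E, I = cfg$I, Lc = cfg$Lc,
    attenuation_lambda = cfg$attenuation_lambda,
    emt_tolerance_band = cfg$emt_tolerance_band,
    anchor_stiffness = cfg$anchor_stiffness)
}

#' @export
residuals.crypt_sim <- function(object, ...) {
  f <- object$final_state$forces
  if (is.null(f)) return(numeric(nrow(object$final_state$cells)))
  sqrt(rowSums(f^2))
}

#' @importFrom stats simulate
#' @export
simulate.crypt_sim <- function(object, nsim = 1, seed = NULL, ...) {
  cfg <- object$config
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    ci <- cfg
    if (!is.null(seed)) ci$seed <- as.integer(seed) + i - 1L
    out[[i]] <- run_crypt_sim(ci, thresholds = object$thresholds)
  }
  if (nsim == 1L) out[[1L]] else out
}

#' @export
plot.crypt_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  tr <- x$trajectory

  # contour evolution
  pts <- lapply(x$contours, function(ct) ct$points)
  rng <- apply(do.call(rbind, pts), 2L, range)
  graphics::plot(NA, xlim = rng[, 1L], ylim = rng[, 2L], asp = 1,
                 xlab = "x", ylab = "z", main = "opening contour")
  cols <- grDevices::hcl.colors(length(pts), "viridis")
  for (i in seq_along(pts)) {
    p <- pts[[i]]
    graphics::polygon(p[, 1L], p[, 2L], border = cols[i])
  }

  graphics::plot(tr$step, tr$F_C_xz, type = "l", xlab = "division",
                 ylab = "F_C_xz", main = "rim-cell pull")
  graphics::abline(h = x$F_crit, lty = 2)
  graphics::plot(tr$step, tr$iso_ratio, type = "l", ylim = c(0, 1),
                 xlab = "division", ylab = "ratio", main = "shape metrics")
  graphics::lines(tr$step, pmin(tr$aspect_ratio / max(tr$aspect_ratio), 1), lty = 3)
  graphics::legend("left", legend = c("isoperimetric", "aspect (scaled)"),
                   lty = c(1, 3), bty = "n", cex = 0.8)
  graphics::plot(tr$step, tr$S_x, type = "l", xlab = "division",
                 ylab = "S_x", main = "net displacement")
  invisible(x)
}
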