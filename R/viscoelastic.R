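#' Hookean stretch displacement of the rim cell under one division
#'
#' The pull `F` transmitted to the focal rim cell by one cell division
#' stretches it against the adhesion spring: `S_n = |F| / K_spring`
#' (magnitudes; the restoring direction is carried as a sign convention, not
#' in the value).
#'
#' @param F Applied force (any sign; magnitude is used).
#' @param K_spring Hooke constant of the effective adhesion spring (> 0).
#' @return Stretch displacement `S_n >= 0`.
#' @export
stretch_displacement <- function(F, K_spring) {
  if (!is.finite(K_spring) || K_spring <= 0)
    stop("K_spring must be > 0", call. = FALSE)
  abs(F) / K_spring
}

#' Lossy recovery distance after one division
#'
#' After the pull relaxes, the cell creeps back against a constant viscous
#' drag `F_v`. Energy balance in magnitudes: the stretch work
#' `W_n = |F| * S_n` is spent on the return path against the drag plus the
#' spring, `W_n = (F_v + K_spring * S_n) * S0_n`, so the recovered distance is
#' `S0_n = W_n / (F_v + K_spring * S_n)`. Recovery is complete (`S0 = S`)
#' only when `F_v = 0`; any viscosity leaves a permanent net displacement
#' `S_n - S0_n > 0` — the hysteresis that lets the tissue "remember" the
#' stretched shape.
#'
#' @param F Applied force.
#' @param K_spring Hooke constant (> 0).
#' @param F_v Constant viscous force per event (>= 0).
#' @return Recovered distance `S0_n`, with `0 <= S0_n <= S_n`.
#' @export
recovery_distance <- function(F, K_spring, F_v) {
  if (!is.finite(F_v) || F_v < 0) stop("F_v must be >= 0", call. = FALSE)
  S <- stretch_displacement(F, K_spring)
  if (S == 0) return(0)
  if (F_v == 0) return(S)   # algebraic lossless limit: W / (K*S) = S exactly
  W <- abs(F) * S
  W / (F_v + K_spring * S)
}

#' Accumulate the division-by-division displacement ledger
#'
#' Runs the stretch/recovery cycle for an ordered sequence of division
#' events and accumulates the net displacement
#' `S_x = sum over n of (S_n - S0_n)`. Per event the ledger records the
#' stretch `S_n`, the recovered distance `S0_n`, the net increment, the
#' running sum, and the dissipated energy `W_n - K_spring*S0_n^2/2`
#' (never negative). `S_x` is non-decreasing in `n`, strictly increasing
#' exactly when `F_v > 0` and `F != 0`.
#'
#' @param events A data frame with columns `F`, `K_spring`, `F_v` (one row
#'   per division), or a list of length-3 vectors `(F, K_spring, F_v)`.
#' @return An object of class `displacement_ledger`: a data frame with
#'   columns `n, F, K_spring, F_v, S_n, S0_n, net, S_x_cumulative` and
#'   attributes `S_x` (final net displacement) and `dissipated` (per-event
#'   dissipated energy).
#' @examples
#' accumulate_displacement(data.frame(F = 1, K_spring = 1, F_v = 1)[rep(1, 10), ])
#' @export
accumulate_displacement <- function(events) {
  if (is.list(events) && !is.data.frame(events)) {
    events <- do.call(rbind, lapply(events, function(e) {
      e <- as.numeric(e)
      if (length(e) != 3L) stop("each event must be (F, K_spring, F_v)", call. = FALSE)
      data.frame(F = e[1L], K_spring = e[2L], F_v = e[3L])
    }))
  }
  if (is.null(events) || nrow(events) == 0L) {
    led <- data.frame(n = integer(), F = numeric(), K_spring = numeric(),
                      F_v = numeric(), S_n = numeric(), S0_n = numeric(),
                      net = numeric(), S_x_cumulative = numeric())
    return(structure(led, S_x = 0, dissipated = numeric(),
                     class = c("displacement_ledger", "data.frame")))
  }
  if (!all(c("F", "K_spring", "F_v") %in% names(events)))
    stop("`events` needs columns F, K_spring, F_v", call. = FALSE)
  n <- nrow(events)
  S <- mapply(stretch_displacement, events$F, events$K_spring)
  S0 <- mapply(recovery_distance, events$F, events$K_spring, events$F_v)
  net <- S - S0
  W <- abs(events$F) * S
  diss <- W - 0.5 * events$K_spring * S0^2
  led <- data.frame(n = seq_len(n), F = events$F, K_spring = events$K_spring,
                    F_v = events$F_v, S_n = S, S0_n = S0, net = net,
                    S_x_cumulative = cumsum(net))
  structure(led, S_x = sum(net), dissipated = diss,
            class = c("displacement_ledger", "data.frame"))
}

#' @export
print.displacement_ledger <- function(x, ...) {
  cat(sprintf("<displacement_ledger> %d events, S_x = %.6g\n", nrow(x), attr(x, "S_x")))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  invisible(x)
}
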