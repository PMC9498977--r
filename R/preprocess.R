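# Resampling of a raw exploration to the constant 0.2 s grid that every
# downstream computation uses, plus trimming to the actively touched interval.
# Touch maps are binary, so "interpolation" is a zero-order hold (the map of
# the latest raw sample at or before each grid time); orientation quaternions
# are SLERP-interpolated along the shortest arc.

#' Grid times for a session
#' @noRd
grid_times <- function(t, dt) {
  if (length(t) < 2 || (t[length(t)] - t[1]) <= dt) {
    stop("trial too short: raw samples must span more than dt", call. = FALSE)
  }
  n_steps <- floor((t[length(t)] - t[1]) / dt + 1e-9)
  t[1] + dt * (0:n_steps)
}

#' Resample touch maps onto the constant grid (zero-order hold)
#'
#' Each grid sample takes the touch map of the latest raw sample at or before
#' the grid time, so the grid never contains a map that was not observed and
#' values stay binary.
#'
#' @param session An [icube_session()].
#' @param dt Grid step in seconds (default 0.2).
#' @return Integer matrix, grid samples x 96 cells.
#' @export
interpolate_touch <- function(session, dt = 0.2) {
  g <- grid_times(session$t, dt)
  idx <- findInterval(g + 1e-9, session$t)
  session$touch[idx, , drop = FALSE]
}

#' Resample orientation onto the constant grid via SLERP
#'
#' Grid quaternions are spherical linear interpolations of the bracketing raw
#' quaternions at the proportional parameter, along the shortest great-circle
#' arc; grid times beyond the raw range hold the nearest endpoint.
#'
#' @inheritParams interpolate_touch
#' @return Numeric matrix, grid samples x 4, unit quaternions.
#' @export
interpolate_orientation <- function(session, dt = 0.2) {
  g <- grid_times(session$t, dt)
  t <- session$t
  lo <- pmin(pmax(findInterval(g + 1e-9, t), 1L), length(t) - 1L)
  hi <- lo + 1L
  u <- (g - t[lo]) / (t[hi] - t[lo])
  u <- pmin(pmax(u, 0), 1)
  quat_slerp(session$q[lo, , drop = FALSE], session$q[hi, , drop = FALSE], u)
}

#' Build the constant-rate trial grid
#'
#' Combines [interpolate_touch()] and [interpolate_orientation()] for one
#' annotation window and returns the untrimmed grid; pass the result through
#' [trim_trial()] before computing metrics. Raw gaps longer than
#' `gap_warning_s` are held (the zero-order hold extends across them) with a
#' warning.
#'
#' @inheritParams interpolate_touch
#' @param gap_warning_s Warn when consecutive raw samples are further apart
#'   than this many seconds (default 2).
#' @return A `trial_grid`: list with `dt`, `t0` (absolute time of the first
#'   grid sample), `touch` (T x 96 integer matrix) and `q` (T x 4 matrix).
#' @export
make_trial_grid <- function(session, dt = 0.2, gap_warning_s = 2.0) {
  gaps <- diff(session$t)
  if (length(gaps) && any(gaps > gap_warning_s)) {
    warning(sprintf("raw gap of %.2f s held across (> %.1f s)",
                    max(gaps), gap_warning_s), call. = FALSE)
  }
  structure(
    list(dt = dt, t0 = session$t[1],
         touch = interpolate_touch(session, dt),
         q = interpolate_orientation(session, dt)),
    class = "trial_grid"
  )
}

#' @export
print.trial_grid <- function(x, ...) {
  cat(sprintf("<trial_grid> %d samples at dt = %.3g s, t0 = %.3f s\n",
              nrow(x$touch), x$dt, x$t0))
  invisible(x)
}

#' Trim a trial grid to the actively touched interval
#'
#' Removes leading and trailing grid samples whose total active-cell count
#' (summed over all six faces) is below `min_active_cells`; interior samples
#' are never touched, so the operation is idempotent.
#'
#' @param grid A `trial_grid` from [make_trial_grid()].
#' @param min_active_cells Minimum whole-cube active-cell count for a sample to
#'   anchor the trial (default 2, the criterion used for manual cutting of the
#'   initial and final recording phases).
#' @return The trimmed `trial_grid`, with attributes `trim_start`/`trim_end`
#'   giving the retained grid-index range of the input.
#' @export
trim_trial <- function(grid, min_active_cells = 2) {
  stopifnot(inherits(grid, "trial_grid"))
  active <- rowSums(grid$touch)
  keep <- which(active >= min_active_cells)
  if (!length(keep)) {
    stop("empty trial: no grid sample reaches the minimum active-cell count",
         call. = FALSE)
  }
  i0 <- keep[1]; i1 <- keep[length(keep)]
  if (i1 - i0 + 1 < 2) {
    stop("empty trial: fewer than two grid samples after trimming",
         call. = FALSE)
  }
  out <- structure(
    list(dt = grid$dt, t0 = grid$t0 + (i0 - 1) * grid$dt,
         touch = grid$touch[i0:i1, , drop = FALSE],
         q = grid$q[i0:i1, , drop = FALSE]),
    class = "trial_grid"
  )
  attr(out, "trim_start") <- i0
  attr(out, "trim_end") <- i1
  out
}
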