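# Explorative-touch filtering and the touch-based per-trial metrics.
#
# The filter rests on the simple matching coefficient (SMC) between the 16-cell
# binary maps of a face at consecutive grid samples. Holding touches are stable
# in time (SMC near 1); explorative touches change the activation pattern, so
# at each grid sample the face(s) attaining the lowest SMC with respect to the
# previous sample are taken as explored — unless every face has SMC 1, which
# indicates an untouched cube.

#' Simple matching coefficient of two tactile maps
#'
#' SMC = (M00 + M11) / 16, the fraction of the 16 cells whose binary state
#' agrees between the two maps: 1 is perfect similarity, 0 perfect diversity.
#'
#' @param map_a,map_b Binary vectors of length 16.
#' @return A list of class `smc` with elements `value`, `m00`, `m01`, `m10`,
#'   `m11`.
#' @export
smc <- function(map_a, map_b) {
  if (length(map_a) != 16 || length(map_b) != 16 ||
      !all(map_a %in% c(0, 1)) || !all(map_b %in% c(0, 1))) {
    stop("tactile maps must be binary vectors of length 16", call. = FALSE)
  }
  m11 <- sum(map_a == 1 & map_b == 1)
  m00 <- sum(map_a == 0 & map_b == 0)
  m01 <- sum(map_a == 0 & map_b == 1)
  m10 <- sum(map_a == 1 & map_b == 0)
  structure(list(value = (m00 + m11) / 16,
                 m00 = m00, m01 = m01, m10 = m10, m11 = m11),
            class = "smc")
}

#' @export
print.smc <- function(x, ...) {
  cat(sprintf("SMC = %.4f (m00 %d, m01 %d, m10 %d, m11 %d)\n",
              x$value, x$m00, x$m01, x$m10, x$m11))
  invisible(x)
}

# per-face block column indices
face_cols <- function(f) (f - 1L) * N_CELLS + seq_len(N_CELLS)

# rowsums of a T x 96 matrix within each 16-column face block -> T x 6
face_block_sums <- function(m) {
  out <- matrix(0, nrow(m), N_FACES)
  for (f in seq_len(N_FACES)) {
    out[, f] <- rowSums(m[, face_cols(f), drop = FALSE])
  }
  out
}

#' Classify explorative touches on a trial grid
#'
#' For every grid sample after the first, computes each face's SMC with respect
#' to the previous sample and marks as explored all faces attaining the minimum
#' SMC; when the minimum is 1 (no face changed) the sample carries no explored
#' face. Sample 1 has no predecessor and is not classified.
#'
#' @param grid A trimmed `trial_grid`.
#' @return A tibble of class `exploration_frames` with one row per grid sample
#'   from 2 to T: `grid_index`, `min_smc`, `n_explored`, `face` (lowest-id
#'   explored face, `NA` when none), `active_cells` (active cells summed over
#'   the explored faces at that sample). Attributes `explored` (T-1 x 6 logical
#'   matrix), `smc` (T-1 x 6 per-face SMC), `onsets` (T-1 x 6 per-face counts
#'   of 0 to 1 cell transitions) and `dt` carry the full classification.
#' @export
classify_explorative <- function(grid) {
  stopifnot(inherits(grid, "trial_grid"))
  tch <- grid$touch
  T_ <- nrow(tch)
  if (T_ < 2) stop("trial grid must have at least 2 samples", call. = FALSE)
  cur <- tch[-1, , drop = FALSE]
  prev <- tch[-T_, , drop = FALSE]
  matches <- face_block_sums((cur == prev) * 1)
  smc_m <- matches / N_CELLS
  min_smc <- do.call(pmin, as.data.frame(smc_m))
  explored <- smc_m == min_smc & min_smc < 1
  active_face <- face_block_sums(cur)
  onsets <- face_block_sums((cur == 1 & prev == 0) * 1)
  face <- apply(explored, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  out <- tibble::tibble(
    grid_index = 2:T_,
    min_smc = min_smc,
    n_explored = rowSums(explored),
    face = as.integer(face),
    active_cells = rowSums(active_face * explored)
  )
  attr(out, "explored") <- explored
  attr(out, "smc") <- smc_m
  attr(out, "onsets") <- onsets
  attr(out, "dt") <- grid$dt
  class(out) <- c("exploration_frames", class(out))
  out
}

#' Exploration duration of a trial
#'
#' Time between the first and the last grid sample with at least one active
#' cell anywhere on the cube.
#'
#' @param grid A trimmed `trial_grid`.
#' @return Duration in seconds.
#' @export
exploration_duration <- function(grid) {
  active <- which(rowSums(grid$touch) >= 1)
  if (!length(active)) stop("empty trial: no active samples", call. = FALSE)
  (active[length(active)] - active[1]) * grid$dt
}

#' Number of touches in a trial
#'
#' A touch is a single cell turning on (0 to 1 between consecutive grid
#' samples) on a face explored at that sample.
#'
#' @param frames An `exploration_frames` tibble from [classify_explorative()].
#' @return Integer count of touch onsets.
#' @export
count_touches <- function(frames) {
  sum(attr(frames, "onsets") * attr(frames, "explored"))
}

#' Touch frequency
#'
#' @inheritParams count_touches
#' @param duration Exploration duration in seconds (must be positive).
#' @return Touches per second.
#' @export
touch_frequency <- function(frames, duration) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  count_touches(frames) / duration
}

#' Per-face exploration-duration mean and variability
#'
#' Each physical face accumulates `dt` seconds for every grid sample in which
#' it is an explored face; faces never explored contribute zero. Returns the
#' mean and the sample standard deviation of the six per-face totals.
#'
#' @inheritParams count_touches
#' @return Named list with `per_face` (length-6 seconds), `mean` and `sd`.
#' @export
per_face_duration_stats <- function(frames) {
  dt <- attr(frames, "dt")
  per_face <- colSums(attr(frames, "explored")) * dt
  list(per_face = per_face, mean = mean(per_face), sd = stats::sd(per_face))
}

#' Mean active cells per explored sample
#'
#' Mean over the frames with a non-empty explored-face set and at least one
#' active cell on those faces of the active-cell count on the explored faces.
#'
#' @inheritParams count_touches
#' @return Cells per sample.
#' @export
mean_active_cells <- function(frames) {
  keep <- frames$n_explored > 0 & frames$active_cells > 0
  if (!any(keep)) stop("undefined metric: no explored frames with active cells",
                       call. = FALSE)
  mean(frames$active_cells[keep])
}

#' Mean SMC of the explored faces
#'
#' Mean over the frames with a non-empty explored-face set of the (shared)
#' minimum SMC. Low values indicate rapid change of the touched-cell pattern.
#'
#' @inheritParams count_touches
#' @return Dimensionless value in `[0, 1)`.
#' @export
mean_smc <- function(frames) {
  keep <- frames$n_explored > 0
  if (!any(keep)) stop("undefined metric: no explored frames", call. = FALSE)
  mean(frames$min_smc[keep])
}
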