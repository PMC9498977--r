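# Rotation quantification. The instantaneous angular variation is the angle
# traversed between consecutive grid samples by each of the three unit body
# axes orthogonal to the cube faces. For a body axis with world positions v_t
# and v_{t-1} the per-step angle is
#
#   atan2(|v_t x v_{t-1}|, v_t . v_{t-1}) * 180 / pi
#
# which coincides with arctan of the |cross|/dot quotient on (0, 90) degrees
# while staying well defined at and past 90 degrees. The amount of rotation of
# a trial is the maximum over the three axes of the time-integrated per-step
# angles; rotation speed averages per-axis instantaneous speeds over the
# instants in which the cube is in motion.

#' Per-axis traversal angles between two orientations
#'
#' @param q_t,q_prev Unit quaternions (w, x, y, z), body-to-world.
#' @return Length-3 vector of degrees traversed by the body +X, +Y, +Z axes,
#'   each in `[0, 180]`.
#' @export
axis_delta <- function(q_t, q_prev) {
  if (abs(sum(q_t^2) - 1) > 1e-6 || abs(sum(q_prev^2) - 1) > 1e-6) {
    stop("axis_delta expects unit quaternions", call. = FALSE)
  }
  R_t <- quat_to_matrix(q_t)
  R_p <- quat_to_matrix(q_prev)
  vapply(1:3, function(a) {
    v1 <- R_t[, a]; v0 <- R_p[, a]
    cr <- c(v1[2] * v0[3] - v1[3] * v0[2],
            v1[3] * v0[1] - v1[1] * v0[3],
            v1[1] * v0[2] - v1[2] * v0[1])
    atan2(sqrt(sum(cr^2)), sum(v1 * v0)) * 180 / pi
  }, numeric(1))
}

# vectorized per-step traversal angles for a whole grid: (T-1) x 3 degrees
grid_axis_deltas <- function(grid) {
  R <- quat_to_matrix(grid$q)        # T x 9, columns 1:3 body X, 4:6 Y, 7:9 Z
  T_ <- nrow(R)
  if (T_ < 2) stop("trial grid must have at least 2 samples", call. = FALSE)
  out <- matrix(0, T_ - 1, 3)
  for (a in 1:3) {
    cols <- (a - 1) * 3 + 1:3
    v1 <- R[-1, cols, drop = FALSE]
    v0 <- R[-T_, cols, drop = FALSE]
    dot <- rowSums(v1 * v0)
    cr1 <- v1[, 2] * v0[, 3] - v1[, 3] * v0[, 2]
    cr2 <- v1[, 3] * v0[, 1] - v1[, 1] * v0[, 3]
    cr3 <- v1[, 1] * v0[, 2] - v1[, 2] * v0[, 1]
    out[, a] <- atan2(sqrt(cr1^2 + cr2^2 + cr3^2), dot) * 180 / pi
  }
  out
}

#' Amount of rotation of a trial
#'
#' Integrates the per-step traversal angles of the three body axes over the
#' whole grid and returns the maximum of the three cumulative totals.
#'
#' @param grid A trimmed `trial_grid`.
#' @return Degrees.
#' @export
amount_of_rotation <- function(grid) {
  max(colSums(grid_axis_deltas(grid)))
}

#' Mean rotation speed while in motion
#'
#' Per-step, per-axis speeds are the traversal angles divided by the grid step.
#' An instant counts as in motion when the mean of the three axis speeds
#' exceeds `motion_threshold_dps`; the result is the mean of the per-axis
#' speeds over the three axes and all in-motion instants (0 when no instant
#' qualifies).
#'
#' @param grid A trimmed `trial_grid`.
#' @param motion_threshold_dps Motion threshold in degrees per second
#'   (default 1).
#' @return Degrees per second.
#' @export
rotation_speed <- function(grid, motion_threshold_dps = 1.0) {
  speeds <- grid_axis_deltas(grid) / grid$dt
  moving <- rowMeans(speeds) > motion_threshold_dps
  if (!any(moving)) {
    message("no in-motion instants above the threshold; rotation speed is 0")
    return(0)
  }
  mean(speeds[moving, , drop = FALSE])
}

RELATIVE_LABELS <- c("up", "down", "front", "rear", "left", "right")
ABSOLUTE_LABELS <- c("North", "South", "East", "West", "Up", "Down")

# body-frame outward normals of faces 1..6
FACE_NORMALS <- rbind(
  c(1, 0, 0), c(-1, 0, 0),
  c(0, 1, 0), c(0, -1, 0),
  c(0, 0, 1), c(0, 0, -1)
)

#' Default participant frame
#'
#' World directions of the participant's up and front; the left direction is
#' `up x front` (right-handed). The default declares world +Z as up and world
#' +X as the participant's front.
#'
#' @param up,front Length-3 world vectors (orthogonal, need not be unit).
#' @return List with unit `up`, `front`, `left`.
#' @export
participant_frame <- function(up = c(0, 0, 1), front = c(1, 0, 0)) {
  up <- up / sqrt(sum(up^2))
  front <- front / sqrt(sum(front^2))
  if (abs(sum(up * front)) > 1e-8) {
    stop("up and front must be orthogonal", call. = FALSE)
  }
  left <- c(up[2] * front[3] - up[3] * front[2],
            up[3] * front[1] - up[1] * front[3],
            up[1] * front[2] - up[2] * front[1])
  list(up = up, front = front, left = left)
}

label_dirs_relative <- function(frame) {
  rbind(up = frame$up, down = -frame$up,
        front = frame$front, rear = -frame$front,
        left = frame$left, right = -frame$left)
}

label_dirs_absolute <- function() {
  rbind(North = c(0, 1, 0), South = c(0, -1, 0),
        East = c(1, 0, 0), West = c(-1, 0, 0),
        Up = c(0, 0, 1), Down = c(0, 0, -1))
}

# Greedy bijective assignment of faces to labels by descending dot product of
# the world-frame face normals with the canonical label directions; ties break
# by label order, then face order. Coincides with per-face argmax away from
# degenerate orientations and guarantees a bijection everywhere.
assign_labels <- function(world_normals, dirs) {
  D <- world_normals %*% t(dirs)         # 6 faces x 6 labels
  res <- character(6)
  faces_left <- 1:6
  labels_left <- 1:6
  for (k in 1:6) {
    sub <- D[faces_left, labels_left, drop = FALSE]
    best <- which(sub >= max(sub) - 1e-12, arr.ind = TRUE)
    # ties: lowest label index first, then lowest face index
    best <- best[order(best[, 2], best[, 1]), , drop = FALSE]
    f <- faces_left[best[1, 1]]
    l <- labels_left[best[1, 2]]
    res[f] <- rownames(dirs)[l]
    faces_left <- setdiff(faces_left, f)
    labels_left <- setdiff(labels_left, l)
  }
  res
}

#' Relative and absolute orientation labels of the six faces
#'
#' Assigns each face's world-frame normal the relative label (up, down, front,
#' rear, left, right, in the participant's frame) and the absolute cardinal
#' label (North, South, East, West, Up, Down) of the canonical direction it is
#' most aligned with. Labels are assigned greedily by descending alignment so
#' that both maps are bijections at every orientation; ties break by the fixed
#' label order.
#'
#' @param q Unit quaternion (body-to-world).
#' @param frame A [participant_frame()].
#' @return List with named character vectors `relative` and `absolute`
#'   (element `i` labels face `i`).
#' @export
orientation_labels <- function(q, frame = participant_frame()) {
  world_normals <- FACE_NORMALS %*% t(quat_to_matrix(q))
  list(relative = assign_labels(world_normals, label_dirs_relative(frame)),
       absolute = assign_labels(world_normals, label_dirs_absolute()))
}

#' Relative orientation label of the explored face at each grid sample
#'
#' @param grid A trimmed `trial_grid`.
#' @param frames The matching `exploration_frames`.
#' @param frame A [participant_frame()].
#' @return Character vector aligned with `frames` rows: the relative label of
#'   the (lowest-id) explored face, `NA` for unexplored samples.
#' @export
relative_label_per_sample <- function(grid, frames, frame = participant_frame()) {
  dirs <- label_dirs_relative(frame)
  out <- rep(NA_character_, nrow(frames))
  idx <- which(!is.na(frames$face))
  if (!length(idx)) return(out)
  qsub <- grid$q[frames$grid_index[idx], , drop = FALSE]
  # orientation is piecewise constant in typical explorations: label each
  # distinct orientation once
  key <- apply(round(qsub, 9), 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  lab_by_key <- lapply(which(uniq), function(j) {
    R <- quat_to_matrix(qsub[j, ])
    assign_labels(FACE_NORMALS %*% t(R), dirs)
  })
  names(lab_by_key) <- key[uniq]
  for (j in seq_along(idx)) {
    out[idx[j]] <- lab_by_key[[key[j]]][frames$face[idx[j]]]
  }
  out
}
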