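# Per-trial metric extraction: one row of the thirteen dependent variables per
# exploration. Column names follow the variable list of the statistical stage:
# accuracy, exploration_duration, n_touches, touch_frequency,
# amount_of_rotation, rotation_speed, max_diagonal_score,
# n_different_transitions, duration_per_face, duration_per_face_sd, n_returns,
# mean_active_cells, mean_smc.

HAPTIC_VARIABLES <- c(
  "exploration_duration", "n_touches", "touch_frequency",
  "amount_of_rotation", "rotation_speed", "max_diagonal_score",
  "n_different_transitions", "duration_per_face", "duration_per_face_sd",
  "n_returns", "mean_active_cells", "mean_smc"
)

#' The twelve haptic per-trial variables
#'
#' Column names of the haptic (non-accuracy) dependent variables produced by
#' [trial_metrics()], in the order used by the statistical stage.
#'
#' @return Character vector of length 12.
#' @export
haptic_variables <- function() HAPTIC_VARIABLES

#' Compute the haptic metrics of one exploration
#'
#' Runs the full single-trial pipeline: constant-rate grid, trimming to the
#' touched interval, explorative-touch classification, rotation
#' quantification, episode building and transition scores.
#'
#' @param session An `icube_session` restricted to one exploration window (see
#'   [window_session()]).
#' @param dt Grid step in seconds.
#' @param frame A [participant_frame()].
#' @param min_active_cells Trimming criterion, see [trim_trial()].
#' @return A one-row tibble with the twelve haptic variables.
#' @export
trial_metrics <- function(session, dt = 0.2, frame = participant_frame(),
                          min_active_cells = 2) {
  grid <- trim_trial(make_trial_grid(session, dt = dt),
                     min_active_cells = min_active_cells)
  frames <- classify_explorative(grid)
  labels <- relative_label_per_sample(grid, frames, frame)
  episodes <- build_episodes(frames, labels)
  tm <- transition_matrix(episodes)
  duration <- exploration_duration(grid)
  pf <- per_face_duration_stats(frames)
  tibble::tibble(
    exploration_duration = duration,
    n_touches = count_touches(frames),
    touch_frequency = touch_frequency(frames, duration),
    amount_of_rotation = amount_of_rotation(grid),
    rotation_speed = rotation_speed(grid),
    max_diagonal_score = max_diagonal_score(tm),
    n_different_transitions = n_different_transitions(tm),
    duration_per_face = pf$mean,
    duration_per_face_sd = pf$sd,
    n_returns = n_returns(episodes),
    mean_active_cells = mean_active_cells(frames),
    mean_smc = mean_smc(frames)
  )
}

#' Recognition accuracy per participant
#'
#' Proportion of recall phases whose response matches the ground truth.
#'
#' @param annotations A validated annotation tibble.
#' @return Tibble with `participant_id`, `group`, `accuracy`.
#' @export
accuracy_by_participant <- function(annotations) {
  annotations <- validate_annotations(annotations)
  rec <- annotations[annotations$phase == "recall", ]
  sp <- split(rec, rec$participant_id)
  tibble::tibble(
    participant_id = names(sp),
    group = vapply(sp, function(d) d$group[1], character(1)),
    accuracy = vapply(sp, function(d) mean(d$response == d$truth), numeric(1))
  )
}

#' Metrics table for one session
#'
#' Applies [trial_metrics()] to every annotated exploration window and joins
#' the participant's recognition accuracy.
#'
#' @param session An `icube_session` covering the whole recording.
#' @param annotations A validated annotation tibble for that session.
#' @inheritParams trial_metrics
#' @return Tibble with identifier columns (`participant_id`, `group`,
#'   `trial_index`, `trial_type`), `accuracy`, and the twelve haptic
#'   variables; one row per exploration.
#' @export
session_metrics <- function(session, annotations, dt = 0.2,
                            frame = participant_frame(),
                            min_active_cells = 2) {
  annotations <- validate_annotations(annotations)
  acc <- accuracy_by_participant(annotations)
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    win <- window_session(session, a$t_start, a$t_end)
    m <- trial_metrics(win, dt = dt, frame = frame,
                       min_active_cells = min_active_cells)
    tibble::tibble(
      participant_id = a$participant_id, group = a$group,
      trial_index = a$trial_index, trial_type = a$phase,
      accuracy = acc$accuracy[acc$participant_id == a$participant_id],
      m
    )
  })
  do.call(rbind, rows)
}

#' Metrics table for a simulated or loaded cohort
#'
#' @param cohort A list of per-participant records, each a list with elements
#'   `session` and `annotations` (as produced by [simulate_cohort()]).
#' @inheritParams trial_metrics
#' @return Row-bound [session_metrics()] of every participant.
#' @export
cohort_metrics <- function(cohort, dt = 0.2, frame = participant_frame(),
                           min_active_cells = 2) {
  do.call(rbind, lapply(cohort, function(p) {
    session_metrics(p$session, p$annotations, dt = dt, frame = frame,
                    min_active_cells = min_active_cells)
  }))
}

#' Write a metrics table to CSV
#'
#' Deterministic column order and full double precision, so identical metric
#' tables serialize to byte-identical files.
#'
#' @param metrics A metrics tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  df <- as.data.frame(metrics)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    vapply(x, function(v) formatC(v, format = "g", digits = 17), character(1))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
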