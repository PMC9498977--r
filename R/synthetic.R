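# Scripted exploration-trace simulator. Sessions are generated with known
# ground truth so every pipeline stage can be tested without recordings:
#
# * Irregular sampling: raw timestamps with truncated-Gaussian intervals
#   (mean 0.203 s, SD 0.113 s, floor 0.05 s), the device's published cadence;
#   samples are also forced at every motion-phase boundary so the SLERP
#   reconstruction at 0.2 s lies exactly on the scripted orientation path.
# * Touch dynamics: one holding face carries a constant 2-cell pattern; the
#   explored face's map changes only at the raw samples the 0.2 s zero-order
#   hold will select ("keyframes"), so the changed-cell count per grid step is
#   under direct control. Active-cell counts follow a mean-calibrated bounded
#   birth-death chain; changed-cell counts are steered by an error-diffusion
#   controller so the expected SMC over explored frames equals the target.
# * Rotations: episodes are separated by single-axis rotation segments (an
#   alignment move bringing the next face to the preferred relative
#   orientation with the preset's focus probability, plus net-identity
#   back-and-forth segments that consume the per-trial rotation budget),
#   flanked by short pauses so no grid step spans two segments.

PAUSE_S <- 0.4
LEAD_S <- 1.2

#' Construct a simulation preset
#'
#' @param target_active_cells Mean active cells per explored sample (1..16).
#' @param target_smc Target mean SMC of the explored face per 0.2 s step; must
#'   be at most 0.9 (the explored face changes at least ~1.6 cells per step on
#'   average: one changed cell is the floor of an explorative step, and parity
#'   of the count change forces part of the mass onto two-cell changes) and at
#'   least `1 - target_active_cells / 8` (a map with n active cells can change
#'   at most 2n cells per step).
#' @param total_rotation Target amount of rotation per exploration (degrees).
#' @param rotation_speed Angular speed of rotation segments (degrees/s).
#' @param focus Probability that an inter-episode rotation aligns the next
#'   face with `preferred_label` (drives diagonal transitions).
#' @param preferred_label Relative orientation the participant favors.
#' @param n_episodes Episodes per exploration.
#' @param trial_duration Nominal exploration duration (s).
#' @param accuracy Probability of a correct same/different response.
#' @param trial_jitter_cells SD of the per-exploration active-cells target, as
#'   a fraction of `target_active_cells`.
#' @param trial_jitter_smc Absolute SD of the per-exploration SMC target.
#' @param rotation_jitter Log-scale SD of the mean-preserving lognormal
#'   per-exploration rotation budget.
#' @param duration_slope Slope of log exploration duration on the
#'   per-exploration active-cells z-score (negative values plant the
#'   larger-touch-surface/shorter-exploration coupling).
#' @param duration_log_noise SD of the log-duration noise.
#' @param rest_rate Mean fraction of within-episode steps in which the hand
#'   rests (no cell changes); varies between explorations, giving touch
#'   frequency a component independent of the SMC target.
#' @param dwell_shape Gamma shape of the episode dwell-time weights; small
#'   values concentrate exploration time on few faces (focused, systematic
#'   exploration), large values spread it evenly.
#' @param holding_face Face carrying the constant holding pattern (1..6).
#' @return A list of class `sim_preset`.
#' @export
make_preset <- function(target_active_cells, target_smc, total_rotation,
                        rotation_speed = 25, focus = 0.15,
                        preferred_label = "front", n_episodes = 12,
                        trial_duration = 60, accuracy = 0.75,
                        trial_jitter_cells = 0.25, trial_jitter_smc = 0.025,
                        rotation_jitter = 0.45, duration_slope = -0.057,
                        duration_log_noise = 0.14, rest_rate = 0.10,
                        dwell_shape = 4, holding_face = 6L) {
  if (target_active_cells < 1 || target_active_cells > 16) {
    stop("target_active_cells must lie in [1, 16]", call. = FALSE)
  }
  k_target <- 16 * (1 - target_smc)
  if (k_target > 2 * target_active_cells + 1e-9) {
    stop(sprintf(paste0(
      "target_smc = %g is incompatible with target_active_cells = %g: a ",
      "stationary map with on average n active cells can change at most 2n ",
      "cells per step (complete replacement), so the SMC target must be at ",
      "least 1 - n/8 = %.3f"), target_smc, target_active_cells,
      1 - target_active_cells / 8), call. = FALSE)
  }
  if (target_smc < 0 || k_target < 1.6 - 1e-9) {
    stop(sprintf(paste0(
      "infeasible target_smc = %g: the expected changed-cell count per step, ",
      "16 * (1 - target_smc) = %.2f, must be at least 1.6 (an explorative ",
      "face changes at least one cell per step, and count-change parity puts ",
      "part of the mass on two-cell changes)"), target_smc, k_target),
      call. = FALSE)
  }
  if (rotation_speed <= 0) stop("rotation_speed must be positive", call. = FALSE)
  if (!preferred_label %in% RELATIVE_LABELS) {
    stop("preferred_label must be a relative orientation label", call. = FALSE)
  }
  structure(list(
    target_active_cells = target_active_cells, target_smc = target_smc,
    total_rotation = total_rotation, rotation_speed = rotation_speed,
    focus = focus, preferred_label = preferred_label,
    n_episodes = as.integer(n_episodes), trial_duration = trial_duration,
    accuracy = accuracy, trial_jitter_cells = trial_jitter_cells,
    trial_jitter_smc = trial_jitter_smc, rotation_jitter = rotation_jitter,
    duration_slope = duration_slope, duration_log_noise = duration_log_noise,
    rest_rate = rest_rate, dwell_shape = dwell_shape,
    holding_face = as.integer(holding_face)
  ), class = "sim_preset")
}

#' Group presets with the published exploration profiles
#'
#' Targets are the published group means: active cells per sample 5.24 (CB),
#' 4.32 (LB), 4.14 (SI); mean SMC 0.77, 0.81, 0.80; amount of rotation 560,
#' 517 and 710 degrees; recognition accuracy 72%, 77% and 69%. The remaining
#' fields use the package defaults (60 s explorations, 12 episodes, 25 deg/s
#' rotation segments); focus probabilities and jitter magnitudes are
#' calibrated in the methods vignette.
#'
#' @return Named list of [make_preset()] objects for CB, LB and SI.
#' @export
group_presets <- function() {
  # dwell_shape encodes the focused-exploration profile of the blind groups:
  # concentrated dwell on few faces versus the even spread of the sighted
  list(
    CB = make_preset(5.24, 0.77, 560, accuracy = 0.72, focus = 0.20,
                     dwell_shape = 0.5),
    LB = make_preset(4.32, 0.81, 517, accuracy = 0.77, focus = 0.19,
                     dwell_shape = 1.0),
    SI = make_preset(4.14, 0.80, 710, accuracy = 0.69, focus = 0.15,
                     dwell_shape = 12)
  )
}

# ---- RNG scoping -----------------------------------------------------------

with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- orientation machinery -------------------------------------------------

mat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  quat_normalize(q)
}

# the 24 proper rotations of the cube, as quaternions
cube_group_quats <- function() {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in seq_len(nrow(perms))) {
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      R <- matrix(0, 3, 3)
      R[perms[p, 1], 1] <- s1
      R[perms[p, 2], 2] <- s2
      R[perms[p, 3], 3] <- s3
      if (abs(det(R) - 1) < 1e-9) out[[length(out) + 1]] <- mat_to_quat(R)
    }
  }
  do.call(rbind, out)
}

# ---- active-cell count chain -----------------------------------------------

# stationary distribution: 5-point support around the target, Gaussian base
# weights tilted exp(theta * s) with theta solved so the mean equals the target
count_stationary <- function(lambda) {
  c0 <- round(lambda)
  support <- max(1, c0 - 2):min(16, c0 + 2)
  base <- exp(-(support - lambda)^2 / 2)
  mean_at <- function(theta) {
    w <- base * exp(theta * support)
    sum(w * support) / sum(w) - lambda
  }
  lo <- -12; hi <- 12
  theta <- if (mean_at(lo) >= 0) lo else if (mean_at(hi) <= 0) hi else
    stats::uniroot(mean_at, c(lo, hi), tol = 1e-10)$root
  w <- base * exp(theta * support)
  list(support = support, prob = w / sum(w))
}

count_draw <- function(chain) {
  sample(chain$support, 1, prob = chain$prob)
}

count_step <- function(chain, n) {
  prop <- n + sample(c(-1L, 1L), 1)
  if (!prop %in% chain$support) return(n)
  pi_n <- chain$prob[match(n, chain$support)]
  pi_p <- chain$prob[match(prop, chain$support)]
  if (stats::runif(1) < pi_p / pi_n) prop else n
}

# feasible changed-cell count closest (after error diffusion) to the target
choose_k <- function(net, n_prev, k_target, err) {
  k_min <- if (net %% 2 == 0) max(abs(net), 2L) else max(abs(net), 1L)
  k_max <- min(2L * (16L - n_prev) - net, 2L * n_prev + net)
  if (k_max < k_min) k_max <- k_min  # onset from empty face: k = |net| only
  cand <- seq(k_min, min(k_max, k_min + 12L), by = 2L)
  cand[which.min(abs(err + cand - k_target))]
}

apply_flips <- function(map, net, k) {
  n_on <- (k + net) %/% 2L
  n_off <- (k - net) %/% 2L
  act <- which(map == 1L)
  inact <- which(map == 0L)
  n_on <- min(n_on, length(inact))
  n_off <- min(n_off, length(act))
  if (n_off > 0) map[act[sample.int(length(act), n_off)]] <- 0L
  if (n_on > 0) map[inact[sample.int(length(inact), n_on)]] <- 1L
  attr(map, "n_on") <- n_on
  map
}

# ---- timeline planning -----------------------------------------------------

# One exploration: returns phases (data.frame), segments per gap and the
# planted per-axis rotation totals.
plan_exploration <- function(pr) {
  K <- pr$n_episodes
  faces_pool <- setdiff(1:6, pr$holding_face)
  faces <- integer(K)
  faces[1] <- sample(faces_pool, 1)
  for (k in seq_len(K - 1)) {
    faces[k + 1] <- sample(setdiff(faces_pool, faces[k]), 1)
  }
  q0 <- cube_group_quats()[sample.int(24, 1), ]
  d_pref <- label_dirs_relative(participant_frame())[pr$preferred_label, ]
  world_axes <- diag(3)

  # alignment moves (gap k sits between episodes k and k+1): with the focus
  # probability the cube is rotated so the next face reaches the preferred
  # relative orientation; touch is released during this short move, which is
  # what makes self-transitions of a label possible at all
  aligns <- vector("list", K - 1)
  cum <- c(0, 0, 0)               # planted traversal per body axis
  q_cur <- q0
  for (k in seq_len(max(K - 1, 0))) {
    if (stats::runif(1) < pr$focus) {
      v <- drop(quat_to_matrix(q_cur) %*% FACE_NORMALS[faces[k + 1], ])
      a_dot <- sum(v * d_pref)
      if (a_dot < 1 - 1e-9) {
        if (a_dot < -1 + 1e-9) {
          # antipodal: 180 degrees about a coordinate axis orthogonal to d_pref
          perp <- which(abs(world_axes %*% d_pref) < 0.5)
          u <- world_axes[sample(perp, 1), ]
          ang <- 180
        } else {
          u <- c(v[2] * d_pref[3] - v[3] * d_pref[2],
                 v[3] * d_pref[1] - v[1] * d_pref[3],
                 v[1] * d_pref[2] - v[2] * d_pref[1])
          u <- u / sqrt(sum(u^2))
          ang <- acos(max(-1, min(1, a_dot))) * 180 / pi
        }
        aligns[[k]] <- list(kind = "world", axis = u, angle = ang)
        # contribution: body axes not parallel to u traverse |ang|
        Rb <- quat_to_matrix(q_cur)
        par <- abs(drop(t(Rb) %*% u)) > 0.5
        cum[!par] <- cum[!par] + abs(ang)
        q_cur <- quat_multiply(quat_from_axis_angle(u, ang), q_cur)
      }
    }
  }

  # net-identity fidget pairs consume the remaining rotation budget; the hand
  # keeps exploring the current face through them
  fidgets <- rep(list(list()), max(K - 1, 0))
  if (K >= 2) {
    for (iter in 1:60) {
      deficit <- pr$rot_total - max(cum)
      if (deficit <= 2) break
      a <- which.min(cum)
      delta <- min(80, deficit / 2)
      g <- sample.int(K - 1, 1)
      fidgets[[g]] <- c(fidgets[[g]],
                        list(list(kind = "body", axis = a, angle = delta),
                             list(kind = "body", axis = a, angle = -delta)))
      cum[-a] <- cum[-a] + 2 * delta
    }
  }

  # time budget: shrink fidgets if the duration cannot host them
  seg_time <- function() {
    tot <- 0
    for (k in seq_len(max(K - 1, 0))) {
      tot <- tot + PAUSE_S +
        sum(vapply(fidgets[[k]], function(s) abs(s$angle) / pr$speed + PAUSE_S,
                   numeric(1))) +
        (if (!is.null(aligns[[k]]))
          abs(aligns[[k]]$angle) / pr$speed + PAUSE_S else 0)
    }
    tot
  }
  min_dwell <- 0.8
  budget <- pr$duration - 2 * LEAD_S - seg_time()
  while (budget < K * min_dwell) {
    nf <- vapply(fidgets, length, integer(1))
    if (!any(nf > 0)) break
    g <- which.max(nf)
    drop_idx <- utils::tail(seq_along(fidgets[[g]]), 2)
    a <- fidgets[[g]][[drop_idx[1]]]$axis
    delta <- abs(fidgets[[g]][[drop_idx[1]]]$angle)
    fidgets[[g]] <- fidgets[[g]][-drop_idx]
    cum[-a] <- cum[-a] - 2 * delta
    budget <- pr$duration - 2 * LEAD_S - seg_time()
  }
  if (budget < K * min_dwell) {
    # last resort: no rotation at all in a trial too short to host it
    aligns <- vector("list", max(K - 1, 0))
    fidgets <- rep(list(list()), max(K - 1, 0))
    cum <- c(0, 0, 0)
    budget <- pr$duration - 2 * LEAD_S - seg_time()
  }
  if (budget < K * min_dwell) {
    stop("trial_duration too short for n_episodes at this rotation budget",
         call. = FALSE)
  }
  w <- stats::rgamma(K, pr$dwell_shape, 1)
  dwell <- min_dwell + (budget - K * min_dwell) * w / sum(w)

  # assemble phases: lead, episodes and gaps, trail. Touch is released for
  # the whole gap (the hands turn the cube), so the pre-switch explored label
  # is the episode's own and gap time never enters the explored-frame
  # statistics.
  phases <- list()
  t <- 0
  add <- function(type, dur, face = NA_integer_, seg = NULL, explore = FALSE) {
    phases[[length(phases) + 1]] <<- list(type = type, t0 = t, t1 = t + dur,
                                          face = face, seg = seg,
                                          explore = explore)
    t <<- t + dur
  }
  add("lead", LEAD_S)
  for (k in seq_len(K)) {
    add("episode", dwell[k], face = faces[k], explore = TRUE)
    if (k < K) {
      add("pause", PAUSE_S)
      for (s in fidgets[[k]]) {
        add("rot", abs(s$angle) / pr$speed, seg = s)
        add("pause", PAUSE_S)
      }
      if (!is.null(aligns[[k]])) {
        s <- aligns[[k]]
        add("rot", abs(s$angle) / pr$speed, seg = s, explore = FALSE)
        add("pause", PAUSE_S, explore = FALSE)
      }
    }
  }
  add("trail", LEAD_S)
  list(phases = phases, t_end = t, q0 = q0, faces = faces, cum = cum)
}

# evaluate the scripted orientation at the raw timestamps
orientation_at <- function(plan, pr, t_raw) {
  q <- matrix(0, length(t_raw), 4)
  q_cur <- plan$q0
  for (ph in plan$phases) {
    idx <- which(t_raw >= ph$t0 - 1e-9 & t_raw < ph$t1 - 1e-9)
    if (ph$type == "rot") {
      s <- ph$seg
      u <- if (s$kind == "world") s$axis else
        drop(quat_to_matrix(q_cur) %*% diag(3)[, s$axis])
      rate <- sign(s$angle) * pr$speed
      for (i in idx) {
        q[i, ] <- quat_multiply(
          quat_from_axis_angle(u, rate * (t_raw[i] - ph$t0)), q_cur)
      }
      q_cur <- quat_multiply(quat_from_axis_angle(u, s$angle), q_cur)
    } else {
      if (length(idx)) q[idx, ] <- matrix(q_cur, length(idx), 4, byrow = TRUE)
    }
  }
  q[length(t_raw), ] <- q_cur  # t_end sample
  q
}

raw_timestamps <- function(t_end, boundaries, sampling) {
  if (sampling == "regular") {
    ts <- seq(0, t_end, by = 0.15)
  } else {
    n_guess <- ceiling(t_end / 0.05) + 10
    iv <- stats::rnorm(n_guess, 0.203, 0.113)
    iv <- iv[iv >= 0.05]
    while (sum(iv) < t_end) {
      extra <- stats::rnorm(50, 0.203, 0.113)
      iv <- c(iv, extra[extra >= 0.05])
    }
    ts <- cumsum(c(0, iv))
    ts <- ts[ts <= t_end]
  }
  ts <- sort(unique(round(c(ts, boundaries, t_end), 6)))
  ts[ts <= t_end + 1e-9]
}

# ---- single exploration ----------------------------------------------------

sim_exploration <- function(pr, sampling) {
  plan <- plan_exploration(pr)
  bounds <- unlist(lapply(plan$phases, function(p) p$t0))
  t_raw <- raw_timestamps(plan$t_end, bounds, sampling)
  n_raw <- length(t_raw)
  q_raw <- orientation_at(plan, pr, t_raw)

  # grid the 0.2 s pipeline will build, and the raw samples it selects
  n_steps <- floor((t_raw[n_raw] - t_raw[1]) / 0.2 + 1e-9)
  g <- t_raw[1] + 0.2 * (0:n_steps)
  keyframes <- unique(findInterval(g + 1e-9, t_raw))

  phase_t0 <- vapply(plan$phases, function(p) p$t0, numeric(1))
  phase_of <- findInterval(t_raw + 1e-9, phase_t0)
  ptype <- vapply(plan$phases, function(p) p$type, character(1))
  # touch is released during rotation gaps; only episode phases explore
  expl_face <- rep(NA_integer_, length(plan$phases))
  last_f <- NA_integer_
  for (j in seq_along(plan$phases)) {
    if (ptype[j] == "episode") last_f <- plan$phases[[j]]$face
    expl_face[j] <- if (isTRUE(plan$phases[[j]]$explore)) last_f else NA_integer_
  }

  chain <- count_stationary(pr$lambda)
  k_target <- 16 * (1 - pr$smc)
  err <- 0
  touch <- matrix(0L, n_raw, N_FACES * N_CELLS)
  state <- integer(N_FACES * N_CELLS)
  hold_cells <- (pr$holding_face - 1L) * N_CELLS + sample.int(N_CELLS, 2)
  lead_cell <- hold_cells[1]
  last_face <- NA_integer_
  n_cur <- NA_integer_
  onsets_total <- 0L
  explored_steps <- 0L
  is_key <- logical(n_raw)
  is_key[keyframes] <- TRUE
  first_episode_seen <- FALSE
  trail_cleared <- FALSE

  for (i in seq_len(n_raw)) {
    ph <- phase_of[i]
    tp <- ptype[ph]
    if (is_key[i]) {
      f <- expl_face[ph]
      if (tp == "lead") {
        state[] <- 0L
        state[lead_cell] <- 1L
      } else if (!is.na(f)) {
        cols <- face_cols(f)
        if (!first_episode_seen) {
          # grip: second holding cell arrives with the first explored touch
          state[hold_cells] <- 1L
          first_episode_seen <- TRUE
        }
        new_face <- !identical(f, last_face)
        if (!new_face && stats::runif(1) < pr$rest) {
          touch[i, ] <- state
          next
        }
        map <- state[cols]
        n_prev <- sum(map)
        n_new <- if (new_face) count_draw(chain) else count_step(chain, n_cur)
        net <- n_new - n_prev
        k <- choose_k(net, n_prev, k_target, err)
        err <- err + (k - k_target)
        flipped <- apply_flips(map, net, k)
        state[cols] <- flipped
        onsets_total <- onsets_total + attr(flipped, "n_on")
        explored_steps <- explored_steps + 1L
        n_cur <- sum(state[cols])
        last_face <- f
      } else if (tp == "trail") {
        if (!trail_cleared) {
          state[] <- 0L
          state[lead_cell] <- 1L
          trail_cleared <- TRUE
        } else {
          state[] <- 0L
        }
      }
      # pause / rot keyframes: maps frozen
    }
    touch[i, ] <- state
  }

  # scripted episode ground truth with relative labels from the plan
  ep <- Filter(function(p) p$type == "episode", plan$phases)
  ep_faces <- vapply(ep, function(p) p$face, integer(1))
  ep_t0 <- vapply(ep, function(p) p$t0, numeric(1))
  ep_t1 <- vapply(ep, function(p) p$t1, numeric(1))
  ep_labels <- vapply(seq_along(ep), function(k) {
    i <- which(t_raw >= ep_t0[k] - 1e-9)[1]
    orientation_labels(q_raw[i, ])$relative[ep_faces[k]]
  }, character(1))

  list(
    t = t_raw, touch = touch, q = q_raw, t_end = plan$t_end,
    script = list(
      faces = ep_faces, labels = ep_labels,
      episode_start = ep_t0, episode_end = ep_t1,
      rotation_per_axis = plan$cum, rotation_max = max(plan$cum),
      lambda = pr$lambda, smc = pr$smc, duration = pr$duration,
      onsets = onsets_total, explored_steps = explored_steps
    )
  )
}

# resolve per-exploration parameters from a preset
resolve_trial_params <- function(preset) {
  lambda <- preset$target_active_cells *
    (1 + stats::rnorm(1, 0, preset$trial_jitter_cells))
  lambda <- min(max(lambda, 1.05), 15.9)
  z <- if (preset$trial_jitter_cells > 0) {
    (lambda - preset$target_active_cells) /
      (preset$target_active_cells * preset$trial_jitter_cells)
  } else 0
  smc <- preset$target_smc + stats::rnorm(1, 0, preset$trial_jitter_smc)
  smc <- min(max(smc, 0.3), 0.9)
  duration <- preset$trial_duration *
    exp(preset$duration_slope * z + stats::rnorm(1, 0, preset$duration_log_noise))
  duration <- min(max(duration, 12), preset$trial_duration * 3)
  # mean-preserving lognormal budget: the published rotation contrast is far
  # from significance, implying within-group variability of hundreds of
  # degrees per trial
  sj <- preset$rotation_jitter
  rot <- preset$total_rotation * exp(stats::rnorm(1, 0, sj) - sj^2 / 2)
  rot <- max(rot, 30)
  # episode count scales with the realized duration: short explorations visit
  # fewer faces
  n_ep <- round(preset$n_episodes * duration / preset$trial_duration)
  n_ep <- min(max(n_ep, 3L), 2L * preset$n_episodes)
  rest <- min(max(stats::rnorm(1, preset$rest_rate, 0.10), 0), 0.45)
  list(lambda = lambda, smc = smc, duration = duration, rot_total = rot,
       speed = preset$rotation_speed, focus = preset$focus,
       preferred_label = preset$preferred_label, rest = rest,
       n_episodes = n_ep, dwell_shape = preset$dwell_shape,
       holding_face = preset$holding_face)
}

#' Simulate one participant's session
#'
#' Generates `n_trials` memorization + recall exploration pairs with the
#' statistical structure of the preset, an annotation table (two "different"
#' and one "same" trial per three, responses correct with the preset's
#' accuracy), and the full simulation script (scripted episode sequence,
#' planted rotation totals, per-exploration targets) as ground truth.
#'
#' @param preset A [make_preset()] object.
#' @param seed Integer seed; identical seeds give identical sessions.
#' @param n_trials Number of memorization + recall pairs.
#' @param participant_id,group Labels written into the annotations.
#' @param sampling `"irregular"` draws truncated-Gaussian sampling intervals
#'   (mean 0.203 s, SD 0.113 s, floor 0.05 s); `"regular"` samples every
#'   0.15 s, a noise-free mode in which the pipeline recovers the scripted
#'   episode sequence exactly.
#' @return List with `session` (an `icube_session`), `annotations` (tibble)
#'   and `script` (per-exploration ground-truth list).
#' @export
simulate_session <- function(preset, seed, n_trials = 3,
                             participant_id = "p01", group = "SI",
                             sampling = c("irregular", "regular")) {
  sampling <- match.arg(sampling)
  stopifnot(inherits(preset, "sim_preset"), n_trials >= 1)
  with_local_seed(seed, {
    t_cursor <- 0
    all_t <- list(); all_touch <- list(); all_q <- list()
    ann <- list(); scripts <- list()
    truth_pool <- c(rep(c("different", "different", "same"),
                        length.out = n_trials))
    truth_pool <- sample(truth_pool)
    for (trial in seq_len(n_trials)) {
      for (phase in PHASES) {
        pr <- resolve_trial_params(preset)
        ex <- sim_exploration(pr, sampling)
        all_t[[length(all_t) + 1]] <- ex$t + t_cursor
        all_touch[[length(all_touch) + 1]] <- ex$touch
        all_q[[length(all_q) + 1]] <- ex$q
        truth <- if (phase == "recall") truth_pool[trial] else "none"
        response <- if (phase == "recall") {
          if (stats::runif(1) < preset$accuracy) truth else
            setdiff(c("same", "different"), truth)
        } else "none"
        ann[[length(ann) + 1]] <- tibble::tibble(
          participant_id = participant_id, group = group,
          trial_index = trial, phase = phase,
          t_start = t_cursor, t_end = t_cursor + ex$t_end,
          response = response, truth = truth
        )
        scripts[[length(scripts) + 1]] <- c(
          list(participant_id = participant_id, group = group,
               trial_index = trial, phase = phase, t_offset = t_cursor),
          ex$script
        )
        t_cursor <- t_cursor + ex$t_end + 2.0
      }
    }
    session <- icube_session(
      unlist(all_t), do.call(rbind, all_touch), do.call(rbind, all_q))
    list(session = session,
         annotations = validate_annotations(do.call(rbind, ann)),
         script = scripts)
  })
}

#' Simulate a three-group cohort
#'
#' Per-participant seeds are derived from the master seed; each participant's
#' targets get small between-participant jitter (SD `participant_jitter` of
#' each target) around the group preset.
#'
#' @param seed Master seed.
#' @param n_per_group Named integer vector of participants per group; the
#'   default is the published cohort size (CB 6, LB 10, SI 16).
#' @param presets Named list of group presets (default [group_presets()]).
#' @param n_trials Trials (memorization + recall pairs) per participant.
#' @param participant_jitter Between-participant SD as a fraction of each
#'   jittered target. The SMC target uses the smaller `participant_jitter_smc`
#'   (the full fraction would exceed the within-group SMC variability implied
#'   by the published test statistics).
#' @param participant_jitter_smc Between-participant SD fraction for the SMC
#'   target.
#' @param sampling Passed to [simulate_session()].
#' @return List of participant records (`session`, `annotations`, `script`),
#'   one per participant, with ids like `cb01`, `si12`.
#' @export
simulate_cohort <- function(seed, n_per_group = c(CB = 6, LB = 10, SI = 16),
                            presets = group_presets(), n_trials = 3,
                            participant_jitter = 0.05,
                            participant_jitter_smc = 0.03,
                            sampling = c("irregular", "regular")) {
  sampling <- match.arg(sampling)
  stopifnot(all(names(n_per_group) %in% names(presets)),
            all(n_per_group >= 2))
  with_local_seed(seed, {
    total <- sum(n_per_group)
    seeds <- sample.int(.Machine$integer.max - 1L, total)
    jit <- matrix(stats::rnorm(total * 3, 0, participant_jitter), total, 3)
    jit[, 2] <- jit[, 2] * participant_jitter_smc / participant_jitter
    out <- list()
    idx <- 0
    for (grp in names(n_per_group)) {
      base <- presets[[grp]]
      for (j in seq_len(n_per_group[[grp]])) {
        idx <- idx + 1
        p <- base
        p$target_active_cells <- min(max(
          base$target_active_cells * (1 + jit[idx, 1]), 1.1), 15.5)
        p$target_smc <- min(max(base$target_smc * (1 + jit[idx, 2]), 0.4), 0.9)
        p$total_rotation <- max(base$total_rotation * (1 + jit[idx, 3]), 50)
        pid <- sprintf("%s%02d", tolower(grp), j)
        out[[pid]] <- simulate_session(p, seed = seeds[idx],
                                       n_trials = n_trials,
                                       participant_id = pid, group = grp,
                                       sampling = sampling)
      }
    }
    out
  })
}
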