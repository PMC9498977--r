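# In-code fixtures shared across the suite. All builders are deterministic
# given the RNG state at the call site.

# a session with explicit per-sample (face, cells) activations
# spec: list of lists: each element gives active cell indices (1..96) at one
# sample; times default to an exact 0.2 s grid
fixture_session <- function(active, t = NULL, q = NULL) {
  n <- length(active)
  if (is.null(t)) t <- seq(0, by = 0.2, length.out = n)
  touch <- matrix(0L, n, 96)
  for (i in seq_len(n)) touch[i, active[[i]]] <- 1L
  if (is.null(q)) q <- matrix(rep(c(1, 0, 0, 0), n), n, 4, byrow = TRUE)
  icube_session(t, touch, q)
}

# cell index helper: cell (1..16) of face (1..6)
cell_of <- function(face, cell) (face - 1L) * 16L + cell

# random unit quaternion
rand_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# a trial_grid built directly from matrices (bypassing interpolation)
fixture_grid <- function(touch, q = NULL, dt = 0.2) {
  if (is.null(q)) q <- matrix(rep(c(1, 0, 0, 0), nrow(touch)), ncol = 4,
                              byrow = TRUE)
  structure(list(dt = dt, t0 = 0, touch = touch, q = q), class = "trial_grid")
}

# rotation-matrix geodesic SLERP oracle: interpolate by rotating q0's matrix
# along the relative axis-angle path (Rodrigues), independent of quaternions
slerp_oracle_matrix <- function(q0, q1, u) {
  R0 <- quat_to_matrix(q0)
  R1 <- quat_to_matrix(q1)
  Rrel <- R1 %*% t(R0)
  ang <- acos(max(-1, min(1, (sum(diag(Rrel)) - 1) / 2)))
  if (ang < 1e-12) return(R0)
  ax <- c(Rrel[3, 2] - Rrel[2, 3], Rrel[1, 3] - Rrel[3, 1],
          Rrel[2, 1] - Rrel[1, 2]) / (2 * sin(ang))
  th <- u * ang
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  (diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)) %*% R0
}

# annotations for one participant with n trials
fixture_annotations <- function(participant = "p01", group = "SI", n = 1,
                                t_step = 100) {
  rows <- list()
  t <- 0
  for (i in seq_len(n)) {
    for (ph in c("memorization", "recall")) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = participant, group = group, trial_index = i,
        phase = ph, t_start = t, t_end = t + t_step / 2 - 1,
        response = if (ph == "recall") "same" else "none",
        truth = if (ph == "recall") "same" else "none")
      t <- t + t_step / 2
    }
  }
  do.call(rbind, rows)
}
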