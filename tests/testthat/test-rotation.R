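test_that("axis_delta matches the vector-angle oracle and handles q -> -q", {
  expect_equal(axis_delta(c(1, 0, 0, 0), c(1, 0, 0, 0)), c(0, 0, 0))
  # 30 degrees about +Z moves X and Y by 30, Z by 0
  d <- axis_delta(quat_from_axis_angle(c(0, 0, 1), 30), c(1, 0, 0, 0))
  expect_equal(d, c(30, 30, 0), tolerance = 1e-10)
  set.seed(41)
  for (i in 1:100) {
    qa <- rand_quat(); qb <- rand_quat()
    d <- axis_delta(qa, qb)
    Ra <- quat_to_matrix(qa); Rb <- quat_to_matrix(qb)
    oracle <- sapply(1:3, function(a) {
      acos(max(-1, min(1, sum(Ra[, a] * Rb[, a])))) * 180 / pi
    })
    expect_equal(d, oracle, tolerance = 1e-9)
    expect_equal(axis_delta(-qa, qb), d, tolerance = 1e-12)
    expect_equal(axis_delta(qa, -qb), d, tolerance = 1e-12)
    expect_true(all(d >= 0 & d <= 180))
  }
  expect_error(axis_delta(c(2, 0, 0, 0), c(1, 0, 0, 0)), "unit")
})

test_that("amount_of_rotation integrates a scripted turn and is additive", {
  # 360 degrees about +Z sampled exactly on the grid: X and Y traverse 360
  ts <- seq(0, 36, 0.2)
  q <- t(sapply(ts, function(t) quat_from_axis_angle(c(0, 0, 1), 10 * t)))
  touch <- matrix(0L, length(ts), 96); touch[, 1:2] <- 1L
  grid <- fixture_grid(touch, q)
  expect_equal(amount_of_rotation(grid), 360, tolerance = 1e-6)
  # static cube
  static <- fixture_grid(touch[1:10, ])
  expect_equal(amount_of_rotation(static), 0)
  # additivity over concatenation at matching endpoints
  g1 <- fixture_grid(touch[1:91, ], q[1:91, ])
  g2 <- fixture_grid(touch[91:181, ], q[91:181, ])
  expect_equal(amount_of_rotation(g1) + amount_of_rotation(g2),
               amount_of_rotation(grid), tolerance = 1e-9)
})

test_that("coarse sampling can only lose path length on smooth motions", {
  # spiraling motion: rotate about an axis that drifts
  t_fine <- seq(0, 20, 0.001)
  qf <- t(sapply(t_fine, function(t) {
    quat_multiply(quat_from_axis_angle(c(0, 0, 1), 12 * t),
                  quat_from_axis_angle(c(1, 0, 0), 4 * t))
  }))
  touch_f <- matrix(0L, length(t_fine), 96); touch_f[, 1:2] <- 1L
  fine <- fixture_grid(touch_f, qf, dt = 0.001)
  idx <- seq(1, length(t_fine), 200)  # 0.2 s subsample
  coarse <- fixture_grid(touch_f[idx, ], qf[idx, ], dt = 0.2)
  expect_lte(amount_of_rotation(coarse),
             amount_of_rotation(fine) * 1.01)
})

test_that("rotation speed averages axes over in-motion instants only", {
  # constant 10 deg/s about a fixed axis: cross-axis mean is 20/3
  ts <- seq(0, 20, 0.2)
  q <- t(sapply(ts, function(t) quat_from_axis_angle(c(0, 1, 0), 10 * t)))
  touch <- matrix(0L, length(ts), 96); touch[, 1:2] <- 1L
  expect_equal(rotation_speed(fixture_grid(touch, q)), 20 / 3,
               tolerance = 1e-9)
  # sub-threshold motion yields zero with a note
  slow <- t(sapply(ts, function(t) quat_from_axis_angle(c(0, 1, 0), 0.2 * t)))
  expect_message(v <- rotation_speed(fixture_grid(touch, slow)), "threshold")
  expect_equal(v, 0)
  # alternating static/moving: only moving segments contribute
  ts2 <- seq(0, 40, 0.2)
  ang <- cumsum(c(0, ifelse(ts2[-1] <= 20, 10, 0) * 0.2))
  q2 <- t(sapply(ang, function(a) quat_from_axis_angle(c(0, 1, 0), a)))
  touch2 <- matrix(0L, length(ts2), 96); touch2[, 1:2] <- 1L
  expect_equal(rotation_speed(fixture_grid(touch2, q2)), 20 / 3,
               tolerance = 1e-9)
})

test_that("orientation labels are the declared convention and always bijective", {
  lab <- orientation_labels(c(1, 0, 0, 0))
  expect_equal(lab$relative[[5]], "up")     # face 5 = +Z
  expect_equal(lab$relative[[1]], "front")  # face 1 = +X
  expect_equal(lab$absolute[[5]], "Up")
  # 90 degrees about the up axis: +X goes to +Y = participant's left
  lab90 <- orientation_labels(quat_from_axis_angle(c(0, 0, 1), 90))
  expect_equal(lab90$relative[[1]], "left")
  expect_equal(lab90$relative[[3]], "rear") # +Y -> -X
  set.seed(42)
  for (i in 1:300) {
    l <- orientation_labels(rand_quat())
    expect_equal(sort(unname(l$relative)), sort(c("up", "down", "front",
                                                  "rear", "left", "right")))
    expect_equal(length(unique(l$absolute)), 6)
  }
})

test_that("labels stay bijective at degenerate 45-degree orientations", {
  q45 <- quat_from_axis_angle(c(0, 0, 1), 45)
  l <- orientation_labels(q45)
  expect_equal(length(unique(l$relative)), 6)
  q2 <- quat_multiply(quat_from_axis_angle(c(1, 0, 0), 45), q45)
  expect_equal(length(unique(orientation_labels(q2)$relative)), 6)
})
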