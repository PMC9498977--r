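test_that("smc reproduces the counting formula on canonical cases", {
  a <- rep(1, 16)
  expect_equal(smc(a, a)$value, 1)
  expect_equal(smc(a, 1 - a)$value, 0)
  b <- a; b[1:4] <- 0
  expect_equal(smc(a, b)$value, 0.75)
  s <- smc(c(rep(1, 8), rep(0, 8)), c(rep(0, 4), rep(1, 8), rep(0, 4)))
  expect_equal(s$m00 + s$m01 + s$m10 + s$m11, 16)
  expect_equal(s$value, (s$m00 + s$m11) / 16)
  expect_error(smc(rep(2, 16), a), "binary")
})

test_that("smc is symmetric and matches brute-force counting on random pairs", {
  set.seed(31)
  for (i in 1:200) {
    a <- rbinom(16, 1, runif(1))
    b <- rbinom(16, 1, runif(1))
    expect_identical(smc(a, b)$value, sum(a == b) / 16)
    expect_identical(smc(a, b)$value, smc(b, a)$value)
  }
})

test_that("the minimum-SMC filter selects changing faces, ties and untouched cubes", {
  # sample 1 -> 2: face 1 changes 3 cells; 2 -> 3: faces 1 and 2 change 2
  # cells each; 3 -> 4: nothing changes
  t1 <- integer(0)
  touch <- matrix(0L, 4, 96)
  touch[1, cell_of(1, 1:4)] <- 1L
  touch[2, cell_of(1, 1)] <- 1L                       # 3 cells of face 1 off
  touch[3, c(cell_of(1, 1:3), cell_of(2, 1:2))] <- 1L # f1 +2, f2 +2
  touch[4, ] <- touch[3, ]
  fr <- classify_explorative(fixture_grid(touch))
  expl <- attr(fr, "explored")
  expect_equal(which(expl[1, ]), 1)
  expect_equal(which(expl[2, ]), c(1, 2))
  expect_equal(which(expl[3, ]), integer(0))
  expect_equal(fr$face, c(1L, 1L, NA))
  expect_equal(fr$min_smc, c(13 / 16, 14 / 16, 1))
  # tied faces: active cells summed over both
  expect_equal(fr$active_cells[2], 3 + 2)
})

test_that("holding patterns never enter the metrics", {
  # face 6 carries a constant 2-cell pattern; face 3 is explored
  set.seed(32)
  T_ <- 30
  touch <- matrix(0L, T_, 96)
  touch[, cell_of(6, c(3, 9))] <- 1L
  state <- rep(0L, 16); state[1:4] <- 1L
  for (i in seq_len(T_)) {
    flip <- sample.int(16, 2)
    state[flip] <- 1L - state[flip]
    touch[i, cell_of(3, 1:16)] <- state
  }
  fr <- classify_explorative(fixture_grid(touch))
  moved <- fr$n_explored > 0
  expect_true(all(fr$face[moved] == 3))
  pf <- per_face_duration_stats(fr)
  expect_equal(pf$per_face[6], 0)
  # relabeling the constant holding pattern leaves classification unchanged
  touch2 <- touch
  touch2[, cell_of(6, c(3, 9))] <- 0L
  touch2[, cell_of(6, c(1, 16))] <- 1L
  fr2 <- classify_explorative(fixture_grid(touch2))
  expect_equal(fr$face, fr2$face)
  expect_equal(fr$min_smc, fr2$min_smc)
})

test_that("duration, touch counting and frequency follow their definitions", {
  touch <- matrix(0L, 50, 96)
  touch[1:50, cell_of(2, 1)] <- 1L
  grid <- fixture_grid(touch)
  expect_equal(exploration_duration(grid), 49 * 0.2)

  # a cell turning on once and staying on is one touch
  touch <- matrix(0L, 10, 96)
  touch[3:10, cell_of(1, 5)] <- 1L
  touch[1, cell_of(1, 1)] <- 1L  # so sample pairs exist with change
  fr <- classify_explorative(fixture_grid(touch))
  expect_equal(count_touches(fr), 1)
  expect_equal(touch_frequency(fr, 10), 0.1)
  expect_error(touch_frequency(fr, 0), "positive")

  # 5 onsets over 10 s -> 0.5 /s
  touch <- matrix(0L, 51, 96)
  on_at <- c(5, 15, 25, 35, 45)
  for (i in seq_len(51)) {
    k <- sum(on_at <= i)
    if (k > 0) touch[i, cell_of(1, seq_len(k))] <- 1L
  }
  fr <- classify_explorative(fixture_grid(touch))
  expect_equal(count_touches(fr), 5)
  expect_equal(touch_frequency(fr, 10), 0.5)
})

test_that("per-face duration statistics include never-explored faces as zeros", {
  # only face 1 explored, 30 changing samples = 6 s
  touch <- matrix(0L, 31, 96)
  state <- rep(0L, 16); state[1:3] <- 1L
  set.seed(33)
  for (i in 2:31) {
    flip <- sample.int(16, 1)
    state[flip] <- 1L - state[flip]
    touch[i, cell_of(1, 1:16)] <- state
  }
  fr <- classify_explorative(fixture_grid(touch))
  pf <- per_face_duration_stats(fr)
  expect_equal(pf$per_face[1], 6)
  expect_equal(pf$mean, 1)
  expect_equal(pf$sd, sd(c(6, 0, 0, 0, 0, 0)))
  # equal exploration of all faces has zero variability
  pf_eq <- list(per_face = rep(2, 6))
  expect_equal(sd(pf_eq$per_face), 0)
})

test_that("mean active cells and mean SMC average the explored frames only", {
  touch <- matrix(0L, 6, 96)
  touch[1, cell_of(1, 1:4)] <- 1L
  touch[2, cell_of(1, 2:5)] <- 1L   # 2 changes, 4 active
  touch[3, cell_of(1, 2:5)] <- 1L   # unchanged -> unexplored frame
  touch[4, cell_of(1, 1:4)] <- 1L   # 2 changes, 4 active
  touch[5, cell_of(1, 1:4)] <- 1L   # unchanged
  touch[6, cell_of(1, 3:6)] <- 1L   # 4 changes, 4 active
  fr <- classify_explorative(fixture_grid(touch))
  expect_equal(mean_active_cells(fr), 4)
  expect_equal(mean_smc(fr), mean(c(14, 14, 12) / 16))
  quiet <- classify_explorative(fixture_grid(matrix(0L, 3, 96)))
  expect_error(mean_smc(quiet), "undefined")
  expect_error(mean_active_cells(quiet), "undefined")
})

test_that("lower cell-change probability raises measured mean SMC monotonically", {
  set.seed(34)
  res <- sapply(c(1, 2, 4, 6), function(k) {
    touch <- matrix(0L, 400, 96)
    state <- rep(0L, 16); state[1:6] <- 1L
    for (i in seq_len(400)) {
      flip <- sample.int(16, k)
      state[flip] <- 1L - state[flip]
      touch[i, cell_of(4, 1:16)] <- state
    }
    mean_smc(classify_explorative(fixture_grid(touch)))
  })
  expect_true(all(diff(res) < 0))
  expect_equal(res, (16 - c(1, 2, 4, 6)) / 16, tolerance = 1e-9)
})
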