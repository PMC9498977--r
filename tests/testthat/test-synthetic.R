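test_that("identical seeds reproduce sessions byte for byte", {
  pr <- make_preset(4.5, 0.8, 300, trial_duration = 30, n_episodes = 6)
  a <- simulate_session(pr, seed = 99, n_trials = 1)
  b <- simulate_session(pr, seed = 99, n_trials = 1)
  expect_identical(a$session$t, b$session$t)
  expect_identical(a$session$touch, b$session$touch)
  expect_identical(a$session$q, b$session$q)
  expect_identical(a$annotations, b$annotations)
  c <- simulate_session(pr, seed = 100, n_trials = 1)
  expect_false(identical(a$session$t, c$session$t))
})

test_that("infeasible SMC targets are rejected with the constraint named", {
  expect_error(make_preset(5, 1.0, 300), "infeasible target_smc")
  expect_error(make_preset(5, 0.95, 300), "changed-cell")
  expect_error(make_preset(0.5, 0.8, 300), "target_active_cells")
  # a map with n active cells cannot change more than 2n cells per step
  expect_error(make_preset(2, 0.7, 300), "incompatible")
  expect_silent(make_preset(5, 0.9, 300))
  expect_silent(make_preset(2, 0.75, 300))
})

test_that("published presets carry the published targets", {
  pre <- group_presets()
  expect_equal(pre$CB$target_active_cells, 5.24)
  expect_equal(pre$LB$target_active_cells, 4.32)
  expect_equal(pre$SI$target_active_cells, 4.14)
  expect_equal(pre$CB$target_smc, 0.77)
  expect_equal(pre$LB$target_smc, 0.81)
  expect_equal(pre$SI$target_smc, 0.80)
  expect_equal(pre$CB$total_rotation, 560)
  expect_equal(pre$LB$total_rotation, 517)
  expect_equal(pre$SI$total_rotation, 710)
  expect_equal(pre$CB$accuracy, 0.72)
  expect_equal(pre$SI$accuracy, 0.69)
})

test_that("the pipeline recovers scripted targets on a noise-free session", {
  pr <- make_preset(5.24, 0.77, 400, trial_duration = 90, n_episodes = 8,
                    trial_jitter_cells = 0, trial_jitter_smc = 0,
                    duration_log_noise = 0, rest_rate = 0)
  sim <- simulate_session(pr, seed = 7, n_trials = 1, sampling = "regular")
  m <- session_metrics(sim$session, sim$annotations)
  expect_equal(mean(m$mean_active_cells), 5.24, tolerance = 0.05)
  expect_equal(mean(m$mean_smc), 0.77, tolerance = 0.01)
  # planted rotation totals are recovered within a degree
  planted <- vapply(sim$script, function(s) s$rotation_max, numeric(1))
  expect_equal(m$amount_of_rotation, planted, tolerance = 1e-3)
})

test_that("the scripted episode sequence is recovered exactly under regular sampling", {
  pr <- make_preset(6, 0.78, 250, trial_duration = 60, n_episodes = 8,
                    trial_jitter_cells = 0, trial_jitter_smc = 0,
                    duration_log_noise = 0, rest_rate = 0)
  sim <- simulate_session(pr, seed = 13, n_trials = 1, sampling = "regular")
  a <- sim$annotations[1, ]
  win <- window_session(sim$session, a$t_start, a$t_end)
  grid <- trim_trial(make_trial_grid(win))
  fr <- classify_explorative(grid)
  labs <- relative_label_per_sample(grid, fr)
  ep <- build_episodes(fr, labs)
  script <- sim$script[[1]]
  expect_equal(ep$face, script$faces)
  expect_equal(n_returns(ep), length(script$faces) -
                 length(unique(script$faces)))
  expect_equal(ep$label, unname(script$labels))
})

test_that("increasing the scripted rotation increases the measured amount", {
  measure <- function(rot) {
    # focus = 0: no alignment moves, so the planted budget equals the target
    pr <- make_preset(5, 0.8, rot, trial_duration = 60, n_episodes = 6,
                      focus = 0, trial_jitter_cells = 0, trial_jitter_smc = 0,
                      duration_log_noise = 0, rotation_jitter = 0)
    sim <- simulate_session(pr, seed = 17, n_trials = 1)
    a <- sim$annotations[1, ]
    win <- window_session(sim$session, a$t_start, a$t_end)
    amount_of_rotation(trim_trial(make_trial_grid(win)))
  }
  res <- vapply(c(150, 300, 500), measure, numeric(1))
  expect_true(all(diff(res) > 0))
  expect_equal(res, c(150, 300, 500), tolerance = 0.02)
})

test_that("cohorts have the published composition and are reproducible", {
  coh <- simulate_cohort(seed = 5, n_per_group = c(CB = 2, LB = 2, SI = 3),
                         n_trials = 1)
  expect_equal(length(coh), 7)
  expect_equal(names(coh)[1], "cb01")
  groups <- vapply(coh, function(p) p$annotations$group[1], character(1))
  expect_equal(unname(table(groups)[c("CB", "LB", "SI")]), c(2L, 2L, 3L),
               ignore_attr = TRUE)
  coh2 <- simulate_cohort(seed = 5, n_per_group = c(CB = 2, LB = 2, SI = 3),
                          n_trials = 1)
  expect_identical(coh$si03$session$touch, coh2$si03$session$touch)
})

test_that("default cohort sizes follow the study composition", {
  # 6 + 10 + 16 participants; verified cheaply via the formals
  f <- formals(simulate_cohort)
  expect_equal(eval(f$n_per_group), c(CB = 6, LB = 10, SI = 16))
})
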