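test_that("target_offset integrates the piecewise-linear phase rates", {
  p <- session_protocol(3, 12, recovery_s = 92, weight_kg = 10)
  cfg <- sim_config(frame_shape = c(32, 24), noise_sd = 0)
  expect_equal(target_offset(0, p, cfg), 0)
  # one minute inside the first active set of a single-set session
  p1 <- session_protocol(1, 15, recovery_s = 300, weight_kg = 10)
  expect_equal(target_offset(60, p1, cfg), 0.13)
  # end of a 92 s recovery after a 48 s set: 0.13 * 0.8 + 0.47 * 92/60
  expect_equal(target_offset(140, p, cfg), 0.13 * 0.8 + 0.47 * 92 / 60)
  expect_error(target_offset(-1, p, cfg), "nonnegative")
})

test_that("target_offset plateaus after the configured recovery minutes", {
  p1 <- session_protocol(1, 15, recovery_s = 300, weight_kg = 10)
  cfg <- sim_config(frame_shape = c(32, 24), noise_sd = 0,
                    post_plateau_rate = 0)
  at_plateau <- target_offset(60 + 180, p1, cfg)
  expect_equal(target_offset(60 + 240, p1, cfg), at_plateau)
  cfg_decay <- sim_config(frame_shape = c(32, 24), noise_sd = 0,
                          post_plateau_rate = -0.06)
  expect_equal(target_offset(60 + 240, p1, cfg_decay), at_plateau - 0.06)
})

test_that("passive (0 kg) protocols produce no temperature offset", {
  p0 <- session_protocol(3, 12, recovery_s = 92, weight_kg = 0)
  cfg <- sim_config(frame_shape = c(32, 24), noise_sd = 0)
  expect_equal(target_offset(c(0, 100, 328), p0, cfg), c(0, 0, 0))
})

test_that("muscle centers land in their heat-map regions", {
  geom <- list(center = c(50, 40), semi = c(40, 20), rotation_deg = 0)
  d <- muscle_center("deltoid", geom)
  expect_lt(d[1], 50)                       # upper half
  b <- muscle_center("biceps", geom)
  expect_gt(b[1], 50)
  expect_lt(b[2], 40)                       # lower-left quadrant
  tr <- muscle_center("triceps", geom)
  expect_gt(tr[1], 50)
  expect_gt(tr[2], 40)                      # lower-right quadrant
  for (m in c("deltoid", "biceps", "triceps")) {
    px <- muscle_center(m, geom)
    expect_lte(((px[1] - 50) / 40)^2 + ((px[2] - 40) / 20)^2, 1)
  }
  expect_error(muscle_center("vague", geom), "no localized")
})

test_that("noiseless frames are baseline inside the arm at t = 0 and peak at the muscle center", {
  p <- session_protocol(3, 12, recovery_s = 92, weight_kg = 10,
                        target_muscle = "biceps")
  cfg <- sim_config(frame_shape = c(64, 48), noise_sd = 0)
  f0 <- render_frame(0, p, cfg)
  sc <- brachytherm:::scene_geometry(cfg)
  expect_true(all(f0$temperatures[sc$inside] == cfg$baseline_skin_C))
  expect_true(all(f0$temperatures[!sc$inside] == cfg$ambient_C))

  f1 <- render_frame(328, p, cfg)
  peak <- which(f1$temperatures == max(f1$temperatures), arr.ind = TRUE)
  ctr <- muscle_center("biceps", cfg$arm_geometry)
  expect_lt(sqrt(sum((peak[1, ] - ctr)^2)), 2)
})

test_that("simulation is reproducible under a seed and noise-independent otherwise", {
  p <- session_protocol(3, 12, recovery_s = 92, weight_kg = 10)
  cfg <- function(s, n) sim_config(frame_shape = c(40, 32), noise_sd = n,
                                   seed = s)
  r1 <- simulate_session(p, cfg(11, 0.05))
  r2 <- simulate_session(p, cfg(11, 0.05))
  expect_identical(lapply(r1$frames, `[[`, "temperatures"),
                   lapply(r2$frames, `[[`, "temperatures"))
  r3 <- simulate_session(p, cfg(12, 0.05))
  expect_false(identical(r1$frames[[1]]$temperatures,
                         r3$frames[[1]]$temperatures))
  # two seeds share the identical noiseless component
  n1 <- simulate_session(p, cfg(11, 0))
  n2 <- simulate_session(p, cfg(12, 0))
  expect_identical(lapply(n1$frames, `[[`, "temperatures"),
                   lapply(n2$frames, `[[`, "temperatures"))
})

test_that("a 3 x 48 s session at 4 s intervals yields 83 frames covering 0..328 s", {
  rec <- tiny_session(frame_shape = c(40, 32))
  expect_length(rec$frames, 83)
  ts <- vapply(rec$frames, `[[`, 0, "timestamp_s")
  expect_equal(ts[1], 0)
  expect_equal(ts[83], 328)
  expect_error(simulate_session(rec$protocol,
                                sim_config(frame_interval_s = 0)),
               "frame_interval_s")
})

test_that("target-region mean is nondecreasing without post-plateau decay", {
  p <- session_protocol(3, 12, recovery_s = 92, weight_kg = 10,
                        target_muscle = "biceps")
  cfg <- sim_config(frame_shape = c(64, 48), noise_sd = 0,
                    post_plateau_rate = 0)
  sc <- brachytherm:::scene_geometry(cfg)
  quad <- sc$inside & sc$u <= 0 & sc$v >= 0
  rec <- simulate_session(p, cfg)
  means <- vapply(rec$frames, function(f) mean(f$temperatures[quad]), 0)
  expect_true(all(diff(means) >= -1e-12))
})
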