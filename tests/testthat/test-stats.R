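test_that("elevation rates reproduce the worked single-set examples", {
  # 10 kg training minute: 35.98 -> 36.11 C over 1 min
  expect_equal(elevation_rate(35.98, 36.11, 1)$rate, 0.13)
  # 5 kg recovery: 36.07 -> 36.34 C over 5 min
  expect_equal(elevation_rate(36.07, 36.34, 5)$rate, 0.05)
  expect_equal(elevation_rate(36.0, 36.0, 10)$rate, 0)
  expect_error(elevation_rate(36, 37, 0), "positive")
})

test_that("elevation_rate is antisymmetric and scales inversely with duration", {
  set.seed(61)
  for (i in 1:20) {
    a <- runif(1, 30, 38)
    b <- runif(1, 30, 38)
    d <- runif(1, 0.5, 10)
    expect_equal(elevation_rate(a, b, d)$rate_raw,
                 -elevation_rate(b, a, d)$rate_raw)
    expect_equal(elevation_rate(a, b, 2 * d)$rate_raw,
                 elevation_rate(a, b, d)$rate_raw / 2)
  }
})

test_that("reported rates use half-even rounding at two decimals", {
  # .125 and .375 are exactly representable half-way cases
  expect_equal(elevation_rate(36.000, 36.125, 1)$rate, 0.12)
  expect_equal(elevation_rate(36.000, 36.375, 1)$rate, 0.38)
})

test_that("target-vs-nontarget trajectories match hand arithmetic", {
  set <- constant_map_set(list(
    S1 = c(deltoid = 33.0, biceps = 33.2, triceps = 33.1),
    E3 = c(deltoid = 33.4, biceps = 34.0, triceps = 33.5)))
  tr <- region_difference_trajectory(set, "biceps")
  expect_equal(nrow(tr), 4)
  expect_equal(tr$delta[tr$label == "S1" & tr$nontarget == "deltoid"],
               33.2 - 33.0)
  expect_equal(tr$delta[tr$label == "E3" & tr$nontarget == "triceps"],
               34.0 - 33.5)
  expect_error(region_difference_trajectory(set, "vague"), "target")
})

test_that("with no diffuse warming the target contrast strictly increases", {
  p <- session_protocol(3, 12, recovery_s = 92, weight_kg = 10,
                        target_muscle = "biceps")
  cfg <- sim_config(frame_shape = c(128, 96), noise_sd = 0,
                    nontarget_fraction = 0)
  set <- select_set_heatmaps(simulate_session(p, cfg))
  tr <- region_difference_trajectory(set, "biceps")
  for (nt in c("deltoid", "triceps")) {
    d <- tr$delta[tr$nontarget == nt]
    expect_true(all(diff(d) > 0))
  }
})

test_that("vague (diffuse-only) sessions show near-zero regional contrast", {
  rec <- tiny_session(target = "vague", noise_sd = 0.05, seed = 23)
  set <- select_set_heatmaps(rec)
  tr <- region_difference_trajectory(set, "biceps")
  expect_lt(max(abs(tr$delta)), 0.15)
})

test_that("trajectory aggregation returns mean and sd per time point", {
  sets <- list(
    constant_map_set(list(S1 = c(deltoid = 33, biceps = 33.2, triceps = 33.1),
                          E3 = c(deltoid = 33.4, biceps = 34.0, triceps = 33.5))),
    constant_map_set(list(S1 = c(deltoid = 33, biceps = 33.4, triceps = 33.1),
                          E3 = c(deltoid = 33.4, biceps = 34.4, triceps = 33.5))))
  agg <- trajectory_summary(sets, c("biceps", "biceps"))
  row <- agg[agg$label == "S1" & agg$nontarget == "deltoid", ]
  expect_equal(row$mean, mean(c(0.2, 0.4)))
  expect_equal(row$sd, sd(c(0.2, 0.4)))
})

test_that("Kruskal-Wallis H matches the hand rank-sum formula", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  res <- kruskal_wallis(groups)
  expect_equal(res$H, 7.2)
  expect_equal(res$H, kw_handformula(groups))
  expect_equal(res$df, 2)
  set.seed(71)
  for (i in 1:10) {
    g <- list(runif(7), runif(9), runif(5))
    expect_equal(kruskal_wallis(g)$H, kw_handformula(g))
  }
})

test_that("complete ties give H = 0 and degenerate inputs error", {
  res <- kruskal_wallis(list(1, 1, 1))
  expect_equal(res$H, 0)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "nonempty")
})

test_that("the test is invariant under strictly monotone transforms", {
  set.seed(81)
  g <- list(rnorm(8), rnorm(8, 0.5), rnorm(8, 1))
  h0 <- kruskal_wallis(g)$H
  expect_equal(kruskal_wallis(lapply(g, exp))$H, h0)
  expect_equal(kruskal_wallis(lapply(g, function(x) 3 * x - 10))$H, h0)
})

test_that("permutation p-values broadly agree with the chi-squared approximation", {
  set.seed(91)
  g <- list(rnorm(8), rnorm(8, 1.2), rnorm(8))
  approx_p <- kruskal_wallis(g)$p
  perm_p <- kruskal_wallis(g, exact = TRUE, n_perm = 2000)$p
  expect_lt(abs(approx_p - perm_p), 0.05)
})

test_that("order-randomized identical dynamics do not trigger the order test", {
  # three training orders with the same underlying heating: p should be
  # comfortably nonsignificant on typical draws
  set.seed(101)
  groups <- lapply(1:3, function(o) 0.8 + rnorm(10, 0, 0.1))
  expect_gt(kruskal_wallis(groups)$p, 0.01)
})
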