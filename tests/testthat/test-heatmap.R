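test_that("heat map of a constant fully-masked ROI is constant with no missing cells", {
  f <- thermal_frame(matrix(36.0, 120, 40))
  hm <- make_heatmap(f, NULL, 60, 20)
  expect_equal(dim(hm), c(60, 20))
  expect_true(all(hm == 36.0))
  expect_equal(sum(is.na(hm)), 0)
})

test_that("grid cell means equal brute-force block means", {
  set.seed(41)
  for (i in 1:5) {
    nr <- sample(100:150, 1)
    nc <- sample(30:70, 1)
    m <- matrix(runif(nr * nc, 25, 40), nr, nc)
    mask <- matrix(runif(nr * nc) > 0.2, nr, nc)
    f <- thermal_frame(m)
    hm <- make_heatmap(f, mask, 60, 20)
    expect_equal(unclass(hm)[, ], heatmap_bruteforce(m, mask, 60, 20),
                 ignore_attr = TRUE)
  }
  # test-scale grid: 2 x 2 on a 120 x 40 ROI
  m <- matrix(runif(120 * 40, 25, 40), 120, 40)
  hm2 <- make_heatmap(thermal_frame(m), NULL, 2, 2)
  expect_equal(hm2[1, 1], mean(m[1:60, 1:20]))
  expect_equal(hm2[2, 2], mean(m[61:120, 21:40]))
})

test_that("cells below the masked-fraction threshold are missing", {
  m <- matrix(30, 120, 40)
  mask <- matrix(TRUE, 120, 40)
  mask[1:2, 1:2] <- FALSE          # kills cell (1,1) of a 60 x 20 grid
  mask[3, 1] <- FALSE              # cell (2,1): 1 of 4 masked out -> kept
  hm <- make_heatmap(thermal_frame(m), mask, 60, 20)
  expect_true(is.na(hm[1, 1]))
  expect_false(is.na(hm[2, 1]))
  expect_error(make_heatmap(thermal_frame(matrix(30, 50, 10)), NULL, 60, 20),
               "smaller than")
})

test_that("a session yields 2 x n_sets labeled heat maps", {
  rec <- tiny_session(frame_shape = c(128, 96), seed = 13)
  set <- select_set_heatmaps(rec)
  expect_named(set, c("S1", "E1", "S2", "E2", "S3", "E3"))
  expect_true(all(vapply(set, function(x) all(dim(x) == c(60, 20)), TRUE)))
  rec1 <- tiny_session(n_sets = 1, frame_shape = c(128, 96), seed = 13)
  expect_named(select_set_heatmaps(rec1), c("S1", "E1"))
})

test_that("difference maps are later-minus-earlier and telescope", {
  rec <- tiny_session(frame_shape = c(128, 96), seed = 17, noise_sd = 0.05)
  set <- select_set_heatmaps(rec)
  d0 <- diff_heatmap(set, c("S1", "S1"))
  expect_true(all(abs(d0) < 1e-12, na.rm = TRUE))
  d_s1e3 <- diff_heatmap(set, "S1-E3")
  d_s1s3 <- diff_heatmap(set, "S1-S3")
  d_s3e3 <- diff_heatmap(set, c("S3", "E3"))
  expect_equal(unclass_keep_na(d_s1s3) + unclass_keep_na(d_s3e3),
               unclass_keep_na(d_s1e3), tolerance = 1e-9)
  # heating is positive on the warming simulation
  expect_gt(mean(d_s1e3, na.rm = TRUE), 0)
  expect_error(diff_heatmap(set, "S1-E9"), "unknown")
})

test_that("simple difference arithmetic is exact", {
  set <- constant_map_set(list(
    S1 = c(deltoid = 36.0, biceps = 36.0, triceps = 36.0),
    E3 = c(deltoid = 36.9, biceps = 36.9, triceps = 36.9)))
  d <- diff_heatmap(set, "S1-E3")
  expect_true(all(abs(d - 0.9) < 1e-12, na.rm = TRUE))
})

test_that("region means follow the deltoid/biceps/triceps layout", {
  m <- matrix(NA_real_, 60, 20)
  m[1:30, ] <- 37
  m[31:60, 1:10] <- 36
  m[31:60, 11:20] <- 35
  hm <- brachytherm:::new_heat_map(m)
  expect_equal(region_means(hm),
               c(deltoid = 37, biceps = 36, triceps = 35))
  const <- brachytherm:::new_heat_map(matrix(33.3, 60, 20))
  expect_equal(unname(region_means(const)), rep(33.3, 3))
})

test_that("region means match the index-enumeration oracle on random maps", {
  set.seed(51)
  for (i in 1:100) {
    m <- matrix(runif(1200, -1, 2), 60, 20)
    m[sample(1200, 150)] <- NA
    hm <- brachytherm:::new_heat_map(m)
    expect_equal(region_means(hm), region_means_enum(m))
  }
  all_missing <- matrix(runif(1200), 60, 20)
  all_missing[1:30, ] <- NA
  expect_error(region_means(brachytherm:::new_heat_map(all_missing)),
               "deltoid")
})

test_that("pair scores equal hand-computed region-mean differences", {
  set <- constant_map_set(list(
    S1 = c(deltoid = 33.0, biceps = 33.1, triceps = 33.0),
    S2 = c(deltoid = 33.2, biceps = 33.6, triceps = 33.3),
    E3 = c(deltoid = 33.5, biceps = 34.2, triceps = 33.6)))
  expect_equal(pair_score(set, "biceps", "S1-E3"), 34.2 - 33.1)
  expect_equal(pair_score(set, "deltoid", "S1-S2"), 33.2 - 33.0)
  expect_error(pair_score(set, "vague", "S1-E3"), "target")
})

test_that("zero dynamics gives zero pair scores everywhere", {
  v <- c(deltoid = 33, biceps = 33, triceps = 33)
  set <- constant_map_set(list(S1 = v, E1 = v, S2 = v, E2 = v,
                               S3 = v, E3 = v))
  scores <- vapply(names(heatmap_pairs()), function(p)
    pair_score(set, "biceps", p), 0)
  expect_true(all(scores == 0))
})

test_that("ties break toward the later pair", {
  v0 <- c(deltoid = 33, biceps = 33, triceps = 33)
  v1 <- c(deltoid = 33, biceps = 33.5, triceps = 33)
  set <- constant_map_set(list(S1 = v0, E1 = v1, S2 = v1, E2 = v1,
                               S3 = v1, E3 = v1))
  expect_equal(rank_pairs(set, "biceps"), "S1-E3")
})

test_that("rank table uses floor percentages and reproduces the 85% first-and-third share", {
  counts <- c("S1-E3" = 36, "S1-S3" = 24, "S1-E2" = 4, "S1-S2" = 2,
              "S1-E1" = 4)
  tab <- pair_rank_table(counts)
  expect_equal(tab$count[tab$pair == "S1-E3"], 36L)
  expect_equal(tab$pct[tab$pair == "S1-E3"], 51)
  expect_equal(tab$pct[tab$pair == "S1-S3"], 34)
  expect_equal(tab$pct[tab$pair == "S1-S2"], 2)
  expect_equal(first_third_share(tab), 85)
  single <- pair_rank_table("S1-S3")
  expect_equal(single$count[single$pair == "S1-S3"], 1L)
  expect_equal(single$pct[single$pair == "S1-S3"], 100)
  expect_error(pair_rank_table(character(0)), "no sessions")
})
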