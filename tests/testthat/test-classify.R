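# A tiny synthetic "heat map set" factory with a movable warm block lets the
# classifier tests run without full-frame simulation.
blockmap_set <- function(region, amp = 1, seed = 1) {
  set.seed(seed)
  base <- matrix(33 + rnorm(1200, 0, 0.01), 60, 20)
  hot <- matrix(0, 60, 20)
  if (region == "deltoid") hot[5:25, 5:15] <- amp
  if (region == "biceps") hot[35:55, 2:9] <- amp
  if (region == "triceps") hot[35:55, 12:19] <- amp
  if (region == "vague") hot[] <- amp * 0.3
  maps <- list(S1 = brachytherm:::new_heat_map(base, "S1", "blk"),
               S3 = brachytherm:::new_heat_map(base + 0.7 * hot, "S3", "blk"),
               E3 = brachytherm:::new_heat_map(base + hot, "E3", "blk"))
  structure(maps, class = "heat_map_set", session_id = paste0("blk-", seed),
            protocol = session_protocol(3, 12, recovery_s = 92,
                                        target_muscle = if (region == "vague")
                                          "vague" else region))
}

make_blk_dataset <- function(n_per_class, seed0 = 0) {
  labels <- rep(muscle_classes(), n_per_class)
  sets <- lapply(seq_along(labels), function(i)
    blockmap_set(labels[i], amp = 0.8 + 0.05 * (i %% 5), seed = seed0 + i))
  build_dataset(sets, labels)
}

test_that("dataset assembly yields one labeled map per session x pair", {
  ds <- make_blk_dataset(3)
  expect_length(ds, 12 * 2)
  expect_setequal(unique(vapply(ds, `[[`, "", "pair")),
                  c("S1-E3", "S1-S3"))
  expect_true(all(vapply(ds, function(d) all(is.finite(d$image)), TRUE)))
  expect_true(all(vapply(ds, function(d)
    min(d$image) >= 0 && max(d$image) <= 1, TRUE)))
  vague_labels <- vapply(ds, `[[`, "", "label")[
    vapply(ds, `[[`, "", "session_id") == "blk-4"]
  expect_true(all(vague_labels == "vague"))
  expect_length(build_dataset(list(), character(0)), 0)
})

test_that("degenerate difference maps are excluded with a warning", {
  sets <- list(blockmap_set("biceps"), blockmap_set("triceps"))
  # remove the whole deltoid region of one S3 map -> region-undefined
  bad <- sets[[2]]
  bad$S3[1:30, ] <- NA
  sets[[2]] <- bad
  expect_warning(ds <- build_dataset(sets, c("biceps", "triceps")),
                 "degenerate")
  expect_length(ds, 3)
})

test_that("the split is a reproducible partition with a floored test size", {
  ds <- make_blk_dataset(17)[1:134]
  sp <- split_dataset(ds, 0.1, seed = 2)
  expect_length(sp$train, 121)
  expect_length(sp$test, 13)
  ids <- function(x) vapply(x, function(d)
    paste(d$session_id, d$pair), "")
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(ds))
  sp2 <- split_dataset(ds, 0.1, seed = 2)
  expect_identical(ids(sp$test), ids(sp2$test))
  expect_length(split_dataset(ds[1:10], 0.1, seed = 1)$test, 1)
  expect_error(split_dataset(list(), 0.1), "empty")
})

test_that("augmentation is an exact factorial with labels preserved", {
  ds <- make_blk_dataset(1)           # 8 maps
  cfg <- aug_config(out_size = 32)
  aug <- augment_maps(ds, cfg, seed = 3)
  expect_length(aug, length(ds) * 3 * 3 * 2)
  expect_equal(vapply(aug, `[[`, "", "label"),
               rep(vapply(ds, `[[`, "", "label"), each = 18))
  expect_true(all(vapply(aug, function(d)
    all(dim(d$image) == c(32, 32)), TRUE)))
  expect_identical(augment_maps(ds, cfg, seed = 3), aug)
  expect_length(augment_maps(list(), cfg), 0)
  # a custom factorial scales accordingly
  cfg2 <- aug_config(rotations_deg = 0, scales = c(1, 1.1), out_size = 16)
  expect_length(augment_maps(ds, cfg2), length(ds) * 1 * 2 * 2)
})

test_that("the identity augmentation variant preserves the resized image", {
  ds <- make_blk_dataset(1)[1]
  cfg <- aug_config(out_size = 30)
  aug <- augment_maps(ds, cfg, seed = 5)
  # variants are ordered rot x scale x noise; identity combination is
  # rot = 0, scale = 1, noise off -> index (2-1)*6 + (2-1)*2 + 1 = 9
  ident <- aug[[9]]
  expect_equal(ident$image,
               brachytherm:::resize_map(ds[[1]]$image, 30))
})

test_that("a small CNN separates well-separated synthetic classes", {
  ds <- make_blk_dataset(6, seed0 = 100)     # 48 maps
  sp <- split_dataset(ds, 0.15, seed = 4)
  cfg <- train_config(epochs = 12, seed = 9, channels = c(8, 16))
  model <- train_classifier(sp$train, cfg, out_size = 32)
  expect_equal(nrow(model$curve), 12)
  ev <- evaluate_model(model, sp$test)
  expect_gte(ev$accuracy, 0.85)
  probs <- predict(model, sp$test)
  expect_equal(rowSums(probs), rep(1, length(sp$test)), tolerance = 1e-6)
  expect_equal(dim(ev$confusion), c(4, 4))
  expect_equal(sum(ev$confusion), length(sp$test))
})

test_that("training is deterministic under a fixed seed", {
  ds <- make_blk_dataset(2, seed0 = 50)
  cfg <- train_config(epochs = 3, seed = 13, channels = c(4, 8))
  m1 <- train_classifier(ds, cfg, out_size = 32)
  m2 <- train_classifier(ds, cfg, out_size = 32)
  expect_identical(m1$curve, m2$curve)
  expect_identical(m1$params$Wd, m2$params$Wd)
})

test_that("an untrained epoch on shuffled labels stays near chance", {
  ds <- make_blk_dataset(5, seed0 = 200)
  labels <- sample(rep(muscle_classes(), 10))
  for (i in seq_along(ds)) ds[[i]]$label <- labels[i]
  cfg <- train_config(epochs = 1, seed = 3, channels = c(4, 8))
  model <- train_classifier(ds, cfg, out_size = 32)
  expect_lt(model$curve$accuracy[1], 0.6)
  expect_gt(model$curve$accuracy[1], 0.05)
})

test_that("single-class training sets are rejected", {
  ds <- make_blk_dataset(2, seed0 = 80)
  only_biceps <- ds[vapply(ds, `[[`, "", "label") == "biceps"]
  expect_error(train_classifier(only_biceps, train_config(epochs = 1)),
               "two classes")
  expect_error(train_classifier(list(), train_config()), "empty")
  expect_error(evaluate_model(structure(list(), class = "muscle_cnn"),
                              list()), "empty")
})
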