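#' Augmentation configuration
#'
#' The training-set augmentation is a full factorial of small rotations,
#' scalings, and Gaussian noise on/off, followed by resizing to the
#' classifier's square input resolution: with the defaults each input map
#' yields 3 x 3 x 2 = 18 variants (the identity combination included).
#' Noise is additive on normalized (0-1) intensities with mean 0.07.
#'
#' @param rotations_deg Rotation angles in degrees.
#' @param scales Zoom factors (> 1 crops in, < 1 pads out).
#' @param noise_mean,noise_sd Parameters of the additive Gaussian noise
#'   variant (applied on normalized intensities).
#' @param out_size Output resolution in pixels (square).
#' @return An `aug_config` object.
#' @export
aug_config <- function(rotations_deg = c(-1, 0, 1), scales = c(0.9, 1, 1.1),
                       noise_mean = 0.07, noise_sd = 0.07, out_size = 244) {
  if (!length(rotations_deg) || !length(scales))
    stop("rotations_deg and scales must be nonempty")
  if (out_size <= 0) stop("out_size must be positive")
  structure(list(rotations_deg = rotations_deg, scales = scales,
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 out_size = as.integer(out_size)),
            class = "aug_config")
}

#' Training configuration for the activation classifier
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param channels Channel widths of the four conv-ReLU-maxpool blocks.
#' @param seed Integer seed controlling initialization and shuffling.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16,
                         epochs = 50, channels = c(8, 16, 32, 32),
                         seed = 1) {
  if (learning_rate <= 0 || batch_size < 1 || epochs < 1)
    stop("hyperparameters must be positive")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 channels = as.integer(channels), seed = seed),
            class = "train_config")
}

#' Assemble the labeled difference-heat-map dataset
#'
#' One labeled map per session x pair: the pair's difference heat map with
#' missing cells imputed to 0 delta-C, then min-max normalized to 0-1.
#' Maps whose difference grid is degenerate (fewer than `min_defined`
#' defined cells, or any muscle region entirely missing) are excluded with
#' a warning — the quality flag that can shrink the nominal
#' sessions x pairs count.
#'
#' @param sets List of `heat_map_set`s.
#' @param labels Class label per session (one of [muscle_classes()]).
#' @param pairs Pair names to difference (default the first-vs-third-set
#'   pairs `"S1-E3"` and `"S1-S3"`).
#' @param min_defined Minimum fraction of defined cells.
#' @return List of `labeled_map`s: each has `image` (normalized matrix),
#'   `label`, `session_id`, `pair`.
#' @export
build_dataset <- function(sets, labels, pairs = c("S1-E3", "S1-S3"),
                          min_defined = 0.5) {
  stopifnot(length(sets) == length(labels))
  labels <- unname(vapply(as.character(labels), match.arg, "",
                          choices = muscle_classes()))
  out <- list()
  for (i in seq_along(sets)) {
    for (p in pairs) {
      d <- tryCatch(diff_heatmap(sets[[i]], p), error = function(e) NULL)
      ok <- !is.null(d) && mean(!is.na(d)) >= min_defined &&
        !inherits(tryCatch(region_means(d), error = identity), "error")
      if (!ok) {
        warning(sprintf("skipping session %d pair %s: degenerate map",
                        i, p))
        next
      }
      img <- unclass_map(d)
      img[is.na(img)] <- 0
      rng <- range(img)
      img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
      out[[length(out) + 1]] <- structure(
        list(image = img, label = labels[i],
             session_id = attr(sets[[i]], "session_id") %||% i, pair = p),
        class = "labeled_map")
    }
  }
  out
}

#' Random train/test split
#'
#' The test set takes `floor(test_fraction * N)` randomly selected maps;
#' the split is a partition (disjoint and exhaustive) and reproducible
#' under `seed`.
#'
#' @param dataset List of `labeled_map`s from [build_dataset()].
#' @param test_fraction Fraction of data held out (0 < f < 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` sublists.
#' @export
split_dataset <- function(dataset, test_fraction = 0.1, seed = 1) {
  n <- length(dataset)
  if (n == 0) stop("cannot split an empty dataset")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  n_test <- floor(test_fraction * n)
  idx <- withr::with_seed(seed, sample.int(n, n_test))
  list(train = dataset[setdiff(seq_len(n), idx)], test = dataset[idx])
}

#' Augment a training set
#'
#' Applies the full factorial rotations x scales x noise-on/off of
#' `config` to every input map and resizes each variant to
#' `out_size` x `out_size` (bilinear). Output count is exactly
#' `|input| * |rotations| * |scales| * 2`; labels are preserved.
#'
#' @param train List of `labeled_map`s.
#' @param config An [aug_config()].
#' @param seed Integer seed for the noise draws.
#' @return List of augmented `labeled_map`s.
#' @export
augment_maps <- function(train, config = aug_config(), seed = 1) {
  stopifnot(inherits(config, "aug_config"))
  withr::with_seed(seed, {
    out <- vector("list",
                  length(train) * length(config$rotations_deg) *
                    length(config$scales) * 2L)
    k <- 0L
    for (lm in train) {
      for (rot in config$rotations_deg) {
        for (sc in config$scales) {
          base <- transform_map(lm$image, rot, sc)
          for (noisy in c(FALSE, TRUE)) {
            img <- base
            if (noisy)
              img <- img + matrix(
                stats::rnorm(length(img), config$noise_mean,
                             config$noise_sd), nrow(img), ncol(img))
            img <- resize_map(img, config$out_size)
            k <- k + 1L
            out[[k]] <- structure(
              list(image = img, label = lm$label,
                   session_id = lm$session_id, pair = lm$pair),
              class = "labeled_map")
          }
        }
      }
    }
    out
  })
}

# rotate about the center (bilinear, background 0), then zoom: scale > 1
# enlarges and center-crops back, scale < 1 shrinks and zero-pads back
transform_map <- function(img, rot_deg, scale) {
  x <- EBImage::Image(img)
  if (rot_deg != 0)
    x <- EBImage::rotate(x, rot_deg, filter = "bilinear",
                         output.dim = dim(img), bg.col = 0)
  if (scale != 1) {
    w <- max(1L, round(dim(img)[1] * scale))
    h <- max(1L, round(dim(img)[2] * scale))
    x <- EBImage::resize(x, w = w, h = h, filter = "bilinear")
    m <- as.matrix(EBImage::imageData(x))
    full <- matrix(0, dim(img)[1], dim(img)[2])
    if (scale > 1) {
      r0 <- (nrow(m) - nrow(full)) %/% 2
      c0 <- (ncol(m) - ncol(full)) %/% 2
      full <- m[r0 + seq_len(nrow(full)), c0 + seq_len(ncol(full)),
                drop = FALSE]
    } else {
      r0 <- (nrow(full) - nrow(m)) %/% 2
      c0 <- (ncol(full) - ncol(m)) %/% 2
      full[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
    }
    return(full)
  }
  as.matrix(EBImage::imageData(x))
}

resize_map <- function(img, out_size) {
  if (all(dim(img) == out_size)) return(img)
  as.matrix(EBImage::imageData(
    EBImage::resize(EBImage::Image(img), w = out_size, h = out_size,
                    filter = "bilinear")))
}

dataset_cube <- function(maps, out_size) {
  imgs <- lapply(maps, function(m) resize_map(m$image, out_size))
  array(unlist(imgs, use.names = FALSE),
        dim = c(out_size, out_size, length(maps)))
}

#' Train the four-class activation classifier
#'
#' A small convolutional network — four conv(3x3)-ReLU-maxpool(2x2) blocks
#' and a linear softmax head — trained with Adam on cross-entropy loss.
#' Training is deterministic under `config$seed` (single-threaded). The
#' per-epoch training accuracy and loss curve is recorded.
#'
#' @param train List of `labeled_map`s (at least two classes present).
#' @param config A [train_config()].
#' @param out_size Input resolution the images are resized to.
#' @return A `muscle_cnn` model object with elements `params`, `classes`,
#'   `out_size`, `curve`.
#' @export
train_classifier <- function(train, config = train_config(),
                             out_size = 64) {
  stopifnot(inherits(config, "train_config"))
  if (!length(train)) stop("empty training set")
  classes <- muscle_classes()
  y <- match(vapply(train, `[[`, "", "label"), classes) - 1L
  if (length(unique(y)) < 2)
    stop("training set must contain at least two classes")
  X <- dataset_cube(train, out_size)
  n <- length(train)
  nblock <- length(config$channels)
  feat_hw <- out_size %/% (2^nblock)
  if (feat_hw < 1) stop("out_size too small for the network depth")
  nfeat <- feat_hw^2 * config$channels[nblock]

  withr::with_seed(config$seed, {
    cin <- c(1L, config$channels[-nblock])
    params <- list(
      W = lapply(seq_len(nblock), function(l)
        matrix(stats::rnorm(config$channels[l] * 9 * cin[l],
                            sd = sqrt(2 / (9 * cin[l]))),
               config$channels[l], 9 * cin[l])),
      b = lapply(config$channels, function(co) rep(0, co)),
      Wd = matrix(stats::rnorm(4 * nfeat, sd = sqrt(2 / nfeat)), 4, nfeat),
      bd = rep(0, 4))
    adam <- init_adam(params)
    curve <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                        accuracy = NA_real_)
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- accs <- ws <- numeric(0)
      for (b0 in seq(1, n, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
        res <- cpp_cnn_batch(X[, , idx, drop = FALSE], y[idx], params$W,
                             params$b, params$Wd, params$bd, TRUE)
        step <- step + 1L
        upd <- adam_update(params, adam, res, config$learning_rate, step)
        params <- upd$params
        adam <- upd$adam
        losses <- c(losses, res$loss)
        accs <- c(accs, res$acc)
        ws <- c(ws, length(idx))
      }
      curve$loss[ep] <- stats::weighted.mean(losses, ws)
      curve$accuracy[ep] <- stats::weighted.mean(accs, ws)
    }
  })
  structure(list(params = params, classes = classes, out_size = out_size,
                 config = config, curve = curve),
            class = "muscle_cnn")
}

init_adam <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params))
}

adam_update <- function(params, adam, res, lr, step,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  grads <- list(W = res$gW, b = res$gb, Wd = res$gWd, bd = res$gbd)
  upd1 <- function(p, m, v, g) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^step)
    vh <- v / (1 - beta2^step)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (nm in c("W", "b")) {
    for (l in seq_along(params[[nm]])) {
      u <- upd1(params[[nm]][[l]], adam$m[[nm]][[l]], adam$v[[nm]][[l]],
                grads[[nm]][[l]])
      params[[nm]][[l]] <- u$p
      adam$m[[nm]][[l]] <- u$m
      adam$v[[nm]][[l]] <- u$v
    }
  }
  for (nm in c("Wd", "bd")) {
    u <- upd1(params[[nm]], adam$m[[nm]], adam$v[[nm]], grads[[nm]])
    params[[nm]] <- u$p
    adam$m[[nm]] <- u$m
    adam$v[[nm]] <- u$v
  }
  list(params = params, adam = adam)
}

#' @export
print.muscle_cnn <- function(x, ...) {
  cat(sprintf(
    "<muscle_cnn> %d-block CNN, input %d x %d, final train acc %.3f\n",
    length(x$params$W), x$out_size, x$out_size,
    utils::tail(x$curve$accuracy, 1)))
  invisible(x)
}

#' Class probabilities for new maps
#'
#' @param object A `muscle_cnn`.
#' @param maps List of `labeled_map`s (labels ignored if present).
#' @param ... Unused.
#' @return Matrix (n x 4) of class probabilities, columns named by class.
#' @export
predict.muscle_cnn <- function(object, maps, ...) {
  X <- dataset_cube(maps, object$out_size)
  probs <- matrix(NA_real_, length(maps), 4)
  for (b0 in seq(1, length(maps), by = 64)) {
    idx <- b0:min(b0 + 63, length(maps))
    res <- cpp_cnn_batch(X[, , idx, drop = FALSE],
                         rep(-1L, length(idx)), object$params$W,
                         object$params$b, object$params$Wd,
                         object$params$bd, FALSE)
    probs[idx, ] <- res$probs
  }
  colnames(probs) <- object$classes
  probs
}

#' Evaluate the classifier on a labeled test set
#'
#' @param model A `muscle_cnn`.
#' @param test List of `labeled_map`s.
#' @return List with `accuracy`, `per_item` (data.frame of truth,
#'   prediction and class probabilities) and `confusion` (4 x 4 counts,
#'   rows = truth).
#' @export
evaluate_model <- function(model, test) {
  if (!length(test)) stop("empty test set")
  probs <- predict(model, test)
  truth <- factor(vapply(test, `[[`, "", "label"), levels = model$classes)
  pred <- factor(model$classes[max.col(probs, ties.method = "first")],
                 levels = model$classes)
  per_item <- data.frame(truth = truth, pred = pred, probs,
                         check.names = FALSE)
  list(accuracy = mean(pred == truth), per_item = per_item,
       confusion = table(truth = truth, pred = pred))
}
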