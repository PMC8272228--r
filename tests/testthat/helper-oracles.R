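# Independent oracles and small fixtures shared across tests.

# Exhaustive-search Otsu: try every one of the 256 candidate bin edges and
# maximize between-class variance directly.
otsu_bruteforce <- function(m, levels = 256) {
  r <- range(m)
  br <- seq(r[1], r[2], length.out = levels + 1)
  idx <- pmin(pmax(findInterval(m, br, rightmost.closed = TRUE), 1), levels)
  h <- as.numeric(tabulate(idx, levels))
  n <- length(m)
  best <- -Inf
  bt <- NA_real_
  for (k in 1:(levels - 1)) {
    w0 <- sum(h[1:k])
    w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:k] * (1:k)) / w0
    m1 <- sum(h[(k + 1):levels] * ((k + 1):levels)) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) {
      best <- v
      bt <- br[k + 1]
    }
  }
  bt
}

# Hand rank-sum Kruskal-Wallis statistic (no tie correction; use on
# tie-free data only).
kw_handformula <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  rk <- rank(x)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  rsum <- mapply(function(s, e) sum(rk[s:e]), starts, ends)
  12 / (n * (n + 1)) * sum(rsum^2 / sizes) - 3 * (n + 1)
}

# Index-enumeration region means: walk every cell index explicitly.
region_means_enum <- function(map) {
  nr <- nrow(map)
  nc <- ncol(map)
  acc <- c(deltoid = 0, biceps = 0, triceps = 0)
  cnt <- c(deltoid = 0, biceps = 0, triceps = 0)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- map[i, j]
      if (is.na(v)) next
      rg <- if (i <= nr %/% 2) "deltoid"
      else if (j <= nc %/% 2) "biceps"
      else "triceps"
      acc[rg] <- acc[rg] + v
      cnt[rg] <- cnt[rg] + 1
    }
  }
  acc / cnt
}

# Brute-force block means for a grid whose trailing cells absorb the
# remainder one pixel each.
block_bounds <- function(n, k) {
  base <- n %/% k
  r <- n %% k
  sizes <- rep(base, k)
  if (r > 0) sizes[(k - r + 1):k] <- base + 1
  ends <- cumsum(sizes)
  cbind(start = c(1, head(ends, -1) + 1), end = ends)
}

heatmap_bruteforce <- function(m, mask, n_rows, n_cols, min_cover = 0.5) {
  rb <- block_bounds(nrow(m), n_rows)
  cb <- block_bounds(ncol(m), n_cols)
  out <- matrix(NA_real_, n_rows, n_cols)
  for (i in seq_len(n_rows)) {
    for (j in seq_len(n_cols)) {
      rows <- rb[i, 1]:rb[i, 2]
      cols <- cb[j, 1]:cb[j, 2]
      mm <- mask[rows, cols]
      if (mean(mm) < min_cover) next
      out[i, j] <- mean(m[rows, cols][mm])
    }
  }
  out
}

# A tiny noiseless biceps session used by several tests.
tiny_session <- function(target = "biceps", noise_sd = 0, seed = 7,
                         n_sets = 3, weight_kg = 10, arm_side = "left",
                         frame_shape = c(128, 96), ...) {
  protocol <- session_protocol(n_sets, 12, recovery_s = 92,
                               weight_kg = weight_kg,
                               target_muscle = target, arm_side = arm_side)
  cfg <- sim_config(frame_shape = frame_shape, noise_sd = noise_sd,
                    seed = seed, ...)
  simulate_session(protocol, cfg)
}

# Hand-built heat-map set with constant region blocks for arithmetic tests.
constant_map_set <- function(region_values_by_label) {
  maps <- lapply(names(region_values_by_label), function(lab) {
    v <- region_values_by_label[[lab]]
    m <- matrix(NA_real_, 60, 20)
    m[1:30, ] <- v["deltoid"]
    m[31:60, 1:10] <- v["biceps"]
    m[31:60, 11:20] <- v["triceps"]
    brachytherm:::new_heat_map(m, label = lab, session_id = "hand")
  })
  names(maps) <- names(region_values_by_label)
  structure(maps, class = "heat_map_set", session_id = "hand",
            protocol = session_protocol(3, 12, recovery_s = 92))
}

# strip heat-map class/attrs but keep dim and NAs
unclass_keep_na <- function(map) {
  m <- map
  attributes(m) <- list(dim = dim(map))
  m
}
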