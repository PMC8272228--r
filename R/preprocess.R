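#' Align a frame so the biceps-facing side is on the left
#'
#' Frames of the right arm are mirrored horizontally; left-arm frames pass
#' through unchanged. The convention is stateless (aligning twice mirrors
#' twice), with columns increasing rightward.
#'
#' @param frame A [thermal_frame()].
#' @param arm_side `"left"` or `"right"`.
#' @return A [thermal_frame()].
#' @export
align_frame <- function(frame, arm_side) {
  arm_side <- match.arg(arm_side, c("left", "right"))
  if (arm_side == "left") return(frame)
  m <- frame$temperatures[, rev(seq_len(ncol(frame$temperatures))),
                          drop = FALSE]
  thermal_frame(m, timestamp_s = frame$timestamp_s)
}

#' Moving-average smoothing
#'
#' Replaces each pixel with the mean of its `kernel_rows` x `kernel_cols`
#' neighborhood, with borders handled by edge replication. Kernel
#' dimensions must be odd.
#'
#' @param frame A [thermal_frame()].
#' @param kernel_rows,kernel_cols Odd positive kernel dimensions
#'   (default 3 x 3, a minimal denoising step before global thresholding).
#' @return A smoothed [thermal_frame()].
#' @export
smooth_frame <- function(frame, kernel_rows = 3, kernel_cols = 3) {
  if (kernel_rows %% 2 == 0 || kernel_cols %% 2 == 0 ||
      kernel_rows < 1 || kernel_cols < 1)
    stop("kernel dimensions must be odd and positive")
  if (kernel_rows == 1 && kernel_cols == 1) return(frame)
  m <- frame$temperatures
  k <- matrix(1 / (kernel_rows * kernel_cols), kernel_rows, kernel_cols)
  sm <- EBImage::filter2(m, k, boundary = "replicate")
  sm <- matrix(as.numeric(sm), nrow(m), ncol(m))
  thermal_frame(sm, timestamp_s = frame$timestamp_s)
}

#' Otsu's global threshold
#'
#' Quantizes the frame into a 256-bin histogram over its min-max range and
#' returns the bin edge maximizing the between-class variance of the two
#' classes it induces.
#'
#' @param frame A [thermal_frame()] or numeric matrix.
#' @param levels Number of histogram bins.
#' @return Threshold in degrees C.
#' @export
otsu_threshold <- function(frame, levels = 256) {
  m <- if (inherits(frame, "thermal_frame")) frame$temperatures else frame
  rng <- range(m)
  if (diff(rng) == 0)
    stop("degenerate histogram: frame has a single value")
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  idx <- pmin(pmax(findInterval(m, breaks, rightmost.closed = TRUE), 1L),
              levels)
  h <- as.numeric(tabulate(idx, nbins = levels))
  n <- length(m)
  w0 <- cumsum(h)
  mu0 <- cumsum(h * seq_len(levels))
  mu_t <- mu0[levels]
  k <- seq_len(levels - 1)
  w1 <- n - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  bcv <- rep(-Inf, levels - 1)
  bcv[valid] <- (mu_t * w0[k][valid] / n - mu0[k][valid])^2 /
    (w0[k][valid] / n * (1 - w0[k][valid] / n))
  best <- which.max(bcv)
  breaks[best + 1]
}

#' Segment the arm from a thermal frame
#'
#' Thresholds the frame with [otsu_threshold()] (foreground = warmer than
#' threshold, since skin is warmer than the background), keeps the largest
#' 8-connected component, and fills its holes.
#'
#' @param frame A [thermal_frame()].
#' @param levels Histogram bins for the threshold.
#' @return An `arm_mask`: a logical matrix with attribute `threshold`.
#' @export
segment_arm <- function(frame, levels = 256) {
  th <- otsu_threshold(frame, levels)
  fg <- frame$temperatures > th
  if (!any(fg)) stop("segmentation error: empty foreground")
  lab <- cpp_label8(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- lab == keep
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
  mask <- matrix(as.logical(mask), nrow(fg), ncol(fg))
  structure(mask, class = c("arm_mask", "matrix", "array"), threshold = th)
}

#' Crop a frame and mask to the mask's tight bounding box
#'
#' @param frame A [thermal_frame()].
#' @param mask A logical matrix ([segment_arm()] output) of the same shape.
#' @return List with elements `frame` (cropped [thermal_frame()]) and
#'   `mask` (cropped logical matrix).
#' @export
crop_roi <- function(frame, mask) {
  stopifnot(all(dim(frame$temperatures) == dim(mask)))
  if (!any(mask)) stop("cannot crop: empty mask")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  f <- thermal_frame(
    frame$temperatures[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
    timestamp_s = frame$timestamp_s)
  m <- unclass(mask)[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  list(frame = f, mask = m)
}

#' Full single-frame preprocessing
#'
#' Align (biceps left), smooth, segment, crop: the standard path from a raw
#' frame to the region of interest fed to [make_heatmap()]. An optional
#' user-supplied mask override (aligned to the full frame) replaces the
#' automatic segmentation, standing in for manual touch-up.
#'
#' @param frame A [thermal_frame()].
#' @param arm_side `"left"` or `"right"`.
#' @param kernel Smoothing kernel dims `c(rows, cols)`.
#' @param mask_override Optional logical matrix replacing [segment_arm()].
#' @return List with `frame` and `mask` cropped to the arm bounding box.
#' @export
preprocess_frame <- function(frame, arm_side = "left", kernel = c(3, 3),
                             mask_override = NULL) {
  f <- align_frame(frame, arm_side)
  f <- smooth_frame(f, kernel[1], kernel[2])
  mask <- if (is.null(mask_override)) segment_arm(f) else mask_override
  crop_roi(f, mask)
}
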