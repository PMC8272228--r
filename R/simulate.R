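#' Simulation configuration for synthetic thermal sessions
#'
#' Defaults encode the study conditions the pipeline assumes: a 512 x 640 px
#' camera with thermal sensitivity (noise) 0.05 C, skin warming at
#' 0.13 C/min during exercise and 0.47 C/min during recovery, a plateau
#' after 3 min of recovery, and a warm arm-shaped ellipse on a cooler
#' background. Temperature dynamics are piecewise linear per phase; the
#' localized activation is an elliptical Gaussian hotspot centered on the
#' target muscle, on top of diffuse arm-wide warming.
#'
#' The default hotspot width is proportional to the arm's semi-axes
#' (fraction `hotspot_sigma_frac`), calibrated so that the hotspot's
#' target-quadrant mean plus the diffuse fraction makes the target-region
#' mean of the processed heat maps track the configured rates one-to-one,
#' which is what lets [session_rates()] recover them.
#'
#' @param frame_shape Frame size in pixels, `c(rows, cols)`.
#' @param frame_interval_s Seconds between consecutive frames.
#' @param baseline_skin_C Resting skin temperature inside the arm, C.
#' @param ambient_C Background temperature, C; must be below baseline.
#' @param exercise_rate Peak heating rate during active sets, C/min.
#' @param recovery_rate Peak heating rate during recovery, C/min.
#' @param plateau_after_min Minutes of recovery after which the temperature
#'   plateaus and starts to decay.
#' @param post_plateau_rate Rate after the plateau, C/min (<= 0).
#' @param nontarget_fraction Fraction of the hotspot offset applied
#'   arm-wide as diffuse warming, in `[0, 1]`.
#' @param hotspot_sigma Optional isotropic hotspot standard deviation in
#'   pixels; `NULL` (default) uses an elliptical hotspot with per-axis sigma
#'   `hotspot_sigma_frac * semi_axis`.
#' @param hotspot_sigma_frac Hotspot width as a fraction of the arm
#'   semi-axes (used when `hotspot_sigma` is `NULL`).
#' @param hotspot_jitter Uniform jitter half-width, in normalized ellipse
#'   units, applied per session to the hotspot center (stays within the
#'   target muscle's region).
#' @param noise_sd Additive i.i.d. Gaussian sensor noise, C.
#' @param arm_geometry List with `center` (row, col), `semi` (row, col
#'   semi-axes in px) and `rotation_deg`; `NULL` derives an upright ellipse
#'   from `frame_shape` (semi-axes 0.40 x rows, 0.22 x cols).
#' @param seed Optional integer seed; when set, [simulate_session()] is
#'   fully reproducible.
#' @return A `sim_config` object.
#' @export
sim_config <- function(frame_shape = c(512, 640), frame_interval_s = 4,
                       baseline_skin_C = 33, ambient_C = 25,
                       exercise_rate = 0.13, recovery_rate = 0.47,
                       plateau_after_min = 3, post_plateau_rate = -0.02,
                       nontarget_fraction = 0.3, hotspot_sigma = NULL,
                       hotspot_sigma_frac = 0.465, hotspot_jitter = 0,
                       noise_sd = 0.05, arm_geometry = NULL, seed = NULL) {
  if (ambient_C >= baseline_skin_C)
    stop("invalid config: ambient_C must be below baseline_skin_C")
  if (noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  if (nontarget_fraction < 0 || nontarget_fraction > 1)
    stop("invalid config: nontarget_fraction must be in [0, 1]")
  if (!is.null(hotspot_sigma) && hotspot_sigma <= 0)
    stop("invalid config: hotspot_sigma must be positive")
  if (post_plateau_rate > 0)
    stop("invalid config: post_plateau_rate must be <= 0")
  if (is.null(arm_geometry))
    arm_geometry <- list(center = (frame_shape + 1) / 2,
                         semi = c(0.40 * frame_shape[1],
                                  0.22 * frame_shape[2]),
                         rotation_deg = 0)
  stopifnot(all(c("center", "semi") %in% names(arm_geometry)))
  arm_geometry$rotation_deg <- arm_geometry$rotation_deg %||% 0
  structure(
    list(frame_shape = as.integer(frame_shape),
         frame_interval_s = frame_interval_s,
         baseline_skin_C = baseline_skin_C, ambient_C = ambient_C,
         exercise_rate = exercise_rate, recovery_rate = recovery_rate,
         plateau_after_min = plateau_after_min,
         post_plateau_rate = post_plateau_rate,
         nontarget_fraction = nontarget_fraction,
         hotspot_sigma = hotspot_sigma,
         hotspot_sigma_frac = hotspot_sigma_frac,
         hotspot_jitter = hotspot_jitter,
         noise_sd = noise_sd, arm_geometry = arm_geometry, seed = seed),
    class = "sim_config")
}

# normalized (v = row, u = col) hotspot centers within the unit ellipse,
# matching the heat-map region layout: deltoid upper half, biceps lower
# left, triceps lower right (rows increase downward).
hotspot_centers_norm <- list(
  deltoid = c(v = -0.45, u = 0),
  biceps  = c(v = 0.35, u = -0.45),
  triceps = c(v = 0.35, u = 0.45))

#' Pixel coordinates of a muscle's hotspot center
#'
#' Maps a target muscle to a point inside the arm ellipse lying in the
#' muscle's heat-map region: deltoid in the upper half, biceps in the
#' lower-left quadrant, triceps in the lower-right quadrant.
#'
#' @param region `"biceps"`, `"triceps"` or `"deltoid"` (`"vague"` has no
#'   center and is an error).
#' @param arm_geometry Geometry list as in [sim_config()].
#' @return Numeric `c(row, col)` pixel coordinates.
#' @export
muscle_center <- function(region, arm_geometry) {
  region <- match.arg(region, muscle_classes())
  if (region == "vague")
    stop("the vague class has no localized activation center")
  norm_to_pixel(hotspot_centers_norm[[region]], arm_geometry)
}

norm_to_pixel <- function(vu, geom) {
  d <- c(vu[1] * geom$semi[1], vu[2] * geom$semi[2])
  th <- geom$rotation_deg * pi / 180
  rot <- c(cos(th) * d[1] - sin(th) * d[2],
           sin(th) * d[1] + cos(th) * d[2])
  unname(geom$center + rot)
}

#' Cumulative hotspot temperature offset at time t
#'
#' Piecewise-linear temperature dynamics: during each active set the offset
#' grows at `exercise_rate`; during each recovery it grows at
#' `recovery_rate` until `plateau_after_min` minutes have elapsed within
#' that recovery, then follows `post_plateau_rate` (a plateau or slow
#' decay). The function is continuous in `t` and zero at `t = 0`. Passive
#' protocols (weight 0 kg) produce no offset.
#'
#' @param t Time(s) in seconds from session start (>= 0); vectorized.
#' @param protocol A [session_protocol()].
#' @param config A [sim_config()].
#' @return Offset(s) in degrees C.
#' @export
target_offset <- function(t, protocol, config) {
  if (any(t < 0)) stop("t must be nonnegative")
  if (protocol$weight_kg == 0) return(rep(0, length(t)))
  seg <- offset_segments(protocol, config)
  off <- numeric(length(t))
  for (i in seq_len(nrow(seg))) {
    overlap <- pmax(0, pmin(t, seg$t1[i]) - seg$t0[i])
    off <- off + seg$rate_per_s[i] * overlap
  }
  off
}

# segment table (t0, t1, rate per second) implementing the phase rules
offset_segments <- function(protocol, config) {
  ph <- session_phases(protocol)
  plateau_s <- config$plateau_after_min * 60
  segs <- list()
  for (i in seq_len(nrow(ph))) {
    if (ph$phase[i] == "active") {
      segs[[length(segs) + 1]] <-
        data.frame(t0 = ph$t0[i], t1 = ph$t1[i],
                   rate_per_s = config$exercise_rate / 60)
    } else {
      cut <- min(ph$t1[i], ph$t0[i] + plateau_s)
      segs[[length(segs) + 1]] <-
        data.frame(t0 = ph$t0[i], t1 = cut,
                   rate_per_s = config$recovery_rate / 60)
      if (ph$t1[i] > cut)
        segs[[length(segs) + 1]] <-
          data.frame(t0 = cut, t1 = ph$t1[i],
                     rate_per_s = config$post_plateau_rate / 60)
    }
  }
  do.call(rbind, segs)
}

# static per-session scene geometry: inside mask and normalized coords
scene_geometry <- function(config) {
  g <- config$arm_geometry
  nr <- config$frame_shape[1]; nc <- config$frame_shape[2]
  r <- matrix(seq_len(nr), nr, nc) - g$center[1]
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc) - g$center[2]
  th <- -g$rotation_deg * pi / 180
  dr <- cos(th) * r - sin(th) * cc
  dc <- sin(th) * r + cos(th) * cc
  v <- dr / g$semi[1]
  u <- dc / g$semi[2]
  list(inside = v^2 + u^2 <= 1, v = v, u = u, geom = g)
}

render_frame_impl <- function(t, protocol, config, scene,
                              hotspot_norm = NULL) {
  off <- target_offset(t, protocol, config)
  m <- matrix(config$ambient_C, config$frame_shape[1], config$frame_shape[2])
  inside <- scene$inside
  m[inside] <- config$baseline_skin_C + config$nontarget_fraction * off
  target <- protocol$target_muscle
  if (target != "vague" && off != 0) {
    ctr <- hotspot_norm %||% hotspot_centers_norm[[target]]
    # the scene is the raw camera view: on a right arm the biceps faces the
    # image's right side, and align_frame() later mirrors it to the left
    if (protocol$arm_side == "right") ctr[2] <- -ctr[2]
    if (is.null(config$hotspot_sigma)) {
      k <- config$hotspot_sigma_frac
      bump <- exp(-((scene$v[inside] - ctr[1])^2 +
                      (scene$u[inside] - ctr[2])^2) / (2 * k^2))
    } else {
      px <- norm_to_pixel(ctr, scene$geom)
      nr <- config$frame_shape[1]
      rows <- matrix(seq_len(nr), nr, config$frame_shape[2])[inside]
      cols <- matrix(rep(seq_len(config$frame_shape[2]), each = nr),
                     nr, config$frame_shape[2])[inside]
      d2 <- (rows - px[1])^2 + (cols - px[2])^2
      bump <- exp(-d2 / (2 * config$hotspot_sigma^2))
    }
    m[inside] <- m[inside] + off * bump
  }
  if (config$noise_sd > 0)
    m <- m + matrix(stats::rnorm(length(m), 0, config$noise_sd),
                    nrow(m), ncol(m))
  thermal_frame(m, timestamp_s = t)
}

#' Render one synthetic thermal frame
#'
#' Pixels outside the arm ellipse sit at ambient temperature; inside, the
#' baseline skin temperature plus diffuse warming
#' (`nontarget_fraction * offset`) plus, for non-vague targets, a Gaussian
#' hotspot of peak [target_offset()] centered on the target muscle. i.i.d.
#' Gaussian sensor noise is added last (uses the current RNG state).
#'
#' @inheritParams target_offset
#' @param t Time in seconds.
#' @return A [thermal_frame()].
#' @export
render_frame <- function(t, protocol, config) {
  stopifnot(length(t) == 1)
  render_frame_impl(t, protocol, config, scene_geometry(config))
}

#' Construct a session recording
#'
#' @param frames List of [thermal_frame()] with strictly increasing
#'   timestamps and a common shape.
#' @param protocol The [session_protocol()] the frames follow.
#' @param subject_id,session_id Identifiers.
#' @return A `session_recording` object.
#' @export
session_recording <- function(frames, protocol, subject_id = "sim",
                              session_id = "sim") {
  stopifnot(length(frames) >= 1, inherits(protocol, "session_protocol"))
  ts <- vapply(frames, `[[`, 0, "timestamp_s")
  if (any(diff(ts) <= 0))
    stop("frame timestamps must be strictly increasing")
  shp <- vapply(frames, function(f) dim(f$temperatures), integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("all frames must share one shape")
  last_needed <- max(frame_times(protocol)$time_s)
  if (max(ts) < last_needed)
    stop(sprintf("recording ends at %g s but the protocol needs %g s",
                 max(ts), last_needed))
  structure(list(frames = frames, protocol = protocol,
                 subject_id = subject_id, session_id = session_id),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  ts <- vapply(x$frames, `[[`, 0, "timestamp_s")
  cat(sprintf("<session_recording> %s/%s: %d frames, %g..%g s, %d x %d px\n",
              x$subject_id, x$session_id, length(x$frames), min(ts), max(ts),
              nrow(x$frames[[1]]$temperatures),
              ncol(x$frames[[1]]$temperatures)))
  print(x$protocol)
  invisible(x)
}

#' Simulate a full thermal session recording
#'
#' Frames are rendered at multiples of `frame_interval_s` from t = 0
#' through the end of the last set (plus `extra_s`, e.g. to observe the
#' final recovery). With `config$seed` set the recording is bit-identical
#' across calls. A per-session hotspot-center jitter (uniform within the
#' target muscle's region) is drawn once when `config$hotspot_jitter > 0`.
#'
#' @inheritParams target_offset
#' @param subject_id,session_id Identifiers attached to the recording.
#' @param extra_s Seconds to keep recording after the last set ends.
#' @return A `session_recording`.
#' @export
simulate_session <- function(protocol, config, subject_id = "sim",
                             session_id = "sim", extra_s = 0) {
  if (config$frame_interval_s <= 0)
    stop("invalid config: frame_interval_s must be positive")
  run <- function() {
    hotspot <- NULL
    if (protocol$target_muscle != "vague" && config$hotspot_jitter > 0)
      hotspot <- jitter_hotspot(protocol$target_muscle,
                                config$hotspot_jitter)
    t_end <- max(frame_times(protocol)$time_s) + extra_s
    times <- seq(0, t_end, by = config$frame_interval_s)
    scene <- scene_geometry(config)
    frames <- lapply(times, render_frame_impl, protocol = protocol,
                     config = config, scene = scene, hotspot_norm = hotspot)
    session_recording(frames, protocol, subject_id, session_id)
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

# draw a jittered hotspot center, kept inside the muscle's region and the
# unit ellipse (rejection with a clamped fallback)
jitter_hotspot <- function(target, jitter) {
  nom <- hotspot_centers_norm[[target]]
  box <- switch(target,
    deltoid = list(v = c(-0.75, -0.1), u = c(-0.6, 0.6)),
    biceps  = list(v = c(0.1, 0.7), u = c(-0.75, -0.1)),
    triceps = list(v = c(0.1, 0.7), u = c(0.1, 0.75)))
  for (i in 1:20) {
    cand <- nom + stats::runif(2, -jitter, jitter)
    ok <- cand[1] >= box$v[1] && cand[1] <= box$v[2] &&
      cand[2] >= box$u[1] && cand[2] <= box$u[2] &&
      sum(cand^2) <= 0.85
    if (ok) return(cand)
  }
  nom
}
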