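#' Simulate a cohort of training sessions as heat-map sets
#'
#' Generates synthetic sessions under the multi-muscle study conditions —
#' three sets of twelve repetitions at 15 rpm with 92 s recovery, 5 or
#' 10 kg, both arms — runs each recording through preprocessing and
#' [select_set_heatmaps()], and returns the per-session heat-map sets with
#' their class labels. Sessions labeled `"vague"` are simulated as diffuse
#' warming with no localized hotspot.
#'
#' With `randomize = TRUE` (the default), per-session baseline skin
#' temperature, heating rates and hotspot position are drawn from ranges
#' around the nominal values (baseline 32-34 C; exercise rate
#' 0.10-0.16 C/min; recovery rate 0.40-0.54 C/min; hotspot jitter 0.1
#' normalized units), emulating between-subject and between-session
#' variability. With `randomize = FALSE` every session uses the nominal
#' configuration exactly.
#'
#' @param targets Character vector of session labels (one of
#'   [muscle_classes()] per session); its length sets the cohort size.
#' @param seed Integer seed; the whole cohort is reproducible under it.
#' @param frame_shape Simulated frame size (desk-scale default 128 x 96).
#' @param noise_sd Sensor noise, C.
#' @param randomize Randomize per-session baseline/rates/hotspot position.
#' @param grid Heat-map grid `c(rows, cols)`.
#' @param weight_kg Dumbbell weights sampled per session.
#' @param config_fn Optional function `(i, target)` returning a
#'   [sim_config()] to fully override the per-session configuration.
#' @return List with `sets` (list of `heat_map_set`), `labels`,
#'   `protocols`.
#' @export
simulate_cohort <- function(targets, seed = 1, frame_shape = c(128, 96),
                            noise_sd = 0.05, randomize = TRUE,
                            grid = c(60, 20), weight_kg = c(5, 10),
                            config_fn = NULL) {
  targets <- unname(vapply(as.character(targets), match.arg, "",
                           choices = muscle_classes()))
  withr::with_seed(seed, {
    sets <- vector("list", length(targets))
    protocols <- vector("list", length(targets))
    for (i in seq_along(targets)) {
      arm <- c("left", "right")[1 + (i %% 2)]
      protocol <- session_protocol(
        n_sets = 3, reps_per_set = 12, rep_rate = 15, recovery_s = 92,
        weight_kg = if (length(weight_kg) > 1) sample(weight_kg, 1)
                    else weight_kg,
        target_muscle = targets[i], arm_side = arm)
      cfg <- if (!is.null(config_fn)) config_fn(i, targets[i])
      else if (randomize) {
        sim_config(frame_shape = frame_shape, noise_sd = noise_sd,
                   baseline_skin_C = stats::runif(1, 32, 34),
                   exercise_rate = stats::runif(1, 0.10, 0.16),
                   recovery_rate = stats::runif(1, 0.40, 0.54),
                   hotspot_jitter = 0.1)
      } else {
        sim_config(frame_shape = frame_shape, noise_sd = noise_sd)
      }
      rec <- simulate_session(protocol, cfg,
                              subject_id = sprintf("sub%02d", i),
                              session_id = sprintf("ses%03d", i))
      sets[[i]] <- select_set_heatmaps(rec, n_rows = grid[1],
                                       n_cols = grid[2])
      protocols[[i]] <- protocol
    }
    list(sets = sets, labels = targets, protocols = protocols)
  })
}

#' Balanced cohort labels
#'
#' Convenience for building a cohort with `n_per_class` sessions of each
#' class, in interleaved order.
#'
#' @param n_per_class Sessions per class.
#' @param classes Classes to include.
#' @return Character vector of labels.
#' @export
cohort_labels <- function(n_per_class,
                          classes = muscle_classes()) {
  rep(classes, times = n_per_class)
}
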