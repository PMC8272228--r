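#' Muscle activation classes
#'
#' The four labels used throughout the pipeline: the three target muscles of
#' the brachium plus `"vague"`, meaning no valid localized muscle activation
#' was observed.
#'
#' @return Character vector of the four class labels.
#' @export
muscle_classes <- function() c("biceps", "triceps", "deltoid", "vague")

#' Construct a resistance-training session protocol
#'
#' A protocol describes one recorded session: how many sets were performed,
#' the repetitions per set, the metronome rate, any passive (no-movement)
#' hold appended to each set, the recovery time between sets, the dumbbell
#' weight and the target muscle. Weight 0 encodes passive/control training.
#'
#' @param n_sets Number of sets (>= 1).
#' @param reps_per_set Repetitions per set (>= 1).
#' @param rep_rate Repetition rate in repetitions per minute (> 0); the
#'   study metronome ran at 15.
#' @param passive_s Seconds of passive (no movement, holding weight) training
#'   appended to each set.
#' @param recovery_s Recovery time in seconds between sets.
#' @param weight_kg Dumbbell weight in kg; 0 means passive/control.
#' @param target_muscle One of `"biceps"`, `"triceps"`, `"deltoid"`, or
#'   `"vague"` for control sessions with no valid localized activation.
#' @param arm_side `"left"` or `"right"`.
#' @return A `session_protocol` object.
#' @examples
#' session_protocol(3, 12, recovery_s = 92, weight_kg = 10,
#'                  target_muscle = "biceps", arm_side = "left")
#' @export
session_protocol <- function(n_sets, reps_per_set, rep_rate = 15,
                             passive_s = 0, recovery_s = 92, weight_kg = 10,
                             target_muscle = "biceps", arm_side = "left") {
  stopifnot(length(n_sets) == 1, length(reps_per_set) == 1)
  if (n_sets < 1 || reps_per_set < 1)
    stop("invalid protocol: n_sets and reps_per_set must be >= 1")
  if (rep_rate <= 0) stop("invalid protocol: rep_rate must be positive")
  if (passive_s < 0 || recovery_s < 0)
    stop("invalid protocol: passive_s and recovery_s must be >= 0")
  if (weight_kg < 0) stop("invalid protocol: weight_kg must be >= 0")
  target_muscle <- match.arg(target_muscle, muscle_classes())
  arm_side <- match.arg(arm_side, c("left", "right"))
  structure(
    list(n_sets = as.integer(n_sets), reps_per_set = as.integer(reps_per_set),
         rep_rate = rep_rate, passive_s = passive_s, recovery_s = recovery_s,
         weight_kg = weight_kg, target_muscle = target_muscle,
         arm_side = arm_side),
    class = "session_protocol")
}

#' @export
print.session_protocol <- function(x, ...) {
  cat(sprintf(
    "<session_protocol> %d set(s) x %d reps @ %g rpm (+%g s passive), %g s recovery, %g kg, target %s, %s arm\n",
    x$n_sets, x$reps_per_set, x$rep_rate, x$passive_s, x$recovery_s,
    x$weight_kg, x$target_muscle, x$arm_side))
  invisible(x)
}

#' Duration of one training set
#'
#' A set of `reps` repetitions at `rep_rate` repetitions per minute lasts
#' `reps / rep_rate * 60` seconds, plus any passive holding time. At the
#' study rate of 15 rpm, 12 reps take 48 s, 15 reps take 60 s, and 8 reps
#' plus a 4 s passive hold take 36 s.
#'
#' @param reps Repetitions in the set (>= 1).
#' @param rep_rate Repetitions per minute (> 0).
#' @param passive_s Passive training seconds appended to the set.
#' @return Set duration in seconds.
#' @examples
#' set_duration(12, 15)      # 48
#' set_duration(8, 15, 4)    # 36
#' @export
set_duration <- function(reps, rep_rate = 15, passive_s = 0) {
  if (any(rep_rate <= 0)) stop("invalid protocol: rep_rate must be positive")
  if (any(reps < 1)) stop("invalid protocol: reps must be >= 1")
  reps / rep_rate * 60 + passive_s
}

#' Frame-selection times for a session
#'
#' Computes the timestamps of the start (S) and end (E) of every set, with
#' t = 0 at the first frame of the session (S1). These are the times at
#' which heat maps S1..Sn and E1..En are taken.
#'
#' @param protocol A [session_protocol()].
#' @return A data.frame with columns `label` (S1, E1, S2, ...) and `time_s`,
#'   strictly increasing, of length `2 * n_sets`.
#' @examples
#' p <- session_protocol(3, 12, recovery_s = 92)
#' frame_times(p)
#' @export
frame_times <- function(protocol) {
  stopifnot(inherits(protocol, "session_protocol"))
  dur <- set_duration(protocol$reps_per_set, protocol$rep_rate,
                      protocol$passive_s)
  n <- protocol$n_sets
  starts <- (seq_len(n) - 1) * (dur + protocol$recovery_s)
  ends <- starts + dur
  out <- data.frame(
    label = as.vector(rbind(paste0("S", seq_len(n)), paste0("E", seq_len(n)))),
    time_s = as.vector(rbind(starts, ends)),
    stringsAsFactors = FALSE)
  out
}

# Phase table used by the simulator and rate recovery: one row per
# active/recovery phase with start, end (Inf for the trailing recovery).
session_phases <- function(protocol) {
  ft <- frame_times(protocol)
  n <- protocol$n_sets
  starts <- ft$time_s[seq(1, 2 * n, by = 2)]
  ends <- ft$time_s[seq(2, 2 * n, by = 2)]
  phases <- data.frame(
    phase = rep(c("active", "recovery"), n),
    set = rep(seq_len(n), each = 2),
    t0 = as.vector(rbind(starts, ends)),
    t1 = as.vector(rbind(ends, c(starts[-1], Inf))),
    stringsAsFactors = FALSE)
  phases
}
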