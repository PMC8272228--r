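#' Average temperature elevation rate
#'
#' Rate of skin-temperature change over a phase, in degrees C per minute.
#' The reported rate is half-even rounded to two decimals, matching
#' field-standard reporting; the raw value is retained.
#'
#' @param T_start,T_end Temperatures at the phase boundaries, C.
#' @param duration_min Phase duration in minutes (> 0).
#' @return A `rate_result` list with `rate` (2-decimal), `rate_raw`,
#'   `T_start`, `T_end`, `duration_min`.
#' @examples
#' elevation_rate(35.98, 36.11, 1)$rate   # 0.13
#' @export
elevation_rate <- function(T_start, T_end, duration_min) {
  if (duration_min <= 0) stop("duration must be positive")
  raw <- (T_end - T_start) / duration_min
  structure(list(rate = round(raw, 2), rate_raw = raw, T_start = T_start,
                 T_end = T_end, duration_min = duration_min),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("<rate_result> %.2f C/min (%.2f -> %.2f C over %g min)\n",
              x$rate, x$T_start, x$T_end, x$duration_min))
  invisible(x)
}

#' Recover phase heating rates from a session's heat maps
#'
#' Estimates the exercise-phase and recovery-phase elevation rates of the
#' target muscle region from the S/E heat-map trajectory: the exercise rate
#' averages (E_i - S_i) over the set duration for each set, the recovery
#' rate averages (S_(i+1) - E_i) over the recovery time for recoveries not
#' exceeding `plateau_min` minutes.
#'
#' @param set A `heat_map_set` (with its protocol attribute), e.g. from
#'   [select_set_heatmaps()].
#' @param target Region to track; defaults to the protocol's target muscle.
#' @param plateau_min Recoveries longer than this are skipped (the plateau
#'   would bias the linear rate).
#' @return List with `exercise_rate` and `recovery_rate` in C/min (raw,
#'   unrounded) and the per-set region temperatures `trajectory`.
#' @export
session_rates <- function(set, target = NULL, plateau_min = 3) {
  protocol <- attr(set, "protocol")
  stopifnot(inherits(protocol, "session_protocol"))
  if (is.null(target)) target <- protocol$target_muscle
  ft <- frame_times(protocol)
  temps <- vapply(ft$label, function(l) region_means(set[[l]])[target], 0)
  n <- protocol$n_sets
  dur_min <- set_duration(protocol$reps_per_set, protocol$rep_rate,
                          protocol$passive_s) / 60
  ex <- mean(vapply(seq_len(n), function(i)
    (temps[paste0("E", i)] - temps[paste0("S", i)]) / dur_min, 0))
  rec <- NA_real_
  if (n > 1 && protocol$recovery_s / 60 <= plateau_min) {
    rec <- mean(vapply(seq_len(n - 1), function(i)
      (temps[paste0("S", i + 1)] - temps[paste0("E", i)]) /
        (protocol$recovery_s / 60), 0))
  }
  list(exercise_rate = ex, recovery_rate = rec,
       trajectory = data.frame(label = ft$label, time_s = ft$time_s,
                               temp = unname(temps)))
}

#' Target-vs-nontarget temperature-difference trajectory
#'
#' For each heat map of a session (S1, E1, ..., En) emits the target
#' muscle's region mean minus each nontarget muscle's region mean: the
#' spatial contrast that localizes the activation.
#'
#' @param set A `heat_map_set`.
#' @param target Target muscle (not `"vague"`).
#' @return data.frame with columns `label`, `nontarget`, `delta` (C).
#' @export
region_difference_trajectory <- function(set, target) {
  target <- match.arg(target, muscle_classes())
  if (target == "vague")
    stop("trajectories need a concrete target muscle")
  nontargets <- setdiff(c("deltoid", "biceps", "triceps"), target)
  labs <- names(set)
  out <- do.call(rbind, lapply(labs, function(l) {
    rm_ <- region_means(set[[l]])
    data.frame(label = l, nontarget = nontargets,
               delta = unname(rm_[target] - rm_[nontargets]),
               stringsAsFactors = FALSE)
  }))
  out$label <- factor(out$label, levels = labs)
  out
}

#' Aggregate difference trajectories across sessions
#'
#' @param sets List of `heat_map_set`s.
#' @param targets Target muscle per session.
#' @return data.frame with mean and standard deviation of the
#'   target-minus-nontarget difference per label and nontarget.
#' @export
trajectory_summary <- function(sets, targets) {
  stopifnot(length(sets) == length(targets))
  all <- do.call(rbind, lapply(seq_along(sets), function(i) {
    tr <- region_difference_trajectory(sets[[i]], targets[i])
    tr$session <- i
    tr
  }))
  agg <- stats::aggregate(delta ~ label + nontarget, data = all,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  data.frame(label = agg$label, nontarget = agg$nontarget,
             mean = agg$delta[, "mean"], sd = agg$delta[, "sd"])
}

#' Kruskal-Wallis rank test across groups
#'
#' Nonparametric test for a location difference among two or more
#' independent groups of temperature differences, used to test whether
#' training order affects heating. The statistic uses rank sums with tie
#' correction; the p-value comes from the chi-squared approximation with
#' k - 1 degrees of freedom, or from a label-permutation null when
#' `exact = TRUE` (useful for very small groups).
#'
#' @param groups List of (>= 2) nonempty numeric vectors.
#' @param exact Use a permutation p-value instead of the chi-squared
#'   approximation.
#' @param n_perm Number of permutations when `exact = TRUE`.
#' @return An `order_test_result` list: `H`, `p`, `df`, `group_sizes`.
#' @export
kruskal_wallis <- function(groups, exact = FALSE, n_perm = 10000) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  if (any(lengths(groups) == 0)) stop("all groups must be nonempty")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1) {
    # complete ties: no rank information at all, H = 0 by convention
    return(structure(list(H = 0, p = 1, df = length(groups) - 1L,
                          group_sizes = lengths(groups),
                          method = "chi-squared"),
                     class = "order_test_result"))
  }
  kt <- stats::kruskal.test(x, g)
  H <- unname(kt$statistic)
  p <- kt$p.value
  if (exact) {
    stat1 <- function(xx) {
      unname(stats::kruskal.test(xx, g)$statistic)
    }
    perms <- vapply(seq_len(n_perm), function(i) stat1(sample(x)), 0)
    p <- (1 + sum(perms >= H)) / (n_perm + 1)
  }
  structure(list(H = H, p = p, df = unname(kt$parameter),
                 group_sizes = lengths(groups),
                 method = if (exact) "permutation" else "chi-squared"),
            class = "order_test_result")
}

#' @export
print.order_test_result <- function(x, ...) {
  cat(sprintf("<order_test> H = %.4g, df = %d, p = %.4g (%s), n = %s\n",
              x$H, x$df, x$p, x$method,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}
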