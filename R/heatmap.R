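#' Admissible heat-map pairs for difference maps
#'
#' The five pairs compared per session, from earliest to latest second
#' member; the first member is always S1. Names follow the field's
#' "(S1-E3)" notation, which names the pair (the difference itself is
#' computed later-minus-earlier so heating is positive).
#'
#' @return A named list of `c(earlier, later)` label pairs.
#' @export
heatmap_pairs <- function() {
  list("S1-E1" = c("S1", "E1"), "S1-S2" = c("S1", "S2"),
       "S1-E2" = c("S1", "E2"), "S1-S3" = c("S1", "S3"),
       "S1-E3" = c("S1", "E3"))
}

# tie-break preference: later pair wins; index into this order
pair_preference <- c("S1-E1", "S1-S2", "S1-E2", "S1-S3", "S1-E3")

new_heat_map <- function(cells, label = NA_character_,
                         session_id = NA_character_) {
  structure(cells, class = c("heat_map", "matrix", "array"),
            label = label, session_id = session_id)
}

#' Build a grid heat map from a segmented ROI
#'
#' Partitions the ROI bounding box into `n_rows` x `n_cols` near-equal
#' rectangles (remainder pixels go to the last row/column of cells) and
#' takes the mean temperature of the masked (foreground) pixels in each
#' cell. Cells whose masked-pixel fraction is below `min_cover` are marked
#' missing (`NA`). The default 60 x 20 grid follows the study's division of
#' the arm into 20 sections across and 60 down.
#'
#' @param roi_frame Cropped [thermal_frame()] from [crop_roi()].
#' @param roi_mask Matching logical mask (`NULL` = all foreground).
#' @param n_rows,n_cols Grid dimensions.
#' @param label Heat-map label (`"S1"`..`"E3"`).
#' @param session_id Session identifier.
#' @param min_cover Minimum masked-pixel fraction for a cell to be defined.
#' @return A `heat_map`: `n_rows` x `n_cols` numeric matrix with `NA`
#'   missing cells and attributes `label` and `session_id`.
#' @export
make_heatmap <- function(roi_frame, roi_mask = NULL, n_rows = 60,
                         n_cols = 20, label = NA_character_,
                         session_id = NA_character_, min_cover = 0.5) {
  m <- roi_frame$temperatures
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(m), ncol(m))
  stopifnot(all(dim(m) == dim(roi_mask)))
  if (nrow(m) < n_rows || ncol(m) < n_cols)
    stop(sprintf("ROI %d x %d px is smaller than the %d x %d grid",
                 nrow(m), ncol(m), n_rows, n_cols))
  ri <- grid_index(nrow(m), n_rows)
  ci <- grid_index(ncol(m), n_cols)
  cell <- (matrix(ci, nrow(m), ncol(m), byrow = TRUE) - 1L) * n_rows +
    matrix(ri, nrow(m), ncol(m))
  npix <- tabulate(cell, nbins = n_rows * n_cols)
  nfg <- tabulate(cell[roi_mask], nbins = n_rows * n_cols)
  sumfg <- as.vector(rowsum(m[roi_mask], cell[roi_mask]))
  vals <- rep(NA_real_, n_rows * n_cols)
  vals[sort(unique(cell[roi_mask]))] <- sumfg / nfg[nfg > 0]
  vals[nfg / npix < min_cover] <- NA_real_
  new_heat_map(matrix(vals, n_rows, n_cols), label, session_id)
}

# assign 1..n pixels to 1..k near-equal cells: base size floor(n/k), the
# n %% k remainder pixels go one each to the trailing cells
grid_index <- function(n, k) {
  base <- n %/% k
  r <- n %% k
  sizes <- rep(base, k)
  if (r > 0) sizes[(k - r + 1):k] <- base + 1L
  rep(seq_len(k), times = sizes)
}

#' @export
print.heat_map <- function(x, ...) {
  cat(sprintf("<heat_map %s> %d x %d cells, %d missing, range [%.2f, %.2f]\n",
              attr(x, "label"), nrow(x), ncol(x), sum(is.na(x)),
              min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

#' Select and build the six per-set heat maps of a session
#'
#' For each set, the frame at (or just after) the set start and at (or just
#' before) the set end is preprocessed ([preprocess_frame()]) and converted
#' to a heat map, yielding labels S1..Sn and E1..En.
#'
#' @param recording A `session_recording`.
#' @param n_rows,n_cols Grid dimensions.
#' @param kernel Smoothing kernel passed to [preprocess_frame()].
#' @return A `heat_map_set`: named list of `heat_map`s with attributes
#'   `session_id`, `protocol`.
#' @export
select_set_heatmaps <- function(recording, n_rows = 60, n_cols = 20,
                                kernel = c(3, 3)) {
  stopifnot(inherits(recording, "session_recording"))
  ft <- frame_times(recording$protocol)
  ts <- vapply(recording$frames, `[[`, 0, "timestamp_s")
  maps <- vector("list", nrow(ft))
  names(maps) <- ft$label
  for (i in seq_len(nrow(ft))) {
    is_start <- startsWith(ft$label[i], "S")
    idx <- if (is_start) {
      cand <- which(ts >= ft$time_s[i])
      if (!length(cand))
        stop("timeline error: no frame at or after ", ft$time_s[i], " s")
      cand[1]
    } else {
      cand <- which(ts <= ft$time_s[i])
      if (!length(cand))
        stop("timeline error: no frame at or before ", ft$time_s[i], " s")
      cand[length(cand)]
    }
    roi <- preprocess_frame(recording$frames[[idx]],
                            arm_side = recording$protocol$arm_side,
                            kernel = kernel)
    maps[[i]] <- make_heatmap(roi$frame, roi$mask, n_rows, n_cols,
                              label = ft$label[i],
                              session_id = recording$session_id)
  }
  structure(maps, class = "heat_map_set",
            session_id = recording$session_id,
            protocol = recording$protocol)
}

#' @export
print.heat_map_set <- function(x, ...) {
  cat(sprintf("<heat_map_set %s> maps: %s\n", attr(x, "session_id"),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Difference heat map for a labeled pair
#'
#' Cellwise later-minus-earlier temperature change, so heating is positive;
#' a cell is missing if it is missing in either operand.
#'
#' @param set A `heat_map_set`.
#' @param pair Pair name (`"S1-E3"`) or `c(earlier, later)` labels.
#' @return A `diff_heat_map` with attribute `pair`.
#' @export
diff_heatmap <- function(set, pair) {
  pair <- resolve_pair(pair)
  if (!all(pair %in% names(set)))
    stop("unknown heat map label(s): ", paste(pair, collapse = ", "))
  d <- unclass_map(set[[pair[2]]]) - unclass_map(set[[pair[1]]])
  structure(d, class = c("diff_heat_map", "matrix", "array"),
            pair = pair, session_id = attr(set, "session_id"))
}

resolve_pair <- function(pair) {
  if (length(pair) == 1) {
    p <- heatmap_pairs()[[pair]]
    if (is.null(p)) {
      labs <- strsplit(pair, "-", fixed = TRUE)[[1]]
      if (length(labs) != 2) stop("unknown pair: ", pair)
      p <- labs
    }
    p
  } else {
    stopifnot(length(pair) == 2)
    as.character(pair)
  }
}

#' Muscle-region means of a heat map
#'
#' The grid is divided into three fixed regions mirroring muscle anatomy on
#' the aligned arm: the upper half of the rows is the deltoid, the
#' lower-left quadrant the biceps, and the lower-right quadrant the
#' triceps. Missing cells are excluded; a region with no defined cells is
#' an error.
#'
#' @param map A `heat_map` or `diff_heat_map`.
#' @return Named numeric vector `c(deltoid, biceps, triceps)` in degrees C
#'   (or delta-C for difference maps).
#' @export
region_means <- function(map) {
  nr <- nrow(map); nc <- ncol(map)
  half_r <- nr %/% 2; half_c <- nc %/% 2
  m <- unclass_map(map)
  regions <- list(
    deltoid = m[seq_len(half_r), , drop = FALSE],
    biceps = m[(half_r + 1):nr, seq_len(half_c), drop = FALSE],
    triceps = m[(half_r + 1):nr, (half_c + 1):nc, drop = FALSE])
  out <- vapply(names(regions), function(rg) {
    v <- regions[[rg]]
    if (all(is.na(v)))
      stop("region undefined: all cells missing in ", rg, " region")
    mean(v, na.rm = TRUE)
  }, 0)
  out
}

#' Temperature-difference score of a heat-map pair for a target muscle
#'
#' The target muscle's region mean of the pair's difference heat map: how
#' much the target region warmed between the two time points.
#'
#' @param set A `heat_map_set`.
#' @param target Target muscle (not `"vague"`).
#' @param pair Pair name or label pair (see [diff_heatmap()]).
#' @return Temperature difference in delta-C.
#' @export
pair_score <- function(set, target, pair) {
  target <- match.arg(target, muscle_classes())
  if (target == "vague") stop("pair_score needs a concrete target muscle")
  unname(region_means(diff_heatmap(set, pair))[target])
}

#' Best heat-map pair of a session
#'
#' Scores every admissible pair with [pair_score()] and returns the name of
#' the maximal one; ties break toward the later pair
#' (E3 > S3 > E2 > S2 > E1).
#'
#' @inheritParams pair_score
#' @return Pair name, e.g. `"S1-E3"`.
#' @export
rank_pairs <- function(set, target) {
  scores <- vapply(names(heatmap_pairs()), function(p)
    pair_score(set, target, p), 0)
  ord <- match(names(scores), pair_preference)
  best <- which(scores == max(scores))
  names(scores)[best[which.max(ord[best])]]
}

#' Tabulate best pairs across sessions
#'
#' Counts, per admissible pair, how many sessions attained their highest
#' target-region temperature difference at that pair, with floor-rounded
#' integer percentages.
#'
#' @param best_pairs Character vector of per-session best pairs
#'   ([rank_pairs()] output), or a named integer vector of counts per pair.
#' @return data.frame with columns `pair`, `count`, `pct` ordered latest
#'   pair first.
#' @export
pair_rank_table <- function(best_pairs) {
  if (is.numeric(best_pairs)) {
    counts <- best_pairs[intersect(rev(pair_preference), names(best_pairs))]
  } else {
    if (!length(best_pairs)) stop("no sessions to tabulate")
    counts <- table(factor(best_pairs, levels = rev(pair_preference)))
  }
  total <- sum(counts)
  data.frame(pair = names(counts), count = as.integer(counts),
             pct = floor(as.integer(counts) / total * 100),
             stringsAsFactors = FALSE)
}

#' Share of sessions peaking at first-and-third-set pairs
#'
#' The fraction (floor-rounded integer percent) of sessions whose best pair
#' spans the first and third sets, i.e. (S1-E3) or (S1-S3).
#'
#' @param rank_table Output of [pair_rank_table()].
#' @return Integer percentage.
#' @export
first_third_share <- function(rank_table) {
  sel <- rank_table$pair %in% c("S1-E3", "S1-S3")
  floor(sum(rank_table$count[sel]) / sum(rank_table$count) * 100)
}
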