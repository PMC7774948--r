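#' Restrict a trace to a set of time windows
#'
#' Keeps the samples whose timestamps fall in any of the half-open windows
#' `[start, end)`. Used to confine the coordination analysis to the
#' visual-search trials.
#'
#' @param trace an `effector_trace`.
#' @param windows data.frame with columns `start` and `end` (seconds),
#'   non-overlapping and sorted.
#' @return An `effector_trace` containing the concatenated window samples.
#' @export
restrict_to_trials <- function(trace, windows) {
  stopifnot(is_effector_trace(trace))
  if (nrow(windows) == 0) {
    return(effector_trace(numeric(0), numeric(0), numeric(0), logical(0),
                          effector = trace$effector, frame = trace$frame,
                          rate = trace$rate))
  }
  if (is.unsorted(windows$start) ||
      any(windows$start[-1] < windows$end[-nrow(windows)]))
    stop("windows must be sorted and non-overlapping", call. = FALSE)
  t <- trace$samples$t
  keep <- rep(FALSE, length(t))
  for (k in seq_len(nrow(windows)))
    keep <- keep | (t >= windows$start[k] & t < windows$end[k])
  s <- trace$samples[keep, , drop = FALSE]
  effector_trace(s$t, s$yaw, s$pitch, s$valid, effector = trace$effector,
                 frame = trace$frame, rate = trace$rate)
}

#' Density-filter (eye, head) angle pairs
#'
#' Counts pairs on a grid of `bin_deg` x `bin_deg` cells (half-open bins
#' `[k*bin, (k+1)*bin)` anchored at 0 deg) and removes every pair lying in a
#' cell with fewer than `min_count` occurrences. This excludes low-density
#' outliers and artefacts before the regression; the defaults (1 deg bins,
#' fewer than 20 occurrences removed) are the analysis constants.
#'
#' @param eye,head paired angle vectors in degrees.
#' @param bin_deg bin size in degrees (> 0).
#' @param min_count minimum occurrences for a cell to be retained.
#' @return A list with `eye`, `head` (retained pairs), `retained` (logical
#'   index into the input), and `grid` (data.frame `eye_bin`, `head_bin`,
#'   `count` of occupied cells; bin indices are the cells' lower edges in
#'   units of `bin_deg`).
#' @export
density_filter <- function(eye, head, bin_deg = 1, min_count = 20) {
  stopifnot(length(eye) == length(head), bin_deg > 0, min_count >= 0)
  if (length(eye) == 0) {
    return(list(eye = numeric(0), head = numeric(0), retained = logical(0),
                grid = data.frame(eye_bin = integer(0), head_bin = integer(0),
                                  count = integer(0))))
  }
  bx <- floor(eye / bin_deg)
  by <- floor(head / bin_deg)
  key <- paste(bx, by)
  counts <- table(key)
  grid_keys <- names(counts)
  parts <- strsplit(grid_keys, " ", fixed = TRUE)
  grid <- data.frame(
    eye_bin = as.integer(vapply(parts, `[[`, "", 1L)),
    head_bin = as.integer(vapply(parts, `[[`, "", 2L)),
    count = as.integer(counts)
  )
  keep <- as.integer(counts[key]) >= min_count
  list(eye = eye[keep], head = head[keep], retained = keep, grid = grid)
}

#' Fit the eye-head coordination slope for one axis
#'
#' Ordinary least squares of head rotation (response) on eye rotation
#' (predictor) over the retained pairs of one participant and condition. A
#' slope of 0 means the eyes move without any head rotation; larger
#' magnitudes mean the head is more involved in coordinated eye-head
#' movements.
#'
#' @param eye,head retained angle pairs in degrees.
#' @param axis `"yaw"` or `"pitch"` (recorded in the result).
#' @param n_total number of pairs before density filtering (defaults to the
#'   number supplied).
#' @param participant,condition,group labels carried into the result.
#' @return A `regression_result`: list with `axis`, `slope`, `intercept`,
#'   `n_retained`, `n_total` and the labels.
#' @export
fit_eye_head_slope <- function(eye, head, axis = c("yaw", "pitch"),
                               n_total = length(eye), participant = NA,
                               condition = NA, group = NA) {
  axis <- match.arg(axis)
  ok <- is.finite(eye) & is.finite(head)
  eye <- eye[ok]; head <- head[ok]
  if (length(unique(eye)) < 2)
    stop(sprintf(
      "degenerate eye-angle predictor (participant %s, condition %s, axis %s): need >= 2 distinct values",
      participant, condition, axis), call. = FALSE)
  fit <- stats::lm.fit(cbind(1, eye), head)
  structure(list(axis = axis,
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 n_retained = length(eye), n_total = n_total,
                 participant = participant, condition = condition,
                 group = group),
            class = "regression_result")
}

#' Eye-head coordination slopes for one session
#'
#' Runs the full per-session coordination analysis: restrict the synced eye
#' and head traces to the visual-search trial windows, pair them sample by
#' sample (same clock tick, no lag compensation), density-filter the pairs
#' per axis, and fit the head-on-eye OLS slope for yaw and pitch.
#'
#' @param session a `gaze_session`.
#' @param bin_deg,min_count density-filter constants (1 deg, 20).
#' @return A data.frame with one row per axis: slope, intercept,
#'   n_retained, n_total and the session labels.
#' @export
session_slopes <- function(session, bin_deg = 1, min_count = 20) {
  stopifnot(inherits(session, "gaze_session"))
  eye_tr <- restrict_to_trials(session$eye, session$trials)
  head_tr <- restrict_to_trials(session$head, session$trials)
  rows <- lapply(c("yaw", "pitch"), function(ax) {
    e <- eye_tr$samples[[ax]]
    h <- head_tr$samples[[ax]]
    ok <- eye_tr$samples$valid & head_tr$samples$valid
    filt <- density_filter(e[ok], h[ok], bin_deg, min_count)
    r <- fit_eye_head_slope(filt$eye, filt$head, axis = ax,
                            n_total = sum(ok),
                            participant = session$meta$participant,
                            condition = session$meta$condition,
                            group = session$meta$group)
    data.frame(participant = r$participant, condition = r$condition,
               group = r$group, axis = r$axis, slope = r$slope,
               intercept = r$intercept, n_retained = r$n_retained,
               n_total = r$n_total)
  })
  do.call(rbind, rows)
}

#' Average slopes per condition x group x axis cell
#'
#' Individual regression slopes are averaged across the participants of each
#' condition x group x axis cell, mirroring how per-participant slopes are
#' summarised across a cohort.
#'
#' @param results data.frame of per-session slopes (e.g. rows from
#'   [session_slopes()]).
#' @return A data.frame with per-cell `mean`, `sd` and `n`; cells with a
#'   single observation have `sd = NA` and are flagged in `note`, empty
#'   cells are absent (missing, not zero).
#' @export
group_average_slopes <- function(results) {
  stopifnot(all(c("condition", "group", "axis", "slope") %in% names(results)))
  agg <- stats::aggregate(slope ~ condition + group + axis, data = results,
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x),
                                              n = length(x)))
  out <- data.frame(agg[c("condition", "group", "axis")],
                    mean = agg$slope[, "mean"], sd = agg$slope[, "sd"],
                    n = as.integer(agg$slope[, "n"]))
  out$note <- ifelse(out$n < 2, "single observation: SD undefined", "")
  out[order(out$axis, out$condition, out$group), ]
}
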