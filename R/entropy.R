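#' Divide a trace into fixed-duration displacement bins
#'
#' Cuts a uniform-clock trace into contiguous half-open time bins
#' `[k*bin_ms, (k+1)*bin_ms)` anchored at the trace start (the default
#' 120 ms approximates the minimum fixation duration; at 120 Hz each bin
#' holds 14 or 15 samples). Each bin's net displacement is the Euclidean
#' distance between the (yaw, pitch) of its first and last valid samples —
#' a single displacement, not an arc length. A trailing partial bin is
#' discarded; bins with more than 50% invalid samples are flagged invalid.
#'
#' @param trace an `effector_trace` on a uniform clock.
#' @param bin_ms bin width in milliseconds (> 0).
#' @return A `bin_series`: data.frame with columns `start` (s),
#'   `displacement` (degrees, `NA` when no valid sample), `valid`; the bin
#'   width is carried in attribute `bin_ms`.
#' @export
bin_series <- function(trace, bin_ms = 120) {
  stopifnot(is_effector_trace(trace))
  if (bin_ms <= 0) stop("bin_ms must be > 0", call. = FALSE)
  s <- trace$samples
  n <- nrow(s)
  if (n == 0) stop("empty trace", call. = FALSE)
  dt <- 1 / trace$rate
  bin_s <- bin_ms / 1000
  duration <- n * dt
  n_bins <- floor(duration / bin_s + 1e-9)
  if (n_bins < 1) stop("trace shorter than one bin", call. = FALSE)
  rel <- s$t - s$t[1]
  idx <- floor(rel / bin_s + 1e-9) + 1L
  in_range <- idx >= 1L & idx <= n_bins
  idx <- idx[in_range]
  yaw <- s$yaw[in_range]; pitch <- s$pitch[in_range]
  ok <- s$valid[in_range] & is.finite(yaw) & is.finite(pitch)

  total_ct <- tabulate(idx, n_bins)
  valid_ct <- tabulate(idx[ok], n_bins)

  vb <- idx[ok]
  yv <- yaw[ok]; pv <- pitch[ok]
  first <- !duplicated(vb)
  last <- !duplicated(vb, fromLast = TRUE)
  disp <- rep(NA_real_, n_bins)
  disp[vb[first]] <- sqrt((yv[last] - yv[first])^2 + (pv[last] - pv[first])^2)

  out <- data.frame(start = s$t[1] + (seq_len(n_bins) - 1L) * bin_s,
                    displacement = disp,
                    valid = valid_ct > 0.5 * total_ct & valid_ct > 0)
  attr(out, "bin_ms") <- bin_ms
  class(out) <- c("bin_series", "data.frame")
  out
}

#' Assign a movement state to every bin
#'
#' Encodes each bin's "transition pattern" as a discrete state. Policies:
#' \describe{
#'   \item{`displacement_threshold`}{`"shift"` if the bin's net displacement
#'     exceeds `theta` degrees, else `"stay"` — a dichotomy applicable
#'     uniformly to eye, head and gaze (the default, `theta = 1`).}
#'   \item{`displacement_quantiles`}{`k` states cut at the empirical
#'     quantile edges of the valid-bin displacements (type-1 quantiles;
#'     ties break toward the lower state).}
#'   \item{`aoi_labels`}{majority area-of-interest label within the bin
#'     (gaze only; requires `aoi`, the per-sample label sequence).}
#' }
#' Invalid bins receive `NA`, a sentinel excluded from transition counts.
#'
#' @param bins a `bin_series`.
#' @param policy `"displacement_threshold"`, `"displacement_quantiles"` or
#'   `"aoi_labels"`.
#' @param theta displacement threshold in degrees.
#' @param k number of quantile states.
#' @param aoi per-sample AOI labels (from [assign_aoi()]) for the
#'   `aoi_labels` policy; must match the trace the bins came from.
#' @param trace the source `effector_trace` (only needed for `aoi_labels`,
#'   to map samples onto bins).
#' @return Character vector of states, one per bin (`NA` = invalid).
#' @export
assign_states <- function(bins, policy = c("displacement_threshold",
                                           "displacement_quantiles",
                                           "aoi_labels"),
                          theta = 1, k = 2, aoi = NULL, trace = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(bins, "bin_series"))
  d <- bins$displacement
  ok <- bins$valid & !is.na(d)
  states <- rep(NA_character_, nrow(bins))
  if (policy == "displacement_threshold") {
    states[ok] <- ifelse(d[ok] > theta, "shift", "stay")
  } else if (policy == "displacement_quantiles") {
    if (k < 2) stop("k must be >= 2", call. = FALSE)
    edges <- stats::quantile(d[ok], probs = seq_len(k - 1) / k, type = 1,
                             names = FALSE)
    # ties break toward the lower state: state = number of edges strictly below d
    states[ok] <- paste0("q", findInterval(d[ok], edges, left.open = TRUE) + 1L)
  } else {
    if (is.null(aoi) || is.null(trace))
      stop("aoi_labels policy requires `aoi` and `trace` (gaze only)",
           call. = FALSE)
    if (!is_effector_trace(trace) || trace$effector != "gaze")
      stop("aoi_labels policy applies to gaze traces only", call. = FALSE)
    if (length(aoi) != nrow(trace$samples))
      stop("`aoi` must have one label per trace sample", call. = FALSE)
    bin_s <- attr(bins, "bin_ms") / 1000
    idx <- floor((trace$samples$t - trace$samples$t[1]) / bin_s + 1e-9) + 1L
    keep <- idx >= 1L & idx <= nrow(bins)
    maj <- tapply(aoi[keep], idx[keep], function(x) {
      tb <- sort(table(x), decreasing = TRUE)
      names(tb)[1]
    })
    states[as.integer(names(maj))] <- as.character(maj)
    states[!ok] <- NA_character_
  }
  states
}

#' Empirical first-order transition model of a state sequence
#'
#' Counts transitions over consecutive valid-bin pairs (pairs spanning an
#' invalid bin are dropped) and derives the joint probabilities `p(i,j)`
#' (count / total pairs), the stationary probabilities `p_i` (row marginals
#' of the joint), and the conditional probabilities `p(j|i)` on occupied
#' rows.
#'
#' @param states character vector of per-bin states; `NA` marks invalid bins.
#' @return A `transition_model`: list with `states` (labels), `counts`,
#'   `joint`, `p_i`, `conditional`, `n_pairs`.
#' @export
transition_model <- function(states) {
  ok <- !is.na(states)
  if (sum(ok) < 2) stop("need at least 2 valid bins", call. = FALSE)
  from_ok <- ok[-length(ok)] & ok[-1]
  if (!any(from_ok)) stop("no consecutive pair of valid bins", call. = FALSE)
  from <- states[-length(states)][from_ok]
  to <- states[-1][from_ok]
  labels <- sort(unique(c(from, to)))
  counts <- table(factor(from, levels = labels), factor(to, levels = labels))
  counts <- unclass(counts)
  joint <- counts / sum(counts)
  p_i <- rowSums(joint)
  conditional <- joint
  occ <- p_i > 0
  conditional[occ, ] <- joint[occ, , drop = FALSE] / p_i[occ]
  structure(list(states = labels, counts = counts, joint = joint,
                 p_i = p_i, conditional = conditional,
                 n_pairs = sum(counts)),
            class = "transition_model")
}

#' Conditional (transition) entropy of a transition model
#'
#' Default `"standard"` mode computes the Shannon conditional entropy of the
#' first-order chain,
#' \deqn{H = -\sum_i p_i \sum_j p(j|i) \log_2 p(j|i),}
#' which measures the complexity and randomness of the scanpath: 0 bits for
#' deterministic transitions, `log2(n)` bits for maximally unpredictable
#' ones. `"literal"` mode instead evaluates
#' \deqn{-\sum_i p_i \sum_j p(i,j) \log_2 p(i,j)}
#' with the joint probability inside the logarithm — retained as an explicit
#' variant for comparison (see the package vignette for why both are
#' offered). In both modes `0 log 0 = 0` and the result is normalized by
#' `log2(n)` over the realized state set so it ranges within [0, 1]; a
#' single-state model has normalized entropy 0 by convention.
#'
#' @param model a `transition_model`.
#' @param mode `"standard"` (default) or `"literal"`.
#' @return An `entropy_result`: list with `raw_bits`, `normalized`,
#'   `n_states`, `n_pairs`, `mode`.
#' @export
conditional_entropy <- function(model, mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "transition_model"))
  xlogx <- function(p) ifelse(p > 0, p * log2(p), 0)
  if (mode == "standard") {
    # -sum_ij p(i,j) log2 p(j|i), identical to the p_i-weighted row form
    raw <- -sum(model$joint * ifelse(model$conditional > 0,
                                     log2(model$conditional), 0))
  } else {
    raw <- -sum(model$p_i * rowSums(xlogx(model$joint)))
  }
  raw <- raw + 0 # avoid IEEE negative zero from -sum(...)
  n <- length(model$states)
  normalized <- if (n > 1) raw / log2(n) else 0
  structure(list(raw_bits = raw, normalized = normalized, n_states = n,
                 n_pairs = model$n_pairs, mode = mode),
            class = "entropy_result")
}

#' Time-based transition entropy of one session effector
#'
#' The full entropy pipeline over the whole driving scenario (not only the
#' visual-search trials): bin the effector's trace into `bin_ms`
#' displacement bins, assign movement states, build the first-order
#' transition model, and compute the normalized conditional entropy.
#'
#' @param session a `gaze_session`.
#' @param effector `"eye"`, `"head"` or `"gaze"` (gaze is reconstructed from
#'   eye and head if not already present).
#' @param policy,theta,k state policy, see [assign_states()].
#' @param mode entropy formula mode, see [conditional_entropy()].
#' @param bin_ms bin width in ms (120 by default; a first-class parameter —
#'   slower effectors such as the head may warrant longer windows).
#' @param gaze_mode combination rule for gaze reconstruction, see
#'   [reconstruct_gaze()].
#' @return An `entropy_result` with added fields `effector`, `policy`,
#'   `theta`, `bin_ms`, `n_bins`.
#' @export
session_entropy <- function(session, effector = c("eye", "head", "gaze"),
                            policy = "displacement_threshold", theta = 1,
                            k = 2, mode = "standard", bin_ms = 120,
                            gaze_mode = "compose") {
  effector <- match.arg(effector)
  stopifnot(inherits(session, "gaze_session"))
  trace <- if (effector == "gaze") {
    session$gaze %||% reconstruct_gaze(session$eye, session$head, gaze_mode)
  } else {
    session[[effector]]
  }
  bins <- bin_series(trace, bin_ms)
  if (policy == "aoi_labels") {
    aoi <- assign_aoi(trace, session$geometry)
    states <- assign_states(bins, policy, aoi = aoi, trace = trace)
  } else {
    states <- assign_states(bins, policy, theta = theta, k = k)
  }
  res <- conditional_entropy(transition_model(states), mode)
  res$effector <- effector
  res$policy <- policy
  res$theta <- if (policy == "displacement_threshold") theta else NA
  res$bin_ms <- bin_ms
  res$n_bins <- nrow(bins)
  res
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result>%s %.4f bits, normalized %.4f (%d states, %d pairs, mode %s)\n",
              if (!is.null(x$effector)) paste0(" ", x$effector) else "",
              x$raw_bits, x$normalized, x$n_states, x$n_pairs, x$mode))
  invisible(x)
}
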