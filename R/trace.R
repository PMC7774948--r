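#' Effector traces
#'
#' An `effector_trace` holds a timestamped yaw/pitch series for one effector
#' (eye, head, or reconstructed gaze) in a declared coordinate frame. Eye
#' traces live in the head frame; head and gaze traces live in the world
#' frame. Angles are stored in degrees throughout: negative yaw is left,
#' positive yaw is right; negative pitch is downward, positive pitch upward.
#'
#' @param t numeric vector of timestamps in seconds, non-decreasing.
#' @param yaw,pitch numeric vectors of rotation angles in degrees.
#' @param valid logical vector flagging usable samples (recycled).
#' @param effector one of `"eye"`, `"head"`, `"gaze"`.
#' @param frame one of `"head_frame"`, `"world_frame"`. Defaults to the
#'   conventional frame for the effector.
#' @param rate nominal sampling rate in Hz (120 by default).
#' @param roll optional roll angle series in degrees (head only; carried but
#'   ignored by the analysis).
#' @return An object of class `effector_trace`: a list with elements
#'   `effector`, `frame`, `rate` and `samples` (a data.frame with columns
#'   `t`, `yaw`, `pitch`, `valid` and optionally `roll`).
#' @export
effector_trace <- function(t, yaw, pitch, valid = TRUE,
                           effector = c("eye", "head", "gaze"),
                           frame = NULL, rate = 120, roll = NULL) {
  effector <- match.arg(effector)
  if (is.null(frame)) {
    frame <- if (effector == "eye") "head_frame" else "world_frame"
  }
  frame <- match.arg(frame, c("head_frame", "world_frame"))
  if (effector == "eye" && frame != "head_frame")
    stop("eye traces must be in the head frame", call. = FALSE)
  if (effector != "eye" && frame != "world_frame")
    stop(sprintf("%s traces must be in the world frame", effector), call. = FALSE)
  n <- length(t)
  if (length(yaw) != n || length(pitch) != n)
    stop("t, yaw and pitch must have equal length", call. = FALSE)
  if (n > 1 && any(diff(t) < 0))
    stop("timestamps must be non-decreasing", call. = FALSE)
  valid <- rep_len(as.logical(valid), n)
  samples <- data.frame(t = as.numeric(t), yaw = as.numeric(yaw),
                        pitch = as.numeric(pitch), valid = valid)
  if (!is.null(roll)) samples$roll <- rep_len(as.numeric(roll), n)
  structure(list(effector = effector, frame = frame, rate = rate,
                 samples = samples),
            class = "effector_trace")
}

#' @export
print.effector_trace <- function(x, ...) {
  s <- x$samples
  cat(sprintf("<effector_trace> %s (%s), %d samples @ %g Hz, t in [%.3f, %.3f] s, %d invalid\n",
              x$effector, x$frame, nrow(s), x$rate,
              if (nrow(s)) min(s$t) else NA, if (nrow(s)) max(s$t) else NA,
              sum(!s$valid)))
  invisible(x)
}

#' @export
length.effector_trace <- function(x) nrow(x$samples)

is_effector_trace <- function(x) inherits(x, "effector_trace")

# Direction cosine conventions: right-handed world frame, +x right, +y up,
# +z forward from the driver. Yaw rotates about +y (positive = rightward),
# pitch is the elevation of the direction vector (positive = upward).

#' Convert yaw/pitch angles to unit direction vectors
#'
#' Uses the package's right-handed frame (+x right, +y up, +z forward):
#' the direction for yaw \eqn{\psi} and pitch \eqn{\theta} is
#' \eqn{(\cos\theta \sin\psi,\ \sin\theta,\ \cos\theta \cos\psi)}.
#'
#' @param yaw,pitch angles in degrees.
#' @return An n x 3 matrix of unit vectors.
#' @export
angles_to_dir <- function(yaw, pitch) {
  psi <- yaw * pi / 180
  th <- pitch * pi / 180
  cbind(x = cos(th) * sin(psi), y = sin(th), z = cos(th) * cos(psi))
}

#' Convert unit direction vectors back to yaw/pitch angles
#'
#' Inverse of [angles_to_dir()] for pitch strictly inside (-90, 90) degrees.
#'
#' @param dir an n x 3 matrix (or length-3 vector) of direction vectors;
#'   need not be normalised.
#' @return A data.frame with columns `yaw` and `pitch` in degrees.
#' @export
dir_to_angles <- function(dir) {
  if (is.null(dim(dir))) dir <- matrix(dir, nrow = 1)
  nrm <- sqrt(rowSums(dir^2))
  d <- dir / nrm
  data.frame(yaw = atan2(d[, 1], d[, 3]) * 180 / pi,
             pitch = asin(pmin(1, pmax(-1, d[, 2]))) * 180 / pi)
}

# Rotation matrix for a (yaw, pitch) orientation: yaw about the world
# vertical first, then pitch about the rotated horizontal axis, so that
# R %*% c(0,0,1) equals angles_to_dir(yaw, pitch). Roll is ignored.
rotmat_yaw_pitch <- function(yaw, pitch) {
  psi <- yaw * pi / 180
  th <- pitch * pi / 180
  Ry <- matrix(c(cos(psi), 0, -sin(psi),
                 0, 1, 0,
                 sin(psi), 0, cos(psi)), 3, 3)
  Rx <- matrix(c(1, 0, 0,
                 0, cos(th), -sin(th),
                 0, sin(th), cos(th)), 3, 3)
  Ry %*% Rx
}
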