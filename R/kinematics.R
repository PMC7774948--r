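#' Resample eye and head traces onto a common uniform clock
#'
#' Eye and head recordings from separate devices rarely share timestamps.
#' This resamples both traces onto one uniform clock over their temporal
#' overlap, linearly interpolating between valid samples. Grid points whose
#' bracketing valid source samples are further apart than `max_gap_s` (e.g.
#' across blinks or tracking loss) are flagged invalid rather than silently
#' interpolated.
#'
#' @param eye,head `effector_trace` objects that overlap in time.
#' @param rate target sampling rate in Hz.
#' @param max_gap_s longest gap (s) between valid source samples across which
#'   interpolation is still trusted.
#' @return A list with elements `eye` and `head`, both resampled onto the
#'   identical clock.
#' @export
resample_and_sync <- function(eye, head, rate = 120, max_gap_s = 0.1) {
  stopifnot(is_effector_trace(eye), is_effector_trace(head))
  t0 <- max(min(eye$samples$t), min(head$samples$t))
  t1 <- min(max(eye$samples$t), max(head$samples$t))
  if (t1 <= t0) stop("traces have no temporal overlap", call. = FALSE)
  grid <- seq(t0, t1, by = 1 / rate)
  list(eye = resample_trace(eye, grid, rate, max_gap_s),
       head = resample_trace(head, grid, rate, max_gap_s))
}

resample_trace <- function(trace, grid, rate, max_gap_s) {
  s <- trace$samples
  v <- which(s$valid & is.finite(s$yaw) & is.finite(s$pitch))
  if (length(v) < 2) stop("trace has fewer than 2 valid samples", call. = FALSE)
  tv <- s$t[v]
  yaw <- stats::approx(tv, s$yaw[v], xout = grid, rule = 2)$y
  pitch <- stats::approx(tv, s$pitch[v], xout = grid, rule = 2)$y
  # a grid point is valid when its bracketing valid samples are close enough
  iv <- findInterval(grid, tv)
  lo <- pmax(iv, 1L)
  hi <- pmin(iv + 1L, length(tv))
  gap <- tv[hi] - tv[lo]
  inside <- iv >= 1L & iv < length(tv)
  at_node <- abs(grid - tv[pmin(pmax(iv, 1L), length(tv))]) < 1e-9
  ok <- (inside & gap <= max_gap_s) | at_node
  effector_trace(grid, yaw, pitch, valid = ok, effector = trace$effector,
                 frame = trace$frame, rate = rate)
}

#' Reconstruct gaze-in-space from eye-in-head and head-in-world traces
#'
#' Combines the eye-in-head orientation with the head-in-world orientation to
#' give the gaze (eye-in-space) direction, per sample. Two combination rules
#' are provided: `"compose"` applies the head rotation (yaw about the world
#' vertical, then pitch about the rotated horizontal axis) to the eye-in-head
#' direction vector and converts back to world yaw/pitch; `"additive"` simply
#' sums the yaw and pitch angles. The two agree exactly when either input is
#' at zero or when pitch is identically zero, and to within about half a
#' degree for combined angles below ~15 degrees. Head roll is ignored.
#'
#' @param eye eye trace in the head frame.
#' @param head head trace in the world frame, on the same clock as `eye`.
#' @param mode `"compose"` (default) or `"additive"`.
#' @return A gaze `effector_trace` in the world frame; samples invalid in
#'   either input are invalid in the output.
#' @export
reconstruct_gaze <- function(eye, head, mode = c("compose", "additive")) {
  mode <- match.arg(mode)
  stopifnot(is_effector_trace(eye), is_effector_trace(head))
  if (eye$effector != "eye" || eye$frame != "head_frame")
    stop("`eye` must be an eye trace in the head frame", call. = FALSE)
  if (head$effector != "head" || head$frame != "world_frame")
    stop("`head` must be a head trace in the world frame", call. = FALSE)
  es <- eye$samples
  hs <- head$samples
  if (nrow(es) != nrow(hs) || any(abs(es$t - hs$t) > 1e-6))
    stop("eye and head traces must share one clock; run resample_and_sync() first",
         call. = FALSE)
  if (mode == "additive") {
    yaw <- es$yaw + hs$yaw
    pitch <- es$pitch + hs$pitch
  } else {
    d <- angles_to_dir(es$yaw, es$pitch)
    hy <- hs$yaw * pi / 180
    hp <- hs$pitch * pi / 180
    # R_head %*% d, written out per-sample (vectorised): first pitch about
    # the head's horizontal axis, then yaw about the world vertical.
    y1 <- cos(hp) * d[, 2] + sin(hp) * d[, 3]
    z1 <- -sin(hp) * d[, 2] + cos(hp) * d[, 3]
    x1 <- d[, 1]
    x2 <- cos(hy) * x1 + sin(hy) * z1
    z2 <- -sin(hy) * x1 + cos(hy) * z1
    ang <- dir_to_angles(cbind(x2, y1, z2))
    yaw <- ang$yaw
    pitch <- ang$pitch
  }
  effector_trace(es$t, yaw, pitch, valid = es$valid & hs$valid,
                 effector = "gaze", frame = "world_frame", rate = eye$rate)
}

#' Bounded scene planes and scene geometry
#'
#' A `scene_plane` is a rectangle in 3D world coordinates (meters), given by
#' its center, outward normal (toward the viewer), an up-hint fixing the
#' in-plane axes, and its width/height. `scene_geometry` bundles the central
#' simulator screen and the navigation-device plane with the eye origin.
#'
#' @param center,normal length-3 numeric vectors (m; normal need not be unit).
#' @param width,height rectangle extents in meters.
#' @param up length-3 up-hint used to orient the in-plane axes.
#' @return `scene_plane`: a list with unit `normal`, in-plane axes `u`
#'   (rightward) and `v` (upward) and half-extents.
#' @export
scene_plane <- function(center, normal, width, height, up = c(0, 1, 0)) {
  stopifnot(length(center) == 3, length(normal) == 3, width > 0, height > 0)
  n <- normal / sqrt(sum(normal^2))
  if (!is.finite(sum(n))) stop("degenerate plane normal", call. = FALSE)
  u <- c(up[2] * n[3] - up[3] * n[2],
         up[3] * n[1] - up[1] * n[3],
         up[1] * n[2] - up[2] * n[1])
  if (sum(u^2) < 1e-12) stop("up-hint parallel to plane normal", call. = FALSE)
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  structure(list(center = as.numeric(center), normal = n, u = u, v = v,
                 half_w = width / 2, half_h = height / 2),
            class = "scene_plane")
}

#' @param eye_origin 3D eye position (m), default the world origin.
#' @param central_screen,device `scene_plane` objects.
#' @rdname scene_plane
#' @export
scene_geometry <- function(central_screen, device, eye_origin = c(0, 0, 0)) {
  stopifnot(inherits(central_screen, "scene_plane"), inherits(device, "scene_plane"))
  structure(list(eye_origin = as.numeric(eye_origin),
                 central_screen = central_screen, device = device),
            class = "scene_geometry")
}

#' Default driving-simulator scene geometry
#'
#' A wide central screen 2 m ahead of the driver and an 8-inch navigation
#' device on the center console, about 0.7 m away, down and to the right
#' (direction yaw +22 deg, pitch -18 deg), both facing the driver.
#'
#' @return A `scene_geometry` object.
#' @export
default_geometry <- function() {
  dev_dir <- as.numeric(angles_to_dir(22, -18))
  dev_center <- 0.7 * dev_dir
  scene_geometry(
    central_screen = scene_plane(center = c(0, 0, 2), normal = c(0, 0, -1),
                                 width = 7, height = 1.7),
    device = scene_plane(center = dev_center, normal = -dev_dir,
                         width = 0.163, height = 0.122)
  )
}

#' Intersect a ray with a bounded plane
#'
#' Returns the intersection point of the ray `origin + t * direction`
#' (`t > 0`) with the plane, provided the point falls inside the rectangle
#' bounds; otherwise `NULL`. A ray parallel to the plane yields `NULL`.
#'
#' @param origin 3D ray origin (m).
#' @param direction 3D unit direction vector.
#' @param plane a `scene_plane`.
#' @return Length-3 numeric point, or `NULL` for a miss.
#' @export
intersect_plane <- function(origin, direction, plane) {
  stopifnot(inherits(plane, "scene_plane"))
  if (abs(sum(direction^2) - 1) > 1e-6)
    stop("direction must be a unit vector", call. = FALSE)
  denom <- sum(plane$normal * direction)
  if (abs(denom) < 1e-12) return(NULL)
  tt <- sum(plane$normal * (plane$center - origin)) / denom
  if (tt <= 0) return(NULL)
  p <- origin + tt * direction
  rel <- p - plane$center
  if (abs(sum(rel * plane$u)) > plane$half_w ||
      abs(sum(rel * plane$v)) > plane$half_h) return(NULL)
  p
}

# Vectorised hit test for n directions against one plane; returns logical n.
ray_hits_plane <- function(origin, dirs, plane) {
  denom <- dirs %*% plane$normal
  tt <- as.numeric(sum(plane$normal * (plane$center - origin)) / denom)
  p_rel <- dirs * tt
  rel <- sweep(p_rel, 2, plane$center - origin, `-`)
  loc_u <- rel %*% plane$u
  loc_v <- rel %*% plane$v
  ok <- abs(denom) > 1e-12 & tt > 0 &
    abs(loc_u) <= plane$half_w & abs(loc_v) <= plane$half_h
  as.logical(ok)
}

#' Label each gaze sample with its area of interest
#'
#' Casts the gaze direction of every sample from the eye origin and labels it
#' `"device"` if the ray hits the navigation-device rectangle (tested first:
#' the device is nearer and occludes the screen along shared rays), else
#' `"central_screen"` if it hits the screen, else `"other"`. Invalid samples
#' are labelled `"other"`.
#'
#' @param gaze a gaze `effector_trace` in the world frame.
#' @param geom a `scene_geometry`.
#' @return Character vector of labels, one per sample (an AOI sequence).
#' @export
assign_aoi <- function(gaze, geom) {
  stopifnot(is_effector_trace(gaze), inherits(geom, "scene_geometry"))
  if (gaze$frame != "world_frame")
    stop("gaze must be in the world frame", call. = FALSE)
  s <- gaze$samples
  dirs <- angles_to_dir(s$yaw, s$pitch)
  lab <- rep("other", nrow(s))
  hit_dev <- ray_hits_plane(geom$eye_origin, dirs, geom$device)
  hit_scr <- ray_hits_plane(geom$eye_origin, dirs, geom$central_screen)
  lab[hit_scr] <- "central_screen"
  lab[hit_dev] <- "device"
  lab[!s$valid] <- "other"
  lab
}

#' Read scene geometry from a JSON or YAML file
#'
#' The file must contain `central_screen` and `device` entries, each with
#' `center`, `normal`, `width`, `height` (meters, right-handed world frame:
#' +x right, +y up, +z forward from the driver), and optionally `eye_origin`.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A `scene_geometry`.
#' @export
read_geometry <- function(path) {
  cfg <- read_config(path)
  mk <- function(p) scene_plane(as.numeric(p$center), as.numeric(p$normal),
                                p$width, p$height)
  scene_geometry(mk(cfg$central_screen), mk(cfg$device),
                 eye_origin = as.numeric(cfg$eye_origin %||% c(0, 0, 0)))
}
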