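test_that("already-aligned traces pass through resampling unchanged", {
  eye <- make_trace(sin(1:1200 / 40) * 10, cos(1:1200 / 40) * 5)
  head <- make_trace(1:1200 / 100, rep(0, 1200), effector = "head")
  out <- resample_and_sync(eye, head, rate = 120)
  expect_equal(out$eye$samples$yaw, eye$samples$yaw, tolerance = 1e-9)
  expect_equal(out$head$samples$yaw, head$samples$yaw, tolerance = 1e-9)
  expect_equal(out$eye$samples$t, out$head$samples$t)
  # 10 s of overlap at 120 Hz -> 1200 common samples
  expect_equal(length(out$eye), 1200)
})

test_that("half-period offsets interpolate to neighbour midpoints", {
  # for a linear signal, the value at a midpoint is the neighbour average
  yaw <- seq(0, 20, length.out = 241) # 2 s at 120 Hz
  eye <- make_trace(yaw, t0 = 0)
  head <- make_trace(yaw, t0 = 0.5 / 120, effector = "head")
  out <- resample_and_sync(eye, head, rate = 120)
  t <- out$head$samples$t
  inner <- t > 0.5 / 120 + 1e-9 & t < 2 - 1e-9
  expected <- stats::approx(head$samples$t, head$samples$yaw, xout = t[inner])$y
  expect_equal(out$head$samples$yaw[inner], expected, tolerance = 1e-9)
  expect_error(resample_and_sync(eye, make_trace(1:10, t0 = 100,
                                                 effector = "head")),
               "overlap")
})

test_that("interpolation across long invalid gaps is flagged invalid", {
  valid <- rep(TRUE, 240)
  valid[60:110] <- FALSE # 0.42 s gap > default 0.1 s limit
  eye <- make_trace(sin(1:240 / 10), valid = valid)
  head <- make_trace(rep(0, 240), effector = "head")
  out <- resample_and_sync(eye, head, rate = 120)
  # last valid sample before the gap is at t = 58/120, first after at 110/120
  t <- out$eye$samples$t
  mid_gap <- t > 58 / 120 + 1e-9 & t < 110 / 120 - 1e-9
  expect_true(all(!out$eye$samples$valid[mid_gap]))
  expect_true(all(out$eye$samples$valid[!mid_gap]))
})

test_that("gaze reconstruction identities hold in both modes", {
  for (mode in c("compose", "additive")) {
    # primary eye position: gaze equals head
    eye0 <- make_trace(rep(0, 50), rep(0, 50))
    head <- make_trace(rep(20, 50), rep(-5, 50), effector = "head")
    g <- reconstruct_gaze(eye0, head, mode)
    expect_equal(g$samples$yaw, rep(20, 50), tolerance = 1e-9)
    expect_equal(g$samples$pitch, rep(-5, 50), tolerance = 1e-9)
    # zero head: gaze equals eye
    eye <- make_trace(rep(10, 50), rep(4, 50))
    head0 <- make_trace(rep(0, 50), rep(0, 50), effector = "head")
    g <- reconstruct_gaze(eye, head0, mode)
    expect_equal(g$samples$yaw, rep(10, 50), tolerance = 1e-9)
    expect_equal(g$samples$pitch, rep(4, 50), tolerance = 1e-9)
  }
  expect_error(reconstruct_gaze(make_trace(1:5, effector = "head"),
                                make_trace(1:5, effector = "head")),
               "eye")
})

test_that("compose mode matches the rotation-matrix oracle", {
  # independent oracle: build both rotation matrices, multiply, extract
  oracle <- function(ey, ep, hy, hp) {
    rot <- function(yaw, pitch) {
      psi <- yaw * pi / 180; th <- pitch * pi / 180
      Ry <- rbind(c(cos(psi), 0, sin(psi)), c(0, 1, 0),
                  c(-sin(psi), 0, cos(psi)))
      # positive pitch tilts the forward axis upward
      Rp <- rbind(c(1, 0, 0), c(0, cos(th), sin(th)),
                  c(0, -sin(th), cos(th)))
      Ry %*% Rp
    }
    v <- rot(hy, hp) %*% rot(ey, ep) %*% c(0, 0, 1)
    c(yaw = atan2(v[1], v[3]) * 180 / pi, pitch = asin(v[2]) * 180 / pi)
  }
  set.seed(42)
  cases <- rbind(c(10, 5, 20, -10),
                 cbind(runif(30, -40, 40), runif(30, -30, 30),
                       runif(30, -40, 40), runif(30, -30, 30)))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    eye <- make_trace(cs[1], cs[2])
    head <- make_trace(cs[3], cs[4], effector = "head")
    g <- reconstruct_gaze(eye, head, "compose")
    exp <- oracle(cs[1], cs[2], cs[3], cs[4])
    expect_equal(g$samples$yaw, unname(exp["yaw"]), tolerance = 1e-9)
    expect_equal(g$samples$pitch, unname(exp["pitch"]), tolerance = 1e-9)
  }
})

test_that("additive mode approximates compose mode for small gaze shifts", {
  # gaze shifts of amplitude <= 15 deg, split between eye and head: the
  # regime where single-effector shifts occur and the additive small-angle
  # approximation is claimed to hold within half a degree
  set.seed(7)
  n <- 500
  ecc <- 15 * sqrt(runif(n)); ang <- runif(n, 0, 2 * pi)
  gy <- ecc * cos(ang); gp <- ecc * sin(ang)
  ky <- runif(n); kp <- runif(n)
  eye <- make_trace((1 - ky) * gy, (1 - kp) * gp)
  head <- make_trace(ky * gy, kp * gp, effector = "head")
  gc <- reconstruct_gaze(eye, head, "compose")
  ga <- reconstruct_gaze(eye, head, "additive")
  expect_lt(max(abs(gc$samples$yaw - ga$samples$yaw)), 0.5)
  expect_lt(max(abs(gc$samples$pitch - ga$samples$pitch)), 0.5)
  # the reference configuration: eye (10, 5), head (20, -10)
  e1 <- make_trace(10, 5); h1 <- make_trace(20, -10, effector = "head")
  c1 <- reconstruct_gaze(e1, h1, "compose")
  a1 <- reconstruct_gaze(e1, h1, "additive")
  expect_lt(abs(c1$samples$yaw - a1$samples$yaw), 0.5)
  expect_lt(abs(c1$samples$pitch - a1$samples$pitch), 0.5)
})

test_that("yaw-only rotations make compose and additive modes agree exactly", {
  set.seed(8)
  ey <- runif(100, -90, 90); hy <- runif(100, -90, 90)
  eye <- make_trace(ey, rep(0, 100))
  head <- make_trace(hy, rep(0, 100), effector = "head")
  gc <- reconstruct_gaze(eye, head, "compose")
  ga <- reconstruct_gaze(eye, head, "additive")
  # rotations about a common axis commute; wrap to (-180, 180]
  wrap <- function(a) ((a + 180) %% 360) - 180
  expect_equal(wrap(gc$samples$yaw), wrap(ga$samples$yaw), tolerance = 1e-9)
  expect_equal(gc$samples$pitch, rep(0, 100), tolerance = 1e-9)
})

test_that("direction/angle conversion round-trips on unit vectors", {
  set.seed(9)
  yaw <- runif(500, -179, 179)
  pitch <- runif(500, -89, 89)
  d <- angles_to_dir(yaw, pitch)
  expect_equal(rowSums(d^2), rep(1, 500), tolerance = 1e-12)
  back <- dir_to_angles(d)
  expect_equal(back$yaw, yaw, tolerance = 1e-9)
  expect_equal(back$pitch, pitch, tolerance = 1e-9)
})

test_that("ray-plane intersection obeys the forward-and-bounded contract", {
  plane <- scene_plane(center = c(0, 0, 2), normal = c(0, 0, -1),
                       width = 2, height = 2)
  expect_equal(intersect_plane(c(0, 0, 0), c(0, 0, 1), plane), c(0, 0, 2))
  # behind the origin
  expect_null(intersect_plane(c(0, 0, 0), c(0, 0, -1), plane))
  # parallel ray
  expect_null(intersect_plane(c(0, 0, 0), c(1, 0, 0), plane))
  # outside the bounds
  expect_null(intersect_plane(c(0, 0, 0),
                              as.numeric(angles_to_dir(45, 0)), plane))
  expect_error(intersect_plane(c(0, 0, 0), c(0, 0, 2), plane), "unit")
  expect_error(scene_plane(c(0, 0, 2), c(0, 0, 0), 1, 1), "degenerate")
})

test_that("oblique intersections match the algebraic oracle to 1e-9 m", {
  set.seed(10)
  for (rep in 1:25) {
    nrm <- stats::rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
    if (nrm[3] > -0.2) nrm <- -nrm # face roughly toward the origin
    center <- c(runif(1, -1, 1), runif(1, -1, 1), runif(1, 1, 3))
    plane <- scene_plane(center, nrm, width = 50, height = 50)
    dir <- as.numeric(angles_to_dir(runif(1, -30, 30), runif(1, -30, 30)))
    origin <- c(runif(1, -0.2, 0.2), runif(1, -0.2, 0.2), 0)
    got <- intersect_plane(origin, dir, plane)
    # oracle: solve n . (o + t d - c) = 0 for t directly
    t_star <- sum(nrm * (center - origin)) / sum(nrm * dir)
    if (t_star > 0) {
      expect_equal(got, origin + t_star * dir, tolerance = 1e-9)
      expect_lt(abs(sum(nrm * (got - center))), 1e-9)
    } else {
      expect_null(got)
    }
  }
})

test_that("AOI labels are exhaustive and follow device precedence", {
  geom <- default_geometry()
  dev_angles <- dir_to_angles(geom$device$center)
  gaze <- make_trace(c(dev_angles$yaw, 0, 0, -70, 22),
                     c(dev_angles$pitch, 0, 80, -60, -18),
                     effector = "gaze")
  lab <- assign_aoi(gaze, geom)
  expect_equal(lab[1], "device")          # aimed at device center
  expect_equal(lab[2], "central_screen")  # straight ahead
  expect_equal(lab[3], "other")           # far above all bounds
  expect_equal(lab[5], "device")          # device occludes the screen
  # invalid samples are labelled other
  gaze_inv <- make_trace(rep(0, 3), rep(0, 3), effector = "gaze",
                         valid = c(TRUE, FALSE, TRUE))
  expect_equal(assign_aoi(gaze_inv, geom),
               c("central_screen", "other", "central_screen"))
  # exhaustiveness over random directions
  set.seed(11)
  g <- make_trace(runif(500, -180, 180), runif(500, -89, 89),
                  effector = "gaze")
  labs <- assign_aoi(g, geom)
  expect_true(all(labs %in% c("device", "central_screen", "other")))
  expect_length(labs, 500)
})

test_that("scene geometry round-trips through JSON and YAML configs", {
  geom <- default_geometry()
  cfg <- list(
    eye_origin = c(0, 0, 0),
    central_screen = list(center = c(0, 0, 2), normal = c(0, 0, -1),
                          width = 7, height = 1.7),
    device = list(center = as.numeric(geom$device$center),
                  normal = as.numeric(geom$device$normal),
                  width = 0.163, height = 0.122)
  )
  jp <- file.path(tempdir(), "geom.json")
  jsonlite::write_json(cfg, jp, auto_unbox = TRUE, digits = NA)
  gj <- read_geometry(jp)
  expect_equal(gj$device$center, geom$device$center, tolerance = 1e-12)
  yp <- file.path(tempdir(), "geom.yaml")
  yaml::write_yaml(cfg, yp)
  gy <- read_geometry(yp)
  expect_equal(gy$central_screen$half_w, 3.5)
  tp <- file.path(tempdir(), "geom.txt")
  writeLines("not a geometry", tp)
  expect_error(read_geometry(tp), "format")
})
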