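test_that("speed, acceleration and distance follow their definitions", {
  ds <- make_ds(cbind(p = rep(5, 10)), cbind(p = rep(7, 10)), units = "cm")
  kin <- compute_kinematics(ds, "p")
  expect_equal(unname(kin$speed[, "p"]), rep(0, 10))
  expect_equal(unname(kin$distance_cm["p"]), 0)

  ds2 <- make_ds(cbind(p = seq(0, by = 2, length.out = 101)),
                 cbind(p = rep(0, 101)), units = "cm")
  kin2 <- compute_kinematics(ds2, "p")
  expect_equal(unname(kin2$speed[-1, "p"]), rep(50, 100))
  expect_equal(unname(kin2$distance_cm["p"]), 200)
  expect_equal(unname(kin2$acceleration[-(1:2), "p"]), rep(0, 99))

  expect_error(compute_kinematics(make_ds(cbind(p = 1), cbind(p = 1),
                                          units = "cm")),
               class = "skeletrack_invalid")
  expect_error(compute_kinematics(make_ds(cbind(p = 1:5), cbind(p = 1:5))),
               class = "skeletrack_uncalibrated")
})

test_that("cumulative distance equals an independent resum of steps", {
  withr::with_seed(13, {
    x <- cumsum(rnorm(200)); y <- cumsum(rnorm(200))
    ds <- make_ds(cbind(p = x), cbind(p = y), units = "cm")
    kin <- compute_kinematics(ds, "p")
    brute <- 0
    for (f in 2:200) {
      brute <- brute + sqrt((x[f] - x[f - 1])^2 + (y[f] - y[f - 1])^2)
    }
    expect_equal(unname(kin$distance_cm["p"]), brute, tolerance = 1e-12)
  })
})

test_that("time in zone counts frames and entry transitions", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  inside <- make_ds(cbind(body_centre = rep(5, 50)),
                    cbind(body_centre = rep(5, 50)), units = "cm")
  tz <- time_in_zone(inside, sq)
  expect_equal(tz$seconds, 2)   # 50 frames at 25 fps
  expect_equal(tz$visits, 1)

  outside <- make_ds(cbind(body_centre = rep(50, 50)),
                     cbind(body_centre = rep(5, 50)), units = "cm")
  expect_equal(time_in_zone(outside, sq)$seconds, 0)
  expect_equal(time_in_zone(outside, sq)$visits, 0)

  # scripted double crossing: 10 in, 10 out, 15 in, 15 out
  xs <- c(rep(5, 10), rep(50, 10), rep(5, 15), rep(50, 15))
  path <- make_ds(cbind(body_centre = xs), cbind(body_centre = rep(5, 50)),
                  units = "cm")
  tz2 <- time_in_zone(path, sq)
  expect_equal(tz2$seconds, 1)
  expect_equal(tz2$visits, 2)
  expect_error(time_in_zone(path, sq, "nope"),
               class = "skeletrack_unknown_keypoint")
})

test_that("zone times over a partition sum to the session duration", {
  sim <- simulate_session(synthetic_scenario("OFT", duration_s = 20, seed = 2))
  rep <- suppressWarnings(analyze_session(sim$tracking,
                                          default_session_config("OFT")))
  m <- rep$measures
  expect_equal(m$time_in_center_s + m$time_in_periphery_s, m$duration_s,
               tolerance = 1e-9)
  expect_equal(m$time_in_wall_band_s + m$time_in_inner_s, m$duration_s,
               tolerance = 1e-9)
})

test_that("occupancy maps conserve total time and localize a still animal", {
  still <- make_ds(cbind(body_centre = rep(5, 75)),
                   cbind(body_centre = rep(5, 75)), units = "cm")
  g <- occupancy_map(still, bin_size = 2)
  expect_equal(sum(g), 3)
  expect_equal(sum(g > 0), 1)

  withr::with_seed(21, {
    mv <- make_ds(cbind(body_centre = runif(250, 0, 45)),
                  cbind(body_centre = runif(250, 0, 45)), units = "cm")
    g2 <- occupancy_map(mv, bin_size = 5, bbox = c(0, 45, 0, 45))
    expect_equal(sum(g2), 10)
  })
  expect_error(occupancy_map(still, bin_size = 0),
               class = "skeletrack_domain")
})

test_that("head angle signs and magnitudes follow the image convention", {
  # body axis east on screen; collinear head
  ds <- make_ds(cbind(nose = 3, neck = 2, tail_base = 0),
                cbind(nose = 0, neck = 0, tail_base = 0))
  expect_equal(head_angle(ds), 0)
  # nose up-screen (-y): the animal's left when viewed from above
  dsl <- make_ds(cbind(nose = 2, neck = 2, tail_base = 0),
                 cbind(nose = -1, neck = 0, tail_base = 0))
  expect_equal(head_angle(dsl), 90)
  dsr <- make_ds(cbind(nose = 2, neck = 2, tail_base = 0),
                 cbind(nose = 1, neck = 0, tail_base = 0))
  expect_equal(head_angle(dsr), -90)
  # zero-length head axis is missing
  dz <- make_ds(cbind(nose = 2, neck = 2, tail_base = 0),
                cbind(nose = 0, neck = 0, tail_base = 0))
  expect_true(is.na(head_angle(dz)))
})

test_that("head angle is rotation invariant and negates under mirroring", {
  withr::with_seed(19, {
    n <- 200
    pos <- cbind(runif(n, 0, 40), runif(n, 0, 40))
    theta <- runif(n, -pi, pi)
    ds <- template_ds(pos, theta)
    # bend the head: displace the nose laterally by a known wiggle
    ds$y[, "nose"] <- ds$y[, "nose"] + rnorm(n)
    base <- head_angle(ds)
    th <- runif(1, 0, 2 * pi); sh <- runif(2, -50, 50)
    rot <- ds
    cx <- cos(th) * ds$x - sin(th) * ds$y + sh[1]
    cy <- sin(th) * ds$x + cos(th) * ds$y + sh[2]
    rot$x <- cx; rot$y <- cy
    expect_equal(head_angle(rot), base, tolerance = 1e-9)
    mir <- ds; mir$y <- -ds$y
    expect_equal(head_angle(mir), -base, tolerance = 1e-12)
  })
})
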