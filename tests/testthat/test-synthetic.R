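test_that("simulation is a pure function of the scenario seed", {
  sc <- synthetic_scenario("OFT", duration_s = 10, seed = 12)
  a <- simulate_session(sc)
  b <- simulate_session(sc)
  expect_identical(a$tracking$x, b$tracking$x)
  expect_identical(a$tracking$likelihood, b$tracking$likelihood)
  expect_identical(a$annotations$segments, b$annotations$segments)
  c <- simulate_session(synthetic_scenario("OFT", duration_s = 10, seed = 13))
  expect_false(identical(a$tracking$x, c$tracking$x))
  # the global RNG stream is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); simulate_session(sc); after <- runif(1)
  expect_identical(before, after)
})

test_that("likelihoods split into confident samples and scripted dropout", {
  sc <- synthetic_scenario("OFT", duration_s = 40, dropout_rate = 0.05,
                           seed = 3)
  sim <- simulate_session(sc)
  lk <- as.numeric(sim$tracking$likelihood)
  dropped <- lk < 0.95
  expect_true(all(lk[!dropped] >= 0.95))
  expect_true(all(lk[dropped] == 0.1))
  # dropout fraction within binomial 99% bounds
  n <- length(lk)
  expect_lt(abs(mean(dropped) - 0.05), 2.58 * sqrt(0.05 * 0.95 / n) + 1e-9)
})

test_that("scripted bouts are emitted verbatim as ground-truth annotations", {
  script <- data.frame(behavior = c("supported_rear", "unsupported_rear"),
                       onset_s = c(5, 20), offset_s = c(6.5, 21))
  sim <- simulate_session(synthetic_scenario("OFT", duration_s = 30,
                                             behavior_script = script,
                                             seed = 8))
  expect_equal(sim$annotations$segments$onset_s, script$onset_s)
  expect_equal(sim$annotations$segments$offset_s, script$offset_s)
  expect_equal(sim$annotations$segments$behavior, script$behavior)
})

test_that("rear bouts deform the skeleton as designed", {
  script <- data.frame(behavior = c("supported_rear", "unsupported_rear"),
                       onset_s = c(5, 20), offset_s = c(7, 22))
  sim <- simulate_session(synthetic_scenario("OFT", duration_s = 30, seed = 9,
                                             behavior_script = script,
                                             noise_sd_px = 0, dropout_rate = 0))
  rep <- suppressWarnings(analyze_session(sim$tracking,
                                          default_session_config("OFT")))
  ft <- extract_skeleton_features(rep$dataset)$features
  lab <- annotations_to_frame_labels(sim$annotations, 25,
                                     rep$dataset$n_frames)
  body_len <- ft[, "len_nose_tailbase"]
  base <- median(body_len[lab == "none"])
  # both rear types compress the nose-tailbase axis by >= 30%
  expect_lt(max(body_len[lab != "none"]), 0.7 * base)
  # unsupported rears compress more than supported ones
  expect_lt(max(body_len[lab == "unsupported_rear"]),
            min(body_len[lab == "supported_rear"]))
  # supported rears happen within the wall band, unsupported in the interior
  wb <- rep$arena$zones$wall_band
  bc <- keypoint_xy(rep$dataset, "body_centre")
  expect_true(all(point_in_zone(bc[lab == "supported_rear", ], wb)))
  expect_false(any(point_in_zone(bc[lab == "unsupported_rear", ], wb)))
})

test_that("a noiseless pipeline recovers the generator's path length", {
  sim <- simulate_session(synthetic_scenario("OFT", duration_s = 60, seed = 10,
                                             noise_sd_px = 0,
                                             dropout_rate = 0))
  # true integrated path from the emitted pixels at the true scale
  px <- keypoint_xy(sim$tracking, "body_centre")
  true_cm <- sum(sqrt(rowSums(diff(px)^2))) / 10
  rep <- analyze_session(sim$tracking, default_session_config("OFT"))
  expect_equal(rep$measures$distance_cm, true_cm, tolerance = 0.01)
  expect_equal(rep$measures$px_per_cm, 10, tolerance = 0.001)
})

test_that("incompatible behavior scripts are rejected", {
  expect_error(synthetic_scenario("FST", duration_s = 30,
                                  behavior_script = data.frame(
                                    behavior = "head_dip", onset_s = 1,
                                    offset_s = 2)),
               "head_dip", class = "skeletrack_invalid")
  expect_error(synthetic_scenario("OFT", duration_s = 10,
                                  behavior_script = data.frame(
                                    behavior = "supported_rear",
                                    onset_s = c(1, 1.5),
                                    offset_s = c(2, 3))),
               "overlap", class = "skeletrack_invalid")
})

test_that("the fixture suite writes parseable, reproducible sessions", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  dur <- c(OFT = 60, EPM = 60, FST = 60)
  m1 <- make_fixture_suite(dir1, seed = 2, duration_s = dur)
  m2 <- make_fixture_suite(dir2, seed = 2, duration_s = dur)
  expect_equal(nrow(m1), 7)
  expect_equal(sum(m1$test_type == "OFT"), 3)
  for (i in seq_len(nrow(m1))) {
    ds <- read_dlc_tracking(file.path(dir1, m1$tracking[i]), fps = 25)
    expect_equal(ds$n_frames, 60 * 25)
    ann <- read_annotations(file.path(dir1, m1$annotations[i]))
    expect_gt(nrow(ann$segments), 0)
    cfg <- yaml::read_yaml(file.path(dir1, m1$config[i]))
    expect_equal(cfg$test_type, m1$test_type[i])
    # byte-identical regeneration
    expect_identical(readLines(file.path(dir1, m1$tracking[i])),
                     readLines(file.path(dir2, m2$tracking[i])))
  }
})
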