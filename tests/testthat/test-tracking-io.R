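test_that("well-formed DLC tables parse with frames and keypoints intact", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scorer,net,net,net,net,net,net",
    "bodyparts,nose,nose,nose,tail_base,tail_base,tail_base",
    "coords,x,y,likelihood,x,y,likelihood",
    "0,1.5,2.5,0.99,10,20,0.98",
    "1,2.5,3.5,0.97,11,21,0.96",
    "2,3.5,4.5,0.95,12,22,0.94",
    "3,4.5,5.5,0.93,13,23,0.92",
    "4,5.5,6.5,0.91,14,24,0.90"), path)
  ds <- read_dlc_tracking(path, fps = 25)
  expect_equal(ds$n_frames, 5)
  expect_equal(keypoint_names(ds), c("nose", "tail_base"))
  expect_equal(ds$x[, "nose"], c(1.5, 2.5, 3.5, 4.5, 5.5))
  expect_equal(unname(ds$likelihood[3, "tail_base"]), 0.94)
})

test_that("frames are reordered by the index column and blanks become NA", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scorer,net,net,net",
    "bodyparts,nose,nose,nose",
    "coords,x,y,likelihood",
    "1,2,20,0.9",
    "0,1,10,0.8",
    "2,,30,0.7"), path)
  ds <- read_dlc_tracking(path, fps = 25)
  expect_equal(ds$x[, "nose"], c(1, 2, NA))
  expect_equal(ds$likelihood[, "nose"], c(0.8, 0.9, 0.7))
})

test_that("the single-animal 'individuals' header variant is accepted", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scorer,net,net,net",
    "individuals,animal0,animal0,animal0",
    "bodyparts,nose,nose,nose",
    "coords,x,y,likelihood",
    "0,1,2,0.9"), path)
  ds <- read_dlc_tracking(path, fps = 30)
  expect_equal(ds$n_frames, 1)
  expect_equal(ds$fps, 30)
})

test_that("malformed headers raise format errors naming the problem", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scorer,net,net,net,net,net,net",
    "bodyparts,nose,nose,nose,tail_base,tail_base,tail_base",
    "coords,x,y,likelihood,x,y,z",
    "0,1,2,0.9,1,2,0.9"), path)
  expect_error(read_dlc_tracking(path, fps = 25),
               "coords row.*tail_base", class = "skeletrack_format")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scorer,a,a,a", "coords,x,y,likelihood", "0,1,2,0.9"), path2)
  expect_error(read_dlc_tracking(path2, fps = 25),
               "bodyparts", class = "skeletrack_format")
})

test_that("write-then-read round trips preserve every numeric value", {
  sim <- simulate_session(synthetic_scenario("OFT", duration_s = 4, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dlc_tracking(sim$tracking, path)
  back <- read_dlc_tracking(path, fps = sim$tracking$fps,
                            landmark_names = sim$tracking$landmark_names)
  expect_identical(unname(back$x), unname(sim$tracking$x))
  expect_identical(unname(back$y), unname(sim$tracking$y))
  expect_identical(unname(back$likelihood), unname(sim$tracking$likelihood))
  # 13 mouse points plus the arena landmarks on the bodyparts row
  expect_true(all(mouse_schema() %in% keypoint_names(back)))
  expect_length(keypoint_names(back, animal_only = TRUE), 13)
})

test_that("an empty dataset writes a header-only file that re-reads", {
  ds <- make_ds(matrix(numeric(), 0, 2, dimnames = list(NULL, c("a", "b"))),
                matrix(numeric(), 0, 2, dimnames = list(NULL, c("a", "b"))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dlc_tracking(ds, path)
  expect_length(readLines(path), 3)
  back <- read_dlc_tracking(path, fps = 25)
  expect_equal(back$n_frames, 0)
  expect_equal(keypoint_names(back), c("a", "b"))
})

test_that("annotation CSVs parse, sort, and validate onset < offset", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("behavior,onset_s,offset_s",
               "supported rear,5.5,6.5",
               "supported rear,1.0,2.0"), path)
  ann <- read_annotations(path)
  expect_equal(nrow(ann$segments), 2)
  expect_equal(ann$segments$onset_s, c(1.0, 5.5))
  expect_equal(ann$segments$behavior[1], "supported rear")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("behavior,onset_s,offset_s", empty)
  expect_equal(nrow(read_annotations(empty)$segments), 0)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("behavior,onset_s,offset_s", "rear,1,2", "rear,5,4"), bad)
  expect_error(read_annotations(bad), "row 2", class = "skeletrack_invalid")
})

test_that("annotation round trip preserves segments", {
  ann <- annotation_track(data.frame(
    behavior = c("floating", "floating"),
    onset_s = c(1.25, 8), offset_s = c(3.75, 9.5)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  expect_equal(read_annotations(path)$segments, ann$segments)
})

test_that("frame labels follow the frame-midpoint convention", {
  ann <- annotation_track(data.frame(behavior = "rear", onset_s = 1,
                                     offset_s = 2))
  lab <- annotations_to_frame_labels(ann, fps = 25, n_frames = 100)
  expect_length(lab, 100)
  # 0-based frames 25..49 have midpoints in [1, 2)
  expect_equal(which(lab == "rear"), 26:50)

  none <- annotations_to_frame_labels(
    annotation_track(data.frame(behavior = character(), onset_s = numeric(),
                                offset_s = numeric())), 25, 10)
  expect_equal(none, rep("none", 10))

  whole <- annotations_to_frame_labels(
    annotation_track(data.frame(behavior = "b", onset_s = 0, offset_s = 4)),
    25, 100)
  expect_equal(unique(whole), "b")
})

test_that("overlapping segments with different labels are rejected", {
  ann <- annotation_track(data.frame(behavior = c("a", "b"),
                                     onset_s = c(0, 0.5),
                                     offset_s = c(1, 1.5)))
  expect_error(annotations_to_frame_labels(ann, 25, 50),
               "overlapping", class = "skeletrack_invalid")
})

test_that("total labeled time matches clipped segment durations", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      fps <- sample(c(25, 30), 1)
      n <- sample(50:200, 1)
      k <- sample(1:4, 1)
      on <- sort(runif(k, 0, n / fps))
      seg <- data.frame(behavior = "b", onset_s = on,
                        offset_s = on + runif(k, 0.2, 2))
      seg <- seg[c(TRUE, seg$onset_s[-1] >= seg$offset_s[-k]), , drop = FALSE]
      ann <- annotation_track(seg)
      lab <- annotations_to_frame_labels(ann, fps, n)
      expect_length(lab, n)
      clipped <- sum(pmax(0, pmin(ann$segments$offset_s, n / fps) -
                            pmin(ann$segments$onset_s, n / fps)))
      labeled <- sum(lab == "b") / fps
      expect_lt(abs(labeled - clipped),
                (nrow(ann$segments) + 1) / fps)
    }
  })
})
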