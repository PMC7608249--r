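square45 <- rbind(c(0, 0), c(45, 0), c(45, 45), c(0, 45))

test_that("shoelace areas match simple shapes", {
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_equal(polygon_area(square45), 2025)
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 0))),
               class = "skeletrack_domain")
})

test_that("polygon scaling hits the requested area fraction", {
  expect_equal(scale_polygon(square45, 1), square45)
  half <- scale_polygon(square45, 0.5)
  expect_equal(polygon_area(half), 1012.5, tolerance = 1e-12)
  # concentric: same centroid
  expect_equal(polygon_centroid(half), polygon_centroid(square45))
  expect_error(scale_polygon(square45, 0), class = "skeletrack_domain")
  expect_error(scale_polygon(square45, 1.2), class = "skeletrack_domain")
})

test_that("area fraction holds for random simple polygons (shoelace oracle)", {
  withr::with_seed(17, {
    for (rep in 1:50) {
      poly <- random_star_polygon(sample(4:12, 1))
      f <- runif(1, 0.05, 1)
      out <- scale_polygon(poly, f)
      expect_equal(shoelace_oracle(out) / shoelace_oracle(poly), f,
                   tolerance = 1e-9)
    }
  })
})

test_that("point-in-zone agrees with a brute-force ray-casting oracle", {
  withr::with_seed(23, {
    poly <- random_star_polygon(9, r_range = c(2, 6))
    pts <- cbind(runif(1000, -7, 7), runif(1000, -7, 7))
    got <- point_in_zone(pts, poly)
    want <- vapply(seq_len(nrow(pts)), function(i) pip_oracle(pts[i, ], poly),
                   logical(1))
    expect_identical(got, want)
  })
  expect_true(point_in_zone(c(22.5, 22.5), square45))
  expect_false(point_in_zone(c(1000, 1000), square45))
  # boundary counts as inside
  expect_true(point_in_zone(c(0, 20), square45))
  expect_true(point_in_zone(c(45, 45), square45))
})

test_that("zone regions exclude hole interiors but keep hole boundaries", {
  hole <- scale_polygon(square45, 0.5)
  ring <- zone_region(square45, holes = list(hole))
  expect_true(point_in_zone(c(1, 1), ring))
  expect_false(point_in_zone(c(22.5, 22.5), ring))
  expect_true(point_in_zone(hole[1, ], ring))
  expect_equal(zone_area(ring), 1012.5, tolerance = 1e-9)
})

test_that("wall band splits the arena by a true edge offset", {
  wb <- wall_band_zones(square45, 12.5)
  expect_equal(polygon_area(wb$inner_zone), 400, tolerance = 1e-9)
  expect_equal(zone_area(wb$wall_zone) + polygon_area(wb$inner_zone),
               2025, tolerance = 1e-9)
  wb0 <- wall_band_zones(square45, 0)
  expect_equal(polygon_area(wb0$inner_zone), 2025)
  expect_error(wall_band_zones(square45, 23), class = "skeletrack_domain")
})

test_that("every inner-zone vertex keeps the band distance from all walls", {
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
    sqrt(sum((a + t * ab - p)^2))
  }
  withr::with_seed(31, {
    for (rep in 1:20) {
      # random convex polygon: hull of random points
      pts <- matrix(runif(24, 0, 50), ncol = 2)
      hull <- pts[chull(pts), ]
      band <- runif(1, 0.5, 3)
      inner <- wall_band_zones(hull, band)$inner_zone
      n <- nrow(hull)
      dmin <- min(vapply(seq_len(nrow(inner)), function(v) {
        min(vapply(seq_len(n), function(e) {
          seg_dist(inner[v, ], hull[e, ], hull[if (e == n) 1 else e + 1, ])
        }, 0))
      }, 0))
      expect_gte(dmin, band - 1e-9)
      # areas are conserved by the split
      expect_equal(zone_area(wall_band_zones(hull, band)$wall_zone) +
                     polygon_area(inner), polygon_area(hull),
                   tolerance = 1e-9)
    }
  })
})

test_that("landmark estimation is a per-axis gated median", {
  x <- cbind(lm = c(rep(3, 99), 100), p = rep(0, 100))
  y <- cbind(lm = c(rep(4, 99), 100), p = rep(0, 100))
  ds <- make_ds(x, y, landmark_names = "lm")
  est <- estimate_landmarks(ds, "lm")
  expect_equal(est$lm, c(3, 4))
  # low-likelihood frames are excluded before the median
  lik <- matrix(1, 100, 2, dimnames = list(NULL, c("lm", "p")))
  lik[1:60, "lm"] <- 0.2
  x2 <- x; x2[1:60, "lm"] <- 777
  ds2 <- make_ds(x2, y, lik, landmark_names = "lm")
  expect_equal(estimate_landmarks(ds2, "lm")$lm, c(3, 4))
  expect_error(estimate_landmarks(ds, "nope"),
               class = "skeletrack_unknown_keypoint")
  expect_equal(length(estimate_landmarks(make_ds(
    cbind(a = 1, b = 2), cbind(a = 1, b = 2)), c("a", "b"))), 2)
})

test_that("OFT arena template calibrates and derives the canonical zones", {
  lms <- list(corner_1 = c(50, 50), corner_2 = c(500, 50),
              corner_3 = c(500, 500), corner_4 = c(50, 500))
  arena <- build_arena("OFT", lms, list(width = 45, height = 45))
  expect_equal(arena$px_per_cm, 10)
  expect_equal(zone_area(arena$zones$center), 1012.5, tolerance = 1e-9)
  expect_equal(zone_area(arena$zones$periphery), 1012.5, tolerance = 1e-9)
  expect_equal(polygon_area(arena$zones$inner), 400, tolerance = 1e-9)
  expect_error(build_arena("OFT", lms[1:3], list(width = 45, height = 45)),
               "corner_4", class = "skeletrack_invalid")
})

test_that("arena construction is invariant to rotating the camera frame", {
  lms <- list(corner_1 = c(0, 0), corner_2 = c(450, 0),
              corner_3 = c(450, 450), corner_4 = c(0, 450))
  base <- build_arena("OFT", lms, list(width = 45, height = 45))
  withr::with_seed(5, {
    for (rep in 1:5) {
      th <- runif(1, 0, 2 * pi); sh <- runif(2, -100, 100)
      R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
      rot <- lapply(lms, function(p) as.numeric(R %*% p) + sh)
      arena <- build_arena("OFT", rot, list(width = 45, height = 45))
      expect_equal(arena$px_per_cm, base$px_per_cm, tolerance = 1e-9)
      for (nm in names(base$zones)) {
        expect_equal(zone_area(arena$zones[[nm]]),
                     zone_area(base$zones[[nm]]), tolerance = 1e-6)
      }
    }
  })
})

test_that("EPM template yields five named zones of the right size", {
  lms <- skeletrack:::synthetic_landmarks("EPM",
    list(arm_length = 65.5, arm_width = 5.5))
  lms <- lapply(lms, function(p) (p + 80) * 7)   # place and scale
  arena <- build_arena("EPM", lms, list(arm_length = 65.5, arm_width = 5.5))
  expect_setequal(names(arena$zones),
                  c("open1", "open2", "closed1", "closed2", "centre"))
  expect_equal(arena$px_per_cm, 7, tolerance = 1e-9)
  expect_equal(zone_area(arena$zones$open1), 65.5 * 5.5, tolerance = 1e-6)
  expect_equal(zone_area(arena$zones$centre), 5.5^2, tolerance = 1e-6)
})

test_that("FST rim points recover the beaker circle within 1%", {
  withr::with_seed(9, {
    th <- runif(8, 0, 2 * pi)
    lms <- stats::setNames(lapply(th, function(a) {
      c(300 + 80 * cos(a), 200 + 80 * sin(a))
    }), paste0("rim_", 1:8))
    arena <- build_arena("FST", lms, list(diameter = 20))
    expect_equal(arena$px_per_cm, 8, tolerance = 0.01)
    # polygon diameter in cm
    d <- 2 * sqrt(polygon_area(arena$arena_polygon) / pi)
    expect_equal(d, 20, tolerance = 0.01 * 20 + 0.1)
  })
})
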