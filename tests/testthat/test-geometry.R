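# Synthetic anatomy generation, contour-file round trips and validation.

# independent shoelace oracle (written without reference to the package's
# own polygon code)
shoelace <- function(p) {
  n <- nrow(p)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
  }
  abs(s) / 2
}

test_that("synthetic anatomies match the published geometric statistics", {
  cs_d <- fixture_distal()
  cs_p <- fixture_proximal()
  expect_length(cs_d$fascicles, 31)
  expect_length(cs_p$fascicles, 37)
  # distal envelope: 11.5 x 6.4 mm ellipse, ~58.2 mm^2
  expect_equal(shoelace(cs_d$outline), 58.2, tolerance = 0.02)
  bb <- apply(cs_d$outline, 2, function(v) diff(range(v)))
  expect_equal(unname(bb), c(11.5, 6.4), tolerance = 1e-9)
  bbp <- apply(cs_p$outline, 2, function(v) diff(range(v)))
  expect_equal(unname(bbp), c(18.7, 8.8), tolerance = 1e-6)
  # total fascicular area below the envelope area, recomputed independently
  tot <- sum(vapply(cs_d$fascicles, function(f) shoelace(f$contour), 1))
  expect_lt(tot, shoelace(cs_d$outline))
  expect_equal(tot, fascicular_area(cs_d)$fascicular_mm2, tolerance = 1e-9)
  # all three size classes populated
  for (cs in list(cs_d, cs_p)) {
    cls <- classify_fascicle_size(
      vapply(cs$fascicles, `[[`, 1, "equivalent_diameter"))
    expect_setequal(unique(cls), c("small", "medium", "big"))
  }
})

test_that("same seed gives bitwise-identical geometry", {
  a <- synthesize_cross_section("distal", 7)
  b <- synthesize_cross_section("distal", 7)
  expect_identical(a, b)
  expect_false(identical(a, synthesize_cross_section("distal", 8)))
})

test_that("unknown anatomy label is rejected naming the valid ones", {
  expect_error(synthesize_cross_section("ulnar", 1), "proximal.*distal")
})

test_that("fascicles are disjoint, inside the outline, with 3% perineurium", {
  cs <- fixture_distal()
  for (f in cs$fascicles) {
    expect_true(all(points_in_polygon(f$contour[, 1], f$contour[, 2],
                                      cs$outline)))
    expect_equal(f$perineurium_thickness, 0.03 * f$equivalent_diameter,
                 tolerance = 1e-9)
    # thin perineurium ring area ~ pi * d * t within 2%
    ring <- poly_perimeter(f$contour) * f$perineurium_thickness
    expect_equal(ring,
                 pi * f$equivalent_diameter * f$perineurium_thickness,
                 tolerance = 0.02)
  }
  n <- length(cs$fascicles)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
    expect_false(nervestim:::cpp_polys_edges_intersect(
      cs$fascicles[[i]]$contour, cs$fascicles[[j]]$contour))
})

test_that("size classification uses the stated cut-offs", {
  expect_equal(classify_fascicle_size(0.3), "small")
  expect_equal(classify_fascicle_size(0.6), "medium")
  expect_equal(classify_fascicle_size(0.9), "big")
  expect_equal(classify_fascicle_size(c(0.39, 0.41, 0.81)),
               c("small", "medium", "big"))
})

test_that("contour files round-trip and validate", {
  cs <- fixture_distal()
  f <- tempfile(fileext = ".contours")
  write_cross_section(cs, f)
  cs2 <- read_cross_section(f)
  expect_length(cs2$fascicles, length(cs$fascicles))
  for (i in seq_along(cs$fascicles))
    expect_lt(max(abs(cs$fascicles[[i]]$contour - cs2$fascicles[[i]]$contour)),
              1e-9)
  expect_lt(max(abs(cs$outline - cs2$outline)), 1e-9)

  # a 1 mm circular fascicle inside a 5 mm circle -> 0.030 mm perineurium
  f2 <- tempfile(fileext = ".contours")
  outer <- ellipse_polygon(c(0, 0), 2.5, 2.5, 0, 64)
  inner <- ellipse_polygon(c(0, 0), 0.5, 0.5, 0, 64)
  writeLines(c("NERVE", sprintf("%.9f %.9f", outer[, 1], outer[, 2]), "",
               "FASCICLE 0", sprintf("%.9f %.9f", inner[, 1], inner[, 2])),
             f2)
  cs3 <- read_cross_section(f2)
  expect_equal(cs3$fascicles[[1]]$perineurium_thickness, 0.030,
               tolerance = 1e-6)

  # fascicle crossing the outline is rejected with its id
  f3 <- tempfile(fileext = ".contours")
  bad <- ellipse_polygon(c(2.4, 0), 0.5, 0.5, 0, 64)
  writeLines(c("NERVE", sprintf("%.9f %.9f", outer[, 1], outer[, 2]), "",
               "FASCICLE 4", sprintf("%.9f %.9f", bad[, 1], bad[, 2])),
             f3)
  expect_error(read_cross_section(f3), "fascicle 5")
})

test_that("validation rejects overlapping fascicles", {
  outer <- ellipse_polygon(c(0, 0), 3, 3, 0, 64)
  a <- nervestim:::new_fascicle(1, ellipse_polygon(c(0, 0), 0.6, 0.6, 0, 40))
  b <- nervestim:::new_fascicle(2, ellipse_polygon(c(0.5, 0), 0.6, 0.6, 0, 40))
  cs <- nervestim:::new_cross_section(outer, list(a, b), "custom")
  expect_error(validate_cross_section(cs), "overlap")
})
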