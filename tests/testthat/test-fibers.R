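# Fiber population rules: clustering, density, diameters, node offsets.

test_that("populations per fascicle follow the size class (1/3/5)", {
  cs <- fixture_distal()
  d <- vapply(cs$fascicles, `[[`, 1, "equivalent_diameter")
  ks <- vapply(cs$fascicles, function(f)
    assign_populations(f, seed = 2)$n_populations, integer(1))
  expect_equal(ks, unname(c(small = 1L, medium = 3L, big = 5L)[
    classify_fascicle_size(d)]))
  f <- cs$fascicles[[which.max(d)]]
  expect_identical(assign_populations(f, 5), assign_populations(f, 5))
  a <- assign_populations(f, 5)$anchors
  expect_true(all(points_in_polygon(a[, 1], a[, 2], f$contour)))
})

test_that("realized density matches the 240/mm^2 target within 5%", {
  cs <- fixture_distal()
  fib <- populate_fibers(cs, seed = 3, density = 240)
  a <- fascicular_area(cs)$endoneurial_mm2
  expect_equal(nrow(fib) / a, 240, tolerance = 0.05)
  expect_true(all(tabulate(fib$fascicle_id, 31) >= 1))
})

test_that("a 0.5 mm^2 fascicle receives about 120 fibers", {
  f <- nervestim:::new_fascicle(
    1, ellipse_polygon(c(0, 0), sqrt(0.5 / pi), sqrt(0.5 / pi), 0, 48))
  cs <- nervestim:::new_cross_section(
    ellipse_polygon(c(0, 0), 2, 2, 0, 64), list(f), "custom")
  counts <- vapply(1:20, function(s)
    nrow(populate_fibers(cs, s, 240)), integer(1))
  # endoneurial area is slightly below 0.5 mm^2 (perineurium ring)
  a <- fascicular_area(cs)$endoneurial_mm2
  expect_equal(mean(counts), 240 * a, tolerance = 0.10)
  expect_true(all(counts > 240 * a - 4 * sqrt(240 * a)))
  expect_true(all(counts < 240 * a + 4 * sqrt(240 * a)))
})

test_that("fibers lie inside their fascicle's endoneurium", {
  cs <- fixture_distal()
  fib <- fixture_distal_fibers()
  for (f in cs$fascicles) {
    sub <- fib[fib$fascicle_id == f$id, ]
    expect_true(all(points_in_polygon(sub$x, sub$y, f$contour)))
    expect_true(all(distance_to_polygon(sub$x, sub$y, f$contour) >
                    f$perineurium_thickness))
  }
})

test_that("diameters are snapped to MRG values on the A-beta support", {
  fib <- fixture_distal_fibers()
  tab <- mrg_parameter_table()$fiber_diameter_um
  expect_true(all(fib$diameter_um %in% tab))
  expect_true(all(fib$diameter_raw_um >= 5.7 & fib$diameter_raw_um <= 16))
  # raw draws follow the configured mixture (KS test, alpha = 0.01)
  mix <- diameter_mixture_default()
  ks <- suppressWarnings(
    ks.test(fib$diameter_raw_um, function(q) nervestim:::mixture_cdf(q, mix)))
  expect_gt(ks$p.value, 0.01)
})

test_that("node offsets are randomized but internode spacing is exact", {
  fib <- fixture_distal_fibers()
  L <- 100 * fib$diameter_um * 1e-3
  expect_true(all(fib$z_offset_mm >= 0 & fib$z_offset_mm < L))
  expect_gt(length(unique(round(fib$z_offset_mm, 9))), nrow(fib) * 0.9)
  geo <- mrg_compartments(10)
  nodes_z <- geo$z_mm[geo$node_index > 0]
  expect_lt(max(abs(diff(nodes_z) - 1.0)), 1e-9)  # L = 100 * 10 um = 1 mm
  expect_equal(sum(geo$node_index > 0), 21)
  expect_equal(length(geo$z_mm), 221)
})

test_that("fiber populations are seed-stable and exportable", {
  cs <- fixture_distal()
  a <- populate_fibers(cs, 4, 60)
  b <- populate_fibers(cs, 4, 60)
  expect_identical(a, b)
  f <- tempfile(fileext = ".csv")
  write_fibers(a, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(a))
  expect_equal(back$x, a$x, tolerance = 1e-12)
})
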