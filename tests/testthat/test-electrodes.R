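# Parametric electrode construction and placement.

test_that("TIME geometry follows the published dimensions", {
  e <- time_electrode(20, "proximal")
  expect_equal(e$shaft_length, 18)
  expect_equal(sum(e$as_face == 1), 10)
  expect_equal(sum(e$as_face == -1), 10)
  expect_equal(e$shaft_thickness, 0.020)
  expect_equal(e$as_shape$diameter, 0.060)
  d <- time_electrode(12, "distal")
  expect_equal(d$shaft_length, 10)
  expect_equal(sum(d$as_face == 1), 6)
  # width interpolates 0.380 (12 AS) to 0.670 mm (24 AS), monotonically
  w <- vapply(c(12, 16, 20, 24),
              function(n) time_electrode(n, "distal")$shaft_width, 1)
  expect_equal(w[1], 0.380)
  expect_equal(w[4], 0.670)
  expect_true(all(diff(w) > 0))
  expect_error(time_electrode(14, "proximal"), "12, 16, 20, 24")
})

test_that("TIME sites sit on the faces, evenly pitched, half-pitch offset", {
  e <- time_electrode(16, "proximal")
  pos <- e$as_positions
  expect_true(all(abs(abs(pos[, 2]) - e$shaft_thickness / 2) < 1e-9))
  top <- sort(pos[e$as_face == 1, 1])
  bot <- sort(pos[e$as_face == -1, 1])
  pitch <- e$shaft_length / (e$n_as / 2)
  expect_lt(max(abs(diff(top) - pitch)), 1e-9)
  expect_lt(max(abs(diff(bot) - pitch)), 1e-9)
  expect_lt(max(abs(bot - top - pitch / 2)), 1e-9)
  expect_true(all(abs(pos[, 1]) <= e$shaft_length / 2))
})

test_that("FINE geometry follows the published dimensions", {
  e <- fine_electrode(20, "proximal")
  expect_equal(e$shaft_length, 18.75)
  expect_equal(e$shaft_width, 8.85)
  expect_equal(sum(e$as_positions[, 2] > 0), 10)
  expect_equal(e$as_shape$side, 0.5)
  d <- fine_electrode(12, "distal")
  expect_equal(d$shaft_length, 10.9)
  expect_equal(d$n_as, 12)
  expect_error(fine_electrode(24, "distal"), "12, 16 or 20")
  # even spacing along the long faces
  top <- sort(e$as_positions[e$as_face == 1, 1])
  expect_lt(max(abs(diff(top) - 18.75 / 10)), 1e-9)
})

test_that("TIME implants are parallel, inside, and deterministic", {
  cs <- fixture_proximal()
  e <- time_electrode(20, "proximal")
  pls <- place_implants(cs, e, 3)
  expect_length(pls, 3)
  ys <- vapply(pls, function(p) p$insertion_point[2], 1)
  expect_equal(length(unique(ys)), 3)
  for (p in pls)
    expect_gte(nervestim:::shaft_inside_fraction(cs, p), 0.6)
  # single centered implant crosses the nerve centroid
  p1 <- place_implants(cs, e, 1, strategy = "centered")[[1]]
  ctr <- poly_centroid(cs$outline)
  expect_equal(p1$insertion_point[2], ctr[2], tolerance = 1e-9)
  expect_true(abs(ctr[1] - p1$insertion_point[1]) < e$shaft_length / 2)
  expect_identical(place_implants(cs, e, 2), place_implants(cs, e, 2))
})

test_that("multi-implant placement is TIME-only and FINE circumscribes", {
  cs <- fixture_distal()
  expect_error(place_implants(cs, fine_electrode(16, "distal"), 2),
               "TIME-only")
  pl <- place_implants(cs, fine_electrode(12, "distal"), 1)[[1]]
  bb <- apply(cs$outline, 2, range)
  expect_gte(pl$electrode$shaft_length, diff(bb[, 1]))
  expect_gte(pl$electrode$shaft_width, diff(bb[, 2]))
})
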