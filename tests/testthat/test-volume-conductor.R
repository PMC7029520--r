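# Volume-conductor solver: closed-form point-source oracles, linearity,
# superposition, interpolation, tissue classification and shielding.

test_that("solver matches the isotropic point-source closed form within 10%", {
  s <- solve_homogeneous(2, 2)
  for (r in c(0.5, 1, 2, 4)) {
    v <- nervestim:::cpp_trilinear(s$xs, s$xs, s$zc, s$V, r, 0, 0)
    expect_equal(v, s$ana(r, 0, 0), tolerance = 0.10)
  }
})

test_that("solver matches the anisotropic point-source closed form within 10%", {
  s <- solve_homogeneous(0.0826, 0.571)
  for (p in list(c(0.5, 0, 0), c(2, 0, 0), c(0, 0, 2), c(1, 1, 3))) {
    v <- nervestim:::cpp_trilinear(s$xs, s$xs, s$zc, s$V, p[1], p[2], p[3])
    expect_equal(v, s$ana(p[1], p[2], p[3]), tolerance = 0.10)
  }
  # equipotentials elongated along z: V(0,0,z) > V(rho,0,0) at equal distance
  v_z <- nervestim:::cpp_trilinear(s$xs, s$xs, s$zc, s$V, 0, 0, 2)
  v_t <- nervestim:::cpp_trilinear(s$xs, s$xs, s$zc, s$V, 2, 0, 0)
  expect_gt(v_z, v_t)
})

test_that("lead fields scale linearly with injected current", {
  cs <- fixture_distal()
  pl <- place_implants(cs, time_electrode(12, "distal"), 1)
  map <- conductivity_map(cs, pl, "test")
  lf1 <- solve_lead_field(map, 3, I_ref = 2e-6)
  lf2 <- solve_lead_field(map, 3, I_ref = 4e-6)
  i <- which(abs(lf1$V) > 1e-7)
  expect_lt(max(abs(lf2$V[i] / lf1$V[i] - 2)), 1e-5)
})

test_that("superposition is pointwise and polarity-aware", {
  lfs <- fixture_distal_fields()
  pts <- cbind(runif(40, -4, 4), runif(40, -2, 2), runif(40, -3, 3))
  # identity: weight I on one site only
  sup1 <- superpose_fields(lfs[1], weights = lfs[[1]]$I_ref)
  expect_equal(sample_potential(sup1, pts), sample_potential(lfs[[1]], pts),
               tolerance = 1e-12)
  # cancellation: +I and -I on the same site
  sup0 <- superpose_fields(list(lfs[[1]], lfs[[1]]), weights = c(1e-6, -1e-6))
  expect_lt(max(abs(sample_potential(sup0, pts))), 1e-15)
  # anti-polar pair: midpoint potential smaller than either monopolar one
  p1 <- lfs[[1]]$position; p2 <- lfs[[2]]$position
  mid <- matrix((p1 + p2) / 2, nrow = 1)
  bi <- superpose_fields(list(lfs[[1]], lfs[[2]]), weights = c(1e-6, -1e-6))
  expect_lt(abs(sample_potential(bi, mid)),
            max(abs(sample_potential(lfs[[1]], mid, current = 1e-6)),
                abs(sample_potential(lfs[[2]], mid, current = 1e-6))))
})

test_that("interpolation reproduces grid values and decays with distance", {
  lfs <- fixture_distal_fields()
  lf <- lfs[[3]]
  # exact grid vertex
  i <- c(30, 31, 12)
  v <- sample_potential(lf, cbind(lf$xs[i[1]], lf$ys[i[2]], lf$zc[i[3]]))
  arr <- array(lf$V, c(length(lf$xs), length(lf$ys), length(lf$zc)))
  expect_equal(v, arr[i[1], i[2], i[3]], tolerance = 1e-12)
  # |V| decreases with node distance from the site along a nearby fiber
  pos <- lf$position
  z <- seq(0, 6, by = 0.5)
  vals <- abs(sample_potential(lf, cbind(pos[1], pos[2] + 0.5, pos[3] + z)))
  expect_true(all(diff(vals) < 0))
  # out-of-domain node is rejected with its index
  expect_error(sample_potential(lf, rbind(c(0, 0, 0), c(50, 0, 0))),
               "node 2")
})

test_that("tissue classification matches the conductivity constants", {
  cs <- fixture_distal()
  pl <- place_implants(cs, time_electrode(12, "distal"), 1)
  map <- conductivity_map(cs, pl, "test")
  f <- cs$fascicles[[3]]
  expect_equal(classify_tissue(map, matrix(f$centroid, 1)), "endoneurium")
  out <- cs$outline[which.max(cs$outline[, 1]), ] + c(1, 0)
  expect_equal(classify_tissue(map, matrix(out, 1)), "saline")
  ip <- pl[[1]]$insertion_point
  expect_equal(classify_tissue(map, matrix(c(ip[1], ip[2], 0), 1)),
               "substrate")
  # a point just inside a fascicle contour is perineurium
  edge <- f$contour[1, ] + 0.2 * (f$centroid - f$contour[1, ]) *
    (f$perineurium_thickness / sqrt(sum((f$centroid - f$contour[1, ])^2)))
  expect_equal(classify_tissue(map, matrix(edge, 1)), "perineurium")
  sig <- tissue_conductivities()
  expect_equal(sig$endoneurium, c(0.0826, 0.571))
  expect_equal(sig$saline[1], 2)
  expect_equal(sig$substrate[1], 6.67e-14)
  expect_equal(sig$perineurium[1], 0.00088)
})

test_that("the perineurium sheet shields the fascicle interior", {
  cs <- fixture_distal()
  pl <- place_implants(cs, time_electrode(12, "distal"), 1)
  map <- conductivity_map(cs, pl, "test")
  lf <- solve_lead_field(map, 2)
  map0 <- map
  map0$peri_res <- rep(0, length(map0$peri_res))
  lf0 <- solve_lead_field(map0, 2)
  # the resistive sheath attenuates the field penetrating a fascicle: the
  # potential variation across a non-target fascicle's interior shrinks
  pos <- lf$position
  dc <- vapply(cs$fascicles, function(f)
    sqrt(sum((f$centroid - pos[1:2])^2)), 1)
  f <- cs$fascicles[[order(dc)[3]]]
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  r <- 0.35 * f$equivalent_diameter
  pts <- cbind(f$centroid[1] + r * cos(th), f$centroid[2] + r * sin(th), 0)
  spread <- function(x) diff(range(x))
  expect_lt(spread(sample_potential(lf, pts)),
            spread(sample_potential(lf0, pts)))
})

test_that("potentials vanish on the grounded outer boundary", {
  lf <- fixture_distal_fields()[[1]]
  nx <- length(lf$xs)
  arr <- array(lf$V, c(nx, length(lf$ys), length(lf$zc)))
  expect_lt(max(abs(arr[1, , ])), 1e-12)
  expect_lt(max(abs(arr[, , 1])), 1e-12)
})

test_that("grid refinement changes fascicle potentials by less than 5%", {
  cs <- fixture_toy_nerve()
  pl <- nervestim:::new_placement(time_electrode(12, "distal"),
                                  c(0, 0), 0, 0, 1L)
  prof <- list(h_xy = 0.15, h_z = 0.2, z_fine = 1.0, growth = 1.8,
               h_z_max = 4.0)
  prof2 <- modifyList(prof, list(h_xy = 0.075, h_z = 0.1))
  lf1 <- solve_lead_field(conductivity_map(cs, list(pl), prof), 3)
  lf2 <- solve_lead_field(conductivity_map(cs, list(pl), prof2), 3)
  probes <- do.call(rbind,
                    lapply(cs$fascicles, function(f) c(f$centroid, 0)))
  v1 <- sample_potential(lf1, probes)
  v2 <- sample_potential(lf2, probes)
  expect_lt(max(abs(v1 / v2 - 1)), 0.05)
})
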