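# Shared fixtures. Heavy objects (cross-sections, lead fields) are built
# once per test run and memoized here; tests use the coarse "test" solver
# profile and reduced fiber densities so the whole suite stays desk-scale.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fixture_distal <- function() memo("distal", synthesize_cross_section("distal", 1))
fixture_proximal <- function() memo("proximal", synthesize_cross_section("proximal", 1))

# Distal TIME-12 lead fields at test resolution.
fixture_distal_fields <- function() {
  memo("distal_lfs", {
    cs <- fixture_distal()
    pl <- place_implants(cs, time_electrode(12, "distal"), 1)
    solve_placement_fields(cs, pl[[1]], resolution = "test")
  })
}

fixture_distal_fibers <- function(seed = 1, density = 60) {
  memo(sprintf("distal_fib_%d_%d", seed, density),
       populate_fibers(fixture_distal(), seed, density))
}

# A small five-fascicle nerve for exact selectivity oracles: an 11 x 6 mm
# ellipse with five well-separated circular fascicles along the major axis.
fixture_toy_nerve <- function() {
  memo("toy", {
    mk <- function(cx, cy, d) ellipse_polygon(c(cx, cy), d / 2, d / 2, 0, 40)
    outline <- ellipse_polygon(c(0, 0), 5.5, 3.0, 0, 96)
    specs <- list(c(-3.6, 0.8, 1.0), c(-1.8, -0.9, 0.8), c(0, 0.9, 1.2),
                  c(1.9, -0.8, 0.9), c(3.6, 0.7, 0.8))
    fas <- lapply(seq_along(specs), function(i) {
      s <- specs[[i]]
      nervestim:::new_fascicle(i, mk(s[1], s[2], s[3]))
    })
    cs <- nervestim:::new_cross_section(outline, fas, "custom")
    validate_cross_section(cs)
  })
}

fixture_toy_fields <- function() {
  memo("toy_lfs", {
    cs <- fixture_toy_nerve()
    e <- time_electrode(12, "distal")
    pl <- nervestim:::new_placement(e, c(0, 0), 0, 0, 1L)
    solve_placement_fields(cs, pl, resolution = "test")
  })
}

fixture_toy_fibers <- function(seed = 1) {
  memo(sprintf("toy_fib_%d", seed),
       populate_fibers(fixture_toy_nerve(), seed, density = 60))
}

# Analytic anisotropic point-source potential (V) at distance rho (mm) from
# a unit 1 A source, evaluated along a fiber's compartments; the
# independent oracle for solver and biophysics tests.
aniso_point_profile <- function(diameter_um, rho_mm, z_off_mm = 0,
                                sig_t = 0.0826, sig_z = 0.571) {
  geo <- mrg_compartments(diameter_um)
  z <- geo$z_mm + z_off_mm
  r_eff <- sqrt(rho_mm^2 / sig_t + z^2 / sig_z) * 1e-3
  1 / (4 * pi * sqrt(sig_t * sig_z) * r_eff)
}

# Short sweep for cheap threshold tests.
sweep_short <- function() stimulus_sweep(20, 0.5, 60)
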