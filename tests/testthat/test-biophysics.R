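# MRG fiber dynamics: recruitment behavior, threshold search, and the
# charge bookkeeping of the stimulus sweep.

test_that("the charge sweep spans 0.5-60 nC in 60 monotone steps", {
  sw <- stimulus_sweep()
  expect_equal(sw$n, 60)
  expect_equal(length(sw$charges_nC), 60)
  expect_equal(sw$charges_nC[1], 0.5)
  expect_equal(sw$charges_nC[60], 60)
  expect_true(all(diff(sw$charges_nC) > 0))
  expect_equal(charge_to_current(0.5, 50), 10e-6)
  expect_equal(charge_to_current(60, 50), 1200e-6)
  # halving the pulse width at fixed current halves the delivered charge
  I <- charge_to_current(10, 50)
  expect_equal(I * 25e-6 * 1e9, 5)
})

test_that("no drive means no recruitment; suprathreshold drive recruits", {
  expect_false(simulate_fiber(10, rep(0, 221)))
  sw <- stimulus_sweep()
  prof <- -aniso_point_profile(10, 0.5)
  th <- find_threshold(10, prof, sw)
  expect_false(is.na(th$threshold_nC))
  I_th <- charge_to_current(th$threshold_nC)
  expect_true(simulate_fiber(10, prof * I_th * 1.3))
  expect_false(simulate_fiber(10, prof * I_th * 0.2))
})

test_that("extreme amplitudes initiate but block propagation", {
  # the cathodal-block regime: the doubled-cable response is not monotone
  # at very high charge, which is why recruitment curves are cumulative
  prof <- -aniso_point_profile(10, 0.1)
  r <- nervestim:::cpp_mrg_simulate(10, prof * 1e3, 1.2e-3, 0.05, 1e-3,
                                    4e-3, 2, nervestim:::mrg_resting_state(10))
  expect_false(r$recruited)
  sw <- stimulus_sweep()
  th <- find_threshold(10, prof, sw)
  expect_false(is.na(th$threshold_nC))  # the search still finds the window
})

test_that("the resting state is stable near -80 mV", {
  eq <- nervestim:::mrg_resting_state(10)
  expect_true(all(eq$vm > -82 & eq$vm < -78))
  tr <- simulate_fiber(10, rep(0, 221), trace = TRUE)
  expect_false(tr$recruited)
})

test_that("larger fibers recruit at lower thresholds (inverse order)", {
  set.seed(42)
  n_ok <- 0
  n <- 40
  sw <- sweep_short()
  for (i in seq_len(n)) {
    rho <- runif(1, 0.2, 1.2)
    zoff <- runif(1, 0, 1)
    th_big <- find_threshold(14, -aniso_point_profile(14, rho, zoff), sw)
    th_small <- find_threshold(7.3, -aniso_point_profile(7.3, rho, zoff), sw)
    big <- if (is.na(th_big$threshold_nC)) Inf else th_big$threshold_nC
    small <- if (is.na(th_small$threshold_nC)) Inf else th_small$threshold_nC
    if (big <= small) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n, 0.95)
})

test_that("bisection equals the exhaustive sweep on random fibers", {
  set.seed(7)
  sw <- sweep_short()
  for (i in 1:50) {
    D <- sample(c(5.7, 7.3, 10, 12.8, 16), 1)
    rho <- runif(1, 0.15, 1.1)
    prof <- -aniso_point_profile(D, rho, runif(1, 0, 1))
    a <- find_threshold(D, prof, sw)
    b <- find_threshold(D, prof, sw, exhaustive = TRUE)
    expect_identical(a$index, b$index)
    expect_lte(a$n_sims, 12)
  }
})

test_that("recruitment is monotone with charge at ordinary distances", {
  sw <- sweep_short()
  for (rho in c(0.4, 0.7, 1.0)) {
    prof <- -aniso_point_profile(10, rho)
    rec <- vapply(seq_len(sw$n), function(k)
      simulate_fiber(10, prof * sw$currents_A[k]), logical(1))
    if (any(rec))
      expect_true(all(rec[seq.int(which(rec)[1], sw$n)]))
  }
})

test_that("threshold charge grows with distance from the source", {
  sw <- stimulus_sweep()
  th <- vapply(c(0.3, 0.6, 1.0, 1.5), function(rho) {
    t <- find_threshold(11.5, -aniso_point_profile(11.5, rho), sw)
    if (is.na(t$threshold_nC)) Inf else t$threshold_nC
  }, 1)
  expect_true(all(diff(th) >= 0))
})

test_that("numerical integration converges: halved dt shifts no threshold", {
  # the grid threshold with the production step sizes matches the one with
  # half the step sizes for a representative fiber
  sw <- sweep_short()
  prof <- -aniso_point_profile(10, 0.5)
  a <- find_threshold(10, prof, sw)
  st <- nervestim:::mrg_sim_settings(50)
  res <- nervestim:::cpp_mrg_threshold(
    10, prof * 1e3, sw$currents_A, st$pulse_ms, st$dt_on / 2, st$dt_off / 2,
    st$t_max, nervestim:::mrg_resting_state(10), FALSE)
  expect_lte(abs(res$index - a$index), 1)
})
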