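# R-level interface to the MRG double-cable axon model: parameter tables,
# compartment geometry, the charge sweep, single-fiber simulation and the
# grid threshold search. Resting states are equilibrated once per tabulated
# diameter and cached for the session.

.mrg_env <- new.env(parent = emptyenv())

#' MRG fiber parameter table
#'
#' Diameter-dependent geometry of the tabulated MRG fibers (node and axon
#' diameters, paranode length, myelin lamellae count). Electrical constants
#' and nodal channel kinetics are fixed; internode length follows the
#' `L = 100 * D` rule.
#'
#' @return Data frame with one row per tabulated fiber diameter.
#' @export
mrg_parameter_table <- function() cpp_mrg_table()

#' MRG compartment geometry for a fiber diameter
#'
#' 21 nodes of Ranvier and 20 internodes (MYSA, FLUT, 6 STIN each); the
#' central node sits at z = 0.
#'
#' @param diameter_um Fiber diameter in um (snapped to the nearest
#'   tabulated value for all parameters except the internode length).
#' @return List with per-compartment `type` (0 node, 1 MYSA, 2 FLUT,
#'   3 STIN), `node_index`, `z_mm`, `length_um`, `diameter_um`.
#' @export
mrg_compartments <- function(diameter_um) cpp_mrg_compartments(diameter_um)

mrg_resting_state <- function(diameter_um) {
  key <- sprintf("d%.1f", snap_to_mrg_diameter(diameter_um))
  if (is.null(.mrg_env[[key]]))
    .mrg_env[[key]] <- cpp_mrg_equilibrium(diameter_um)
  .mrg_env[[key]]
}

#' The charge sweep of the threshold search
#'
#' 60 monotone charges from 0.5 to 60 nC delivered as rectangular cathodic
#' pulses of fixed width (50 us by default), so the site current is
#' `Q / pulse_width` (10 uA at 0.5 nC, 1.2 mA at 60 nC).
#'
#' @param n Number of amplitudes.
#' @param min_nC,max_nC Sweep limits in nC.
#' @param pulse_us Pulse width in us.
#' @return List with `charges_nC`, `currents_A`, `pulse_us`, `n`.
#' @export
stimulus_sweep <- function(n = 60, min_nC = 0.5, max_nC = 60, pulse_us = 50) {
  charges <- seq(min_nC, max_nC, length.out = n)
  list(charges_nC = charges,
       currents_A = charge_to_current(charges, pulse_us),
       pulse_us = pulse_us, n = n)
}

#' Convert charge to current at a given pulse width
#'
#' @param charge_nC Charge in nC.
#' @param pulse_us Pulse width in us.
#' @return Current in A.
#' @export
charge_to_current <- function(charge_nC, pulse_us = 50) {
  charge_nC * 1e-9 / (pulse_us * 1e-6)
}

# Integration settings: 1 us implicit steps during the pulse, 5 us after,
# 2 ms total window.
mrg_sim_settings <- function(pulse_us = 50) {
  list(pulse_ms = pulse_us * 1e-3, dt_on = 1e-3, dt_off = 5e-3, t_max = 2.0)
}

#' Simulate one fiber under an extracellular potential profile
#'
#' Integrates the MRG double-cable dynamics with the profile applied outside
#' the myelin during a rectangular pulse. The fiber counts as recruited when
#' the action potential propagates over its entire length, i.e. the membrane
#' potential crosses 0 mV at both terminal nodes after stimulus onset.
#'
#' @param diameter_um Fiber diameter in um.
#' @param potentials_V Extracellular potential (volts) at every compartment
#'   (use [fiber_potentials()] to sample them from a lead field).
#' @param scale Dimensionless multiplier on the profile (e.g. a current
#'   ratio under linear scaling).
#' @param pulse_us Pulse width in us.
#' @param trace Return membrane-potential traces for inspection.
#' @return Logical `recruited` (or a list with traces when `trace = TRUE`).
#' @export
simulate_fiber <- function(diameter_um, potentials_V, scale = 1,
                           pulse_us = 50, trace = FALSE) {
  st <- mrg_sim_settings(pulse_us)
  res <- cpp_mrg_simulate(diameter_um, potentials_V * 1e3, scale,
                          st$pulse_ms, st$dt_on, st$dt_off, st$t_max,
                          mrg_resting_state(diameter_um), trace)
  if (trace) res else res$recruited
}

#' Grid threshold search for one fiber
#'
#' Finds the smallest sweep charge that recruits the fiber, scaling the
#' unit-current potential profile linearly over the sweep. Uses bisection
#' anchored at the sweep cap, complemented by a doubling-ladder scan from
#' the bottom of the grid for fibers whose high-amplitude response is closed
#' by cathodal block; `exhaustive = TRUE` forces the plain first-to-recruit
#' scan (the oracle the bisection is tested against).
#'
#' @param diameter_um Fiber diameter in um.
#' @param potentials_per_A Extracellular potential profile per compartment
#'   for +1 A of configuration current (volts/ampere); cathodic polarity is
#'   carried by the profile's sign.
#' @param sweep A [stimulus_sweep()].
#' @param exhaustive Use the exhaustive bottom-up scan.
#' @return List: `threshold_nC` (NA if not recruited at the cap),
#'   `index` (0 if none), `n_sims`.
#' @export
find_threshold <- function(diameter_um, potentials_per_A,
                           sweep = stimulus_sweep(), exhaustive = FALSE) {
  st <- mrg_sim_settings(sweep$pulse_us)
  res <- cpp_mrg_threshold(diameter_um, potentials_per_A * 1e3,
                           sweep$currents_A, st$pulse_ms, st$dt_on,
                           st$dt_off, st$t_max,
                           mrg_resting_state(diameter_um), exhaustive)
  list(threshold_nC = if (res$index > 0) sweep$charges_nC[res$index] else NA_real_,
       index = res$index, n_sims = res$n_sims)
}

#' Sample a potential field along a fiber's compartments
#'
#' The fiber runs longitudinally at its (x, y) position with its central
#' node shifted by `z_offset_mm`. Compartments beyond the solver's axial
#' extent take the grounded-boundary value 0. With `nodes_only = TRUE` only
#' the nodes of Ranvier are sampled and internodal compartments receive
#' linearly interpolated values.
#'
#' @param field A `lead_field` or `superposed_field`.
#' @param fiber One row of a `fiber_population` (or a list with `x`, `y`,
#'   `diameter_um`, `z_offset_mm`).
#' @param current Current (A) for a single lead field (see
#'   [sample_potential()]).
#' @param nodes_only Sample nodes of Ranvier only.
#' @return Potential in volts per compartment.
#' @export
fiber_potentials <- function(field, fiber, current = NULL,
                             nodes_only = FALSE) {
  geo <- mrg_compartments(fiber$diameter_um)
  z <- geo$z_mm + fiber$z_offset_mm
  zlim <- if (inherits(field, "superposed_field"))
    range(field$fields[[1]]$zc) else range(field$zc)
  inside <- z >= zlim[1] & z <= zlim[2]
  v <- numeric(length(z))
  if (nodes_only) {
    nd <- geo$node_index > 0
    use <- nd & inside
    pts <- cbind(fiber$x, fiber$y, z[use])
    vn <- sample_potential(field, pts, current = current)
    zn <- z[use]
    v[inside] <- approx(zn, vn, xout = z[inside], rule = 2)$y
  } else {
    pts <- cbind(fiber$x, fiber$y, z[inside])
    v[inside] <- sample_potential(field, pts, current = current)
  }
  v
}
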