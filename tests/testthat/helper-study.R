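# Memoized scaled-down studies shared by the reproduction tests: one
# anatomy seed, the coarse "test" solver grid, reduced fiber density and a
# common lead-field cache. Several criteria reuse the same study objects.

study_solver_cache <- function() memo("study_cache", new.env(parent = emptyenv()))

fixture_study <- function(anatomy, kind, n_as, n_implants = 1,
                          policy = "monopolar", seeds = 1:2, density = 60) {
  key <- paste("study", anatomy, kind, n_as, n_implants, policy,
               paste(seeds, collapse = "."), density, sep = "_")
  memo(key, selectivity_study(anatomy, kind, n_as, n_implants = n_implants,
                              policy = policy, fiber_seeds = seeds,
                              density = density, resolution = "test",
                              cache = study_solver_cache()))
}

# Direct low-level solve on a homogeneous box with Dirichlet boundary set
# to the closed-form potential, so the free-medium point-source solution
# applies exactly.
solve_homogeneous <- function(sig_t, sig_z, h = 0.25, half = 6, I = 1e-6) {
  xs <- seq(-half, half, by = h)
  n <- length(xs)
  zed <- seq(-half - h / 2, half + h / 2, by = h)
  zc <- (zed[-1] + zed[-length(zed)]) / 2
  nz <- length(zc)
  lab <- integer(n * n)
  sig <- matrix(c(sig_t, sig_z), nrow = 1)
  mask <- array(TRUE, c(n, n, nz))
  mask[c(1, n), , ] <- FALSE
  mask[, c(1, n), ] <- FALSE
  mask[, , c(1, nz)] <- FALSE
  ana <- function(x, y, z)
    I / (4 * pi * sqrt(sig_t * sig_z) *
         sqrt((x^2 + y^2) / sig_t + z^2 / sig_z) * 1e-3)
  vb <- array(0, c(n, n, nz))
  for (k in c(1, nz)) vb[, , k] <- outer(xs, xs, ana, z = zc[k])
  for (i in c(1, n)) for (k in seq_len(nz)) vb[i, , k] <- ana(xs[i], xs, zc[k])
  for (j in c(1, n)) for (k in seq_len(nz)) vb[, j, k] <- ana(xs, xs[j], zc[k])
  ic <- which.min(abs(xs)); kc <- which.min(abs(zc))
  src <- (ic - 1L) + n * ((ic - 1L) + n * (kc - 1L))
  sol <- nervestim:::cpp_solve_leadfield(
    xs, xs, zed, lab, sig, numeric(0), matrix(0, 0, 6),
    as.vector(mask), as.vector(vb), src, 1.0, I, 1e-8, 20000L)
  list(xs = xs, zc = zc, V = sol$V, ana = ana, sol = sol)
}
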