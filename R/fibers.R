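# Myelinated sensory fiber populations. Each fascicle receives 1, 3 or 5
# clustered populations according to its size class; fibers are sampled at
# 240 per mm^2 of endoneurial area with diameters from a configurable
# two-component mixture over the A-beta range, snapped to the tabulated MRG
# diameters, and nodes of Ranvier shifted by a random longitudinal offset.

FIBER_DENSITY_DEFAULT <- 240  # fibers per mm^2 of endoneurial area

#' Default fiber-diameter mixture
#'
#' Two equal-weight Gaussian components (modes ~7 and ~12 um, sd 1.5 um)
#' truncated to the 5.7-16 um A-beta support.
#'
#' @return List with `means`, `sds`, `weights`, `support` (um).
#' @export
diameter_mixture_default <- function() {
  list(means = c(7, 12), sds = c(1.5, 1.5), weights = c(0.5, 0.5),
       support = c(5.7, 16.0))
}

sample_mixture <- function(n, mix) {
  out <- numeric(0)
  while (length(out) < n) {
    comp <- sample.int(length(mix$weights), n, replace = TRUE,
                       prob = mix$weights)
    d <- rnorm(n, mix$means[comp], mix$sds[comp])
    out <- c(out, d[d >= mix$support[1] & d <= mix$support[2]])
  }
  out[seq_len(n)]
}

mixture_cdf <- function(q, mix) {
  lo <- mix$support[1]; hi <- mix$support[2]
  raw <- function(x) sum(mix$weights * stats::pnorm(x, mix$means, mix$sds))
  z <- vapply(pmin(pmax(q, lo), hi), raw, numeric(1))
  (z - raw(lo)) / (raw(hi) - raw(lo))
}

#' Snap diameters to the tabulated MRG fiber diameters
#'
#' @param d Diameters in um.
#' @return Nearest tabulated diameters (5.7-16 um).
#' @export
snap_to_mrg_diameter <- function(d) {
  tab <- mrg_parameter_table()$fiber_diameter_um
  tab[vapply(d, function(x) which.min(abs(tab - x)), integer(1))]
}

# Sample points uniformly in the endoneurium (inside the contour, clear of
# the perineurium ring) by rejection.
sample_in_endoneurium <- function(n, fascicle) {
  bb <- apply(fascicle$contour, 2, range)
  out <- matrix(numeric(0), ncol = 2)
  guard <- 0
  while (nrow(out) < n) {
    m <- max(4 * (n - nrow(out)), 16)
    px <- runif(m, bb[1, 1], bb[2, 1])
    py <- runif(m, bb[1, 2], bb[2, 2])
    ok <- points_in_polygon(px, py, fascicle$contour)
    if (any(ok)) {
      d <- distance_to_polygon(px[ok], py[ok], fascicle$contour)
      keep <- d > fascicle$perineurium_thickness
      out <- rbind(out, cbind(px[ok][keep], py[ok][keep]))
    }
    guard <- guard + 1
    if (guard > 2000)
      stop("could not sample fibers inside fascicle ", fascicle$id,
           call. = FALSE)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Assign clustered population regions to a fascicle
#'
#' Small fascicles carry one population covering the endoneurium; medium
#' and big fascicles are split into 3 or 5 disjoint Voronoi cells around
#' random interior anchor points, so each population occupies its own area
#' while its fibers stay grouped.
#'
#' @param fascicle A fascicle from a `nerve_cross_section`.
#' @param seed Integer seed; identical seeds give identical regions.
#' @return List with `n_populations` and `anchors` (k x 2 matrix, mm);
#'   population membership of a point is the nearest anchor.
#' @export
assign_populations <- function(fascicle, seed = 1L) {
  k <- switch(classify_fascicle_size(fascicle$equivalent_diameter),
              small = 1L, medium = 3L, big = 5L)
  anchors <- with_seed(derive_seed(seed, paste0("pop.", fascicle$id)),
                       sample_in_endoneurium(k, fascicle))
  list(n_populations = k, anchors = anchors)
}

#' Populate a cross-section with myelinated fibers
#'
#' Fiber counts per fascicle are Poisson with mean `density` times the
#' endoneurial area (minimum 1); positions are uniform in the endoneurium;
#' diameters are drawn from `mixture` and snapped to the tabulated MRG
#' values; node z-offsets are uniform on `[0, L)` with the internode length
#' `L = 100 * D`.
#'
#' @param cs A `nerve_cross_section`.
#' @param seed Integer seed.
#' @param density Fibers per mm^2 of endoneurial area (default 240).
#' @param mixture Diameter mixture, see [diameter_mixture_default()].
#' @return A `fiber_population` data frame: `fiber_id`, `fascicle_id`,
#'   `population_id`, `x`, `y` (mm), `diameter_um` (snapped),
#'   `diameter_raw_um`, `z_offset_mm`.
#' @export
populate_fibers <- function(cs, seed = 1L, density = FIBER_DENSITY_DEFAULT,
                            mixture = diameter_mixture_default()) {
  stopifnot(inherits(cs, "nerve_cross_section"))
  rows <- list()
  for (f in cs$fascicles) {
    pops <- assign_populations(f, seed)
    rows[[f$id]] <- with_seed(derive_seed(seed, paste0("fibers.", f$id)), {
      ring <- poly_perimeter(f$contour) * f$perineurium_thickness
      a_endo <- max(f$area - ring, 0.25 * f$area)
      n <- max(1L, rpois(1, density * a_endo))
      xy <- sample_in_endoneurium(n, f)
      d_raw <- sample_mixture(n, mixture)
      d <- snap_to_mrg_diameter(d_raw)
      L <- 100 * d * 1e-3  # mm
      pop <- if (pops$n_populations == 1) rep(1L, n) else {
        dm <- outer(xy[, 1], pops$anchors[, 1], `-`)^2 +
          outer(xy[, 2], pops$anchors[, 2], `-`)^2
        max.col(-dm)
      }
      data.frame(fascicle_id = f$id, population_id = as.integer(pop),
                 x = xy[, 1], y = xy[, 2],
                 diameter_um = d, diameter_raw_um = d_raw,
                 z_offset_mm = runif(n, 0, L))
    })
  }
  out <- do.call(rbind, rows)
  out <- cbind(fiber_id = seq_len(nrow(out)), out)
  class(out) <- c("fiber_population", "data.frame")
  attr(out, "density") <- density
  attr(out, "seed") <- seed
  out
}

#' @export
print.fiber_population <- function(x, ...) {
  cat(sprintf("fiber population: %d fibers in %d fascicles (seed %s)\n",
              nrow(x), length(unique(x$fascicle_id)),
              format(attr(x, "seed"))))
  cat(sprintf("  diameters %.1f-%.1f um; density %.0f /mm^2 endoneurium\n",
              min(x$diameter_um), max(x$diameter_um), attr(x, "density")))
  invisible(x)
}

#' Export a fiber table to CSV
#'
#' @param fibers A `fiber_population`.
#' @param file Output path.
#' @export
write_fibers <- function(fibers, file) {
  write.csv(as.data.frame(fibers), file, row.names = FALSE)
  invisible(file)
}
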