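# Lead fields: the extracellular potential produced by a unit (reference)
# current at one active site, solved on the conductivity map and queryable
# anywhere in the domain by trilinear interpolation. Laplace linearity makes
# every other amplitude, polarity and multi-site configuration a scaled
# superposition of lead fields.

REFERENCE_CURRENT <- c(TIME = 2e-6, FINE = 20e-6)  # A

# Grid cells receiving the active-site source current, on the correct side
# of the substrate crack.
source_cells <- function(map, as_row) {
  xs <- map$xs; ys <- map$ys; zc <- map$zc
  nx <- length(xs); ny <- length(ys)
  if (as_row$kind == "TIME") {
    i <- which.min(abs(xs - as_row$x))
    k <- which.min(abs(zc - as_row$z))
    jlow <- max(which(ys < as_row$y))
    j <- if (as_row$face > 0) jlow + 1L else jlow
    idx <- (i - 1L) + nx * ((j - 1L) + ny * (k - 1L))
    list(idx = idx, w = 1.0)
  } else {
    side <- as_row$side
    ii <- which(abs(xs - as_row$x) <= side / 2 + 1e-9)
    if (!length(ii)) ii <- which.min(abs(xs - as_row$x))
    kk <- which(abs(zc - as_row$z) <= side / 2 + 1e-9)
    if (!length(kk)) kk <- which.min(abs(zc - as_row$z))
    jlow <- max(which(ys < as_row$y))
    j <- if (as_row$face > 0) jlow else jlow + 1L  # inner side of the wall
    g <- expand.grid(i = ii, k = kk)
    idx <- (g$i - 1L) + nx * ((j - 1L) + ny * (g$k - 1L))
    list(idx = idx, w = rep(1 / nrow(g), nrow(g)))
  }
}

#' Solve the lead field of one active site
#'
#' Solves `div(sigma grad V) = 0` with the reference current (2 uA TIME,
#' 20 uA FINE) injected uniformly over the active-site surface and V = 0 on
#' the grounded outer cylinder, using a preconditioned conjugate-gradient
#' finite-volume scheme. Potentials at any other current follow by linear
#' scaling.
#'
#' @param map A `conductivity_map` with at least one placement.
#' @param as_id Active-site id (row of `map$as_table`).
#' @param I_ref Reference current in A (default by electrode kind).
#' @param tol Relative residual tolerance of the linear solve.
#' @param boundary_values Optional 3D array of Dirichlet values (V) on and
#'   outside the grounded boundary (defaults to 0 everywhere; used mainly
#'   for verification against closed-form solutions).
#' @return A `lead_field`: grid axes, potential array (V at `I_ref`),
#'   solver diagnostics and active-site metadata.
#' @export
solve_lead_field <- function(map, as_id, I_ref = NULL, tol = 1e-7,
                             boundary_values = NULL) {
  stopifnot(inherits(map, "conductivity_map"))
  if (is.null(map$as_table) || !as_id %in% map$as_table$as_id)
    stop("active site ", as_id, " not present in the conductivity map",
         call. = FALSE)
  row <- map$as_table[map$as_table$as_id == as_id, ]
  row$side <- if (row$kind == "FINE")
    map$placements[[row$placement]]$electrode$as_shape$side else NA
  if (is.null(I_ref)) I_ref <- REFERENCE_CURRENT[[row$kind]]
  src <- source_cells(map, row)
  nx <- length(map$xs); ny <- length(map$ys); nz <- length(map$zc)
  vb <- if (is.null(boundary_values)) numeric(nx * ny * nz)
        else as.vector(boundary_values)
  sol <- cpp_solve_leadfield(map$xs, map$ys, map$zedges, map$label2d,
                             map$tissue_sigma, map$peri_res, map$cracks,
                             map$mask, vb, as.integer(src$idx), src$w,
                             I_ref, tol, 20000L)
  if (sol$relres > tol)
    stop(sprintf("lead-field solve did not converge (relative residual %.2e)",
                 sol$relres), call. = FALSE)
  structure(list(xs = map$xs, ys = map$ys, zc = map$zc,
                 V = sol$V, I_ref = I_ref, as_id = as_id,
                 position = c(row$x, row$y, row$z), kind = row$kind,
                 face = row$face, placement = row$placement,
                 iterations = sol$iterations, relres = sol$relres,
                 signature = c(nx, ny, nz, map$radius)),
            class = "lead_field")
}

#' Solve lead fields for all active sites of a map
#'
#' @inheritParams solve_lead_field
#' @param as_ids Which active sites (default: all in the map).
#' @param progress Print one line per solved site.
#' @return Named list of `lead_field`s (names `as<id>`).
#' @export
solve_lead_fields <- function(map, as_ids = NULL, I_ref = NULL, tol = 1e-7,
                              progress = FALSE) {
  if (is.null(as_ids)) as_ids <- map$as_table$as_id
  out <- lapply(as_ids, function(a) {
    lf <- solve_lead_field(map, a, I_ref = I_ref, tol = tol)
    if (progress)
      message(sprintf("AS %d: %d CG iterations (relres %.1e)", a,
                      lf$iterations, lf$relres))
    lf
  })
  names(out) <- paste0("as", as_ids)
  out
}

#' Superpose lead fields with signed currents
#'
#' Pointwise weighted sum of lead fields from the same conductivity map;
#' polarity is the sign of the weight. Weights are actual currents in A.
#'
#' @param fields List of `lead_field`s.
#' @param weights Signed currents (A), one per field.
#' @return A `superposed_field` usable with [sample_potential()].
#' @export
superpose_fields <- function(fields, weights) {
  stopifnot(length(fields) == length(weights), length(fields) >= 1)
  sig <- fields[[1]]$signature
  for (f in fields)
    if (!identical(f$signature, sig))
      stop("lead fields come from different conductivity maps", call. = FALSE)
  structure(list(fields = fields, weights = weights),
            class = "superposed_field")
}

#' Sample a potential field at arbitrary points
#'
#' Trilinear interpolation of the discrete solution. For a `lead_field` the
#' potential is returned at current `current` (default its reference
#' current); for a `superposed_field` the weights already carry the
#' currents.
#'
#' @param field A `lead_field` or `superposed_field`.
#' @param points `n x 3` matrix (x, y, z) in mm.
#' @param current Current in A at which to evaluate a single lead field.
#' @return Potential in volts at each point.
#' @export
sample_potential <- function(field, points, current = NULL) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  if (inherits(field, "superposed_field")) {
    v <- 0
    for (i in seq_along(field$fields)) {
      f <- field$fields[[i]]
      v <- v + field$weights[i] / f$I_ref *
        cpp_trilinear(f$xs, f$ys, f$zc, f$V, points[, 1], points[, 2],
                      points[, 3])
    }
  } else {
    stopifnot(inherits(field, "lead_field"))
    if (is.null(current)) current <- field$I_ref
    v <- current / field$I_ref *
      cpp_trilinear(field$xs, field$ys, field$zc, field$V,
                    points[, 1], points[, 2], points[, 3])
  }
  if (anyNA(v)) {
    bad <- which(is.na(v))
    stop("node ", bad[1], " lies outside the solved domain (coordinates ",
         paste(signif(points[bad[1], ], 4), collapse = ", "), ")",
         call. = FALSE)
  }
  v
}

#' Save / load lead fields
#'
#' Lead-field caches are runtime artifacts stored in the package's native
#' serialized format together with their grid axes and metadata.
#'
#' @param fields List of `lead_field`s.
#' @param file Path.
#' @return `file` (write) or the list of fields (read).
#' @export
write_lead_fields <- function(fields, file) {
  saveRDS(fields, file)
  invisible(file)
}

#' @rdname write_lead_fields
#' @export
read_lead_fields <- function(file) readRDS(file)

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("lead field of AS %d (%s, I_ref = %.0f uA)\n",
              x$as_id, x$kind, x$I_ref * 1e6))
  cat(sprintf("  grid %d x %d x %d; CG %d iterations, relres %.1e\n",
              length(x$xs), length(x$ys), length(x$zc), x$iterations,
              x$relres))
  invisible(x)
}
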