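# Tissue conductivity map on a structured solver grid. The cross-section is
# extruded along z; tissue labels therefore live on the 2D in-plane grid.
# Thin layers (perineurium, polyimide substrate) are represented as face
# impedances rather than volumetric cells: the perineurium as a sheet
# resistance t/sigma on grid faces crossing a fascicle contour, the
# electrode substrate as insulating crack faces.

#' Tissue conductivities
#'
#' Conductivity tensors (S/m) used by the volume conductor: isotropic
#' epineurium 0.0826, anisotropic endoneurium (0.0826 transverse, 0.571
#' longitudinal), perineurium 0.00088, surrounding saline 2, polyimide
#' electrode substrate 6.67e-14.
#'
#' @return Named list of `c(transverse, longitudinal)` pairs.
#' @export
tissue_conductivities <- function() {
  list(saline = c(2, 2),
       epineurium = c(0.0826, 0.0826),
       endoneurium = c(0.0826, 0.571),
       perineurium = c(0.00088, 0.00088),
       substrate = c(6.67e-14, 6.67e-14))
}

solver_profiles <- function() {
  list(fine = list(h_xy = 0.10, h_z = 0.20, z_fine = 2.0, growth = 1.4, h_z_max = 2.0),
       coarse = list(h_xy = 0.25, h_z = 0.30, z_fine = 1.5, growth = 1.6, h_z_max = 3.0),
       test = list(h_xy = 0.45, h_z = 0.50, z_fine = 1.0, growth = 1.8, h_z_max = 4.0))
}

resolve_profile <- function(resolution) {
  if (is.list(resolution)) return(resolution)
  pr <- solver_profiles()
  if (!resolution %in% names(pr))
    stop("unknown solver resolution '", resolution, "'; use ",
         paste(names(pr), collapse = ", "), " or a parameter list",
         call. = FALSE)
  pr[[resolution]]
}

# Insulating crack rectangles (see solver.cpp) for a placement.
placement_cracks <- function(placement) {
  e <- placement$electrode
  ip <- placement$insertion_point
  if (e$kind == "TIME") {
    # shaft plane normal to y; width is the z extent
    matrix(c(1, ip[2], ip[1] - e$shaft_length / 2, ip[1] + e$shaft_length / 2,
             placement$z_center - e$shaft_width / 2,
             placement$z_center + e$shaft_width / 2),
           nrow = 1)
  } else {
    W <- e$shaft_length; H <- e$shaft_width
    wz <- e$as_shape$wall_z / 2
    zr <- c(placement$z_center - wz, placement$z_center + wz)
    rbind(
      c(1, ip[2] + H / 2, ip[1] - W / 2, ip[1] + W / 2, zr[1], zr[2]),
      c(1, ip[2] - H / 2, ip[1] - W / 2, ip[1] + W / 2, zr[1], zr[2]),
      c(0, ip[1] + W / 2, ip[2] - H / 2, ip[2] + H / 2, zr[1], zr[2]),
      c(0, ip[1] - W / 2, ip[2] - H / 2, ip[2] + H / 2, zr[1], zr[2]))
  }
}

#' Build a conductivity map for the volume-conductor solver
#'
#' Classifies the solver grid into saline, epineurium and per-fascicle
#' endoneurium, attaches perineurium sheet impedances to faces crossing
#' fascicle contours and insulating cracks where electrode substrates lie,
#' and grounds the outer cylinder (Dirichlet V = 0). The cylinder diameter
#' is `max(16 mm, nerve bounding box + 8 mm)`; its half-length is 15.4 mm.
#'
#' @param cs A `nerve_cross_section`.
#' @param placements List of `electrode_placement`s (may be empty).
#' @param resolution `"fine"`, `"coarse"`, `"test"`, or a list with
#'   `h_xy`, `h_z`, `z_fine`, `growth`, `h_z_max` (mm).
#' @return A `conductivity_map`.
#' @export
conductivity_map <- function(cs, placements = list(), resolution = "coarse") {
  stopifnot(inherits(cs, "nerve_cross_section"))
  if (inherits(placements, "electrode_placement")) placements <- list(placements)
  prof <- resolve_profile(resolution)
  ctr <- poly_centroid(cs$outline)
  rad <- sqrt((cs$outline[, 1] - ctr[1])^2 + (cs$outline[, 2] - ctr[2])^2)
  rmax <- max(rad)
  for (pl in placements) {
    e <- pl$electrode
    if (e$kind == "FINE")
      rmax <- max(rmax, sqrt((e$shaft_length / 2)^2 + (e$shaft_width / 2)^2))
    else
      rmax <- max(rmax, e$shaft_length / 2)
  }
  R <- max(8, rmax + 4)
  Lz <- 15.4
  h <- prof$h_xy
  # cell centers offset by h/2 so that symmetry planes (and the substrate
  # cracks of centered placements) fall on cell faces, not cell centers
  nh <- ceiling((R + 2 * h) / h)
  xs <- (seq(-nh, nh - 1) + 0.5) * h + ctr[1]
  ys <- (seq(-nh, nh - 1) + 0.5) * h + ctr[2]
  # graded axial edges, symmetric about z = 0
  e <- 0; hz <- prof$h_z; edges <- 0
  while (e < Lz + hz) {
    if (e >= prof$z_fine) hz <- min(hz * prof$growth, prof$h_z_max)
    e <- e + hz
    edges <- c(edges, e)
  }
  zedges <- c(-rev(edges[-1]), edges)
  zc <- (zedges[-1] + zedges[-length(zedges)]) / 2

  label2d <- cpp_label_grid(xs, ys, cs$outline,
                            lapply(cs$fascicles, `[[`, "contour"))
  # Inside a FINE aperture the nerve conforms to the flat frame (same
  # dimensions, no compression of the fascicles): the sliver between the
  # elliptical outline and the rectangular frame is connective tissue with
  # epineurial conductivity, not a saline shunt around the nerve.
  for (pl in placements) {
    if (pl$electrode$kind != "FINE") next
    e <- pl$electrode
    lab <- matrix(label2d, length(xs), length(ys))
    inside <- outer(abs(xs - pl$insertion_point[1]) < e$shaft_length / 2,
                    abs(ys - pl$insertion_point[2]) < e$shaft_width / 2, `&`)
    lab[inside & lab == 0L] <- 1L
    label2d <- as.integer(lab)
  }
  sig <- tissue_conductivities()
  nf <- length(cs$fascicles)
  tissue_sigma <- rbind(sig$saline, sig$epineurium,
                        matrix(rep(sig$endoneurium, nf), ncol = 2, byrow = TRUE))
  peri_res <- vapply(cs$fascicles, function(f)
    f$perineurium_thickness * 1e-3 / sig$perineurium[1], numeric(1))
  cracks <- if (length(placements))
    do.call(rbind, lapply(placements, placement_cracks))
  else matrix(0, 0, 6)
  # a crack plane falling exactly on a row of cell centers would cut no
  # face; nudge it by a negligible h/1000 onto one side
  if (nrow(cracks)) for (k in seq_len(nrow(cracks))) {
    cc <- if (cracks[k, 1] == 1) ys else xs
    if (min(abs(cracks[k, 2] - cc)) < 1e-9 * h)
      cracks[k, 2] <- cracks[k, 2] + 1e-3 * h
  }

  nx <- length(xs); ny <- length(ys); nz <- length(zc)
  r2 <- outer((xs - ctr[1])^2, (ys - ctr[2])^2, `+`)
  mask2 <- r2 < R^2
  mask <- array(mask2, c(nx, ny, nz))
  mask[, , abs(zc) >= Lz] <- FALSE

  as_table <- NULL
  for (pl in placements) {
    ap <- placement_as_positions(pl)
    as_table <- rbind(as_table,
                      data.frame(placement = pl$id,
                                 as_index = seq_len(nrow(ap)),
                                 x = ap[, 1], y = ap[, 2], z = ap[, 3],
                                 face = pl$electrode$as_face,
                                 kind = pl$electrode$kind))
  }
  if (!is.null(as_table))
    as_table$as_id <- seq_len(nrow(as_table))

  structure(list(cs = cs, placements = placements, profile = prof,
                 xs = xs, ys = ys, zedges = zedges, zc = zc,
                 center = ctr, radius = R, half_length = Lz,
                 label2d = label2d, tissue_sigma = tissue_sigma,
                 peri_res = peri_res, cracks = cracks,
                 mask = as.vector(mask), as_table = as_table),
            class = "conductivity_map")
}

#' Classify points by tissue
#'
#' @param map A `conductivity_map`.
#' @param points `n x 2` or `n x 3` matrix of x, y (and optionally z) coordinates in mm.
#' @return Character vector: saline, epineurium, perineurium, endoneurium or
#'   substrate. Points outside the solver cylinder are an error.
#' @export
classify_tissue <- function(map, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  x <- points[, 1]; y <- points[, 2]
  z <- if (ncol(points) >= 3) points[, 3] else rep(0, length(x))
  r <- sqrt((x - map$center[1])^2 + (y - map$center[2])^2)
  bad <- which(r >= map$radius | abs(z) >= map$half_length)
  if (length(bad))
    stop("point ", bad[1], " lies outside the solver domain (coordinates ",
         paste(signif(points[bad[1], ], 4), collapse = ", "), ")",
         call. = FALSE)
  out <- rep("saline", length(x))
  # electrode substrate slabs (thin: within thickness/2 of the crack plane)
  for (pl in map$placements) {
    e <- pl$electrode
    cr <- placement_cracks(pl)
    th <- e$shaft_thickness / 2
    for (k in seq_len(nrow(cr))) {
      d <- if (cr[k, 1] == 1) abs(y - cr[k, 2]) else abs(x - cr[k, 2])
      o <- if (cr[k, 1] == 1) x else y
      hit <- d <= th & o >= cr[k, 3] & o <= cr[k, 4] &
        z >= cr[k, 5] & z <= cr[k, 6]
      out[hit] <- "substrate"
    }
  }
  inside <- points_in_polygon(x, y, map$cs$outline)
  for (pl in map$placements) {
    if (pl$electrode$kind != "FINE") next
    e <- pl$electrode
    inside <- inside | (abs(x - pl$insertion_point[1]) < e$shaft_length / 2 &
                        abs(y - pl$insertion_point[2]) < e$shaft_width / 2 &
                        abs(z) <= e$as_shape$wall_z / 2)
  }
  out[inside & out != "substrate"] <- "epineurium"
  for (f in map$cs$fascicles) {
    inf <- points_in_polygon(x, y, f$contour) & out != "substrate"
    if (!any(inf)) next
    d <- distance_to_polygon(x[inf], y[inf], f$contour)
    out[inf] <- ifelse(d < f$perineurium_thickness, "perineurium",
                       "endoneurium")
  }
  out
}

#' @export
print.conductivity_map <- function(x, ...) {
  nz <- length(x$zc)
  cat(sprintf("conductivity map: %d x %d x %d grid (h = %.2f mm in-plane)\n",
              length(x$xs), length(x$ys), nz, x$profile$h_xy))
  cat(sprintf("  grounded cylinder: radius %.1f mm, half-length %.1f mm\n",
              x$radius, x$half_length))
  cat(sprintf("  %d fascicles, %d placements, %d active sites\n",
              length(x$cs$fascicles), length(x$placements),
              if (is.null(x$as_table)) 0L else nrow(x$as_table)))
  invisible(x)
}
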