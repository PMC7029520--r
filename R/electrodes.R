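# Parametric TIME and FINE electrode geometries and their placement in a
# nerve cross-section. Local electrode coordinates: x along the shaft/frame
# length, y across it, z longitudinal; the electrode center is the origin.

VALID_AS_COUNTS <- c(12L, 16L, 20L, 24L)
SUBSTRATE_SIGMA <- 6.67e-14  # polyimide, S/m

new_electrode <- function(kind, n_as, anatomy_label, dims, as_local, as_face,
                          as_shape) {
  structure(list(kind = kind, n_as = as.integer(n_as),
                 anatomy_label = anatomy_label,
                 shaft_length = dims[["length"]],
                 shaft_width = dims[["width"]],
                 shaft_thickness = dims[["thickness"]],
                 as_positions = as_local,  # n_as x 3, local mm
                 as_face = as_face,        # +1 / -1 (top/bottom face)
                 as_shape = as_shape,
                 substrate_conductivity = SUBSTRATE_SIGMA),
            class = "electrode_spec")
}

#' Build a TIME electrode
#'
#' Transversal intrafascicular multichannel electrode: a 20-um-thick
#' polyimide shaft with circular 60-um active sites (AS), half on each face,
#' evenly pitched along the shaft with the opposite face shifted by half the
#' inter-site pitch. Shaft length is 18 mm for the proximal and 10 mm for
#' the distal anatomy; shaft width grows linearly with the AS count from
#' 0.380 mm (12 AS) to 0.670 mm (24 AS).
#'
#' @param n_as Number of active sites: 12, 16, 20 or 24.
#' @param anatomy_label `"proximal"` or `"distal"`.
#' @return An `electrode_spec`.
#' @examples
#' e <- time_electrode(20, "proximal")
#' e$shaft_length  # 18
#' @export
time_electrode <- function(n_as, anatomy_label = c("proximal", "distal")) {
  anatomy_label <- match.arg(anatomy_label)
  if (!n_as %in% VALID_AS_COUNTS)
    stop("invalid active-site count ", n_as, "; valid counts are ",
         paste(VALID_AS_COUNTS, collapse = ", "), call. = FALSE)
  len <- if (anatomy_label == "proximal") 18 else 10
  width <- 0.380 + (n_as - 12) / 12 * (0.670 - 0.380)
  thick <- 0.020
  half <- n_as / 2
  pitch <- len / half
  x_top <- -len / 2 + (seq_len(half) - 0.75) * pitch
  x_bot <- x_top + pitch / 2
  as_local <- rbind(cbind(x_top, thick / 2, 0), cbind(x_bot, -thick / 2, 0))
  colnames(as_local) <- c("x", "y", "z")
  as_face <- c(rep(1L, half), rep(-1L, half))
  new_electrode("TIME", n_as, anatomy_label,
                c(length = len, width = width, thickness = thick),
                as_local, as_face,
                list(shape = "circle", diameter = 0.060))
}

#' Build a FINE electrode
#'
#' No-compression flat interface nerve electrode: a rectangular frame whose
#' inner opening matches the nerve (18.75 x 8.85 mm proximal, 10.9 x 7 mm
#' distal) with square 0.5 x 0.5 mm active sites evenly split between the
#' two long inner faces. The distal anatomy admits at most 20 AS.
#'
#' @inheritParams time_electrode
#' @return An `electrode_spec`.
#' @export
fine_electrode <- function(n_as, anatomy_label = c("proximal", "distal")) {
  anatomy_label <- match.arg(anatomy_label)
  if (!n_as %in% VALID_AS_COUNTS)
    stop("invalid active-site count ", n_as, "; valid counts are ",
         paste(VALID_AS_COUNTS, collapse = ", "), call. = FALSE)
  if (anatomy_label == "distal" && n_as == 24)
    stop("FINE-24 does not fit the distal anatomy ",
         "(0.5 mm sites exceed the 10.9 mm frame); use 12, 16 or 20",
         call. = FALSE)
  dims <- if (anatomy_label == "proximal") c(18.75, 8.85) else c(10.9, 7.0)
  half <- n_as / 2
  pitch <- dims[1] / half
  xs <- -dims[1] / 2 + (seq_len(half) - 0.5) * pitch
  as_local <- rbind(cbind(xs, dims[2] / 2, 0), cbind(xs, -dims[2] / 2, 0))
  colnames(as_local) <- c("x", "y", "z")
  as_face <- c(rep(1L, half), rep(-1L, half))
  # the frame extends 10 mm axially, the scale of implanted cuffs; an
  # axially short frame would let the stimulating current escape around
  # the walls instead of crossing the nerve
  new_electrode("FINE", n_as, anatomy_label,
                c(length = dims[1], width = dims[2], thickness = 0.1),
                as_local, as_face,
                list(shape = "square", side = 0.5, wall_z = 10.0))
}

#' @export
print.electrode_spec <- function(x, ...) {
  cat(sprintf("%s electrode, %d active sites (%s anatomy)\n",
              x$kind, x$n_as, x$anatomy_label))
  if (x$kind == "TIME")
    cat(sprintf("  shaft %.1f x %.3f x %.3f mm, circular AS d = %.0f um\n",
                x$shaft_length, x$shaft_width, x$shaft_thickness,
                x$as_shape$diameter * 1e3))
  else
    cat(sprintf("  frame %.2f x %.2f mm, square AS %.1f x %.1f mm\n",
                x$shaft_length, x$shaft_width, x$as_shape$side, x$as_shape$side))
  invisible(x)
}

new_placement <- function(electrode, insertion_point, orientation, z_center,
                          id) {
  structure(list(electrode = electrode,
                 insertion_point = insertion_point,
                 orientation = orientation,
                 z_center = z_center,
                 id = as.integer(id)),
            class = "electrode_placement")
}

#' Global active-site positions of a placement
#'
#' @param placement An `electrode_placement`.
#' @return `n_as x 3` matrix of active-site centers (x, y, z) in mm.
#' @export
placement_as_positions <- function(placement) {
  e <- placement$electrode
  p <- e$as_positions
  cbind(p[, 1] + placement$insertion_point[1],
        p[, 2] + placement$insertion_point[2],
        p[, 3] + placement$z_center)
}

# Fraction of the shaft chord (local x axis at the insertion y) inside the
# nerve outline, sampled along the shaft.
shaft_inside_fraction <- function(cs, placement) {
  e <- placement$electrode
  xs <- seq(-e$shaft_length / 2, e$shaft_length / 2, length.out = 101) +
    placement$insertion_point[1]
  mean(points_in_polygon(xs, rep(placement$insertion_point[2], 101), cs$outline))
}

#' Place one or more electrode implants in a cross-section
#'
#' TIME shafts are inserted transversally, parallel to the nerve's major
#' axis, through insertion points spread across the minor axis: a single
#' implant crosses the centroid, multiple implants sit at evenly spaced
#' quantiles of the minor-axis extent (1/3 and 2/3 for two implants,
#' quartiles for three, fifths for four). FINE frames circumscribe the nerve
#' (expanded to the nerve's bounding box when the nominal inner opening is
#' smaller). Placement is deterministic given the seed.
#'
#' @param cs A `nerve_cross_section`.
#' @param electrode An `electrode_spec`.
#' @param n_implants 1 to 4; values above 1 are TIME-only.
#' @param strategy `"evenly-spaced"` or `"centered"` (single implant at the
#'   nerve centroid).
#' @param seed Integer seed (reserved for randomized strategies; the
#'   deterministic strategies ignore it beyond reproducibility bookkeeping).
#' @return List of `electrode_placement`s.
#' @export
place_implants <- function(cs, electrode, n_implants = 1,
                           strategy = c("evenly-spaced", "centered"),
                           seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(cs, "nerve_cross_section"),
            inherits(electrode, "electrode_spec"))
  if (n_implants < 1 || n_implants > 4)
    stop("n_implants must be between 1 and 4", call. = FALSE)
  if (electrode$kind != "TIME" && n_implants > 1)
    stop("multi-implant placement is TIME-only", call. = FALSE)
  ctr <- poly_centroid(cs$outline)
  if (electrode$kind == "FINE") {
    bb <- apply(cs$outline, 2, range)
    need <- c(diff(bb[, 1]), diff(bb[, 2])) + 0.05
    e <- electrode
    if (e$shaft_length < need[1] || e$shaft_width < need[2]) {
      e$shaft_length <- max(e$shaft_length, need[1])
      e$shaft_width <- max(e$shaft_width, need[2])
      half <- e$n_as / 2
      pitch <- e$shaft_length / half
      xs <- -e$shaft_length / 2 + (seq_len(half) - 0.5) * pitch
      e$as_positions <- rbind(cbind(xs, e$shaft_width / 2, 0),
                              cbind(xs, -e$shaft_width / 2, 0))
      colnames(e$as_positions) <- c("x", "y", "z")
    }
    return(list(new_placement(e, c(mean(bb[, 1]), mean(bb[, 2])), 0, 0, 1L)))
  }
  ys <- range(cs$outline[, 2])
  q <- switch(as.character(n_implants),
              "1" = if (strategy == "centered") 0.5 else 0.5,
              "2" = c(1, 2) / 3, "3" = c(1, 2, 3) / 4, "4" = c(1:4) / 5)
  ypos <- ys[1] + q * diff(ys)
  if (n_implants == 1 && strategy == "centered") ypos <- ctr[2]
  placements <- lapply(seq_len(n_implants), function(i) {
    new_placement(electrode, c(ctr[1], ypos[i]), 0, 0, i)
  })
  for (pl in placements) {
    fr <- shaft_inside_fraction(cs, pl)
    if (fr < 0.6)
      stop(sprintf(paste0("TIME shaft %d at y = %.2f mm lies mostly outside ",
                          "the nerve (%.0f%% inside)"),
                   pl$id, pl$insertion_point[2], 100 * fr), call. = FALSE)
  }
  placements
}
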