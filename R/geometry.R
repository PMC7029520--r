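# Nerve cross-section geometry: synthetic multi-fascicular anatomies,
# contour-file input/output and validation. All coordinates in mm; x is the
# medio-lateral (major) axis, z the longitudinal axis of the extruded nerve.

# Published geometric statistics of the two reference anatomies.
anatomy_params <- function(anatomy_label) {
  switch(anatomy_label,
    proximal = list(
      semi_axes = c(9.35, 4.40),     # 18.7 x 8.8 mm envelope
      n_fascicles = 37L,
      n_by_class = c(small = 6L, medium = 12L, big = 19L),
      fascicular_fill = 0.44),
    distal = list(
      semi_axes = c(5.75, 3.20),     # 11.5 x 6.4 mm envelope, 58.2 mm^2
      n_fascicles = 31L,
      n_by_class = c(small = 6L, medium = 11L, big = 14L),
      fascicular_fill = 0.44),
    stop("unknown anatomy_label '", anatomy_label,
         "'; valid labels are 'proximal' and 'distal'", call. = FALSE)
  )
}

#' Fascicle size class
#'
#' Classifies a fascicle by its equivalent diameter: small (< 0.4 mm),
#' medium (0.4-0.8 mm) or big (> 0.8 mm). The class determines how many
#' fiber populations the fascicle receives.
#'
#' @param x Either a fascicle (as found in a `nerve_cross_section`'s
#'   `fascicles` list) or a numeric equivalent diameter in mm.
#' @return Character vector: `"small"`, `"medium"` or `"big"`.
#' @examples
#' classify_fascicle_size(0.3)  # "small"
#' classify_fascicle_size(0.6)  # "medium"
#' classify_fascicle_size(0.9)  # "big"
#' @export
classify_fascicle_size <- function(x) {
  d <- if (is.list(x)) x$equivalent_diameter else x
  stopifnot(is.numeric(d), all(d > 0))
  ifelse(d < 0.4, "small", ifelse(d <= 0.8, "medium", "big"))
}

new_fascicle <- function(id, contour) {
  area <- poly_area(contour)
  d <- 2 * sqrt(area / pi)
  list(id = as.integer(id),
       contour = contour,
       centroid = poly_centroid(contour),
       area = area,
       equivalent_diameter = d,
       perineurium_thickness = 0.03 * d)
}

new_cross_section <- function(outline, fascicles, anatomy_label,
                              extrusion_length = 2 * 15.4) {
  structure(list(outline = outline,
                 fascicles = fascicles,
                 anatomy_label = anatomy_label,
                 extrusion_length = extrusion_length),
            class = "nerve_cross_section")
}

# Draw per-class equivalent diameters whose total area matches the target
# fascicular area; big-class diameters are capped at 2 mm.
draw_diameters <- function(n_by_class, target_area) {
  d_small <- runif(n_by_class[["small"]], 0.18, 0.38)
  d_medium <- runif(n_by_class[["medium"]], 0.42, 0.78)
  area_sm <- sum(pi * d_small^2 / 4) + sum(pi * d_medium^2 / 4)
  n_big <- n_by_class[["big"]]
  w <- exp(rnorm(n_big, 0, 0.35))
  a_big <- pmax(target_area - area_sm, n_big * pi * 0.82^2 / 4) * w / sum(w)
  d_big <- pmin(2.0, pmax(0.82, sqrt(4 * a_big / pi)))
  c(d_small, d_medium, d_big)
}

#' Synthesize a multi-fascicular nerve cross-section
#'
#' Generates an anatomically plausible sciatic-nerve cross-section matching
#' the published statistics of the two reference levels: the proximal
#' anatomy (18.7 x 8.8 mm elliptical envelope, 37 fascicles) and the distal
#' anatomy (11.5 x 6.4 mm, about 58.2 mm^2, 31 fascicles). Fascicles are
#' elliptical contours spanning the small/medium/big size classes, packed by
#' seeded rejection sampling with a minimum 50 um inter-fascicle gap, and
#' each carries a perineurium 3% of its equivalent diameter thick.
#'
#' @param anatomy_label `"proximal"` or `"distal"`.
#' @param seed Non-negative integer; identical seeds give bitwise-identical
#'   geometry.
#' @return A `nerve_cross_section` object: `outline` (closed polygon, mm),
#'   `fascicles` (list with `id`, `contour`, `centroid`, `area`,
#'   `equivalent_diameter`, `perineurium_thickness`), `anatomy_label`,
#'   `extrusion_length` (mm).
#' @examples
#' cs <- synthesize_cross_section("distal", seed = 1)
#' length(cs$fascicles)  # 31
#' @export
synthesize_cross_section <- function(anatomy_label, seed = 1L) {
  p <- anatomy_params(anatomy_label)
  stopifnot(length(seed) == 1, seed >= 0, seed == floor(seed))
  a <- p$semi_axes[1]; b <- p$semi_axes[2]
  target_area <- p$fascicular_fill * pi * a * b
  with_seed(derive_seed(seed, paste0("anatomy.", anatomy_label)), {
    d <- draw_diameters(p$n_by_class, target_area)
    ord <- order(d, decreasing = TRUE)
    d <- d[ord]
    polys <- vector("list", length(d))
    placed_max_r <- numeric(0)
    centers <- matrix(numeric(0), ncol = 2)
    gap <- 0.05
    for (i in seq_along(d)) {
      di <- d[i]
      shrink <- 0
      repeat {
        aspect <- runif(1, 0.78, 1.0)
        ang <- runif(1, 0, pi)
        ra <- di / 2 / sqrt(aspect); rb <- di / 2 * sqrt(aspect)
        margin <- 0.03 * di + 0.1
        ok <- FALSE
        for (att in seq_len(600)) {
          cx <- runif(1, -a, a); cy <- runif(1, -b, b)
          # candidate bounding-circle inside the (margin-shrunk) envelope
          rmax <- max(ra, rb) * 1.01
          if ((cx / (a - margin - rmax))^2 + (cy / (b - margin - rmax))^2 > 1)
            next
          if (nrow(centers) > 0) {
            dc <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
            if (any(dc < placed_max_r + rmax + gap)) {
              # conservative bound failed; exact test only when plausible
              close_ok <- TRUE
              for (j in which(dc < placed_max_r + rmax + gap)) {
                cand <- ellipse_polygon(c(cx, cy), ra, rb, ang)
                if (poly_min_distance(cand, polys[[j]]) < gap ||
                    cpp_polys_edges_intersect(cand, polys[[j]]) ||
                    points_in_polygon(cx, cy, polys[[j]])) {
                  close_ok <- FALSE; break
                }
              }
              if (!close_ok) next
            }
          }
          polys[[i]] <- ellipse_polygon(c(cx, cy), ra, rb, ang)
          centers <- rbind(centers, c(cx, cy))
          placed_max_r <- c(placed_max_r, rmax)
          ok <- TRUE
          break
        }
        if (ok) break
        shrink <- shrink + 1
        if (shrink > 30)
          stop("failed to pack fascicles for anatomy '", anatomy_label, "'")
        di <- di * 0.94
        ra <- ra * 0.94; rb <- rb * 0.94
      }
    }
    outline <- ellipse_polygon(c(0, 0), a, b, 0, n = 128, exact_vertices = TRUE)
    fascicles <- lapply(seq_along(polys), function(i) new_fascicle(i, polys[[i]]))
    cs <- new_cross_section(outline, fascicles, anatomy_label)
    validate_cross_section(cs)
    cs
  })
}

#' Validate a nerve cross-section
#'
#' Checks that the outline and all fascicle contours are simple polygons
#' with positive area, that every fascicle lies strictly inside the nerve
#' outline, that fascicles are pairwise disjoint, and that each perineurium
#' thickness equals 3% of the fascicle's equivalent diameter.
#'
#' @param cs A `nerve_cross_section`.
#' @return `cs`, invisibly; errors name the offending fascicle id.
#' @export
validate_cross_section <- function(cs) {
  stopifnot(inherits(cs, "nerve_cross_section"))
  if (cpp_poly_self_intersects(cs$outline))
    stop("nerve outline is self-intersecting", call. = FALSE)
  if (poly_area(cs$outline) <= 0) stop("nerve outline has zero area", call. = FALSE)
  for (f in cs$fascicles) {
    if (cpp_poly_self_intersects(f$contour))
      stop("fascicle ", f$id, " contour is self-intersecting", call. = FALSE)
    if (f$area <= 0) stop("fascicle ", f$id, " has non-positive area", call. = FALSE)
    if (abs(f$perineurium_thickness - 0.03 * f$equivalent_diameter) >
        1e-9 * f$equivalent_diameter)
      stop("fascicle ", f$id, " perineurium thickness is not 3% of diameter",
           call. = FALSE)
    inside <- points_in_polygon(f$contour[, 1], f$contour[, 2], cs$outline)
    if (!all(inside) || cpp_polys_edges_intersect(f$contour, cs$outline))
      stop("fascicle ", f$id, " crosses or lies outside the nerve outline",
           call. = FALSE)
  }
  n <- length(cs$fascicles)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      fi <- cs$fascicles[[i]]; fj <- cs$fascicles[[j]]
      if (cpp_polys_edges_intersect(fi$contour, fj$contour) ||
          points_in_polygon(fi$centroid[1], fi$centroid[2], fj$contour) ||
          points_in_polygon(fj$centroid[1], fj$centroid[2], fi$contour))
        stop("fascicles ", fi$id, " and ", fj$id, " overlap", call. = FALSE)
    }
  }
  tot <- sum(vapply(cs$fascicles, `[[`, numeric(1), "area"))
  if (tot >= poly_area(cs$outline))
    stop("total fascicular area exceeds the nerve outline area", call. = FALSE)
  invisible(cs)
}

#' Write a cross-section to a plain-text contour file
#'
#' One polygon per block: a header line `NERVE` or `FASCICLE <id>` (0-based
#' ids) followed by `x y` vertex pairs in mm.
#'
#' @param cs A `nerve_cross_section`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_cross_section <- function(cs, file) {
  con <- file(file, "w")
  on.exit(close(con))
  emit <- function(header, poly) {
    writeLines(header, con)
    writeLines(sprintf("%.9f %.9f", poly[, 1], poly[, 2]), con)
    writeLines("", con)
  }
  emit("NERVE", cs$outline)
  for (f in cs$fascicles) emit(paste("FASCICLE", f$id - 1L), f$contour)
  invisible(file)
}

#' Read a cross-section from a plain-text contour file
#'
#' @param file Path to a contour file in the dialect written by
#'   [write_cross_section()].
#' @param anatomy_label Label recorded on the result (default `"custom"`).
#' @return A validated `nerve_cross_section`.
#' @export
read_cross_section <- function(file, anatomy_label = "custom") {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  heads <- grepl("^(NERVE|FASCICLE)", lines)
  if (!any(heads)) stop("no polygon headers found in ", file, call. = FALSE)
  idx <- which(heads)
  blocks <- Map(function(from, to) lines[seq.int(from, to)],
                idx, c(idx[-1] - 1L, length(lines)))
  outline <- NULL
  fasc <- list()
  for (bl in blocks) {
    head <- bl[1]
    verts <- do.call(rbind, lapply(strsplit(bl[-1], "\\s+"), as.numeric))
    if (is.null(verts) || nrow(verts) < 3 || ncol(verts) != 2 ||
        anyNA(verts))
      stop("malformed polygon block '", head, "' in ", file, call. = FALSE)
    if (head == "NERVE") {
      outline <- verts
    } else {
      id0 <- suppressWarnings(as.integer(sub("^FASCICLE\\s+", "", head)))
      if (is.na(id0)) stop("malformed header '", head, "'", call. = FALSE)
      fasc[[length(fasc) + 1L]] <- new_fascicle(id0 + 1L, verts)
    }
  }
  if (is.null(outline)) stop("contour file has no NERVE block", call. = FALSE)
  if (length(fasc) == 0) stop("contour file has no FASCICLE blocks", call. = FALSE)
  cs <- new_cross_section(outline, fasc, anatomy_label)
  validate_cross_section(cs)
  cs
}

#' Total fascicular and endoneurial area
#'
#' Endoneurial area discounts the perineurium as a thin ring of width
#' `0.03 * equivalent_diameter` along each fascicle contour.
#'
#' @param cs A `nerve_cross_section`.
#' @return List with `fascicular_mm2` and `endoneurial_mm2`.
#' @export
fascicular_area <- function(cs) {
  areas <- vapply(cs$fascicles, `[[`, numeric(1), "area")
  ring <- vapply(cs$fascicles, function(f)
    poly_perimeter(f$contour) * f$perineurium_thickness, numeric(1))
  list(fascicular_mm2 = sum(areas),
       endoneurial_mm2 = sum(pmax(areas - ring, 0)))
}

#' @export
print.nerve_cross_section <- function(x, ...) {
  ar <- fascicular_area(x)
  d <- vapply(x$fascicles, `[[`, numeric(1), "equivalent_diameter")
  cls <- table(factor(classify_fascicle_size(d),
                      levels = c("small", "medium", "big")))
  cat("Nerve cross-section (", x$anatomy_label, ")\n", sep = "")
  cat(sprintf("  envelope area: %.1f mm^2, %d fascicles (%.1f mm^2 fascicular)\n",
              poly_area(x$outline), length(x$fascicles), ar$fascicular_mm2))
  cat(sprintf("  size classes: %d small / %d medium / %d big; d = %.2f-%.2f mm\n",
              cls[1], cls[2], cls[3], min(d), max(d)))
  cat(sprintf("  extrusion length: %.1f mm\n", x$extrusion_length))
  invisible(x)
}

#' Plot a nerve cross-section
#'
#' @param x A `nerve_cross_section`.
#' @param placements Optional list of electrode placements to overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nerve_cross_section <- function(x, placements = NULL, ...) {
  graphics::plot(x$outline[, 1], x$outline[, 2], type = "n", asp = 1,
                 xlab = "x [mm]", ylab = "y [mm]",
                 main = paste0("nerve cross-section (", x$anatomy_label, ")"),
                 ...)
  graphics::polygon(x$outline, border = "grey30", lwd = 2)
  for (f in x$fascicles)
    graphics::polygon(f$contour, col = "lightsteelblue", border = "steelblue")
  if (!is.null(placements)) {
    for (pl in placements) {
      ap <- placement_as_positions(pl)
      graphics::points(ap[, 1], ap[, 2], pch = 16, col = "firebrick", cex = 0.6)
    }
  }
  invisible(x)
}
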