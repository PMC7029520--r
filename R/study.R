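# High-level study drivers: solve-and-score pipelines over replicate fiber
# populations, multi-implant comparisons and policy comparisons. Lead
# fields depend only on geometry (not on fiber seeds), so they are solved
# once per placement and shared; an optional cache environment reuses them
# across studies of the same anatomy.

placement_cache_key <- function(cs, placement, resolution) {
  e <- placement$electrode
  prof <- resolve_profile(resolution)
  paste(cs$anatomy_label, e$kind, e$n_as,
        paste(signif(unlist(prof), 6), collapse = ","),
        paste(signif(c(placement$insertion_point, placement$z_center,
                       e$shaft_length, e$shaft_width), 8), collapse = ","),
        sep = "|")
}

#' Solve the lead fields of a placement (with caching)
#'
#' Builds a conductivity map containing this placement alone and solves one
#' lead field per active site. The 20-um substrate of a parallel implant a
#' few millimetres away has a negligible far-field effect, so per-placement
#' maps keep multi-implant lead fields reusable across implant counts.
#'
#' @param cs A `nerve_cross_section`.
#' @param placement An `electrode_placement`.
#' @param resolution Solver resolution (see [conductivity_map()]).
#' @param cache Optional environment for cross-study reuse.
#' @param tol Linear-solver tolerance.
#' @return Named list of `lead_field`s (`p<placement>.as<k>`).
#' @export
solve_placement_fields <- function(cs, placement, resolution = "coarse",
                                   cache = NULL, tol = 1e-7) {
  key <- placement_cache_key(cs, placement, resolution)
  if (!is.null(cache) && !is.null(cache[[key]])) {
    lfs <- cache[[key]]
  } else {
    map <- conductivity_map(cs, list(placement), resolution)
    lfs <- solve_lead_fields(map, tol = tol)
    if (!is.null(cache)) cache[[key]] <- lfs
  }
  for (i in seq_along(lfs)) lfs[[i]]$placement <- placement$id
  names(lfs) <- paste0("p", placement$id, ".as", seq_along(lfs))
  lfs
}

#' Run a selectivity study
#'
#' End-to-end pipeline: synthesize (or accept) a cross-section, place the
#' electrode(s), solve all lead fields, populate fibers for each replicate
#' seed, run the charge sweep and score the electrode. Scores are averaged
#' over the replicate fiber populations.
#'
#' @param anatomy `"proximal"` or `"distal"` (ignored when `cs` is given).
#' @param electrode_kind `"TIME"` or `"FINE"`.
#' @param n_as Active-site count (12, 16, 20, 24).
#' @param n_implants Number of parallel implants (TIME only above 1).
#' @param policy `"monopolar"`, `"bipolar"` or `"combined"`.
#' @param fiber_seeds Integer vector of replicate fiber-population seeds.
#' @param density Fibers per mm^2 of endoneurial area.
#' @param resolution Solver resolution profile.
#' @param anatomy_seed Seed of the synthetic anatomy.
#' @param sweep A [stimulus_sweep()].
#' @param nodes_only See [evaluate_policy()].
#' @param cache Optional environment to reuse lead fields across studies.
#' @param cs Optional pre-built `nerve_cross_section`.
#' @param progress Emit progress messages.
#' @return A `selectivity_summary`.
#' @export
selectivity_study <- function(anatomy = c("proximal", "distal"),
                              electrode_kind = c("TIME", "FINE"),
                              n_as = 20, n_implants = 1,
                              policy = "monopolar", fiber_seeds = 1:3,
                              density = FIBER_DENSITY_DEFAULT,
                              resolution = "coarse", anatomy_seed = 1,
                              sweep = stimulus_sweep(), nodes_only = FALSE,
                              cache = NULL, cs = NULL, progress = FALSE) {
  electrode_kind <- match.arg(electrode_kind)
  if (is.null(cs)) {
    anatomy <- match.arg(anatomy)
    cs <- synthesize_cross_section(anatomy, anatomy_seed)
  }
  electrode <- if (electrode_kind == "TIME")
    time_electrode(n_as, cs$anatomy_label)
  else fine_electrode(n_as, cs$anatomy_label)
  placements <- place_implants(cs, electrode, n_implants)
  lead_fields <- list()
  for (pl in placements) {
    if (progress) message("solving lead fields of implant ", pl$id)
    lead_fields <- c(lead_fields,
                     solve_placement_fields(cs, pl, resolution, cache))
  }
  reports <- lapply(fiber_seeds, function(s) {
    if (progress) message("evaluating fiber seed ", s)
    fibers <- populate_fibers(cs, s, density)
    evaluate_policy(cs, lead_fields, fibers, policy, sweep)
  })
  scores <- vapply(reports, `[[`, numeric(1), "score")
  mono <- vapply(reports, `[[`, numeric(1), "mono_score")
  rel <- vapply(reports, `[[`, numeric(1), "improvement_relative")
  thr <- unlist(lapply(reports, function(r) r$as_thresholds$threshold_nC))
  structure(list(anatomy_label = cs$anatomy_label,
                 electrode_kind = electrode_kind, n_as = n_as,
                 n_implants = n_implants, policy = policy,
                 fiber_seeds = fiber_seeds, density = density,
                 m = length(cs$fascicles),
                 scores = scores,
                 score_mean = mean(scores), score_sd = sd(scores),
                 mono_scores = mono,
                 improvement_mean = mean(scores - mono),
                 improvement_sd = sd(scores - mono),
                 improvement_relative_mean = mean(rel),
                 threshold_nC_mean = mean(thr, na.rm = TRUE),
                 threshold_nC_sd = sd(thr, na.rm = TRUE),
                 reports = reports),
            class = "selectivity_summary")
}

#' @export
print.selectivity_summary <- function(x, ...) {
  cat(sprintf("%s-%d, %s anatomy, %d implant(s), %s policy\n",
              x$electrode_kind, x$n_as, x$anatomy_label, x$n_implants,
              x$policy))
  cat(sprintf("  score: %.1f +/- %.1f %% of %d fascicles (%d seeds)\n",
              x$score_mean, ifelse(is.na(x$score_sd), 0, x$score_sd),
              x$m, length(x$fiber_seeds)))
  if (x$policy != "monopolar")
    cat(sprintf("  bipolar improvement: %+.1f +/- %.1f points (%+.1f%% of the count)\n",
                x$improvement_mean,
                ifelse(is.na(x$improvement_sd), 0, x$improvement_sd),
                x$improvement_relative_mean))
  if (!is.nan(x$threshold_nC_mean))
    cat(sprintf("  10%%-recruitment threshold: %.2f +/- %.2f nC\n",
                x$threshold_nC_mean, x$threshold_nC_sd))
  invisible(x)
}

#' Compare implant counts
#'
#' Evaluates 1..n parallel TIME implants (union of selectively recruited
#' fascicles over all implants' sites) on the same anatomy and seeds.
#'
#' @inheritParams selectivity_study
#' @param n_implants Integer vector of implant counts to compare.
#' @return A `multi_implant_comparison`: per-count summaries and a tidy
#'   `table` with mean and SD scores.
#' @export
evaluate_multi_implant <- function(anatomy = "proximal", n_as = 20,
                                   n_implants = 1:4, fiber_seeds = 1:3,
                                   density = FIBER_DENSITY_DEFAULT,
                                   resolution = "coarse", anatomy_seed = 1,
                                   sweep = stimulus_sweep(), cache = NULL,
                                   cs = NULL, progress = FALSE) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  summaries <- lapply(n_implants, function(n) {
    selectivity_study(anatomy, "TIME", n_as, n_implants = n,
                      policy = "monopolar", fiber_seeds = fiber_seeds,
                      density = density, resolution = resolution,
                      anatomy_seed = anatomy_seed, sweep = sweep,
                      cache = cache, cs = cs, progress = progress)
  })
  tab <- data.frame(n_implants = n_implants,
                    score_mean = vapply(summaries, `[[`, numeric(1), "score_mean"),
                    score_sd = vapply(summaries, `[[`, numeric(1), "score_sd"))
  structure(list(table = tab, summaries = summaries),
            class = "multi_implant_comparison")
}

#' @export
print.multi_implant_comparison <- function(x, ...) {
  cat("multi-implant comparison (TIME):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Compare monopolar and bipolar reports
#'
#' @param report_mono,report_bi `selectivity_report`s evaluated on the same
#'   anatomy and fiber seed (the bipolar report's configurations must be a
#'   superset of the monopolar's).
#' @return List: `improvement_points`, `new_fascicles` (selective under the
#'   bipolar policy only).
#' @export
compare_policies <- function(report_mono, report_bi) {
  stopifnot(inherits(report_mono, "selectivity_report"),
            inherits(report_bi, "selectivity_report"))
  if (!identical(report_mono$anatomy_label, report_bi$anatomy_label) ||
      !identical(report_mono$fiber_seed, report_bi$fiber_seed))
    stop("reports were computed on different geometry or fiber seeds",
         call. = FALSE)
  list(improvement_points = report_bi$score - report_mono$score,
       new_fascicles = setdiff(report_bi$selective_union,
                               report_mono$selective_union))
}

#' Bar plot of electrode scores
#'
#' @param x A `selectivity_summary` or list of them.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.selectivity_summary <- function(x, ...) {
  xs <- if (inherits(x, "selectivity_summary")) list(x) else x
  h <- vapply(xs, `[[`, numeric(1), "score_mean")
  s <- vapply(xs, `[[`, numeric(1), "score_sd")
  lab <- vapply(xs, function(z)
    sprintf("%s-%d", z$electrode_kind, z$n_as), character(1))
  bp <- graphics::barplot(h, names.arg = lab,
                          ylab = "fascicles selectively recruited [%]",
                          ylim = c(0, max(h + ifelse(is.na(s), 0, s)) * 1.2),
                          ...)
  graphics::arrows(bp, h - s, bp, h + s, angle = 90, code = 3, length = 0.05)
  invisible(x)
}
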