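# Recruitment curves, selectivity indexes and electrode scoring.
#
# A stimulation configuration is a set of active sites with signed currents
# of equal magnitude (one cathodic site for monopolar stimulation, a signed
# pair for bipolar). For each configuration the threshold charge of every
# retained fiber is found on the 60-point sweep; cumulative per-fascicle
# recruitment curves then yield the spatial (Sel_i) and functional
# (Sel_s_i) selectivity indexes, the selective-fascicle criterion
# (Sel_i > 0.6 and Sel_s_i > 0.9 with at least one recruited fiber, at any
# sweep amplitude), and the electrode score (percentage of fascicles
# selectively recruited by at least one configuration).

#' Spatial selectivity index
#'
#' `Sel_i = mu_i - mean of the other fascicles' recruitment fractions`,
#' where `mu_i` is the recruited fraction of fascicle `i`.
#'
#' @param mu Recruitment fractions over the m fascicles (values in 0..1).
#' @param i Target fascicle index.
#' @return `Sel_i` in `[-1, 1]`.
#' @examples
#' spatial_selectivity(c(0.8, 0.1, 0.1), 1)  # 0.7
#' @export
spatial_selectivity <- function(mu, i) {
  m <- length(mu)
  if (m < 2)
    stop("spatial selectivity requires at least 2 fascicles", call. = FALSE)
  stopifnot(i >= 1, i <= m, all(mu >= 0), all(mu <= 1))
  mu[i] - sum(mu[-i]) / (m - 1)
}

#' Functional (sensory) selectivity index
#'
#' `Sel_s_i = n_i / sum(n_j)`: the fraction of all recruited fibers that
#' belong to the target fascicle.
#'
#' @param n Recruited fiber counts over the m fascicles.
#' @param i Target fascicle index.
#' @return `Sel_s_i` in `[0, 1]`.
#' @export
functional_selectivity <- function(n, i) {
  stopifnot(all(n >= 0))
  tot <- sum(n)
  if (tot == 0)
    stop("functional selectivity is undefined with zero recruited fibers",
         call. = FALSE)
  n[i] / tot
}

#' Effective stimulation range
#'
#' Radial distance from an active site beyond which fibers are excluded
#' from simulation: 2 mm for TIME (both anatomies), 4 mm for the proximal
#' and 3 mm for the distal FINE. Custom anatomies default to no filtering.
#'
#' @param kind `"TIME"` or `"FINE"`.
#' @param anatomy_label `"proximal"`, `"distal"` or `"custom"`.
#' @return Range in mm (possibly `Inf`).
#' @export
effective_range <- function(kind, anatomy_label) {
  if (kind == "TIME") return(2.0)
  switch(anatomy_label, proximal = 4.0, distal = 3.0, Inf)
}

#' Filter fibers by the effective stimulation range
#'
#' Fibers farther than `range_mm` (in-plane distance) from every active
#' site of the configuration are excluded from simulation and counted as
#' non-recruited; any fascicle with at least one fiber inside the range is
#' implicated as a whole, so all of its fibers enter the selectivity
#' bookkeeping (recruitment-fraction denominators).
#'
#' @param fibers A `fiber_population`.
#' @param as_positions `k x 3` matrix of active-site positions (mm).
#' @param range_mm Effective range in mm.
#' @return List: `fibers` (rows to simulate: in-range fibers of implicated
#'   fascicles), `retained` (all fibers of implicated fascicles),
#'   `implicated` (fascicle ids).
#' @export
effective_range_filter <- function(fibers, as_positions, range_mm) {
  if (is.null(dim(as_positions))) as_positions <- matrix(as_positions, nrow = 1)
  if (!is.finite(range_mm))
    return(list(fibers = fibers, retained = fibers,
                implicated = sort(unique(fibers$fascicle_id))))
  dmin <- rep(Inf, nrow(fibers))
  for (k in seq_len(nrow(as_positions)))
    dmin <- pmin(dmin, sqrt((fibers$x - as_positions[k, 1])^2 +
                            (fibers$y - as_positions[k, 2])^2))
  in_range <- dmin <= range_mm
  implicated <- sort(unique(fibers$fascicle_id[in_range]))
  list(fibers = fibers[in_range, , drop = FALSE],
       retained = fibers[fibers$fascicle_id %in% implicated, , drop = FALSE],
       implicated = implicated)
}

# ---------------------------------------------------------- configurations

#' Enumerate bipolar configurations of an electrode
#'
#' For every anchor site A: a pair with the nearest opposite-face site (B)
#' and with the nearest same-face site (C), each in the anti-polarity
#' (cathodic anchor, anodic partner) and same-polarity (both cathodic)
#' patterns, with equal current magnitudes. With `dedup = TRUE` duplicate
#' weight assignments (mutual same-polarity pairs) are removed.
#'
#' @param electrode An `electrode_spec`.
#' @param dedup Remove duplicated weight assignments.
#' @return Data frame: `anchor`, `partner`, `pair_type`
#'   (`"opposite_face"`/`"same_face"`), `pattern` (`"anti"`/`"same"`),
#'   `w_anchor`, `w_partner`.
#' @export
enumerate_bipolar_configs <- function(electrode, dedup = TRUE) {
  stopifnot(inherits(electrode, "electrode_spec"))
  n <- electrode$n_as
  if (n < 2)
    return(data.frame(anchor = integer(0), partner = integer(0),
                      pair_type = character(0), pattern = character(0),
                      w_anchor = numeric(0), w_partner = numeric(0)))
  pos <- electrode$as_positions
  face <- electrode$as_face
  rows <- list()
  for (a in seq_len(n)) {
    d <- sqrt((pos[, 1] - pos[a, 1])^2 + (pos[, 2] - pos[a, 2])^2)
    d[a] <- Inf
    opp <- which(face != face[a])
    same <- setdiff(which(face == face[a]), a)
    partners <- c(if (length(opp)) opp[which.min(d[opp])],
                  if (length(same)) same[which.min(d[same])])
    types <- c(if (length(opp)) "opposite_face", if (length(same)) "same_face")
    for (t in seq_along(partners)) for (pat in c("anti", "same"))
      rows[[length(rows) + 1L]] <- data.frame(
        anchor = a, partner = partners[t], pair_type = types[t],
        pattern = pat, w_anchor = -1,
        w_partner = if (pat == "anti") 1 else -1)
  }
  out <- do.call(rbind, rows)
  if (dedup) {
    key <- vapply(seq_len(nrow(out)), function(r) {
      ids <- c(out$anchor[r], out$partner[r])
      w <- c(out$w_anchor[r], out$w_partner[r])
      o <- order(ids)
      paste(ids[o], w[o], sep = ":", collapse = "|")
    }, character(1))
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Build stimulation configurations over a named list of lead fields.
# Monopolar: each site cathodic. Bipolar pairing follows
# enumerate_bipolar_configs within each placement.
stimulation_configs <- function(lead_fields,
                                policy = c("monopolar", "bipolar",
                                           "combined")) {
  policy <- match.arg(policy)
  nm <- names(lead_fields)
  meta <- data.frame(
    name = nm,
    placement = vapply(lead_fields, `[[`, numeric(1), "placement"),
    x = vapply(lead_fields, function(f) f$position[1], numeric(1)),
    y = vapply(lead_fields, function(f) f$position[2], numeric(1)),
    z = vapply(lead_fields, function(f) f$position[3], numeric(1)),
    face = vapply(lead_fields, function(f) sign(f$face %||% 1), numeric(1)),
    stringsAsFactors = FALSE)
  mono <- lapply(seq_len(nrow(meta)), function(i)
    list(label = paste0("M.", meta$name[i]), lf_names = meta$name[i],
         weights = -1, anchor = c(meta$x[i], meta$y[i], meta$z[i]),
         monopolar = TRUE))
  names(mono) <- vapply(mono, `[[`, character(1), "label")
  if (policy == "monopolar") return(mono)
  bi <- list()
  for (pl in unique(meta$placement)) {
    sub <- meta[meta$placement == pl, , drop = FALSE]
    if (nrow(sub) < 2) next
    for (a in seq_len(nrow(sub))) {
      d <- sqrt((sub$x - sub$x[a])^2 + (sub$y - sub$y[a])^2)
      d[a] <- Inf
      opp <- which(sub$face != sub$face[a])
      same <- setdiff(which(sub$face == sub$face[a]), a)
      partners <- c(if (length(opp)) opp[which.min(d[opp])],
                    if (length(same)) same[which.min(d[same])])
      for (p in partners) for (pat in c("anti", "same")) {
        w <- c(-1, if (pat == "anti") 1 else -1)
        ids <- c(a, p)
        o <- order(ids * ifelse(w < 0, 1, 1))  # order by site
        key <- paste(sub$name[ids][order(ids)],
                     w[order(ids)], sep = ":", collapse = "|")
        if (!is.null(bi[[key]])) next
        bi[[key]] <- list(label = paste0("B.", sub$name[a], ifelse(pat == "anti", "+", "-"),
                                         sub$name[p]),
                          lf_names = sub$name[c(a, p)], weights = w,
                          anchor = c(sub$x[a], sub$y[a], sub$z[a]),
                          monopolar = FALSE)
      }
    }
  }
  bi <- unname(bi)
  names(bi) <- vapply(bi, `[[`, character(1), "label")
  c(mono, bi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ------------------------------------------------------- recruitment cores

#' Build per-fascicle recruitment curves from fiber thresholds
#'
#' Recruitment is cumulative along the sweep: a fiber counts as recruited
#' at every amplitude at and above its threshold charge.
#'
#' @param threshold_index Per-fiber sweep index of the threshold (0 = never
#'   recruited).
#' @param fascicle_id Per-fiber fascicle id.
#' @param fascicle_totals Total fiber count per fascicle id (named or
#'   indexed 1..m over the whole nerve).
#' @param sweep A [stimulus_sweep()].
#' @return A `recruitment_matrix`: counts `n` and fractions `mu`
#'   (`m x n_amplitudes`), `charges_nC`, `totals`, `implicated`.
#' @export
build_recruitment_matrix <- function(threshold_index, fascicle_id,
                                     fascicle_totals,
                                     sweep = stimulus_sweep()) {
  m <- length(fascicle_totals)
  K <- sweep$n
  n <- matrix(0, m, K)
  rec <- threshold_index > 0
  if (any(rec)) {
    for (f in unique(fascicle_id[rec])) {
      idx <- threshold_index[rec & fascicle_id == f]
      n[f, ] <- cumsum(tabulate(idx, nbins = K))
    }
  }
  mu <- n / pmax(fascicle_totals, 1)
  structure(list(n = n, mu = mu, totals = fascicle_totals,
                 charges_nC = sweep$charges_nC,
                 implicated = sort(unique(fascicle_id))),
            class = "recruitment_matrix")
}

#' Selectively recruited fascicles of one configuration
#'
#' A fascicle is selectively recruited when, at some sweep amplitude, it
#' has at least one recruited fiber, `Sel_i > 0.6` and `Sel_s_i > 0.9`
#' (strict inequalities).
#'
#' @param rm A `recruitment_matrix`.
#' @param sel_min,sels_min Criterion thresholds.
#' @return Integer vector of fascicle ids.
#' @export
selective_fascicles <- function(rm, sel_min = 0.6, sels_min = 0.9) {
  stopifnot(inherits(rm, "recruitment_matrix"))
  m <- nrow(rm$n)
  if (m < 2)
    stop("selectivity requires at least 2 fascicles", call. = FALSE)
  tot_n <- colSums(rm$n)
  sum_mu <- colSums(rm$mu)
  out <- integer(0)
  for (i in seq_len(m)) {
    ok_k <- which(rm$n[i, ] >= 1 & tot_n > 0)
    if (!length(ok_k)) next
    sel <- rm$mu[i, ok_k] - (sum_mu[ok_k] - rm$mu[i, ok_k]) / (m - 1)
    sels <- rm$n[i, ok_k] / tot_n[ok_k]
    if (any(sel > sel_min & sels > sels_min)) out <- c(out, i)
  }
  out
}

#' Fascicle threshold charge (10% recruitment)
#'
#' The smallest sweep charge at which the fascicle's recruitment fraction
#' reaches `frac` (default 10%), or NA if never reached.
#'
#' @param rm A `recruitment_matrix`.
#' @param fascicle Fascicle id.
#' @param frac Recruitment fraction defining the threshold.
#' @return Charge in nC, or NA.
#' @export
fascicle_threshold_charge <- function(rm, fascicle, frac = 0.10) {
  stopifnot(inherits(rm, "recruitment_matrix"))
  k <- which(rm$mu[fascicle, ] >= frac)
  if (!length(k)) NA_real_ else rm$charges_nC[k[1]]
}

# Potential profiles (V per +1 A configuration current) for all retained
# fibers of a configuration; 221 x n_fibers matrix.
config_profiles <- function(config, lead_fields, fibers,
                            nodes_only = FALSE) {
  nf <- nrow(fibers)
  geo <- lapply(fibers$diameter_um, mrg_compartments)
  ncomp <- length(geo[[1]]$z_mm)
  zmat <- vapply(seq_len(nf), function(i) geo[[i]]$z_mm + fibers$z_offset_mm[i],
                 numeric(ncomp))
  px <- rep(fibers$x, each = ncomp)
  py <- rep(fibers$y, each = ncomp)
  pz <- as.vector(zmat)
  prof <- numeric(ncomp * nf)
  for (j in seq_along(config$lf_names)) {
    lf <- lead_fields[[config$lf_names[j]]]
    zlim <- range(lf$zc)
    inside <- pz >= zlim[1] & pz <= zlim[2]
    v <- numeric(length(pz))
    v[inside] <- config$weights[j] / lf$I_ref *
      cpp_trilinear(lf$xs, lf$ys, lf$zc, lf$V, px[inside], py[inside],
                    pz[inside])
    if (anyNA(v))
      stop("fiber compartment outside the solved domain", call. = FALSE)
    prof <- prof + v
  }
  prof <- matrix(prof, ncomp, nf)
  if (nodes_only) {
    nd <- which(geo[[1]]$node_index > 0)
    for (i in seq_len(nf)) {
      prof[, i] <- approx(zmat[nd, i], prof[nd, i], xout = zmat[, i],
                          rule = 2)$y
    }
  }
  prof
}

# Thresholds (sweep indices) for all retained fibers of one configuration.
config_thresholds <- function(config, lead_fields, fibers, sweep,
                              nodes_only = FALSE, exhaustive = FALSE) {
  if (nrow(fibers) == 0) return(integer(0))
  prof <- config_profiles(config, lead_fields, fibers, nodes_only)
  st <- mrg_sim_settings(sweep$pulse_us)
  vapply(seq_len(nrow(fibers)), function(i) {
    d <- fibers$diameter_um[i]
    res <- cpp_mrg_threshold(d, prof[, i] * 1e3, sweep$currents_A,
                             st$pulse_ms, st$dt_on, st$dt_off, st$t_max,
                             mrg_resting_state(d), exhaustive)
    as.integer(res$index)
  }, integer(1))
}

# ------------------------------------------------------------- evaluation

#' Evaluate a stimulation policy on one fiber population
#'
#' Runs the full charge sweep for every configuration of the policy
#' (monopolar: each site cathodic; bipolar: monopolar plus signed
#' nearest-site pairs), applying the effective-range filter, and scores the
#' electrode: the percentage of fascicles selectively recruited by at least
#' one configuration at some amplitude. For bipolar policies the monopolar
#' subscore and the improvement in percentage points are also reported.
#'
#' @param cs The `nerve_cross_section`.
#' @param lead_fields Named list of `lead_field`s (one per active site).
#' @param fibers A `fiber_population` for `cs`.
#' @param policy `"monopolar"`, `"bipolar"` or `"combined"` (alias of
#'   bipolar: the bipolar policy always includes the monopolar
#'   configurations).
#' @param sweep A [stimulus_sweep()].
#' @param range_mm Effective range override (mm; default from the electrode
#'   kind and anatomy, see [effective_range()]).
#' @param nodes_only Sample extracellular potentials at nodes of Ranvier
#'   only (internodal compartments interpolated).
#' @param keep_matrices Keep per-configuration recruitment matrices.
#' @return A `selectivity_report`.
#' @export
evaluate_policy <- function(cs, lead_fields, fibers,
                            policy = c("monopolar", "bipolar", "combined"),
                            sweep = stimulus_sweep(), range_mm = NULL,
                            nodes_only = FALSE, keep_matrices = FALSE) {
  policy <- match.arg(policy)
  m <- length(cs$fascicles)
  if (m < 2)
    stop("selectivity evaluation requires at least 2 fascicles", call. = FALSE)
  if (is.null(range_mm))
    range_mm <- effective_range(lead_fields[[1]]$kind, cs$anatomy_label)
  configs <- stimulation_configs(lead_fields,
                                 if (policy == "monopolar") "monopolar"
                                 else "bipolar")
  totals <- tabulate(fibers$fascicle_id, nbins = m)
  as_pos_all <- t(vapply(lead_fields, `[[`, numeric(3), "position"))
  rownames(as_pos_all) <- names(lead_fields)
  sel_sets <- vector("list", length(configs))
  q10 <- rep(NA_real_, length(configs))
  nearest <- rep(NA_integer_, length(configs))
  mats <- if (keep_matrices) vector("list", length(configs)) else NULL
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    flt <- effective_range_filter(fibers,
                                  as_pos_all[cfg$lf_names, , drop = FALSE],
                                  range_mm)
    idx <- config_thresholds(cfg, lead_fields, flt$fibers, sweep, nodes_only)
    rm_ <- build_recruitment_matrix(idx, flt$fibers$fascicle_id, totals, sweep)
    sel_sets[[ci]] <- selective_fascicles(rm_)
    if (isTRUE(cfg$monopolar)) {
      nf <- nearest_fascicle(cs, cfg$anchor[1:2])
      nearest[ci] <- nf
      q10[ci] <- fascicle_threshold_charge(rm_, nf)
    }
    if (keep_matrices) mats[[ci]] <- rm_
  }
  names(sel_sets) <- names(configs)
  is_mono <- vapply(configs, function(c) isTRUE(c$monopolar), logical(1))
  union_all <- sort(unique(unlist(sel_sets)))
  union_mono <- sort(unique(unlist(sel_sets[is_mono])))
  score <- 100 * length(union_all) / m
  mono_score <- 100 * length(union_mono) / m
  structure(list(policy = policy, m = m,
                 anatomy_label = cs$anatomy_label,
                 fiber_seed = attr(fibers, "seed"),
                 n_fibers = nrow(fibers),
                 range_mm = range_mm,
                 configs = names(configs),
                 selective_sets = sel_sets,
                 selective_union = union_all,
                 score = score,
                 mono_score = mono_score,
                 improvement = score - mono_score,
                 improvement_relative = if (mono_score > 0)
                   100 * (score - mono_score) / mono_score else NA_real_,
                 as_thresholds = data.frame(
                   config = names(configs)[is_mono],
                   nearest_fascicle = nearest[is_mono],
                   threshold_nC = q10[is_mono]),
                 matrices = mats),
            class = "selectivity_report")
}

#' Nearest fascicle to a point
#'
#' @param cs A `nerve_cross_section`.
#' @param point Length-2 (x, y) in mm.
#' @return Fascicle id (distance 0 if the point lies inside a fascicle).
#' @export
nearest_fascicle <- function(cs, point) {
  d <- vapply(cs$fascicles, function(f) {
    if (points_in_polygon(point[1], point[2], f$contour)) 0
    else distance_to_polygon(point[1], point[2], f$contour)
  }, numeric(1))
  which.min(d)
}

#' @export
print.selectivity_report <- function(x, ...) {
  cat(sprintf("selectivity report (%s policy, %s anatomy, seed %s)\n",
              x$policy, x$anatomy_label, format(x$fiber_seed)))
  cat(sprintf("  %d fascicles, %d fibers, range filter %.1f mm\n",
              x$m, x$n_fibers, x$range_mm))
  cat(sprintf("  score: %.1f%% (%d of %d fascicles selectively recruited)\n",
              x$score, length(x$selective_union), x$m))
  if (x$policy != "monopolar")
    cat(sprintf("  monopolar subscore: %.1f%%; bipolar improvement: %+.1f points\n",
                x$mono_score, x$improvement))
  q <- x$as_thresholds$threshold_nC
  if (any(!is.na(q)))
    cat(sprintf("  nearest-fascicle 10%% thresholds: %.1f +/- %.1f nC (n=%d)\n",
                mean(q, na.rm = TRUE), sd(q, na.rm = TRUE), sum(!is.na(q))))
  invisible(x)
}

#' Maximum recruitment distance at the sweep cap
#'
#' Simulates every fiber at the sweep's maximum charge for each (cathodic,
#' monopolar) active site and reports the largest in-plane distance between
#' a recruiting site and a recruited fiber. Used to verify the effective
#' stimulation range.
#'
#' @param lead_fields Named list of `lead_field`s.
#' @param fibers A `fiber_population`.
#' @param sweep A [stimulus_sweep()].
#' @return List: `max_distance_mm`, per-site maxima `by_site`.
#' @export
max_recruitment_distance <- function(lead_fields, fibers,
                                     sweep = stimulus_sweep()) {
  st <- mrg_sim_settings(sweep$pulse_us)
  Icap <- sweep$currents_A[sweep$n]
  by_site <- numeric(length(lead_fields))
  names(by_site) <- names(lead_fields)
  for (nm in names(lead_fields)) {
    cfg <- list(lf_names = nm, weights = -1)
    prof <- config_profiles(cfg, lead_fields, fibers)
    pos <- lead_fields[[nm]]$position
    dist <- sqrt((fibers$x - pos[1])^2 + (fibers$y - pos[2])^2)
    rec <- vapply(seq_len(nrow(fibers)), function(i) {
      d <- fibers$diameter_um[i]
      cpp_mrg_simulate(d, prof[, i] * 1e3, Icap, st$pulse_ms, st$dt_on,
                       st$dt_off, st$t_max,
                       mrg_resting_state(d))$recruited
    }, logical(1))
    by_site[nm] <- if (any(rec)) max(dist[rec]) else 0
  }
  list(max_distance_mm = max(by_site), by_site = by_site)
}
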