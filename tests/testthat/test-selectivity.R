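# Selectivity indexes, the selective-fascicle criterion, recruitment
# bookkeeping, bipolar enumeration and the range filter.

test_that("spatial selectivity follows its definition", {
  expect_equal(spatial_selectivity(c(1, 0, 0), 1), 1.0)
  expect_equal(spatial_selectivity(c(0.5, 0.5), 1), 0.0)
  expect_equal(spatial_selectivity(c(0.8, 0.1, 0.1), 1), 0.7)
  expect_equal(spatial_selectivity(c(0.1, 0.8, 0.1), 2), 0.7)
  expect_error(spatial_selectivity(c(1), 1), "at least 2")
})

test_that("functional selectivity follows its definition", {
  expect_equal(functional_selectivity(c(10, 0, 0), 1), 1.0)
  expect_equal(functional_selectivity(c(9, 1, 0), 1), 0.9)
  expect_error(functional_selectivity(c(0, 0, 0), 1), "zero recruited")
})

test_that("the selective criterion uses strict inequalities", {
  sw <- stimulus_sweep(5, 10, 50)
  # fascicle 1: mu = 0.7, others 0.1 -> Sel = 0.7 - 0.1 = 0.6 exactly
  totals <- c(100, 100, 100)
  idx <- c(rep(1L, 70), rep(1L, 10), rep(1L, 10))
  fid <- c(rep(1L, 70), rep(2L, 10), rep(3L, 10))
  rm_ <- build_recruitment_matrix(idx, fid, totals, sw)
  expect_equal(spatial_selectivity(rm_$mu[, 1], 1), 0.6)
  expect_false(1 %in% selective_fascicles(rm_))
  # functional selectivity 0.9 exactly is also not selective
  idx2 <- c(rep(1L, 90), rep(1L, 10))
  fid2 <- c(rep(1L, 90), rep(2L, 10))
  rm2 <- build_recruitment_matrix(idx2, fid2, c(1000, 1000, 1000), sw)
  expect_equal(functional_selectivity(rm2$n[, 1], 1), 0.9)
  expect_false(1 %in% selective_fascicles(rm2))
  # clearly selective case
  idx3 <- rep(1L, 50)
  rm3 <- build_recruitment_matrix(idx3, rep(1L, 50), c(60, 50, 50), sw)
  expect_equal(selective_fascicles(rm3), 1L)
})

test_that("functional selectivities sum to one wherever fibers are recruited", {
  set.seed(11)
  sw <- stimulus_sweep(12, 1, 40)
  for (rep_i in 1:20) {
    m <- sample(3:8, 1)
    nfib <- sample(50:200, 1)
    fid <- sample.int(m, nfib, replace = TRUE)
    idx <- sample(0:sw$n, nfib, replace = TRUE)
    rm_ <- build_recruitment_matrix(as.integer(idx), fid,
                                    tabulate(fid, m) + 5, sw)
    tot <- colSums(rm_$n)
    for (k in which(tot > 0)) {
      sels <- vapply(seq_len(m), function(i)
        functional_selectivity(rm_$n[, k], i), 1)
      expect_equal(sum(sels), 1)
      expect_true(all(rm_$mu[, k] >= 0 & rm_$mu[, k] <= 1))
      expect_true(all(diff(rm_$n[1, ]) >= 0))
    }
  }
})

test_that("fascicle threshold charge is the first 10% crossing", {
  sw <- stimulus_sweep(10, 1, 10)
  # 100-fiber fascicle first reaching 10 recruited at 6 nC
  idx <- c(rep(3L, 4), rep(6L, 6), rep(9L, 20))
  rm_ <- build_recruitment_matrix(idx, rep(1L, 30), c(100, 50), sw)
  expect_equal(fascicle_threshold_charge(rm_, 1), 6)
  # never reaches 10%
  rm2 <- build_recruitment_matrix(rep(2L, 5), rep(1L, 5), c(100, 50), sw)
  expect_true(is.na(fascicle_threshold_charge(rm2, 1)))
  # monotone recruitment makes the crossing unique
  mu <- rm_$mu[1, ]
  expect_true(all(diff(mu) >= 0))
  expect_equal(which(mu >= 0.1)[1], 6)
})

test_that("bipolar enumeration follows the nearest-pair rule", {
  e <- time_electrode(12, "distal")
  raw <- enumerate_bipolar_configs(e, dedup = FALSE)
  expect_equal(nrow(raw), 12 * 2 * 2)  # anchors x pair types x polarities
  expect_setequal(unique(raw$pair_type), c("opposite_face", "same_face"))
  # partners are on the stated faces
  for (r in seq_len(nrow(raw))) {
    same <- e$as_face[raw$anchor[r]] == e$as_face[raw$partner[r]]
    expect_equal(same, raw$pair_type[r] == "same_face")
  }
  ded <- enumerate_bipolar_configs(e)
  expect_lt(nrow(ded), nrow(raw))
  # duplicated same-polarity mutual pairs are merged, anti-polar pairs are
  # kept in both orientations (they generate different fields)
  key <- function(d) paste(pmin(d$anchor, d$partner),
                           pmax(d$anchor, d$partner), d$pattern)
  same_pol <- ded[ded$pattern == "same", ]
  expect_false(any(duplicated(key(same_pol))))
  # single-site electrode has no pairs
  one <- nervestim:::new_electrode("TIME", 12, "distal",
                                   c(length = 10, width = 0.4, thickness = 0.02),
                                   matrix(c(0, 0.01, 0), 1), 1L,
                                   list(shape = "circle", diameter = 0.06))
  one$n_as <- 1L
  expect_equal(nrow(enumerate_bipolar_configs(one)), 0)
})

test_that("the range filter excludes far fibers but implicates fascicles", {
  fib <- fixture_toy_fibers()
  cs <- fixture_toy_nerve()
  as_pos <- matrix(c(0, 0, 0), 1)
  flt <- effective_range_filter(fib, as_pos, 2.0)
  d <- sqrt((fib$x - 0)^2 + (fib$y - 0)^2)
  expect_true(all(sqrt(flt$fibers$x^2 + flt$fibers$y^2) <= 2.0))
  expect_setequal(flt$implicated, unique(fib$fascicle_id[d <= 2]))
  # every fiber of an implicated fascicle is retained for the bookkeeping
  expect_setequal(flt$retained$fiber_id,
                  fib$fiber_id[fib$fascicle_id %in% flt$implicated])
  # a fascicle with a single in-range fiber is implicated as a whole
  one_in <- flt$implicated[1]
  expect_gt(sum(flt$retained$fascicle_id == one_in),
            sum(flt$fibers$fascicle_id == one_in) - 1)
  # infinite range keeps everything
  all_in <- effective_range_filter(fib, as_pos, Inf)
  expect_equal(nrow(all_in$fibers), nrow(fib))
  # published ranges
  expect_equal(effective_range("TIME", "proximal"), 2)
  expect_equal(effective_range("TIME", "distal"), 2)
  expect_equal(effective_range("FINE", "proximal"), 4)
  expect_equal(effective_range("FINE", "distal"), 3)
})

test_that("policy evaluation scores the toy nerve consistently", {
  cs <- fixture_toy_nerve()
  lfs <- fixture_toy_fields()
  fib <- fixture_toy_fibers()
  mono <- evaluate_policy(cs, lfs, fib, "monopolar", range_mm = 2)
  expect_true(all(mono$selective_union %in% 1:5))
  expect_equal(mono$score, 100 * length(mono$selective_union) / 5)
  # bipolar includes monopolar configurations: score can only grow
  bi <- evaluate_policy(cs, lfs, fib, "bipolar", range_mm = 2)
  expect_gte(bi$score, mono$score)
  expect_equal(bi$mono_score, mono$score)
  expect_gte(bi$improvement, 0)
  cmp <- compare_policies(mono, bi)
  expect_equal(cmp$improvement_points, bi$score - mono$score)
  expect_setequal(cmp$new_fascicles,
                  setdiff(bi$selective_union, mono$selective_union))
})

test_that("the range filter leaves the selective sets unchanged", {
  cs <- fixture_toy_nerve()
  lfs <- fixture_toy_fields()
  fib <- fixture_toy_fibers()
  filt <- evaluate_policy(cs, lfs, fib, "monopolar", range_mm = 2)
  full <- evaluate_policy(cs, lfs, fib, "monopolar", range_mm = Inf)
  expect_identical(filt$selective_sets, full$selective_sets)
  expect_equal(filt$score, full$score)
})

test_that("scores are invariant to site order and fascicle labels", {
  cs <- fixture_toy_nerve()
  lfs <- fixture_toy_fields()
  fib <- fixture_toy_fibers()
  base <- evaluate_policy(cs, lfs, fib, "monopolar", range_mm = 2)
  perm <- rev(lfs)
  again <- evaluate_policy(cs, perm, fib, "monopolar", range_mm = 2)
  expect_equal(again$score, base$score)
  expect_setequal(again$selective_union, base$selective_union)
})

test_that("selectivity evaluation requires at least two fascicles", {
  cs <- fixture_toy_nerve()
  one <- nervestim:::new_cross_section(cs$outline, cs$fascicles[1], "custom")
  lfs <- fixture_toy_fields()
  fib <- fixture_toy_fibers()
  expect_error(evaluate_policy(one, lfs, fib[fib$fascicle_id == 1, ],
                               "monopolar", range_mm = 2),
               "at least 2 fascicles")
})
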