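# Configuration-driven experiment runner: determinism and serialization.

minimal_config <- function(out = NULL) {
  list("anatomy.label" = "distal", "electrode.kind" = "TIME",
       "electrode.n_as" = 12L, "fibers.seeds" = 1L,
       "fibers.density" = 40, "solver.resolution" = "test",
       "out.dir" = out)
}

test_that("a minimal experiment produces a complete, deterministic report", {
  out1 <- tempfile("run1"); out2 <- tempfile("run2")
  s1 <- run_experiment(minimal_config(out1))
  s2 <- run_experiment(minimal_config(out2))
  expect_s3_class(s1, "selectivity_summary")
  r <- attr(s1, "report")
  expect_equal(r$m_fascicles, 31)
  expect_true(is.numeric(r$score_mean_percent))
  expect_true(file.exists(file.path(out1, "report.json")))
  expect_true(file.exists(file.path(out1, "as_thresholds.csv")))
  expect_true(file.exists(file.path(out1, "run.log")))
  # byte-identical reports across runs (timestamps live only in the log)
  expect_identical(readLines(file.path(out1, "report.json")),
                   readLines(file.path(out2, "report.json")))
  thr <- read.csv(file.path(out1, "as_thresholds.csv"))
  expect_equal(nrow(thr), 12)
})

test_that("YAML configurations round-trip and unknown keys are rejected", {
  skip_if_not_installed("yaml")
  f <- tempfile(fileext = ".yaml")
  writeLines(c("anatomy.label: distal", "electrode.n_as: 16"), f)
  cfg <- read_experiment_config(f)
  expect_equal(cfg[["electrode.n_as"]], 16)
  expect_equal(cfg[["policy"]], "monopolar")
  writeLines("not.a.key: 1", f)
  expect_error(read_experiment_config(f), "unknown configuration keys")
})

test_that("policy comparison rejects mismatched runs", {
  cs <- fixture_toy_nerve()
  lfs <- fixture_toy_fields()
  a <- evaluate_policy(cs, lfs, fixture_toy_fibers(), "monopolar",
                       range_mm = 2)
  b <- evaluate_policy(cs, lfs, populate_fibers(cs, 2, 60), "monopolar",
                       range_mm = 2)
  expect_error(compare_policies(a, b), "different geometry or fiber seeds")
  expect_equal(compare_policies(a, a)$improvement_points, 0)
})
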