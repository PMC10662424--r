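# Benchmark orchestration: manifest-driven runs, reduction matrices and
# rendered outputs.

four_preset_manifest <- function(seed = 42L) {
  list(samples = lapply(names(preset_classes), function(nm)
    list(name = nm, preset = nm, seed = seed)))
}

test_that("run_benchmark analyses all presets and recovers their classes", {
  bt <- run_benchmark(four_preset_manifest())
  expect_s3_class(bt, "benchmark_table")
  expect_equal(nrow(bt$records), 4L)
  expect_identical(bt$records$class, unname(preset_classes))
  expect_true(all(bt$records$note == ""))
  # every modality produced a finite summary
  for (col in c("eta_at_50", "t_b", "max_eta_extensional", "max_trouton",
                "boundary_mu", "mu_at_reference", "removal_percent",
                "t_saturation_min"))
    expect_true(all(is.finite(bt$records[[col]])), label = col)
  # breakup times keep the class ordering: liquid << viscous liquid << gel
  tb <- setNames(bt$records$t_b, bt$records$name)
  expect_true(tb["liquid"] < tb["viscous_liquid"] &&
                tb["viscous_liquid"] < tb["gel"])
  # determinism end to end
  bt2 <- run_benchmark(four_preset_manifest())
  expect_identical(bt$records, bt2$records)
})

test_that("run_benchmark isolates per-sample failures", {
  man <- list(samples = list(
    list(name = "ok", preset = "gel", seed = 1L),
    list(name = "broken", flow = "no/such/file.csv")))
  bt <- run_benchmark(man)
  expect_equal(nrow(bt$records), 2L)
  expect_identical(bt$records$note[1L], "")
  expect_match(bt$records$note[2L], "flow")
  expect_true(is.finite(bt$records$eta_at_50[1L]))
  expect_true(is.na(bt$records$eta_at_50[2L]))
  # empty manifest: empty table, not an error
  expect_equal(nrow(run_benchmark(list(samples = list()))$records), 0L)
})

test_that("reduction matrices follow the pairwise-reduction algebra", {
  bt <- run_benchmark(four_preset_manifest())
  m <- reduction_matrix(bt, "liquid")
  expect_identical(colnames(m), c("liquid", "saliva"))
  expect_equal(m["liquid", "liquid"], 0)
  expect_equal(m["saliva", "saliva"], 0)
  # antisymmetry: (1 - r_ab/100)(1 - r_ba/100) = 1
  r_ab <- m["gel", "liquid"]
  m2 <- reduction_matrix(bt, "gel")
  r_ba <- m2["liquid", "gel"]
  expect_equal((1 - r_ab / 100) * (1 - r_ba / 100), 1, tolerance = 1e-12)
  # no members of the reference class: empty matrix
  none <- reduction_matrix(bt, "nonexistent_class")
  expect_equal(ncol(none), 0L)
})

test_that("render_benchmark writes a stable CSV, log and plots", {
  bt <- run_benchmark(four_preset_manifest())
  out <- withr::local_tempdir()
  files <- render_benchmark(bt, out)
  csv <- file.path(out, "benchmark_table.csv")
  expect_true(all(file.exists(files)))
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 4L)
  # absent fields render as empty cells, not NA strings
  man <- list(samples = list(list(name = "flow_only",
                                  flow = "missing.csv")))
  out2 <- withr::local_tempdir()
  render_benchmark(run_benchmark(man), out2, plots = FALSE)
  line <- readLines(file.path(out2, "benchmark_table.csv"))[2L]
  expect_false(grepl("NA|NaN", line))
  # re-rendering is byte-identical
  first <- readBin(csv, "raw", file.size(csv))
  render_benchmark(bt, out)
  expect_identical(readBin(csv, "raw", file.size(csv)), first)
})

test_that("a YAML manifest with generated CSV files round-trips", {
  dir <- withr::local_tempdir()
  s <- generate_preset_sample("viscous_liquid", 5L)
  write_synthetic_sample(s, dir, 5L)
  man <- list(samples = list(list(
    name = "from_files",
    flow = file.path(dir, "flow_curve.csv"),
    thinning = file.path(dir, "thinning.csv"),
    friction = file.path(dir, "friction.csv"),
    qcmd = file.path(dir, "qcmd.csv"),
    sigma = 0.06,
    injection_time = s$params$qcmd$injection_time,
    rinse_time = s$params$qcmd$rinse_time)))
  path <- file.path(dir, "manifest_run.yaml")
  yaml::write_yaml(man, path)
  bt <- run_benchmark(path)
  expect_identical(bt$records$note, "")
  expect_identical(bt$records$class, "viscous_liquid")
  expect_equal(bt$records$t_b, 0.31, tolerance = 0.02)
  # ground truth recorded next to the data
  gt <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_identical(gt$preset, "viscous_liquid")
  expect_equal(gt$ground_truth$thinning$t_b, 0.31)
})
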