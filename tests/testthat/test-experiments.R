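tiny_config <- function(seed = 1, out_dir = NULL)
  experiment_config(n_trials_per_object = 2, n_folds = 2, onset_ms = 50,
                    hold_ms = 200, offset_ms = 50, windows_ms = c(100, 300),
                    count_window_ms = c(0, 150),
                    fault_fractions = c(0, 0.5), n_fault_seeds = 2,
                    master_seed = seed, out_dir = out_dir)

test_that("seed derivation is deterministic, in range, and stream-separated", {
  expect_identical(derive_seed(1, 2, 3), derive_seed(1, 2, 3))
  s <- c(derive_seed(1), derive_seed(1, 1), derive_seed(1, 1, 1),
         derive_seed(2), derive_seed(2, 1))
  expect_true(all(s >= 1 & s <= 2^31 - 2))
  expect_length(unique(s), 5)
  expect_true(is.integer(derive_seed(1e9, 5, 7)))
})

test_that("dataset serialisation round-trips through disk", {
  ds <- quick_dataset(n_trials = 1, master_seed = 3)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  back <- read_dataset(dir)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$master_seed, ds$master_seed)
  for (i in seq_along(ds$trials)) {
    expect_identical(back$trials[[i]]$frames, ds$trials[[i]]$frames)
    expect_identical(back$trials[[i]]$object$label, ds$trials[[i]]$object$label)
  }
})

test_that("spike trains serialise to tabular and event-stream formats", {
  r <- encode_trial(quick_trial("cone", 1), build_innervation(seed = 2),
                    nociceptor_spec())
  f <- withr::local_tempfile(fileext = ".csv")
  write_spike_trains(r, f)
  back <- read_spike_trains(f)
  expect_equal(back$duration_ms, r$duration_ms)
  expect_length(back$trains, 23)
  for (i in 1:23) {
    expect_identical(back$trains[[i]]$times_ms, r$trains[[i]]$times_ms)
    expect_identical(back$trains[[i]]$kind, r$trains[[i]]$kind)
  }
  ev <- withr::local_tempfile(fileext = ".txt")
  write_event_stream(r, ev)
  lines <- readLines(ev)
  expect_length(lines, sum(vapply(r$trains, function(t) length(t$times_ms),
                                  integer(1))))
  times <- as.integer(sub(" .*", "", lines))
  expect_true(all(diff(times) >= 0))
})

test_that("raster export draws 23 channel lanes deterministically", {
  r <- encode_trial(quick_trial("cube", 1), build_innervation(seed = 2),
                    nociceptor_spec())
  f <- withr::local_tempfile(fileext = ".png")
  export_raster(r, f)
  expect_true(file.exists(f) && file.size(f) > 0)
  # an empty response still produces a (blank) plot
  r0 <- r
  for (i in seq_along(r0$trains)) r0$trains[[i]]$times_ms <- integer(0)
  f0 <- withr::local_tempfile(fileext = ".png")
  export_raster(r0, f0)
  expect_true(file.exists(f0) && file.size(f0) > 0)
})

test_that("innervation sweep tabulates accuracy and rate per field size", {
  res <- run_innervation_sweep(tiny_config(seed = 2),
                               mean_taxels_grid = c(1, 3))
  expect_equal(nrow(res), 2 * 2)  # 2 field sizes x 2 windows
  expect_named(res, c("mean_taxels", "window_ms", "accuracy",
                      "mean_rate_hz", "master_seed"))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  # firing rate grows with receptive-field size
  rate_by_mt <- tapply(res$mean_rate_hz, res$mean_taxels, unique)
  expect_gte(rate_by_mt["3"], rate_by_mt["1"])
  # deterministic: identical config -> identical table
  expect_identical(res, run_innervation_sweep(tiny_config(seed = 2),
                                              mean_taxels_grid = c(1, 3)))
})

test_that("window sweep covers scopes, codings and written tables", {
  dir <- withr::local_tempdir()
  res <- run_window_sweep(tiny_config(seed = 3, out_dir = dir))
  expect_equal(nrow(res), 3 * 2 * 2)  # scopes x windows x codings
  expect_setequal(unique(res$scope), c("all", "group_I", "group_II"))
  expect_setequal(unique(res$coding), c("rate", "temporal"))
  csv <- file.path(dir, "window_sweep.csv")
  expect_true(file.exists(csv))
  # byte-identical on rerun (6-decimal fixed formatting)
  first <- readLines(csv)
  run_window_sweep(tiny_config(seed = 3, out_dir = dir))
  expect_identical(readLines(csv), first)
})

test_that("contribution analysis reports subsets and firing-rate gradients", {
  res <- run_contribution(tiny_config(seed = 4))
  expect_named(res, c("accuracy", "firing_rate"))
  expect_equal(nrow(res$accuracy), 2 * 7)  # 2 groups x 7 subsets
  expect_setequal(unique(res$accuracy$subset),
                  c("NOC", "SA1", "RA1", "NOC+SA1", "NOC+RA1", "SA1+RA1",
                    "all"))
  expect_equal(nrow(res$firing_rate), 2 * 4 * 3)  # groups x sizes x kinds
})

test_that("fault sweep experiment spans the requested modes", {
  res <- run_fault_sweep(tiny_config(seed = 5), modes = c("taxel", "channel"))
  expect_equal(nrow(res), 2 * 2)  # 2 modes x 2 fractions
  expect_setequal(unique(res$mode), c("taxel", "channel"))
  expect_true(all(res$mean_accuracy >= 0 & res$mean_accuracy <= 1))
})
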