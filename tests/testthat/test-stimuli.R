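test_that("trapezoidal depth profile conserves its endpoints and plateau", {
  p <- indentation_profile()
  d <- depth_series(p)
  expect_length(d, 2501)
  expect_identical(d[1], 0)
  expect_identical(d[length(d)], 0)
  hold <- d[(p$onset_ms + 1):(p$onset_ms + p$hold_ms) + 1]
  expect_true(all(hold == p$depth_mm))
  # maximal exactly on [onset, onset + hold]
  expect_true(all(d[-((p$onset_ms:(p$onset_ms + p$hold_ms)) + 1)] <
                    p$depth_mm))
  # ramps are linear at constant speed
  expect_equal(diff(d[1:(p$onset_ms + 1)]),
               rep(p$depth_mm / p$onset_ms, p$onset_ms))
})

test_that("contact footprint obeys the sharpness geometry contracts", {
  grid <- grid_spec()
  # no contact at zero depth; negative depth rejected
  expect_equal(contact_footprint(stimulus_object("cone", 1), 0, grid),
               matrix(0, 5, 5))
  expect_error(contact_footprint(stimulus_object("cone", 1), -1, grid))
  # footprint entirely off the grid warns and returns zeros
  expect_warning(
    fp <- contact_footprint(stimulus_object("cone", 1), 1, grid,
                            center_offset_mm = c(100, 100)))
  expect_equal(fp, matrix(0, 5, 5))

  # wide cube covers strictly more taxels than a narrow one at equal depth
  f1 <- contact_footprint(stimulus_object("cube", 1), 1.4, grid)
  f9 <- contact_footprint(stimulus_object("cube", 9), 1.4, grid)
  thr <- 0.1 * max(f1)
  expect_gt(sum(f9 > thr), sum(f1 > thr))
  # sharp cone presses harder on its peak taxel than a blunt one
  c1 <- contact_footprint(stimulus_object("cone", 1), 1.4, grid)
  c9 <- contact_footprint(stimulus_object("cone", 9), 1.4, grid)
  expect_gt(max(c1), max(c9))

  # monotone sharpness contract over the whole default set, both shapes:
  # half-peak active-taxel count strictly increases with feature size,
  # peak pressure strictly decreases, total force grows with contact area
  for (shape in c("cone", "cube")) {
    peaks <- counts <- totals <- numeric(0)
    for (s in c(1, 3, 5, 9)) {
      fp <- contact_footprint(stimulus_object(shape, s), 1.4, grid)
      peaks <- c(peaks, max(fp))
      counts <- c(counts, sum(fp > 0.5 * max(fp)))
      totals <- c(totals, sum(fp))
    }
    expect_true(all(diff(peaks) < 0))
    expect_true(all(diff(counts) > 0))
    expect_true(all(diff(totals) > 0))
  }
  # total pressure is proportional to depth
  f_half <- contact_footprint(stimulus_object("cone", 3), 0.7, grid)
  f_full <- contact_footprint(stimulus_object("cone", 3), 1.4, grid)
  expect_equal(sum(f_full), 2 * sum(f_half))
})

test_that("generated trials are quantised, plateau-constant and reproducible", {
  tr <- quick_trial(noise_sd = 0, jitter_mm = 0)
  expect_s3_class(tr, "tactile_trial")
  expect_equal(nrow(tr$frames), 301)  # onset + hold + offset + 1 at dt = 1 ms
  expect_true(all(tr$frames >= 0 & tr$frames <= 1023))
  expect_true(is.integer(tr$frames))
  # noise-free hold phase is constant in time
  hold <- tr$frames[52:250, ]
  expect_true(all(apply(hold, 2, function(col) length(unique(col)) == 1L)))

  # default profile gives 2501 frames
  tr_full <- generate_trial(stimulus_object("cube", 3), seed = 2)
  expect_equal(nrow(tr_full$frames), 2501)

  # determinism: identical (object, profile, seed) -> bit-identical record
  a <- generate_trial(stimulus_object("cone", 5), short_profile(), seed = 42)
  b <- generate_trial(stimulus_object("cone", 5), short_profile(), seed = 42)
  expect_identical(a, b)
  expect_false(identical(
    a$frames,
    generate_trial(stimulus_object("cone", 5), short_profile(),
                   seed = 43)$frames))
})

test_that("dataset generation follows the 8 x 10 trial protocol", {
  ds <- quick_dataset(n_trials = 2, master_seed = 7)
  expect_s3_class(ds, "tactile_dataset")
  expect_length(ds$trials, 16)
  expect_equal(as.vector(table(ds$labels)), rep(2, 8))

  one <- generate_dataset(list(stimulus_object("cone", 1)), 1,
                          profile = short_profile(), master_seed = 1)
  expect_length(one$trials, 1)

  expect_error(generate_dataset(list(), 1))

  # different master seeds: same labels, different realisations
  ds2 <- quick_dataset(n_trials = 2, master_seed = 8)
  expect_identical(ds$labels, ds2$labels)
  expect_false(identical(ds$trials[[1]]$frames, ds2$trials[[1]]$frames))
  # and the full default experiment counts 80 trials
  expect_equal(length(default_objects()) * 10L, 80L)
})
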