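test_that("the Euler step reproduces the discretized dynamics and reset law", {
  rs <- izhikevich_params("sa1")
  fs <- izhikevich_params("noc")
  # a step that crosses 30 mV resets v to c and increments u by d
  st <- list(v = 20, u = 0)
  out_rs <- izhikevich_step(st, I = 2000, rs)
  expect_true(out_rs$spiked)
  expect_identical(out_rs$state$v, rs$c)
  expect_identical(out_rs$state$u, st$u + rs$d)  # 8 for regular spiking
  out_fs <- izhikevich_step(st, I = 2000, fs)
  expect_identical(out_fs$state$u, st$u + fs$d)  # 2 for fast spiking
  expect_error(izhikevich_step(list(v = NaN, u = 0), 0, rs))
  expect_error(izhikevich_step(list(v = 0, u = 0), Inf, rs))
})

test_that("compiled simulation equals the scalar step to machine precision", {
  set.seed(21)
  for (kind in c("sa1", "noc")) {
    p <- izhikevich_params(kind)
    I <- runif(400, 0, 400)
    st <- list(v = p$c, u = p$b * p$c)
    spikes_r <- integer(0)
    for (n in seq_along(I)) {
      out <- izhikevich_step(st, I[n], p)
      st <- out$state
      if (out$spiked) spikes_r <- c(spikes_r, n)
    }
    ts <- simulate_izhikevich(I, p)
    expect_identical(as.integer(ts), spikes_r)
    fin <- attr(ts, "final_state")
    expect_equal(fin$v, st$v, tolerance = 1e-12)
    expect_equal(fin$u, st$u, tolerance = 1e-12)
  }
})

test_that("the regular-spiking neuron settles at the quadratic fixed point", {
  p <- izhikevich_params("sa1")
  ts <- simulate_izhikevich(rep(0, 2500), p)
  expect_length(ts, 0)
  expect_equal(attr(ts, "final_state")$v, rs_rest_oracle(p$b),
               tolerance = 0.1 / 75)  # within 0.1 mV
  # fast spiking fires at a strictly higher steady rate than regular
  # spiking for the same effective input
  n_fs <- length(simulate_izhikevich(rep(12, 2000),
                                     izhikevich_params("noc"), k_scale = 1))
  n_rs <- length(simulate_izhikevich(rep(12, 2000), p, k_scale = 1))
  expect_gt(n_fs, n_rs)
  expect_gt(n_rs, 0)
})

test_that("RA front-end rectifies the derivative and silences the plateau", {
  expect_equal(ra_front_end(rep(5, 100)), rep(0, 99))
  # linear ramp of slope s: constant output k3 * |s| * dt
  ramp <- seq(0, 500, by = 2.5)
  expect_equal(ra_front_end(ramp, k3 = 128), rep(128 * 2.5, length(ramp) - 1))
  expect_equal(ra_front_end(rev(ramp), k3 = 128),
               rep(128 * 2.5, length(ramp) - 1))  # offset excites too
  expect_length(ra_front_end(1:10), 9)
  expect_error(ra_front_end(5))
  # trapezoidal drive: nonzero exactly during onset and offset
  d <- depth_series(short_profile()) * 100
  out <- ra_front_end(d)
  expect_true(all(out[51:250] == 0))
  expect_true(all(out[c(1:50, 251:300)] > 0))
})

test_that("nociceptor input implements the MCV / NoT rule in both modes", {
  spec <- nociceptor_spec(threshold_adc = 500)
  f <- matrix(0, 5, 5)
  expect_identical(nociceptor_input(f, spec), 0)          # gentle touch
  f[2, 2] <- 400
  expect_identical(nociceptor_input(f, spec), 0)          # below threshold
  f[] <- 0; f[3, 3] <- 1000
  expect_equal(nociceptor_input(f, spec), 1000)           # sharp: NoT = 1
  f[] <- 0; f[1, 1:5] <- 1000; f[2, 1:5] <- 1000          # ten taxels at 1000
  expect_equal(nociceptor_input(f, spec), 100)            # exact division
  expect_equal(nociceptor_input(f, spec, shift_divide = TRUE),
               1000 / 2^4)                                # 1000 >> 4 = 62.5
  # shift uses ceil(log2(NoT)): three taxels -> divide by 4
  f[] <- 0; f[1, 1:3] <- 800
  expect_equal(nociceptor_input(f, spec, shift_divide = TRUE), 200)
  # vectorised series agrees with the per-frame operation
  tr <- quick_trial("cone", 1)
  series <- neurotact:::nociceptor_input_series(tr$frames, spec)
  expect_equal(series[100],
               nociceptor_input(tr$frames[100, ], spec))
})

test_that("trial encoding produces the 23-channel population layout", {
  map <- build_innervation(seed = 6)
  noc <- nociceptor_spec()
  tr <- quick_trial("cone", 3, seed = 2)
  r <- encode_trial(tr, map, noc)
  expect_s3_class(r, "population_response")
  expect_length(r$trains, 23)
  kinds <- vapply(r$trains, `[[`, "", "kind")
  expect_identical(kinds, c(rep("NOC", 5), rep("SA1", 6), rep("RA1", 12)))
  expect_identical(vapply(r$trains, `[[`, 0L, "channel_id"), 1:23)
  expect_equal(r$duration_ms, nrow(tr$frames) - 1L)
  # spike times strictly increasing within trial bounds
  for (t in r$trains) {
    expect_true(all(diff(t$times_ms) > 0))
    expect_true(all(t$times_ms >= 0 & t$times_ms <= r$duration_ms))
  }
  # deterministic
  expect_identical(r, encode_trial(tr, map, noc))

  # an all-zero trial yields 23 empty trains
  tr0 <- tr; tr0$frames[] <- 0L
  r0 <- encode_trial(tr0, map, noc)
  expect_true(all(vapply(r0$trains, function(t) length(t$times_ms),
                         integer(1)) == 0L))

  # grid mismatch rejected
  tr_bad <- tr; tr_bad$frames <- tr$frames[, 1:24]
  expect_error(encode_trial(tr_bad, map, noc))
})

test_that("RA-I spikes stay near onset and offset on noise-free trapezoids", {
  map <- build_innervation(seed = 8)
  noc <- nociceptor_spec()
  p <- short_profile()
  for (size in c(1, 9)) {
    r <- encode_trial(quick_trial("cube", size, profile = p), map, noc)
    kinds <- vapply(r$trains, `[[`, "", "kind")
    ra <- unlist(lapply(r$trains[kinds == "RA1"], `[[`, "times_ms"))
    onset_win <- ra <= p$onset_ms + 50
    offset_win <- ra >= p$onset_ms + p$hold_ms
    expect_true(all(onset_win | offset_win))
    # SA-I stays active through the hold phase
    sa <- unlist(lapply(r$trains[kinds == "SA1"], `[[`, "times_ms"))
    expect_gt(sum(sa > p$onset_ms + 50 & sa < p$onset_ms + p$hold_ms), 0)
  }
})

test_that("sharpness shifts activity from mechanoreceptors to nociceptors", {
  # noise-free trapezoids at 1.4 mm; rates averaged over innervation maps
  maps <- lapply(1:4, function(i) build_innervation(seed = 30 + i))
  noc <- nociceptor_spec()
  p <- short_profile()
  rates <- function(size) {
    per_map <- vapply(maps, function(m) {
      r <- encode_trial(quick_trial("cone", size, profile = p), m, noc)
      kinds <- vapply(r$trains, `[[`, "", "kind")
      n <- vapply(r$trains, function(t) length(t$times_ms), integer(1))
      c(noc = mean(n[kinds == "NOC"]), sa = mean(n[kinds == "SA1"]))
    }, numeric(2))
    rowMeans(per_map)
  }
  sharp <- rates(1); blunt <- rates(9)
  expect_gt(sharp["noc"], blunt["noc"])
  expect_gt(blunt["sa"], sharp["sa"])
})
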