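#' Izhikevich parameter presets for the digital afferent classes
#'
#' Two-variable quadratic spiking model in its power-of-two-rescaled form
#' (the continuous-time voltage equation `v' = 0.04 v^2 + 5 v + 140 - u +
#' ks I / Cm` multiplied by 0.78125 so every coefficient is a power of two:
#' `v' = v^2/32 + 4 v + 109.375 - u + ks I / Cm`). SA-I afferents and RA-I
#' afferents use the regular-spiking (RS) preset (a = 0.02, b = 0.2, c = -65,
#' d = 8); nociceptors use the fast-spiking (FS) preset (a = 0.1, b = 0.2,
#' c = -65, d = 2). Input gains: `k1 = 1/32` (SA-I), `k2 = 1/8` (nociceptor),
#' `k3 = 128` with time constant `tau = 1 s` applied to the rectified
#' derivative (RA-I). Membrane capacitance `Cm = 1 F`; spike cutoff 30 mV;
#' Euler step `dt = 1 ms`.
#'
#' @param kind `"sa1"`, `"ra1"` or `"noc"`.
#' @return An `izhikevich_params` list: `a`, `b`, `c`, `d`, `k_scale`, `Cm`,
#'   `v_thresh`, `dynamic` (`"RS"` or `"FS"`), and `tau` (RA-I only).
#' @examples
#' izhikevich_params("noc")$d  # fast-spiking recovery increment, 2 mV
#' @export
izhikevich_params <- function(kind = c("sa1", "ra1", "noc")) {
  kind <- match.arg(kind)
  p <- switch(kind,
    sa1 = list(a = 0.02, b = 0.2, c = -65, d = 8, k_scale = 1 / 32,
               dynamic = "RS"),
    ra1 = list(a = 0.02, b = 0.2, c = -65, d = 8, k_scale = 128,
               tau = 1, dynamic = "RS"),
    noc = list(a = 0.1, b = 0.2, c = -65, d = 2, k_scale = 1 / 8,
               dynamic = "FS"))
  p$Cm <- 1
  p$v_thresh <- 30
  p$kind <- kind
  structure(p, class = "izhikevich_params")
}

#' One Euler step of the rescaled Izhikevich model
#'
#' Applies, at `dt = 1 ms`, `v <- v + (v^2/32 + 4 v + 109.375 - u + ks I)`
#' and `u <- u + a (b v - u)` (the recovery update uses the pre-update `v`);
#' if the updated `v` reaches the 30 mV cutoff the step reports a spike and
#' applies the reset `v <- c`, `u <- u_pre + d`.
#'
#' This scalar step is the reference definition; [simulate_izhikevich()] runs
#' the same recursion in compiled code over a whole input series.
#'
#' @param state list with membrane potential `v` (mV) and recovery `u`.
#' @param I input current (already in ADC-derived units; multiplied by
#'   `params$k_scale / params$Cm` inside the step).
#' @param params an [izhikevich_params()] preset.
#' @return List with `state` (updated `v`, `u`) and logical `spiked`.
#' @export
izhikevich_step <- function(state, I, params) {
  stopifnot(inherits(params, "izhikevich_params"))
  if (!is.finite(state$v) || !is.finite(state$u) || !is.finite(I))
    stop("non-finite neuron state or input")
  ks <- params$k_scale / params$Cm
  v_new <- state$v + (state$v^2 / 32 + 4 * state$v + 109.375 - state$u +
                        ks * I)
  u_new <- state$u + params$a * (params$b * state$v - state$u)
  spiked <- v_new >= params$v_thresh
  if (spiked) {
    v_new <- params$c
    u_new <- state$u + params$d
  }
  list(state = list(v = v_new, u = u_new), spiked = spiked)
}

#' Simulate one neuron over an input current series
#'
#' Runs the Euler recursion of [izhikevich_step()] over `I[1], I[2], ...`
#' (one sample per ms) in compiled code, in double precision or in Q13.18
#' fixed-point arithmetic (see [to_fixed_point()]). The spike emitted while
#' processing `I[n]` is stamped at `n` ms. Initial conditions default to the
#' standard rest state `v0 = c`, `u0 = b * c`.
#'
#' @param I numeric input series (units as in [izhikevich_step()]).
#' @param params an [izhikevich_params()] preset.
#' @param fixed_point logical; run the update in Q13.18 arithmetic.
#' @param v0,u0 initial state.
#' @param k_scale input gain override; defaults to `params$k_scale`. Pass 1
#'   when the gain has already been applied upstream (RA-I front-end).
#' @return Integer vector of spike times (ms), with attributes `final_state`
#'   (list `v`, `u`) and `overflow` (fixed-point saturation occurred).
#' @export
simulate_izhikevich <- function(I, params, fixed_point = FALSE,
                                v0 = params$c, u0 = params$b * params$c,
                                k_scale = NULL) {
  stopifnot(inherits(params, "izhikevich_params"), is.numeric(I))
  ks <- if (is.null(k_scale)) params$k_scale / params$Cm else k_scale
  f <- if (fixed_point) cpp_izh_simulate_fixed else cpp_izh_simulate
  res <- f(as.numeric(I), params$a, params$b, params$c, params$d, ks, v0, u0)
  structure(as.integer(res$times_ms),
            final_state = list(v = res$v, u = res$u),
            overflow = res$overflow)
}

#' Rapidly adapting front-end: rectified derivative of the drive
#'
#' RA-I afferents respond to changes in indentation, not to sustained
#' pressure: the drive series is differenced at the 1 ms sampling step and
#' full-wave rectified, then scaled by `k3`, so both onset (increasing
#' pressure) and offset (decreasing pressure) excite the neuron while the
#' hold phase yields zero input.
#'
#' @param drive_series numeric drive samples at 1 ms (length >= 2).
#' @param k3 derivative gain (default 128).
#' @return `k3 * abs(diff(drive_series))`, length `length(drive_series) - 1`,
#'   all values non-negative.
#' @export
ra_front_end <- function(drive_series, k3 = 128) {
  if (length(drive_series) < 2)
    stop("drive_series must contain at least 2 samples")
  k3 * abs(diff(as.numeric(drive_series)))
}

#' Nociceptor population specification
#'
#' @param threshold_adc taxel activation threshold in ADC counts, in
#'   `(0, adc_max]`. Default 102 (10% of the 10-bit full scale): low enough
#'   that every object of the default set registers at full indentation —
#'   blunt touches stay innocuous not because they are invisible to the
#'   nociceptor but because their force spreads over many taxels, making the
#'   MCV/NoT input small.
#' @param n_noc number of nociceptor channels (default 5).
#' @param gain_jitter half-range of the multiplicative input-gain
#'   perturbation applied per nociceptor (default 0.05, i.e. gains uniform in
#'   `[0.95, 1.05]`), so the channels are not bit-identical copies.
#' @param seed seed for the per-channel gains.
#' @return A `nociceptor_spec` object; `gains` holds the realised per-channel
#'   gains.
#' @export
nociceptor_spec <- function(threshold_adc = 102L, n_noc = 5L,
                            gain_jitter = 0.05, seed = 1L) {
  stopifnot(threshold_adc > 0, n_noc >= 0, gain_jitter >= 0)
  gains <- if (n_noc > 0) {
    set.seed(seed)
    1 + runif(n_noc, -gain_jitter, gain_jitter)
  } else numeric(0)
  structure(
    list(threshold_adc = as.integer(threshold_adc), n_noc = as.integer(n_noc),
         gain_jitter = gain_jitter, seed = as.integer(seed), gains = gains),
    class = "nociceptor_spec")
}

#' Nociceptor input statistic for one pressure frame
#'
#' The nociceptor reads the whole array: `NoT` is the number of taxels whose
#' value exceeds `threshold_adc` and `MCV` is the maximum taxel value. The
#' input is `MCV / NoT` (0 when no taxel is above threshold): concentrated
#' high pressure — few active taxels with a large maximum — yields a large,
#' noxious input, whereas the same maximum spread over many taxels is
#' innocuous. With `shift_divide = TRUE` the division is emulated the way a
#' digital implementation would, as a right-shift by `ceil(log2(NoT))`
#' (i.e. division by the next power of two), on a register that keeps
#' fractional bits.
#'
#' @param frame numeric matrix or vector of taxel ADC counts.
#' @param spec a [nociceptor_spec()].
#' @param shift_divide use the power-of-two shift instead of exact division.
#' @return A single non-negative number.
#' @examples
#' f <- matrix(0, 5, 5); f[3, 3] <- 1000
#' nociceptor_input(f, nociceptor_spec(threshold_adc = 500))  # 1000: sharp
#' @export
nociceptor_input <- function(frame, spec = nociceptor_spec(),
                             shift_divide = FALSE) {
  stopifnot(inherits(spec, "nociceptor_spec"))
  v <- as.numeric(frame)
  not <- sum(v > spec$threshold_adc)
  if (not == 0) return(0)
  mcv <- max(v)
  if (shift_divide) mcv / 2^ceiling(log2(not)) else mcv / not
}

# Vectorised NoT/MCV input over all frames (rows) of a trial.
nociceptor_input_series <- function(frames, spec, shift_divide = FALSE) {
  mcv <- do.call(pmax, as.data.frame(frames))
  not <- rowSums(frames > spec$threshold_adc)
  inp <- numeric(length(mcv))
  pos <- not > 0
  inp[pos] <- if (shift_divide) mcv[pos] / 2^ceiling(log2(not[pos]))
              else mcv[pos] / not[pos]
  inp
}

#' Encode a full trial into a population spike response
#'
#' Runs the complete spiking front-end over one trial: each SA-I afferent
#' receives its receptive-field drive (weighted taxel sum) scaled by
#' `k1 / Cm` into regular-spiking dynamics; each RA-I afferent receives the
#' rectified derivative of its drive ([ra_front_end()]) into regular-spiking
#' dynamics; each nociceptor receives the frame-wise `MCV / NoT` statistic
#' scaled by its channel gain and `k2 / Cm` into fast-spiking dynamics. All
#' neurons start from rest (`v = c`, `u = b c`). The encoding is fully
#' deterministic given the trial, map and nociceptor spec.
#'
#' The interface circuit's ADC-to-current conversion gain is a free
#' calibration per afferent class (`gains`): defaults 2 for SA-I, 1 for
#' nociceptors (one ADC count = one current unit) and 1/32 for the RA-I
#' derivative pathway. The RA-I value compensates the large derivative gain
#' `k3 = 128` so that, for the default trapezoid, onset/offset inputs land in
#' the same moderate suprathreshold range as the sustained SA-I inputs. The
#' calibration keeps every class at physiological firing rates (SA-I tens of
#' Hz, graded with contact area), where the 1 ms Euler update is well
#' behaved: large sustained inputs drive the recovery variable so high that
#' the discretization overshoots the quadratic nullcline and fires
#' spuriously after the stimulus ends.
#'
#' @param trial a `tactile_trial` from [generate_trial()].
#' @param map an `innervation_map` from [build_innervation()].
#' @param noc a [nociceptor_spec()].
#' @param fixed_point logical; run neuron updates in Q13.18 arithmetic and
#'   the nociceptor division as a power-of-two right-shift.
#' @param params list with elements `sa1`, `ra1`, `noc` of
#'   [izhikevich_params()]; defaults to the standard presets.
#' @param gains per-class ADC-to-current conversion gains, list with
#'   elements `sa1`, `ra1`, `noc`.
#' @return A `population_response`: list with `trains` (one per channel, in
#'   order nociceptors, SA-I, RA-I — 5 + 6 + 12 = 23 by default; each a
#'   `spike_train` list with `channel_id`, `kind`, integer `times_ms`) and
#'   `duration_ms`.
#' @export
encode_trial <- function(trial, map, noc = nociceptor_spec(),
                         fixed_point = FALSE,
                         params = list(sa1 = izhikevich_params("sa1"),
                                       ra1 = izhikevich_params("ra1"),
                                       noc = izhikevich_params("noc")),
                         gains = list(sa1 = 2, ra1 = 1 / 32, noc = 1)) {
  stopifnot(inherits(trial, "tactile_trial"), inherits(map, "innervation_map"),
            inherits(noc, "nociceptor_spec"))
  n_taxels <- trial$grid$rows * trial$grid$cols
  if (ncol(trial$frames) != n_taxels)
    stop("trial frame width does not match its grid")
  if (any(dim(map$fields[[1]]$weights) != c(trial$grid$rows, trial$grid$cols)))
    stop("innervation map grid does not match trial grid")
  frames <- trial$frames
  n_steps <- nrow(frames) - 1L
  drives <- frames %*% innervation_weight_matrix(map)  # (T+1) x n_fields

  trains <- vector("list", noc$n_noc + map$n_sa + map$n_ra)
  ch <- 0L
  noc_inp <- nociceptor_input_series(frames, noc, shift_divide = fixed_point)
  for (j in seq_len(noc$n_noc)) {
    ch <- ch + 1L
    times <- simulate_izhikevich(
      gains$noc * noc$gains[j] * noc_inp[seq_len(n_steps)],
      params$noc, fixed_point = fixed_point)
    trains[[ch]] <- spike_train(ch, "NOC", times)
  }
  for (j in seq_len(map$n_sa)) {
    ch <- ch + 1L
    times <- simulate_izhikevich(gains$sa1 * drives[seq_len(n_steps), j],
                                 params$sa1, fixed_point = fixed_point)
    trains[[ch]] <- spike_train(ch, "SA1", times)
  }
  for (j in seq_len(map$n_ra)) {
    ch <- ch + 1L
    inp <- ra_front_end(gains$ra1 * drives[, map$n_sa + j],
                        k3 = params$ra1$k_scale)
    times <- simulate_izhikevich(inp, params$ra1, fixed_point = fixed_point,
                                 k_scale = 1 / params$ra1$Cm)
    trains[[ch]] <- spike_train(ch, "RA1", times)
  }
  structure(list(trains = trains, duration_ms = n_steps),
            class = "population_response")
}

# Constructor/validator for a single channel's spike train.
spike_train <- function(channel_id, kind, times_ms) {
  times_ms <- as.integer(times_ms)
  if (is.unsorted(times_ms, strictly = TRUE))
    stop("spike times must be strictly increasing")
  structure(list(channel_id = as.integer(channel_id), kind = kind,
                 times_ms = times_ms),
            class = "spike_train")
}

#' @export
print.population_response <- function(x, ...) {
  kinds <- vapply(x$trains, `[[`, "", "kind")
  n <- vapply(x$trains, function(tr) length(tr$times_ms), integer(1))
  cat(sprintf("<population_response> %d channels (%s), %d ms, %d spikes\n",
              length(x$trains),
              paste(sprintf("%d %s", as.vector(table(kinds)[unique(kinds)]),
                            unique(kinds)), collapse = ", "),
              x$duration_ms, sum(n)))
  invisible(x)
}

#' Encode every trial of a dataset
#'
#' @param dataset a `tactile_dataset` from [generate_dataset()].
#' @param map,noc,fixed_point,params,gains as in [encode_trial()].
#' @return List of `population_response`, one per trial, with the dataset's
#'   `labels` attached as an attribute.
#' @export
encode_dataset <- function(dataset, map, noc = nociceptor_spec(),
                           fixed_point = FALSE,
                           params = list(sa1 = izhikevich_params("sa1"),
                                         ra1 = izhikevich_params("ra1"),
                                         noc = izhikevich_params("noc")),
                           gains = list(sa1 = 2, ra1 = 1 / 32, noc = 1)) {
  stopifnot(inherits(dataset, "tactile_dataset"))
  responses <- lapply(dataset$trials, encode_trial, map = map, noc = noc,
                      fixed_point = fixed_point, params = params,
                      gains = gains)
  attr(responses, "labels") <- dataset$labels
  responses
}

#' Convert real numbers to Q13.18 fixed point
#'
#' Signed 32-bit two's-complement representation with 13 integer and 18
#' fractional bits, as used by the fixed-point simulation mode: conversion
#' rounds to the nearest representable multiple of `2^-18`; values beyond
#' the representable range `[-8192, 8192)` saturate and are flagged. All
#' model constants (109.375, 1/32, 1/8, 128, the RS/FS presets up to the
#' rounding of a) are dyadic rationals, most exactly representable.
#'
#' @param x numeric vector, `|x| < 2^13` for exact-range representation.
#' @return Numeric vector of the represented values, with attributes `raw`
#'   (the integer register contents, `value * 2^18`) and `overflow` (logical
#'   vector flagging saturated entries).
#' @examples
#' to_fixed_point(109.375)  # exactly representable
#' @export
to_fixed_point <- function(x) {
  stopifnot(is.numeric(x))
  raw <- round(x * 2^18)
  ovf <- raw > 2^31 - 1 | raw < -2^31
  raw <- pmin(pmax(raw, -2^31), 2^31 - 1)
  if (any(ovf)) warning("value(s) outside Q13.18 range saturated")
  structure(raw / 2^18, raw = raw, overflow = ovf)
}
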