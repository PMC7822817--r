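#' Stimulus objects: cones and cubes of graded sharpness
#'
#' The benchmark stimulus set consists of two groups of 3D-printed objects
#' pressed into a pressure-sensor array: Group-I are cones characterised by
#' their apex diameter, Group-II are cubes characterised by their width.
#' Smaller feature sizes are sharper: they concentrate the contact force on
#' fewer taxels at higher pressure.
#'
#' @param shape `"cone"` or `"cube"`.
#' @param feature_size_mm positive contact feature size in mm (cone apex
#'   diameter or cube width). The default object set uses 1, 3, 5 and 9 mm.
#' @return An object of class `stimulus_object` with fields `shape`,
#'   `feature_size_mm`, `group` (`"I"` for cones, `"II"` for cubes) and a
#'   human-readable `label`.
#' @seealso [default_objects()], [contact_footprint()]
#' @examples
#' stimulus_object("cone", 1)
#' @export
stimulus_object <- function(shape = c("cone", "cube"), feature_size_mm) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(feature_size_mm), length(feature_size_mm) == 1L,
            feature_size_mm > 0)
  structure(
    list(shape = shape,
         feature_size_mm = feature_size_mm,
         group = if (shape == "cone") "I" else "II",
         label = sprintf("%s_%gmm", shape, feature_size_mm)),
    class = "stimulus_object")
}

#' @export
print.stimulus_object <- function(x, ...) {
  cat(sprintf("<stimulus_object> %s (group %s), feature size %g mm\n",
              x$shape, x$group, x$feature_size_mm))
  invisible(x)
}

#' The default eight-object benchmark set
#'
#' Four cones (apex diameters 1, 3, 5, 9 mm; Group-I) and four cubes (widths
#' 1, 3, 5, 9 mm; Group-II).
#'
#' @return A list of eight [stimulus_object()]s.
#' @export
default_objects <- function() {
  sizes <- c(1, 3, 5, 9)
  c(lapply(sizes, function(s) stimulus_object("cone", s)),
    lapply(sizes, function(s) stimulus_object("cube", s)))
}

#' Trapezoidal indentation profile
#'
#' Each trial indents the object with a trapezoidal depth profile: a linear
#' onset ramp, a constant hold phase, and a linear offset ramp, at constant
#' ramp speed. Defaults follow the robotic protocol: 250 ms onset, 2000 ms
#' hold, 250 ms offset (2500 ms total) at 1.4 mm depth.
#'
#' @param onset_ms,hold_ms,offset_ms non-negative phase durations in ms.
#' @param depth_mm positive hold-phase indentation depth in mm.
#' @return An `indentation_profile` object.
#' @examples
#' p <- indentation_profile()
#' d <- depth_series(p)
#' length(d)  # 2501 samples at 1 ms
#' @export
indentation_profile <- function(onset_ms = 250, hold_ms = 2000,
                                offset_ms = 250, depth_mm = 1.4) {
  stopifnot(onset_ms >= 0, hold_ms >= 0, offset_ms >= 0, depth_mm > 0)
  structure(
    list(onset_ms = as.integer(onset_ms), hold_ms = as.integer(hold_ms),
         offset_ms = as.integer(offset_ms), depth_mm = depth_mm,
         total_ms = as.integer(onset_ms + hold_ms + offset_ms)),
    class = "indentation_profile")
}

#' Sampled indentation depth at 1 ms resolution
#'
#' @param profile an [indentation_profile()].
#' @return Numeric vector of depths (mm) at t = 0, 1, ..., total_ms;
#'   length `total_ms + 1`. Zero at both ends, maximal and constant exactly
#'   on the hold phase.
#' @rdname indentation_profile
#' @export
depth_series <- function(profile) {
  stopifnot(inherits(profile, "indentation_profile"))
  t <- 0:profile$total_ms
  on <- profile$onset_ms
  off_start <- profile$onset_ms + profile$hold_ms
  d <- numeric(length(t))
  if (on > 0) {
    ramp <- t <= on
    d[ramp] <- profile$depth_mm * t[ramp] / on
  }
  d[t > on & t <= off_start] <- profile$depth_mm
  if (profile$offset_ms > 0) {
    ramp <- t > off_start
    d[ramp] <- profile$depth_mm * (profile$total_ms - t[ramp]) / profile$offset_ms
  }
  d
}

#' Tactile sensor grid specification
#'
#' @param rows,cols grid dimensions (default 5 x 5).
#' @param pitch_mm taxel pitch in mm (default 2.8, i.e. a 14 x 14 mm active
#'   area).
#' @param adc_bits ADC resolution; taxel values are integer counts in
#'   `[0, 2^adc_bits - 1]` (default 10 bits, 0-1023).
#' @return A `grid_spec` object; `adc_max` is the full-scale count.
#' @export
grid_spec <- function(rows = 5L, cols = 5L, pitch_mm = 2.8, adc_bits = 10L) {
  stopifnot(rows >= 1, cols >= 1, pitch_mm > 0, adc_bits >= 1)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         pitch_mm = pitch_mm, adc_bits = as.integer(adc_bits),
         adc_max = as.integer(2^adc_bits - 1)),
    class = "grid_spec")
}

# Taxel centre coordinates (mm), grid centred at the origin.
# Returns list(x, y) with x varying along columns, y along rows.
taxel_centers <- function(grid) {
  x <- (seq_len(grid$cols) - (grid$cols + 1) / 2) * grid$pitch_mm
  y <- (seq_len(grid$rows) - (grid$rows + 1) / 2) * grid$pitch_mm
  list(x = x, y = y)
}

# Smooth membership of a point in the object's contact cross-section.
# dx, dy: coordinates relative to the contact centre. Inside the footprint
# the weight is 1; outside it decays as a Gaussian of the distance to the
# footprint boundary, emulating the force-dispersing silicone layer.
footprint_membership <- function(object, dx, dy, blur_mm) {
  half <- object$feature_size_mm / 2
  if (object$shape == "cone") {
    s <- sqrt(dx^2 + dy^2) - half          # signed distance to disc edge
    s[s < 0] <- 0
  } else {
    ox <- pmax(abs(dx) - half, 0)          # distance outside the square
    oy <- pmax(abs(dy) - half, 0)
    s <- sqrt(ox^2 + oy^2)
  }
  exp(-s^2 / (2 * blur_mm^2))
}

#' Static per-taxel pressure pattern of an indented object
#'
#' Minimal contact-mechanics model. Per-taxel pressure is
#' `adc_gain * depth_mm * feature_size_mm^(-1/2) * coverage`, where
#' `coverage` is the object's contact cross-section — a disc of diameter
#' `feature_size_mm` for cones, a square of that side for cubes, smoothed at
#' the edge by a Gaussian kernel of width `blur_mm` standing in for the
#' force-dispersing silicone layer — integrated over each taxel's cell. The
#' `feature_size_mm^(-1/2)` factor models Hertz-like contact-stress
#' concentration at a fixed indentation depth: sharp indentors press on a
#' small area at high local stress, blunt ones on a large area at lower
#' stress. Consequences, over the default object set at fixed depth: peak
#' per-taxel pressure strictly decreases with feature size, the number of
#' active taxels strictly increases, and the summed (total) pressure grows
#' with contact area — all proportional to depth.
#'
#' @param object a [stimulus_object()].
#' @param depth_mm indentation depth (mm), must be `>= 0`; 0 gives an all-zero
#'   matrix.
#' @param grid a [grid_spec()].
#' @param center_offset_mm length-2 numeric `(x, y)` offset of the contact
#'   centre from the grid centre, in mm.
#' @param adc_gain contact-stress gain in ADC counts per mm of depth at 1 mm
#'   feature size (default 750: the sharpest default objects at 1.4 mm depth
#'   drive their peak taxel near the 10-bit full scale).
#' @param blur_mm Gaussian edge-smoothing width of the silicone dispersion
#'   layer (default 1.4 mm, half the taxel pitch).
#' @param n_sub per-axis subsampling points used to integrate the footprint
#'   over each taxel cell.
#' @return A `rows x cols` numeric matrix of (unquantised) pressure values in
#'   ADC-count units. If the footprint misses the grid entirely, an all-zero
#'   matrix with a warning.
#' @examples
#' fp <- contact_footprint(stimulus_object("cone", 1), 1.4, grid_spec())
#' round(max(fp))  # near full scale
#' @export
contact_footprint <- function(object, depth_mm, grid = grid_spec(),
                              center_offset_mm = c(0, 0),
                              adc_gain = 750, blur_mm = 1.4, n_sub = 7L) {
  stopifnot(inherits(object, "stimulus_object"), inherits(grid, "grid_spec"))
  if (!is.numeric(depth_mm) || length(depth_mm) != 1L || depth_mm < 0)
    stop("depth_mm must be a single non-negative number")
  if (depth_mm == 0)
    return(matrix(0, grid$rows, grid$cols))
  cov <- footprint_coverage(object, grid, center_offset_mm, blur_mm, n_sub)
  if (sum(cov) <= .Machine$double.eps) {
    warning("contact footprint lies entirely off the sensor grid")
    return(matrix(0, grid$rows, grid$cols))
  }
  (adc_gain * depth_mm / sqrt(object$feature_size_mm)) * cov
}

# Unnormalised per-taxel footprint coverage (cell-integrated membership).
footprint_coverage <- function(object, grid, center_offset_mm, blur_mm, n_sub) {
  ctr <- taxel_centers(grid)
  h <- grid$pitch_mm / 2
  # midpoint rule inside each cell
  sub <- (seq_len(n_sub) - 0.5) / n_sub * grid$pitch_mm - h
  cov <- matrix(0, grid$rows, grid$cols)
  for (r in seq_len(grid$rows)) {
    for (cc in seq_len(grid$cols)) {
      px <- ctr$x[cc] + sub - center_offset_mm[1]
      py <- ctr$y[r] + sub - center_offset_mm[2]
      w <- footprint_membership(object, outer(rep(1, n_sub), px),
                                outer(py, rep(1, n_sub)), blur_mm)
      cov[r, cc] <- mean(w)
    }
  }
  cov
}

#' Generate one synthetic indentation trial
#'
#' Emulates a single robotic touch: the object is pressed into the sensor
#' following the trapezoidal depth profile, sampled at 1 ms. Trial-to-trial
#' variability comes from (i) additive Gaussian sensor noise per frame and
#' taxel and (ii) one random contact-centre jitter per trial, uniform in
#' `[-jitter_mm, jitter_mm]` on both axes. Values are clipped and quantised
#' to the ADC range. Identical `(object, profile, seed)` give bit-identical
#' frames.
#'
#' @param object a [stimulus_object()].
#' @param profile an [indentation_profile()].
#' @param grid a [grid_spec()].
#' @param noise_sd sensor noise standard deviation in ADC counts per frame
#'   and taxel (default 0.5, i.e. sub-LSB effective ADC noise). At 1 kHz
#'   sampling the white noise floor must stay below about one count:
#'   anything larger would be amplified by the RA-I derivative gain
#'   (`k3 = 128`) into sustained firing during the hold phase, which the
#'   rapidly adapting afferents do not exhibit. Trial-to-trial variability
#'   is dominated by the contact-centre jitter.
#' @param jitter_mm half-range of the uniform contact-centre jitter (mm).
#' @param seed integer seed for this trial's noise and jitter.
#' @param adc_gain,blur_mm contact-model constants, see [contact_footprint()].
#' @return A `tactile_trial` object: list with `object`, `profile`, `grid`,
#'   `frames` (a `(total_ms + 1) x (rows * cols)` integer matrix, one row per
#'   ms, taxels in row-major order), `center_offset_mm`, `seed`, `fault`
#'   (`NULL` until faults are injected).
#' @examples
#' tr <- generate_trial(stimulus_object("cube", 9), seed = 1)
#' dim(tr$frames)
#' @export
generate_trial <- function(object, profile = indentation_profile(),
                           grid = grid_spec(), noise_sd = 0.5,
                           jitter_mm = 1, seed = 1L,
                           adc_gain = 750, blur_mm = 1.4) {
  stopifnot(inherits(object, "stimulus_object"),
            inherits(profile, "indentation_profile"),
            noise_sd >= 0, jitter_mm >= 0)
  set.seed(seed)
  offset <- if (jitter_mm > 0) runif(2, -jitter_mm, jitter_mm) else c(0, 0)
  d <- depth_series(profile)
  cov <- footprint_coverage(object, grid, offset, blur_mm, n_sub = 7L)
  # row-major taxel order; pressure per mm of depth
  unit <- (adc_gain / sqrt(object$feature_size_mm)) * as.vector(t(cov))
  frames <- outer(d, unit)
  if (noise_sd > 0)
    frames <- frames + matrix(rnorm(length(frames), sd = noise_sd),
                              nrow = nrow(frames))
  frames[] <- pmin(pmax(round(frames), 0L), grid$adc_max)
  storage.mode(frames) <- "integer"
  structure(
    list(object = object, profile = profile, grid = grid, frames = frames,
         center_offset_mm = offset, seed = as.integer(seed), fault = NULL),
    class = "tactile_trial")
}

#' @export
print.tactile_trial <- function(x, ...) {
  cat(sprintf("<tactile_trial> %s, %d frames (%d taxels), seed %d%s\n",
              x$object$label, nrow(x$frames), ncol(x$frames), x$seed,
              if (is.null(x$fault)) "" else ", faulted"))
  invisible(x)
}

#' Generate a full synthetic dataset of repeated touches
#'
#' Default study conditions: the eight-object benchmark set touched 10 times
#' each (80 trials), trapezoidal 250/2000/250 ms indentation at 1.4 mm depth.
#' Per-trial seeds are derived deterministically from `master_seed` so the
#' whole dataset is reproducible from one integer.
#'
#' @param objects list of [stimulus_object()]s.
#' @param n_trials_per_object trials per object (default 10).
#' @param profile,grid,noise_sd,jitter_mm,adc_gain,blur_mm per-trial settings,
#'   see [generate_trial()].
#' @param master_seed integer master seed.
#' @return A `tactile_dataset`: list with `trials` (list of `tactile_trial`),
#'   `labels` (character vector, one per trial), `objects`, and `master_seed`.
#' @examples
#' ds <- generate_dataset(n_trials_per_object = 1, master_seed = 7)
#' length(ds$trials)
#' @export
generate_dataset <- function(objects = default_objects(),
                             n_trials_per_object = 10L,
                             profile = indentation_profile(),
                             grid = grid_spec(), noise_sd = 0.5,
                             jitter_mm = 1, master_seed = 1L,
                             adc_gain = 750, blur_mm = 1.4) {
  if (length(objects) == 0) stop("objects must be a non-empty list")
  stopifnot(n_trials_per_object >= 1)
  trials <- vector("list", length(objects) * n_trials_per_object)
  labels <- character(length(trials))
  i <- 0L
  for (oi in seq_along(objects)) {
    for (ti in seq_len(n_trials_per_object)) {
      i <- i + 1L
      trials[[i]] <- generate_trial(
        objects[[oi]], profile, grid, noise_sd, jitter_mm,
        seed = derive_seed(master_seed, stream = 1L, index = i),
        adc_gain = adc_gain, blur_mm = blur_mm)
      labels[i] <- objects[[oi]]$label
    }
  }
  structure(
    list(trials = trials, labels = labels, objects = objects,
         master_seed = as.integer(master_seed)),
    class = "tactile_dataset")
}

#' @export
print.tactile_dataset <- function(x, ...) {
  cat(sprintf("<tactile_dataset> %d trials, %d objects, master seed %d\n",
              length(x$trials), length(x$objects), x$master_seed))
  invisible(x)
}
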