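#' Experiment configuration
#'
#' Bundles every tunable of the pipeline — stimulus, innervation, encoder,
#' coding, evaluation and fault settings — plus one master seed, so a whole
#' experiment is reproducible from the config alone. The master seed fans
#' out to the individual random streams (trial noise/jitter, innervation,
#' nociceptor gains, CV splits, fault subsets) via [derive_seed()].
#'
#' @param objects stimulus set (default the eight-object benchmark).
#' @param n_trials_per_object trials per object (default 10).
#' @param depth_mm hold-phase indentation depth (default 1.4 mm).
#' @param onset_ms,hold_ms,offset_ms trapezoid phases (defaults 250/2000/250).
#' @param grid a [grid_spec()].
#' @param noise_sd,jitter_mm trial variability, see [generate_trial()].
#' @param n_sa,n_ra,mean_taxels innervation settings.
#' @param noc_threshold_adc,n_noc,noc_gain_jitter nociceptor settings.
#' @param q Victor-Purpura shift cost (1/ms).
#' @param windows_ms cumulative spike-count windows (ms) swept in the window
#'   and innervation experiments.
#' @param count_window_ms default window for single-window analyses.
#' @param k_neighbors,n_folds evaluation settings.
#' @param fault_fractions fault sweep grid.
#' @param n_fault_seeds fault subsets per fraction.
#' @param fixed_point run the encoder in Q13.18 arithmetic.
#' @param master_seed integer master seed.
#' @param out_dir optional directory; when set, `run_*` functions write
#'   their result tables there as CSV.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(objects = default_objects(),
                              n_trials_per_object = 10L,
                              depth_mm = 1.4, onset_ms = 250L,
                              hold_ms = 2000L, offset_ms = 250L,
                              grid = grid_spec(), noise_sd = 0.5,
                              jitter_mm = 1, n_sa = 6L, n_ra = 12L,
                              mean_taxels = 3,
                              noc_threshold_adc = 102L, n_noc = 5L,
                              noc_gain_jitter = 0.05, q = 0.05,
                              windows_ms = c(50, 100, 200, 300, 500, 1000,
                                             1500, 2500),
                              count_window_ms = c(0, 500),
                              k_neighbors = 5L, n_folds = 5L,
                              fault_fractions = seq(0, 0.5, by = 0.1),
                              n_fault_seeds = 10L, fixed_point = FALSE,
                              master_seed = 1L, out_dir = NULL) {
  structure(as.list(environment()), class = "experiment_config")
}

# Instantiate the standard pipeline pieces of a config.
config_profile <- function(config)
  indentation_profile(config$onset_ms, config$hold_ms, config$offset_ms,
                      config$depth_mm)

config_dataset <- function(config)
  generate_dataset(config$objects, config$n_trials_per_object,
                   config_profile(config), config$grid, config$noise_sd,
                   config$jitter_mm, master_seed = config$master_seed)

config_map <- function(config, mean_taxels = config$mean_taxels)
  build_innervation(config$n_sa, config$n_ra, mean_taxels, config$grid,
                    seed = derive_seed(config$master_seed, stream = 2L))

config_noc <- function(config)
  nociceptor_spec(config$noc_threshold_adc, config$n_noc,
                  config$noc_gain_jitter,
                  seed = derive_seed(config$master_seed, stream = 3L))

config_eval <- function(config)
  eval_config(config$k_neighbors, config$n_folds,
              seed = derive_seed(config$master_seed, stream = 4L))

# Mean firing rate (Hz) over the full trial duration, per channel kind.
mean_rate_by_kind <- function(responses, kinds = NULL) {
  layout <- vapply(responses[[1]]$trains, `[[`, "", "kind")
  if (is.null(kinds)) kinds <- unique(layout)
  dur_s <- responses[[1]]$duration_ms / 1000
  rates <- vapply(responses, function(r)
    vapply(r$trains, function(tr) length(tr$times_ms), numeric(1)) / dur_s,
    numeric(length(layout)))
  vapply(kinds, function(k) mean(rates[layout == k, , drop = FALSE]),
         numeric(1))
}

maybe_write <- function(df, config, name) {
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_table(df, file.path(config$out_dir, paste0(name, ".csv")))
  }
  df
}

#' Innervation sweep: receptive-field size vs classification and firing rate
#'
#' Re-runs the rate-code pipeline with 1, 3, 7 and 9 taxels innervated on
#' average per afferent, over the configured cumulative count windows, and
#' records the mean SA-I/RA-I firing rate per receptive-field size.
#'
#' @param config an [experiment_config()].
#' @param mean_taxels_grid receptive-field sizes to sweep.
#' @return Data frame: `mean_taxels`, `window_ms`, `accuracy`,
#'   `mean_rate_hz` (mean over SA-I and RA-I channels, full trial),
#'   `master_seed`.
#' @export
run_innervation_sweep <- function(config = experiment_config(),
                                  mean_taxels_grid = c(1, 3, 7, 9)) {
  dataset <- config_dataset(config)
  noc <- config_noc(config)
  ev <- config_eval(config)
  res <- lapply(mean_taxels_grid, function(mt) {
    map <- build_innervation(config$n_sa, config$n_ra, mt, config$grid,
                             seed = derive_seed(config$master_seed,
                                                stream = 2L, index = mt))
    responses <- encode_dataset(dataset, map, noc,
                                fixed_point = config$fixed_point)
    rate <- mean(mean_rate_by_kind(responses, c("SA1", "RA1")))
    do.call(rbind, lapply(config$windows_ms, function(w) {
      acc <- knn_rate(spike_count_features(responses, c(0, w)),
                      dataset$labels, ev)$accuracy
      data.frame(mean_taxels = mt, window_ms = w, accuracy = acc,
                 mean_rate_hz = rate, master_seed = config$master_seed)
    }))
  })
  maybe_write(do.call(rbind, res), config, "innervation_sweep")
}

#' Window sweep: rate vs temporal decoding over cumulative windows
#'
#' Classifies the full population with the spike-count (rate) and
#' Victor-Purpura (temporal) decoders over growing analysis windows, for
#' all objects and for each object group separately.
#'
#' @param config an [experiment_config()].
#' @return Data frame: `scope` (`all`, `group_I`, `group_II`), `window_ms`,
#'   `coding` (`rate`/`temporal`), `accuracy`, `master_seed`.
#' @export
run_window_sweep <- function(config = experiment_config()) {
  dataset <- config_dataset(config)
  map <- config_map(config)
  noc <- config_noc(config)
  ev <- config_eval(config)
  responses <- encode_dataset(dataset, map, noc,
                              fixed_point = config$fixed_point)
  groups <- vapply(dataset$trials, function(tr) tr$object$group, "")
  scopes <- list(all = seq_along(responses),
                 group_I = which(groups == "I"),
                 group_II = which(groups == "II"))
  res <- lapply(names(scopes), function(sc) {
    idx <- scopes[[sc]]
    labs <- dataset$labels[idx]
    do.call(rbind, lapply(config$windows_ms, function(w) {
      counts <- spike_count_features(responses[idx], c(0, w))
      acc_rate <- knn_rate(counts, labs, ev)$accuracy
      D <- population_vp_matrix(responses[idx], q = config$q,
                                window_ms = c(0, w))
      acc_temp <- knn_temporal(D, labs, ev)$accuracy
      data.frame(scope = sc, window_ms = w,
                 coding = c("rate", "temporal"),
                 accuracy = c(acc_rate, acc_temp),
                 master_seed = config$master_seed)
    }))
  })
  maybe_write(do.call(rbind, res), config, "window_sweep")
}

#' Contribution analysis: afferent classes and their synergies
#'
#' Evaluates every afferent-class subpopulation (NOC, SA1, RA1, the three
#' pairs, and the full population) per object group with the rate decoder,
#' and tabulates each channel kind's mean firing rate per feature size.
#'
#' @param config an [experiment_config()].
#' @return List of two data frames: `accuracy` (`group`, `subset`,
#'   `accuracy`) and `firing_rate` (`group`, `kind`, `feature_size_mm`,
#'   `mean_rate_hz`).
#' @export
run_contribution <- function(config = experiment_config()) {
  dataset <- config_dataset(config)
  map <- config_map(config)
  noc <- config_noc(config)
  ev <- config_eval(config)
  responses <- encode_dataset(dataset, map, noc,
                              fixed_point = config$fixed_point)
  groups <- vapply(dataset$trials, function(tr) tr$object$group, "")
  sizes <- vapply(dataset$trials, function(tr) tr$object$feature_size_mm, 0)
  subsets <- list(NOC = "NOC", SA1 = "SA1", RA1 = "RA1",
                  `NOC+SA1` = c("NOC", "SA1"), `NOC+RA1` = c("NOC", "RA1"),
                  `SA1+RA1` = c("SA1", "RA1"),
                  all = c("NOC", "SA1", "RA1"))
  acc <- do.call(rbind, lapply(c("I", "II"), function(g) {
    idx <- which(groups == g)
    do.call(rbind, lapply(names(subsets), function(ss) {
      r <- subpopulation_eval(responses[idx], dataset$labels[idx],
                              subsets[[ss]], config$count_window_ms, ev)
      data.frame(group = g, subset = ss, accuracy = r$accuracy,
                 master_seed = config$master_seed)
    }))
  }))
  fr <- do.call(rbind, lapply(c("I", "II"), function(g) {
    do.call(rbind, lapply(sort(unique(sizes)), function(s) {
      idx <- which(groups == g & sizes == s)
      rates <- mean_rate_by_kind(responses[idx])
      data.frame(group = g, kind = names(rates), feature_size_mm = s,
                 mean_rate_hz = as.numeric(rates),
                 master_seed = config$master_seed)
    }))
  }))
  maybe_write(acc, config, "contribution_accuracy")
  maybe_write(fr, config, "contribution_firing_rate")
  list(accuracy = acc, firing_rate = fr)
}

#' Fault sweep experiment
#'
#' Delegates to [robustness_sweep()] for damaged taxels, damaged channels,
#' and both combined, over the configured fault-fraction grid.
#'
#' @param config an [experiment_config()].
#' @param modes fault modes to run.
#' @return Data frame with one row per (mode, fraction).
#' @export
run_fault_sweep <- function(config = experiment_config(),
                            modes = c("taxel", "channel", "both")) {
  dataset <- config_dataset(config)
  map <- config_map(config)
  noc <- config_noc(config)
  ev <- config_eval(config)
  res <- do.call(rbind, lapply(modes, function(m)
    robustness_sweep(dataset, map, noc, config$fault_fractions, mode = m,
                     n_seeds = config$n_fault_seeds, config = ev,
                     window_ms = config$count_window_ms,
                     fault_master_seed = derive_seed(config$master_seed,
                                                     stream = 5L))))
  res$master_seed <- config$master_seed
  maybe_write(res, config, "fault_sweep")
}

#' Raster plot of a population response
#'
#' One lane per channel, grouped and coloured by kind: nociceptors (red)
#' at the bottom, then SA-I (orange) and RA-I (blue).
#'
#' @param x a `population_response`.
#' @param main plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.population_response <- function(x, main = "Population response", ...) {
  cols <- c(NOC = "#d62728", SA1 = "#ff7f0e", RA1 = "#1f77b4")
  n <- length(x$trains)
  graphics::plot(NULL, xlim = c(0, x$duration_ms), ylim = c(0.5, n + 0.5),
                 xlab = "time (ms)", ylab = "channel", yaxs = "i",
                 main = main, ...)
  for (i in seq_len(n)) {
    tr <- x$trains[[i]]
    if (length(tr$times_ms) > 0)
      graphics::segments(tr$times_ms, i - 0.4, tr$times_ms, i + 0.4,
                         col = cols[[tr$kind]], lwd = 1)
  }
  invisible(x)
}

#' Export a raster plot to an image file
#'
#' @param response a `population_response`.
#' @param path output file; format chosen by extension (`.png` or `.svg`).
#' @param width,height device size in pixels (png) or inches (svg).
#' @param ... passed to [plot.population_response()].
#' @return `path`, invisibly.
#' @export
export_raster <- function(response, path, width = 900, height = 600, ...) {
  if (grepl("\\.svg$", path)) grDevices::svg(path, width = width / 100,
                                             height = height / 100)
  else grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot(response, ...)
  invisible(path)
}
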