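#' Fault specification for taxels and channels
#'
#' Describes persistent damage: a seeded random subset of taxels whose
#' output is forced to zero at the sensor interface (before innervation and
#' before the nociceptor NoT/MCV statistic), and/or a seeded random subset
#' of afferent/nociceptor channels that are permanently silenced after
#' encoding. Realised counts are `round-half-up(fraction * population
#' size)`. The same damaged subsets apply to every trial of one evaluated
#' condition.
#'
#' @param taxel_fraction,channel_fraction fractions in `[0, 1]`.
#' @param seed integer seed; taxel and channel subsets are drawn from
#'   independent streams derived from it.
#' @return A `fault_spec` object.
#' @export
fault_spec <- function(taxel_fraction = 0, channel_fraction = 0, seed = 1L) {
  stopifnot(taxel_fraction >= 0, taxel_fraction <= 1,
            channel_fraction >= 0, channel_fraction <= 1)
  structure(list(taxel_fraction = taxel_fraction,
                 channel_fraction = channel_fraction,
                 seed = as.integer(seed)),
            class = "fault_spec")
}

round_half_up <- function(x) floor(x + 0.5)

# Deterministic faulty subsets for a given spec and population size.
faulty_taxels <- function(spec, n_taxels) {
  n <- round_half_up(spec$taxel_fraction * n_taxels)
  if (n == 0) return(integer(0))
  set.seed(derive_seed(spec$seed, stream = 51L))
  sort(sample.int(n_taxels, n))
}

faulty_channels <- function(spec, n_channels) {
  n <- round_half_up(spec$channel_fraction * n_channels)
  if (n == 0) return(integer(0))
  set.seed(derive_seed(spec$seed, stream = 52L))
  sort(sample.int(n_channels, n))
}

#' Zero out damaged taxels in a trial
#'
#' The seeded subset of taxels has its output forced to 0 in every frame,
#' emulating interface-level sensor damage. Because the subset depends only
#' on the spec, the same taxels are damaged in every trial it is applied to.
#'
#' @param trial a `tactile_trial`.
#' @param spec a [fault_spec()].
#' @return The trial with zeroed taxel columns and the spec (plus realised
#'   subset) recorded in `$fault`.
#' @export
apply_taxel_faults <- function(trial, spec) {
  stopifnot(inherits(trial, "tactile_trial"), inherits(spec, "fault_spec"))
  idx <- faulty_taxels(spec, ncol(trial$frames))
  if (length(idx) > 0) trial$frames[, idx] <- 0L
  trial$fault <- c(spec, list(taxel_idx = idx))
  trial
}

#' Silence damaged afferent/nociceptor channels
#'
#' The seeded subset of channels is replaced by empty spike trains
#' (deactivated neurons cannot fire).
#'
#' @param response a `population_response`.
#' @param spec a [fault_spec()].
#' @return The response with silenced channels; the realised subset is
#'   attached as attribute `silenced`.
#' @export
apply_channel_faults <- function(response, spec) {
  stopifnot(inherits(response, "population_response"),
            inherits(spec, "fault_spec"))
  idx <- faulty_channels(spec, length(response$trains))
  for (ch in idx) response$trains[[ch]]$times_ms <- integer(0)
  attr(response, "silenced") <- idx
  response
}

#' Classification robustness under increasing fault levels
#'
#' For each fault fraction and each fault seed: damage the system (zero
#' taxels and re-encode, silence channels post-encoding, or both), extract
#' spike-count features and run the rate-code classifier. Fraction 0
#' reproduces the unfaulted accuracy.
#'
#' @param dataset a `tactile_dataset`.
#' @param map an `innervation_map`.
#' @param noc a [nociceptor_spec()].
#' @param fault_fractions ascending fractions to sweep
#'   (default `0, 0.1, ..., 0.5`).
#' @param mode `"taxel"`, `"channel"` or `"both"`; in `"both"` the same
#'   fraction is applied to taxels and channels.
#' @param n_seeds random fault subsets averaged per fraction (default 10).
#' @param config an [eval_config()].
#' @param window_ms spike-count window.
#' @param fault_master_seed master seed from which the per-replicate fault
#'   seeds are derived.
#' @return A data frame with one row per fraction: `fraction`, `mode`,
#'   `mean_accuracy`, `sd_accuracy`, `n_seeds`.
#' @export
robustness_sweep <- function(dataset, map, noc = nociceptor_spec(),
                             fault_fractions = seq(0, 0.5, by = 0.1),
                             mode = c("taxel", "channel", "both"),
                             n_seeds = 10L, config = eval_config(),
                             window_ms = c(0, 500),
                             fault_master_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(!is.unsorted(fault_fractions))
  base_responses <- if (mode == "channel")
    encode_dataset(dataset, map, noc) else NULL
  res <- lapply(fault_fractions, function(fr) {
    accs <- vapply(seq_len(n_seeds), function(s) {
      spec <- fault_spec(
        taxel_fraction = if (mode != "channel") fr else 0,
        channel_fraction = if (mode != "taxel") fr else 0,
        seed = derive_seed(fault_master_seed, stream = 53L, index = s))
      responses <- if (mode == "channel") base_responses
      else {
        faulted <- dataset
        faulted$trials <- lapply(dataset$trials, apply_taxel_faults, spec)
        encode_dataset(faulted, map, noc)
      }
      if (mode != "taxel")
        responses <- lapply(responses, apply_channel_faults, spec)
      counts <- spike_count_features(responses, window_ms)
      knn_rate(counts, dataset$labels, config)$accuracy
    }, numeric(1))
    data.frame(fraction = fr, mode = mode, mean_accuracy = mean(accs),
               sd_accuracy = if (n_seeds > 1) sd(accs) else NA_real_,
               n_seeds = n_seeds)
  })
  do.call(rbind, res)
}
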