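#' Write a dataset to a directory
#'
#' One gzip-compressed CSV per trial (`t_ms` plus one column per taxel in
#' row-major order) and a YAML manifest recording the object labels,
#' per-trial seeds, indentation profile and grid, so a dataset directory is
#' self-describing.
#'
#' @param dataset a `tactile_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "tactile_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    master_seed = dataset$master_seed,
    n_trials = length(dataset$trials),
    profile = unclass(dataset$trials[[1]]$profile),
    grid = unclass(dataset$trials[[1]]$grid),
    trials = lapply(seq_along(dataset$trials), function(i) {
      tr <- dataset$trials[[i]]
      list(file = sprintf("trial_%03d.csv.gz", i), label = tr$object$label,
           shape = tr$object$shape,
           feature_size_mm = tr$object$feature_size_mm,
           seed = tr$seed)
    }))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  for (i in seq_along(dataset$trials)) {
    tr <- dataset$trials[[i]]
    df <- data.frame(t_ms = 0:(nrow(tr$frames) - 1L), tr$frames)
    names(df) <- c("t_ms", sprintf("v%02d", seq_len(ncol(tr$frames))))
    con <- gzfile(file.path(dir, sprintf("trial_%03d.csv.gz", i)), "w")
    write.csv(df, con, row.names = FALSE)
    close(con)
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.yaml`.
#' @return A `tactile_dataset`.
#' @export
read_dataset <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  profile <- indentation_profile(manifest$profile$onset_ms,
                                 manifest$profile$hold_ms,
                                 manifest$profile$offset_ms,
                                 manifest$profile$depth_mm)
  grid <- grid_spec(manifest$grid$rows, manifest$grid$cols,
                    manifest$grid$pitch_mm, manifest$grid$adc_bits)
  trials <- lapply(manifest$trials, function(m) {
    df <- read.csv(gzfile(file.path(dir, m$file)))
    frames <- as.matrix(df[, -1, drop = FALSE])
    dimnames(frames) <- NULL
    storage.mode(frames) <- "integer"
    structure(
      list(object = stimulus_object(m$shape, m$feature_size_mm),
           profile = profile, grid = grid, frames = frames,
           center_offset_mm = NA_real_, seed = m$seed, fault = NULL),
      class = "tactile_trial")
  })
  structure(
    list(trials = trials,
         labels = vapply(manifest$trials, `[[`, "", "label"),
         objects = unique(lapply(trials, `[[`, "object")),
         master_seed = manifest$master_seed),
    class = "tactile_dataset")
}

#' Serialize spike trains
#'
#' `write_spike_trains()` writes one tabular CSV per response
#' (`channel_id, kind, spike_time_ms`; silent channels appear with an `NA`
#' spike time so the channel layout is preserved). `write_event_stream()`
#' writes the plain event-stream text format: one line per spike,
#' `"<time_ms> <channel_id>"`, in time order.
#'
#' @param response a `population_response`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(response, path) {
  stopifnot(inherits(response, "population_response"))
  rows <- lapply(response$trains, function(tr) {
    if (length(tr$times_ms) == 0)
      data.frame(channel_id = tr$channel_id, kind = tr$kind,
                 spike_time_ms = NA_integer_)
    else
      data.frame(channel_id = tr$channel_id, kind = tr$kind,
                 spike_time_ms = tr$times_ms)
  })
  df <- do.call(rbind, rows)
  attr(df, "duration_ms") <- response$duration_ms
  con <- file(path, "w")
  writeLines(sprintf("# duration_ms=%d", response$duration_ms), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  first <- readLines(path, n = 1L)
  duration <- as.integer(sub("# duration_ms=", "", first, fixed = TRUE))
  df <- read.csv(path, comment.char = "#")
  ids <- unique(df$channel_id)
  trains <- lapply(ids, function(id) {
    sub <- df[df$channel_id == id, ]
    spike_train(id, sub$kind[1], sort(sub$spike_time_ms[!is.na(sub$spike_time_ms)]))
  })
  structure(list(trains = trains[order(ids)], duration_ms = duration),
            class = "population_response")
}

#' @rdname write_spike_trains
#' @export
write_event_stream <- function(response, path) {
  stopifnot(inherits(response, "population_response"))
  ev <- do.call(rbind, lapply(response$trains, function(tr) {
    if (length(tr$times_ms) == 0) return(NULL)
    cbind(tr$times_ms, tr$channel_id)
  }))
  con <- file(path, "w")
  if (!is.null(ev)) {
    ev <- ev[order(ev[, 1], ev[, 2]), , drop = FALSE]
    writeLines(sprintf("%d %d", ev[, 1], ev[, 2]), con)
  }
  close(con)
  invisible(path)
}

# Result tables are written with numeric columns fixed to 6 decimals so a
# rerun with the same config and master seed is byte-identical.
write_result_table <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.6f", out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
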