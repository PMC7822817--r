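#' Windowed spike-count features (rate code)
#'
#' One row per trial, one column per channel, each entry the number of
#' spikes falling in `(window_ms[1], window_ms[2]]`, with windows measured
#' from contact onset (t = 0, the start of the trial). Cumulative windows
#' `(0, w]` therefore give counts that are non-decreasing in `w`.
#'
#' @param responses list of `population_response` (equal channel layout).
#' @param window_ms numeric length-2 interval `(start, end]` in ms with
#'   `start <= end`; a zero-length window yields all-zero counts.
#' @return Integer matrix `n_trials x n_channels` with the channel kinds as
#'   the `"kinds"` attribute.
#' @examples
#' \dontrun{counts <- spike_count_features(responses, c(0, 500))}
#' @export
spike_count_features <- function(responses, window_ms = c(0, 500)) {
  stopifnot(length(responses) >= 1, length(window_ms) == 2)
  if (window_ms[2] < window_ms[1]) stop("window end must be >= window start")
  kinds <- vapply(responses[[1]]$trains, `[[`, "", "kind")
  x <- t(vapply(responses, function(r) {
    if (length(r$trains) != length(kinds))
      stop("responses have differing channel layouts")
    vapply(r$trains, function(tr) {
      sum(tr$times_ms > window_ms[1] & tr$times_ms <= window_ms[2])
    }, integer(1))
  }, integer(length(kinds))))
  attr(x, "kinds") <- kinds
  x
}

#' Victor-Purpura distance between two spike trains
#'
#' Minimal cost to transform one train into the other, where deleting or
#' inserting a spike costs 1 and shifting a spike by `dt` costs `q * |dt|`.
#' Computed exactly by dynamic programming over the two sorted trains.
#' `q = 0` reduces to the absolute spike-count difference (pure rate
#' metric); large `q` approaches `n1 + n2 - 2 * (coincident spikes)`
#' (coincidence metric). The distance is a metric for `q >= 0`.
#'
#' @param t1,t2 numeric vectors of sorted spike times (ms), or `spike_train`
#'   objects.
#' @param q shift-cost parameter in 1/ms (default 0.05, a 2/q = 40 ms
#'   insert-vs-shift crossover).
#' @return A single non-negative number.
#' @examples
#' vp_distance(c(10, 50), c(12, 50), q = 0.05)
#' @export
vp_distance <- function(t1, t2, q = 0.05) {
  if (inherits(t1, "spike_train")) t1 <- t1$times_ms
  if (inherits(t2, "spike_train")) t2 <- t2$times_ms
  if (is.unsorted(t1) || is.unsorted(t2))
    stop("spike trains must be sorted")
  if (q < 0) stop("q must be non-negative")
  cpp_vp_distance(as.numeric(t1), as.numeric(t2), q)
}

# Restrict a spike train to a (start, end] window.
window_times <- function(times_ms, window_ms) {
  times_ms[times_ms > window_ms[1] & times_ms <= window_ms[2]]
}

#' Population-level Victor-Purpura distance matrix (temporal code)
#'
#' Distance between two trials is the labelled-line sum over corresponding
#' channels of the per-channel VP distance on the windowed trains: channels
#' are physically distinct afferents, so no cross-channel spike exchange is
#' allowed.
#'
#' @param responses list of `population_response` with identical channel
#'   layouts.
#' @param q shift-cost parameter (1/ms).
#' @param window_ms analysis window `(start, end]` in ms.
#' @param channels optional integer vector restricting which channels enter
#'   the sum (default all).
#' @return An `n x n` symmetric numeric matrix with zero diagonal, carrying
#'   `q` as an attribute.
#' @export
population_vp_matrix <- function(responses, q = 0.05, window_ms = c(0, 500),
                                 channels = NULL) {
  n <- length(responses)
  stopifnot(n >= 1)
  layout <- vapply(responses[[1]]$trains, `[[`, "", "kind")
  if (is.null(channels)) channels <- seq_along(layout)
  wins <- lapply(responses, function(r) {
    if (length(r$trains) != length(layout))
      stop("responses have differing channel layouts")
    lapply(r$trains[channels],
           function(tr) as.numeric(window_times(tr$times_ms, window_ms)))
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- 0
      for (ch in seq_along(channels))
        d <- d + cpp_vp_distance(wins[[i]][[ch]], wins[[j]][[ch]], q)
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "q") <- q
  D
}

#' Fit a PCA projection on training features
#'
#' Mean-centred principal component analysis ([stats::prcomp()]) retaining
#' the top `n_components` axes. Held-out trials must be projected with a fit
#' obtained from training data only ([pca_project()]), never refit.
#'
#' @param features numeric matrix (trials x channels).
#' @param n_components number of components to keep (default 3).
#' @param scale standardise each channel to unit variance before rotation
#'   (correlation-scale PCA). Default `FALSE`; the rate-code classifier
#'   standardises so that a few high-variance noisy channels cannot crowd
#'   informative low-rate channels out of the leading components.
#' @return A `pca_fit` object (centre, per-channel scale and rotation).
#' @export
pca_fit <- function(features, n_components = 3L, scale = FALSE) {
  stopifnot(is.matrix(features), n_components >= 1,
            n_components <= ncol(features))
  if (all(apply(features, 2, function(col) length(unique(col)) == 1L)))
    warning("degenerate features: all rows identical")
  scl <- if (scale) {
    s <- apply(features, 2, sd)
    s[s == 0] <- 1  # constant channels carry no variance either way
    s
  } else rep(1, ncol(features))
  z <- sweep(features, 2, scl, `/`)
  p <- prcomp(z, center = TRUE, scale. = FALSE, rank. = n_components)
  structure(list(center = p$center, scale = scl, rotation = p$rotation,
                 sdev = p$sdev, n_components = as.integer(n_components)),
            class = "pca_fit")
}

#' @rdname pca_fit
#' @param fit a `pca_fit`.
#' @export
pca_project <- function(fit, features) {
  stopifnot(inherits(fit, "pca_fit"))
  sweep(sweep(features, 2, fit$scale, `/`), 2, fit$center) %*% fit$rotation
}

#' Reduce features to principal components
#'
#' Convenience wrapper: fits on `features` (treat them as the training
#' split) and returns the projected scores with the fit attached as an
#' attribute for projecting held-out data.
#'
#' @inheritParams pca_fit
#' @return `n x n_components` score matrix with attribute `fit`.
#' @export
pca_reduce <- function(features, n_components = 3L, scale = FALSE) {
  fit <- pca_fit(features, n_components, scale = scale)
  structure(pca_project(fit, features), fit = fit)
}
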