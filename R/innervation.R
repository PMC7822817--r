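#' Build random weighted receptive fields (innervation map)
#'
#' Each digital afferent innervates a small set of spatially nearby taxels
#' with random weights, forming its receptive field; fields of different
#' afferents overlap. Construction per afferent: (1) a field centre is drawn
#' uniformly over the grid; (2) the number of innervated taxels is drawn as
#' `1 + Poisson(mean_taxels - 1)`, capped at the neighbourhood size, so the
#' pre-cap mean equals `mean_taxels` and `mean_taxels = 1` gives exactly one
#' taxel; (3) that many taxels are sampled without replacement from the
#' centre's Chebyshev neighbourhood (radius 1, i.e. the 3x3 block, for
#' `mean_taxels <= 9`; radius 2 otherwise); (4) weights are i.i.d. uniform on
#' (0.25, 1]. Weights are not normalised per field, so afferent drive — and
#' with it firing rate — grows with receptive-field size.
#'
#' @param n_sa,n_ra number of SA-I and RA-I afferents (defaults 6 and 12).
#' @param mean_taxels target mean number of innervated taxels per afferent,
#'   in `[1, rows * cols]` (default 3).
#' @param grid a [grid_spec()].
#' @param seed integer seed; identical arguments and seed give an identical
#'   map.
#' @param radius Chebyshev neighbourhood radius override; `NULL` (default)
#'   applies the size rule above. Pass `max(rows, cols) - 1` to let fields
#'   span the whole grid.
#' @return An `innervation_map`: list with `fields` (length `n_sa + n_ra`;
#'   SA-I fields first, then RA-I; each a `receptive_field` with
#'   `afferent_kind`, a `rows x cols` non-negative `weights` matrix and
#'   `center = (row, col)`), plus `n_sa`, `n_ra`, `mean_taxels`, `seed`.
#' @examples
#' m <- build_innervation(seed = 1)
#' length(m$fields)
#' @export
build_innervation <- function(n_sa = 6L, n_ra = 12L, mean_taxels = 3,
                              grid = grid_spec(), seed = 1L, radius = NULL) {
  stopifnot(inherits(grid, "grid_spec"), n_sa >= 0, n_ra >= 0,
            n_sa + n_ra >= 1)
  if (mean_taxels < 1 || mean_taxels > grid$rows * grid$cols)
    stop("mean_taxels must lie in [1, rows * cols]")
  set.seed(seed)
  if (is.null(radius)) radius <- if (mean_taxels <= 9) 1L else 2L
  kinds <- c(rep("SA1", n_sa), rep("RA1", n_ra))
  fields <- lapply(seq_along(kinds), function(i) {
    center <- c(sample.int(grid$rows, 1L), sample.int(grid$cols, 1L))
    rr <- max(1L, center[1] - radius):min(grid$rows, center[1] + radius)
    cc <- max(1L, center[2] - radius):min(grid$cols, center[2] + radius)
    hood <- as.matrix(expand.grid(row = rr, col = cc))
    # saturate deterministically once the target mean fills the neighbourhood
    n_tax <- if (mean_taxels >= nrow(hood)) nrow(hood)
    else min(1L + rpois(1L, mean_taxels - 1), nrow(hood))
    picked <- hood[sample.int(nrow(hood), n_tax), , drop = FALSE]
    w <- matrix(0, grid$rows, grid$cols)
    w[picked] <- runif(n_tax, 0.25, 1)
    structure(list(afferent_kind = kinds[i], weights = w, center = center),
              class = "receptive_field")
  })
  structure(
    list(fields = fields, n_sa = as.integer(n_sa), n_ra = as.integer(n_ra),
         mean_taxels = mean_taxels, seed = as.integer(seed)),
    class = "innervation_map")
}

#' @export
print.innervation_map <- function(x, ...) {
  sizes <- vapply(x$fields, function(f) sum(f$weights > 0), integer(1))
  cat(sprintf(paste0("<innervation_map> %d SA-I + %d RA-I fields, ",
                     "mean %.2f taxels/field (target %g), seed %d\n"),
              x$n_sa, x$n_ra, mean(sizes), x$mean_taxels, x$seed))
  invisible(x)
}

#' Scalar drive of one afferent for one pressure frame
#'
#' The receptive-field weight matrix is multiplied element-by-element with
#' the taxel values and summed: `sum_ij w_ij * x_ij`. Linear in the frame and
#' non-negative for non-negative frames.
#'
#' @param field a `receptive_field` from [build_innervation()].
#' @param frame a `rows x cols` numeric matrix of taxel values (or a vector
#'   of length `rows * cols` in row-major taxel order).
#' @return A single non-negative number.
#' @export
afferent_drive <- function(field, frame) {
  stopifnot(inherits(field, "receptive_field"))
  if (is.matrix(frame)) {
    if (!all(dim(frame) == dim(field$weights)))
      stop("frame dimensions do not match receptive-field weights")
    sum(field$weights * frame)
  } else {
    if (length(frame) != length(field$weights))
      stop("frame length does not match receptive-field weights")
    sum(as.vector(t(field$weights)) * frame)
  }
}

#' Coverage statistics of an innervation map
#'
#' @param map an `innervation_map`.
#' @param grid the [grid_spec()] the map was built for.
#' @return List with `unused_taxel_count` (taxels with zero weight in every
#'   field) and `mean_overlap` (mean over taxels of the number of fields
#'   innervating it).
#' @export
coverage_stats <- function(map, grid = grid_spec()) {
  stopifnot(inherits(map, "innervation_map"))
  hits <- Reduce(`+`, lapply(map$fields, function(f) (f$weights > 0) * 1))
  list(unused_taxel_count = sum(hits == 0), mean_overlap = mean(hits))
}

# Stack field weights into a (rows*cols) x n_fields matrix (row-major taxel
# order), so per-frame drives for all afferents are one matrix product.
innervation_weight_matrix <- function(map) {
  do.call(cbind, lapply(map$fields, function(f) as.vector(t(f$weights))))
}
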