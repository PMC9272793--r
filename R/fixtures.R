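# Synthetic clustered point clouds with controlled spatial overlap, for
# tests, demos and benchmarking. Blobs are isotropic Gaussians: the 2-D
# analogue of a compact cell cluster in a UMAP embedding.

#' Sample Gaussian blobs as a clustered point table
#'
#' Draws isotropic Gaussian point clouds, one per specification row, and
#' stacks them into the standard point-table format.
#'
#' @param specs Data frame with one row per blob and columns `x`, `y`
#'   (center), `spread` (per-axis standard deviation, > 0), `n` (point
#'   count, >= 1) and `cluster` (label).
#' @param seed Integer seed; the output is deterministic given (specs, seed).
#' @return A tibble with columns `x`, `y`, `cluster`, rows in spec order.
#' @examples
#' make_blobs(data.frame(x = c(0, 4), y = 0, spread = 1, n = 100,
#'                       cluster = c("a", "b")), seed = 1)
#' @export
make_blobs <- function(specs, seed) {
  if (!is.data.frame(specs) || nrow(specs) == 0 ||
      !all(c("x", "y", "spread", "n", "cluster") %in% names(specs))) {
    stop("`specs` must be a data frame with columns x, y, spread, n, cluster",
         call. = FALSE)
  }
  if (any(specs$spread <= 0) || any(specs$n < 1)) {
    stop("blob `spread` must be positive and `n` at least 1", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required for reproducibility",
                          call. = FALSE)
  set.seed(as.integer(seed))
  out <- purrr::map(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    tibble::tibble(
      x = stats::rnorm(s$n, s$x, s$spread),
      y = stats::rnorm(s$n, s$y, s$spread),
      cluster = as.character(s$cluster)
    )
  })
  dplyr::bind_rows(out)
}

#' Two-blob fixtures with decreasing separation
#'
#' Builds a ladder of two-cluster point tables in which the center distance
#' between two equal blobs shrinks linearly from 10 spreads down to 0,
#' everything else held fixed. The same sampled point offsets are reused at
#' every level (only blob "b" is shifted), so levels differ purely in
#' separation — running the spatial-overlap pipeline down the ladder probes
#' how the Jaccard score responds to adjacency.
#'
#' @param n_levels Number of separation levels (>= 2); default 5.
#' @param n_points Points per blob; default 500.
#' @param spread Per-axis standard deviation of each blob; default 1.
#' @param seed Integer seed.
#' @return A named list of `n_levels` point tables (clusters `"a"` and
#'   `"b"`), ordered from the widest separation to coincident centers;
#'   names give the separation in spreads, and the numeric separations are
#'   attached as attribute `"separation"`.
#' @examples
#' ladder <- overlap_ladder(n_levels = 3, n_points = 50, seed = 1)
#' attr(ladder, "separation")
#' @export
overlap_ladder <- function(n_levels = 5, n_points = 500, spread = 1, seed) {
  if (!is.numeric(n_levels) || n_levels < 2) {
    stop("`n_levels` must be at least 2", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required for reproducibility",
                          call. = FALSE)
  set.seed(as.integer(seed))
  offsets_a <- matrix(stats::rnorm(2 * n_points, 0, spread), ncol = 2)
  offsets_b <- matrix(stats::rnorm(2 * n_points, 0, spread), ncol = 2)
  separations <- 10 * spread * (n_levels - seq_len(n_levels)) / (n_levels - 1)
  out <- purrr::map(separations, function(d) {
    tibble::tibble(
      x = c(offsets_a[, 1], offsets_b[, 1] + d),
      y = c(offsets_a[, 2], offsets_b[, 2]),
      cluster = rep(c("a", "b"), each = n_points)
    )
  })
  names(out) <- sprintf("sep=%g", separations / spread)
  attr(out, "separation") <- separations
  out
}
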