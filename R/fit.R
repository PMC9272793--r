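#' Spatially aware palette assignment for clustered 2-D data
#'
#' End-to-end optimization of a categorical color palette for a clustered
#' embedding (UMAP/t-SNE) or spatial map, so that spatially neighboring
#' clusters receive visually distinct colors. The pipeline: (1) fit a
#' kernel density per cluster on a shared `grid_size` x `grid_size` grid;
#' (2) derive each cluster's hot-grid-point cutoff as the `percentile`-th
#' percentile of its density field under one random permutation of the
#' cluster labels; (3) score spatial adjacency of every cluster pair by the
#' Jaccard overlap of their hot sets; (4) compute pairwise weighted RGB
#' distances between palette colors, optionally after color-vision-
#' deficiency simulation; (5) maximize the overlap-weighted sum of assigned
#' color distances over injective assignments by `n_restarts` random
#' restarts followed by up to `max_exchanges` greedy pairwise exchanges
#' with early stopping.
#'
#' One RNG stream, seeded by `seed`, drives the label permutation, the
#' restarts and the exchange proposals (in that order), so a single seed
#' fixes the entire run.
#'
#' @param points Data frame with numeric columns `x`, `y` and a `cluster`
#'   label column (see [read_points()] for file input).
#' @param palette Character vector of `#RRGGBB` colors, at least as many as
#'   there are clusters.
#' @param weights Three nonnegative RGB channel weights; default `c(1,1,1)`.
#' @param cvd Color-vision-deficiency simulation applied before computing
#'   color distances: `"none"` (default), `"protan"`, `"deutan"`, `"tritan"`.
#' @param cvd_severity CVD severity on \[0, 1\]; default 1.
#' @param grid_size Density grid points per axis; default 100.
#' @param percentile Hot-point cutoff percentile; default 95.
#' @param n_restarts Random restarts; default 1000.
#' @param max_exchanges Maximum exchange proposals; default 2000.
#' @param patience Consecutive rejected proposals before early stop;
#'   default 500.
#' @param seed Integer seed for the run; default 1.
#' @return An object of class `palette_fit` with, among others, `pal` (a
#'   named cluster -> hex vector ready for
#'   `ggplot2::scale_color_manual(values = pal)`), `mapping` (tibble of
#'   `cluster`, `color`), `score`, `restart_score`, `trace`, and the
#'   intermediate `overlap` ([cluster_overlap] object) and `distances`
#'   matrix. Supports `tidy()`, `glance()`, `autoplot()`.
#' @examples
#' pts <- make_blobs(data.frame(x = c(0, 1, 8), y = 0, spread = 1, n = 60,
#'                              cluster = c("a", "b", "c")), seed = 3)
#' fit <- optimize_palette(pts, c("#000000", "#808080", "#FFFFFF"),
#'                         n_restarts = 50, seed = 3)
#' fit$pal
#' @export
optimize_palette <- function(points, palette, weights = c(1, 1, 1),
                             cvd = "none", cvd_severity = 1,
                             grid_size = 100, percentile = 95,
                             n_restarts = 1000, max_exchanges = 2000,
                             patience = 500, seed = 1) {
  points <- with_stage("validating points", check_points(points))
  colors <- with_stage("parsing palette", {
    p <- if (is.data.frame(palette)) check_colors(palette) else
      parse_palette(palette)
    if (nrow(p) < length(cluster_levels(points$cluster))) {
      stop("palette must have at least as many colors as clusters",
           call. = FALSE)
    }
    p
  })
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  set.seed(as.integer(seed))
  overlap <- with_stage(
    "spatial overlap",
    cluster_overlap(points, grid_size = grid_size, percentile = percentile))
  D <- with_stage(
    "color distances",
    color_distance_matrix(colors, weights = weights, cvd = cvd,
                          severity = cvd_severity))
  J <- overlap$jaccard
  start <- with_stage("random restarts", random_restart(J, D, n_restarts))
  refined <- with_stage(
    "exchange refinement",
    exchange_refinement(start$assignment, J, D, max_exchanges, patience))
  pal <- colors$hex[refined$assignment]
  names(pal) <- overlap$clusters
  structure(
    list(
      pal = pal,
      mapping = tibble::tibble(cluster = overlap$clusters, color = unname(pal)),
      assignment = refined$assignment,
      score = refined$score,
      restart_score = start$score,
      restart_scores = start$restart_scores,
      trace = refined$trace,
      n_proposals = refined$n_proposals,
      stopped_early = refined$stopped_early,
      overlap = overlap,
      distances = D,
      palette = colors$hex,
      points = points,
      config = list(weights = check_weights(weights), cvd = cvd,
                    cvd_severity = cvd_severity, grid_size = grid_size,
                    percentile = percentile, n_restarts = n_restarts,
                    max_exchanges = max_exchanges, patience = patience,
                    seed = as.integer(seed))
    ),
    class = "palette_fit"
  )
}

# Re-signal any error with the pipeline stage that raised it.
with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
    }
  )
}

#' @export
print.palette_fit <- function(x, ...) {
  cat(sprintf("<palette_fit> %d clusters, %d palette colors\n",
              length(x$pal), length(x$palette)))
  cat(sprintf("color score: %.4f (best restart %.4f; %d exchange proposals%s)\n",
              x$score, x$restart_score, x$n_proposals,
              if (x$stopped_early) ", stopped early" else ""))
  print(stats::setNames(unname(x$pal), names(x$pal)))
  invisible(x)
}

#' Tidy a palette fit into the cluster-to-color mapping
#'
#' @param x A [optimize_palette()] result.
#' @param ... Unused.
#' @return A tibble with columns `cluster` (canonical order) and `color`
#'   (hex string, byte-for-byte from the input palette).
#' @method tidy palette_fit
#' @export
tidy.palette_fit <- function(x, ...) {
  x$mapping
}

#' One-row summary of a palette fit
#'
#' @param x A [optimize_palette()] result.
#' @param ... Unused.
#' @return A one-row tibble: `n_clusters`, `n_colors`, `score`,
#'   `restart_score`, `n_proposals`, `stopped_early`, `seed`.
#' @method glance palette_fit
#' @export
glance.palette_fit <- function(x, ...) {
  tibble::tibble(
    n_clusters = length(x$pal),
    n_colors = length(x$palette),
    score = x$score,
    restart_score = x$restart_score,
    n_proposals = x$n_proposals,
    stopped_early = x$stopped_early,
    seed = x$config$seed
  )
}

#' Scatter plot of the points under the optimized palette
#'
#' @param object A [optimize_palette()] result.
#' @param point_size Point size passed to `geom_point()`.
#' @param ... Unused.
#' @return A ggplot object; one point per cell/spot, colored by cluster
#'   with the optimized palette.
#' @method autoplot palette_fit
#' @export
autoplot.palette_fit <- function(object, point_size = 0.8, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$x, .data$y, color = .data$cluster)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::scale_color_manual(values = object$pal) +
    ggplot2::guides(color = ggplot2::guide_legend(
      override.aes = list(size = 3))) +
    ggplot2::theme_minimal()
}

#' Score trace of the exchange refinement
#'
#' @param fit A [optimize_palette()] result.
#' @return A ggplot of the running best color score against the exchange
#'   proposal index; non-decreasing by construction of the acceptance rule.
#' @export
plot_score_trace <- function(fit) {
  stopifnot(inherits(fit, "palette_fit"))
  ggplot2::ggplot(fit$trace, ggplot2::aes(.data$iteration, .data$score)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "exchange proposal", y = "best color score") +
    ggplot2::theme_minimal()
}
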