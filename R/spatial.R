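# Per-cluster spatial footprints on a shared density grid.
#
# Every cluster's kernel density is evaluated on ONE grid spanning the
# bounding box of all points: Jaccard overlap between hot-grid-point sets is
# only meaningful when the sets index a common lattice.

# Validate a point table; returns a tibble with character cluster labels.
check_points <- function(points) {
  if (!is.data.frame(points)) {
    stop("`points` must be a data frame with columns x, y, cluster",
         call. = FALSE)
  }
  missing_cols <- setdiff(c("x", "y", "cluster"), names(points))
  if (length(missing_cols) > 0) {
    stop(sprintf("`points` is missing column(s) %s; available: %s",
                 paste(missing_cols, collapse = ", "),
                 paste(names(points), collapse = ", ")), call. = FALSE)
  }
  if (nrow(points) == 0) stop("`points` has no rows", call. = FALSE)
  for (col in c("x", "y")) {
    v <- points[[col]]
    if (!is.numeric(v)) {
      stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
    }
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop(sprintf("column '%s' has %d missing/non-finite value(s), first at row %d",
                   col, length(bad), bad[1]), call. = FALSE)
    }
  }
  if (anyNA(points$cluster)) {
    stop("column 'cluster' contains missing values", call. = FALSE)
  }
  out <- tibble::as_tibble(points[, c("x", "y", "cluster")])
  out$cluster <- as.character(out$cluster)
  out
}

# Canonical cluster order: lexicographic on the label text, locale-fixed.
cluster_levels <- function(cluster) {
  sort(unique(as.character(cluster)), method = "radix")
}

#' Build the shared density grid
#'
#' Lays an `n` x `n` lattice of equally spaced grid points over the bounding
#' box of all points, pooled across clusters. A zero-range axis (all points
#' share one coordinate) is padded by 0.5 coordinate units on each side,
#' with a warning, so the grid stays non-degenerate.
#'
#' @param points A data frame with numeric columns `x` and `y` (a `cluster`
#'   column is allowed and ignored: the extent pools all clusters).
#' @param grid_size Number of grid points per axis; default 100.
#' @return A list with strictly increasing numeric vectors `x` and `y` of
#'   length `grid_size`.
#' @examples
#' make_density_grid(data.frame(x = 0:99, y = 0:99, cluster = "a"))$x[1:5]
#' @export
make_density_grid <- function(points, grid_size = 100) {
  if (!is.numeric(grid_size) || length(grid_size) != 1 || grid_size < 10) {
    stop("`grid_size` must be a single number >= 10", call. = FALSE)
  }
  if (!is.data.frame(points) || !all(c("x", "y") %in% names(points))) {
    stop("`points` must be a data frame with columns x and y", call. = FALSE)
  }
  axis_seq <- function(v, name) {
    r <- range(v)
    if (diff(r) == 0) {
      warning(sprintf("all points share one %s value; padding the %s range by ±0.5",
                      name, name), call. = FALSE)
      r <- r + c(-0.5, 0.5)
    }
    seq(r[1], r[2], length.out = grid_size)
  }
  list(x = axis_seq(points$x, "x"), y = axis_seq(points$y, "y"))
}

#' Normal-reference bandwidth for one axis
#'
#' The normal-reference rule used by classical 2-D KDE:
#' `h = 4 * 1.06 * min(sd, IQR / 1.34) * n^(-1/5)`, where the factor 4
#' reflects the convention that the Gaussian kernel's standard deviation is
#' `h / 4`. Degenerate inputs fall back: zero IQR uses the standard
#' deviation alone; zero standard deviation (or fewer than two values) uses
#' `floor_h`, so tiny or zero-variance clusters never yield a zero or
#' undefined bandwidth.
#'
#' @param values Numeric coordinate vector.
#' @param floor_h Positive fallback bandwidth for degenerate inputs.
#' @return A positive scalar bandwidth.
#' @examples
#' nrd_bandwidth(rnorm(100))
#' @export
nrd_bandwidth <- function(values, floor_h = 1e-6) {
  if (!is.numeric(values) || anyNA(values)) {
    stop("`values` must be numeric with no missing values", call. = FALSE)
  }
  n <- length(values)
  if (n < 2) return(floor_h)
  s <- stats::sd(values)
  if (s == 0) return(floor_h)
  iqr <- diff(stats::quantile(values, c(0.25, 0.75), names = FALSE))
  spread <- if (iqr == 0) s else min(s, iqr / 1.34)
  4 * 1.06 * spread * n^(-1 / 5)
}

# Per-axis bandwidths for one cluster's points; floors scale with the grid
# extent so degenerate clusters get a kernel far narrower than the map.
cluster_bandwidths <- function(x, y, grid) {
  c(
    hx = nrd_bandwidth(x, floor_h = 1e-6 * diff(range(grid$x))),
    hy = nrd_bandwidth(y, floor_h = 1e-6 * diff(range(grid$y)))
  )
}

#' Evaluate a 2-D Gaussian kernel density on a grid
#'
#' Direct-summation product-kernel density: at grid node (gx, gy),
#' `density = (1/n) * sum_i dnorm((gx - x_i)/sx) * dnorm((gy - y_i)/sy) / (sx * sy)`
#' with per-axis kernel standard deviations `sx = hx/4`, `sy = hy/4` (the
#' classical kde2d convention for its bandwidth arguments).
#'
#' @param x,y Numeric point coordinates (equal length, at least 1).
#' @param grid Grid from [make_density_grid()].
#' @param hx,hy Positive per-axis bandwidths (see [nrd_bandwidth()]).
#' @return A `length(grid$x)` x `length(grid$y)` matrix of nonnegative
#'   densities; rows index `grid$x`, columns index `grid$y`.
#' @examples
#' g <- make_density_grid(data.frame(x = c(0, 1), y = c(0, 1)), grid_size = 10)
#' f <- kde_field(c(0, 1), c(0, 1), g, hx = 0.5, hy = 0.5)
#' dim(f)
#' @export
kde_field <- function(x, y, grid, hx, hy) {
  n <- length(x)
  if (n == 0 || length(y) != n) {
    stop("`x` and `y` must be equal-length non-empty vectors", call. = FALSE)
  }
  if (!is.numeric(hx) || !is.numeric(hy) || hx <= 0 || hy <= 0) {
    stop("bandwidths must be positive", call. = FALSE)
  }
  sx <- hx / 4
  sy <- hy / 4
  ax <- stats::dnorm(outer(grid$x, x, "-") / sx) / sx   # |grid| x n
  ay <- stats::dnorm(outer(grid$y, y, "-") / sy) / sy
  tcrossprod(ax, ay) / n
}

#' Per-cluster density fields on the shared grid
#'
#' Fits a kernel density for every cluster (its own points, its own
#' normal-reference bandwidths) on the common grid.
#'
#' @param points A point table with columns `x`, `y`, `cluster`.
#' @param grid Grid from [make_density_grid()]; built from `points` if NULL.
#' @return A tibble with one row per cluster in canonical (lexicographic)
#'   order: `cluster`, `n` (point count), `hx`, `hy` (bandwidths) and
#'   `field` (list column of density matrices).
#' @examples
#' pts <- make_blobs(data.frame(x = c(0, 5), y = 0, spread = 1, n = 50,
#'                              cluster = c("a", "b")), seed = 1)
#' cluster_density(pts)
#' @export
cluster_density <- function(points, grid = NULL) {
  points <- check_points(points)
  if (is.null(grid)) grid <- make_density_grid(points)
  levels <- cluster_levels(points$cluster)
  rows <- purrr::map(levels, function(k) {
    p <- points[points$cluster == k, ]
    bw <- cluster_bandwidths(p$x, p$y, grid)
    tibble::tibble(
      cluster = k, n = nrow(p), hx = bw[["hx"]], hy = bw[["hy"]],
      field = list(kde_field(p$x, p$y, grid, bw[["hx"]], bw[["hy"]]))
    )
  })
  dplyr::bind_rows(rows)
}

#' Permutation-null density cutoffs per cluster
#'
#' Randomly permutes the cluster labels once (coordinates fixed, cluster
#' sizes preserved), refits each permuted cluster's density on the same
#' grid, and returns for every cluster the chosen percentile (default 95th)
#' of its permuted field's grid values. Densities above this cutoff are
#' unlikely under spatially random cluster membership, so exceeding it marks
#' a grid point as part of the cluster's genuine footprint. Uses the current
#' RNG state; seed upstream for reproducibility.
#'
#' @param points Point table with columns `x`, `y`, `cluster`.
#' @param grid Grid from [make_density_grid()].
#' @param percentile Percentile of permuted-field grid values, in (0, 100);
#'   default 95. Linear interpolation between order statistics.
#' @return Named numeric vector of cutoffs, one per cluster, canonical order.
#' @export
permutation_cutoffs <- function(points, grid, percentile = 95) {
  points <- check_points(points)
  if (!is.numeric(percentile) || length(percentile) != 1 ||
      percentile <= 0 || percentile >= 100) {
    stop("`percentile` must be a single number in (0, 100)", call. = FALSE)
  }
  permuted <- sample(points$cluster)
  levels <- cluster_levels(points$cluster)
  cutoffs <- vapply(levels, function(k) {
    idx <- permuted == k
    bw <- cluster_bandwidths(points$x[idx], points$y[idx], grid)
    f <- kde_field(points$x[idx], points$y[idx], grid, bw[["hx"]], bw[["hy"]])
    stats::quantile(f, percentile / 100, names = FALSE)
  }, numeric(1))
  names(cutoffs) <- levels
  cutoffs
}

#' Hot grid points per cluster
#'
#' A grid point is "hot" for a cluster when the cluster's density there
#' strictly exceeds the cluster's cutoff. The hot set is a cluster's spatial
#' footprint on the lattice.
#'
#' @param fields Cluster density tibble from [cluster_density()].
#' @param cutoffs Named cutoff vector from [permutation_cutoffs()].
#' @return Named list (canonical cluster order) of sorted integer vectors of
#'   linear grid indices. Empty hot sets are permitted but trigger a warning.
#' @export
hot_sets <- function(fields, cutoffs) {
  if (!setequal(fields$cluster, names(cutoffs))) {
    stop("`fields` and `cutoffs` must cover the same clusters", call. = FALSE)
  }
  sets <- purrr::map(seq_len(nrow(fields)), function(i) {
    which(fields$field[[i]] > cutoffs[[fields$cluster[i]]])
  })
  names(sets) <- fields$cluster
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty) > 0) {
    warning(sprintf("cluster(s) %s have no hot grid points (density never exceeds the cutoff)",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  sets
}

#' Jaccard overlap matrix between cluster hot sets
#'
#' `J(a, b) = |S_a intersect S_b| / |S_a union S_b|` over hot-grid-point
#' sets. When both sets are empty the ratio is 0/0; it is defined as 0 (no
#' evidence of spatial adjacency), with a warning.
#'
#' @param sets Named list of integer index vectors from [hot_sets()].
#' @return A symmetric C x C matrix with entries in \[0, 1\], rows/columns
#'   named and ordered by the (canonical) order of `sets`.
#' @examples
#' jaccard_matrix(list(a = 1:4, b = 3:6))
#' @export
jaccard_matrix <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1)
  nms <- names(sets)
  C <- length(sets)
  J <- matrix(0, C, C, dimnames = list(nms, nms))
  warned <- FALSE
  for (a in seq_len(C)) {
    for (b in a:C) {
      u <- length(union(sets[[a]], sets[[b]]))
      if (u == 0) {
        if (!warned && a != b) {
          warning("Jaccard index 0/0 (two empty hot sets) defined as 0",
                  call. = FALSE)
          warned <- TRUE
        }
        J[a, b] <- J[b, a] <- 0
      } else {
        J[a, b] <- J[b, a] <- length(intersect(sets[[a]], sets[[b]])) / u
      }
    }
  }
  J
}

#' Spatial overlap between clusters of a 2-D point table
#'
#' End-to-end spatial stage: shared grid, per-cluster kernel densities,
#' one-permutation null cutoffs, hot sets, and the Jaccard overlap matrix.
#'
#' @param points Data frame with columns `x`, `y` (numeric, finite) and
#'   `cluster` (labels).
#' @param grid_size Grid points per axis, default 100.
#' @param percentile Cutoff percentile of the permuted density fields,
#'   default 95.
#' @param seed Optional integer; when given, seeds the RNG before the label
#'   permutation. Leave NULL to use (and advance) the caller's RNG stream.
#' @return An object of class `cluster_overlap`: a list with `jaccard`
#'   (C x C matrix), `cutoffs`, `hot_sets`, `density` (the
#'   [cluster_density()] tibble), `grid`, `clusters`, `grid_size`,
#'   `percentile`. Supports [generics::tidy()] (pairwise tibble) and
#'   [ggplot2::autoplot()] (heatmap).
#' @examples
#' pts <- make_blobs(data.frame(x = c(0, 1, 9), y = 0, spread = 0.5, n = 80,
#'                              cluster = c("a", "b", "c")), seed = 7)
#' ov <- cluster_overlap(pts, seed = 7)
#' tidy(ov)
#' @export
cluster_overlap <- function(points, grid_size = 100, percentile = 95,
                            seed = NULL) {
  points <- check_points(points)
  if (!is.null(seed)) set.seed(seed)
  grid <- make_density_grid(points, grid_size)
  density <- cluster_density(points, grid)
  cutoffs <- permutation_cutoffs(points, grid, percentile)
  sets <- hot_sets(density, cutoffs)
  structure(
    list(
      jaccard = jaccard_matrix(sets),
      cutoffs = cutoffs,
      hot_sets = sets,
      density = density,
      grid = grid,
      clusters = density$cluster,
      grid_size = grid_size,
      percentile = percentile
    ),
    class = "cluster_overlap"
  )
}

#' @export
print.cluster_overlap <- function(x, ...) {
  cat(sprintf("<cluster_overlap> %d clusters on a %dx%d grid (cutoff: %gth percentile)\n",
              length(x$clusters), x$grid_size, x$grid_size, x$percentile))
  pairs <- tidy(x)
  pairs <- pairs[pairs$jaccard > 0, ]
  if (nrow(pairs) == 0) {
    cat("no spatially overlapping cluster pairs\n")
  } else {
    cat("overlapping pairs:\n")
    print(as.data.frame(pairs), row.names = FALSE)
  }
  invisible(x)
}

#' Tidy a cluster_overlap object into a pairwise tibble
#'
#' @param x A [cluster_overlap()] result.
#' @param ... Unused.
#' @return A tibble with columns `cluster_a`, `cluster_b`, `jaccard`, one
#'   row per unordered cluster pair (a < b), descending by `jaccard`.
#' @method tidy cluster_overlap
#' @export
tidy.cluster_overlap <- function(x, ...) {
  C <- length(x$clusters)
  idx <- which(upper.tri(x$jaccard), arr.ind = TRUE)
  out <- tibble::tibble(
    cluster_a = x$clusters[idx[, 1]],
    cluster_b = x$clusters[idx[, 2]],
    jaccard = x$jaccard[idx]
  )
  dplyr::arrange(out, dplyr::desc(.data$jaccard), .data$cluster_a)
}

#' Heatmap of the cluster overlap matrix
#'
#' @param object A [cluster_overlap()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_overlap
#' @export
autoplot.cluster_overlap <- function(object, ...) {
  df <- tidyr::expand_grid(
    cluster_a = object$clusters, cluster_b = object$clusters)
  df$jaccard <- object$jaccard[cbind(df$cluster_a, df$cluster_b)]
  ggplot2::ggplot(df, ggplot2::aes(.data$cluster_a, .data$cluster_b,
                                   fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard",
                  title = "Spatial overlap between clusters") +
    ggplot2::theme_minimal()
}
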