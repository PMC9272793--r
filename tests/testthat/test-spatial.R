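test_that("the shared grid spans the pooled bounding box with equal spacing", {
  pts <- data.frame(x = 0:99, y = seq(0, 9.9, by = 0.1),
                    cluster = rep(c("a", "b"), 50))
  g <- make_density_grid(pts, grid_size = 100)
  expect_equal(g$x, as.numeric(0:99))
  expect_true(all(diff(g$y) > 0))
  expect_equal(length(g$y), 100)
  # extent pools all clusters: labels are irrelevant
  pts2 <- pts
  pts2$cluster <- "z"
  expect_equal(make_density_grid(pts2, 100), g)
  expect_error(make_density_grid(pts, grid_size = 5), ">= 10")
})

test_that("a zero-range axis is padded by half a unit with a warning", {
  pts <- data.frame(x = rep(2, 5), y = 1:5, cluster = "a")
  expect_warning(g <- make_density_grid(pts, 10), "padding")
  expect_equal(range(g$x), c(1.5, 2.5))
  expect_true(all(diff(g$x) > 0))
})

test_that("normal-reference bandwidth matches the hand-evaluated rule", {
  # for values (0, 1): sd = sqrt(0.5); type-7 quartiles 0.25/0.75 give
  # IQR = 0.5, and IQR/1.34 < sd
  h_expected <- 4 * 1.06 * (0.5 / 1.34) * 2^(-1 / 5)
  expect_equal(nrd_bandwidth(c(0, 1)), h_expected, tolerance = 1e-12)

  # agrees with the classical implementation on generic samples
  set.seed(11)
  for (rep in 1:5) {
    v <- rnorm(50 + rep * 13, sd = runif(1, 0.5, 5))
    expect_equal(nrd_bandwidth(v), MASS::bandwidth.nrd(v), tolerance = 1e-12)
  }
})

test_that("bandwidth is degree-1 homogeneous and degenerate-safe", {
  v <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  for (k in c(0.01, 3, 100)) {
    expect_equal(nrd_bandwidth(k * v), k * nrd_bandwidth(v),
                 tolerance = 1e-12)
  }
  expect_equal(nrd_bandwidth(rep(2, 10), floor_h = 1e-3), 1e-3)
  expect_equal(nrd_bandwidth(5, floor_h = 1e-3), 1e-3)
  # zero IQR with positive sd falls back to sd, not to the floor
  v2 <- c(rep(1, 8), 0, 2)
  expect_equal(nrd_bandwidth(v2), 4 * 1.06 * sd(v2) * 10^(-1 / 5),
               tolerance = 1e-12)
})

test_that("kde_field matches the analytic single-kernel value and symmetry", {
  g <- list(x = seq(-2, 2, length.out = 21), y = seq(-2, 2, length.out = 21))
  f <- kde_field(0, 0, g, hx = 2, hy = 1)
  sx <- 2 / 4
  sy <- 1 / 4
  expect_equal(f[11, 11], 1 / (2 * pi * sx * sy), tolerance = 1e-12)
  # two points mirrored in x give a field symmetric under that reflection
  f2 <- kde_field(c(-1, 1), c(0, 0), g, hx = 1.5, hy = 1.5)
  expect_equal(f2, f2[rev(seq_len(21)), ], tolerance = 1e-12)
})

test_that("kde_field agrees with the direct-sum oracle and with kde2d", {
  set.seed(21)
  g <- list(x = seq(-3, 8, length.out = 25), y = seq(-5, 5, length.out = 25))
  for (rep in 1:3) {
    n <- sample(3:60, 1)
    x <- runif(n, -3, 8)
    y <- runif(n, -5, 5)
    hx <- runif(1, 0.5, 3)
    hy <- runif(1, 0.5, 3)
    f <- kde_field(x, y, g, hx, hy)
    expect_equal(f, kde_oracle(x, y, g, hx, hy), tolerance = 1e-12)
    ref <- MASS::kde2d(x, y, h = c(hx, hy), n = 25,
                       lims = c(range(g$x), range(g$y)))
    expect_equal(f, ref$z, tolerance = 1e-10)
    expect_true(all(f >= 0))
  }
})

test_that("cluster_density fits each cluster on the common grid in canonical order", {
  pts <- make_blobs(data.frame(x = c(0, 6), y = 0, spread = 1, n = c(40, 60),
                               cluster = c("b", "a")), seed = 2)
  cd <- cluster_density(pts)
  expect_equal(cd$cluster, c("a", "b"))
  expect_equal(cd$n, c(60, 40))
  expect_equal(dim(cd$field[[1]]), c(100, 100))
  # densities are invariant under renaming labels; only row order changes
  pts2 <- pts
  pts2$cluster <- ifelse(pts$cluster == "a", "z2", "z1")
  cd2 <- cluster_density(pts2)
  expect_equal(cd2$cluster, c("z1", "z2"))
  expect_equal(cd2$field[[1]], cd$field[[2]])
  expect_equal(cd2$field[[2]], cd$field[[1]])
})

test_that("permutation cutoffs match an independently scripted recomputation", {
  pts <- make_blobs(data.frame(x = c(0, 2, 5), y = c(0, 1, 0), spread = 1,
                               n = c(30, 40, 50), cluster = c("a", "b", "c")),
                    seed = 3)
  grid <- make_density_grid(pts, 40)

  set.seed(123)
  cut_pkg <- permutation_cutoffs(pts, grid, percentile = 95)

  # oracle: same RNG contract, naive KDE, explicit quantile
  set.seed(123)
  perm <- sample(pts$cluster)
  cut_ref <- sapply(sort(unique(pts$cluster)), function(k) {
    x <- pts$x[perm == k]
    y <- pts$y[perm == k]
    hx <- nrd_bandwidth(x, 1e-6 * diff(range(grid$x)))
    hy <- nrd_bandwidth(y, 1e-6 * diff(range(grid$y)))
    quantile(kde_oracle(x, y, grid, hx, hy), 0.95, names = FALSE)
  })
  expect_equal(cut_pkg, cut_ref, tolerance = 1e-12)
  expect_error(permutation_cutoffs(pts, grid, percentile = 0), "0, 100")
})

test_that("a single cluster's cutoff is the percentile of its own field", {
  # with one cluster the label permutation cannot change membership
  pts <- make_blobs(data.frame(x = 0, y = 0, spread = 1, n = 80,
                               cluster = "only"), seed = 4)
  grid <- make_density_grid(pts, 30)
  cd <- cluster_density(pts, grid)
  set.seed(1)
  cuts <- permutation_cutoffs(pts, grid)
  expect_equal(unname(cuts), quantile(cd$field[[1]], 0.95, names = FALSE),
               tolerance = 1e-12)
})

test_that("hot sets use a strict cutoff and warn when empty", {
  pts <- make_blobs(data.frame(x = 0, y = 0, spread = 1, n = 50,
                               cluster = "a"), seed = 5)
  grid <- make_density_grid(pts, 20)
  cd <- cluster_density(pts, grid)
  f <- cd$field[[1]]
  expect_equal(hot_sets(cd, c(a = -1))$a, seq_len(400))
  expect_warning(empty <- hot_sets(cd, c(a = max(f))), "no hot grid points")
  expect_length(empty$a, 0)
  mid <- median(f)
  expect_equal(hot_sets(cd, c(a = mid))$a, which(as.vector(f) > mid))
})

test_that("Jaccard matrix follows the set formula with 0/0 defined as 0", {
  J <- jaccard_matrix(list(a = 1:4, b = 1:4, c = 10:13, d = c(3, 4, 20, 21)))
  expect_equal(J["a", "b"], 1)
  expect_equal(J["a", "c"], 0)
  expect_equal(J["a", "d"], 2 / 6)
  expect_equal(jaccard_matrix(list(a = c(1, 2, 3), b = c(2, 3, 4)))[1, 2],
               0.5) # |∩|=2, |∪|=4
  expect_warning(J0 <- jaccard_matrix(list(a = integer(0), b = integer(0))),
                 "0/0")
  expect_equal(unname(J0), matrix(0, 2, 2))
  # diagonal is 1 for non-empty hot sets, 0 for empty ones
  expect_equal(diag(J), c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(diag(J0), c(a = 0, b = 0))
})

test_that("overlap matrices are symmetric with entries in [0,1] on random data", {
  set.seed(31)
  for (rep in 1:5) {
    C <- sample(2:5, 1)
    specs <- data.frame(x = runif(C, 0, 10), y = runif(C, 0, 10),
                        spread = runif(C, 0.3, 2),
                        n = sample(20:80, C, replace = TRUE),
                        cluster = paste0("k", seq_len(C)))
    pts <- make_blobs(specs, seed = 100 + rep)
    ov <- suppressWarnings(cluster_overlap(pts, grid_size = 40,
                                           seed = 100 + rep))
    expect_identical(ov$jaccard, t(ov$jaccard))
    expect_true(all(ov$jaccard >= 0 & ov$jaccard <= 1))
    expect_equal(rownames(ov$jaccard), sort(unique(pts$cluster)))
  }
})

test_that("integer rescaling and translation of coordinates leave overlap unchanged", {
  pts <- make_blobs(data.frame(x = c(0, 1.5), y = 0, spread = 1, n = 200,
                               cluster = c("a", "b")), seed = 6)
  ov1 <- cluster_overlap(pts, grid_size = 50, seed = 99)
  pts2 <- dplyr::mutate(pts, x = 3 * x - 7, y = 3 * y + 11)
  ov2 <- cluster_overlap(pts2, grid_size = 50, seed = 99)
  # affine maps carry the grid onto itself: hot sets and J match exactly
  expect_identical(ov1$hot_sets, ov2$hot_sets)
  expect_identical(ov1$jaccard, ov2$jaccard)
})

test_that("well-separated blobs do not overlap; coincident blobs do", {
  far <- make_blobs(data.frame(x = c(0, 30), y = 0, spread = 1, n = 250,
                               cluster = c("a", "b")), seed = 7)
  ov_far <- cluster_overlap(far, seed = 7)
  expect_equal(ov_far$jaccard["a", "b"], 0)

  near <- make_blobs(data.frame(x = c(0, 0), y = 0, spread = 1, n = 500,
                                cluster = c("a", "b")), seed = 7)
  ov_near <- cluster_overlap(near, seed = 7)
  expect_gt(ov_near$jaccard["a", "b"], 0.5)
})

test_that("tidy and autoplot summarize a cluster_overlap", {
  pts <- two_near_one_far(seed = 8, n = 100)
  ov <- cluster_overlap(pts, grid_size = 40, seed = 8)
  td <- tidy(ov)
  expect_equal(nrow(td), 3)
  expect_equal(td$cluster_a[1], "a") # a-b overlap ranks first
  expect_equal(td$cluster_b[1], "b")
  expect_equal(td$jaccard,
               ov$jaccard[cbind(td$cluster_a, td$cluster_b)],
               ignore_attr = TRUE)
  expect_s3_class(autoplot(ov), "ggplot")
  expect_output(print(ov), "overlapping pairs")
})

test_that("invalid point tables are rejected informatively", {
  expect_error(cluster_overlap(data.frame(x = 1:3, y = 1:3)), "cluster")
  expect_error(
    cluster_overlap(data.frame(x = c(1, NA), y = c(1, 2), cluster = "a")),
    "row 2")
  expect_error(
    cluster_overlap(data.frame(x = c(1, Inf), y = c(1, 2), cluster = "a")),
    "non-finite")
})
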