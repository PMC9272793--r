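# Independent oracles: deliberately naive re-implementations used to check
# the package's vectorized code paths.

# Direct-sum KDE, looping over grid nodes (the package loops over points
# via matrix products).
kde_oracle <- function(x, y, grid, hx, hy) {
  sx <- hx / 4
  sy <- hy / 4
  n <- length(x)
  f <- matrix(0, length(grid$x), length(grid$y))
  for (i in seq_along(grid$x)) {
    for (j in seq_along(grid$y)) {
      f[i, j] <- sum(dnorm((grid$x[i] - x) / sx) *
                       dnorm((grid$y[j] - y) / sy)) / (n * sx * sy)
    }
  }
  f
}

# Color score by explicit double loop over unordered cluster pairs.
score_oracle <- function(J, D, assignment) {
  C <- nrow(J)
  s <- 0
  if (C >= 2) {
    for (a in 1:(C - 1)) {
      for (b in (a + 1):C) {
        s <- s + J[a, b] * D[assignment[a], assignment[b]]
      }
    }
  }
  s
}

# Weighted RGB distance matrix by explicit element-wise recomputation.
dist_oracle <- function(colors, w) {
  m <- nrow(colors)
  D <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      D[i, j] <- sqrt(w[1] * (colors$r[i] - colors$r[j])^2 +
                        w[2] * (colors$g[i] - colors$g[j])^2 +
                        w[3] * (colors$b[i] - colors$b[j])^2)
    }
  }
  D
}

# Random symmetric overlap matrix with unit diagonal and entries in [0, 1].
random_overlap <- function(C) {
  J <- matrix(0, C, C)
  J[upper.tri(J)] <- runif(C * (C - 1) / 2)
  J <- J + t(J)
  diag(J) <- 1
  J
}

# Random palette of distinct 8-bit hex colors.
random_palette <- function(m) {
  stopifnot(m <= 100)
  bytes <- sample.int(256^3, m) - 1L
  sprintf("#%06X", bytes)
}

# A three-cluster table: two heavily overlapping blobs plus one far away.
two_near_one_far <- function(seed, n = 300) {
  make_blobs(
    data.frame(x = c(0, 0.8, 20), y = 0, spread = 1, n = n,
               cluster = c("a", "b", "c")),
    seed = seed
  )
}
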