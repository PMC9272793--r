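# Overlap-weighted palette assignment search: best of random restarts, then
# greedy pairwise color exchanges with an early-stopping patience rule.

# Validate (J, D, assignment) dimensions and injectivity.
check_assignment <- function(J, D, assignment) {
  if (!is.matrix(J) || nrow(J) != ncol(J)) {
    stop("`J` must be a square overlap matrix", call. = FALSE)
  }
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("`D` must be a square distance matrix", call. = FALSE)
  }
  C <- nrow(J)
  M <- nrow(D)
  a <- as.integer(assignment)
  if (length(a) != C) {
    stop(sprintf("assignment has length %d but there are %d clusters",
                 length(a), C), call. = FALSE)
  }
  if (anyNA(a) || any(a < 1) || any(a > M) || anyDuplicated(a)) {
    stop("assignment must map clusters to distinct palette indices in 1..M",
         call. = FALSE)
  }
  a
}

#' Color score of a palette assignment
#'
#' The optimization objective: the sum over unordered cluster pairs of the
#' pair's spatial overlap times the distance between its assigned colors,
#' `sum_{a<b} J(a,b) * D(P_a, P_b)`. Larger scores mean spatially
#' overlapping cluster pairs carry more dissimilar colors. (Summing over
#' ordered pairs would double every term and cannot change the argmax.)
#'
#' @param J C x C symmetric overlap matrix (e.g. `cluster_overlap()$jaccard`).
#' @param D M x M palette distance matrix from [color_distance_matrix()],
#'   M >= C.
#' @param assignment Integer vector of length C of distinct palette indices;
#'   `assignment[k]` is the palette color of cluster `k`.
#' @return A nonnegative scalar.
#' @examples
#' J <- matrix(c(1, 0.5, 0.5, 1), 2)
#' D <- color_distance_matrix(c("#000000", "#FFFFFF"))
#' color_score(J, D, c(1, 2)) # 0.5 * sqrt(3)
#' @export
color_score <- function(J, D, assignment) {
  a <- check_assignment(J, D, assignment)
  sum(J * D[a, a, drop = FALSE]) / 2
}

# Score many assignments; P is n x C, one assignment per row. Uses the
# exact arithmetic of color_score() so scores from different search stages
# compare exactly, never merely to rounding error.
score_assignments <- function(J, D, P) {
  vapply(seq_len(nrow(P)), function(i) {
    a <- P[i, ]
    sum(J * D[a, a, drop = FALSE]) / 2
  }, numeric(1))
}

#' Best-of-random-restarts initial assignment
#'
#' Draws `n_restarts` uniformly random injective assignments of palette
#' colors to clusters and keeps the highest-scoring one (ties keep the
#' earliest drawn). Uses the current RNG state.
#'
#' @inheritParams color_score
#' @param n_restarts Number of random assignments to draw; default 1000.
#' @return A list with `assignment` (integer vector), `score`, and
#'   `restart_scores` (all `n_restarts` scores, in draw order).
#' @export
random_restart <- function(J, D, n_restarts = 1000) {
  C <- nrow(J)
  M <- nrow(D)
  if (M < C) {
    stop("palette must have at least as many colors as clusters",
         call. = FALSE)
  }
  if (!is.numeric(n_restarts) || n_restarts < 1) {
    stop("`n_restarts` must be a positive integer", call. = FALSE)
  }
  P <- matrix(0L, n_restarts, C)
  for (i in seq_len(n_restarts)) {
    P[i, ] <- sample.int(M, C)
  }
  scores <- score_assignments(J, D, P)
  best <- which.max(scores) # first maximum: earliest drawn wins ties
  list(assignment = P[best, ], score = scores[best], restart_scores = scores)
}

#' Greedy pairwise-exchange refinement
#'
#' Refines an assignment by repeatedly proposing a swap: either the colors
#' of two distinct uniformly chosen clusters, or (when the palette is larger
#' than the cluster count) one cluster's color with an unused pool color —
#' each possible swap equally likely. A proposal is accepted only if it
#' strictly increases the color score. The search stops after
#' `max_exchanges` proposals, or earlier once `patience` consecutive
#' proposals have been rejected.
#'
#' @inheritParams color_score
#' @param assignment Starting assignment (integer vector, length C,
#'   distinct palette indices).
#' @param max_exchanges Maximum number of swap proposals; default 2000.
#' @param patience Consecutive rejected proposals that trigger early
#'   stopping; default 500. Must not exceed `max_exchanges`.
#' @return A list with `assignment`, `score`, `trace` (tibble of
#'   `iteration`, `score`, `accepted`; row 0 is the start, the score column
#'   is the running best and is non-decreasing), `n_proposals`, and
#'   `stopped_early`.
#' @export
exchange_refinement <- function(assignment, J, D, max_exchanges = 2000,
                                patience = 500) {
  a <- check_assignment(J, D, assignment)
  if (max_exchanges < 1 || patience < 1) {
    stop("`max_exchanges` and `patience` must be positive integers",
         call. = FALSE)
  }
  if (patience > max_exchanges) {
    stop("`patience` must not exceed `max_exchanges`", call. = FALSE)
  }
  C <- nrow(J)
  M <- nrow(D)
  pool <- setdiff(seq_len(M), a)
  P <- length(pool)
  n_cc <- if (C >= 2) C * (C - 1L) / 2L else 0L
  n_cp <- C * P
  score <- color_score(J, D, a)
  trace_iter <- 0L
  trace_score <- score
  trace_accept <- NA
  if (n_cc + n_cp == 0) {
    return(list(assignment = a, score = score,
                trace = tibble::tibble(iteration = trace_iter,
                                       score = trace_score,
                                       accepted = trace_accept),
                n_proposals = 0L, stopped_early = FALSE))
  }
  pairs <- which(upper.tri(matrix(nrow = C, ncol = C)), arr.ind = TRUE)
  rejected_run <- 0L
  n_prop <- 0L
  for (it in seq_len(max_exchanges)) {
    u <- sample.int(n_cc + n_cp, 1L)
    prop <- a
    pool_slot <- NA_integer_
    if (u <= n_cc) {
      i <- pairs[u, 1]
      j <- pairs[u, 2]
      prop[c(i, j)] <- a[c(j, i)]
    } else {
      v <- u - n_cc
      ci <- (v - 1L) %/% P + 1L
      pool_slot <- (v - 1L) %% P + 1L
      prop[ci] <- pool[pool_slot]
    }
    new_score <- sum(J * D[prop, prop, drop = FALSE]) / 2
    n_prop <- it
    if (new_score > score) { # strict improvement only; ties are rejections
      if (!is.na(pool_slot)) pool[pool_slot] <- setdiff(a, prop)
      a <- prop
      score <- new_score
      rejected_run <- 0L
    } else {
      rejected_run <- rejected_run + 1L
    }
    trace_iter <- c(trace_iter, it)
    trace_score <- c(trace_score, score)
    trace_accept <- c(trace_accept, rejected_run == 0L)
    if (rejected_run >= patience) break
  }
  list(
    assignment = a, score = score,
    trace = tibble::tibble(iteration = trace_iter, score = trace_score,
                           accepted = trace_accept),
    n_proposals = n_prop,
    stopped_early = n_prop < max_exchanges
  )
}

#' Exact optimum by exhaustive enumeration
#'
#' Enumerates every injective assignment of M palette colors to C clusters
#' and returns a maximum-score assignment. Intended as a ground-truth
#' reference for small instances (it errors beyond ~1e6 assignments); the
#' stochastic search in [random_restart()] / [exchange_refinement()] scales
#' to realistic cluster counts.
#'
#' @inheritParams color_score
#' @return A list with `assignment` (the first enumerated argmax) and
#'   `score`.
#' @examples
#' J <- matrix(c(1, 0.5, 0.5, 1), 2)
#' D <- color_distance_matrix(c("#000000", "#FFFFFF"))
#' exhaustive_search(J, D)
#' @export
exhaustive_search <- function(J, D) {
  C <- nrow(J)
  M <- nrow(D)
  if (M < C) {
    stop("palette must have at least as many colors as clusters",
         call. = FALSE)
  }
  n_total <- choose(M, C) * factorial(C)
  if (n_total > 1e6) {
    stop(sprintf("%g injective assignments is too many to enumerate", n_total),
         call. = FALSE)
  }
  P <- injective_assignments(M, C)
  scores <- score_assignments(J, D, P)
  best <- which.max(scores)
  list(assignment = P[best, ], score = scores[best])
}

# All permutations of the vector v, one per row.
permutations_of <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(v[i], permutations_of(v[-i]))
  }))
}

# All ordered selections of C distinct values from 1..M, one per row.
injective_assignments <- function(M, C) {
  if (C == 1) return(matrix(seq_len(M), ncol = 1))
  subsets <- utils::combn(M, C)
  do.call(rbind, lapply(seq_len(ncol(subsets)), function(j) {
    permutations_of(subsets[, j])
  }))
}
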