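## K-medoids (PAM-style) clustering on a precomputed distance matrix and
## elbow-based choice of the number of clusters.

#' K-medoids clustering of a distance matrix
#'
#' PAM-style alternation: assign each item to its nearest medoid, then move
#' each cluster's medoid to the member minimizing the within-cluster sum of
#' distances, until the medoid set is stable. Each restart is initialized
#' by distance-weighted farthest-point seeding (first medoid uniform, each
#' further medoid sampled with probability proportional to its distance to
#' the nearest already-chosen medoid); the best of `restarts` solutions is
#' returned. Deterministic given `seed`. Ties in assignment and medoid
#' updates break toward the smaller index.
#'
#' @param D symmetric non-negative distance matrix with zero diagonal.
#' @param k number of clusters, `1 <= k <= nrow(D)`.
#' @param seed integer seed.
#' @param restarts number of seeded restarts (default 10).
#' @param max_iter iteration cap per restart.
#' @return list of class `kmedoids_result`: `k`, `medoids` (item indices),
#'   `assignment` (medoid index per item), `cost` (sum of distances to the
#'   assigned medoid), `cost_trace` (cost after each iteration of the best
#'   restart), `restart_costs`.
#' @export
kMedoids <- function(D, k, seed = 1L, restarts = 10L, max_iter = 100L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k > n) stop("k (", k, ") exceeds number of items (", n, ")")
  if (k < 1L) stop("k must be >= 1")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-10)))
    stop("distance matrix must be symmetric")
  best <- NULL
  restart_costs <- numeric(restarts)
  withSeed(seed, {
    for (r in seq_len(restarts)) {
      med <- seedMedoids(D, k)
      trace <- numeric(0)
      for (it in seq_len(max_iter)) {
        assign_idx <- apply(D[, med, drop = FALSE], 1L, which.min)
        new_med <- med
        for (c in seq_len(k)) {
          members <- which(assign_idx == c)
          if (!length(members)) next
          within <- colSums(D[members, members, drop = FALSE])
          new_med[c] <- members[which.min(within)]
        }
        assign_idx <- apply(D[, new_med, drop = FALSE], 1L, which.min)
        trace <- c(trace, sum(D[cbind(seq_len(n), new_med[assign_idx])]))
        if (identical(sort(new_med), sort(med)) && it > 1L) break
        med <- new_med
      }
      cost <- trace[length(trace)]
      restart_costs[r] <- cost
      if (is.null(best) || cost < best$cost - 1e-12) {
        best <- list(medoids = med, assignment = assign_idx, cost = cost,
                     cost_trace = trace)
      }
    }
  })
  structure(list(k = k, medoids = best$medoids,
                 assignment = best$medoids[best$assignment],
                 cluster = best$assignment,
                 cost = best$cost, cost_trace = best$cost_trace,
                 restart_costs = restart_costs, seed = seed),
            class = "kmedoids_result")
}

## Distance-weighted farthest-point seeding (k-means++ style on distances).
seedMedoids <- function(D, k) {
  n <- nrow(D)
  med <- sample.int(n, 1L)
  while (length(med) < k) {
    dmin <- apply(D[, med, drop = FALSE], 1L, min)
    dmin[med] <- 0
    if (sum(dmin) == 0) {
      med <- c(med, setdiff(seq_len(n), med)[1L])
    } else {
      med <- c(med, sample.int(n, 1L, prob = dmin / sum(dmin)))
    }
  }
  med
}

#' @export
print.kmedoids_result <- function(x, ...) {
  cat("K-medoids: k =", x$k, ", cost =", format(x$cost, digits = 6),
      "\n medoids:", paste(x$medoids, collapse = ", "), "\n")
  tab <- table(factor(x$assignment, levels = x$medoids))
  cat(" cluster sizes:", paste(as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}

#' Choose the number of clusters by the elbow method
#'
#' Given total clustering costs for consecutive `k = 1..K`, returns the
#' interior `k` whose point `(k, cost_k)` lies furthest (perpendicular
#' distance) from the chord joining `(1, cost_1)` and `(K, cost_K)`. Ties
#' break toward smaller `k`, so an exactly linear cost curve yields
#' `k = 2`. The choice is invariant to uniform scaling of the costs.
#'
#' @param costs numeric vector of costs for `k = 1..length(costs)`.
#' @return chosen `k` (integer) with attribute `"distances"`.
#' @export
elbowK <- function(costs) {
  K <- length(costs)
  if (K == 0L) stop("no costs supplied")
  if (K < 3L) {
    warning("fewer than 3 candidate k; returning K = ", K)
    return(structure(K, distances = rep(0, K)))
  }
  k <- seq_len(K)
  ## perpendicular distance from (k, c_k) to the chord (1,c_1)-(K,c_K);
  ## the k-independent denominator is dropped (argmax unchanged).
  num <- abs((K - 1) * (costs - costs[1]) - (k - 1) * (costs[K] - costs[1]))
  interior <- 2:(K - 1)
  kk <- interior[which.max(num[interior])]
  structure(as.integer(kk), distances = num / sqrt((K - 1)^2 +
                                                     (costs[K] - costs[1])^2))
}

#' Cluster extension trajectories end-to-end
#'
#' Convenience wrapper: pairwise banded DTW distances, K-medoids for each
#' candidate `k`, and elbow selection of the cluster count.
#'
#' @param trajectories list of trajectory matrices ([eventTrajectories()]).
#' @param window_s DTW warping window (s).
#' @param fps frames per second (taken from the trajectories if absent).
#' @param kmax largest candidate number of clusters.
#' @param seed integer seed for the K-medoids restarts.
#' @param restarts restarts per candidate `k`.
#' @return list: `distance_matrix`, `costs` (per candidate k), `k`
#'   (elbow choice), `result` (the chosen [kMedoids()] solution).
#' @export
clusterTrajectories <- function(trajectories, window_s = 0.25, fps = NULL,
                                kmax = 10, seed = 1L, restarts = 10L) {
  D <- pairwiseDistances(trajectories, window_s = window_s, fps = fps)
  kmax <- min(kmax, nrow(D))
  fits <- lapply(seq_len(kmax), function(k)
    kMedoids(D, k, seed = seed + k, restarts = restarts))
  costs <- vapply(fits, `[[`, numeric(1), "cost")
  k <- as.integer(elbowK(costs))
  list(distance_matrix = D, costs = costs, k = k, result = fits[[k]])
}
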