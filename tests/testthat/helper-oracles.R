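# Independent oracles used by the unit and acceptance suites.

# F-distribution quantile by root-finding on the numerically integrated
# density (independent check of qf-based critical limits)
quantile_f_oracle <- function(prob, df1, df2) {
  cdf <- function(q) stats::integrate(function(x) stats::df(x, df1, df2),
                                      0, q, rel.tol = 1e-10)$value
  stats::uniroot(function(q) cdf(q) - prob, c(1e-6, 1e4), tol = 1e-9)$root
}

# brute-force Ward agglomeration: evaluate every candidate merge by its
# exact within-cluster sum-of-squares increase
brute_force_ward <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  merges <- list()
  cost <- function(a, b) {
    ca <- colMeans(x[a, , drop = FALSE]); cb <- colMeans(x[b, , drop = FALSE])
    length(a) * length(b) / (length(a) + length(b)) * sum((ca - cb)^2)
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_cost <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        cc <- cost(clusters[[i]], clusters[[j]])
        if (cc < best_cost) { best_cost <- cc; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_cost)
    merges <- c(merges, list(sort(c(clusters[[best[1]]], clusters[[best[2]]]))))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# leaf sets of each internal node of an hclust-style tree
merge_leaf_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    grab <- function(k) if (k < 0) -k else sets[[k]]
    sets[[m]] <- sort(c(grab(hc$merge[m, 1]), grab(hc$merge[m, 2])))
  }
  sets
}

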