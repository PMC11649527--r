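# Agglomerative Ward clustering: each merge is the pair whose fusion
# minimally increases the total within-cluster sum of squares.

#' Ward hierarchical clustering
#'
#' Agglomerative clustering under Ward's minimum-variance criterion.  The
#' merge cost between clusters i and j is
#' `|i||j| / (|i| + |j|) * ||centroid_i - centroid_j||^2`, the increase in
#' within-cluster sum of squares; heights are these costs and are
#' non-decreasing along the merge sequence.  Updates use the
#' Lance-Williams recurrence.  The returned object is `hclust`-compatible
#' (plot, cutree work), with the display order placing the larger subtree
#' first at every merge ("sorted by size").
#'
#' @param x numeric matrix (samples x variables, typically autoscaled).
#' @param labels leaf labels (default rownames).
#' @return Object of class `c("ward_cluster", "hclust")` with `merge`,
#'   `height`, `order`, `labels`, and `sizes` (cluster size at each merge).
#' @export
ward_cluster <- function(x, labels = rownames(x)) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # D holds twice the merge cost (Lance-Williams on squared Euclidean)
  D <- as.matrix(stats::dist(x))^2
  diag(D) <- Inf
  size <- rep(1L, n)
  id <- -seq_len(n)           # hclust convention: negatives are leaves
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  sizes <- integer(n - 1)
  children <- vector("list", n - 1)
  for (m in seq_len(n - 1)) {
    Dv <- D
    Dv[!active, ] <- Inf; Dv[, !active] <- Inf
    ij <- arrayInd(which.min(Dv), dim(Dv))
    i <- min(ij); j <- max(ij)
    height[m] <- D[i, j] / 2     # within-SS increase
    merge[m, ] <- sort(c(id[i], id[j]))
    sizes[m] <- size[i] + size[j]
    children[[m]] <- c(id[i], id[j])
    # Lance-Williams update for Ward (on D = 2 * cost)
    k <- which(active & seq_len(n) != i & seq_len(n) != j)
    if (length(k) > 0) {
      D[i, k] <- D[k, i] <- ((size[i] + size[k]) * D[i, k] +
                             (size[j] + size[k]) * D[j, k] -
                             size[k] * D[i, j]) / (size[i] + size[j] + size[k])
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- m
  }
  # display order: recursive expansion, larger subtree first
  subtree_size <- function(node) if (node < 0) 1L else sizes[node]
  expand <- function(node) {
    if (node < 0) return(-node)
    ch <- children[[node]]
    ch <- ch[order(-vapply(ch, subtree_size, integer(1)))]
    c(expand(ch[1]), expand(ch[2]))
  }
  structure(list(merge = merge, height = height,
                 order = expand(n - 1L), labels = labels, sizes = sizes,
                 method = "ward", call = match.call(),
                 dist.method = "euclidean"),
            class = c("ward_cluster", "hclust"))
}
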