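#' Hierarchical density-based clustering (HDBSCAN*)
#'
#' Extracts the densest regions of a feature cloud as flat clusters of at
#' least `min_cluster_size` members and labels everything else noise. The
#' implementation follows the standard HDBSCAN* pipeline: a minimum
#' spanning tree of the mutual-reachability graph (with neighborhood size
#' `k`, so `k = 1` reduces the metric to plain Euclidean distance), the
#' single-linkage hierarchy over its edges, a condensed cluster tree at the
#' given minimum size, and excess-of-mass stability selection.
#'
#' @param X Numeric matrix, one row per object.
#' @param min_cluster_size Minimum cluster size `m` (at least 2).
#' @param k Neighborhood size used for core distances (default 1).
#' @param cluster_selection `"eom"` (excess-of-mass, the algorithm default)
#'   or `"leaf"` (deepest clusters of the condensed tree, which yields
#'   smaller, purer cores at the cost of fragmentation).
#' @param allow_single_cluster Whether the root of the condensed tree may be
#'   selected (default `FALSE`, the usual convention).
#' @return Integer vector of cluster labels per row; `0` means noise.
#'   Cluster labels `1..K` are ordered by decreasing cluster size.
#' @export
hdbscan_star <- function(X, min_cluster_size, k = 1,
                         cluster_selection = c("eom", "leaf"),
                         allow_single_cluster = FALSE) {
  cluster_selection <- match.arg(cluster_selection)
  stopifnot(is.matrix(X), min_cluster_size >= 2, k >= 1)
  n <- nrow(X)
  if (n < min_cluster_size || n < 2) return(integer(n))

  xt <- t(X)
  core <- if (k == 1) numeric(n) else core_distances(xt, as.integer(k))
  mst <- prim_mst(xt, core)

  sl <- single_linkage_from_mst(n, mst$from, mst$to, mst$weight)
  cond <- condense_tree(n, sl, min_cluster_size)
  if (cond$n_clusters == 0) return(integer(n))
  sel <- if (cluster_selection == "leaf") {
    leaf_select(cond, allow_single_cluster)
  } else {
    eom_select(cond, allow_single_cluster)
  }

  # nearest selected ancestor (self included) of every condensed cluster
  cl_label <- integer(cond$n_clusters)
  for (c in seq_len(cond$n_clusters)) {
    a <- c
    while (a != 0 && !sel[a]) a <- cond$cl_parent[a]
    cl_label[c] <- a
  }
  lab <- ifelse(cond$point_cl > 0, cl_label[pmax(cond$point_cl, 1L)], 0L)
  # relabel selected clusters 1..K by decreasing size
  keep <- sort(unique(lab[lab > 0]))
  if (length(keep) == 0) return(integer(n))
  sizes <- vapply(keep, function(c) sum(lab == c), integer(1))
  ord <- keep[order(-sizes, keep)]
  match(lab, ord, nomatch = 0L)
}

# Single-linkage hierarchy from MST edges via union-find.
# Nodes: 1..n leaves, n+1..2n-1 internal (in merge order, heights ascending).
single_linkage_from_mst <- function(n, from, to, weight) {
  ord <- order(weight, from, to)
  parent <- seq_len(2L * n - 1L)  # union-find over tree nodes
  node_of <- seq_len(n)           # uf root -> current tree node
  child_l <- integer(n - 1L)
  child_r <- integer(n - 1L)
  height <- numeric(n - 1L)
  size <- c(rep(1L, n), integer(n - 1L))

  for (i in seq_len(n - 1L)) {
    e <- ord[i]
    a <- from[e]
    while (parent[a] != a) {
      parent[a] <- parent[parent[a]]
      a <- parent[a]
    }
    b <- to[e]
    while (parent[b] != b) {
      parent[b] <- parent[parent[b]]
      b <- parent[b]
    }
    na <- node_of[a]
    nb <- node_of[b]
    child_l[i] <- na
    child_r[i] <- nb
    height[i] <- weight[e]
    size[n + i] <- size[na] + size[nb]
    parent[a] <- b
    node_of[b] <- n + i
  }
  list(child_l = child_l, child_r = child_r, height = height, size = size)
}

# Condense the single-linkage tree: walking from the root, splits where both
# sides hold >= m points create two child clusters; smaller sides fall out
# of the running cluster as individual points at the split's lambda = 1/d.
condense_tree <- function(n, sl, m) {
  max_cl <- max(2L, 2L * (n %/% max(m, 1L)) + 2L)
  cl_parent <- integer(max_cl)
  cl_birth <- numeric(max_cl)
  stability <- numeric(max_cl)
  point_cl <- integer(n)
  point_lambda <- numeric(n)

  subtree_leaves <- function(node) {
    out <- integer(0)
    stack <- node
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (v <= n) out <- c(out, v)
      else stack <- c(stack, sl$child_l[v - n], sl$child_r[v - n])
    }
    out
  }

  n_cl <- 1L  # cluster 1 = root, birth lambda 0
  stack_node <- integer(2L * n)
  stack_cl <- integer(2L * n)
  top <- 1L
  stack_node[1] <- 2L * n - 1L
  stack_cl[1] <- 1L
  while (top > 0L) {
    node <- stack_node[top]
    cl <- stack_cl[top]
    top <- top - 1L
    i <- node - n
    lam <- 1 / max(sl$height[i], .Machine$double.xmin)
    l <- sl$child_l[i]
    r <- sl$child_r[i]
    nl <- sl$size[l]
    nr <- sl$size[r]
    if (nl >= m && nr >= m) {
      stability[cl] <- stability[cl] + (nl + nr) * (lam - cl_birth[cl])
      for (ch in c(l, r)) {
        n_cl <- n_cl + 1L
        cl_parent[n_cl] <- cl
        cl_birth[n_cl] <- lam
        top <- top + 1L
        stack_node[top] <- ch
        stack_cl[top] <- n_cl
      }
    } else if (nl >= m || nr >= m) {
      keep <- if (nl >= m) l else r
      drop <- if (nl >= m) r else l
      pts <- subtree_leaves(drop)
      point_cl[pts] <- cl
      point_lambda[pts] <- lam
      stability[cl] <- stability[cl] + length(pts) * (lam - cl_birth[cl])
      top <- top + 1L
      stack_node[top] <- keep
      stack_cl[top] <- cl
    } else {
      pts <- c(subtree_leaves(l), subtree_leaves(r))
      point_cl[pts] <- cl
      point_lambda[pts] <- lam
      stability[cl] <- stability[cl] + length(pts) * (lam - cl_birth[cl])
    }
  }
  list(n_clusters = n_cl,
       cl_parent = cl_parent[seq_len(n_cl)],
       cl_birth = cl_birth[seq_len(n_cl)],
       stability = stability[seq_len(n_cl)],
       point_cl = point_cl, point_lambda = point_lambda)
}

# Excess-of-mass cluster selection: keep a cluster when its own stability is
# at least the summed (propagated) stability of its children; the root is
# excluded unless allow_single_cluster.
eom_select <- function(cond, allow_single_cluster = FALSE) {
  n_cl <- length(cond$cl_parent)
  hat <- numeric(n_cl)
  selected <- logical(n_cl)
  for (c in rev(seq_len(n_cl))) {
    kids <- which(cond$cl_parent == c)
    cs <- sum(hat[kids])
    if (c == 1L && !allow_single_cluster) {
      hat[c] <- cs
    } else if (length(kids) == 0L || cond$stability[c] >= cs) {
      selected[c] <- TRUE
      hat[c] <- cond$stability[c]
    } else {
      hat[c] <- cs
    }
  }
  # a selected ancestor shadows its descendants
  for (c in seq_len(n_cl)) {
    if (!selected[c]) next
    a <- cond$cl_parent[c]
    while (a != 0L) {
      if (selected[a]) { selected[c] <- FALSE; break }
      a <- cond$cl_parent[a]
    }
  }
  selected
}

# Leaf selection: the deepest condensed clusters (no children); the root is
# only eligible when it has no children and allow_single_cluster is set.
leaf_select <- function(cond, allow_single_cluster = FALSE) {
  n_cl <- length(cond$cl_parent)
  has_child <- seq_len(n_cl) %in% cond$cl_parent
  selected <- !has_child
  if (!allow_single_cluster) selected[1] <- FALSE
  selected
}
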