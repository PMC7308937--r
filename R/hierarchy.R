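#' Build the cluster hierarchy by average-linkage (UPGMA) clustering
#'
#' Validated clusters are arranged into a rooted tree by agglomerative
#' clustering of their centroids (computed over *all* members, seed plus
#' grown) with average linkage, so similar clusters end up as close
#' neighbors and can be named or merged together. Merge heights are half
#' the average inter-group centroid distance, so two clusters at centroid
#' distance `d` join at height `d/2`. Ties are broken by the
#' lexicographically smallest cluster-id pair, making the tree
#' deterministic.
#'
#' @param clusters Nonempty list of `seed_cluster` objects.
#' @param features Feature tibble or matrix covering every member id.
#' @return A `cluster_hierarchy`: list with `nodes` (tibble: `node_id`,
#'   `parent`, `height`, `name`, `approved`, `leaf`, `cluster_id`) and
#'   `members` (named list, node id to member ids, leaves only). Leaves are
#'   nodes `1..K`; the root has `parent = NA`.
#' @export
build_hierarchy <- function(clusters, features) {
  stopifnot(length(clusters) >= 1)
  X <- if (is.matrix(features)) features else feature_matrix(features)
  K <- length(clusters)
  ids <- vapply(clusters, `[[`, "", "cluster_id")
  cent <- do.call(rbind, lapply(clusters, function(cl) {
    colMeans(X[cluster_members(cl), , drop = FALSE])
  }))

  nodes <- tibble::tibble(
    node_id = seq_len(2L * K - 1L),
    parent = NA_integer_,
    height = 0,
    name = NA_character_,
    approved = FALSE,
    leaf = c(rep(TRUE, K), rep(FALSE, K - 1L)),
    cluster_id = c(ids, rep(NA_character_, K - 1L))
  )
  members <- setNames(lapply(clusters, cluster_members), as.character(seq_len(K)))

  if (K > 1) {
    D <- as.matrix(stats::dist(cent))
    active <- seq_len(K)           # row/col index into D
    node_of <- seq_len(K)          # D index -> tree node id
    rep_id <- ids                  # smallest cluster_id under each D index
    size <- rep(1L, K)             # number of leaves per group
    for (s in seq_len(K - 1L)) {
      best <- NULL
      for (ii in seq_along(active)[-length(active)]) {
        for (jj in seq((ii + 1), length(active))) {
          i <- active[ii]; j <- active[jj]
          d <- D[i, j]
          lo <- min(rep_id[i], rep_id[j]); hi <- max(rep_id[i], rep_id[j])
          if (is.null(best) || d < best$d ||
              (d == best$d && (lo < best$lo || (lo == best$lo && hi < best$hi)))) {
            best <- list(i = i, j = j, d = d, lo = lo, hi = hi)
          }
        }
      }
      new_node <- K + s
      nodes$height[new_node] <- best$d / 2
      nodes$parent[node_of[best$i]] <- new_node
      nodes$parent[node_of[best$j]] <- new_node
      # average-linkage distance update, weighted by group sizes
      for (kk in setdiff(active, c(best$i, best$j))) {
        dn <- (size[best$i] * D[best$i, kk] + size[best$j] * D[best$j, kk]) /
          (size[best$i] + size[best$j])
        D[best$i, kk] <- dn
        D[kk, best$i] <- dn
      }
      size[best$i] <- size[best$i] + size[best$j]
      rep_id[best$i] <- min(rep_id[best$i], rep_id[best$j])
      node_of[best$i] <- new_node
      active <- setdiff(active, best$j)
    }
  }
  structure(list(nodes = nodes, members = members), class = "cluster_hierarchy")
}

#' @export
print.cluster_hierarchy <- function(x, ...) {
  cat(sprintf("<cluster_hierarchy> %d leaves, %d nodes, %d named, depth %d\n",
              sum(x$nodes$leaf), nrow(x$nodes), sum(!is.na(x$nodes$name)),
              tree_depth(x)))
  invisible(x)
}

tree_root <- function(tree) tree$nodes$node_id[is.na(tree$nodes$parent)]

node_children <- function(tree, id) tree$nodes$node_id[!is.na(tree$nodes$parent) & tree$nodes$parent == id]

node_ancestors <- function(tree, id) {
  out <- integer()
  p <- tree$nodes$parent[match(id, tree$nodes$node_id)]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- tree$nodes$parent[match(p, tree$nodes$node_id)]
  }
  out
}

node_descendants <- function(tree, id) {
  out <- integer()
  stack <- node_children(tree, id)
  while (length(stack) > 0) {
    v <- stack[1]
    stack <- stack[-1]
    out <- c(out, v)
    stack <- c(stack, node_children(tree, v))
  }
  out
}

#' Depth of a node / of the tree
#'
#' The root has depth 0.
#'
#' @param tree A `cluster_hierarchy`.
#' @param node_id Node id; `node_depth()` returns its depth,
#'   `tree_depth()` the maximum over all nodes.
#' @export
node_depth <- function(tree, node_id) length(node_ancestors(tree, node_id))

#' @rdname node_depth
#' @export
tree_depth <- function(tree) max(vapply(tree$nodes$node_id, function(i) node_depth(tree, i), integer(1)))

subtree_members <- function(tree, id) {
  nn <- c(id, node_descendants(tree, id))
  leaves <- intersect(nn, tree$nodes$node_id[tree$nodes$leaf])
  unlist(tree$members[as.character(leaves)], use.names = FALSE)
}

# remove unary internal nodes (and empty internals) introduced by edits
contract_tree <- function(tree) {
  repeat {
    internal <- tree$nodes$node_id[!tree$nodes$leaf]
    changed <- FALSE
    for (id in internal) {
      kids <- node_children(tree, id)
      if (length(kids) == 1) {
        p <- tree$nodes$parent[match(id, tree$nodes$node_id)]
        tree$nodes$parent[match(kids, tree$nodes$node_id)] <- p
        tree$nodes <- tree$nodes[tree$nodes$node_id != id, ]
        changed <- TRUE
        break
      }
      if (length(kids) == 0) {
        tree$nodes <- tree$nodes[tree$nodes$node_id != id, ]
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  tree
}

#' Merge hierarchy nodes into one
#'
#' Used when the annotator perceives clusters as identical. The nodes must
#' be directly related: either they share a common parent, or one of them is
#' an ancestor of all the others (unrelated branches must be moved first).
#' All objects under the merged nodes end up in a single leaf; the object
#' multiset is conserved. Merging a node with itself is a no-op.
#'
#' @param tree A `cluster_hierarchy`.
#' @param node_ids Ids of the nodes to merge (>= 1).
#' @return The edited tree.
#' @export
merge_nodes <- function(tree, node_ids) {
  node_ids <- unique(as.integer(node_ids))
  stopifnot(all(node_ids %in% tree$nodes$node_id))
  if (length(node_ids) == 1) return(tree)

  is_anc <- vapply(node_ids, function(a) {
    all(vapply(setdiff(node_ids, a), function(b) a %in% node_ancestors(tree, b), logical(1)))
  }, logical(1))
  parents <- tree$nodes$parent[match(node_ids, tree$nodes$node_id)]
  siblings <- !anyNA(parents) && length(unique(parents)) == 1

  if (any(is_anc)) {
    target <- node_ids[which(is_anc)[1]]
  } else if (siblings) {
    target <- node_ids[1]
  } else {
    abort("nodes must share a parent or be ancestor-related to merge; move them first")
  }

  absorbed <- setdiff(node_ids, target)
  all_members <- unique(unlist(c(
    lapply(c(target, absorbed), function(id) subtree_members(tree, id))
  ), use.names = FALSE))

  drop_ids <- unique(unlist(lapply(absorbed, function(id) c(id, node_descendants(tree, id)))))
  drop_ids <- union(drop_ids, node_descendants(tree, target))
  idx <- match(target, tree$nodes$node_id)
  keep_cluster <- tree$nodes$cluster_id[idx]
  if (is.na(keep_cluster)) {
    leaf_ids <- intersect(c(target, drop_ids), tree$nodes$node_id[tree$nodes$leaf])
    cands <- sort(tree$nodes$cluster_id[match(leaf_ids, tree$nodes$node_id)])
    keep_cluster <- cands[1]
  }
  tree$members[as.character(drop_ids)] <- NULL
  tree$nodes <- tree$nodes[!(tree$nodes$node_id %in% drop_ids), ]
  idx <- match(target, tree$nodes$node_id)
  tree$nodes$leaf[idx] <- TRUE
  tree$nodes$height[idx] <- 0
  tree$nodes$cluster_id[idx] <- keep_cluster
  tree$members[[as.character(target)]] <- all_members
  contract_tree(tree)
}

#' Move a node under a new parent
#'
#' The destination must be an internal node that is not the moved node
#' itself nor one of its descendants (no cycles).
#'
#' @param tree A `cluster_hierarchy`.
#' @param node_id Node to move (not the root).
#' @param new_parent_id Destination internal node.
#' @return The edited tree.
#' @export
move_node <- function(tree, node_id, new_parent_id) {
  stopifnot(node_id %in% tree$nodes$node_id, new_parent_id %in% tree$nodes$node_id)
  if (is.na(tree$nodes$parent[match(node_id, tree$nodes$node_id)])) {
    abort("cannot move the root")
  }
  if (tree$nodes$leaf[match(new_parent_id, tree$nodes$node_id)]) {
    abort("the new parent must be an internal node")
  }
  if (node_id == new_parent_id || new_parent_id %in% node_descendants(tree, node_id)) {
    abort("moving a node under itself or its descendant would create a cycle")
  }
  tree$nodes$parent[match(node_id, tree$nodes$node_id)] <- new_parent_id
  contract_tree(tree)
}

#' Name a hierarchy node
#'
#' Names are free-form nonempty strings; naming is idempotent and marks the
#' node approved.
#'
#' @param tree A `cluster_hierarchy`.
#' @param node_id Node to name.
#' @param name Nonempty string.
#' @return The edited tree.
#' @export
name_node <- function(tree, node_id, name) {
  stopifnot(node_id %in% tree$nodes$node_id)
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    abort("name must be a nonempty string")
  }
  idx <- match(node_id, tree$nodes$node_id)
  tree$nodes$name[idx] <- name
  tree$nodes$approved[idx] <- TRUE
  tree
}

#' Flatten the hierarchy into an object-level labeling
#'
#' Every object receives the name of its leaf's nearest named ancestor (the
#' leaf's own name preferred); objects under branches that were never named
#' get the reserved label `"unnamed"`. Objects outside the hierarchy
#' (residuals) are absent from the result.
#'
#' @param tree A `cluster_hierarchy`.
#' @return Label tibble (`object_id`, `label`).
#' @export
flatten_labels <- function(tree) {
  leaves <- tree$nodes$node_id[tree$nodes$leaf]
  out <- purrr::map_dfr(leaves, function(leaf) {
    lab <- UNNAMED_LABEL
    for (id in c(leaf, node_ancestors(tree, leaf))) {
      nm <- tree$nodes$name[match(id, tree$nodes$node_id)]
      if (!is.na(nm)) { lab <- nm; break }
    }
    tibble::tibble(object_id = tree$members[[as.character(leaf)]], label = lab)
  })
  dplyr::arrange(out, .data$object_id)
}

#' Export a hierarchy to Newick or JSON
#'
#' Newick carries merge heights as branch lengths and node names as labels
#' (quoted when needed, via \pkg{ape}); the JSON dialect additionally
#' carries per-leaf member lists.
#'
#' @param tree A `cluster_hierarchy`.
#' @param path Output file.
#' @param format `"newick"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(tree, path, format = c("newick", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    nodes <- tree$nodes
    payload <- list(
      nodes = nodes,
      members = tree$members
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  leaves <- tree$nodes$node_id[tree$nodes$leaf]
  if (length(leaves) == 1) {
    lab <- tree$nodes$name[match(leaves, tree$nodes$node_id)]
    if (is.na(lab)) lab <- tree$nodes$cluster_id[match(leaves, tree$nodes$node_id)]
    writeLines(paste0(gsub(" ", "_", lab), ";"), path)
    return(invisible(path))
  }
  ape::write.tree(hierarchy_phylo(tree), file = path)
  invisible(path)
}

#' Convert a hierarchy to an \pkg{ape} `phylo` object
#'
#' Tips are leaves (labeled by name, falling back to cluster id); branch
#' lengths are parent-child height differences, floored at zero.
#'
#' @param tree A `cluster_hierarchy` with at least two leaves.
#' @return A `phylo` object.
#' @export
hierarchy_phylo <- function(tree) {
  nodes <- tree$nodes
  leaves <- nodes$node_id[nodes$leaf]
  internals <- nodes$node_id[!nodes$leaf]
  stopifnot(length(leaves) >= 2)
  tip_no <- setNames(seq_along(leaves), leaves)
  int_no <- setNames(length(leaves) + seq_along(c(tree_root(tree), setdiff(internals, tree_root(tree)))),
                     c(tree_root(tree), setdiff(internals, tree_root(tree))))
  num <- c(tip_no, int_no)
  has_parent <- !is.na(nodes$parent)
  edge <- cbind(num[as.character(nodes$parent[has_parent])],
                num[as.character(nodes$node_id[has_parent])])
  hgt <- setNames(nodes$height, nodes$node_id)
  elen <- pmax(0, hgt[as.character(nodes$parent[has_parent])] -
                 hgt[as.character(nodes$node_id[has_parent])])
  tip_label <- vapply(leaves, function(id) {
    i <- match(id, nodes$node_id)
    if (!is.na(nodes$name[i])) nodes$name[i] else nodes$cluster_id[i]
  }, character(1))
  node_label <- vapply(names(int_no), function(id) {
    nm <- nodes$name[match(as.integer(id), nodes$node_id)]
    if (is.na(nm)) "" else nm
  }, character(1))
  phy <- list(edge = unname(edge), tip.label = unname(tip_label),
              edge.length = unname(as.numeric(elen)),
              Nnode = length(int_no), node.label = unname(node_label))
  class(phy) <- "phylo"
  phy
}
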