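test_that("tiny hierarchies match the UPGMA definition", {
  # one cluster: single-leaf tree
  X1 <- matrix(c(1, 2), 1, 2, dimnames = list("a", NULL))
  t1 <- build_hierarchy(point_clusters(X1), X1)
  expect_equal(nrow(t1$nodes), 1L)
  expect_true(t1$nodes$leaf)

  # two clusters at centroid distance d join at height d/2
  X2 <- matrix(c(0, 3), 2, 1, dimnames = list(c("a", "b"), NULL))
  t2 <- build_hierarchy(point_clusters(X2), X2)
  expect_equal(max(t2$nodes$height), 1.5)

  # four leaves: d(A,B)=1, d(C,D)=2, all cross distances 10
  y <- sqrt(100 - 1.25)
  X4 <- rbind(A = c(-0.5, 0, 0), B = c(0.5, 0, 0),
              C = c(0, y, -1), D = c(0, y, 1))
  t4 <- build_hierarchy(point_clusters(X4), X4)
  internal <- sort(t4$nodes$height[!t4$nodes$leaf])
  expect_equal(internal, c(0.5, 1.0, 5.0), tolerance = 1e-9)
  expect_equal(tree_merge_sets(t4), list(c("A", "B"), c("C", "D"), c("A", "B", "C", "D")))
})

test_that("the hierarchy agrees with brute-force UPGMA on random instances", {
  withr::with_seed(42, {
    for (trial in 1:25) {
      K <- sample(2:12, 1)
      X <- matrix(rnorm(K * 3), K, 3)
      rownames(X) <- sprintf("L%02d", seq_len(K))
      tree <- build_hierarchy(point_clusters(X), X)
      oracle <- upgma_bruteforce(as.matrix(dist(X)), rownames(X))
      expect_equal(tree$nodes$height[!tree$nodes$leaf], oracle$heights,
                   tolerance = 1e-9)
      expect_identical(tree_merge_sets(tree), oracle$merges)
    }
  })
})

test_that("merge heights are non-decreasing and match hclust average linkage", {
  withr::with_seed(8, {
    X <- matrix(rnorm(30), 10, 3)
  })
  rownames(X) <- sprintf("L%02d", 1:10)
  tree <- build_hierarchy(point_clusters(X), X)
  h <- tree$nodes$height[!tree$nodes$leaf]
  expect_true(all(diff(h) >= -1e-12))
  hc <- stats::hclust(dist(X), method = "average")
  expect_equal(sort(2 * h), sort(hc$height), tolerance = 1e-9)
})

test_that("centroids for the hierarchy include grown members", {
  X <- matrix(c(0, 2, 10, 30), 4, 1,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  cl1 <- clustergrow:::new_cluster("c1", "a", X["a", ], 1L)
  cl1$approved <- TRUE
  cl1$grown_members <- "b"   # full centroid moves to 1
  cl2 <- clustergrow:::new_cluster("c2", "c", X["c", ], 1L)
  cl2$approved <- TRUE
  tree <- build_hierarchy(list(cl1, cl2), X)
  expect_equal(max(tree$nodes$height), (10 - 1) / 2)
})

test_that("sibling leaves merge into one leaf conserving objects", {
  X <- rbind(a = c(0, 0), b = c(1, 0), c = c(20, 0))
  tree <- build_hierarchy(point_clusters(X), X)
  before <- sort(unname(unlist(tree$members)))
  leaves <- tree$nodes$node_id[tree$nodes$leaf]
  sibs <- leaves[tree$nodes$cluster_id[match(leaves, tree$nodes$node_id)] %in% c("a", "b")]
  merged <- merge_nodes(tree, sibs)
  expect_equal(sum(merged$nodes$leaf), 2L)
  expect_setequal(sort(unname(unlist(merged$members))), before)
  kept <- intersect(sibs, merged$nodes$node_id)
  expect_setequal(merged$members[[as.character(kept)]], c("a", "b"))

  # self-merge is a no-op; unrelated merges are refused
  expect_identical(merge_nodes(tree, sibs[1]), tree)
  other <- setdiff(leaves, sibs)
  expect_error(merge_nodes(tree, c(sibs[1], other)), "share a parent")
})

test_that("an ancestor absorbs its descendants into a single leaf", {
  X <- rbind(a = c(0, 0), b = c(1, 0), c = c(20, 0), d = c(40, 40))
  tree <- build_hierarchy(point_clusters(X), X)
  # internal node over {a, b}
  anc <- tree$nodes$node_id[!tree$nodes$leaf][1]
  kids <- clustergrow:::node_descendants(tree, anc)
  merged <- merge_nodes(tree, c(anc, kids))
  expect_setequal(merged$members[[as.character(anc)]], c("a", "b"))
  expect_setequal(sort(unname(unlist(merged$members))), c("a", "b", "c", "d"))
})

test_that("moves re-parent without cycles and shorten depth when moving up", {
  withr::with_seed(31, {
    X <- matrix(rnorm(16), 8, 2)
  })
  rownames(X) <- letters[1:8]
  tree <- build_hierarchy(point_clusters(X), X)
  root <- clustergrow:::tree_root(tree)
  deepest <- tree$nodes$node_id[which.max(vapply(tree$nodes$node_id,
                                                 function(i) node_depth(tree, i), integer(1)))]
  moved <- move_node(tree, deepest, root)
  expect_equal(node_depth(moved, deepest), 1L)

  expect_error(move_node(tree, root, deepest), "root")
  leaf <- tree$nodes$node_id[tree$nodes$leaf][1]
  other_leaf <- tree$nodes$node_id[tree$nodes$leaf][2]
  expect_error(move_node(tree, other_leaf, leaf), "internal")
  internal <- setdiff(tree$nodes$node_id[!tree$nodes$leaf], root)[1]
  expect_error(move_node(tree, internal, internal), "cycle")

  # property: random scripts of upward moves never deepen the tree
  for (trial in 1:10) {
    t2 <- tree
    withr::with_seed(trial, {
      for (step in 1:5) {
        nds <- setdiff(t2$nodes$node_id, clustergrow:::tree_root(t2))
        nd <- nds[sample.int(length(nds), 1)]
        anc <- clustergrow:::node_ancestors(t2, nd)
        anc <- setdiff(anc, t2$nodes$parent[match(nd, t2$nodes$node_id)])
        if (length(anc) == 0) next
        t2 <- move_node(t2, nd, anc[sample.int(length(anc), 1)])
      }
    })
    expect_lte(tree_depth(t2), tree_depth(tree))
    expect_setequal(sort(unname(unlist(t2$members))), sort(unname(unlist(tree$members))))
  }
})

test_that("naming is validated and idempotent", {
  X <- rbind(a = c(0, 0), b = c(10, 0))
  tree <- build_hierarchy(point_clusters(X), X)
  leaf <- tree$nodes$node_id[tree$nodes$leaf][1]
  named <- name_node(tree, leaf, "copepod")
  expect_identical(name_node(named, leaf, "copepod"), named)
  expect_error(name_node(tree, leaf, ""), "nonempty")
})

test_that("flattening assigns the nearest named ancestor", {
  X <- rbind(a = c(0, 0), b = c(1, 0), c = c(20, 0))
  tree <- build_hierarchy(point_clusters(X), X)
  leaves <- tree$nodes$node_id[tree$nodes$leaf]
  leaf_a <- leaves[tree$nodes$cluster_id[match(leaves, tree$nodes$node_id)] == "a"]
  inner <- tree$nodes$parent[match(leaf_a, tree$nodes$node_id)]

  # fully unnamed tree -> everything "unnamed"
  expect_equal(unique(flatten_labels(tree)$label), "unnamed")

  # named leaf wins; unnamed leaf inherits the internal node's name
  tree <- name_node(tree, leaf_a, "copepod")
  tree <- name_node(tree, inner, "detritus")
  lab <- flatten_labels(tree)
  expect_equal(lab$label[lab$object_id == "a"], "copepod")
  expect_equal(lab$label[lab$object_id == "b"], "detritus")
  expect_equal(lab$label[lab$object_id == "c"], "unnamed")
  # exactly one label per clustered object
  expect_equal(sort(lab$object_id), c("a", "b", "c"))
})

test_that("newick export round-trips through ape", {
  withr::with_seed(12, {
    X <- matrix(rnorm(12), 6, 2)
  })
  rownames(X) <- sprintf("L%d", 1:6)
  tree <- build_hierarchy(point_clusters(X), X)
  tree <- name_node(tree, 1L, "calanoid copepod")  # space forces quoting
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_hierarchy(tree, tmp, format = "newick")
  phy <- ape::read.tree(tmp)
  expect_equal(ape::Ntip(phy), 6)
  expect_true(any(grepl("calanoid", phy$tip.label)))
  # branch lengths encode merge heights: root-to-tip distance = root height
  expect_equal(max(ape::node.depth.edgelength(phy)), max(tree$nodes$height),
               tolerance = 1e-9)

  tmp2 <- withr::local_tempfile(fileext = ".json")
  write_hierarchy(tree, tmp2, format = "json")
  back <- jsonlite::fromJSON(tmp2)
  expect_equal(nrow(back$nodes), nrow(tree$nodes))
  expect_setequal(unname(unlist(back$members)), unname(unlist(tree$members)))
})
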