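#' Run the full annotation process end to end
#'
#' For each minimum cluster size in the schedule: extract density seeds from
#' the unassigned pool, have the annotator validate each seed (largest
#' first), then grow every newly approved cluster (flagged clusters first,
#' then by descending seed size) with the paged boundary-search protocol.
#' After the schedule is exhausted the validated clusters are arranged into
#' a UPGMA hierarchy, named (by [oracle_namer()] when the annotator is an
#' oracle), and flattened into an object labeling. The partition invariant
#' is asserted after every stage. Objects never assigned are reported as
#' residuals.
#'
#' @param features Feature tibble (`object_id` + numeric columns).
#' @param annotator An annotator object.
#' @param m_schedule Strictly decreasing minimum cluster sizes
#'   (default `c(128, 64, 32, 16, 8, 4)`).
#' @param k Density neighborhood size (default 1).
#' @param page_size Growth page size (default 50).
#' @param turtle Whether turtle mode may activate during growth.
#' @param turtle_patience Consecutive rejections ending a turtle scan.
#' @param rng_seed Seed for any internal randomness.
#' @param cluster_selection Condensed-tree selection method for seeding
#'   (`"eom"` default).
#' @param stop_on_empty Stop early when an iteration validates no seed.
#' @param namer Optional `function(tree)` that names the hierarchy; defaults
#'   to [oracle_namer()] with the oracle's truth when available.
#' @return An `annotation_run`: list with `labels` (tibble), `clusters`
#'   (tibble, one row per validated cluster with list-columns
#'   `seed_members` and `grown_members`), `hierarchy`, `events`,
#'   `residual_ids` and the configuration used.
#' @export
run_full <- function(features, annotator, m_schedule = c(128, 64, 32, 16, 8, 4),
                     k = 1, page_size = 50, turtle = TRUE, turtle_patience = 50,
                     rng_seed = 0, cluster_selection = "eom",
                     stop_on_empty = FALSE, namer = NULL) {
  if (nrow(features) == 0) {
    return(structure(list(
      labels = tibble::tibble(object_id = character(), label = character()),
      clusters = empty_cluster_tibble(), hierarchy = NULL, events = event_log(),
      residual_ids = character(), n_objects = 0L,
      m_schedule = as.integer(m_schedule), page_size = as.integer(page_size),
      rng_seed = as.integer(rng_seed)
    ), class = "annotation_run"))
  }
  state <- new_process(features, m_schedule = m_schedule, k = k,
                       page_size = page_size, rng_seed = rng_seed,
                       cluster_selection = cluster_selection)
  repeat {
    state <- next_iteration(state)
    if (isTRUE(state$done)) break
    new_ids <- state$new_seed_ids

    # validation, largest seed first (already ordered by seed_clusters)
    for (cid in new_ids) {
      state <- validate_seed(state, cid, annotator)
    }
    approved_new <- intersect(new_ids, names(state$clusters))

    # growth queue: flagged first, then descending seed size
    if (length(approved_new) > 0) {
      info <- tibble::tibble(
        cid = approved_new,
        flagged = vapply(state$clusters[approved_new], `[[`, TRUE, "flagged"),
        n_seed = vapply(state$clusters[approved_new],
                        function(cl) length(cl$seed_members), integer(1))
      )
      queue <- info$cid[order(-info$flagged, -info$n_seed, info$cid)]
      for (cid in queue) {
        pool <- unassigned_ids(state)
        res <- grow_cluster(state$clusters[[cid]], pool, state$X, annotator,
                            page_size = state$page_size, turtle = turtle,
                            turtle_patience = turtle_patience)
        state$clusters[[cid]] <- res$cluster
        state$events <- log_event(state$events, "grow", "grow",
                                  length(res$accepted))
        assert_conservation(state)
      }
    }
    if (stop_on_empty && length(approved_new) == 0) {
      state$done <- TRUE
      state$residual_ids <- unassigned_ids(state)
      break
    }
  }
  if (is.null(state$residual_ids)) state$residual_ids <- unassigned_ids(state)

  clusters <- state$clusters
  tree <- NULL
  labels <- tibble::tibble(object_id = character(), label = character())
  if (length(clusters) > 0) {
    tree <- build_hierarchy(clusters, state$X)
    if (is.null(namer)) {
      if (inherits(annotator, "oracle_annotator")) {
        truth <- tibble::tibble(object_id = names(annotator$truth),
                                label = unname(annotator$truth))
        namer <- function(t) oracle_namer(t, truth)
      } else {
        namer <- identity
      }
    }
    tree <- namer(tree)
    for (leaf in tree$nodes$node_id[tree$nodes$leaf]) {
      state$events <- log_event(state$events, "name", "name_leaf",
                                length(tree$members[[as.character(leaf)]]))
    }
    labels <- flatten_labels(tree)
  }

  structure(list(
    labels = labels,
    clusters = cluster_tibble(clusters, tree),
    hierarchy = tree,
    events = state$events,
    residual_ids = state$residual_ids,
    n_objects = nrow(state$X),
    m_schedule = state$m_schedule,
    page_size = state$page_size,
    rng_seed = state$rng_seed
  ), class = "annotation_run")
}

empty_cluster_tibble <- function() {
  tibble::tibble(cluster_id = character(), iteration = integer(),
                 n_seed = integer(), n_grown = integer(), flagged = logical(),
                 name = character(), seed_members = list(), grown_members = list())
}

cluster_tibble <- function(clusters, tree = NULL) {
  if (length(clusters) == 0) return(empty_cluster_tibble())
  tb <- tibble::tibble(
    cluster_id = vapply(clusters, `[[`, "", "cluster_id"),
    iteration = vapply(clusters, `[[`, 1L, "iteration"),
    n_seed = vapply(clusters, function(cl) length(cl$seed_members), integer(1)),
    n_grown = vapply(clusters, function(cl) length(cl$grown_members), integer(1)),
    flagged = vapply(clusters, `[[`, TRUE, "flagged"),
    name = NA_character_,
    seed_members = lapply(clusters, `[[`, "seed_members"),
    grown_members = lapply(clusters, `[[`, "grown_members")
  )
  if (!is.null(tree)) {
    # post-naming, clusters can have been merged into hierarchy leaves: a
    # cluster's name is the flattened label of its (absorbed) members
    leaf_rows <- tree$nodes[tree$nodes$leaf, ]
    for (i in seq_len(nrow(leaf_rows))) {
      leaf <- leaf_rows$node_id[i]
      lab <- UNNAMED_LABEL
      for (id in c(leaf, node_ancestors(tree, leaf))) {
        nm <- tree$nodes$name[match(id, tree$nodes$node_id)]
        if (!is.na(nm)) { lab <- nm; break }
      }
      mem <- tree$members[[as.character(leaf)]]
      hit <- vapply(seq_len(nrow(tb)), function(j) tb$seed_members[[j]][1] %in% mem, logical(1))
      tb$name[hit] <- lab
    }
  }
  tb
}

#' @export
print.annotation_run <- function(x, ...) {
  cat(sprintf("<annotation_run> %d objects -> %d clusters, %d named classes, %d residual (%.1f%%)\n",
              x$n_objects, nrow(x$clusters),
              length(setdiff(unique(x$labels$label), UNNAMED_LABEL)),
              length(x$residual_ids),
              100 * length(x$residual_ids) / max(1, x$n_objects)))
  invisible(x)
}

#' Name a hierarchy from ground truth
#'
#' Automates the leaves-to-root naming walk for tests and benchmarks: every
#' leaf is named by the predominant ground-truth label of its members (ties
#' broken lexicographically), then same-named sibling leaves are merged
#' until no such pair remains. Deterministic.
#'
#' @param tree A `cluster_hierarchy`.
#' @param truth Ground-truth label tibble covering all clustered objects.
#' @return The named (and possibly merged) tree.
#' @export
oracle_namer <- function(tree, truth) {
  tv <- labels_as_vector(truth)
  for (leaf in tree$nodes$node_id[tree$nodes$leaf]) {
    labs <- tv[tree$members[[as.character(leaf)]]]
    if (anyNA(labs)) abort("truth does not cover all clustered objects")
    tab <- table(labs)
    tree <- name_node(tree, leaf, names(tab)[order(-tab, names(tab))][1])
  }
  repeat {
    leaves <- tree$nodes[tree$nodes$leaf, ]
    leaves <- leaves[!is.na(leaves$parent), , drop = FALSE]
    if (nrow(leaves) == 0) break
    grp <- split(leaves$node_id, paste(leaves$parent, leaves$name))
    grp <- grp[vapply(grp, length, integer(1)) > 1]
    if (length(grp) == 0) break
    ids <- grp[[1]]
    nm <- tree$nodes$name[match(ids[1], tree$nodes$node_id)]
    tree <- merge_nodes(tree, sort(ids))
    kept <- intersect(ids, tree$nodes$node_id)
    tree <- name_node(tree, kept[1], nm)
  }
  tree
}
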