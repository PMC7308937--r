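#' Start an annotation process over a feature set
#'
#' Holds everything the iterative seed / validate / grow loop needs: the
#' feature matrix, the shrinking minimum-cluster-size schedule, the current
#' cluster list and the event log. Objects live in exactly one place at all
#' times: either the implicit unassigned pool or a single cluster's member
#' sets (see [unassigned_ids()] and [assert_conservation()]).
#'
#' @param features Feature tibble (`object_id` + numeric feature columns).
#' @param m_schedule Strictly decreasing minimum cluster sizes, one per
#'   iteration (default `c(128, 64, 32, 16, 8, 4)`).
#' @param k Neighborhood size for density clustering (default 1).
#' @param page_size Page size used during growing (default 50).
#' @param rng_seed Seed for any internal randomness.
#' @param cluster_selection Condensed-tree selection method for seeding
#'   (`"eom"` default, `"leaf"` for smaller purer cores).
#' @return An object of class `annotation_process`.
#' @export
new_process <- function(features, m_schedule = c(128, 64, 32, 16, 8, 4),
                        k = 1, page_size = 50, rng_seed = 0,
                        cluster_selection = "eom") {
  check_feature_table(features)
  m_schedule <- as.integer(m_schedule)
  if (length(m_schedule) == 0 || any(m_schedule < 2) || any(diff(m_schedule) >= 0)) {
    abort("m_schedule must be strictly decreasing positive integers (>= 2)")
  }
  structure(list(
    X = feature_matrix(features),
    m_schedule = m_schedule,
    k = k,
    page_size = as.integer(page_size),
    rng_seed = as.integer(rng_seed),
    cluster_selection = cluster_selection,
    iteration = 0L,
    clusters = list(),
    events = event_log(),
    done = FALSE
  ), class = "annotation_process")
}

#' @export
print.annotation_process <- function(x, ...) {
  cat(sprintf("<annotation_process> %d objects, iteration %d/%d, %d clusters, %d unassigned\n",
              nrow(x$X), x$iteration, length(x$m_schedule),
              length(x$clusters), length(unassigned_ids(x))))
  invisible(x)
}

new_cluster <- function(cluster_id, seed_members, centroid, iteration) {
  stopifnot(length(seed_members) > 0)
  structure(list(
    cluster_id = cluster_id,
    iteration = as.integer(iteration),
    seed_members = seed_members,
    grown_members = character(),
    centroid = centroid,
    approved = FALSE,
    flagged = FALSE,
    name = NA_character_
  ), class = "seed_cluster")
}

cluster_members <- function(cluster) c(cluster$seed_members, cluster$grown_members)

#' Ids not assigned to any cluster
#'
#' Recomputed from the cluster list so the partition invariant is always
#' checkable against the full object set.
#'
#' @param state An `annotation_process`.
#' @return Character vector of unassigned object ids.
#' @export
unassigned_ids <- function(state) {
  assigned <- unlist(lapply(state$clusters, cluster_members), use.names = FALSE)
  setdiff(rownames(state$X), assigned)
}

#' Assert the partition invariant
#'
#' Every object id must sit in exactly one of: the unassigned pool, or one
#' cluster's seed or grown member set. Called internally after every stage.
#'
#' @param state An `annotation_process`.
#' @return `state`, invisibly; aborts on violation.
#' @export
assert_conservation <- function(state) {
  assigned <- unlist(lapply(state$clusters, cluster_members), use.names = FALSE)
  if (anyDuplicated(assigned)) {
    abort("conservation violated: an object belongs to more than one cluster member set")
  }
  if (!all(assigned %in% rownames(state$X))) {
    abort("conservation violated: cluster member not in the feature set")
  }
  n <- length(assigned) + length(setdiff(rownames(state$X), assigned))
  if (n != nrow(state$X)) {
    abort("conservation violated: member counts do not partition the object set")
  }
  invisible(state)
}

#' Extract density-based cluster seeds from a pool of objects
#'
#' Runs HDBSCAN* (see [hdbscan_star()]) on the given objects and returns
#' one unapproved cluster per detected dense region, each with at least `m`
#' members. Objects labeled noise stay unassigned. Returned seeds are
#' ordered by decreasing size (the order in which they are presented for
#' validation).
#'
#' @param features Feature tibble restricted to the unassigned pool.
#' @param m Minimum cluster size (>= 2).
#' @param k Neighborhood size (default 1).
#' @param iteration Iteration number recorded on each seed.
#' @param id_prefix Prefix for generated cluster ids.
#' @param cluster_selection Condensed-tree selection method passed to
#'   [hdbscan_star()] (`"eom"` default).
#' @return List of `seed_cluster` objects (possibly empty). The centroid of
#'   each seed is the arithmetic mean of its members' feature rows.
#' @export
seed_clusters <- function(features, m, k = 1, iteration = 1L,
                          id_prefix = sprintf("it%d", iteration),
                          cluster_selection = "eom") {
  check_feature_table(features)
  stopifnot(m >= 2)
  X <- feature_matrix(features)
  if (nrow(X) < m) return(list())
  lab <- hdbscan_star(X, min_cluster_size = m, k = k,
                      cluster_selection = cluster_selection)
  ks <- setdiff(sort(unique(lab)), 0L)
  out <- lapply(ks, function(kk) {
    ids <- rownames(X)[lab == kk]
    new_cluster(
      cluster_id = sprintf("%s_c%03d", id_prefix, kk),
      seed_members = ids,
      centroid = colMeans(X[ids, , drop = FALSE]),
      iteration = iteration
    )
  })
  out[order(-vapply(out, function(cl) length(cl$seed_members), integer(1)))]
}

#' Advance the process to its next clustering iteration
#'
#' Re-clusters the current unassigned pool with the next (smaller) minimum
#' cluster size in the schedule and appends the resulting unapproved seeds.
#' When the schedule is exhausted the process is marked done and the
#' remaining pool becomes the *residual objects*.
#'
#' @param state An `annotation_process` whose current iteration's validation
#'   and growing are complete.
#' @return The updated state; `state$new_seed_ids` holds the ids of the
#'   seeds added in this iteration (empty when done).
#' @export
next_iteration <- function(state) {
  stopifnot(inherits(state, "annotation_process"))
  state$new_seed_ids <- character()
  if (state$iteration >= length(state$m_schedule)) {
    state$done <- TRUE
    state$residual_ids <- unassigned_ids(state)
    return(state)
  }
  state$iteration <- state$iteration + 1L
  m <- state$m_schedule[state$iteration]
  pool <- unassigned_ids(state)
  if (length(pool) >= m) {
    feats <- tibble::as_tibble(state$X[pool, , drop = FALSE], rownames = "object_id")
    seeds <- seed_clusters(feats, m = m, k = state$k, iteration = state$iteration,
                           cluster_selection = state$cluster_selection)
    state$clusters <- c(state$clusters, setNames(seeds, vapply(seeds, `[[`, "", "cluster_id")))
    state$new_seed_ids <- vapply(seeds, `[[`, "", "cluster_id")
  }
  assert_conservation(state)
  state
}
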