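#' Arrange cluster members for maximally contrasting display
#'
#' Orders members so that consecutive items are far apart in feature space,
#' which makes impurities stand out during seed validation. Greedy rule:
#' start from the pair at maximum distance (ties broken by the
#' lexicographically smallest id pair, smaller id first), then repeatedly
#' append the member farthest from the previously placed item (ties broken
#' by object id).
#'
#' @param members Nonempty character vector of object ids.
#' @param features Feature tibble or numeric matrix with ids as row names.
#' @return A permutation of `members`.
#' @export
arrange_dissimilar <- function(members, features) {
  stopifnot(length(members) > 0)
  X <- if (is.matrix(features)) features else feature_matrix(features)
  if (length(members) == 1) return(members)
  members <- sort(members)
  D <- as.matrix(stats::dist(X[members, , drop = FALSE]))
  n <- length(members)
  # starting pair: maximum distance, smallest id pair on ties
  best <- c(1L, 2L)
  bestd <- -Inf
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
    }
  }
  ord <- best
  remaining <- setdiff(seq_len(n), ord)
  while (length(remaining) > 0) {
    last <- ord[length(ord)]
    d <- D[last, remaining]
    pick <- remaining[order(-d, members[remaining])][1]
    ord <- c(ord, pick)
    remaining <- setdiff(remaining, pick)
  }
  members[ord]
}

#' Rank growth candidates by distance to a seed centroid
#'
#' Pure function: the pool sorted by ascending Euclidean distance to the
#' centroid, ties broken by object id ascending.
#'
#' @param centroid Numeric D-vector.
#' @param pool Character vector of candidate object ids.
#' @param features Feature tibble or matrix with ids as row names.
#' @return `pool` reordered; empty pool gives an empty vector.
#' @export
rank_candidates <- function(centroid, pool, features) {
  if (length(pool) == 0) return(character())
  X <- if (is.matrix(features)) features else feature_matrix(features)
  d <- sqrt(rowSums((X[pool, , drop = FALSE] -
                       matrix(centroid, length(pool), length(centroid), byrow = TRUE))^2))
  pool[order(d, pool)]
}

#' Validate a cluster seed
#'
#' Presents an unapproved seed to the annotator. Accepted seeds are marked
#' approved (and optionally flagged for preferred treatment during growth);
#' rejected seeds are deleted and their members return to the unassigned
#' pool. Either way the total object count is conserved.
#'
#' @param state An `annotation_process`.
#' @param cluster_id Id of an unapproved cluster in `state`.
#' @param annotator An annotator object.
#' @param flag Whether an accepted seed is additionally flagged.
#' @return The updated state.
#' @export
validate_seed <- function(state, cluster_id, annotator, flag = FALSE) {
  cl <- state$clusters[[cluster_id]]
  if (is.null(cl)) abort(sprintf("no cluster '%s'", cluster_id))
  if (isTRUE(cl$approved)) abort(sprintf("cluster '%s' is already approved", cluster_id))
  verdict <- judge_cluster(annotator, cl$seed_members)
  if (verdict$decision == "accept") {
    cl$approved <- TRUE
    cl$flagged <- isTRUE(flag)
    state$clusters[[cluster_id]] <- cl
    state$events <- log_event(state$events, "validate", "approve",
                              length(cl$seed_members))
  } else {
    state$clusters[[cluster_id]] <- NULL
    state$events <- log_event(state$events, "validate", "reject",
                              length(cl$seed_members))
  }
  assert_conservation(state)
  state
}

#' Grow a validated cluster by paged boundary search
#'
#' Candidates from the pool are ranked by distance to the seed centroid and
#' cut into pages of `page_size`. The protocol finds the last fully matching
#' page `b` with few judgments:
#'
#' * *Galloping phase*: pages 1, 2, 4, 8, ... (index multiplied by
#'   `gallop_factor`, capped at the last page) are judged until one
#'   mismatches, bracketing the boundary.
#' * *Binary phase*: standard binary search inside the bracket; pages below
#'   the last matching probe are never re-judged (if a page matches, all
#'   earlier pages are assumed to match too).
#' * *Turtle mode* (optional): when the first mismatching page is only
#'   partially foreign, every candidate from that page onward is judged
#'   individually until `turtle_patience` consecutive rejections, trading
#'   speed for an exact border.
#'
#' All objects of pages `1..b`, plus any individually accepted objects, move
#' from the pool into `cluster$grown_members`.
#'
#' @param cluster An approved `seed_cluster`.
#' @param pool Character vector of unassigned candidate ids.
#' @param features Feature tibble or matrix with ids as row names.
#' @param annotator An annotator object.
#' @param page_size Objects per page (default 50).
#' @param turtle Whether turtle mode may activate (default `TRUE`).
#' @param turtle_patience Consecutive individual rejections that end a
#'   turtle scan (default 50, one page worth).
#' @param gallop_factor Page-index growth factor of the galloping phase.
#' @return A list with `cluster` (updated), `pool` (shrunk), `accepted`
#'   (ids added, in rank order), `boundary_page`, `n_page_judgments`,
#'   `n_object_judgments` and `turtle_activated`.
#' @export
grow_cluster <- function(cluster, pool, features, annotator, page_size = 50,
                         turtle = TRUE, turtle_patience = 50, gallop_factor = 2) {
  stopifnot(inherits(cluster, "seed_cluster"), isTRUE(cluster$approved),
            page_size >= 1, gallop_factor >= 2)
  out <- list(cluster = cluster, pool = pool, accepted = character(),
              boundary_page = 0L, n_page_judgments = 0L,
              n_object_judgments = 0L, turtle_activated = FALSE)
  if (length(pool) == 0) return(out)

  ranked <- rank_candidates(cluster$centroid, pool, features)
  P <- ceiling(length(ranked) / page_size)
  page_of <- function(p) ranked[(((p - 1) * page_size) + 1):min(p * page_size, length(ranked))]
  seed_label <- seed_reference_label(annotator, cluster$seed_members)

  judged <- vector("list", P)
  judge <- function(p) {
    if (is.null(judged[[p]])) {
      judged[[p]] <<- judge_page(annotator, page_of(p), seed_label)
      out$n_page_judgments <<- out$n_page_judgments + 1L
    }
    judged[[p]]
  }

  # galloping phase: bracket the boundary
  g <- 0L
  f <- NA_integer_
  probe <- 1L
  repeat {
    res <- judge(probe)
    if (res$match) {
      g <- probe
      if (probe == P) break
      probe <- min(P, probe * gallop_factor)
    } else {
      f <- probe
      break
    }
  }
  # binary phase: last matching page in (g, f)
  if (!is.na(f)) {
    while (f - g > 1L) {
      mid <- (g + f) %/% 2L
      if (judge(mid)$match) g <- mid else f <- mid
    }
  }
  b <- g
  accepted <- if (b > 0) ranked[seq_len(min(b * page_size, length(ranked)))] else character()

  # turtle mode: exact border when the first mismatching page is partial
  if (turtle && !is.na(f)) {
    first_bad <- judged[[f]]
    page_ids <- page_of(f)
    if (length(first_bad$offending) < length(page_ids)) {
      out$turtle_activated <- TRUE
      start <- (f - 1L) * page_size + 1L
      consec <- 0L
      for (i in start:length(ranked)) {
        ok <- judge_object(annotator, ranked[i], seed_label)
        out$n_object_judgments <- out$n_object_judgments + 1L
        if (ok) {
          accepted <- c(accepted, ranked[i])
          consec <- 0L
        } else {
          consec <- consec + 1L
          if (consec >= turtle_patience) break
        }
      }
    }
  }

  cluster$grown_members <- c(cluster$grown_members, accepted)
  out$cluster <- cluster
  out$pool <- setdiff(pool, accepted)
  out$accepted <- accepted
  out$boundary_page <- as.integer(b)
  out
}
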