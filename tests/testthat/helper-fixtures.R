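# Gaussian blob fixture: one class per row of `centers`.
make_blobs <- function(centers, n_per, sd = 1, seed = 1, prefix = "b") {
  centers <- as.matrix(centers)
  if (length(n_per) == 1) n_per <- rep(n_per, nrow(centers))
  withr::with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(stats::rnorm(n_per[i] * ncol(centers), sd = sd), n_per[i]) +
        matrix(centers[i, ], n_per[i], ncol(centers), byrow = TRUE)
    }))
  })
  n <- sum(n_per)
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  features <- tibble::as_tibble(rows, .name_repair = ~ sprintf("f%d", seq_len(ncol(centers))))
  features <- dplyr::bind_cols(tibble::tibble(object_id = ids), features)
  labels <- tibble::tibble(object_id = ids,
                           label = rep(sprintf("class_%d", seq_len(nrow(centers))), n_per))
  list(features = features, labels = labels)
}

# A feature table whose candidates sit at ranks 1, 2, ... from the origin
# (1-d line), with the first `n_match` objects labeled `match_label`.
make_ranked_line <- function(n, n_match, match_label = "X", other_label = "Y") {
  ids <- sprintf("o%04d", seq_len(n))
  features <- tibble::tibble(object_id = ids, f1 = as.numeric(seq_len(n)))
  labels <- tibble::tibble(object_id = ids,
                           label = c(rep(match_label, n_match),
                                     rep(other_label, n - n_match)))
  list(features = features, labels = labels, ids = ids)
}

# Independent page-by-page linear scan: accept whole pages until the first
# mismatching page. Oracle for the galloping + binary growth protocol.
linear_page_scan <- function(ranked, page_size, annotator, seed_label) {
  P <- ceiling(length(ranked) / page_size)
  accepted <- character()
  for (p in seq_len(P)) {
    page <- ranked[(((p - 1) * page_size) + 1):min(p * page_size, length(ranked))]
    if (!judge_page(annotator, page, seed_label)$match) break
    accepted <- c(accepted, page)
  }
  accepted
}

# Brute-force UPGMA over a leaf distance matrix, recomputing every group
# distance as the mean of the original pairwise distances (the definition,
# not the recursive update). Ties broken by smallest leaf-id pair.
upgma_bruteforce <- function(D, ids) {
  groups <- as.list(seq_along(ids))
  active <- seq_along(groups)
  heights <- numeric(0)
  merges <- list()
  while (length(active) > 1) {
    best <- NULL
    for (ai in seq_len(length(active) - 1)) {
      for (bj in seq(ai + 1, length(active))) {
        a <- active[ai]; b <- active[bj]
        d <- mean(D[groups[[a]], groups[[b]]])
        lo <- min(ids[c(groups[[a]], groups[[b]])])
        reps <- sort(c(min(ids[groups[[a]]]), min(ids[groups[[b]]])))
        if (is.null(best) || d < best$d ||
            (d == best$d && (reps[1] < best$r1 ||
                             (reps[1] == best$r1 && reps[2] < best$r2)))) {
          best <- list(a = a, b = b, d = d, r1 = reps[1], r2 = reps[2])
        }
      }
    }
    groups[[best$a]] <- c(groups[[best$a]], groups[[best$b]])
    heights <- c(heights, best$d / 2)
    merges <- c(merges, list(sort(ids[groups[[best$a]]])))
    active <- setdiff(active, best$b)
  }
  list(heights = heights, merges = merges)
}

# Leaf cluster-id sets below each internal node of a freshly built
# hierarchy, in merge order (node K+1 .. 2K-1).
tree_merge_sets <- function(tree) {
  K <- sum(tree$nodes$leaf)
  lapply(seq(K + 1, 2 * K - 1), function(id) {
    nn <- intersect(c(id, clustergrow:::node_descendants(tree, id)),
                    tree$nodes$node_id[tree$nodes$leaf])
    sort(tree$nodes$cluster_id[match(nn, tree$nodes$node_id)])
  })
}

# Point clusters (one seed member each) for hierarchy tests.
point_clusters <- function(X, ids = rownames(X)) {
  lapply(seq_len(nrow(X)), function(i) {
    cl <- clustergrow:::new_cluster(ids[i], ids[i], X[i, ], 1L)
    cl$approved <- TRUE
    cl
  })
}

# Event log at fixed minute offsets from a base time.
log_at_minutes <- function(minutes, phase = "validate", counts = 1L) {
  base <- as.POSIXct("2026-01-01 09:00:00", tz = "UTC")
  if (length(counts) == 1) counts <- rep(counts, length(minutes))
  if (length(phase) == 1) phase <- rep(phase, length(minutes))
  log <- event_log()
  for (i in seq_along(minutes)) {
    log <- log_event(log, phase[i], "act", counts[i], base + minutes[i] * 60)
  }
  log
}
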