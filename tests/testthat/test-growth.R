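test_that("dissimilar arrangement spans the widest gaps", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), "f1"))
  expect_equal(arrange_dissimilar("a", X), "a")
  expect_equal(arrange_dissimilar(c("b", "a"), X), c("a", "b"))

  ord <- arrange_dissimilar(c("a", "b", "c", "d"), X)
  expect_setequal(ord, c("a", "b", "c", "d"))
  gaps <- abs(diff(X[ord, 1]))
  expect_true(all(gaps >= 9))

  # deterministic under permuted input
  expect_identical(ord, arrange_dissimilar(c("d", "c", "b", "a"), X))
})

test_that("candidate ranking is distance-ascending with id tie-break", {
  X <- matrix(c(3, 1, 2, 1), ncol = 1,
              dimnames = list(c("p", "q", "r", "a"), "f1"))
  expect_equal(rank_candidates(0, character(), X), character())
  expect_equal(rank_candidates(0, c("p", "q", "r"), X), c("q", "r", "p"))
  # q and a both at distance 1: id ascending
  expect_equal(rank_candidates(0, c("q", "a"), X), c("a", "q"))
})

test_that("seed validation conserves objects on both branches", {
  centers <- rbind(c(0, 0), c(25, 0))
  blobs <- make_blobs(centers, 150, seed = 3)
  ann <- oracle_annotator(blobs$labels)
  state <- new_process(blobs$features, m_schedule = c(100, 50))
  state <- next_iteration(state)
  n_total <- nrow(state$X)
  for (cid in state$new_seed_ids) {
    state <- validate_seed(state, cid, ann)
    members <- unlist(lapply(state$clusters, clustergrow:::cluster_members))
    expect_equal(length(members) + length(unassigned_ids(state)), n_total)
  }
  # pure seeds under the oracle are approved with membership unchanged
  expect_true(all(vapply(state$clusters, `[[`, TRUE, "approved")))

  # a 50/50 mixed seed is deleted and its members return to the pool
  state2 <- new_process(blobs$features, m_schedule = c(100, 50))
  mixed <- clustergrow:::new_cluster("mix", blobs$labels$object_id[c(1:5, 151:155)],
                                     rep(0, 2), 1L)
  state2$clusters[["mix"]] <- mixed
  expect_equal(length(unassigned_ids(state2)), 290L)
  state2 <- validate_seed(state2, "mix", ann)
  expect_null(state2$clusters[["mix"]])
  expect_equal(length(unassigned_ids(state2)), 300L)
})

grown_setup <- function(n, n_match, page_size = 50) {
  fx <- make_ranked_line(n, n_match)
  ann <- oracle_annotator(dplyr::bind_rows(
    fx$labels, tibble::tibble(object_id = "seed1", label = "X")))
  X <- rbind(feature_matrix(fx$features), seed1 = 0)
  cl <- clustergrow:::new_cluster("c1", "seed1", 0, 1L)
  cl$approved <- TRUE
  list(cl = cl, pool = fx$ids, X = X, ann = ann)
}

test_that("an immediately mismatching first page adds nothing", {
  s <- grown_setup(200, 0)
  res <- grow_cluster(s$cl, s$pool, s$X, s$ann, turtle = FALSE)
  expect_equal(res$accepted, character())
  expect_equal(res$boundary_page, 0L)
  expect_equal(res$pool, s$pool)
})

test_that("all-matching candidates are absorbed with logarithmic judgments", {
  for (P in c(1, 2, 3, 5, 8, 13, 16, 31, 32, 33, 64)) {
    s <- grown_setup(P * 50, P * 50)
    res <- grow_cluster(s$cl, s$pool, s$X, s$ann, turtle = FALSE)
    expect_length(res$accepted, P * 50)
    # galloping probes only: 1, 2, 4, ..., capped at P
    expected <- floor(log2(P)) + 1 + as.integer(2^floor(log2(P)) != P)
    expect_equal(res$n_page_judgments, expected)
  }
})

test_that("growth reproduces the linear page scan for monotone boundaries", {
  P <- 40
  withr::with_seed(99, bounds <- sample(0:P, 30, replace = TRUE))
  for (b in bounds) {
    s <- grown_setup(P * 50, b * 50)
    res <- grow_cluster(s$cl, s$pool, s$X, s$ann, turtle = FALSE)
    seed_label <- seed_reference_label(s$ann, s$cl$seed_members)
    ranked <- rank_candidates(s$cl$centroid, s$pool, s$X)
    expect_identical(sort(res$accepted),
                     sort(linear_page_scan(ranked, 50, s$ann, seed_label)))
    expect_lte(res$n_page_judgments, 2 * ceiling(log2(P + 1)) + 2)
    expect_equal(length(res$pool) + length(res$accepted), length(s$pool))
    expect_length(intersect(res$pool, res$cluster$grown_members), 0)
  }
})

test_that("turtle mode recovers a partially foreign boundary page", {
  # pages: 1 fully matching, page 2 holds 49 matches + 1 foreign object,
  # everything later is foreign
  fx <- make_ranked_line(150, 100)
  fx$labels$label[60] <- "Y"
  ann <- oracle_annotator(dplyr::bind_rows(
    fx$labels, tibble::tibble(object_id = "seed1", label = "X")))
  X <- rbind(feature_matrix(fx$features), seed1 = 0)
  cl <- clustergrow:::new_cluster("c1", "seed1", 0, 1L)
  cl$approved <- TRUE

  res <- grow_cluster(cl, fx$ids, X, ann, turtle = TRUE, turtle_patience = 50)
  expect_true(res$turtle_activated)
  expect_length(res$accepted, 50 + 49)
  expect_false("o0060" %in% res$accepted)
  expect_true(all(fx$ids[c(1:59, 61:100)] %in% res$accepted))

  # with turtle disabled the partial page is dropped wholesale
  res2 <- grow_cluster(cl, fx$ids, X, ann, turtle = FALSE)
  expect_length(res2$accepted, 50)
  expect_equal(res2$boundary_page, 1L)
})

test_that("growth is deterministic under a deterministic annotator", {
  s <- grown_setup(500, 230)
  r1 <- grow_cluster(s$cl, s$pool, s$X, s$ann)
  r2 <- grow_cluster(s$cl, s$pool, s$X, s$ann)
  expect_identical(r1$accepted, r2$accepted)
  expect_identical(r1$n_page_judgments, r2$n_page_judgments)
})
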