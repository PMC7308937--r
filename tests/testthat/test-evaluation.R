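test_that("sampled review reproduces the precision arithmetic", {
  truth <- tibble::tibble(object_id = sprintf("o%02d", 1:14),
                          label = c(rep("A", 4), rep("B", 10)))
  ann <- oracle_annotator(truth)

  # perfectly labeled objects: every class precision 1
  ev0 <- precision_by_review(truth, ann, cap = 500, rng_seed = 1)
  expect_equal(ev0$per_class$precision, c(1, 1))
  expect_equal(ev0$macro_precision, 1)

  # a class of 4 with 3 inliers -> 0.75; a clean class -> 1.0; macro 0.875
  labels <- truth                 # labeling claims o01..o04 are A
  truth2 <- truth
  truth2$label[4] <- "B"          # but o04 is truly B
  ann2 <- oracle_annotator(truth2)
  ev <- precision_by_review(labels, ann2, cap = 500, rng_seed = 1)
  a <- ev$per_class[ev$per_class$label == "A", ]
  expect_equal(a$tp, 3L)
  expect_equal(a$fp, 1L)
  expect_equal(a$precision, 0.75)
  expect_equal(ev$macro_precision, mean(c(0.75, 1)))

  # two classes at 0.5 and 1.0 average to 0.75 regardless of class size
  truth3 <- tibble::tibble(object_id = sprintf("p%02d", 1:6),
                           label = c("X", "Y", rep("Y", 4)))
  labels3 <- tibble::tibble(object_id = sprintf("p%02d", 1:6),
                            label = c("X", "X", rep("Y", 4)))
  ev3 <- precision_by_review(labels3, oracle_annotator(truth3), rng_seed = 2)
  expect_equal(ev3$macro_precision, 0.75)
})

test_that("a generous cap equals exhaustive review and sampling is capped", {
  withr::with_seed(5, {
    truth <- tibble::tibble(object_id = sprintf("q%03d", 1:300),
                            label = sample(c("A", "B", "C"), 300, replace = TRUE))
    labels <- truth
    flip <- sample(300, 60)
    labels$label[flip] <- sample(c("A", "B", "C"), 60, replace = TRUE)
  })
  ann <- oracle_annotator(truth)
  exact <- dplyr::inner_join(labels, truth, by = "object_id",
                             suffix = c("", "_true")) |>
    dplyr::group_by(label) |>
    dplyr::summarise(p = mean(label == label_true)) |>
    dplyr::arrange(label)
  ev <- precision_by_review(labels, ann, cap = 10000, rng_seed = 9)
  expect_equal(ev$per_class$precision, exact$p)

  ev_cap <- precision_by_review(labels, ann, cap = 20, rng_seed = 9)
  expect_true(all(ev_cap$per_class$n_sampled <= 20))
})

test_that("group maps split the report and unknown classes are excluded", {
  truth <- tibble::tibble(object_id = sprintf("g%02d", 1:30),
                          label = rep(c("cop", "det", "mix_odd"), each = 10))
  ann <- oracle_annotator(truth)
  gm <- tibble::tibble(label = c("cop", "det"), group = c("living", "non-living"))
  ev <- precision_by_review(truth, ann, rng_seed = 1, group_map = gm)
  expect_setequal(ev$by_group$group, c("living", "non-living"))
  expect_equal(ev$per_class$group[ev$per_class$label == "mix_odd"], "excluded")
})

test_that("relative overlap satisfies its identities", {
  expect_equal(relative_overlap(c("a", "b"), c("a", "b")), 1)
  expect_equal(relative_overlap(c("a", "b"), c("c", "d")), 0)
  expect_equal(relative_overlap(character(), character()), 0)
  expect_equal(relative_overlap(c("a", "b", "c", "d"), c("c", "d", "e", "f", "g", "h")),
               0.25)
  withr::with_seed(3, {
    for (i in 1:20) {
      a <- sample(letters, sample(0:10, 1))
      b <- sample(letters, sample(0:10, 1))
      o <- relative_overlap(a, b)
      expect_gte(o, 0)
      expect_lte(o, 1)
      expect_equal(o, relative_overlap(b, a))
    }
  })
})

test_that("correspondence of a labeling with itself is the identity", {
  lab <- tibble::tibble(object_id = sprintf("s%02d", 1:20),
                        label = rep(c("A", "B", "C", "D"), each = 5))
  co <- correspondence(lab, lab)
  expect_equal(co$macro_agreement, 1)
  expect_equal(co$by_class_b$predominant_a, co$by_class_b$class_b)
  diag_cells <- co$overlap[co$overlap$class_a == co$overlap$class_b, ]
  expect_true(all(diag_cells$overlap == 1))
  off <- co$overlap[co$overlap$class_a != co$overlap$class_b, ]
  expect_true(all(off$overlap == 0))
})

test_that("predominant labels and agreement follow the majority count", {
  ref <- tibble::tibble(object_id = sprintf("t%02d", 1:10),
                        label = c(rep("X", 7), rep("Y", 3)))
  res <- tibble::tibble(object_id = sprintf("t%02d", 1:10),
                        label = "cluster1")
  co <- correspondence(ref, res)
  expect_equal(co$by_class_b$predominant_a, "X")
  expect_equal(co$by_class_b$agreement, 0.7)
  expect_false(co$by_class_b$tie)

  # result classes with no reference-labeled members are excluded
  res2 <- dplyr::bind_rows(res,
                           tibble::tibble(object_id = "zz99", label = "cluster2"))
  co2 <- correspondence(ref, res2)
  expect_equal(co2$by_class_b$class_b, "cluster1")

  expect_error(correspondence(ref, tibble::tibble(object_id = "nope", label = "c")),
               "share no objects")
})

test_that("overlap matrices transpose when the labelings swap", {
  withr::with_seed(17, {
    la <- tibble::tibble(object_id = sprintf("u%02d", 1:30),
                         label = sample(c("A", "B"), 30, replace = TRUE))
    lb <- tibble::tibble(object_id = sprintf("u%02d", 1:30),
                         label = sample(c("P", "Q", "R"), 30, replace = TRUE))
  })
  ab <- tidy(correspondence(la, lb))
  ba <- tidy(correspondence(lb, la))
  joined <- dplyr::inner_join(ab, ba,
                              by = c(class_a = "class_b", class_b = "class_a"))
  expect_equal(joined$overlap.x, joined$overlap.y)
})

test_that("macro precision ignores class sizes (unweighted mean)", {
  truth <- tibble::tibble(object_id = sprintf("w%03d", 1:110),
                          label = c(rep("big", 100), rep("small", 10)))
  labels <- truth
  labels$label[1:50] <- "small"   # big: 50/... claims under small
  # recompute: class small has 10 true + 50 false claims
  ann <- oracle_annotator(truth)
  ev <- precision_by_review(labels, ann, cap = 1000, rng_seed = 4)
  small <- ev$per_class[ev$per_class$label == "small", ]
  expect_equal(small$precision, 10 / 60)
  expect_equal(ev$macro_precision, mean(c(1, 10 / 60)))
})

test_that("recovery reporting handles missing and unretrievable classes", {
  blobs <- make_blobs(rbind(c(0, 0), c(30, 0)), c(400, 120), seed = 14)
  # add a single-object class: can never be seeded with m >= 4
  solo <- tibble::tibble(object_id = "solo1", f1 = 60, f2 = 60)
  features <- dplyr::bind_rows(blobs$features, solo)
  labels <- dplyr::bind_rows(blobs$labels,
                             tibble::tibble(object_id = "solo1", label = "loner"))
  ann <- oracle_annotator(labels)
  run <- run_full(features, ann, m_schedule = c(64, 16, 4))
  rep <- recovery_report(run, labels)
  expect_true(all(rep$retrieved[rep$label %in% c("class_1", "class_2")]))
  loner <- rep[rep$label == "loner", ]
  expect_false(loner$retrieved)
  expect_true(is.na(loner$first_seed_iteration))
})
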