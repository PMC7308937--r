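#' Per-class precision by sampled review
#'
#' For every class in a labeling, up to `cap` objects are sampled without
#' replacement and shown to the annotator, who marks each as an inlier or
#' outlier of the class. The precision of a class is the inlier fraction
#' `TP / (TP + FP)`; *macro precision* is the unweighted mean over classes
#' and `pr10` the empirical 10th percentile of the per-class precisions
#' (linear interpolation).
#'
#' @param labels Label tibble (`object_id`, `label`) to evaluate.
#' @param annotator An annotator object (the reviewer).
#' @param cap Maximum objects sampled per class (default 500).
#' @param rng_seed Seed for the sampling.
#' @param group_map Optional tibble (`label`, `group`) assigning classes to
#'   category groups (e.g. living / non-living); classes absent from the map
#'   are reported as `"excluded"`.
#' @return An `evaluation_report`: list with `per_class` tibble (`label`,
#'   `n_sampled`, `tp`, `fp`, `precision`, `group`), scalars
#'   `macro_precision`, `pr10`, `n_classes`, and `by_group` tibble.
#' @export
precision_by_review <- function(labels, annotator, cap = 500, rng_seed = 0,
                                group_map = NULL) {
  stopifnot(nrow(labels) > 0, cap >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)

  per_class <- labels |>
    dplyr::group_by(.data$label) |>
    dplyr::group_map(function(df, key) {
      ids <- df$object_id
      take <- if (length(ids) > cap) sort(sample(ids, cap)) else ids
      ok <- vapply(take, function(id) judge_object(annotator, id, key$label), logical(1))
      tibble::tibble(label = key$label, n_sampled = length(take),
                     tp = sum(ok), fp = sum(!ok),
                     precision = sum(ok) / length(take))
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$label)

  if (!is.null(group_map)) {
    per_class <- dplyr::left_join(per_class, group_map, by = "label")
    per_class$group[is.na(per_class$group)] <- "excluded"
  } else {
    per_class$group <- NA_character_
  }
  by_group <- if (!is.null(group_map)) {
    per_class |>
      dplyr::filter(.data$group != "excluded") |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(macro_precision = mean(.data$precision),
                       pr10 = unname(quantile(.data$precision, 0.1)),
                       n_classes = dplyr::n(), .groups = "drop")
  } else {
    tibble::tibble(group = character(), macro_precision = numeric(),
                   pr10 = numeric(), n_classes = integer())
  }
  structure(list(
    per_class = per_class,
    macro_precision = mean(per_class$precision),
    pr10 = unname(quantile(per_class$precision, 0.1)),
    n_classes = nrow(per_class),
    by_group = by_group
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d classes, macro precision %.3f, Pr10 %.3f\n",
              x$n_classes, x$macro_precision, x$pr10))
  invisible(x)
}

#' Relative overlap (Jaccard index) of two object sets
#'
#' `|a intersect b| / |a union b|`; 0 when both sets are empty.
#'
#' @param set_a,set_b Character vectors of object ids.
#' @return A number in `[0, 1]`.
#' @export
relative_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  u <- length(set_a) + length(set_b) - length(intersect(set_a, set_b))
  if (u == 0) return(0)
  length(intersect(set_a, set_b)) / u
}

#' Correspondence between two labelings
#'
#' Compares a result labeling `labels_b` against a reference `labels_a` on
#' their shared objects (the "spiked" ids). For every B-class the
#' composition of A-labels among its members is computed; its *predominant*
#' A-label is the most frequent one (ties broken lexicographically and
#' flagged) and its *agreement* the fraction of members carrying it. Macro
#' agreement averages over B-classes with at least one shared object. The
#' overlap matrix holds the relative overlap (Jaccard) of every class pair.
#'
#' @param labels_a Reference label tibble.
#' @param labels_b Result label tibble.
#' @return A `correspondence` object: list with `by_class_b` tibble
#'   (`class_b`, `n_shared`, `predominant_a`, `agreement`, `tie`),
#'   `overlap` tibble (`class_a`, `class_b`, `overlap`), and scalar
#'   `macro_agreement`.
#' @export
correspondence <- function(labels_a, labels_b) {
  shared <- dplyr::inner_join(
    dplyr::rename(labels_a, label_a = "label"),
    dplyr::rename(labels_b, label_b = "label"),
    by = "object_id"
  )
  if (nrow(shared) == 0) abort("the two labelings share no objects")

  by_class_b <- shared |>
    dplyr::count(.data$label_b, .data$label_a, name = "n") |>
    dplyr::group_by(.data$label_b) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$label_a, .by_group = TRUE) |>
    dplyr::summarise(
      n_shared = sum(.data$n),
      predominant_a = dplyr::first(.data$label_a),
      agreement = dplyr::first(.data$n) / sum(.data$n),
      tie = sum(.data$n == dplyr::first(.data$n)) > 1,
      .groups = "drop"
    ) |>
    dplyr::rename(class_b = "label_b")

  sets_a <- split(shared$object_id, shared$label_a)
  sets_b <- split(shared$object_id, shared$label_b)
  overlap <- tidyr::expand_grid(class_a = names(sets_a), class_b = names(sets_b))
  overlap$overlap <- purrr::map2_dbl(overlap$class_a, overlap$class_b, function(a, b) {
    relative_overlap(sets_a[[a]], sets_b[[b]])
  })

  structure(list(
    by_class_b = by_class_b,
    overlap = overlap,
    macro_agreement = mean(by_class_b$agreement),
    n_shared = nrow(shared)
  ), class = "correspondence")
}

#' @export
print.correspondence <- function(x, ...) {
  cat(sprintf("<correspondence> %d shared objects, %d result classes, macro agreement %.3f\n",
              x$n_shared, nrow(x$by_class_b), x$macro_agreement))
  invisible(x)
}

#' Annotation throughput from an event log
#'
#' Objects affected divided by summed session durations (sessions re-split
#' per phase with the same gap rule as [split_sessions()]), per phase and
#' overall. Phases without events are omitted; zero total duration yields
#' `NA` (undefined rate).
#'
#' @param log Event log tibble.
#' @param max_gap_min Session gap threshold in minutes (default 10).
#' @return Tibble with `phase` (including `"total"`), `objects`, `hours`,
#'   `objects_per_hour`.
#' @export
throughput <- function(log, max_gap_min = 10) {
  stopifnot(nrow(log) > 0)
  one <- function(df, phase) {
    ses <- split_sessions(df, max_gap_min)
    hours <- sum(ses$duration_min) / 60
    tibble::tibble(phase = phase, objects = sum(df$object_count), hours = hours,
                   objects_per_hour = if (hours > 0) sum(df$object_count) / hours else NA_real_)
  }
  per_phase <- purrr::map_dfr(sort(unique(log$phase)), function(ph) {
    one(log[log$phase == ph, ], ph)
  })
  dplyr::bind_rows(per_phase, one(log, "total"))
}

#' Class recovery report
#'
#' Compares an engine run against ground truth at the class level: a truth
#' class is *retrieved* when it is the predominant truth label of at least
#' one named cluster. The iteration of first seeding records when a class
#' was first caught by a validated seed holding at least 5% of the class's
#' final assigned size, and the report's Spearman rank correlation between
#' class size and that iteration summarizes the larger-classes-first
#' behavior (negative values mean larger classes were found earlier).
#'
#' @param run An `annotation_run` (see [run_full()]).
#' @param truth Ground-truth label tibble covering the run's objects.
#' @param indicator_classes Character vector of truth classes flagged as
#'   held-out indicators (reported, not treated specially).
#' @param seed_fraction Minimum fraction of the final class size a seed must
#'   hold to count as first discovery (default 0.05).
#' @return A tibble with one row per truth class (noise excluded): `label`,
#'   `size`, `n_assigned`, `retrieved`, `first_seed_iteration`, `indicator`;
#'   the Spearman correlation is attached as attribute `spearman` and via
#'   [glance()].
#' @export
recovery_report <- function(run, truth, indicator_classes = character(),
                            seed_fraction = 0.05) {
  stopifnot(inherits(run, "annotation_run"))
  tv <- labels_as_vector(truth)
  classes <- sort(setdiff(unique(truth$label), NOISE_LABEL))

  cl <- run$clusters
  named <- cl[!is.na(cl$name) & cl$name != UNNAMED_LABEL, , drop = FALSE]
  predominant <- vapply(seq_len(nrow(named)), function(i) {
    labs <- tv[c(named$seed_members[[i]], named$grown_members[[i]])]
    tab <- table(labs)
    names(tab)[order(-tab, names(tab))][1]
  }, character(1))

  rows <- purrr::map_dfr(classes, function(cls) {
    cls_ids <- names(tv)[tv == cls]
    assigned <- 0L
    first_it <- NA_integer_
    if (nrow(cl) > 0) {
      in_cluster <- vapply(seq_len(nrow(cl)), function(i) {
        sum(c(cl$seed_members[[i]], cl$grown_members[[i]]) %in% cls_ids)
      }, integer(1))
      assigned <- sum(in_cluster)
      seed_counts <- vapply(seq_len(nrow(cl)), function(i) {
        sum(cl$seed_members[[i]] %in% cls_ids)
      }, integer(1))
      thr <- max(1, ceiling(seed_fraction * assigned))
      hit <- seed_counts >= thr
      if (any(hit)) first_it <- min(cl$iteration[hit])
    }
    tibble::tibble(
      label = cls,
      size = sum(tv == cls),
      n_assigned = assigned,
      retrieved = cls %in% predominant,
      first_seed_iteration = first_it,
      indicator = cls %in% indicator_classes
    )
  })
  ok <- !is.na(rows$first_seed_iteration)
  rho <- if (sum(ok) >= 3) {
    suppressWarnings(cor(rows$size[ok], rows$first_seed_iteration[ok], method = "spearman"))
  } else NA_real_
  attr(rows, "spearman") <- rho
  rows
}
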