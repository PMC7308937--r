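#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for engine results
#'
#' `tidy()` returns one row per cluster (for runs), per class (for
#' evaluation reports and recovery reports) or per class pair (for
#' correspondences); `glance()` returns a one-row summary.
#'
#' @param x An `annotation_run`, `evaluation_report` or `correspondence`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.annotation_run <- function(x, ...) {
  dplyr::select(x$clusters, "cluster_id", "iteration", "n_seed", "n_grown",
                "flagged", "name")
}

#' @rdname tidy.annotation_run
#' @export
glance.annotation_run <- function(x, ...) {
  tibble::tibble(
    n_objects = x$n_objects,
    n_clusters = nrow(x$clusters),
    n_named_classes = length(setdiff(unique(x$labels$label), UNNAMED_LABEL)),
    n_residual = length(x$residual_ids),
    residual_fraction = length(x$residual_ids) / max(1L, x$n_objects)
  )
}

#' @rdname tidy.annotation_run
#' @export
tidy.evaluation_report <- function(x, ...) x$per_class

#' @rdname tidy.annotation_run
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(macro_precision = x$macro_precision, pr10 = x$pr10,
                 n_classes = x$n_classes)
}

#' @rdname tidy.annotation_run
#' @export
tidy.correspondence <- function(x, ...) x$overlap

#' @rdname tidy.annotation_run
#' @export
glance.correspondence <- function(x, ...) {
  tibble::tibble(macro_agreement = x$macro_agreement,
                 n_classes_b = nrow(x$by_class_b), n_shared = x$n_shared)
}

#' Plot cluster discovery over the iterations of a run
#'
#' One point per cluster: iteration of discovery against total cluster size
#' (log scale), mirroring the larger-classes-first behavior of the shrinking
#' minimum-cluster-size schedule.
#'
#' @param object An `annotation_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.annotation_run <- function(object, ...) {
  df <- tidy(object)
  df$size <- df$n_seed + df$n_grown
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$iteration), y = .data$size)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "cluster size (seed + grown)",
                  title = "Cluster discovery across the shrinking-m schedule")
}

#' Heatmap of the correspondence between two labelings
#'
#' @param object A `correspondence`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.correspondence <- function(object, ...) {
  ggplot2::ggplot(object$overlap,
                  ggplot2::aes(x = .data$class_b, y = .data$class_a,
                               fill = .data$overlap)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick", limits = c(0, 1)) +
    ggplot2::labs(x = "result class", y = "reference class", fill = "relative\noverlap") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Plot class size against iteration of first seeding
#'
#' @param report A [recovery_report()] tibble.
#' @return A ggplot.
#' @export
plot_recovery <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$size, y = .data$first_seed_iteration,
                               shape = .data$indicator, color = .data$retrieved)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "true class size", y = "iteration of first seed",
                  title = "Larger classes are seeded earlier")
}
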