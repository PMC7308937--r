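#' Persist / restore an annotation process as JSON
#'
#' The feature matrix itself is not embedded: a state file references
#' objects by id and is re-attached to the same feature table on reload, so
#' command-line stages (`cluster`, `grow`, `tree`) can be chained.
#'
#' @param state An `annotation_process`.
#' @param path JSON file path.
#' @return `write_process_state()`: `path`, invisibly.
#' @export
write_process_state <- function(state, path) {
  stopifnot(inherits(state, "annotation_process"))
  payload <- list(
    iteration = state$iteration,
    m_schedule = state$m_schedule,
    k = state$k,
    page_size = state$page_size,
    rng_seed = state$rng_seed,
    cluster_selection = state$cluster_selection,
    done = isTRUE(state$done),
    clusters = lapply(unname(state$clusters), function(cl) {
      list(cluster_id = cl$cluster_id, iteration = cl$iteration,
           seed_members = as.list(cl$seed_members),
           grown_members = as.list(cl$grown_members),
           approved = cl$approved, flagged = cl$flagged,
           name = if (is.na(cl$name)) NULL else cl$name)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_process_state
#' @param features The feature table the state was built from.
#' @export
read_process_state <- function(path, features) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  state <- new_process(features,
                       m_schedule = unlist(raw$m_schedule),
                       k = raw$k, page_size = raw$page_size,
                       rng_seed = raw$rng_seed,
                       cluster_selection = raw$cluster_selection %||% "eom")
  state$iteration <- as.integer(raw$iteration)
  state$done <- isTRUE(raw$done)
  X <- state$X
  clusters <- lapply(raw$clusters, function(cl) {
    seed <- unlist(cl$seed_members)
    obj <- new_cluster(cl$cluster_id, seed,
                       colMeans(X[seed, , drop = FALSE]), cl$iteration)
    obj$grown_members <- as.character(unlist(cl$grown_members))
    obj$approved <- isTRUE(cl$approved)
    obj$flagged <- isTRUE(cl$flagged)
    nm <- unlist(cl$name)
    obj$name <- if (length(nm) == 0 || is.na(nm)) NA_character_ else as.character(nm)
    obj
  })
  state$clusters <- setNames(clusters,
                             vapply(clusters, `[[`, "", "cluster_id"))
  assert_conservation(state)
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a
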