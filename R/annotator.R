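#' Annotator contract
#'
#' The engine never looks at ground truth itself; every judgment call goes
#' through an *annotator*, an object answering three kinds of question:
#'
#' * [judge_cluster()] -- is this set of objects homogeneous enough to
#'   validate as a cluster seed?
#' * [judge_page()] -- does every object on this page of growth candidates
#'   match the seed's class?
#' * [judge_object()] -- does this single object match the seed's class?
#'
#' [oracle_annotator()] answers from a complete ground-truth label table and
#' is deterministic; [console_annotator()] asks a human on the terminal and
#' is intended for interactive use only.
#'
#' @param truth Complete ground-truth label tibble (`object_id`, `label`).
#' @param purity_threshold Minimum modal-label fraction for a seed to be
#'   accepted (default 0.9). The reserved `"noise"` label never counts as an
#'   acceptable modal label.
#' @return An object of class `oracle_annotator`/`annotator`.
#' @export
oracle_annotator <- function(truth, purity_threshold = 0.9) {
  stopifnot(is.data.frame(truth), all(c("object_id", "label") %in% names(truth)),
            purity_threshold > 0, purity_threshold <= 1)
  structure(list(truth = labels_as_vector(truth),
                 purity_threshold = purity_threshold),
            class = c("oracle_annotator", "annotator"))
}

#' @rdname oracle_annotator
#' @export
console_annotator <- function() {
  structure(list(), class = c("console_annotator", "annotator"))
}

#' Judge a cluster seed for homogeneity
#'
#' @param annotator An annotator object.
#' @param members Nonempty character vector of object ids.
#' @return A list with elements `decision` (`"accept"` or `"reject"`),
#'   `modal_label` and `purity` (oracle only).
#' @export
judge_cluster <- function(annotator, members) UseMethod("judge_cluster")

#' @export
judge_cluster.oracle_annotator <- function(annotator, members) {
  labs <- oracle_lookup(annotator, members)
  tab <- sort(table(labs), decreasing = TRUE)
  modal <- names(tab)[order(-tab, names(tab))][1]
  purity <- as.numeric(tab[[modal]]) / length(labs)
  accept <- purity >= annotator$purity_threshold && modal != NOISE_LABEL
  list(decision = if (accept) "accept" else "reject",
       modal_label = modal, purity = purity)
}

#' @export
judge_cluster.console_annotator <- function(annotator, members) {
  cat(sprintf("Cluster seed with %d members:\n", length(members)))
  print(utils::head(members, 20))
  ans <- readline("Accept this seed? [y/N] ")
  list(decision = if (tolower(ans) %in% c("y", "yes")) "accept" else "reject",
       modal_label = NA_character_, purity = NA_real_)
}

#' Judge a page of growth candidates against a seed label
#'
#' @param annotator An annotator object.
#' @param page Nonempty character vector of object ids (one page).
#' @param seed_label The seed's class label (for the oracle, its modal
#'   ground-truth label).
#' @return A list with `match` (logical) and `offending` (character vector
#'   of mismatching ids; empty iff `match` is `TRUE`).
#' @export
judge_page <- function(annotator, page, seed_label) UseMethod("judge_page")

#' @export
judge_page.oracle_annotator <- function(annotator, page, seed_label) {
  stopifnot(length(page) > 0)
  labs <- oracle_lookup(annotator, page)
  off <- page[labs != seed_label]
  list(match = length(off) == 0, offending = off)
}

#' @export
judge_page.console_annotator <- function(annotator, page, seed_label) {
  cat(sprintf("Page of %d candidates for seed class '%s':\n", length(page), seed_label))
  print(page)
  ans <- readline("All matching? [y]; else enter offending ids comma-separated: ")
  if (tolower(ans) %in% c("y", "yes", "")) return(list(match = TRUE, offending = character()))
  off <- trimws(strsplit(ans, ",")[[1]])
  list(match = FALSE, offending = intersect(off, page))
}

#' Judge a single object against a seed label
#'
#' @inheritParams judge_page
#' @param object_id A single object id.
#' @return `TRUE` iff the object matches the seed's class.
#' @export
judge_object <- function(annotator, object_id, seed_label) UseMethod("judge_object")

#' @export
judge_object.oracle_annotator <- function(annotator, object_id, seed_label) {
  unname(oracle_lookup(annotator, object_id) == seed_label)
}

#' @export
judge_object.console_annotator <- function(annotator, object_id, seed_label) {
  ans <- readline(sprintf("Does '%s' belong to class '%s'? [y/N] ", object_id, seed_label))
  tolower(ans) %in% c("y", "yes")
}

#' The label an annotator would use to refer to a seed
#'
#' For the oracle this is the modal ground-truth label of the seed members;
#' the console annotator is its own reference and returns a placeholder.
#'
#' @inheritParams judge_cluster
#' @export
seed_reference_label <- function(annotator, members) UseMethod("seed_reference_label")

#' @export
seed_reference_label.oracle_annotator <- function(annotator, members) {
  judge_cluster(annotator, members)$modal_label
}

#' @export
seed_reference_label.console_annotator <- function(annotator, members) "seed"

oracle_lookup <- function(annotator, ids) {
  labs <- annotator$truth[ids]
  if (anyNA(labs)) {
    abort(sprintf("object id(s) missing from the oracle's truth table: %s",
                  paste(head(ids[is.na(labs)], 5), collapse = ", ")))
  }
  labs
}
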