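#' Read a feature table
#'
#' Reads a delimited text file with one row per object: a leading
#' `object_id` column followed by `D` numeric feature columns (the deep
#' feature vector of the object). Files ending in `.csv` are read as
#' comma-separated, anything else as tab-separated.
#'
#' @param path Path to the delimited file. The header row must start with
#'   `object_id`.
#' @param expected_dim Optional integer; if given, the number of feature
#'   columns must equal it.
#' @return A tibble with column `object_id` (character) and `D` numeric
#'   feature columns, preserving file row order.
#' @export
load_features <- function(path, expected_dim = NULL) {
  raw <- read_delim_auto(path)
  if (ncol(raw) < 2 || names(raw)[1] != "object_id") {
    abort(sprintf("'%s': expected a header starting with 'object_id' followed by feature columns", path))
  }
  ids <- as.character(raw[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate object_id(s): %s", paste(head(dup, 5), collapse = ", ")))
  }
  feat_cols <- names(raw)[-1]
  if (!is.null(expected_dim) && length(feat_cols) != expected_dim) {
    abort(sprintf("'%s' has %d feature columns, expected %d", path, length(feat_cols), expected_dim))
  }
  out <- tibble::tibble(object_id = ids)
  for (col in feat_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]) | !is.finite(vals))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric or non-finite value in column '%s', row %d (object_id '%s')",
                    col, bad[1], ids[bad[1]]))
    }
    if (anyNA(vals)) {
      abort(sprintf("missing value in column '%s', row %d", col, which(is.na(vals))[1]))
    }
    out[[col]] <- vals
  }
  out
}

#' Write a feature table
#'
#' Inverse of [load_features()]: writes `object_id` plus feature columns as
#' delimited text (TSV, or CSV when `path` ends in `.csv`).
#'
#' @param features Tibble as returned by [load_features()] or
#'   [generate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  check_feature_table(features)
  write_delim_auto(features, path)
  invisible(path)
}

#' Read / write a label table
#'
#' A label table is two-column delimited text mapping `object_id` to a class
#' `label`. The mapping may be partial: unlabeled objects are simply absent.
#' Duplicated ids are tolerated when the labels agree (rows are deduplicated)
#' and are an error when they conflict.
#'
#' @param path Path to a two-column delimited file (TSV, or CSV by extension).
#' @return `load_labels()`: a tibble with character columns `object_id` and
#'   `label`.
#' @export
load_labels <- function(path) {
  raw <- read_delim_auto(path)
  if (ncol(raw) == 0 || nrow(raw) == 0) {
    return(tibble::tibble(object_id = character(), label = character()))
  }
  if (ncol(raw) != 2) {
    abort(sprintf("'%s': expected two columns (object_id, label), found %d", path, ncol(raw)))
  }
  out <- tibble::tibble(object_id = as.character(raw[[1]]), label = as.character(raw[[2]]))
  out <- dplyr::distinct(out)
  conflict <- out$object_id[duplicated(out$object_id)]
  if (length(conflict) > 0) {
    abort(sprintf("conflicting labels for object_id(s): %s",
                  paste(head(unique(conflict), 5), collapse = ", ")))
  }
  out
}

#' @rdname load_labels
#' @param labels Tibble with columns `object_id` and `label`.
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("object_id", "label") %in% names(labels)))
  write_delim_auto(labels[, c("object_id", "label")], path)
  invisible(path)
}

#' Extract the numeric feature matrix from a feature table
#'
#' @param features Feature tibble (`object_id` + numeric columns).
#' @return Numeric matrix with object ids as row names.
#' @export
feature_matrix <- function(features) {
  check_feature_table(features)
  m <- as.matrix(features[, setdiff(names(features), "object_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- features$object_id
  m
}

check_feature_table <- function(features) {
  if (!is.data.frame(features) || !"object_id" %in% names(features)) {
    abort("features must be a data frame with an 'object_id' column")
  }
  if (anyDuplicated(features$object_id)) {
    abort("features$object_id contains duplicates")
  }
  num <- setdiff(names(features), "object_id")
  if (length(num) == 0) abort("features has no feature columns")
  ok <- vapply(features[num], function(x) is.numeric(x) && all(is.finite(x)), logical(1))
  if (!all(ok)) {
    abort(sprintf("non-numeric or non-finite feature column: %s", num[!ok][1]))
  }
  invisible(features)
}

labels_as_vector <- function(labels) {
  setNames(labels$label, labels$object_id)
}

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE)
}

write_delim_auto <- function(df, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(df, path, delim = delim)
}
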