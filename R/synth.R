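#' Configuration for the synthetic benchmark generator
#'
#' Describes a long-tailed Gaussian-mixture feature cloud of the kind
#' produced by a deep feature extractor over a large plankton image set:
#' many well-separated classes whose sizes follow a power law spanning
#' orders of magnitude, a diffuse uniform background ("noise") component,
#' and a few small held-out *indicator* classes used to probe novelty
#' retrieval.
#'
#' @param n_classes Number of real classes (indicator classes included).
#' @param total_objects Total number of objects, noise included.
#' @param dim Feature dimensionality (default 32, the usual size of a
#'   reduced deep feature vector).
#' @param size_exponent Power-law (Zipf) exponent for class sizes: class at
#'   rank `r` receives weight `r^-size_exponent`. The default 1.8 makes the
#'   few largest classes hold the bulk of the objects (with 50 classes the
#'   top five hold over 80%), mimicking the severe imbalance of field data.
#' @param separation Minimum inter-centroid distance in units of the
#'   within-class standard deviation (which is 1).
#' @param noise_fraction Fraction of objects drawn uniformly from the
#'   bounding box of the class cloud and labeled `"noise"`.
#' @param indicator_class_count Number of classes tagged as held-out
#'   indicators; they are ordinary small classes, flagged by name only.
#' @param indicator_size Objects per indicator class (default 50).
#' @param rng_seed Integer seed; generation is fully reproducible.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_classes = 30, total_objects = 20000, dim = 32,
                         size_exponent = 1.8, separation = 10,
                         noise_fraction = 0.02, indicator_class_count = 2,
                         indicator_size = 50, rng_seed = 0) {
  stopifnot(n_classes >= 1, total_objects >= n_classes, dim >= 1,
            size_exponent > 0, separation >= 0,
            noise_fraction >= 0, noise_fraction < 1,
            indicator_class_count >= 0, indicator_class_count <= n_classes,
            indicator_size >= 1)
  structure(list(
    n_classes = as.integer(n_classes), total_objects = as.integer(total_objects),
    dim = as.integer(dim), size_exponent = size_exponent, separation = separation,
    noise_fraction = noise_fraction,
    indicator_class_count = as.integer(indicator_class_count),
    indicator_size = as.integer(indicator_size), rng_seed = as.integer(rng_seed)
  ), class = "synth_config")
}

#' Generate a synthetic feature cloud with ground truth
#'
#' Class sizes are drawn from a discrete power law with exponent
#' `size_exponent` and scaled (largest-remainder rounding) so that class
#' members plus noise sum exactly to `total_objects`. Class centroids are
#' rejection-sampled in a box until all pairwise distances are at least
#' `separation` (in within-class sigma units); members are isotropic
#' Gaussian (sigma = 1) around their centroid; noise objects are uniform
#' over the slightly expanded bounding box of the class members. Indicator
#' classes are fixed at `indicator_size` objects and named
#' `indicator_01, ...`; the engine itself receives no knowledge of them.
#'
#' @param config A [synth_config()].
#' @return A list with elements `features` (tibble: `object_id` + `f1..fD`),
#'   `labels` (complete ground-truth tibble: `object_id`, `label`),
#'   `indicator_classes` (character vector of class names) and `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$rng_seed)

  n_noise <- round(config$noise_fraction * config$total_objects)
  n_members <- config$total_objects - n_noise
  if (n_members < config$n_classes) {
    abort("too few non-noise objects to give every class at least one member")
  }
  sizes <- power_law_sizes(config$n_classes, n_members,
                           config$size_exponent,
                           config$indicator_class_count, config$indicator_size)

  n_regular <- config$n_classes - config$indicator_class_count
  class_names <- c(sprintf("class_%02d", seq_len(n_regular)),
                   if (config$indicator_class_count > 0)
                     sprintf("indicator_%02d", seq_len(config$indicator_class_count)))

  centroids <- place_centroids(config$n_classes, config$dim, config$separation)

  X <- matrix(0, nrow = config$total_objects, ncol = config$dim)
  label <- character(config$total_objects)
  row <- 1L
  for (i in seq_len(config$n_classes)) {
    ni <- sizes[i]
    X[row:(row + ni - 1L), ] <- matrix(stats::rnorm(ni * config$dim), ni) +
      matrix(centroids[i, ], ni, config$dim, byrow = TRUE)
    label[row:(row + ni - 1L)] <- class_names[i]
    row <- row + ni
  }
  if (n_noise > 0) {
    member_rows <- X[seq_len(n_members), , drop = FALSE]
    lo <- apply(member_rows, 2, min)
    hi <- apply(member_rows, 2, max)
    pad <- 0.1 * (hi - lo)
    X[row:(row + n_noise - 1L), ] <- vapply(seq_len(config$dim), function(j) {
      stats::runif(n_noise, lo[j] - pad[j], hi[j] + pad[j])
    }, numeric(n_noise))
    label[row:(row + n_noise - 1L)] <- NOISE_LABEL
  }

  perm <- sample.int(config$total_objects)
  X <- X[perm, , drop = FALSE]
  label <- label[perm]
  ids <- sprintf("obj_%06d", seq_len(config$total_objects))

  features <- tibble::as_tibble(X, .name_repair = ~ sprintf("f%d", seq_len(config$dim)))
  features <- dplyr::bind_cols(tibble::tibble(object_id = ids), features)
  list(
    features = features,
    labels = tibble::tibble(object_id = ids, label = label),
    indicator_classes = if (config$indicator_class_count > 0)
      sprintf("indicator_%02d", seq_len(config$indicator_class_count)) else character(),
    config = config
  )
}

# Zipf-style sizes for the regular classes, fixed sizes for indicators;
# largest-remainder rounding so sizes sum exactly to `total`, min 1 each.
power_law_sizes <- function(n_classes, total, exponent, n_indicator, indicator_size) {
  n_regular <- n_classes - n_indicator
  n_ind_total <- n_indicator * indicator_size
  if (n_regular == 0) {
    if (n_ind_total != total) {
      # absorb rounding into the first indicator class
      sizes <- rep(indicator_size, n_indicator)
      sizes[1] <- sizes[1] + (total - n_ind_total)
      return(sizes)
    }
    return(rep(indicator_size, n_indicator))
  }
  budget <- total - n_ind_total
  if (budget < n_regular) abort("indicator classes leave too few objects for the regular classes")
  w <- seq_len(n_regular)^(-exponent)
  raw <- budget * w / sum(w)
  sizes <- pmax(1L, floor(raw))
  rem <- budget - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - floor(raw), decreasing = TRUE)
    sizes[extra[seq_len(rem)]] <- sizes[extra[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    donors <- order(sizes, decreasing = TRUE)
    i <- 1L
    while (rem < 0) {
      d <- donors[i]
      if (sizes[d] > 1L) { sizes[d] <- sizes[d] - 1L; rem <- rem + 1L }
      i <- if (i == n_regular) 1L else i + 1L
    }
  }
  c(as.integer(sizes), rep(indicator_size, n_indicator))
}

# Rejection-sample centroids in a box until pairwise distances >= separation.
place_centroids <- function(n_classes, dim, separation) {
  half <- max(1, 2 * separation)
  cent <- matrix(0, n_classes, dim)
  cent[1, ] <- stats::runif(dim, -half, half)
  tries <- 0L
  max_tries <- 200L * n_classes
  i <- 2L
  while (i <= n_classes) {
    cand <- stats::runif(dim, -half, half)
    d2 <- rowSums((cent[seq_len(i - 1L), , drop = FALSE] -
                     matrix(cand, i - 1L, dim, byrow = TRUE))^2)
    if (all(d2 >= separation^2)) {
      cent[i, ] <- cand
      i <- i + 1L
    }
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(sprintf("cannot place %d centroids at separation %g in %d dimensions",
                    n_classes, separation, dim))
    }
  }
  cent
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
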