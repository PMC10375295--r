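#' Augmentation parameters
#'
#' Random translation plus anisotropic scaling used to expand the labeled
#' training clouds; defaults are the published ranges: per-axis translations
#' drawn from `[-0.2, 0.2]`, per-axis scale factors from `[0.65, 1.7]`, six
#' copies per source cloud.
#'
#' @param translation_range Interval the three translation components are
#'   drawn from.
#' @param scale_range Interval the three per-axis scale factors are drawn
#'   from; must be strictly positive.
#' @param copies Number of augmented copies per input cloud.
#' @param seed Integer seed.
#' @return An `augment_params` list.
#' @export
augment_params <- function(translation_range = c(-0.2, 0.2),
                           scale_range = c(0.65, 1.7), copies = 6,
                           seed = NULL) {
  stopifnot(length(translation_range) == 2,
            translation_range[1] <= translation_range[2],
            length(scale_range) == 2, scale_range[1] <= scale_range[2],
            scale_range[1] > 0, copies >= 1)
  structure(list(translation_range = translation_range,
                 scale_range = scale_range, copies = as.integer(copies),
                 seed = seed),
            class = "augment_params")
}

#' Augment a labeled cloud by random translation and anisotropic scaling
#'
#' Each copy applies, in this order, per-axis scale factors (three draws from
#' `scale_range`) and then a translation vector (three draws from
#' `translation_range`) to every point; labels are unchanged. The drawn
#' transform of each copy is attached as attribute `"transform"`
#' (`list(translation, scale)`).
#'
#' @param cloud A labeled point cloud.
#' @param params An [augment_params()].
#' @return A list of `params$copies` transformed point clouds.
#' @export
augment_cloud <- function(cloud, params = augment_params()) {
  cloud <- as_point_cloud(cloud)
  if (!is_labeled(cloud)) abort("augmentation requires a labeled cloud")
  with_seed_or_current(params$seed, {
    lapply(seq_len(params$copies), function(i) {
      tr <- runif(3, params$translation_range[1], params$translation_range[2])
      sc <- runif(3, params$scale_range[1], params$scale_range[2])
      out <- cloud
      out$x <- cloud$x * sc[1] + tr[1]
      out$y <- cloud$y * sc[2] + tr[2]
      out$z <- cloud$z * sc[3] + tr[3]
      attr(out, "transform") <- list(translation = tr, scale = sc)
      out
    })
  })
}

#' Split clouds into train / validation / test sets
#'
#' Random disjoint partition covering all clouds. Validation and test sizes
#' are rounded to nearest (halves rounding down) and the remainder goes to the
#' training set. If `groups` is given (e.g. the source plant of each augmented
#' copy), all members of a group land in the same partition, preventing
#' augmentation leakage across splits.
#'
#' @param clouds A list of clouds (or any objects to partition).
#' @param fractions Train/validation/test fractions summing to 1; default
#'   `c(0.70, 0.15, 0.15)`.
#' @param seed Integer seed.
#' @param groups Optional group id per cloud.
#' @return A list with elements `train`, `validation`, `test` (lists of
#'   clouds) and `indices` (the corresponding positions).
#' @export
split_dataset <- function(clouds, fractions = c(0.70, 0.15, 0.15), seed = NULL,
                          groups = NULL) {
  n <- length(clouds)
  if (n < 3) abort("need at least 3 clouds to split")
  if (abs(sum(fractions) - 1) > 1e-8) abort("fractions must sum to 1")
  n_val <- ceiling(n * fractions[2] - 0.5)
  n_test <- ceiling(n * fractions[3] - 0.5)
  n_train <- n - n_val - n_test
  idx <- with_seed_or_current(seed, {
    if (is.null(groups)) {
      perm <- sample.int(n)
      list(train = perm[seq_len(n_train)],
           validation = perm[n_train + seq_len(n_val)],
           test = perm[n_train + n_val + seq_len(n_test)])
    } else {
      stopifnot(length(groups) == n)
      gs <- sample(unique(groups))
      assign <- list(train = integer(), validation = integer(),
                     test = integer())
      want <- c(train = n_train, validation = n_val, test = n_test)
      for (g in gs) {
        members <- which(groups == g)
        deficit <- want - lengths(assign)
        part <- names(which.max(deficit))
        assign[[part]] <- c(assign[[part]], members)
      }
      lapply(assign, sort)
    }
  })
  list(train = clouds[idx$train], validation = clouds[idx$validation],
       test = clouds[idx$test], indices = idx)
}
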