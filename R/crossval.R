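#' Cross-validation / permutation configuration
#'
#' @param k_folds Number of folds (3).
#' @param n_partitionings Random fold partitionings to average over (10).
#' @param n_permutations Label permutations for the null distribution (1000).
#' @param seed Integer seed (mandatory).
#' @param max_retries Redraws allowed per partitioning when a training set
#'   lacks one of the labels.
#' @return A `cv_config` list.
#' @export
cv_config <- function(k_folds = 3, n_partitionings = 10,
                      n_permutations = 1000, seed, max_retries = 100) {
  if (missing(seed)) stop("cv_config(): seed is mandatory", call. = FALSE)
  stopifnot(k_folds >= 2, n_partitionings >= 1, n_permutations >= 1)
  structure(as.list(environment()), class = "cv_config")
}

# Random fold assignment with sizes differing by at most 1.
make_folds <- function(n, k) {
  sample(rep(seq_len(k), length.out = n))
}

# draw partitionings such that every training set (complement of each fold)
# contains both labels
draw_partitionings <- function(labels, config) {
  n <- length(labels)
  lapply(seq_len(config$n_partitionings), function(i) {
    for (r in seq_len(config$max_retries)) {
      f <- make_folds(n, config$k_folds)
      ok <- all(vapply(seq_len(config$k_folds), function(fi) {
        tr <- labels[f != fi]
        length(unique(tr)) == 2
      }, logical(1)))
      if (ok) return(f)
    }
    stop("could not draw folds with both labels in every training set",
         call. = FALSE)
  })
}

# Residual variance proportion for one label assignment, averaged over folds
# and partitionings. The linear model on a binary label reduces to the
# training-fold group means.
rvp_for_labels <- function(diffs, labels, partitionings, k) {
  v <- stats::var(diffs)
  total <- 0
  m <- 0L
  for (f in partitionings) {
    for (fi in seq_len(k)) {
      test <- f == fi
      tr <- !test
      l1 <- labels == labels[1]
      m1 <- mean(diffs[tr & l1])
      m2 <- mean(diffs[tr & !l1])
      pred <- ifelse(l1[test], m1, m2)
      if (anyNA(pred)) return(NA_real_)
      total <- total + mean((diffs[test] - pred)^2) / v
      m <- m + 1L
    }
  }
  total / m
}

#' Cross-validated residual variance proportion
#'
#' Predicts each participant's CS+/CS- difference from the drug label in a
#' k-fold cross-validation: a linear model (group means, since the label is
#' binary) is trained on the other folds and predicts the held-out fold. The
#' statistic is the sum of squared prediction errors divided by the number of
#' data points and by the variance of the differences, averaged over the
#' folds and the random partitionings. A value near 0 means the label
#' predicts the difference almost perfectly; near 1 means it predicts no
#' better than the grand mean.
#'
#' @param data Tibble with one row per participant.
#' @param diff Column of CS+/CS- differences (name, default `"diff"`).
#' @param label Column of group labels (two levels, default `"group"`).
#' @param config A [cv_config()].
#' @return The residual variance proportion (scalar).
#' @export
cv_statistic <- function(data, diff = "diff", label = "group", config) {
  diffs <- data[[diff]]
  labels <- as.character(data[[label]])
  stopifnot(length(unique(labels)) == 2,
            length(diffs) >= config$k_folds)
  withr::with_seed(as.integer(config$seed) %% .Machine$integer.max, {
    parts <- draw_partitionings(labels, config)
    rvp_for_labels(diffs, labels, parts, config$k_folds)
  })
}

#' Label-permutation test of the cross-validated prediction
#'
#' Recomputes the full averaged residual variance proportion under random
#' permutations of the drug labels (the fold partitionings are drawn once and
#' shared between the observed and permuted computations, so partitioning
#' noise cancels). The p value is the rate at which permuted statistics are
#' strictly smaller than the observed one; an add-one corrected variant is
#' available.
#'
#' @inheritParams cv_statistic
#' @param corrected Use the add-one permutation p value
#'   `(1 + #smaller) / (1 + n_permutations)` instead of the literal rate.
#' @return A `cv_perm` object: `statistic`, `permutation_distribution`,
#'   `p_value`, `config`. `tidy()`/`glance()`/`autoplot()` methods available.
#' @export
permutation_test <- function(data, diff = "diff", label = "group", config,
                             corrected = FALSE) {
  diffs <- data[[diff]]
  labels <- as.character(data[[label]])
  stopifnot(length(unique(labels)) == 2)
  res <- withr::with_seed(as.integer(config$seed) %% .Machine$integer.max, {
    parts <- draw_partitionings(labels, config)
    obs <- rvp_for_labels(diffs, labels, parts, config$k_folds)
    perm <- vapply(seq_len(config$n_permutations), function(i) {
      rvp_for_labels(diffs, sample(labels), parts, config$k_folds)
    }, numeric(1))
    list(obs = obs, perm = perm)
  })
  n_smaller <- sum(res$perm < res$obs, na.rm = TRUE)
  p <- if (corrected) (1 + n_smaller) / (1 + config$n_permutations) else
    n_smaller / config$n_permutations
  structure(list(statistic = res$obs, permutation_distribution = res$perm,
                 p_value = p, corrected = corrected, config = config,
                 n = length(diffs)),
            class = "cv_perm")
}

#' @export
print.cv_perm <- function(x, ...) {
  cat(sprintf(
    "<cv_perm> residual variance proportion %.3f, p %s %.4g (%d permutations)\n",
    x$statistic, if (x$p_value == 0) "<" else "=",
    max(x$p_value, 1 / x$config$n_permutations), x$config$n_permutations))
  invisible(x)
}

#' @export
tidy.cv_perm <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n = x$n, n_permutations = x$config$n_permutations)
}

#' @export
glance.cv_perm <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value, n = x$n,
                 k_folds = x$config$k_folds,
                 n_partitionings = x$config$n_partitionings,
                 n_permutations = x$config$n_permutations,
                 null_mean = mean(x$permutation_distribution))
}

#' Histogram of the permutation null with the observed statistic
#'
#' @param object A `cv_perm` object.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.cv_perm <- function(object, ...) {
  df <- tibble::tibble(stat = object$permutation_distribution)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "red") +
    ggplot2::labs(x = "residual variance proportion (permuted labels)",
                  y = "count",
                  title = sprintf("Permutation test: p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}
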