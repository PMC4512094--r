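#' Bayesian score of a single interval
#'
#' Log Dirichlet-multinomial marginal likelihood of the class counts falling
#' into one interval, under a symmetric Dirichlet prior with weight `alpha`
#' per class:
#' \deqn{\log\frac{\Gamma(C\alpha)}{\Gamma(C\alpha+n)} +
#'       \sum_c \log\frac{\Gamma(\alpha+n_c)}{\Gamma(\alpha)}}
#' where `C` is the number of classes and `n` the interval total. An empty
#' interval scores 0 (the empty product).
#'
#' @param class_counts non-negative integer vector, one count per class.
#' @param alpha symmetric Dirichlet prior weight (default 1).
#' @return The log marginal likelihood.
#' @export
interval_score <- function(class_counts, alpha = 1) {
  if (any(class_counts < 0)) stop("negative class count")
  C <- length(class_counts)
  if (C < 1L) stop("at least one class required")
  n <- sum(class_counts)
  lgamma(C * alpha) - lgamma(C * alpha + n) +
    sum(lgamma(alpha + class_counts) - lgamma(alpha))
}

#' Supervised Bayesian discretization of one variable
#'
#' Finds the cut-point set maximizing the total Bayesian score
#' (structure prior plus the sum of per-interval Dirichlet-multinomial
#' scores) over all partitions whose boundaries lie at midpoints between
#' consecutive distinct sorted values. Solved exactly by dynamic programming
#' over boundary positions, `O(B^2)` in the number of candidate boundaries.
#' The structure prior penalizes each cut by `lambda` on the log scale
#' (`log P(M) = -k * lambda` for `k` cuts); the default `lambda = log(B)`
#' over `B` candidate boundaries corresponds to a uniform prior on each
#' cut's position and keeps spurious cuts off pure-noise variables.
#'
#' Intervals follow the right-closed convention `(-Inf, c1], (c1, c2], ...,
#' (ck, +Inf)`. Ties between equal-score partitions are broken toward fewer
#' cuts, then toward the smaller leftmost cut, so output is deterministic.
#'
#' @param values numeric vector of observed values.
#' @param labels class label per value.
#' @param class_domain ordered class values (default: first appearance).
#' @param alpha Dirichlet prior weight per class.
#' @param lambda per-cut log-scale penalty; `NULL` (the default) uses
#'   `log(B)` with `B` the variable's number of candidate boundaries.
#' @return A list with `cuts` (strictly increasing numeric vector, possibly
#'   empty), `score` (the maximized log score) and `n_intervals`.
#' @export
ebd_discretize <- function(values, labels, class_domain = NULL,
                           alpha = 1, lambda = NULL) {
  if (length(values) == 0) stop("empty input")
  if (length(values) != length(labels)) stop("values/labels length mismatch")
  class_domain <- class_domain %||% unique(as.character(labels))
  y <- factor(as.character(labels), levels = class_domain)
  ord <- order(values)
  v <- values[ord]; y <- y[ord]
  # blocks of tied values; per-block class counts
  distinct <- unique(v)
  block <- match(v, distinct)
  counts <- t(vapply(seq_along(distinct), function(b) {
    tabulate(y[block == b], nbins = length(class_domain))
  }, integer(length(class_domain))))
  nb <- length(distinct)
  boundaries <- if (nb > 1) (distinct[-nb] + distinct[-1L]) / 2 else numeric(0)
  lambda <- lambda %||% log(max(length(boundaries), 1L))
  # cumulative counts for O(1) segment scores
  cum <- rbind(0, apply(counts, 2L, cumsum))
  C <- length(class_domain)

  # f[[j]]: best (score, cuts) for the first j blocks; the transition over
  # the last interval (blocks i..j) is vectorized over i
  best_score <- rep(-Inf, nb + 1L)
  best_cuts <- vector("list", nb + 1L)
  best_score[1L] <- 0
  best_cuts[[1L]] <- numeric(0)
  for (j in seq_len(nb)) {
    seg <- rep(cum[j + 1L, ], each = j) - cum[seq_len(j), , drop = FALSE]
    seg_scores <- lgamma(C * alpha) - lgamma(C * alpha + rowSums(seg)) +
      rowSums(lgamma(alpha + seg)) - C * lgamma(alpha)
    cand <- best_score[seq_len(j)] + seg_scores -
      lambda * (seq_len(j) > 1L)
    tied <- which(cand >= max(cand) - 1e-12)
    for (i in tied) {  # resolve score ties by the deterministic ordering
      cand_cuts <- if (i > 1L) c(best_cuts[[i]], boundaries[i - 1L])
                   else numeric(0)
      if (better_partition(cand[i], cand_cuts,
                           best_score[j + 1L], best_cuts[[j + 1L]])) {
        best_score[j + 1L] <- cand[i]
        best_cuts[[j + 1L]] <- cand_cuts
      }
    }
  }
  cuts <- best_cuts[[nb + 1L]]
  list(cuts = cuts, score = best_score[nb + 1L],
       n_intervals = length(cuts) + 1L)
}

# TRUE when (score_a, cuts_a) beats (score_b, cuts_b) under the deterministic
# ordering: higher score, then fewer cuts, then smaller leftmost cut.
better_partition <- function(score_a, cuts_a, score_b, cuts_b) {
  tol <- 1e-12
  if (score_a > score_b + tol) return(TRUE)
  if (score_a < score_b - tol) return(FALSE)
  if (length(cuts_a) != length(cuts_b)) {
    return(length(cuts_a) < length(cuts_b))
  }
  for (i in seq_along(cuts_a)) {
    if (cuts_a[i] < cuts_b[i] - tol) return(TRUE)
    if (cuts_a[i] > cuts_b[i] + tol) return(FALSE)
  }
  FALSE
}

#' Discretize every variable of a dataset
#'
#' Runs [ebd_discretize()] independently on each variable, returning a
#' discretization scheme (per-variable ordered cut points, interval counts
#' and Bayesian scores).
#'
#' @param dataset a continuous [trlfm_dataset()].
#' @inheritParams ebd_discretize
#' @return An object of class `trlfm_scheme`: list with `cuts` (named list),
#'   `scores`, `alpha`, `lambda`.
#' @export
ebd_scheme <- function(dataset, alpha = 1, lambda = NULL) {
  if (dataset$discrete) stop("dataset is already discrete")
  fits <- lapply(dataset$variable_names, function(v) {
    ebd_discretize(dataset$values[, v], dataset$class_labels,
                   class_domain = dataset$class_domain,
                   alpha = alpha, lambda = lambda)
  })
  names(fits) <- dataset$variable_names
  structure(list(cuts = lapply(fits, `[[`, "cuts"),
                 scores = vapply(fits, `[[`, numeric(1), "score"),
                 alpha = alpha, lambda = lambda),
            class = "trlfm_scheme")
}

# Numeric bounds of interval `i` under a cut vector.
interval_bounds <- function(cuts, i) {
  lo <- if (i == 1L) -Inf else cuts[i - 1L]
  hi <- if (i > length(cuts)) Inf else cuts[i]
  c(lo, hi)
}

# 1-based interval index of each value: index i means value in (c[i-1], c[i]].
interval_index <- function(x, cuts) {
  if (length(cuts) == 0) return(rep(1L, length(x)))
  findInterval(x, cuts, left.open = TRUE) + 1L
}

#' Apply a discretization scheme to a dataset
#'
#' Replaces each value by its 1-based interval index under the right-closed
#' convention; values beyond the training range fall into the open end
#' intervals.
#'
#' @param dataset a continuous [trlfm_dataset()].
#' @param scheme a `trlfm_scheme` covering every variable of `dataset`.
#' @return A discrete [trlfm_dataset()] carrying per-variable interval
#'   counts.
#' @export
apply_scheme <- function(dataset, scheme) {
  missing <- setdiff(dataset$variable_names, names(scheme$cuts))
  if (length(missing) > 0) {
    stop("variables missing from scheme: ", paste(missing, collapse = ", "))
  }
  vals <- vapply(dataset$variable_names, function(v) {
    interval_index(dataset$values[, v], scheme$cuts[[v]])
  }, integer(nrow(dataset$values)))
  if (nrow(dataset$values) == 1L) {
    vals <- matrix(vals, nrow = 1L,
                   dimnames = list(NULL, dataset$variable_names))
  }
  intervals <- vapply(scheme$cuts[dataset$variable_names], length,
                      integer(1)) + 1L
  trlfm_dataset(vals, class_labels = dataset$class_labels,
                sample_ids = dataset$sample_ids,
                variable_names = dataset$variable_names,
                class_domain = dataset$class_domain,
                discrete = TRUE, intervals = intervals)
}

#' Select discriminative variables from a scheme
#'
#' Variables discretized into a single interval carry no class signal and
#' are filtered out; the survivors are the "relevant variables" fed to
#' functional-module discovery and rule learning.
#'
#' @param scheme a `trlfm_scheme`.
#' @return Character vector of variables with at least two intervals.
#' @export
select_features <- function(scheme) {
  names(scheme$cuts)[lengths(scheme$cuts) >= 1L]
}
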