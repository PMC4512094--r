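#' Stratified k-fold assignment
#'
#' Partitions samples into k folds with per-class counts differing by at
#' most one across folds. When the rarest class has fewer than k members, k
#' is reduced to that count with a warning.
#'
#' @param labels class label per sample.
#' @param k number of folds (default 10).
#' @param seed RNG seed; identical seeds give identical folds.
#' @return List of k integer vectors of sample indices (disjoint,
#'   exhaustive).
#' @export
stratified_kfold <- function(labels, k = 10L, seed = NULL) {
  if (k < 2L) stop("k must be at least 2")
  min_class <- min(table(labels))
  if (min_class < k) {
    warning("rarest class has ", min_class, " samples; reducing k from ",
            k, " to ", min_class)
    k <- min_class
    if (k < 2L) stop("cannot stratify: a class has fewer than 2 samples")
  }
  with_seed(seed, {
    fold_of <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
    lapply(seq_len(k), function(f) which(fold_of == f))
  })
}

#' Rank-based AUC
#'
#' Mann-Whitney estimator of the area under the ROC curve with half-credit
#' for tied scores. Abstaining predictions enter at the neutral score 0 and
#' therefore count as ties.
#'
#' @param scores real-valued classifier scores (higher = more positive).
#' @param labels class label per score.
#' @param positive_class the positive class (default: first label value).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, positive_class = NULL) {
  positive_class <- positive_class %||% labels[1L]
  pos <- labels == positive_class
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC needs at least one instance per class")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validate a rule learner
#'
#' Stratified k-fold cross-validation of the baseline rule learner or the
#' transfer learner. Within each fold, discretization is computed on the
#' training split only and applied to the held-out split; for the transfer
#' learner, functional modules are discovered once per dataset (from the
#' full-data discretization) while prior-rule eligibility uses each fold's
#' own selected variables.
#'
#' @param dataset a continuous [trlfm_dataset()].
#' @param criteria a [rule_criteria()] object.
#' @param k number of folds (default 10).
#' @param seed RNG seed driving fold assignment and clustering.
#' @param learner `"rl"` (baseline) or `"trlfm"`.
#' @param sources,annotations,ontology,mode,threshold,also_identical
#'   transfer inputs, required when `learner = "trlfm"`; see
#'   [trlfm_learn()].
#' @param positive_class positive class for AUC (default: first class).
#' @param alpha,lambda discretization priors.
#' @return A list of class `trlfm_cv` with `fold_auc`, `mean_auc`, `sem`
#'   (sample SD of fold AUCs over sqrt(k)), `abstention_rate`, `k`.
#' @export
cross_validate <- function(dataset, criteria = rule_criteria(), k = 10L,
                           seed = NULL, learner = c("rl", "trlfm"),
                           sources = NULL, annotations = NULL,
                           ontology = NULL, mode = "union", threshold = 0.5,
                           also_identical = FALSE, positive_class = NULL,
                           alpha = 1, lambda = NULL) {
  learner <- match.arg(learner)
  positive_class <- positive_class %||% dataset$class_domain[1L]
  folds <- stratified_kfold(dataset$class_labels, k = k, seed = seed)
  k <- length(folds)

  set1 <- character(0)
  modules <- list()
  if (learner == "trlfm") {
    if (is.null(sources) || is.null(annotations) || is.null(ontology)) {
      stop("trlfm cross-validation needs sources, annotations and ontology")
    }
    set1 <- suppressWarnings(source_variables(sources))
    full_scheme <- ebd_scheme(dataset, alpha = alpha, lambda = lambda)
    set2_full <- select_features(full_scheme)
    if (length(set1) > 0 && length(set2_full) > 0) {
      fmres <- suppressWarnings(
        discover_modules(union(set1, set2_full), annotations, ontology,
                         threshold = threshold, seed = seed))
      modules <- fmres$modules
    }
  }

  fold_auc <- rep(NA_real_, k)
  abstained <- 0L
  total <- 0L
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train <- dataset_subset(dataset, samples = setdiff(seq_along(
      dataset$sample_ids), test_idx))
    test <- dataset_subset(dataset, samples = test_idx)
    scheme <- ebd_scheme(train, alpha = alpha, lambda = lambda)
    kept <- select_features(scheme)
    scores <- if (length(kept) == 0) {
      abstained <- abstained + length(test_idx)
      rep(0, length(test_idx))
    } else {
      dtrain <- apply_scheme(dataset_subset(train, variables = kept), scheme)
      priors <- list()
      if (learner == "trlfm" && length(modules) > 0 && length(set1) > 0) {
        prov <- eligible_targets(set1, kept, modules, mode = mode,
                                 also_identical = also_identical)
        if (nrow(prov) > 0) {
          priors <- generate_prior_rules(unique(prov$target), scheme,
                                         dataset$class_domain)
        }
      }
      model <- learn_rules(dtrain, criteria, priors = priors,
                           seed = derive_seed(seed, f))
      dtest <- apply_scheme(dataset_subset(test, variables = kept), scheme)
      pred <- predict(model, dtest, positive_class = positive_class)
      abstained <- abstained + sum(pred$prediction == "ABSTAIN")
      pred$score
    }
    total <- total + length(test_idx)
    labs <- test$class_labels
    if (length(unique(labs)) >= 2L) {
      fold_auc[f] <- auc(scores, labs, positive_class = positive_class)
    }
  }
  ok <- !is.na(fold_auc)
  structure(list(fold_auc = fold_auc,
                 mean_auc = mean(fold_auc[ok]),
                 sem = stats::sd(fold_auc[ok]) / sqrt(sum(ok)),
                 abstention_rate = abstained / total,
                 k = k),
            class = "trlfm_cv")
}

#' @export
print.trlfm_cv <- function(x, ...) {
  cat(sprintf("<trlfm_cv> %d folds: mean AUC %.3f (SEM %.3f), abstention %.1f%%\n",
              x$k, x$mean_auc, x$sem, 100 * x$abstention_rate))
  invisible(x)
}

#' Enumerate leave-one-dataset-out-as-target experiments
#'
#' For every study set of n datasets, produces n experiments in which each
#' dataset in turn is the target and the remaining n-1 are the sources
#' (three sets of seven datasets give 21 experiments).
#'
#' @param study_sets named list of study sets, each a character vector of
#'   at least two dataset names.
#' @return A list of experiments, each a list with `study`, `target`,
#'   `sources`.
#' @export
experiment_grid <- function(study_sets) {
  if (is.null(names(study_sets))) {
    names(study_sets) <- paste0("study", seq_along(study_sets))
  }
  out <- list()
  for (s in names(study_sets)) {
    ds <- study_sets[[s]]
    if (length(ds) < 2L) stop("study set '", s, "' has fewer than 2 datasets")
    for (d in ds) {
      out[[length(out) + 1L]] <- list(study = s, target = d,
                                      sources = setdiff(ds, d))
    }
  }
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences; zero differences are
#' dropped first. Uses the exact distribution for 25 or fewer non-zero
#' pairs without ties, and the normal approximation with tie and continuity
#' correction otherwise. All-zero differences give p = 1.
#'
#' @param paired_a,paired_b equal-length numeric vectors of paired
#'   measurements (e.g. per-target AUCs of two methods).
#' @return Two-sided p-value.
#' @export
signed_rank_test <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b)) stop("unequal lengths")
  d <- paired_a - paired_b
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  res <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  min(res$p.value, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; output order matches input order.
#'
#' @param pvalues numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}
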