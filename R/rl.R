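# Rule objects are lists with parallel vectors `vars` / `intervals`
# (the antecedent conjuncts), a `class` consequent, and the statistics
# tp, fp, coverage, cf, p. The canonical key string (sorted conjuncts plus
# consequent) identifies a rule for deduplication.

new_rule <- function(vars, intervals, class, tp = NA_integer_,
                     fp = NA_integer_, cf = NA_real_, p = NA_real_) {
  if (anyDuplicated(vars)) stop("conjuncts must reference distinct variables")
  ord <- order(vars)
  structure(list(vars = as.character(vars)[ord],
                 intervals = as.integer(intervals)[ord],
                 class = as.character(class),
                 tp = as.integer(tp), fp = as.integer(fp),
                 coverage = as.integer(tp + fp),
                 cf = cf, p = p),
            class = "trlfm_rule")
}

rule_key <- function(rule) {
  paste0(paste(rule$vars, rule$intervals, sep = "=", collapse = "&"),
         "=>", rule$class)
}

#' Format a rule as an IF-THEN string
#'
#' When a discretization scheme is supplied the interval indices are
#' rendered as threshold tests (e.g. `gene1 > 1680`), otherwise as
#' `variable = interval`.
#'
#' @param rule a rule object.
#' @param scheme optional `trlfm_scheme` for threshold rendering.
#' @export
format_rule <- function(rule, scheme = NULL) {
  conj <- vapply(seq_along(rule$vars), function(i) {
    v <- rule$vars[i]; iv <- rule$intervals[i]
    if (!is.null(scheme) && v %in% names(scheme$cuts) &&
        length(scheme$cuts[[v]]) > 0) {
      b <- interval_bounds(scheme$cuts[[v]], iv)
      if (is.infinite(b[1L]) && is.finite(b[2L])) {
        sprintf("%s <= %g", v, b[2L])
      } else if (is.finite(b[1L]) && is.infinite(b[2L])) {
        sprintf("%s > %g", v, b[1L])
      } else if (is.finite(b[1L])) {
        sprintf("%s in (%g, %g]", v, b[1L], b[2L])
      } else {
        sprintf("%s = any", v)
      }
    } else {
      sprintf("%s = %d", v, iv)
    }
  }, character(1))
  sprintf("IF (%s) THEN (Class = %s)  [CF=%.3f, P=%.3g, TP=%d, FP=%d]",
          paste(conj, collapse = " AND "), rule$class,
          rule$cf, rule$p, rule$tp, rule$fp)
}

#' @export
print.trlfm_rule <- function(x, ...) {
  cat(format_rule(x), "\n")
  invisible(x)
}

#' Certainty factor of a rule
#'
#' `precision` is `tp / (tp + fp)` (0 at zero coverage); `laplace` is
#' `(tp + 1) / (tp + fp + C)` with `C` the number of classes.
#'
#' @param tp,fp non-negative true/false positive counts.
#' @param method `"laplace"` (default) or `"precision"`.
#' @param n_classes number of classes `C` for the Laplace estimate.
#' @return The certainty factor in `[0, 1]`.
#' @export
certainty_factor <- function(tp, fp, method = c("laplace", "precision"),
                             n_classes = 2L) {
  method <- match.arg(method)
  if (tp < 0 || fp < 0) stop("negative count")
  if (method == "precision") {
    if (tp + fp == 0) 0 else tp / (tp + fp)
  } else {
    (tp + 1) / (tp + fp + n_classes)
  }
}

#' One-sided Fisher exact p-value for a 2x2 table
#'
#' Enrichment tail `P(X >= a)` of the hypergeometric distribution at fixed
#' margins for the table `(a, b; c, d)` (rows: consequent class vs rest;
#' columns: matched vs unmatched). Computed on the log scale via
#' [stats::phyper()].
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return p-value in `(0, 1]`.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + c == 0) return(1)  # empty coverage column
  stats::phyper(a - 1, m = a + b, n = c + d, k = a + c, lower.tail = FALSE)
}

#' Compute a rule's statistics on a discrete dataset
#'
#' An instance matches when every conjunct's interval contains its value.
#' `tp` counts matches of the consequent class, `fp` all other matches;
#' the certainty factor comes from [certainty_factor()] and the p-value
#' from [fisher_exact_p()] on the consequent-vs-rest by matched-vs-unmatched
#' table.
#'
#' @param rule a rule (statistics may be unset).
#' @param dataset a discrete [trlfm_dataset()].
#' @param cf_function certainty-factor estimator.
#' @return The rule with `tp`, `fp`, `coverage`, `cf`, `p` filled in.
#' @export
rule_statistics <- function(rule, dataset,
                            cf_function = c("laplace", "precision")) {
  cf_function <- match.arg(cf_function)
  unknown <- setdiff(rule$vars, dataset$variable_names)
  if (length(unknown) > 0) {
    stop("unknown variable in antecedent: ", paste(unknown, collapse = ", "))
  }
  match <- rep(TRUE, nrow(dataset$values))
  for (i in seq_along(rule$vars)) {
    match <- match & dataset$values[, rule$vars[i]] == rule$intervals[i]
  }
  pos <- dataset$class_labels == rule$class
  tp <- sum(match & pos)
  fp <- sum(match) - tp
  rule$tp <- as.integer(tp)
  rule$fp <- as.integer(fp)
  rule$coverage <- as.integer(tp + fp)
  rule$cf <- certainty_factor(tp, fp, cf_function,
                              n_classes = length(dataset$class_domain))
  rule$p <- fisher_exact_p(tp, sum(pos) - tp, fp, sum(!pos) - fp)
  rule
}

#' Seed rules: one per variable, interval and class
#'
#' For every discretized interval value of every variable, creates one
#' single-conjunct rule per class value (for a Case/Control problem, two
#' rules per discretized marker value), with statistics attached.
#'
#' @param dataset a discrete [trlfm_dataset()].
#' @param cf_function certainty-factor estimator.
#' @return List of rules.
#' @export
initial_rules <- function(dataset, cf_function = "laplace") {
  rules <- list()
  for (v in dataset$variable_names) {
    for (iv in seq_len(dataset$intervals[[v]])) {
      for (cl in dataset$class_domain) {
        rules[[length(rules) + 1L]] <-
          rule_statistics(new_rule(v, iv, cl), dataset, cf_function)
      }
    }
  }
  rules
}

#' Specialize a rule by one conjunct
#'
#' Returns every rule formed by appending a single (variable, interval)
#' conjunct on a variable not already tested, with statistics recomputed.
#' Returns an empty list when the rule is already at `max_conjuncts`.
#'
#' @param rule a rule with statistics.
#' @param dataset a discrete [trlfm_dataset()].
#' @param max_conjuncts antecedent length cap.
#' @param cf_function certainty-factor estimator.
#' @return List of specialized rules.
#' @export
specialize <- function(rule, dataset, max_conjuncts = Inf,
                       cf_function = "laplace") {
  if (length(rule$vars) >= max_conjuncts) return(list())
  out <- list()
  for (v in setdiff(dataset$variable_names, rule$vars)) {
    for (iv in seq_len(dataset$intervals[[v]])) {
      out[[length(out) + 1L]] <- rule_statistics(
        new_rule(c(rule$vars, v), c(rule$intervals, iv), rule$class),
        dataset, cf_function)
    }
  }
  out
}

#' Does a rule satisfy the good-rule criteria?
#'
#' Checks `cf >= min_cf`, `coverage >= min_coverage`,
#' `fp / negatives <= max_fp_rate` (negatives = training instances of the
#' other classes) and antecedent length `<= max_conjuncts`. Inductive
#' strengthening is checked separately at model admission via the
#' `covered` argument: when supplied, the rule must have at least
#' `inductive_strengthening` true positives outside `covered`.
#'
#' @param rule a rule with statistics.
#' @param criteria a [rule_criteria()] object.
#' @param dataset the discrete training dataset.
#' @param covered optional logical vector (per sample) of instances already
#'   covered by accepted rules of the same consequent.
#' @return Logical.
#' @export
is_good <- function(rule, criteria, dataset, covered = NULL) {
  if (length(rule$vars) > criteria$max_conjuncts) return(FALSE)
  if (rule$coverage < criteria$min_coverage) return(FALSE)
  if (rule$cf < criteria$min_cf) return(FALSE)
  negatives <- sum(dataset$class_labels != rule$class)
  fp_rate <- if (negatives == 0) 0 else rule$fp / negatives
  if (fp_rate > criteria$max_fp_rate) return(FALSE)
  if (!is.null(covered) && criteria$inductive_strengthening > 0) {
    m <- rule_matches(rule, dataset)
    new_tp <- sum(m & dataset$class_labels == rule$class & !covered)
    if (new_tp < criteria$inductive_strengthening) return(FALSE)
  }
  TRUE
}

rule_matches <- function(rule, dataset) {
  m <- rep(TRUE, nrow(dataset$values))
  for (i in seq_along(rule$vars)) {
    m <- m & dataset$values[, rule$vars[i]] == rule$intervals[i]
  }
  m
}

# Total order on rules: cf desc, coverage desc, antecedent length asc,
# lexicographic antecedent asc, consequent asc. Returns a permutation.
beam_order <- function(rules) {
  if (length(rules) == 0) return(integer(0))
  order(-vapply(rules, `[[`, numeric(1), "cf"),
        -vapply(rules, function(r) as.numeric(r$coverage), numeric(1)),
        vapply(rules, function(r) length(r$vars), integer(1)),
        vapply(rules, rule_key, character(1)),
        method = "radix")
}

# Sort rules by the beam key, drop duplicates, truncate to capacity.
beam_trim <- function(rules, width) {
  if (length(rules) == 0) return(rules)
  keys <- vapply(rules, rule_key, character(1))
  rules <- rules[!duplicated(keys)]
  rules <- rules[beam_order(rules)]
  rules[seq_len(min(length(rules), width))]
}

#' Learn a classification rule model by beam search
#'
#' General-to-specific beam search with covering with replacement (no
#' training instance is ever removed). The beam is initialized with the
#' supplied prior rules (statistics recomputed on this dataset) plus the
#' single-conjunct seed rules; every beam rule satisfying the good-rule
#' criteria is repeatedly specialized, children enter the beam if they
#' satisfy the criteria, and the search stops when no rule yields a new
#' accepted specialization. The model is the set of beam rules passing the
#' criteria, in beam order, after the inductive-strengthening admission
#' filter.
#'
#' @param dataset a discrete [trlfm_dataset()].
#' @param criteria a [rule_criteria()] object.
#' @param priors optional list of prior rules used to seed the beam (e.g.
#'   from [generate_prior_rules()]).
#' @param seed unused by the (deterministic) search; kept so every learner
#'   entry point shares a signature.
#' @return A `trlfm_rule_model`: list with `rules`, `criteria`, `metadata`.
#' @export
learn_rules <- function(dataset, criteria = rule_criteria(), priors = list(),
                        seed = NULL) {
  if (!dataset$discrete) stop("learn_rules requires a discrete dataset")
  cf_fun <- criteria$cf_function
  priors <- lapply(priors, function(r) {
    rule_statistics(new_rule(r$vars, r$intervals, r$class), dataset, cf_fun)
  })
  beam <- beam_trim(c(priors, initial_rules(dataset, cf_fun)),
                    criteria$beam_width)
  seen <- new.env(parent = emptyenv())
  for (r in beam) assign(rule_key(r), TRUE, envir = seen)
  specialized <- new.env(parent = emptyenv())

  repeat {
    parents <- Filter(function(r) {
      length(r$vars) < criteria$max_conjuncts &&
        is.null(specialized[[rule_key(r)]]) &&
        is_good(r, criteria, dataset)
    }, beam)
    if (length(parents) == 0) break
    children <- list()
    for (p in parents) {
      assign(rule_key(p), TRUE, envir = specialized)
      for (ch in specialize(p, dataset, criteria$max_conjuncts, cf_fun)) {
        key <- rule_key(ch)
        if (!is.null(seen[[key]])) next
        if (!is_good(ch, criteria, dataset)) next
        assign(key, TRUE, envir = seen)
        children[[length(children) + 1L]] <- ch
      }
    }
    if (length(children) == 0) next
    beam <- beam_trim(c(beam, children), criteria$beam_width)
  }

  candidates <- Filter(function(r) is_good(r, criteria, dataset), beam)
  rules <- list()
  covered_by_class <- lapply(stats::setNames(dataset$class_domain,
                                             dataset$class_domain),
                             function(cl) rep(FALSE, nrow(dataset$values)))
  for (r in candidates) {
    cov <- covered_by_class[[r$class]]
    if (is_good(r, criteria, dataset, covered = cov)) {
      rules[[length(rules) + 1L]] <- r
      covered_by_class[[r$class]] <- cov | rule_matches(r, dataset)
    }
  }
  new_rule_model(rules, criteria,
                 metadata = list(n_samples = nrow(dataset$values),
                                 class_domain = dataset$class_domain,
                                 n_priors = length(priors)))
}

new_rule_model <- function(rules, criteria, metadata = list()) {
  structure(list(rules = rules, criteria = criteria, metadata = metadata),
            class = "trlfm_rule_model")
}

#' @export
print.trlfm_rule_model <- function(x, ...) {
  cat(sprintf("<trlfm_rule_model> %d rule(s)\n", length(x$rules)))
  scheme <- x$metadata$scheme
  for (r in utils::head(x$rules, 10L)) cat(" ", format_rule(r, scheme), "\n")
  if (length(x$rules) > 10L) cat("  ...\n")
  invisible(x)
}

#' Predict with a rule model (abstaining)
#'
#' Matching rules vote with weight CF; the predicted class is the argmax of
#' the summed weights (ties resolved by class-domain order). An instance
#' matched by no rule receives `ABSTAIN`. The AUC score is the summed CF of
#' matching positive-class rules minus the summed CF for the other classes;
#' abstentions score 0 (neutral).
#'
#' @param object a `trlfm_rule_model`.
#' @param dataset a discrete [trlfm_dataset()] aligned with the training
#'   discretization.
#' @param positive_class class treated as positive for the score (default:
#'   first class of the training domain).
#' @param ... unused.
#' @return A data.frame with columns `sample`, `prediction` (class or
#'   `"ABSTAIN"`) and `score`.
#' @export
predict.trlfm_rule_model <- function(object, dataset,
                                     positive_class = NULL, ...) {
  classes <- object$metadata$class_domain %||% dataset$class_domain
  positive_class <- positive_class %||% classes[1L]
  n <- nrow(dataset$values)
  votes <- matrix(0, nrow = n, ncol = length(classes),
                  dimnames = list(NULL, classes))
  n_matching <- rep(0L, n)
  for (r in object$rules) {
    m <- rule_matches(r, dataset)
    votes[m, r$class] <- votes[m, r$class] + r$cf
    n_matching <- n_matching + m
  }
  any_match <- n_matching > 0L
  prediction <- rep("ABSTAIN", n)
  if (any(any_match)) {
    prediction[any_match] <- classes[max.col(votes[any_match, , drop = FALSE],
                                             ties.method = "first")]
  }
  score <- votes[, positive_class] -
    rowSums(votes[, setdiff(classes, positive_class), drop = FALSE])
  data.frame(sample = dataset$sample_ids, prediction = prediction,
             score = as.numeric(score), stringsAsFactors = FALSE)
}
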