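#' Variables carried by source knowledge (Set1)
#'
#' The union of every variable appearing in any antecedent of any source
#' rule model; alternatively, a literal biomarker list when no source
#' dataset is available.
#'
#' @param sources a list of `trlfm_rule_model` objects, a single model, or
#'   a character vector of biomarker symbols.
#' @return Character vector of variable names (possibly empty, with a
#'   warning: transfer then degenerates to the baseline learner).
#' @export
source_variables <- function(sources) {
  if (is.character(sources)) {
    out <- unique(sources)
  } else {
    if (inherits(sources, "trlfm_rule_model")) sources <- list(sources)
    out <- unique(unlist(lapply(sources, function(m) {
      unlist(lapply(m$rules, `[[`, "vars"))
    })))
    out <- out %||% character(0)
  }
  if (length(out) == 0) {
    warning("empty source variable set; transfer degenerates to baseline")
  }
  out
}

#' Target variables eligible for prior-rule instantiation
#'
#' A target variable `a_Tj` is selected when it belongs to Set2 and shares
#' a functional module `FM_k` with some Set1 variable `a_Si` (the variable
#' may license itself when the same symbol occurs in both sets and in a
#' module). In `single_fm` mode only the named module can license; in
#' `union` mode any module can.
#'
#' @param set1 source variable set, see [source_variables()].
#' @param set2 target's discretization-selected variable set.
#' @param modules module list from [discover_modules()].
#' @param mode `"union"` (default) or the id (e.g. `"FM2"`) / index of a
#'   single module.
#' @param also_identical if `TRUE`, symbols present in both sets are
#'   additionally eligible regardless of module co-membership (emulates
#'   plain identical-variable transfer).
#' @return A data.frame of licensing triples with columns `target`,
#'   `source`, `module`; the eligible variables are `unique(out$target)`.
#' @export
eligible_targets <- function(set1, set2, modules, mode = "union",
                             also_identical = FALSE) {
  in_scope <- if (identical(mode, "union")) {
    modules
  } else {
    id <- if (is.numeric(mode)) paste0("FM", mode) else as.character(mode)
    Filter(function(m) identical(m$id, id), modules)
  }
  rows <- list()
  for (m in in_scope) {
    s1 <- intersect(set1, m$genes)
    s2 <- intersect(set2, m$genes)
    if (length(s1) == 0 || length(s2) == 0) next
    for (tj in s2) {
      for (si in s1) {
        rows[[length(rows) + 1L]] <- data.frame(
          target = tj, source = si, module = m$id,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (also_identical) {
    for (tj in intersect(set1, set2)) {
      rows[[length(rows) + 1L]] <- data.frame(
        target = tj, source = tj, module = "identical",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(target = character(0), source = character(0),
                      module = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$target, out$module, out$source), , drop = FALSE]
}

#' Instantiate prior rules over a target's discrete ranges
#'
#' For every eligible variable, builds one single-conjunct rule per
#' (interval, class) pair: a two-interval variable under Case/Control
#' yields the four structures `IF (a = LOW/HIGH) THEN (Class =
#' Case/Control)`. Statistics stay unset until the rules are recomputed on
#' the target data inside [learn_rules()].
#'
#' @param eligible character vector of eligible target variables.
#' @param scheme the target's `trlfm_scheme`.
#' @param classes the target's class domain.
#' @return List of prior rules (empty for an empty eligible list).
#' @export
generate_prior_rules <- function(eligible, scheme, classes) {
  rules <- list()
  for (v in unique(eligible)) {
    if (!v %in% names(scheme$cuts)) {
      stop("eligible variable missing from the target scheme: ", v)
    }
    for (iv in seq_len(length(scheme$cuts[[v]]) + 1L)) {
      for (cl in classes) {
        rules[[length(rules) + 1L]] <- new_rule(v, iv, cl)
      }
    }
  }
  rules
}

#' Transfer rule learning through functional modules
#'
#' Full pipeline on a target dataset: supervised discretization defines
#' Set2 (the relevant target variables); functional modules are discovered
#' over Set1 union Set2; eligible target variables are selected by module
#' co-membership with Set1; prior rules instantiated over the target's own
#' discrete ranges seed the beam; and the rule learner runs as usual, so
#' priors failing the good-rule criteria are pruned exactly like any rule.
#' With no functional link between Set1 and Set2 the result is identical
#' to the baseline [learn_rules()] at the same seed.
#'
#' @param sources source rule models (list or single) or a biomarker
#'   character vector.
#' @param target a continuous or discrete [trlfm_dataset()].
#' @param annotations a `trlfm_annotations` map.
#' @param ontology a `trlfm_ontology`.
#' @param criteria a [rule_criteria()] object.
#' @param mode `"union"` or a single module id/index, see
#'   [eligible_targets()].
#' @param threshold module retention threshold on average silhouette.
#' @param alpha,lambda discretization priors, see [ebd_discretize()]
#'   (`lambda = NULL` uses the per-variable positional default).
#' @param also_identical see [eligible_targets()].
#' @param seed RNG seed (used by the module-discovery clustering).
#' @return A `trlfm_rule_model` whose metadata records the licensing
#'   triples (`provenance`), Set1, Set2 and the discretization scheme.
#' @export
trlfm_learn <- function(sources, target, annotations, ontology,
                        criteria = rule_criteria(), mode = "union",
                        threshold = 0.5, alpha = 1, lambda = NULL,
                        also_identical = FALSE, seed = NULL) {
  set1 <- suppressWarnings(source_variables(sources))
  if (!target$discrete) {
    scheme <- ebd_scheme(target, alpha = alpha, lambda = lambda)
    set2 <- select_features(scheme)
    dtarget <- if (length(set2) > 0) {
      apply_scheme(dataset_subset(target, variables = set2), scheme)
    } else {
      apply_scheme(target, scheme)
    }
  } else {
    scheme <- NULL
    set2 <- target$variable_names[target$intervals >= 2L]
    dtarget <- if (length(set2) > 0) {
      dataset_subset(target, variables = set2)
    } else {
      target
    }
  }
  prov <- data.frame(target = character(0), source = character(0),
                     module = character(0), stringsAsFactors = FALSE)
  priors <- list()
  fm <- NULL
  if (length(set1) > 0 && length(set2) > 0) {
    fm <- suppressWarnings(
      discover_modules(union(set1, set2), annotations, ontology,
                       threshold = threshold, seed = seed))
    prov <- eligible_targets(set1, set2, fm$modules, mode = mode,
                             also_identical = also_identical)
    eligible <- unique(prov$target)
    if (length(eligible) > 0) {
      if (!is.null(scheme)) {
        priors <- generate_prior_rules(eligible, scheme,
                                       target$class_domain)
      } else {
        # discrete target: ranges come from the observed interval counts
        pseudo <- structure(list(cuts = lapply(
          stats::setNames(eligible, eligible),
          function(v) seq_len(dtarget$intervals[[v]] - 1L))),
          class = "trlfm_scheme")
        priors <- generate_prior_rules(eligible, pseudo,
                                       target$class_domain)
      }
      message(nrow(prov), " licensing triple(s) over ",
              length(eligible), " eligible target variable(s)")
    }
  }
  model <- learn_rules(dtarget, criteria, priors = priors, seed = seed)
  model$metadata$set1 <- set1
  model$metadata$set2 <- set2
  model$metadata$provenance <- prov
  model$metadata$mode <- if (is.numeric(mode)) paste0("FM", mode) else mode
  model$metadata$modules <- fm$modules
  model$metadata$scheme <- scheme
  model
}
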