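#' Expression dataset
#'
#' Container for a samples-by-variables expression table with one class label
#' per sample. Values are either continuous measurements or, after
#' discretization, 1-based interval indices.
#'
#' @param values numeric matrix, samples in rows, variables in columns.
#' @param class_labels character vector of per-sample class labels.
#' @param sample_ids optional sample identifiers (default: rownames of
#'   `values`, else `s1`, `s2`, ...).
#' @param variable_names optional variable (gene) names (default: colnames).
#' @param class_domain ordered set of class values; defaults to the labels in
#'   order of first appearance. The first class is treated as the positive
#'   class for TP/FP/AUC unless overridden downstream.
#' @param discrete logical; `TRUE` when `values` holds interval indices.
#' @param intervals for discrete datasets, a named integer vector giving the
#'   number of intervals per variable (default: max observed index).
#'
#' @return An object of class `trlfm_dataset`: a list with elements
#'   `values`, `sample_ids`, `variable_names`, `class_labels`, `class_domain`,
#'   `discrete` and (when discrete) `intervals`.
#' @export
trlfm_dataset <- function(values, class_labels, sample_ids = NULL,
                          variable_names = NULL, class_domain = NULL,
                          discrete = FALSE, intervals = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (length(class_labels) != n) {
    stop("class_labels must have one entry per sample (row of values)")
  }
  sample_ids <- sample_ids %||% rownames(values) %||% paste0("s", seq_len(n))
  variable_names <- variable_names %||% colnames(values) %||%
    (if (ncol(values) > 0) paste0("v", seq_len(ncol(values))) else character(0))
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  }
  if (anyDuplicated(variable_names)) {
    stop("duplicate variable name: ",
         variable_names[duplicated(variable_names)][1L])
  }
  class_labels <- as.character(class_labels)
  class_domain <- class_domain %||% unique(class_labels)
  if (!all(class_labels %in% class_domain)) {
    stop("class labels outside the class domain: ",
         paste(setdiff(class_labels, class_domain), collapse = ", "))
  }
  if (length(class_domain) < 2L) {
    stop("class domain must contain at least two classes")
  }
  if (anyNA(values)) {
    stop("missing values in the expression table; impute or filter first")
  }
  dimnames(values) <- list(sample_ids, variable_names)
  ds <- list(values = values, sample_ids = sample_ids,
             variable_names = variable_names, class_labels = class_labels,
             class_domain = class_domain, discrete = isTRUE(discrete))
  if (ds$discrete) {
    storage.mode(ds$values) <- "integer"
    if (is.null(intervals)) {
      intervals <- if (ncol(values) > 0) {
        apply(ds$values, 2L, max)
      } else {
        integer(0)
      }
      names(intervals) <- variable_names
    }
    ds$intervals <- intervals[variable_names]
  }
  structure(ds, class = "trlfm_dataset")
}

#' @export
print.trlfm_dataset <- function(x, ...) {
  cat(sprintf("<trlfm_dataset> %d samples x %d variables (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$discrete) "discrete" else "continuous"))
  tab <- table(factor(x$class_labels, levels = x$class_domain))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

# Subset a dataset by sample index and/or variable names, preserving metadata.
dataset_subset <- function(dataset, samples = NULL, variables = NULL) {
  idx <- samples %||% seq_along(dataset$sample_ids)
  vars <- variables %||% dataset$variable_names
  missing <- setdiff(vars, dataset$variable_names)
  if (length(missing) > 0) {
    stop("unknown variables: ", paste(missing, collapse = ", "))
  }
  trlfm_dataset(dataset$values[idx, vars, drop = FALSE],
                class_labels = dataset$class_labels[idx],
                sample_ids = dataset$sample_ids[idx],
                variable_names = vars,
                class_domain = dataset$class_domain,
                discrete = dataset$discrete,
                intervals = if (dataset$discrete) dataset$intervals[vars])
}
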