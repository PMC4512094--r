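#' Read an expression table from TSV
#'
#' Expects a tab-separated file with a header row: one sample per row, one
#' gene per column, plus a class-label column (default name `class`). If the
#' first column is named `sample` it supplies the sample identifiers;
#' otherwise samples are numbered in file order. Numeric parsing uses the dot
#' decimal separator regardless of locale.
#'
#' @param path path to the TSV file.
#' @param label_column name of the class-label column.
#' @param discrete logical; `TRUE` if the file holds interval indices.
#' @return A [trlfm_dataset()] whose class domain follows first appearance
#'   order in the file.
#' @export
read_expression_table <- function(path, label_column = "class",
                                  discrete = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          fill = FALSE, stringsAsFactors = FALSE)
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found in ", path)
  }
  if (names(df)[1L] == "sample") {
    sample_ids <- df[["sample"]]
    df <- df[, -1L, drop = FALSE]
    dup <- sample_ids[duplicated(sample_ids)]
    if (length(dup) > 0) {
      row <- which(duplicated(sample_ids))[1L] + 1L  # +1 for the header row
      stop("duplicate sample id '", dup[1L], "' at row ", row)
    }
  } else {
    sample_ids <- paste0("s", seq_len(nrow(df)))
  }
  labels <- df[[label_column]]
  df <- df[, setdiff(names(df), label_column), drop = FALSE]
  values <- vapply(df, function(col) {
    x <- suppressWarnings(as.numeric(col))
    if (anyNA(x)) stop("non-numeric expression value: ",
                       col[is.na(x)][1L])
    x
  }, numeric(nrow(df)))
  if (nrow(df) == 1L) values <- matrix(values, nrow = 1L,
                                       dimnames = list(NULL, names(df)))
  trlfm_dataset(values, class_labels = labels, sample_ids = sample_ids,
                discrete = discrete)
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression_table()]; the sample-id column is written
#' first under the name `sample` and the label column last under `class`.
#'
#' @param dataset a [trlfm_dataset()].
#' @param path output path.
#' @export
write_expression_table <- function(dataset, path) {
  df <- data.frame(sample = dataset$sample_ids,
                   dataset$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$class <- dataset$class_labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-term annotation map
#'
#' Parses a two-column TSV (gene, term id) with no header, emulating an
#' extract from a GO annotation database. Rows are aggregated into term sets
#' per gene; duplicate rows are idempotent.
#'
#' @param path path to the TSV file.
#' @param ontology optional [read_ontology()] result; when supplied, every
#'   term id must exist in it.
#' @return A named list mapping gene symbol to a character vector of term
#'   ids, of class `trlfm_annotations`.
#' @export
read_annotations <- function(path, ontology = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(structure(stats::setNames(list(), character(0)),
                     class = "trlfm_annotations"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) {
    stop("malformed annotation row at line ", bad[1L],
         " (expected 2 tab-separated fields)")
  }
  genes <- vapply(parts, `[[`, character(1), 1L)
  terms <- vapply(parts, `[[`, character(1), 2L)
  ann <- lapply(split(terms, factor(genes, levels = unique(genes))),
                function(x) sort(unique(x)))
  ann <- structure(ann, class = "trlfm_annotations")
  if (!is.null(ontology)) validate_annotations(ann, ontology)
  ann
}

#' @rdname read_annotations
#' @param annotations a `trlfm_annotations` map (a named list of term-id
#'   vectors also works).
#' @export
write_annotations <- function(annotations, path) {
  genes <- rep(names(annotations), lengths(annotations))
  terms <- unlist(annotations, use.names = FALSE)
  writeLines(paste(genes, terms, sep = "\t"), path)
  invisible(path)
}

# Annotation invariant: non-empty term sets, all terms known to the ontology.
validate_annotations <- function(annotations, ontology) {
  if (any(lengths(annotations) == 0)) {
    stop("annotation map contains a gene with an empty term set")
  }
  orphan <- setdiff(unique(unlist(annotations)), ontology$terms)
  if (length(orphan) > 0) {
    stop("annotation terms absent from the ontology: ",
         paste(orphan, collapse = ", "))
  }
  invisible(annotations)
}

#' Build an ontology graph from child-parent edges
#'
#' @param edges two-column data.frame or matrix of (child, parent) pairs,
#'   is_a semantics.
#' @return An object of class `trlfm_ontology`: list with `terms`,
#'   `edges` (child/parent data.frame), `root` and an internal `igraph`
#'   representation with edges directed child to parent.
#' @export
ontology_graph <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges) <- c("child", "parent")
  terms <- unique(c(edges$child, edges$parent))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = terms)
  if (!igraph::is_dag(g)) {
    stop("ontology contains a cycle")
  }
  roots <- setdiff(terms, edges$child)
  if (length(roots) != 1L) {
    stop("ontology must have exactly one root, found ",
         length(roots), ": ", paste(roots, collapse = ", "))
  }
  # every term must reach the root along is_a edges
  reach <- names(igraph::subcomponent(g, roots, mode = "in"))
  stray <- setdiff(terms, reach)
  if (length(stray) > 0) {
    stop("terms cannot reach the root: ", paste(stray, collapse = ", "))
  }
  structure(list(terms = terms, edges = edges, root = roots, graph = g),
            class = "trlfm_ontology")
}

#' Read an ontology from an edge-list TSV or a minimal OBO subset
#'
#' Edge-list files contain one `child TAB parent` pair per line (is_a
#' semantics). Files whose first non-empty line starts a stanza (`[Term]`)
#' or a tag (`id:`) are parsed as an OBO subset restricted to `id:` and
#' `is_a:` lines; other OBO tags are ignored.
#'
#' @param path input path.
#' @return A `trlfm_ontology`, see [ontology_graph()].
#' @export
read_ontology <- function(path) {
  lines <- readLines(path)
  nonempty <- lines[nzchar(trimws(lines))]
  if (length(nonempty) == 0) stop("empty ontology file: ", path)
  if (grepl("^\\[Term\\]|^id:|^format-version:", nonempty[1L])) {
    return(ontology_graph(parse_obo_edges(lines)))
  }
  parts <- strsplit(nonempty, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) {
    stop("malformed ontology edge at line ", bad[1L])
  }
  ontology_graph(data.frame(
    child = vapply(parts, `[[`, character(1), 1L),
    parent = vapply(parts, `[[`, character(1), 2L),
    stringsAsFactors = FALSE))
}

parse_obo_edges <- function(lines) {
  child <- character(0); parent <- character(0)
  current <- NA_character_
  for (ln in lines) {
    ln <- trimws(ln)
    if (startsWith(ln, "id:")) {
      current <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      if (is.na(current)) stop("is_a line before any id: line")
      child <- c(child, current)
      parent <- c(parent, tgt)
    }
  }
  data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
}

#' @rdname read_ontology
#' @param ontology a `trlfm_ontology`.
#' @export
write_ontology <- function(ontology, path) {
  writeLines(paste(ontology$edges$child, ontology$edges$parent, sep = "\t"),
             path)
  invisible(path)
}

#' Good-rule criteria
#'
#' Admission thresholds a candidate rule must satisfy: minimum certainty
#' factor, minimum coverage, maximum false-positive rate, maximum antecedent
#' length, and inductive strengthening (the minimum number of previously
#' uncovered true positives a rule must add to enter the final model).
#'
#' @param min_cf minimum certainty factor in `[0, 1]`.
#' @param min_coverage minimum number of matched training instances.
#' @param max_fp_rate maximum `fp / negatives` rate in `[0, 1]`.
#' @param max_conjuncts maximum antecedent length.
#' @param inductive_strengthening minimum new true positives at model
#'   admission; `0` disables the check.
#' @param beam_width beam capacity (default 1000).
#' @param cf_function certainty-factor estimator, `"laplace"` or
#'   `"precision"`.
#' @return A list of class `trlfm_criteria`.
#' @export
rule_criteria <- function(min_cf = 0.85, min_coverage = 4L,
                          max_fp_rate = 0.1, max_conjuncts = 3L,
                          inductive_strengthening = 1L,
                          beam_width = 1000L,
                          cf_function = c("laplace", "precision")) {
  cf_function <- match.arg(cf_function)
  stopifnot(min_cf >= 0, min_cf <= 1,
            min_coverage >= 1, max_fp_rate >= 0, max_fp_rate <= 1,
            max_conjuncts >= 1, inductive_strengthening >= 0,
            beam_width >= 1)
  structure(list(min_cf = min_cf,
                 min_coverage = as.integer(min_coverage),
                 max_fp_rate = max_fp_rate,
                 max_conjuncts = as.integer(max_conjuncts),
                 inductive_strengthening = as.integer(inductive_strengthening),
                 beam_width = as.integer(beam_width),
                 cf_function = cf_function),
            class = "trlfm_criteria")
}

#' Read good-rule criteria from a JSON or YAML config file
#'
#' Fields mirror [rule_criteria()]; missing fields take their defaults.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A `trlfm_criteria` list.
#' @export
read_criteria <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(rule_criteria))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown criteria fields: ", paste(unknown, collapse = ", "))
  }
  do.call(rule_criteria, cfg)
}

#' Serialize a rule model to JSON
#'
#' Writes the rule list (conjuncts as variable/interval pairs with interval
#' bounds when a discretization scheme is attached, consequent, TP, FP,
#' coverage, CF, p), the criteria used, and provenance metadata. Infinite
#' interval bounds are written as the distinguished tokens `"-Inf"` /
#' `"+Inf"`. [read_rule_model()] reproduces the model exactly.
#'
#' @param model a `trlfm_rule_model` from [learn_rules()].
#' @param path output path.
#' @export
serialize_rule_model <- function(model, path) {
  scheme <- model$metadata$scheme
  rules <- lapply(model$rules, function(r) {
    conj <- lapply(seq_along(r$vars), function(i) {
      v <- r$vars[i]; iv <- r$intervals[i]
      out <- list(variable = v, interval = iv)
      if (!is.null(scheme) && v %in% names(scheme$cuts)) {
        b <- interval_bounds(scheme$cuts[[v]], iv)
        out$lower <- encode_bound(b[1L]); out$upper <- encode_bound(b[2L])
      }
      out
    })
    list(conjuncts = conj, consequent = r$class, tp = r$tp, fp = r$fp,
         coverage = r$coverage, cf = r$cf, p = r$p)
  })
  doc <- list(rules = rules,
              criteria = unclass(model$criteria),
              metadata = serializable_metadata(model$metadata))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

encode_bound <- function(x) {
  if (is.infinite(x)) (if (x > 0) "+Inf" else "-Inf") else x
}
decode_bound <- function(x) {
  if (is.character(x)) (if (x == "+Inf") Inf else -Inf) else as.numeric(x)
}

serializable_metadata <- function(meta) {
  meta$scheme <- NULL
  if (!is.null(meta$provenance)) {
    meta$provenance <- as.list(as.data.frame(meta$provenance))
  }
  meta
}

#' @rdname serialize_rule_model
#' @return `read_rule_model()` returns the reconstructed `trlfm_rule_model`.
#' @export
read_rule_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(doc$rules, function(r) {
    vars <- vapply(r$conjuncts, function(cj) cj$variable, character(1))
    ivs <- vapply(r$conjuncts, function(cj) as.integer(cj$interval),
                  integer(1))
    new_rule(vars, ivs, r$consequent,
             tp = as.integer(r$tp), fp = as.integer(r$fp),
             cf = as.numeric(r$cf), p = as.numeric(r$p))
  })
  crit <- do.call(rule_criteria, doc$criteria)
  meta <- doc$metadata
  if (!is.null(meta$provenance)) {
    meta$provenance <- as.data.frame(
      lapply(meta$provenance, unlist),
      stringsAsFactors = FALSE)
  }
  meta <- lapply(meta, function(x) {
    if (is.list(x) && !is.data.frame(x) && all(lengths(x) == 1L)) {
      unlist(x)
    } else {
      x
    }
  })
  new_rule_model(rules, crit, meta)
}
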