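#' Specification for synthetic fixtures
#'
#' Parameters of the seeded generators that emulate the study regime: small
#' case/control cohorts, many variables with few informative ones, module
#' structure among informative genes encoded in a toy ontology, and partial
#' symbol overlap between source and target so that transfer requires
#' functional mapping.
#'
#' @param n_samples samples per generated dataset.
#' @param n_genes total variables per dataset (informative + noise).
#' @param n_modules number of planted functional modules (>= 2).
#' @param genes_per_module genes per planted module.
#' @param effect_size class-conditional mean shift of informative genes, in
#'   SD units.
#' @param case_fraction fraction of Case samples.
#' @param symbol_overlap_fraction fraction of informative genes sharing the
#'   same symbol between source and target; at 0 transfer is only possible
#'   through module mapping.
#' @param noise_annotation_rate probability that a gene receives one extra
#'   annotation in a foreign branch.
#' @param seed RNG seed; every generator is fully deterministic under it.
#' @return A validated list of class `trlfm_synth_spec`.
#' @export
synth_spec <- function(n_samples = 100L, n_genes = 30L, n_modules = 2L,
                       genes_per_module = 3L, effect_size = 2,
                       case_fraction = 0.5, symbol_overlap_fraction = 0,
                       noise_annotation_rate = 0, seed = 1L) {
  stopifnot(n_samples >= 4, n_modules >= 2, genes_per_module >= 2,
            effect_size >= 0,
            case_fraction > 0, case_fraction < 1,
            symbol_overlap_fraction >= 0, symbol_overlap_fraction <= 1,
            noise_annotation_rate >= 0, noise_annotation_rate <= 1,
            n_genes >= n_modules)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_modules = as.integer(n_modules),
                 genes_per_module = as.integer(genes_per_module),
                 effect_size = effect_size,
                 case_fraction = case_fraction,
                 symbol_overlap_fraction = symbol_overlap_fraction,
                 noise_annotation_rate = noise_annotation_rate,
                 seed = as.integer(seed)),
            class = "trlfm_synth_spec")
}

module_gene <- function(m, i) sprintf("M%dG%d", m, i)

#' Generate a toy ontology with module-structured annotations
#'
#' Builds a single-root DAG with one well-separated branch per planted
#' module: branch m has a branch-root term under the global root and one
#' leaf term per module gene. Gene i of module m is annotated to its own
#' leaf and its successor leaf (cyclically), so terms within a branch share
#' the high-IC branch root while terms across branches share only the
#' zero-IC global root. With zero annotation noise every gene maps to
#' exactly one branch; otherwise each gene gains one foreign-branch leaf
#' with the stated probability.
#'
#' @param spec a [synth_spec()].
#' @return List with `ontology` (a `trlfm_ontology`), `annotations`
#'   (a `trlfm_annotations`) and `planted` (list of per-module gene sets).
#' @export
make_ontology_and_annotations <- function(spec) {
  q <- spec$genes_per_module
  edges <- list()
  ann <- list()
  planted <- list()
  for (m in seq_len(spec$n_modules)) {
    branch <- sprintf("GO:B%d", m)
    edges[[length(edges) + 1L]] <- c(branch, "GO:ROOT")
    genes <- vapply(seq_len(q), function(i) module_gene(m, i), character(1))
    planted[[m]] <- genes
    for (i in seq_len(q)) {
      leaf <- sprintf("GO:B%dL%d", m, i)
      edges[[length(edges) + 1L]] <- c(leaf, branch)
    }
    for (i in seq_len(q)) {
      own <- sprintf("GO:B%dL%d", m, i)
      succ <- sprintf("GO:B%dL%d", m, (i %% q) + 1L)
      ann[[genes[i]]] <- sort(unique(c(own, succ)))
    }
  }
  onto <- ontology_graph(do.call(rbind, edges))
  if (spec$noise_annotation_rate > 0) {
    ann <- with_seed(derive_seed(spec$seed, 11L), {
      for (m in seq_len(spec$n_modules)) {
        for (g in planted[[m]]) {
          if (stats::runif(1) < spec$noise_annotation_rate) {
            fm <- sample(setdiff(seq_len(spec$n_modules), m), 1L)
            leaf <- sprintf("GO:B%dL%d", fm, sample.int(q, 1L))
            ann[[g]] <- sort(unique(c(ann[[g]], leaf)))
          }
        }
      }
      ann
    })
  }
  list(ontology = onto,
       annotations = structure(ann, class = "trlfm_annotations"),
       planted = planted)
}

# Class-conditional Gaussian expression matrix for one dataset.
synth_dataset <- function(informative, n_noise, noise_prefix, spec, seed) {
  with_seed(seed, {
    n <- spec$n_samples
    n_case <- max(1L, min(n - 1L, round(spec$case_fraction * n)))
    labels <- c(rep("Case", n_case), rep("Control", n - n_case))
    noise_genes <- if (n_noise > 0) paste0(noise_prefix, seq_len(n_noise))
                   else character(0)
    genes <- c(informative, noise_genes)
    vals <- matrix(stats::rnorm(n * length(genes)), nrow = n,
                   dimnames = list(NULL, genes))
    vals[labels == "Case", informative] <-
      vals[labels == "Case", informative] + spec$effect_size
    trlfm_dataset(vals, class_labels = labels,
                  class_domain = c("Case", "Control"))
  })
}

#' Generate a source/target expression pair with transferable signal
#'
#' Each dataset carries one informative gene per planted module (Gaussian
#' class-conditional mean shift of `effect_size` SD) plus standard-normal
#' noise genes. A fraction `symbol_overlap_fraction` of the informative
#' genes share their symbol between source and target; the rest use
#' different symbols drawn from the same planted module, so that transfer
#' to them is only achievable via functional mapping. Noise-gene symbols
#' never overlap between the two datasets.
#'
#' @param spec a [synth_spec()].
#' @return List with `source` and `target` datasets plus
#'   `source_informative` / `target_informative` symbol vectors.
#' @export
make_expression_pair <- function(spec) {
  n_same <- round(spec$symbol_overlap_fraction * spec$n_modules)
  src_inf <- vapply(seq_len(spec$n_modules),
                    function(m) module_gene(m, 1L), character(1))
  tgt_inf <- vapply(seq_len(spec$n_modules), function(m) {
    if (m <= n_same) module_gene(m, 1L) else module_gene(m, 2L)
  }, character(1))
  n_noise <- spec$n_genes - spec$n_modules
  list(source = synth_dataset(src_inf, n_noise, "SNOISE",
                              spec, derive_seed(spec$seed, 1L)),
       target = synth_dataset(tgt_inf, n_noise, "TNOISE",
                              spec, derive_seed(spec$seed, 2L)),
       source_informative = src_inf,
       target_informative = tgt_inf)
}

#' The worked-example dataset
#'
#' A deterministic two-marker discrete dataset reconstructed from the
#' printed rule `IF (gene1 > 1680) AND (gene2 <= 28.6) THEN (Class = Case)`
#' and its statistics: 60 instances match the antecedent (56 Case, 4
#' Control), plus 30 Case and 30 Control non-matching filler instances so
#' the Fisher table is well defined. Both markers have two intervals;
#' the matching cell is `gene1` interval 2 with `gene2` interval 1. The
#' corresponding cut points (1680 and 28.6) are attached as the `scheme`
#' attribute.
#'
#' @return A discrete [trlfm_dataset()] with a `scheme` attribute.
#' @export
worked_example_dataset <- function() {
  block <- function(n, g1, g2, cl) {
    data.frame(gene1 = rep(g1, n), gene2 = rep(g2, n),
               class = rep(cl, n), stringsAsFactors = FALSE)
  }
  df <- rbind(block(56, 2L, 1L, "Case"),
              block(4, 2L, 1L, "Control"),
              block(30, 1L, 2L, "Case"),
              block(30, 1L, 2L, "Control"))
  ds <- trlfm_dataset(as.matrix(df[, c("gene1", "gene2")]),
                      class_labels = df$class,
                      class_domain = c("Case", "Control"),
                      discrete = TRUE,
                      intervals = c(gene1 = 2L, gene2 = 2L))
  attr(ds, "scheme") <- structure(
    list(cuts = list(gene1 = 1680, gene2 = 28.6),
         scores = c(gene1 = NA_real_, gene2 = NA_real_),
         alpha = 1, lambda = log(2)),
    class = "trlfm_scheme")
  ds
}

#' Write a full synthetic study to disk
#'
#' Emits the expression TSVs, annotation TSV and ontology edge list that
#' the other entry points consume.
#'
#' @param spec a [synth_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
write_synth_study <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  oa <- make_ontology_and_annotations(spec)
  pair <- make_expression_pair(spec)
  paths <- list(
    source = file.path(dir, "source.tsv"),
    target = file.path(dir, "target.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    ontology = file.path(dir, "ontology.tsv"))
  write_expression_table(pair$source, paths$source)
  write_expression_table(pair$target, paths$target)
  write_annotations(oa$annotations, paths$annotations)
  write_ontology(oa$ontology, paths$ontology)
  invisible(paths)
}
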