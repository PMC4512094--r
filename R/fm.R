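#' Union of annotation terms over a gene list
#'
#' Forms the set union of the annotating terms of every mapped gene; genes
#' absent from the map are reported through the `unmapped` attribute (and a
#' warning), never fatally.
#'
#' @param annotations a `trlfm_annotations` map, see [read_annotations()].
#' @param genes character vector of gene symbols.
#' @return Sorted character vector of term ids with attribute `unmapped`.
#' @export
term_union <- function(annotations, genes) {
  genes <- unique(genes)
  mapped <- intersect(genes, names(annotations))
  unmapped <- setdiff(genes, mapped)
  if (length(unmapped) > 0) {
    warning(length(unmapped), " gene(s) not in the annotation map: ",
            paste(utils::head(unmapped, 5L), collapse = ", "),
            if (length(unmapped) > 5L) ", ...")
  }
  terms <- sort(unique(unlist(annotations[mapped], use.names = FALSE)))
  structure(terms %||% character(0), unmapped = unmapped)
}

# term -> set of ancestor terms including the term itself, along is_a edges.
term_ancestors <- function(ontology, term) {
  if (!term %in% ontology$terms) stop("term absent from ontology: ", term)
  names(igraph::subcomponent(ontology$graph, term, mode = "out"))
}

# Gene counts per term after propagating each gene's annotations to all
# ancestors. The IC corpus is the annotation map itself.
annotation_corpus_counts <- function(annotations, ontology) {
  counts <- stats::setNames(integer(length(ontology$terms)), ontology$terms)
  anc_cache <- new.env(parent = emptyenv())
  for (g in names(annotations)) {
    terms <- annotations[[g]]
    anc <- unique(unlist(lapply(terms, function(t) {
      if (is.null(anc_cache[[t]])) anc_cache[[t]] <- term_ancestors(ontology, t)
      anc_cache[[t]]
    })))
    counts[anc] <- counts[anc] + 1L
  }
  counts
}

#' Information content of ontology terms
#'
#' IC(t) = -log p(t), where p(t) is the fraction of corpus genes annotated
#' to `t` or any of its descendants (ancestor propagation), relative to the
#' genes reaching the root. The root always has IC 0. The corpus is the
#' supplied annotation map itself, so IC values shift with the map.
#'
#' @param annotations a `trlfm_annotations` map.
#' @param ontology a `trlfm_ontology`.
#' @return Named numeric vector of IC values over all ontology terms
#'   (`Inf` for terms annotating no corpus gene).
#' @export
information_content <- function(annotations, ontology) {
  counts <- annotation_corpus_counts(annotations, ontology)
  total <- counts[[ontology$root]]
  if (total == 0) stop("no annotated genes reach the ontology root")
  -log(counts / total)
}

#' Pairwise semantic similarity of ontology terms
#'
#' Lin similarity `2 IC(MICA) / (IC(t1) + IC(t2))`, where MICA is the
#' maximum-IC common ancestor; defined as 1 for identical terms and 0 when
#' both ICs are 0 (e.g. the root with itself). The Resnik alternative
#' normalizes `IC(MICA)` by the maximum finite IC in the corpus so values
#' stay in `[0, 1]`.
#'
#' @param t1,t2 term ids.
#' @param ic named IC vector from [information_content()].
#' @param ontology a `trlfm_ontology`.
#' @param method `"lin"` (default) or `"resnik"`.
#' @return Similarity in `[0, 1]`.
#' @export
semantic_similarity <- function(t1, t2, ic, ontology,
                                method = c("lin", "resnik")) {
  method <- match.arg(method)
  if (t1 == t2) return(1)
  common <- intersect(term_ancestors(ontology, t1),
                      term_ancestors(ontology, t2))
  mica_ic <- max(ic[common][is.finite(ic[common])], 0)
  if (method == "lin") {
    denom <- ic[[t1]] + ic[[t2]]
    if (denom == 0) return(0)
    2 * mica_ic / denom
  } else {
    max_ic <- max(ic[is.finite(ic)])
    if (max_ic == 0) return(0)
    min(mica_ic / max_ic, 1)
  }
}

#' Term-term similarity matrix
#'
#' @param terms character vector of term ids.
#' @inheritParams semantic_similarity
#' @return Symmetric matrix in `[0, 1]` with unit diagonal, of class
#'   `matrix`, rows/columns named by term.
#' @export
term_similarity_matrix <- function(terms, annotations, ontology,
                                   method = c("lin", "resnik")) {
  method <- match.arg(method)
  ic <- information_content(annotations, ontology)
  anc <- lapply(stats::setNames(terms, terms),
                function(t) term_ancestors(ontology, t))
  n <- length(terms)
  S <- diag(1, n)
  dimnames(S) <- list(terms, terms)
  max_ic <- max(ic[is.finite(ic)])
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      common <- intersect(anc[[i]], anc[[j]])
      mica_ic <- max(ic[common][is.finite(ic[common])], 0)
      S[i, j] <- S[j, i] <- if (method == "lin") {
        denom <- ic[[terms[i]]] + ic[[terms[j]]]
        if (denom == 0) 0 else 2 * mica_ic / denom
      } else {
        if (max_ic == 0) 0 else min(mica_ic / max_ic, 1)
      }
    }
  }
  S
}

#' Spectral clustering of a similarity matrix
#'
#' Ng-Jordan-Weiss procedure: the affinity is the similarity matrix with a
#' zeroed diagonal; form the symmetric-normalized Laplacian, take the top-k
#' eigenvectors, row-normalize the embedding, and run seeded k-means on the
#' embedded rows (10 restarts, best inertia kept). If k-means returns an
#' empty cluster it is retried up to a fixed restart budget.
#'
#' @param S symmetric similarity matrix in `[0, 1]`.
#' @param k number of clusters, `2 <= k <= nrow(S)`.
#' @param seed RNG seed for k-means.
#' @return Named integer vector mapping each term to a cluster in `1..k`.
#' @export
spectral_cluster <- function(S, k, seed = NULL) {
  if (!isSymmetric(unname(S), tol = 1e-8)) stop("similarity matrix must be symmetric")
  n <- nrow(S)
  if (k < 2 || k > n) stop("k out of range [2, ", n, "]")
  if (k == n) {
    return(stats::setNames(seq_len(n), rownames(S)))
  }
  W <- S
  diag(W) <- 0
  d <- pmax(rowSums(W), .Machine$double.eps)
  Dhalf <- 1 / sqrt(d)
  L <- W * (Dhalf %o% Dhalf)
  eig <- eigen(L, symmetric = TRUE)
  X <- eig$vectors[, seq_len(k), drop = FALSE]
  rn <- pmax(sqrt(rowSums(X^2)), .Machine$double.eps)
  Y <- X / rn
  with_seed(seed, {
    for (attempt in 1:20) {
      km <- suppressWarnings(
        stats::kmeans(Y, centers = k, nstart = 10, iter.max = 100))
      if (all(tabulate(km$cluster, nbins = k) > 0)) break
    }
    stats::setNames(km$cluster, rownames(S))
  })
}

#' Silhouette widths on a similarity matrix
#'
#' Uses distance `d = 1 - similarity`. For term i with mean within-cluster
#' distance `a` and smallest mean distance to a foreign cluster `b`,
#' `s(i) = (b - a) / max(a, b)`; terms in singleton clusters score 0, as do
#' degenerate terms with `a = b = 0`.
#'
#' @param S similarity matrix.
#' @param assignment named cluster vector from [spectral_cluster()].
#' @return List with `widths` (per term), `cluster_avg` (named by cluster)
#'   and `overall` (mean width; `NA` with a message when only one cluster
#'   exists, where the value is undefined).
#' @export
silhouette_widths <- function(S, assignment) {
  D <- 1 - S
  terms <- rownames(S)
  cl <- assignment[terms]
  ks <- sort(unique(cl))
  if (length(ks) < 2L) {
    return(list(widths = stats::setNames(rep(NA_real_, length(terms)), terms),
                cluster_avg = stats::setNames(NA_real_, ks),
                overall = NA_real_))
  }
  widths <- vapply(seq_along(terms), function(i) {
    own <- which(cl == cl[i])
    if (length(own) == 1L) return(0)  # singleton convention
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(ks, cl[i]), function(kk) {
      mean(D[i, which(cl == kk)])
    }, numeric(1)))
    if (max(a, b) == 0) return(0)     # all-identical convention
    (b - a) / max(a, b)
  }, numeric(1))
  names(widths) <- terms
  cluster_avg <- vapply(ks, function(kk) mean(widths[cl == kk]), numeric(1))
  names(cluster_avg) <- ks
  list(widths = widths, cluster_avg = cluster_avg, overall = mean(widths))
}

#' Choose the number of clusters by average silhouette
#'
#' Runs [spectral_cluster()] for each candidate k and keeps the k with the
#' highest overall average silhouette width; ties go to the smallest k.
#'
#' @param S similarity matrix.
#' @param k_range integer vector of candidate cluster counts.
#' @param seed RNG seed (the same seed is used for every candidate k).
#' @return List with `k`, `assignment`, `silhouette` (the
#'   [silhouette_widths()] result for the winner) and `profile` (named
#'   vector of overall widths per candidate k).
#' @export
select_k <- function(S, k_range = NULL, seed = NULL) {
  n <- nrow(S)
  k_range <- k_range %||% seq(2L, min(15L, n - 1L))
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) stop("empty k range")
  if (any(k_range < 2L | k_range > n)) stop("k range outside [2, ", n, "]")
  profile <- stats::setNames(rep(NA_real_, length(k_range)),
                             as.character(k_range))
  best <- NULL
  for (k in k_range) {
    asg <- spectral_cluster(S, k, seed = seed)
    sil <- silhouette_widths(S, asg)
    profile[as.character(k)] <- sil$overall
    if (is.null(best) || (is.finite(sil$overall) &&
                          sil$overall > best$silhouette$overall + 1e-12)) {
      best <- list(k = k, assignment = asg, silhouette = sil)
    }
  }
  c(best, list(profile = profile))
}

#' Build functional modules from a term clustering
#'
#' Term clusters whose average silhouette passes the retention threshold
#' become modules; gene `g` joins the module of cluster `C` iff at least one
#' of its annotating terms lies in `C`, so genes may belong to several
#' modules. Gene-empty modules are dropped. Modules are numbered `FM1...`
#' in descending gene-count order (ties by ascending cluster id).
#'
#' @param annotations a `trlfm_annotations` map.
#' @param genes gene symbols considered for membership.
#' @param assignment term-to-cluster vector.
#' @param cluster_sil named per-cluster average silhouettes.
#' @param threshold retention threshold on a cluster's average silhouette
#'   (default 0.5).
#' @return List of modules, each a list with `id`, `terms`, `genes`,
#'   `avg_silhouette`.
#' @export
build_modules <- function(annotations, genes, assignment, cluster_sil,
                          threshold = 0.5) {
  keep <- names(cluster_sil)[!is.na(cluster_sil) & cluster_sil >= threshold]
  mods <- lapply(keep, function(kk) {
    terms <- names(assignment)[assignment == as.integer(kk)]
    members <- sort(Filter(function(g) {
      g %in% names(annotations) && length(intersect(annotations[[g]], terms)) > 0
    }, unique(genes)))
    list(cluster = as.integer(kk), terms = sort(terms), genes = members,
         avg_silhouette = unname(cluster_sil[[kk]]))
  })
  mods <- Filter(function(m) length(m$genes) > 0, mods)
  if (length(mods) == 0) return(list())
  ord <- order(-vapply(mods, function(m) length(m$genes), integer(1)),
               vapply(mods, `[[`, integer(1), "cluster"))
  mods <- mods[ord]
  for (i in seq_along(mods)) mods[[i]]$id <- paste0("FM", i)
  mods
}

#' Discover functional modules among a gene list
#'
#' End-to-end protocol: map genes to their annotating terms, form the term
#' union, build the semantic-similarity matrix, spectral-cluster the terms
#' with silhouette-based selection of the cluster count, retain clusters
#' whose average silhouette passes the threshold, and back-map genes into
#' the retained clusters.
#'
#' @inheritParams build_modules
#' @param ontology a `trlfm_ontology`.
#' @param k_range candidate cluster counts (default `2..min(15, T-1)` for
#'   `T` terms).
#' @param method similarity measure, `"lin"` or `"resnik"`.
#' @param seed RNG seed for the clustering.
#' @return List with `modules` (see [build_modules()]), `assignment`,
#'   `silhouette`, `k`, `terms`, `unmapped`.
#' @export
discover_modules <- function(genes, annotations, ontology, k_range = NULL,
                             threshold = 0.5, method = c("lin", "resnik"),
                             seed = NULL) {
  method <- match.arg(method)
  terms <- term_union(annotations, genes)
  unmapped <- attr(terms, "unmapped")
  if (length(terms) < 3L) {
    if (length(terms) > 0) {
      warning("fewer than 3 annotation terms; no modules discovered")
    }
    return(list(modules = list(), assignment = NULL, silhouette = NULL,
                k = NA_integer_, terms = as.character(terms),
                unmapped = unmapped))
  }
  S <- term_similarity_matrix(as.character(terms), annotations, ontology,
                              method = method)
  sel <- select_k(S, k_range = k_range, seed = seed)
  modules <- build_modules(annotations, genes, sel$assignment,
                           sel$silhouette$cluster_avg, threshold = threshold)
  list(modules = modules, assignment = sel$assignment,
       silhouette = sel$silhouette, k = sel$k,
       terms = as.character(terms), unmapped = unmapped)
}

#' Write discovered modules to TSV
#'
#' Columns: module id, average silhouette, comma-joined genes, comma-joined
#' terms.
#'
#' @param modules module list from [discover_modules()].
#' @param path output path.
#' @export
write_modules <- function(modules, path) {
  lines <- vapply(modules, function(m) {
    paste(m$id, format(m$avg_silhouette, digits = 6),
          paste(m$genes, collapse = ","),
          paste(m$terms, collapse = ","), sep = "\t")
  }, character(1))
  writeLines(c("module_id\tavg_silhouette\tgenes\tterms", lines), path)
  invisible(path)
}
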