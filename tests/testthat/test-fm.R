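# Toy fixtures -------------------------------------------------------------

diamond_fixture <- function() {
  onto <- ontology_graph(data.frame(child = c("a", "a", "b", "c"),
                                    parent = c("b", "c", "d", "d")))
  ann <- structure(list(g1 = "a", g2 = "b", g3 = "c"),
                   class = "trlfm_annotations")
  list(onto = onto, ann = ann)
}

two_block_similarity <- function(block_size = 3L, within = 1, between = 0) {
  n <- 2L * block_size
  S <- matrix(between, n, n)
  S[seq_len(block_size), seq_len(block_size)] <- within
  S[(block_size + 1):n, (block_size + 1):n] <- within
  diag(S) <- 1
  dimnames(S) <- list(paste0("t", seq_len(n)), paste0("t", seq_len(n)))
  S
}

partition_sets <- function(assignment) {
  unname(lapply(split(names(assignment), assignment), sort))
}

# Term union ----------------------------------------------------------------

test_that("term union pools annotations and reports unmapped genes", {
  ann <- structure(list(g1 = c("go1", "go3"), g2 = "go3"),
                   class = "trlfm_annotations")
  u <- term_union(ann, c("g1", "g2"))
  expect_setequal(as.character(u), c("go1", "go3"))

  expect_warning(u2 <- term_union(ann, c("gX", "gY")), "not in the annotation")
  expect_length(as.character(u2), 0L)
  expect_setequal(attr(u2, "unmapped"), c("gX", "gY"))

  u3 <- suppressWarnings(term_union(ann, c("g2", "g1")))
  expect_equal(as.character(u3), as.character(u))
})

# Information content and similarity ----------------------------------------

test_that("information content follows ancestor-propagated frequencies", {
  onto <- ontology_graph(data.frame(child = c("t1", "t2"),
                                    parent = c("root", "root")))
  ann <- structure(list(gA = "t1", gB = "t2", gC = "t2", gD = "t2"),
                   class = "trlfm_annotations")
  ic <- information_content(ann, onto)
  expect_equal(unname(ic[["root"]]), 0)
  expect_equal(unname(ic[["t1"]]), -log(1 / 4))
  expect_equal(unname(ic[["t2"]]), -log(3 / 4))
})

test_that("IC never decreases from parent to child", {
  fx <- diamond_fixture()
  ic <- information_content(fx$ann, fx$onto)
  for (i in seq_len(nrow(fx$onto$edges))) {
    expect_gte(ic[[fx$onto$edges$child[i]]], ic[[fx$onto$edges$parent[i]]])
  }
})

test_that("Lin similarity matches hand computation on the diamond DAG", {
  fx <- diamond_fixture()
  ic <- information_content(fx$ann, fx$onto)
  # counts after propagation: a=1, b=2, c=2, d=3 of 3 genes
  expect_equal(unname(ic[["a"]]), log(3))
  expect_equal(semantic_similarity("a", "a", ic, fx$onto), 1)
  # b and c only share the root-like term d with IC 0
  expect_equal(semantic_similarity("b", "c", ic, fx$onto), 0)
  want <- 2 * log(3 / 2) / (log(3) + log(3 / 2))
  expect_equal(semantic_similarity("a", "b", ic, fx$onto), want)

  S <- term_similarity_matrix(c("a", "b", "c"), fx$ann, fx$onto)
  expect_true(isSymmetric(S))
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_equal(S["a", "b"], want)
})

# Spectral clustering -------------------------------------------------------

test_that("perfect blocks are recovered exactly", {
  S <- two_block_similarity()
  asg <- spectral_cluster(S, 2L, seed = 5L)
  expect_setequal(partition_sets(asg),
                  list(c("t1", "t2", "t3"), c("t4", "t5", "t6")))
})

test_that("k equal to the term count yields singletons", {
  S <- two_block_similarity(2L)
  asg <- spectral_cluster(S, 4L, seed = 1L)
  expect_equal(sort(unname(asg)), 1:4)
})

test_that("permuting term order permutes labels, not the partition", {
  S <- two_block_similarity()
  perm <- c(4L, 1L, 5L, 2L, 6L, 3L)
  asg1 <- spectral_cluster(S, 2L, seed = 9L)
  asg2 <- spectral_cluster(S[perm, perm], 2L, seed = 9L)
  expect_setequal(partition_sets(asg1), partition_sets(asg2))
})

test_that("degenerate similarity inputs are rejected", {
  S <- two_block_similarity()
  expect_error(spectral_cluster(S, 1L), "out of range")
  expect_error(spectral_cluster(S, 7L), "out of range")
  S2 <- S; S2[1, 2] <- 0.5
  expect_error(spectral_cluster(S2, 2L), "symmetric")
})

# Silhouette ----------------------------------------------------------------

test_that("silhouette matches the hand formula on a 4-point instance", {
  S <- matrix(0, 4, 4, dimnames = list(paste0("t", 1:4), paste0("t", 1:4)))
  S[1, 2] <- S[2, 1] <- 0.9
  S[3, 4] <- S[4, 3] <- 0.9
  diag(S) <- 1
  asg <- stats::setNames(c(1L, 1L, 2L, 2L), rownames(S))
  sil <- silhouette_widths(S, asg)
  expect_equal(unname(sil$widths), rep((1 - 0.1) / 1, 4))
  expect_equal(sil$overall, 0.9)
})

test_that("silhouette conventions cover degenerate cases", {
  # all terms identical: a = b = 0 -> 0 by convention
  S <- matrix(1, 4, 4, dimnames = list(paste0("t", 1:4), paste0("t", 1:4)))
  asg <- stats::setNames(c(1L, 1L, 2L, 2L), rownames(S))
  expect_equal(unname(silhouette_widths(S, asg)$widths), rep(0, 4))

  # singleton clusters score 0
  S2 <- two_block_similarity(2L)
  asg2 <- stats::setNames(c(1L, 1L, 1L, 2L), rownames(S2))
  expect_equal(unname(silhouette_widths(S2, asg2)$widths[4L]), 0)

  # a term equidistant to its own and the nearest foreign cluster scores 0
  S3 <- matrix(0.5, 3, 3, dimnames = list(paste0("t", 1:3), paste0("t", 1:3)))
  diag(S3) <- 1
  asg3 <- stats::setNames(c(1L, 1L, 2L), rownames(S3))
  expect_equal(unname(silhouette_widths(S3, asg3)$widths[1L]), 0)

  # one overall cluster: undefined, signalled as NA
  expect_true(is.na(silhouette_widths(
    S, stats::setNames(rep(1L, 4), rownames(S)))$overall))
})

# Cluster-count selection ---------------------------------------------------

test_that("silhouette selection finds the true block count", {
  S <- two_block_similarity()
  sel <- select_k(S, k_range = 2:5, seed = 13L)
  expect_equal(sel$k, 2L)
  expect_setequal(partition_sets(sel$assignment),
                  list(c("t1", "t2", "t3"), c("t4", "t5", "t6")))

  single <- select_k(S, k_range = 3L, seed = 13L)
  expect_equal(single$k, 3L)

  sel2 <- select_k(S, k_range = 2:5, seed = 13L)
  expect_identical(sel$assignment, sel2$assignment)
  expect_error(select_k(S, k_range = integer(0)), "empty k range")
})

# Module construction -------------------------------------------------------

test_that("genes back-map into retained clusters, multi-membership allowed", {
  ann <- structure(list(g1 = "t1", g2 = "t2", g3 = c("t1", "t3")),
                   class = "trlfm_annotations")
  asg <- c(t1 = 1L, t2 = 1L, t3 = 2L)
  sil <- c(`1` = 0.8, `2` = 0.6)
  mods <- build_modules(ann, c("g1", "g2", "g3"), asg, sil, threshold = 0.5)
  expect_length(mods, 2L)
  expect_equal(mods[[1L]]$id, "FM1")
  expect_setequal(mods[[1L]]$genes, c("g1", "g2", "g3"))
  expect_equal(mods[[2L]]$genes, "g3")  # g3 sits in both modules

  # soundness: every member gene is annotated by a member term
  for (m in mods) {
    for (g in m$genes) {
      expect_gt(length(intersect(ann[[g]], m$terms)), 0L)
    }
  }

  expect_length(build_modules(ann, c("g1", "g2", "g3"), asg, sil,
                              threshold = 0.9), 0L)
})

test_that("the FM pipeline recovers planted modules exactly", {
  oa <- make_ontology_and_annotations(synth_spec(seed = 31L))
  genes <- unlist(oa$planted)
  res <- discover_modules(genes, oa$annotations, oa$ontology, seed = 31L)
  expect_equal(res$k, 2L)
  expect_setequal(lapply(res$modules, `[[`, "genes"),
                  lapply(oa$planted, sort))
  for (m in res$modules) expect_gte(m$avg_silhouette, 0.5)

  # permuting the input gene order leaves the module set unchanged
  res2 <- discover_modules(rev(genes), oa$annotations, oa$ontology,
                           seed = 31L)
  expect_setequal(lapply(res2$modules, `[[`, "genes"),
                  lapply(res$modules, `[[`, "genes"))
})

test_that("module TSV export writes one row per module", {
  oa <- make_ontology_and_annotations(synth_spec(seed = 31L))
  res <- discover_modules(unlist(oa$planted), oa$annotations, oa$ontology,
                          seed = 31L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_modules(res$modules, path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), length(res$modules))
  expect_named(tab, c("module_id", "avg_silhouette", "genes", "terms"))
})
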