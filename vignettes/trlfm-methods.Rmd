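---
title: "Methods: rule learning, functional modules, and cross-study transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule learning, functional modules, and cross-study transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trlfm)
```

## The problem

Case/control gene-expression studies of the same disease are typically small
(tens of samples) and high-dimensional (thousands of genes), and different
studies measure different platforms with different gene panels. A classifier
trained on one study therefore cannot be reused directly on another: the
informative variables may not even exist in the new study under the same
symbol. `trlfm` addresses this by transferring knowledge at the level of
*function* rather than symbol: variables from source models are mapped to
target variables through functional modules — clusters of ontology terms
together with the genes they annotate — and the mapped target variables seed
a rule learner on the target data.

The package learns abstaining, human-readable models: disjunctive sets of
IF-THEN rules over discretized expression intervals, such as

```
IF (gene1 > 1680 AND gene2 <= 28.6) THEN (Class = Case)
```

with per-rule statistics TP, FP, coverage = TP + FP, a certainty factor
(CF), and a one-sided Fisher exact p-value.

## Supervised Bayesian discretization

Each continuous variable is discretized independently against the class
label. A partition of the real line into intervals
$(-\infty, c_1], (c_1, c_2], \ldots, (c_k, +\infty)$ is scored by the sum of
per-interval log Dirichlet–multinomial marginal likelihoods of the class
counts $n_{ic}$,

$$\log P(D \mid M) \;=\; \sum_i \left[ \log\frac{\Gamma(C\alpha)}{\Gamma(C\alpha + n_i)}
 + \sum_{c=1}^{C} \log\frac{\Gamma(\alpha + n_{ic})}{\Gamma(\alpha)} \right],$$

plus a structure prior $\log P(M) = -k\lambda$ that charges $\lambda$ per
cut. Candidate cut points are midpoints between consecutive distinct sorted
values, and the maximizing partition is found exactly by dynamic programming
over boundary positions, $O(B^2)$ in the number of candidate boundaries
$B$. Ties are broken toward fewer cuts, then toward the smaller leftmost
cut, so the output is deterministic.

Defaults and why:

* `alpha = 1` — a flat symmetric Dirichlet prior on interval class
  proportions; with two classes an empty interval scores 0 and a pure
  interval always outscores a mixed one of the same size.
* `lambda = log(B)` per cut, where `B` is the variable's own number of
  candidate boundaries. This is the cost of pointing at one position among
  `B` under a uniform positional prior. We also evaluated a flat
  `log(2)`-per-cut penalty: on simulated null variables (100 samples,
  standard normal, balanced classes) it leaves spurious cuts on about 95%
  of pure-noise variables, which defeats the purpose of single-interval
  filtering; the positional prior removes essentially all of them while
  retaining every variable with a 2-SD class shift. `lambda` remains a
  plain argument for users who want a different trade-off.
* Right-closed intervals, so learned rules render as `gene <= c` /
  `gene > c`.

Variables whose optimal partition is a single interval carry no class
signal and are filtered out; the survivors ("relevant variables") feed both
module discovery and rule learning. In cross-validation the scheme is
always fit on the training fold only and applied to the held-out fold;
out-of-range values fall into the open end intervals.

## Functional modules

Given a gene list, the protocol is:

1. map each gene to its annotating terms and form the term union;
2. build a pairwise term similarity matrix: Lin similarity
   $\mathrm{sim}(t_1,t_2) = 2\,\mathrm{IC}(\mathrm{MICA})/(\mathrm{IC}(t_1)+\mathrm{IC}(t_2))$
   by default, where IC is $-\log$ relative annotation frequency after
   propagating each gene's annotations to all ancestors, and MICA is the
   maximum-IC common ancestor. A max-normalized Resnik variant is
   available; both keep values in $[0,1]$ as the clustering affinity
   requires;
3. spectral-cluster the terms (Ng–Jordan–Weiss: zero-diagonal affinity,
   symmetric-normalized Laplacian, top-$k$ eigenvectors, row-normalized
   embedding, seeded k-means with 10 restarts);
4. choose $k$ over `2..min(15, T-1)` by the highest overall average
   silhouette width (distance $1-\mathrm{sim}$), ties to the smallest $k$;
5. retain clusters whose average silhouette is at least 0.5, and back-map:
   gene $g$ joins a retained cluster's module iff at least one of $g$'s
   terms lies in the cluster. Genes may belong to several modules;
   gene-empty clusters are dropped; modules are numbered in descending
   gene-count order.

The IC corpus is the supplied annotation map itself, not a genome-wide
corpus, so the tool is self-contained; IC values (and hence similarities)
shift with the map, which is the intended behavior for a study-specific
gene list. Degenerate conventions required by small inputs: a term in a
singleton cluster has silhouette 0, as does a term whose within- and
between-cluster mean distances are both 0; a single overall cluster has no
defined average silhouette and is reported as `NA`; fewer than three terms
yield no modules (and hence no transfer) rather than a forced clustering.

## Rule learning

The learner performs a general-to-specific beam search with covering *with
replacement* — no training instance is ever removed, so every rule is
scored on the full data.

* Seeds: one single-conjunct rule per (variable, interval, class); a
  binary-class problem gets two rules per discretized marker value.
* Statistics: an instance matches a rule when every conjunct's interval
  contains its value; TP counts matches of the consequent class and FP the
  rest. CF is the Laplace estimate $(TP+1)/(TP+FP+C)$ by default
  (robust at tiny coverage), with precision $TP/(TP+FP)$ as an option.
  The p-value is the one-sided hypergeometric enrichment tail of the
  consequent-vs-rest by matched-vs-unmatched table.
* Good-rule criteria: `min_cf` (default 0.85), `min_coverage` (4),
  `max_fp_rate` (0.1 of the consequent's negatives), `max_conjuncts` (3),
  `beam_width` (1000), all boundary-inclusive. Rules on the beam that
  satisfy the criteria are specialized by appending one conjunct on a
  fresh variable; children enter the beam only if they satisfy the
  criteria; the search stops when no rule yields a new accepted
  specialization.
* The beam is a bounded priority queue ordered by CF (desc), coverage
  (desc), antecedent length (asc), then the lexicographic antecedent
  string — a total order, so learning is bit-reproducible without any
  randomness.
* Inductive strengthening (default 1) is applied at model admission, not
  beam admission: walking the final beam in order, a rule enters the model
  only if it covers at least that many true positives not yet covered by
  already-admitted rules of the same consequent. This keeps the model free
  of duplicate-coverage rules while letting the beam explore freely.

Prediction abstains on instances matched by no rule. Matching rules vote
with weight CF; the predicted class is the argmax of summed weights. For
ranking (AUC) the score is the summed CF of matching positive-class rules
minus the summed CF of the rest, with abstentions at the neutral score 0,
where they tie against every opposite-class instance. The voting scheme
and the neutral abstention score are this package's design choices; an
abstaining rule set does not come with a canonical ranking.

A note on the worked example above: its printed CF of 0.98 corresponds
neither to precision (56/60 = 0.933) nor to the binary Laplace estimate
(57/62 = 0.919) of its printed TP/FP; the package does not attempt to
emulate that value and asserts only the combinatorial statistics.

## Transfer through functional mapping

Let Set1 be the union of variables in the source models' antecedents (or a
user-supplied biomarker list when no source data exist), and Set2 the
target's discretization-selected variables. Modules are discovered over
Set1 ∪ Set2. A target variable $a_{Tj}$ is *eligible* when
$a_{Tj} \in \mathrm{Set2}$, $a_{Si} \in \mathrm{Set1}$, and both lie in
the same module $FM_k$ — in single-module mode only the named module
licenses, in the default union mode any module does. For each eligible
variable, one prior rule is instantiated per (interval × class) over the
*target's own* discretized ranges — never the source's, which sidesteps
cross-platform value mapping entirely. The priors seed the beam, their
statistics are recomputed on the target, and they are pruned by the same
good-rule criteria as any other rule. Consequences that are tested as
contracts:

* empty Set1, no modules, or empty eligibility reduce the transfer
  learner to the baseline learner, bit-identically at the same seed;
* the prior count equals $\sum_{\text{eligible } v} \mathrm{intervals}(v)
  \times |\text{classes}|$;
* every licensing triple (source, target, module) is recorded as
  provenance and re-checkable against the eligibility condition.

An identical symbol present in both sets is eligible exactly when it
co-occurs with a Set1 variable (possibly itself) in a module; raw
symbol-overlap seeding without module support is available behind
`also_identical = TRUE` for comparison runs, off by default because an
unannotated shared symbol carries no functional evidence.

## Evaluation harness

Stratified k-fold cross-validation (default 10; k is reduced with a
warning when the rarest class is smaller) with per-fold discretization;
the fold AUC is the rank-based Mann–Whitney estimator with half-credit for
ties. The summary is the mean fold AUC with the SEM taken across folds.
For the transfer learner, modules are discovered once per target dataset
(from the full-data discretization) rather than per fold; eligibility is
still evaluated against each fold's own selected variables. Leave-one-out
experiment enumeration, the two-sided Wilcoxon signed-rank test on paired
AUCs (exact for ≤ 25 untied non-zero differences, normal approximation
with tie correction otherwise) and Benjamini–Hochberg adjustment support
multi-dataset comparisons. "Abstention rate" is the fraction of held-out
instances matched by no rule.

## Synthetic fixtures

The generators produce the regime the method targets, not realistic
microarray noise:

* `make_ontology_and_annotations()`: one root, one well-separated branch
  per planted module, one leaf per module gene; each gene is annotated to
  its own leaf and the cyclic successor, so each leaf annotates two genes.
  With the default two modules of three genes, within-branch Lin
  similarity is $\log 2/\log 3 \approx 0.63$ and between-branch
  similarity is 0, so the planted partition is recoverable and retained at
  the 0.5 silhouette threshold — but not by an implausible margin.
* `make_expression_pair()`: class-conditional Gaussians; informative genes
  (one per module per dataset) are shifted by `effect_size` SD in cases
  (default 2, a strong but realistic microarray effect); noise genes are
  standard normal. At `symbol_overlap_fraction = 0` the source and target
  informative genes are different members of the same planted module, so
  transfer is possible only through functional mapping.
* `worked_example_dataset()`: the deterministic two-marker dataset behind
  the worked rule; the 60 matching instances are fixed by the printed
  statistics (56 Case, 4 Control) and the non-matching filler is set to 30
  Case + 30 Control — the filler balance is a free choice since the
  printed TP/FP depend only on matching instances.

What passing on these fixtures does *not* show: robustness to batch
effects, probe-level noise, annotation incompleteness, or modules that
overlap in the ontology — real expression data and real ontologies are
messier on all four axes.

## Problem sizes and numerical choices

The test suite runs exhaustive-oracle comparisons at the scales where
enumeration is exact and fast: discretization against all $2^B$ boundary
subsets at up to 10 samples; beam search against full rule enumeration on
toys with up to 3 binary variables and 8 instances (under
coverage-monotone criteria — with non-monotone thresholds a good
specialization of a bad rule is unreachable by any general-to-specific
search, so exact equivalence is a theorem only in the monotone case);
Fisher tails against table enumeration at totals ≤ 12; signed-rank
p-values against all $2^n$ sign assignments at n ≤ 8; AUC against $O(n^2)$
pair counting. Cross-validation tests use 40–200 samples, 4–10 genes and
4–5 folds. Floating-point score ties in the discretizer and the beam are
resolved with a $10^{-12}$ tolerance before the deterministic
tie-breaks.

## Known limitations

* The discretizer is exact but quadratic in the number of distinct values;
  for very deep single-cell matrices a pre-binning step would be needed.
* IC from a small annotation map is coarse; with few genes per term the
  similarity matrix can be nearly block-constant and the silhouette
  profile flat across k.
* Transfer quality is bounded by annotation quality: a mis-annotated gene
  licenses wrong priors, and the learner's only defense is that bad priors
  die under the good-rule criteria.
* Negative-transfer detection ("when to transfer") is out of scope; the
  harness reports per-module and union results so a user can see
  degradation, but nothing prevents it.
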