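# Independent brute-force oracles used across the suite. They deliberately
# avoid the code paths they check.

# Exhaustive discretization: best score over all 2^B boundary subsets.
oracle_discretize <- function(values, labels, class_domain, alpha = 1,
                              lambda = log(2)) {
  ord <- order(values)
  v <- values[ord]
  y <- factor(as.character(labels)[ord], levels = class_domain)
  dv <- unique(v)
  B <- length(dv) - 1L
  bounds <- if (B > 0) (dv[-length(dv)] + dv[-1L]) / 2 else numeric(0)
  best <- NULL
  for (mask in 0:(2^B - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(B) - 1L)) > 0)
    cuts <- bounds[sel]
    idx <- findInterval(v, cuts, left.open = TRUE) + 1L
    sc <- -length(cuts) * lambda
    for (iv in unique(idx)) {
      sc <- sc + interval_score(tabulate(y[idx == iv],
                                         nbins = length(class_domain)),
                                alpha)
    }
    if (is.null(best) || sc > best$score + 1e-12) {
      best <- list(score = sc, cuts = cuts)
    }
  }
  best
}

# Exhaustive rule search: every conjunction up to max_conjuncts, every class,
# statistics by direct counting, filtered by the criteria thresholds.
oracle_rule_search <- function(dataset, criteria) {
  vars <- dataset$variable_names
  rules <- list()
  add_conjunctions <- function(chosen_vars) {
    grids <- lapply(chosen_vars, function(v) seq_len(dataset$intervals[[v]]))
    combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(combos))) {
      ivs <- as.integer(unlist(combos[r, ]))
      for (cl in dataset$class_domain) {
        match <- rep(TRUE, nrow(dataset$values))
        for (i in seq_along(chosen_vars)) {
          match <- match & dataset$values[, chosen_vars[i]] == ivs[i]
        }
        tp <- sum(match & dataset$class_labels == cl)
        fp <- sum(match) - tp
        cf <- certainty_factor(tp, fp, criteria$cf_function,
                               n_classes = length(dataset$class_domain))
        neg <- sum(dataset$class_labels != cl)
        fp_rate <- if (neg == 0) 0 else fp / neg
        if (cf >= criteria$min_cf && tp + fp >= criteria$min_coverage &&
            fp_rate <= criteria$max_fp_rate) {
          rules[[length(rules) + 1L]] <<- paste0(
            paste(sort(paste(chosen_vars, ivs, sep = "=")), collapse = "&"),
            "=>", cl)
        }
      }
    }
  }
  for (len in seq_len(min(criteria$max_conjuncts, length(vars)))) {
    for (set in utils::combn(vars, len, simplify = FALSE)) {
      add_conjunctions(set)
    }
  }
  sort(unlist(rules))
}

# Pair-counting AUC: concordant pairs + half credit for ties.
oracle_auc <- function(scores, labels, positive_class) {
  pos <- which(labels == positive_class)
  neg <- which(labels != positive_class)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  total / (length(pos) * length(neg))
}

# Fisher enrichment tail by enumerating all tables with the observed margins.
oracle_fisher <- function(a, b, c, d) {
  row1 <- a + b; col1 <- a + c; n <- a + b + c + d
  lo <- max(0L, col1 - (n - row1))
  hi <- min(row1, col1)
  prob <- vapply(lo:hi, function(x) {
    choose(row1, x) * choose(n - row1, col1 - x) / choose(n, col1)
  }, numeric(1))
  sum(prob[(lo:hi) >= a])
}

# Exact two-sided signed-rank p by enumerating all sign assignments.
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1L), function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0
    sum(r[signs])
  }, numeric(1))
  p_ge <- mean(ws >= w_obs)
  p_le <- mean(ws <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Small random discrete toy dataset for rule-learner checks.
random_toy_dataset <- function(n_vars = 3L, n_samples = 8L, n_intervals = 2L) {
  vals <- matrix(sample.int(n_intervals, n_vars * n_samples, replace = TRUE),
                 nrow = n_samples,
                 dimnames = list(NULL, paste0("v", seq_len(n_vars))))
  labels <- sample(c("Case", "Control"), n_samples, replace = TRUE)
  # guarantee both classes appear
  labels[1L] <- "Case"; labels[2L] <- "Control"
  trlfm_dataset(vals, class_labels = labels,
                class_domain = c("Case", "Control"), discrete = TRUE,
                intervals = stats::setNames(rep(n_intervals, n_vars),
                                            colnames(vals)))
}
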