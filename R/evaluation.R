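## Threshold-dependent metrics, rank-based ROC/AUC, stratified k-fold
## cross-validation, and the per-position enrichment statistics used to
## contrast positive and negative peptide sets.

#' Confusion counts from predictions and truth
#'
#' @param predicted Logical (or label) vector of positive calls.
#' @param truth Class labels.
#' @return Named list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  truth <- normalize_labels(truth)
  if (!is.logical(predicted)) predicted <- normalize_labels(predicted) == "positive"
  stopifnot(length(predicted) == length(truth))
  list(TP = sum(predicted & truth == "positive"),
       TN = sum(!predicted & truth == "negative"),
       FP = sum(predicted & truth == "negative"),
       FN = sum(!predicted & truth == "positive"))
}

#' Threshold-dependent classification metrics
#'
#' Computes sensitivity `Sn = TP / (TP + FN)`, specificity
#' `Sp = TN / (TN + FP)`, accuracy `Ac = (TP + TN) / total`, and the
#' Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TN+FN)(TP+FP)(TN+FP)(TP+FN))`.
#' A metric whose denominator is zero is reported as `NA` (undefined),
#' never coerced to 0.
#'
#' @param counts Confusion counts (list with `TP`, `TN`, `FP`, `FN`), or
#'   `TP` given as a single integer together with `tn`, `fp`, `fn`.
#' @param tn,fp,fn Individual counts when `counts` is scalar `TP`.
#' @return Named list with `Sn`, `Sp`, `Ac`, `MCC`.
#' @export
compute_metrics <- function(counts, tn = NULL, fp = NULL, fn = NULL) {
  if (!is.list(counts)) counts <- list(TP = counts, TN = tn, FP = fp, FN = fn)
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  total <- tp + tn + fp + fn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- prod(c(tn + fn, tp + fp, tn + fp, tp + fn))
  list(
    Sn = safe_div(tp, tp + fn),
    Sp = safe_div(tn, tn + fp),
    Ac = safe_div(tp + tn, total),
    MCC = if (mcc_den > 0) (tp * tn - fp * fn) / sqrt(mcc_den) else NA_real_
  )
}

#' ROC curve and AUC by the rank (Mann-Whitney) statistic
#'
#' AUC is the probability a random positive outscores a random negative,
#' ties counted 1/2 -- computed from mid-ranks, which is exact under ties.
#' ROC points are returned for plotting: one `(FPR, TPR)` pair per distinct
#' score cutoff (rule: positive iff score >= cutoff), including the (0,0)
#' and (1,1) endpoints.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Class labels; both classes must be present.
#' @return List with `auc` and `roc` (data.frame `cutoff`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- normalize_labels(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  pos <- labels == "positive"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                       # mid-ranks handle ties as 1/2
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  cutoffs <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(cutoffs, function(th) sum(scores[pos] >= th) / n1, numeric(1))
  fpr <- vapply(cutoffs, function(th) sum(scores[!pos] >= th) / n0, numeric(1))
  roc <- data.frame(cutoff = c(Inf, cutoffs), fpr = c(0, fpr), tpr = c(0, tpr))
  list(auc = auc, roc = roc)
}

#' Stratified fold assignment
#'
#' Randomly assigns each sample to one of `k` folds, stratified by class so
#' every fold's class ratio is within one sample of the global ratio.
#'
#' @param labels Class labels.
#' @param k Number of folds (default 10); each class must have at least `k`
#'   members.
#' @param seed Integer seed; fixed seed gives a reproducible assignment.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(labels, k = 10, seed = 1) {
  labels <- normalize_labels(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("each class needs at least k = ", k, " samples (have ",
         paste(counts, collapse = ", "), ")")
  }
  folds <- integer(length(labels))
  set.seed(seed)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' K-fold cross-validated forest scores and metrics
#'
#' Runs the full cross-validation protocol for one feature encoding: random
#' stratified folds, a forest trained on each training split, scores for
#' the held-out fold, per-fold metrics at a 0.5 score cutoff plus AUC, and
#' their across-fold averages. The out-of-fold score vector (every sample
#' scored exactly once, by a model that never saw it) is retained -- it is
#' what the weight grid search and the threshold calibration consume.
#'
#' @param x Feature matrix (samples x features).
#' @param labels Class labels.
#' @param k Number of folds (default 10).
#' @param seed Seed controlling fold assignment and forest randomness.
#' @param n_trees,mtry Forest settings (see [train_forest()]).
#' @return List with `oof_scores`, `folds`, `fold_metrics` (data.frame),
#'   `mean_metrics`, and pooled out-of-fold `auc`.
#' @export
kfold_cv <- function(x, labels, k = 10, seed = 1, n_trees = 1000, mtry = NULL) {
  labels <- normalize_labels(labels)
  folds <- make_folds(labels, k = k, seed = seed)
  oof <- numeric(length(labels))
  fm <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- train_forest(x[!test, , drop = FALSE], labels[!test],
                        n_trees = n_trees, mtry = mtry, seed = seed + f)
    sc <- predict(fit, x[test, , drop = FALSE])
    oof[test] <- sc
    cm <- compute_metrics(confusion_counts(sc >= 0.5, labels[test]))
    fm[[f]] <- data.frame(fold = f, Sn = cm$Sn, Sp = cm$Sp, Ac = cm$Ac,
                          MCC = cm$MCC,
                          AUC = roc_auc(sc, labels[test])$auc)
  }
  fold_metrics <- do.call(rbind, fm)
  list(oof_scores = oof,
       folds = folds,
       fold_metrics = fold_metrics,
       mean_metrics = colMeans(fold_metrics[, -1], na.rm = TRUE),
       auc = roc_auc(oof, labels)$auc)
}

## ---------------------------------------------------------------------------
## Positional enrichment statistics

ANALYSIS_ALPHABET <- c(AA20, "O")

window_to_matrix <- function(windows, span) {
  m <- do.call(rbind, strsplit(windows, ""))
  if (ncol(m) != span) stop("all windows must have exactly ", span, " symbols")
  bad <- setdiff(unique(as.vector(m)), ANALYSIS_ALPHABET)
  if (length(bad) > 0) stop("symbols outside the analysis alphabet: ",
                            paste(bad, collapse = ", "))
  m
}

welch_indicator_p <- function(a, b) {
  ## Welch two-sample t on 0/1 indicators; degenerate (constant) cases are
  ## resolved by hand: equal constants -> p = 1, different constants -> p = 0.
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
}

#' Per-position residue enrichment between two peptide groups (Welch test)
#'
#' For each of the first `span` N-terminal positions and each symbol of the
#' analysis alphabet (20 residues plus `O` for "no residue"), compares the
#' per-peptide presence indicator between the two groups with a Welch
#' two-sample t-test, in the style of two-sample sequence-logo servers.
#' Rows with `p < alpha` are flagged, with the direction of enrichment in
#' `group_a`.
#'
#' @param group_a,group_b Character vectors of `span`-symbol analysis
#'   windows (see [nterm_window()]).
#' @param alpha Significance threshold, default 0.05.
#' @param span Window length, default 15.
#' @return data.frame with columns `position`, `residue`, `freq_a`,
#'   `freq_b`, `direction` (`"over"`/`"under"` in group_a), `p_value`,
#'   `flagged`.
#' @export
positional_welch <- function(group_a, group_b, alpha = 0.05,
                             span = NTERM_SPAN) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  ma <- window_to_matrix(group_a, span)
  mb <- window_to_matrix(group_b, span)
  rows <- list(); n <- 0
  for (pos in seq_len(span)) {
    for (res in ANALYSIS_ALPHABET) {
      ia <- as.numeric(ma[, pos] == res)
      ib <- as.numeric(mb[, pos] == res)
      if (sum(ia) == 0 && sum(ib) == 0) next   # residue absent at position
      n <- n + 1
      p <- welch_indicator_p(ia, ib)
      rows[[n]] <- data.frame(
        position = pos, residue = res,
        freq_a = mean(ia), freq_b = mean(ib),
        direction = if (mean(ia) >= mean(ib)) "over" else "under",
        p_value = p, flagged = p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-position Kruskal-Wallis contrast with Bonferroni correction
#'
#' For each aligned position, tests whether a per-peptide positional value
#' (e.g. the average PSSM score, an AAindex channel, or a structural
#' channel) differs between two groups by the Kruskal-Wallis rank test.
#' P-values are Bonferroni-corrected over the positions
#' (`p_adj = min(1, p * n_positions)`); corrected `p < alpha` rows are
#' flagged. A position where every value ties gets `p = 1`.
#'
#' @param profile_a,profile_b Numeric matrices, one row per peptide, one
#'   column per position (same column count).
#' @param alpha Significance level on the corrected p-value, default 0.05.
#' @return data.frame with `position`, `statistic`, `p_value`,
#'   `p_bonferroni`, `flagged`.
#' @export
positional_kw <- function(profile_a, profile_b, alpha = 0.05) {
  profile_a <- as.matrix(profile_a); profile_b <- as.matrix(profile_b)
  if (ncol(profile_a) != ncol(profile_b)) {
    stop("groups must have the same number of positions")
  }
  np <- ncol(profile_a)
  grp <- factor(rep(c("a", "b"), c(nrow(profile_a), nrow(profile_b))))
  res <- lapply(seq_len(np), function(pos) {
    v <- c(profile_a[, pos], profile_b[, pos])
    keep <- !is.na(v)
    if (length(unique(v[keep])) <= 1 || length(unique(grp[keep])) < 2) {
      return(data.frame(position = pos, statistic = 0, p_value = 1))
    }
    kw <- stats::kruskal.test(v[keep], droplevels(grp[keep]))
    data.frame(position = pos, statistic = unname(kw$statistic),
               p_value = kw$p.value)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p_value * np)
  out$flagged <- out$p_bonferroni < alpha
  out
}

#' Average PSSM value per N-terminal position
#'
#' Per-peptide mean of the (raw) position-specific scores across the 20
#' residue columns at each of the first `span` positions; peptides shorter
#' than `span` contribute `NA` beyond their length. This is the positional
#' conservation summary contrasted between classes with [positional_kw()].
#'
#' @param profiles List of [pssm_profile()] objects.
#' @param span Number of N-terminal positions, default 15.
#' @return Numeric matrix, one row per profile, `span` columns.
#' @export
average_pssm_profile <- function(profiles, span = NTERM_SPAN) {
  t(vapply(profiles, function(p) {
    v <- rep(NA_real_, span)
    n <- min(p$L, span)
    v[seq_len(n)] <- rowMeans(p$matrix[seq_len(n), , drop = FALSE])
    v
  }, numeric(span)))
}

#' Per-position values of one AAindex channel
#'
#' Looks up one index row for the residue at each of the first `span`
#' positions of each peptide (`NA` beyond the peptide length). Contrasted
#' between classes with [positional_kw()].
#'
#' @param sequences Ungapped residue strings.
#' @param index_row Named numeric vector of 20 values (one row of an index
#'   table, e.g. `default_aaindex()["hydropathy", ]`).
#' @param span Number of N-terminal positions, default 15.
#' @return Numeric matrix, one row per peptide.
#' @export
positional_index_profile <- function(sequences, index_row, span = NTERM_SPAN) {
  t(vapply(sequences, function(s) {
    ch <- strsplit(s, "")[[1]]
    v <- rep(NA_real_, span)
    n <- min(length(ch), span)
    v[seq_len(n)] <- unname(index_row[match(ch[seq_len(n)], AA20)])
    v
  }, numeric(span), USE.NAMES = FALSE))
}
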