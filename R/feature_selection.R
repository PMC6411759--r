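## Information-gain feature ranking. Used for interpretation (which residue
## pairs separate the classes), not for pruning the model inputs: selection
## did not help prediction here, so trained forests see full feature vectors
## by default.

#' Shannon entropy of a class label sequence (bits)
#'
#' `H = -sum_i P(u_i) log2 P(u_i)` over the observed values; 0 for a single
#' class.
#'
#' @param labels Vector of class values (any atomic type).
#' @return Entropy in bits.
#' @export
entropy_bits <- function(labels) {
  if (length(labels) == 0) stop("empty label vector")
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

discretize_feature <- function(feature, bins) {
  if (!is.numeric(feature)) return(as.factor(feature))
  rng <- range(feature)
  if (diff(rng) == 0) return(factor(rep(1L, length(feature))))
  cut(feature, breaks = seq(rng[1], rng[2], length.out = bins + 1),
      include.lowest = TRUE)
}

#' Information gain of a feature about the class labels (bits)
#'
#' `IG = H(labels) - H(labels | feature)` with continuous features
#' discretized into `bins` equal-width bins over their observed range.
#' Always in `[0, H(labels)]`; equals `H(labels)` exactly when the
#' discretized feature determines the label, and 0 for a constant feature.
#'
#' @param feature Numeric (or categorical) feature column.
#' @param labels Class labels, same length.
#' @param bins Number of equal-width bins for continuous features
#'   (default 10).
#' @return Information gain in bits.
#' @export
information_gain <- function(feature, labels, bins = 10) {
  if (length(feature) != length(labels)) {
    stop("feature and labels must have equal length")
  }
  if (bins < 2) stop("bins must be >= 2")
  v <- discretize_feature(feature, bins)
  h <- entropy_bits(labels)
  cond <- 0
  for (lev in levels(droplevels(v))) {
    sel <- v == lev
    cond <- cond + mean(sel) * entropy_bits(labels[sel])
  }
  max(0, h - cond)
}

#' Rank features by information gain
#'
#' Scores every column of a feature matrix by [information_gain()] and
#' returns the top `top_n` with per-class mean feature values. Ties share a
#' dense rank and keep the original (stable) column order.
#'
#' @param x Feature matrix with column names (peptides x features).
#' @param labels Class labels (one per row).
#' @param top_n How many features to return (default 20); if larger than
#'   the number of columns, all are returned with a warning.
#' @param bins Discretization bins (see [information_gain()]).
#' @return data.frame of class `ig_ranking` with columns `rank`, `feature`,
#'   `motif` (spacing-motif rendering for KSAAP-style names, `NA`
#'   otherwise), `ig`, `mean_pos`, `mean_neg`.
#' @export
rank_features <- function(x, labels, top_n = 20, bins = 10) {
  if (is.null(colnames(x))) stop("feature matrix must have column names")
  labels <- normalize_labels(labels)
  ig <- apply(x, 2, information_gain, labels = labels, bins = bins)
  if (top_n > length(ig)) {
    warning("top_n (", top_n, ") exceeds feature count (", length(ig),
            "); returning all", call. = FALSE)
    top_n <- length(ig)
  }
  ord <- order(-ig)                      # stable: ties keep column order
  sel <- ord[seq_len(top_n)]
  score_sorted <- ig[ord]
  dense_rank <- cumsum(!duplicated(score_sorted))
  out <- data.frame(
    rank = dense_rank[seq_len(top_n)],
    feature = colnames(x)[sel],
    motif = ksaap_motif(colnames(x)[sel]),
    ig = unname(ig[sel]),
    mean_pos = colMeans(x[labels == "positive", sel, drop = FALSE]),
    mean_neg = colMeans(x[labels == "negative", sel, drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("ig_ranking", "data.frame")
  out
}

#' Write an information-gain ranking as TSV
#'
#' @param ranking An `ig_ranking` from [rank_features()].
#' @param path Output TSV path.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
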