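## Per-encoder random forests, convex score fusion, exhaustive lattice grid
## search for the fusion weights, and specificity-anchored threshold
## calibration. The fused score is
##
##   combined = w1*SPIDER2 + w2*PEP2D + w3*KSAAP + w4*AAindex + w5*pKSAAP
##
## with non-negative weights summing to 1. Weights are searched on a 0.05
## lattice over out-of-fold cross-validation scores only: resubstitution
## scores would bias the fused AUC upward.

#' Train a random forest scorer for one encoder
#'
#' Fits a fully grown classification forest (Gini splits, unpruned trees,
#' `mtry = sqrt(#features)` by default) and scores peptides by the fraction
#' of trees voting for the positive class, a probability-like value in
#' \[0, 1\]. The engine is `ranger`; a fixed `seed` makes training and
#' scoring reproducible.
#'
#' @param x Feature matrix (samples x features), finite values.
#' @param labels Class labels; both classes must be present with at least
#'   two members each.
#' @param n_trees Number of trees, default 1000.
#' @param mtry Features tried per split; default `floor(sqrt(ncol(x)))`.
#' @param seed Integer seed.
#' @param encoder_name Optional encoder tag stored on the model.
#' @return Object of class `aip_forest`.
#' @export
train_forest <- function(x, labels, n_trees = 1000, mtry = NULL, seed = 1,
                         encoder_name = NULL) {
  labels <- normalize_labels(labels)
  if (anyNA(labels)) stop("all training samples must be labeled")
  if (length(unique(labels)) < 2 || any(table(labels) < 2)) {
    stop("training needs at least two samples of each class")
  }
  if (!all(is.finite(x))) stop("feature matrix contains non-finite values")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fit <- ranger::ranger(
    x = x, y = labels,
    num.trees = n_trees, mtry = mtry, min.node.size = 1,
    splitrule = "gini", seed = seed, num.threads = 1
  )
  structure(list(forest = fit, n_trees = n_trees, mtry = mtry, seed = seed,
                 encoder_name = encoder_name, n_features = ncol(x),
                 feature_names = colnames(x)),
            class = "aip_forest")
}

#' Score peptides with a trained forest
#'
#' @param object An `aip_forest`.
#' @param newdata Feature matrix with the same columns the model was
#'   trained on.
#' @param ... Unused.
#' @return Numeric vector in \[0, 1\]: fraction of trees voting positive.
#' @export
predict.aip_forest <- function(object, newdata, ...) {
  if (ncol(newdata) != object$n_features) {
    stop("feature dimension mismatch: model expects ", object$n_features,
         ", got ", ncol(newdata))
  }
  colnames(newdata) <- object$feature_names
  pr <- stats::predict(object$forest, data = newdata, predict.all = TRUE,
                       num.threads = 1)
  ## per-tree predictions are level indices into forest$levels
  pos_code <- which(object$forest$forest$levels == "positive")
  rowMeans(pr$predictions == pos_code)
}

#' @export
print.aip_forest <- function(x, ...) {
  cat("aip_forest", if (!is.null(x$encoder_name)) paste0("[", x$encoder_name, "]"),
      ": ", x$n_trees, " trees, mtry ", x$mtry, ", ", x$n_features,
      " features\n", sep = "")
  invisible(x)
}

#' Construct/validate ensemble fusion weights
#'
#' @param w Numeric vector of 5 non-negative weights for
#'   (SPIDER2, PEP2D, KSAAP, AAindex, pKSAAP), summing to 1 (tolerance
#'   1e-9). Names are attached in that fixed order.
#' @return Named numeric vector of class `ensemble_weights`.
#' @export
ensemble_weights <- function(w) {
  w <- unname(as.numeric(w))
  if (length(w) != 5) stop("exactly 5 weights required")
  if (any(w < 0)) stop("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1 (got ", sum(w), ")")
  structure(stats::setNames(w, ENCODER_ORDER), class = "ensemble_weights")
}

#' Fuse per-encoder scores into the combined score
#'
#' `combined = sum_i w_i * score_i` over the five encoders in fixed order.
#' An encoder with weight 0 needs no score: its `NA` entries contribute 0.
#'
#' @param scores Numeric vector (or matrix, samples x 5) of per-encoder
#'   scores in \[0, 1\], ordered (SPIDER2, PEP2D, KSAAP, AAindex, pKSAAP);
#'   `NA` allowed only where the weight is 0.
#' @param weights An [ensemble_weights()] vector.
#' @return Combined score(s) in \[0, 1\].
#' @export
combine_scores <- function(scores, weights) {
  weights <- ensemble_weights(weights)
  m <- if (is.matrix(scores)) scores else matrix(scores, nrow = 1)
  if (ncol(m) != 5) stop("scores must have 5 columns (one per encoder)")
  active <- weights > 0
  vals <- m[, active, drop = FALSE]
  if (anyNA(vals)) stop("NA score for an encoder with non-zero weight")
  if (any(vals < 0 | vals > 1)) stop("scores must lie in [0, 1]")
  out <- as.vector(vals %*% weights[active])
  if (!is.matrix(scores)) out else unname(out)
}

#' Enumerate the weight lattice
#'
#' All non-negative weight vectors on the `step` lattice summing to 1, in
#' lexicographic order of (w1, ..., wn) with each coordinate ascending --
#' the enumeration (and hence grid-search tie-breaking) order. For 5
#' encoders at step 0.05 this is `choose(24, 4) = 10626` candidates.
#'
#' @param n_encoders Number of weights (default 5).
#' @param step Lattice step; `1/step` must be a whole number.
#' @return Matrix, one candidate per row.
#' @export
weight_lattice <- function(n_encoders = 5, step = 0.05) {
  units <- round(1 / step)
  if (abs(units - 1 / step) > 1e-9) stop("1/step must be a whole number")
  compose <- function(total, parts) {
    if (parts == 1) return(matrix(total, ncol = 1))
    do.call(rbind, lapply(0:total, function(first) {
      rest <- compose(total - first, parts - 1)
      cbind(first, rest, deparse.level = 0)
    }))
  }
  compose(units, n_encoders) * step
}

#' Grid-search the fusion weights on out-of-fold scores
#'
#' Exhaustively evaluates every lattice candidate (see [weight_lattice()])
#' and returns the weight vector maximizing the AUC of the combined
#' out-of-fold score. Encoders whose score column is `NA` (not run) are
#' constrained to weight 0. Ties keep the first candidate in enumeration
#' order, so the result is deterministic.
#'
#' @param cv_scores Matrix of out-of-fold scores, samples x 5 columns in
#'   encoder order (`NA` columns for inactive encoders). Must come from
#'   cross-validation, never resubstitution.
#' @param labels Class labels.
#' @param step Lattice step, default 0.05.
#' @return An [ensemble_weights()] vector with attributes `auc` (achieved
#'   combined AUC) and `n_candidates`.
#' @export
grid_search_weights <- function(cv_scores, labels, step = 0.05) {
  labels <- normalize_labels(labels)
  if (length(unique(labels)) < 2) stop("both classes required")
  m <- as.matrix(cv_scores)
  if (ncol(m) != 5) stop("cv_scores must have 5 columns in encoder order")
  inactive <- apply(m, 2, function(col) all(is.na(col)))
  if (all(inactive)) stop("no active encoder score columns")
  if (any(!inactive & apply(m, 2, anyNA))) {
    stop("active score columns must have no missing values")
  }
  lattice <- weight_lattice(5, step)
  keep <- rowSums(lattice[, inactive, drop = FALSE]) == 0
  lattice <- lattice[keep, , drop = FALSE]

  active_m <- m[, !inactive, drop = FALSE]
  combined <- active_m %*% t(lattice[, !inactive, drop = FALSE])
  pos <- labels == "positive"
  n1 <- sum(pos); n0 <- sum(!pos)
  aucs <- apply(combined, 2, function(s) {
    r <- rank(s)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
  best <- which.max(aucs)          # first maximum in enumeration order
  w <- ensemble_weights(lattice[best, ])
  attr(w, "auc") <- aucs[best]
  attr(w, "n_candidates") <- nrow(lattice)
  w
}

#' Calibrate decision thresholds to target specificities
#'
#' The prediction rule is positive iff `score >= cutoff`. For each target
#' specificity the cutoff is the smallest candidate value (the observed
#' scores plus one value just above the maximum) whose achieved specificity
#' on the calibration scores is at least the target; the achieved
#' specificity is recorded. Because the above-maximum candidate always
#' attains specificity 1, every target is attainable; when the cutoff
#' falls there (the rule predicts everything negative) a warning is issued.
#' Cutoffs are non-increasing in the target, so
#' `high >= moderate >= low`.
#'
#' @param scores Combined calibration scores (out-of-fold, never
#'   resubstitution).
#' @param labels Class labels; both classes must be present.
#' @param sp_targets Named target specificities, default
#'   `c(high = 0.9, moderate = 0.8, low = 0.7)`.
#' @return data.frame of class `threshold_set` with columns `level`,
#'   `target_sp`, `cutoff`, `achieved_sp`.
#' @export
calibrate_thresholds <- function(scores, labels,
                                 sp_targets = c(high = 0.9, moderate = 0.8,
                                                low = 0.7)) {
  labels <- normalize_labels(labels)
  if (length(unique(labels)) < 2) stop("both classes required")
  if (is.null(names(sp_targets))) {
    names(sp_targets) <- paste0("level", seq_along(sp_targets))
  }
  neg <- scores[labels == "negative"]
  eps_top <- max(scores) + 1e-9
  candidates <- sort(unique(c(scores, eps_top)))
  sp_at <- vapply(candidates, function(th) mean(neg < th), numeric(1))
  rows <- lapply(seq_along(sp_targets), function(i) {
    ok <- which(sp_at >= sp_targets[i])
    j <- ok[1]                       # smallest qualifying cutoff
    if (candidates[j] == eps_top) {
      warning("target specificity ", sp_targets[i],
              " only attained by predicting all peptides negative",
              call. = FALSE)
    }
    data.frame(level = names(sp_targets)[i], target_sp = sp_targets[i],
               cutoff = candidates[j], achieved_sp = sp_at[j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("threshold_set", "data.frame")
  out
}

## ---------------------------------------------------------------------------
## Full training / prediction pipeline

#' Train the fused anti-inflammatory-peptide model
#'
#' End-to-end training: encodes the labeled peptides with each active
#' encoder, runs stratified k-fold cross-validation per encoder to obtain
#' out-of-fold scores and CV metrics, grid-searches the fusion weights on
#' the out-of-fold score columns, calibrates the high/moderate/low
#' thresholds on the fused out-of-fold score, and finally refits each
#' encoder's forest on the full training set for use at prediction time.
#'
#' By default the sequence-informed encoders (KSAAP, AAindex, pKSAAP) are
#' active; the structural encoders join only when structural tables are
#' supplied.
#'
#' @param dataset Labeled [aip_dataset()].
#' @param encoders Character vector of active encoders (subset of
#'   [encoder_names()]).
#' @param pssm Named list of [pssm_profile()] objects (ids matching the
#'   dataset); peptides without one fall back to one-hot self-profiles.
#' @param structural Named list of two named lists (`SPIDER2`, `PEP2D`) of
#'   [structural_table()] objects, required when a structural encoder is
#'   active.
#' @param aaindex Physicochemical index table, default [default_aaindex()].
#' @param k_max Largest pair spacing, default 4.
#' @param n_trees Trees per forest, default 1000.
#' @param folds Cross-validation folds, default 10.
#' @param step Weight-lattice step, default 0.05.
#' @param sp_targets Specificity targets for threshold calibration.
#' @param seed Master seed for folds and forests.
#' @return Object of class `aip_model`.
#' @export
aip_train <- function(dataset, encoders = c("KSAAP", "AAindex", "pKSAAP"),
                      pssm = NULL, structural = NULL,
                      aaindex = default_aaindex(), k_max = 4,
                      n_trees = 1000, folds = 10, step = 0.05,
                      sp_targets = c(high = 0.9, moderate = 0.8, low = 0.7),
                      seed = 1) {
  stopifnot(inherits(dataset, "aip_dataset"))
  encoders <- match.arg(encoders, ENCODER_ORDER, several.ok = TRUE)
  labels <- dataset$label
  if (anyNA(labels)) stop("all training peptides must be labeled")

  feats <- lapply(stats::setNames(encoders, encoders), function(enc) {
    encode_dataset(dataset, enc,
                   pssm = pssm,
                   structural = if (!is.null(structural)) structural[[enc]],
                   aaindex = aaindex, k_max = k_max)
  })

  oof <- matrix(NA_real_, nrow = nrow(dataset), ncol = 5,
                dimnames = list(dataset$id, ENCODER_ORDER))
  cv <- list()
  for (enc in encoders) {
    cv[[enc]] <- kfold_cv(feats[[enc]], labels, k = folds,
                          seed = seed + match(enc, ENCODER_ORDER) * 1000L,
                          n_trees = n_trees)
    oof[, enc] <- cv[[enc]]$oof_scores
  }

  weights <- grid_search_weights(oof, labels, step = step)
  combined_oof <- combine_scores(oof, weights)
  thresholds <- calibrate_thresholds(combined_oof, labels,
                                     sp_targets = sp_targets)

  forests <- lapply(stats::setNames(encoders, encoders), function(enc) {
    train_forest(feats[[enc]], labels, n_trees = n_trees,
                 seed = seed + match(enc, ENCODER_ORDER),
                 encoder_name = enc)
  })

  structure(list(
    encoders = encoders,
    forests = forests,
    weights = weights,
    thresholds = thresholds,
    cv = cv,
    oof_scores = oof,
    combined_oof = combined_oof,
    combined_cv_auc = attr(weights, "auc"),
    aaindex = aaindex,
    config = list(k_max = k_max, n_trees = n_trees, folds = folds,
                  step = step, sp_targets = sp_targets, seed = seed)
  ), class = "aip_model")
}

#' @export
print.aip_model <- function(x, ...) {
  cat("aip_model: encoders ", paste(x$encoders, collapse = ", "), "\n",
      "  fusion weights: ",
      paste(sprintf("%s=%.2f", ENCODER_ORDER, x$weights), collapse = " "), "\n",
      "  combined CV AUC: ", round(x$combined_cv_auc, 4), "\n", sep = "")
  print(as.data.frame(x$thresholds))
  invisible(x)
}

#' Predict anti-inflammatory activity for new peptides
#'
#' Scores each peptide with every trained encoder forest, fuses the scores
#' with the model's weights, and reports three-level calls against the
#' calibrated cutoffs (`call_high`, `call_moderate`, `call_low`; a peptide
#' above the high cutoff is positive at all three levels). Inactive
#' encoders are reported as `NA` and contribute weight 0.
#'
#' @param object A trained `aip_model`.
#' @param dataset [aip_dataset()] of peptides to score.
#' @param pssm Optional named list of [pssm_profile()] objects.
#' @param structural Optional structural table lists (as in [aip_train()]).
#' @param ... Unused.
#' @return data.frame: `id`, one column per encoder score, `combined`, and
#'   logical `call_high`, `call_moderate`, `call_low`.
#' @export
predict.aip_model <- function(object, dataset, pssm = NULL,
                              structural = NULL, ...) {
  stopifnot(inherits(dataset, "aip_dataset"))
  scores <- matrix(NA_real_, nrow = nrow(dataset), ncol = 5,
                   dimnames = list(dataset$id, ENCODER_ORDER))
  for (enc in object$encoders) {
    x <- encode_dataset(dataset, enc, pssm = pssm,
                        structural = if (!is.null(structural)) structural[[enc]],
                        aaindex = object$aaindex,
                        k_max = object$config$k_max)
    scores[, enc] <- predict(object$forests[[enc]], x)
  }
  combined <- combine_scores(scores, object$weights)
  th <- object$thresholds
  cuts <- stats::setNames(th$cutoff, th$level)
  out <- data.frame(id = dataset$id, scores,
                    combined = combined,
                    call_high = combined >= cuts[["high"]],
                    call_moderate = combined >= cuts[["moderate"]],
                    call_low = combined >= cuts[["low"]],
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[2:6] <- ENCODER_ORDER
  out
}

#' Save / load a trained model bundle
#'
#' The bundle is a single RDS archive holding the fitted forests, fusion
#' weights, thresholds, encoder configuration and seeds.
#'
#' @param model An `aip_model`.
#' @param path Bundle path (`.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "aip_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "aip_model")) stop("not an aip_model bundle: ", path)
  model
}
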