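## Independent brute-force oracles and small fixture builders shared across
## test files. The oracles deliberately share no code with the package
## implementations they check.

AA <- aa_alphabet()

random_peptide <- function(len = sample(4:25, 1)) {
  paste(sample(AA, len, replace = TRUE), collapse = "")
}

## Brute-force k-spaced pair composition: enumerate every (i, i + k + 1)
## index pair and count matches per ordered residue pair.
brute_ksaap <- function(padded, k_max = 4) {
  ch <- strsplit(padded, "")[[1]]
  W <- length(ch)
  out <- numeric(0)
  for (k in 0:k_max) {
    block <- setNames(numeric(400),
                      as.vector(t(outer(AA, AA, paste0))))
    valid <- 0
    for (i in seq_len(W)) {
      j <- i + k + 1
      if (j > W) next
      if (ch[i] %in% AA && ch[j] %in% AA) {
        valid <- valid + 1
        block[paste0(ch[i], ch[j])] <- block[paste0(ch[i], ch[j])] + 1
      }
    }
    if (valid > 0) block <- block / valid
    out <- c(out, block)
  }
  unname(out)
}

## Brute-force profile pair composition from an already-squashed matrix.
brute_pksaap <- function(M, k_max = 4) {
  L <- nrow(M)
  out <- numeric(0)
  for (k in 0:k_max) {
    block <- numeric(400)
    n <- L - k - 1
    if (n > 0) {
      idx <- 0
      for (a in 1:20) for (b in 1:20) {
        idx <- idx + 1
        s <- 0
        for (i in seq_len(n)) s <- s + M[i, a] * M[i + k + 1, b]
        block[idx] <- s / n
      }
    }
    out <- c(out, block)
  }
  out
}

## Brute-force AUC: average over all positive-negative pairs, ties 1/2.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

## Direct evaluation of the four metric formulas.
direct_metrics <- function(tp, tn, fp, fn) {
  list(Sn = tp / (tp + fn),
       Sp = tn / (tn + fp),
       Ac = (tp + tn) / (tp + tn + fp + fn),
       MCC = (tp * tn - fp * fn) /
         sqrt((tn + fn) * (tp + fp) * (tn + fp) * (tp + fn)))
}

random_labels <- function(n, n_pos = NULL) {
  if (is.null(n_pos)) n_pos <- sample(seq_len(n - 1), 1)
  sample(rep(c("positive", "negative"), c(n_pos, n - n_pos)))
}

## Small labeled dataset for classifier tests.
tiny_dataset <- function(n_per_class = 12, effect = 4, seed = 1) {
  generate_peptides(generator_config(n_per_class, n_per_class,
                                     effect_size = effect, seed = seed))
}

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

## End-to-end pipeline run on a fresh synthetic train/test split; returns
## the held-out AUC and the fused weights. Sized for a single CPU.
run_pipeline <- function(seed, effect, n_train = 300, n_test = 150,
                         n_trees = 200, folds = 5, with_pssm = TRUE) {
  train <- generate_peptides(generator_config(n_train, n_train,
                                              effect_size = effect,
                                              seed = seed))
  test <- generate_peptides(generator_config(n_test, n_test,
                                             effect_size = effect,
                                             seed = seed + 500))
  pssm_tr <- pssm_te <- NULL
  if (with_pssm) {
    pssm_tr <- setNames(lapply(seq_len(nrow(train)), function(i) {
      simulate_pssm(train$sequence[i], seed = seed * 10000L + i,
                    id = train$id[i])
    }), train$id)
    pssm_te <- setNames(lapply(seq_len(nrow(test)), function(i) {
      simulate_pssm(test$sequence[i], seed = seed * 10000L + 5000L + i,
                    id = test$id[i])
    }), test$id)
  }
  model <- aip_train(train, pssm = pssm_tr, n_trees = n_trees,
                     folds = folds, seed = seed)
  preds <- predict(model, test, pssm = pssm_te)
  list(model = model,
       weights = as.numeric(model$weights),
       holdout_auc = roc_auc(preds$combined, test$label)$auc,
       predictions = preds,
       test = test)
}
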