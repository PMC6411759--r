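## Synthetic labeled peptide datasets with planted position-specific residue
## enrichment, plus matched synthetic PSSM profiles and structural tables.
## The generator emulates the statistical structure the predictor assumes --
## short peptides (4-25 residues, mean about 15), class-contrasted
## N-terminal residue preferences, and per-position profile scores peaked at
## the true residue -- so every pipeline stage is testable without any
## external search tools or downloads.

#' Default planted motifs for the positive class
#'
#' Position -> residue-set map of N-terminal enrichment planted in positive
#' peptides: leucine at positions 5, 7, 10, 11 and 15, cysteine at 7 and
#' 10, isoleucine at 2 and 7, arginine at 5, phenylalanine at 8, lysine at
#' 15.
#'
#' @return Named list mapping position (as character) to residue vector.
#' @export
default_positive_motifs <- function() {
  list(`2` = "I", `5` = c("L", "R"), `7` = c("L", "C", "I"), `8` = "F",
       `10` = c("L", "C"), `11` = "L", `15` = c("L", "K"))
}

#' Default planted motifs for the negative class
#'
#' Aspartate at positions 4, 5, 10, 13 and 15, threonine at 3 and 7,
#' valine at 15 -- the residues depleted from the positive class.
#'
#' @return Named list mapping position (as character) to residue vector.
#' @export
default_negative_motifs <- function() {
  list(`3` = "T", `4` = "D", `5` = "D", `7` = "T", `10` = "D", `13` = "D",
       `15` = c("D", "V"))
}

## Approximate Swiss-Prot background residue frequencies (alphabetical order).
NATURAL_FREQS <- c(A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
                   G = 0.0708, H = 0.0228, I = 0.0593, K = 0.0581, L = 0.0965,
                   M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
                   S = 0.0661, T = 0.0535, V = 0.0687, W = 0.0110, Y = 0.0292)

#' Configuration for the synthetic peptide generator
#'
#' @param n_pos,n_neg Peptides per class (both must be positive).
#' @param length_range Inclusive length bounds, default `c(4, 25)`.
#' @param mean_length Target mean length, default 15 (lengths are drawn
#'   from a normal rounded and truncated to `length_range`).
#' @param length_sd Standard deviation of the length draw, default 4.5.
#' @param effect_size Log-odds boost of the planted residue set at its
#'   position (0 makes the classes exchangeable), default 3.
#' @param pos_motifs,neg_motifs Position -> residue-set maps (defaults
#'   [default_positive_motifs()] / [default_negative_motifs()]).
#' @param background `"uniform"` (default; makes the null exactly
#'   exchangeable) or `"natural"` residue frequencies.
#' @param seed Integer seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_pos, n_neg, length_range = c(4, 25),
                             mean_length = 15, length_sd = 4.5,
                             effect_size = 3,
                             pos_motifs = default_positive_motifs(),
                             neg_motifs = default_negative_motifs(),
                             background = c("uniform", "natural"),
                             seed = 1) {
  background <- match.arg(background)
  if (n_pos < 1 || n_neg < 1) stop("n_pos and n_neg must be positive")
  if (effect_size < 0) stop("effect_size must be >= 0")
  stopifnot(length(length_range) == 2, length_range[1] >= 1,
            length_range[2] >= length_range[1])
  structure(list(n_pos = n_pos, n_neg = n_neg, length_range = length_range,
                 mean_length = mean_length, length_sd = length_sd,
                 effect_size = effect_size, pos_motifs = pos_motifs,
                 neg_motifs = neg_motifs, background = background,
                 seed = seed),
            class = "generator_config")
}

draw_lengths <- function(n, config) {
  lo <- config$length_range[1]; hi <- config$length_range[2]
  out <- integer(0)
  while (length(out) < n) {
    cand <- round(stats::rnorm(2 * n, config$mean_length, config$length_sd))
    out <- c(out, cand[cand >= lo & cand <= hi])
  }
  out[seq_len(n)]
}

sample_residue <- function(n, base_probs) {
  sample(AA20, n, replace = TRUE, prob = base_probs)
}

generate_one <- function(len, motifs, effect_size, base_probs) {
  seq_chars <- sample_residue(len, base_probs)
  ## One latent uniform per peptide makes the planted events comonotone:
  ## each position is still planted with its own boosted marginal
  ## probability, but motif positions co-occur within a peptide, emulating
  ## the motif-bearing subfamily structure of real peptide sets (and the
  ## k-spaced pair signal it produces).
  u <- stats::runif(1)
  for (pos_chr in names(motifs)) {
    pos <- as.integer(pos_chr)
    if (pos > len) next
    set <- motifs[[pos_chr]]
    base_p <- sum(base_probs[match(set, AA20)])
    p <- stats::plogis(stats::qlogis(base_p) + effect_size)
    if (u < p) {
      in_set_probs <- base_probs[match(set, AA20)]
      seq_chars[pos] <- sample(set, 1, prob = in_set_probs)
    } else {
      rest <- setdiff(AA20, set)
      seq_chars[pos] <- sample(rest, 1, prob = base_probs[match(rest, AA20)])
    }
  }
  paste(seq_chars, collapse = "")
}

#' Generate a labeled synthetic peptide dataset
#'
#' Lengths are drawn from a rounded normal truncated to the configured
#' range; background residues are drawn independently from the configured
#' composition; at each planted-motif position (when within the peptide's
#' length) the residue comes from the class's planted set with its
#' background probability boosted by `effect_size` on the log-odds scale.
#' Planting events are comonotone within a peptide (driven by one shared
#' latent uniform), so motif positions co-occur as they do in motif-bearing
#' peptide families while each position keeps exactly its boosted marginal
#' probability. At `effect_size = 0` the two classes are exchangeable.
#' Deterministic under the config seed.
#'
#' @param config A [generator_config()].
#' @return Labeled [aip_dataset()] (ids `pos_1..`, `neg_1..`).
#' @export
generate_peptides <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  base_probs <- if (config$background == "uniform") rep(1 / 20, 20)
                else unname(NATURAL_FREQS[AA20])
  len_pos <- draw_lengths(config$n_pos, config)
  len_neg <- draw_lengths(config$n_neg, config)
  seq_pos <- vapply(len_pos, generate_one, character(1),
                    motifs = config$pos_motifs,
                    effect_size = config$effect_size, base_probs = base_probs)
  seq_neg <- vapply(len_neg, generate_one, character(1),
                    motifs = config$neg_motifs,
                    effect_size = config$effect_size, base_probs = base_probs)
  aip_dataset(
    id = c(paste0("pos_", seq_len(config$n_pos)),
           paste0("neg_", seq_len(config$n_neg))),
    sequence = c(seq_pos, seq_neg),
    label = rep(c("positive", "negative"), c(config$n_pos, config$n_neg))
  )
}

#' Simulate a PSSM profile consistent with a peptide sequence
#'
#' Produces an integer-valued position-specific score matrix whose rows
#' peak at the true residue: the observed residue scores
#' `+concentration`, every other residue `-concentration`, plus
#' independent unit-variance Gaussian noise, rounded to integers (the
#' precision real profile searches print). As `concentration` grows the
#' logistic-squashed profile approaches the one-hot indicator of the
#' sequence.
#'
#' @param sequence Ungapped residue string.
#' @param concentration Peak sharpness (> 0), default 2.
#' @param seed Integer seed (deterministic output).
#' @param id Peptide identifier.
#' @return A [pssm_profile()].
#' @export
simulate_pssm <- function(sequence, concentration = 2, seed = 1,
                          id = "peptide") {
  if (concentration <= 0) stop("concentration must be > 0")
  idx <- match(strsplit(sequence, "")[[1]], AA20)
  if (anyNA(idx)) stop("invalid residue in sequence")
  set.seed(seed)
  L <- length(idx)
  m <- matrix(-concentration, nrow = L, ncol = 20)
  m[cbind(seq_len(L), idx)] <- concentration
  m <- round(m + matrix(stats::rnorm(L * 20), nrow = L))
  pssm_profile(m, id = id)
}

#' Simulate a per-residue structural feature table
#'
#' SPIDER2 flavor: ASA from a folded normal (mean 60, sd 30, floored at 0),
#' backbone angles uniform on \[-180, 180\], secondary-structure
#' propensities on the 3-simplex. PEP2D flavor: helix/sheet/coil
#' probability rows drawn on the 3-simplex (each row sums to 1).
#' Deterministic under `seed`; one row per residue.
#'
#' @param sequence Ungapped residue string.
#' @param flavor `"SPIDER2"` or `"PEP2D"`.
#' @param seed Integer seed.
#' @return A [structural_table()].
#' @export
simulate_structural <- function(sequence, flavor = c("SPIDER2", "PEP2D"),
                                seed = 1) {
  flavor <- match.arg(flavor)
  L <- nchar(sequence)
  set.seed(seed)
  simplex3 <- function(n) {
    g <- matrix(stats::rgamma(3 * n, shape = 2), nrow = n)
    g / rowSums(g)
  }
  if (flavor == "PEP2D") {
    s <- simplex3(L)
    tab <- data.frame(helix = s[, 1], sheet = s[, 2], coil = s[, 3])
  } else {
    s <- simplex3(L)
    tab <- data.frame(
      ASA = pmax(0, stats::rnorm(L, 60, 30)),
      phi = stats::runif(L, -180, 180),
      psi = stats::runif(L, -180, 180),
      theta = stats::runif(L, -180, 180),
      tau = stats::runif(L, -180, 180),
      coil = s[, 1], strand = s[, 2], helix = s[, 3]
    )
  }
  structural_table(tab, flavor)
}

#' Write a complete synthetic fixture directory
#'
#' Lays out everything the command-line pipeline consumes: `peptides.fasta`,
#' `labels.tsv`, per-peptide PSI-BLAST-style profile files under `pssm/`,
#' and (optionally) structural tables under `spider2/` and `pep2d/`.
#' Per-peptide seeds are derived from the dataset seed so the directory is
#' byte-identical across re-runs.
#'
#' @param dataset Labeled [aip_dataset()].
#' @param dir Output directory (created if needed).
#' @param pssm Write PSSM files (default `TRUE`).
#' @param structural Write structural tables (default `FALSE`).
#' @param concentration PSSM peak sharpness (see [simulate_pssm()]).
#' @param seed Base seed for the per-peptide simulations.
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(dataset, dir, pssm = TRUE, structural = FALSE,
                           concentration = 2, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset, file.path(dir, "peptides.fasta"))
  utils::write.table(
    data.frame(id = dataset$id, label = as.character(dataset$label)),
    file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (pssm) {
    dir.create(file.path(dir, "pssm"), showWarnings = FALSE)
    for (i in seq_len(nrow(dataset))) {
      prof <- simulate_pssm(dataset$sequence[i],
                            concentration = concentration,
                            seed = seed + i, id = dataset$id[i])
      write_pssm(prof, file.path(dir, "pssm", paste0(dataset$id[i], ".pssm")),
                 sequence = dataset$sequence[i])
    }
  }
  if (structural) {
    for (flavor in c("SPIDER2", "PEP2D")) {
      sub <- file.path(dir, tolower(flavor))
      dir.create(sub, showWarnings = FALSE)
      for (i in seq_len(nrow(dataset))) {
        tab <- simulate_structural(dataset$sequence[i], flavor,
                                   seed = seed + i)
        utils::write.table(as.data.frame(tab),
                           file.path(sub, paste0(dataset$id[i], ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  invisible(dir)
}

#' Read the per-peptide PSSM files of a fixture directory
#'
#' @param dir Directory holding `<id>.pssm` files.
#' @return Named list of [pssm_profile()] objects.
#' @export
read_pssm_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.pssm$", full.names = TRUE)
  profs <- lapply(files, read_pssm)
  stats::setNames(profs, vapply(profs, function(p) p$id, character(1)))
}

#' Read the structural tables of a fixture directory
#'
#' @param dir Directory holding `<id>.tsv` tables.
#' @param flavor `"SPIDER2"` or `"PEP2D"`.
#' @return Named list of [structural_table()] objects.
#' @export
read_structural_dir <- function(dir, flavor = c("SPIDER2", "PEP2D")) {
  flavor <- match.arg(flavor)
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  tabs <- lapply(files, read_structural_table, flavor = flavor)
  stats::setNames(tabs, sub("\\.tsv$", "", basename(files)))
}
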