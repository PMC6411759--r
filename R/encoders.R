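## Feature encoders: KSAAP, AAindex, pKSAAP (PSSM-based), and structural
## tables. Every encoder returns a fixed-dimension named numeric vector
## regardless of peptide length, so feature matrices can be stacked row-wise.
##
## Pair ordering is frozen: ordered pairs (a, b) over the alphabetical
## 20-letter alphabet, a-major (AA, AC, AD, ..., AY, CA, ..., YY), blocks
## concatenated in k order (k = 0 first). Position-major encoders emit all
## channels for position 1, then position 2, etc.

#' KSAAP feature names
#'
#' Names of the k-spaced amino-acid-pair composition features in their
#' frozen order: for each spacing k = 0..`k_max`, the 400 ordered residue
#' pairs in a-major alphabetical order. A feature `k1_LL` is the composition
#' of the motif `LxL` (an L, any one residue, then an L).
#'
#' @param k_max Largest spacing, default 4.
#' @return Character vector of length `400 * (k_max + 1)`.
#' @export
ksaap_feature_names <- function(k_max = 4) {
  pairs <- as.vector(t(outer(AA20, AA20, paste0)))
  unlist(lapply(0:k_max, function(k) paste0("k", k, "_", pairs)))
}

#' Render a KSAAP feature name as a spacing motif
#'
#' `k1_LL` becomes `LxL`, `k0_AC` becomes `AC` ('x' stands for any residue).
#'
#' @param feature Feature name(s) as produced by [ksaap_feature_names()].
#' @return Motif string(s).
#' @export
ksaap_motif <- function(feature) {
  m <- regmatches(feature, regexec("^k([0-9]+)_([A-Y])([A-Y])$", feature))
  vapply(m, function(g) {
    if (length(g) != 4) return(NA_character_)
    paste0(g[3], strrep("x", as.integer(g[2])), g[4])
  }, character(1))
}

#' K-spaced amino-acid-pair composition (KSAAP)
#'
#' For each spacing k in 0..`k_max` and each of the 400 ordered residue
#' pairs, counts positions i where the symbols at i and i + k + 1 are both
#' residues (not gaps) and form that pair, divided by the total number of
#' valid (gap-free) pairs at that spacing. With left-aligned gap padding the
#' valid pairs at spacing k are exactly the first `L - k - 1` index pairs,
#' so the encoding is invariant to the amount of padding and each k block
#' sums to 1 whenever any valid pair exists (all-zero block otherwise).
#'
#' @param padded Padded peptide string(s) of length 25 (see [pad_peptide()]).
#' @param k_max Largest spacing, default 4 (dimension `400 * (k_max + 1)` =
#'   2000).
#' @return Named numeric vector (single peptide) or matrix with one row per
#'   peptide.
#' @export
encode_ksaap <- function(padded, k_max = 4) {
  if (length(padded) > 1) {
    out <- t(vapply(padded, encode_ksaap, numeric(400 * (k_max + 1)),
                    k_max = k_max, USE.NAMES = FALSE))
    dimnames(out) <- list(names(padded), ksaap_feature_names(k_max))
    return(out)
  }
  W <- nchar(padded)
  if (k_max < 0) stop("k_max must be >= 0")
  if (k_max + 2 > W) stop("k_max + 2 exceeds the window length ", W)
  ch <- strsplit(padded, "")[[1]]
  idx <- match(ch, AA20)          # NA for gaps
  out <- numeric(400 * (k_max + 1))
  for (k in 0:k_max) {
    i <- seq_len(W - k - 1)
    a <- idx[i]; b <- idx[i + k + 1]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      pair <- (a[ok] - 1L) * 20L + b[ok]
      counts <- tabulate(pair, nbins = 400)
      out[k * 400 + seq_len(400)] <- counts / sum(ok)
    }
  }
  names(out) <- ksaap_feature_names(k_max)
  out
}

#' Default physicochemical index table
#'
#' Eight classical amino-acid indices used as the default AAindex encoding
#' channels: Kyte-Doolittle hydropathy, Hopp-Woods hydrophilicity, residue
#' molecular weight, Zimmerman isoelectric point, Chou-Fasman helix and
#' sheet propensities, Grantham polarity and Grantham volume. The selection
#' is configurable: supply any table with the same shape to
#' [encode_aaindex()] (see [read_aaindex_table()]).
#'
#' @param scale If `TRUE` (default) each index row is min-max scaled to
#'   \[0, 1\] so channels are commensurate.
#' @return 8 x 20 numeric matrix; rownames are index names, colnames the
#'   amino acids in alphabetical order.
#' @export
default_aaindex <- function(scale = TRUE) {
  ## values keyed in alphabetical residue order A C D E F G H I K L M N P Q R S T V W Y
  tab <- rbind(
    hydropathy     = c( 1.8,  2.5, -3.5, -3.5,  2.8, -0.4, -3.2,  4.5, -3.9,  3.8,
                        1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7,  4.2, -0.9, -1.3),
    hydrophilicity = c(-0.5, -1.0,  3.0,  3.0, -2.5,  0.0, -0.5, -1.8,  3.0, -1.8,
                       -1.3,  0.2,  0.0,  0.2,  3.0,  0.3, -0.4, -1.5, -3.4, -2.3),
    mass           = c(89.09, 121.15, 133.10, 147.13, 165.19, 75.07, 155.16, 131.17,
                       146.19, 131.17, 149.21, 132.12, 115.13, 146.15, 174.20,
                       105.09, 119.12, 117.15, 204.23, 181.19),
    isoelectric    = c(6.00, 5.05, 2.77, 3.22, 5.48, 5.97, 7.59, 6.02, 9.74, 5.98,
                       5.74, 5.41, 6.30, 5.65, 10.76, 5.68, 5.66, 5.96, 5.89, 5.66),
    helix_prop     = c(1.42, 0.70, 1.01, 1.51, 1.13, 0.57, 1.00, 1.08, 1.16, 1.21,
                       1.45, 0.67, 0.57, 1.11, 0.98, 0.77, 0.83, 1.06, 1.08, 0.69),
    sheet_prop     = c(0.83, 1.19, 0.54, 0.37, 1.38, 0.75, 0.87, 1.60, 0.74, 1.30,
                       1.05, 0.89, 0.55, 1.10, 0.93, 0.75, 1.19, 1.70, 1.37, 1.47),
    polarity       = c(8.1, 5.5, 13.0, 12.3, 5.2, 9.0, 10.4, 5.2, 11.3, 4.9,
                       5.7, 11.6, 8.0, 10.5, 10.5, 9.2, 8.6, 5.9, 5.4, 6.2),
    volume         = c(31, 55, 54, 83, 132, 3, 96, 111, 119, 111,
                       105, 56, 32.5, 85, 124, 32, 61, 84, 170, 136)
  )
  colnames(tab) <- AA20
  if (scale) tab <- t(apply(tab, 1, function(r) (r - min(r)) / (max(r) - min(r))))
  tab
}

#' Read a physicochemical index table from TSV
#'
#' Expected layout: one row per index, first column the index name, then 20
#' columns named with the amino-acid one-letter codes (any column order;
#' stored in alphabetical order).
#'
#' @param path TSV path with a header row.
#' @param scale Min-max scale each row to \[0, 1\] (default `TRUE`).
#' @return Numeric matrix as in [default_aaindex()].
#' @export
read_aaindex_table <- function(path, scale = TRUE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(AA20 %in% names(tab))) {
    stop("AAindex table must have one column per amino acid; missing: ",
         paste(setdiff(AA20, names(tab)), collapse = ", "))
  }
  m <- as.matrix(tab[, AA20])
  rownames(m) <- tab[[1]]
  if (anyNA(m) || !is.numeric(m)) stop("AAindex table has missing/non-numeric cells")
  if (scale) m <- t(apply(m, 1, function(r) (r - min(r)) / (max(r) - min(r))))
  m
}

#' Per-position physicochemical (AAindex) encoding
#'
#' Position-major encoding over the 25-symbol window: for each position the
#' index values of the residue there, one channel per index row of `table`;
#' gap positions contribute 0 on every channel. Dimension is
#' `25 * nrow(table)` (200 for the default 8-index table).
#'
#' @param padded Padded peptide string(s) (see [pad_peptide()]).
#' @param table Index matrix as from [default_aaindex()].
#' @return Named numeric vector or one-row-per-peptide matrix.
#' @export
encode_aaindex <- function(padded, table = default_aaindex()) {
  stopifnot(is.matrix(table), ncol(table) == 20)
  if (is.null(colnames(table)) || !all(colnames(table) == AA20)) {
    stop("AAindex table columns must be the amino acids in alphabetical order")
  }
  if (length(padded) > 1) {
    out <- t(vapply(padded, encode_aaindex, numeric(25 * nrow(table)),
                    table = table, USE.NAMES = FALSE))
    dimnames(out) <- list(names(padded),
                          names(encode_aaindex(padded[1], table)))
    return(out)
  }
  W <- nchar(padded)
  ch <- strsplit(padded, "")[[1]]
  idx <- match(ch, AA20)
  bad <- which(!is.na(match(ch, setdiff(LETTERS, c(AA20, GAP)))))
  if (length(bad) > 0) {
    stop("residue '", ch[bad[1]], "' not present in the index table")
  }
  vals <- matrix(0, nrow = nrow(table), ncol = W)
  ok <- !is.na(idx)
  vals[, ok] <- table[, idx[ok], drop = FALSE]
  out <- as.vector(vals)                     # position-major: all channels of pos 1 first
  names(out) <- paste0("p", sprintf("%02d", rep(seq_len(W), each = nrow(table))),
                       "_", rep(rownames(table), W))
  out
}

## ---------------------------------------------------------------------------
## PSSM profiles

#' Construct a PSSM profile object
#'
#' @param matrix L x 20 numeric matrix of position-specific scores; columns
#'   must be the amino acids in alphabetical order (reorder before calling,
#'   or use [read_pssm()] which does this).
#' @param id Peptide identifier.
#' @return Object of class `pssm_profile` with fields `id`, `matrix`, `L`.
#' @export
pssm_profile <- function(matrix, id = "peptide") {
  if (!is.matrix(matrix) || ncol(matrix) != 20) {
    stop("PSSM matrix must have 20 columns")
  }
  if (nrow(matrix) < 1) stop("PSSM matrix must have at least one row")
  if (anyNA(matrix) || !is.numeric(matrix)) stop("PSSM matrix has missing cells")
  colnames(matrix) <- AA20
  structure(list(id = id, matrix = matrix, L = nrow(matrix)),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("pssm_profile '", x$id, "': ", x$L, " positions x 20 residues\n", sep = "")
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the standard PSI-BLAST `-out_ascii_pssm` layout: header lines,
#' then one row per position beginning with the position number and the
#' query residue, followed by 20 integer log-odds columns in PSI-BLAST
#' residue order (A R N D C Q E G H I L K M F P S T W Y V). Any trailing
#' columns (weighted percentages, information content) are ignored. The
#' stored matrix is re-ordered to alphabetical residue columns.
#'
#' @param path PSSM file path.
#' @param id Peptide identifier; defaults to the file name without extension.
#' @return A [pssm_profile()].
#' @export
read_pssm <- function(path, id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  ## matrix rows: "<pos> <residue> <20+ numbers>"
  rows <- grep("^\\s*[0-9]+\\s+[A-Z]\\s+-?[0-9]", lines, value = TRUE)
  if (length(rows) == 0) stop("no PSSM matrix rows found in ", path)
  parsed <- lapply(rows, function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (anyNA(vals)) stop("non-numeric cell in PSSM row: ", trimws(l))
    if (length(vals) < 20) {
      stop("PSSM row has ", length(vals), " score columns (need 20): ",
           trimws(l))
    }
    vals[1:20]
  })
  m <- do.call(rbind, parsed)
  colnames(m) <- PSIBLAST_ORDER
  pssm_profile(m[, AA20, drop = FALSE], id = id)
}

#' Write a PSSM profile as a PSI-BLAST-style ASCII file
#'
#' Emits the log-odds block in PSI-BLAST residue column order with the same
#' row layout `read_pssm()` expects, so write/read round-trips exactly for
#' integer-valued profiles.
#'
#' @param profile A [pssm_profile()].
#' @param path Output path.
#' @param sequence Residue string of length `profile$L` for the query column;
#'   defaults to `X` placeholders.
#' @export
write_pssm <- function(profile, path, sequence = NULL) {
  stopifnot(inherits(profile, "pssm_profile"))
  res <- if (is.null(sequence)) rep("X", profile$L)
         else strsplit(sequence, "")[[1]]
  if (length(res) != profile$L) stop("sequence length does not match profile")
  m <- profile$matrix[, PSIBLAST_ORDER, drop = FALSE]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
               paste0("           ", paste(sprintf("%3s", PSIBLAST_ORDER), collapse = " "))),
             con)
  for (i in seq_len(profile$L)) {
    writeLines(paste0(sprintf("%5d %s ", i, res[i]),
                      paste(sprintf("%5g", m[i, ]), collapse = " ")), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Degenerate one-hot profile for a peptide without a real PSSM
#'
#' Builds a profile whose logistic-squashed form is exactly one-hot (1 at
#' the observed residue, 0 elsewhere), by using +/-999 scores. Encoding this
#' profile with [encode_pksaap()] reproduces [encode_ksaap()] of the
#' underlying sequence, so the pipeline runs end-to-end when no profile
#' search output is available.
#'
#' @param sequence Ungapped residue string.
#' @param id Peptide identifier.
#' @return A [pssm_profile()].
#' @export
onehot_profile <- function(sequence, id = "peptide") {
  idx <- match(strsplit(sequence, "")[[1]], AA20)
  if (anyNA(idx)) stop("invalid residue in sequence")
  m <- matrix(-999, nrow = length(idx), ncol = 20)
  m[cbind(seq_along(idx), idx)] <- 999
  pssm_profile(m, id = id)
}

#' Profile-based k-spaced pair composition (pKSAAP)
#'
#' Applies the KSAAP construction to a position-specific scoring matrix:
#' each raw score x is squashed to `M = 1 / (1 + exp(-x))`, and the feature
#' for spacing k and ordered pair (a, b) is
#' `sum_i M[i, a] * M[i + k + 1, b] / (L - k - 1)` over the valid positions.
#' Blocks and pairs are ordered exactly as in [encode_ksaap()]; a spacing
#' with `L - k - 1 <= 0` contributes an all-zero block. When the squashed
#' profile is one-hot per row this reduces to the sequence KSAAP.
#'
#' @param profile A [pssm_profile()] (or a list of them).
#' @param k_max Largest spacing, default 4 (dimension 2000).
#' @return Named numeric vector, or a matrix with one row per profile.
#' @export
encode_pksaap <- function(profile, k_max = 4) {
  if (is.list(profile) && !inherits(profile, "pssm_profile")) {
    out <- t(vapply(profile, encode_pksaap, numeric(400 * (k_max + 1)),
                    k_max = k_max))
    dimnames(out) <- list(vapply(profile, function(p) p$id, character(1)),
                          ksaap_feature_names(k_max))
    return(out)
  }
  stopifnot(inherits(profile, "pssm_profile"))
  M <- stats::plogis(profile$matrix)
  L <- profile$L
  out <- numeric(400 * (k_max + 1))
  for (k in 0:k_max) {
    n <- L - k - 1
    if (n > 0) {
      block <- crossprod(M[seq_len(n), , drop = FALSE],
                         M[(k + 2):L, , drop = FALSE]) / n   # 20 x 20, [a, b]
      out[k * 400 + seq_len(400)] <- as.vector(t(block))     # a-major
    }
  }
  names(out) <- ksaap_feature_names(k_max)
  out
}

## ---------------------------------------------------------------------------
## Structural tables

SPIDER2_CHANNELS <- c("ASA", "phi", "psi", "theta", "tau", "coil", "strand", "helix")
PEP2D_CHANNELS <- c("helix", "sheet", "coil")
ANGLE_CHANNELS <- c("phi", "psi", "theta", "tau")

#' Read a per-residue structural feature table
#'
#' Delimited text with a header naming the channels: SPIDER2 flavor needs
#' columns `ASA, phi, psi, theta, tau, coil, strand, helix` (one row per
#' residue); PEP2D flavor needs secondary-structure probability columns
#' `helix, sheet, coil`, each row summing to 1 (tolerance 1e-6).
#'
#' @param path File path (tab- or whitespace-delimited, header row).
#' @param flavor `"SPIDER2"` or `"PEP2D"`.
#' @return data.frame of class `structural_table` with attribute `flavor`.
#' @export
read_structural_table <- function(path, flavor = c("SPIDER2", "PEP2D")) {
  flavor <- match.arg(flavor)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  structural_table(tab, flavor)
}

#' Construct/validate a structural feature table
#'
#' @param tab data.frame containing the flavor's channel columns.
#' @param flavor `"SPIDER2"` or `"PEP2D"`.
#' @return data.frame of class `structural_table`.
#' @export
structural_table <- function(tab, flavor = c("SPIDER2", "PEP2D")) {
  flavor <- match.arg(flavor)
  want <- if (flavor == "SPIDER2") SPIDER2_CHANNELS else PEP2D_CHANNELS
  if (!all(want %in% names(tab))) {
    stop(flavor, " table missing column(s): ",
         paste(setdiff(want, names(tab)), collapse = ", "))
  }
  tab <- tab[, want, drop = FALSE]
  if (anyNA(tab)) stop("structural table has missing cells")
  if (flavor == "PEP2D") {
    s <- rowSums(tab)
    if (any(abs(s - 1) > 1e-6)) {
      stop("PEP2D probability rows must sum to 1 (worst deviation ",
           format(max(abs(s - 1))), ")")
    }
  }
  structure(tab, class = c("structural_table", "data.frame"), flavor = flavor)
}

#' Structural feature encoding
#'
#' Position-major flattening of a per-residue structural table over the
#' 25-position window: SPIDER2 gives 8 channels per position (dimension
#' 200), PEP2D 3 (dimension 75). Missing positions are zero-filled; tables
#' with more than 25 rows are truncated with a warning. Backbone angle
#' channels (phi, psi, theta, tau) are rescaled to \[-1, 1\] by dividing by
#' 180.
#'
#' @param table A [structural_table()].
#' @param window Window length, default 25.
#' @return Named numeric vector.
#' @export
encode_structural <- function(table, window = PEPTIDE_WINDOW) {
  stopifnot(inherits(table, "structural_table"))
  flavor <- attr(table, "flavor")
  channels <- if (flavor == "SPIDER2") SPIDER2_CHANNELS else PEP2D_CHANNELS
  m <- t(as.matrix(as.data.frame(table)[, channels, drop = FALSE]))
  ang <- channels %in% ANGLE_CHANNELS
  if (any(ang)) m[ang, ] <- m[ang, ] / 180
  if (ncol(m) > window) {
    warning("structural table has ", ncol(m), " rows; truncated to ", window,
            call. = FALSE)
    m <- m[, seq_len(window), drop = FALSE]
  }
  full <- matrix(0, nrow = nrow(m), ncol = window)
  full[, seq_len(ncol(m))] <- m
  out <- as.vector(full)
  names(out) <- paste0("p", sprintf("%02d", rep(seq_len(window), each = nrow(m))),
                       "_", rep(channels, window))
  out
}

## ---------------------------------------------------------------------------
## Dataset-level feature matrices

#' Build the feature matrix of one encoder for a whole dataset
#'
#' @param dataset An [aip_dataset()].
#' @param encoder One of `"KSAAP"`, `"AAindex"`, `"pKSAAP"`, `"SPIDER2"`,
#'   `"PEP2D"`.
#' @param pssm Named list of [pssm_profile()] objects (names = peptide ids)
#'   for `"pKSAAP"`. Peptides without a profile fall back to the one-hot
#'   degenerate profile with a message.
#' @param structural Named list of [structural_table()] objects for the
#'   structural encoders.
#' @param aaindex Index table for `"AAindex"` (default [default_aaindex()]).
#' @param k_max Largest spacing for the pair-composition encoders.
#' @return Numeric matrix, one row per peptide (rownames = ids).
#' @export
encode_dataset <- function(dataset, encoder = ENCODER_ORDER, pssm = NULL,
                           structural = NULL, aaindex = default_aaindex(),
                           k_max = 4) {
  encoder <- match.arg(encoder)
  padded <- pad_peptide(dataset$sequence)
  out <- switch(encoder,
    KSAAP = encode_ksaap(padded, k_max = k_max),
    AAindex = encode_aaindex(padded, table = aaindex),
    pKSAAP = {
      profs <- lapply(seq_len(nrow(dataset)), function(i) {
        id <- dataset$id[i]
        if (!is.null(pssm) && !is.null(pssm[[id]])) pssm[[id]]
        else onehot_profile(dataset$sequence[i], id = id)
      })
      n_fallback <- if (is.null(pssm)) nrow(dataset)
                    else sum(!(dataset$id %in% names(pssm)))
      if (n_fallback > 0) {
        message(n_fallback, " peptide(s) without a PSSM profile; ",
                "using one-hot self-profiles")
      }
      encode_pksaap(profs, k_max = k_max)
    },
    SPIDER2 = ,
    PEP2D = {
      if (is.null(structural)) stop(encoder, " encoding needs structural tables")
      missing_ids <- setdiff(dataset$id, names(structural))
      if (length(missing_ids) > 0) {
        stop("no structural table for peptide(s): ",
             paste(utils::head(missing_ids, 5), collapse = ", "))
      }
      m <- t(vapply(dataset$id,
                    function(id) encode_structural(structural[[id]]),
                    numeric(if (encoder == "SPIDER2") 200 else 75)))
      colnames(m) <- names(encode_structural(structural[[dataset$id[1]]]))
      m
    })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(out)))
  rownames(out) <- dataset$id
  out
}
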