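## Reading, validating and padding peptide sequences.
##
## Peptides enter as FASTA; records are validated against the 20-letter
## standard alphabet, upper-cased if needed, and truncated to the 25-residue
## window the classifier uses. Padded form is always left-aligned with a
## gap ('-') suffix.

#' Construct a peptide dataset
#'
#' Builds the data frame representation used throughout the package: one row
#' per peptide with columns `id`, `sequence` (validated, upper-case, no
#' gaps), `raw_length`, and `label` (factor with levels `negative`,
#' `positive`, or `NA` when unlabeled).
#'
#' @param id Character vector of identifiers.
#' @param sequence Character vector of residue strings over the 20 standard
#'   amino acids.
#' @param label Optional labels; anything in `c("positive", "pos", "1")`
#'   (case-insensitive) maps to positive, `c("negative", "neg", "0")` to
#'   negative.
#' @return A `data.frame` of class `aip_dataset`.
#' @export
aip_dataset <- function(id, sequence, label = NULL) {
  stopifnot(length(id) == length(sequence))
  sequence <- toupper(as.character(sequence))
  bad <- vapply(sequence, function(s) {
    ch <- strsplit(s, "")[[1]]
    anyNA(match(ch, AA20)) || length(ch) == 0
  }, logical(1))
  if (any(bad)) {
    stop("invalid residues in sequence(s): ", paste(id[bad], collapse = ", "))
  }
  df <- data.frame(
    id = as.character(id),
    sequence = sequence,
    raw_length = nchar(sequence),
    stringsAsFactors = FALSE
  )
  df$label <- if (is.null(label)) factor(rep(NA_character_, nrow(df)),
                                         levels = c("negative", "positive"))
              else normalize_labels(label)
  class(df) <- c("aip_dataset", "data.frame")
  df
}

normalize_labels <- function(label) {
  x <- tolower(as.character(label))
  out <- rep(NA_character_, length(x))
  out[x %in% c("positive", "pos", "1", "true", "aip")] <- "positive"
  out[x %in% c("negative", "neg", "0", "false", "non-aip")] <- "negative"
  if (anyNA(out[!is.na(x)])) {
    stop("unrecognized label value(s): ",
         paste(unique(x[is.na(out) & !is.na(x)]), collapse = ", "))
  }
  factor(out, levels = c("negative", "positive"))
}

#' Read peptides from a FASTA file
#'
#' Parses a FASTA file into an [aip_dataset()]. Sequences are upper-cased
#' (with a warning if any were lower-case), truncated to the first
#' `max_length` residues (with a warning), and records containing characters
#' outside the 20 standard amino-acid letters are rejected with a diagnostic
#' naming the offending symbol and its position.
#'
#' Labels may come from three places, in order of precedence: the `labels`
#' argument (path to a two-column TSV of `id<TAB>label`), a `label=` token in
#' the FASTA header (e.g. `>pep1 label=positive`), or the bare second
#' whitespace-delimited header field when it is a recognized label word.
#'
#' @param path FASTA file path.
#' @param labels Optional path to a tab-separated label file (`id`, `label`,
#'   no header required; a header line `id<TAB>label` is tolerated).
#' @param max_length Residues kept per peptide (window size); longer entries
#'   are truncated to their first `max_length` residues.
#' @return An [aip_dataset()]; rejected records are dropped with a warning.
#' @export
read_fasta <- function(path, labels = NULL, max_length = PEPTIDE_WINDOW) {
  if (!file.exists(path)) stop("file not found: ", path)
  entries <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       forceDNAtolower = FALSE),
    error = function(e) stop("cannot parse FASTA '", path, "': ",
                             conditionMessage(e))
  )
  if (length(entries) == 0) stop("empty FASTA file: ", path)

  ids <- names(entries)
  seqs <- toupper_with_warning(vapply(entries, as.character, character(1)), ids)
  annots <- vapply(entries, function(e) attr(e, "Annot"), character(1))

  keep <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "")[[1]]
    pos <- which(is.na(match(ch, AA20)))
    if (length(ch) == 0) {
      warning("record '", ids[i], "' rejected: empty sequence", call. = FALSE)
      keep[i] <- FALSE
    } else if (length(pos) > 0) {
      warning("record '", ids[i], "' rejected: non-standard residue '",
              ch[pos[1]], "' at position ", pos[1], call. = FALSE)
      keep[i] <- FALSE
    }
  }
  if (!any(keep)) stop("no valid peptide records in ", path)
  ids <- ids[keep]; seqs <- seqs[keep]; annots <- annots[keep]

  over <- nchar(seqs) > max_length
  if (any(over)) {
    warning(sum(over), " sequence(s) longer than ", max_length,
            " residues truncated to their first ", max_length,
            " residues: ", paste(ids[over], collapse = ", "), call. = FALSE)
    seqs[over] <- substr(seqs[over], 1, max_length)
  }

  lab <- header_labels(annots)
  if (!is.null(labels)) {
    tab <- read_label_file(labels)
    lab <- as.character(tab$label[match(ids, tab$id)])
  }
  aip_dataset(ids, seqs, label = lab)
}

toupper_with_warning <- function(seqs, ids) {
  lower <- grepl("[a-z]", seqs)
  if (any(lower)) {
    warning("lower-case residues upper-cased in: ",
            paste(ids[lower], collapse = ", "), call. = FALSE)
  }
  toupper(seqs)
}

header_labels <- function(annots) {
  vapply(annots, function(a) {
    a <- sub("^>\\S*\\s*", "", a)
    m <- regmatches(a, regexpr("label=\\S+", a))
    if (length(m) == 1) return(sub("^label=", "", m))
    tok <- strsplit(trimws(a), "\\s+")[[1]]
    if (length(tok) >= 1 &&
        tolower(tok[1]) %in% c("positive", "pos", "negative", "neg", "0", "1"))
      return(tok[1])
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Read a two-column label file
#'
#' @param path TSV with columns id and label (header optional).
#' @return data.frame with columns `id`, `label`.
#' @export
read_label_file <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("label file must have two columns (id, label)")
  tab <- tab[, 1:2]
  names(tab) <- c("id", "label")
  if (identical(tolower(tab$id[1]), "id")) tab <- tab[-1, , drop = FALSE]
  tab$label <- as.character(normalize_labels(tab$label))
  tab
}

#' Read positive and negative FASTA files into one labeled dataset
#'
#' Convenience for the common dataset shape of one FASTA per class.
#'
#' @param positive,negative FASTA paths.
#' @param ... Passed to [read_fasta()].
#' @return A labeled [aip_dataset()].
#' @export
read_labeled_fasta <- function(positive, negative, ...) {
  pos <- read_fasta(positive, ...)
  neg <- read_fasta(negative, ...)
  pos$label <- factor("positive", levels = c("negative", "positive"))
  neg$label <- factor("negative", levels = c("negative", "positive"))
  out <- rbind(pos, neg)
  class(out) <- c("aip_dataset", "data.frame")
  out
}

#' Write peptides to FASTA
#'
#' Writes upper-case, ungapped sequences; the header is the id, followed by
#' ` label=<label>` when the record is labeled.
#'
#' @param dataset An [aip_dataset()].
#' @param path Output file.
#' @export
write_fasta <- function(dataset, path) {
  headers <- dataset$id
  has_lab <- !is.na(dataset$label)
  headers[has_lab] <- paste0(dataset$id[has_lab], " label=",
                             dataset$label[has_lab])
  seqinr::write.fasta(as.list(dataset$sequence), names = headers,
                      file.out = path, as.string = TRUE, nbchar = 80)
  invisible(path)
}

#' Pad a peptide to the classifier window
#'
#' Left-aligns the residues and appends gap characters (`-`) so that the
#' result has exactly `window` symbols. This is the padded form every
#' encoder consumes.
#'
#' @param sequence Residue string (1 to `window` residues, no gaps).
#' @param window Window length, default 25.
#' @return String of exactly `window` symbols; gaps only as a suffix.
#' @export
pad_peptide <- function(sequence, window = PEPTIDE_WINDOW) {
  n <- nchar(sequence)
  if (any(n == 0)) stop("cannot pad an empty sequence")
  if (any(n > window)) {
    stop("sequence longer than window (", max(n), " > ", window,
         "); truncate first")
  }
  vapply(seq_along(sequence), function(i) {
    paste0(sequence[i], strrep(GAP, window - n[i]))
  }, character(1))
}

#' Strip gap padding from a padded peptide
#'
#' @param padded Padded string(s).
#' @return The original residues (inverse of [pad_peptide()]).
#' @export
strip_gaps <- function(padded) gsub(GAP, "", padded, fixed = TRUE)

#' N-terminal analysis window with 'O' fill
#'
#' Returns the first `span` N-terminal symbols of a peptide for positional
#' enrichment analysis; positions beyond the peptide's length are coded `O`
#' (the analysis alphabet is the 20 standard residues plus `O` for
#' "no residue").
#'
#' @param sequence Residue string(s), ungapped.
#' @param span Window length, default 15.
#' @return String(s) of exactly `span` symbols.
#' @export
nterm_window <- function(sequence, span = NTERM_SPAN) {
  vapply(sequence, function(s) {
    s <- substr(s, 1, span)
    paste0(s, strrep("O", span - nchar(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Write a prediction table
#'
#' Tab-separated with a header row; `NA` encoder scores are written as `NA`.
#'
#' @param predictions Data frame as returned by [predict.aip_model()].
#' @param path Output TSV path.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.aip_dataset <- function(x, ...) {
  nlab <- sum(!is.na(x$label))
  cat("aip_dataset: ", nrow(x), " peptides (",
      sum(x$label == "positive", na.rm = TRUE), " positive, ",
      sum(x$label == "negative", na.rm = TRUE), " negative, ",
      nrow(x) - nlab, " unlabeled); lengths ",
      min(x$raw_length), "-", max(x$raw_length), "\n", sep = "")
  invisible(x)
}
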