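#' Observed symbol sequences
#'
#' An observed sequence is stored as an integer vector of symbol indices with
#' the ordered alphabet attached as an attribute. Symbols are indexed by their
#' position in the declared alphabet.
#'
#' @param symbols Character vector of symbol tokens, or integer indices.
#' @param alphabet Ordered character vector of valid symbols. Required when
#'   `symbols` is integer; inferred (sorted unique) otherwise if missing.
#' @return An integer vector of class `"hmm_seq"` with attribute `alphabet`.
#' @examples
#' hmm_seq(c("a", "b", "a"), alphabet = c("a", "b"))
#' @export
hmm_seq <- function(symbols, alphabet = NULL) {
  if (is.numeric(symbols)) {
    if (is.null(alphabet)) stop("alphabet is required for index input", call. = FALSE)
    idx <- as.integer(symbols)
  } else {
    symbols <- as.character(symbols)
    if (is.null(alphabet)) alphabet <- sort(unique(symbols))
    idx <- match(symbols, alphabet)
    if (anyNA(idx)) {
      bad <- unique(symbols[is.na(idx)])
      stop("symbol(s) not in alphabet: ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (length(idx) && (min(idx) < 1L || max(idx) > length(alphabet)))
    stop("symbol index out of range", call. = FALSE)
  structure(idx, alphabet = alphabet, class = "hmm_seq")
}

#' @export
print.hmm_seq <- function(x, ...) {
  cat("Observed sequence, L = ", length(x), " over {",
      paste(attr(x, "alphabet"), collapse = ", "), "}\n", sep = "")
  cat(paste(attr(x, "alphabet")[unclass(x)], collapse = " "), "\n")
  invisible(x)
}

seq_alphabet <- function(x) attr(x, "alphabet")

#' Coerce to an observed sequence
#'
#' @param x A character/integer vector, an `hmm_seq`, or a data frame with a
#'   `symbol` column (e.g. the output of [sample_hmm()]).
#' @param alphabet Ordered symbol labels.
#' @return An [hmm_seq()].
#' @export
as_hmm_seq <- function(x, alphabet = NULL) {
  if (inherits(x, "hmm_seq")) return(x)
  if (is.data.frame(x)) {
    if (is.null(alphabet)) alphabet <- attr(x, "alphabet")
    return(hmm_seq(x$symbol, alphabet))
  }
  hmm_seq(x, alphabet)
}

# normalize seqs argument: a single sequence or a list of sequences
as_seq_list <- function(seqs, alphabet = NULL) {
  if (inherits(seqs, "hmm_seq") || is.data.frame(seqs) ||
      (!is.list(seqs) && is.atomic(seqs)))
    seqs <- list(seqs)
  lapply(seqs, as_hmm_seq, alphabet = alphabet)
}

check_seq_for_hmm <- function(params, v, min_length = 2L) {
  if (length(v) < min_length)
    stop("observed sequence must have length >= ", min_length, call. = FALSE)
  if (max(unclass(v)) > length(params$alphabet))
    stop("sequence uses symbol indices outside the model alphabet", call. = FALSE)
  invisible(v)
}

#' Sample an observed sequence (and its hidden path) from an HMM
#'
#' @param params An [hmm()] object with valid (row-stochastic) parameters.
#' @param L Sequence length, a positive integer.
#' @param seed Optional integer seed; identical seeds give identical samples.
#' @return A tibble with columns `position`, `hidden` (generating state
#'   label), `symbol` (observed symbol label), carrying the alphabet as an
#'   attribute so [as_hmm_seq()] recovers the sequence directly.
#' @examples
#' p <- random_hmm(2, 2)
#' sample_hmm(p, 10, seed = 1)
#' @export
sample_hmm <- function(params, L, seed = NULL) {
  validate_hmm(params)
  stopifnot(L >= 1)
  if (!is.null(seed)) set.seed(seed)
  nh <- length(params$pi)
  nv <- length(params$alphabet)
  h <- integer(L); v <- integer(L)
  h[1] <- sample.int(nh, 1, prob = params$pi)
  v[1] <- sample.int(nv, 1, prob = params$psi[h[1], ])
  if (L > 1) for (l in 2:L) {
    h[l] <- sample.int(nh, 1, prob = params$theta[h[l - 1], ])
    v[l] <- sample.int(nv, 1, prob = params$psi[h[l], ])
  }
  out <- tibble::tibble(position = seq_len(L),
                        hidden = params$hidden[h],
                        symbol = params$alphabet[v])
  attr(out, "alphabet") <- params$alphabet
  out
}

#' Read or write observed sequences
#'
#' The plain format is whitespace/newline-separated symbol tokens, one
#' sequence per file or separated by blank lines. FASTA-like records
#' (`>name` headers) are accepted for single-character alphabets, each record
#' becoming one sequence.
#'
#' @param path File path.
#' @param alphabet Ordered character vector of valid symbols.
#' @return A list of [hmm_seq()] objects.
#' @export
read_sequences <- function(path, alphabet) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  if (any(grepl("^>", lines))) {
    if (any(nchar(alphabet) != 1L))
      stop("FASTA input requires a single-character alphabet", call. = FALSE)
    recs <- split_fasta(lines)
    return(lapply(recs, function(s) hmm_seq(strsplit(s, "")[[1]], alphabet)))
  }
  groups <- cumsum(!nzchar(trimws(lines)))
  chunks <- split(lines, groups)
  chunks <- Filter(function(ch) any(nzchar(trimws(ch))), chunks)
  lapply(chunks, function(ch) {
    toks <- unlist(strsplit(trimws(ch), "\\s+"))
    hmm_seq(toks[nzchar(toks)], alphabet)
  })
}

split_fasta <- function(lines) {
  hdr <- grepl("^>", lines)
  id <- cumsum(hdr)
  if (id[1] == 0) stop("malformed FASTA: sequence before first header", call. = FALSE)
  recs <- split(lines[!hdr], id[!hdr])
  vapply(recs, function(x) paste(trimws(x), collapse = ""), character(1))
}

#' @rdname read_sequences
#' @param seqs A sequence or list of sequences (anything [as_hmm_seq()] takes).
#' @param header Optional comment lines (prefixed `#`) written before the data.
#' @export
write_sequences <- function(seqs, path, alphabet = NULL, header = NULL) {
  seqs <- as_seq_list(seqs, alphabet)
  out <- character(0)
  if (!is.null(header)) out <- paste0("# ", header)
  for (i in seq_along(seqs)) {
    ab <- seq_alphabet(seqs[[i]])
    out <- c(out, paste(ab[unclass(seqs[[i]])], collapse = " "), "")
  }
  writeLines(out[-length(out)], path)
  invisible(path)
}
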