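#' Tokenize raw text into normalized word tokens
#'
#' Lowercases the text and extracts maximal runs of letters. Internal
#' apostrophes are kept (so "it's" is one token) and hyphens/dashes
#' split words; both behaviours are configurable. Digits and all other
#' punctuation are discarded. The conventions exist to make dictionary
#' lookup well defined, not to model any particular orthography.
#'
#' @param text A character scalar (UTF-8).
#' @param keep_apostrophes Keep internal apostrophes inside tokens.
#' @param split_hyphens Treat hyphens and dashes as separators; if
#'   `FALSE`, internal hyphens are kept inside tokens.
#' @param source_id Optional text identifier attached to the result.
#' @return Character vector of tokens (empty for empty input), with
#'   attribute `source_id`.
#' @examples
#' tokenize("Row, row!")          # "row" "row"
#' tokenize("It's low-row")       # "it's" "low" "row"
#' @export
tokenize <- function(text, keep_apostrophes = TRUE, split_hyphens = TRUE,
                     source_id = NULL) {
  if (length(text) != 1L || !is.character(text))
    stop("'text' must be a single character string")
  x <- tolower(enc2utf8(text))
  x <- gsub("’", "'", x)               # curly -> straight apostrophe
  if (split_hyphens)
    x <- gsub("[-‐-―]", " ", x)
  core <- if (split_hyphens) "\\p{L}" else "[\\p{L}-]"
  pat <- if (keep_apostrophes)
    sprintf("%s+(?:'%s+)*", core, core)
  else
    sprintf("%s+", core)
  toks <- regmatches(x, gregexpr(pat, x, perl = TRUE))[[1]]
  toks <- toks[nzchar(toks)]
  attr(toks, "source_id") <- source_id
  toks
}

#' Load a pronunciation lexicon
#'
#' Reads a flat-file pronunciation dictionary with one entry per line,
#' `WORD<TAB>PH1 PH2 ... PHk` (CMUdict-like dialect; lines starting
#' with `;;;` are comments). Orthographic keys are lowercased;
#' duplicate keys keep the first occurrence with a warning.
#'
#' @param path Path to the lexicon file (UTF-8).
#' @return An object of class `"lexicon"`: a list with `entries` (named
#'   list mapping word to character vector of phoneme symbols) and
#'   `inventory` (sorted unique phoneme symbols).
#' @export
load_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^;;;", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  words <- character(0)
  prons <- list()
  for (i in idx) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !nzchar(trimws(parts[1])))
      stop(sprintf("malformed lexicon line %d: %s", i,
                   dQuote(lines[i])), call. = FALSE)
    phones <- strsplit(trimws(paste(parts[-1], collapse = " ")),
                       "[ \t]+")[[1]]
    phones <- phones[nzchar(phones)]
    if (length(phones) == 0L)
      stop(sprintf("malformed lexicon line %d: empty pronunciation", i),
           call. = FALSE)
    words <- c(words, tolower(trimws(parts[1])))
    prons[[length(prons) + 1L]] <- phones
  }
  dup <- duplicated(words)
  if (any(dup)) {
    warning(sprintf("lexicon: %d duplicate key(s) dropped (first kept): %s",
                    sum(dup),
                    paste(utils::head(unique(words[dup]), 5L),
                          collapse = ", ")))
    prons <- prons[!dup]
    words <- words[!dup]
  }
  names(prons) <- words
  structure(list(entries = prons,
                 inventory = sort(unique(unlist(prons, use.names = FALSE)))),
            class = "lexicon")
}

# Construct a lexicon object from an in-memory named list of phoneme
# sequences (used by the synthetic-corpus generator).
as_lexicon <- function(entries) {
  stopifnot(is.list(entries), !is.null(names(entries)),
            all(nzchar(names(entries))))
  if (anyDuplicated(names(entries)))
    stop("lexicon entries must have unique keys")
  if (any(lengths(entries) == 0L))
    stop("lexicon entries must have non-empty pronunciations")
  structure(list(entries = entries,
                 inventory = sort(unique(unlist(entries, use.names = FALSE)))),
            class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("Pronunciation lexicon: %d entries, %d phoneme symbols\n",
              length(x$entries), length(x$inventory)))
  invisible(x)
}

#' Write a lexicon to a flat file
#'
#' Inverse of [load_lexicon()]; writes the tab-separated dialect.
#'
#' @param lexicon A `"lexicon"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "lexicon"))
  lines <- vapply(seq_along(lexicon$entries), function(i)
    paste0(names(lexicon$entries)[i], "\t",
           paste(lexicon$entries[[i]], collapse = " ")),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Count phonemes in a token sequence
#'
#' Maps tokens through the lexicon and accumulates phoneme counts under
#' one of the two word-selection modes: `"all_words"` counts phoneme
#' multiplicities over every token occurrence, `"different_words"`
#' counts each distinct in-lexicon word type once. Out-of-lexicon words
#' are skipped and reported; corpus statistics cover in-lexicon material
#' only.
#'
#' @param tokens Character vector of normalized tokens (see
#'   [tokenize()]).
#' @param lexicon A `"lexicon"` object.
#' @param mode `"all_words"` or `"different_words"`.
#' @param oov_warn_fraction Warn if the out-of-lexicon fraction of word
#'   types exceeds this (default 0.05); guards against a lexicon/corpus
#'   mismatch.
#' @return A list with `counts` (class `"phoneme_counts"`: named integer
#'   vector of phoneme counts, with attributes `mode` and `oov`, the
#'   out-of-lexicon types with token counts) and `stats` (class
#'   `"corpus_stats"`: `n_tw` total in-lexicon tokens, `n_pht` phonemes
#'   over all tokens, `n_dw` distinct in-lexicon types, `n_phd` phonemes
#'   over distinct types).
#' @export
count_phonemes <- function(tokens, lexicon,
                           mode = c("all_words", "different_words"),
                           oov_warn_fraction = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(lexicon, "lexicon"))
  if (length(lexicon$entries) == 0L) stop("lexicon is empty")
  tokens <- as.character(tokens)
  type_counts <- table(tokens)
  types <- names(type_counts)
  known <- types %in% names(lexicon$entries)
  oov <- as.integer(type_counts[!known])
  names(oov) <- types[!known]
  if (!any(known))
    stop("no transcribable content: every token is out-of-lexicon")
  if (length(types) > 0L &&
      sum(!known) / length(types) > oov_warn_fraction)
    warning(sprintf(
      "out-of-lexicon fraction of word types is %.1f%% (threshold %.1f%%)",
      100 * sum(!known) / length(types), 100 * oov_warn_fraction))

  in_types <- types[known]
  tok_mult <- as.numeric(type_counts[known])     # token multiplicities
  prons <- lexicon$entries[in_types]
  lens <- lengths(prons)
  phones <- unlist(prons, use.names = FALSE)

  weight <- if (mode == "all_words") tok_mult else rep(1, length(in_types))
  counts_tab <- rowsum(rep(weight, lens), group = phones)
  counts <- as.integer(counts_tab[, 1L])
  names(counts) <- rownames(counts_tab)
  counts <- counts[order(names(counts))]

  stats <- structure(list(
    n_tw  = as.integer(sum(tok_mult)),
    n_pht = as.integer(sum(tok_mult * lens)),
    n_dw  = length(in_types),
    n_phd = as.integer(sum(lens))), class = "corpus_stats")

  counts <- structure(counts, mode = mode, oov = oov,
                      class = "phoneme_counts")
  list(counts = counts, stats = stats)
}

#' @export
print.phoneme_counts <- function(x, ...) {
  cat(sprintf("Phoneme counts (%s): %d symbols, %d phoneme tokens, %d OOV types\n",
              attr(x, "mode"), length(x), sum(x), length(attr(x, "oov"))))
  invisible(x)
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf(
    "Corpus stats: %d word tokens (%d phonemes), %d word types (%d phonemes)\n",
    x$n_tw, x$n_pht, x$n_dw, x$n_phd))
  invisible(x)
}

#' Remove the shared vocabulary of two texts
#'
#' Given the word-type sets of two texts, removes their intersection
#' from each — the ablation used to test whether author similarity
#' survives once the words common to both texts are discarded.
#'
#' @param types_i,types_j Character vectors of word types.
#' @return A list of two character vectors: each input minus the shared
#'   types.
#' @examples
#' exclude_common_words(c("a", "b", "c"), c("b", "c", "d"))
#' @export
exclude_common_words <- function(types_i, types_j) {
  if (length(types_i) == 0L || length(types_j) == 0L)
    stop("both type sets must be non-empty")
  common <- intersect(types_i, types_j)
  out_i <- setdiff(types_i, common)
  out_j <- setdiff(types_j, common)
  if (length(out_i) == 0L || length(out_j) == 0L)
    stop("texts share entire vocabulary: nothing left after exclusion")
  list(out_i, out_j)
}

#' Normalize phoneme counts to labeled frequencies
#'
#' Divides counts by their total over a supplied phoneme inventory;
#' inventory symbols absent from the counts get frequency zero. Counts
#' carrying a symbol outside the inventory are an error.
#'
#' @param counts A `"phoneme_counts"` object or named numeric vector.
#' @param inventory Character vector of phoneme symbols (defaults to the
#'   symbols present in `counts`).
#' @param source_id Optional text identifier.
#' @return Named numeric vector of class `"labeled_freqs"` over the
#'   sorted inventory, summing to 1.
#' @export
normalize_frequencies <- function(counts, inventory = NULL,
                                  source_id = NULL) {
  x <- as.numeric(counts)
  names(x) <- names(counts)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("'counts' must be a named vector")
  if (is.null(inventory)) inventory <- names(x)
  inventory <- sort(unique(as.character(inventory)))
  extra <- setdiff(names(x), inventory)
  if (length(extra) > 0L)
    stop(sprintf("counts contain symbols outside the inventory: %s",
                 paste(utils::head(extra, 5L), collapse = ", ")))
  total <- sum(x)
  if (!(total > 0)) stop("total count must be positive")
  freq <- stats::setNames(numeric(length(inventory)), inventory)
  freq[names(x)] <- x / total
  structure(freq, source_id = source_id, class = "labeled_freqs")
}

#' @export
print.labeled_freqs <- function(x, ...) {
  id <- attr(x, "source_id")
  cat(sprintf("Labeled phoneme frequencies over %d symbols%s\n",
              length(x),
              if (is.null(id)) "" else paste0(" [", id, "]")))
  print(round(unclass(x), 4), ...)
  invisible(x)
}

#' Rank frequencies in non-increasing order
#'
#' Sorts a labeled frequency vector into the descending rank-frequency
#' form `f_1 >= f_2 >= ... >= f_n`. Ties are broken by phoneme symbol
#' (lexicographic), making the ranking deterministic.
#'
#' @param lf A `"labeled_freqs"` object or named numeric vector.
#' @return Numeric vector of class `"ranked_freqs"` (phoneme labels kept
#'   as names), non-increasing.
#' @export
rank_frequencies <- function(lf) {
  x <- as.numeric(lf)
  names(x) <- names(lf)
  ord <- if (is.null(names(x))) order(-x) else order(-x, names(x))
  structure(x[ord], source_id = attr(lf, "source_id"),
            class = "ranked_freqs")
}

#' @export
print.ranked_freqs <- function(x, ...) {
  cat(sprintf("Ranked frequencies, n = %d (f1 = %.4g ... fn = %.4g)\n",
              length(x), x[1], x[length(x)]))
  invisible(x)
}
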