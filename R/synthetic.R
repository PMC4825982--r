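#' Specification of a synthetic corpus
#'
#' Describes a corpus with the statistical structure the analysis
#' assumes: each author has a phoneme probability profile drawn from a
#' symmetric Dirichlet with an author-specific concentration; a
#' vocabulary of synthetic words is composed by drawing phonemes
#' independently from those profiles; texts sample word tokens from a
#' Zipf--Mandelbrot law over the author's vocabulary. A configurable
#' fraction of the vocabulary is shared by all authors, with
#' pronunciations composed from a neutral profile at the average
#' concentration; the author-specific block occupies the top usage
#' ranks and the shared block the tail, so that each author keeps a
#' distinctive high-frequency phoneme stream while every pair of texts
#' still has a common vocabulary for the ablation.
#'
#' Defaults emulate the reference study's scale: a 44-phoneme
#' inventory, three authors with concentrations 0.6/0.7/0.8 (inside the
#' 0.5--1 band typical of English texts, separated by 0.1), three texts
#' per author, 1e5 word tokens per text, a vocabulary of 1e4 words with
#' Zipf exponent 1, a quarter of it shared, and word lengths with mean
#' 3.5 phonemes (the phoneme-per-token ratio of the reference corpus).
#' The shared fraction is kept at a quarter so the type-mode phoneme
#' profile stays dominated by the author's own vocabulary and fitted
#' concentrations remain in the study's range.
#'
#' @param n_phonemes Inventory size.
#' @param betas Named numeric vector of author concentrations (> 0);
#'   names become author labels.
#' @param texts_per_author Texts generated per author.
#' @param tokens_per_text Word tokens per text.
#' @param vocab_size Words in each author's vocabulary.
#' @param zipf_exponent Exponent of the Zipf--Mandelbrot token law.
#' @param zipf_offset Mandelbrot flattening offset.
#' @param shared_vocab_fraction Fraction of the vocabulary common to
#'   all authors.
#' @param word_length_mean Mean phonemes per word (truncated geometric).
#' @param word_length_max Maximum phonemes per word.
#' @param seed Master seed; all corpus randomness derives from it.
#' @return An object of class `"synthetic_corpus_spec"`.
#' @export
synthetic_corpus_spec <- function(n_phonemes = 44,
                                  betas = c(A = 0.6, B = 0.7, C = 0.8),
                                  texts_per_author = 3,
                                  tokens_per_text = 1e5,
                                  vocab_size = 1e4,
                                  zipf_exponent = 1,
                                  zipf_offset = 2.7,
                                  shared_vocab_fraction = 0.25,
                                  word_length_mean = 3.5,
                                  word_length_max = 12,
                                  seed = 1) {
  if (is.null(names(betas)))
    names(betas) <- paste0("A", seq_along(betas))
  stopifnot(n_phonemes >= 1, all(betas > 0), texts_per_author >= 1,
            tokens_per_text >= 1, vocab_size >= 2,
            zipf_exponent > 0, zipf_offset >= 0,
            shared_vocab_fraction >= 0, shared_vocab_fraction <= 1,
            word_length_mean >= 1, word_length_max >= word_length_mean)
  structure(list(n_phonemes = as.integer(n_phonemes), betas = betas,
                 texts_per_author = as.integer(texts_per_author),
                 tokens_per_text = as.integer(tokens_per_text),
                 vocab_size = as.integer(vocab_size),
                 zipf_exponent = zipf_exponent,
                 zipf_offset = zipf_offset,
                 shared_vocab_fraction = shared_vocab_fraction,
                 word_length_mean = word_length_mean,
                 word_length_max = as.integer(word_length_max),
                 seed = as.integer(seed)),
            class = "synthetic_corpus_spec")
}

#' @export
print.synthetic_corpus_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic corpus: %d authors (beta %s), %d x %d texts, %g tokens each\n",
    length(x$betas), paste(x$betas, collapse = "/"),
    length(x$betas), x$texts_per_author, x$tokens_per_text))
  invisible(x)
}

phoneme_symbols <- function(n) sprintf("p%02d", seq_len(n))

# Deterministic letter-only orthographic keys ("a", ..., "z", "ba", ...)
# so that synthetic words survive tokenization unchanged.
int2word <- function(i) {
  vapply(i, function(k) {
    k <- k - 1L
    s <- character(0)
    repeat {
      s <- c(letters[k %% 26L + 1L], s)
      k <- k %/% 26L
      if (k == 0L) break
      k <- k - 1L
    }
    paste(s, collapse = "")
  }, character(1))
}

# --- unseeded cores (called under one with_seed() by gen_corpus) -----

profile_core <- function(n, beta) {
  g <- stats::rgamma(n, shape = beta)
  while (sum(g) == 0) g <- stats::rgamma(n, shape = beta)
  stats::setNames(g / sum(g), phoneme_symbols(n))
}

lexicon_core <- function(n_words, profile, prefix, length_mean,
                         length_max) {
  lens <- pmin(1L + stats::rgeom(n_words, prob = 1 / length_mean),
               length_max)
  phones <- sample(names(profile), sum(lens), replace = TRUE,
                   prob = profile)
  entries <- split(phones, rep.int(seq_len(n_words), lens))
  names(entries) <- paste0(prefix, int2word(seq_len(n_words)))
  entries
}

zipf_probs <- function(v, s, q) {
  w <- (seq_len(v) + q)^(-s)
  w / sum(w)
}

text_core <- function(ranked_words, tokens, s, q) {
  sample(ranked_words, tokens, replace = TRUE,
         prob = zipf_probs(length(ranked_words), s, q))
}

# --- seeded public generators ----------------------------------------

#' Draw an author phoneme profile
#'
#' One draw from the symmetric Dirichlet via normalized gamma variates.
#'
#' @param n Inventory size.
#' @param beta Concentration.
#' @param seed Integer seed.
#' @return Named probability vector of length `n` (symbols
#'   `p01`, `p02`, ...).
#' @export
gen_author_profile <- function(n, beta, seed) {
  stopifnot(n >= 1, beta > 0)
  with_seed(seed, profile_core(n, beta))
}

#' Generate a synthetic pronunciation lexicon
#'
#' Composes `vocab_size` words; each word gets a truncated-geometric
#' length and that many phonemes drawn independently from `profile`.
#'
#' @param spec A [synthetic_corpus_spec()] (supplies vocabulary size and
#'   word-length law).
#' @param profile Phoneme probability vector the words are composed
#'   from.
#' @param seed Integer seed.
#' @param prefix Prefix for the generated orthographic keys.
#' @return A `"lexicon"` object.
#' @export
gen_lexicon <- function(spec, profile, seed, prefix = "w") {
  stopifnot(inherits(spec, "synthetic_corpus_spec"))
  as_lexicon(with_seed(seed,
    lexicon_core(spec$vocab_size, profile, prefix,
                 spec$word_length_mean, spec$word_length_max)))
}

#' Sample a Zipfian token sequence
#'
#' Draws `tokens_per_text` word tokens from a Zipf--Mandelbrot
#' distribution `p_r` proportional to `(r + offset)^(-exponent)` over a
#' ranked vocabulary.
#'
#' @param lexicon A `"lexicon"` object (or character vector of words);
#'   vocabulary order defines the ranks.
#' @param spec A [synthetic_corpus_spec()].
#' @param seed Integer seed.
#' @return Character vector of tokens.
#' @export
gen_text <- function(lexicon, spec, seed) {
  stopifnot(inherits(spec, "synthetic_corpus_spec"))
  words <- if (inherits(lexicon, "lexicon")) names(lexicon$entries)
           else as.character(lexicon)
  with_seed(seed, text_core(words, spec$tokens_per_text,
                            spec$zipf_exponent, spec$zipf_offset))
}

#' Generate a full synthetic corpus with ground truth
#'
#' Builds the corpus described by `spec`: one Dirichlet profile per
#' author; a shared vocabulary block (composed from a neutral profile at
#' the mean concentration) plus an author-specific block composed from
#' each author's profile; a per-author rank order over its vocabulary;
#' and Zipf--Mandelbrot token sampling for each text. All randomness
#' derives from `spec$seed`.
#'
#' @param spec A [synthetic_corpus_spec()].
#' @param dir Optional directory: if given, one `.txt` file per text,
#'   the union lexicon (`lexicon.tsv`) and the ground truth
#'   (`ground_truth.json`) are written there.
#' @return A list: `texts` (named list of token vectors), `lexicon`
#'   (union `"lexicon"`), `ground_truth` (author concentrations,
#'   profiles, text-to-author map), and `spec`.
#' @export
gen_corpus <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_corpus_spec"))
  authors <- names(spec$betas)
  with_seed(spec$seed, {
    profiles <- vapply(spec$betas, function(b)
      profile_core(spec$n_phonemes, b), numeric(spec$n_phonemes))
    neutral <- profile_core(spec$n_phonemes, mean(spec$betas))

    n_shared <- round(spec$shared_vocab_fraction * spec$vocab_size)
    n_spec <- spec$vocab_size - n_shared
    shared <- if (n_shared > 0)
      lexicon_core(n_shared, neutral, "x", spec$word_length_mean,
                   spec$word_length_max)
    else list()

    texts <- list()
    text_authors <- character(0)
    union_entries <- shared
    for (a in seq_along(authors)) {
      own <- if (n_spec > 0)
        lexicon_core(n_spec, profiles[, a],
                     paste0(letters[a], "q"),  # key prefix per author
                     spec$word_length_mean, spec$word_length_max)
      else list()
      union_entries <- c(union_entries, own)
      # author-specific words take the top usage ranks (permuted per
      # author); the shared block fills the tail
      ranked <- c(sample(names(own)), sample(names(shared)))
      for (t in seq_len(spec$texts_per_author)) {
        id <- sprintf("%s_t%d", authors[a], t)
        texts[[id]] <- text_core(ranked, spec$tokens_per_text,
                                 spec$zipf_exponent, spec$zipf_offset)
        text_authors[id] <- authors[a]
      }
    }

    ground_truth <- list(betas = spec$betas,
                         profiles = profiles,
                         text_authors = text_authors)
    lexicon <- as_lexicon(union_entries)

    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      for (id in names(texts)) {
        con <- file(file.path(dir, paste0(id, ".txt")),
                    open = "w", encoding = "UTF-8")
        # wrap tokens into lines of 12 to keep files diff-friendly
        toks <- texts[[id]]
        grp <- ceiling(seq_along(toks) / 12)
        writeLines(vapply(split(toks, grp), paste, character(1),
                          collapse = " "), con)
        close(con)
      }
      write_lexicon(lexicon, file.path(dir, "lexicon.tsv"))
      jsonlite::write_json(
        list(betas = as.list(spec$betas),
             profiles = as.data.frame(profiles),
             text_authors = as.list(text_authors)),
        file.path(dir, "ground_truth.json"),
        auto_unbox = TRUE, digits = NA)
    }

    list(texts = texts, lexicon = lexicon,
         ground_truth = ground_truth, spec = spec)
  })
}
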