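small_spec <- function(...) {
  synthetic_corpus_spec(n_phonemes = 15,
                        betas = c(P = 0.6, Q = 0.8),
                        texts_per_author = 2,
                        tokens_per_text = 3000,
                        vocab_size = 400,
                        seed = 11, ...)
}

test_that("author profiles are seeded Dirichlet draws with the right concentration behavior", {
  p <- gen_author_profile(20, 0.7, seed = 4)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_identical(p, gen_author_profile(20, 0.7, seed = 4))
  expect_false(identical(p, gen_author_profile(20, 0.7, seed = 5)))
  # small beta concentrates mass: mean top entry larger at 0.5 than 5
  top05 <- mean(sample_ordered(dirichlet_spec(20, 0.5), 2000, 7)[, 1])
  top5 <- mean(sample_ordered(dirichlet_spec(20, 5), 2000, 7)[, 1])
  expect_gt(top05, top5)
})

test_that("synthetic lexicon words are composed from the author profile", {
  spec <- synthetic_corpus_spec(n_phonemes = 20, vocab_size = 5000,
                                seed = 1)
  prof <- gen_author_profile(20, 0.8, seed = 2)
  lex <- gen_lexicon(spec, prof, seed = 3)
  expect_s3_class(lex, "lexicon")
  expect_length(lex$entries, 5000)
  expect_true(all(lengths(lex$entries) >= 1))
  expect_true(all(lengths(lex$entries) <= spec$word_length_max))
  expect_identical(lex, gen_lexicon(spec, prof, seed = 3))
  # pooled phoneme frequencies converge to the profile (multinomial SE)
  pool <- table(unlist(lex$entries, use.names = FALSE))
  n_draws <- sum(pool)
  emp <- stats::setNames(as.numeric(pool) / n_draws, names(pool))
  for (s in names(prof)) {
    se <- sqrt(prof[s] * (1 - prof[s]) / n_draws)
    expect_lt(abs((if (s %in% names(emp)) emp[s] else 0) - prof[s]),
              4 * se + 1e-6)
  }
  # mean word length near the configured mean
  expect_equal(mean(lengths(lex$entries)), spec$word_length_mean,
               tolerance = 0.1)
})

test_that("token sampling is Zipf-Mandelbrot with the configured exponent", {
  spec <- synthetic_corpus_spec(n_phonemes = 10, vocab_size = 2000,
                                tokens_per_text = 5e4, seed = 9)
  prof <- gen_author_profile(10, 0.8, seed = 2)
  lex <- gen_lexicon(spec, prof, seed = 3)
  toks <- gen_text(lex, spec, seed = 21)
  expect_length(toks, spec$tokens_per_text)
  expect_lt(length(unique(toks)), length(toks))
  expect_identical(toks, gen_text(lex, spec, seed = 21))
  # regression of log-frequency on log(rank + offset) over top ranks
  cnt <- sort(table(toks), decreasing = TRUE)
  r <- 1:100
  slope <- coef(lm(log(as.numeric(cnt[r])) ~
                     log(r + spec$zipf_offset)))[2]
  expect_equal(unname(slope), -spec$zipf_exponent, tolerance = 0.1)
})

test_that("corpus generation yields the requested layout and is pure in (spec, seed)", {
  spec <- small_spec()
  corp <- gen_corpus(spec)
  expect_length(corp$texts, 4)
  expect_equal(unname(corp$ground_truth$text_authors),
               rep(c("P", "Q"), each = 2))
  expect_equal(colSums(corp$ground_truth$profiles), c(P = 1, Q = 1),
               tolerance = 1e-12)
  expect_true(all(lengths(corp$texts) == spec$tokens_per_text))
  corp2 <- gen_corpus(spec)
  expect_identical(corp$texts, corp2$texts)
  expect_identical(corp$lexicon, corp2$lexicon)
  # disk layout
  dir <- withr::local_tempdir()
  gen_corpus(spec, dir = dir)
  expect_length(list.files(dir, pattern = "\\.txt$"), 4)
  expect_true(file.exists(file.path(dir, "lexicon.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  # written text round-trips through the tokenizer
  toks <- tokenize(paste(readLines(file.path(dir, "P_t1.txt")),
                         collapse = "\n"))
  expect_equal(as.character(toks), corp$texts$P_t1)
})

test_that("disjoint-vocabulary authors share only the common block", {
  spec <- small_spec(shared_vocab_fraction = 0)
  corp <- gen_corpus(spec)
  ta <- unique(corp$texts$P_t1)
  tb <- unique(corp$texts$Q_t1)
  expect_length(intersect(ta, tb), 0)
  expect_error(exclude_common_words(ta, tb), NA)
})

test_that("text-level ranked frequencies converge to the ranked author profile", {
  # type mode, no shared vocabulary: the only gaps to the profile are
  # lexicon-composition and type-sampling noise, both shrinking with
  # size
  spec_small <- synthetic_corpus_spec(
    n_phonemes = 20, betas = c(Z = 0.8), texts_per_author = 1,
    tokens_per_text = 2000, vocab_size = 3000,
    shared_vocab_fraction = 0, seed = 31)
  spec_big <- synthetic_corpus_spec(
    n_phonemes = 20, betas = c(Z = 0.8), texts_per_author = 1,
    tokens_per_text = 2e5, vocab_size = 3000,
    shared_vocab_fraction = 0, seed = 31)
  target <- NULL
  sup <- vapply(list(spec_small, spec_big), function(sp) {
    corp <- gen_corpus(sp)
    ph <- phonemize_tokens(corp$texts[[1]], corp$lexicon,
                           "different_words")
    target <<- sort(corp$ground_truth$profiles[, 1], decreasing = TRUE)
    max(abs(as.numeric(ph$ranked) - as.numeric(target)))
  }, numeric(1))
  expect_lt(sup[2], sup[1])
  expect_lt(sup[2], 0.02)
})

test_that("averaged ranked profiles reproduce the Dirichlet order-statistic curve", {
  # the generative link the analysis rests on: many author profiles at
  # one concentration average to the model's expected ranked curve
  n <- 20; beta <- 0.8; draws <- 400
  m <- sample_ordered(dirichlet_spec(n, beta), draws, seed = 77)
  fhat <- expected_curve(dirichlet_spec(n, beta))
  se <- apply(m, 2, sd) / sqrt(draws)
  expect_true(all(abs(colMeans(m) - fhat) <= 4 * se))
})
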