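# Independent oracles used across test files.

# Exhaustive subset-witness form of the total-variation distance:
# max over all subsets W of |sum_{a in W} (p_a - q_a)|. Only feasible
# for small n; used to cross-check rho0.
brute_force_tv <- function(p, q) {
  stopifnot(identical(names(p), names(q)))
  d <- p - q
  n <- length(d)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    s <- sum(d[bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0])
    best <- max(best, abs(s))
  }
  best
}

# A random point on the probability simplex with named coordinates.
rand_simplex <- function(n, labels = sprintf("s%02d", seq_len(n))) {
  x <- stats::rexp(n)
  stats::setNames(x / sum(x), labels)
}

# A tiny lexicon shared by phonemizer tests.
toy_lexicon <- function() {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("row\tr əʊ",
               "low\tl əʊ",
               "cat\tk æ t",
               "mat\tm æ t",
               "the\tð ə"),
             path, useBytes = TRUE)
  load_lexicon(path)
}
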