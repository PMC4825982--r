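#' Bundled reference study: nine English novels by three authors
#'
#' The package ships, as plain-text fixtures, the published summary
#' tables of a reference corpus of nine novels — three each by Jane
#' Austen, Charles Dickens and J.R.R. Tolkien (texts numbered 1--9 in
#' that order): per-text corpus sizes, fitted Dirichlet concentrations
#' under both word-selection modes, pairwise variational distances under
#' three modes, and shared-vocabulary fractions. Distances and
#' vocabulary fractions are stored exactly as printed, as integers
#' scaled by 1e5; the loaders also return them on the natural scale.
#' These tables drive the package's worked examples and regression
#' tests; the underlying novels themselves are not shipped.
#'
#' @name reference_study
#' @keywords datasets
NULL

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "phonorank")
  if (!nzchar(p)) stop(sprintf("missing fixture %s", file))
  p
}

read_ref <- function(file) {
  utils::read.delim(ref_path(file), fileEncoding = "UTF-8",
                    stringsAsFactors = FALSE)
}

#' @describeIn reference_study Per-text corpus statistics: token and
#'   type counts and their phoneme totals, with author labels.
#' @export
reference_corpus_stats <- function() {
  read_ref("reference_corpus_stats.tsv")
}

#' @describeIn reference_study Author label of each of the nine texts,
#'   in text order.
#' @export
reference_authors <- function() {
  reference_corpus_stats()$author
}

#' @describeIn reference_study Fitted concentration, error sum
#'   (`ss_err_e7`, scaled by 1e7 as printed) and squared correlation per
#'   text.
#' @param mode Word-selection mode of the underlying frequencies.
#' @export
reference_fits <- function(mode = c("all_words", "different_words")) {
  mode <- match.arg(mode)
  read_ref(sprintf("reference_fits_%s.tsv", mode))
}

#' @describeIn reference_study Pairwise variational distances; columns
#'   `rho0_e5`/`rho1_e5` hold the printed 1e5-scaled integers, `rho0`/
#'   `rho1` the same values on the natural scale.
#' @export
reference_distances <- function(mode = c("all_words", "different_words",
                                         "no_common_words")) {
  mode <- match.arg(mode)
  d <- read_ref(sprintf("reference_distances_%s.tsv", mode))
  d$rho0 <- d$rho0_e5 / 1e5
  d$rho1 <- d$rho1_e5 / 1e5
  d
}

#' @describeIn reference_study Pairwise distances of one mode assembled
#'   into a symmetric 9 x 9 matrix (zero diagonal).
#' @param lambda 0 for the label-aligned distance, 1 for the
#'   rank-aligned one.
#' @param scaled If `TRUE` return the printed 1e5-scaled integers
#'   instead of the natural scale.
#' @export
reference_distance_matrix <- function(mode = c("all_words",
                                               "different_words",
                                               "no_common_words"),
                                      lambda = c(0, 1),
                                      scaled = FALSE) {
  mode <- match.arg(mode)
  lambda <- match.arg(as.character(lambda[1]), c("0", "1"))
  d <- reference_distances(mode)
  col <- if (lambda == "0") "rho0" else "rho1"
  if (scaled) col <- paste0(col, "_e5")
  ids <- sort(unique(c(d$i, d$j)))
  m <- matrix(0, length(ids), length(ids),
              dimnames = list(ids, ids))
  for (k in seq_len(nrow(d))) {
    m[as.character(d$i[k]), as.character(d$j[k])] <- d[[col]][k]
    m[as.character(d$j[k]), as.character(d$i[k])] <- d[[col]][k]
  }
  m
}

#' @describeIn reference_study Shared-vocabulary (Jaccard) fraction per
#'   text pair; `p_e5` as printed, `p` on the natural scale.
#' @export
reference_common_word_fractions <- function() {
  d <- read_ref("reference_common_word_fraction.tsv")
  d$p <- d$p_e5 / 1e5
  d
}

#' @describeIn reference_study Path to the bundled miniature RP-style
#'   pronunciation lexicon (a small fixture, not a full dictionary).
#' @export
mini_lexicon_path <- function() {
  ref_path("mini_lexicon_rp.tsv")
}

#' @describeIn reference_study The default 44-symbol RP-style phoneme
#'   inventory, as a character vector.
#' @export
rp_inventory <- function() {
  readLines(ref_path("rp_inventory.txt"), encoding = "UTF-8")
}
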