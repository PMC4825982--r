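#' Phonemize one token sequence
#'
#' Convenience wrapper chaining [count_phonemes()],
#' [normalize_frequencies()] and [rank_frequencies()] for a single
#' text.
#'
#' @param tokens Character vector of normalized tokens.
#' @param lexicon A `"lexicon"` object.
#' @param mode Word-selection mode.
#' @param inventory Phoneme inventory (defaults to the lexicon's).
#' @param source_id Optional text identifier.
#' @return A list with `counts`, `stats`, `labeled` (frequencies by
#'   phoneme) and `ranked` (descending frequencies).
#' @export
phonemize_tokens <- function(tokens, lexicon,
                             mode = c("all_words", "different_words"),
                             inventory = NULL, source_id = NULL) {
  mode <- match.arg(mode)
  if (is.null(inventory)) inventory <- lexicon$inventory
  cp <- count_phonemes(tokens, lexicon, mode)
  lf <- normalize_frequencies(cp$counts, inventory, source_id)
  list(counts = cp$counts, stats = cp$stats, labeled = lf,
       ranked = rank_frequencies(lf))
}

# In-lexicon word types of a token sequence.
lexicon_types <- function(tokens, lexicon) {
  intersect(unique(as.character(tokens)), names(lexicon$entries))
}

# Pairwise distances after removing each pair's shared vocabulary:
# frequencies are recomputed from the surviving types only (type mode),
# then compared. Returns rho0 and rho1 matrices.
nocommon_distances <- function(texts, lexicon, inventory) {
  ids <- names(texts)
  k <- length(ids)
  types <- lapply(texts, lexicon_types, lexicon = lexicon)
  r0 <- r1 <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      ex <- exclude_common_words(types[[i]], types[[j]])
      fi <- normalize_frequencies(
        count_phonemes(ex[[1]], lexicon, "different_words")$counts,
        inventory)
      fj <- normalize_frequencies(
        count_phonemes(ex[[2]], lexicon, "different_words")$counts,
        inventory)
      r0[i, j] <- r0[j, i] <- rho0(fi, fj)
      r1[i, j] <- r1[j, i] <- rho1(rank_frequencies(fi),
                                   rank_frequencies(fj))
    }
  }
  list(rho0 = r0, rho1 = r1)
}

#' Full author-comparison analysis of a corpus
#'
#' Runs the complete pipeline on a set of tokenized texts: phoneme
#' frequencies under both word-selection modes, pairwise variational
#' distances (including the pairwise common-word ablation), per-author
#' distance gaps, optional Dirichlet fits with per-author concentration
#' gaps, shared-vocabulary fractions, and the cross-mode inequality
#' report.
#'
#' @param texts Named list of token vectors (names are text ids).
#' @param lexicon A `"lexicon"` object.
#' @param authors Author label per text (same order as `texts`).
#' @param inventory Phoneme inventory (defaults to the lexicon's).
#' @param fit If `TRUE` also fit the Dirichlet concentration per text
#'   and mode.
#' @param fit_interval,fit_tol Passed to [fit_beta()].
#' @param ablation If `TRUE` include the pairwise common-word ablation.
#' @return A list with elements `frequencies` (per mode, per text),
#'   `distances` (per mode: `rho0`, `rho1` matrices), `z_gaps`,
#'   `fits`, `b_gaps`, `common_words`, and `report` (a
#'   [mode_comparison_report()]).
#' @export
compare_corpus <- function(texts, lexicon, authors, inventory = NULL,
                           fit = TRUE, fit_interval = c(0.3, 1.5),
                           fit_tol = 1e-3, ablation = TRUE) {
  stopifnot(is.list(texts), !is.null(names(texts)),
            length(authors) == length(texts))
  if (length(texts) < 2L) stop("need at least two texts")
  if (is.null(inventory)) inventory <- lexicon$inventory
  ids <- names(texts)
  authors <- as.character(authors)

  modes <- c("all_words", "different_words")
  freqs <- lapply(stats::setNames(modes, modes), function(m)
    lapply(stats::setNames(ids, ids), function(id)
      phonemize_tokens(texts[[id]], lexicon, m, inventory, id)))

  distances <- lapply(freqs, function(fm) list(
    rho0 = distance_matrix(lapply(fm, `[[`, "labeled"), 0),
    rho1 = distance_matrix(lapply(fm, `[[`, "ranked"), 1)))
  if (ablation)
    distances$no_common_words <- nocommon_distances(texts, lexicon,
                                                    inventory)

  z_gaps <- lapply(distances, function(d) list(
    rho0 = cluster_gaps(d$rho0, authors, "distance_gap"),
    rho1 = cluster_gaps(d$rho1, authors, "distance_gap")))

  fits <- b_gaps <- NULL
  if (fit) {
    fits <- lapply(freqs, function(fm)
      lapply(fm, function(x)
        fit_beta(x$ranked, interval = fit_interval, tol = fit_tol)))
    b_gaps <- lapply(fits, function(fl) {
      betas <- vapply(fl, `[[`, numeric(1), "beta_hat")
      cluster_gaps(betas, authors, "beta_gap")
    })
  }

  types <- lapply(texts, lexicon_types, lexicon = lexicon)
  pairs <- utils::combn(seq_along(ids), 2L)
  common_words <- data.frame(
    i = ids[pairs[1L, ]], j = ids[pairs[2L, ]],
    p = apply(pairs, 2L, function(p)
      common_word_fraction(types[[p[1L]]], types[[p[2L]]])$p))

  report <- mode_comparison_report(
    rho_all = distances$all_words,
    rho_diff = distances$different_words,
    rho_nocommon = if (ablation) distances$no_common_words,
    beta_all = if (fit)
      vapply(fits$all_words, `[[`, numeric(1), "beta_hat"),
    beta_diff = if (fit)
      vapply(fits$different_words, `[[`, numeric(1), "beta_hat"),
    authors = authors)

  list(frequencies = freqs, distances = distances, z_gaps = z_gaps,
       fits = fits, b_gaps = b_gaps, common_words = common_words,
       report = report, authors = stats::setNames(authors, ids))
}

read_text_file <- function(path) {
  paste(readLines(path, encoding = "UTF-8", warn = FALSE),
        collapse = "\n")
}

write_freq_tsv <- function(x, path) {
  ranked <- x$ranked
  counts <- x$counts
  cnt <- as.integer(counts[names(ranked)])
  cnt[is.na(cnt)] <- 0L
  d <- data.frame(rank = seq_along(ranked), phoneme = names(ranked),
                  count = cnt,
                  frequency = signif(as.numeric(ranked), 6))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Phonemize text files to frequency tables
#'
#' Reads plain-text files, tokenizes them, and writes per text and per
#' word-selection mode a ranked-frequency TSV (`rank`, `phoneme`,
#' `count`, `frequency`), a corpus-statistics JSON, and an OOV report.
#' A file that cannot be processed is reported and skipped; the run
#' continues.
#'
#' @param text_paths Named character vector of text file paths (names
#'   become text ids; basenames are used otherwise).
#' @param lexicon_path Path to the pronunciation lexicon.
#' @param out_dir Output directory (created if needed).
#' @param modes Word-selection modes to process.
#' @param inventory_path Optional file with one phoneme symbol per line.
#' @return Invisibly, a data frame listing the written files; failed
#'   inputs are attached as attribute `"failed"`.
#' @export
run_phonemize <- function(text_paths, lexicon_path, out_dir,
                          modes = c("all_words", "different_words"),
                          inventory_path = NULL) {
  lexicon <- load_lexicon(lexicon_path)
  inventory <- if (is.null(inventory_path)) lexicon$inventory
               else readLines(inventory_path, encoding = "UTF-8")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ids <- names(text_paths)
  if (is.null(ids))
    ids <- sub("\\.[^.]*$", "", basename(text_paths))
  rows <- list(); failed <- character(0)
  for (k in seq_along(text_paths)) {
    id <- ids[k]
    res <- tryCatch({
      toks <- tokenize(read_text_file(text_paths[k]), source_id = id)
      if (length(toks) == 0L) stop("empty text")
      out <- list()
      for (m in modes) {
        ph <- phonemize_tokens(toks, lexicon, m, inventory, id)
        f <- file.path(out_dir, sprintf("%s_%s_ranked.tsv", id, m))
        write_freq_tsv(ph, f)
        out[[m]] <- f
        jsonlite::write_json(
          ph$stats[c("n_tw", "n_pht", "n_dw", "n_phd")],
          file.path(out_dir, sprintf("%s_%s_stats.json", id, m)),
          auto_unbox = TRUE, digits = NA)
        oov <- attr(ph$counts, "oov")
        utils::write.table(
          data.frame(word = names(oov), tokens = as.integer(oov)),
          file.path(out_dir, sprintf("%s_%s_oov.tsv", id, m)),
          sep = "\t", quote = FALSE, row.names = FALSE,
          fileEncoding = "UTF-8")
      }
      data.frame(id = id, mode = modes,
                 file = unlist(out[modes], use.names = FALSE))
    }, error = function(e) {
      message(sprintf("phonemize: skipping %s: %s", id,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failed <- c(failed, id) else
      rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), mode = character(0),
               file = character(0))
  attr(out, "failed") <- failed
  invisible(out)
}

#' Fit the Dirichlet concentration to ranked-frequency tables
#'
#' Reads ranked-frequency TSVs (as written by [run_phonemize()]) and
#' fits each with [fit_beta()], producing a per-text table of `beta`,
#' `ss_err` scaled by 1e7, and squared correlation.
#'
#' @param freq_paths Character vector of ranked-frequency TSV paths.
#' @param interval,tol Passed to [fit_beta()].
#' @param out Optional path for a TSV copy of the result table.
#' @return A data frame with one row per input file.
#' @export
run_fit <- function(freq_paths, interval = c(0.3, 1.5), tol = 1e-3,
                    out = NULL) {
  rows <- lapply(freq_paths, function(p) {
    d <- tryCatch(
      utils::read.delim(p, fileEncoding = "UTF-8"),
      error = function(e) stop(sprintf("cannot parse %s: %s", p,
                                       conditionMessage(e)),
                               call. = FALSE))
    if (!"frequency" %in% names(d))
      stop(sprintf("cannot parse %s: no 'frequency' column", p))
    fit <- fit_beta(d$frequency, interval = interval, tol = tol)
    data.frame(file = basename(p), n = fit$n,
               beta = round(fit$beta_hat, 3),
               ss_err_e7 = round(fit$ss_err * 1e7),
               r_squared = round(fit$r_squared, 4),
               converged = fit$converged)
  })
  res <- do.call(rbind, rows)
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  res
}

#' Run the author-comparison pipeline on text files
#'
#' Front end of [compare_corpus()] for files on disk: reads and
#' tokenizes the texts, runs the full comparison, and (optionally)
#' writes distance matrices (natural scale and 1e5-scaled integers),
#' gap statistics and the inequality report to `out_dir`.
#'
#' @param text_paths Named character vector of text file paths.
#' @param lexicon_path Path to the pronunciation lexicon.
#' @param authors Author label per text.
#' @param out_dir Optional output directory.
#' @param ... Passed on to [compare_corpus()].
#' @return The [compare_corpus()] result, invisibly when writing.
#' @export
run_compare <- function(text_paths, lexicon_path, authors,
                        out_dir = NULL, ...) {
  if (length(text_paths) < 2L) stop("need at least two texts")
  if (length(authors) != length(text_paths))
    stop("missing author label: 'authors' must cover every text")
  lexicon <- load_lexicon(lexicon_path)
  ids <- names(text_paths)
  if (is.null(ids))
    ids <- sub("\\.[^.]*$", "", basename(text_paths))
  texts <- lapply(text_paths, function(p)
    tokenize(read_text_file(p)))
  names(texts) <- ids
  res <- compare_corpus(texts, lexicon, authors, ...)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (m in names(res$distances)) {
      for (lam in c("rho0", "rho1")) {
        mat <- res$distances[[m]][[lam]]
        utils::write.table(
          round(mat * 1e5),
          file.path(out_dir, sprintf("%s_%s_e5.tsv", lam, m)),
          sep = "\t", quote = FALSE, fileEncoding = "UTF-8")
        utils::write.table(
          mat, file.path(out_dir, sprintf("%s_%s.tsv", lam, m)),
          sep = "\t", quote = FALSE, fileEncoding = "UTF-8")
      }
    }
    gaps <- list(z_gaps = res$z_gaps, b_gaps = res$b_gaps,
                 inequality_summary = res$report$summary)
    jsonlite::write_json(gaps, file.path(out_dir, "gaps.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(res$common_words,
                       file.path(out_dir, "common_word_fraction.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    return(invisible(res))
  }
  res
}

#' Generate and write a synthetic corpus
#'
#' Thin wrapper over [gen_corpus()] writing the corpus to disk.
#'
#' @param out_dir Output directory.
#' @param ... Passed to [synthetic_corpus_spec()].
#' @return The generated corpus, invisibly.
#' @export
run_simulate <- function(out_dir, ...) {
  spec <- synthetic_corpus_spec(...)
  invisible(gen_corpus(spec, dir = out_dir))
}
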