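#' Rank-aligned variational distance
#'
#' Half the L1 distance between two descending rank-frequency vectors.
#' Because both vectors are sorted before differencing, the distance
#' ignores which phoneme carries which frequency; permutation-equivalent
#' profiles are at distance zero. This is the coarse-grained companion
#' of [rho0()], and never exceeds it.
#'
#' @param fi,fj Ranked frequency vectors of equal length (sorted
#'   internally if needed).
#' @return A value in \[0, 1\].
#' @export
rho1 <- function(fi, fj) {
  fi <- as.numeric(fi); fj <- as.numeric(fj)
  if (length(fi) != length(fj))
    stop("frequency vectors must have equal length")
  sum(abs(sort(fi, decreasing = TRUE) -
            sort(fj, decreasing = TRUE))) / 2
}

#' Label-aligned variational distance
#'
#' Half the L1 distance between two phoneme frequency vectors aligned by
#' phoneme label over the union of their inventories (absent symbols
#' count as zero). Equals the largest probability discrepancy
#' `max_W |sum_{a in W} (p_a - q_a)|` over composite events W, i.e. the
#' total-variation distance between the two distributions.
#'
#' @param fi,fj Named frequency vectors (`"labeled_freqs"` or named
#'   numerics).
#' @return A value in \[0, 1\].
#' @export
rho0 <- function(fi, fj) {
  if (is.null(names(fi)) || is.null(names(fj)))
    stop("label-aligned distance needs named frequency vectors")
  inv <- sort(union(names(fi), names(fj)))
  a <- stats::setNames(numeric(length(inv)), inv)
  b <- a
  a[names(fi)] <- as.numeric(fi)
  b[names(fj)] <- as.numeric(fj)
  sum(abs(a - b)) / 2
}

#' Shared-vocabulary fraction of two texts
#'
#' `p = n_ij / (n_i + n_j - n_ij)` where `n_i`, `n_j` are the word-type
#' counts of the two texts and `n_ij` the number of shared types: the
#' Jaccard index of the two vocabularies.
#'
#' @param types_i,types_j Character vectors of word types (non-empty).
#' @return A list with `n_i`, `n_j`, `n_ij`, and `p`.
#' @export
common_word_fraction <- function(types_i, types_j) {
  if (length(types_i) == 0L || length(types_j) == 0L)
    stop("both type sets must be non-empty")
  types_i <- unique(types_i); types_j <- unique(types_j)
  n_ij <- length(intersect(types_i, types_j))
  list(n_i = length(types_i), n_j = length(types_j), n_ij = n_ij,
       p = n_ij / (length(types_i) + length(types_j) - n_ij))
}

#' Author-cluster separation gap
#'
#' The cluster-gap statistic: (minimum cross-cluster value) minus
#' (maximum within-cluster value). A positive gap means every text of
#' the target cluster is closer — in the chosen statistic — to its
#' cluster mates than to any outside text.
#'
#' Two kinds are supported. `"beta_gap"` works on per-text scalar values
#' (fitted concentrations): within-cluster values are all `|b_i - b_j|`
#' for pairs inside the cluster, cross-cluster values all `|b_i - b_k|`
#' with `i` inside and `k` outside. `"distance_gap"` works on a
#' symmetric pairwise distance matrix, using the distances themselves.
#'
#' @param x For `"beta_gap"`, a numeric vector of per-text values; for
#'   `"distance_gap"`, a symmetric numeric matrix of pairwise distances.
#' @param labels Cluster label per text (same length/order as `x` rows).
#' @param target The cluster to score (must have >= 2 members, and at
#'   least one text must lie outside it).
#' @param kind `"beta_gap"` or `"distance_gap"`.
#' @return The gap, a single number (sign unconstrained).
#' @examples
#' b <- c(0.61, 0.63, 0.61, 0.67, 0.69, 0.69, 0.75, 0.74, 0.79)
#' a <- rep(c("A", "D", "T"), each = 3)
#' cluster_gap(b, a, "A", "beta_gap")  # 0.02
#' @export
cluster_gap <- function(x, labels, target,
                        kind = c("beta_gap", "distance_gap")) {
  kind <- match.arg(kind)
  labels <- as.character(labels)
  if (kind == "beta_gap") {
    x <- as.numeric(x)
    if (length(x) != length(labels))
      stop("'labels' must match 'x' in length")
    inside <- which(labels == target)
    outside <- which(labels != target)
    if (length(inside) < 2L)
      stop("target cluster needs >= 2 members")
    if (length(outside) < 1L)
      stop("no texts outside the target cluster")
    within <- abs(outer(x[inside], x[inside], "-"))
    within <- within[upper.tri(within)]
    cross <- abs(outer(x[inside], x[outside], "-"))
    min(cross) - max(within)
  } else {
    if (!is.matrix(x) || nrow(x) != ncol(x))
      stop("'x' must be a square distance matrix")
    if (max(abs(x - t(x))) > 1e-12)
      stop("'x' must be symmetric")
    if (length(labels) != nrow(x))
      stop("'labels' must match the matrix dimension")
    inside <- which(labels == target)
    outside <- which(labels != target)
    if (length(inside) < 2L)
      stop("target cluster needs >= 2 members")
    if (length(outside) < 1L)
      stop("no texts outside the target cluster")
    within <- x[inside, inside, drop = FALSE]
    within <- within[upper.tri(within)]
    cross <- x[inside, outside, drop = FALSE]
    min(cross) - max(within)
  }
}

#' Cluster gaps for every cluster
#'
#' Convenience wrapper computing [cluster_gap()] for each distinct label.
#'
#' @inheritParams cluster_gap
#' @return Named numeric vector of gaps, one per cluster.
#' @export
cluster_gaps <- function(x, labels, kind = c("beta_gap", "distance_gap")) {
  kind <- match.arg(kind)
  labs <- unique(as.character(labels))
  stats::setNames(
    vapply(labs, function(a) cluster_gap(x, labels, a, kind), numeric(1)),
    labs)
}

#' Pairwise distance matrix between texts
#'
#' Builds the symmetric matrix of [rho0()] (label-aligned,
#' `lambda = 0`) or [rho1()] (rank-aligned, `lambda = 1`) distances for
#' a list of frequency vectors.
#'
#' @param freqs Named list of frequency vectors (`"labeled_freqs"` for
#'   `lambda = 0`; any numeric for `lambda = 1`).
#' @param lambda 0 for label-aligned, 1 for rank-aligned.
#' @return A symmetric matrix with zero diagonal, dimnames from
#'   `names(freqs)`.
#' @export
distance_matrix <- function(freqs, lambda = c(0, 1)) {
  lambda <- match.arg(as.character(lambda[1]), c("0", "1"))
  k <- length(freqs)
  if (k < 2L) stop("need at least two texts")
  d <- matrix(0, k, k, dimnames = list(names(freqs), names(freqs)))
  fun <- if (lambda == "0") rho0 else rho1
  for (i in seq_len(k - 1L))
    for (j in seq.int(i + 1L, k))
      d[i, j] <- d[j, i] <- fun(freqs[[i]], freqs[[j]])
  d
}

# One inequality family of the mode-comparison report.
ineq_frame <- function(instance, left, right) {
  data.frame(instance = instance, left = left, right = right,
             holds = left > right, row.names = NULL)
}

same_author_pairs <- function(authors) {
  idx <- seq_along(authors)
  pairs <- utils::combn(idx, 2L)
  keep <- authors[pairs[1L, ]] == authors[pairs[2L, ]]
  pairs[, keep, drop = FALSE]
}

#' Compare word-selection modes across a corpus
#'
#' Evaluates the families of deterministic inequalities that contrast
#' the token mode ("all words"), the type mode ("different words"), and
#' the common-word ablation ("no common words") of the same corpus:
#'
#' * per-text concentration: `beta[different] > beta[all]`;
#' * per-author beta gaps: `b[different](a) > b[all](a)`;
#' * same-author pairwise distances: `rho_lambda[all](ij) >
#'   rho_lambda[different](ij)`;
#' * per-author distance gaps: `z_lambda[different](a) >
#'   z_lambda[all](a)`;
#' * ablation: `z_lambda[no common](a) > 0`,
#'   `rho_lambda[no common](ij) > rho_lambda[different](ij)`, and
#'   `z_lambda[no common](a) > z_lambda[different](a)`.
#'
#' Each family is reported as a data frame of instances with both sides
#' of the inequality and whether it holds; ties count as not holding.
#'
#' @param rho_all,rho_diff Lists with elements `rho0` and `rho1`,
#'   symmetric distance matrices for the all-words and different-words
#'   modes (same texts, same order).
#' @param rho_nocommon Optional list like `rho_all` for the common-word
#'   ablation.
#' @param beta_all,beta_diff Optional per-text fitted concentrations for
#'   the two modes.
#' @param authors Author label per text.
#' @return An object of class `"mode_comparison"`: a list of per-family
#'   data frames plus a `summary` data frame of holding counts.
#' @export
mode_comparison_report <- function(rho_all, rho_diff, rho_nocommon = NULL,
                                   beta_all = NULL, beta_diff = NULL,
                                   authors) {
  check_pair <- function(m, what) {
    if (!is.list(m) || !all(c("rho0", "rho1") %in% names(m)))
      stop(sprintf("'%s' must be a list with rho0 and rho1 matrices",
                   what))
    if (!identical(dim(m$rho0), dim(m$rho1)))
      stop(sprintf("'%s': rho0 and rho1 dimensions differ", what))
    if (nrow(m$rho0) != length(authors))
      stop(sprintf("'%s': matrix does not cover every text", what))
    m
  }
  rho_all <- check_pair(rho_all, "rho_all")
  rho_diff <- check_pair(rho_diff, "rho_diff")
  if (!is.null(rho_nocommon))
    rho_nocommon <- check_pair(rho_nocommon, "rho_nocommon")
  authors <- as.character(authors)
  texts <- rownames(rho_all$rho0)
  if (is.null(texts)) texts <- as.character(seq_along(authors))

  out <- list()

  if (!is.null(beta_all) && !is.null(beta_diff)) {
    if (length(beta_all) != length(authors) ||
        length(beta_diff) != length(authors))
      stop("beta vectors must cover every text")
    out$beta_per_text <- ineq_frame(
      paste0("beta[diff](", texts, ") > beta[all](", texts, ")"),
      as.numeric(beta_diff), as.numeric(beta_all))
    ga <- cluster_gaps(beta_all, authors, "beta_gap")
    gd <- cluster_gaps(beta_diff, authors, "beta_gap")
    out$beta_gaps <- ineq_frame(
      paste0("b[diff](", names(ga), ") > b[all](", names(ga), ")"),
      as.numeric(gd[names(ga)]), as.numeric(ga))
  }

  pairs <- same_author_pairs(authors)
  sa <- function(mats_hi, mats_lo, tag_hi, tag_lo) {
    res <- list()
    for (lam in c("rho0", "rho1")) {
      hi <- mats_hi[[lam]][cbind(pairs[1L, ], pairs[2L, ])]
      lo <- mats_lo[[lam]][cbind(pairs[1L, ], pairs[2L, ])]
      res[[lam]] <- ineq_frame(
        sprintf("%s[%s](%s,%s) > %s[%s](%s,%s)", lam, tag_hi,
                texts[pairs[1L, ]], texts[pairs[2L, ]],
                lam, tag_lo, texts[pairs[1L, ]], texts[pairs[2L, ]]),
        hi, lo)
    }
    do.call(rbind, res)
  }
  out$same_author_all_vs_diff <- sa(rho_all, rho_diff, "all", "diff")

  zg <- function(mats) {
    rbind(
      data.frame(lambda = 0,
                 author = names(cluster_gaps(mats$rho0, authors,
                                             "distance_gap")),
                 gap = as.numeric(cluster_gaps(mats$rho0, authors,
                                               "distance_gap"))),
      data.frame(lambda = 1,
                 author = names(cluster_gaps(mats$rho1, authors,
                                             "distance_gap")),
                 gap = as.numeric(cluster_gaps(mats$rho1, authors,
                                               "distance_gap"))))
  }
  z_all <- zg(rho_all); z_diff <- zg(rho_diff)
  out$z_gaps_diff_vs_all <- ineq_frame(
    sprintf("z%d[diff](%s) > z%d[all](%s)", z_all$lambda, z_all$author,
            z_all$lambda, z_all$author),
    z_diff$gap, z_all$gap)

  if (!is.null(rho_nocommon)) {
    z_nc <- zg(rho_nocommon)
    out$z_nocommon_positive <- ineq_frame(
      sprintf("z%d[nocomm](%s) > 0", z_nc$lambda, z_nc$author),
      z_nc$gap, 0)
    out$same_author_nocommon_vs_diff <-
      sa(rho_nocommon, rho_diff, "nocomm", "diff")
    out$z_nocommon_vs_diff <- ineq_frame(
      sprintf("z%d[nocomm](%s) > z%d[diff](%s)", z_nc$lambda,
              z_nc$author, z_nc$lambda, z_nc$author),
      z_nc$gap, z_diff$gap)
  }

  out$summary <- data.frame(
    family = names(out),
    n_hold = vapply(out, function(d) sum(d$holds), integer(1)),
    n_total = vapply(out, nrow, integer(1)),
    row.names = NULL)
  class(out) <- "mode_comparison"
  out
}

#' @export
print.mode_comparison <- function(x, ...) {
  cat("Mode-comparison report\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
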