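#' Per-donor mean feature matrix
#'
#' Collapses an upstream table to one row per donor x subset: for a
#' `usage_table` the per-donor frequencies are spread to one column per
#' key (absent keys 0-filled); for a property table the numeric columns
#' are averaged over clonotypes (rows with missing values dropped).
#'
#' @param upstream A `usage_table` or a property table.
#' @param features Optional character vector restricting the feature
#'   columns (property tables only).
#' @return A `donor_matrix` tibble: `donor_id`, `subset`, then one numeric
#'   column per feature.
#' @export
donor_means <- function(upstream, features = NULL) {
  tab <- as_tibble(upstream)
  if (all(c("key", "frequency") %in% names(tab))) {
    wide <- tidyr::pivot_wider(tab[, c("donor_id", "subset", "key", "frequency")],
                               names_from = "key", values_from = "frequency",
                               values_fill = 0)
    out <- dplyr::arrange(wide, .data$donor_id, .data$subset)
  } else {
    num <- names(tab)[vapply(tab, is.numeric, logical(1))]
    num <- setdiff(num, c("member_count", "duplicate_count"))
    if (!is.null(features)) num <- intersect(num, features)
    tab <- tab[stats::complete.cases(tab[, num, drop = FALSE]), , drop = FALSE]
    out <- dplyr::summarise(
      dplyr::group_by(tab, .data$donor_id, .data$subset),
      dplyr::across(dplyr::all_of(num), mean), .groups = "drop")
    out <- dplyr::arrange(out, .data$donor_id, .data$subset)
  }
  structure(out, class = c("donor_matrix", class(out)))
}

donor_matrix_values <- function(m) {
  m <- as_tibble(m)
  as.matrix(m[, setdiff(names(m), c("donor_id", "subset")), drop = FALSE])
}

# between-subset centroid dispersion over total dispersion in the first
# two PC dimensions; an artifact surrogate for the visual group
# separation of a score plot
separation_statistic <- function(scores, subset) {
  s <- scores[, seq_len(min(2L, ncol(scores))), drop = FALSE]
  centre <- colMeans(s)
  tot <- sum(sweep(s, 2, centre)^2)
  if (tot < 1e-12) return(0)
  between <- 0
  for (g in unique(subset)) {
    rows <- subset == g
    cg <- colMeans(s[rows, , drop = FALSE])
    between <- between + sum(rows) * sum((cg - centre)^2)
  }
  between / tot
}

#' Principal component analysis of a donor-mean matrix
#'
#' SVD-based PCA (via [stats::prcomp()]) of the per-donor-mean feature
#' matrix, centred by default and unscaled (the R `prcomp` default, which
#' is what the repertoire analyses use). Component signs are fixed by
#' convention: the largest-magnitude loading of each component is made
#' positive, so results are fully deterministic. When a `subset` column is
#' present a separation statistic (between-subset centroid dispersion over
#' total dispersion in the PC1-2 plane) is computed.
#'
#' @param m A `donor_matrix` from [donor_means()] (>= 3 rows, >= 2
#'   features).
#' @param center,scale Passed to [stats::prcomp()].
#' @return A `rep_pca` object: `scores` (tibble with `donor_id`, `subset`,
#'   `PC1`..), `loadings`, `explained_variance_ratio`, `separation_stat`,
#'   `center`, `scale`.
#' @export
run_pca <- function(m, center = TRUE, scale = FALSE) {
  vals <- donor_matrix_values(m)
  if (nrow(vals) < 3L || ncol(vals) < 2L) {
    stop("run_pca: need at least 3 rows and 2 features")
  }
  if (all(apply(vals, 2, stats::var) < 1e-12)) stop("zero variance matrix")
  p <- stats::prcomp(vals, center = center, scale. = scale)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  p$rotation <- sweep(p$rotation, 2, flip, "*")
  p$x <- sweep(p$x, 2, flip, "*")
  evr <- p$sdev^2 / sum(p$sdev^2)
  mt <- as_tibble(m)
  scores <- dplyr::bind_cols(mt[, intersect(c("donor_id", "subset"), names(mt))],
                             as_tibble(p$x))
  sep <- if ("subset" %in% names(mt)) {
    separation_statistic(p$x, mt$subset)
  } else NA_real_
  structure(list(scores = scores, loadings = p$rotation,
                 explained_variance_ratio = evr, separation_stat = sep,
                 center = p$center, scale = p$scale, sdev = p$sdev),
            class = "rep_pca")
}

#' @exportS3Method base::print
print.rep_pca <- function(x, ...) {
  cat("PCA of donor-mean matrix:", nrow(x$scores), "rows,",
      nrow(x$loadings), "features\n")
  cat("explained variance ratio:",
      paste(sprintf("%.3f", utils::head(x$explained_variance_ratio, 4)),
            collapse = " "), "...\n")
  if (!is.na(x$separation_stat)) {
    cat(sprintf("subset separation statistic (PC1-2): %.3f\n",
                x$separation_stat))
  }
  invisible(x)
}

# fast internal path: donor x subset means via rowsum on an integer index
fast_donor_means <- function(vals, donor, subset) {
  g <- paste(donor, subset, sep = "\r")
  sums <- rowsum(vals, g, reorder = TRUE)
  n <- as.vector(table(g)[rownames(sums)])
  list(m = sums / n,
       subset = sub("^.*\r", "", rownames(sums)))
}

fast_sep_stat <- function(vals, donor, subset, center = TRUE) {
  dm <- fast_donor_means(vals, donor, subset)
  p <- stats::prcomp(dm$m, center = center, scale. = FALSE)
  separation_statistic(p$x, dm$subset)
}

#' Randomization control for PCA group separation
#'
#' Permutation test of whether the subset separation seen in the
#' donor-mean PCA could arise by chance: subset labels are shuffled across
#' sequences (within each donor by default, preserving subset sizes and
#' donor effects under the null), the donor-mean PCA separation statistic
#' is recomputed for each shuffle, and the p-value is
#' `(1 + #{perm >= observed}) / (n_perm + 1)`.
#'
#' @param tbl Clonotype-level tibble with `donor_id`, `subset` and feature
#'   columns.
#' @param features Character vector of feature columns; default all
#'   numeric columns.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed; results are exactly reproducible.
#' @param shuffle `"within_donor"` (default) or `"global"`.
#' @param center Centre features in the PCA (default TRUE).
#' @return A `rep_perm` object: `observed`, `perm_stats`, `separation_p`,
#'   `n_perm`.
#' @export
randomization_control <- function(tbl, features = NULL, n_perm = 199L,
                                  seed = 1L,
                                  shuffle = c("within_donor", "global"),
                                  center = TRUE) {
  shuffle <- match.arg(shuffle)
  if (n_perm < 99L) stop("n_perm must be at least 99")
  tbl <- as_tibble(tbl)
  if (length(unique(tbl$subset)) < 2L) {
    stop("randomization_control: need at least 2 subsets")
  }
  if (is.null(features)) {
    features <- names(tbl)[vapply(tbl, is.numeric, logical(1))]
    features <- setdiff(features, c("member_count", "duplicate_count"))
  }
  vals <- as.matrix(tbl[, features, drop = FALSE])
  donor <- tbl$donor_id
  subset <- tbl$subset
  observed <- fast_sep_stat(vals, donor, subset, center)
  perm_stats <- withr::with_seed(seed, {
    donor_rows <- split(seq_along(donor), donor)
    vapply(seq_len(n_perm), function(i) {
      perm <- subset
      if (shuffle == "within_donor") {
        for (rows in donor_rows) perm[rows] <- sample(perm[rows])
      } else {
        perm <- sample(perm)
      }
      fast_sep_stat(vals, donor, perm, center)
    }, numeric(1))
  })
  p <- (1 + sum(perm_stats >= observed)) / (n_perm + 1)
  structure(list(observed = observed, perm_stats = perm_stats,
                 separation_p = p, n_perm = n_perm), class = "rep_perm")
}

#' @exportS3Method base::print
print.rep_perm <- function(x, ...) {
  cat(sprintf("permutation control: observed separation %.3f, p = %.4f (%d permutations)\n",
              x$observed, x$separation_p, x$n_perm))
  invisible(x)
}

#' Minkowski power-4 hierarchical clustering
#'
#' Pairwise Minkowski distances \eqn{d(x, y) = (\sum_i |x_i - y_i|^p)^{1/p}}
#' between donor x subset rows (power 4 by default, which emphasizes the
#' largest coordinate differences), followed by agglomerative clustering
#' and Newick serialization of the dendrogram with branch lengths taken
#' from merge heights.
#'
#' @param m A `donor_matrix`.
#' @param power Minkowski exponent, >= 1 (a power below 1 is not a
#'   metric).
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   `"complete"`.
#' @return A `rep_dendro` object: `hclust`, `phylo` (ape tree), `newick`
#'   string, `labels`, `subset`.
#' @export
minkowski_cluster <- function(m, power = 4, linkage = "complete") {
  if (power < 1) stop("power must be >= 1 (not a metric otherwise)")
  vals <- donor_matrix_values(m)
  mt <- as_tibble(m)
  labels <- if (all(c("donor_id", "subset") %in% names(mt))) {
    paste(mt$donor_id, mt$subset, sep = "_")
  } else {
    paste0("row", seq_len(nrow(vals)))
  }
  rownames(vals) <- labels
  d <- stats::dist(vals, method = "minkowski", p = power)
  hc <- stats::hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = phy,
                 newick = ape::write.tree(phy),
                 labels = labels,
                 subset = if ("subset" %in% names(mt)) mt$subset else NULL),
            class = "rep_dendro")
}

#' @exportS3Method base::print
print.rep_dendro <- function(x, ...) {
  cat("Minkowski dendrogram over", length(x$labels), "rows\n")
  cat(substr(x$newick, 1, 70), "...\n")
  invisible(x)
}

#' Root split of a dendrogram
#'
#' Cuts the dendrogram at its root into two clades and returns their leaf
#' labels — useful for asking whether one cell subset forms the outgroup.
#'
#' @param x A `rep_dendro`.
#' @return List of two character vectors of labels.
#' @export
root_split <- function(x) {
  stopifnot(inherits(x, "rep_dendro"))
  cl <- stats::cutree(x$hclust, k = 2L)
  split(names(cl), cl)
}
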