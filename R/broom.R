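#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy PCA scores
#'
#' One row per observation x component with the score value.
#'
#' @param x A `rep_pca`.
#' @param ... Unused.
#' @return A long tibble: identifier columns, `component`, `score`.
#' @export
tidy.rep_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, dplyr::starts_with("PC"),
                      names_to = "component", values_to = "score")
}

#' One-row PCA summary
#'
#' @param x A `rep_pca`.
#' @param ... Unused.
#' @return Tibble with `n_rows`, `n_features`, `pc1_var`, `pc2_var`,
#'   `separation_stat`.
#' @export
glance.rep_pca <- function(x, ...) {
  tibble(n_rows = nrow(x$scores), n_features = nrow(x$loadings),
         pc1_var = x$explained_variance_ratio[1],
         pc2_var = x$explained_variance_ratio[2],
         separation_stat = x$separation_stat)
}

#' Tidy permutation-control results
#'
#' @param x A `rep_perm`.
#' @param ... Unused.
#' @return One row per permutation with its separation statistic.
#' @export
tidy.rep_perm <- function(x, ...) {
  tibble(permutation = seq_along(x$perm_stats), statistic = x$perm_stats)
}

#' One-row permutation-control summary
#'
#' @param x A `rep_perm`.
#' @param ... Unused.
#' @return Tibble with `observed`, `separation_p`, `n_perm`.
#' @export
glance.rep_perm <- function(x, ...) {
  tibble(observed = x$observed, separation_p = x$separation_p,
         n_perm = x$n_perm)
}

#' Tidy a dendrogram's pairwise merge structure
#'
#' @param x A `rep_dendro`.
#' @param ... Unused.
#' @return Tibble of merge steps with heights.
#' @export
tidy.rep_dendro <- function(x, ...) {
  hc <- x$hclust
  tibble(step = seq_along(hc$height), height = hc$height,
         left = hc$merge[, 1], right = hc$merge[, 2])
}
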