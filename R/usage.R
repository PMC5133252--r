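#' Per-donor gene or family usage frequencies
#'
#' Percent frequency of each gene (or gene family) among unique clonotypes
#' for every donor x subset cell, for one chain and segment. Keys absent
#' from a donor x subset cell are present with frequency 0, and the
#' clonotype denominator is recorded, so frequencies sum to 100 per cell.
#' Frequencies are computed over unique clonotypes, never raw reads: pass
#' the output of [cluster_duplicates()].
#'
#' @param clonotypes Clonotype tibble.
#' @param axis `"family"` (e.g. IGHV3) or `"gene"` (e.g. IGHV3-23).
#' @param chain Chain to tabulate (`"IGH"`, `"IGK"`, `"IGL"`).
#' @param segment Segment to tabulate (`"V"`, `"D"`, `"J"`).
#' @return A `usage_table` tibble: `donor_id`, `subset`, `key`, `n`,
#'   `frequency` (percent), `denominator`.
#' @export
usage_frequencies <- function(clonotypes, axis = c("family", "gene"),
                              chain = "IGH", segment = c("V", "D", "J")) {
  axis <- match.arg(axis)
  segment <- match.arg(segment)
  cl <- dplyr::filter(as_tibble(clonotypes), .data$chain == !!chain)
  call_col <- paste0(tolower(segment), "_call")
  fam_col <- paste0(tolower(segment), "_family")
  if (!fam_col %in% names(cl)) {
    cl[[fam_col]] <- parse_gene_names(cl[[call_col]])$family
  }
  cl$key <- if (axis == "family") {
    paste0(chain, segment, cl[[fam_col]])
  } else {
    cl[[call_col]]
  }
  cl <- dplyr::filter(cl, !is.na(.data[[fam_col]]))
  tally_usage(cl, axis = axis, chain = chain, segment = segment)
}

tally_usage <- function(cl, axis, chain, segment = NULL) {
  counts <- dplyr::count(cl, .data$donor_id, .data$subset, .data$key)
  counts <- tidyr::complete(
    dplyr::group_by(counts, .data$donor_id, .data$subset),
    key = unique(cl$key), fill = list(n = 0L))
  counts <- dplyr::ungroup(counts)
  denom <- dplyr::count(cl, .data$donor_id, .data$subset, name = "denominator")
  out <- dplyr::inner_join(counts, denom, by = c("donor_id", "subset"))
  out$frequency <- 100 * out$n / out$denominator
  out <- dplyr::arrange(out, .data$donor_id, .data$subset, .data$key)
  structure(out, class = c("usage_table", class(out)),
            axis = axis, chain = chain, segment = segment)
}

#' Family-combination usage tensor
#'
#' Percent frequency of each VDJ (heavy chain) or VJ (light chain) family
#' combination among unique clonotypes, per donor x subset, plus
#' across-donor mean frequencies for bubble plotting.
#'
#' @inheritParams usage_frequencies
#' @return A list with `table` (a `usage_table` with key columns
#'   `v_fam`/`d_fam`/`j_fam` and combination `key`) and `means`
#'   (per subset x key mean frequency across donors).
#' @export
combination_tensor <- function(clonotypes, chain = "IGH") {
  cl <- dplyr::filter(as_tibble(clonotypes), .data$chain == !!chain)
  for (seg in c("v", "d", "j")) {
    fam_col <- paste0(seg, "_family")
    if (!fam_col %in% names(cl)) {
      cl[[fam_col]] <- parse_gene_names(cl[[paste0(seg, "_call")]])$family
    }
  }
  heavy <- chain == "IGH"
  cl <- dplyr::filter(cl, !is.na(.data$v_family), !is.na(.data$j_family))
  if (heavy) cl <- dplyr::filter(cl, !is.na(.data$d_family))
  cl$key <- if (heavy) {
    paste0("V", cl$v_family, "-D", cl$d_family, "-J", cl$j_family)
  } else {
    paste0("V", cl$v_family, "-J", cl$j_family)
  }
  tab <- tally_usage(cl, axis = "family_combination", chain = chain)
  keyparts <- stringr::str_match(tab$key, "^V(\\d+)(?:-D(\\d+))?-J(\\d+)$")
  tab$v_fam <- as.integer(keyparts[, 2])
  tab$d_fam <- as.integer(keyparts[, 3])
  tab$j_fam <- as.integer(keyparts[, 4])
  means <- dplyr::summarise(
    dplyr::group_by(as_tibble(tab), .data$subset, .data$key,
                    .data$v_fam, .data$d_fam, .data$j_fam),
    mean_frequency = mean(.data$frequency), .groups = "drop")
  list(table = tab, means = means)
}

# Holm-Sidak step-down adjustment (the multiple-comparison convention of
# the common graphing software); BH available via p.adjust
adjust_p <- function(p, method = c("holm_sidak", "bh", "none")) {
  method <- match.arg(method)
  if (method == "bh") return(stats::p.adjust(p, "BH"))
  if (method == "none") return(p)
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

#' Compare usage frequencies between subsets
#'
#' Univariate comparisons of per-donor usage frequencies between cell
#' subsets. The default `"anova"` method fits a two-way ANOVA (subset x
#' key) on the per-donor frequencies and performs per-key post-hoc subset
#' contrasts using the pooled residual error, Holm--Sidak adjusted across
#' keys within each subset pair. The `"wilcoxon"` method runs a paired
#' Wilcoxon signed-rank test when the two subsets share the same donors
#' (matched bone-marrow/blood sampling) and a Mann--Whitney test
#' otherwise.
#'
#' @param table A `usage_table` from [usage_frequencies()].
#' @param comparisons List of 2-vectors of subset names; default all pairs
#'   present.
#' @param method `"anova"` (default) or `"wilcoxon"`.
#' @param adjust Multiplicity correction across keys: `"holm_sidak"`
#'   (default), `"bh"` or `"none"`.
#' @return Tibble with one row per key x comparison: `key`, `group1`,
#'   `group2`, `statistic`, `raw_p`, `adjusted_p`, `method`, `effect`
#'   (mean(group2) - mean(group1), percentage points), `n1`, `n2`, `note`.
#' @export
compare_usage <- function(table, comparisons = NULL,
                          method = c("anova", "wilcoxon"),
                          adjust = c("holm_sidak", "bh", "none")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  tab <- as_tibble(table)
  subsets <- intersect(subset_levels(), unique(tab$subset))
  if (is.null(comparisons)) {
    comparisons <- utils::combn(subsets, 2L, simplify = FALSE)
  }
  tab$subset <- factor(tab$subset, levels = subsets)
  tab$key <- factor(tab$key)

  mse <- NA_real_; dfe <- NA_integer_
  if (method == "anova") {
    form <- if (nlevels(tab$key) > 1L) frequency ~ subset * key
            else frequency ~ subset
    fit <- tryCatch(stats::aov(form, data = tab), error = function(e) NULL)
    if (!is.null(fit)) {
      ms <- summary(fit)[[1]]
      mse <- ms["Residuals", "Mean Sq"]
      dfe <- ms["Residuals", "Df"]
    }
  }

  rows <- list()
  for (cmp in comparisons) {
    g1 <- cmp[1]; g2 <- cmp[2]
    res <- purrr::map_dfr(levels(tab$key), function(k) {
      d1 <- dplyr::filter(tab, .data$key == k, .data$subset == g1)
      d2 <- dplyr::filter(tab, .data$key == k, .data$subset == g2)
      n1 <- nrow(d1); n2 <- nrow(d2)
      eff <- mean(d2$frequency) - mean(d1$frequency)
      note <- if (n1 < 2L || n2 < 2L) "insufficient_replication" else ""
      if (note != "") {
        return(tibble(key = k, group1 = g1, group2 = g2,
                      statistic = NA_real_, raw_p = NA_real_,
                      method = method, effect = eff, n1 = n1, n2 = n2,
                      note = note))
      }
      if (method == "anova" && (is.na(mse) || is.na(dfe) || dfe < 1L)) {
        # pooled error inestimable (e.g. saturated design): Welch fallback
        tt <- tryCatch(stats::t.test(d2$frequency, d1$frequency),
                       error = function(e) NULL)
        stat <- if (is.null(tt)) NA_real_ else unname(tt$statistic)
        p <- if (is.null(tt)) NA_real_ else tt$p.value
        mname <- "welch_t"
      } else if (method == "anova") {
        se <- sqrt(mse * (1 / n1 + 1 / n2))
        if (se < 1e-12) {
          stat <- 0
          p <- if (abs(eff) < 1e-9) 1 else .Machine$double.xmin
        } else {
          stat <- eff / se
          p <- 2 * stats::pt(-abs(stat), dfe)
        }
        mname <- "anova_posthoc_t"
      } else {
        paired <- n1 == n2 && setequal(d1$donor_id, d2$donor_id)
        if (paired) {
          d2 <- d2[match(d1$donor_id, d2$donor_id), , drop = FALSE]
          wt <- suppressWarnings(
            stats::wilcox.test(d2$frequency, d1$frequency, paired = TRUE))
          mname <- "wilcoxon_paired"
        } else {
          wt <- suppressWarnings(
            stats::wilcox.test(d2$frequency, d1$frequency))
          mname <- "mann_whitney"
        }
        stat <- unname(wt$statistic)
        p <- if (is.na(wt$p.value)) 1 else wt$p.value
      }
      tibble(key = k, group1 = g1, group2 = g2, statistic = stat,
             raw_p = p, method = mname, effect = eff, n1 = n1, n2 = n2,
             note = "")
    })
    ok <- !is.na(res$raw_p)
    res$adjusted_p <- NA_real_
    res$adjusted_p[ok] <- adjust_p(res$raw_p[ok], adjust)
    rows[[length(rows) + 1L]] <- res
  }
  out <- dplyr::bind_rows(rows)
  dplyr::relocate(out, "adjusted_p", .after = "raw_p")
}

#' Mixed-model likelihood-ratio test for a CDR3 property
#'
#' Fits a Gaussian random-intercept model for one physicochemical property
#' with cell subset as the fixed effect and donor as the random effect,
#' by maximum likelihood (ML rather than REML, as required for a
#' likelihood-ratio test on a fixed effect):
#' `property ~ subset + (1 | donor)` against the null
#' `property ~ 1 + (1 | donor)`. The LRT statistic 2(l1 - l0) is referred
#' to a chi-square with (number of subsets - 1) degrees of freedom.
#'
#' @param data Property table (e.g. from [property_table()]) with columns
#'   for the property, `subset` and `donor_id`.
#' @param property Name of the property column to test.
#' @param subsets Optional subset pair/vector to restrict the comparison.
#' @return One-row tibble: `property`, `statistic`, `df`, `raw_p`,
#'   `adjusted_p` (= raw here), `method`, `effect` (range of subset
#'   means), `converged`, `note`.
#' @export
mixed_model_lrt <- function(data, property, subsets = NULL) {
  data <- as_tibble(data)
  stopifnot(property %in% names(data))
  if (!is.null(subsets)) data <- dplyr::filter(data, .data$subset %in% subsets)
  data <- data[stats::complete.cases(data[, c(property, "subset", "donor_id")]), ]
  y <- data[[property]]
  k <- length(unique(data$subset))
  if (k < 2L) stop("mixed_model_lrt: need at least 2 subsets")
  means <- tapply(y, data$subset, mean)
  eff <- diff(range(means))
  if (stats::var(y) == 0) {
    return(tibble(property = property, statistic = 0, df = k - 1L,
                  raw_p = 1, adjusted_p = 1, method = "lrt_chisq",
                  effect = 0, converged = TRUE, note = "zero_variance"))
  }
  d <- data.frame(y = y, subset = factor(data$subset),
                  donor_id = factor(data$donor_id))
  note <- ""
  fits <- withCallingHandlers({
    full <- lme4::lmer(y ~ subset + (1 | donor_id), data = d, REML = FALSE)
    null <- lme4::lmer(y ~ 1 + (1 | donor_id), data = d, REML = FALSE)
    list(full = full, null = null)
  }, warning = function(w) {
    note <<- paste0(note, if (nzchar(note)) "; ", conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  stat <- max(0, 2 * (as.numeric(stats::logLik(fits$full)) -
                      as.numeric(stats::logLik(fits$null))))
  df <- k - 1L
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  conv <- !grepl("converge", note, ignore.case = TRUE)
  tibble(property = property, statistic = stat, df = df, raw_p = p,
         adjusted_p = p, method = "lrt_chisq", effect = eff,
         converged = conv, note = note)
}
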