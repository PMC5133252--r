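two_subset_clonotypes <- function(freq_by_subset, n = 40,
                                  donors = c("D01", "D02")) {
  # freq_by_subset: named list subset -> named vector of v_call proportions
  rows <- list()
  for (d in donors) for (s in names(freq_by_subset)) {
    p <- freq_by_subset[[s]]
    calls <- rep(names(p), round(p * n))
    r <- make_rearrangements(strrep("GCT", 12 + seq_along(calls) %% 3),
                             donor_id = d, subset = s)
    r$v_call <- calls
    r$sequence_id <- paste(d, s, seq_along(calls), sep = "_")
    rows[[length(rows) + 1L]] <- r
  }
  dplyr::bind_rows(rows)
}

test_that("usage frequencies tally clonotypes per donor and subset", {
  cl <- make_rearrangements(strrep("GCT", 10:13))
  cl$v_call <- c("IGHV3-23", "IGHV3-30", "IGHV1-69", "IGHV4-34")
  u <- usage_frequencies(cl, "family", "IGH", "V")
  expect_equal(u$frequency[u$key == "IGHV3"], 50)
  expect_equal(u$frequency[u$key == "IGHV1"], 25)
  expect_equal(sum(u$frequency), 100)
  single <- usage_frequencies(cl[1, ], "family", "IGH", "V")
  expect_equal(single$frequency, 100)
})

test_that("usage frequencies match a manual tally on a mixed fixture", {
  set.seed(3)
  calls <- sample(c("IGHV3-23", "IGHV3-7", "IGHV1-2", "IGHV5-51"), 20,
                  replace = TRUE, prob = c(0.4, 0.2, 0.3, 0.1))
  cl <- make_rearrangements(strrep("GCT", 10 + seq_along(calls) %% 4))
  cl$v_call <- calls
  u <- usage_frequencies(cl, "family", "IGH", "V")
  fam <- sub("^IGHV(\\d).*", "IGHV\\1", calls)
  for (k in unique(u$key)) {
    expect_equal(u$frequency[u$key == k], 100 * sum(fam == k) / 20)
  }
  # gene axis
  ug <- usage_frequencies(cl, "gene", "IGH", "V")
  expect_equal(ug$frequency[ug$key == "IGHV3-23"],
               100 * sum(calls == "IGHV3-23") / 20)
})

test_that("frequencies sum to 100 per donor x subset on simulated data", {
  sim <- simulate_repertoire(
    simulation_config(n_donors = 3, clonotypes_per_subset = 120,
                      pcr_copies_mean = 1, error_rate_sub = 0,
                      error_rate_indel = 0, seed = 2),
    chains = c("IGH", "IGK"))
  reads <- suppressMessages(normalize_rearrangements(sim$reads))
  cl <- cluster_duplicates(apply_filters(reads, stage = "gene_stage")$kept)
  for (seg in c("V", "D", "J")) {
    u <- usage_frequencies(cl, "family", "IGH", seg)
    sums <- tapply(u$frequency, paste(u$donor_id, u$subset), sum)
    expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-9)
  }
})

test_that("the combination tensor marginalizes to V-family usage", {
  sim <- simulate_repertoire(
    simulation_config(n_donors = 2, clonotypes_per_subset = 150,
                      pcr_copies_mean = 1, error_rate_sub = 0,
                      error_rate_indel = 0, seed = 8))
  reads <- suppressMessages(normalize_rearrangements(sim$reads))
  cl <- cluster_duplicates(apply_filters(reads, stage = "gene_stage")$kept)
  combo <- combination_tensor(cl, "IGH")
  u <- usage_frequencies(cl, "family", "IGH", "V")
  marg <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(combo$table), donor_id, subset, v_fam),
    frequency = sum(frequency), .groups = "drop")
  joined <- dplyr::inner_join(
    marg, dplyr::mutate(u, v_fam = as.integer(sub("IGHV", "", key))),
    by = c("donor_id", "subset", "v_fam"))
  expect_gt(nrow(joined), 0)
  expect_equal(joined$frequency.x, joined$frequency.y, tolerance = 1e-9)
  # single-combination degenerate case
  cl1 <- make_rearrangements(rep("GCTGCTGCTGCT", 3))
  combo1 <- combination_tensor(cl1, "IGH")
  expect_equal(combo1$table$frequency, 100)
})

test_that("identical groups give adjusted p near 1 and planted shifts are caught", {
  null_freqs <- list(
    preB = c("IGHV3-23" = 0.5, "IGHV1-2" = 0.3, "IGHV4-4" = 0.2),
    naive = c("IGHV3-23" = 0.5, "IGHV1-2" = 0.3, "IGHV4-4" = 0.2))
  u0 <- usage_frequencies(two_subset_clonotypes(null_freqs), "family", "IGH", "V")
  res0 <- compare_usage(u0)
  expect_true(all(res0$adjusted_p >= 0.99))
  expect_equal(res0$effect, rep(0, nrow(res0)))

  shift <- list(
    preB = c("IGHV3-23" = 0.5, "IGHV1-2" = 0.3, "IGHV4-4" = 0.2),
    naive = c("IGHV3-23" = 0.3, "IGHV1-2" = 0.5, "IGHV4-4" = 0.2))
  donors <- sprintf("D%02d", 1:8)
  set.seed(12)
  cl <- two_subset_clonotypes(shift, n = 40, donors = donors)
  # jitter: drop a few clonotypes at random so donors differ slightly
  cl <- cl[-sample(nrow(cl), 25), ]
  u <- usage_frequencies(cl, "family", "IGH", "V")
  res <- compare_usage(u)
  v3 <- res[res$key == "IGHV3", ]
  expect_lt(v3$adjusted_p, 0.05)
  expect_lt(v3$effect, 0)   # effect = mean(naive) - mean(preB) < 0
  expect_true(all(res$adjusted_p >= res$raw_p - 1e-12, na.rm = TRUE))
})

test_that("wilcoxon route pairs donors when subsets share them", {
  shift <- list(
    preB = c("IGHV3-23" = 0.6, "IGHV1-2" = 0.4),
    naive = c("IGHV3-23" = 0.3, "IGHV1-2" = 0.7))
  donors <- sprintf("D%02d", 1:6)
  set.seed(4)
  cl <- two_subset_clonotypes(shift, n = 30, donors = donors)
  cl <- cl[-sample(nrow(cl), 15), ]
  u <- usage_frequencies(cl, "family", "IGH", "V")
  res <- compare_usage(u, method = "wilcoxon")
  expect_true(all(res$method == "wilcoxon_paired"))
  # unpaired when donor sets differ
  cl2 <- cl
  cl2$donor_id[cl2$subset == "naive"] <-
    sub("D0", "X0", cl2$donor_id[cl2$subset == "naive"])
  u2 <- usage_frequencies(cl2, "family", "IGH", "V")
  res2 <- compare_usage(u2, method = "wilcoxon")
  expect_true(all(res2$method == "mann_whitney"))
})

test_that("too few donors flags insufficient replication", {
  freqs <- list(preB = c("IGHV3-23" = 1), naive = c("IGHV3-23" = 1))
  cl <- two_subset_clonotypes(freqs, n = 5, donors = "D01")
  u <- usage_frequencies(cl, "family", "IGH", "V")
  res <- compare_usage(u)
  expect_true(all(res$note == "insufficient_replication"))
  expect_true(all(is.na(res$raw_p)))
})

test_that("Holm-Sidak adjustment is monotone and bounded", {
  p <- c(0.001, 0.04, 0.2, 0.8, 0.012)
  adj <- bcrdev:::adjust_p(p, "holm_sidak")
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_equal(order(adj), order(p))
  # single test: Sidak with m=1 is the identity
  expect_equal(bcrdev:::adjust_p(0.03, "holm_sidak"), 0.03)
})

test_that("mixed-model LRT detects a planted subset effect and not a null", {
  set.seed(77)
  donors <- sprintf("D%02d", 1:8)
  make_props <- function(delta) {
    dplyr::bind_rows(lapply(donors, function(d) {
      u <- rnorm(1, 0, 0.3)   # donor random intercept
      tibble::tibble(
        donor_id = d,
        subset = rep(c("preB", "naive"), each = 60),
        length = c(rnorm(60, 15 + u), rnorm(60, 15 + u + delta)))
    }))
  }
  alt <- mixed_model_lrt(make_props(1), "length")
  expect_lt(alt$raw_p, 1e-6)
  expect_true(alt$converged)
  null <- mixed_model_lrt(make_props(0), "length")
  expect_gt(null$raw_p, 0.01)
  expect_equal(null$df, 1L)
})

test_that("zero-variance response yields a zero LRT statistic", {
  d <- tibble::tibble(donor_id = rep(c("D01", "D02", "D03"), each = 10),
                      subset = rep(c("preB", "naive"), 15),
                      length = 12)
  res <- mixed_model_lrt(d, "length")
  expect_equal(res$statistic, 0)
  expect_equal(res$raw_p, 1)
})

test_that("ML fit matches a brute-force profile-likelihood grid", {
  set.seed(55)
  donor <- factor(rep(sprintf("D%02d", 1:5), each = 10))
  subset <- factor(rep(rep(c("preB", "naive"), each = 5), 5))
  y <- 10 + 0.8 * (subset == "naive") +
    rnorm(5, 0, 0.6)[as.integer(donor)] + rnorm(50, 0, 0.9)
  d <- tibble::tibble(donor_id = donor, subset = subset, length = y)
  fit <- lme4::lmer(length ~ subset + (1 | donor_id), data = d, REML = FALSE)
  oracle <- oracle_lmm_loglik(y, subset, donor)
  expect_equal(as.numeric(logLik(fit)), oracle, tolerance = 1e-3)
})
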