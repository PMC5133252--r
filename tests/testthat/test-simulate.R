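test_that("the germline bundle has the expected structure and anchors", {
  b <- germline_bundle()
  expect_gte(sum(b$locus == "IGH" & b$segment == "V"), 25L)
  expect_gte(sum(b$locus == "IGH" & b$segment == "D"), 10L)
  expect_equal(sum(b$locus == "IGH" & b$segment == "J"), 6L)
  v <- b[b$segment == "V", ]
  # every V carries the in-frame conserved Cys codon before its head
  expect_true(all(substr(v$sequence, nchar(v$stem) + 1,
                         nchar(v$stem) + 3) == "TGT"))
  expect_true(all(nchar(v$stem) %% 3 == 0))
  j <- b[b$segment == "J", ]
  anchor <- substr(j$sequence, nchar(j$tail) + 1, nchar(j$tail) + 3)
  expect_true(all(anchor == ifelse(j$locus == "IGH", "TGG", "TTT")))
})

test_that("bundle regeneration under the same seed is bit-identical", {
  b1 <- build_germline_bundle(1L)
  b2 <- build_germline_bundle(1L)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  # and matches the checked-in copy
  shipped <- germline_bundle()
  expect_equal(as.data.frame(b1), as.data.frame(tibble::as_tibble(shipped)))
  b3 <- build_germline_bundle(2L)
  expect_false(identical(b1$sequence, b3$sequence))
})

test_that("default profiles are normalized and encode the printed shifts", {
  profs <- default_profiles()
  for (p in profs) {
    expect_equal(sum(p$v_family_freqs), 1, tolerance = 1e-9)
    expect_equal(sum(p$j_family_freqs), 1, tolerance = 1e-9)
    if (!is.null(p$d_family_freqs)) {
      expect_equal(sum(p$d_family_freqs), 1, tolerance = 1e-9)
    }
    expect_true(all(p$v_family_freqs >= 0))
  }
  g <- function(chain, s) profs[[paste0(chain, "_", s)]]
  # IGHV3 drops 14 points from bone marrow to naive (> 13 reported)
  expect_equal(g("IGH", "preB")$v_family_freqs[["3"]] -
                 g("IGH", "naive")$v_family_freqs[["3"]], 0.14)
  expect_equal(g("IGH", "preB")$v_family_freqs,
               g("IGH", "immature")$v_family_freqs)
  # IGHJ6 is 9.5 points higher in transitional cells (> 9 reported)
  expect_equal(g("IGH", "transitional")$j_family_freqs[["6"]] -
                 g("IGH", "preB")$j_family_freqs[["6"]], 0.095)
  # and decreased in naive cells
  expect_lt(g("IGH", "naive")$j_family_freqs[["6"]],
            g("IGH", "preB")$j_family_freqs[["6"]])
  # IGHD2 falls 7 points in the peripheral subsets (> 6 reported)
  expect_equal(g("IGH", "preB")$d_family_freqs[["2"]] -
                 g("IGH", "naive")$d_family_freqs[["2"]], 0.07)
  expect_equal(g("IGH", "transitional")$d_family_freqs[["2"]],
               g("IGH", "naive")$d_family_freqs[["2"]])
  # IGHD3 is raised in transitional cells only
  d3_others <- c(g("IGH", "preB")$d_family_freqs[["3"]],
                 g("IGH", "immature")$d_family_freqs[["3"]],
                 g("IGH", "naive")$d_family_freqs[["3"]])
  expect_equal(g("IGH", "transitional")$d_family_freqs[["3"]] -
                 mean(d3_others), 0.055)
  # IGLV2 rises 12 points after the immature stage (10-15 reported)
  expect_equal(g("IGL", "naive")$v_family_freqs[["2"]] -
                 g("IGL", "immature")$v_family_freqs[["2"]], 0.12)
  # IGLJ1 rises at the expense of IGLJ3 (2-5 reported)
  dj1 <- g("IGL", "naive")$j_family_freqs[["1"]] -
    g("IGL", "immature")$j_family_freqs[["1"]]
  expect_gte(dj1, 0.02); expect_lte(dj1, 0.05)
  expect_lt(g("IGL", "naive")$j_family_freqs[["3"]],
            g("IGL", "immature")$j_family_freqs[["3"]])
  # kappa is flat across subsets
  expect_equal(g("IGK", "immature")$v_family_freqs,
               g("IGK", "naive")$v_family_freqs)
  # heavy CDR3 mean length shrinks from pre-B to naive
  lens <- vapply(subset_levels(), function(s) g("IGH", s)$cdr3_len_mean, 1)
  expect_true(all(diff(lens) < 0))
})

test_that("a noise-free simulation is the identity under dedup", {
  cfg <- simulation_config(n_donors = 2, clonotypes_per_subset = 100,
                           pcr_copies_mean = 1, error_rate_sub = 0,
                           error_rate_indel = 0, seed = 5)
  sim <- simulate_repertoire(cfg, chains = "IGH")
  expect_equal(nrow(sim$reads), nrow(sim$clonotypes))
  expect_equal(nrow(sim$clonotypes), 2 * 4 * 100)
  reads <- suppressMessages(normalize_rearrangements(sim$reads))
  expect_true(all(reads$flag_reason == ""))
  cl <- cluster_duplicates(apply_filters(reads, stage = "gene_stage")$kept,
                           threshold = 0)
  # no two same-key clonotypes share a CDR3 at this scale under seed 5
  expect_equal(nrow(cl), nrow(sim$clonotypes))
})

test_that("reads carry consistent junctions, translations and truth links", {
  sim <- simulate_repertoire(
    simulation_config(n_donors = 2, clonotypes_per_subset = 80, seed = 6),
    chains = c("IGH", "IGK", "IGL"))
  reads <- sim$reads
  expect_true(all(reads$clone_id %in% sim$clonotypes$clone_id))
  clean <- reads$n_errors == 0   # errors may hit the anchor codons
  expect_true(all(startsWith(reads$junction[clean], "TGT")))
  heavy <- reads$chain == "IGH"
  expect_true(all(is.na(reads$d_call[!heavy])))
  expect_true(all(!is.na(reads$d_call[heavy])))
  prod <- reads$productive
  expect_true(all(nchar(reads$junction[prod]) %% 3 == 0))
  aa <- reads$junction_aa[prod & clean]
  expect_true(all(startsWith(aa, "C")))
  expect_true(all(substr(aa, nchar(aa), nchar(aa)) %in% c("W", "F")))
  aa <- reads$junction_aa[prod]
  expect_false(any(grepl("*", aa, fixed = TRUE)))
  # unproductive reads have no junction translation
  expect_true(all(reads$junction_aa[!prod] == ""))
  # roughly two-thirds of error-free reads are productive
  expect_gt(mean(reads$productive[clean]), 0.60)
  expect_lt(mean(reads$productive[clean]), 0.73)
})

test_that("empirical family frequencies track the profile probabilities", {
  sim <- simulate_repertoire(
    simulation_config(n_donors = 1, clonotypes_per_subset = 10000,
                      pcr_copies_mean = 1, error_rate_sub = 0,
                      error_rate_indel = 0, seed = 1),
    profiles = Filter(function(p) p$subset == "preB", default_profiles()),
    chains = "IGH")
  fam <- parse_gene_names(sim$clonotypes$v_call)$family
  emp <- 100 * mean(fam == 3L)
  expect_lt(abs(emp - 55), 1.5)   # binomial bound at n = 10,000
})

test_that("simulation output is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_donors = 2, clonotypes_per_subset = 60, seed = 33)
  s1 <- simulate_repertoire(cfg, chains = c("IGH", "IGL"))
  s2 <- simulate_repertoire(cfg, chains = c("IGH", "IGL"))
  expect_identical(as.data.frame(s1$reads), as.data.frame(s2$reads))
  expect_identical(as.data.frame(s1$clonotypes), as.data.frame(s2$clonotypes))
  s3 <- simulate_repertoire(simulation_config(n_donors = 2,
                                              clonotypes_per_subset = 60,
                                              seed = 34),
                            chains = c("IGH", "IGL"))
  expect_false(identical(s1$reads$junction, s3$reads$junction))
})

test_that("older donors show an attenuated CDR3 length decline", {
  profs <- Filter(function(p) p$chain == "IGH", default_profiles())
  young <- simulation_config(n_donors = 2, donor_ages = c(25, 30),
                             clonotypes_per_subset = 1500,
                             pcr_copies_mean = 1, error_rate_sub = 0,
                             error_rate_indel = 0, seed = 10)
  old <- simulation_config(n_donors = 2, donor_ages = c(75, 85),
                           clonotypes_per_subset = 1500,
                           pcr_copies_mean = 1, error_rate_sub = 0,
                           error_rate_indel = 0, seed = 10)
  decline <- function(sim) {
    cl <- sim$clonotypes[sim$clonotypes$productive, ]
    len <- nchar(cl$cdr3_nt) / 3
    mean(len[cl$subset == "preB"]) - mean(len[cl$subset == "naive"])
  }
  sy <- simulate_repertoire(young, profiles = profs, chains = "IGH")
  so <- simulate_repertoire(old, profiles = profs, chains = "IGH")
  expect_gt(decline(sy), decline(so))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(error_rate_sub = 0.2))
  expect_error(simulation_config(pcr_copies_mean = 0.5))
  expect_error(simulate_repertoire(simulation_config(n_donors = 1),
                                   profiles = list(), chains = "IGH"),
               "no profiles")
})
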