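NT <- c("A", "C", "G", "T")
stop_codons <- c("TAA", "TAG", "TGA")
all_codons <- as.vector(outer(as.vector(outer(NT, NT, paste0)), NT, paste0))
sense_codons <- setdiff(all_codons, stop_codons)

rand_nt <- function(lengths) {
  total <- sum(lengths)
  if (total == 0L) return(rep("", length(lengths)))
  chars <- sample(NT, total, replace = TRUE)
  out <- rep("", length(lengths))
  pos <- lengths > 0L
  out[pos] <- vapply(split(chars, rep(seq_along(lengths), lengths)),
                     paste, "", collapse = "")
  out
}

rand_orf <- function(n_codons) {
  paste(sample(sense_codons, n_codons, replace = TRUE), collapse = "")
}

germline_gene_plan <- function() {
  list(
    IGH = list(
      V = c("IGHV1-2", "IGHV1-18", "IGHV1-24", "IGHV1-46", "IGHV1-69",
            "IGHV2-5", "IGHV2-26", "IGHV2-70",
            "IGHV3-7", "IGHV3-9", "IGHV3-11", "IGHV3-15", "IGHV3-21",
            "IGHV3-23", "IGHV3-30", "IGHV3-33", "IGHV3-48", "IGHV3-53",
            "IGHV4-4", "IGHV4-31", "IGHV4-34", "IGHV4-39", "IGHV4-59",
            "IGHV5-51", "IGHV6-1", "IGHV7-4"),
      D = c("IGHD1-1", "IGHD1-7", "IGHD1-26",
            "IGHD2-2", "IGHD2-8", "IGHD2-15", "IGHD2-21",
            "IGHD3-3", "IGHD3-9", "IGHD3-10", "IGHD3-22",
            "IGHD4-17", "IGHD4-23", "IGHD5-12", "IGHD6-13", "IGHD6-19",
            "IGHD7-27"),
      J = paste0("IGHJ", 1:6)),
    IGK = list(
      V = c("IGKV1-5", "IGKV1-9", "IGKV1-33", "IGKV1-39",
            "IGKV2-28", "IGKV2-30", "IGKV3-11", "IGKV3-15", "IGKV3-20",
            "IGKV4-1", "IGKV5-2", "IGKV6-21", "IGKV7-3"),
      J = paste0("IGKJ", 1:5)),
    IGL = list(
      V = c("IGLV1-40", "IGLV1-44", "IGLV1-47", "IGLV1-51",
            "IGLV2-8", "IGLV2-11", "IGLV2-14", "IGLV2-23",
            "IGLV3-1", "IGLV3-19", "IGLV3-21", "IGLV3-25",
            "IGLV4-69", "IGLV5-45", "IGLV6-57", "IGLV7-43", "IGLV7-46",
            "IGLV8-61"),
      J = paste0("IGLJ", c(1, 2, 3, 7))))
}

#' Build the synthetic germline gene bundle
#'
#' Deterministically generates a synthetic germline segment set covering
#' the V, D and J genes analysed in early B-cell repertoires. Every V
#' sequence ends with an in-frame conserved Cys codon (TGT) followed by
#' its CDR3 head region, and every J carries the conserved Trp (heavy) or
#' Phe (light) anchor followed by a Gly-rich stem, so CDR3 extraction is
#' well defined. The sequences are synthetic stand-ins generated from the
#' seed, not the true human germline alleles; only the gene names and
#' family structure mirror the locus.
#'
#' @param seed Integer seed; regeneration with the same seed is
#'   bit-identical.
#' @return A `germline_bundle`: tibble with `gene_label`, `locus`,
#'   `segment`, `family`, region sequences (`stem`, `head`, `core`,
#'   `tail`) and the assembled `sequence`, plus a `version` attribute.
#' @export
build_germline_bundle <- function(seed = 1L) {
  plan <- germline_gene_plan()
  withr::with_seed(seed, {
    rows <- list()
    for (locus in names(plan)) {
      for (segment in names(plan[[locus]])) {
        genes <- plan[[locus]][[segment]]
        fam <- parse_gene_names(genes)$family
        for (i in seq_along(genes)) {
          if (segment == "V") {
            stem <- rand_orf(18L)
            head <- rand_nt(sample(6:12, 1L))
            core <- ""
            tail <- ""
            sequence <- paste0(stem, "TGT", head)
          } else if (segment == "D") {
            stem <- ""
            head <- ""
            core <- rand_nt(sample(12:24, 1L))
            tail <- ""
            sequence <- core
          } else {
            anchor <- if (locus == "IGH") "TGG" else "TTT"
            stem <- rand_orf(7L)
            head <- ""
            core <- ""
            tail <- rand_nt(sample(9:18, 1L))
            sequence <- paste0(tail, anchor, "GG", stem)
          }
          rows[[length(rows) + 1L]] <- tibble(
            gene_label = genes[i], locus = locus, segment = segment,
            family = fam[i], stem = stem, head = head, core = core,
            tail = tail, sequence = sequence)
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    structure(out, class = c("germline_bundle", class(out)),
              seed = seed, version = "germline-1.0")
  })
}

#' Load the checked-in germline bundle
#'
#' Reads the bundled germline table shipped under `extdata/germline/`
#' (generated by [build_germline_bundle()] with seed 1). Cached per
#' session.
#'
#' @return A `germline_bundle` tibble.
#' @export
germline_bundle <- function() {
  if (!is.null(the$germline)) return(the$germline)
  path <- system.file("extdata", "germline", "germline_genes.tsv",
                      package = "bcrdev")
  if (!nzchar(path)) stop("bundled germline table not found")
  g <- readr::read_tsv(path, col_types = "cccicccc", progress = FALSE,
                       na = character())
  the$germline <- structure(g, class = c("germline_bundle", class(g)),
                            seed = 1L, version = "germline-1.0")
  the$germline
}

#' Write a germline bundle to FASTA and TSV
#'
#' @param bundle A `germline_bundle`.
#' @param dir Output directory.
#' @return Paths of the files written, invisibly.
#' @export
write_germline_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "germline_genes.tsv")
  fasta <- file.path(dir, "germline_genes.fasta")
  write_table(as_tibble(bundle), tsv)
  seqs <- Biostrings::DNAStringSet(bundle$sequence)
  names(seqs) <- bundle$gene_label
  Biostrings::writeXStringSet(seqs, fasta, width = 70L)
  invisible(c(tsv, fasta))
}

new_subset_profile <- function(subset, chain, v, d = NULL, j,
                               cdr3_len_mean, cdr3_len_sd,
                               trim_mean = 2, n_insert_mean = 4) {
  for (m in Filter(Negate(is.null), list(v, d, j))) {
    stopifnot(abs(sum(m) - 1) < 1e-9, all(m >= 0))
  }
  structure(list(subset = subset, chain = chain,
                 v_family_freqs = v, d_family_freqs = d, j_family_freqs = j,
                 cdr3_len_mean = cdr3_len_mean, cdr3_len_sd = cdr3_len_sd,
                 trim_mean = trim_mean, n_insert_mean = n_insert_mean),
            class = "subset_profile")
}

# redistribute frequency mass proportionally over the families not named
# in `fixed`, so the map sums to 1 ("small changes in all other families
# to compensate")
reweight <- function(base, fixed) {
  out <- base
  out[names(fixed)] <- fixed
  rest <- setdiff(names(base), names(fixed))
  out[rest] <- base[rest] * (1 - sum(fixed)) / sum(base[rest])
  out
}

#' Default subset profiles
#'
#' The simulator's study conditions: gene-family frequency maps and CDR3
#' length statistics for every cell subset and chain. The baseline family
#' frequencies are artifact constructs (the source study reports only the
#' between-subset differences, not absolute baselines); the planted
#' between-subset deltas encode the reported repertoire shifts: IGHV3
#' falling 14 points from bone marrow to naive (a ">13%" decrease), IGHJ6
#' raised 9.5 points in transitional cells and lowered to 15% in naive,
#' IGHD2 falling 7 points in the peripheral subsets (">6%"), IGHD3 raised
#' 5.5 points in transitional cells only, a flat kappa repertoire, IGLV2
#' raised 12 points (within the reported 10--15%) and IGLJ1 raised 3.5
#' points at the expense of IGLJ3 (within 2--5%). Light-chain profiles
#' cover immature, transitional and naive cells (pre-B cells do not yet
#' express a light chain). Heavy-chain CDR3 mean lengths shrink from 16.0
#' (pre-B) to 15.0 (naive) amino acids.
#'
#' @return List of `subset_profile` objects covering IGH x 4 subsets and
#'   IGK/IGL x 3 subsets.
#' @export
default_profiles <- function() {
  profs <- list()
  # --- heavy chain ---
  v_base <- c("1" = 0.15, "2" = 0.03, "3" = 0.55, "4" = 0.12,
              "5" = 0.06, "6" = 0.05, "7" = 0.04)
  d_base <- c("1" = 0.18, "2" = 0.16, "3" = 0.25, "4" = 0.12,
              "5" = 0.10, "6" = 0.11, "7" = 0.08)
  j_base <- c("1" = 0.05, "2" = 0.05, "3" = 0.15, "4" = 0.40,
              "5" = 0.15, "6" = 0.20)
  igh_v <- list(preB = v_base, immature = v_base,
                transitional = reweight(v_base, c("3" = 0.48)),
                naive = reweight(v_base, c("3" = 0.41)))
  igh_d <- list(preB = d_base, immature = d_base,
                transitional = reweight(d_base, c("2" = 0.09, "3" = 0.305)),
                naive = reweight(d_base, c("2" = 0.09, "3" = 0.25)))
  j_trans <- reweight(j_base, c("6" = 0.295, "1" = 0.05, "2" = 0.05))
  igh_j <- list(preB = j_base, immature = j_base,
                transitional = j_trans,
                naive = reweight(j_base, c("6" = 0.15)))
  len_mean <- c(preB = 16.0, immature = 15.7, transitional = 15.4,
                naive = 15.0)
  for (s in subset_levels()) {
    profs[[paste0("IGH_", s)]] <- new_subset_profile(
      s, "IGH", v = igh_v[[s]], d = igh_d[[s]], j = igh_j[[s]],
      cdr3_len_mean = unname(len_mean[s]), cdr3_len_sd = 3.0)
  }
  # --- kappa: flat across subsets ---
  k_v <- c("1" = 0.30, "2" = 0.15, "3" = 0.30, "4" = 0.15,
           "5" = 0.04, "6" = 0.04, "7" = 0.02)
  k_j <- c("1" = 0.35, "2" = 0.25, "3" = 0.20, "4" = 0.12, "5" = 0.08)
  # --- lambda: IGLV2 and IGLJ1 rise after the immature stage ---
  l_v_base <- c("1" = 0.22, "2" = 0.25, "3" = 0.20, "4" = 0.08,
                "5" = 0.06, "6" = 0.05, "7" = 0.08, "8" = 0.06)
  l_j_base <- c("1" = 0.08, "2" = 0.30, "3" = 0.47, "7" = 0.15)
  l_v_late <- reweight(l_v_base, c("2" = 0.37))
  l_j_late <- c("1" = 0.115, "2" = 0.30, "3" = 0.435, "7" = 0.15)
  for (s in c("immature", "transitional", "naive")) {
    profs[[paste0("IGK_", s)]] <- new_subset_profile(
      s, "IGK", v = k_v, j = k_j, cdr3_len_mean = 9.7, cdr3_len_sd = 1.5)
    late <- s != "immature"
    profs[[paste0("IGL_", s)]] <- new_subset_profile(
      s, "IGL", v = if (late) l_v_late else l_v_base,
      j = if (late) l_j_late else l_j_base,
      cdr3_len_mean = 9.7, cdr3_len_sd = 1.5)
  }
  profs
}

#' Simulation configuration
#'
#' @param n_donors Number of donors.
#' @param donor_ages Donor ages in years; default evenly spans 24--86.
#' @param clonotypes_per_subset True clonotypes per donor x subset x
#'   chain.
#' @param pcr_copies_mean Mean reads per clonotype (>= 1); each clonotype
#'   is observed `1 + Poisson(pcr_copies_mean - 1)` times.
#' @param error_rate_sub Per-base substitution rate within the junction.
#' @param error_rate_indel Per-base indel rate within the junction.
#' @param seed Integer seed; identical configurations reproduce
#'   byte-identical output.
#' @param age_length_coupling Extra mean heavy-chain CDR3 length (amino
#'   acids) per decade of donor age past 50, applied in proportion to how
#'   far a subset's mean has declined from the pre-B value — so the
#'   pre-B-to-naive length decline is attenuated in older donors.
#' @param productive_fraction Fraction of clonotypes forced in-frame and
#'   stop-free.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_donors = 5L, donor_ages = NULL,
                              clonotypes_per_subset = 1000L,
                              pcr_copies_mean = 3, error_rate_sub = 0.002,
                              error_rate_indel = 0.0005, seed = 1L,
                              age_length_coupling = 0.25,
                              productive_fraction = 2 / 3) {
  if (is.null(donor_ages)) {
    donor_ages <- round(seq(24, 86, length.out = n_donors))
  }
  stopifnot(length(donor_ages) == n_donors, pcr_copies_mean >= 1,
            error_rate_sub >= 0, error_rate_sub <= 0.05,
            error_rate_indel >= 0, error_rate_indel <= 0.05)
  structure(list(n_donors = as.integer(n_donors), donor_ages = donor_ages,
                 clonotypes_per_subset = as.integer(clonotypes_per_subset),
                 pcr_copies_mean = pcr_copies_mean,
                 error_rate_sub = error_rate_sub,
                 error_rate_indel = error_rate_indel,
                 seed = as.integer(seed),
                 age_length_coupling = age_length_coupling,
                 productive_fraction = productive_fraction),
            class = "sim_config")
}

# repair in-frame stop codons deterministically (TAA->CAA, TAG->CAG,
# TGA->GGA) so forced-productive junctions translate cleanly
repair_stops <- function(s) {
  n <- nchar(s)
  cod <- substring(s, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  cod[cod == "TAA"] <- "CAA"
  cod[cod == "TAG"] <- "CAG"
  cod[cod == "TGA"] <- "GGA"
  paste(cod, collapse = "")
}

sample_families <- function(freqs, n) {
  fams <- as.integer(names(freqs))
  fams[sample.int(length(fams), n, replace = TRUE, prob = freqs)]
}

# pick a gene uniformly within each sampled family
sample_genes <- function(fams, genes_by_family) {
  out <- integer(length(fams))
  for (f in unique(fams)) {
    rows <- which(fams == f)
    g <- genes_by_family[[as.character(f)]]
    out[rows] <- g[sample.int(length(g), length(rows), replace = TRUE)]
  }
  out
}

#' Simulate an annotated repertoire with ground truth
#'
#' Generates reads emulating the statistical structure of early B-cell
#' repertoires: per clonotype, V/(D)/J segments are sampled by family
#' frequency then uniformly within family; segment junction ends are
#' trimmed geometrically; non-templated N nucleotides fill the junction to
#' a CDR3 length drawn per subset; a configurable fraction of clonotypes
#' is forced in-frame and stop-free (productive); and each clonotype is
#' then expanded into `1 + Poisson(pcr_copies_mean - 1)` reads carrying
#' per-base substitution and indel errors within the junction.
#' Productivity and junction translation are re-derived per read from the
#' observed (error-bearing) sequence, as an annotation pipeline would.
#'
#' @param cfg A [simulation_config()].
#' @param profiles List of subset profiles, default [default_profiles()].
#' @param chains Chains to simulate (default `"IGH"`).
#' @param bundle Germline bundle, default the checked-in one.
#' @return A list: `reads` (AIRR-style tibble with truth columns
#'   `clone_id` and `n_errors`), `clonotypes` (true clonotype table),
#'   `config` and `profiles` echoes.
#' @export
simulate_repertoire <- function(cfg = simulation_config(),
                                profiles = default_profiles(),
                                chains = "IGH",
                                bundle = germline_bundle()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    all_reads <- list()
    all_truth <- list()
    for (chain in chains) {
      chain_profiles <- Filter(function(p) p$chain == chain, profiles)
      if (!length(chain_profiles)) {
        stop("no profiles supplied for chain ", chain)
      }
      res <- simulate_chain(cfg, chain_profiles, chain, bundle)
      all_reads[[chain]] <- res$reads
      all_truth[[chain]] <- res$clonotypes
    }
    reads <- dplyr::bind_rows(all_reads)
    reads$sequence_id <- sprintf("read%08d", seq_len(nrow(reads)))
    list(reads = reads, clonotypes = dplyr::bind_rows(all_truth),
         config = cfg, profiles = profiles)
  })
}

simulate_chain <- function(cfg, profiles, chain, bundle) {
  heavy <- chain == "IGH"
  g <- as_tibble(bundle)[as_tibble(bundle)$locus == chain, ]
  seg_tab <- function(seg) g[g$segment == seg, , drop = FALSE]
  vt <- seg_tab("V"); jt <- seg_tab("J")
  dt <- if (heavy) seg_tab("D") else NULL
  by_family <- function(tab) split(seq_len(nrow(tab)), tab$family)
  v_by_fam <- by_family(vt); j_by_fam <- by_family(jt)
  d_by_fam <- if (heavy) by_family(dt) else NULL

  subsets <- vapply(profiles, function(p) p$subset, "")
  donors <- sprintf("D%02d", seq_len(cfg$n_donors))
  n_per <- cfg$clonotypes_per_subset

  blocks <- list()
  for (pi in seq_along(profiles)) {
    prof <- profiles[[pi]]
    for (di in seq_len(cfg$n_donors)) {
      n <- n_per
      vf <- sample_families(prof$v_family_freqs, n)
      jf <- sample_families(prof$j_family_freqs, n)
      v_idx <- sample_genes(vf, v_by_fam)
      j_idx <- sample_genes(jf, j_by_fam)
      len_mean <- prof$cdr3_len_mean
      if (heavy && cfg$donor_ages[di] > 50 && cfg$age_length_coupling > 0 &&
          all(c("preB", "naive") %in% subsets)) {
        pre_mean <- profiles[[which(subsets == "preB")[1]]]$cdr3_len_mean
        nai_mean <- profiles[[which(subsets == "naive")[1]]]$cdr3_len_mean
        decline <- (pre_mean - len_mean) / max(pre_mean - nai_mean, 1e-9)
        len_mean <- min(pre_mean,
                        len_mean + cfg$age_length_coupling *
                          (cfg$donor_ages[di] - 50) / 10 * decline)
      }
      block <- tibble(donor_id = donors[di], subset = prof$subset,
                      v_idx = v_idx, j_idx = j_idx,
                      len_aa = pmin(pmax(round(stats::rnorm(n, len_mean,
                                                            prof$cdr3_len_sd)),
                                         5L),
                                    if (heavy) 32L else 18L),
                      trim_p = 1 / (1 + prof$trim_mean))
      if (heavy) {
        df <- sample_families(prof$d_family_freqs, n)
        block$d_idx <- sample_genes(df, d_by_fam)
      }
      blocks[[length(blocks) + 1L]] <- block
    }
  }
  cl <- dplyr::bind_rows(blocks)
  n <- nrow(cl)

  v_head <- vt$head[cl$v_idx]
  j_tail <- jt$tail[cl$j_idx]
  trim <- function(len) pmax(len - stats::rgeom(n, cl$trim_p), 0L)
  vh_len <- trim(nchar(v_head))
  jt_len <- trim(nchar(j_tail))
  if (heavy) {
    d_core <- dt$core[cl$d_idx]
    d_len <- pmax(nchar(d_core) - stats::rgeom(n, cl$trim_p) -
                    stats::rgeom(n, cl$trim_p), 0L)
  } else {
    d_len <- integer(n)
  }
  productive <- stats::runif(n) < cfg$productive_fraction
  target <- 3L * cl$len_aa +
    ifelse(productive, 0L, sample(1:2, n, replace = TRUE))
  # shrink templated parts (D first, then J tail, then V head) when they
  # overshoot the target junction length
  over <- pmax(vh_len + d_len + jt_len - target, 0L)
  cut_d <- pmin(d_len, over); d_len <- d_len - cut_d; over <- over - cut_d
  cut_j <- pmin(jt_len, over); jt_len <- jt_len - cut_j; over <- over - cut_j
  vh_len <- vh_len - pmin(vh_len, over)
  n_total <- target - (vh_len + d_len + jt_len)
  n1 <- stats::rbinom(n, n_total, 0.5)
  n2 <- n_total - n1

  d_start <- if (heavy) {
    stats::rgeom(n, cl$trim_p) %% pmax(nchar(d_core) - d_len + 1L, 1L)
  } else integer(n)
  cdr3 <- paste0(substr(v_head, 1L, vh_len),
                 rand_nt(n1),
                 if (heavy) substr(d_core, d_start + 1L, d_start + d_len) else "",
                 rand_nt(n2),
                 substr(j_tail, nchar(j_tail) - jt_len + 1L, nchar(j_tail)))
  # cheap superset prefilter; repair_stops touches in-frame stops only
  idx_fix <- which(productive & grepl("TAA|TAG|TGA", cdr3))
  if (length(idx_fix)) {
    cdr3[idx_fix] <- vapply(cdr3[idx_fix], repair_stops, "")
  }
  anchor_nt <- if (heavy) "TGG" else "TTT"
  anchor_aa <- if (heavy) "W" else "F"
  junction <- paste0("TGT", cdr3, anchor_nt)
  cdr3_aa <- rep("", n)
  cdr3_aa[productive] <- translate_nt(cdr3[productive])
  junction_aa <- ifelse(productive & !is.na(cdr3_aa) & nzchar(cdr3_aa),
                        paste0("C", cdr3_aa, anchor_aa), "")

  clone_id <- sprintf("%s_%s_%s_c%06d", chain, cl$donor_id, cl$subset,
                      seq_len(n))
  truth <- tibble(clone_id = clone_id, donor_id = cl$donor_id,
                  subset = cl$subset, chain = chain,
                  v_call = vt$gene_label[cl$v_idx],
                  d_call = if (heavy) dt$gene_label[cl$d_idx] else NA_character_,
                  j_call = jt$gene_label[cl$j_idx],
                  cdr3_nt = cdr3, productive = productive)

  # PCR expansion and per-base error within the junction
  copies <- 1L + stats::rpois(n, cfg$pcr_copies_mean - 1)
  ridx <- rep(seq_len(n), copies)
  r_junction <- junction[ridx]
  nr <- length(ridx)
  n_sub <- stats::rbinom(nr, nchar(r_junction), cfg$error_rate_sub)
  n_ind <- stats::rbinom(nr, nchar(r_junction), cfg$error_rate_indel)
  n_err <- n_sub + n_ind
  hit <- which(n_err > 0L)
  if (length(hit)) {
    r_junction[hit] <- mutate_seqs(r_junction[hit], n_sub[hit], n_ind[hit])
  }

  reads <- tibble(donor_id = cl$donor_id[ridx], subset = cl$subset[ridx],
                  chain = chain,
                  v_call = truth$v_call[ridx],
                  d_call = truth$d_call[ridx],
                  j_call = truth$j_call[ridx],
                  junction = r_junction,
                  junction_aa = junction_aa[ridx],
                  productive = productive[ridx],
                  sequence = paste0(vt$stem[cl$v_idx][ridx], r_junction,
                                    "GG", jt$stem[cl$j_idx][ridx]),
                  clone_id = clone_id[ridx],
                  n_errors = n_err)
  # re-derive annotation for error-bearing reads from the observed read
  if (length(hit)) {
    jl <- nchar(reads$junction[hit])
    obs_cdr3 <- substr(reads$junction[hit], 4L, jl - 3L)
    aa <- translate_nt(obs_cdr3)
    ok <- !is.na(aa) & !grepl("*", aa, fixed = TRUE) & jl %% 3L == 0L
    reads$productive[hit] <- ok
    reads$junction_aa[hit] <- ifelse(ok, paste0("C", aa, anchor_aa), "")
  }
  list(reads = reads, clonotypes = truth)
}

# apply per-read substitutions then indels at random junction positions
mutate_seqs <- function(seqs, n_sub, n_ind) {
  for (i in seq_along(seqs)) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    if (n_sub[i] > 0L) {
      pos <- sample.int(length(s), min(n_sub[i], length(s)))
      for (p in pos) s[p] <- sample(setdiff(NT, s[p]), 1L)
    }
    if (n_ind[i] > 0L) {
      for (k in seq_len(n_ind[i])) {
        if (stats::runif(1) < 0.5 && length(s) > 1L) {
          s <- s[-sample.int(length(s), 1L)]
        } else {
          p <- sample.int(length(s) + 1L, 1L)
          s <- append(s, sample(NT, 1L), after = p - 1L)
        }
      }
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}
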