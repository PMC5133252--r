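#' Levenshtein edit distance
#'
#' Unit-cost edit distance (substitution, insertion, deletion) between two
#' strings, as used to cluster CDR3 regions into unique gene
#' rearrangements. Thin wrapper around the C implementation in
#' [utils::adist()].
#'
#' @param a,b Strings (nucleotide or amino-acid alphabet).
#' @return Non-negative integer distance.
#' @examples
#' levenshtein("kitten", "sitting") # 3
#' @export
levenshtein <- function(a, b) {
  stopifnot(is.character(a), is.character(b))
  as.integer(utils::adist(a, b))
}

#' Select the modal representative of a duplicate cluster
#'
#' Returns the member whose full read sequence (falling back to the CDR3
#' nucleotide string when no `sequence` column is present) is most frequent
#' in the cluster; ties are broken by the lexicographically smallest
#' sequence. The representative's `duplicate_count` is set to the cluster
#' size.
#'
#' @param members Non-empty rearrangement tibble (one cluster).
#' @return One-row tibble.
#' @export
modal_representative <- function(members) {
  members <- as_tibble(members)
  if (nrow(members) == 0L) stop("modal_representative: empty member list")
  key <- if ("sequence" %in% names(members) &&
             all(nzchar(members$sequence))) members$sequence else members$cdr3_nt
  counts <- table(key)
  best <- names(counts)[counts == max(counts)]
  winner <- min(best)  # lexicographic tie-break
  rep <- members[match(winner, key), , drop = FALSE]
  rep$duplicate_count <- nrow(members)
  rep
}

# single-linkage cluster ids for a set of unique strings under edit
# distance <= threshold (transitive closure)
link_unique <- function(u, threshold) {
  k <- length(u)
  if (k == 1L || threshold <= 0) return(seq_len(k))
  d <- utils::adist(u)
  if (k == 2L) {
    return(if (d[1L, 2L] <= threshold) c(1L, 1L) else c(1L, 2L))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  stats::cutree(hc, h = threshold + 0.5)
}

#' Collapse PCR duplicates into unique gene rearrangements
#'
#' Within each grouping key (by default donor x subset x chain x V call x
#' J call), reads whose CDR3 nucleotide sequences are connected under
#' single-linkage Levenshtein distance \eqn{\le} `threshold` are collapsed
#' into one clonotype, represented by its modal sequence. Antigen-naive
#' populations carry no true clonal expansions, so same-CDR3 reads are
#' treated as PCR duplicates; `threshold = 1` additionally absorbs single
#' sequencing errors, `threshold = 0` reproduces exact-CDR3 collapse.
#'
#' Edit distance bounds length difference, so clusters can only span CDR3
#' lengths within `threshold` of each other; no explicit length binning is
#' needed.
#'
#' @param records Rearrangement tibble (should already pass the
#'   `gene_stage` filters).
#' @param threshold Non-negative integer edit-distance threshold
#'   (default 1).
#' @param key Character vector of grouping columns.
#' @return Clonotype tibble: the representative's columns plus
#'   `clonotype_id`, `member_count` and `member_ids` (list column). The sum
#'   of `member_count` equals `nrow(records)`; row order is deterministic.
#' @export
cluster_duplicates <- function(records, threshold = 1L,
                               key = c("donor_id", "subset", "chain",
                                       "v_call", "j_call")) {
  if (threshold < 0) stop("threshold must be non-negative")
  records <- as_tibble(records)
  if (nrow(records) == 0L) return(records)
  missing <- setdiff(c(key, "cdr3_nt", "sequence_id"), names(records))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))

  grp <- do.call(paste, c(records[key], sep = "\r"))
  ord <- order(grp, records$cdr3_nt, records$sequence_id, method = "radix")
  records <- records[ord, , drop = FALSE]
  grp <- grp[ord]
  idx_by_group <- split(seq_len(nrow(records)), factor(grp, levels = unique(grp)))

  has_seq <- "sequence" %in% names(records)
  cdr3_all <- records$cdr3_nt
  seq_all <- if (has_seq) records$sequence else records$cdr3_nt
  id_all <- records$sequence_id

  res_rep <- res_cnt <- res_mem <- vector("list", length(idx_by_group))
  for (gi in seq_along(idx_by_group)) {
    rows <- idx_by_group[[gi]]
    cdr3 <- cdr3_all[rows]
    u <- unique(cdr3)
    cl <- link_unique(u, threshold)[match(cdr3, u)]
    # modal representative per cluster, vectorized: order by (cluster,
    # sequence), collapse runs of identical sequences, pick the run with
    # the highest count (ties: lexicographically smallest sequence)
    s <- seq_all[rows]
    o <- order(cl, s, method = "radix")
    cls <- cl[o]; ss <- s[o]; rr <- rows[o]
    newrun <- c(TRUE, cls[-1L] != cls[-length(cls)] | ss[-1L] != ss[-length(ss)])
    run_id <- cumsum(newrun)
    run_count <- tabulate(run_id)
    fi <- which(newrun)
    run_cl <- cls[fi]
    ro <- order(run_cl, -run_count, ss[fi], method = "radix")
    sel <- ro[!duplicated(run_cl[ro])]        # one run per cluster id
    sel <- sel[order(run_cl[sel])]            # clusters in ascending order
    res_rep[[gi]] <- rr[fi][sel]
    res_cnt[[gi]] <- tabulate(cls)[run_cl[sel]]
    res_mem[[gi]] <- unname(split(id_all[rr], cls))
  }
  rep_rows <- unlist(res_rep, use.names = FALSE)
  counts <- unlist(res_cnt, use.names = FALSE)
  member_ids <- unlist(res_mem, recursive = FALSE, use.names = FALSE)
  out <- records[rep_rows, , drop = FALSE]
  out$duplicate_count <- counts
  out$member_count <- counts
  out$member_ids <- member_ids
  out$clonotype_id <- sprintf("ct%06d", seq_len(nrow(out)))
  out
}
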