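#' CDR3 cleanup policy
#'
#' Length windows and productivity requirement used to remove sequences
#' whose CDR3 is likely inaccurate. Defaults follow the normal distribution
#' of CDR3 lengths: 1--35 amino acids for heavy chain and 1--20 for light
#' chain, both bounds inclusive, together with removal of unproductive
#' rearrangements at the property stage.
#'
#' @param heavy_cdr3_aa_min,heavy_cdr3_aa_max Inclusive heavy-chain CDR3
#'   length window (amino acids).
#' @param light_cdr3_aa_min,light_cdr3_aa_max Inclusive light-chain window.
#' @param require_productive Remove unproductive rearrangements? Applied at
#'   the `cdr3_stage` only.
#' @return A `filter_policy` object.
#' @export
filter_policy <- function(heavy_cdr3_aa_min = 1L, heavy_cdr3_aa_max = 35L,
                          light_cdr3_aa_min = 1L, light_cdr3_aa_max = 20L,
                          require_productive = TRUE) {
  stopifnot(heavy_cdr3_aa_min >= 1L, heavy_cdr3_aa_max >= heavy_cdr3_aa_min,
            light_cdr3_aa_min >= 1L, light_cdr3_aa_max >= light_cdr3_aa_min)
  structure(list(heavy_cdr3_aa_min = heavy_cdr3_aa_min,
                 heavy_cdr3_aa_max = heavy_cdr3_aa_max,
                 light_cdr3_aa_min = light_cdr3_aa_min,
                 light_cdr3_aa_max = light_cdr3_aa_max,
                 require_productive = require_productive),
            class = "filter_policy")
}

cdr3_aa_length <- function(records) {
  aa <- if ("cdr3_aa" %in% names(records)) records$cdr3_aa else ""
  aa <- ifelse(is.na(aa), "", aa)
  nt <- ifelse(is.na(records$cdr3_nt), "", records$cdr3_nt)
  ifelse(nzchar(aa), nchar(aa), nchar(nt) %/% 3L)
}

#' Apply the cleanup filters
#'
#' Two-stage cleanup mirroring the two analysis sets: the `gene_stage`
#' keeps every structurally valid rearrangement (parseable gene calls,
#' non-empty CDR3) for gene-usage analyses, while the stricter `cdr3_stage`
#' additionally removes sequences whose CDR3 amino-acid length falls
#' outside the chain-specific window or that are unproductive, for the
#' physicochemical analyses. Every removed record carries exactly one
#' primary reason code; kept and removed rows partition the input.
#'
#' @param records Rearrangement tibble (see [read_rearrangements()]).
#' @param policy A [filter_policy()].
#' @param stage `"gene_stage"` or `"cdr3_stage"`.
#' @return A list with tibbles `kept` and `removed`; `removed` gains a
#'   `reason` column (`flagged`, `missing_cdr3`, `cdr3_length`,
#'   `unproductive`).
#' @export
apply_filters <- function(records, policy = filter_policy(),
                          stage = c("gene_stage", "cdr3_stage")) {
  stage <- match.arg(stage)
  stopifnot(inherits(policy, "filter_policy"))
  records <- as_tibble(records)
  n <- nrow(records)
  if (n == 0L) {
    return(list(kept = records,
                removed = dplyr::mutate(records, reason = character(0))))
  }
  reason <- rep("", n)
  if ("flag_reason" %in% names(records)) {
    reason[nzchar(records$flag_reason)] <- "flagged"
  }
  len <- cdr3_aa_length(records)
  reason[reason == "" & len == 0L] <- "missing_cdr3"
  if (stage == "cdr3_stage") {
    heavy <- records$chain == "IGH"
    lo <- ifelse(heavy, policy$heavy_cdr3_aa_min, policy$light_cdr3_aa_min)
    hi <- ifelse(heavy, policy$heavy_cdr3_aa_max, policy$light_cdr3_aa_max)
    reason[reason == "" & (len < lo | len > hi)] <- "cdr3_length"
    if (isTRUE(policy$require_productive)) {
      reason[reason == "" & !records$productive] <- "unproductive"
    }
  }
  keep <- reason == ""
  removed <- records[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], removed = removed)
}
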