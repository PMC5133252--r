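#' Parse an IMGT-style immunoglobulin gene name
#'
#' Extracts locus (IGH/IGK/IGL), segment (V/D/J) and family number from a
#' gene name such as `"IGHV3-23"` or `"IGHJ6"`. Allele suffixes (`"*01"`)
#' are stripped deterministically. The family is the run of digits between
#' the segment letter and the first `"-"`, `"S"`, `"/"` or the end of the
#' name, following the standard nomenclature.
#'
#' @param raw A single non-empty gene name string.
#' @return A one-row tibble with columns `locus`, `segment`, `family`
#'   (integer) and `gene_label` (allele suffix stripped).
#' @examples
#' parse_gene_name("IGHV3-30")   # family 3
#' parse_gene_name("IGHJ6")      # family 6
#' parse_gene_name("IGKV4-1*01") # gene_label "IGKV4-1"
#' @export
parse_gene_name <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  out <- parse_gene_names(raw)
  if (is.na(out$family)) {
    stop("not an IMGT-style immunoglobulin gene name: '", raw, "'")
  }
  out
}

#' Vectorized gene-name parser
#'
#' Like [parse_gene_name()] but vectorized and non-throwing: names that do
#' not parse yield `NA` fields so callers can flag rather than drop rows.
#'
#' @param x Character vector of gene names (may contain `NA` or empty
#'   strings, which parse to `NA`).
#' @return Tibble with one row per input: `locus`, `segment`, `family`,
#'   `gene_label`.
#' @export
parse_gene_names <- function(x) {
  x <- as.character(x)
  label <- sub("\\*.*$", "", trimws(x))
  m <- regmatches(label, regexec("^(IGH|IGK|IGL)([VDJ])([0-9]+)", label))
  pick <- function(i) vapply(m, function(g) if (length(g) == 4L) g[i] else NA_character_, "")
  locus <- pick(2L)
  segment <- pick(3L)
  family <- suppressWarnings(as.integer(pick(4L)))
  gene_label <- ifelse(is.na(family), NA_character_, label)
  tibble(locus = locus, segment = segment, family = family,
         gene_label = gene_label)
}

airr_required_cols <- c("sequence_id", "v_call", "j_call", "junction",
                        "productive", "donor_id", "subset", "chain")

#' Cell-subset and chain vocabularies
#'
#' The four early developmental subsets and three immunoglobulin loci the
#' pipeline recognises.
#' @name vocab
#' @export
subset_levels <- function() c("preB", "immature", "transitional", "naive")

#' @rdname vocab
#' @export
chain_levels <- function() c("IGH", "IGK", "IGL")

as_logical_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("t", "true", "1", "yes", "productive")
}

# vectorized in-frame translation; NA where untranslatable
translate_nt <- function(nt) {
  out <- rep(NA_character_, length(nt))
  ok <- !is.na(nt) & nzchar(nt) & nchar(nt) %% 3L == 0L &
    !grepl("[^ACGT]", nt)
  if (any(ok)) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nt[ok]), no.init.codon = TRUE))
    out[ok] <- aa
  }
  out
}

#' Read an annotated rearrangement table
#'
#' Ingests AIRR-style rearrangement TSV (or an IMGT summary CSV via the
#' `imgt_csv` adapter) into the internal rearrangement tibble. Gene names
#' are parsed and normalized; rows that violate the data model (unparseable
#' V/J call, unknown subset or chain, a D call on a light chain) are
#' returned flagged in `flag_reason`, never silently dropped. Counts of
#' accepted and flagged rows are reported with a message.
#'
#' By the IMGT convention the `junction` column includes the conserved
#' anchor residues (C104 and W/F118); with
#' `junction_includes_anchors = TRUE` (default) the anchors are trimmed on
#' load so `cdr3_nt`/`cdr3_aa` hold the CDR3 proper.
#'
#' @param path Path to the input file.
#' @param format `"airr_tsv"` (default) or `"imgt_csv"`.
#' @param junction_includes_anchors Does the junction column include the
#'   conserved anchors? Default `TRUE`.
#' @return A tibble with one row per input row: the AIRR columns plus
#'   `v_family`, `d_family`, `j_family`, `cdr3_nt`, `cdr3_aa`,
#'   `duplicate_count` and `flag_reason` (`""` for clean rows).
#' @export
read_rearrangements <- function(path, format = c("airr_tsv", "imgt_csv"),
                                junction_includes_anchors = TRUE) {
  format <- match.arg(format)
  df <- switch(format,
    airr_tsv = readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                               progress = FALSE),
    imgt_csv = read_imgt_summary(path))
  if (nrow(df) == 0L) {
    warning("empty rearrangement file: ", path)
  }
  missing <- setdiff(airr_required_cols, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  normalize_rearrangements(df, junction_includes_anchors)
}

#' Normalize an in-memory rearrangement table
#'
#' The same normalization [read_rearrangements()] applies after reading:
#' gene-name parsing, anchor trimming, productivity coercion and data-model
#' flagging. Useful for tables produced in memory (e.g. by the simulator).
#'
#' @inheritParams read_rearrangements
#' @param df Data frame with the AIRR-style columns.
#' @return See [read_rearrangements()].
#' @export
normalize_rearrangements <- function(df, junction_includes_anchors = TRUE) {
  df <- as_tibble(df)
  if (!"d_call" %in% names(df)) df$d_call <- NA_character_
  if (!"duplicate_count" %in% names(df)) df$duplicate_count <- 1L
  df$duplicate_count <- as.integer(df$duplicate_count)
  df$productive <- as_logical_flag(df$productive)
  df$junction[is.na(df$junction)] <- ""
  if ("junction_aa" %in% names(df)) {
    df$junction_aa[is.na(df$junction_aa)] <- ""
  }
  if ("sequence" %in% names(df)) df$sequence[is.na(df$sequence)] <- ""

  v <- parse_gene_names(df$v_call)
  j <- parse_gene_names(df$j_call)
  has_d <- !is.na(df$d_call) & nzchar(df$d_call)
  d <- parse_gene_names(ifelse(has_d, df$d_call, NA_character_))
  df$v_call <- ifelse(is.na(v$gene_label), df$v_call, v$gene_label)
  df$j_call <- ifelse(is.na(j$gene_label), df$j_call, j$gene_label)
  df$d_call <- ifelse(has_d & !is.na(d$gene_label), d$gene_label, df$d_call)
  df$v_family <- v$family
  df$d_family <- d$family
  df$j_family <- j$family

  jx <- ifelse(is.na(df$junction), "", df$junction)
  if (junction_includes_anchors) {
    n <- nchar(jx)
    df$cdr3_nt <- ifelse(n > 6L, substr(jx, 4L, n - 3L), "")
    if ("junction_aa" %in% names(df)) {
      ja <- ifelse(is.na(df$junction_aa), "", df$junction_aa)
      na <- nchar(ja)
      df$cdr3_aa <- ifelse(na > 2L, substr(ja, 2L, na - 1L), "")
    } else {
      df$cdr3_aa <- ""
    }
  } else {
    df$cdr3_nt <- jx
    df$cdr3_aa <- if ("junction_aa" %in% names(df)) {
      ifelse(is.na(df$junction_aa), "", df$junction_aa)
    } else ""
  }
  # translate where productive, in-frame and not already provided
  need <- df$productive & !nzchar(df$cdr3_aa) & nzchar(df$cdr3_nt)
  if (any(need)) {
    aa <- translate_nt(df$cdr3_nt[need])
    df$cdr3_aa[need] <- ifelse(is.na(aa) | grepl("\\*", aa), "", aa)
  }

  flag <- rep("", nrow(df))
  flag[is.na(df$v_family) | is.na(df$j_family)] <- "bad_gene_name"
  flag[flag == "" & !(df$subset %in% subset_levels())] <- "bad_subset"
  flag[flag == "" & !(df$chain %in% chain_levels())] <- "bad_chain"
  flag[flag == "" & df$chain != "IGH" & has_d] <- "d_call_on_light"
  df$flag_reason <- flag
  message(sprintf("rearrangements: %d accepted, %d flagged",
                  sum(flag == ""), sum(flag != "")))
  df
}

# IMGT/HighV-QUEST Summary-table adapter: maps the summary headers onto the
# AIRR dialect. Donor/subset/chain must be present as extra columns (the
# summary file itself carries no sample metadata); chain falls back to the
# V-call locus.
read_imgt_summary <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  grab <- function(nm) if (nm %in% names(df)) df[[nm]] else NA_character_
  first_gene <- function(x) {
    m <- regmatches(x, regexpr("IG[HKL][VDJ][0-9][^ ,]*", x))
    out <- rep(NA_character_, length(x))
    out[regexpr("IG[HKL][VDJ][0-9][^ ,]*", x) > 0] <- m
    out
  }
  out <- tibble(
    sequence_id = grab("Sequence ID"),
    v_call = first_gene(grab("V-GENE and allele")),
    d_call = first_gene(grab("D-GENE and allele")),
    j_call = first_gene(grab("J-GENE and allele")),
    junction = grab("JUNCTION"),
    productive = grepl("^productive", tolower(grab("Functionality"))),
    donor_id = grab("donor_id"),
    subset = grab("subset"),
    chain = grab("chain"))
  no_chain <- is.na(out$chain)
  if (any(no_chain)) {
    out$chain[no_chain] <- substr(out$v_call[no_chain], 1L, 3L)
  }
  out
}

#' Write a tabular result to CSV/TSV
#'
#' Writes any pipeline table with a header, UTF-8, in the column order of
#' the input (reproducible). The delimiter follows the file extension
#' (`.tsv` tab, otherwise comma). List columns (e.g. member id lists) are
#' collapsed with `";"`.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(!is.null(records))
  records <- as_tibble(records)
  is_list <- vapply(records, is.list, logical(1))
  for (nm in names(records)[is_list]) {
    records[[nm]] <- vapply(records[[nm]], paste, "", collapse = ";")
  }
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(records, path, progress = FALSE)
  } else {
    readr::write_csv(records, path, progress = FALSE)
  }
  invisible(path)
}
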