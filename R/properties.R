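check_aa <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty amino-acid sequence")
  bad <- regexpr(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), seq)
  if (bad > 0) {
    stop(sprintf("non-standard residue '%s' at position %d",
                 substr(seq, bad, bad), bad))
  }
  invisible(seq)
}

residues <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# residue count matrix for a vector of sequences: one row per sequence,
# one column per standard residue
residue_counts <- function(seqs) {
  ab <- aa_alphabet()
  m <- matrix(0L, nrow = length(seqs), ncol = length(ab),
              dimnames = list(NULL, ab))
  for (i in seq_along(ab)) {
    m[, i] <- nchar(seqs) - nchar(gsub(ab[i], "", seqs, fixed = TRUE))
  }
  m
}

#' GRAVY index
#'
#' Grand average of hydropathy: the mean Kyte--Doolittle value over the
#' residues of a sequence.
#'
#' @param seq Amino-acid sequence (standard 20-letter alphabet).
#' @return Mean hydropathy (dimensionless).
#' @examples
#' gravy("VVVV") # 4.2, the Kyte-Doolittle valine entry
#' @export
gravy <- function(seq) {
  check_aa(seq)
  mean(scale_vector("kyte_doolittle")[residues(seq)])
}

#' Boman index
#'
#' Mean residue-wise protein-binding potential (kcal/mol per residue);
#' higher values indicate a more binding-prone (less membrane-seeking)
#' peptide.
#'
#' @inheritParams gravy
#' @return Mean Boman-scale value.
#' @export
boman_index <- function(seq) {
  check_aa(seq)
  mean(scale_vector("boman")[residues(seq)])
}

#' Peptide molecular weight
#'
#' Sum of average residue masses plus one water mass (Da).
#'
#' @inheritParams gravy
#' @return Molecular weight in Daltons.
#' @export
molecular_weight <- function(seq) {
  check_aa(seq)
  sum(scale_vector("mass_avg")[residues(seq)]) + water_mass
}

# net charge of a peptide at a given pH from ionizable-site counts
# (Henderson-Hasselbalch); `counts` is a named vector over pka sites
peptide_charge <- function(ph, counts) {
  pka <- ig_scales()$pka
  z <- 0
  for (i in seq_len(nrow(pka))) {
    n <- counts[[pka$site[i]]]
    if (is.null(n) || n == 0) next
    if (pka$charge_sign[i] > 0) {
      z <- z + n / (1 + 10^(ph - pka$pka[i]))
    } else {
      z <- z - n / (1 + 10^(pka$pka[i] - ph))
    }
  }
  z
}

ionizable_counts <- function(seq) {
  r <- residues(seq)
  counts <- list(Nterm = 1, Cterm = 1)
  for (site in c("C", "D", "E", "H", "K", "R", "Y")) {
    counts[[site]] <- sum(r == site)
  }
  counts
}

#' Isoelectric point
#'
#' The pH at which the peptide's net charge crosses zero, with
#' Henderson--Hasselbalch charges over the termini and ionizable side
#' chains using the EMBOSS pKa set. Found by bisection on \[0, 14\] until
#' the net charge magnitude drops below 1e-4; deterministic.
#'
#' @inheritParams gravy
#' @return pI in pH units (0 < pI < 14).
#' @export
isoelectric_point <- function(seq) {
  check_aa(seq)
  counts <- ionizable_counts(seq)
  lo <- 0; hi <- 14
  mid <- 7
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    z <- peptide_charge(mid, counts)
    if (abs(z) < 1e-4) break
    if (z > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Aliphatic index
#'
#' Ikai's relative volume of aliphatic side chains:
#' \eqn{X_{Ala} + 2.9 X_{Val} + 3.9 (X_{Ile} + X_{Leu})} where X is the
#' mole percent of the residue.
#'
#' @inheritParams gravy
#' @return Aliphatic index (0 to ~390).
#' @examples
#' aliphatic_index("AAAA") # 100
#' aliphatic_index("VL")   # 340
#' @export
aliphatic_index <- function(seq) {
  check_aa(seq)
  r <- residues(seq)
  x <- function(a) 100 * mean(r == a)
  x("A") + 2.9 * x("V") + 3.9 * (x("I") + x("L"))
}

#' Amino-acid class composition
#'
#' Counts of residues in each of the nine composition classes (tiny,
#' small, aliphatic, aromatic, nonpolar, polar, charged, basic, acidic).
#' Classes overlap, so counts need not sum to the length.
#'
#' @inheritParams gravy
#' @return Named integer vector over the nine classes.
#' @export
class_counts <- function(seq) {
  check_aa(seq)
  r <- residues(seq)
  vapply(ig_scales()$classes, function(set) sum(r %in% set), integer(1))
}

#' Kidera factors of a peptide
#'
#' Component-wise mean over residues of the ten published Kidera factors,
#' a set of orthogonal scales summarizing ~140 measured physical
#' properties of amino acids.
#'
#' @inheritParams gravy
#' @return Named numeric vector `kf1`..`kf10`.
#' @export
kidera_factors <- function(seq) {
  check_aa(seq)
  m <- kidera_matrix()
  colMeans(m[residues(seq), , drop = FALSE])
}

#' Physicochemical property table for clonotypes
#'
#' Computes the full CDR3 descriptor battery (length, GRAVY, Boman index,
#' molecular weight, pI, aliphatic index, nine class counts and the ten
#' Kidera factors) for each clonotype with a non-empty standard-alphabet
#' CDR3 amino-acid sequence. Rows without a usable CDR3 are skipped with a
#' message. Descriptors are computed once per distinct sequence and joined
#' back, so the result is deterministic and fast on duplicated CDR3s.
#'
#' @param clonotypes Clonotype (or rearrangement) tibble with `cdr3_aa`;
#'   identifier and grouping columns are carried through.
#' @param carry Columns to carry through when present.
#' @return Tibble with one row per usable clonotype: carried columns plus
#'   `cdr3_aa`, `length`, `gravy`, `boman`, `mw`, `pi`, `aliphatic_index`,
#'   `n_tiny` .. `n_acidic`, `kf1` .. `kf10`.
#' @export
property_table <- function(clonotypes,
                           carry = c("clonotype_id", "sequence_id",
                                     "donor_id", "subset", "chain",
                                     "v_call", "d_call", "j_call",
                                     "member_count")) {
  clonotypes <- as_tibble(clonotypes)
  aa <- if ("cdr3_aa" %in% names(clonotypes)) clonotypes$cdr3_aa else ""
  aa <- ifelse(is.na(aa), "", aa)
  ok <- nzchar(aa) &
    !grepl(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), aa)
  if (any(!ok)) {
    message(sprintf("property_table: %d row(s) skipped (missing or non-standard CDR3)",
                    sum(!ok)))
  }
  kept <- clonotypes[ok, intersect(carry, names(clonotypes)), drop = FALSE]
  kept$cdr3_aa <- aa[ok]
  u <- unique(kept$cdr3_aa)

  rc <- residue_counts(u)
  len <- nchar(u)
  mean_scale <- function(colname) as.numeric(rc %*% scale_vector(colname)[colnames(rc)]) / len
  props <- tibble(
    cdr3_aa = u,
    length = len,
    gravy = mean_scale("kyte_doolittle"),
    boman = mean_scale("boman"),
    mw = as.numeric(rc %*% scale_vector("mass_avg")[colnames(rc)]) + water_mass,
    pi = pi_vec(rc),
    aliphatic_index = 100 * (rc[, "A"] + 2.9 * rc[, "V"] +
                             3.9 * (rc[, "I"] + rc[, "L"])) / len)
  for (cls in names(ig_scales()$classes)) {
    set <- ig_scales()$classes[[cls]]
    props[[paste0("n_", cls)]] <- as.integer(rowSums(rc[, set, drop = FALSE]))
  }
  kf <- (rc %*% kidera_matrix()[colnames(rc), ]) / len
  colnames(kf) <- paste0("kf", 1:10)
  props <- dplyr::bind_cols(props, as_tibble(kf))
  dplyr::left_join(kept, props, by = "cdr3_aa")
}

# vectorized pI by simultaneous bisection over a residue-count matrix
pi_vec <- function(rc) {
  pka <- ig_scales()$pka
  counts <- cbind(Nterm = 1, Cterm = 1,
                  rc[, c("C", "D", "E", "H", "K", "R", "Y"), drop = FALSE])
  n <- nrow(counts)
  charge_at <- function(ph) {
    z <- numeric(n)
    for (i in seq_len(nrow(pka))) {
      frac <- if (pka$charge_sign[i] > 0) {
        1 / (1 + 10^(ph - pka$pka[i]))
      } else {
        -1 / (1 + 10^(pka$pka[i] - ph))
      }
      z <- z + counts[, pka$site[i]] * frac
    }
    z
  }
  lo <- rep(0, n); hi <- rep(14, n)
  mid <- rep(7, n)
  done <- rep(FALSE, n)
  for (it in 1:100) {
    mid[!done] <- (lo[!done] + hi[!done]) / 2
    z <- charge_at(mid)
    done <- done | abs(z) < 1e-4
    if (all(done)) break
    up <- !done & z > 0
    dn <- !done & z <= 0
    lo[up] <- mid[up]
    hi[dn] <- mid[dn]
  }
  mid
}
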