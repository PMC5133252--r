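# Independent oracles used across the suite. These re-implement the checked
# quantities by a different route (dynamic programming, grid scan, direct
# summation) and must stay independent of the package code paths they test.

# classic dynamic-programming edit distance
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
    }
  }
  d[n + 1, m + 1]
}

# scale tables read straight from the shipped CSVs (not via ig_scales())
scale_csv <- function(name) {
  read.csv(system.file("extdata", "scales", name, package = "bcrdev"),
           stringsAsFactors = FALSE)
}

# per-residue summation oracle for mean-type descriptors
oracle_mean_scale <- function(seq, values, residues) {
  v <- setNames(values, residues)
  r <- strsplit(seq, "")[[1]]
  total <- 0
  for (ch in r) total <- total + v[[ch]]
  total / length(r)
}

# net-charge grid scan for the isoelectric point
oracle_pi <- function(seq, step = 1e-4) {
  pka <- scale_csv("pka_emboss.csv")
  r <- strsplit(seq, "")[[1]]
  counts <- c(Nterm = 1, Cterm = 1,
              vapply(c("C", "D", "E", "H", "K", "R", "Y"),
                     function(a) sum(r == a), numeric(1)))
  ph <- seq(0, 14, by = step)
  z <- numeric(length(ph))
  for (i in seq_len(nrow(pka))) {
    n <- counts[[pka$site[i]]]
    if (n == 0) next
    if (pka$charge_sign[i] > 0) {
      z <- z + n / (1 + 10^(ph - pka$pka[i]))
    } else {
      z <- z - n / (1 + 10^(pka$pka[i] - ph))
    }
  }
  ph[which.min(abs(z))]
}

random_peptide <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# hand-rolled rearrangement rows for unit tests
make_rearrangements <- function(cdr3_nt,
                                donor_id = "D01", subset = "naive",
                                chain = "IGH", v_call = "IGHV3-23",
                                d_call = if (chain == "IGH") "IGHD3-10" else NA,
                                j_call = paste0(chain, "J4"),
                                productive = TRUE, cdr3_aa = NULL) {
  n <- length(cdr3_nt)
  tb <- tibble::tibble(
    sequence_id = sprintf("r%03d", seq_len(n)),
    donor_id = rep_len(donor_id, n), subset = rep_len(subset, n),
    chain = rep_len(chain, n), v_call = rep_len(v_call, n),
    d_call = rep_len(as.character(d_call), n),
    j_call = rep_len(j_call, n),
    cdr3_nt = cdr3_nt,
    cdr3_aa = if (is.null(cdr3_aa)) strrep("A", nchar(cdr3_nt) %/% 3L)
              else rep_len(cdr3_aa, n),
    junction = paste0("TGT", cdr3_nt, "TGG"),
    productive = rep_len(productive, n),
    duplicate_count = 1L, flag_reason = "")
  tb
}

# profile-free ML log-likelihood of the Gaussian random-intercept model,
# maximized over a variance grid with GLS fixed effects (mixed-model oracle)
oracle_lmm_loglik <- function(y, subset, donor) {
  X <- stats::model.matrix(~subset)
  Z <- stats::model.matrix(~donor - 1)
  n <- length(y)
  ll <- function(s2b, s2e) {
    V <- s2b * tcrossprod(Z) + s2e * diag(n)
    ch <- chol(V)
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    b <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
    r <- y - X %*% b
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r * Vi_r))
  }
  # zooming grid search over the two variance components (fixed effects
  # profiled out by GLS at each grid point)
  vtot <- stats::var(y)
  lo <- c(vtot * 1e-4, vtot * 0.01)
  hi <- c(vtot * 3, vtot * 3)
  best <- -Inf; arg <- c(NA, NA)
  for (level in 1:5) {
    sb <- seq(lo[1], hi[1], length.out = 25)
    se <- seq(lo[2], hi[2], length.out = 25)
    for (a in sb) for (b in se) {
      v <- ll(a, b)
      if (v > best) { best <- v; arg <- c(a, b) }
    }
    span_b <- (hi[1] - lo[1]) / 12
    span_e <- (hi[2] - lo[2]) / 12
    lo <- pmax(c(arg[1] - span_b, arg[2] - span_e), c(vtot * 1e-6, vtot * 1e-4))
    hi <- c(arg[1] + span_b, arg[2] + span_e)
  }
  best
}
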