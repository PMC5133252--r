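#' @importFrom rlang .data :=
#' @importFrom tibble tibble as_tibble
NULL

the <- new.env(parent = emptyenv())

#' Standard amino-acid residue letters
#'
#' The 20 standard one-letter residue codes, in the conventional A, R, N, ...
#' order used by the bundled scale tables.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

scale_file <- function(name) {
  path <- system.file("extdata", "scales", name, package = "bcrdev")
  if (!nzchar(path)) stop("bundled scale file not found: ", name)
  path
}

#' Bundled physicochemical scale tables
#'
#' Loads the residue-level scales shipped with the package: Kyte--Doolittle
#' hydropathy, the Boman protein-binding scale (kcal/mol), average residue
#' masses (Da), the ten Kidera factors, the EMBOSS pKa set used for
#' isoelectric-point calculation, and the nine amino-acid composition
#' classes. Tables are read once per session and cached.
#'
#' @return A list with elements `aa` (tibble: residue, kyte_doolittle, boman,
#'   mass_avg), `kidera` (tibble: residue, kf1..kf10), `pka` (tibble: site,
#'   pka, charge_sign), `classes` (named list of residue character vectors)
#'   and `version` (scale bundle version string).
#' @export
ig_scales <- function() {
  if (!is.null(the$scales)) return(the$scales)
  aa <- readr::read_csv(scale_file("aa_scales.csv"), col_types = "cddd")
  kid <- readr::read_csv(scale_file("kidera_factors.csv"),
                         col_types = readr::cols(residue = "c", .default = "d"))
  pka <- readr::read_csv(scale_file("pka_emboss.csv"), col_types = "cdi")
  cls <- readr::read_csv(scale_file("aa_classes.csv"), col_types = "cc")
  classes <- lapply(strsplit(cls$residues, ""), identity)
  names(classes) <- cls$class
  version <- trimws(readLines(scale_file("VERSION"), warn = FALSE)[1])
  the$scales <- list(aa = aa, kidera = kid, pka = pka, classes = classes,
                     version = version)
  the$scales
}

# named numeric lookup vector for one scale column
scale_vector <- function(column) {
  s <- ig_scales()$aa
  stats::setNames(s[[column]], s$residue)
}

kidera_matrix <- function() {
  k <- ig_scales()$kidera
  m <- as.matrix(k[, -1])
  rownames(m) <- k$residue
  m
}

water_mass <- 18.01524
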