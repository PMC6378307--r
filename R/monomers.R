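#' Bundled monomer and basis-species table
#'
#' Molecular formulas and standard Gibbs energies of formation (25 degC,
#' 1 bar, aqueous) for the 20 amino acids, nucleobases, (deoxy)ribose,
#' (deoxy)ribonucleosides, 2'-deoxy- and ribo-nucleoside-5'-monophosphate
#' 2- ions, and the inorganic basis species used to balance biosynthesis
#' reactions. Gibbs energies are approximate transcriptions of the standard
#' geochemical compilations (see the `source` column); every quantity the
#' package reports that depends on them is a relative affinity in which
#' sample-independent terms cancel, and the thermodynamic test surface is
#' property-based rather than value-matching.
#'
#' The hypothetical T-bearing ribonucleoside `rT` supports the
#' thought-experiment single-stranded RNA in which thymine takes the place
#' of uracil, isolating the ribose-for-deoxyribose contribution to Z_C.
#'
#' @param class Optional filter on the `class` column (`"amino_acid"`,
#'   `"nucleobase"`, `"sugar"`, `"deoxyribonucleoside"`, `"ribonucleoside"`,
#'   `"nmp_dna"`, `"nmp_rna"`, `"basis"`).
#' @return A tibble with columns `id`, `class`, `symbol`, `formula`,
#'   `charge`, `gibbs_kj` (kJ/mol), `source`, the parsed element columns
#'   `c`, `h`, `n`, `o`, `s`, `p`, `z`, and `zc` (NOSC; `NA` for
#'   carbon-free species).
#' @examples
#' monomer_table("amino_acid")
#' @export
monomer_table <- function(class = NULL) {
  if (is.null(the$monomers)) {
    path <- system.file("extdata", "monomer_table.tsv", package = "zcmeta",
                        mustWork = TRUE)
    raw <- readr::read_tsv(path, show_col_types = FALSE,
                           na = "NA", progress = FALSE)
    comp <- parse_formula(raw$formula)
    stopifnot(all(comp$z == raw$charge))  # charge column must agree with formula
    tab <- dplyr::bind_cols(
      raw[c("id", "class", "symbol", "formula", "charge")],
      gibbs_kj = convert_gibbs(raw$gibbs_energy, raw$gibbs_units),
      comp,
      tibble(source = raw$source)
    )
    zc_col <- rep(NA_real_, nrow(comp))
    zc_col[comp$c > 0] <- nosc(comp[comp$c > 0, ])
    tab$zc <- zc_col
    the$monomers <- tab
  }
  out <- the$monomers
  if (!is.null(class)) out <- out[out$class %in% class, ]
  out
}

convert_gibbs <- function(value, units) {
  mult <- c("kJ/mol" = 1, "J/mol" = 1e-3, "cal/mol" = 4.184e-3,
            "kcal/mol" = 4.184)
  if (!all(units %in% names(mult))) {
    stop("unknown gibbs_units: ", paste(setdiff(units, names(mult)),
                                        collapse = ", "), call. = FALSE)
  }
  value * unname(mult[units])
}

#' Look up monomers by id
#'
#' @param ids Character vector of `id` values in [monomer_table()].
#' @return The matching rows, in the order requested.
#' @export
monomers <- function(ids) {
  tab <- monomer_table()
  miss <- setdiff(ids, tab$id)
  if (length(miss)) {
    stop("unknown monomer id(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tab[match(ids, tab$id), ]
}

# nucleoside rows keyed by base letter, as a composition tibble
nucleoside_set <- function(type = c("dna", "rna", "rna_thymine")) {
  type <- match.arg(type)
  ids <- switch(type,
    dna = c(A = "dA", C = "dC", G = "dG", T = "dT"),
    rna = c(A = "rA", C = "rC", G = "rG", U = "rU"),
    rna_thymine = c(A = "rA", C = "rC", G = "rG", T = "rT"))
  m <- monomers(ids)
  m$base <- names(ids)
  m
}

# one-letter keyed amino-acid rows
aa_set <- function() {
  m <- monomer_table("amino_acid")
  m[order(m$symbol), ]
}
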