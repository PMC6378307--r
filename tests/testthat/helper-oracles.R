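# Independent oracles: element counts written out by hand from the
# literature formulas, and Eq.-style arithmetic done with plain numbers,
# so these never route through the package's parser or combinators.

# counts are c(C, H, N, O, S)
ORACLE <- list(
  dA = c(10, 13, 5, 3, 0),   # 2'-deoxyadenosine C10H13N5O3
  dC = c(9, 13, 3, 4, 0),    # 2'-deoxycytidine  C9H13N3O4
  dG = c(10, 13, 5, 4, 0),   # 2'-deoxyguanosine C10H13N5O4
  dT = c(10, 14, 2, 5, 0),   # thymidine         C10H14N2O5
  rA = c(10, 13, 5, 4, 0),   # adenosine
  rC = c(9, 13, 3, 5, 0),    # cytidine
  rG = c(10, 13, 5, 5, 0),   # guanosine
  rU = c(9, 12, 2, 6, 0),    # uridine
  rT = c(10, 14, 2, 6, 0)    # 5-methyluridine (hypothetical T-RNA)
)

oracle_zc <- function(counts) {
  (-counts[2] + 3 * counts[3] + 2 * counts[4] + 2 * counts[5]) / counts[1]
}

# Z_C of dsDNA at GC fraction f by summing full nucleoside compositions
oracle_zc_dsdna <- function(f) {
  at <- ORACLE$dA + ORACLE$dT
  gc <- ORACLE$dG + ORACLE$dC
  oracle_zc((1 - f) * at + f * gc)
}

make_reads <- function(seqs, prefix = "r") {
  tibble::tibble(id = paste0(prefix, seq_along(seqs)), seq = seqs)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# hand-coded element/charge content of the basis species, for independent
# verification of balanced reactions (rows: c, h, n, o, s, p, z)
BASIS_M <- cbind(
  H2O   = c(0, 2, 0, 1, 0, 0, 0),
  HCO3  = c(1, 1, 0, 3, 0, 0, -1),
  H2PO4 = c(0, 2, 0, 4, 0, 1, -1),
  NH4   = c(0, 4, 1, 0, 0, 0, 1),
  HS    = c(0, 1, 0, 0, 1, 0, -1),
  `H+`  = c(0, 1, 0, 0, 0, 0, 1),
  `e-`  = c(0, 0, 0, 0, 0, 0, -1)
)

balance_residual <- function(product, rxn) {
  nu <- stats::setNames(rxn$coefficients$coefficient,
                        rxn$coefficients$species)
  b <- as.numeric(product[1, c("c", "h", "n", "o", "s", "p", "z")])
  max(abs(BASIS_M[, names(nu)] %*% nu - b))
}

random_composition <- function() {
  zcmeta::composition(c = sample(1:20, 1), h = sample(0:30, 1),
                      n = sample(0:8, 1), o = sample(0:10, 1),
                      s = sample(0:3, 1), p = sample(0:2, 1),
                      z = sample(-3:3, 1))
}
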