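test_that("formula parsing handles subscripts, fractions and charges", {
  comp <- parse_formula(c("CH4", "C2.5H6NO2", "C10H12N5O6P-2", "NH4+", "e-"))
  expect_equal(comp$c, c(1, 2.5, 10, 0, 0))
  expect_equal(comp$h, c(4, 6, 12, 4, 0))
  expect_equal(comp$p, c(0, 0, 1, 0, 0))
  expect_equal(comp$z, c(0, 0, -2, 1, -1))
  expect_error(parse_formula("C2X5"), "unsupported element")
  expect_error(composition(c = -1), "negative")
})

test_that("zc reproduces the benchmark small molecules", {
  vals <- zc(parse_formula(c("CH4", "CO2", "C5H6N2O2", "C5H5N5O",
                             "C5H10O5", "C5H10O4", "C2H5NO2", "C3H7NO2",
                             "C6H13NO2")))
  expect_equal(vals, c(-4, 4, 0.8, 2.4, 0, -0.4, 1, 0, -1))
  expect_error(zc(composition(h = 4)), "undefined")
})

test_that("combining compositions gives average per-monomer formulas", {
  ala_gly <- combine_compositions(parse_formula(c("C3H7NO2", "C2H5NO2")),
                                  weights = c(50, 50))
  expect_equal(as.numeric(ala_gly[1, c("c", "h", "n", "o")]), c(2.5, 6, 1, 2))
  expect_equal(zc(ala_gly), 0.4)
  ala_leu <- combine_compositions(parse_formula(c("C3H7NO2", "C6H13NO2")),
                                  weights = c(50, 50))
  expect_equal(as.numeric(ala_leu[1, c("c", "h", "n", "o")]), c(4.5, 10, 1, 2))
  expect_equal(zc(ala_leu), -2 / 3)
  # identity case
  gly <- parse_formula("C2H5NO2")
  expect_equal(combine_compositions(gly, weights = 1), gly)
  expect_error(combine_compositions(gly[0, ]), "empty")
  expect_error(combine_compositions(gly, weights = 0), "nonzero")
})

test_that("zc of a combination is the carbon-weighted mean of member zc", {
  set.seed(101)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    comps <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
      composition(c = sample(1:12, 1), h = sample(0:20, 1),
                  n = sample(0:6, 1), o = sample(0:8, 1), s = sample(0:2, 1))
    }))
    w <- runif(k, 0.1, 5)
    mixed <- combine_compositions(comps, weights = w)
    expected <- sum(w * comps$c * zc(comps)) / sum(w * comps$c)
    expect_equal(zc(mixed), expected)
  }
})

test_that("oxidation state survives dehydration, protonation and
           phosphate condensation", {
  set.seed(202)
  for (rep in 1:25) {
    comp <- random_composition()
    comp$h <- comp$h + 4; comp$o <- comp$o + 2   # headroom for dehydration
    expect_equal(zc(dehydrate(comp, 2)), zc(comp))
    # protonation: h and z both +1 (NOSC invariant)
    prot <- comp; prot$h <- prot$h + 1; prot$z <- prot$z + 1
    expect_equal(nosc(prot), nosc(comp))
    # phosphate condensation: +HPO3 (h+1, o+3, p+1)
    phos <- comp
    phos$h <- phos$h + 1; phos$o <- phos$o + 3; phos$p <- phos$p + 1
    expect_equal(nosc(phos), nosc(comp))
  }
  expect_error(dehydrate(composition(c = 1, h = 1, o = 0)), "negative")
})

test_that("nosc reduces to zc for neutral phosphorus-free species and
           reproduces nucleoside values for NMP ions", {
  aa <- monomer_table("amino_acid")
  expect_equal(nosc(aa), zc(aa))
  # 2- NMP ions: charge and phosphate terms cancel back to the nucleoside
  nmp <- monomers(c("dAMP", "dCMP", "dGMP", "dTMP"))
  ns <- monomers(c("dA", "dC", "dG", "dT"))
  expect_equal(nosc(nmp), zc(ns))
})

test_that("nucleoside zc lies strictly between nucleobase and sugar", {
  pairs <- list(c("adenine", "dA"), c("cytosine", "dC"), c("guanine", "dG"),
                c("thymine", "dT"), c("adenine", "rA"), c("cytosine", "rC"),
                c("guanine", "rG"), c("uracil", "rU"))
  bases <- monomer_table("nucleobase")
  expect_true(all(bases$zc >= 0.8 & bases$zc <= 2.4))
  for (p in pairs) {
    base_zc <- monomers(p[1])$zc
    nuc_zc <- monomers(p[2])$zc
    sugar_zc <- monomers(if (startsWith(p[2], "d")) "deoxyribose"
                         else "ribose")$zc
    expect_true(nuc_zc > sugar_zc && nuc_zc < base_zc)
  }
})

test_that("bundled monomer table is complete and unit-aware", {
  tab <- monomer_table()
  expect_equal(sum(tab$class == "amino_acid"), 20)
  expect_true(all(tab$c[tab$class %in% c("amino_acid", "deoxyribonucleoside",
                                         "ribonucleoside")] > 0))
  expect_false(any(is.na(tab$gibbs_kj)))
  expect_equal(zcmeta:::convert_gibbs(c(1000, 1, 1),
                                      c("cal/mol", "kJ/mol", "kcal/mol")),
               c(4.184, 1, 4.184))
})
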