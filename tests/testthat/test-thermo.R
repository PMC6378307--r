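test_that("hand-balanced reference reactions are reproduced", {
  ala <- balance_reaction(monomers("Ala"))
  nu <- setNames(ala$coefficients$coefficient, ala$coefficients$species)
  expect_equal(nu[["HCO3"]], 3)
  expect_equal(nu[["NH4"]], 1)
  expect_equal(nu[["H+"]], 14)
  expect_equal(nu[["e-"]], 12)
  expect_equal(nu[["H2O"]], -7)
  expect_equal(nu[["H2PO4"]], 0)
  expect_equal(ala$n_electrons, 12)                 # = c(4 - Z_C) = 3 * 4
  expect_equal(balance_reaction(monomers("Gly"))$n_electrons, 6)
  # a basis member as product balances onto itself
  h2o <- dplyr::mutate(composition(h = 2, o = 1), gibbs_kj = -237.2)
  nu_w <- balance_reaction(h2o)$coefficients
  expect_equal(nu_w$coefficient[nu_w$species == "H2O"], 1)
  expect_equal(sum(abs(nu_w$coefficient)), 1)
})

test_that("balancing conserves elements and charge on random products and
           the electron count ties to oxidation state", {
  set.seed(404)
  for (rep in 1:30) {
    prod <- random_composition()
    prod$gibbs_kj <- runif(1, -1500, 0)
    rxn <- balance_reaction(prod)
    expect_lt(balance_residual(prod, rxn), 1e-9)
    expect_equal(rxn$n_electrons, prod$c * (4 - nosc(prod)))
  }
  # for neutral P-free products the identity reads c * (4 - Z_C)
  aa <- monomer_table("amino_acid")
  for (i in seq_len(nrow(aa))) {
    rxn <- balance_reaction(aa[i, ])
    expect_equal(rxn$n_electrons, aa$c[i] * (4 - zc(aa[i, ])))
  }
})

test_that("average monomers reproduce worked formulas and energies", {
  gly_pool <- pool_protein(make_reads(strrep("G", 50)))
  m <- average_monomer(gly_pool, "protein")
  gly <- monomers("Gly")
  expect_equal(as.numeric(m[1, c("c", "h", "n", "o", "s")]),
               as.numeric(gly[1, c("c", "h", "n", "o", "s")]))
  expect_equal(m$gibbs_kj, gly$gibbs_kj)
  m2 <- average_monomer(pool_protein(make_reads(strrep("AG", 50))), "protein")
  expect_equal(as.numeric(m2[1, c("c", "h", "n", "o")]), c(2.5, 6, 1, 2))
  expect_equal(m2$gibbs_kj,
               mean(monomers(c("Ala", "Gly"))$gibbs_kj))
  # DNA monomer at GC = 0.5: hand-summed average NMP pair
  pool <- tibble::tibble(at_pairs = 100, gc_pairs = 100)
  md <- average_monomer(pool, "dna")
  hand <- (c(10, 12, 5, 6, 0, 1, -2) + c(10, 13, 2, 8, 0, 1, -2) +
           c(10, 12, 5, 7, 0, 1, -2) + c(9, 12, 3, 7, 0, 1, -2)) / 2
  expect_equal(as.numeric(md[1, c("c", "h", "n", "o", "s", "p", "z")]), hand)
  # phosphate and charge do not perturb the carbon oxidation state
  expect_equal(md$zc, zc_dsdna_gc(0.5))
})

test_that("affinity is affine in Eh with slope -n_e * F / 2.303RT and flat
           for redox-inert products", {
  rxn <- balance_reaction(monomers("Ala"))
  curve <- affinity_curve(rxn, eh = seq(-0.3, 0.1, length.out = 5))
  slopes <- diff(curve$affinity) / diff(curve$eh)
  expected <- -12 * 96485.33212 / (log(10) * 8.314462618 * 298.15)
  expect_equal(slopes, rep(expected, 4))
  expect_equal(expected / 12, -16.90, tolerance = 5e-4)    # per-electron slope
  # n_e = 0 product (fully oxidized carbon): flat in Eh
  inert <- dplyr::mutate(composition(c = 1, o = 2), gibbs_kj = -386)
  flat <- affinity_curve(balance_reaction(inert))
  expect_equal(diff(range(flat$affinity)), 0)
})

test_that("relative affinities are zero-sum, ordered by oxidation state at
           low Eh, and scale-invariant", {
  dna_pools <- list(
    S1 = tibble::tibble(at_pairs = 70, gc_pairs = 30),
    S2 = tibble::tibble(at_pairs = 55, gc_pairs = 45),
    S3 = tibble::tibble(at_pairs = 40, gc_pairs = 60))
  curves <- sample_affinities(dna_pools, "dna")
  rel <- relative_affinity(curves)
  sums <- rel |>
    dplyr::group_by(eh) |>
    dplyr::summarise(s = sum(rel_affinity))
  expect_equal(sums$s, rep(0, nrow(sums)), tolerance = 1e-9)
  # most reduced sample (lowest GC, lowest Z_C) wins at the reducing end
  lo <- rel[rel$eh == min(rel$eh), ]
  expect_equal(lo$sample[which.max(lo$rel_affinity)], "S1")
  hi <- rel[rel$eh == max(rel$eh), ]
  expect_equal(hi$sample[which.max(hi$rel_affinity)], "S3")
  # two affine curves cross at most once
  a1 <- curves$affinity[curves$sample == "S1"]
  a2 <- curves$affinity[curves$sample == "S3"]
  expect_lte(sum(diff(sign(a1 - a2)) != 0), 1)
  # per-monomer normalization: scaling counts changes nothing
  scaled <- sample_affinities(list(S1 = dplyr::mutate(
    dna_pools$S1, at_pairs = at_pairs * 7, gc_pairs = gc_pairs * 7)), "dna")
  expect_equal(scaled$affinity, curves$affinity[curves$sample == "S1"])
  # mismatched grids are refused
  shifted <- curves
  shifted$eh[shifted$sample == "S1"] <- shifted$eh[shifted$sample == "S1"] + 1e-3
  expect_error(relative_affinity(shifted), "common Eh grid")
})

test_that("quadrant classification separates aligned, inverted and
           degenerate gradients", {
  protein_pools <- list(
    S1 = pool_protein(make_reads(strrep("LIVM", 30))),   # reduced
    S2 = pool_protein(make_reads(strrep("LGSA", 30))),
    S3 = pool_protein(make_reads(strrep("GSDN", 30))))   # oxidized
  dna_aligned <- list(
    S1 = tibble::tibble(at_pairs = 70, gc_pairs = 30),
    S2 = tibble::tibble(at_pairs = 55, gc_pairs = 45),
    S3 = tibble::tibble(at_pairs = 40, gc_pairs = 60))
  curves <- function(dna) {
    relative_affinity(dplyr::bind_rows(
      sample_affinities(dna, "dna"),
      sample_affinities(protein_pools, "protein")))
  }
  q <- quadrant_classify(curves(dna_aligned), "S1", "S3")
  expect_true(q$hangs_together)
  expect_equal(q$endpoints$quadrant, c(1L, 1L))
  expect_equal(glance(q)$n_quadrant1, 2L)
  # OMZ-like inversion: DNA trend flipped against the protein trend
  dna_inverted <- setNames(rev(dna_aligned), names(dna_aligned))
  q2 <- quadrant_classify(curves(dna_inverted), "S1", "S3")
  expect_false(q2$hangs_together)
  # identical compositions: endpoints on the axes, never quadrant I
  same <- list(S1 = dna_aligned$S1, S2 = dna_aligned$S1)
  same_prot <- list(S1 = protein_pools$S1, S2 = protein_pools$S1)
  rel0 <- relative_affinity(dplyr::bind_rows(
    sample_affinities(same, "dna"),
    sample_affinities(same_prot, "protein")))
  q3 <- quadrant_classify(rel0, "S1", "S2")
  expect_false(q3$hangs_together)
  expect_true(all(is.na(q3$endpoints$quadrant)))
  expect_error(quadrant_classify(rel0, "S1", "nope"), "absent")
})
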