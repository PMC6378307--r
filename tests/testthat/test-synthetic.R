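test_that("read generation honours GC composition and records its truth", {
  at_only <- gen_reads(0, 20, length_mean = 100, length_sd = 0, seed = 1)
  expect_true(all(grepl("^[AT]+$", at_only$reads$seq)))
  # pooled GC within 3 binomial sd of the target
  big <- gen_reads(0.42, 400, length_mean = 250, length_sd = 0, seed = 2)
  pool <- pool_dsdna(big$reads)
  expect_gte(pool$n_bases, 1e5)
  bound <- 3 * sqrt(0.42 * 0.58 / pool$n_bases)
  expect_lt(abs(pool$gc - 0.42), bound)
  expect_equal(big$truth$zc_dna, zc_dsdna_gc(0.42))
  expect_error(gen_reads(1.2, 10, seed = 1))
  expect_error(gen_reads(0.5, 10), "seed")
})

test_that("injected duplicates are recovered exactly by dereplication", {
  g <- gen_reads(0.5, 1000, length_mean = 120, length_sd = 10,
                 dup_rate = 0.1, seed = 12)
  removed <- nrow(g$reads) - nrow(dereplicate(g$reads))
  expect_equal(removed, g$truth$n_duplicates)
  expect_lt(abs(g$truth$n_duplicates - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  # ambiguity injection is recorded
  ga <- gen_reads(0.5, 50, length_mean = 200, length_sd = 0,
                  ambig_rate = 0.01, seed = 13)
  expect_equal(sum(zcmeta:::n_ambiguous(ga$reads$seq)), ga$truth$n_ambiguous)
})

test_that("GC skew moves single-strand counts but not dsDNA zc", {
  plain <- gen_reads(0.5, 200, length_mean = 200, length_sd = 0, seed = 14)
  skewed <- gen_reads(0.5, 200, length_mean = 200, length_sd = 0,
                      gc_skew = 0.5, seed = 14)
  ps <- pool_dsdna(skewed$reads)
  expect_gt(ps$G, ps$C * 1.5)            # skew is really there on the strand
  bound <- 3 * sqrt(0.25 / ps$n_bases)
  expect_lt(abs(ps$gc - 0.5), bound)     # but GC fraction is unchanged
  expect_lt(abs(zc_dsdna(ps) - zc_dsdna(pool_dsdna(plain$reads))),
            zc_dsdna_gc(0.5 + bound) - zc_dsdna_gc(0.5 - bound))
})

test_that("generated coding sequences translate consistently and reproduce
           target protein zc", {
  gly <- gen_cds(c(Gly = 1), n_genes = 20, seed = 21)
  expect_equal(zc_protein(pool_protein(gly$proteins)), 1)
  mix <- gen_cds(c(Ala = 1, Gly = 1), n_genes = 50, seed = 22)
  expect_equal(mix$truth$zc_protein, 0.4)
  # realized pool is multinomial around the target
  realized <- zc_protein(pool_protein(mix$proteins))
  expect_lt(abs(realized - 0.4), 0.05)
  # translation consistency: oriented CDS re-translates to the proteins
  oriented <- orient_cds(mix$cds, mix$strand)
  retrans <- vapply(oriented$seq, function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
  expect_equal(retrans, mix$proteins$seq)
  # negative-sense emission really happened and orientation undoes it
  expect_true(any(mix$strand == "-"))
  expect_equal(unname(zcmeta:::base_counts(oriented$seq)),
               unname(mix$truth$base_counts))
  # strand is parseable from the gene-caller-style headers
  expect_equal(parse_fgs_strand(mix$cds$id), mix$strand)
})

test_that("generators are deterministic under their seeds", {
  expect_equal(gen_reads(0.4, 50, seed = 77), gen_reads(0.4, 50, seed = 77))
  expect_equal(gen_cds(c(Ala = 1), n_genes = 10, seed = 78),
               gen_cds(c(Ala = 1), n_genes = 10, seed = 78))
  spec <- gradient_spec(n_samples = 2, reads_per_sample = 50, seed = 79)
  expect_equal(gen_gradient(spec), gen_gradient(spec))
})

test_that("gradient truth tables carry closed-form DNA zc and gradients
           are monotone", {
  spec <- gradient_spec(n_samples = 5, gc = c(0.30, 0.60),
                        reads_per_sample = 300, seed = 80)
  g <- gen_gradient(spec)
  expect_equal(g$truth$zc_dna, zc_dsdna_gc(g$truth$gc))
  expect_true(all(diff(g$truth$zc_dna) > 0))
  expect_true(all(diff(g$truth$zc_protein) > 0))
  # estimated dsDNA zc tracks the truth monotonically
  est <- vapply(g$samples, function(s) zc_dsdna(pool_dsdna(s$reads)),
                numeric(1))
  expect_true(all(diff(est) > 0))
  # constant GC and no protein shift: relative affinities all ~ 0
  flat_spec <- gradient_spec(n_samples = 3, gc = rep(0.5, 3),
                             protein_shift = 0, reads_per_sample = 200,
                             seed = 81)
  flat <- gen_gradient(flat_spec)
  dna_pools <- lapply(flat$samples, function(s) pool_dsdna(s$reads))
  rel <- relative_affinity(sample_affinities(dna_pools, "dna"))
  # identical target compositions: only binomial sampling noise in the
  # realized GC (~1e-3 here) separates the curves, orders of magnitude
  # below the spread of a real gradient (see the aligned case above)
  expect_lt(max(abs(rel$rel_affinity)), 0.3)
  aligned_rel <- relative_affinity(sample_affinities(
    lapply(g$samples, function(s) pool_dsdna(s$reads)), "dna"))
  expect_lt(max(abs(rel$rel_affinity)),
            0.05 * max(abs(aligned_rel$rel_affinity)))
})
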