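#' Generate a synthetic read set with known truth
#'
#' Draws reads with i.i.d. bases at P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1 - gc)/2, normally distributed lengths, optional
#' uniform ambiguous-base (N) contamination, and optional injected
#' duplicate reads (each read after the first spawns, with probability
#' `dup_rate`, an extra exact copy of a random earlier original read --
#' emulating over-amplification). The i.i.d. base model is sufficient here
#' because every downstream statistic depends on the pool only through its
#' base composition. An optional GC-skew knob transfers probability mass
#' from C to G on the sequenced strand without changing GC fraction, to
#' exercise the strand invariance of dsDNA pooling.
#'
#' @param gc GC fraction in (0, 1) (0 and 1 allowed for degenerate tests).
#' @param n_reads Number of original (non-duplicate) reads.
#' @param length_mean,length_sd Read-length distribution (bases); lengths
#'   are rounded and floored at 30.
#' @param ambig_rate Per-base probability of replacement by N.
#' @param dup_rate Per-read probability of spawning a duplicate.
#' @param gc_skew Fraction of the G+C mass moved from C to G (0 = none).
#' @param seed Integer seed (required: generated data are study conditions,
#'   not incidental randomness).
#' @param prefix Read-id prefix.
#' @return List: `reads` (tibble `id`, `seq`) and `truth` (list with `gc`,
#'   `zc_dna` from the closed form, `n_duplicates`, `n_ambiguous`).
#' @export
gen_reads <- function(gc, n_reads, length_mean = 250, length_sd = 50,
                      ambig_rate = 0, dup_rate = 0, gc_skew = 0, seed,
                      prefix = "read") {
  stopifnot(gc >= 0, gc <= 1, n_reads >= 1, ambig_rate >= 0, ambig_rate <= 1,
            dup_rate >= 0, dup_rate <= 1, gc_skew >= 0, gc_skew <= 1)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  probs <- c(A = (1 - gc) / 2, C = gc / 2 * (1 - gc_skew),
             G = gc / 2 * (1 + gc_skew), T = (1 - gc) / 2)
  with_seed(seed, {
    lens <- pmax(30L, as.integer(round(rnorm(n_reads, length_mean, length_sd))))
    seqs <- vapply(lens, function(l) {
      paste(sample(names(probs), l, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    n_amb <- 0L
    if (ambig_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        hit <- runif(nchar(s)) < ambig_rate
        n_amb <<- n_amb + sum(hit)
        if (any(hit)) {
          ch <- strsplit(s, "")[[1]]
          ch[hit] <- "N"
          paste(ch, collapse = "")
        } else s
      }, character(1), USE.NAMES = FALSE)
    }
    ids <- sprintf("%s%06d", prefix, seq_len(n_reads))
    reads <- tibble(id = ids, seq = seqs)
    n_dup <- 0L
    if (dup_rate > 0 && n_reads > 1) {
      spawn <- which(runif(n_reads - 1) < dup_rate) + 1L
      n_dup <- length(spawn)
      if (n_dup > 0) {
        src <- vapply(spawn, function(i) sample.int(i - 1L, 1L), integer(1))
        dups <- tibble(id = sprintf("%s%06d_dup", prefix, spawn),
                       seq = seqs[src])
        reads <- dplyr::bind_rows(reads, dups)
        reads <- reads[sample.int(nrow(reads)), ]   # shuffle positions
      }
    }
  })
  list(reads = reads,
       truth = list(gc = gc, zc_dna = zc_dsdna_gc(gc),
                    n_duplicates = n_dup, n_ambiguous = n_amb))
}

#' Generate synthetic coding sequences and their proteins
#'
#' Draws genes codon-by-codon from per-amino-acid frequencies (synonymous
#' codons chosen uniformly under the standard genetic code), translates
#' them, and emits a random half of the genes as negative-sense
#' (reverse-complemented) sequences with strand labels, to exercise
#' [orient_cds()].
#'
#' @param aa_freqs Named numeric vector of amino-acid frequencies
#'   (one-letter or three-letter names); normalized internally.
#' @param n_genes Number of genes.
#' @param len_codons_mean,len_codons_sd Gene length distribution in codons
#'   (floored at 10).
#' @param seed Integer seed.
#' @param prefix Gene-id prefix. Emitted ids follow the
#'   `id_start_end_strand` gene-caller header convention.
#' @return List: `cds` (tibble `id`, `seq`, as emitted, mixed strands),
#'   `proteins` (tibble `id`, `seq`), `strand` (character vector), and
#'   `truth` (list with `aa_freqs`, `zc_protein`, and `base_counts` of the
#'   positive-sense set).
#' @export
gen_cds <- function(aa_freqs, n_genes = 200, len_codons_mean = 100,
                    len_codons_sd = 20, seed, prefix = "gene") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  aa <- aa_set()
  keys <- names(aa_freqs)
  idx <- match(keys, aa$id)
  idx[is.na(idx)] <- match(keys[is.na(idx)], aa$symbol)
  if (any(is.na(idx))) {
    stop("unknown amino acid(s): ", paste(keys[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  letters1 <- aa$symbol[idx]
  freqs <- as.numeric(aa_freqs)
  if (any(freqs < 0) || sum(freqs) <= 0) {
    stop("amino-acid frequencies must be non-negative and not all zero",
         call. = FALSE)
  }
  freqs <- freqs / sum(freqs)
  code <- Biostrings::GENETIC_CODE
  codons_by_aa <- split(names(code), unname(code))
  with_seed(seed, {
    lens <- pmax(10L, as.integer(round(rnorm(n_genes, len_codons_mean,
                                             len_codons_sd))))
    pos_seqs <- vapply(lens, function(l) {
      aas <- sample(letters1, l, replace = TRUE, prob = freqs)
      paste(vapply(aas, function(a) {
        cods <- codons_by_aa[[a]]
        cods[sample.int(length(cods), 1L)]
      }, character(1)), collapse = "")
    }, character(1))
    prot <- vapply(pos_seqs, function(s) {
      as.character(Biostrings::translate(Biostrings::DNAString(s)))
    }, character(1), USE.NAMES = FALSE)
    strand <- rep("+", n_genes)
    strand[sample.int(n_genes, n_genes %/% 2)] <- "-"
  })
  emitted <- pos_seqs
  neg <- strand == "-"
  if (any(neg)) {
    emitted[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(pos_seqs[neg])))
  }
  ids <- sprintf("%s%05d_%d_%d_%s", prefix, seq_len(n_genes), 1L,
                 nchar(emitted), strand)
  list(cds = tibble(id = ids, seq = unname(emitted)),
       proteins = tibble(id = ids, seq = prot),
       strand = strand,
       truth = list(aa_freqs = setNames(freqs, letters1),
                    zc_protein = zc_protein(setNames(freqs, letters1)),
                    base_counts = base_counts(pos_seqs)))
}

#' Specify a synthetic multi-sample redox gradient
#'
#' Bundles the study conditions for a generated gradient: per-sample GC
#' fractions rising toward the oxidizing end, reads per sample, read-length
#' model, contamination rates, coding fraction, and a protein-composition
#' trajectory interpolating between a reduced endmember (aliphatic-rich:
#' Leu/Ile/Val/Phe/Met-heavy) and an oxidized endmember
#' (Gly/Ser/Asp/Asn/Thr-heavy), so DNA GC and protein composition co-vary
#' as they do along natural redox gradients.
#'
#' @param n_samples Number of gradient points (ordered reducing ->
#'   oxidizing).
#' @param gc Per-sample GC fractions (length `n_samples`), or length-2
#'   range interpolated linearly.
#' @param reads_per_sample Original reads generated per sample.
#' @param length_mean,length_sd Read-length model (bases).
#' @param ambig_rate,dup_rate Contamination rates (see [gen_reads()]).
#' @param coding_fraction Fraction of reads-worth of sequence also emitted
#'   as coding genes (sets `n_genes` per sample).
#' @param protein_shift 0..1 amplitude of the endmember interpolation
#'   (0 = identical protein composition in every sample).
#' @param seed Integer seed (mandatory).
#' @return A `gradient_spec` list, input to [gen_gradient()].
#' @export
gradient_spec <- function(n_samples = 5, gc = c(0.30, 0.60),
                          reads_per_sample = 1500, length_mean = 250,
                          length_sd = 50, ambig_rate = 0.002,
                          dup_rate = 0.05, coding_fraction = 0.85,
                          protein_shift = 1, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (length(gc) == 2 && n_samples != 2) {
    gc <- seq(gc[1], gc[2], length.out = n_samples)
  }
  stopifnot(length(gc) == n_samples, all(gc > 0 & gc < 1),
            protein_shift >= 0, protein_shift <= 1)
  structure(list(n_samples = n_samples, gc = gc,
                 reads_per_sample = reads_per_sample,
                 length_mean = length_mean, length_sd = length_sd,
                 ambig_rate = ambig_rate, dup_rate = dup_rate,
                 coding_fraction = coding_fraction,
                 protein_shift = protein_shift, seed = as.integer(seed)),
            class = "gradient_spec")
}

# endmember amino-acid frequency vectors (one-letter keyed, sum to 1)
aa_endmembers <- function() {
  letters20 <- sort(monomer_table("amino_acid")$symbol)
  base <- setNames(rep(1, 20), letters20)
  reduced <- base
  reduced[c("L", "I", "V", "F", "M")] <- 3
  oxidized <- base
  oxidized[c("G", "S", "D", "N", "T")] <- 3
  list(reduced = reduced / sum(reduced), oxidized = oxidized / sum(oxidized))
}

#' Generate a full synthetic gradient dataset
#'
#' Generates one sample per gradient point (reads plus coding genes and
#' proteins), optionally writes FASTA files, a strand sidecar, a manifest
#' TSV and a truth TSV under `dir`, and returns everything in memory.
#' Sample 1 is the most reducing (lowest GC), sample `n` the most
#' oxidizing.
#'
#' @param spec A [gradient_spec()].
#' @param dir Output directory (created); `NULL` for in-memory only.
#' @return List: `samples` (named list with `reads`, `cds`, `proteins`,
#'   `strand`, `truth` per sample), `manifest` (tibble, one row per sample:
#'   `sample`, `rank`, `redox`, `kind`, and file paths when written), and
#'   `truth` (tibble of per-sample true `gc`, `zc_dna`, `zc_protein`).
#' @export
gen_gradient <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "gradient_spec"))
  em <- aa_endmembers()
  n <- spec$n_samples
  mix <- if (n == 1) 0.5 else seq(0, 1, length.out = n)
  samples <- list()
  truth_rows <- list()
  for (i in seq_len(n)) {
    label <- sprintf("S%02d", i)
    rd <- gen_reads(spec$gc[i], spec$reads_per_sample, spec$length_mean,
                    spec$length_sd, spec$ambig_rate, spec$dup_rate,
                    seed = derive_seed(spec$seed, i, 1), prefix = label)
    w <- mix[i] * spec$protein_shift + (1 - spec$protein_shift) * 0.5
    aa_freqs <- (1 - w) * em$reduced + w * em$oxidized
    n_genes <- max(10L, as.integer(round(
      spec$coding_fraction * spec$reads_per_sample *
        spec$length_mean / (3 * 100))))
    cd <- gen_cds(aa_freqs, n_genes = n_genes,
                  seed = derive_seed(spec$seed, i, 2),
                  prefix = paste0(label, "g"))
    samples[[label]] <- c(rd["reads"], cd[c("cds", "proteins", "strand")],
                          list(truth = c(rd$truth, cd$truth)))
    truth_rows[[label]] <- tibble(
      sample = label, rank = i, gc = spec$gc[i],
      zc_dna = rd$truth$zc_dna, zc_protein = cd$truth$zc_protein)
  }
  truth <- dplyr::bind_rows(truth_rows)
  manifest <- tibble(sample = names(samples), rank = seq_len(n),
                     redox = ifelse(seq_len(n) <= n / 2, "reducing",
                                    "oxidizing"),
                     kind = "reads")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- purrr::imap_dfr(samples, function(s, label) {
      reads_path <- file.path(dir, paste0(label, "_reads.fasta"))
      cds_path <- file.path(dir, paste0(label, "_cds.fasta"))
      prot_path <- file.path(dir, paste0(label, "_proteins.fasta"))
      strand_path <- file.path(dir, paste0(label, "_strand.tsv"))
      write_fasta(s$reads, reads_path)
      write_fasta(s$cds, cds_path)
      write_fasta(s$proteins, prot_path)
      readr::write_tsv(tibble(read_id = s$cds$id, strand = s$strand),
                       strand_path, col_names = FALSE)
      tibble(sample = label, reads = reads_path, cds = cds_path,
             proteins = prot_path, strands = strand_path)
    })
    manifest <- dplyr::left_join(manifest, paths, by = "sample")
    readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
    readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  }
  list(samples = samples, manifest = manifest, truth = truth)
}
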