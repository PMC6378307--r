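#' Pool reads into a double-stranded DNA composition
#'
#' Counts unambiguous bases over all reads and base-pairs them: every A or T
#' counted on the sequenced strand contributes one A-T pair, every G or C one
#' G-C pair. Working with the double-stranded composition makes the pooled
#' Z_C invariant to which strand was sequenced and to GC skew between
#' leading and lagging strands. Ambiguity codes are excluded from all counts.
#'
#' @param reads Reads tibble (`id`, `seq`).
#' @param sample Optional sample label stored in the result.
#' @return One-row tibble: `sample`, `n_reads`, `n_bases`, base counts
#'   `A`, `C`, `G`, `T`, pair counts `at_pairs`, `gc_pairs`, and `gc`
#'   (GC fraction).
#' @export
pool_dsdna <- function(reads, sample = NA_character_) {
  check_reads(reads)
  counts <- base_counts(reads$seq)
  n_bases <- sum(counts)
  if (n_bases == 0) stop("no unambiguous bases to pool", call. = FALSE)
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  tibble(sample = sample, n_reads = nrow(reads), n_bases = n_bases,
         A = counts[["A"]], C = counts[["C"]], G = counts[["G"]],
         T = counts[["T"]], at_pairs = at, gc_pairs = gc,
         gc = gc / (at + gc))
}

base_counts <- function(seqs) {
  set <- Biostrings::DNAStringSet(seqs)
  colSums(Biostrings::letterFrequency(set, letters = c("A", "C", "G", "T")))
}

#' GC content of a dsDNA pool
#'
#' @param pool Tibble from [pool_dsdna()].
#' @return Numeric vector of GC fractions.
#' @export
gc_content <- function(pool) {
  pool$gc_pairs / (pool$gc_pairs + pool$at_pairs)
}

#' Z_C of pooled double-stranded DNA
#'
#' Sums the elemental compositions of one dA+dT nucleoside pair per A-T
#' count and one dG+dC pair per G-C count, then applies the carbon
#' oxidation state quotient. Because the only compositional degree of
#' freedom of dsDNA is its GC fraction f, the result equals the closed form
#' (10 + 4f) / (20 - f), available directly as [zc_dsdna_gc()] (used for
#' generator truth tables).
#'
#' @param pool Tibble from [pool_dsdna()] (one or more rows).
#' @return Numeric vector of Z_C values.
#' @examples
#' zc_dsdna_gc(c(0, 1))   # 0.50 and 14/19
#' @export
zc_dsdna <- function(pool) {
  if (any(pool$at_pairs + pool$gc_pairs <= 0)) {
    stop("pool has no base pairs", call. = FALSE)
  }
  ns <- nucleoside_set("dna")
  at_pair <- combine_compositions(ns[ns$base %in% c("A", "T"), ],
                                  normalize = FALSE)
  gc_pair <- combine_compositions(ns[ns$base %in% c("G", "C"), ],
                                  normalize = FALSE)
  vapply(seq_len(nrow(pool)), function(i) {
    comp <- combine_compositions(
      dplyr::bind_rows(at_pair, gc_pair),
      weights = c(pool$at_pairs[i], pool$gc_pairs[i]),
      normalize = FALSE)
    zc(comp)
  }, numeric(1))
}

#' @rdname zc_dsdna
#' @param f GC fraction(s) in \[0, 1\].
#' @export
zc_dsdna_gc <- function(f) {
  stopifnot(all(f >= 0 & f <= 1))
  (10 + 4 * f) / (20 - f)
}

#' Pool coding sequences into an mRNA composition
#'
#' Counts unambiguous bases of positive-sense coding sequences as
#' ribonucleosides (T read as U). Orient the input first with
#' [orient_cds()] if it contains negative-sense genes.
#'
#' @param reads Positive-sense CDS reads tibble.
#' @param sample Optional sample label.
#' @return One-row tibble: `sample`, `n_bases`, `rA`, `rC`, `rG`, `rU`.
#' @export
pool_rna <- function(reads, sample = NA_character_) {
  check_reads(reads)
  counts <- base_counts(reads$seq)
  if (sum(counts) == 0) stop("no unambiguous bases to pool", call. = FALSE)
  tibble(sample = sample, n_bases = sum(counts),
         rA = counts[["A"]], rC = counts[["C"]],
         rG = counts[["G"]], rU = counts[["T"]])
}

#' Z_C of a single-stranded RNA pool
#'
#' Sums ribonucleoside compositions weighted by base counts. With
#' `thymine = TRUE` the hypothetical T-bearing ribonucleoside replaces
#' uridine, isolating the ribose-for-deoxyribose displacement (+0.2 at any
#' fixed base composition) from the uracil-for-thymine substitution.
#'
#' @param rna_pool Tibble from [pool_rna()] (columns `rA`, `rC`, `rG`,
#'   `rU`), or a named numeric vector with those names.
#' @param thymine Use the T-bearing variant of the pyrimidine.
#' @return Numeric vector of Z_C values.
#' @export
zc_rna <- function(rna_pool, thymine = FALSE) {
  if (is.numeric(rna_pool)) rna_pool <- as_tibble(as.list(rna_pool))
  need <- c("rA", "rC", "rG", "rU")
  stopifnot(all(need %in% names(rna_pool)))
  ns <- nucleoside_set(if (thymine) "rna_thymine" else "rna")
  ns <- ns[match(c("A", "C", "G", if (thymine) "T" else "U"), ns$base), ]
  vapply(seq_len(nrow(rna_pool)), function(i) {
    w <- as.numeric(rna_pool[i, need])
    if (sum(w) <= 0) stop("empty RNA pool", call. = FALSE)
    zc(combine_compositions(ns, weights = w, normalize = FALSE))
  }, numeric(1))
}

#' Pool protein sequences into amino-acid counts
#'
#' @param aa_seqs Tibble of predicted protein sequences (`id`, `seq`,
#'   one-letter residues; `*` and `X` are ignored).
#' @param sample Optional sample label.
#' @return One-row tibble: `sample`, `n_aa`, and one count column per
#'   amino-acid one-letter code.
#' @export
pool_protein <- function(aa_seqs, sample = NA_character_) {
  check_reads(aa_seqs)
  letters20 <- sort(monomer_table("amino_acid")$symbol)
  set <- Biostrings::AAStringSet(gsub("[^A-Z]", "", toupper(aa_seqs$seq)))
  counts <- colSums(Biostrings::letterFrequency(set, letters = letters20))
  dplyr::bind_cols(tibble(sample = sample, n_aa = sum(counts)),
                   as_tibble(as.list(counts)))
}

#' Z_C of a pooled protein composition
#'
#' Sums free-amino-acid compositions weighted by residue counts. By the
#' dehydration invariance of the oxidation-state quotient, using free amino
#' acids or peptide residues gives the same Z_C.
#'
#' @param aa_pool Tibble from [pool_protein()], or a named numeric vector of
#'   counts keyed by one-letter or three-letter amino-acid codes.
#' @return Numeric vector of Z_C values.
#' @examples
#' zc_protein(c(Ala = 50, Gly = 50))   # 0.4
#' @export
zc_protein <- function(aa_pool) {
  aa <- aa_set()
  if (is.numeric(aa_pool)) {
    keys <- names(aa_pool)
    idx <- match(keys, aa$id)
    idx[is.na(idx)] <- match(keys[is.na(idx)], aa$symbol)
    if (any(is.na(idx))) {
      stop("unknown amino acid(s): ", paste(keys[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    if (sum(aa_pool) <= 0) stop("empty protein pool", call. = FALSE)
    return(zc(combine_compositions(aa[idx, ], weights = as.numeric(aa_pool),
                                   normalize = FALSE)))
  }
  stopifnot(all(aa$symbol %in% names(aa_pool)))
  vapply(seq_len(nrow(aa_pool)), function(i) {
    w <- as.numeric(aa_pool[i, aa$symbol])
    if (sum(w) <= 0) stop("empty protein pool", call. = FALSE)
    zc(combine_compositions(aa, weights = w, normalize = FALSE))
  }, numeric(1))
}

#' Per-taxon dsDNA pools
#'
#' Splits classified reads by taxon and pools each taxon that makes up at
#' least `min_fraction` of the classified reads *and* carries at least
#' `min_bases` unambiguous bases; taxa below either threshold are too
#' sparsely sampled for a stable species-level composition and are dropped.
#'
#' @param reads Reads tibble (typically post-filtering/dereplication).
#' @param assignments Tibble mapping `read_id` to `taxon_id` (a subset of
#'   reads; unclassified reads are simply absent).
#' @param min_fraction Minimum fraction of classified reads.
#' @param min_bases Minimum total unambiguous bases.
#' @return Tibble, one row per retained taxon: `taxon`, `fraction`, and the
#'   [pool_dsdna()] columns. Zero rows when no taxon qualifies.
#' @export
taxon_pools <- function(reads, assignments, min_fraction = 0.01,
                        min_bases = 20000) {
  groups <- split_taxa(reads, assignments, min_fraction, min_bases)
  if (length(groups) == 0) {
    return(tibble(taxon = character(), fraction = numeric()))
  }
  purrr::imap_dfr(groups, function(g, taxon) {
    dplyr::bind_cols(tibble(taxon = taxon, fraction = g$fraction),
                     pool_dsdna(g$reads))
  })
}

split_taxa <- function(reads, assignments, min_fraction, min_bases) {
  stopifnot(all(c("read_id", "taxon_id") %in% names(assignments)))
  hit <- dplyr::inner_join(reads,
                           dplyr::distinct(assignments, .data$read_id,
                                           .keep_all = TRUE),
                           by = c(id = "read_id"))
  if (nrow(hit) == 0) return(list())
  n_classified <- nrow(hit)
  by_taxon <- split(hit, hit$taxon_id)
  out <- list()
  for (taxon in names(by_taxon)) {
    g <- by_taxon[[taxon]]
    fraction <- nrow(g) / n_classified
    bases <- sum(base_counts(g$seq))
    if (fraction >= min_fraction && bases >= min_bases) {
      out[[taxon]] <- list(reads = g[c("id", "seq")], fraction = fraction)
    }
  }
  out
}

#' Read a taxon-assignment table
#'
#' Two-column TSV (`read_id`, `taxon_id`), the format written by
#' Kraken-style classifiers' per-read output after column selection.
#'
#' @param path TSV path.
#' @return Tibble with columns `read_id`, `taxon_id`.
#' @export
read_taxon_assignments <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("read_id", "taxon_id"),
                         col_types = "cc", progress = FALSE, comment = "#")
  if (identical(tolower(tab$read_id[1]), "read_id")) tab <- tab[-1, ]
  tab
}
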