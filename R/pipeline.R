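#' Default pipeline configuration
#'
#' @param ... Overrides of: `seed` (integer), `target_units` (50,000 bases
#'   or amino acids per subsample), `reps` (100), `taxa_target_units`
#'   (10,000), `eh_min`, `eh_max`, `eh_length` (Eh grid, volts),
#'   `temperature` (K), `basis_activities` (named overrides, see
#'   [default_basis()]), `reducing_samples` / `oxidizing_samples` (labels;
#'   default lowest/highest gradient rank), `rna_offset` (0.28, the display
#'   constant subtracted from Z_C of RNA in trend exports only),
#'   `max_bases` (optional per-sample cap emulating partial input files),
#'   `min_fraction`, `min_bases` (taxon thresholds).
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(seed = 1L, target_units = 50000, reps = 100,
              taxa_target_units = 10000, eh_min = -0.35, eh_max = 0.05,
              eh_length = 128, temperature = 298.15, basis_activities = NULL,
              reducing_samples = NULL, oxidizing_samples = NULL,
              rna_offset = 0.28, max_bases = NULL,
              min_fraction = 0.01, min_bases = 20000)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop("unknown config option(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' @param path YAML (or JSON, a YAML subset) file with any of the
#'   [default_config()] keys.
#' @return Full configuration list (defaults merged).
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' Read a dataset manifest
#'
#' A manifest names the ordered samples of a dataset: columns `sample`,
#' `reads` (FASTA/FASTQ path), `rank` (unique gradient order, reducing ->
#' oxidizing), and optionally `redox` (annotation), `kind` (`"reads"`,
#' the default, or `"contigs"`), `cds`, `proteins`, `strands`, `taxa`
#' (paths to gene-caller outputs, a strand sidecar, and a read-taxon
#' table).
#'
#' @param path TSV or YAML manifest.
#' @return Manifest tibble.
#' @export
read_manifest <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    entries <- yaml::read_yaml(path)
    man <- dplyr::bind_rows(lapply(entries, as_tibble))
  } else {
    man <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  validate_manifest(man)
}

validate_manifest <- function(man) {
  stopifnot(all(c("sample", "reads", "rank") %in% names(man)))
  if (anyDuplicated(man$rank)) stop("gradient ranks must be unique",
                                    call. = FALSE)
  if (!"kind" %in% names(man)) man$kind <- "reads"
  if (!"redox" %in% names(man)) man$redox <- NA_character_
  stopifnot(all(man$kind %in% c("reads", "contigs")))
  man[order(man$rank), ]
}

manifest_path <- function(man, i, col) {
  if (!col %in% names(man)) return(NULL)
  v <- man[[col]][i]
  if (is.na(v) || !nzchar(v)) NULL else v
}

#' Run the whole analysis over a dataset
#'
#' End-to-end orchestration: per sample, read the sequences, (for
#' unassembled reads) length-filter and dereplicate, pool to dsDNA
#' composition, and estimate Z_C of DNA -- and of mRNA and proteins where
#' gene-caller outputs are given -- by subsampling; then fit the
#' thermodynamic model across samples (average-monomer reactions, affinity
#' versus Eh, baseline-relative curves, quadrant verdict) and, where
#' taxon assignments are given, per-species Z_C estimates. Contig inputs
#' skip filtering and dereplication (logged as skipped). Everything is
#' deterministic under the configured seed.
#'
#' @param manifest Manifest tibble (see [read_manifest()]) or path.
#' @param config Configuration list from [default_config()] /
#'   [read_run_config()].
#' @return Object of class `zc_run`: list with tibbles `samples` (per-sample
#'   counts, GC, and Z_C estimates with SDs), `trend` (display table with
#'   the RNA offset applied), `dna_vs_protein`, `affinity` (long table with
#'   `rel_affinity` when >= 2 samples have proteins), `taxa`, `logs`
#'   (per-stage read counts), plus `quadrant` and `config`.
#' @export
run_dataset <- function(manifest, config = default_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  manifest <- validate_manifest(manifest)
  eh <- seq(config$eh_min, config$eh_max, length.out = config$eh_length)
  basis <- default_basis(config$basis_activities)
  logs <- list(); rows <- list(); taxa_rows <- list()
  dna_pools <- list(); protein_pools <- list()
  for (i in seq_len(nrow(manifest))) {
    label <- manifest$sample[i]
    res <- tryCatch(
      process_sample(manifest, i, config),
      error = function(e) {
        stop("sample '", label, "': ", conditionMessage(e), call. = FALSE)
      })
    logs[[label]] <- res$log
    rows[[label]] <- res$row
    dna_pools[[label]] <- res$dna_pool
    if (!is.null(res$protein_pool)) protein_pools[[label]] <- res$protein_pool
    if (!is.null(res$taxa)) taxa_rows[[label]] <- res$taxa
  }
  samples <- dplyr::bind_rows(rows)
  trend <- samples |>
    dplyr::transmute(.data$sample, .data$rank, .data$redox, .data$gc,
                     zc_dna = .data$zc_dna,
                     zc_rna_display = .data$zc_rna - config$rna_offset,
                     zc_protein = .data$zc_protein)
  dna_vs_protein <- samples[c("sample", "rank", "zc_dna", "zc_protein")]
  affinity <- NULL; quadrant <- NULL
  if (length(protein_pools) >= 2) {
    both <- intersect(names(dna_pools), names(protein_pools))
    curves <- dplyr::bind_rows(
      sample_affinities(dna_pools[both], "dna", eh, basis,
                        config$temperature),
      sample_affinities(protein_pools[both], "protein", eh, basis,
                        config$temperature))
    affinity <- relative_affinity(curves)
    red <- config$reducing_samples %||%
      manifest$sample[which.min(manifest$rank)]
    oxi <- config$oxidizing_samples %||%
      manifest$sample[which.max(manifest$rank)]
    red <- intersect(red, both); oxi <- intersect(oxi, both)
    if (length(red) && length(oxi)) {
      quadrant <- quadrant_classify(affinity, red, oxi)
    }
  }
  out <- list(samples = samples, trend = trend,
              dna_vs_protein = dna_vs_protein, affinity = affinity,
              quadrant = quadrant,
              taxa = if (length(taxa_rows)) dplyr::bind_rows(taxa_rows),
              logs = dplyr::bind_rows(logs), config = config)
  class(out) <- "zc_run"
  out
}

process_sample <- function(manifest, i, config) {
  label <- manifest$sample[i]
  kind <- manifest$kind[i]
  reads <- read_sequences(manifest$reads[i], "dna",
                          max_bases = config$max_bases)
  log <- list(tibble(sample = label, stage = "input", n_reads = nrow(reads),
                     note = if (!is.null(config$max_bases))
                       paste0("max_bases=", config$max_bases) else NA))
  if (kind == "reads") {
    reads <- length_filter(reads)
    log <- c(log, list(tibble(sample = label, stage = "length_filter",
                              n_reads = nrow(reads), note = NA)))
    reads <- dereplicate(reads)
    log <- c(log, list(tibble(sample = label, stage = "dereplicate",
                              n_reads = nrow(reads), note = NA)))
  } else {
    log <- c(log, list(tibble(sample = label,
                              stage = c("length_filter", "dereplicate"),
                              n_reads = nrow(reads), note = "skipped (contigs)")))
  }
  pool <- pool_dsdna(reads, sample = label)
  est_dna <- subsample_zc(reads, target_units = config$target_units,
                          reps = config$reps,
                          seed = derive_seed(config$seed, i, 1))
  row <- tibble(sample = label, rank = manifest$rank[i],
                redox = manifest$redox[i], kind = kind,
                n_reads = nrow(reads), n_bases = pool$n_bases, gc = pool$gc,
                zc_dna = est_dna$mean, zc_dna_sd = est_dna$sd,
                zc_rna = NA_real_, zc_rna_sd = NA_real_,
                zc_protein = NA_real_, zc_protein_sd = NA_real_)
  protein_pool <- NULL; taxa <- NULL
  cds_path <- manifest_path(manifest, i, "cds")
  if (!is.null(cds_path)) {
    cds <- read_sequences(cds_path, "dna")
    strand_path <- manifest_path(manifest, i, "strands")
    strand <- if (!is.null(strand_path)) {
      read_strand_table(strand_path, cds)
    }
    cds <- orient_cds(cds, strand)
    est_rna <- subsample_zc(cds, zc_fn = function(r) zc_rna(pool_rna(r)),
                            target_units = config$target_units,
                            reps = config$reps,
                            seed = derive_seed(config$seed, i, 2))
    row$zc_rna <- est_rna$mean; row$zc_rna_sd <- est_rna$sd
    log <- c(log, list(tibble(sample = label, stage = "cds",
                              n_reads = nrow(cds), note = NA)))
  }
  prot_path <- manifest_path(manifest, i, "proteins")
  if (!is.null(prot_path)) {
    prot <- read_sequences(prot_path, "aa")
    protein_pool <- pool_protein(prot, sample = label)
    est_aa <- subsample_zc(prot, zc_fn = function(r) zc_protein(pool_protein(r)),
                           target_units = config$target_units,
                           reps = config$reps,
                           seed = derive_seed(config$seed, i, 3),
                           unit_kind = "amino-acids")
    row$zc_protein <- est_aa$mean; row$zc_protein_sd <- est_aa$sd
    log <- c(log, list(tibble(sample = label, stage = "proteins",
                              n_reads = nrow(prot), note = NA)))
  }
  taxa_path <- manifest_path(manifest, i, "taxa")
  if (!is.null(taxa_path)) {
    assignments <- read_taxon_assignments(taxa_path)
    sp <- species_zc(reads, assignments,
                     target_units = config$taxa_target_units,
                     reps = config$reps,
                     seed = derive_seed(config$seed, i, 4),
                     min_fraction = config$min_fraction,
                     min_bases = config$min_bases)
    if (nrow(sp)) taxa <- dplyr::bind_cols(tibble(sample = label), sp)
    log <- c(log, list(tibble(sample = label, stage = "taxa",
                              n_reads = nrow(sp), note = NA)))
  }
  list(row = row, log = dplyr::bind_rows(log), dna_pool = pool,
       protein_pool = protein_pool, taxa = taxa)
}

#' Write the result tables of a run
#'
#' Emits the per-sample estimates, the trend display table (with the RNA
#' offset), the DNA-versus-protein comparison, the long-format affinity
#' table, the quadrant endpoint summary, per-taxon estimates and per-stage
#' logs as TSV files.
#'
#' @param run A `zc_run` from [run_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset_results <- function(run, dir) {
  stopifnot(inherits(run, "zc_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(run$trend, file.path(dir, "trend.tsv"))
  readr::write_tsv(run$dna_vs_protein, file.path(dir, "dna_vs_protein.tsv"))
  if (!is.null(run$affinity)) {
    readr::write_tsv(run$affinity, file.path(dir, "affinity.tsv"))
  }
  if (!is.null(run$quadrant)) {
    readr::write_tsv(run$quadrant$endpoints,
                     file.path(dir, "quadrant_endpoints.tsv"))
  }
  if (!is.null(run$taxa)) {
    readr::write_tsv(run$taxa, file.path(dir, "taxa.tsv"))
  }
  readr::write_tsv(run$logs, file.path(dir, "logs.tsv"))
  invisible(dir)
}

#' @export
print.zc_run <- function(x, ...) {
  cat("<zc_run>", nrow(x$samples), "samples\n")
  print(x$samples[c("sample", "rank", "gc", "zc_dna", "zc_rna",
                    "zc_protein")])
  if (!is.null(x$quadrant)) {
    cat("thermodynamic model:",
        if (x$quadrant$hangs_together) "hangs together" else "falls apart",
        "\n")
  }
  invisible(x)
}
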