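# run code under a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# deterministic derived seed, kept inside 32-bit integer range
derive_seed <- function(seed, ...) {
  idx <- c(...)
  as.integer((as.double(seed) + sum(as.double(idx) * 7919^seq_along(idx))) %%
               2147483587)
}

#' Subsampling estimate of Z_C
#'
#' Estimates the mean and standard deviation of Z_C over random read
#' subsamples. Each replicate includes every sequence independently with
#' probability `target_units / total_units`, so the expected subsample size
#' equals the target (in bases or amino acids); the supplied `zc_fn` is then
#' evaluated on the included pool. Replicates that draw zero units are
#' redrawn (and counted in `redraws`) so the number of scored replicates
#' stays fixed. The subsample typically covers a small fraction of the data:
#' larger targets shrink the error bars but barely move the means.
#'
#' @param reads Tibble of sequences (`id`, `seq`).
#' @param zc_fn Function mapping a reads tibble to a single Z_C value.
#'   Defaults to pooled dsDNA Z_C.
#' @param target_units Expected subsample size, in `unit_kind` units.
#' @param reps Number of replicates.
#' @param seed Integer seed; the whole estimate is reproducible from it.
#' @param unit_kind `"bases"` (unambiguous ACGT count) or `"amino-acids"`
#'   (residue count); sets how sequence units are counted.
#' @param keep_replicates Attach the per-replicate Z_C values and unit
#'   counts as attribute `"replicates"` (exportable with
#'   [write_zc_replicates()]).
#' @return One-row tibble of class `zc_estimate`: `mean`, `sd`, `reps`,
#'   `target_units`, `unit_kind`, `redraws`.
#' @export
subsample_zc <- function(reads, zc_fn = function(r) zc_dsdna(pool_dsdna(r)),
                         target_units = 50000, reps = 100, seed = NULL,
                         unit_kind = c("bases", "amino-acids"),
                         keep_replicates = FALSE) {
  check_reads(reads)
  unit_kind <- match.arg(unit_kind)
  units <- if (unit_kind == "bases") {
    nchar(gsub("[^ACGT]", "", reads$seq))
  } else {
    nchar(gsub("[^A-Z]", "", toupper(reads$seq)))
  }
  total <- sum(units)
  if (total <= 0) stop("source has zero countable units", call. = FALSE)
  if (target_units > total) {
    stop("target_units (", target_units, ") exceeds source total (", total,
         ")", call. = FALSE)
  }
  p <- target_units / total
  n <- nrow(reads)
  vals <- numeric(reps)
  sizes <- numeric(reps)
  redraws <- 0L
  with_seed(seed, {
    for (i in seq_len(reps)) {
      repeat {
        take <- runif(n) < p
        if (sum(units[take]) > 0) break
        redraws <- redraws + 1L
      }
      vals[i] <- zc_fn(reads[take, ])
      sizes[i] <- sum(units[take])
    }
  })
  est <- tibble(mean = mean(vals), sd = stats::sd(vals), reps = reps,
                target_units = target_units, unit_kind = unit_kind,
                redraws = redraws)
  class(est) <- c("zc_estimate", class(est))
  if (keep_replicates) {
    attr(est, "replicates") <- tibble(replicate = seq_len(reps),
                                      units = sizes, zc = vals)
  }
  est
}

#' Per-species Z_C estimates
#'
#' Applies [subsample_zc()] to the reads classified to each taxon passing
#' the abundance thresholds of [taxon_pools()]. The default 10,000-base
#' target is smaller than the whole-metagenome 50,000 because few reads are
#' classified to any single species; the cost is a larger standard
#' deviation.
#'
#' @inheritParams taxon_pools
#' @inheritParams subsample_zc
#' @return Tibble, one row per retained taxon: `taxon`, `fraction`, plus the
#'   `zc_estimate` columns. Per-taxon substreams are derived
#'   deterministically from `seed` and the taxon's rank order.
#' @export
species_zc <- function(reads, assignments, target_units = 10000, reps = 100,
                       seed = NULL, min_fraction = 0.01, min_bases = 20000) {
  groups <- split_taxa(reads, assignments, min_fraction, min_bases)
  if (length(groups) == 0) {
    return(tibble(taxon = character(), fraction = numeric()))
  }
  taxa <- sort(names(groups))
  purrr::map_dfr(seq_along(taxa), function(i) {
    g <- groups[[taxa[i]]]
    est <- subsample_zc(g$reads, target_units = target_units, reps = reps,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, i))
    dplyr::bind_cols(tibble(taxon = taxa[i], fraction = g$fraction), est)
  })
}

#' Export per-replicate subsample compositions
#'
#' Writes the per-replicate Z_C values and unit counts retained by
#' `subsample_zc(..., keep_replicates = TRUE)` as a TSV, mirroring the
#' intermediate tables a reproducible analysis deposits alongside figures.
#'
#' @param est A `zc_estimate` with the `"replicates"` attribute.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_zc_replicates <- function(est, path) {
  reps <- attr(est, "replicates")
  if (is.null(reps)) {
    stop("estimate was not built with keep_replicates = TRUE", call. = FALSE)
  }
  readr::write_tsv(reps, path)
  invisible(path)
}
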