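#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for pipeline results
#'
#' `tidy()` on a `zc_run` returns the per-sample estimate table; `glance()`
#' returns a one-row dataset summary (sample count, DNA-protein Z_C
#' correlation, rank correlation of Z_C of DNA with gradient order, and the
#' quadrant verdict).
#'
#' @param x A `zc_run` from [run_dataset()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.zc_run <- function(x, ...) {
  x$samples
}

#' @rdname tidy.zc_run
#' @export
glance.zc_run <- function(x, ...) {
  s <- x$samples
  cor_dp <- if (sum(!is.na(s$zc_protein)) >= 3) {
    stats::cor(s$zc_dna, s$zc_protein, use = "complete.obs")
  } else NA_real_
  tibble(
    n_samples = nrow(s),
    cor_dna_protein = cor_dp,
    cor_dna_rank = stats::cor(s$zc_dna, s$rank, method = "spearman"),
    hangs_together = if (!is.null(x$quadrant)) x$quadrant$hangs_together
                     else NA
  )
}

#' Tidiers for balanced reactions and quadrant verdicts
#'
#' `tidy()` on a `zc_reaction` returns the basis coefficients; `glance()` a
#' one-row summary (electron count, standard reaction Gibbs energy).
#' `tidy()` on a `zc_quadrant` returns the endpoint table; `glance()` the
#' verdict.
#'
#' @param x A `zc_reaction` or `zc_quadrant`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.zc_reaction <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.zc_reaction
#' @export
glance.zc_reaction <- function(x, ...) {
  tibble(n_electrons = x$n_electrons, delta_g_kj = x$delta_g_kj,
         zc = nosc(x$product))
}

#' @rdname tidy.zc_reaction
#' @export
tidy.zc_quadrant <- function(x, ...) {
  x$endpoints
}

#' @rdname tidy.zc_reaction
#' @export
glance.zc_quadrant <- function(x, ...) {
  tibble(hangs_together = x$hangs_together,
         n_endpoints = nrow(x$endpoints),
         n_quadrant1 = sum(x$endpoints$quadrant == 1L, na.rm = TRUE))
}
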