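#' Z_C trends along the gradient
#'
#' Plots per-sample Z_C of DNA, RNA and protein against gradient rank
#' (oxidizing conditions to the right), with mean +/- 1 subsampling SD
#' error bars. The display constant configured as `rna_offset` is
#' subtracted from Z_C of RNA so that DNA and RNA fit on one panel; stored
#' values are never offset.
#'
#' @param run A `zc_run` from [run_dataset()].
#' @return A ggplot object.
#' @export
plot_zc_gradient <- function(run) {
  stopifnot(inherits(run, "zc_run"))
  off <- run$config$rna_offset
  s <- run$samples
  long <- dplyr::bind_rows(
    tibble(sample = s$sample, rank = s$rank, kind = "DNA",
           zc = s$zc_dna, sd = s$zc_dna_sd),
    tibble(sample = s$sample, rank = s$rank,
           kind = sprintf("RNA - %.2f", off),
           zc = s$zc_rna - off, sd = s$zc_rna_sd),
    tibble(sample = s$sample, rank = s$rank, kind = "protein",
           zc = s$zc_protein, sd = s$zc_protein_sd))
  long <- long[!is.na(long$zc), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$zc,
                                     colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$zc - .data$sd,
                                        ymax = .data$zc + .data$sd),
                           width = 0.1) +
    ggplot2::labs(x = "gradient rank (oxidizing →)",
                  y = expression(italic(Z)[C]), colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_zc_gradient
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.zc_run <- function(object, ...) {
  plot_zc_gradient(object)
}

#' Affinity and relative-affinity curves
#'
#' `plot_affinity()` shows the (nearly coincident) absolute affinity curves
#' per monomer versus Eh; `plot_relative_affinity()` shows the
#' baseline-subtracted curves on which sample differences are visible.
#'
#' @param curves Long affinity tibble from [sample_affinities()] or
#'   [relative_affinity()] (or the `affinity` element of a `zc_run`).
#' @return A ggplot object.
#' @export
plot_affinity <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$eh, y = .data$affinity,
                                       colour = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = "Eh (V)", y = "A / 2.303RT", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_affinity
#' @export
plot_relative_affinity <- function(curves) {
  stopifnot("rel_affinity" %in% names(curves))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$eh, y = .data$rel_affinity,
                                       colour = .data$sample)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = "Eh (V)", y = "relative A / 2.303RT", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Quadrant cross-plot of relative affinities
#'
#' DNA versus protein relative affinity with the evaluated gradient
#' endpoints marked; a model that hangs together has all endpoint dots in
#' quadrant I.
#'
#' @param rel Tibble from [relative_affinity()] with both kinds.
#' @param quadrant Optional `zc_quadrant` whose endpoints are overplotted.
#' @return A ggplot object.
#' @export
plot_quadrant <- function(rel, quadrant = NULL) {
  wide <- rel |>
    dplyr::select("sample", "kind", "eh", "rel_affinity") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "rel_affinity")
  p <- ggplot2::ggplot(wide, ggplot2::aes(x = .data$dna, y = .data$protein,
                                          colour = .data$sample)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::labs(x = "relative affinity, DNA (per base pair)",
                  y = "relative affinity, protein (per amino acid)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(quadrant)) {
    p <- p + ggplot2::geom_point(data = quadrant$endpoints, size = 3,
                                 ggplot2::aes(x = .data$dna,
                                              y = .data$protein,
                                              colour = .data$sample))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
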