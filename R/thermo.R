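#' Default basis species and activities
#'
#' The inorganic basis in terms of which biomolecule formation reactions are
#' balanced, with fixed decimal log activities: H2O (0), HCO3- (-3),
#' H2PO4- (-5), NH4+ (-7), HS- (-9), H+ (-7, i.e. pH 7); the electron's
#' log activity is not fixed but driven by Eh,
#' log a(e-) = -F.Eh / (2.303RT). The element + charge matrix of this set is
#' full rank, so every CHNOSP composition balances uniquely.
#'
#' @param log_activities Optional named numeric vector overriding the
#'   defaults (names among `H2O`, `HCO3`, `H2PO4`, `NH4`, `HS`, `H+`).
#' @return Tibble of basis species with element columns, `gibbs_kj` and
#'   `log_activity` (`NA` for the electron).
#' @export
default_basis <- function(log_activities = NULL) {
  basis <- monomer_table("basis")
  act <- c(H2O = 0, HCO3 = -3, H2PO4 = -5, NH4 = -7, HS = -9, "H+" = -7,
           "e-" = NA_real_)
  if (!is.null(log_activities)) {
    bad <- setdiff(names(log_activities), setdiff(names(act), "e-"))
    if (length(bad)) {
      stop("unknown basis species in log_activities: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    act[names(log_activities)] <- log_activities
  }
  basis$log_activity <- unname(act[basis$id])
  basis
}

#' Average per-monomer composition and Gibbs energy
#'
#' Collapses a sample's pooled counts to a single average monomer: for DNA,
#' the mole-weighted mean of the two nucleotide-monophosphate base pairs
#' (dAMP2- + dTMP2- and dGMP2- + dCMP2-, weighted by A-T and G-C pair
#' counts); for protein, the mole-weighted mean amino acid. Averaging
#' normalizes away sequence length so that the energetics compare
#' compositions, not molecule sizes. The phosphate and charge carried by
#' the NMP pairs do not alter the carbon oxidation state (`zc` here is the
#' NOSC form), so the DNA monomer's `zc` equals the nucleoside-based
#' [zc_dsdna()] at the same GC fraction.
#'
#' @param pool A [pool_dsdna()] row (`kind = "dna"`) or [pool_protein()]
#'   row (`kind = "protein"`).
#' @param kind `"dna"` or `"protein"`.
#' @return One-row tibble: `kind`, element columns, `gibbs_kj`, `zc`.
#' @export
average_monomer <- function(pool, kind = c("dna", "protein")) {
  kind <- match.arg(kind)
  if (kind == "dna") {
    nmp <- monomer_table("nmp_dna")
    if (any(is.na(nmp$gibbs_kj))) {
      stop("missing Gibbs energy for: ",
           paste(nmp$id[is.na(nmp$gibbs_kj)], collapse = ", "), call. = FALSE)
    }
    pair <- function(bases) {
      rows <- nmp[nmp$symbol %in% bases, ]
      list(comp = combine_compositions(rows, normalize = FALSE),
           gibbs = sum(rows$gibbs_kj))
    }
    at <- pair(c("A", "T")); gcp <- pair(c("G", "C"))
    w <- c(pool$at_pairs, pool$gc_pairs)
    if (sum(w) <= 0) stop("pool has no base pairs", call. = FALSE)
    w <- w / sum(w)
    comp <- combine_compositions(dplyr::bind_rows(at$comp, gcp$comp),
                                 weights = w, normalize = FALSE)
    gibbs <- w[1] * at$gibbs + w[2] * gcp$gibbs
  } else {
    aa <- aa_set()
    if (any(is.na(aa$gibbs_kj))) {
      stop("missing Gibbs energy for: ",
           paste(aa$id[is.na(aa$gibbs_kj)], collapse = ", "), call. = FALSE)
    }
    stopifnot(all(aa$symbol %in% names(pool)))
    w <- as.numeric(pool[1, aa$symbol])
    if (sum(w) <= 0) stop("pool has no amino acids", call. = FALSE)
    w <- w / sum(w)
    comp <- combine_compositions(aa, weights = w, normalize = FALSE)
    gibbs <- sum(w * aa$gibbs_kj)
  }
  dplyr::bind_cols(tibble(kind = kind), comp,
                   tibble(gibbs_kj = gibbs, zc = nosc(comp)))
}

#' Balance a formation reaction against the basis
#'
#' Solves the linear element-and-charge conservation system for the unique
#' basis-species coefficients forming one mole of the product:
#' product = sum(nu_i * basis_i). The electron coefficient `n_electrons`
#' counts the electrons consumed by synthesis; with carbon supplied at +4
#' (HCO3-), nitrogen at -3 (NH4+) and sulfur at -2 (HS-), it equals
#' c * (4 - Z_C) -- the mechanism that ties carbon oxidation state to redox
#' sensitivity.
#'
#' @param product One-row composition tibble with a `gibbs_kj` column (e.g.
#'   from [average_monomer()]).
#' @param basis Basis tibble from [default_basis()].
#' @return Object of class `zc_reaction`: list with `product`,
#'   `coefficients` (tibble of species, coefficient, gibbs_kj,
#'   log_activity), `n_electrons` and `delta_g_kj` (standard reaction Gibbs
#'   energy, kJ/mol of product).
#' @examples
#' ala <- dplyr::mutate(monomers("Ala"), kind = "protein")
#' balance_reaction(ala)$n_electrons   # 12
#' @export
balance_reaction <- function(product, basis = default_basis()) {
  stopifnot(nrow(product) == 1)
  rows <- c("c", "h", "n", "o", "s", "p", "z")
  A <- t(as.matrix(as_composition(basis)[rows]))
  colnames(A) <- basis$id
  if (qr(A)$rank < length(rows)) {
    stop("basis element/charge matrix is singular; reactions cannot be " ,
         "balanced uniquely", call. = FALSE)
  }
  b <- as.numeric(as_composition(product)[1, rows])
  nu <- solve(A, b)
  resid <- max(abs(A %*% nu - b))
  if (resid > 1e-9) {
    stop("balance residual ", format(resid), " exceeds tolerance", call. = FALSE)
  }
  gibbs_prod <- product$gibbs_kj %||% NA_real_
  delta_g <- gibbs_prod - sum(nu * basis$gibbs_kj)
  out <- list(
    product = product,
    coefficients = tibble(species = basis$id, coefficient = unname(nu),
                          gibbs_kj = basis$gibbs_kj,
                          log_activity = basis$log_activity),
    n_electrons = unname(nu[["e-"]]),
    delta_g_kj = delta_g
  )
  class(out) <- "zc_reaction"
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.zc_reaction <- function(x, ...) {
  nz <- x$coefficients[abs(x$coefficients$coefficient) > 1e-12, ]
  lhs <- paste(sprintf("%.4g %s", nz$coefficient, nz$species), collapse = " + ")
  cat("<zc_reaction> product (1 mol) =", lhs, "\n")
  cat("  n_electrons:", format(x$n_electrons), "  deltaG0:",
      format(x$delta_g_kj), "kJ/mol\n")
  invisible(x)
}

log_a_electron <- function(eh, temperature = 298.15) {
  -.FARADAY * eh / (log(10) * .RGAS * temperature)
}

#' Chemical affinity of a formation reaction versus Eh
#'
#' Evaluates A / (2.303RT) = log K - log Q on an Eh grid at fixed basis
#' activities, with the electron activity set by
#' log a(e-) = -F.Eh / (2.303RT) and the product at unit activity by
#' default. The curve is affine in Eh with slope
#' -n_electrons * F / (2.303RT) per volt (about -16.9 * n_e at 25 degC), so
#' reactions consuming electrons are increasingly favored at reducing
#' (low-Eh) conditions.
#'
#' @param rxn A `zc_reaction` from [balance_reaction()].
#' @param eh Numeric Eh grid (volts). The default spans a reducing-to-
#'   oxidizing window; the model makes no claim that one window suits every
#'   environment, and the endpoints define the quadrant evaluation.
#' @param temperature Kelvin (energies are 25 degC values; changing this
#'   only rescales the log units).
#' @param product_logact Decimal log activity of the product (a common
#'   constant that cancels from relative affinities).
#' @return Tibble: `eh`, `affinity` (dimensionless log units),
#'   `affinity_kj` (kJ/mol of monomer, = 2.303RT x affinity).
#' @export
affinity_curve <- function(rxn, eh = default_eh_grid(), temperature = 298.15,
                           product_logact = 0) {
  stopifnot(inherits(rxn, "zc_reaction"))
  if (is.na(rxn$delta_g_kj)) {
    stop("reaction product has no Gibbs energy", call. = FALSE)
  }
  rt_ln10 <- log(10) * .RGAS * temperature          # J/mol per log unit
  log_k <- -rxn$delta_g_kj * 1000 / rt_ln10
  co <- rxn$coefficients
  loga <- co$log_activity
  fixed <- sum(co$coefficient[co$species != "e-"] * loga[co$species != "e-"])
  nu_e <- rxn$n_electrons
  aff <- log_k - product_logact + fixed + nu_e * log_a_electron(eh, temperature)
  tibble(eh = eh, affinity = aff, affinity_kj = aff * rt_ln10 / 1000)
}

#' @rdname affinity_curve
#' @param from,to,length.out Grid limits (volts) and resolution.
#' @export
default_eh_grid <- function(from = -0.35, to = 0.05, length.out = 128) {
  seq(from, to, length.out = length.out)
}

#' Affinity curves for a set of samples
#'
#' Convenience wrapper running [average_monomer()], [balance_reaction()] and
#' [affinity_curve()] for each sample pool.
#'
#' @param pools Named list of sample pools ([pool_dsdna()] or
#'   [pool_protein()] rows), names = sample labels.
#' @param kind `"dna"` or `"protein"`.
#' @inheritParams affinity_curve
#' @param basis Basis tibble from [default_basis()].
#' @return Long tibble: `sample`, `kind`, `eh`, `affinity`, `affinity_kj`.
#' @export
sample_affinities <- function(pools, kind, eh = default_eh_grid(),
                              basis = default_basis(), temperature = 298.15) {
  purrr::imap_dfr(pools, function(pool, label) {
    rxn <- balance_reaction(average_monomer(pool, kind), basis)
    dplyr::bind_cols(tibble(sample = label, kind = kind),
                     affinity_curve(rxn, eh, temperature))
  })
}

#' Relative affinity (per-Eh baseline subtraction)
#'
#' Subtracts, at every Eh grid point (within each `kind`), the mean
#' affinity over all samples. The absolute curves of different samples are
#' nearly indistinguishable because the electron term dominates; the
#' residuals against this virtual baseline expose the compositional
#' differences. Relative curves sum to zero at every grid point by
#' construction.
#'
#' @param curves Long tibble from [sample_affinities()] (one or several
#'   kinds). All samples must share the same Eh grid.
#' @return Input with an added `rel_affinity` column.
#' @export
relative_affinity <- function(curves) {
  stopifnot(all(c("sample", "kind", "eh", "affinity") %in% names(curves)))
  grids <- curves |>
    dplyr::group_by(.data$kind, .data$sample) |>
    dplyr::summarise(grid = paste(signif(.data$eh, 12), collapse = ","),
                     .groups = "drop")
  if (dplyr::n_distinct(grids$grid) != 1) {
    stop("samples are not on a common Eh grid", call. = FALSE)
  }
  if (dplyr::n_distinct(curves$sample) < 2) {
    stop("relative affinities need at least two samples", call. = FALSE)
  }
  curves |>
    dplyr::group_by(.data$kind, .data$eh) |>
    dplyr::mutate(rel_affinity = .data$affinity - mean(.data$affinity)) |>
    dplyr::ungroup()
}

#' Quadrant test of the redox-shaping model
#'
#' Evaluates the (DNA, protein) relative affinities of the designated
#' most-reducing samples at the low-Eh endpoint and of the most-oxidizing
#' samples at the high-Eh endpoint. The model "hangs together" when every
#' such endpoint lies strictly in quadrant I (both relative affinities
#' positive): synthesis of the observed compositions is favored, relative
#' to the dataset baseline, under the redox conditions where they were
#' found.
#'
#' @param rel Tibble from [relative_affinity()] containing both `"dna"` and
#'   `"protein"` kinds.
#' @param reducing_samples,oxidizing_samples Sample labels evaluated at the
#'   low-/high-Eh endpoints.
#' @return Object of class `zc_quadrant`: list with `hangs_together`
#'   (logical) and `endpoints` (tibble: `sample`, `role`, `eh`, `dna`,
#'   `protein`, `quadrant`).
#' @export
quadrant_classify <- function(rel, reducing_samples, oxidizing_samples) {
  stopifnot(all(c("dna", "protein") %in% rel$kind))
  labels <- c(reducing_samples, oxidizing_samples)
  miss <- setdiff(labels, unique(rel$sample))
  if (length(miss)) {
    stop("sample label(s) absent from curves: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lo <- min(rel$eh); hi <- max(rel$eh)
  eval_at <- function(samples, eh_pt, role) {
    purrr::map_dfr(samples, function(s) {
      pick <- function(k) {
        rel$rel_affinity[rel$sample == s & rel$kind == k & rel$eh == eh_pt]
      }
      tibble(sample = s, role = role, eh = eh_pt,
             dna = pick("dna"), protein = pick("protein"))
    })
  }
  pts <- dplyr::bind_rows(eval_at(reducing_samples, lo, "reducing"),
                          eval_at(oxidizing_samples, hi, "oxidizing"))
  pts$quadrant <- dplyr::case_when(
    pts$dna > 0 & pts$protein > 0 ~ 1L,
    pts$dna < 0 & pts$protein > 0 ~ 2L,
    pts$dna < 0 & pts$protein < 0 ~ 3L,
    pts$dna > 0 & pts$protein < 0 ~ 4L,
    TRUE ~ NA_integer_
  )
  out <- list(hangs_together = all(!is.na(pts$quadrant) & pts$quadrant == 1L),
              endpoints = pts)
  class(out) <- "zc_quadrant"
  out
}

#' @export
print.zc_quadrant <- function(x, ...) {
  cat("<zc_quadrant> model",
      if (x$hangs_together) "hangs together" else "falls apart",
      "\n")
  print(x$endpoints)
  invisible(x)
}
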