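#' Elemental compositions
#'
#' A composition is a one-or-more-row tibble with numeric columns `c`, `h`,
#' `n`, `o`, `s` (element counts), `p` (phosphorus count) and `z` (formal
#' charge). Counts may be fractional, so an average per-monomer formula such
#' as C2.5H6NO2 is a first-class composition. Phosphorus and charge are
#' carried for thermodynamic bookkeeping; the carbon oxidation state of
#' Eq.-style CHNOS formulas ignores them (see [zc()] and [nosc()]).
#'
#' @param c,h,n,o,s,p,z Element counts (and formal charge `z`); recycled to a
#'   common length. All element counts must be non-negative.
#' @return A tibble with columns `c`, `h`, `n`, `o`, `s`, `p`, `z`.
#' @examples
#' composition(c = 5, h = 6, n = 2, o = 2)   # thymine
#' @export
composition <- function(c = 0, h = 0, n = 0, o = 0, s = 0, p = 0, z = 0) {
  out <- tibble(c = as.numeric(c), h = as.numeric(h), n = as.numeric(n),
                o = as.numeric(o), s = as.numeric(s), p = as.numeric(p),
                z = as.numeric(z))
  bad <- c("c", "h", "n", "o", "s", "p")
  neg <- vapply(out[bad], function(x) any(x < 0), logical(1))
  if (any(neg)) {
    stop("negative element counts are not allowed: ",
         paste(bad[neg], collapse = ", "), call. = FALSE)
  }
  out
}

.ELEMENT_COLS <- c("c", "h", "n", "o", "s", "p", "z")

# coerce any data frame / named vector into composition columns
as_composition <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- as_tibble(as.list(x))
  }
  stopifnot(is.data.frame(x))
  for (el in .ELEMENT_COLS) {
    if (!el %in% names(x)) x[[el]] <- 0
  }
  x[.ELEMENT_COLS]
}

#' Parse chemical formulas
#'
#' Parses Hill-order formula strings such as `"C5H6N2O2"` or `"C2.5H6NO2"`.
#' Fractional subscripts are accepted (average per-monomer formulas), and a
#' trailing signed charge is recognised (`"C10H12N5O6P-2"`, `"NH4+"`).
#' The bare electron is written `"e-"`.
#'
#' @param formula Character vector of formulas.
#' @return A composition tibble (see [composition()]) with one row per input.
#' @examples
#' parse_formula(c("CH4", "CO2", "C2.5H6NO2", "HCO3-"))
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula))
  rows <- lapply(formula, parse_formula_one)
  dplyr::bind_rows(rows)
}

parse_formula_one <- function(f) {
  f0 <- trimws(f)
  out <- setNames(as.list(numeric(7)), .ELEMENT_COLS)
  if (f0 == "e-") {
    out$z <- -1
    return(as_tibble(out))
  }
  # trailing charge: "+", "-", "+2", "-2"
  m <- regmatches(f0, regexpr("[+-][0-9]*$", f0))
  if (length(m) == 1 && nzchar(m)) {
    mag <- sub("^[+-]", "", m)
    out$z <- (if (substr(m, 1, 1) == "+") 1 else -1) * (if (nzchar(mag)) as.numeric(mag) else 1)
    f0 <- sub("[+-][0-9]*$", "", f0)
  }
  pat <- "([A-Z][a-z]?)([0-9]*\\.?[0-9]*)"
  starts <- gregexpr(pat, f0)[[1]]
  toks <- regmatches(f0, gregexpr(pat, f0))[[1]]
  if (length(toks) == 0 || sum(attr(starts, "match.length")) != nchar(f0)) {
    stop("cannot parse formula: '", f, "'", call. = FALSE)
  }
  known <- c(C = "c", H = "h", N = "n", O = "o", S = "s", P = "p")
  for (tok in toks) {
    sym <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
    num <- sub("^[A-Z][a-z]?", "", tok)
    if (!sym %in% names(known)) {
      stop("unsupported element '", sym, "' in formula '", f, "'", call. = FALSE)
    }
    out[[known[[sym]]]] <- out[[known[[sym]]]] + (if (nzchar(num)) as.numeric(num) else 1)
  }
  as_tibble(out)
}

#' Average oxidation state of carbon
#'
#' `zc()` computes Z_C = (-h + 3n + 2o + 2s) / c for a formula
#' C_c H_h N_n O_o S_s. Phosphorus and charge are ignored by construction;
#' use [nosc()] for species where they are nonzero. `nosc()` computes the
#' nominal oxidation state of carbon, (z - h + 3n + 2o + 2s - 5p) / c, which
#' reduces to `zc()` when `p = z = 0` and is invariant under protonation
#' (h, z both +1) and phosphate condensation (+HPO3: h+1, o+3, p+1). These
#' invariances are why the oxidation state of a DNA strand equals that of
#' its constituent nucleosides: the charged sugar-phosphate backbone adds no
#' C-P bonds and cancels out of the per-carbon electron bookkeeping.
#'
#' @param comp A composition tibble (see [composition()]), a data frame with
#'   element columns, or a named numeric vector.
#' @return Numeric vector of per-row oxidation states.
#' @examples
#' zc(parse_formula(c("CH4", "CO2")))   # -4, +4
#' @export
zc <- function(comp) {
  comp <- as_composition(comp)
  if (any(comp$c <= 0)) {
    stop("Z_C is undefined for compositions without carbon (c must be > 0)",
         call. = FALSE)
  }
  (-comp$h + 3 * comp$n + 2 * comp$o + 2 * comp$s) / comp$c
}

#' @rdname zc
#' @export
nosc <- function(comp) {
  comp <- as_composition(comp)
  if (any(comp$c <= 0)) {
    stop("NOSC is undefined for compositions without carbon (c must be > 0)",
         call. = FALSE)
  }
  (comp$z - comp$h + 3 * comp$n + 2 * comp$o + 2 * comp$s - 5 * comp$p) / comp$c
}

#' Weighted combination of compositions
#'
#' Element-wise weighted sum of compositions. With `normalize = TRUE` the
#' weights are scaled to sum to 1, so the result is the average per-monomer
#' formula (e.g. 50 Ala + 50 Gly -> C2.5H6NO2). The Z_C of a combination is
#' always the carbon-weighted mean of the member Z_C values.
#'
#' @param comp Composition tibble, one row per part.
#' @param weights Non-negative weights, recycled; at least one must be > 0.
#' @param normalize Scale weights to sum to 1 (average formula) or use raw
#'   weights (total formula).
#' @return A one-row composition tibble.
#' @examples
#' ala_gly <- parse_formula(c("C3H7NO2", "C2H5NO2"))
#' combine_compositions(ala_gly)        # C2.5H6NO2
#' @export
combine_compositions <- function(comp, weights = NULL, normalize = TRUE) {
  comp <- as_composition(comp)
  if (nrow(comp) == 0) stop("empty composition set", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(comp))
  weights <- rep_len(as.numeric(weights), nrow(comp))
  if (any(weights < 0) || all(weights == 0)) {
    stop("weights must be non-negative with at least one nonzero", call. = FALSE)
  }
  if (normalize) weights <- weights / sum(weights)
  out <- lapply(comp, function(col) sum(col * weights))
  as_tibble(out)
}

#' Remove water from a composition
#'
#' Subtracts `n_water` H2O units. Dehydration (peptide-bond or phosphodiester
#' condensation) never changes Z_C: the numerator of the quotient changes by
#' -(-2) + 2(-1) = 0 per water.
#'
#' @param comp Composition tibble.
#' @param n_water Number of waters to remove (recycled).
#' @return Composition tibble with h reduced by 2 and o by 1 per water.
#' @export
dehydrate <- function(comp, n_water = 1) {
  comp <- as_composition(comp)
  comp$h <- comp$h - 2 * n_water
  comp$o <- comp$o - n_water
  if (any(comp$h < 0) || any(comp$o < 0)) {
    stop("dehydration would make h or o negative", call. = FALSE)
  }
  comp
}
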