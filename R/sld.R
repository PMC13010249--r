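# Scattering-length-density engine: components, solvent contrasts, H/D
# exchange. All SLDs are in units of 1e-6 A^-2; scattering lengths in fm;
# molecular volumes in A^3. Conversion: sld = 10 * (sum b [fm]) / V [A^3].

#' Coherent scattering length table
#'
#' Returns the bundled table of bound coherent neutron scattering lengths
#' (fm), with deuterium listed under its own symbol \code{"D"}.
#'
#' @return Named numeric vector of scattering lengths in fm.
#' @export
scattering_lengths <- function() {
  if (is.null(.reflmem$b_coh)) {
    path <- system.file("extdata", "scattering_lengths.tsv", package = "reflmem")
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    .reflmem$b_coh <- setNames(tab$b_coh_fm, tab$element)
  }
  .reflmem$b_coh
}

#' Parse a chemical formula into element counts
#'
#' Element symbols are one upper-case letter optionally followed by a
#' lower-case letter; counts may be fractional (mean-residue compositions).
#' \code{"D"} denotes deuterium.
#'
#' @param formula Formula string, e.g. \code{"C10H18NO8P"} or
#'   \code{"C4.9H7.8N1.4O1.5S0.05"}.
#' @return Named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  s <- gsub("\\s", "", formula)
  m <- gregexpr("[A-Z][a-z]?[0-9]*\\.?[0-9]*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse formula: ", formula)
  }
  el <- sub("[0-9.]+$", "", toks)
  n <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", toks)))
  n[is.na(n)] <- 1
  counts <- tapply(n, el, sum)
  out <- as.numeric(counts)
  names(out) <- names(counts)
  if (any(out < 0)) stop("negative element count in formula")
  out
}

#' Construct a chemical component
#'
#' A component is a chemical species (lipid fragment, protein on a
#' per-residue basis, substrate material) with a formula, a molecular
#' volume and a count of labile (solvent-exchangeable) hydrogens.
#'
#' @param name Label.
#' @param formula Formula string (see [parse_formula()]); D sites explicit.
#' @param volume Molecular volume in A^3 (> 0).
#' @param exchangeable_h Number of the formula's H that are labile.
#' @param deuteration Fraction of the non-labile H replaced by D
#'   (biosynthetic deuteration level), in \[0, 1\].
#' @param exchange_fraction Default fraction of labile H that actually
#'   exchanges with the solvent (0.9 is the usual assumption for folded
#'   proteins; 1 for freely exposed sites).
#' @param notes Free text.
#' @return Object of class \code{nr_component}.
#' @export
nr_component <- function(name, formula, volume, exchangeable_h = 0,
                         deuteration = 0, exchange_fraction = 1, notes = "") {
  counts <- parse_formula(formula)
  if (!is.numeric(volume) || volume <= 0) stop("molecular_volume must be > 0")
  nH <- if ("H" %in% names(counts)) counts[["H"]] else 0
  if (exchangeable_h < 0 || exchangeable_h > nH + 1e-9) {
    stop("exchangeable_h must lie in [0, total H]")
  }
  if (deuteration < 0 || deuteration > 1) stop("deuteration must be in [0,1]")
  structure(list(
    name = name, formula = formula, counts = counts, volume = volume,
    exchangeable_h = exchangeable_h, deuteration = deuteration,
    exchange_fraction = exchange_fraction, notes = notes
  ), class = "nr_component")
}

#' @export
print.nr_component <- function(x, ...) {
  cat(sprintf("<nr_component> %s: %s, V = %.1f A^3, labile H = %.2f\n",
              x$name, x$formula, x$volume, x$exchangeable_h))
  invisible(x)
}

#' Load the component reference library
#'
#' Reads a tab-separated component table (bundled by default) into a named
#' list of [nr_component()] objects. Users may point this at their own
#' edited copy.
#'
#' @param path Path to a TSV with columns name, formula, volume,
#'   exchangeable_h, deuteration, exchange_fraction, notes. Defaults to the
#'   bundled library.
#' @return Named list of \code{nr_component} objects.
#' @export
component_library <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.reflmem$components)) return(.reflmem$components)
    path <- system.file("extdata", "components.tsv", package = "reflmem")
    cache <- TRUE
  } else cache <- FALSE
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  lib <- lapply(seq_len(nrow(tab)), function(i) {
    nr_component(tab$name[i], tab$formula[i], tab$volume[i],
                 tab$exchangeable_h[i], tab$deuteration[i],
                 tab$exchange_fraction[i], tab$notes[i])
  })
  names(lib) <- tab$name
  if (cache) .reflmem$components <- lib
  lib
}

#' Solvent isotopic contrast
#'
#' @param d2o_fraction D2O volume fraction of the aqueous solvent, in
#'   \[0, 1\].
#' @param label Optional label; if missing, a standard one is derived
#'   (\code{"H2O"}, \code{"Si-MW"}, \code{"80% D2O"}, \code{"D2O"} at the
#'   conventional fractions, otherwise a percentage).
#' @return Object of class \code{solvent_contrast}.
#' @export
solvent_contrast <- function(d2o_fraction, label = NULL) {
  if (!is.numeric(d2o_fraction) || length(d2o_fraction) != 1L ||
      is.na(d2o_fraction) || d2o_fraction < 0 || d2o_fraction > 1) {
    stop("d2o_fraction must be a single value in [0, 1]")
  }
  if (is.null(label)) {
    label <- if (abs(d2o_fraction) < 1e-6) "H2O"
    else if (abs(d2o_fraction - 1) < 1e-6) "D2O"
    else if (abs(d2o_fraction - 0.38) < 5e-3) "Si-MW"
    else sprintf("%.0f%% D2O", 100 * d2o_fraction)
  }
  structure(list(d2o_fraction = d2o_fraction, label = label),
            class = "solvent_contrast")
}

#' @export
print.solvent_contrast <- function(x, ...) {
  cat(sprintf("<solvent_contrast> %s (%.0f%% D2O)\n", x$label,
              100 * x$d2o_fraction))
  invisible(x)
}

water_volume <- 30.0 # A^3 per molecule

#' Solvent scattering length density
#'
#' Linear mix of the pure H2O and pure D2O SLDs computed from the bundled
#' scattering lengths and the water molecular volume.
#'
#' @param contrast A [solvent_contrast()] or a bare D2O fraction.
#' @return SLD in 1e-6 A^-2.
#' @export
solvent_sld <- function(contrast) {
  x <- if (inherits(contrast, "solvent_contrast")) contrast$d2o_fraction
       else contrast
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("D2O fraction must be in [0, 1]")
  }
  b <- scattering_lengths()
  sld_h2o <- 10 * (2 * b[["H"]] + b[["O"]]) / water_volume
  sld_d2o <- 10 * (2 * b[["D"]] + b[["O"]]) / water_volume
  (1 - x) * sld_h2o + x * sld_d2o
}

#' Component scattering length density under a solvent contrast
#'
#' Sums coherent scattering lengths over the formula and divides by the
#' molecular volume. Each labile H contributes
#' \code{b(H)(1 - x f) + b(D) x f} with \code{x} the solvent D2O fraction
#' and \code{f} the exchange fraction; non-labile H sites carry the
#' component's biosynthetic deuteration level.
#'
#' @param comp [nr_component()].
#' @param contrast [solvent_contrast()] or D2O fraction.
#' @param exchange_fraction Override for the component's default labile-H
#'   exchange fraction, in \[0, 1\].
#' @return SLD in 1e-6 A^-2.
#' @export
component_sld <- function(comp, contrast, exchange_fraction = NULL) {
  stopifnot(inherits(comp, "nr_component"))
  x <- if (inherits(contrast, "solvent_contrast")) contrast$d2o_fraction
       else contrast
  if (x < 0 || x > 1) stop("D2O fraction must be in [0, 1]")
  f <- if (is.null(exchange_fraction)) comp$exchange_fraction else exchange_fraction
  if (f < 0 || f > 1) stop("exchange_fraction must be in [0, 1]")
  if (comp$volume <= 0) stop("component has non-positive molecular volume")
  b <- scattering_lengths()
  counts <- comp$counts
  nH <- if ("H" %in% names(counts)) counts[["H"]] else 0
  nD <- if ("D" %in% names(counts)) counts[["D"]] else 0
  others <- counts[!(names(counts) %in% c("H", "D"))]
  unknown <- setdiff(names(others), names(b))
  if (length(unknown)) stop("no scattering length for element(s): ",
                            paste(unknown, collapse = ", "))
  n_ex <- comp$exchangeable_h
  n_nonex <- nH - n_ex
  bsum <- sum(others * b[names(others)]) +
    n_nonex * ((1 - comp$deuteration) * b[["H"]] + comp$deuteration * b[["D"]]) +
    nD * b[["D"]] +
    n_ex * ((1 - x * f) * b[["H"]] + x * f * b[["D"]])
  10 * bsum / comp$volume
}

#' SLD of a volume-fraction mixture of components
#'
#' @param comps List of [nr_component()].
#' @param fractions Volume fractions (same length; sum may be < 1, the
#'   remainder being solvent if \code{fill_solvent}).
#' @param contrast [solvent_contrast()] or D2O fraction.
#' @param fill_solvent If TRUE the remaining fraction is solvent.
#' @return SLD in 1e-6 A^-2.
#' @export
mixture_sld <- function(comps, fractions, contrast, fill_solvent = TRUE) {
  stopifnot(length(comps) == length(fractions), all(fractions >= -1e-12))
  tot <- sum(fractions)
  if (tot > 1 + 1e-9) stop("volume fractions sum to more than 1")
  s <- sum(vapply(seq_along(comps),
                  function(i) fractions[i] * component_sld(comps[[i]], contrast),
                  numeric(1)))
  if (fill_solvent) s <- s + (1 - tot) * solvent_sld(contrast)
  s
}

#' D2O fraction matching a target SLD
#'
#' Inverts [solvent_sld()]: finds the H2O/D2O mixture whose SLD equals the
#' target. The classic use is silicon-matched water (Si-MW), the mixture
#' matching the substrate's SLD so it becomes invisible.
#'
#' @param target_sld Target SLD in 1e-6 A^-2; must lie between the pure
#'   H2O and pure D2O values.
#' @return D2O volume fraction in \[0, 1\].
#' @export
match_point <- function(target_sld) {
  lo <- solvent_sld(0); hi <- solvent_sld(1)
  if (target_sld < lo - 1e-9 || target_sld > hi + 1e-9) {
    stop(sprintf("target SLD %.3f outside attainable range [%.3f, %.3f]",
                 target_sld, lo, hi))
  }
  min(1, max(0, (target_sld - lo) / (hi - lo)))
}
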