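# Physical parameterization of the supported-bilayer + protein structure:
# Si / native oxide / water gap / lipid bilayer with membrane-embedded
# Bcl-2 / up to two Bax surface distributions / bulk solvent. One
# structure maps deterministically to a per-contrast slab stack and to
# component volume-fraction profiles.

#' Membrane-protein structure
#'
#' Parameterizes a solid-supported lipid bilayer on silicon with an
#' anti-apoptotic protein (Bcl-2) embedded in the bilayer at a single
#' volume fraction and up to two uniform surface distributions of a
#' peripheral protein (Bax), ordered proximal to distal from the outer
#' leaflet. Geometry (thicknesses, roughnesses, fractions) is shared by
#' every solvent contrast; only SLDs change, which is what makes
#' multi-contrast co-refinement well-posed.
#'
#' @param lipids data.frame with columns \code{species}, \code{mole_fraction},
#'   \code{head}, \code{tail} (component names); mole fractions sum to 1.
#' @param bcl2_fraction Volume fraction of the embedded protein in each
#'   bilayer sub-layer (displaces lipid within the covered area).
#' @param bcl2_component Component name of the embedded protein.
#' @param surface_layers data.frame with columns \code{thickness} (A),
#'   \code{coverage} (volume fraction) and \code{component}; 0-2 rows,
#'   proximal first.
#' @param oxide_thickness,oxide_hydration Native oxide layer (A, fraction).
#' @param water_gap Thin solvent layer between oxide and inner headgroups, A.
#' @param head_thickness,tail_thickness Headgroup / chain region
#'   thicknesses, A.
#' @param head_hydration Water fraction inside the lipid-covered headgroup
#'   region.
#' @param lipid_coverage Fraction of the interface area covered by
#'   bilayer material (lipid + embedded protein); the rest is solvent.
#' @param substrate_roughness Si/oxide (and oxide/solution) roughness, A.
#' @param roughness Global roughness of bilayer and protein interfaces, A.
#' @return Object of class \code{membrane_structure}.
#' @export
membrane_structure <- function(lipids = popc_lipids(),
                               bcl2_fraction = 0,
                               bcl2_component = "h_bcl2",
                               surface_layers = NULL,
                               oxide_thickness = 12, oxide_hydration = 0.08,
                               water_gap = 4,
                               head_thickness = 8, tail_thickness = 28,
                               head_hydration = 0.2,
                               lipid_coverage = 0.95,
                               substrate_roughness = 3,
                               roughness = 3) {
  if (is.null(surface_layers)) {
    surface_layers <- data.frame(thickness = numeric(0), coverage = numeric(0),
                                 component = character(0))
  }
  s <- structure(list(
    lipids = lipids,
    bcl2_fraction = bcl2_fraction, bcl2_component = bcl2_component,
    surface_layers = surface_layers,
    oxide_thickness = oxide_thickness, oxide_hydration = oxide_hydration,
    water_gap = water_gap,
    head_thickness = head_thickness, tail_thickness = tail_thickness,
    head_hydration = head_hydration,
    lipid_coverage = lipid_coverage,
    substrate_roughness = substrate_roughness,
    roughness = roughness
  ), class = "membrane_structure")
  validate_structure(s)
}

#' @export
print.membrane_structure <- function(x, ...) {
  cat("<membrane_structure>\n")
  cat(sprintf("  oxide %.1f A (%.0f%% hydrated), gap %.1f A, heads %.1f A, tails %.1f A\n",
              x$oxide_thickness, 100 * x$oxide_hydration, x$water_gap,
              x$head_thickness, x$tail_thickness))
  cat(sprintf("  lipid coverage %.2f, embedded protein %.1f%% (%s)\n",
              x$lipid_coverage, 100 * x$bcl2_fraction, x$bcl2_component))
  if (nrow(x$surface_layers)) {
    for (i in seq_len(nrow(x$surface_layers))) {
      cat(sprintf("  surface layer %d: %.1f A at %.1f%% (%s)\n", i,
                  x$surface_layers$thickness[i],
                  100 * x$surface_layers$coverage[i],
                  x$surface_layers$component[i]))
    }
  }
  invisible(x)
}

validate_structure <- function(s) {
  fr <- c(s$bcl2_fraction, s$oxide_hydration, s$head_hydration,
          s$lipid_coverage, s$surface_layers$coverage)
  if (any(fr < -1e-12 | fr > 1 + 1e-12)) stop("all fractions must be in [0, 1]")
  if (s$bcl2_fraction > s$lipid_coverage + 1e-12) {
    stop("embedded-protein fraction cannot exceed the covered area fraction")
  }
  th <- c(s$oxide_thickness, s$water_gap, s$head_thickness, s$tail_thickness,
          s$surface_layers$thickness)
  if (any(th < 0)) stop("negative layer thickness")
  if (s$substrate_roughness < 0 || s$roughness < 0) stop("negative roughness")
  if (nrow(s$surface_layers) > 2) stop("at most two surface layers")
  if (abs(sum(s$lipids$mole_fraction) - 1) > 1e-9) {
    stop("lipid mole fractions must sum to 1")
  }
  s
}

#' Standard lipid compositions
#'
#' \code{popc_lipids()} is a pure (tail-deuterated by default) POPC
#' bilayer; \code{popc_cl_lipids()} mixes in tetraoleoyl cardiolipin at
#' 10 mol% (the 9:1 POPC:CL mitochondrial-membrane mimic).
#'
#' @param deuterated Use tail-deuterated POPC chains.
#' @return data.frame accepted by [membrane_structure()].
#' @export
popc_lipids <- function(deuterated = TRUE) {
  data.frame(species = "POPC", mole_fraction = 1,
             head = "pc_headgroup",
             tail = if (deuterated) "d_popc_tails" else "popc_tails")
}

#' @rdname popc_lipids
#' @export
popc_cl_lipids <- function(deuterated = TRUE) {
  data.frame(species = c("POPC", "CL"), mole_fraction = c(0.9, 0.1),
             head = c("pc_headgroup", "cl_headgroup"),
             tail = c(if (deuterated) "d_popc_tails" else "popc_tails",
                      "cl_tails"))
}

# per-species volume-weighted fractions within the head / tail regions
lipid_volume_fractions <- function(lipids, which, lib) {
  comps <- lipids[[which]]
  vols <- vapply(comps, function(nm) lib[[nm]]$volume, numeric(1))
  w <- lipids$mole_fraction * vols
  setNames(w / sum(w), comps)
}

# Layer table shared by to_slabs() and volume_fraction_profile():
# per structural sub-layer, thickness, roughness of its lower interface,
# and the volume fraction of every named component (solvent implicit).
structure_layers <- function(s, lib = component_library()) {
  cov <- s$lipid_coverage
  vB <- s$bcl2_fraction
  headw <- lipid_volume_fractions(s$lipids, "head", lib)
  tailw <- lipid_volume_fractions(s$lipids, "tail", lib)
  lip_head <- (cov - vB) * (1 - s$head_hydration)
  lip_tail <- cov - vB

  frac_row <- function(...) {
    v <- c(...)
    v[v > 0]
  }
  head_frac <- function() {
    f <- setNames(lip_head * headw, names(headw))
    if (vB > 0) f <- c(f, setNames(vB, s$bcl2_component))
    f
  }
  tail_frac <- function() {
    f <- setNames(lip_tail * tailw, names(tailw))
    if (vB > 0) f <- c(f, setNames(vB, s$bcl2_component))
    f
  }
  layers <- list(
    list(name = "oxide", thickness = s$oxide_thickness,
         rough = s$substrate_roughness,
         fractions = frac_row(silica = 1 - s$oxide_hydration)),
    list(name = "water_gap", thickness = s$water_gap,
         rough = s$substrate_roughness,
         fractions = numeric(0)),
    list(name = "inner_heads", thickness = s$head_thickness,
         rough = s$roughness, fractions = head_frac()),
    list(name = "tails", thickness = s$tail_thickness,
         rough = s$roughness, fractions = tail_frac()),
    list(name = "outer_heads", thickness = s$head_thickness,
         rough = s$roughness, fractions = head_frac())
  )
  if (nrow(s$surface_layers)) {
    for (i in seq_len(nrow(s$surface_layers))) {
      sl <- s$surface_layers[i, ]
      layers[[length(layers) + 1]] <- list(
        name = paste0("surface_", i), thickness = sl$thickness,
        rough = s$roughness,
        fractions = frac_row(setNames(sl$coverage, sl$component)))
    }
  }
  for (l in layers) {
    if (sum(l$fractions) > 1 + 1e-9) {
      stop("material volume fractions exceed 1 in layer ", l$name)
    }
  }
  layers
}

#' Map a structure to a per-contrast slab stack
#'
#' Produces the slab table for one solvent contrast: one slab per
#' structural sub-layer, SLD the volume-weighted mix of component SLDs at
#' that contrast with solvent filling the remainder. Thickness, roughness
#' and fraction parameters are identical across contrasts — the
#' co-refinement constraint.
#'
#' @param s [membrane_structure()].
#' @param contrast [solvent_contrast()] or D2O fraction.
#' @param lib Component library.
#' @return Slab table (see [slab_stack()]), fronting silicon first,
#'   backing solvent last.
#' @export
to_slabs <- function(s, contrast, lib = component_library()) {
  validate_structure(s)
  layers <- structure_layers(s, lib)
  solv <- solvent_sld(contrast)
  mix <- function(fr) {
    tot <- sum(fr)
    val <- sum(vapply(names(fr), function(nm) {
      fr[[nm]] * component_sld(lib[[nm]], contrast)
    }, numeric(1)))
    val + (1 - tot) * solv
  }
  th <- vapply(layers, `[[`, numeric(1), "thickness")
  rg <- vapply(layers, `[[`, numeric(1), "rough")
  sl <- vapply(layers, function(l) mix(l$fractions), numeric(1))
  nm <- vapply(layers, `[[`, character(1), "name")
  slab_stack(
    thickness = c(0, th, 0),
    sld = c(component_sld(lib[["silicon"]], contrast), sl, solv),
    rough = c(0, rg, s$roughness),
    name = c("silicon", nm, "solvent")
  )
}

#' Component volume-fraction profile
#'
#' phi(z) for every component of the structure, boxcar layer fractions
#' smoothed with error-function interfaces at the fitted roughnesses.
#' z = 0 at the Si/oxide boundary, increasing toward bulk solvent; the
#' substrate is included as a component so fractions sum to one
#' everywhere, solvent filling the remainder.
#'
#' @inheritParams to_slabs
#' @param dz Grid spacing, A (<= 1).
#' @param margin Extent beyond the outermost interface, in multiples of
#'   the largest roughness.
#' @return data.frame of class \code{volume_fraction_profile}: column
#'   \code{z}, one column per component, and \code{solvent}.
#' @export
volume_fraction_profile <- function(s, dz = 0.5, lib = component_library(),
                                    margin = 5) {
  if (dz > 1) stop("dz must be <= 1 A")
  validate_structure(s)
  layers <- structure_layers(s, lib)
  th <- vapply(layers, `[[`, numeric(1), "thickness")
  lo <- cumsum(c(0, th[-length(th)]))
  hi <- cumsum(th)
  rough_lo <- vapply(layers, `[[`, numeric(1), "rough")
  rough_hi <- c(rough_lo[-1], s$roughness)
  pad <- margin * max(s$substrate_roughness, s$roughness, 1)
  z <- seq(-pad, hi[length(hi)] + pad, by = dz)
  box <- function(z, a, b, sa, sb) {
    lo_edge <- if (sa > 0) 0.5 * (1 + erf((z - a) / (sqrt(2) * sa)))
               else as.numeric(z >= a)
    hi_edge <- if (sb > 0) 0.5 * (1 + erf((z - b) / (sqrt(2) * sb)))
               else as.numeric(z >= b)
    lo_edge - hi_edge
  }
  comp_names <- unique(unlist(lapply(layers, function(l) names(l$fractions))))
  prof <- matrix(0, nrow = length(z), ncol = length(comp_names),
                 dimnames = list(NULL, comp_names))
  for (i in seq_along(layers)) {
    fr <- layers[[i]]$fractions
    if (!length(fr) || th[i] == 0) next
    b <- box(z, lo[i], hi[i], rough_lo[i], rough_hi[i])
    for (nm in names(fr)) prof[, nm] <- prof[, nm] + fr[[nm]] * b
  }
  substrate <- if (s$substrate_roughness > 0) {
    1 - 0.5 * (1 + erf(z / (sqrt(2) * s$substrate_roughness)))
  } else as.numeric(z < 0)
  out <- data.frame(z = z, substrate = substrate)
  for (nm in comp_names) out[[nm]] <- prof[, nm]
  out$solvent <- 1 - rowSums(out[, -1, drop = FALSE])
  class(out) <- c("volume_fraction_profile", "data.frame")
  out
}

#' SLD profile of a structure at one contrast
#'
#' Two equivalent construction paths are available: \code{via = "slabs"}
#' smooths the slab-stack SLD steps; \code{via = "fractions"} sums
#' component SLDs weighted by the volume-fraction profile. They agree to
#' numerical precision, which is used as an internal consistency check.
#'
#' @inheritParams to_slabs
#' @param dz Grid spacing, A.
#' @param via Construction path.
#' @return data.frame with \code{z}, \code{sld}.
#' @export
sld_profile <- function(s, contrast, dz = 0.5, lib = component_library(),
                        via = c("slabs", "fractions")) {
  via <- match.arg(via)
  if (via == "slabs") {
    slabs <- to_slabs(s, contrast, lib)
    pad <- 5 * max(s$substrate_roughness, s$roughness, 1)
    n <- nrow(slabs)
    pos <- c(0, cumsum(slabs$thickness[seq(2, n - 1)]))
    z <- seq(-pad, pos[length(pos)] + pad, by = dz)
    sld <- rep(slabs$sld[1], length(z))
    for (j in seq_len(n - 1)) {
      sg <- slabs$rough[j + 1]
      step <- if (sg > 0) 0.5 * (1 + erf((z - pos[j]) / (sqrt(2) * sg)))
              else as.numeric(z >= pos[j])
      sld <- sld + (slabs$sld[j + 1] - slabs$sld[j]) * step
    }
    data.frame(z = z, sld = sld)
  } else {
    vf <- volume_fraction_profile(s, dz = dz, lib = lib, margin = 5)
    comp_cols <- setdiff(names(vf), c("z", "solvent", "substrate"))
    sld <- vf$substrate * component_sld(lib[["silicon"]], contrast) +
      vf$solvent * solvent_sld(contrast)
    for (nm in comp_cols) {
      sld <- sld + vf[[nm]] * component_sld(lib[[nm]], contrast)
    }
    data.frame(z = vf$z, sld = sld)
  }
}

#' Stacked protein units in a surface layer
#'
#' Interprets a fitted protein-layer thickness as a number of vertically
#' stacked monomer units: the ratio thickness / monomer extent, reported
#' together with the two bracketing integers. A ~25 A Bax layer over a
#' ~25 A monomer reads as monomeric; its doubling to ~50 A as a
#' two-unit (dimeric) stack.
#'
#' @param layer_thickness Fitted layer (or envelope) thickness, A (> 0).
#' @param monomer_extent Monomer dimension normal to the membrane, A (> 0).
#' @return Numeric ratio with attribute \code{bracket}, the two
#'   bracketing integers (equal when the ratio is integral).
#' @export
oligomer_units <- function(layer_thickness, monomer_extent) {
  if (!is.numeric(layer_thickness) || layer_thickness <= 0 ||
      !is.numeric(monomer_extent) || monomer_extent <= 0) {
    stop("thickness and monomer extent must be positive")
  }
  r <- layer_thickness / monomer_extent
  lo <- floor(r + 1e-9)
  hi <- ceiling(r - 1e-9)
  if (lo < 1) lo <- 0
  structure(r, bracket = c(lo, hi))
}
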