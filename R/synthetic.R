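# Synthetic-data generator: multi-contrast reflectivity curves and kinetic
# traces with the statistical structure the analysis assumes, plus the
# five reference membrane systems used as recovery fixtures. All
# generators are pure functions of (parameters, seed).

#' Default measurement Q grid
#'
#' 150 log-spaced points over 0.01-0.3 A^-1, the span of a single
#' reflectometry dataset on the beamlines emulated here.
#'
#' @param n Number of points.
#' @param q_min,q_max Range, A^-1.
#' @return Numeric Q vector.
#' @export
default_q_grid <- function(n = 150, q_min = 0.01, q_max = 0.3) {
  exp(seq(log(q_min), log(q_max), length.out = n))
}

#' The four standard solvent contrasts
#'
#' D2O, 80% D2O, silicon-matched water (38% D2O) and H2O.
#'
#' @return List of [solvent_contrast()].
#' @export
standard_contrasts <- function() {
  list(solvent_contrast(1), solvent_contrast(0.8), solvent_contrast(0.38),
       solvent_contrast(0))
}

#' Simulate a multi-contrast reflectivity set
#'
#' Forward-models the structure at each contrast (micro-sliced where
#' needed, resolution-smeared), adds a flat background, then Gaussian
#' noise of width \code{sigma = noise_rel * R + background}; the recorded
#' \code{sigma_r} column is the generating sigma. Deterministic for a
#' given seed.
#'
#' @param s [membrane_structure()].
#' @param contrasts List of [solvent_contrast()].
#' @param q Q grid, A^-1.
#' @param dq_over_q Fractional FWHM resolution (0.035 preset; use 0.07
#'   for the lower-resolution instrument).
#' @param noise_rel Relative noise level (>= 0).
#' @param background Flat background level (also the sigma floor).
#' @param seed Integer seed.
#' @param lib Component library.
#' @return List of [contrast_dataset()].
#' @export
simulate_contrast_set <- function(s, contrasts = standard_contrasts(),
                                  q = default_q_grid(), dq_over_q = 0.035,
                                  noise_rel = 0.02, background = 1e-7,
                                  seed = 1, lib = component_library()) {
  if (noise_rel < 0) stop("noise_rel must be >= 0")
  set.seed(seed)
  lapply(contrasts, function(ct) {
    slabs <- microslice_slabs(to_slabs(s, ct, lib))
    r_model <- smeared_reflectivity(slabs, q, dq_over_q) + background
    sig <- noise_rel * r_model + background
    r_obs <- if (noise_rel > 0) r_model + rnorm(length(q), 0, sig) else r_model
    # the dataset records the background it was generated with, so a model
    # with fixed backgrounds is exact rather than biased at high Q
    contrast_dataset(q, r_obs, pmax(sig, 1e-12), ct, dq_over_q = dq_over_q,
                     background = background)
  })
}

#' Reference membrane systems (recovery fixtures)
#'
#' The five steady-state Bcl-2/Bax systems used as ground truths for
#' parameter-recovery studies: three POPC bilayers and two 9:1 (mol/mol)
#' POPC:CL bilayers, spanning low to high Bcl-2 content. Protein-layer
#' central values follow the tabulated structures for these systems
#' (Bcl-2 in-bilayer volume coverage; proximal and, where resolved,
#' distal Bax surface distributions); the distal layer is present only
#' for systems 1 and 3. Bilayer geometry uses the documented template
#' defaults of [membrane_structure()], which are not system-specific
#' claims.
#'
#' @param column System index, 1-5 (1-3 POPC, 4-5 POPC:CL).
#' @return [membrane_structure()].
#' @export
mom_fixture <- function(column) {
  if (!column %in% 1:5) stop("column must be in 1..5")
  pars <- list(
    list(bcl2 = 0.099, prox = c(88.4, 0.130), dist = c(80.8, 0.058), cl = FALSE),
    list(bcl2 = 0.142, prox = c(67.8, 0.080), dist = NULL, cl = FALSE),
    list(bcl2 = 0.399, prox = c(55.0, 0.262), dist = c(52.7, 0.045), cl = FALSE),
    list(bcl2 = 0.247, prox = c(54.6, 0.198), dist = NULL, cl = TRUE),
    list(bcl2 = 0.387, prox = c(64.7, 0.293), dist = NULL, cl = TRUE)
  )[[column]]
  sl <- data.frame(thickness = pars$prox[1], coverage = pars$prox[2],
                   component = "h_bax")
  if (!is.null(pars$dist)) {
    sl <- rbind(sl, data.frame(thickness = pars$dist[1],
                               coverage = pars$dist[2], component = "h_bax"))
  }
  membrane_structure(
    lipids = if (pars$cl) popc_cl_lipids() else popc_lipids(),
    bcl2_fraction = pars$bcl2, bcl2_component = "h_bcl2",
    surface_layers = sl
  )
}

#' Simulate an exponential-association kinetic trace
#'
#' \code{y(t) = y0 + sum A_i (1 - exp(-t/tau_i))} plus Gaussian noise of
#' width \code{noise_rel} times the plateau amplitude. Deterministic for
#' a given seed.
#'
#' @param amplitudes Component amplitudes.
#' @param taus Time constants, minutes (> 0).
#' @param t_end Trace length, minutes.
#' @param dt Sampling interval, minutes (80 s = 4/3 min for ATR-FTIR;
#'   ~15 min for time-resolved reflectometry).
#' @param noise_rel Relative noise level.
#' @param seed Integer seed.
#' @param y0 Baseline.
#' @param label Trace label.
#' @return [kinetic_trace()] with \code{sigma_y} set to the generating
#'   noise width.
#' @export
simulate_kinetics <- function(amplitudes, taus, t_end = 720, dt = 4 / 3,
                              noise_rel = 0.02, seed = 1, y0 = 0,
                              label = "simulated") {
  stopifnot(length(amplitudes) == length(taus))
  if (length(taus) && any(taus <= 0)) stop("taus must be positive")
  t <- seq(dt, t_end, by = dt)
  set.seed(seed)
  clean <- association_model(t, y0, amplitudes, taus)
  scale <- max(abs(sum(amplitudes)), max(abs(clean)), 1e-12)
  sig <- noise_rel * scale
  y <- if (noise_rel > 0) clean + rnorm(length(t), 0, sig) else clean
  kinetic_trace(t, y, sigma_y = if (noise_rel > 0) rep(sig, length(t)) else NULL,
                label = label)
}

# exponential-approach interpolation of the evolving structural parameters
interp_structure <- function(s0, s1, f) {
  s <- s0
  for (nm in c("bcl2_fraction", "tail_thickness")) {
    s[[nm]] <- s0[[nm]] + f * (s1[[nm]] - s0[[nm]])
  }
  n0 <- nrow(s0$surface_layers); n1 <- nrow(s1$surface_layers)
  nmax <- max(n0, n1)
  pad <- function(sl, n) {
    while (nrow(sl) < n) {
      sl <- rbind(sl, data.frame(thickness = sl$thickness[nrow(sl)],
                                 coverage = 0,
                                 component = sl$component[nrow(sl)]))
    }
    sl
  }
  a <- pad(s0$surface_layers, nmax); b <- pad(s1$surface_layers, nmax)
  s$surface_layers <- data.frame(
    thickness = a$thickness + f * (b$thickness - a$thickness),
    coverage = a$coverage + f * (b$coverage - a$coverage),
    component = b$component
  )
  validate_structure(s)
}

#' Simulate a time-resolved reflectometry series
#'
#' Generates one D2O-contrast dataset per acquisition window while the
#' structure evolves between stage anchors with an exponential approach
#' of configurable time constant (thickness, coverage, embedded-protein
#' fraction and tail thickness are interpolated).
#'
#' @param stages List of \code{list(time = minutes, structure =
#'   membrane_structure)}, ordered in time; at least one.
#' @param t_end End of the series, minutes.
#' @param interval Acquisition window, minutes (~15 for TR-NR).
#' @param tau Approach time constant, minutes.
#' @param q,dq_over_q,noise_rel,background,seed,lib As in
#'   [simulate_contrast_set()].
#' @return List of \code{list(time, span, dataset, structure)}; time is
#'   the mid-acquisition time.
#' @export
simulate_timeresolved_nr <- function(stages, t_end = 720, interval = 15,
                                     tau = 163, q = default_q_grid(),
                                     dq_over_q = 0.035, noise_rel = 0.02,
                                     background = 1e-7, seed = 1,
                                     lib = component_library()) {
  stopifnot(length(stages) >= 1)
  times <- vapply(stages, `[[`, numeric(1), "time")
  if (is.unsorted(times)) stop("stages must be ordered in time")
  ct <- solvent_contrast(1)
  mids <- seq(interval / 2, t_end, by = interval)
  set.seed(seed)
  lapply(mids, function(tm) {
    i <- findInterval(tm, times)
    s <- if (i <= 0) {
      stages[[1]]$structure
    } else if (i >= length(stages)) {
      stages[[length(stages)]]$structure
    } else {
      dt1 <- tm - times[i]
      span <- times[i + 1] - times[i]
      f <- (1 - exp(-dt1 / tau)) / (1 - exp(-span / tau))
      interp_structure(stages[[i]]$structure, stages[[i + 1]]$structure, f)
    }
    slabs <- microslice_slabs(to_slabs(s, ct, lib))
    r_model <- smeared_reflectivity(slabs, q, dq_over_q) + background
    sig <- noise_rel * r_model + background
    r_obs <- if (noise_rel > 0) r_model + rnorm(length(q), 0, sig) else r_model
    list(time = tm, span = interval,
         dataset = contrast_dataset(q, r_obs, pmax(sig, 1e-12), ct,
                                    dq_over_q = dq_over_q,
                                    background = background),
         structure = s)
  })
}
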