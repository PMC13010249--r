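# Simultaneous multi-contrast fitting: chi-squared objective over shared
# structural parameters, differential-evolution global search with
# Nelder-Mead polish, residual-bootstrap confidence intervals and
# table-style reporting.

#' One measured (or simulated) reflectivity dataset
#'
#' @param q,r,sigma_r Momentum transfer (A^-1, strictly increasing),
#'   reflectivity and its standard uncertainty (> 0).
#' @param contrast [solvent_contrast()] or D2O fraction.
#' @param sigma_q Optional per-point Gaussian resolution sigma (A^-1);
#'   when present it overrides the constant dQ/Q.
#' @param dq_over_q Constant fractional FWHM resolution.
#' @param scale,background Multiplicative scale and flat background
#'   applied to the model when comparing with this dataset.
#' @param label Dataset label.
#' @return Object of class \code{contrast_dataset}.
#' @export
contrast_dataset <- function(q, r, sigma_r, contrast, sigma_q = NULL,
                             dq_over_q = 0.035, scale = 1, background = 0,
                             label = NULL) {
  if (!inherits(contrast, "solvent_contrast")) contrast <- solvent_contrast(contrast)
  n <- length(q)
  if (length(r) != n || length(sigma_r) != n) stop("q, r, sigma_r lengths differ")
  validate_q(q)
  if (any(sigma_r <= 0)) stop("sigma_r must be positive")
  if (!is.null(sigma_q) && length(sigma_q) != n) stop("sigma_q length mismatch")
  structure(list(q = q, r = r, sigma_r = sigma_r, sigma_q = sigma_q,
                 contrast = contrast, dq_over_q = dq_over_q,
                 scale = scale, background = background,
                 label = if (is.null(label)) contrast$label else label),
            class = "contrast_dataset")
}

#' @export
print.contrast_dataset <- function(x, ...) {
  cat(sprintf("<contrast_dataset> %s: %d points, Q %.3f-%.3f A^-1\n",
              x$label, length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

dataset_resolution <- function(ds) {
  if (!is.null(ds$sigma_q)) 2.355 * ds$sigma_q / ds$q else ds$dq_over_q
}

# ---- parameter plumbing -----------------------------------------------

# Recognized free-parameter names; surfaceK_* address surface layer K,
# backgroundK the K-th dataset's flat background.
set_structure_param <- function(s, name, value) {
  if (name %in% c("bcl2_fraction", "tail_thickness", "head_thickness",
                  "water_gap", "oxide_thickness", "oxide_hydration",
                  "head_hydration", "lipid_coverage", "roughness",
                  "substrate_roughness")) {
    s[[name]] <- value
  } else if (grepl("^surface[12]_(thickness|coverage)$", name)) {
    k <- as.integer(substr(name, 8, 8))
    field <- sub("^surface[12]_", "", name)
    if (k > nrow(s$surface_layers)) stop("structure has no surface layer ", k)
    s$surface_layers[[field]][k] <- value
  } else {
    stop("unknown structural parameter: ", name)
  }
  s
}

apply_params <- function(problem, par) {
  s <- problem$structure
  datasets <- problem$datasets
  for (nm in names(par)) {
    if (grepl("^background[0-9]+$", nm)) {
      k <- as.integer(sub("background", "", nm))
      datasets[[k]]$background <- par[[nm]]
    } else if (grepl("^scale[0-9]+$", nm)) {
      k <- as.integer(sub("scale", "", nm))
      datasets[[k]]$scale <- par[[nm]]
    } else {
      s <- set_structure_param(s, nm, par[[nm]])
    }
  }
  list(structure = s, datasets = datasets)
}

#' Define a co-refinement problem
#'
#' Couples one [membrane_structure()] to one or more
#' [contrast_dataset()]s through a table of free parameters. Structural
#' parameters are shared by every dataset (the co-refinement constraint);
#' \code{backgroundK} / \code{scaleK} act on dataset K alone. By default
#' the scale is fixed at 1 and each dataset's background is free between
#' 0 and 1e-5.
#'
#' @param structure Starting [membrane_structure()].
#' @param datasets List of [contrast_dataset()].
#' @param free Named list of \code{c(lower, upper)} bounds for the free
#'   parameters (finite bounds required).
#' @param free_backgrounds Add a free background per dataset.
#' @param lib Component library.
#' @return Object of class \code{fit_problem}.
#' @export
fit_problem <- function(structure, datasets, free,
                        free_backgrounds = TRUE, lib = component_library()) {
  stopifnot(length(datasets) >= 1)
  if (free_backgrounds) {
    for (k in seq_along(datasets)) {
      nm <- paste0("background", k)
      if (is.null(free[[nm]])) free[[nm]] <- c(0, 1e-5)
    }
  }
  for (nm in names(free)) {
    b <- free[[nm]]
    if (length(b) != 2 || any(!is.finite(b)) || b[1] >= b[2]) {
      stop("parameter ", nm, " needs finite bounds c(lower, upper)")
    }
  }
  structure(list(structure = validate_structure(structure),
                 datasets = datasets, free = free, lib = lib),
            class = "fit_problem")
}

#' Model reflectivity curves of a problem at given parameters
#'
#' Forward model for every dataset: structure -> slabs at the dataset's
#' contrast, micro-sliced where roughness demands it, resolution-smeared
#' on the dataset's Q grid, then scaled with the dataset's scale and
#' background.
#'
#' @param problem [fit_problem()].
#' @param par Named parameter values (defaults to the problem's current
#'   structure and datasets).
#' @return List of model curves, one numeric vector per dataset.
#' @export
model_curves <- function(problem, par = NULL) {
  st <- if (is.null(par)) list(structure = problem$structure,
                               datasets = problem$datasets)
        else apply_params(problem, par)
  lapply(st$datasets, function(ds) {
    slabs <- to_slabs(st$structure, ds$contrast, problem$lib)
    slabs <- microslice_slabs(slabs)
    r <- smeared_reflectivity(slabs, ds$q, dataset_resolution(ds))
    r * ds$scale + ds$background
  })
}

#' Chi-squared of a co-refinement problem
#'
#' Sum over datasets and points of \code{((model - r) / sigma_r)^2}. The
#' returned value is normalized per point (divided by the total point
#' count); the raw sum and N are attached as attributes since the
#' normalization convention differs between fitting programs.
#'
#' @inheritParams model_curves
#' @return Per-point chi-squared with attributes \code{raw} and \code{n}.
#' @export
chi_squared <- function(problem, par = NULL) {
  st <- if (is.null(par)) list(datasets = problem$datasets)
        else apply_params(problem, par)
  curves <- model_curves(problem, par)
  raw <- 0; n <- 0
  for (k in seq_along(curves)) {
    ds <- st$datasets[[k]]
    raw <- raw + sum(((curves[[k]] - ds$r) / ds$sigma_r)^2)
    n <- n + length(ds$q)
  }
  structure(raw / n, raw = raw, n = n)
}

# ---- optimizers --------------------------------------------------------

# rand/1/bin differential evolution with box constraints.
de_optim <- function(fn, lower, upper, pop, maxiter, tol, F = 0.8, CR = 0.9,
                     trace = FALSE) {
  np <- length(lower)
  X <- matrix(runif(pop * np, lower, upper), nrow = pop, byrow = TRUE)
  cost <- apply(X, 1, fn)
  iter <- 0; converged <- FALSE
  while (iter < maxiter) {
    iter <- iter + 1
    for (i in seq_len(pop)) {
      idx <- sample.int(pop, 3)
      while (any(idx == i)) idx <- sample.int(pop, 3)
      v <- X[idx[1], ] + F * (X[idx[2], ] - X[idx[3], ])
      v <- pmin(pmax(v, lower), upper)
      cross <- runif(np) < CR
      cross[sample.int(np, 1)] <- TRUE
      u <- ifelse(cross, v, X[i, ])
      cu <- fn(u)
      if (cu <= cost[i]) { X[i, ] <- u; cost[i] <- cu }
    }
    spread <- (max(cost) - min(cost)) / (abs(mean(cost)) + 1e-300)
    if (trace && iter %% 10 == 0) {
      message(sprintf("DE iter %d: best %.6g spread %.3g", iter,
                      min(cost), spread))
    }
    if (spread < tol) { converged <- TRUE; break }
  }
  b <- which.min(cost)
  list(par = X[b, ], value = cost[b], iter = iter, converged = converged)
}

# bounded objective wrapper for Nelder-Mead (quadratic penalty outside box)
penalized <- function(fn, lower, upper) {
  function(p) {
    lo <- pmin(p - lower, 0); hi <- pmin(upper - p, 0)
    pen <- sum(lo^2) + sum(hi^2)
    if (pen > 0) return(1e6 * (1 + pen))
    fn(p)
  }
}

#' Fit a co-refinement problem
#'
#' Differential-evolution global search over the free-parameter box,
#' followed by a derivative-free Nelder-Mead polish. Deterministic for a
#' given seed. Non-convergence is flagged on the result, never silent.
#'
#' @param problem [fit_problem()].
#' @param seed Integer seed controlling the stochastic search.
#' @param control List overriding the optimizer budget: \code{pop}
#'   (default 15 x n_params), \code{maxiter} (2000), \code{de_tol}
#'   (relative population spread at which the global stage stops, 1e-6),
#'   \code{polish} (TRUE), \code{polish_maxit} (2000), \code{reltol}
#'   (1e-8), \code{trace}.
#' @param start Optional named start vector included in the initial
#'   population (e.g. the previous state in a staged workflow).
#' @return Object of class \code{nr_fit}: best parameters, per-point and
#'   raw chi-squared, the best-fit structure and datasets, convergence
#'   metadata and the seed.
#' @export
fit <- function(problem, seed = 1, control = list(), start = NULL) {
  stopifnot(inherits(problem, "fit_problem"))
  free <- problem$free
  np <- length(free)
  ctl <- modifyList(list(pop = 15 * np, maxiter = 2000, de_tol = 1e-6,
                         polish = TRUE, polish_maxit = 2000, reltol = 1e-8,
                         trace = FALSE), control)
  pnames <- names(free)
  lower <- vapply(free, `[`, numeric(1), 1)
  upper <- vapply(free, `[`, numeric(1), 2)
  obj <- function(p) {
    names(p) <- pnames
    as.numeric(chi_squared(problem, p))
  }
  if (np == 0) {
    cs <- chi_squared(problem)
    return(structure(list(par = numeric(0), chisq = as.numeric(cs),
                          chisq_raw = attr(cs, "raw"), n_points = attr(cs, "n"),
                          structure = problem$structure,
                          datasets = problem$datasets, problem = problem,
                          seed = seed,
                          convergence = list(converged = TRUE, de_iter = 0),
                          control = ctl),
                     class = "nr_fit"))
  }
  set.seed(seed)
  de <- de_optim(obj, lower, upper, pop = ctl$pop, maxiter = ctl$maxiter,
                 tol = ctl$de_tol, trace = isTRUE(ctl$trace))
  best <- de$par; val <- de$value
  if (!is.null(start)) {
    s0 <- unlist(start)[pnames]
    if (!anyNA(s0)) {
      s0 <- pmin(pmax(s0, lower), upper)
      v0 <- obj(s0)
      if (is.finite(v0) && v0 < val) { best <- s0; val <- v0 }
    }
  }
  nm_conv <- NA_integer_
  if (isTRUE(ctl$polish)) {
    nm <- if (np == 1) {
      optim(best, obj, method = "Brent", lower = lower, upper = upper,
            control = list(maxit = ctl$polish_maxit, reltol = ctl$reltol))
    } else {
      optim(best, penalized(obj, lower, upper), method = "Nelder-Mead",
            control = list(maxit = ctl$polish_maxit, reltol = ctl$reltol))
    }
    if (nm$value <= val) { best <- nm$par; val <- nm$value }
    nm_conv <- nm$convergence
  }
  names(best) <- pnames
  st <- apply_params(problem, best)
  cs <- chi_squared(problem, best)
  structure(list(par = best, chisq = as.numeric(cs),
                 chisq_raw = attr(cs, "raw"), n_points = attr(cs, "n"),
                 structure = st$structure, datasets = st$datasets,
                 problem = problem, seed = seed,
                 convergence = list(converged = de$converged || nm_conv %in% 0,
                                    de_iter = de$iter,
                                    de_converged = de$converged,
                                    nm_code = nm_conv),
                 control = ctl),
            class = "nr_fit")
}

#' @export
print.nr_fit <- function(x, ...) {
  cat(sprintf("<nr_fit> chi2/N = %.4g (raw %.4g over %d points)%s\n",
              x$chisq, x$chisq_raw, x$n_points,
              if (isTRUE(x$convergence$converged)) "" else "  [NOT CONVERGED]"))
  if (length(x$par)) {
    for (nm in names(x$par)) cat(sprintf("  %-22s %.5g\n", nm, x$par[[nm]]))
  }
  invisible(x)
}

# local re-fit used by the bootstrap: Levenberg-Marquardt on the weighted
# residual vector, started from the best fit (cheap, gradient-based; the
# global landscape has already been searched).
refit_local <- function(problem, datasets, start, lower, upper) {
  pnames <- names(start)
  resid_fn <- function(p) {
    p <- pmin(pmax(p, lower), upper)
    names(p) <- pnames
    curves <- model_curves(problem, p)
    unlist(lapply(seq_along(curves), function(k) {
      (curves[[k]] - datasets[[k]]$r) / datasets[[k]]$sigma_r
    }))
  }
  out <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 60, ptol = 1e-6, ftol = 1e-6))
  pmin(pmax(out$par, lower), upper)
}

#' Residual-bootstrap confidence intervals
#'
#' Resamples Gaussian noise of width \code{sigma_r} about the best-fit
#' model curves, refits each resample starting from the best fit, and
#' takes the central 95% of each parameter's refit distribution. The
#' interval is widened, if necessary, to contain the best-fit value.
#' Deterministic for a given seed.
#'
#' @param problem [fit_problem()].
#' @param best [fit()] result.
#' @param n_resamples Number of bootstrap resamples (at least 20).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return data.frame (class \code{nr_ci}) with columns parameter, best,
#'   low, high; the bootstrap draws are attached as attribute
#'   \code{samples}.
#' @export
confidence_intervals <- function(problem, best, n_resamples = 100, seed = 1,
                                 level = 0.95) {
  stopifnot(inherits(best, "nr_fit"))
  if (n_resamples < 20) stop("n_resamples must be at least 20")
  pnames <- names(best$par)
  lower <- vapply(problem$free, `[`, numeric(1), 1)[pnames]
  upper <- vapply(problem$free, `[`, numeric(1), 2)[pnames]
  curves <- model_curves(problem, best$par)
  set.seed(seed)
  samples <- matrix(NA_real_, nrow = n_resamples, ncol = length(pnames),
                    dimnames = list(NULL, pnames))
  for (b in seq_len(n_resamples)) {
    datasets <- problem$datasets
    for (k in seq_along(datasets)) {
      datasets[[k]]$r <- curves[[k]] +
        rnorm(length(curves[[k]]), 0, datasets[[k]]$sigma_r)
    }
    samples[b, ] <- refit_local(problem, datasets, best$par, lower, upper)
  }
  a <- (1 - level) / 2
  lo <- apply(samples, 2, quantile, probs = a, names = FALSE)
  hi <- apply(samples, 2, quantile, probs = 1 - a, names = FALSE)
  out <- data.frame(parameter = pnames, best = as.numeric(best$par),
                    low = pmin(lo, as.numeric(best$par)),
                    high = pmax(hi, as.numeric(best$par)),
                    row.names = NULL)
  attr(out, "samples") <- samples
  attr(out, "level") <- level
  class(out) <- c("nr_ci", "data.frame")
  out
}

#' Structural summary report of a fit
#'
#' Rows mirror the quantities conventionally tabulated for these systems:
#' embedded-protein (Bcl-2) volume coverage in the bilayer (%), proximal
#' and distal surface-layer (Bax) thickness (A) and coverage (%), and the
#' total membrane-bound surface-layer thickness (sum of the layers
#' present). Quantities whose layer is absent are reported as \code{n/a}.
#'
#' @param x [fit()] result (or a bare [membrane_structure()]).
#' @param ci Optional [confidence_intervals()] output; when supplied,
#'   each row carries its interval.
#' @return data.frame of class \code{nr_report} with columns quantity,
#'   value, low, high and a formatted \code{display} column.
#' @export
structure_report <- function(x, ci = NULL) {
  s <- if (inherits(x, "nr_fit")) x$structure else x
  stopifnot(inherits(s, "membrane_structure"))
  nsl <- nrow(s$surface_layers)
  get_ci <- function(param) {
    if (is.null(ci)) return(c(NA_real_, NA_real_))
    row <- ci[ci$parameter == param, ]
    if (nrow(row) != 1) return(c(NA_real_, NA_real_))
    c(row$low, row$high)
  }
  rows <- list()
  add <- function(quantity, value, interval = c(NA_real_, NA_real_)) {
    rows[[length(rows) + 1]] <<- data.frame(
      quantity = quantity, value = value,
      low = interval[1], high = interval[2])
  }
  add("Bcl-2 volume coverage in bilayer/%", 100 * s$bcl2_fraction,
      100 * get_ci("bcl2_fraction"))
  if (nsl >= 1) {
    add("Bax proximal distribution thickness/A", s$surface_layers$thickness[1],
        get_ci("surface1_thickness"))
    add("Bax proximal distribution coverage/%",
        100 * s$surface_layers$coverage[1], 100 * get_ci("surface1_coverage"))
  } else {
    add("Bax proximal distribution thickness/A", NA_real_)
    add("Bax proximal distribution coverage/%", NA_real_)
  }
  if (nsl >= 2) {
    add("Bax distal distribution thickness/A", s$surface_layers$thickness[2],
        get_ci("surface2_thickness"))
    add("Bax distal distribution coverage/%",
        100 * s$surface_layers$coverage[2], 100 * get_ci("surface2_coverage"))
  } else {
    add("Bax distal distribution thickness/A", NA_real_)
    add("Bax distal distribution coverage/%", NA_real_)
  }
  total <- if (nsl >= 1) sum(s$surface_layers$thickness) else NA_real_
  add("total membrane-bound Bax layer thickness/A", total)
  out <- do.call(rbind, rows)
  out$display <- ifelse(
    is.na(out$value), "n/a",
    ifelse(is.na(out$low), sprintf("%.1f", out$value),
           sprintf("%.1f (%.1f-%.1f)", out$value, out$low, out$high)))
  class(out) <- c("nr_report", "data.frame")
  out
}

#' @export
print.nr_report <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-45s %s\n", x$quantity[i], x$display[i]))
  }
  invisible(x)
}

#' Compare one- and two-surface-layer models
#'
#' Fits the problem with one and with two surface layers and keeps the
#' two-layer model only if it lowers the per-point chi-squared by more
#' than 5% and resolves the distal layer at more than 3% coverage;
#' otherwise the single-layer model is preferred.
#'
#' @param structure Starting structure carrying two surface layers (the
#'   second is dropped for the one-layer fit).
#' @param datasets List of [contrast_dataset()].
#' @param free Free-parameter bounds (surface2_* entries are dropped for
#'   the one-layer fit).
#' @param seed,control Passed to [fit()].
#' @param lib Component library.
#' @return The preferred \code{nr_fit}, with attribute
#'   \code{n_surface_layers}.
#' @export
select_surface_layers <- function(structure, datasets, free, seed = 1,
                                  control = list(), lib = component_library()) {
  stopifnot(nrow(structure$surface_layers) == 2)
  s1 <- structure
  s1$surface_layers <- s1$surface_layers[1, , drop = FALSE]
  free1 <- free[!grepl("^surface2_", names(free))]
  f1 <- fit(fit_problem(s1, datasets, free1, lib = lib), seed = seed,
            control = control)
  f2 <- fit(fit_problem(structure, datasets, free, lib = lib), seed = seed,
            control = control)
  cov2 <- f2$structure$surface_layers$coverage[2]
  keep2 <- (f2$chisq < 0.95 * f1$chisq) && (cov2 > 0.03)
  out <- if (keep2) f2 else f1
  attr(out, "n_surface_layers") <- if (keep2) 2L else 1L
  out
}
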