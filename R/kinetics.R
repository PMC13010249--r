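# Exponential-association kinetics for protein-binding time series:
# y(t) = y0 + sum_i A_i (1 - exp(-t / tau_i)), one or two components.
# Covers both integrated ATR-FTIR amide-I band areas and surface-protein
# volume-per-area series extracted from time-resolved reflectometry fits.

#' Kinetic time series
#'
#' @param t Time in minutes, non-negative and strictly increasing.
#' @param y Signal (integrated absorbance, a.u., or protein volume per
#'   unit area).
#' @param sigma_y Optional standard uncertainty per point.
#' @param t_span Optional acquisition span per point (x-uncertainty),
#'   minutes.
#' @param label Trace label.
#' @return Object of class \code{kinetic_trace}.
#' @export
kinetic_trace <- function(t, y, sigma_y = NULL, t_span = NULL, label = "") {
  if (length(t) != length(y)) stop("t and y lengths differ")
  if (any(t < 0)) stop("t must be non-negative")
  if (is.unsorted(t, strictly = TRUE)) stop("t must be strictly increasing")
  if (!is.null(sigma_y)) {
    if (length(sigma_y) != length(t)) stop("sigma_y length mismatch")
    if (any(sigma_y <= 0)) stop("sigma_y must be positive")
  }
  structure(list(t = t, y = y, sigma_y = sigma_y, t_span = t_span,
                 label = label),
            class = "kinetic_trace")
}

association_model <- function(t, y0, A, tau) {
  y <- rep(y0, length(t))
  for (i in seq_along(A)) y <- y + A[i] * (1 - exp(-t / tau[i]))
  y
}

aicc <- function(rss_w, n, k) {
  # Gaussian log-likelihood AICc on (weighted) residual sum of squares
  n * log(rss_w / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Fit an exponential-association model
#'
#' Least-squares fit of \code{y(t) = y0 + sum A_i (1 - exp(-t/tau_i))}
#' with one or two components, by Levenberg-Marquardt from a
#' deterministic multi-start grid of time-constant guesses (log-spaced
#' over the sampled window, plus seeded jitter). Components are returned
#' ordered fast to slow; 1-sigma uncertainties come from the parameter
#' covariance. A degenerate (flat) trace is flagged rather than fitted.
#'
#' @param trace [kinetic_trace()].
#' @param n_components 1 or 2.
#' @param seed Integer seed (jittered restarts).
#' @param n_starts Multi-start budget.
#' @return Object of class \code{kinetic_fit}: \code{y0}, \code{A},
#'   \code{tau}, \code{tau_se}, \code{A_se}, per-point residual summary,
#'   \code{aicc}, \code{converged}, \code{flag}.
#' @export
fit_association <- function(trace, n_components = 1, seed = 1, n_starts = 8) {
  stopifnot(inherits(trace, "kinetic_trace"), n_components %in% c(1, 2))
  t <- trace$t; y <- trace$y
  n <- length(t)
  if (n < 3 + 2 * n_components) stop("too few points for ", n_components,
                                     "-component fit")
  w <- if (is.null(trace$sigma_y)) rep(1, n) else 1 / trace$sigma_y^2
  amp <- diff(range(y))
  if (amp <= 0 || amp < 1e-12 * max(abs(y), 1)) {
    return(structure(list(y0 = mean(y), A = rep(0, n_components),
                          tau = rep(NA_real_, n_components),
                          tau_se = rep(NA_real_, n_components),
                          A_se = rep(NA_real_, n_components),
                          n_components = n_components, rss_w = 0,
                          aicc = NA_real_, converged = FALSE,
                          flag = "degenerate: constant signal"),
                     class = "kinetic_fit"))
  }
  t_pos <- t[t > 0]
  tau_grid <- exp(seq(log(max(min(t_pos), 1e-3)), log(max(t) * 2),
                      length.out = 25))
  set.seed(seed)
  starts <- list()
  if (n_components == 1) {
    base <- exp(seq(log(min(tau_grid)), log(max(tau_grid)),
                    length.out = n_starts))
    for (tau1 in base) starts[[length(starts) + 1]] <-
      c(y0 = y[1], A1 = amp, ltau1 = log(tau1))
  } else {
    base <- exp(seq(log(min(tau_grid)), log(max(tau_grid)), length.out = 5))
    for (t1 in base) for (t2 in base) {
      if (t2 <= t1 * 1.5) next
      starts[[length(starts) + 1]] <-
        c(y0 = y[1], A1 = amp / 2, ltau1 = log(t1), A2 = amp / 2,
          ltau2 = log(t2))
    }
    # seeded jittered restarts around the best grid point are appended after
    # the deterministic grid scan below
  }
  unpack <- function(p) {
    if (n_components == 1) list(y0 = p[[1]], A = p[[2]], tau = exp(p[[3]]))
    else list(y0 = p[[1]], A = c(p[[2]], p[[4]]), tau = exp(c(p[[3]], p[[5]])))
  }
  resid_fn <- function(p) {
    m <- unpack(p)
    sqrt(w) * (association_model(t, m$y0, m$A, m$tau) - y)
  }
  run_one <- function(p0) {
    out <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(out, "try-error")) return(NULL)
    out
  }
  best <- NULL; best_rss <- Inf
  for (p0 in starts) {
    out <- run_one(p0)
    if (!is.null(out) && out$deviance < best_rss) {
      best <- out; best_rss <- out$deviance
    }
  }
  if (!is.null(best)) {
    for (j in seq_len(3)) {
      p0 <- best$par * (1 + rnorm(length(best$par), 0, 0.2))
      out <- run_one(unlist(p0))
      if (!is.null(out) && out$deviance < best_rss) {
        best <- out; best_rss <- out$deviance
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(y0 = NA_real_, A = rep(NA_real_, n_components),
                          tau = rep(NA_real_, n_components),
                          tau_se = rep(NA_real_, n_components),
                          A_se = rep(NA_real_, n_components),
                          n_components = n_components, rss_w = NA_real_,
                          aicc = NA_real_, converged = FALSE,
                          flag = "optimizer failure"),
                     class = "kinetic_fit"))
  }
  p <- unlist(best$par)
  m <- unpack(p)
  k <- length(p)
  # covariance from J^T J at the optimum; delta method for tau = exp(ltau)
  se <- rep(NA_real_, k)
  jt <- try({
    s2 <- best$deviance / max(n - k, 1)
    cv <- s2 * solve(best$hessian)
    sqrt(pmax(diag(cv), 0))
  }, silent = TRUE)
  if (!inherits(jt, "try-error")) se <- jt
  ord <- order(m$tau)
  A <- m$A[ord]; tau <- m$tau[ord]
  if (n_components == 1) {
    A_se <- se[2]; tau_se <- (se[3] * tau)
  } else {
    A_se <- se[c(2, 4)][ord]; tau_se <- (se[c(3, 5)] * m$tau)[ord]
  }
  flag <- NULL
  if (n_components == 2 && is.finite(tau[1]) && is.finite(tau[2]) &&
      tau[2] / tau[1] < 1.2) {
    flag <- "time constants nearly indistinguishable"
  }
  structure(list(y0 = m$y0, A = A, tau = tau, tau_se = tau_se, A_se = A_se,
                 n_components = n_components, rss_w = best$deviance,
                 aicc = aicc(best$deviance, n, k),
                 converged = best$info %in% 1:4, flag = flag),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %d component(s)%s\n", x$n_components,
              if (isTRUE(x$converged)) "" else "  [flagged]"))
  for (i in seq_along(x$tau)) {
    cat(sprintf("  A%d = %.4g +/- %.2g, tau%d = %.4g +/- %.2g min\n",
                i, x$A[i], x$A_se[i], i, x$tau[i], x$tau_se[i]))
  }
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Choose one or two kinetic components
#'
#' Fits both the one- and the two-component association model and keeps
#' the second component only on strong evidence: the two-component AICc
#' must improve on the one-component AICc by more than 10 (and the
#' two-component fit must be non-degenerate).
#'
#' @inheritParams fit_association
#' @param threshold AICc improvement required for the extra component.
#' @return 1 or 2, with both fits attached as attribute \code{fits}.
#' @export
select_components <- function(trace, seed = 1, threshold = 10) {
  f1 <- fit_association(trace, 1, seed = seed)
  f2 <- fit_association(trace, 2, seed = seed)
  two_ok <- isTRUE(f2$converged) && is.null(f2$flag) &&
    is.finite(f2$aicc) && is.finite(f1$aicc) &&
    (f1$aicc - f2$aicc) > threshold
  structure(if (two_ok) 2L else 1L, fits = list(f1 = f1, f2 = f2))
}

#' Surface-protein volume trace from time-stamped structural fits
#'
#' Reduces a series of time-resolved reflectometry fits to the kinetic
#' observable: total surface-layer protein volume per unit area
#' (sum of coverage x thickness over the surface layers), against
#' mid-acquisition time, with the acquisition span as x-uncertainty.
#'
#' @param fits List of [fit()] results or [membrane_structure()]s, one
#'   per time window, each with at least one surface layer.
#' @param times Mid-acquisition times, minutes.
#' @param spans Acquisition spans (x-error), minutes; recycled.
#' @return [kinetic_trace()] of volume per unit area (A^3/A^2 = A).
#' @export
series_to_trace <- function(fits, times, spans = NA) {
  if (length(fits) < 3) stop("need at least 3 time-stamped fits")
  if (length(times) != length(fits)) stop("times length mismatch")
  vol <- vapply(fits, function(f) {
    s <- if (inherits(f, "nr_fit")) f$structure else f
    if (!inherits(s, "membrane_structure") || nrow(s$surface_layers) < 1) {
      stop("a fit lacks a surface protein layer; cannot build the trace")
    }
    sum(s$surface_layers$coverage * s$surface_layers$thickness)
  }, numeric(1))
  ord <- order(times)
  kinetic_trace(times[ord], vol[ord],
                t_span = rep_len(spans, length(times))[ord],
                label = "surface protein volume per area")
}
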