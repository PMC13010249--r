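# Specular reflectivity kernel: Abeles optical matrix (compiled), Parratt
# recursion (pure-R cross-check), Gaussian resolution smearing and
# error-function micro-slicing of rough stacks.

validate_slabs <- function(slabs) {
  req <- c("thickness", "sld", "rough")
  if (!is.data.frame(slabs) || !all(req %in% names(slabs))) {
    stop("slabs must be a data.frame with columns thickness, sld, rough")
  }
  if (nrow(slabs) < 2) stop("need at least 2 slabs (fronting and backing)")
  if (any(slabs$thickness < 0)) stop("negative slab thickness")
  if (any(slabs$rough < 0)) stop("negative interfacial roughness")
  slabs
}

validate_q <- function(q) {
  if (any(!is.finite(q)) || any(q <= 0)) stop("Q values must be positive")
  if (is.unsorted(q, strictly = TRUE)) stop("Q values must be strictly increasing")
  q
}

#' Slab-stack container
#'
#' Convenience constructor for the slab table consumed by the reflectivity
#' kernels. The first and last rows are the semi-infinite fronting
#' (substrate) and backing (solvent) media; their thickness is ignored.
#' \code{rough} is the roughness of the interface between a slab and the
#' one before it (first entry unused).
#'
#' @param thickness Thicknesses in A (>= 0).
#' @param sld SLDs in 1e-6 A^-2.
#' @param rough Interface roughnesses in A (>= 0).
#' @param name Optional slab labels.
#' @return data.frame of class \code{nr_slabs}.
#' @export
slab_stack <- function(thickness, sld, rough = 0, name = NULL) {
  n <- length(thickness)
  rough <- rep_len(rough, n)
  out <- data.frame(thickness = thickness, sld = sld, rough = rough)
  if (!is.null(name)) out$name <- name
  class(out) <- c("nr_slabs", "data.frame")
  validate_slabs(out)
}

#' Reflectivity by the Abeles optical-matrix method
#'
#' Computes specular reflectivity R(Q) of a stack of homogeneous slabs,
#' with interfacial roughness applied as Nevot-Croce damping of each
#' interface's Fresnel coefficient. The beam enters through the fronting
#' medium (first slab); refraction is handled relative to its SLD, so
#' total reflection below the critical edge of a denser backing is exact.
#'
#' @param slabs Slab table (see [slab_stack()]).
#' @param q Strictly increasing momentum-transfer values, A^-1.
#' @return R(Q), dimensionless, in \[0, 1\].
#' @export
reflectivity_abeles <- function(slabs, q) {
  slabs <- validate_slabs(slabs)
  q <- validate_q(q)
  abeles_cpp(q, slabs$thickness, slabs$sld, slabs$rough)
}

#' Reflectivity by the Parratt recursion
#'
#' Independent implementation of the same physics as
#' [reflectivity_abeles()] via the bottom-up Parratt recursion, in pure R.
#' Used as a cross-check of the compiled matrix kernel; the two agree to
#' better than 1e-8 relative on arbitrary stacks.
#'
#' @inheritParams reflectivity_abeles
#' @return R(Q) in \[0, 1\].
#' @export
reflectivity_parratt <- function(slabs, q) {
  slabs <- validate_slabs(slabs)
  q <- validate_q(q)
  th <- slabs$thickness; sld <- slabs$sld; rg <- slabs$rough
  n <- nrow(slabs)
  kz <- lapply(seq_len(n), function(j) {
    sqrt(complex(real = q^2 / 4 - 4 * pi * (sld[j] - sld[1]) * 1e-6,
                 imaginary = 0))
  })
  r <- NULL
  for (j in seq(n - 1, 1)) {
    kj <- kz[[j]]; kj1 <- kz[[j + 1]]
    den <- kj + kj1
    fr <- ifelse(Mod(den) == 0, 0 + 0i, (kj - kj1) / den) *
      exp(-2 * kj * kj1 * rg[j + 1]^2)
    if (is.null(r)) {
      r <- fr
    } else {
      ph <- exp(2i * kj1 * th[j + 1])
      r <- (fr + r * ph) / (1 + fr * r * ph)
    }
  }
  pmin(Mod(r)^2, 1)
}

# Gauss-Hermite nodes/weights by Golub-Welsch; cached per order.
gauss_hermite <- function(n) {
  key <- as.character(n)
  if (is.null(.reflmem$gh)) .reflmem$gh <- list()
  if (!is.null(.reflmem$gh[[key]])) return(.reflmem$gh[[key]])
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- sqrt(pi) * e$vectors[1, ]^2
  ord <- order(x)
  res <- list(nodes = x[ord], weights = w[ord])
  .reflmem$gh[[key]] <- res
  res
}

#' Gaussian resolution smearing of a reflectivity curve
#'
#' Convolves R(Q) with a Gaussian resolution kernel of FWHM
#' \code{dq_over_q * Q} (sigma = FWHM / 2.355), evaluated by 17-point
#' Gauss-Hermite quadrature. This form operates on an already-computed
#' curve by interpolation; model fitting uses the exact-grid equivalent
#' [smeared_reflectivity()].
#'
#' @param q Momentum transfer grid, A^-1.
#' @param r Reflectivity at \code{q}.
#' @param dq_over_q Fractional FWHM resolution (> 0), e.g. 0.035 or 0.07.
#' @param n_quad Quadrature order.
#' @return Smeared reflectivity at \code{q}.
#' @export
smear_curve <- function(q, r, dq_over_q, n_quad = 17) {
  q <- validate_q(q)
  if (dq_over_q <= 0) stop("dq_over_q must be > 0")
  gh <- gauss_hermite(n_quad)
  sig <- dq_over_q * q / 2.355
  out <- numeric(length(q))
  for (i in seq_along(gh$nodes)) {
    qi <- q + sqrt(2) * sig * gh$nodes[i]
    ri <- approx(q, r, xout = qi, rule = 2)$y
    out <- out + gh$weights[i] * ri
  }
  out / sqrt(pi)
}

#' Smeared model reflectivity on an exact shifted grid
#'
#' Evaluates the slab model at every quadrature-shifted Q, so no
#' interpolation error enters. Q shifted below a small floor is clamped.
#'
#' @inheritParams reflectivity_abeles
#' @param dq_over_q Fractional FWHM resolution; either a scalar or one
#'   value per Q point (a per-point sigma_Q column divided by Q).
#' @param n_quad Quadrature order.
#' @return Smeared R(Q).
#' @export
smeared_reflectivity <- function(slabs, q, dq_over_q, n_quad = 17) {
  slabs <- validate_slabs(slabs)
  q <- validate_q(q)
  if (any(dq_over_q <= 0)) stop("dq_over_q must be > 0")
  dq_over_q <- rep_len(dq_over_q, length(q))
  gh <- gauss_hermite(n_quad)
  sig <- dq_over_q * q / 2.355
  qmat <- outer(q, rep(1, n_quad)) +
    outer(sqrt(2) * sig, gh$nodes)
  qmat[qmat < 1e-6] <- 1e-6
  rv <- abeles_cpp(as.vector(qmat), slabs$thickness, slabs$sld, slabs$rough)
  rmat <- matrix(rv, nrow = length(q))
  as.vector(rmat %*% gh$weights) / sqrt(pi)
}

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' SLD depth profile of a slab stack
#'
#' Error-function-broadened SLD(z) of a stack, z = 0 at the first
#' (fronting) interface and increasing toward the backing medium.
#'
#' @inheritParams reflectivity_abeles
#' @param dz Grid spacing in A.
#' @param margin Extra extent beyond the outer interfaces, in multiples of
#'   the largest roughness.
#' @return data.frame with columns \code{z} and \code{sld}.
#' @export
slab_sld_profile <- function(slabs, dz = 0.5, margin = 4) {
  slabs <- validate_slabs(slabs)
  n <- nrow(slabs)
  # interface j (between slab j and j+1) position; first interface at 0
  pos <- c(0, cumsum(slabs$thickness[seq(2, n - 1)]))
  pad <- margin * max(slabs$rough, 1)
  z <- seq(-pad, pos[length(pos)] + pad, by = dz)
  sld <- rep(slabs$sld[1], length(z))
  for (j in seq_len(n - 1)) {
    s <- slabs$rough[j + 1]
    step <- if (s > 0) 0.5 * (1 + erf((z - pos[j]) / (sqrt(2) * s)))
            else as.numeric(z >= pos[j])
    sld <- sld + (slabs$sld[j + 1] - slabs$sld[j]) * step
  }
  data.frame(z = z, sld = sld)
}

#' Micro-slice a rough stack into thin zero-roughness slabs
#'
#' Nevot-Croce damping is accurate only while roughness is small compared
#' with the adjacent layer thicknesses. When any interior roughness
#' exceeds half an adjacent slab's thickness the stack is re-expressed as
#' its error-function SLD profile cut into thin slices (width at most
#' \code{min(2, roughness/3)} A) with zero roughness.
#'
#' After slicing, runs of adjacent slices whose SLD varies by less than
#' \code{merge_tol} are merged into a single slab of their
#' thickness-weighted mean SLD (slabs of identical SLD and zero roughness
#' are exactly equivalent to one thicker slab, so the error is bounded by
#' the tolerance, far below measurement noise).
#'
#' @inheritParams reflectivity_abeles
#' @param force Slice even when Nevot-Croce would be adequate.
#' @param merge_tol SLD window (1e-6 A^-2) within which adjacent slices
#'   are merged; 0 disables merging.
#' @return A slab table, either the input (no slicing needed) or the
#'   sliced equivalent.
#' @export
microslice_slabs <- function(slabs, force = FALSE, merge_tol = 0.001) {
  slabs <- validate_slabs(slabs)
  n <- nrow(slabs)
  if (!force) {
    need <- FALSE
    for (j in seq_len(n - 1)) {
      s <- slabs$rough[j + 1]
      adj <- c(if (j > 1) slabs$thickness[j], if (j < n - 1) slabs$thickness[j + 1])
      if (length(adj) && any(s > adj / 2)) { need <- TRUE; break }
    }
    if (!need) return(slabs)
  }
  rmax <- max(slabs$rough)
  dz <- min(2, if (rmax > 0) rmax / 3 else 2)
  prof <- slab_sld_profile(slabs, dz = dz, margin = 4.5)
  m <- nrow(prof)
  mids <- (prof$sld[-1] + prof$sld[-m]) / 2
  th <- rep(dz, m - 1)
  if (merge_tol > 0 && length(mids) > 1) {
    grp <- integer(length(mids)); grp[1] <- 1L
    glo <- mids[1]; ghi <- mids[1]
    for (i in 2:length(mids)) {
      nlo <- min(glo, mids[i]); nhi <- max(ghi, mids[i])
      if (nhi - nlo <= merge_tol) {
        grp[i] <- grp[i - 1]; glo <- nlo; ghi <- nhi
      } else {
        grp[i] <- grp[i - 1] + 1L; glo <- mids[i]; ghi <- mids[i]
      }
    }
    th_m <- as.numeric(tapply(th, grp, sum))
    sld_m <- as.numeric(tapply(th * mids, grp, sum)) / th_m
    th <- th_m; mids <- sld_m
  }
  slab_stack(
    thickness = c(0, th, 0),
    sld = c(slabs$sld[1], mids, slabs$sld[n]),
    rough = 0
  )
}
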