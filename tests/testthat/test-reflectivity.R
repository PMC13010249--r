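test_that("single smooth interface reproduces the closed-form Fresnel law", {
  q <- tiny_q(80)
  sl <- slab_stack(thickness = c(0, 0), sld = c(2.07, 6.36), rough = 0)
  k0 <- q / 2
  k1 <- sqrt(complex(real = q^2 / 4 - 4 * pi * (6.36 - 2.07) * 1e-6))
  fresnel <- Mod((k0 - k1) / (k0 + k1))^2
  expect_equal(reflectivity_abeles(sl, q), pmin(fresnel, 1), tolerance = 1e-12)
  expect_equal(reflectivity_parratt(sl, q), pmin(fresnel, 1), tolerance = 1e-12)
})

test_that("total external reflection below the critical edge", {
  # Si against D2O: Qc = sqrt(16 pi (rho_b - rho_f))
  sl <- slab_stack(thickness = c(0, 0), sld = c(2.07, 6.36), rough = 0)
  qc <- sqrt(16 * pi * (6.36 - 2.07) * 1e-6)
  q <- seq(qc / 10, qc * 0.98, length.out = 25)
  expect_equal(reflectivity_abeles(sl, q), rep(1, 25), tolerance = 1e-9)
})

test_that("zero-thickness slabs are optically invisible", {
  q <- tiny_q(40)
  base <- slab_stack(thickness = c(0, 30, 80, 0),
                     sld = c(2.07, 3.5, 5.8, 6.36), rough = 0)
  with0 <- slab_stack(thickness = c(0, 30, 0, 80, 0),
                      sld = c(2.07, 3.5, 1.0, 5.8, 6.36), rough = 0)
  expect_equal(reflectivity_abeles(with0, q), reflectivity_abeles(base, q),
               tolerance = 1e-12)
})

test_that("a slab matching both neighbours' SLD leaves R unchanged", {
  q <- tiny_q(40)
  base <- slab_stack(thickness = c(0, 40, 0), sld = c(2.07, 4, 6.36),
                     rough = c(0, 2, 2))
  split <- slab_stack(thickness = c(0, 15, 25, 0), sld = c(2.07, 4, 4, 6.36),
                      rough = c(0, 2, 0, 2))
  expect_equal(reflectivity_abeles(split, q), reflectivity_abeles(base, q),
               tolerance = 1e-12)
})

test_that("Abeles matrix and Parratt recursion agree on random stacks", {
  set.seed(42)
  q <- tiny_q(40)
  worst <- 0
  for (i in 1:300) {
    sl <- rand_stack(n_interior = sample(1:6, 1))
    r1 <- reflectivity_abeles(sl, q)
    r2 <- reflectivity_parratt(sl, q)
    worst <- max(worst, max(abs(r1 - r2) / pmax(r2, 1e-15)))
    # energy bound holds for every stack
    expect_true(all(r1 >= 0 & r1 <= 1))
  }
  expect_lt(worst, 1e-8)
})

test_that("reversing a stack between identical media leaves R unchanged", {
  set.seed(7)
  q <- tiny_q(40)
  for (i in 1:20) {
    th <- c(0, runif(4, 10, 120), 0)
    sld <- c(3, runif(4, -0.5, 7), 3)
    fwd <- slab_stack(th, sld, rough = 0)
    rev <- slab_stack(base::rev(th), base::rev(sld), rough = 0)
    expect_equal(reflectivity_abeles(fwd, q), reflectivity_abeles(rev, q),
                 tolerance = 1e-9)
  }
})

test_that("large-Q reflectivity follows the Fresnel Q^-4 envelope", {
  drho <- (6.36 - 2.07) * 1e-6
  q <- seq(0.4, 0.6, length.out = 10)
  sl <- slab_stack(thickness = c(0, 0), sld = c(2.07, 6.36), rough = 0)
  r <- reflectivity_abeles(sl, q)
  envelope <- (4 * pi * drho)^2 / q^4
  expect_equal(r / envelope, rep(1, 10), tolerance = 0.01)
})

test_that("resolution smearing has the correct limits and damps fringes", {
  q <- tiny_q(120)
  sl <- slab_stack(thickness = c(0, 400, 0), sld = c(2.07, 3.5, 6.36),
                   rough = 0)
  r <- reflectivity_abeles(sl, q)
  # constant curve unchanged by a normalized kernel
  expect_equal(smear_curve(q, rep(0.5, length(q)), 0.035),
               rep(0.5, length(q)), tolerance = 1e-9)
  # vanishing resolution width: smeared equals unsmeared
  r_tiny <- smeared_reflectivity(sl, q, 1e-6)
  expect_equal(r_tiny, r, tolerance = 1e-6)
  # Kiessig fringes of the 400 A layer are damped: peak-to-trough contrast
  # of log R shrinks in the fringe region
  rs <- smeared_reflectivity(sl, q, 0.07)
  win <- q > 0.05 & q < 0.15
  contrast <- function(x) diff(range(log10(x[win])))
  expect_lt(contrast(rs), contrast(r))
  expect_error(smear_curve(q, r, 0), "dq_over_q")
})

test_that("input validation rejects unphysical stacks and grids", {
  sl <- slab_stack(thickness = c(0, 30, 0), sld = c(2, 4, 6), rough = 0)
  expect_error(reflectivity_abeles(sl, c(0.2, 0.1)), "increasing")
  expect_error(reflectivity_abeles(sl, c(-0.1, 0.1)), "positive")
  expect_error(slab_stack(thickness = c(0, -5, 0), sld = c(2, 4, 6)),
               "negative slab thickness")
  expect_error(slab_stack(thickness = c(0, 5, 0), sld = c(2, 4, 6),
                          rough = -1), "negative interfacial roughness")
})

test_that("micro-slicing reproduces Nevot-Croce when roughness is gentle", {
  q <- tiny_q(60)
  # roughness well below half thickness: NC is accurate, slicing must agree
  sl <- slab_stack(thickness = c(0, 40, 60, 0), sld = c(2.07, 3.5, 5.5, 6.36),
                   rough = c(0, 2, 2, 2))
  expect_identical(nrow(microslice_slabs(sl)), nrow(sl)) # not triggered
  sliced <- microslice_slabs(sl, force = TRUE)
  expect_gt(nrow(sliced), 50)
  r_nc <- reflectivity_abeles(sl, q)
  r_sl <- reflectivity_abeles(sliced, q)
  expect_equal(r_sl / pmax(r_nc, 1e-15), rep(1, length(q)), tolerance = 0.02)
  # merging flat runs is numerically transparent
  unmerged <- microslice_slabs(sl, force = TRUE, merge_tol = 0)
  expect_equal(reflectivity_abeles(sliced, q),
               reflectivity_abeles(unmerged, q), tolerance = 5e-3)
  # thin layer flanked by large roughness triggers slicing automatically
  thin <- slab_stack(thickness = c(0, 4, 0), sld = c(2.07, 3.5, 6.36),
                     rough = c(0, 3, 3))
  expect_gt(nrow(microslice_slabs(thin)), nrow(thin))
})
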