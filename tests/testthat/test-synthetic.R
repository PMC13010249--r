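test_that("simulated contrast sets are pure functions of parameters and seed", {
  s <- mom_fixture(2)
  q <- tiny_q(40)
  a <- simulate_contrast_set(s, q = q, seed = 31)
  b <- simulate_contrast_set(s, q = q, seed = 31)
  for (k in 1:4) expect_identical(a[[k]]$r, b[[k]]$r)
  c2 <- simulate_contrast_set(s, q = q, seed = 32)
  expect_false(identical(a[[1]]$r, c2[[1]]$r))
})

test_that("zero noise returns the smeared model exactly", {
  s <- mom_fixture(2)
  q <- tiny_q(40)
  ds <- simulate_contrast_set(s, q = q, noise_rel = 0, background = 1e-7,
                              seed = 1)
  for (k in seq_along(ds)) {
    slabs <- microslice_slabs(to_slabs(s, ds[[k]]$contrast))
    expect_equal(ds[[k]]$r, smeared_reflectivity(slabs, q, 0.035) + 1e-7,
                 tolerance = 1e-15)
  }
})

test_that("generated noise matches its recorded sigma", {
  s <- mom_fixture(3)
  ds <- simulate_contrast_set(s, q = default_q_grid(150), noise_rel = 0.02,
                              seed = 202)
  z <- unlist(lapply(ds, function(d) {
    slabs <- microslice_slabs(to_slabs(s, d$contrast))
    model <- smeared_reflectivity(slabs, d$q, 0.035) + 1e-7
    (d$r - model) / d$sigma_r
  }))
  expect_length(z, 600)
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(var(z) - 1), 0.1)
})

test_that("the five reference systems carry their tabulated parameters", {
  f3 <- mom_fixture(3)
  expect_equal(f3$bcl2_fraction, 0.399)
  expect_equal(f3$surface_layers$thickness, c(55.0, 52.7))
  expect_equal(f3$surface_layers$coverage, c(0.262, 0.045))
  f5 <- mom_fixture(5)
  expect_equal(f5$bcl2_fraction, 0.387)
  expect_equal(f5$surface_layers$thickness, 64.7)
  expect_equal(f5$surface_layers$coverage, 0.293)
  expect_equal(f5$lipids$mole_fraction, c(0.9, 0.1))
  # distal layer only where it was resolved
  expect_equal(nrow(mom_fixture(1)$surface_layers), 2L)
  expect_equal(nrow(mom_fixture(2)$surface_layers), 1L)
  expect_equal(nrow(mom_fixture(4)$surface_layers), 1L)
  expect_error(mom_fixture(6), "column")
})

test_that("kinetic traces plateau at the summed amplitudes", {
  tr <- simulate_kinetics(c(1, 1.5), c(9, 148), t_end = 3000, dt = 10,
                          noise_rel = 0.01, seed = 8, y0 = 0.2)
  tail_mean <- mean(tr$y[tr$t > 2000])
  expect_equal(tail_mean, 0.2 + 2.5, tolerance = 0.02)
  # zero amplitudes: flat noisy baseline around y0
  tr0 <- simulate_kinetics(numeric(0), numeric(0), t_end = 100, dt = 1,
                           noise_rel = 0.02, seed = 9, y0 = 1)
  expect_equal(mean(tr0$y), 1, tolerance = 0.05)
  expect_lt(sd(tr0$y), 0.1)
})

test_that("time-resolved series follow the staged structural evolution", {
  mk <- function(th, cov) membrane_structure(
    bcl2_fraction = 0.3,
    surface_layers = data.frame(thickness = th, coverage = cov,
                                component = "h_bax"))
  q <- tiny_q(25)
  # single stage: identical structures in every window
  one <- simulate_timeresolved_nr(list(list(time = 0, structure = mk(25, 0.1))),
                                  t_end = 90, interval = 15, q = q, seed = 2)
  expect_length(one, 6)
  ths <- vapply(one, function(w) w$structure$surface_layers$thickness[1],
                numeric(1))
  expect_equal(ths, rep(25, 6))
  # monomer layer doubling into an oligomer layer
  stages <- list(list(time = 0, structure = mk(25, 0.1)),
                 list(time = 720, structure = mk(50, 0.25)))
  tr_series <- simulate_timeresolved_nr(stages, t_end = 720, interval = 15,
                                        tau = 163, q = q, seed = 3)
  ths <- vapply(tr_series, function(w) w$structure$surface_layers$thickness[1],
                numeric(1))
  expect_true(all(diff(ths) >= -1e-9))
  expect_equal(ths[1], 25, tolerance = 0.1)
  expect_equal(ths[length(ths)], 50, tolerance = 0.5)
  # the exponential approach is recoverable from a coverage-growth series
  stages2 <- list(list(time = 0, structure = mk(25, 0.1)),
                  list(time = 720, structure = mk(25, 0.25)))
  series2 <- simulate_timeresolved_nr(stages2, t_end = 720, interval = 15,
                                      tau = 163, q = q, seed = 4)
  trace <- series_to_trace(lapply(series2, `[[`, "structure"),
                           times = vapply(series2, `[[`, numeric(1), "time"),
                           spans = 15)
  f <- fit_association(trace, 1, seed = 1)
  expect_equal(f$tau, 163, tolerance = 11 / 163)
})
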