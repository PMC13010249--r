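test_that("chi-squared matches a naive loop and obeys scaling identities", {
  sp <- small_problem(noise_rel = 0.02, seed = 3, n_q = 40)
  p <- sp$problem
  par <- c(tail_thickness = 31)
  curves <- model_curves(p, par)
  # independent naive summation over datasets and points
  raw <- 0; n <- 0
  for (k in seq_along(p$datasets)) {
    ds <- p$datasets[[k]]
    for (i in seq_along(ds$q)) {
      raw <- raw + ((curves[[k]][i] - ds$r[i]) / ds$sigma_r[i])^2
      n <- n + 1
    }
  }
  cs <- chi_squared(p, par)
  expect_equal(attr(cs, "raw"), raw, tolerance = 1e-12)
  expect_equal(as.numeric(cs), raw / n, tolerance = 1e-12)
  expect_identical(attr(cs, "n"), n)
  # doubling every sigma divides chi-squared by 4
  p2 <- p
  for (k in seq_along(p2$datasets)) p2$datasets[[k]]$sigma_r <-
    2 * p2$datasets[[k]]$sigma_r
  expect_equal(as.numeric(chi_squared(p2, par)), as.numeric(cs) / 4,
               tolerance = 1e-12)
})

test_that("model identical to data gives zero chi-squared", {
  sp <- small_problem(noise_rel = 0, seed = 1, n_q = 30, background = 0)
  p <- sp$problem
  # noiseless simulation at the same structure: residuals vanish
  expect_equal(as.numeric(chi_squared(p)), 0, tolerance = 1e-16)
})

test_that("a fully fixed problem returns its input unchanged", {
  sp <- small_problem(noise_rel = 0.02, seed = 2, n_q = 30)
  p <- fit_problem(sp$structure, sp$problem$datasets, free = list(),
                   free_backgrounds = FALSE)
  f <- fit(p, seed = 1)
  expect_length(f$par, 0)
  expect_equal(f$chisq, as.numeric(chi_squared(p)))
  expect_true(f$convergence$converged)
})

test_that("single-parameter fit on noiseless data matches a grid scan", {
  sp <- small_problem(noise_rel = 0, seed = 1, n_q = 40)
  p <- sp$problem
  grid <- seq(20, 40, by = 0.25)
  cost <- vapply(grid, function(v)
    as.numeric(chi_squared(p, c(tail_thickness = v))), numeric(1))
  argmin <- grid[which.min(cost)]
  f <- fit(p, seed = 5, control = fast_control)
  expect_equal(unname(f$par["tail_thickness"]), 28, tolerance = 1e-3)
  expect_equal(unname(f$par["tail_thickness"]), argmin, tolerance = 0.25 / 28)
  # optimum is not beaten by any tested grid point (up to the polish
  # stopping tolerance; the grid contains the exact truth where chi2 = 0)
  expect_lte(f$chisq, min(cost) + 1e-6)
})

test_that("fitting is deterministic under a fixed seed", {
  sp <- small_problem(noise_rel = 0.02, seed = 9, n_q = 30)
  ctl <- list(maxiter = 10, polish_maxit = 100)
  f1 <- fit(sp$problem, seed = 123, control = ctl)
  f2 <- fit(sp$problem, seed = 123, control = ctl)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$chisq, f2$chisq)
})

test_that("bootstrap intervals contain the best fit and shrink with noise", {
  sp <- small_problem(noise_rel = 0.02, seed = 4, n_q = 40)
  f <- fit(sp$problem, seed = 2, control = fast_control)
  expect_error(confidence_intervals(sp$problem, f, n_resamples = 10),
               "at least 20")
  ci <- confidence_intervals(sp$problem, f, n_resamples = 20, seed = 7)
  expect_true(all(ci$low <= ci$best & ci$best <= ci$high))
  # determinism
  ci2 <- confidence_intervals(sp$problem, f, n_resamples = 20, seed = 7)
  expect_identical(ci$low, ci2$low)
  # near-noiseless data: interval collapses toward the estimate
  spq <- small_problem(noise_rel = 1e-4, seed = 4, n_q = 40)
  fq <- fit(spq$problem, seed = 2, control = fast_control)
  ciq <- confidence_intervals(spq$problem, fq, n_resamples = 20, seed = 7)
  expect_lt(ciq$high - ciq$low, (ci$high - ci$low) / 10)
})

test_that("adding a second contrast does not widen identifiability", {
  s <- membrane_structure(bcl2_fraction = 0.2,
                          surface_layers = data.frame(
                            thickness = 40, coverage = 0.2,
                            component = "h_bax"))
  q <- tiny_q(40)
  ds <- simulate_contrast_set(s, contrasts = list(solvent_contrast(1),
                                                  solvent_contrast(0)),
                              q = q, noise_rel = 0.02, seed = 21)
  free <- list(surface1_coverage = c(0.02, 0.5))
  width <- function(datasets) {
    p <- fit_problem(s, datasets, free, free_backgrounds = FALSE)
    f <- fit(p, seed = 3, control = fast_control)
    ci <- confidence_intervals(p, f, n_resamples = 30, seed = 11)
    ci$high - ci$low
  }
  w1 <- width(ds[1])
  w2 <- width(ds)
  # narrower or equal up to the Monte-Carlo noise of the bootstrap widths
  expect_lte(w2, w1 * 1.2)
})

test_that("the structural report mirrors the tabulated quantities", {
  s <- mom_fixture(3)
  rep3 <- structure_report(s)
  get <- function(q) rep3$value[rep3$quantity == q]
  expect_equal(get("Bcl-2 volume coverage in bilayer/%"), 39.9)
  expect_equal(get("Bax proximal distribution thickness/A"), 55.0)
  expect_equal(get("Bax proximal distribution coverage/%"), 26.2)
  expect_equal(get("total membrane-bound Bax layer thickness/A"), 107.7)
  # a single-layer system reports the distal rows as n/a
  rep5 <- structure_report(mom_fixture(5))
  distal <- rep5$display[grepl("distal", rep5$quantity)]
  expect_true(all(distal == "n/a"))
  # total = proximal + distal when both are present
  expect_equal(get("total membrane-bound Bax layer thickness/A"),
               get("Bax proximal distribution thickness/A") +
                 rep3$value[rep3$quantity == "Bax distal distribution thickness/A"])
})
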