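test_that("a protein-free structure maps to a plain supported bilayer", {
  s <- membrane_structure(bcl2_fraction = 0)
  lib <- component_library()
  sl <- to_slabs(s, 1, lib)
  expect_equal(sl$name,
               c("silicon", "oxide", "water_gap", "inner_heads", "tails",
                 "outer_heads", "solvent"))
  # tails slab: coverage * tail SLD + rest solvent, computed by hand
  manual <- 0.95 * component_sld(lib$d_popc_tails, 1) + 0.05 * solvent_sld(1)
  expect_equal(sl$sld[sl$name == "tails"], manual, tolerance = 1e-12)
  # the water gap is indistinguishable from bulk solvent
  expect_equal(sl$sld[sl$name == "water_gap"], solvent_sld(1))
})

test_that("a zero-coverage surface layer is solvent-identical at all contrasts", {
  s <- membrane_structure(surface_layers = data.frame(
    thickness = 50, coverage = 0, component = "h_bax"))
  for (x in c(0, 0.38, 0.8, 1)) {
    sl <- to_slabs(s, x)
    expect_equal(sl$sld[sl$name == "surface_1"], solvent_sld(x),
                 tolerance = 1e-12)
  }
})

test_that("deuterated tails respond to contrast through solvent filling only", {
  s <- membrane_structure(bcl2_fraction = 0)
  lib <- component_library()
  sl_h <- to_slabs(s, 0, lib)
  sl_d <- to_slabs(s, 1, lib)
  dtail <- sl_d$sld[sl_d$name == "tails"] - sl_h$sld[sl_h$name == "tails"]
  # tails have no labile H, so the difference is the solvent term alone
  expect_equal(dtail, (1 - 0.95) * (solvent_sld(1) - solvent_sld(0)),
               tolerance = 1e-12)
})

test_that("geometry is bit-identical across the four contrasts", {
  s <- mom_fixture(3)
  stacks <- lapply(standard_contrasts(), function(ct) to_slabs(s, ct))
  for (k in 2:4) {
    expect_identical(stacks[[k]]$thickness, stacks[[1]]$thickness)
    expect_identical(stacks[[k]]$rough, stacks[[1]]$rough)
  }
})

test_that("volume fractions are in [0,1] and sum to one with solvent", {
  s <- mom_fixture(1)
  vf <- volume_fraction_profile(s, dz = 0.5)
  mat <- as.matrix(vf[, -1])
  expect_true(all(mat >= -1e-9 & mat <= 1 + 1e-9))
  expect_equal(rowSums(mat), rep(1, nrow(mat)), tolerance = 1e-9)
  expect_error(volume_fraction_profile(s, dz = 2), "dz")
})

test_that("erf smoothing conserves layer volume per unit area", {
  s <- mom_fixture(3)
  for (dz in c(1, 0.25)) {
    vf <- volume_fraction_profile(s, dz = dz, margin = 6)
    bax <- vf$h_bax
    integral <- sum(bax) * dz
    expected <- sum(s$surface_layers$coverage * s$surface_layers$thickness)
    expect_equal(integral, expected, tolerance = 1e-4)
  }
})

test_that("zero roughness gives an exactly piecewise-constant profile", {
  s <- membrane_structure(bcl2_fraction = 0.1, substrate_roughness = 0,
                          roughness = 0)
  vf <- volume_fraction_profile(s, dz = 0.5)
  tails_region <- vf$z > 12 + 4 + 8 + 1 & vf$z < 12 + 4 + 8 + 28 - 1
  vals <- unique(round(vf$d_popc_tails[tails_region], 12))
  expect_length(vals, 1)
  expect_equal(vals, 0.95 - 0.1)
})

test_that("SLD profile built from slabs equals the one from fractions", {
  s <- mom_fixture(3)
  for (x in c(0, 1)) {
    p1 <- sld_profile(s, x, dz = 0.5, via = "slabs")
    p2 <- sld_profile(s, x, dz = 0.5, via = "fractions")
    expect_equal(p1$z, p2$z)
    expect_equal(p1$sld, p2$sld, tolerance = 1e-9)
  }
})

test_that("layer thickness reads as stacked monomer units", {
  m <- oligomer_units(25, 25)
  expect_equal(as.numeric(m), 1)
  expect_equal(attr(m, "bracket"), c(1, 1))
  d <- oligomer_units(50, 25)
  expect_equal(as.numeric(d), 2)
  expect_equal(attr(d, "bracket"), c(2, 2))
  e <- oligomer_units(108, 25)
  expect_equal(as.numeric(e), 4.32)
  expect_equal(attr(e, "bracket"), c(4, 5))
  expect_error(oligomer_units(0, 25), "positive")
  expect_error(oligomer_units(25, -1), "positive")
})

test_that("structural invariants are enforced", {
  expect_error(membrane_structure(bcl2_fraction = 1.2), "fractions")
  expect_error(membrane_structure(bcl2_fraction = 0.97, lipid_coverage = 0.95),
               "covered area")
  expect_error(membrane_structure(tail_thickness = -5), "negative")
  sl3 <- data.frame(thickness = c(10, 10, 10), coverage = 0.1,
                    component = "h_bax")
  expect_error(membrane_structure(surface_layers = sl3), "at most two")
})
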