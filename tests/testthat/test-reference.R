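test_that("default reference set carries the optimization targets", {
  ref <- reference_set()
  expect_equal(ref$targets$eps_r$value, 44.5)
  expect_equal(ref$targets$D_OW$value, 2.16e-5)
  expect_equal(ref$targets$rdf_1p$value, 0.280)
  expect_equal(ref$targets$rdf_1h$value, 2.58)
  expect_equal(ref$eps_e, 1.78)
  expect_equal(ref$temperature_grid_K, seq(260, 360, by = 20))
  expect_length(ref$targets$rho_1bar$value, 6)
})

test_that("reference set round-trips through YAML", {
  ref <- reference_set()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_reference_yaml(ref, path)
  ref2 <- read_reference_yaml(path)
  expect_equal(ref2$eps_e, ref$eps_e)
  expect_equal(ref2$temperature_grid_K, ref$temperature_grid_K)
  for (nm in names(ref$targets)) {
    expect_equal(ref2$targets[[nm]]$value, ref$targets[[nm]]$value)
    expect_equal(ref2$targets[[nm]]$units, ref$targets[[nm]]$units)
  }
})

test_that("nuclear dielectric target is eps_r / eps_e", {
  expect_equal(ecc_dielectric_target(1.78, 1.78), 1.0)
  expect_equal(ecc_dielectric_target(79.2, 1.78), 44.49438, tolerance = 1e-6)
  expect_equal(round(ecc_dielectric_target(79.2, 1.78), 1), 44.5)
  # linear in eps_r, inverse in eps_e
  expect_equal(ecc_dielectric_target(2 * 79.2), 2 * ecc_dielectric_target(79.2))
  expect_equal(ecc_dielectric_target(79.2, 2 * 1.78),
               ecc_dielectric_target(79.2, 1.78) / 2)
  # monotone experimental isobar stays monotone after division
  eps_T <- c(87.9, 83.9, 80.2, 76.6, 73.2) # 273-313 K, decreasing
  expect_true(all(diff(ecc_dielectric_target(eps_T)) < 0))
  expect_error(ecc_dielectric_target(79.2, -1), "eps_e")
  expect_error(ecc_dielectric_target(1.0, 1.78), "eps_r")
})

test_that("finite-size diffusion correction reproduces the 832-water target", {
  # 832 waters at ambient density -> cubic box edge ~2.92 nm
  d <- finite_size_diffusion_target(2.41e-5, 300, 0.85e-3, 2.92)
  expect_equal(d, 2.16e-5, tolerance = 2e-3)
  expect_lt(d, 2.41e-5) # the correction is always positive
})

test_that("diffusion correction has the right limits and scaling", {
  d_inf <- finite_size_diffusion_target(2.41e-5, 300, 1e6, 2.92)
  expect_equal(d_inf, 2.41e-5, tolerance = 1e-9)
  c1 <- 2.41e-5 - finite_size_diffusion_target(2.41e-5, 300, 0.85e-3, 2.92)
  c2 <- 2.41e-5 - finite_size_diffusion_target(2.41e-5, 300, 0.85e-3, 5.84)
  expect_equal(c1 / c2, 2, tolerance = 1e-12)
  expect_error(finite_size_diffusion_target(2.41e-5, 300, 0.85e-3, 0), "L_nm")
  expect_error(finite_size_diffusion_target(-1, 300, 0.85e-3, 2.9), "D_exp")
})

test_that("rdf curves validate their invariants", {
  expect_error(rdf_curve(c(0.1, 0.1, 0.3), c(1, 2, 1)), "increasing")
  expect_error(rdf_curve(c(0.1, 0.2), c(1, -0.5)), "non-negative")
  expect_error(rdf_first_peak(rdf_curve(c(0.1, 0.2), c(0, 1))), "3 points")
  flat <- rdf_curve(seq(0.1, 0.5, 0.01), rep(0.9, 41))
  expect_error(rdf_first_peak(flat), "no local maximum")
})

test_that("first-peak extraction recovers a planted Gaussian peak", {
  curve <- generate_rdf_fixture(0.280, 2.58, 0.002)
  pk <- rdf_first_peak(curve)
  expect_lt(abs(pk$position - 0.280), 0.002)
  expect_lt(abs(pk$height - 2.58), 0.05)
})

test_that("the first peak is returned even when a later peak is higher", {
  r <- seq(0.2, 0.8, by = 0.002)
  g <- 1 + 1.0 * exp(-(r - 0.30)^2 / (2 * 0.012^2)) +
    2.5 * exp(-(r - 0.55)^2 / (2 * 0.02^2))
  pk <- rdf_first_peak(rdf_curve(r, g))
  expect_equal(pk$position, 0.30, tolerance = 0.002)
  expect_equal(pk$height, 2.0, tolerance = 0.02)
})

test_that("quadratic interpolation beats the raw argmax on random peaks", {
  set.seed(11)
  for (i in 1:100) {
    pos <- runif(1, 0.26, 0.31)
    height <- runif(1, 1.5, 3.5)
    curve <- generate_rdf_fixture(pos, height, 0.002)
    pk <- rdf_first_peak(curve)
    # brute-force discrete argmax oracle
    argmax <- curve$r[which.max(curve$g)]
    expect_lt(abs(pk$position - argmax), 0.002)  # refinement stays local
    expect_lte(abs(pk$position - pos), 0.002)    # and recovers the plant
  }
})

test_that("rdf files round-trip through the two-column text format", {
  curve <- generate_rdf_fixture(0.28, 2.58, 0.004)
  path <- withr::local_tempfile(fileext = ".dat")
  write_rdf(curve, path)
  curve2 <- read_rdf(path)
  expect_equal(curve2$r, curve$r, tolerance = 1e-6)
  expect_equal(curve2$g, curve$g, tolerance = 1e-6)
})
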