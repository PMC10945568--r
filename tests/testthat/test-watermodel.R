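test_that("parameter construction validates positivity and finiteness", {
  expect_s3_class(water_model_preset("eccw2024"), "water_model_params")
  expect_error(water_model_params(-0.3, 0.7, 0.5, 0.095, 0.015, 105), "sigma")
  expect_error(water_model_params(0.3, 0.7, 0.5, 0.095, NaN, 105), "d_OM")
  expect_error(water_model_params(0.3, 0.7, 0, 0.095, 0.015, 105), "q_H")
})

test_that("bounds validation distinguishes optimizer and standalone paths", {
  b <- parameter_bounds()
  expect_true(check_bounds(water_model_preset("eccw2024"), b))
  # TIP4P-FB's d_OM lies below the search box: warn but stay computable
  fb <- water_model_preset("tip4pfb")
  expect_warning(check_bounds(fb, b, action = "warn"), "d_OM")
  expect_error(check_bounds(fb, b, action = "error"), "d_OM")
  expect_error(parameter_bounds(lower = c(sigma = 0.4)), "sigma")
})

test_that("canonical frame geometry follows its definition", {
  p <- water_model_preset("eccw2024")
  g <- build_geometry(p)
  half <- p$theta / 2 * pi / 180
  expect_equal(g$xyz["H1", ], c(x = p$d_OH * sin(half), y = 0,
                                z = p$d_OH * cos(half)))
  expect_equal(g$xyz["H2", "x"], -p$d_OH * sin(half))
  expect_equal(g$xyz["M", ], c(x = 0, y = 0, z = p$d_OM))
  expect_equal(sum(g$charge), 0)
  # both hydrogens at d_OH from the origin, H-O-H angle = theta
  expect_equal(sqrt(sum(g$xyz["H1", ]^2)), p$d_OH)
  cosang <- sum(g$xyz["H1", ] * g$xyz["H2", ]) / p$d_OH^2
  expect_equal(acos(cosang) * 180 / pi, p$theta)
})

test_that("theta = 180 limiting geometry puts both hydrogens on the x-axis", {
  p <- water_model_params(0.315, 0.75, 0.55, 0.096, 0.0001, 180)
  g <- build_geometry(p)
  expect_equal(unname(g$xyz["H1", c("y", "z")]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(g$xyz["H2", c("y", "z")]), c(0, 0), tolerance = 1e-12)
})

test_that("TIP4P/2005 hydrogens sit at the published O-H distance", {
  g <- build_geometry(water_model_preset("tip4p2005"))
  expect_equal(sqrt(sum(g$xyz["H1", ]^2)), 0.09572, tolerance = 1e-10)
})

test_that("dipole handles degenerate charge configurations", {
  # no charges -> zero dipole
  p <- water_model_params(0.315, 0.75, 1e-30, 0.096, 0.015, 105)
  expect_equal(dipole_moment(build_geometry(p)), 0, tolerance = 1e-25)
  # d_OM at the hydrogen charge centroid -> centroids coincide, zero dipole
  half <- 105 / 2 * pi / 180
  p2 <- water_model_params(0.315, 0.75, 0.55, 0.096, 0.096 * cos(half), 105)
  expect_equal(dipole_moment(build_geometry(p2)), 0, tolerance = 1e-12)
})

test_that("dipole requires charge neutrality", {
  g <- build_geometry(water_model_preset("eccw2024"))
  g$charge["M"] <- g$charge["M"] * 0.9
  expect_error(dipole_moment(g), "neutral")
})

test_that("dipole magnitude is invariant under rigid motions", {
  set.seed(41)
  for (i in 1:20) {
    g <- build_geometry(random_params())
    mu0 <- dipole_moment(g)
    g2 <- transform_geometry(g, random_rotation(), rnorm(3))
    expect_equal(dipole_moment(g2), mu0, tolerance = 1e-10)
  }
})

test_that("Q_T closed form matches the full tensor route and ignores d_OM", {
  set.seed(42)
  for (i in 1:100) {
    p <- random_params()
    qt_tensor <- quadrupole_qt(build_geometry(p))
    qt_closed <- quadrupole_qt_closed_form(p)
    expect_equal(qt_tensor, qt_closed, tolerance = 1e-10)
  }
  # perturbing d_OM alone leaves Q_T unchanged
  p <- water_model_preset("eccw2024")
  qt0 <- quadrupole_qt(build_geometry(p))
  for (dom in c(0.0125, 0.0150, 0.0175)) {
    p2 <- water_model_params(p$sigma, p$epsilon, p$q_H, p$d_OH, dom, p$theta)
    expect_equal(quadrupole_qt(build_geometry(p2)), qt0, tolerance = 1e-12)
  }
})

test_that("dipole decreases strictly with d_OM at fixed other parameters", {
  p <- water_model_preset("tip4p2005")
  doms <- seq(0.012, 0.018, by = 0.001)
  mus <- vapply(doms, function(dom) {
    dipole_moment(build_geometry(
      water_model_params(p$sigma, p$epsilon, p$q_H, p$d_OH, dom, p$theta)))
  }, numeric(1))
  expect_true(all(diff(mus) < 0))
})

test_that("charge scaling follows 1/sqrt(eps_e)", {
  expect_equal(scale_charge(1.0, 1.78), 1 / sqrt(1.78))
  expect_equal(scale_charge(1.0, 1.78), 0.7496, tolerance = 1e-4)
  expect_equal(scale_charge(0, 3.2), 0)
  expect_equal(scale_charge(0.42, 1), 0.42)
  expect_error(scale_charge(1.0, 0.9), "eps_e")
})

test_that("normalization maps bounds to the unit cube and round-trips", {
  b <- parameter_bounds()
  lo <- do.call(water_model_params, as.list(b["lower", ]))
  expect_equal(unname(normalize_params(lo, b)), rep(0, 6))
  # seeding sigma is the midpoint of its range
  expect_equal(normalize_params(initial_params(), b)[["sigma"]], 0.5)
  set.seed(43)
  for (i in 1:100) {
    p <- random_params(b)
    p2 <- denormalize_params(normalize_params(p, b), b)
    expect_equal(params_as_vector(p2), params_as_vector(p), tolerance = 1e-12)
  }
  expect_error(normalize_params(water_model_preset("tip4pfb"), b), "d_OM")
  expect_error(denormalize_params(c(0.5, 0.5, 1.2, 0.5, 0.5, 0.5), b), "q_H")
})

test_that("parameter YAML files round-trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  p <- water_model_preset("eccw2024")
  write_params_yaml(p, path)
  expect_equal(params_as_vector(read_params_yaml(path)), params_as_vector(p),
               tolerance = 1e-12)
})
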