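test_that("default parameters carry the tabulated constants and satisfy invariants", {
  p <- default_parameters()
  expect_s3_class(p, "stenoclot_params")
  expect_equal(p$alpha, 3.33e-2)
  expect_equal(p$k_u, 1.66e1)
  expect_equal(p$Fg0, 9e3)
  expect_equal(p$tau1, 10)
  expect_equal(p$tau2, 20)
  expect_equal(p$mu1, 2e-12)
  expect_equal(p$u0, 100)
  expect_equal(p$Lx, 7.5)
  expect_equal(p$Ly, 1)
  expect_gt(p$alpha, p$chi1)
  expect_silent(validate_parameters(p))
})

test_that("parameter validation rejects broken sets", {
  expect_error(default_parameters(H = 1.2), "H must be <")
  expect_error(default_parameters(tau2 = 5), "tau2")
  expect_error(default_parameters(alpha = 5e-4), "alpha must exceed chi1")
  expect_error(default_parameters(nonsense = 1), "unknown parameter")
  expect_error(default_parameters(nu = -1), "positive")
})

test_that("dimensionless groups match their definitions", {
  p <- default_parameters(V0 = 6.5, H = 0.5, d = 0.5)
  g <- nondimensionalize(p)
  expect_equal(g$Re, 130)
  expect_equal(g$h, 0.5)
  expect_equal(g$d_tilde, 0.5)
  ## mu2 = 3.02e-5 cm/s maps to mu2_tilde ~ 9.5 (direct arithmetic)
  expect_equal(g$mu2_tilde,
               3.02e-5 * 100 * 16.6 / (1 * (3.33e-2 - 8.33e-4)^2 * 5),
               tolerance = 1e-12)
  expect_equal(g$mu2_tilde, 9.5, tolerance = 0.01)
  p0 <- default_parameters(H = 0)
  expect_equal(nondimensionalize(p0)$h, 0)
})

test_that("nondimensionalize and dimensional_permeability are exact inverses", {
  p <- default_parameters()
  for (x in c(1, 7, 9.5, 12)) {
    p2 <- p; p2$mu2 <- dimensional_permeability(x, p)
    expect_equal(nondimensionalize(p2)$mu2_tilde, x, tolerance = 1e-12)
  }
  expect_equal(dimensional_permeability(0, p), 0)
  expect_equal(dimensional_permeability(9.5, p), 3.02e-5, tolerance = 2e-3)
})

test_that("concentration conversion is the nM -> mol/cm^3 map", {
  expect_equal(concentration_to_molar_density(9000), 9e-9)
  expect_equal(concentration_to_molar_density(0), 0)
  expect_equal(concentration_to_molar_density(1), 1e-12)
  expect_error(concentration_to_molar_density(-1), ">= 0")
})

test_that("dimensionless groups are invariant under consistent cm -> m rescaling", {
  p <- default_parameters(V0 = 6.5, H = 0.5)
  q <- p
  L <- 1e-2                     # cm -> m
  for (nm in c("Lx", "Ly", "H", "d")) q[[nm]] <- q[[nm]] * L
  q$V0 <- q$V0 * L
  q$nu <- q$nu * L^2
  for (nm in c("D_u", "D_theta", "D_phi", "D_g", "D")) q[[nm]] <- q[[nm]] * L^2
  q$mu1 <- q$mu1 * L; q$mu2 <- q$mu2 * L
  ## shear thresholds and density do not enter the four groups
  g1 <- nondimensionalize(p); g2 <- nondimensionalize(q)
  expect_equal(g2$Re, g1$Re, tolerance = 1e-12)
  expect_equal(g2$mu2_tilde, g1$mu2_tilde, tolerance = 1e-12)
  expect_equal(g2$h, g1$h)
  expect_equal(g2$d_tilde, g1$d_tilde)
})

test_that("params_from_groups reproduces requested groups", {
  p <- params_from_groups(Re = 180, h = 0.6, d_tilde = 0.4, mu2_tilde = 12)
  g <- nondimensionalize(p)
  expect_equal(g$Re, 180)
  expect_equal(g$h, 0.6)
  expect_equal(g$d_tilde, 0.4)
  expect_equal(g$mu2_tilde, 12, tolerance = 1e-12)
})
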