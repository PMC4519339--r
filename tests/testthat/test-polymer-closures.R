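p <- default_parameters()
pc <- polymer_constants(p)

test_that("crossover length matches the closed form and its scaling laws", {
  l0 <- p$v0^(1 / 3)
  expect_equal(pc$l0, l0)
  expect_equal(pc$Nws, 1 / (p$n0^(2 / 3) * l0^2 * p$K), tolerance = 1e-14)
  expect_equal(pc$Nws, 1.036e4, tolerance = 1e-3)
  expect_equal(crossover_length(8 * p$n0, l0, p$K) * 4,
               crossover_length(p$n0, l0, p$K), tolerance = 1e-14)
  expect_equal(crossover_length(p$n0, l0, 2 * p$K) * 2,
               crossover_length(p$n0, l0, p$K), tolerance = 1e-14)
  expect_equal(pc$Ne, pc$Nws)
})

test_that("weight-average length is the clamped moment ratio", {
  expect_equal(weight_average_length(2, 8, pc$Nws), 4)
  expect_equal(weight_average_length(0, 0, pc$Nws), 1)
  expect_equal(weight_average_length(1, 10 * 100 * pc$Nws, pc$Nws),
               100 * pc$Nws)
  expect_equal(weight_average_length(5, 1, pc$Nws), 1)  # floor at monomer
})

test_that("polymer diffusivity has the friction and reptation limits", {
  expect_equal(polymer_diffusivity(1, p$D, pc$Ne), p$D, tolerance = 1e-4)
  expect_equal(polymer_diffusivity(pc$Ne, p$D, pc$Ne), p$D / (2 * pc$Ne),
               tolerance = 1e-14)
  nw <- 100 * pc$Ne
  expect_equal(polymer_diffusivity(nw, p$D, pc$Ne), p$D * pc$Ne / nw^2,
               tolerance = 0.02)
  ## algebraic identity Df * Nw * (1 + Nw/Ne) = D over random Nw
  set.seed(7)
  nws <- exp(stats::runif(50, 0, log(100 * pc$Nws)))
  expect_equal(polymer_diffusivity(nws, p$D, pc$Ne) * nws * (1 + nws / pc$Ne),
               rep(p$D, 50), tolerance = 1e-13)
})

test_that("transport coefficient interpolates between dilute and gel limits", {
  expect_equal(transport_coefficient(1, pc$Ne), 1, tolerance = 1e-3)
  expect_equal(transport_coefficient(pc$Ne, pc$Ne), 0.5)
  expect_equal(transport_coefficient(100 * pc$Ne, pc$Ne), 1 / 101)
  ## strict monotonicity of bp and Df, strict growth of alpha_p in Nw
  nw <- seq(1, 50 * pc$Ne, length.out = 100)
  expect_true(all(diff(transport_coefficient(nw, pc$Ne)) < 0))
  expect_true(all(diff(polymer_diffusivity(nw, p$D, pc$Ne)) < 0))
  ap <- filtration_resistance(5, transport_coefficient(nw, pc$Ne), pc$alpha0)
  expect_true(all(diff(ap) > 0))
})

test_that("filtration resistance matches the closed form and both routes agree", {
  expect_equal(filtration_resistance(9000, 0, pc$alpha0), 1.27e10,
               tolerance = 0.02)
  expect_equal(filtration_resistance(1, 1, pc$alpha0), 0)
  expect_equal(filtration_resistance(0, 0.3, pc$alpha0), 0)
  expect_equal(pc$alpha0, 1.57e26, tolerance = 0.01)
  ## (1 - bp)/xi^2 route equals alpha0 M1^2 (1 - bp)
  set.seed(11)
  m1 <- exp(stats::runif(20, log(1e-3), log(9e3)))
  bp <- stats::runif(20)
  r1 <- filtration_resistance(m1, bp, pc$alpha0)
  r2 <- (1 - bp) / network_mesh_size(m1, pc$l0, p$K)^2
  expect_equal(r1, r2, tolerance = 1e-13)
  ## xi is independent of chain length by construction (depends on M1 only)
  expect_equal(network_mesh_size(2, pc$l0, p$K),
               network_mesh_size(2, pc$l0, p$K))
})

test_that("the mature-gel cap projects the second moment", {
  expect_equal(apply_gel_cap(1, 2e6, 1e4), 1e6)
  expect_equal(apply_gel_cap(1, 5e5, 1e4), 5e5)
  expect_equal(apply_gel_cap(0, 123, 1e4), 0)
})

test_that("closure_fields bundles consistent per-cell values", {
  M1 <- c(0, 1, 10); M2 <- c(0, 1e6 * 2, 20)
  cf <- closure_fields(M1, M2, p)
  expect_equal(cf$Nw[1], 1)
  expect_equal(cf$Nw[2], 100 * pc$Nws)        # capped
  expect_equal(cf$Nw[3], 2)
  expect_equal(cf$gel_mask, c(0L, 1L, 0L))
  expect_true(all(cf$Df <= p$D), all(cf$bp > 0), all(cf$bp <= 1))
  expect_true(all(cf$alpha_p >= 0))
})
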