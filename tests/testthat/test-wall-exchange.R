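p <- default_parameters()

test_that("permeability law reproduces its three branches and continuity", {
  expect_equal(permeability(5, p), p$mu1)
  expect_equal(permeability(15, p), p$mu1 + 0.5 * (p$mu2 - p$mu1))
  expect_equal(permeability(25, p), p$mu2)
  expect_equal(permeability(p$tau1, p), p$mu1)            # branch agreement
  expect_equal(permeability(p$tau2, p), p$mu2)
  ## global continuity and monotonicity over a dense grid
  taus <- seq(0, 3 * p$tau2, length.out = 4001)
  mus <- permeability(taus, p)
  expect_true(all(diff(mus) >= 0))
  slope <- (p$mu2 - p$mu1) / (p$tau2 - p$tau1)
  expect_lte(max(abs(diff(mus))), slope * diff(taus)[1] * (1 + 1e-9))
  expect_error(permeability(-1, p), ">= 0")
})

test_that("sub-wall activator window covers [-2d, 2d] on the lower wall only", {
  expect_equal(activator_source(0, p$d, p$u0, "lower"), 100)
  expect_equal(activator_source(3 * p$d, p$d, p$u0, "lower"), 0)
  expect_equal(activator_source(2 * p$d, p$d, p$u0, "lower"), 100)
  expect_equal(activator_source(c(-5, 0, 5), p$d, p$u0, "upper"), c(0, 0, 0))
})

test_that("Robin influx closure has the right equilibria and limits", {
  r <- robin_flux(100, 100, 3e-5, p$D_u, dn = 0.01)
  expect_equal(r$flux, 0)
  ## nominal flux without the diffusive closure
  r2 <- robin_flux(0, 100, 3e-5, p$D_u, dn = Inf)
  expect_equal(r2$flux, 3e-3)
  ## impermeable wall -> homogeneous Neumann
  r3 <- robin_flux(42, 100, 0, p$D_u, dn = 0.01)
  expect_equal(r3$flux, 0)
  ## closure: realized flux is the harmonic composition of mu and D_u/dn,
  ## and the wall-face value satisfies the one-sided Robin balance
  mu <- 3e-5; dn <- 0.005
  r4 <- robin_flux(10, 100, mu, p$D_u, dn)
  k <- p$D_u / dn
  expect_equal(r4$flux, mu * k / (mu + k) * 90, tolerance = 1e-12)
  expect_equal(p$D_u * (r4$u_wall - 10) / dn, mu * (100 - r4$u_wall),
               tolerance = 1e-10)
})

test_that("healthy-geometry walls stay closed for all admissible Re", {
  ## flat-channel Poiseuille shear reaches tau1 only at
  ## Re = tau1 Ly^2/(4 rho nu^2) = 1000, beyond the stability ceiling
  Re_open <- p$tau1 * p$Ly^2 / (4 * p$rho * p$nu^2)
  expect_equal(Re_open, 1000)
  tau_at <- function(Re) 4 * p$rho * p$nu * (Re * p$nu / p$Ly) / p$Ly
  expect_lt(tau_at(500), p$tau1)
  expect_equal(permeability(tau_at(500), p), p$mu1)
})

test_that("per-face exchange fields gate on shear and the window", {
  pp <- params_from_groups(130, 0.5, 0.5, 9.5)
  mesh <- build_mesh(pp, 16)
  wx0 <- wall_exchange_fields(mesh, NULL, pp)           # quiescent wall
  wall <- mesh$b_patch %in% 3:4
  expect_true(all(wx0$mu[wall] == pp$mu1))
  expect_true(all(wx0$mu[!wall] == 0))
  low <- mesh$b_patch == 4
  expect_true(all((wx0$u0[low] > 0) == (abs(mesh$b_fcx[low]) <= 2 * pp$d)))
  expect_true(all(wx0$u0[!low] == 0))
  ## sealing the upper wall zeroes its exchange
  wx1 <- wall_exchange_fields(mesh, NULL, pp, upper_exchange = FALSE)
  expect_true(all(wx1$mu[mesh$b_patch == 3] == 0))
})
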