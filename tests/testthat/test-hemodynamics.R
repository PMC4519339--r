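test_that("Poiseuille flow, wall shear and dissipation match closed forms", {
  fx <- fixture_poiseuille(resolution = 32)
  expect_lt(fx$profile_err, 0.01)
  expect_lt(fx$shear_err, 0.01)
  expect_equal(fx$shear_target, 1.3)          # Re = 130: 4 rho nu V0 / Ly
  expect_lt(fx$dissipation_err, 0.05)
  ## divergence contract and global mass balance
  expect_lt(fx$flow$div_max, fx$flow$div_tol_abs)
  mb <- mass_balance(fx$flow, fx$mesh)
  expect_lt(mb$rel_mismatch, 1e-8)
})

test_that("a strong uniform Darcy sink flattens the profile (Brinkman limit)", {
  fb <- fixture_brinkman(resolution = 24, alpha_p = 1e6)
  expect_lt(abs(fb$ratio - 1), 0.05)
})

test_that("uniform Darcy resistance monotonically throttles the flow", {
  p <- default_parameters(V0 = 2, Lx = 1); p$H <- 0
  mesh <- build_mesh(p, 12)
  ## fixed inlet flow: throughput is identical, but the pressure drop to
  ## sustain it must grow strictly with the sink
  drops <- vapply(c(0, 10, 100), function(a) {
    fl <- solve_stationary_flow(mesh, p, alpha_p = a)
    mean(fl$p[mesh$cx < -0.2]) - mean(fl$p[mesh$cx > 0.5])
  }, 0)
  expect_true(all(diff(drops) > 0))
})

test_that("transient stepping honours the stability guard and the fixed point", {
  p <- default_parameters(V0 = 2, Lx = 1); p$H <- 0
  mesh <- build_mesh(p, 12)
  fl <- solve_stationary_flow(mesh, p)
  expect_error(step_flow(fl, 1, 0, mesh, p), "stability bound")
  ## stepping the stationary state leaves it on the same attractor; the
  ## O(dt) Rhie-Chow flux term shifts the discrete fixed point slightly
  ## when the step size differs from the steady solver's local steps
  st <- step_flow(fl, 2e-4, 0, mesh, p)
  expect_lt(max(abs(st$u - fl$u)) / p$V0, 2e-3)
  st2 <- step_flow(st, 2e-4, 0, mesh, p)
  expect_lt(max(abs(st2$u - st$u)) / p$V0, max(abs(st$u - fl$u)) / p$V0)
  expect_lt(st$div_max, st$div_tol_abs)
})

test_that("impulsively started flow relaxes to the steady solver's answer", {
  p <- default_parameters(V0 = 2, Lx = 1, H = 0.3, d = 0.3)
  mesh <- build_mesh(p, 12)
  steady <- solve_stationary_flow(mesh, p)
  st <- uniform_flow_state(mesh, 0)
  st$b_flux <- steady$b_flux * 0
  dt <- 2e-4
  for (k in seq_len(3000)) st <- step_flow(st, dt, 0, mesh, p)
  l2 <- sqrt(sum((st$u - steady$u)^2 + (st$v - steady$v)^2) /
             sum(steady$u^2 + steady$v^2))
  expect_lt(l2, 0.025)   # same physics within the O(dt) projection offset
})

test_that("stenosed flow amplifies wall shear above the flat-channel value", {
  p <- params_from_groups(130, 0.5, 0.5, 9.5)
  p$Lx <- 5
  mesh <- build_mesh(p, 16)
  fl <- solve_stationary_flow(mesh, p)
  ws <- wall_shear(fl, mesh, p)
  flat <- 4 * p$rho * p$nu * p$V0 / p$Ly
  expect_gt(max(abs(ws$tau)), 3 * flat)
  ## peak sits near the apex
  expect_lt(abs(ws$x[which.max(abs(ws$tau))]), 2 * p$d)
  ## Re ceiling guard
  expect_error(solve_stationary_flow(mesh, params_from_groups(600, 0.3), Re_max = 500),
               "ceiling")
})
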