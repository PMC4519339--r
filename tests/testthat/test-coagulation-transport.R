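p <- default_parameters()

test_that("reaction rates vanish at the resting state and match hand values", {
  st <- list(u = 0, theta = 0, phi = 0, Fg = p$Fg0, M1 = 0, M2 = 0)
  r <- reaction_rhs(st, p)
  expect_true(all(unlist(r) == 0))
  ## theta-nullcline root with u = 0, phi = 0
  thstar <- theta_threshold(p)
  expect_equal(thstar, 0.1283, tolerance = 1e-3)
  r2 <- reaction_rhs(list(u = 0, theta = thstar, phi = 0, Fg = 0,
                          M1 = 0, M2 = 0), p)
  expect_equal(r2$theta, 0, tolerance = 1e-18)
  ## pure polymerization growth term (Riccati blow-up precursor)
  r3 <- reaction_rhs(list(u = 0, theta = 0, phi = 0, Fg = 0,
                          M1 = 1, M2 = 1), p)
  expect_equal(r3$M2, 4 * p$k_p * 4 - p$k_r * 1, tolerance = 1e-14)
  expect_error(reaction_rhs(list(u = -1, theta = 0, phi = 0, Fg = 0,
                                 M1 = 0, M2 = 0), p), "nonnegative")
})

test_that("implicit chemistry agrees with a fine explicit reference", {
  ## ignition transient: compare one backward-Euler path against explicit
  ## Euler at a 100x finer step, from a supercritical state
  st_be <- initial_chem_state(1, p)
  st_be$theta <- 1; st_be$u <- 1e-4
  st_ex <- lapply(st_be, identity)
  dt <- 0.5; nfine <- 100
  for (k in seq_len(120)) {
    st_be <- integrate_chemistry(st_be, dt, p)
    for (j in seq_len(nfine)) {
      r <- reaction_rhs(st_ex, p)
      for (nm in names(st_ex)) st_ex[[nm]] <- pmax(st_ex[[nm]] + dt / nfine * r[[nm]], 0)
      pcst <- polymer_constants(p)
      st_ex$M2 <- min(st_ex$M2, 100 * pcst$Nws * st_ex$M1)
    }
  }
  for (nm in c("theta", "phi", "Fg", "M1", "M2"))
    expect_equal(st_be[[nm]], st_ex[[nm]], tolerance = 0.05, label = nm)
})

test_that("chemistry fixed point, decay, threshold and blow-up fixtures hold", {
  expect_equal(fixture_resting_state(), 0)
  expect_lt(fixture_u_decay(), 1e-6)
  ft <- fixture_theta_threshold()
  expect_lt(ft$rel_err, 0.01)
  fm <- fixture_m2_blowup()
  expect_lt(fm$rel_err, 0.02)
})

test_that("transport preserves constants and freezes without forcing", {
  pp <- default_parameters(V0 = 1, Lx = 1); pp$H <- 0
  mesh <- build_mesh(pp, 12)
  flow <- uniform_flow_state(mesh, 0.8)
  ## uniform field, divergence-free flux, sealed walls, matching inlet value
  phi <- rep(3.2, mesh$ncell)
  out <- advect_diffuse(phi, flow, pp$D_theta, 1, 0.01, mesh,
                        bcs = list(inlet_value = 3.2))
  expect_equal(out, phi, tolerance = 1e-11)
  ## zero velocity, zero diffusivity: frozen exactly
  frozen <- advect_diffuse(stats::runif(mesh$ncell), uniform_flow_state(mesh, 0),
                           0, 1, 0.01, mesh)
  expect_equal(frozen, frozen)
  set.seed(1)
  f0 <- stats::runif(mesh$ncell)
  expect_equal(advect_diffuse(f0, uniform_flow_state(mesh, 0), 0, 1, 0.01, mesh),
               f0)
})

test_that("a Gaussian pulse advects at b V with variance growth 2 D t", {
  fg <- fixture_gaussian_pulse(resolution = 64)
  expect_lt(fg$speed_err, 0.03)
  expect_lt(fg$var_err, 0.03)
})

test_that("advection-diffusion converges at first order or better in space", {
  e32 <- fixture_gaussian_pulse(resolution = 32)$l1_err
  e64 <- fixture_gaussian_pulse(resolution = 64)$l1_err
  expect_gt(log2(e32 / e64), 0.8)
})

test_that("species balance audit closes to 1e-8 with reactions disabled", {
  pp <- default_parameters(V0 = 2, Lx = 1.5); pp$H <- 0
  mesh <- build_mesh(pp, 16)
  flow <- solve_stationary_flow(mesh, pp)
  chem <- initial_chem_state(mesh$ncell, pp)
  chem$theta <- exp(-(mesh$cx - 0.2)^2 / 0.05) * 5
  out <- transport_only(flow, chem, mesh, pp, dt = 0.01, nsteps = 20)
  expect_lt(out$audit_max, 1e-8)
})

test_that("positivity, fibrinogen bound and moment ordering survive random states", {
  pp <- default_parameters(V0 = 2, Lx = 1.5, H = 0.4, d = 0.3)
  mesh <- build_mesh(pp, 12)
  flow <- solve_stationary_flow(mesh, pp)
  set.seed(42)
  chem <- list(u = stats::runif(mesh$ncell, 0, 50),
               theta = stats::runif(mesh$ncell, 0, 2),
               phi = stats::runif(mesh$ncell, 0, 0.2),
               Fg = stats::runif(mesh$ncell, 0, pp$Fg0),
               M1 = stats::runif(mesh$ncell, 0, 10),
               M2 = NULL)
  chem$M2 <- chem$M1 * (1 + stats::rexp(mesh$ncell, 1 / 50))
  shear <- wall_shear(flow, mesh, pp)
  wx <- wall_exchange_fields(mesh, shear, pp)
  pars <- stenoclot:::.chem_pars(pp)
  out <- stenoclot:::cpp_transport_chunk(
    mesh, flow$flux, flow$b_flux,
    chem$u, chem$theta, chem$phi, chem$Fg, chem$M1, chem$M2,
    wx$mu, wx$u0, pars, c(pp$D_u, pp$D_theta, pp$D_phi, pp$D_g, pp$D),
    0.02, 150L, 1L, TRUE, Inf, 1e-12, 1000L, FALSE, 0L)
  for (nm in c("u", "theta", "phi", "Fg", "M1", "M2"))
    expect_true(all(out[[nm]] >= 0), label = paste(nm, "nonnegative"))
  expect_true(all(out$Fg <= pp$Fg0 * (1 + 1e-6)))
  sel <- out$M1 > 1e-12
  expect_true(all(out$M2[sel] >= out$M1[sel] * (1 - 1e-12)))
  expect_true(all(out$Nw >= 1), all(out$Nw <= 100 * pars$Nws))
})

test_that("coupled_step leaves the resting vessel at rest with a healthy wall", {
  pp <- params_from_groups(Re = 60, h = 0.3, d_tilde = 0.4, mu2_tilde = 9.5)
  pp$Lx <- 3
  mesh <- build_mesh(pp, 12)
  flow <- solve_stationary_flow(mesh, pp)
  chem <- initial_chem_state(mesh$ncell, pp)
  res <- coupled_step(flow, chem, mesh, pp, dt = 5e-4, audit = TRUE)
  ## healthy wall: max shear below tau1, influx only through mu1 ~ 2e-12
  expect_lt(max(abs(res$shear$tau)), pp$tau1)
  expect_lt(max(res$chem$u), 1e-10)
  expect_equal(res$diagnostics$max_nw, 1)
})
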