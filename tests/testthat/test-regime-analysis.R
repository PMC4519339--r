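test_that("scaling fit recovers the cube law and discriminates against others", {
  xc <- 7; C1 <- 25
  ctrl <- xc + 2^seq(-3, 2, by = 0.5)
  exact <- list(control = ctrl, T_star = (C1 / (ctrl - xc))^(1 / 3))
  fit <- fit_scaling(exact, xc)
  expect_equal(fit$exponent, -1 / 3, tolerance = 1e-10)
  expect_lt(fit$diagnostic, 1e-10)
  expect_equal(fit$constant, C1, tolerance = 1e-10)
  ## 5% multiplicative noise, n = 12: exponent within +-0.05 (Monte Carlo)
  set.seed(99)
  errs <- replicate(60, {
    ctrl <- xc + 2^seq(-3, 2.5, length.out = 12)
    T <- (C1 / (ctrl - xc))^(1 / 3) * exp(stats::rnorm(12, 0, 0.05))
    fit_scaling(list(control = ctrl, T_star = T), xc)$exponent
  })
  expect_lt(max(abs(errs + 1 / 3)), 0.05)
  ## points from a square law: cube-law constancy diagnostic flags it
  Tsq <- (C1 / (ctrl - xc))^(1 / 2)
  fit2 <- fit_scaling(list(control = ctrl, T_star = Tsq), xc)
  expect_gt(fit2$diagnostic, 0.3)
  expect_error(fit_scaling(list(control = xc + c(1, 2, 3), T_star = c(1, 1, 1)), xc),
               "at least 4")
  expect_error(fit_scaling(list(control = xc + rep(1, 6) + 1e-9 * (1:6),
                                T_star = rep(2, 6)), xc), "degenerate")
})

test_that("flat-channel flow has empty topology; stenosed flow recirculates", {
  p <- default_parameters(V0 = 6.5, Lx = 2); p$H <- 0
  mesh <- build_mesh(p, 16)
  fl <- solve_stationary_flow(mesh, p)
  topo <- flow_topology(fl, mesh, p)
  expect_false(topo$has_recirculation)
  expect_equal(topo$recirc_area, 0)
  p2 <- params_from_groups(130, 0.5, 0.5, 9.5); p2$Lx <- 5
  mesh2 <- build_mesh(p2, 16)
  fl2 <- solve_stationary_flow(mesh2, p2)
  topo2 <- flow_topology(fl2, mesh2, p2)
  expect_true(topo2$has_recirculation)
  expect_gt(topo2$reattachment_x, 0)
  expect_gt(topo2$recirc_area, 0)
  expect_s3_class(topo2$separatrix, "data.frame")
  ## separatrix lives behind the apex, inside the channel
  expect_true(all(topo2$separatrix$y >= 0 & topo2$separatrix$y <= p2$Ly))
})

test_that("recirculation grows with Reynolds number at fixed geometry", {
  areas <- vapply(c(80, 130, 180), function(Re) {
    p <- params_from_groups(Re, 0.5, 0.5, 9.5); p$Lx <- 5
    mesh <- build_mesh(p, 12)
    fl <- solve_stationary_flow(mesh, p)
    flow_topology(fl, mesh, p)$recirc_area
  }, 0)
  expect_true(all(diff(areas) > 0))
})

test_that("an impermeable wall yields regime I quickly via the steady criterion", {
  ## mu2 at the intact-wall value: no influx pathway beyond mu1 ~ 2e-12
  p <- params_from_groups(Re = 130, h = 0.4, d_tilde = 0.4, mu2_tilde = 9.5)
  p$mu2 <- p$mu1
  p$Lx <- 3
  cfg <- simulation_config(p, resolution = 12, dt = 0.05, t_max = 400,
                           chunk_s = 5)
  sim <- classify_regime(cfg)
  expect_equal(sim$regime, "I")
  expect_equal(sim$stop_reason, "steady")
  expect_false(sim$censored)
  expect_lt(max(sim$max_nw_series), 1.01)
  expect_true(is.na(sim$T_star_s))
})

test_that("no flow means no shear gating and regime I", {
  p <- params_from_groups(Re = 1e-3, h = 0.4, d_tilde = 0.4, mu2_tilde = 9.5)
  p$Lx <- 2
  cfg <- simulation_config(p, resolution = 12, dt = 0.1, t_max = 300,
                           chunk_s = 10)
  sim <- classify_regime(cfg)
  expect_equal(sim$regime, "I")
  expect_lt(max(abs(sim$shear$tau)), p$tau1)
  ## wall stays at the intact permeability everywhere
  wx <- wall_exchange_fields(sim$mesh, sim$shear, p)
  wall <- sim$mesh$b_patch %in% 3:4
  expect_true(all(wx$mu[wall] == p$mu1))
})

test_that("sweep grids label regimes, refine boundaries and report connectivity", {
  ## synthetic fast sweep on an impermeable system: all regime I
  sw <- sweep_regimes(list(Re = c(50, 100), mu2_tilde = c(1e-6, 2e-6)),
                      fixed = list(h = 0.3, d_tilde = 0.4), budget = 4,
                      config_args = list(resolution = 10, dt = 0.1,
                                         t_max = 60, chunk_s = 10))
  expect_true(all(sw$grid == "I"))
  expect_equal(sw$n_components, 0)
  expect_equal(length(sw$boundaries[[1]]$crossings$value), 0)
  expect_equal(sw$runs, 4)
})

test_that("connected-component counting follows 4-neighbour adjacency", {
  m <- matrix(c(TRUE, FALSE, TRUE,
                FALSE, FALSE, TRUE), 2, 3, byrow = TRUE)
  expect_equal(stenoclot:::.count_components(m), 2)
  expect_equal(stenoclot:::.count_components(matrix(FALSE, 2, 2)), 0)
  expect_equal(stenoclot:::.count_components(matrix(TRUE, 3, 3)), 1)
})
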