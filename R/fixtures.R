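## Analytic verification fixtures: each carries a closed-form reference
## computable without running the full model, a tolerance, and a runner
## that measures the same quantity with the package's solvers.

#' Poiseuille channel fixture
#'
#' Flat channel (`H = 0`) at `Re = 130`: the parabolic inlet profile is an
#' exact steady solution, with wall shear `4 rho nu V0 / Ly`
#' (= 1.3 dyn/cm^2). Returns the relative L-infinity error of the computed
#' velocity profile and of the wall shear.
#'
#' @param resolution cells per cm (default 32).
#' @param Lx channel length used for the fixture, cm.
#' @return list with `profile_err`, `shear_err`, `shear_target`,
#'   `dissipation_err`, the flow state and mesh.
#' @export
fixture_poiseuille <- function(resolution = 32, Lx = 2) {
  p <- default_parameters(H = 1e-12, V0 = 6.5, Lx = Lx)
  p$H <- 0
  mesh <- build_mesh(p, resolution)
  flow <- solve_stationary_flow(mesh, p)
  uex <- 4 * p$V0 * mesh$cy * (p$Ly - mesh$cy) / p$Ly^2
  profile_err <- max(abs(flow$u - uex), abs(flow$v)) / p$V0
  ws <- wall_shear(flow, mesh, p)
  tau_target <- 4 * p$rho * p$nu * p$V0 / p$Ly
  ## measure away from the inlet/outlet adjustment cells
  mid <- ws$x > -Lx / 6 & ws$x < Lx / 3
  shear_err <- max(abs(ws$tau[mid] - tau_target)) / tau_target
  ## kinetic-energy dissipation per unit length vs analytic 16 nu V0^2/(3 Ly),
  ## with du/dy of the computed field by central differences along columns
  um <- field_matrix(mesh, flow$u)
  ym <- field_matrix(mesh, mesh$cy)
  am <- field_matrix(mesh, mesh$area)
  ny <- mesh$ny
  dudy <- um
  dudy[, 2:(ny - 1)] <- (um[, 3:ny] - um[, 1:(ny - 2)]) /
                        (ym[, 3:ny] - ym[, 1:(ny - 2)])
  dudy[, 1] <- um[, 1] / ym[, 1]                     # one-sided at the walls
  dudy[, ny] <- -um[, ny] / (p$Ly - ym[, ny])
  diss_target <- 16 * p$nu * p$V0^2 / (3 * p$Ly)
  diss_num <- sum(p$nu * dudy^2 * am) / Lx
  dissipation_err <- abs(diss_num - diss_target) / diss_target
  list(profile_err = profile_err, shear_err = shear_err,
       shear_target = tau_target, dissipation_err = dissipation_err,
       flow = flow, mesh = mesh, params = p)
}

#' Brinkman (uniform Darcy sink) flattening fixture
#'
#' Flat channel with a strong uniform filtration resistance
#' (`alpha_p = 1e6` cm^-2): the exact Brinkman profile is plug-like with a
#' boundary layer of thickness `1/sqrt(alpha_p)`, so the
#' centerline-to-mean velocity ratio approaches 1 (it is 1.5 for
#' Poiseuille).
#'
#' @param resolution cells per cm.
#' @param alpha_p uniform sink, cm^-2.
#' @return list with `ratio` (centerline/mean at mid-channel), `flow`,
#'   `mesh`.
#' @export
fixture_brinkman <- function(resolution = 24, alpha_p = 1e6) {
  p <- default_parameters(V0 = 1, Lx = 1.5)
  p$H <- 0
  mesh <- build_mesh(p, resolution)
  flow <- solve_stationary_flow(mesh, p, alpha_p = alpha_p)
  xmid <- mesh$cx > 0 & mesh$cx < 0.25
  col <- which(xmid)
  um <- flow$u[col]; ar <- mesh$area[col]; yy <- mesh$cy[col]
  mean_u <- sum(um * ar) / sum(ar)
  center <- um[which.min(abs(yy - p$Ly / 2))]
  list(ratio = center / mean_u, flow = flow, mesh = mesh)
}

#' Advection--diffusion Gaussian pulse fixture
#'
#' Uniform velocity override in a flat channel; a Gaussian pulse must
#' advect at `b V` and its variance grow as `2 D t`. Also returns the L1
#' error against the exact spreading Gaussian for order-of-accuracy
#' studies.
#'
#' @param resolution cells per cm.
#' @param V uniform velocity, cm/s.
#' @param b convective multiplier.
#' @param D diffusivity, cm^2/s.
#' @param t_end integration time, s.
#' @return list with `speed_err`, `var_err` (relative), `l1_err`, and the
#'   measured/target values.
#' @export
fixture_gaussian_pulse <- function(resolution = 64, V = 0.5, b = 0.5,
                                   D = 0.1, t_end = 0.5) {
  p <- default_parameters(Lx = 3.6, Ly = 0.25, V0 = V)
  p$H <- 0
  mesh <- build_mesh(p, resolution, bl_factor = 1)   # uniform cells
  flow <- uniform_flow_state(mesh, V)
  sigma0 <- 0.15; x0 <- 0.2
  phi0 <- exp(-(mesh$cx - x0)^2 / (2 * sigma0^2))
  dx <- p$Lx / mesh$nx
  dt <- 0.4 * dx^2 / (4 * D)
  nsteps <- ceiling(t_end / dt); dt <- t_end / nsteps
  phi <- advect_diffuse(phi0, flow, D, b, dt, mesh,
                        bcs = list(inlet_value = 0), nsteps = nsteps)
  moments <- function(f) {
    w <- f * mesh$area
    m <- sum(w * mesh$cx) / sum(w)
    v <- sum(w * (mesh$cx - m)^2) / sum(w)
    c(mean = m, var = v)
  }
  m0 <- moments(phi0); m1 <- moments(phi)
  speed <- (m1["mean"] - m0["mean"]) / t_end
  dvar <- m1["var"] - m0["var"]
  sig2 <- sigma0^2 + 2 * D * t_end
  exact <- sigma0 / sqrt(sig2) *
    exp(-(mesh$cx - x0 - b * V * t_end)^2 / (2 * sig2))
  l1 <- sum(abs(phi - exact) * mesh$area) / sum(exact * mesh$area)
  list(speed = unname(speed), speed_target = b * V,
       speed_err = unname(abs(speed - b * V) / (b * V)),
       dvar = unname(dvar), dvar_target = 2 * D * t_end,
       var_err = unname(abs(dvar - 2 * D * t_end) / (2 * D * t_end)),
       l1_err = l1, dt = dt, nsteps = nsteps)
}

#' Chemistry resting-state fixed point fixture
#'
#' The quiescent state (all species zero, fibrinogen at `Fg0`) must be an
#' exact fixed point of the implicit chemistry.
#'
#' @param dt step size, s.
#' @return maximal absolute drift over one step, nM.
#' @export
fixture_resting_state <- function(dt = 100) {
  p <- default_parameters()
  st <- initial_chem_state(4, p)
  out <- integrate_chemistry(st, dt, p)
  max(abs(out$u), abs(out$theta), abs(out$phi), abs(out$Fg - p$Fg0),
      abs(out$M1), abs(out$M2))
}

#' Primary-activator exponential-decay fixture
#'
#' `u(t) = u(0) exp(-k_d t)` over `t = 1e5` s; sub-stepped backward Euler
#' must match within 1e-6 relative.
#'
#' @param nsub number of sub-steps (backward Euler is first order in time;
#'   the default resolves the decay to ~7e-7 relative).
#' @return relative error of the decay factor.
#' @export
fixture_u_decay <- function(nsub = 20000) {
  p <- default_parameters()
  t_end <- 1e5
  ## pure-decay subsystem: the activator feed is switched off so nothing
  ## downstream ignites over this very long horizon
  pars <- .chem_pars(p)
  pars$k_u <- 0
  out <- cpp_integrate_chemistry(1, 0, 0, p$Fg0, 0, 0, t_end, pars, as.integer(nsub))
  target <- exp(-p$k_d * t_end)
  abs(out$u - target) / target
}

#' Activator excitation-threshold fixture
#'
#' Bisects the initial `theta` between growing and decaying trajectories of
#' the local kinetics (no primary activator) and compares the separatrix
#' against the closed-form nullcline root
#' `theta* = chi1 theta0 / (alpha - chi1)`.
#'
#' @param dt integration step, s.
#' @param t_max trajectory horizon, s.
#' @param rel_tol bisection tolerance.
#' @return list with `theta_star` (measured), `target`, `rel_err`.
#' @export
fixture_theta_threshold <- function(dt = 10, t_max = 4000, rel_tol = 1e-4) {
  p <- default_parameters()
  target <- theta_threshold(p)
  grows <- function(th0) {
    st <- initial_chem_state(1, p); st$theta <- th0
    for (k in seq_len(ceiling(t_max / dt))) {
      st <- integrate_chemistry(st, dt, p)
      if (st$theta > 10 * target) return(TRUE)
      if (st$theta < 0.05 * target) return(FALSE)
    }
    st$theta > th0
  }
  lo <- target / 10; hi <- target * 10
  stopifnot(!grows(lo), grows(hi))
  while ((hi - lo) / target > rel_tol) {
    mid <- sqrt(lo * hi)
    if (grows(mid)) hi <- mid else lo <- mid
  }
  est <- sqrt(lo * hi)
  list(theta_star = est, target = target,
       rel_err = abs(est - target) / target)
}

#' Second-moment blow-up (Riccati) fixture
#'
#' Reduced subsystem: polymerization growth only
#' (`dM2/dt = 4 k_p (M2 + M1)^2`, `M1` frozen at 1 nM), whose solution
#' blows up at `t* = 1 / (4 k_p (M2(0) + M1)) = 500 s`. The implicit
#' integrator (with adaptive sub-division near the singularity) must cross
#' a large threshold within 2% of `t*`.
#'
#' @param dt step size, s.
#' @param M_big crossing threshold, nM.
#' @return list with `t_cross`, `target`, `rel_err`.
#' @export
fixture_m2_blowup <- function(dt = 0.5, M_big = 1e4) {
  p <- default_parameters()
  pars <- .chem_pars(p)
  pars$k_g <- 0; pars$k_b <- 0; pars$k_r <- 0; pars$k_d <- 0; pars$k_u <- 0
  pars$Nws <- 1e7; pars$Ne <- 1e7       # push the gel cap out of the way
  M1 <- 1; M2 <- 1
  t <- 0; target <- 1 / (4 * p$k_p * (M2 + M1))
  repeat {
    prev <- M2
    out <- cpp_integrate_chemistry(0, 0, 0, p$Fg0, M1, M2, dt, pars, 1L)
    M2 <- out$M2; t <- t + dt
    if (M2 >= M_big) {
      ## 1/(M2+M1) decreases linearly at rate 4 k_p (exact for Riccati)
      t_cross <- t - dt + (1 / (prev + M1) - 1 / (M_big + M1)) / (4 * p$k_p)
      break
    }
    if (t > 3 * target) stop("blow-up not reached")
  }
  list(t_cross = t_cross, target = target,
       rel_err = abs(t_cross - target) / target)
}

#' Run the whole verification-fixture suite
#'
#' Executes the analytic fixtures (flow, transport, chemistry, closures,
#' permeability law, scaling-fit recovery) and reports measured errors
#' against their tolerances.
#'
#' @param fast logical: skip the two steady-flow fixtures (several seconds
#'   each) and check the cheap ones only.
#' @return data.frame with `name`, `value`, `tol`, `pass`; attribute
#'   `all_pass`.
#' @export
verify_fixtures <- function(fast = FALSE) {
  rows <- list()
  add <- function(name, value, tol)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, value = value,
                                             tol = tol, pass = value <= tol)
  if (!fast) {
    fp <- fixture_poiseuille()
    add("poiseuille_profile_rel_err", fp$profile_err, 0.01)
    add("poiseuille_wall_shear_rel_err", fp$shear_err, 0.01)
    fb <- fixture_brinkman()
    add("brinkman_flattening_ratio_err", abs(fb$ratio - 1), 0.05)
  }
  fg <- fixture_gaussian_pulse()
  add("pulse_center_speed_rel_err", fg$speed_err, 0.03)
  add("pulse_variance_growth_rel_err", fg$var_err, 0.03)
  add("chemistry_resting_drift_nM", fixture_resting_state(), 1e-12)
  add("u_decay_rel_err", fixture_u_decay(), 1e-6)
  ft <- fixture_theta_threshold()
  add("theta_threshold_rel_err", ft$rel_err, 0.01)
  fm <- fixture_m2_blowup()
  add("m2_blowup_time_rel_err", fm$rel_err, 0.02)
  ## closure algebra identities
  p <- default_parameters()
  pc <- polymer_constants(p)
  nw <- exp(seq(log(1), log(pc$Nw_cap), length.out = 37))
  idn <- max(abs(polymer_diffusivity(nw, p$D, pc$Ne) *
                 nw * (1 + nw / pc$Ne) / p$D - 1))
  add("closure_identity_Df_rel_err", idn, 1e-12)
  m1 <- c(1e-3, 1, 9000)
  bp <- transport_coefficient(c(2, 50, 2e4), pc$Ne)
  route1 <- filtration_resistance(m1, bp, pc$alpha0)
  route2 <- (1 - bp) / network_mesh_size(m1, pc$l0, p$K)^2
  add("closure_identity_alpha_p_rel_err",
      max(abs(route1 - route2) / pmax(route1, 1e-300)), 1e-12)
  ## permeability law continuity + monotonicity
  taus <- seq(0, 2.5 * p$tau2, length.out = 2001)
  mus <- permeability(taus, p)
  add("permeability_monotone_violation", max(0, -min(diff(mus))), 0)
  jump <- max(abs(diff(mus))) / (p$mu2 - p$mu1)
  add("permeability_max_jump_fraction", jump, 2.5 * p$tau2 / 2000 / (p$tau2 - p$tau1) + 1e-9)
  ## scaling-law fit recovery on constructed points
  xc <- 5; C <- 40
  ctrl <- xc + c(0.2, 0.4, 0.8, 1.6, 3.2)
  fit <- fit_scaling(list(control = ctrl, T_star = (C / (ctrl - xc))^(1 / 3)), xc)
  add("scaling_fit_exponent_err", abs(fit$exponent + 1 / 3), 1e-10)
  add("scaling_fit_constancy", fit$diagnostic, 1e-10)
  out <- do.call(rbind, rows)
  attr(out, "all_pass") <- all(out$pass)
  out
}
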