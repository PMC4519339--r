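## Regime classification (liquid vs. clotting), nucleation times,
## parametric sweeps and the cube-law scaling fit.

#' Simulation configuration
#'
#' Bundles the physical parameters with the numerical controls of a
#' thrombus-formation run.
#'
#' @param params a `stenoclot_params` object.
#' @param resolution mesh cells per cm.
#' @param bl_factor wall-layer grading factor.
#' @param dt transport/chemistry time step, s.
#' @param chem_sub chemistry sub-steps per transport step.
#' @param quasi_steady re-solve the steady flow only when the filtration
#'   resistance field changes appreciably (clot growth is slow against the
#'   flow time scale); `FALSE` advances the flow transiently inside every
#'   step.
#' @param refresh_ds quasi-steady refresh threshold on the saturating
#'   resistance metric `alpha_p/(1+alpha_p)`.
#' @param flow_tol,flow_max_steps,cfl steady flow solver controls.
#' @param t_max censoring horizon, s.
#' @param steady_tol relative L-infinity change of all chemical fields per
#'   kinetic time window below which the state is declared stationary.
#' @param run_past_gel_s continue this long (s) after gel nucleation to
#'   develop the clot (scenario diagnostics); 0 stops at nucleation.
#' @param upper_exchange Robin exchange on the healthy upper wall.
#' @param chunk_s scheduling granularity of the integration loop, s.
#' @param snapshot_every_s store field snapshots at this cadence (Inf: none).
#' @param Re_max flow-solver stability ceiling.
#' @param scheme scalar-convection scheme: `"limited"` (deferred van Leer
#'   TVD, the default -- its low numerical diffusion is needed to represent
#'   accumulation in the recirculation eddy on affordable meshes) or
#'   `"upwind"` (first-order). The limited scheme's explicit antidiffusive
#'   part caps `dt` at `scalar_cfl` times the cell residence-time bound.
#' @param scalar_cfl optional Courant number capping `dt` for the limited
#'   scheme; `Inf` (the default) relies on the donor-cell clip for
#'   robustness and uses `dt` as given.
#' @param alpha_p_flow_cap resistance ceiling passed to the flow solver,
#'   cm^-2. Beyond ~1e4 the Darcy screening length drops below any cell
#'   size used here, so the gel is already immobile; the cap only protects
#'   the linear solvers' conditioning. The transported closure field is
#'   never capped.
#' @return an object of class `stenoclot_config`.
#' @export
simulation_config <- function(params, resolution = 24, bl_factor = 0.35,
                              dt = 0.02, chem_sub = 1L, quasi_steady = TRUE,
                              refresh_ds = 0.02, flow_tol = 2e-5,
                              flow_max_steps = 40000L, cfl = 0.7,
                              t_max = 5000, steady_tol = 1e-6,
                              run_past_gel_s = 0, upper_exchange = TRUE,
                              chunk_s = 2, snapshot_every_s = Inf,
                              Re_max = 500, scheme = c("limited", "upwind"),
                              scalar_cfl = Inf, alpha_p_flow_cap = 1e4) {
  stopifnot(inherits(params, "stenoclot_params"))
  scheme <- match.arg(scheme)
  cfg <- list(params = params, resolution = resolution, bl_factor = bl_factor,
              dt = dt, chem_sub = as.integer(chem_sub),
              quasi_steady = isTRUE(quasi_steady), refresh_ds = refresh_ds,
              flow_tol = flow_tol, flow_max_steps = as.integer(flow_max_steps),
              cfl = cfl, t_max = t_max, steady_tol = steady_tol,
              run_past_gel_s = run_past_gel_s,
              upper_exchange = isTRUE(upper_exchange), chunk_s = chunk_s,
              snapshot_every_s = snapshot_every_s, Re_max = Re_max,
              scheme = scheme, scalar_cfl = scalar_cfl,
              alpha_p_flow_cap = alpha_p_flow_cap)
  class(cfg) <- "stenoclot_config"
  cfg
}

.chem_scales <- function(p) c(u = p$u0, theta = p$theta0, phi = p$phi0 * 10,
                              Fg = p$Fg0, M1 = p$Fg0, M2 = p$Fg0)

#' Classify a parameter point into coagulation regime I or II
#'
#' Runs the coupled simulation from the resting state (stationary clean
#' flow, all species zero except fibrinogen) until either the weight-average
#' chain length `Nw` reaches the gelation threshold `Nws` anywhere in the
#' vessel (regime II, with the nucleation time `T*` recorded), or all
#' chemical fields become stationary with `max Nw < Nws/2` (regime I), or
#' the censoring horizon `t_max` is reached (regime I, flagged censored).
#'
#' @param config a `stenoclot_config` (see [simulation_config()]).
#' @param verbose print progress lines.
#' @return an object of class `stenoclot_sim`: regime (`"I"`/`"II"`),
#'   `T_star_s` and dimensionless `T_star` (kinetic units), the first-gel
#'   location, the per-step max-`Nw` series, the stopping reason, the final
#'   fields, flow state, wall shear and the run's maximal shear rate.
#' @export
classify_regime <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "stenoclot_config"))
  p <- config$params
  tkin <- kinetic_time_scale(p)
  mesh <- build_mesh(p, config$resolution, config$bl_factor)
  pars <- .chem_pars(p)
  Nws <- pars$Nws
  flow <- solve_stationary_flow(mesh, p, 0, tol = config$flow_tol,
                                max_steps = config$flow_max_steps,
                                cfl = config$cfl, Re_max = config$Re_max)
  shear <- wall_shear(flow, mesh, p)
  max_gamma <- max(shear$gamma_dot)
  wx <- wall_exchange_fields(mesh, shear, p, config$upper_exchange)
  chem <- initial_chem_state(mesh$ncell, p)
  ap_solved <- numeric(mesh$ncell)
  Dvec <- c(p$D_u, p$D_theta, p$D_phi, p$D_g, p$D)
  scheme_int <- match(config$scheme, c("upwind", "limited")) - 1L
  pick_dt <- function(fl) {
    if (config$scheme == "limited")
      min(config$dt, config$scalar_cfl * transport_dt_bound(fl, mesh))
    else config$dt
  }
  dt <- pick_dt(flow)
  chunk_steps <- max(1L, as.integer(round(config$chunk_s / dt)))
  scl <- .chem_scales(p)
  window <- tkin
  snapshot <- chem; snap_t <- 0
  t <- 0
  maxnw_chunks <- list(); time_chunks <- list()
  stop_reason <- "t_max"; censored <- TRUE
  T_star_s <- NA_real_; gel_cell <- NA_integer_
  flow_solves <- 1L
  crossed <- FALSE; t_cross <- NA_real_
  snapshots <- list()
  next_snap <- config$snapshot_every_s

  nws_stop <- Nws
  t_stop <- config$t_max
  while (t < t_stop) {
    n_do <- min(chunk_steps, max(1L, ceiling((t_stop - t) / dt)))
    if (!config$quasi_steady) {
      res <- coupled_step(flow, chem, mesh, p, dt, upper_exchange = config$upper_exchange,
                          chem_sub = config$chem_sub)
      flow <- res$flow; chem <- res$chem
      shear <- res$shear
      max_gamma <- max(max_gamma, max(shear$gamma_dot))
      wx <- wall_exchange_fields(mesh, shear, p, config$upper_exchange)
      out <- list(max_nw = res$diagnostics$max_nw, steps_done = 1L,
                  crossed = FALSE, alpha_p = res$closures$alpha_p)
      nwmax <- res$diagnostics$max_nw
      time_chunks[[length(time_chunks) + 1L]] <- t + dt
      if (!crossed && nwmax >= nws_stop) {
        out$crossed <- TRUE; out$cross_frac <- 1
        out$cross_cell <- which.max(res$closures$Nw)
      }
      t <- t + dt
      maxnw_chunks[[length(maxnw_chunks) + 1L]] <- nwmax
    } else {
      out <- cpp_transport_chunk(mesh, flow$flux, flow$b_flux,
                                 chem$u, chem$theta, chem$phi, chem$Fg,
                                 chem$M1, chem$M2, wx$mu, wx$u0, pars, Dvec,
                                 dt, n_do, config$chem_sub, TRUE,
                                 if (crossed) Inf else nws_stop,
                                 1e-12, 1000L, FALSE, scheme_int)
      chem <- out[c("u", "theta", "phi", "Fg", "M1", "M2")]
      time_chunks[[length(time_chunks) + 1L]] <- t + dt * seq_len(out$steps_done)
      t <- t + out$steps_done * dt
      maxnw_chunks[[length(maxnw_chunks) + 1L]] <- out$max_nw
    }
    if (!crossed && isTRUE(out$crossed)) {
      crossed <- TRUE
      t_cross <- t - dt + out$cross_frac * dt
      T_star_s <- t_cross
      gel_cell <- out$cross_cell
      stop_reason <- "gel"; censored <- FALSE
      if (verbose) message(sprintf("  gel at t = %.1f s", t_cross))
      if (config$run_past_gel_s <= 0) break
      t_stop <- t_cross + config$run_past_gel_s
    }
    ## quasi-steady flow refresh when the clot resistance moved
    if (config$quasi_steady) {
      ap_new <- pmin(out$alpha_p, config$alpha_p_flow_cap)
      ds <- max(abs(ap_new / (1 + ap_new) - ap_solved / (1 + ap_solved)))
      if (ds > config$refresh_ds) {
        flow <- solve_stationary_flow(mesh, p, ap_new, tol = config$flow_tol,
                                      max_steps = min(config$flow_max_steps, 8000L),
                                      cfl = config$cfl, warm_start = flow,
                                      Re_max = config$Re_max)
        shear <- wall_shear(flow, mesh, p)
        max_gamma <- max(max_gamma, max(shear$gamma_dot))
        wx <- wall_exchange_fields(mesh, shear, p, config$upper_exchange)
        ap_solved <- ap_new
        flow_solves <- flow_solves + 1L
        new_dt <- pick_dt(flow)
        if (new_dt < dt * 0.999) {
          dt <- new_dt
          chunk_steps <- max(1L, as.integer(round(config$chunk_s / dt)))
        }
      }
    }
    if (is.finite(next_snap) && t >= next_snap) {
      snapshots[[length(snapshots) + 1L]] <- c(list(t = t), chem)
      next_snap <- next_snap + config$snapshot_every_s
    }
    ## stationarity check (regime I) on kinetic-time windows
    if (!crossed && t - snap_t >= window) {
      rel <- 0
      for (nm in names(chem)) {
        ref <- if (nm == "Fg") abs(snapshot[[nm]] - p$Fg0) else snapshot[[nm]]
        delta <- max(abs(chem[[nm]] - snapshot[[nm]]))
        rel <- max(rel, delta / (max(abs(ref)) + scl[[nm]] * 1e-3))
      }
      rel <- rel / ((t - snap_t) / window)     # per-window rate
      snapshot <- chem; snap_t <- t
      nwmax_now <- utils::tail(out$max_nw, 1)
      if (rel < config$steady_tol && nwmax_now < 0.5 * Nws) {
        stop_reason <- "steady"; censored <- FALSE
        break
      }
    }
    if (verbose && length(maxnw_chunks) %% 25 == 0)
      message(sprintf("  t = %.1f s, max Nw = %.3g", t, utils::tail(out$max_nw, 1)))
    if (!crossed && t >= config$t_max) break
  }
  maxnw <- unlist(maxnw_chunks, use.names = FALSE)
  times <- unlist(time_chunks, use.names = FALSE)[seq_along(maxnw)]
  cls <- closure_fields(chem$M1, chem$M2, p)
  res <- list(
    regime = if (stop_reason == "gel") "II" else "I",
    T_star_s = T_star_s,
    T_star = T_star_s / tkin,
    first_gel_xy = if (!is.na(gel_cell)) c(x = mesh$cx[gel_cell], y = mesh$cy[gel_cell]) else NULL,
    stop_reason = stop_reason, censored = censored,
    t_end = t, max_nw_series = maxnw, max_nw_times = times, dt = dt,
    max_shear_rate = max_gamma, flow_solves = flow_solves,
    chem = chem, closures = cls, flow = flow, shear = shear, mesh = mesh,
    snapshots = snapshots,
    groups = nondimensionalize(p), config = config)
  class(res) <- "stenoclot_sim"
  res
}

#' @export
print.stenoclot_sim <- function(x, ...) {
  g <- x$groups
  cat(sprintf("Regime %s (%s) at Re = %g, mu2_tilde = %.3g, h = %g, d_tilde = %g\n",
              x$regime, x$stop_reason, g$Re, g$mu2_tilde, g$h, g$d_tilde))
  if (x$regime == "II")
    cat(sprintf("  nucleation T* = %.1f s (%.3g kinetic units), first gel at x = %.3f, y = %.3f cm\n",
                x$T_star_s, x$T_star, x$first_gel_xy["x"], x$first_gel_xy["y"]))
  cat(sprintf("  run to t = %.1f s; max shear rate %.3g 1/s; %d flow solves\n",
              x$t_end, x$max_shear_rate, x$flow_solves))
  invisible(x)
}

#' @export
summary.stenoclot_sim <- function(object, ...) {
  print(object)
  cat(sprintf("  final: max Nw = %.4g (Nws = %.4g), gel cells = %d, max M1 = %.3g nM\n",
              max(object$closures$Nw), object$closures$constants$Nws,
              sum(object$closures$Nw >= object$closures$constants$Nws),
              max(object$chem$M1)))
  invisible(object)
}

#' @export
plot.stenoclot_sim <- function(x, ...) {
  tt <- x$max_nw_times
  graphics::plot(tt, x$max_nw_series, type = "l", log = "y",
                 xlab = "time (s)", ylab = "max Nw",
                 main = sprintf("Regime %s", x$regime), ...)
  graphics::abline(h = x$closures$constants$Nws, lty = 2)
  invisible(x)
}

#' Parametric sweep over dimensionless controls
#'
#' Classifies every point of a 2D grid in two of the dimensionless controls
#' (`Re`, `mu2_tilde`, `h`, `d_tilde`), refines regime boundaries along the
#' first axis by bisection, and reports the activation thresholds and the
#' connectivity of the clotting region.
#'
#' @param axes named list of two monotone numeric grids, e.g.
#'   `list(Re = c(50, 130, 300), mu2_tilde = c(5, 9.5))`.
#' @param fixed named list of the remaining dimensionless controls.
#' @param budget maximal number of simulation runs (grid + refinement).
#' @param config_args further arguments passed to [simulation_config()].
#' @param refine_tol named bisection tolerances (defaults `Re = 2`,
#'   `mu2_tilde = 0.1`, `h = 0.02`, `d_tilde = 0.02`).
#' @param verbose print one line per run.
#' @return an object of class `stenoclot_sweep`: `results` data.frame (one
#'   row per run), `grid` label matrix, `boundaries` (refined crossing
#'   points per transect, with `Re1`/`Re2` where applicable), `mu2_min`
#'   estimate (when `mu2_tilde` is an axis), `n_components` of region II,
#'   and `budget_exhausted`.
#' @export
sweep_regimes <- function(axes, fixed = list(), budget = 50L,
                          config_args = list(), refine_tol = NULL,
                          verbose = FALSE) {
  stopifnot(length(axes) == 2L, !is.null(names(axes)))
  nm <- names(axes)
  allowed <- c("Re", "mu2_tilde", "h", "d_tilde")
  stopifnot(all(nm %in% allowed))
  tol_def <- c(Re = 2, mu2_tilde = 0.1, h = 0.02, d_tilde = 0.02)
  if (!is.null(refine_tol)) tol_def[names(refine_tol)] <- unlist(refine_tol)
  runs <- 0L
  results <- list()
  run_point <- function(vals) {
    if (runs >= budget) return(NULL)
    runs <<- runs + 1L
    gp <- list(Re = 130, h = 0, d_tilde = 0.4, mu2_tilde = 9.5)
    gp[names(fixed)] <- fixed
    gp[names(vals)] <- vals
    p <- params_from_groups(gp$Re, gp$h, gp$d_tilde, gp$mu2_tilde)
    cfg <- do.call(simulation_config, c(list(params = p), config_args))
    sim <- classify_regime(cfg)
    row <- data.frame(Re = gp$Re, mu2_tilde = gp$mu2_tilde, h = gp$h,
                      d_tilde = gp$d_tilde, regime = sim$regime,
                      T_star_s = sim$T_star_s, T_star = sim$T_star,
                      stop_reason = sim$stop_reason, censored = sim$censored,
                      max_shear_rate = sim$max_shear_rate)
    results[[length(results) + 1L]] <<- row
    if (verbose)
      message(sprintf("  run %d: %s=%g %s=%g -> regime %s", runs,
                      nm[1], vals[[nm[1]]], nm[2], vals[[nm[2]]], sim$regime))
    sim$regime
  }
  a1 <- axes[[1]]; a2 <- axes[[2]]
  lab <- matrix(NA_character_, length(a1), length(a2))
  for (j in seq_along(a2)) for (i in seq_along(a1)) {
    v <- stats::setNames(list(a1[i], a2[j]), nm)
    r <- run_point(v)
    if (is.null(r)) break
    lab[i, j] <- r
  }
  exhausted <- runs >= budget && any(is.na(lab))
  ## boundary refinement along axis 1, per transect of axis 2
  boundaries <- list()
  for (j in seq_along(a2)) {
    col <- lab[, j]
    if (any(is.na(col))) next
    pts <- list()
    for (i in seq_len(length(a1) - 1L)) {
      if (col[i] != col[i + 1L]) {
        lo <- a1[i]; hi <- a1[i + 1L]; rlo <- col[i]
        while (hi - lo > tol_def[[nm[1]]] && runs < budget) {
          mid <- 0.5 * (lo + hi)
          v <- stats::setNames(list(mid, a2[j]), nm)
          rm_ <- run_point(v)
          if (is.null(rm_)) break
          if (rm_ == rlo) lo <- mid else hi <- mid
        }
        pts[[length(pts) + 1L]] <-
          data.frame(value = 0.5 * (lo + hi), from = col[i], to = col[i + 1L])
      }
    }
    pts <- if (length(pts)) do.call(rbind, pts) else
      data.frame(value = numeric(0), from = character(0), to = character(0))
    entry <- list(transect = a2[j], crossings = pts)
    if (nm[1] == "Re" && nrow(pts) > 0) {
      into_II <- pts$value[pts$to == "II" | pts$from == "II"]
      entry$Re1 <- min(into_II); entry$Re2 <- max(into_II)
    }
    boundaries[[j]] <- entry
  }
  ## mu2_min estimate when mu2_tilde is the second axis
  mu2_min <- NA_real_
  if (nm[2] == "mu2_tilde" && all(!is.na(lab))) {
    has_II <- apply(lab == "II", 2, any)
    if (any(has_II) && any(!has_II)) {
      below <- a2[!has_II & a2 < min(a2[has_II])]
      mu2_min <- if (length(below)) 0.5 * (max(below) + min(a2[has_II])) else min(a2[has_II])
    } else if (all(has_II)) mu2_min <- min(a2)
  }
  res <- do.call(rbind, results)
  out <- list(axes = axes, fixed = fixed, results = res, grid = lab,
              boundaries = boundaries, mu2_min = mu2_min,
              n_components = .count_components(lab == "II"),
              runs = runs, budget_exhausted = exhausted)
  class(out) <- "stenoclot_sweep"
  out
}

## 4-neighbour connected components of a logical matrix (NA = FALSE)
.count_components <- function(mask) {
  mask[is.na(mask)] <- FALSE
  n <- 0L
  lab <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      n <- n + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        a <- ij[1]; b <- ij[2]
        if (a < 1 || b < 1 || a > nrow(mask) || b > ncol(mask)) next
        if (!mask[a, b] || lab[a, b] != 0L) next
        lab[a, b] <- n
        stack <- c(stack, list(c(a - 1, b), c(a + 1, b), c(a, b - 1), c(a, b + 1)))
      }
    }
  }
  n
}

#' @export
print.stenoclot_sweep <- function(x, ...) {
  cat(sprintf("Parametric sweep: %d runs (%s x %s), region II components: %d\n",
              x$runs, names(x$axes)[1], names(x$axes)[2], x$n_components))
  print(x$grid)
  if (!is.na(x$mu2_min)) cat(sprintf("  mu2_tilde_min ~ %.3g\n", x$mu2_min))
  invisible(x)
}

#' Fit the cube-root scaling of the nucleation time
#'
#' Near the regime boundary the nucleation time diverges as
#' `(x - x_crit) T*^3 = C`: this fits the free exponent `p` in
#' `T* ~ (x - x_crit)^p` by least squares on the log--log points and
#' reports the constancy diagnostic of the cube-law product
#' `(x - x_crit) T*^3` (relative standard deviation; near zero when the
#' cube law holds).
#'
#' @param points data.frame/list with `control` (the swept parameter) and
#'   `T_star` (> 0).
#' @param critical_value the boundary value of the control parameter.
#' @return list: `exponent` (expected -1/3), `constant` (mean cube-law
#'   product), `diagnostic` (relative sd of the product), `n`, and the
#'   underlying `lm` fit.
#' @export
fit_scaling <- function(points, critical_value) {
  x <- points$control - critical_value
  T <- points$T_star
  ok <- is.finite(x) & is.finite(T) & x > 0 & T > 0
  x <- x[ok]; T <- T[ok]
  if (length(x) < 4) stop("need at least 4 points on one side of the critical value")
  lx <- log(x)
  if (diff(range(lx)) < 0.1) stop("degenerate spread of control values")
  fit <- stats::lm(log(T) ~ lx)
  C <- x * T^3
  list(exponent = unname(stats::coef(fit)[2]),
       constant = mean(C),
       diagnostic = stats::sd(C) / mean(C),
       n = length(x), fit = fit)
}
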