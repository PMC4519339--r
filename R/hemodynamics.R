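## Incompressible 2D flow in the stenosed channel with the Darcy
## filtration-resistance sink, and wall shear extraction.

.flow_state <- function(mesh, sol, alpha_p) {
  st <- list(u = sol$u, v = sol$v, p = sol$p,
             flux = sol$flux, b_flux = sol$b_flux,
             alpha_p = alpha_p,
             resid = sol$resid, resid_hist = sol$resid_hist,
             converged = isTRUE(sol$converged), steps = sol$steps,
             div_max = sol$div_max, div_tol_abs = sol$div_tol_abs,
             dt_min = sol$dt_min, time = 0)
  class(st) <- "stenoclot_flow"
  st
}

#' Solve the stationary flow problem
#'
#' Steady incompressible flow in the stenosed channel: parabolic inlet
#' profile of centerline speed `V0`, zero outlet pressure, no-slip walls,
#' and the Darcy sink `-alpha_p nu V` representing drag of the fibrin gel.
#' The solver pseudo-time-marches a collocated finite-volume projection
#' scheme (first-order upwind convection, deferred-correction viscous and
#' pressure terms, implicit Darcy drag) with local time stepping until the
#' momentum residual drops below `tol`. The face-flux field of the returned
#' state is discretely divergence free to the configured tolerance.
#'
#' @param mesh a `stenoclot_mesh`.
#' @param p a `stenoclot_params` object (uses `V0`, `Ly`, `nu`).
#' @param alpha_p per-cell filtration resistance, cm^-2 (scalar or vector);
#'   default 0 (clean vessel).
#' @param tol steady residual tolerance (acceleration-scaled).
#' @param max_steps pseudo-time step budget.
#' @param cfl pseudo-time CFL number.
#' @param div_tol divergence contract in units of `V0/Ly` per cell.
#' @param warm_start optional previous `stenoclot_flow` to continue from.
#' @param Re_max stability ceiling on the Reynolds number.
#' @param n_nonorth deferred non-orthogonal pressure corrections per step.
#' @return a `stenoclot_flow` object (cell velocities `u`, `v`, kinematic
#'   pressure `p`, divergence-free face fluxes, residual history).
#' @export
solve_stationary_flow <- function(mesh, p, alpha_p = 0, tol = 2e-5,
                                  max_steps = 40000L, cfl = 0.7,
                                  div_tol = 1e-8, warm_start = NULL,
                                  Re_max = 500, n_nonorth = 1L) {
  Re <- p$V0 * p$Ly / p$nu
  if (Re > Re_max)
    stop("Re = ", Re, " exceeds the configured stability ceiling ", Re_max)
  ap <- rep_len(alpha_p, mesh$ncell)
  if (any(ap < 0)) stop("alpha_p must be >= 0")
  if (is.null(warm_start)) {
    y <- mesh$cy
    u0 <- 4 * p$V0 * y * (p$Ly - y) / p$Ly^2
    v0 <- numeric(mesh$ncell); p0 <- numeric(mesh$ncell)
  } else {
    u0 <- warm_start$u; v0 <- warm_start$v; p0 <- warm_start$p
  }
  sol <- cpp_flow_solve(mesh, u0, v0, p0, ap, p$V0, p$Ly, p$nu,
                        cfl, tol, as.integer(max_steps), as.integer(n_nonorth),
                        div_tol, 2000L, TRUE, 0, 25L)
  if (!is.null(sol$error)) stop(sol$error)
  ## a warm start can very occasionally be thrown off by a large jump in
  ## the resistance field; fall back to a cold start once
  if (!is.null(warm_start) && (!all(is.finite(sol$u)) || !all(is.finite(sol$p)))) {
    return(solve_stationary_flow(mesh, p, alpha_p, tol, max_steps, cfl,
                                 div_tol, warm_start = NULL, Re_max = Re_max,
                                 n_nonorth = n_nonorth))
  }
  if (!all(is.finite(sol$u))) stop("stationary flow solver diverged")
  st <- .flow_state(mesh, sol, ap)
  if (!st$converged)
    warning("stationary flow solver stopped at residual ", signif(st$resid, 3),
            " after ", st$steps, " pseudo-steps")
  st
}

#' Advance the flow by one transient step
#'
#' One pressure--velocity coupled step of size `dt` with the current Darcy
#' sink field. `dt` must satisfy the advective/viscous stability bound or
#' the step is rejected.
#'
#' @param state a `stenoclot_flow` object.
#' @param dt time step, s.
#' @param alpha_p per-cell filtration resistance (scalar or vector).
#' @param mesh the mesh the state lives on.
#' @param p a `stenoclot_params` object.
#' @param cfl maximal Courant number admitted for `dt`.
#' @param div_tol divergence contract in units of `V0/Ly`.
#' @return updated `stenoclot_flow`.
#' @export
step_flow <- function(state, dt, alpha_p, mesh, p, cfl = 0.5, div_tol = 1e-8) {
  ap <- rep_len(alpha_p, mesh$ncell)
  sol <- cpp_flow_solve(mesh, state$u, state$v, state$p, ap, p$V0, p$Ly, p$nu,
                        cfl, 0, 1L, 1L, div_tol, 2000L, FALSE, dt, 1L)
  if (!is.null(sol$error))
    stop(sol$error, " (dt_max = ", signif(sol$dt_max, 3), " s)")
  st <- .flow_state(mesh, sol, ap)
  st$converged <- TRUE
  st$time <- state$time + dt
  st
}

#' Wall shear stress and shear rate
#'
#' `tau = rho nu dV_t/dn` on every wall face, from the tangential velocity
#' of the wall-adjacent cell and its wall-normal distance; signed along the
#' downstream (+x) tangent, so separation/reattachment show as sign
#' changes. The shear rate is `|tau| / (rho nu)`.
#'
#' @param state a `stenoclot_flow`.
#' @param mesh the mesh.
#' @param p a `stenoclot_params` object (uses `rho`, `nu`).
#' @return data.frame with `face` (boundary-face index), `patch`
#'   (`"wall_lower"`/`"wall_upper"`), `x`, `tau` (dyn/cm^2), `gamma_dot`
#'   (s^-1).
#' @export
wall_shear <- function(state, mesh, p) {
  sel <- which(mesh$b_patch %in% c(3L, 4L))
  o <- mesh$b_own[sel]
  nx <- mesh$b_Sx[sel] / mesh$b_len[sel]
  ny <- mesh$b_Sy[sel] / mesh$b_len[sel]
  tx <- -ny; ty <- nx
  flip <- tx < 0
  tx[flip] <- -tx[flip]; ty[flip] <- -ty[flip]
  vt <- state$u[o] * tx + state$v[o] * ty
  tau <- p$rho * p$nu * vt / mesh$b_dn[sel]
  data.frame(face = sel,
             patch = ifelse(mesh$b_patch[sel] == 4L, "wall_lower", "wall_upper"),
             x = mesh$b_fcx[sel], tau = tau,
             gamma_dot = abs(tau) / (p$rho * p$nu))
}

#' Global mass balance of a flow state
#'
#' @param state a `stenoclot_flow`.
#' @param mesh the mesh.
#' @return list with inlet and outlet volumetric fluxes (cm^2/s, per unit
#'   depth) and their relative mismatch.
#' @export
mass_balance <- function(state, mesh) {
  qin <- -sum(state$b_flux[mesh$b_patch == 1L])
  qout <- sum(state$b_flux[mesh$b_patch == 2L])
  list(inflow = qin, outflow = qout,
       rel_mismatch = abs(qin - qout) / max(abs(qin), 1e-300))
}

#' Synthetic uniform flow state (verification fixture helper)
#'
#' Builds a `stenoclot_flow` whose face fluxes correspond to a prescribed
#' uniform velocity -- exactly divergence free on any mesh. Used by the
#' advection--diffusion fixtures; not a solution of the momentum equations.
#'
#' @param mesh a `stenoclot_mesh`.
#' @param ux,uy uniform velocity components, cm/s.
#' @return a `stenoclot_flow` object.
#' @export
uniform_flow_state <- function(mesh, ux, uy = 0) {
  st <- list(u = rep(ux, mesh$ncell), v = rep(uy, mesh$ncell),
             p = numeric(mesh$ncell),
             flux = ux * mesh$Sx + uy * mesh$Sy,
             b_flux = ux * mesh$b_Sx + uy * mesh$b_Sy,
             alpha_p = numeric(mesh$ncell),
             resid = 0, resid_hist = numeric(0), converged = TRUE,
             steps = 0L, div_max = 0, div_tol_abs = NA_real_,
             dt_min = NA_real_, time = 0)
  class(st) <- "stenoclot_flow"
  st
}

#' @export
print.stenoclot_flow <- function(x, ...) {
  cat(sprintf("Flow state: max |V| = %.4g cm/s, residual %.3g (%s, %d steps), max divergence %.3g\n",
              max(sqrt(x$u^2 + x$v^2)), x$resid,
              if (x$converged) "converged" else "NOT converged",
              x$steps, x$div_max))
  invisible(x)
}
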