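## Finite-volume transport of the chemical species and the coupled
## flow--transport--chemistry step.

.diffusion_number_check <- function(mesh, Dmax, dt) {
  if (Dmax <= 0) return(invisible(TRUE))
  s <- numeric(mesh$ncell)
  acc <- Dmax * mesh$E
  for (side in 1:2) {
    idx <- if (side == 1) mesh$own else mesh$nbr
    s <- s + unname(tapply(acc, factor(idx, levels = seq_len(mesh$ncell)),
                           sum, default = 0))
  }
  dtmax <- 0.5 * min(mesh$area / pmax(s, 1e-300))
  if (dt > dtmax)
    stop("dt = ", dt, " exceeds the explicit diffusion bound ", signif(dtmax, 3))
  invisible(TRUE)
}

#' One advection--diffusion step of a scalar field
#'
#' Finite-volume step on the divergence-free face fluxes of a flow state:
#' implicit first-order upwind convection of `b_field * V * phi`
#' (unconditionally stable), explicit diffusion with the per-cell
#' diffusivity, inlet Dirichlet / outlet zero-gradient boundaries, and
#' either sealed or Robin-exchanging walls.
#'
#' @param field cell vector to advance.
#' @param flow a `stenoclot_flow` (supplies face fluxes).
#' @param D_field per-cell diffusivity (scalar or vector), cm^2/s.
#' @param b_field per-cell convective multiplier (scalar or vector; 1 for
#'   ordinary scalars, the polymer transport coefficient for moments).
#' @param dt time step, s (checked against the explicit diffusion bound).
#' @param mesh the mesh.
#' @param bcs list: `inlet_value` (Dirichlet, default 0), `wall_mu`
#'   (per-wall-face permeability or scalar, default 0 = sealed),
#'   `wall_u0` (sub-wall concentration per wall face or scalar, default 0),
#'   `D_wall` (diffusivity used in the Robin closure, default `max(D_field)`).
#' @param nsteps number of identical steps to take (loops in compiled code).
#' @param scheme convection scheme: `"upwind"` (first-order, default) or
#'   `"limited"` (deferred van Leer TVD correction toward second order).
#' @return the advanced cell vector.
#' @export
advect_diffuse <- function(field, flow, D_field, b_field, dt, mesh,
                           bcs = list(), nsteps = 1L,
                           scheme = c("upwind", "limited")) {
  scheme <- match.arg(scheme)
  stopifnot(length(field) == mesh$ncell, dt > 0)
  Dc <- rep_len(D_field, mesh$ncell)
  bc <- rep_len(b_field, mesh$ncell)
  .diffusion_number_check(mesh, max(Dc), dt)
  nb <- length(mesh$b_own)
  mu <- rep_len(bcs$wall_mu %||% 0, nb)
  u0 <- rep_len(bcs$wall_u0 %||% 0, nb)
  inlet <- bcs$inlet_value %||% 0
  Dw <- bcs$D_wall %||% max(Dc)
  cpp_advect_diffuse(mesh, flow$flux, flow$b_flux, as.numeric(field),
                     Dc, bc, inlet, mu, u0, Dw, dt, 1e-12, 1000L,
                     as.integer(nsteps), match(scheme, c("upwind", "limited")) - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One fully coupled step of the thrombus-formation model
#'
#' The reference splitting sequence: (1) a transient flow step with the
#' current filtration resistance; (2) wall shear evaluation, permeability
#' law, and the Robin activator influx; (3) transport of all six species on
#' the new fluxes; (4) implicit chemistry with the mature-gel cap; (5)
#' closure update (`Nw`, `bp`, `Df`, `alpha_p`).
#'
#' @param flow a `stenoclot_flow`.
#' @param chem chemical state list (six cell vectors).
#' @param mesh the mesh.
#' @param p a `stenoclot_params` object.
#' @param dt time step, s.
#' @param closures current closure fields (from [closure_fields()]); if
#'   `NULL`, computed from `chem`.
#' @param upper_exchange exchange on the healthy upper wall (see
#'   [wall_exchange_fields()]).
#' @param chem_sub chemistry sub-steps per transport step.
#' @param audit collect the species-balance audit (small extra cost).
#' @return list with updated `flow`, `chem`, `closures`, the wall `shear`
#'   data.frame, and `diagnostics` (max Nw, audit residual, clip count,
#'   activator influx).
#' @export
coupled_step <- function(flow, chem, mesh, p, dt, closures = NULL,
                         upper_exchange = TRUE, chem_sub = 1L, audit = FALSE,
                         scheme = c("upwind", "limited")) {
  scheme <- match.arg(scheme)
  if (is.null(closures)) closures <- closure_fields(chem$M1, chem$M2, p)
  flow <- step_flow(flow, dt, closures$alpha_p, mesh, p)
  shear <- wall_shear(flow, mesh, p)
  wx <- wall_exchange_fields(mesh, shear, p, upper_exchange)
  pars <- .chem_pars(p)
  out <- cpp_transport_chunk(mesh, flow$flux, flow$b_flux,
                             chem$u, chem$theta, chem$phi, chem$Fg,
                             chem$M1, chem$M2, wx$mu, wx$u0, pars,
                             c(p$D_u, p$D_theta, p$D_phi, p$D_g, p$D),
                             dt, 1L, as.integer(chem_sub), TRUE,
                             Inf, 1e-12, 1000L, audit,
                             match(scheme, c("upwind", "limited")) - 1L)
  chem <- out[c("u", "theta", "phi", "Fg", "M1", "M2")]
  cls <- list(Nw = out$Nw, bp = out$bp, Df = out$Df, alpha_p = out$alpha_p,
              gel_mask = as.integer(out$Nw >= 100 * pars$Nws * (1 - 1e-12)),
              constants = polymer_constants(p))
  list(flow = flow, chem = chem, closures = cls, shear = shear,
       diagnostics = list(max_nw = max(out$Nw), audit_max = out$audit_max,
                          clip_count = out$clip_count, influx_u = out$influx_u))
}

#' Transport-only advance of the chemical state (reactions off)
#'
#' Used by conservation audits and fixtures: advances all six species over
#' `nsteps` steps of size `dt` on frozen fluxes with the chemistry
#' disabled.
#'
#' @inheritParams coupled_step
#' @param nsteps number of steps.
#' @param wall_mu,wall_u0 Robin data for the activator (defaults sealed).
#' @return list(chem, audit_max, influx_u).
#' @export
transport_only <- function(flow, chem, mesh, p, dt, nsteps = 1L,
                           wall_mu = 0, wall_u0 = 0) {
  nb <- length(mesh$b_own)
  pars <- .chem_pars(p)
  out <- cpp_transport_chunk(mesh, flow$flux, flow$b_flux,
                             chem$u, chem$theta, chem$phi, chem$Fg,
                             chem$M1, chem$M2,
                             rep_len(wall_mu, nb), rep_len(wall_u0, nb), pars,
                             c(p$D_u, p$D_theta, p$D_phi, p$D_g, p$D),
                             dt, as.integer(nsteps), 1L, FALSE,
                             Inf, 1e-12, 1000L, TRUE, 0L)
  list(chem = out[c("u", "theta", "phi", "Fg", "M1", "M2")],
       audit_max = out$audit_max, influx_u = out$influx_u)
}


#' Advective time-step bound for the scalar transport
#'
#' The limited (deferred-correction) convection scheme is explicit in its
#' antidiffusive part and requires a Courant-type bound; the first-order
#' implicit upwind scheme does not.
#'
#' @param flow a `stenoclot_flow`.
#' @param mesh the mesh.
#' @return the minimal cell residence time `min(area / sum |F_f|)`, s.
#' @export
transport_dt_bound <- function(flow, mesh) {
  s <- numeric(mesh$ncell)
  af <- abs(flow$flux)
  for (side in 1:2) {
    idx <- if (side == 1) mesh$own else mesh$nbr
    s <- s + unname(tapply(af, factor(idx, levels = seq_len(mesh$ncell)),
                           sum, default = 0))
  }
  s <- s + unname(tapply(abs(flow$b_flux),
                         factor(mesh$b_own, levels = seq_len(mesh$ncell)),
                         sum, default = 0))
  min(mesh$area / pmax(s, 1e-300))
}
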