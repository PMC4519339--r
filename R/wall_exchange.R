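## Shear-gated wall exchange: piecewise-linear permeability law, the
## sub-wall activator distribution, and the Robin influx condition.

#' Shear-gated wall permeability
#'
#' Piecewise-linear, continuous, non-decreasing law: the intact-wall value
#' `mu1` up to the onset stress `tau1`, the fully-opened value `mu2` beyond
#' the saturation stress `tau2`, and linear interpolation in between.
#'
#' @param tau_abs magnitude of wall shear stress, dyn/cm^2 (vectorized).
#' @param law list with `mu1`, `mu2`, `tau1`, `tau2` (a `stenoclot_params`
#'   object works).
#' @return permeability, cm/s.
#' @export
#' @examples
#' permeability(15, default_parameters())  # halfway up the ramp
permeability <- function(tau_abs, law) {
  stopifnot(all(tau_abs >= 0))
  frac <- pmin(pmax((tau_abs - law$tau1) / (law$tau2 - law$tau1), 0), 1)
  law$mu1 + frac * (law$mu2 - law$mu1)
}

#' Sub-wall activator concentration
#'
#' The thrombogenic tissue sits under the stenosed lower wall only:
#' `u0` for `|x| <= 2d` on the lower wall, zero elsewhere and everywhere on
#' the healthy upper wall.
#'
#' @param x streamwise position(s), cm.
#' @param d plaque half-width, cm.
#' @param u0 sub-wall activator level, nM.
#' @param wall `"lower"` or `"upper"`.
#' @return concentration(s), nM.
#' @export
activator_source <- function(x, d, u0, wall = c("lower", "upper")) {
  wall <- match.arg(wall)
  if (wall == "upper") return(rep(0, length(x)))
  ifelse(abs(x) <= 2 * d, u0, 0)
}

#' Robin wall-influx closure
#'
#' The activator leaks through the wall at rate `mu (u0 - u|wall)`, balanced
#' by diffusion into the lumen. Solving the one-sided discrete closure for
#' the wall-face value gives the realized influx per unit wall length
#' `q = mu k / (mu + k) (u0 - u_cell)` with `k = D_u / dn` the diffusive
#' conductance across the wall-adjacent half-cell (`dn` the wall-normal
#' distance of the adjacent cell center).
#'
#' @param u_cell activator concentration in the wall-adjacent cell, nM.
#' @param u0_pm sub-wall concentration on this face, nM.
#' @param mu wall permeability, cm/s.
#' @param D_u activator diffusivity, cm^2/s.
#' @param dn wall-normal distance to the adjacent cell center, cm; `Inf`
#'   recovers the nominal flux `mu (u0 - u_cell)`.
#' @return list with `flux` (nM cm/s, per unit wall length, positive into
#'   the lumen) and `u_wall` (the closed wall-face value, nM).
#' @export
robin_flux <- function(u_cell, u0_pm, mu, D_u, dn = Inf) {
  stopifnot(all(mu >= 0))
  k <- ifelse(is.finite(dn), D_u / dn, Inf)
  eff <- ifelse(mu == 0, 0, ifelse(is.finite(k), mu * k / (mu + k), mu))
  u_wall <- ifelse(mu + k == 0 | !is.finite(k),
                   u_cell,
                   (mu * u0_pm + k * u_cell) / (mu + k))
  list(flux = eff * (u0_pm - u_cell), u_wall = u_wall)
}

#' Per-face wall exchange data for a mesh
#'
#' Evaluates the permeability law on the current wall shear field and the
#' sub-wall activator window, for every boundary face. Non-wall patches get
#' zero exchange. The healthy upper wall exchanges against `u0+ = 0`
#' (a leak out of the lumen) unless `upper_exchange = FALSE` seals it.
#'
#' @param mesh a `stenoclot_mesh`.
#' @param shear a wall-shear field from [wall_shear()] (or `NULL` for a
#'   quiescent wall, which stays at `mu1`).
#' @param p a `stenoclot_params` object.
#' @param upper_exchange logical; exchange on the upper wall as printed
#'   (default) or sealed.
#' @return list with per-boundary-face vectors `mu` and `u0`.
#' @export
wall_exchange_fields <- function(mesh, shear, p, upper_exchange = TRUE) {
  nb <- length(mesh$b_own)
  mu <- numeric(nb); u0 <- numeric(nb)
  wall <- mesh$b_patch %in% c(3L, 4L)
  tau_abs <- numeric(nb)
  if (!is.null(shear)) tau_abs[wall] <- abs(shear$tau[match(which(wall), shear$face)])
  mu[wall] <- permeability(tau_abs[wall], p)
  lower <- mesh$b_patch == 4L
  u0[lower] <- activator_source(mesh$b_fcx[lower], p$d, p$u0, "lower")
  if (!upper_exchange) mu[mesh$b_patch == 3L] <- 0
  list(mu = mu, u0 = u0)
}
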