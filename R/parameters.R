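#' Default model parameters
#'
#' Returns the full set of dimensional constants of the coupled
#' hemodynamics--coagulation model: cascade kinetics, fibrin polymerization
#' rates, diffusivities, the shear-gated wall permeability law, polymer
#' constants and the vessel geometry/flow settings. All values are in CGS
#' units with concentrations in nM.
#'
#' The inhibitor clearance rate `chi2` is stored as a first-order rate
#' (s^-1), the only dimensionally consistent reading of the inhibitor
#' balance equation.
#'
#' @param ... named overrides for any parameter field, e.g. `V0 = 6.5`,
#'   `H = 0.5`.
#' @return An object of class `stenoclot_params`: a named list of all model
#'   constants (validated).
#' @export
#' @examples
#' p <- default_parameters()
#' p$alpha            # cascade autocatalysis rate, s^-1
#' p2 <- default_parameters(H = 0.5, V0 = 6.5)
default_parameters <- function(...) {
  p <- list(
    ## coagulation cascade kinetics
    alpha  = 3.33e-2,   # s^-1, activator autocatalysis
    theta0 = 5,         # nM, autocatalysis half-saturation
    chi1   = 8.33e-4,   # s^-1, activator clearance
    gamma  = 8.33e-2,   # (nM s)^-1, inhibition of activator
    beta   = 2.5e-5,    # s^-1, inhibitor production
    c      = 5,         # nM, inhibitor production saturation
    eps_g  = 1.66e-6,   # s^-1, fibrinogen replenishment
    phi0   = 0.05,      # nM, inhibitor self-acceleration scale
    chi2   = 0.35,      # s^-1, inhibitor clearance (dimensionally forced)
    k_g    = 5e-6,      # (nM s)^-1, fibrinogen -> fibrin conversion
    k_p    = 2.5e-4,    # (nM s)^-1, polymerization (pairwise sticking)
    k_b    = 1.67e-3,   # s^-1, chain breakage
    k_r    = 1.67e-2,   # s^-1, fibrin removal (fibrinolysis)
    k_d    = 1.66e-6,   # s^-1, primary activator decay
    k_u    = 1.66e1,    # s^-1, primary activator -> cascade activation
    ## polymer physics
    n0     = 1e10,      # cm^-3, heterogeneous nucleation center density
    Fg0    = 9e3,       # nM, plasma fibrinogen level
    K      = 10,        # monomers per Kuhn segment
    v0     = 3e-18,     # cm^3, fibrin monomer volume
    ## diffusivities
    D_u     = 3e-7,     # cm^2/s
    D_theta = 3e-7,
    D_phi   = 3e-7,
    D_g     = 3e-7,
    D       = 3e-7,     # cm^2/s, monomer diffusivity (moment equations)
    ## shear-gated wall permeability
    tau1 = 10,          # dyn/cm^2, permeability onset shear stress
    tau2 = 20,          # dyn/cm^2, saturation shear stress
    mu1  = 2e-12,       # cm/s, intact-wall permeability
    mu2  = 3.02e-5,     # cm/s, fully opened wall (mu2_tilde ~ 9.5)
    u0   = 100,         # nM, sub-wall activator concentration
    ## blood
    nu  = 5e-2,         # cm^2/s, kinematic viscosity
    rho = 1,            # g/cm^3
    ## geometry and flow
    Lx = 7.5,           # cm, vessel length; x in [-Lx/3, 2 Lx/3]
    Ly = 1,             # cm, vessel width
    H  = 0,             # cm, plaque height
    d  = 0.4,           # cm, plaque half-width
    V0 = 6.5            # cm/s, inlet centerline velocity
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  class(p) <- "stenoclot_params"
  validate_parameters(p)
  p
}

#' Validate model parameters
#'
#' Checks the structural invariants of the parameter set: positivity of all
#' rates, diffusivities, lengths and densities; `0 <= H < Ly` (the lumen is
#' never fully occluded); `tau2 > tau1 > 0`; `mu2 >= mu1 > 0`; and
#' `alpha > chi1` (the net kinetic rate that sets the nondimensional time
#' scale must be positive).
#'
#' @param p a `stenoclot_params` object or plain named list.
#' @return `p`, invisibly; errors with an informative message on violation.
#' @export
validate_parameters <- function(p) {
  pos <- c("alpha", "theta0", "chi1", "gamma", "beta", "c", "eps_g", "phi0",
           "chi2", "k_g", "k_p", "k_b", "k_r", "k_d", "k_u", "n0", "Fg0",
           "K", "v0", "D_u", "D_theta", "D_phi", "D_g", "D", "tau1", "tau2",
           "mu1", "u0", "nu", "rho", "Lx", "Ly", "d", "V0")
  miss <- setdiff(c(pos, "mu2", "tau2", "H"), names(p))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single positive finite number")
  }
  if (!is.numeric(p$H) || p$H < 0) stop("H must be >= 0")
  if (p$H >= p$Ly) stop("H must be < Ly (lumen never fully occluded)")
  if (p$tau2 <= p$tau1) stop("tau2 must exceed tau1")
  if (p$mu2 < p$mu1) stop("mu2 must be >= mu1")
  if (p$alpha <= p$chi1) stop("alpha must exceed chi1")
  invisible(p)
}

#' Kinetic time scale
#'
#' The reciprocal net amplification rate `1 / (alpha - chi1)` used to
#' nondimensionalize time: nucleation times are reported both in seconds and
#' in units of this scale.
#'
#' @param p a `stenoclot_params` object.
#' @return time scale in seconds.
#' @export
kinetic_time_scale <- function(p) {
  if (p$alpha <= p$chi1) stop("alpha must exceed chi1")
  1 / (p$alpha - p$chi1)
}

#' Dimensionless groups of the model
#'
#' Computes the four dimensionless control parameters: the Reynolds number
#' `Re = V0 Ly / nu`, the relative plaque height `h = H / Ly`, the relative
#' plaque half-width `d_tilde = d / Ly`, and the dimensionless maximal wall
#' permeability
#' `mu2_tilde = mu2 u0 k_u / (Ly (alpha - chi1)^2 theta0)`.
#' The permeability grouping is the unique dimensionless placement of the
#' printed symbols and is recorded in the result's `grouping` attribute.
#'
#' @param p a `stenoclot_params` object.
#' @return An object of class `stenoclot_groups` with fields `Re`,
#'   `mu2_tilde`, `d_tilde`, `h`.
#' @export
#' @examples
#' g <- nondimensionalize(default_parameters(V0 = 6.5))
#' g$Re   # 130
nondimensionalize <- function(p) {
  validate_parameters(p)
  g <- list(
    Re        = p$V0 * p$Ly / p$nu,
    mu2_tilde = p$mu2 * p$u0 * p$k_u / (p$Ly * (p$alpha - p$chi1)^2 * p$theta0),
    d_tilde   = p$d / p$Ly,
    h         = p$H / p$Ly
  )
  attr(g, "grouping") <- "mu2_tilde = mu2*u0*k_u / (Ly*(alpha-chi1)^2*theta0)"
  class(g) <- "stenoclot_groups"
  stopifnot(g$Re >= 0, g$h >= 0, g$h < 1, g$d_tilde > 0, g$mu2_tilde >= 0)
  g
}

#' Dimensional wall permeability from its dimensionless value
#'
#' Inverse of the `mu2_tilde` grouping in [nondimensionalize()]: returns the
#' dimensional maximal permeability `mu2` (cm/s) that maps to the requested
#' dimensionless value, so the pair round-trips to machine precision.
#'
#' @param mu2_tilde dimensionless maximal permeability, `>= 0`.
#' @param p a `stenoclot_params` object (supplies `u0`, `k_u`, `Ly`,
#'   `alpha`, `chi1`, `theta0`).
#' @return permeability in cm/s.
#' @export
dimensional_permeability <- function(mu2_tilde, p) {
  if (any(mu2_tilde < 0)) stop("mu2_tilde must be >= 0")
  if (p$alpha <= p$chi1) stop("alpha must exceed chi1")
  mu2_tilde * p$Ly * (p$alpha - p$chi1)^2 * p$theta0 / (p$u0 * p$k_u)
}

#' Convert a concentration in nM to molar density
#'
#' `1 nM = 1e-9 mol/L = 1e-12 mol/cm^3`. Used inside the filtration
#' resistance closure, where the first fibrin moment multiplies Avogadro's
#' number.
#'
#' @param value concentration in nM, `>= 0` (vectorized).
#' @return molar density in mol/cm^3.
#' @export
concentration_to_molar_density <- function(value) {
  if (any(value < 0)) stop("concentration must be >= 0")
  value * 1e-12
}

#' Configure parameters from dimensionless controls
#'
#' Convenience constructor: takes the four dimensionless groups of the
#' parametric studies and returns a full dimensional parameter set with all
#' other constants at their defaults.
#'
#' @param Re Reynolds number (sets `V0 = Re nu / Ly`).
#' @param h relative plaque height (sets `H = h Ly`).
#' @param d_tilde relative plaque half-width (sets `d = d_tilde Ly`).
#' @param mu2_tilde dimensionless maximal wall permeability (sets `mu2`).
#' @param ... further dimensional overrides passed to [default_parameters()].
#' @return a `stenoclot_params` object.
#' @export
params_from_groups <- function(Re, h = 0, d_tilde = 0.4, mu2_tilde = 9.5, ...) {
  p <- default_parameters(...)
  p$V0 <- Re * p$nu / p$Ly
  p$H <- h * p$Ly
  p$d <- d_tilde * p$Ly
  p$mu2 <- dimensional_permeability(mu2_tilde, p)
  validate_parameters(p)
  p
}

#' @export
print.stenoclot_params <- function(x, ...) {
  g <- nondimensionalize(x)
  cat("Coupled hemodynamics-coagulation model parameters (CGS + nM)\n")
  cat(sprintf("  geometry: Lx = %g, Ly = %g, H = %g, d = %g cm\n",
              x$Lx, x$Ly, x$H, x$d))
  cat(sprintf("  flow:     V0 = %g cm/s, nu = %g cm^2/s  (Re = %g)\n",
              x$V0, x$nu, g$Re))
  cat(sprintf("  wall:     mu1 = %g, mu2 = %g cm/s (mu2_tilde = %.3g), tau1 = %g, tau2 = %g dyn/cm^2\n",
              x$mu1, x$mu2, g$mu2_tilde, x$tau1, x$tau2))
  cat(sprintf("  kinetic time scale 1/(alpha-chi1) = %.4g s\n",
              kinetic_time_scale(x)))
  invisible(x)
}

#' @export
print.stenoclot_groups <- function(x, ...) {
  cat(sprintf("Dimensionless groups: Re = %g, mu2_tilde = %g, d_tilde = %g, h = %g\n",
              x$Re, x$mu2_tilde, x$d_tilde, x$h))
  cat("  ", attr(x, "grouping"), "\n")
  invisible(x)
}
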