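## Local (well-mixed) coagulation kinetics: the six-species reaction terms
## and their implicit integration. Transport is handled separately.

.chem_pars <- function(p, eps = 1e-12, cap_mult = 100) {
  pc <- polymer_constants(p, cap_mult)
  c(p[c("alpha", "theta0", "chi1", "gamma", "beta", "c", "eps_g", "phi0",
        "chi2", "k_g", "k_p", "k_b", "k_r", "k_d", "k_u", "Fg0")],
    list(Nws = pc$Nws, Ne = pc$Ne, alpha0 = pc$alpha0,
         eps_floor = eps, cap_mult = cap_mult))
}

#' Local reaction rates of the coagulation cascade
#'
#' Chemistry-only time derivatives (nM/s) of the six species at one or more
#' states: primary activator `u` (first-order decay), cascade activator
#' `theta` (fed by `u`, autocatalytic with saturation, cleared linearly and
#' by the inhibitor), inhibitor `phi` (theta-driven production with
#' self-acceleration and saturation, linear clearance), fibrinogen `Fg`
#' (consumption by theta, relaxation back to `Fg0`), and the fibrin moments
#' `M1`, `M2` (common polymerization source, pairwise sticking growth of
#' `M2`, chain breakage, fibrinolytic removal).
#'
#' @param state list or data.frame with numeric fields `u`, `theta`, `phi`,
#'   `Fg`, `M1`, `M2` (vectorized).
#' @param p a `stenoclot_params` object.
#' @param eps floor for `M1` inside the breakage term `M2^2/M1` (the term
#'   vanishes in the empty-pool limit).
#' @return list of the six rate vectors, nM/s.
#' @export
#' @examples
#' p <- default_parameters()
#' r <- reaction_rhs(list(u = 0, theta = 0, phi = 0, Fg = p$Fg0,
#'                        M1 = 0, M2 = 0), p)
#' unlist(r)   # the resting state is a fixed point: all zero
reaction_rhs <- function(state, p, eps = 1e-12) {
  u <- state$u; th <- state$theta; ph <- state$phi
  Fg <- state$Fg; M1 <- state$M1; M2 <- state$M2
  if (any(u < 0 | th < 0 | ph < 0 | Fg < 0 | M1 < 0 | M2 < 0))
    stop("reaction_rhs requires a nonnegative state")
  S <- p$k_g * Fg * th
  brk <- ifelse(M1 > eps, p$k_b / 3 * (M2^2 / pmax(M1, eps) - M1), 0)
  r <- list(
    u     = -p$k_d * u,
    theta = p$k_u * u + p$alpha * th^2 / (th + p$theta0) - p$chi1 * th -
            p$gamma * th * ph,
    phi   = p$beta * th * (1 - ph / p$c) * (1 + (ph / p$phi0)^2) - p$chi2 * ph,
    Fg    = -S - p$eps_g * (Fg - p$Fg0),
    M1    = S - p$k_r * M1,
    M2    = S + 4 * p$k_p * (M2 + M1)^2 - brk - p$k_r * M2
  )
  if (any(!vapply(r, function(x) all(is.finite(x)), logical(1))))
    stop("non-finite reaction rate")
  r
}

#' Implicit integration of the local chemistry
#'
#' Advances the six-species kinetics in every cell over `dt` by backward
#' Euler, solved exactly in dependency order (the `theta`--`phi` block by
#' damped Newton, the `M2` balance as a quadratic in closed form). Steps in
#' which the second moment would blow up are subdivided adaptively; the
#' mature-gel cap `M2 <= 100 Nws M1` is projected after every (sub)step.
#'
#' @param state list with cell vectors `u`, `theta`, `phi`, `Fg`, `M1`,
#'   `M2` (nM).
#' @param dt time step, s.
#' @param p a `stenoclot_params` object.
#' @param nsub number of equal chemistry sub-steps within `dt`.
#' @param eps monomer-pool floor, nM.
#' @return updated state list (same shape).
#' @export
integrate_chemistry <- function(state, dt, p, nsub = 1, eps = 1e-12) {
  stopifnot(dt > 0, nsub >= 1)
  pars <- .chem_pars(p, eps)
  out <- cpp_integrate_chemistry(as.numeric(state$u), as.numeric(state$theta),
                                 as.numeric(state$phi), as.numeric(state$Fg),
                                 as.numeric(state$M1), as.numeric(state$M2),
                                 dt, pars, as.integer(nsub))
  out[c("u", "theta", "phi", "Fg", "M1", "M2")]
}

#' Excitation threshold of the cascade activator
#'
#' With the primary activator and the inhibitor absent, the activator
#' balance `alpha theta^2/(theta+theta0) = chi1 theta` has the nontrivial
#' root `theta* = chi1 theta0 / (alpha - chi1)`: initial excursions above
#' it self-amplify, below it decay.
#'
#' @param p a `stenoclot_params` object.
#' @return threshold concentration, nM.
#' @export
theta_threshold <- function(p) p$chi1 * p$theta0 / (p$alpha - p$chi1)

#' Fresh chemical state on a mesh
#'
#' All species zero except fibrinogen at its plasma level `Fg0`.
#'
#' @param ncell number of cells.
#' @param p a `stenoclot_params` object.
#' @return state list of six cell vectors.
#' @export
initial_chem_state <- function(ncell, p) {
  z <- numeric(ncell)
  list(u = z, theta = z, phi = z, Fg = rep(p$Fg0, ncell), M1 = z, M2 = z)
}
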