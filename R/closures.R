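#' Dilute/semidilute crossover chain length
#'
#' The weight-average chain length at which growing fibrin coils, nucleated
#' on heterogeneous centers of number density `n0`, begin to overlap:
#' `Nws = 1 / (n0^(2/3) l0^2 K)`, with `l0` the monomer size and `K` the
#' number of monomers per Kuhn segment. Gelation is declared where `Nw`
#' reaches this value.
#'
#' @param n0 nucleation-center density, cm^-3.
#' @param l0 monomer size, cm (`l0 = v0^(1/3)`).
#' @param K monomers per Kuhn segment.
#' @return dimensionless crossover length.
#' @export
crossover_length <- function(n0, l0, K) {
  stopifnot(n0 > 0, l0 > 0, K > 0)
  1 / (n0^(2 / 3) * l0^2 * K)
}

#' Polymer-physics constants derived from the parameter set
#'
#' Computes `l0 = v0^(1/3)`, the crossover length `Nws`, the entanglement
#' parameter `Ne` (taken equal to `Nws`), the filtration-resistance
#' prefactor `alpha0 = l0^4 K^2 Na^2`, and the mature-gel cap
#' `Nw_cap = 100 Nws`.
#'
#' @param p a `stenoclot_params` object.
#' @param cap_mult mature-gel multiplier (default 100).
#' @return list with `l0`, `Nws`, `Ne`, `alpha0`, `Nw_cap`, `cap_mult`.
#' @export
polymer_constants <- function(p, cap_mult = 100) {
  Na <- 6.02214076e23
  l0 <- p$v0^(1 / 3)
  Nws <- crossover_length(p$n0, l0, p$K)
  stopifnot(Nws > 1)
  list(l0 = l0, Nws = Nws, Ne = Nws, alpha0 = l0^4 * p$K^2 * Na^2,
       Nw_cap = cap_mult * Nws, cap_mult = cap_mult)
}

#' Weight-average chain length from the first two fibrin moments
#'
#' `Nw = M2 / M1`, clamped to `[1, 100 Nws]`. A vanishing fibrin pool
#' (`M1` below the floor `eps`) consists of monomers: `Nw = 1`.
#'
#' @param M1,M2 first and second moments, nM (vectorized).
#' @param Nws crossover length (for the cap).
#' @param eps monomer-pool floor, nM.
#' @param cap_mult mature-gel multiplier.
#' @return dimensionless weight-average length.
#' @export
weight_average_length <- function(M1, M2, Nws, eps = 1e-12, cap_mult = 100) {
  stopifnot(all(M1 >= 0), all(M2 >= 0))
  nw <- ifelse(M1 > eps, M2 / M1, 1)
  pmin(pmax(nw, 1), cap_mult * Nws)
}

#' Moment-dependent polymer diffusivity
#'
#' `Df = D / (Nw (1 + Nw/Ne))`: hydrodynamic-friction scaling `Df ~ 1/Nw`
#' for short chains and the reptation asymptote `Df ~ Ne/Nw^2` for
#' entangled ones.
#'
#' @param Nw weight-average chain length, `>= 1`.
#' @param D monomer diffusivity, cm^2/s.
#' @param Ne entanglement parameter.
#' @return diffusivity, cm^2/s.
#' @export
polymer_diffusivity <- function(Nw, D, Ne) {
  stopifnot(all(Nw >= 1))
  D / (Nw * (1 + Nw / Ne))
}

#' Polymer convective transport coefficient
#'
#' Fraction of the flow velocity at which chains of length `Nw` drift:
#' `bp = 1 / (1 + Nw/Ne)`; unity for dilute chains, vanishing for an
#' entangled gel.
#'
#' @param Nw weight-average chain length, `>= 1`.
#' @param Ne entanglement parameter.
#' @return dimensionless coefficient in (0, 1].
#' @export
transport_coefficient <- function(Nw, Ne) {
  stopifnot(all(Nw >= 1))
  1 / (1 + Nw / Ne)
}

#' Darcy filtration resistance of the fibrin network
#'
#' `alpha_p = alpha0 M1^2 (1 - bp)` with `M1` converted to mol/cm^3,
#' equivalently `(1 - bp) / xi^2` with `xi` the network mesh size. Zero for
#' fully dilute solutions (`bp = 1`) and for a vanishing monomer pool.
#'
#' @param M1 first fibrin moment, nM.
#' @param bp transport coefficient in (0, 1].
#' @param alpha0 prefactor `l0^4 K^2 Na^2`, cm^4 mol^-2.
#' @return filtration resistance, cm^-2.
#' @export
filtration_resistance <- function(M1, bp, alpha0) {
  m1 <- concentration_to_molar_density(M1)
  alpha0 * m1^2 * (1 - bp)
}

#' Network mesh size
#'
#' `xi = 1 / (l0^2 K Na M1)` (cm), the average pore size of the fibrin
#' network; independent of chain length. Used as an independent route to
#' the filtration resistance in consistency checks.
#'
#' @param M1 first fibrin moment, nM.
#' @param l0 monomer size, cm.
#' @param K monomers per Kuhn segment.
#' @return mesh size in cm (Inf at `M1 = 0`).
#' @export
network_mesh_size <- function(M1, l0, K) {
  Na <- 6.02214076e23
  m1 <- concentration_to_molar_density(M1)
  1 / (l0^2 * K * Na * m1)
}

#' Mature-gel cap on the second moment
#'
#' Regions whose chains exceed 100 times the crossover length are treated
#' as mature gel: the second moment is projected onto its maximal value
#' `100 M1 Nws`.
#'
#' @param M1,M2 fibrin moments, nM.
#' @param Nws crossover length.
#' @param cap_mult mature-gel multiplier (default 100).
#' @return capped second moment `M2'`.
#' @export
apply_gel_cap <- function(M1, M2, Nws, cap_mult = 100) {
  stopifnot(all(M1 >= 0), all(M2 >= 0))
  pmin(M2, cap_mult * Nws * M1)
}

#' Evaluate all polymer closure fields from the fibrin moments
#'
#' @param M1,M2 fibrin moments, nM (cell vectors).
#' @param p a `stenoclot_params` object.
#' @param eps monomer-pool floor, nM.
#' @return list with `Nw`, `bp`, `Df`, `alpha_p`, `gel_mask` (cells at the
#'   mature-gel cap) and the `constants` used.
#' @export
closure_fields <- function(M1, M2, p, eps = 1e-12) {
  pc <- polymer_constants(p)
  Nw <- weight_average_length(M1, M2, pc$Nws, eps, pc$cap_mult)
  bp <- transport_coefficient(Nw, pc$Ne)
  list(Nw = Nw, bp = bp,
       Df = polymer_diffusivity(Nw, p$D, pc$Ne),
       alpha_p = filtration_resistance(M1, bp, pc$alpha0),
       gel_mask = as.integer(Nw >= pc$Nw_cap * (1 - 1e-12)),
       constants = pc)
}
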