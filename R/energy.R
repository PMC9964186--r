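#' Boundary energy cost per link between two owners
#'
#' The contact energy of one boundary link. Contacts with the wall (or
#' barrier) sentinel cost zero; contacts between two cells cost the arithmetic
#' mean of the two cells' effective adhesion coefficients, which reduces to
#' the common `lambda_adh` for same-type live contacts and to 0 against
#' fully switched-off partners.
#'
#' @param lattice A [cpm_lattice].
#' @param a,b Cell ids, or 0 for the wall sentinel. Must be distinct owners.
#' @return Energy per boundary link.
#' @export
contact_cost <- function(lattice, a, b) {
  if (a == b) stop("contact_cost requires two distinct owners")
  if (a == 0 || b == 0) return(0)
  eff <- effective_params(lattice)
  ia <- match(a, eff$cell_id)
  ib <- match(b, eff$cell_id)
  if (is.na(ia) || is.na(ib)) stop("unknown cell id")
  (eff$lambda_adh[ia] + eff$lambda_adh[ib]) / 2
}

#' Total energy of a lattice configuration
#'
#' Sums, over all cells with their effective parameters, the quadratic area
#' term \eqn{\lambda_{area}(A_\alpha - A_0)^2}, the quadratic perimeter term
#' \eqn{\lambda_{cont} L_\alpha^2}, and the contact cost of every unordered
#' boundary link between distinct owners (counted exactly once; links to the
#' wall cost zero).
#'
#' @param lattice A [cpm_lattice].
#' @return Scalar energy.
#' @export
total_energy <- function(lattice) {
  if (sum(lattice$cells$area) != free_area(lattice))
    stop("integrity error: registry areas do not match the grid")
  s <- cstate(lattice)
  cpm_total_energy_cpp(lattice$owner, s$type, s$alive, s$area, s$perim,
                       s$tt, s$temperature)
}

#' Energy change of one elementary pixel copy
#'
#' Computes, from the local neighbourhood only, the exact energy difference
#' of copying the owner of `source` into the adjacent pixel `target` (the
#' losing cell's area drops by one, the gaining cell's rises by one).
#'
#' @param lattice A [cpm_lattice].
#' @param source,target 1-based `c(row, col)` pixel coordinates; must be
#'   order-1 neighbours with distinct, non-wall owners.
#' @return Scalar energy difference.
#' @export
delta_energy <- function(lattice, source, target) {
  stopifnot(length(source) == 2, length(target) == 2)
  if (sum(abs(source - target)) != 1)
    stop("source and target must be order-1 neighbours")
  s <- lattice$owner[source[1], source[2]]
  t <- lattice$owner[target[1], target[2]]
  if (s == t) stop("source and target have the same owner")
  if (s == 0) stop("source pixel is wall/barrier")
  if (t == 0) stop("target pixel is wall/barrier")
  st <- cstate(lattice)
  cpm_delta_energy_cpp(lattice$owner, st$type, st$alive, st$area, st$perim,
                       st$tt, st$temperature,
                       source[1], source[2], target[1], target[2])
}

#' Metropolis acceptance rule
#'
#' Accepts with probability 1 when `delta_e <= 0` and with probability
#' `exp(-delta_e / temperature)` otherwise; a single uniform draw from the
#' R random number stream is consumed only in the positive branch.
#'
#' @param delta_e Energy change of the proposed copy.
#' @param temperature Fluctuation temperature, positive.
#' @return Logical.
#' @export
metropolis_accept <- function(delta_e, temperature = 50) {
  if (temperature <= 0) stop("temperature must be positive")
  cpm_metropolis_cpp(delta_e, temperature)
}

#' Advance the lattice by whole Monte Carlo steps
#'
#' One Monte Carlo step (MCS) performs as many elementary copy attempts as
#' there are non-wall pixels. Each attempt draws a uniformly random lattice
#' site and a uniformly random order-1 neighbour, skips if the owners are
#' equal or either is wall/barrier (skips still count as attempts), and
#' otherwise copies the site's owner into the neighbour with Metropolis
#' acceptance. Registry areas and perimeters are updated incrementally.
#'
#' @param lattice A [cpm_lattice].
#' @param n Number of sweeps.
#' @return The updated lattice, with an attribute `sweep_stats` holding
#'   `attempts` and `accepts` counts.
#' @export
mcs_sweep <- function(lattice, n = 1) {
  res <- run_mcs(lattice, n_mcs = n, turnover = FALSE)
  out <- res$lattice
  attr(out, "sweep_stats") <- list(attempts = res$attempts,
                                   accepts = res$accepts)
  out
}
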