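#' Deterministic small fixtures for tests and examples
#'
#' \describe{
#'   \item{two_cell_toy}{Two 2x2 cells side by side in a 2x4 interior
#'     (`lambda_area = 1`, `lambda_cont = 1`, `lambda_adh = -10`, `A0 = 4`):
#'     the classic hand-computable configuration with total energy 108
#'     (two perimeters of 8 links, one shared 2-link edge).}
#'   \item{four_cell_grid}{Four 10x10 cells tiling a 20x20 interior
#'     (`A0 = 100`, otherwise as above): total energy computable by
#'     enumeration (4 x 40^2 contractility - 10 x 40 shared links = 6000).}
#'   \item{mixed_viability}{The four-cell grid with cells 2 and 3 switched
#'     to the dead-cell parameter set.}
#'   \item{moving_front_synthetic}{Not a lattice: a synthetic stage-3 time
#'     series whose invading-type count grows at an exactly known rate,
#'     for exercising the speed pipeline. Returns a list with `series`,
#'     `speed` (widths/MCS), `rho` (cells per squared width) and `L`.}
#' }
#'
#' @param kind Fixture name.
#' @param seed Seed for any randomised detail (currently unused by the
#'   deterministic kinds; kept for interface stability).
#' @return A [cpm_lattice], or a list for `moving_front_synthetic`.
#' @export
make_fixture <- function(kind = c("two_cell_toy", "four_cell_grid",
                                  "mixed_viability",
                                  "moving_front_synthetic"),
                         seed = 1) {
  kind <- match.arg(kind)
  if (kind == "two_cell_toy") {
    owner <- matrix(0L, 4, 6)
    owner[2:3, 2:3] <- 1L
    owner[2:3, 4:5] <- 2L
    types <- list(cell_type(1, lambda_area = 1, lambda_cont = 1,
                            lambda_adh = -10, A0 = 4))
    return(lattice_from_grid(owner, types, type_of = c(1L, 1L)))
  }
  if (kind %in% c("four_cell_grid", "mixed_viability")) {
    owner <- matrix(0L, 22, 22)
    owner[2:11, 2:11] <- 1L
    owner[12:21, 2:11] <- 2L
    owner[2:11, 12:21] <- 3L
    owner[12:21, 12:21] <- 4L
    types <- list(cell_type(1, lambda_area = 1, lambda_cont = 1,
                            lambda_adh = -10, A0 = 100))
    alive <- rep(TRUE, 4)
    if (kind == "mixed_viability") alive[c(2, 3)] <- FALSE
    return(lattice_from_grid(owner, types, type_of = rep(1L, 4),
                             alive = alive))
  }
  # moving_front_synthetic: front sweeping a 2-widths-long domain at an
  # exact speed s, invader at equilibrium density rho (so the invading
  # count grows with slope rho * L * s)
  s <- 0.002
  rho <- 50
  t <- seq(0, 900, by = 10)
  n1 <- 100 + rho * s * t
  n2 <- 100 - rho * s * t
  series <- data.frame(
    mcs = rep(t, 2),
    type_id = rep(c(1L, 2L), each = length(t)),
    live = as.integer(round(c(n1, n2))),
    dead = 0L,
    stage = 3L)
  list(series = series, speed = s, rho = rho, L = 1)
}
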