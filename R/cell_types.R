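#' Mechanical and turnover parameters of a cell type
#'
#' Bundles the per-type parameters of the cellular Potts energy together with
#' the stochastic turnover probabilities. Energies are in the model's
#' dimensionless units; areas in pixels; perimeters in boundary links.
#'
#' @param type_id Small positive integer label; types used in one lattice must
#'   be numbered consecutively from 1.
#' @param lambda_area Area-compressibility coefficient (energy per pixel^2),
#'   non-negative. Penalises deviations of the cell area from `A0`.
#' @param lambda_cont Perimeter-contractility coefficient (energy per
#'   boundary-link^2), non-negative. Represents cortical actomyosin tension.
#' @param lambda_adh Cell-cell boundary energy per boundary link. Must be
#'   non-positive for live cells: negative adhesion energy makes cells
#'   preferentially share boundary with neighbours rather than walls.
#' @param A0 Target area in pixels, non-negative.
#' @param birth_prob Division probability per Monte Carlo step (MCS) for cells
#'   at or above `A0`; in [0, 1].
#' @param death_prob Death probability per MCS for live cells; in [0, 1].
#'
#' @return An object of class `cpm_cell_type`.
#' @examples
#' soft <- cell_type(1, lambda_area = 10, lambda_cont = 0.5, lambda_adh = -10,
#'                   A0 = 100, birth_prob = 0.03, death_prob = 0.001)
#' @export
cell_type <- function(type_id, lambda_area, lambda_cont, lambda_adh, A0,
                      birth_prob = 0, death_prob = 0) {
  stopifnot(length(type_id) == 1, type_id >= 1, type_id == as.integer(type_id))
  if (!is.numeric(lambda_area) || lambda_area < 0)
    stop("lambda_area must be non-negative")
  if (!is.numeric(lambda_cont) || lambda_cont < 0)
    stop("lambda_cont must be non-negative")
  if (!is.numeric(A0) || A0 < 0) stop("A0 must be non-negative")
  if (!is.numeric(lambda_adh) || lambda_adh > 0)
    stop("lambda_adh must be non-positive for live cell types")
  if (birth_prob < 0 || birth_prob > 1)
    stop("birth_prob must be a probability in [0, 1]")
  if (death_prob < 0 || death_prob > 1)
    stop("death_prob must be a probability in [0, 1]")
  structure(
    list(type_id = as.integer(type_id),
         lambda_area = as.numeric(lambda_area),
         lambda_cont = as.numeric(lambda_cont),
         lambda_adh = as.numeric(lambda_adh),
         A0 = as.numeric(A0),
         birth_prob = as.numeric(birth_prob),
         death_prob = as.numeric(death_prob)),
    class = "cpm_cell_type")
}

#' @export
print.cpm_cell_type <- function(x, ...) {
  cat(sprintf(
    "cell type %d: lambda_area=%g lambda_cont=%g lambda_adh=%g A0=%g B=%g M=%g\n",
    x$type_id, x$lambda_area, x$lambda_cont, x$lambda_adh, x$A0,
    x$birth_prob, x$death_prob))
  invisible(x)
}

#' Parameter set in force for a dead cell
#'
#' When a cell dies its contractility and adhesion are switched off, its
#' target area is set to zero, and its area compressibility is raised to 200
#' so that the corpse shrinks under pressure from its neighbours and is
#' extruded from the layer.
#'
#' @return Named numeric vector with elements `lambda_area`, `lambda_cont`,
#'   `lambda_adh`, `A0`.
#' @export
dead_cell_params <- function() {
  c(lambda_area = 200, lambda_cont = 0, lambda_adh = 0, A0 = 0)
}

#' Global Potts dynamics settings
#'
#' @param temperature Fluctuation temperature `T` of the Metropolis rule, the
#'   energy scale at which energy-increasing copies are accepted. Must be
#'   positive; the default 50 yields realistic cell shapes in both the soft
#'   (low contractility) and hard (high contractility) regimes.
#' @param neighborhood_order Neighbourhood used both for copy-candidate
#'   selection and for boundary-link counting. Only order 1 (the 4-pixel von
#'   Neumann neighbourhood) is supported.
#'
#' @return An object of class `cpm_potts_config`.
#' @export
potts_config <- function(temperature = 50, neighborhood_order = 1) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive")
  if (neighborhood_order != 1)
    stop("only neighborhood_order = 1 is supported")
  structure(list(temperature = as.numeric(temperature),
                 neighborhood_order = 1L),
            class = "cpm_potts_config")
}

# per-type parameter matrix handed to the compiled core; rows are type ids
# 1..n in order, columns lambda_area, lambda_cont, lambda_adh, A0, B, M
type_table <- function(types) {
  ids <- vapply(types, function(t) t$type_id, integer(1))
  if (!identical(sort(ids), seq_along(ids)))
    stop("cell types must be numbered consecutively from 1")
  types <- types[order(ids)]
  m <- t(vapply(types, function(t) {
    c(t$lambda_area, t$lambda_cont, t$lambda_adh, t$A0,
      t$birth_prob, t$death_prob)
  }, numeric(6)))
  colnames(m) <- c("lambda_area", "lambda_cont", "lambda_adh", "A0", "B", "M")
  m
}
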