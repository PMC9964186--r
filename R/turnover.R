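#' Sample stochastic death events for one MCS
#'
#' Each live cell is independently selected with its type's per-MCS death
#' probability `M`; dead cells are never selected. One uniform draw is
#' consumed per live cell, in registry-id order, so runs are reproducible.
#'
#' @param lattice A [cpm_lattice].
#' @return Integer vector of cell ids selected to die (possibly empty).
#' @export
sample_deaths <- function(lattice) {
  s <- cstate(lattice)
  cpm_sample_deaths_cpp(lattice$owner, s$type, s$alive, s$area, s$perim,
                        s$tt, s$temperature)
}

#' Switch cells to the dead-cell parameter set
#'
#' Marks live cells dead: from then on their effective parameters are the
#' [dead_cell_params()] switch (contractility and adhesion zero, target area
#' zero, area compressibility 200), so they shrink over subsequent sweeps
#' until extruded. Type and cell id are preserved for bookkeeping. Marking an
#' already dead cell is a contract violation, not a no-op.
#'
#' @param lattice A [cpm_lattice].
#' @param cell_ids Ids of live cells to mark.
#' @return The updated lattice.
#' @export
mark_dead <- function(lattice, cell_ids) {
  i <- match(cell_ids, lattice$cells$cell_id)
  if (anyNA(i)) stop("unknown cell id")
  if (any(!lattice$cells$alive[i])) stop("cell is already dead")
  lattice$cells$alive[i] <- FALSE
  lattice
}

#' Sample stochastic division events for one MCS
#'
#' Only live cells whose current area has reached their type's target area
#' (`A >= A0`) are eligible; each eligible cell is independently selected
#' with its type's per-MCS division probability `B`. One uniform draw is
#' consumed per eligible cell, in registry-id order.
#'
#' @param lattice A [cpm_lattice].
#' @return Integer vector of cell ids selected to divide (possibly empty).
#' @export
sample_divisions <- function(lattice) {
  s <- cstate(lattice)
  cpm_sample_divisions_cpp(lattice$owner, s$type, s$alive, s$area, s$perim,
                           s$tt, s$temperature)
}

#' Divide a cell into two daughters
#'
#' The cell's pixel set is partitioned by a straight line through its area
#' centroid at a uniformly random orientation; one side keeps the parent id,
#' the other receives a fresh id with the parent's type parameters. Both
#' daughters are alive with the type's target area, their areas sum exactly
#' to the parent's, and they then grow back toward `A0` under sweeps. If a
#' random cut leaves one side empty it is redrawn (up to 8 retries), then a
#' pixel-count median split along the longer bounding-box axis is used.
#' Cells of fewer than 2 pixels are not divided (a warning is raised).
#'
#' @param lattice A [cpm_lattice].
#' @param cell_id Id of a live cell.
#' @param mcs Time stamp recorded in the event log.
#' @return List with elements `lattice` (updated) and `daughters` (the pair
#'   of daughter ids, parent id first; `NULL` if the division was skipped).
#' @export
divide_cell <- function(lattice, cell_id, mcs = 0L) {
  i <- match(cell_id, lattice$cells$cell_id)
  if (is.na(i)) stop("unknown cell id")
  if (!lattice$cells$alive[i]) stop("cannot divide a dead cell")
  if (lattice$cells$area[i] < 2) {
    warning(sprintf("cell %d has area < 2; division skipped", cell_id))
    return(list(lattice = lattice, daughters = NULL))
  }
  s <- cstate(lattice)
  res <- cpm_divide_cell_cpp(lattice$owner, s$type, s$alive, s$area, s$perim,
                             s$tt, s$temperature, cell_id, as.integer(mcs))
  list(lattice = update_lattice(lattice, res),
       daughters = res$daughters)
}

#' Remove vanished cells from the registry
#'
#' Deletes every registry entry whose area has reached zero; the grid is
#' untouched since such cells own no pixels. A live cell with zero area is an
#' integrity error.
#'
#' @param lattice A [cpm_lattice].
#' @return List with elements `lattice` and `removed` (ids removed).
#' @export
purge_vanished <- function(lattice) {
  gone <- lattice$cells$area == 0
  if (any(gone & lattice$cells$alive))
    stop("integrity error: live cell with zero area")
  removed <- lattice$cells$cell_id[gone]
  lattice$cells <- lattice$cells[!gone, , drop = FALSE]
  rownames(lattice$cells) <- NULL
  list(lattice = lattice, removed = removed)
}

#' Run Monte Carlo steps with optional turnover
#'
#' The workhorse loop, executed in compiled code. Each MCS performs, in
#' fixed order: one Metropolis sweep; then (if `turnover`) death draws,
#' division draws and divisions, and removal of vanished cells. Per-MCS
#' live/dead counts by type are recorded, together with an event log.
#'
#' @param lattice A [cpm_lattice].
#' @param n_mcs Number of Monte Carlo steps.
#' @param turnover Enable division/death events.
#' @param stop_extinct Stop early as soon as any cell type has zero live
#'   cells (checked after each MCS).
#' @param mcs0 Time offset added to recorded MCS stamps.
#' @return List with elements `lattice`, `series` (data frame `mcs`,
#'   `type_id`, `live`, `dead`), `events` (data frame `mcs`, `event`,
#'   `cell_id`, `daughter1`, `daughter2`), `attempts`, `accepts`, `n_done`.
#' @export
run_mcs <- function(lattice, n_mcs, turnover = TRUE, stop_extinct = FALSE,
                    mcs0 = 0L) {
  stopifnot(n_mcs >= 1)
  s <- cstate(lattice)
  res <- cpm_run_cpp(lattice$owner, s$type, s$alive, s$area, s$perim,
                     s$tt, s$temperature, as.integer(n_mcs),
                     isTRUE(turnover), isTRUE(stop_extinct),
                     as.integer(mcs0))
  ntypes <- nrow(s$tt)
  n_done <- res$n_done
  series <- data.frame(
    mcs = rep(mcs0 + seq_len(n_done), times = ntypes),
    type_id = rep(seq_len(ntypes), each = n_done),
    live = as.integer(res$live),
    dead = as.integer(res$dead))
  ev <- res$events
  events <- data.frame(
    mcs = as.integer(ev[, "mcs"]),
    event = c("death", "division", "removal", "division_skipped")[ev[, "code"]],
    cell_id = as.integer(ev[, "cell_id"]),
    daughter1 = as.integer(ev[, "d1"]),
    daughter2 = as.integer(ev[, "d2"]))
  list(lattice = update_lattice(lattice, res),
       series = series, events = events,
       attempts = res$attempts, accepts = res$accepts, n_done = n_done)
}
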