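#' Lattice state of a cellular Potts simulation
#'
#' A `cpm_lattice` is a list with components:
#' \describe{
#'   \item{owner}{integer matrix (rows = y, columns = x) of cell ids;
#'     0 is the wall/barrier sentinel. Stored with a one-pixel wall ring so
#'     cells never touch the matrix edge.}
#'   \item{wall}{logical matrix marking immutable wall pixels.}
#'   \item{barrier}{logical matrix marking the removable separating strip;
#'     barrier pixels behave exactly like walls until removed.}
#'   \item{cells}{the registry: data frame with columns `cell_id`, `type_id`,
#'     `alive`, `area`, `perimeter`. `type_id` 0 marks the transient
#'     placeholder created when the barrier is removed.}
#'   \item{types}{list of [cell_type()] parameter sets.}
#'   \item{config}{a [potts_config()].}
#' }
#'
#' The x axis (columns) is the invasion axis in two-compartment runs.
#' Coordinates given to functions such as [delta_energy()] are 1-based
#' `c(row, col)` pairs into the full owner matrix.
#'
#' @name cpm_lattice
NULL

new_lattice <- function(owner, wall, barrier, cells, types, config) {
  structure(list(owner = owner, wall = wall, barrier = barrier,
                 cells = cells, types = types, config = config),
            class = "cpm_lattice")
}

#' Build a lattice from an owner grid
#'
#' Constructs a full lattice state from an integer owner matrix: every pixel
#' with value 0 is treated as wall, every positive value as a cell id. Areas
#' and perimeters are recounted from the grid.
#'
#' @param owner Integer matrix of owner ids (0 = wall).
#' @param types List of [cell_type()] objects covering every `type_id` used.
#' @param type_of Integer vector assigning a type to each cell id present
#'   (indexed by cell id). Defaults to type 1 for all cells.
#' @param alive Logical vector indexed by cell id; defaults to all alive.
#' @param config A [potts_config()].
#' @return A [cpm_lattice] object.
#' @export
lattice_from_grid <- function(owner, types, type_of = NULL, alive = NULL,
                              config = potts_config()) {
  storage.mode(owner) <- "integer"
  ids <- sort(unique(owner[owner > 0]))
  if (!length(ids)) stop("owner grid contains no cells")
  max_id <- max(ids)
  if (is.null(type_of)) type_of <- rep(1L, max_id)
  if (is.null(alive)) alive <- rep(TRUE, max_id)
  rc <- cpm_recount_cpp(owner, max_id)
  cells <- data.frame(cell_id = ids,
                      type_id = as.integer(type_of[ids]),
                      alive = as.logical(alive[ids]),
                      area = as.integer(rc$area[ids]),
                      perimeter = as.integer(rc$perim[ids]))
  lat <- new_lattice(owner, owner == 0L,
                     matrix(FALSE, nrow(owner), ncol(owner)),
                     cells, types, config)
  lattice_check(lat)
  lat
}

#' Check lattice integrity
#'
#' Verifies the invariants that every non-wall, non-barrier pixel is owned by
#' exactly one registered cell, that registry areas and perimeters agree with
#' a full recount from the grid, and that registry areas sum to the free pixel
#' count. Errors on violation.
#'
#' @param lattice A [cpm_lattice].
#' @return Invisibly `TRUE`.
#' @export
lattice_check <- function(lattice) {
  o <- lattice$owner
  blocked <- lattice$wall | lattice$barrier
  if (any(o[blocked] != 0L)) stop("wall/barrier pixels must have owner 0")
  if (any(o[!blocked] == 0L)) stop("free pixels must be owned by a cell")
  free_ids <- unique(o[o > 0])
  if (!all(free_ids %in% lattice$cells$cell_id))
    stop("grid refers to unregistered cell ids")
  if (!all(lattice$cells$cell_id %in% free_ids))
    stop("registry contains cells owning no pixels")
  max_id <- max(lattice$cells$cell_id)
  rc <- cpm_recount_cpp(o, max_id)
  i <- lattice$cells$cell_id
  if (!all(lattice$cells$area == rc$area[i]))
    stop("registry areas disagree with grid recount")
  if (!all(lattice$cells$perimeter == rc$perim[i]))
    stop("registry perimeters disagree with grid recount")
  if (sum(lattice$cells$area) != sum(!blocked))
    stop("areas do not sum to the free pixel count")
  invisible(TRUE)
}

#' Effective parameters currently in force for each cell
#'
#' Live cells carry their type's parameters; dead cells (and the barrier
#' placeholder) carry the [dead_cell_params()] switch.
#'
#' @param lattice A [cpm_lattice].
#' @return Data frame with one row per registry entry: `cell_id`, `type_id`,
#'   `alive`, `lambda_area`, `lambda_cont`, `lambda_adh`, `A0`.
#' @export
effective_params <- function(lattice) {
  tt <- type_table(lattice$types)
  cells <- lattice$cells
  dp <- dead_cell_params()
  out <- data.frame(cell_id = cells$cell_id, type_id = cells$type_id,
                    alive = cells$alive,
                    lambda_area = dp[["lambda_area"]],
                    lambda_cont = dp[["lambda_cont"]],
                    lambda_adh = dp[["lambda_adh"]],
                    A0 = dp[["A0"]])
  liv <- cells$alive
  out$lambda_area[liv] <- tt[cells$type_id[liv], "lambda_area"]
  out$lambda_cont[liv] <- tt[cells$type_id[liv], "lambda_cont"]
  out$lambda_adh[liv] <- tt[cells$type_id[liv], "lambda_adh"]
  out$A0[liv] <- tt[cells$type_id[liv], "A0"]
  out
}

# pack the lattice into flat id-indexed vectors for the compiled core
cstate <- function(lattice) {
  cells <- lattice$cells
  max_id <- max(cells$cell_id)
  type <- integer(max_id)
  alive <- rep(-1L, max_id)
  area <- numeric(max_id)
  perim <- numeric(max_id)
  i <- cells$cell_id
  type[i] <- cells$type_id
  alive[i] <- ifelse(cells$alive, 1L, 0L)
  area[i] <- cells$area
  perim[i] <- cells$perimeter
  list(type = type, alive = alive, area = area, perim = perim,
       tt = type_table(lattice$types),
       temperature = lattice$config$temperature)
}

# rebuild the R-side lattice from what the compiled core returned
update_lattice <- function(lattice, res) {
  keep <- which(res$alive >= 0L)
  lattice$owner <- res$owner
  lattice$cells <- data.frame(cell_id = keep,
                              type_id = res$type[keep],
                              alive = res$alive[keep] == 1L,
                              area = as.integer(res$area[keep]),
                              perimeter = as.integer(res$perim[keep]))
  lattice
}

#' Number of free (cell-owned) pixels
#' @param lattice A [cpm_lattice].
#' @return Integer count of non-wall, non-barrier pixels.
#' @export
free_area <- function(lattice) sum(lattice$owner != 0L)

#' @export
print.cpm_lattice <- function(x, ...) {
  cat(sprintf("cpm_lattice: %d x %d grid, %d cells (%d live, %d dead), T=%g\n",
              nrow(x$owner), ncol(x$owner), nrow(x$cells),
              sum(x$cells$alive), sum(!x$cells$alive),
              x$config$temperature))
  invisible(x)
}

#' Write and read lattice snapshots
#'
#' The owner grid is written as whitespace-separated integers (one row per
#' lattice row, wall sentinel 0) and the registry as a CSV sidecar with
#' columns `cell_id`, `type_id`, `alive`, `area`, `perimeter`.
#'
#' @param lattice A [cpm_lattice].
#' @param path Base path; `<path>.grid` and `<path>.cells.csv` are written.
#' @return Invisibly the two file paths.
#' @export
write_lattice <- function(lattice, path) {
  grid_file <- paste0(path, ".grid")
  cells_file <- paste0(path, ".cells.csv")
  write.table(lattice$owner, grid_file, row.names = FALSE, col.names = FALSE)
  write.csv(lattice$cells, cells_file, row.names = FALSE)
  invisible(c(grid_file, cells_file))
}

#' @rdname write_lattice
#' @param types List of [cell_type()] objects for the reconstructed lattice.
#' @param config A [potts_config()].
#' @export
read_lattice <- function(path, types, config = potts_config()) {
  grid_file <- paste0(path, ".grid")
  cells_file <- paste0(path, ".cells.csv")
  owner <- as.matrix(read.table(grid_file))
  dimnames(owner) <- NULL
  storage.mode(owner) <- "integer"
  cells <- read.csv(cells_file)
  max_id <- max(cells$cell_id)
  type_of <- integer(max_id)
  alive <- logical(max_id)
  type_of[cells$cell_id] <- cells$type_id
  alive[cells$cell_id] <- cells$alive
  lattice_from_grid(owner, types, type_of = type_of, alive = alive,
                    config = config)
}
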