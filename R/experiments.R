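#' Configuration of a simulation experiment
#'
#' Collects the lattice geometry, cell types, stage schedule and stationarity
#' settings of the two protocols. Dimensions refer to the interior (the
#' cell-bearing region); a one-pixel wall ring is added around it.
#'
#' For two-compartment runs the interior consists of two square-tileable
#' halves separated by a full-height barrier strip of width `barrier_width`
#' (default: one cell side), so `width = 2 * half + barrier_width` with each
#' half a multiple of `initial_cell_side`.
#'
#' @param width,height Interior dimensions in pixels.
#' @param cell_types List of [cell_type()] objects (one for homogeneous runs,
#'   two for invasion runs; type 1 starts on the left).
#' @param initial_cell_side Side of the initial square cells in pixels; the
#'   default 10 gives initial areas of 100 pixels.
#' @param temperature Fluctuation temperature.
#' @param stage1_mcs Sweeps of stage 1 (mechanical relaxation, turnover off,
#'   barrier on).
#' @param stage2_max_mcs Cap for stage 2 (turnover on, barrier on, run until
#'   each side's total cell count is stationary).
#' @param stage3_max_mcs Cap for stage 3 (barrier removed, run until one type
#'   goes extinct).
#' @param window,tol Stationarity criterion: two consecutive windows of
#'   `window` MCS whose mean total counts differ by less than relative `tol`.
#' @param max_mcs Cap for homogeneous equilibrium runs.
#' @param measure_mcs Extra MCS run after stationarity is detected, over
#'   which summary statistics are averaged.
#' @param barrier_width Width in pixels of the separating strip.
#' @param seed Optional RNG seed applied at the start of a run.
#' @return An object of class `cpm_experiment_config` (a validated list).
#' @export
experiment_config <- function(width = 200, height = 200,
                              cell_types = list(cell_type(
                                1, lambda_area = 10, lambda_cont = 0.5,
                                lambda_adh = -10, A0 = 100,
                                birth_prob = 0.03, death_prob = 0.001)),
                              initial_cell_side = 10,
                              temperature = 50,
                              stage1_mcs = 500,
                              stage2_max_mcs = 3000,
                              stage3_max_mcs = 50000,
                              window = 500,
                              tol = 0.02,
                              max_mcs = 5000,
                              measure_mcs = 1500,
                              barrier_width = NULL,
                              seed = NULL) {
  if (is.null(barrier_width)) barrier_width <- initial_cell_side
  stopifnot(width >= initial_cell_side, height >= initial_cell_side,
            initial_cell_side >= 1, stage1_mcs >= 1, stage2_max_mcs >= 1,
            stage3_max_mcs >= 1, window >= 2, tol > 0, max_mcs >= 1,
            measure_mcs >= 0, barrier_width >= 1)
  if (!length(cell_types) || !all(vapply(cell_types, inherits, logical(1),
                                         "cpm_cell_type")))
    stop("cell_types must be a non-empty list of cell_type() objects")
  structure(list(width = as.integer(width), height = as.integer(height),
                 cell_types = cell_types,
                 initial_cell_side = as.integer(initial_cell_side),
                 temperature = temperature,
                 stage1_mcs = as.integer(stage1_mcs),
                 stage2_max_mcs = as.integer(stage2_max_mcs),
                 stage3_max_mcs = as.integer(stage3_max_mcs),
                 window = as.integer(window), tol = tol,
                 max_mcs = as.integer(max_mcs),
                 measure_mcs = as.integer(measure_mcs),
                 barrier_width = as.integer(barrier_width),
                 seed = seed),
            class = "cpm_experiment_config")
}

# tile a block of the interior with square cells, assigning consecutive ids
tile_block <- function(owner, rows, cols, side, first_id) {
  nr <- length(rows) %/% side
  nc <- length(cols) %/% side
  id <- first_id
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      rr <- rows[((i - 1) * side + 1):(i * side)]
      cc <- cols[((j - 1) * side + 1):(j * side)]
      owner[rr, cc] <- id
      id <- id + 1L
    }
  }
  list(owner = owner, next_id = id)
}

#' Build a homogeneous square-tiled monolayer
#'
#' Tiles the interior with square cells of side `initial_cell_side`, each at
#' its target area, and surrounds the domain with a one-pixel wall ring so
#' cells never stick to the lattice boundary. A 200x200 interior with side-10
#' cells yields the standard 400-cell initial condition.
#'
#' @param config An [experiment_config()] with a single cell type.
#' @return A [cpm_lattice].
#' @export
build_monolayer <- function(config) {
  if (length(config$cell_types) != 1)
    stop("build_monolayer requires exactly one cell type")
  side <- config$initial_cell_side
  if (config$width %% side != 0 || config$height %% side != 0)
    stop("interior dimensions must be multiples of initial_cell_side")
  H <- config$height + 2L
  W <- config$width + 2L
  owner <- matrix(0L, H, W)
  tiled <- tile_block(owner, 2:(H - 1), 2:(W - 1), side, 1L)
  lattice_from_grid(tiled$owner, config$cell_types,
                    type_of = rep(1L, tiled$next_id - 1L),
                    config = potts_config(config$temperature))
}

#' Build a two-compartment monolayer separated by a barrier
#'
#' The left half is tiled with type 1, the right half with type 2, and a
#' full-height barrier strip of `barrier_width` pixels sits between them.
#' Barrier pixels behave exactly like walls (zero contact energy, never
#' copied) until [remove_barrier()] is called.
#'
#' @param config An [experiment_config()] with exactly two cell types and
#'   `width = 2 * half + barrier_width`, each half a multiple of
#'   `initial_cell_side`.
#' @return A [cpm_lattice] with its `barrier` mask set.
#' @export
build_two_compartment <- function(config) {
  if (length(config$cell_types) != 2)
    stop("build_two_compartment requires exactly two cell types")
  side <- config$initial_cell_side
  bw <- config$barrier_width
  half <- (config$width - bw) / 2
  if (half <= 0 || half != as.integer(half) || half %% side != 0)
    stop("width minus barrier_width must split into two halves, ",
         "each a multiple of initial_cell_side")
  if (config$height %% side != 0)
    stop("height must be a multiple of initial_cell_side")
  H <- config$height + 2L
  W <- config$width + 2L
  owner <- matrix(0L, H, W)
  rows <- 2:(H - 1)
  left_cols <- 2:(half + 1)
  right_cols <- (half + bw + 2):(W - 1)
  t1 <- tile_block(owner, rows, left_cols, side, 1L)
  t2 <- tile_block(t1$owner, rows, right_cols, side, t1$next_id)
  n1 <- t1$next_id - 1L
  n2 <- t2$next_id - t1$next_id
  type_of <- rep(c(1L, 2L), c(n1, n2))
  lat <- lattice_from_grid(t2$owner, config$cell_types, type_of = type_of,
                           config = potts_config(config$temperature))
  lat$barrier[rows, (half + 2):(half + bw + 1)] <- TRUE
  lat$wall <- lat$owner == 0L & !lat$barrier
  lattice_check(lat)
  lat
}

#' Remove the separating barrier
#'
#' The barrier strip becomes ordinary free pixels owned by a transient
#' placeholder "cell" with the dead-cell parameter set (zero target area,
#' strong compressibility), so the neighbouring cells on both sides claim the
#' strip through ordinary Metropolis dynamics within a few MCS, without any
#' ad hoc pixel assignment that could bias the front.
#'
#' @param lattice A [cpm_lattice] with a barrier.
#' @return The updated lattice.
#' @export
remove_barrier <- function(lattice) {
  px <- which(lattice$barrier)
  if (!length(px)) stop("lattice has no barrier")
  nid <- max(lattice$cells$cell_id) + 1L
  lattice$owner[px] <- nid
  lattice$barrier[] <- FALSE
  rc <- cpm_recount_cpp(lattice$owner, nid)
  lattice$cells <- rbind(lattice$cells,
                         data.frame(cell_id = nid, type_id = 0L,
                                    alive = FALSE,
                                    area = as.integer(rc$area[nid]),
                                    perimeter = as.integer(rc$perim[nid])))
  rownames(lattice$cells) <- NULL
  lattice
}

# earliest MCS at which two consecutive sliding windows of the total count
# have relative mean difference below tol; NA if never
detect_stationarity <- function(mcs, total, window, tol) {
  if (length(mcs) < 2 * window) return(NA_integer_)
  cs0 <- c(0, cumsum(total))
  n <- length(total)
  ends <- (2 * window):n
  m2 <- (cs0[ends + 1] - cs0[ends - window + 1]) / window
  m1 <- (cs0[ends - window + 1] - cs0[ends - 2 * window + 1]) / window
  rel <- abs(m2 - m1) / pmax(m1, 1)
  hit <- which(rel <= tol)
  if (!length(hit)) return(NA_integer_)
  mcs[ends[hit[1]] - window]
}

#' Run a single-type monolayer to homeostatic equilibrium
#'
#' Builds the monolayer and runs sweeps with turnover until the total cell
#' count is stationary (two consecutive windows of `window` MCS whose means
#' differ by less than relative `tol`), then continues for `measure_mcs`
#' further MCS over which summary statistics are averaged. If the `max_mcs`
#' cap is reached without stationarity the result is flagged non-stationary
#' and statistics are computed over the final window.
#'
#' @param config An [experiment_config()] with a single cell type.
#' @return An object of class `cpm_equilibrium`: list with `series` (per-MCS
#'   live/dead counts), `lattice`, `events`, `stationary` (logical),
#'   `stationary_from` (MCS), `summary` (means and SDs of live, dead and
#'   total counts and the dead fraction over the measurement window).
#' @export
run_homogeneous_equilibrium <- function(config) {
  if (length(config$cell_types) != 1)
    stop("run_homogeneous_equilibrium requires a single cell type")
  ct <- config$cell_types[[1]]
  if (ct$birth_prob == 0 && ct$death_prob > 0)
    warning("B = 0 with M > 0: the population will go extinct")
  if (!is.null(config$seed)) set.seed(config$seed)
  lat <- build_monolayer(config)
  w <- config$window
  series <- NULL
  events <- NULL
  mcs <- 0L
  stat_from <- NA_integer_
  while (mcs < config$max_mcs) {
    chunk <- min(w, config$max_mcs - mcs)
    r <- run_mcs(lat, chunk, turnover = TRUE, mcs0 = mcs)
    lat <- r$lattice
    series <- rbind(series, r$series)
    events <- rbind(events, r$events)
    mcs <- mcs + r$n_done
    tot <- series$live + series$dead
    stat_from <- detect_stationarity(series$mcs, tot, w, config$tol)
    if (!is.na(stat_from)) break
    if (nrow(lat$cells) == 0 || all(!lat$cells$alive)) break
  }
  stationary <- !is.na(stat_from)
  if (stationary && config$measure_mcs > 0 && sum(lat$cells$alive) > 0) {
    r <- run_mcs(lat, config$measure_mcs, turnover = TRUE, mcs0 = mcs)
    lat <- r$lattice
    series <- rbind(series, r$series)
    events <- rbind(events, r$events)
    mcs <- mcs + r$n_done
  }
  from <- if (stationary) stat_from else max(1L, mcs - w + 1L)
  win <- series$mcs >= from
  tot <- series$live + series$dead
  summary <- data.frame(
    live_mean = mean(series$live[win]), live_sd = sd(series$live[win]),
    dead_mean = mean(series$dead[win]), dead_sd = sd(series$dead[win]),
    total_mean = mean(tot[win]), total_sd = sd(tot[win]),
    dead_fraction = mean(series$dead[win] / pmax(tot[win], 1)))
  series$stage <- 1L
  attr(series, "stationary") <- stationary
  structure(list(series = series, lattice = lat, events = events,
                 stationary = stationary, stationary_from = from,
                 summary = summary, config = config),
            class = "cpm_equilibrium")
}

#' @export
print.cpm_equilibrium <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "cpm_equilibrium: %s (from MCS %d)\n",
    "  live %.1f +/- %.1f, dead %.1f +/- %.1f, total %.1f +/- %.1f\n",
    "  dead fraction %.3f\n"),
    if (x$stationary) "stationary" else "NON-STATIONARY (cap reached)",
    x$stationary_from, s$live_mean, s$live_sd, s$dead_mean, s$dead_sd,
    s$total_mean, s$total_sd, s$dead_fraction))
  invisible(x)
}

#' Run the three-stage two-type invasion protocol
#'
#' Stage 1: turnover off, barrier on, `stage1_mcs` sweeps so both types reach
#' their mechanical equilibrium shapes. Stage 2: turnover on, barrier on,
#' until each type's total count is stationary (or `stage2_max_mcs`). Stage
#' 3: the barrier is removed and the run continues until one type has no
#' live cells left, or `stage3_max_mcs` is reached (in which case the result
#' is flagged incomplete).
#'
#' @param config An [experiment_config()] with two cell types.
#' @return An object of class `cpm_invasion`: list with `series` (per-MCS
#'   live/dead counts per type with a `stage` column), `events`, `lattice`,
#'   `stages` (named MCS marks: `stage1_end`, `barrier_removed`, `end`),
#'   `winner` (type id or NA, from [invasion_direction()]), `complete`
#'   (logical: a type went extinct before the cap).
#' @export
run_invasion <- function(config) {
  if (length(config$cell_types) != 2)
    stop("run_invasion requires exactly two cell types")
  if (!is.null(config$seed)) set.seed(config$seed)
  lat <- build_two_compartment(config)

  r1 <- run_mcs(lat, config$stage1_mcs, turnover = FALSE, mcs0 = 0L)
  lat <- r1$lattice
  s1 <- r1$series; s1$stage <- 1L
  mcs <- r1$n_done

  w <- config$window
  s2 <- NULL
  events <- NULL
  stage2_start <- mcs
  repeat {
    done2 <- mcs - stage2_start
    if (done2 >= config$stage2_max_mcs) break
    chunk <- min(w, config$stage2_max_mcs - done2)
    r <- run_mcs(lat, chunk, turnover = TRUE, mcs0 = mcs)
    lat <- r$lattice
    rs <- r$series; rs$stage <- 2L
    s2 <- rbind(s2, rs)
    events <- rbind(events, r$events)
    mcs <- mcs + r$n_done
    # per-side stationarity, assessed independently for each type
    ok <- vapply(unique(s2$type_id), function(ty) {
      st <- s2[s2$type_id == ty, ]
      !is.na(detect_stationarity(st$mcs, st$live + st$dead, w, config$tol))
    }, logical(1))
    if (all(ok)) break
  }
  barrier_removed <- mcs

  lat <- remove_barrier(lat)
  r3 <- run_mcs(lat, config$stage3_max_mcs, turnover = TRUE,
                stop_extinct = TRUE, mcs0 = mcs)
  lat <- r3$lattice
  s3 <- r3$series; s3$stage <- 3L
  events <- rbind(events, r3$events)
  mcs <- mcs + r3$n_done

  series <- rbind(s1, s2, s3)
  attr(series, "stages") <- c(stage1_end = config$stage1_mcs,
                              barrier_removed = barrier_removed, end = mcs)
  final_live <- tapply(s3$live[s3$mcs == max(s3$mcs)],
                       s3$type_id[s3$mcs == max(s3$mcs)], sum)
  complete <- any(final_live == 0)
  winner <- invasion_direction(series)
  structure(list(series = series, events = events, lattice = lat,
                 stages = c(stage1_end = config$stage1_mcs,
                            barrier_removed = barrier_removed, end = mcs),
                 winner = winner, complete = complete, config = config),
            class = "cpm_invasion")
}

#' @export
print.cpm_invasion <- function(x, ...) {
  cat(sprintf(paste0(
    "cpm_invasion: barrier removed at MCS %d, ended at MCS %d (%s)\n",
    "  winner: %s\n"),
    x$stages[["barrier_removed"]], x$stages[["end"]],
    if (x$complete) "extinction" else "cap reached, incomplete",
    if (is.na(x$winner)) "none detected" else paste("type", x$winner)))
  invisible(x)
}
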