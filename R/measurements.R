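#' Time-averaged dead-cell fraction
#'
#' Fraction dead/(dead+live), aggregated over types per MCS and averaged over
#' a time window. In a biologically functional epithelium this fraction stays
#' well below 10 percent for death rates up to about 0.003 per MCS.
#'
#' @param series Time-series data frame with columns `mcs`, `type_id`,
#'   `live`, `dead` (as produced by [run_mcs()] and the protocols).
#' @param window Length-2 numeric `c(from, to)` in MCS (inclusive); `NULL`
#'   uses the whole series.
#' @return Fraction in [0, 1].
#' @export
dead_fraction <- function(series, window = NULL) {
  s <- series
  if (!is.null(window)) s <- s[s$mcs >= window[1] & s$mcs <= window[2], ]
  if (!nrow(s)) stop("empty window")
  live <- tapply(s$live, s$mcs, sum)
  dead <- tapply(s$dead, s$mcs, sum)
  mean(dead / pmax(dead + live, 1))
}

#' Equilibrium cell density
#'
#' Mean live-cell count per unit domain area over a stationary window. By
#' convention the width of the domain perpendicular to the invasion axis is
#' the length unit (L = 1), so `domain_area` is expressed in squared widths
#' and the density in cells per squared width; invasion speeds derived from
#' it are in widths per MCS. Only live cells are counted, dead cells being
#' transient.
#'
#' @param series Time-series data frame (see [dead_fraction()]).
#' @param domain_area Domain area in units where the perpendicular width is 1
#'   (e.g. 1 for a square domain, 2 for a 2:1 domain).
#' @param window Length-2 MCS window; `NULL` for the whole series.
#' @return Density in cells per squared width.
#' @export
equilibrium_density <- function(series, domain_area, window = NULL) {
  stopifnot(domain_area > 0)
  if (isFALSE(attr(series, "stationary")))
    warning("series is flagged non-stationary")
  s <- series
  if (!is.null(window)) s <- s[s$mcs >= window[1] & s$mcs <= window[2], ]
  if (!nrow(s)) stop("empty window")
  live <- tapply(s$live, s$mcs, sum)
  mean(live) / domain_area
}

# default stage-3 fit window: from barrier removal to 80% of the loser's
# extinction time (or the end of the data if no extinction)
auto_fit_window <- function(series, type_id) {
  s3 <- series[series$stage == 3, ]
  if (!nrow(s3)) stop("series has no stage-3 data")
  start <- min(s3$mcs)
  other <- s3[s3$type_id != type_id, ]
  ext <- other$mcs[other$live == 0]
  end <- if (length(ext)) start + 0.8 * (min(ext) - start) else max(s3$mcs)
  c(start, end)
}

#' Least-squares slope of the invader's growth
#'
#' Ordinary least-squares fit of the total (live + dead) count of one type
#' against MCS over a stage-3 window. During invasion this growth is
#' approximately linear, reflecting a front that advances at constant speed.
#'
#' @param series Time-series data frame with a `stage` column.
#' @param type_id Type whose count is fitted.
#' @param window Length-2 MCS window; `NULL` selects automatically from
#'   barrier removal to 80 percent of the opposing type's extinction time.
#' @return List with `slope` (cells per MCS), `stderr`, `window`,
#'   `r_squared`, `n`.
#' @export
fit_linear_growth <- function(series, type_id, window = NULL) {
  if (is.null(window)) window <- auto_fit_window(series, type_id)
  s <- series[series$type_id == type_id &
                series$mcs >= window[1] & series$mcs <= window[2], ]
  if (nrow(s) < 10) stop("fit window contains fewer than 10 points")
  fit <- lm(I(live + dead) ~ mcs, data = s)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       stderr = sm$coefficients[2, 2],
       window = window,
       r_squared = sm$r.squared,
       n = nrow(s))
}

#' Invasion front speed from count growth
#'
#' Converts the linear growth rate of the invading type's cell count into a
#' front speed: `v = slope / (L * rho)`, with the domain width perpendicular
#' to the invasion as the length unit (L = 1) and `rho` the invader's
#' single-type equilibrium density in cells per squared width. The result is
#' in widths per MCS.
#'
#' @param slope Cells per MCS (from [fit_linear_growth()]).
#' @param rho Equilibrium density of the invading type (cells per squared
#'   width), positive.
#' @param L Perpendicular width in length units (1 by convention).
#' @return Speed in widths per MCS.
#' @export
invasion_speed <- function(slope, rho, L = 1) {
  if (rho <= 0) stop("rho must be positive")
  slope / (L * rho)
}

#' Crowding bound on the live-cell count
#'
#' For a dead cell's neighbours to reach the division threshold `A0`, the
#' average live-cell area must satisfy `A >= A0 * Nc / (1 + Nc)`, where `Nc`
#' is the mean number of live neighbours of a dead cell (about 6 in a
#' honeycomb-like layer). This bounds the equilibrium live-cell count above
#' by `free_area * (1 + Nc) / (A0 * Nc)`: 480 cells for a 40000-pixel domain
#' with `A0 = 100` and `Nc = 6`.
#'
#' @param free_area Cell-bearing area in pixels.
#' @param A0 Target area in pixels, positive.
#' @param Nc Coordination number, at least 1.
#' @return Maximum live-cell count (not rounded).
#' @export
crowding_bound <- function(free_area, A0, Nc = 6) {
  if (A0 <= 0) stop("A0 must be positive")
  if (Nc < 1) stop("Nc must be at least 1")
  free_area * (1 + Nc) / (A0 * Nc)
}

#' Identify the invading type
#'
#' Returns the type whose live count grows during stage 3 while the opponent
#' reaches zero or trends towards it. If neither type is extinct, a two-sided
#' OLS slope test on the live-count difference decides; below significance
#' level `alpha` the result is `NA` (no winner).
#'
#' @param series Time-series data frame with a `stage` column and two types.
#' @param alpha Significance level of the slope test.
#' @return Winning type id, or `NA_integer_`.
#' @export
invasion_direction <- function(series, alpha = 0.01) {
  s3 <- series[series$stage == 3, ]
  if (!nrow(s3)) stop("series has no stage-3 data")
  types <- sort(unique(s3$type_id))
  if (length(types) != 2) stop("invasion_direction requires two types")
  last <- max(s3$mcs)
  final_live <- vapply(types, function(ty)
    sum(s3$live[s3$type_id == ty & s3$mcs == last]), numeric(1))
  if (any(final_live == 0) && !all(final_live == 0))
    return(types[which.max(final_live)])
  a <- s3[s3$type_id == types[1], ]
  b <- s3[s3$type_id == types[2], ]
  d <- data.frame(mcs = a$mcs, diff = a$live - b$live[match(a$mcs, b$mcs)])
  if (nrow(d) < 10) return(NA_integer_)
  fit <- summary(lm(diff ~ mcs, data = d))
  p <- fit$coefficients[2, 4]
  if (is.na(p) || p >= alpha) return(NA_integer_)
  if (coef(lm(diff ~ mcs, data = d))[2] > 0) types[1] else types[2]
}

#' Summarise an invasion run
#'
#' Convenience wrapper computing the winner, the linear growth slope of the
#' winner and the invasion speed given the invader's single-type equilibrium
#' density.
#'
#' @param invasion A `cpm_invasion` object from [run_invasion()].
#' @param rho Equilibrium density of the invading type (cells per squared
#'   width); if `NA` the speed is omitted.
#' @return List with `winner`, `slope`, `stderr`, `speed`, `fit_window`,
#'   `complete`.
#' @export
invasion_summary <- function(invasion, rho = NA) {
  w <- invasion$winner
  if (is.na(w)) {
    return(list(winner = NA_integer_, slope = NA_real_, stderr = NA_real_,
                speed = NA_real_, fit_window = NULL,
                complete = invasion$complete))
  }
  fit <- fit_linear_growth(invasion$series, w)
  speed <- if (is.na(rho)) NA_real_ else invasion_speed(fit$slope, rho)
  list(winner = w, slope = fit$slope, stderr = fit$stderr, speed = speed,
       fit_window = fit$window, complete = invasion$complete)
}
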