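#' Parameters of the two-species competition reaction-diffusion model
#'
#' The continuum counterpart of the two-type invasion simulation:
#' \deqn{\partial_t \rho_1 = b_1 \rho_1 (1 - \rho_1 - \rho_2) - m_1 \rho_1 + D \nabla^2 \rho_1}
#' \deqn{\partial_t \rho_2 = b_2 \rho_2 (1 - \rho_1 - \rho_2) - m_2 \rho_2 + D \nabla^2 \rho_2}
#' with reproduction rate constants `b1`, `b2`, mortality parameters `m1`,
#' `m2` (per time) and a common diffusion coefficient `D` (length^2/time).
#'
#' @param b1,b2 Reproduction rates, non-negative.
#' @param m1,m2 Mortality rates, non-negative.
#' @param D Diffusion coefficient, positive for front problems.
#' @return An object of class `rd_params`.
#' @export
rd_params <- function(b1, b2, m1, m2, D = 1) {
  stopifnot(b1 >= 0, b2 >= 0, m1 >= 0, m2 >= 0, D >= 0)
  structure(list(b1 = b1, b2 = b2, m1 = m1, m2 = m2, D = D),
            class = "rd_params")
}

#' Uniform steady states of the competition model
#'
#' The spatially uniform system has exactly three steady states: extinction
#' `(0, 0)` and the two single-species states `(1 - m1/b1, 0)` and
#' `(0, 1 - m2/b2)`. There is no coexistence state except in the degenerate
#' case `b1/m1 = b2/m2`. A single-species state with non-positive density is
#' flagged nonviable (the species cannot persist); with `b = 0` it is
#' undefined.
#'
#' @param params An [rd_params()].
#' @return List of three entries, each a list with `state` (length-2 numeric)
#'   and `viable` (logical, `NA` when undefined).
#' @export
rd_steady_states <- function(params) {
  s1 <- if (params$b1 > 0) 1 - params$m1 / params$b1 else NA_real_
  s2 <- if (params$b2 > 0) 1 - params$m2 / params$b2 else NA_real_
  list(
    extinction = list(state = c(0, 0), viable = TRUE),
    species1 = list(state = c(s1, 0),
                    viable = if (is.na(s1)) NA else s1 > 0),
    species2 = list(state = c(0, s2),
                    viable = if (is.na(s2)) NA else s2 > 0))
}

# Jacobian of the reaction part at a uniform state
rd_jacobian <- function(params, state) {
  r1 <- state[1]; r2 <- state[2]
  with(params, matrix(c(
    b1 * (1 - 2 * r1 - r2) - m1, -b1 * r1,
    -b2 * r2,                    b2 * (1 - r1 - 2 * r2) - m2),
    2, 2, byrow = TRUE))
}

#' Linear stability of a uniform steady state
#'
#' Eigenvalues of the 2x2 reaction Jacobian at the given state; the state is
#' stable iff both real parts are negative. For `b1/m1 > b2/m2` species 1 is
#' dominant: `(1 - m1/b1, 0)` is the stable state and the other
#' single-species state is unstable (and vice versa). At `b1/m1 = b2/m2` the
#' comparison is neutral and flagged as degenerate.
#'
#' @param params An [rd_params()].
#' @param state Length-2 numeric uniform state.
#' @return List with `eigenvalues`, `stable` (logical), `degenerate`
#'   (logical: the neutral case).
#' @export
rd_stability <- function(params, state) {
  J <- rd_jacobian(params, state)
  ev <- eigen(J, only.values = TRUE)$values
  degenerate <- isTRUE(all.equal(params$b1 * params$m2,
                                 params$b2 * params$m1))
  list(eigenvalues = ev,
       stable = all(Re(ev) < 0),
       degenerate = degenerate)
}

#' Closed-form pulled-front speed
#'
#' For spatially separated initial conditions the dominant species invades as
#' a Fisher-Kolmogorov pulled front whose asymptotic speed is set by the
#' linear instability at the leading edge:
#' \deqn{v = 2 \sqrt{D (b_1 m_2 - b_2 m_1) / b_2}}
#' when species 1 dominates (`b1 m2 > b2 m1`). With equal mortalities
#' `m1 = m2 = m` this reduces to `2 sqrt(D m (b1 - b2) / b2)` and with equal
#' reproduction rates `b1 = b2` to `2 sqrt(D (m2 - m1))`. If species 2
#' dominates the roles are swapped and `invader = 2` is returned; at exact
#' balance the speed is zero.
#'
#' @param params An [rd_params()].
#' @return List with `speed` (non-negative) and `invader` (1, 2 or `NA` at
#'   balance).
#' @export
rd_front_speed <- function(params) {
  stopifnot(params$D > 0, params$b1 > 0, params$b2 > 0)
  disc <- params$b1 * params$m2 - params$b2 * params$m1
  if (disc > 0) {
    list(speed = 2 * sqrt(params$D * disc / params$b2), invader = 1L)
  } else if (disc < 0) {
    list(speed = 2 * sqrt(params$D * (-disc) / params$b1), invader = 2L)
  } else {
    list(speed = 0, invader = NA_integer_)
  }
}

#' Integrate the competition model in one dimension
#'
#' Explicit central-difference scheme with no-flux (reflecting) boundaries.
#' The default time step respects the diffusive stability limit
#' `dt <= 0.4 dx^2 / (2 D)`; densities are checked to remain bounded.
#'
#' @param params An [rd_params()].
#' @param length Domain length.
#' @param nx Number of grid points.
#' @param t_end Final time.
#' @param dt Time step; `NULL` chooses the stability-limited default.
#' @param init `"separated"` places the dominant species at its carrying
#'   capacity on the left 10 percent of the domain and the other species at
#'   its carrying capacity elsewhere (a sharp interface, as required for the
#'   pulled-front speed to be selected). Alternatively a list with numeric
#'   vectors `rho1` and `rho2` of length `nx`.
#' @param n_record Number of recorded time slices (evenly spaced).
#' @return An object of class `rd_front`: list with `x`, `times`, `rho1`,
#'   `rho2` (matrices of dim `n_record` x `nx`), `params`, `invader`.
#' @export
rd_solve_1d <- function(params, length = 300, nx = 3000, t_end = 60,
                        dt = NULL, init = "separated", n_record = 120) {
  stopifnot(params$D > 0, nx >= 10, t_end > 0)
  dx <- length / (nx - 1)
  x <- seq(0, length, length.out = nx)
  rate_max <- max(params$b1, params$b2, params$m1, params$m2, 1e-12)
  if (is.null(dt)) dt <- min(0.4 * dx^2 / (2 * params$D), 0.1 / rate_max)
  if (dt > 0.5 * dx^2 / params$D)
    stop("dt violates the diffusive stability limit")
  inv <- rd_front_speed(params)$invader
  if (identical(init, "separated")) {
    k1 <- max(0, 1 - params$m1 / params$b1)
    k2 <- max(0, 1 - params$m2 / params$b2)
    left <- x <= 0.1 * length
    if (is.na(inv) || inv == 1L) {
      rho1 <- ifelse(left, k1, 0); rho2 <- ifelse(left, 0, k2)
    } else {
      rho2 <- ifelse(left, k2, 0); rho1 <- ifelse(left, 0, k1)
    }
  } else {
    stopifnot(is.list(init), length(init$rho1) == nx, length(init$rho2) == nx)
    rho1 <- as.numeric(init$rho1); rho2 <- as.numeric(init$rho2)
  }
  nsteps <- ceiling(t_end / dt)
  rec_at <- unique(pmax(1, round(seq(1, nsteps, length.out = n_record))))
  R1 <- matrix(NA_real_, length(rec_at), nx)
  R2 <- matrix(NA_real_, length(rec_at), nx)
  times <- numeric(length(rec_at))
  ri <- 1L
  lap <- function(u) {
    n <- base::length(u)
    (c(u[2], u[1:(n - 1)]) - 2 * u + c(u[2:n], u[n - 1])) / dx^2
  }
  for (s in seq_len(nsteps)) {
    comp <- 1 - rho1 - rho2
    f1 <- params$b1 * rho1 * comp - params$m1 * rho1
    f2 <- params$b2 * rho2 * comp - params$m2 * rho2
    rho1 <- rho1 + dt * (f1 + params$D * lap(rho1))
    rho2 <- rho2 + dt * (f2 + params$D * lap(rho2))
    if (ri <= length(rec_at) && s == rec_at[ri]) {
      if (anyNA(rho1) || anyNA(rho2) ||
          max(rho1, rho2) > 1 + 1e-6 || min(rho1, rho2) < -1e-6)
        stop("numerical instability detected; reduce dt")
      R1[ri, ] <- rho1; R2[ri, ] <- rho2
      times[ri] <- s * dt
      ri <- ri + 1L
    }
  }
  structure(list(x = x, times = times, rho1 = R1, rho2 = R2,
                 params = params, invader = inv),
            class = "rd_front")
}

#' Empirical front speed from a solved profile
#'
#' Locates, at each recorded time, the rightmost level crossing of the
#' invader's density (by default at half its carrying capacity, a level
#' insensitive to tail shape) with linear interpolation, then fits position
#' against time by least squares over the final third of the run. A warning
#' is raised if the front approaches the domain boundary.
#'
#' @param solution An `rd_front` from [rd_solve_1d()].
#' @param level Crossing level; `NULL` uses half the invader's carrying
#'   capacity.
#' @return List with `speed`, `stderr`, `positions`, `times`, `level`.
#' @export
rd_measure_front_speed <- function(solution, level = NULL) {
  p <- solution$params
  inv <- solution$invader
  if (is.na(inv)) stop("no dominant species; front speed undefined")
  field <- if (inv == 1L) solution$rho1 else solution$rho2
  if (is.null(level)) {
    b <- if (inv == 1L) p$b1 else p$b2
    m <- if (inv == 1L) p$m1 else p$m2
    level <- 0.5 * (1 - m / b)
  }
  x <- solution$x
  nx <- length(x)
  pos <- vapply(seq_along(solution$times), function(i) {
    u <- field[i, ]
    above <- which(u >= level)
    if (!length(above)) return(NA_real_)
    j <- max(above)
    if (j == nx) return(x[nx])
    x[j] + (x[j + 1] - x[j]) * (u[j] - level) / (u[j] - u[j + 1])
  }, numeric(1))
  keep <- !is.na(pos)
  t <- solution$times[keep]; pos <- pos[keep]
  if (length(t) < 5) stop("too few valid front positions")
  if (max(pos) > x[nx] - 10 * (x[2] - x[1]))
    warning("front reached the domain boundary; speed window truncated")
  tail_i <- t >= t[1] + 2 / 3 * (t[length(t)] - t[1])
  fit <- summary(lm(pos[tail_i] ~ t[tail_i]))
  list(speed = fit$coefficients[2, 1], stderr = fit$coefficients[2, 2],
       positions = pos, times = t, level = level)
}
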