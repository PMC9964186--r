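# central-difference Jacobian of the reaction part, independent of the
# analytic expressions used by the package
fd_jacobian <- function(p, state, h = 1e-5) {
  f <- function(s) c(p$b1 * s[1] * (1 - s[1] - s[2]) - p$m1 * s[1],
                     p$b2 * s[2] * (1 - s[1] - s[2]) - p$m2 * s[2])
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    J[, j] <- (f(state + e) - f(state - e)) / (2 * h)
  }
  J
}

test_that("the three uniform steady states follow from the rates", {
  p <- rd_params(1, 1, 0.5, 0.5)
  ss <- rd_steady_states(p)
  expect_equal(ss$extinction$state, c(0, 0))
  expect_equal(ss$species1$state, c(0.5, 0))
  expect_equal(ss$species2$state, c(0, 0.5))
  p2 <- rd_params(2, 1, 0.5, 0.5)
  expect_equal(rd_steady_states(p2)$species1$state, c(0.75, 0))
  # m >= b: the species cannot persist
  p3 <- rd_params(1, 1, 1.2, 0.5)
  expect_false(rd_steady_states(p3)$species1$viable)
  # b = 0: the state is undefined
  p4 <- rd_params(0, 1, 0.5, 0.5)
  expect_true(is.na(rd_steady_states(p4)$species1$viable))
})

test_that("stability classification matches the dominance rule and a
           finite-difference Jacobian", {
  p <- rd_params(2, 1, 0.5, 0.5)  # b1/m1 = 4 > b2/m2 = 2: species 1 wins
  ss <- rd_steady_states(p)
  expect_false(rd_stability(p, ss$extinction$state)$stable)
  s1 <- rd_stability(p, ss$species1$state)
  s2 <- rd_stability(p, ss$species2$state)
  expect_true(s1$stable)
  expect_false(s2$stable)
  # eigenvalues agree with a numerical Jacobian
  ev_num <- sort(Re(eigen(fd_jacobian(p, ss$species1$state))$values))
  expect_equal(sort(Re(s1$eigenvalues)), ev_num, tolerance = 1e-8)
  # degenerate balance is flagged
  pd <- rd_params(2, 1, 0.5, 0.25)
  expect_true(rd_stability(pd, c(0, 0))$degenerate)
})

test_that("closed-form front speeds obey their algebraic identities", {
  expect_equal(rd_front_speed(rd_params(1, 1, 0.3, 0.3))$speed, 0)
  p <- rd_params(2, 1, 0.25, 0.5, D = 1)
  expect_equal(rd_front_speed(p)$speed, 2 * sqrt(0.75), tolerance = 1e-12)
  # swapping the species flips the invader, same magnitude
  ps <- rd_params(1, 2, 0.5, 0.25, D = 1)
  expect_equal(rd_front_speed(ps)$speed, rd_front_speed(p)$speed)
  expect_equal(rd_front_speed(ps)$invader, 2L)
  # equal division rates: speed reduces to 2 sqrt(D (m2 - m1)) exactly
  set.seed(16)
  for (i in 1:20) {
    b <- runif(1, 0.5, 3)
    m1 <- runif(1, 0.05, 0.4)
    m2 <- m1 + runif(1, 0.05, 0.5)
    D <- runif(1, 0.2, 3)
    p <- rd_params(b, b, m1, m2, D)
    expect_equal(rd_front_speed(p)$speed, 2 * sqrt(D * (m2 - m1)),
                 tolerance = 1e-12)
  }
})

test_that("the 1D solver relaxes a single species to its carrying capacity", {
  p <- rd_params(1, 1, 0.5, 0.5, D = 0.1)
  sol <- rd_solve_1d(p, length = 50, nx = 200, t_end = 60,
                     init = list(rho1 = rep(0.1, 200), rho2 = rep(0, 200)))
  final <- sol$rho1[nrow(sol$rho1), ]
  expect_true(all(abs(final - 0.5) < 1e-3))
  expect_true(all(sol$rho2 == 0))
})

test_that("species-swap symmetry is preserved by the solver", {
  p <- rd_params(1, 1, 0.3, 0.3, D = 0.5)
  nx <- 200
  bump <- exp(-((seq(0, 50, length.out = nx) - 25) / 5)^2)
  sol <- rd_solve_1d(p, length = 50, nx = nx, t_end = 10,
                     init = list(rho1 = 0.4 * bump, rho2 = 0.4 * rev(bump)))
  for (i in c(1, nrow(sol$rho1))) {
    expect_equal(sol$rho1[i, ], rev(sol$rho2[i, ]), tolerance = 1e-10)
  }
})

test_that("the classical single-species pulled front travels at 2 sqrt(r D)", {
  # logistic invasion into the empty (unstable) state with linear rate
  # r = b - m; competition with an absent second species
  p <- rd_params(1.5, 1, 0.5, 0.5, D = 1)
  nx <- 1500
  rho1 <- ifelse(seq(0, 150, length.out = nx) <= 15, 1 - 0.5 / 1.5, 0)
  sol <- rd_solve_1d(p, length = 150, nx = nx, t_end = 40,
                     init = list(rho1 = rho1, rho2 = rep(0, nx)))
  emp <- rd_measure_front_speed(sol, level = 0.5 * (1 - 0.5 / 1.5))
  expect_lt(abs(emp$speed - 2) / 2, 0.05)
})

test_that("competition fronts propagate at the linear-spreading prediction", {
  p <- rd_params(2, 1, 0.25, 0.5, D = 1)
  sol <- rd_solve_1d(p, length = 200, nx = 2000, t_end = 45)
  emp <- rd_measure_front_speed(sol)
  v <- rd_front_speed(p)$speed
  expect_lt(abs(emp$speed - v) / v, 0.05)
  # front position is linear in time over the fitted window
  tail_i <- emp$times >= emp$times[1] + 2 / 3 * diff(range(emp$times))
  fit <- summary(lm(emp$positions[tail_i] ~ emp$times[tail_i]))
  expect_gt(fit$r.squared, 0.99)
})

test_that("vanishing diffusion freezes the front", {
  p <- rd_params(2, 1, 0.25, 0.5, D = 1e-4)
  sol <- rd_solve_1d(p, length = 30, nx = 300, t_end = 30)
  emp <- rd_measure_front_speed(sol)
  expect_lt(abs(emp$speed), 0.05)
})

test_that("the long-time solver outcome agrees with the stability
           classification", {
  set.seed(17)
  for (i in 1:10) {
    b1 <- runif(1, 0.5, 2); b2 <- runif(1, 0.5, 2)
    m1 <- runif(1, 0.1, 0.45 * b1); m2 <- runif(1, 0.1, 0.45 * b2)
    if (abs(b1 * m2 - b2 * m1) < 0.05) next
    p <- rd_params(b1, b2, m1, m2, D = 0.01)
    nx <- 16
    sol <- rd_solve_1d(p, length = 1, nx = nx, t_end = 400,
                       init = list(rho1 = rep(0.3, nx), rho2 = rep(0.3, nx)))
    final <- c(mean(sol$rho1[nrow(sol$rho1), ]),
               mean(sol$rho2[nrow(sol$rho2), ]))
    ss <- rd_steady_states(p)
    stable <- if (rd_stability(p, ss$species1$state)$stable)
      ss$species1$state else ss$species2$state
    expect_equal(final, stable, tolerance = 0.02)
  }
})
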