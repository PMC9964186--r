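# Shared simulation runs, cached so that acceptance checks and property
# tests exercising the same protocol reuse one computation.
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# cell type with the standard invasion-study mechanics (lambda_area = 70,
# lambda_cont = 7, lambda_adh = -10, A0 = 100) and given turnover rates
mech_type <- function(id, B, M) cell_type(id, 70, 7, -10, 100, B, M)

# reduced-scale two-compartment invasion: 70 + 10 + 70 x 80 interior
invasion_run <- function(ct1, ct2, seed, stage3_max = 30000) {
  key <- paste("inv", ct1$lambda_area, ct1$lambda_cont, ct1$lambda_adh,
               ct1$birth_prob, ct1$death_prob, ct2$lambda_area,
               ct2$lambda_cont, ct2$lambda_adh, ct2$birth_prob,
               ct2$death_prob, seed, stage3_max, sep = "_")
  cached(key, {
    cfg <- experiment_config(width = 150, height = 80,
                             cell_types = list(ct1, ct2),
                             stage1_mcs = 300, stage2_max_mcs = 1500,
                             stage3_max_mcs = stage3_max, window = 400,
                             seed = seed)
    run_invasion(cfg)
  })
}

# single-type equilibrium density on an 80x80 domain (= one squared width of
# the 80-px-high invasion lattice), standard mechanics
rho_run <- function(B, M, seed) {
  key <- paste("rho", B, M, seed, sep = "_")
  cached(key, {
    cfg <- experiment_config(width = 80, height = 80,
                             cell_types = list(mech_type(1, B, M)),
                             seed = seed)
    eq <- run_homogeneous_equilibrium(cfg)
    eq$summary$live_mean
  })
}

# measured invasion speed of type 1, averaged over seeds
invasion_speed_avg <- function(ct1, ct2, seeds, rho, stage3_max = 30000) {
  mean(vapply(seeds, function(s) {
    inv <- invasion_run(ct1, ct2, s, stage3_max)
    fit <- fit_linear_growth(inv$series, 1L)
    invasion_speed(fit$slope, rho)
  }, numeric(1)))
}

# the two monotonicity grids (division-rate difference, death-rate
# difference), each point averaged over two seeds
bgrid_speeds <- function() {
  cached("bgrid", {
    B1 <- c(0.2, 0.3, 0.45, 0.6, 0.75, 0.9)
    v <- vapply(seq_along(B1), function(i) {
      rho <- rho_run(B1[i], 0.003, 900 + i)
      invasion_speed_avg(mech_type(1, B1[i], 0.003), mech_type(2, 0.1, 0.003),
                         c(11, 12) + i, rho)
    }, numeric(1))
    list(B1 = B1, B2 = 0.1, M = 0.003, v = v)
  })
}

mgrid_speeds <- function() {
  cached("mgrid", {
    M2 <- c(0.002, 0.003, 0.005, 0.008, 0.012, 0.016)
    rho <- rho_run(0.1, 0.001, 950)
    v <- vapply(seq_along(M2), function(i) {
      invasion_speed_avg(mech_type(1, 0.1, 0.001), mech_type(2, 0.1, M2[i]),
                         c(21, 22) + i, rho)
    }, numeric(1))
    list(M1 = 0.001, M2 = M2, B = 0.1, v = v)
  })
}
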