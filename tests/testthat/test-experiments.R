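test_that("monolayer tiling produces square cells at target area", {
  cfg <- experiment_config(width = 20, height = 20,
                           cell_types = list(cell_type(1, 10, 0.5, -10, 100)))
  lat <- build_monolayer(cfg)
  expect_equal(nrow(lat$cells), 4)
  expect_true(all(lat$cells$area == 100))
  expect_equal(sum(lat$cells$area), 20 * 20)
  big <- build_monolayer(experiment_config(width = 200, height = 200))
  expect_equal(nrow(big$cells), 400)
  expect_true(all(big$cells$area == 100))
  expect_error(build_monolayer(experiment_config(width = 25, height = 20)),
               "multiple")
})

test_that("two-compartment construction tiles both halves and isolates them
           with the barrier", {
  two <- list(cell_type(1, 70, 7, -10, 100, 0.9, 0.003),
              cell_type(2, 70, 7, -10, 100, 0.1, 0.003))
  cfg <- experiment_config(width = 150, height = 80, cell_types = two)
  lat <- build_two_compartment(cfg)
  expect_equal(sum(lat$cells$type_id == 1), 56)
  expect_equal(sum(lat$cells$type_id == 2), 56)
  expect_equal(sum(lat$barrier), 10 * 80)
  # nominal full-scale geometry: 300-px halves, 900 cells per side
  cfg2 <- experiment_config(width = 610, height = 300, cell_types = two)
  lat2 <- build_two_compartment(cfg2)
  expect_equal(as.integer(table(lat2$cells$type_id)), c(900L, 900L))
  expect_error(build_two_compartment(
    experiment_config(width = 155, height = 80, cell_types = two)), "halves")

  # while the barrier exists no owner ever crosses it
  set.seed(4)
  r <- run_mcs(lat, 50, turnover = TRUE)
  o <- r$lattice$owner
  typemap <- with(r$lattice$cells, setNames(type_id, cell_id))
  left_ids <- unique(o[, 1:71][o[, 1:71] > 0])
  right_ids <- unique(o[, 82:152][o[, 82:152] > 0])
  expect_true(all(typemap[as.character(left_ids)] == 1L))
  expect_true(all(typemap[as.character(right_ids)] == 2L))
  expect_true(all(o[lat$barrier] == 0L))
})

test_that("barrier removal hands the strip to a shrinking placeholder that
           disappears", {
  two <- list(cell_type(1, 70, 7, -10, 100, 0.5, 0.003),
              cell_type(2, 70, 7, -10, 100, 0.5, 0.003))
  cfg <- experiment_config(width = 70, height = 30, cell_types = two,
                           initial_cell_side = 10)
  lat <- build_two_compartment(cfg)
  expect_error(remove_barrier(remove_barrier(lat)), "no barrier")
  lat2 <- remove_barrier(lat)
  ph <- setdiff(lat2$cells$cell_id, lat$cells$cell_id)
  expect_length(ph, 1)
  expect_equal(lat2$cells$area[lat2$cells$cell_id == ph], 10 * 30)
  expect_false(any(lat2$barrier))
  expect_true(lattice_check(lat2))
  set.seed(6)
  r <- run_mcs(lat2, 300, turnover = TRUE)
  expect_false(ph %in% r$lattice$cells$cell_id)  # strip fully claimed
})

test_that("without turnover the homogeneous protocol keeps counts constant", {
  cfg <- experiment_config(width = 40, height = 40,
                           cell_types = list(cell_type(1, 10, 0.5, -10, 100,
                                                       0, 0)),
                           window = 50, max_mcs = 200, measure_mcs = 0,
                           seed = 1)
  eq <- run_homogeneous_equilibrium(cfg)
  expect_true(all(eq$series$live == 16))
  expect_true(all(eq$series$dead == 0))
  expect_true(eq$stationary)
})

test_that("the homogeneous equilibrium is denser than the initial tiling and
           its dead count grows with the death rate", {
  eqm <- lapply(c(0.001, 0.01), function(M) {
    cfg <- experiment_config(width = 100, height = 100,
                             cell_types = list(cell_type(1, 10, 0.5, -10, 100,
                                                         0.03, M)),
                             window = 300, max_mcs = 3000, measure_mcs = 600,
                             seed = 7)
    run_homogeneous_equilibrium(cfg)
  })
  totals <- vapply(eqm, function(e) e$summary$total_mean, numeric(1))
  deads <- vapply(eqm, function(e) e$summary$dead_mean, numeric(1))
  expect_true(all(totals > 100))  # denser than the 100-cell tiling
  expect_lt(deads[1], deads[2])   # dead load increases with M
})

test_that("the three-stage invasion protocol records stages and respects the
           crowding envelope", {
  inv <- invasion_run(mech_type(1, 0.9, 0.003), mech_type(2, 0.1, 0.003), 1)
  expect_s3_class(inv, "cpm_invasion")
  expect_equal(sort(unique(inv$series$stage)), 1:3)
  # stage 1 has no turnover events
  s1_end <- inv$stages[["stage1_end"]]
  expect_false(any(inv$events$mcs <= s1_end))
  # total live count in stage 3 stays within a loose crowding envelope
  s3 <- inv$series[inv$series$stage == 3, ]
  tot_live <- tapply(s3$live, s3$mcs, sum)
  bound <- crowding_bound(150 * 80, 100, 6)
  expect_true(all(tot_live <= 1.15 * bound))
  expect_true(inv$complete)
  expect_equal(inv$winner, 1L)
})

test_that("identical cell types give no systematic winner across seeds", {
  ct <- function(id) cell_type(id, 10, 0.5, -10, 100, 0.5, 0.01)
  wins1 <- 0
  for (s in 1:10) {
    cfg <- experiment_config(width = 70, height = 30,
                             cell_types = list(ct(1), ct(2)),
                             stage1_mcs = 100, stage2_max_mcs = 400,
                             stage3_max_mcs = 1500, window = 100,
                             seed = 1000 + s)
    inv <- run_invasion(cfg)
    s3 <- inv$series[inv$series$stage == 3, ]
    last <- s3[s3$mcs == max(s3$mcs), ]
    n1 <- sum(last$live[last$type_id == 1])
    n2 <- sum(last$live[last$type_id == 2])
    if (n1 > n2) wins1 <- wins1 + 1
  }
  # two-sided sign test at alpha = 0.01 rejects only 0/10 or 10/10
  expect_gte(wins1, 1)
  expect_lte(wins1, 9)
})
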