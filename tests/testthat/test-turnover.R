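turnover_fixture <- function(B = 0, M = 0, A0 = 100) {
  owner <- matrix(0L, 22, 22)
  owner[2:11, 2:11] <- 1L
  owner[12:21, 2:11] <- 2L
  owner[2:11, 12:21] <- 3L
  owner[12:21, 12:21] <- 4L
  lattice_from_grid(owner, list(cell_type(1, 10, 0.5, -10, A0,
                                          birth_prob = B, death_prob = M)),
                    type_of = rep(1L, 4))
}

test_that("death sampling respects probabilities and viability", {
  set.seed(1)
  expect_length(sample_deaths(turnover_fixture(M = 0)), 0)
  expect_equal(sample_deaths(turnover_fixture(M = 1)), 1:4)
  # dead cells are never drawn again
  lat <- mark_dead(turnover_fixture(M = 1), c(2L, 3L))
  expect_equal(sample_deaths(lat), c(1L, 4L))
  # binomial mean: n * M over repeated draws
  lat2 <- turnover_fixture(M = 0.2)
  set.seed(2)
  draws <- replicate(400, length(sample_deaths(lat2)))
  expect_lt(abs(mean(draws) - 4 * 0.2),
            3 * sqrt(4 * 0.2 * 0.8 / 400))
})

test_that("marking dead is not idempotent and preserves identity", {
  lat <- turnover_fixture()
  lat <- mark_dead(lat, 1L)
  expect_false(lat$cells$alive[lat$cells$cell_id == 1])
  expect_error(mark_dead(lat, 1L), "already dead")
  expect_error(mark_dead(lat, 99L), "unknown")
  expect_equal(lat$cells$type_id[lat$cells$cell_id == 1], 1L)
})

test_that("dead cells shrink under sweeps until removal", {
  set.seed(5)
  lat <- mark_dead(turnover_fixture(), 1L)
  a0 <- lat$cells$area[lat$cells$cell_id == 1]
  lat <- mcs_sweep(lat, 40)
  a1 <- lat$cells$area[lat$cells$cell_id == 1]
  expect_lt(a1, a0 / 2)
  # with dividing neighbours replenishing the pressure, the corpse is
  # extruded completely and purged from the registry
  set.seed(5)
  lat2 <- mark_dead(turnover_fixture(B = 0.2), 1L)
  r <- run_mcs(lat2, 400, turnover = TRUE)
  expect_true("removal" %in% r$events$event)
  expect_false(1L %in% r$lattice$cells$cell_id)
})

test_that("division sampling requires the target area to be reached", {
  # below A0 never eligible even at B = 1
  set.seed(1)
  expect_length(sample_divisions(turnover_fixture(B = 1, A0 = 101)), 0)
  # at the boundary A = A0 with B = 1, all eligible
  expect_equal(sample_divisions(turnover_fixture(B = 1, A0 = 100)), 1:4)
  # binomial mean n * B
  lat <- turnover_fixture(B = 0.3)
  set.seed(3)
  draws <- replicate(400, length(sample_divisions(lat)))
  expect_lt(abs(mean(draws) - 4 * 0.3),
            3 * sqrt(4 * 0.3 * 0.7 / 400))
})

test_that("division conserves pixels, is local, and balances daughters", {
  set.seed(9)
  lat <- turnover_fixture()
  before <- lat$owner
  d <- divide_cell(lat, 1L)
  expect_length(d$daughters, 2)
  cells <- d$lattice$cells
  a <- cells$area[match(d$daughters, cells$cell_id)]
  expect_equal(sum(a), 100)            # pixels conserved exactly
  expect_true(all(a >= 20))            # roughly balanced halves
  expect_true(all(cells$alive[match(d$daughters, cells$cell_id)]))
  # no other cell's pixels were touched
  other <- before != 1L
  expect_identical(d$lattice$owner[other], before[other])
  expect_true(lattice_check(d$lattice))
  expect_error(divide_cell(mark_dead(lat, 2L), 2L), "dead")
})

test_that("division of a 1-pixel cell is skipped with a warning", {
  owner <- matrix(0L, 5, 5)
  owner[2:4, 2:4] <- 1L
  owner[3, 3] <- 2L
  lat <- lattice_from_grid(owner, list(cell_type(1, 1, 0, 0, 4)),
                           type_of = c(1L, 1L))
  expect_warning(d <- divide_cell(lat, 2L), "skipped")
  expect_null(d$daughters)
  expect_identical(d$lattice$owner, owner)
})

test_that("daughters regrow toward the target area in an uncrowded layer", {
  set.seed(12)
  cfg <- experiment_config(width = 60, height = 60,
                           cell_types = list(cell_type(1, 0.5, 0.5, -10, 100)))
  lat <- build_monolayer(cfg)
  ctr <- lat$owner[31, 31]
  d <- divide_cell(lat, ctr)
  lat2 <- mcs_sweep(d$lattice, 200)
  a <- lat2$cells$area[match(d$daughters, lat2$cells$cell_id)]
  expect_true(all(a > 0.8 * 100))
})

test_that("purge removes exactly the vanished dead cells", {
  lat <- turnover_fixture()
  expect_length(purge_vanished(lat)$removed, 0)
  lat$cells$alive[2] <- FALSE
  lat$cells$area[2] <- 0L
  p <- purge_vanished(lat)
  expect_equal(p$removed, 2L)
  expect_false(2L %in% p$lattice$cells$cell_id)
  lat2 <- turnover_fixture()
  lat2$cells$area[3] <- 0L  # live cell with zero area is an integrity error
  expect_error(purge_vanished(lat2), "integrity")
})

test_that("with no turnover the registry is invariant; with deaths only the
           population goes extinct", {
  set.seed(20)
  lat <- turnover_fixture(B = 0, M = 0)
  r <- run_mcs(lat, 50, turnover = TRUE)
  expect_equal(nrow(r$lattice$cells), 4)
  expect_true(all(r$series$live == 4))
  expect_equal(nrow(r$events), 0)
  # B = 0, M > 0: live count non-increasing, reaches zero
  lat2 <- turnover_fixture(B = 0, M = 0.05)
  r2 <- run_mcs(lat2, 2000, turnover = TRUE, stop_extinct = TRUE)
  expect_true(all(diff(r2$series$live) <= 0))
  expect_equal(r2$series$live[r2$n_done], 0)
})

test_that("identical seeds reproduce identical event logs and grids", {
  cfg_lat <- function() {
    cfg <- experiment_config(width = 60, height = 60,
                             cell_types = list(cell_type(1, 10, 0.5, -10, 100,
                                                         0.1, 0.01)))
    build_monolayer(cfg)
  }
  set.seed(31); r1 <- run_mcs(cfg_lat(), 150, turnover = TRUE)
  set.seed(31); r2 <- run_mcs(cfg_lat(), 150, turnover = TRUE)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$lattice$owner, r2$lattice$owner)
  expect_identical(r1$series, r2$series)
})
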