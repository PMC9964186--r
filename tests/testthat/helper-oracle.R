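# Brute-force energy oracle, independent of the package's incremental path:
# recounts every area, perimeter and boundary link directly from the owner
# grid with matrix shifts.
oracle_terms <- function(lat) {
  o <- lat$owner
  eff <- effective_params(lat)
  H <- nrow(o); W <- ncol(o)
  cell_terms <- numeric(nrow(eff))
  for (i in seq_len(nrow(eff))) {
    id <- eff$cell_id[i]
    m <- o == id
    A <- sum(m)
    up <- rbind(rep(FALSE, W), m[-H, , drop = FALSE])
    dn <- rbind(m[-1, , drop = FALSE], rep(FALSE, W))
    lf <- cbind(rep(FALSE, H), m[, -W, drop = FALSE])
    rt <- cbind(m[, -1, drop = FALSE], rep(FALSE, H))
    L <- sum(m & !up) + sum(m & !dn) + sum(m & !lf) + sum(m & !rt)
    cell_terms[i] <- eff$lambda_area[i] * (A - eff$A0[i])^2 +
      eff$lambda_cont[i] * L^2
  }
  ladh <- numeric(max(eff$cell_id))
  ladh[eff$cell_id] <- eff$lambda_adh
  contact <- function(a, b) {
    sel <- a != b & a > 0 & b > 0
    if (!any(sel)) return(0)
    sum((ladh[a[sel]] + ladh[b[sel]]) / 2)
  }
  list(cell_terms = cell_terms,
       contact = contact(o[, -W], o[, -1]) + contact(o[-H, ], o[-1, ]))
}

oracle_energy <- function(lat) {
  tm <- oracle_terms(lat)
  sum(tm$cell_terms) + tm$contact
}

# full-recomputation energy difference of one pixel copy. Areas, perimeters
# and link counts are recounted from both grids as exact integers and
# differenced before scaling by the coefficients, so the comparison is not
# polluted by cancellation in large energy totals.
oracle_delta <- function(lat, src, tgt) {
  lat2 <- lat
  lat2$owner[tgt[1], tgt[2]] <- lat$owner[src[1], src[2]]
  eff <- effective_params(lat)
  recount <- function(o, id) {
    H <- nrow(o); W <- ncol(o)
    m <- o == id
    up <- rbind(rep(FALSE, W), m[-H, , drop = FALSE])
    dn <- rbind(m[-1, , drop = FALSE], rep(FALSE, W))
    lf <- cbind(rep(FALSE, H), m[, -W, drop = FALSE])
    rt <- cbind(m[, -1, drop = FALSE], rep(FALSE, H))
    c(sum(m),
      sum(m & !up) + sum(m & !dn) + sum(m & !lf) + sum(m & !rt))
  }
  d <- 0
  for (i in seq_len(nrow(eff))) {
    id <- eff$cell_id[i]
    a0 <- recount(lat$owner, id)
    a1 <- recount(lat2$owner, id)
    if (identical(a0, a1)) next
    d <- d + eff$lambda_area[i] *
      ((a1[1] - eff$A0[i])^2 - (a0[1] - eff$A0[i])^2) +
      eff$lambda_cont[i] * (a1[2]^2 - a0[2]^2)
  }
  d + (oracle_terms(lat2)$contact - oracle_terms(lat)$contact)
}

# random multi-cell fixture: k nearest-seed cells on a (size x size) interior,
# random per-type mechanics, a random subset dead
random_lattice <- function(seed, size = 20, k = NULL) {
  set.seed(seed)
  if (is.null(k)) k <- sample(2:6, 1)
  H <- size + 2L
  owner <- matrix(0L, H, H)
  idx <- sample((size * size), k)
  sr <- (idx - 1) %% size + 2L
  sc <- (idx - 1) %/% size + 2L
  for (r in 2:(H - 1L)) {
    for (c in 2:(H - 1L)) {
      d2 <- (r - sr)^2 + (c - sc)^2
      owner[r, c] <- which.min(d2)
    }
  }
  types <- lapply(seq_len(k), function(i) {
    cell_type(i,
              lambda_area = runif(1, 0.5, 20),
              lambda_cont = runif(1, 0, 7),
              lambda_adh = -runif(1, 0, 100),
              A0 = sample(0:150, 1),
              birth_prob = runif(1),
              death_prob = runif(1))
  })
  alive <- runif(k) > 0.25
  if (!any(alive)) alive[1] <- TRUE
  lattice_from_grid(owner, types, type_of = seq_len(k), alive = alive)
}

# a random legal copy attempt (adjacent pixels, distinct non-wall owners)
random_attempt <- function(lat) {
  H <- nrow(lat$owner); W <- ncol(lat$owner)
  repeat {
    r <- sample(2:(H - 1), 1); c <- sample(2:(W - 1), 1)
    k <- sample(4, 1)
    dr <- c(-1, 1, 0, 0)[k]; dc <- c(0, 0, -1, 1)[k]
    s <- lat$owner[r, c]; t <- lat$owner[r + dr, c + dc]
    if (s != t && s != 0 && t != 0)
      return(list(src = c(r, c), tgt = c(r + dr, c + dc)))
  }
}
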