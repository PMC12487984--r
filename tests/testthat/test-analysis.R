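test_that("RDF: delta pair, brute-force equality, ideal-gas flatness", {
  ## two fixed particles at distance d: a single occupied bin containing d
  d <- 3.3
  tr <- one_frame_traj(rbind(c(1, 1, 1), c(1 + d, 1, 1)), box = c(20, 20, 20))
  rdf <- compute_rdf(tr, 1:2, r_max = 10, n_bins = 50)
  hit <- which(rdf$counts > 0)
  expect_length(hit, 1L)
  expect_lt(abs(rdf$r[hit] - d), 10 / 50)

  ## brute-force histogram oracle on a random frame (exact bin counts)
  set.seed(31)
  n <- 60
  x <- matrix(runif(n * 3, 0, 16), n, 3)
  tr2 <- one_frame_traj(x, box = c(16, 16, 16))
  rdf2 <- compute_rdf(tr2, 1:n, r_max = 8, n_bins = 40)
  counts <- numeric(40)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dd <- x[i, ] - x[j, ]
    dd <- dd - 16 * round(dd / 16)
    r <- sqrt(sum(dd^2))
    if (r < 8) {
      b <- min(40L, 1L + floor(r / 0.2))
      counts[b] <- counts[b] + 1
    }
  }
  expect_equal(rdf2$counts, counts)

  ## ideal gas: g(r) consistent with 1 within 3 Poisson standard errors
  set.seed(77)
  nf <- 40; ng <- 150
  coords <- array(runif(ng * 3 * nf, 0, 20), c(ng, 3, nf))
  tr3 <- cg_trajectory(coords, box = c(20, 20, 20), bead_types = rep(1L, ng),
                       lipid_index = seq_len(ng))
  rdf3 <- compute_rdf(tr3, 1:ng, r_max = 9, n_bins = 30)
  sel <- rdf3$r > 2
  se <- 1 / sqrt(pmax(rdf3$counts[sel], 1))
  expect_true(all(abs(rdf3$g[sel] - 1) < 3.5 * se))
  expect_error(compute_rdf(tr3, 1:ng, r_max = 15), "geometry")
})

test_that("z-density integrates to one and recovers a known Gaussian layer", {
  z0 <- 4
  x <- cbind(runif(50, 0, 10), runif(50, 0, 10), rep(z0, 50))
  tr <- one_frame_traj(x, box = c(10, 10, 40))
  prof <- compute_zdensity(tr, 1:50, n_bins = 80, recenter = TRUE)
  dz <- diff(prof$z)[1]
  expect_equal(sum(prof$density) * dz, 1, tolerance = 1e-12)
  expect_length(which(prof$density > 0), 1L)   # single occupied bin

  set.seed(12)
  nf <- 30; n <- 200
  coords <- array(0, c(n, 3, nf))
  for (t in 1:nf) coords[, , t] <- cbind(runif(n, 0, 40), runif(n, 0, 40),
                                         rnorm(n, 20, 3))
  tr2 <- cg_trajectory(coords, box = c(40, 40, 80), bead_types = rep(1L, n),
                       lipid_index = 1:n)
  prof2 <- compute_zdensity(tr2, 1:n, n_bins = 100, recenter = FALSE,
                            z_range = c(0, 40))
  dz2 <- diff(prof2$z)[1]
  expect_equal(sum(prof2$density) * dz2, 1, tolerance = 1e-12)
  mu_hat <- sum(prof2$z * prof2$density) * dz2
  sd_hat <- sqrt(sum((prof2$z - mu_hat)^2 * prof2$density) * dz2)
  expect_lt(abs(mu_hat - 20), 0.5)
  expect_lt(abs(sd_hat / 3 - 1), 0.10)
  expect_error(compute_zdensity(tr2, integer(0)), "selection")
})

test_that("thickness: planar leaflets, corrugated analytic surface, mask semantics", {
  ## flat leaflets at +-20: every occupied cell reads 40
  nhg <- 64
  xy <- as.matrix(expand.grid(x = seq(2.5, 37.5, 5), y = seq(2.5, 37.5, 5)))
  x <- rbind(cbind(xy, 20), cbind(xy, -20))
  tr <- one_frame_traj(x, box = c(40, 40, 80))
  tm <- compute_thickness(tr, 1:(2 * nhg), cell_size = 10)
  expect_equal(tm$thickness, 40, tolerance = 1e-12)
  expect_true(all(abs(tm$grid[!is.na(tm$grid)] - 40) < 1e-12))

  ## sinusoidal corrugation: cell means match the analytic average
  L <- 40; A <- 2
  xs <- seq(0.25, L - 0.25, 0.5)
  grid_xy <- as.matrix(expand.grid(x = xs, y = xs))
  zu <- 20 + A * sin(2 * pi * grid_xy[, 1] / L)
  zl <- -20 + A * sin(2 * pi * grid_xy[, 1] / L)
  x2 <- rbind(cbind(grid_xy, zu), cbind(grid_xy, zl))
  tr2 <- one_frame_traj(x2, box = c(L, L, 100))
  tm2 <- compute_thickness(tr2, seq_len(nrow(x2)), cell_size = 10)
  expect_true(all(abs(tm2$grid - 40) < 1e-9))   # corrugation cancels in the difference
  ## upper-minus-lower with different amplitudes does not cancel:
  zu3 <- 20 + A * sin(2 * pi * grid_xy[, 1] / L)
  x3 <- rbind(cbind(grid_xy, zu3), cbind(grid_xy, rep(-20, nrow(grid_xy))))
  tm3 <- compute_thickness(one_frame_traj(x3, box = c(L, L, 100)),
                           seq_len(nrow(x3)), cell_size = 10)
  cellmean <- function(a, b) mean(40 + A * sin(2 * pi * seq(a + 0.25, b - 0.25, 0.5) / L))
  for (cx in 1:4) {
    want <- cellmean((cx - 1) * 10, cx * 10)
    expect_equal(mean(tm3$grid[cx, ]), want, tolerance = 0.02)
  }

  ## translation invariance
  tr_shift <- tr2
  tr_shift$coords[, 3, ] <- tr_shift$coords[, 3, ] + 7.7
  tm_s <- compute_thickness(tr_shift, seq_len(nrow(x2)), cell_size = 10)
  expect_equal(tm_s$thickness, tm2$thickness, tolerance = 1e-9)

  ## sparse occupancy: empty cells flagged, not imputed
  x4 <- rbind(c(5, 5, 20), c(5, 5, -20))
  tm4 <- compute_thickness(one_frame_traj(x4, box = c(40, 40, 80)), 1:2,
                           cell_size = 10)
  expect_equal(sum(!is.na(tm4$grid)), 1L)
  expect_equal(tm4$thickness, 40)
})

test_that("order parameter hits its analytic limits and isotropic average", {
  mk <- function(vecs) {
    n <- nrow(vecs)
    x <- matrix(0, 2 * n, 3)
    x[seq(1, 2 * n, 2), ] <- 50 + vecs
    x[seq(2, 2 * n, 2), ] <- 50
    one_frame_traj(x, box = c(100, 100, 100))
  }
  bp <- cbind(seq(1, 40, 2), seq(2, 40, 2))
  along_z <- matrix(rep(c(0, 0, 3), 20), ncol = 3, byrow = TRUE)
  expect_equal(compute_order_parameter(mk(along_z), bp)$S, 1)
  th <- seq(0, 2 * pi, length.out = 20)
  in_plane <- cbind(cos(th), sin(th), 0) * 2.5
  expect_equal(compute_order_parameter(mk(in_plane), bp)$S, -0.5)
  magic <- t(replicate(20, c(sqrt(2 / 3), 0, sqrt(1 / 3)) * 3))
  expect_equal(compute_order_parameter(mk(magic), bp)$S, 0, tolerance = 1e-12)

  ## isotropic orientations: |S| below 3 standard errors of zero
  set.seed(41)
  nb <- 1e5
  u <- matrix(rnorm(3 * nb), nb, 3)
  u <- u / sqrt(rowSums(u^2))
  x <- matrix(0, 2 * nb, 3)
  x[seq(1, 2 * nb, 2), ] <- 500 + u
  x[seq(2, 2 * nb, 2), ] <- 500
  tr <- one_frame_traj(x, box = c(1000, 1000, 1000))
  bpL <- cbind(seq(1, 2 * nb, 2), seq(2, 2 * nb, 2))
  S <- compute_order_parameter(tr, bpL)$S
  expect_lt(abs(S), 3 * sqrt(1 / (5 * nb)))   # var of P2(cos) under isotropy is 1/5

  ## bounded on arbitrary random input
  set.seed(6)
  xr <- matrix(runif(60, 0, 30), 20, 3)
  Sr <- compute_order_parameter(one_frame_traj(xr, box = c(30, 30, 30)),
                                cbind(1:10, 11:20))$S
  expect_gte(Sr, -0.5); expect_lte(Sr, 1)
  expect_error(compute_order_parameter(mk(along_z * 0), bp), "degenerate-bond")
})

test_that("MSD: stationary, ballistic, time-origin oracle and random-walk diffusion", {
  n <- 5; nt <- 20
  still <- cg_trajectory(array(rep(matrix(runif(n * 3), n, 3), nt), c(n, 3, nt)),
                         box = c(50, 50, 50), bead_types = rep(1L, n),
                         lipid_index = 1:n, times = (0:(nt - 1)) * 10,
                         unwrapped = TRUE)
  m0 <- compute_msd(still, 1:n)
  expect_true(all(m0$msd == 0))
  expect_equal(m0$D, 0)

  ## deterministic drift x = v t: MSD(t) = v^2 t^2
  v <- 0.3
  coords <- array(0, c(1, 3, nt))
  coords[1, 1, ] <- v * (0:(nt - 1))
  drift <- cg_trajectory(coords, box = c(1000, 10, 10), bead_types = 1L,
                         lipid_index = 1L, times = 0:(nt - 1), unwrapped = TRUE)
  md <- compute_msd(drift, 1, max_lag = 10)
  expect_equal(md$msd, (v * md$lag_time)^2, tolerance = 1e-12)

  ## explicit double-loop oracle for time-origin averaging
  set.seed(9)
  coords2 <- array(cumsum(rnorm(2 * 3 * 12, sd = 0.5)), c(2, 3, 12))
  tr2 <- cg_trajectory(coords2, box = c(100, 100, 100), bead_types = c(1L, 1L),
                       lipid_index = 1:2, times = 0:11, unwrapped = TRUE)
  m2 <- compute_msd(tr2, 1:2, max_lag = 6)
  for (lag in 1:6) {
    acc <- 0; cnt <- 0
    for (tau in 1:(12 - lag)) for (i in 1:2) {
      d <- coords2[i, 1:2, tau + lag] - coords2[i, 1:2, tau]
      acc <- acc + sum(d^2); cnt <- cnt + 1
    }
    expect_equal(m2$msd[lag + 1], acc / cnt, tolerance = 1e-12)
  }

  ## seeded 2-D random walk: D within 10% of sigma^2 / (2 dt)
  set.seed(55)
  nw <- 400; ntw <- 200; sig <- 0.8; dtw <- 5
  steps <- array(rnorm(nw * 2 * (ntw - 1), sd = sig), c(nw, 2, ntw - 1))
  cw <- array(0, c(nw, 3, ntw))
  cw[, 1:2, -1] <- aperm(apply(steps, c(1, 2), cumsum), c(2, 3, 1))
  trw <- cg_trajectory(cw, box = c(1e5, 1e5, 10), bead_types = rep(1L, nw),
                       lipid_index = seq_len(nw), times = (0:(ntw - 1)) * dtw,
                       unwrapped = TRUE)
  mw <- compute_msd(trw, seq_len(nw))
  expect_lt(abs(mw$D / (sig^2 / (2 * dtw)) - 1), 0.10)

  ## wrapped-coordinate detection
  cwrap <- array(0, c(1, 3, 5))
  cwrap[1, 1, ] <- c(0.5, 9.5, 0.5, 9.5, 0.5)   # jumps > box/2
  trap <- cg_trajectory(cwrap, box = c(10, 10, 10), bead_types = 1L,
                        lipid_index = 1L, unwrapped = FALSE)
  expect_error(compute_msd(trap, 1), "unwrap")
  unw <- unwrap_trajectory(trap)
  expect_silent(compute_msd(unw, 1))
})
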