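test_that("Boltzmann inversion recovers harmonic bond parameters from oracle samples", {
  samp <- sample_harmonic_bond(2e4, k = 5, r0 = 3, temperature = 300, seed = 11)
  bp <- fit_bond_prior(samp, 300)
  expect_lt(abs(bp$k / 5 - 1), 0.05)
  expect_lt(abs(bp$r0 / 3 - 1), 0.01)
  ## degenerate distribution
  expect_error(fit_bond_prior(rep(3, 500), 300), "degenerate")
  expect_error(fit_bond_prior(1:50, 300), "sample-size")
})

test_that("V0 is a pure offset: identical forces for any base potential", {
  sys <- dimer_system(1)
  p0 <- prior_force_field(bonds = list(`A-A` = bond_prior(5, 4, V0 = 0)),
                          repulsions = list(`A:A` = repulsive_prior(0, 0)),
                          cutoff = 8)
  p7 <- prior_force_field(bonds = list(`A-A` = bond_prior(5, 4, V0 = 7)),
                          repulsions = list(`A:A` = repulsive_prior(0, 0)),
                          cutoff = 8)
  f0 <- evaluate_prior(sys$frame, sys$topo, p0)
  f7 <- evaluate_prior(sys$frame, sys$topo, p7)
  expect_equal(f0$forces, f7$forces)
  expect_equal(f7$energy - f0$energy, 7)
})

test_that("repulsive prior: analytic force values, limits, and recovery from samples", {
  rp <- repulsive_prior(1, 0)
  ## |dV/dr| at r = 1 with eps = 1 is 24 (V = 4 eps r^-6)
  expect_equal(24 * rp$epsilon * 1^-7, 24)
  ## force decays to zero at long range
  expect_lt(24 * rp$epsilon * 50^-7, 1e-10)
  samp <- sample_repulsive_wall(5e4, eps = 1, temperature = 300,
                                rlo = 0.9, rhi = 2.5, seed = 13)
  fit <- fit_repulsive_prior(samp, 300, fit_range = c(0.95, 1.6))
  expect_lt(abs(fit$epsilon / 1 - 1), 0.10)
  expect_error(fit_repulsive_prior(samp, 300, fit_range = c(5, 6)), "fit-domain")
})

test_that("prior energy/forces: minimum, momentum conservation, gradient oracle", {
  sys <- dimer_system(1, bond_r = 4)
  prior <- prior_force_field(bonds = list(`A-A` = bond_prior(5, 4, V0 = 2)),
                             repulsions = list(`A:A` = repulsive_prior(0, 0)),
                             cutoff = 8)
  ef <- evaluate_prior(sys$frame, sys$topo, prior)
  expect_equal(ef$energy, 2)            # bond at r0: only V0 remains
  expect_equal(max(abs(ef$forces)), 0)  # and zero force

  fr <- random_frame(30, box = c(15, 15, 15), seed = 3, min_sep = 1.6)
  topo <- structure(list(bond_pairs = rbind(c(1L, 2L), c(3L, 4L)),
                         bond_type = c("A-A", "A-A"),
                         bead_types = fr$bead_types,
                         type_codes = c(A = 1L, B = 2L, C = 3L),
                         lipid_index = fr$lipid_index, n_beads = 30L),
                    class = "cg_topology")
  prior2 <- uniform_prior(c("A", "B", "C"), eps = 50,
                          bonds = list(`A-A` = bond_prior(3, 2.5)), cutoff = 6)
  ef2 <- evaluate_prior(fr, topo, prior2)
  expect_lt(max(abs(colSums(ef2$forces))), 1e-9)  # Newton's third law
  h <- 1e-5
  for (i in c(1, 13, 30)) for (k in 1:3) {
    fp <- fr; fp$coords[i, k] <- fp$coords[i, k] + h
    fm <- fr; fm$coords[i, k] <- fm$coords[i, k] - h
    fd <- -(evaluate_prior(fp, topo, prior2)$energy -
              evaluate_prior(fm, topo, prior2)$energy) / (2 * h)
    expect_lt(abs(fd - ef2$forces[i, k]) / max(1, abs(fd)), 1e-5)
  }
})

test_that("prior forces are translation invariant and rotation equivariant", {
  fr <- random_frame(20, box = c(200, 200, 200), seed = 6, min_sep = 1.6)
  fr$coords <- fr$coords / 10 + 90   # compact cluster far from the boundary
  topo <- structure(list(bond_pairs = NULL, bond_type = character(0),
                         bead_types = fr$bead_types,
                         type_codes = c(A = 1L, B = 2L, C = 3L),
                         lipid_index = fr$lipid_index, n_beads = 20L),
                    class = "cg_topology")
  prior <- uniform_prior(c("A", "B", "C"), eps = 100, cutoff = 6)
  f0 <- evaluate_prior(fr, topo, prior)
  fr_t <- fr; fr_t$coords <- sweep(fr$coords, 2, c(-3, 1, 2))
  ft <- evaluate_prior(fr_t, topo, prior)
  expect_equal(ft$energy, f0$energy, tolerance = 1e-12)
  expect_equal(ft$forces, f0$forces, tolerance = 1e-10)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ctr <- colMeans(fr$coords)
  fr_r <- fr
  fr_r$coords <- sweep(sweep(fr$coords, 2, ctr) %*% t(R), 2, ctr, "+")
  frot <- evaluate_prior(fr_r, topo, prior)
  expect_equal(frot$energy, f0$energy, tolerance = 1e-9)
  expect_equal(frot$forces, f0$forces %*% t(R), tolerance = 1e-9)
})

test_that("delta forces satisfy the exact decomposition identity", {
  set.seed(2)
  mapped <- matrix(rnorm(30), 10, 3)
  priorf <- matrix(rnorm(30), 10, 3)
  delta <- compute_delta_forces(mapped, priorf)
  expect_equal(delta, mapped - priorf)                    # brute-force oracle
  expect_equal(compute_delta_forces(mapped, 0 * priorf), mapped)
  expect_equal(compute_delta_forces(mapped, mapped), 0 * mapped)
  expect_equal(priorf + delta, mapped, tolerance = 1e-15) # identity
  expect_error(compute_delta_forces(mapped, priorf[1:5, ]), "dimension")
})

test_that("B-spline bonded term resolves bimodal and unimodal distributions", {
  set.seed(31)
  bim <- c(rnorm(2e4, 3.3, 0.15), rnorm(2e4, 4.4, 0.15))
  ## sparse far tails leave empty interior bins: warned, then interpolated
  expect_warning(term <- fit_spline_bond(bim, 300, n_knots = 14),
                 "empty histogram bin")
  grid <- seq(min(bim) + 0.05, max(bim) - 0.05, length.out = 2000)
  v <- eval_spline_bond(term, grid)
  interior <- which(diff(sign(diff(v))) == 2) + 1L  # local minima
  minima <- grid[interior]
  expect_true(any(abs(minima - 3.3) < 0.1))
  expect_true(any(abs(minima - 4.4) < 0.1))

  uni <- rnorm(2e4, 3.5, 0.2)
  term_u <- suppressWarnings(fit_spline_bond(uni, 300, n_knots = 10))
  g2 <- seq(3.0, 4.0, length.out = 2000)
  expect_lt(abs(g2[which.min(eval_spline_bond(term_u, g2))] / 3.5 - 1), 0.02)

  term0 <- term
  term0$coefficients[] <- 0
  expect_equal(eval_spline_bond(term0, grid), rep(0, length(grid)))
  ## C1 extrapolation: derivative continuous at the boundary
  lo <- term$knots[1]
  expect_equal(eval_spline_bond(term, lo - 1e-6, deriv = 1),
               eval_spline_bond(term, lo + 1e-6, deriv = 1), tolerance = 1e-3)
})

test_that("Boltzmann-inversion round trip recovers the fitted bond", {
  bp <- bond_prior(k = 4, r0 = 3.5)
  samp <- sample_harmonic_bond(2e4, bp$k, bp$r0, 300, seed = 17)
  refit <- fit_bond_prior(samp, 300)
  expect_lt(abs(refit$k / bp$k - 1), 0.05)
  expect_lt(abs(refit$r0 / bp$r0 - 1), 0.01)
})

test_that("prior force field serialization round-trips", {
  prior <- prior_force_field(
    bonds = list(`HG-MG` = bond_prior(5.1, 4.83, 0.2)),
    repulsions = list(`HG:HG` = repulsive_prior(123.45, -0.7)),
    cutoff = 11.5, r_guard = 0.4)
  path <- tempfile(fileext = ".json")
  write_prior(prior, path)
  back <- read_prior(path)
  expect_equal(back$bonds$`HG-MG`$k, prior$bonds$`HG-MG`$k)
  expect_equal(back$repulsions$`HG:HG`$epsilon, prior$repulsions$`HG:HG`$epsilon)
  expect_equal(back$cutoff, prior$cutoff)
})
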