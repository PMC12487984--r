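test_that("neighbor search honors the minimum image and matches brute force", {
  fr <- cg_frame(rbind(c(0, 0, 0), c(9, 0, 0)), bead_types = c(1L, 1L),
                 lipid_index = c(1L, 2L), box = c(10, 10, 10))
  np <- neighbor_pairs(fr, 2)
  expect_equal(length(np$r), 1L)
  expect_equal(np$r, 1)                      # wrap case

  fr2 <- random_frame(20, seed = 2, min_sep = 1.2)
  expect_equal(length(neighbor_pairs(fr2, 0.1)$r), 0L)  # empty graph

  fr3 <- random_frame(50, box = c(12, 12, 12), seed = 7, min_sep = 1.0)
  np3 <- neighbor_pairs(fr3, 5)
  ## O(N^2) double-loop oracle
  got <- sort(paste(np3$i, np3$j))
  want <- character(0)
  for (i in 1:49) for (j in (i + 1):50) {
    d <- fr3$coords[i, ] - fr3$coords[j, ]
    d <- d - 12 * round(d / 12)
    if (sqrt(sum(d^2)) < 5) want <- c(want, paste(i, j))
  }
  expect_equal(got, sort(want))
  expect_error(neighbor_pairs(fr3, 7), "geometry")
})

test_that("both trainable potentials are translation and permutation invariant", {
  tc <- c(HG = 1L, MG = 2L, T1 = 3L)
  fr <- random_frame(15, box = c(14, 14, 14), seed = 5, min_sep = 1.3)
  models <- list(
    graph = graph_potential(graph_config(2, 12, 8, 5, 8), tc, seed = 3),
    spline = local({
      m <- spline_pair_potential(tc, cutoff = 5, n_knots = 6)
      set.param <- set_param_vector(m, rnorm(length(param_vector(m)), sd = 0.3))
      set.param
    }))
  for (m in models) {
    e0 <- energy_and_forces(m, fr)
    fr_t <- fr; fr_t$coords <- sweep(fr$coords, 2, c(2.5, -1, 0.3), "+")
    et <- energy_and_forces(m, fr_t)
    expect_equal(et$energy, e0$energy, tolerance = 1e-10)
    expect_equal(et$forces, e0$forces, tolerance = 1e-9)
    ## swap two beads of the same type
    same <- which(fr$bead_types == fr$bead_types[1])
    if (length(same) >= 2) {
      i <- same[1]; j <- same[2]
      fr_p <- fr
      fr_p$coords[c(i, j), ] <- fr$coords[c(j, i), ]
      ep <- energy_and_forces(m, fr_p)
      expect_equal(ep$energy, e0$energy, tolerance = 1e-10)
    }
  }
  ## unknown bead type
  fr_bad <- fr; fr_bad$bead_types[1] <- 9L
  expect_error(energy_and_forces(models$graph, fr_bad), "vocabulary")
})

test_that("forces are exact negative energy gradients (finite-difference oracle)", {
  tc <- c(A = 1L, B = 2L)
  fr <- random_frame(20, box = c(12, 12, 12), types = 1:2, seed = 9, min_sep = 1.1)
  g <- graph_potential(graph_config(2, 10, 8, 4.5, 6), tc, seed = 2)
  s <- spline_pair_potential(tc, cutoff = 4.5, n_knots = 6)
  s <- set_param_vector(s, rnorm(length(param_vector(s)), sd = 0.5))
  for (m in list(g, s)) {
    ef <- energy_and_forces(m, fr)
    h <- 1e-5
    for (i in c(1, 10, 20)) for (k in 1:3) {
      fp <- fr; fp$coords[i, k] <- fp$coords[i, k] + h
      fm <- fr; fm$coords[i, k] <- fm$coords[i, k] - h
      fd <- -(energy_and_forces(m, fp)$energy -
                energy_and_forces(m, fm)$energy) / (2 * h)
      expect_lt(abs(fd - ef$forces[i, k]) / max(1e-6, abs(fd)), 1e-4)
    }
  }
})

test_that("energy is continuous as a neighbor crosses the cutoff", {
  tc <- c(A = 1L)
  rc <- 5
  for (m in list(graph_potential(graph_config(1, 8, 6, rc, 6), tc, seed = 4),
                 set_param_vector(spline_pair_potential(tc, rc, 6),
                                  rnorm(8 + 0, sd = 1) |> rep(length.out = 8)))) {
    e <- vapply(c(rc - 1e-4, rc - 1e-7, rc + 1e-7), function(d) {
      fr <- cg_frame(rbind(c(1, 1, 1), c(1 + d, 1, 1)), bead_types = c(1L, 1L),
                     lipid_index = 1:2, box = c(20, 20, 20))
      energy_and_forces(m, fr)$energy
    }, 0)
    expect_lt(abs(e[2] - e[3]), 1e-8)        # continuous across the cutoff
    expect_lt(abs(e[1] - e[2]), 1e-3)        # and smoothly approaching zero
  }
})

test_that("parameter gradient of the force-matching loss is exact for the graph net", {
  tc <- c(A = 1L, B = 2L)
  fr <- random_frame(12, box = c(10, 10, 10), types = 1:2, seed = 12, min_sep = 1.1)
  m <- graph_potential(graph_config(2, 8, 6, 4, 5), tc, seed = 6)
  set.seed(1)
  tgt <- matrix(rnorm(36), 12, 3)
  lg <- fm_loss_grad(m, fr, tgt)
  v <- param_vector(m)
  idx <- sample(length(v), 25)
  h <- 1e-4
  for (ii in idx) {
    vp <- v; vp[ii] <- vp[ii] + h
    vm <- v; vm[ii] <- vm[ii] - h
    fd <- (fm_loss_grad(set_param_vector(m, vp), fr, tgt)$loss -
             fm_loss_grad(set_param_vector(m, vm), fr, tgt)$loss) / (2 * h)
    expect_lt(abs(fd - lg$grad[ii]) / (abs(fd) + 1e-4), 1e-5)
  }
})

test_that("spline potential reproduces a tabulated pair potential it is fit to", {
  tc <- c(A = 1L)
  rc <- 6
  m <- spline_pair_potential(tc, cutoff = rc, n_knots = 12)
  vtab <- function(r) 2 * exp(-(r - 3)^2 / 0.8)     # target pair potential
  rg <- seq(0.5, rc - 0.01, length.out = 300)
  env <- 0.5 * (cos(pi * rg / rc) + 1)
  B <- splines::splineDesign(m$knots, rg, ord = 4)
  cf <- qr.solve(B * env, vtab(rg) * env)           # fit V*env with basis*env
  m$coefs[, "1:1"] <- cf
  test_r <- seq(1.5, 5, length.out = 50)
  got <- vapply(test_r, function(d) {
    fr <- cg_frame(rbind(c(1, 1, 1), c(1 + d, 1, 1)), bead_types = c(1L, 1L),
                   lipid_index = 1:2, box = c(30, 30, 30))
    energy_and_forces(m, fr)$energy
  }, 0)
  want <- vtab(test_r) * 0.5 * (cos(pi * test_r / rc) + 1)
  expect_lt(sqrt(mean((got - want)^2)), 0.02)
})

test_that("total force field is the elementwise sum of prior and model", {
  sys <- dimer_system(3, bond_r = 3.5)
  prior <- prior_force_field(bonds = list(`A-A` = bond_prior(4, 4)),
                             repulsions = list(`A:A` = repulsive_prior(200, 0)),
                             cutoff = 8)
  m <- spline_pair_potential(c(A = 1L), cutoff = 8, n_knots = 6)
  m1 <- set_param_vector(m, rnorm(length(param_vector(m)), sd = 0.2))
  fp <- evaluate_prior(sys$frame, sys$topo, prior)
  fmod <- energy_and_forces(m1, sys$frame)
  tot <- total_force_field(sys$frame, sys$topo, prior, m1)
  expect_equal(tot$forces, fp$forces + fmod$forces, tolerance = 1e-12)
  ## zero-parameter model reduces to the prior alone
  expect_equal(total_force_field(sys$frame, sys$topo, prior, m)$forces,
               fp$forces, tolerance = 1e-12)
  ## no prior reduces to the model alone
  expect_equal(total_force_field(sys$frame, sys$topo, NULL, m1)$forces,
               fmod$forces, tolerance = 1e-12)
})

test_that("checkpoints round-trip bit-stably for both model families", {
  tc <- c(HG = 1L, T1 = 2L)
  g <- graph_potential(graph_config(2, 10, 6, 6, 8), tc, seed = 11)
  g <- set_param_vector(g, param_vector(g) * pi)   # non-trivial values
  p1 <- tempfile(fileext = ".json")
  save_checkpoint(g, p1)
  expect_identical(param_vector(load_checkpoint(p1)), param_vector(g))

  s <- spline_pair_potential(tc, cutoff = 7.3, n_knots = 9)
  s <- set_param_vector(s, rnorm(length(param_vector(s))))
  p2 <- tempfile(fileext = ".json")
  save_checkpoint(s, p2)
  s2 <- load_checkpoint(p2)
  expect_identical(param_vector(s2), param_vector(s))
  expect_identical(s2$knots, s$knots)
  expect_error(load_checkpoint(tempfile()), "not found")
})
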