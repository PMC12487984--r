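test_that("bead positions are mass-weighted group means", {
  sch <- mapping_scheme("X",
    beads = list(list(label = "A", type = "HG", atoms = 1L, masses = 2)),
    bonds = list(), n_atoms = 1L)
  fr <- atomistic_frame(coords = matrix(c(1, 2, 3), 1), forces = matrix(0, 1, 3),
                        masses = 2, lipid_index = 1L, lipid_type = "X",
                        box = c(10, 10, 10))
  expect_equal(map_coordinates(fr, sch), matrix(c(1, 2, 3), 1))

  sch2 <- mapping_scheme("X",
    beads = list(list(label = "A", type = "HG", atoms = 1:2, masses = c(1, 1))),
    bonds = list(), n_atoms = 2L)
  fr2 <- atomistic_frame(coords = rbind(c(0, 0, 0), c(2, 0, 0)),
                         forces = matrix(0, 2, 3), masses = c(1, 1),
                         lipid_index = c(1L, 1L), lipid_type = "X",
                         box = c(10, 10, 10))
  expect_equal(map_coordinates(fr2, sch2), matrix(c(1, 0, 0), 1))
})

test_that("mapping matches an explicit per-group loop oracle and yields six beads", {
  set.seed(21)
  n_lip <- 3
  apb <- 4
  masses <- runif(6 * apb, 1, 15)
  beads <- lapply(1:6, function(j)
    list(label = paste0("B", j), type = c("HG", "MG", "T1", "T2", "T1", "T2")[j],
         atoms = ((j - 1) * apb + 1):(j * apb),
         masses = masses[((j - 1) * apb + 1):(j * apb)]))
  sch <- mapping_scheme("DOPCISH", beads,
                        bonds = list(c("B1", "B2"), c("B2", "B3"), c("B3", "B4"),
                                     c("B2", "B5"), c("B5", "B6")),
                        n_atoms = 24L)
  na <- 24 * n_lip
  fr <- atomistic_frame(coords = matrix(runif(na * 3, 0, 30), na),
                        forces = matrix(rnorm(na * 3), na),
                        masses = rep(masses, n_lip),
                        lipid_index = rep(1:n_lip, each = 24),
                        lipid_type = "DOPCISH", box = c(100, 100, 100))
  xm <- map_coordinates(fr, sch)
  fm <- map_forces(fr, sch)
  expect_equal(nrow(xm), 6 * n_lip)  # six beads per lipid
  ## brute-force oracle with explicit loops (box large: no wrapping involved)
  for (lip in 1:n_lip) for (j in 1:6) {
    rows <- (lip - 1) * 24 + beads[[j]]$atoms
    m <- beads[[j]]$masses
    com <- c(sum(fr$coords[rows, 1] * m), sum(fr$coords[rows, 2] * m),
             sum(fr$coords[rows, 3] * m)) / sum(m)
    expect_equal(unname(xm[(lip - 1) * 6 + j, ]), unname(com), tolerance = 1e-12)
    expect_equal(unname(fm[(lip - 1) * 6 + j, ]), unname(colSums(fr$forces[rows, ])),
                 tolerance = 1e-12)
  }
})

test_that("force mapping conserves the total force and cancels internal pairs", {
  sch <- mapping_scheme("X",
    beads = list(list(label = "A", type = "HG", atoms = 1:2, masses = c(1, 3))),
    bonds = list(), n_atoms = 2L)
  fr <- atomistic_frame(coords = rbind(c(0, 0, 0), c(1, 0, 0)),
                        forces = rbind(c(1, 0, 0), c(-1, 0, 0)),
                        masses = c(1, 3), lipid_index = c(1L, 1L),
                        lipid_type = "X", box = c(10, 10, 10))
  expect_equal(map_forces(fr, sch), matrix(0, 1, 3))

  set.seed(4)
  spec <- fixture_spec(4, "random-gas", seed = 8, n_frames = 2,
                       save_every = 100, burn_in = 100, timestep = 4)
  ds <- generate_cg_dataset(spec)
  ex <- expand_pseudo_atomistic(ds, atoms_per_bead = 3, seed = 2)
  for (t in 1:2) {
    fm <- map_forces(ex$frames[[t]], ex$scheme)
    expect_equal(colSums(fm), colSums(ex$frames[[t]]$forces), tolerance = 1e-12)
  }
})

test_that("mapping is translation equivariant and conserves mass, across the PBC", {
  set.seed(9)
  spec <- fixture_spec(4, "random-gas", seed = 5, n_frames = 1,
                       save_every = 100, burn_in = 100, timestep = 4)
  ds <- generate_cg_dataset(spec)
  ex <- expand_pseudo_atomistic(ds, atoms_per_bead = 2, seed = 3)
  fr <- ex$frames[[1]]
  x0 <- map_coordinates(fr, ex$scheme)
  t_shift <- c(1.3, -2.2, 0.7)
  fr2 <- fr; fr2$coords <- sweep(fr$coords, 2, -t_shift)
  expect_equal(map_coordinates(fr2, ex$scheme), sweep(x0, 2, -t_shift),
               tolerance = 1e-12)
  ## per-lipid mass conservation
  sch_mass <- sum(unlist(lapply(ex$scheme$beads, `[[`, "masses")))
  expect_equal(sum(fr$masses[fr$lipid_index == 1]), sch_mass)
})

test_that("topology counting, indexing and error cases are right", {
  topo1 <- six_bead_topology(1)
  expect_equal(nrow(topo1$bond_pairs), 5L)
  expect_equal(topo1$n_beads, 6L)
  topo512 <- six_bead_topology(512)
  expect_equal(nrow(topo512$bond_pairs), 2560L)
  expect_equal(topo512$n_beads, 3072L)
  expect_true(all(topo512$bond_pairs >= 1 & topo512$bond_pairs <= 3072))
  expect_error(six_bead_topology(0), "config error")
})

test_that("mapping errors are explicit", {
  sch <- mapping_scheme("X",
    beads = list(list(label = "A", type = "HG", atoms = 1L, masses = 1)),
    bonds = list(), n_atoms = 1L)
  fr <- atomistic_frame(coords = matrix(0, 2, 3), forces = matrix(0, 2, 3),
                        masses = c(1, 1), lipid_index = c(1L, 1L),
                        lipid_type = "X", box = c(10, 10, 10))
  expect_error(map_coordinates(fr, sch), "coverage")
  expect_error(mapping_scheme("X",
    beads = list(list(label = "A", type = "HG", atoms = 1L, masses = -1)),
    bonds = list(), n_atoms = 1L), "positive")
})
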