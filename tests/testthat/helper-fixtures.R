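# Shared fixture builders and independent oracles.

kB <- cg_units()$kB

# Two-bead "dimer" molecules on a sparse grid: n_mol identical molecules,
# one A-A bond each, in a large box.
dimer_system <- function(n_mol = 20, bond_r = 4, sep = 15, box = c(80, 80, 80)) {
  topo <- build_topology(mapping_scheme(
    "DIMER",
    beads = list(list(label = "A1", type = "A", atoms = 1L, masses = 1),
                 list(label = "A2", type = "A", atoms = 2L, masses = 1)),
    bonds = list(c("A1", "A2")), n_atoms = 2L), c(DIMER = n_mol))
  x <- do.call(rbind, lapply(seq_len(n_mol), function(i) {
    c0 <- c((i - 1) %% 5, (i - 1) %/% 5, 0) * sep + 10
    rbind(c0 - c(bond_r / 2, 0, 0), c0 + c(bond_r / 2, 0, 0))
  }))
  list(topo = topo,
       frame = cg_frame(x, bead_types = topo$bead_types,
                        lipid_index = topo$lipid_index, box = box))
}

# Random frame of n beads with a minimum separation (keeps prior forces tame).
random_frame <- function(n, box = c(20, 20, 20), types = 1:3, seed = 1,
                         min_sep = 1.5) {
  set.seed(seed)
  x <- matrix(NA_real_, n, 3)
  placed <- 0L
  while (placed < n) {
    cand <- runif(3, 0, box)
    ok <- placed == 0L ||
      min(sqrt(rowSums(min_image(sweep(x[seq_len(placed), , drop = FALSE],
                                       2, cand), box)^2))) > min_sep
    if (ok) { placed <- placed + 1L; x[placed, ] <- cand }
  }
  cg_frame(x, bead_types = sample(types, n, replace = TRUE),
           lipid_index = rep_len(1:4, n), box = box)
}

# Inverse-CDF sampler from the radial Boltzmann density p(r) ~ r^2 exp(-V/kBT)
# of a harmonic bond V = k (r - r0)^2 -- the independent oracle for
# Boltzmann-inversion tests.
sample_harmonic_bond <- function(n, k, r0, temperature, seed,
                                 rmin = max(0.2, r0 - 2), rmax = r0 + 2) {
  grid <- seq(rmin, rmax, length.out = 8001)
  dens <- grid^2 * exp(-k * (grid - r0)^2 / (kB * temperature))
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  set.seed(seed)
  stats::approx(cdf, grid, runif(n), rule = 2, ties = "ordered")$y
}

# Analytic radial-Boltzmann CDF of a harmonic bond on [rmin, rmax]
# (trapezoid-integrated on a fine grid; used as the KS reference).
harmonic_bond_cdf <- function(k, r0, temperature, rmin, rmax) {
  grid <- seq(rmin, rmax, length.out = 20001)
  dens <- grid^2 * exp(-k * (grid - r0)^2 / (kB * temperature))
  cdf <- cumsum(c(0, (dens[-1] + dens[-length(dens)]) / 2 * diff(grid)))
  cdf <- cdf / cdf[length(cdf)]
  function(q) stats::approx(grid, cdf, q, rule = 2)$y
}

# Rejection sampler from p(r) ~ r^2 exp(-4 eps r^-6 / kBT) in a shell.
sample_repulsive_wall <- function(n, eps, temperature, rlo, rhi, seed) {
  set.seed(seed)
  out <- numeric(0)
  fmax <- rhi^2
  while (length(out) < n) {
    r <- runif(2 * n, rlo, rhi)
    acc <- runif(2 * n) < r^2 * exp(-4 * eps * r^-6 / (kB * temperature)) / fmax
    out <- c(out, r[acc])
  }
  out[seq_len(n)]
}

# Uniform prior force field over the given type labels.
uniform_prior <- function(type_labels, eps = 500, bonds = list(), cutoff = 8) {
  g <- expand.grid(a = type_labels, b = type_labels, stringsAsFactors = FALSE)
  g <- g[g$a <= g$b, ]
  reps <- stats::setNames(
    lapply(seq_len(nrow(g)), function(i) repulsive_prior(eps, 0)),
    pair_key(g$a, g$b))
  prior_force_field(bonds = bonds, repulsions = reps, cutoff = cutoff)
}

# Trajectory with a single static frame.
one_frame_traj <- function(coords, box, types = NULL) {
  cg_trajectory(array(coords, c(nrow(coords), 3, 1)), box = box,
                bead_types = types %||% rep(1L, nrow(coords)),
                lipid_index = seq_len(nrow(coords)), unwrapped = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
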