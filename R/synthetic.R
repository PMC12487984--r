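## Ground-truth fixtures: a toy CG lipid force field with known parameters,
## bilayer/gas/dimer configurations, exact forces, and pseudo-atomistic
## expansions that the mapping inverts exactly.

#' Toy CG lipid force field with known parameters
#'
#' Stands in for a reference atomistic ensemble: harmonic bonds plus pairwise
#' terms of the form `(a r^-6 + b exp(-(r-rm)^2/(2 w^2))) * envelope(r)` —
#' a short-range repulsion with an optional Gaussian cohesion well, smoothly
#' truncated at the cutoff. Forces are exact analytic gradients. The default
#' parameters make a six-bead bilayer metastable over fixture-length runs:
#' tail beads attract each other (solvent-free cohesion), headgroups repel
#' tails.
#'
#' @param bonds named list (bond type "A-B") of `list(k, r0)` in
#'   kcal mol^-1 A^-2 and A; convention `V = k (r - r0)^2`.
#' @param pairs named list (type pair "A:B") of `list(a, b, rm, w)`:
#'   `a` (kcal mol^-1 A^6) repulsion, `b` (kcal mol^-1) well depth (negative
#'   = cohesive), `rm`/`w` (A) well position and width.
#' @param cutoff pair cutoff (A); 1-2 bonded pairs are excluded.
#' @param masses named per-bead-type masses (amu).
#' @return Object of class `toy_force_field`.
#' @export
toy_force_field <- function(bonds, pairs, cutoff = 12,
                            masses = c(HG = 90, MG = 120, T1 = 110, T2 = 110)) {
  structure(list(bonds = bonds, pairs = pairs, cutoff = cutoff,
                 masses = masses),
            class = "toy_force_field")
}

#' Default toy lipid force field
#' @return A [toy_force_field()] for the HG/MG/T1/T2 six-bead lipid.
#' @export
toy_lipid_ff <- function() {
  rep_only <- function(a) list(a = a, b = 0, rm = 5, w = 1.5)
  cohesive <- function(a, b) list(a = a, b = b, rm = 5, w = 1.5)
  toy_force_field(
    bonds = list(`HG-MG` = list(k = 5, r0 = 4.8),
                 `MG-T1` = list(k = 5, r0 = 4.4),
                 `T1-T2` = list(k = 5, r0 = 4.0)),
    pairs = list(`HG:HG` = rep_only(12000),
                 `HG:MG` = rep_only(10000),
                 `HG:T1` = rep_only(12000),
                 `HG:T2` = rep_only(12000),
                 `MG:MG` = rep_only(8000),
                 `MG:T1` = cohesive(8000, -0.6),
                 `MG:T2` = rep_only(8000),
                 `T1:T1` = cohesive(6000, -1.5),
                 `T1:T2` = cohesive(6000, -1.5),
                 `T2:T2` = cohesive(6000, -1.5)),
    cutoff = 12)
}

#' Evaluate the toy force field
#'
#' @param frame a [cg_frame()].
#' @param topo matching topology (for bonds and 1-2 exclusions).
#' @param ff a [toy_force_field()].
#' @return List with `energy` and `forces` (exact analytic gradients).
#' @export
evaluate_toy <- function(frame, topo, ff) {
  n <- nrow(frame$coords)
  energy <- 0; forces <- matrix(0, n, 3L)
  bp <- topo$bond_pairs
  if (!is.null(bp) && nrow(bp) > 0L) {
    dx <- min_image(frame$coords[bp[, 1], , drop = FALSE] -
                      frame$coords[bp[, 2], , drop = FALSE], frame$box)
    r <- sqrt(rowSums(dx * dx))
    k <- vapply(ff$bonds[topo$bond_type], `[[`, 0, "k")
    r0 <- vapply(ff$bonds[topo$bond_type], `[[`, 0, "r0")
    energy <- energy + sum(k * (r - r0)^2)
    fvec <- dx * (-(2 * k * (r - r0)) / r)
    forces <- forces + .accumulate_rows(n, c(bp[, 1], bp[, 2]), rbind(fvec, -fvec))
  }
  pairs <- .exclude_bonded(neighbor_pairs(frame, ff$cutoff), topo)
  if (length(pairs$r) > 0L) {
    tpos <- match(frame$bead_types, topo$type_codes)
    idx <- cbind(tpos[pairs$i], tpos[pairs$j])
    a <- .pair_param_matrix(ff$pairs, "a", topo$type_codes)[idx]
    b <- .pair_param_matrix(ff$pairs, "b", topo$type_codes)[idx]
    rm_ <- .pair_param_matrix(ff$pairs, "rm", topo$type_codes)[idx]
    w <- .pair_param_matrix(ff$pairs, "w", topo$type_codes)[idx]
    if (anyNA(a)) {
      labs <- .code_to_label(frame$bead_types, topo$type_codes)
      stop("missing toy pair term for: ",
           paste(unique(pair_key(labs[pairs$i], labs[pairs$j])[is.na(a)]),
                 collapse = ", "))
    }
    r <- pairs$r
    env <- .envelope(r, ff$cutoff); envd <- .envelope_d(r, ff$cutoff)
    gauss <- exp(-(r - rm_)^2 / (2 * w^2))
    core <- a * r^-6 + b * gauss
    dcore <- -6 * a * r^-7 + b * gauss * (-(r - rm_) / w^2)
    energy <- energy + sum(core * env)
    forces <- forces + .central_forces(n, pairs, dcore * env + core * envd)
  }
  list(energy = energy, forces = forces)
}

#' Per-bead masses for a topology
#' @param topo a topology from [build_topology()].
#' @param masses named per-type masses (amu).
#' @return Numeric vector, one mass per bead.
#' @export
bead_masses <- function(topo, masses) {
  labs <- .code_to_label(topo$bead_types, topo$type_codes)
  unname(masses[labs])
}

#' Fixture specification
#'
#' @param n_lipids number of lipids (bilayer geometry needs `2 k^2`).
#' @param geometry "bilayer", "random-gas" or "dimer".
#' @param temperature sampling temperature (K).
#' @param seed mandatory fixture seed.
#' @param n_frames frames to store after burn-in.
#' @param save_every steps between stored frames (>= 100 to reduce
#'   autocorrelation between samples).
#' @param burn_in equilibration steps discarded before storing.
#' @param timestep integration step (fs).
#' @param damping thermostat friction (ps^-1) used while generating the
#'   fixture ensemble (stronger than production damping, for sampling
#'   efficiency).
#' @param spacing bilayer in-plane lattice constant (A).
#' @param box_z box height (A) for the bilayer; full box for other
#'   geometries is derived from the spec.
#' @param atoms_per_bead atoms per bead for the pseudo-atomistic expansion.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_lipids, geometry = c("bilayer", "random-gas", "dimer"),
                         temperature = 300, seed, n_frames = 100L,
                         save_every = 100L, burn_in = 2000L, timestep = 8,
                         damping = 10, spacing = 8, box_z = 60,
                         atoms_per_bead = 3L) {
  if (missing(seed)) stop("a fixture seed is mandatory")
  geometry <- match.arg(geometry)
  structure(list(n_lipids = as.integer(n_lipids), geometry = geometry,
                 temperature = temperature, seed = as.integer(seed),
                 n_frames = as.integer(n_frames),
                 save_every = as.integer(save_every),
                 burn_in = as.integer(burn_in), timestep = timestep,
                 damping = damping, spacing = spacing, box_z = box_z,
                 atoms_per_bead = as.integer(atoms_per_bead)),
            class = "fixture_spec")
}

## Six-bead lipid template (upper leaflet, centered on x0/y0); the two tails
## hang from MG toward the midplane, splayed +-1.75 A laterally so that the
## unexcluded 1-3 tail-tail contact starts outside the repulsive core.
.lipid_template <- function(x0, y0, upper = TRUE) {
  s <- if (upper) 1 else -1
  rbind(c(x0,        y0, s * 13.0),   # HG
        c(x0,        y0, s * 8.2),    # MG
        c(x0 - 1.75, y0, s * 4.16),   # T1a (MG-T1 distance ~4.4)
        c(x0 - 1.75, y0, s * 0.16),   # T2a
        c(x0 + 1.75, y0, s * 4.16),   # T1b
        c(x0 + 1.75, y0, s * 0.16))   # T2b
}

#' Standard six-bead lipid mapping-scheme topology (bead level)
#'
#' Bead order HG, MG, T1a, T2a, T1b, T2b with the five bonds
#' HG-MG, MG-T1a, T1a-T2a, MG-T1b, T1b-T2b.
#'
#' @param n_lipids lipid count.
#' @return A `cg_topology` for identical six-bead lipids.
#' @export
six_bead_topology <- function(n_lipids) {
  beads <- list(
    list(label = "HG", type = "HG", atoms = 1L, masses = 1),
    list(label = "MG", type = "MG", atoms = 2L, masses = 1),
    list(label = "T1a", type = "T1", atoms = 3L, masses = 1),
    list(label = "T2a", type = "T2", atoms = 4L, masses = 1),
    list(label = "T1b", type = "T1", atoms = 5L, masses = 1),
    list(label = "T2b", type = "T2", atoms = 6L, masses = 1))
  sch <- mapping_scheme("TOY", beads,
                        bonds = list(c("HG", "MG"), c("MG", "T1a"),
                                     c("T1a", "T2a"), c("MG", "T1b"),
                                     c("T1b", "T2b")),
                        n_atoms = 6L)
  build_topology(sch, c(TOY = n_lipids))
}

#' Build the initial configuration for a fixture
#' @param spec a [fixture_spec()].
#' @return List with `frame` (a [cg_frame()]) and `topo`.
#' @export
initial_configuration <- function(spec) {
  if (spec$geometry == "dimer") {
    topo <- build_topology(
      mapping_scheme("DIMER",
                     beads = list(list(label = "A1", type = "A", atoms = 1L, masses = 1),
                                  list(label = "A2", type = "A", atoms = 2L, masses = 1)),
                     bonds = list(c("A1", "A2")), n_atoms = 2L),
      c(DIMER = spec$n_lipids))
    old <- .Random.seed_save(); set.seed(spec$seed)
    centers <- matrix(stats::runif(3 * spec$n_lipids, 10, 40), ncol = 3)
    .Random.seed_restore(old)
    x <- do.call(rbind, lapply(seq_len(spec$n_lipids), function(i)
      rbind(centers[i, ] - c(2, 0, 0), centers[i, ] + c(2, 0, 0))))
    frame <- cg_frame(x, bead_types = topo$bead_types,
                      lipid_index = topo$lipid_index, box = c(50, 50, 50))
    return(list(frame = frame, topo = topo))
  }
  topo <- six_bead_topology(spec$n_lipids)
  if (spec$geometry == "bilayer") {
    per_leaf <- spec$n_lipids / 2
    k <- round(sqrt(per_leaf))
    if (spec$n_lipids %% 2 != 0 || k * k != per_leaf)
      stop("bilayer geometry needs n_lipids = 2 k^2 (e.g. 18, 32, 50)")
    box <- c(k * spec$spacing, k * spec$spacing, spec$box_z)
    sites <- expand.grid(ix = seq_len(k) - 1L, iy = seq_len(k) - 1L)
    coords <- vector("list", spec$n_lipids)
    li <- 0L
    for (upper in c(TRUE, FALSE)) {
      off <- if (upper) spec$spacing / 2 else 0  # stagger leaflets
      for (s in seq_len(k * k)) {
        li <- li + 1L
        coords[[li]] <- .lipid_template(sites$ix[s] * spec$spacing + off,
                                        sites$iy[s] * spec$spacing + off,
                                        upper = upper)
      }
    }
    x <- do.call(rbind, coords)
    x[, 3] <- x[, 3] + box[3] / 2   # midplane at box center
  } else {  # random-gas: randomly oriented chains on a sparse jittered grid
    ng <- ceiling(spec$n_lipids^(1 / 3))
    spacing <- 20
    box <- rep(ng * spacing, 3)
    sites <- expand.grid(ix = seq_len(ng), iy = seq_len(ng), iz = seq_len(ng))
    old <- .Random.seed_save(); set.seed(spec$seed)
    x <- do.call(rbind, lapply(seq_len(spec$n_lipids), function(i) {
      c0 <- (unlist(sites[i, ]) - 0.5) * spacing + stats::runif(3, -2, 2)
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      p <- c(-u[2], u[1], 0)
      if (sum(p^2) < 1e-6) p <- c(1, 0, 0)
      p <- p / sqrt(sum(p^2))
      s <- c(0, 4.8, 9.2, 13.2, 9.2, 13.2) - 6.6   # along the chain axis
      q <- c(0, 0, -1.2, -1.2, 1.2, 1.2)           # split the two tails
      do.call(rbind, lapply(1:6, function(j) c0 + s[j] * u + q[j] * p)) +
        matrix(stats::rnorm(18, sd = 0.2), 6, 3)
    }))
    .Random.seed_restore(old)
  }
  frame <- cg_frame(x, bead_types = topo$bead_types,
                    lipid_index = topo$lipid_index, box = box)
  list(frame = frame, topo = topo)
}

.hash_obj <- function(obj) {
  tmp <- tempfile()
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Generate a CG dataset with exact ground-truth forces
#'
#' Samples configurations by Langevin simulation under the toy force field
#' (burn-in discarded, frames stored at decorrelating intervals) and attaches
#' to every stored frame the toy forces re-evaluated at the stored
#' coordinates — exact by construction. The fixture is bit-reproducible from
#' (spec, seed); the spec hash is embedded in the output.
#'
#' @param spec a [fixture_spec()].
#' @param ff a [toy_force_field()]; defaults to [toy_lipid_ff()] (or a
#'   harmonic dimer field for the dimer geometry).
#' @return Object of class `cg_dataset`: list with `frames` (each carrying
#'   exact forces), `topo`, `initial`, `spec`, `ff` and `hash`.
#' @export
generate_cg_dataset <- function(spec, ff = NULL) {
  init <- initial_configuration(spec)
  if (is.null(ff)) {
    ff <- if (spec$geometry == "dimer")
      toy_force_field(bonds = list(`A-A` = list(k = 5, r0 = 4)),
                      pairs = list(`A:A` = list(a = 0, b = 0, rm = 5, w = 1)),
                      cutoff = 12, masses = c(A = 100))
    else toy_lipid_ff()
  }
  if (spec$burn_in %% spec$save_every != 0L)
    stop("burn_in must be a multiple of save_every")
  cfg <- langevin_config(temperature = spec$temperature, damping = spec$damping,
                         timestep = spec$timestep,
                         n_steps = spec$burn_in + spec$n_frames * spec$save_every,
                         save_every = spec$save_every, seed = spec$seed,
                         masses = bead_masses(init$topo, ff$masses))
  traj <- tryCatch(
    run_simulation(init$frame, init$topo, prior = ff, model = NULL, cfg),
    error = function(e) stop("fixture equilibration failed (", conditionMessage(e),
                             "); consider a smaller timestep", call. = FALSE))
  keep <- which(traj$energy_log$step > spec$burn_in - 1L &
                  traj$energy_log$step > 0L)
  keep <- utils::tail(keep, spec$n_frames)
  frames <- lapply(keep, function(i) {
    fr <- traj_frame(traj, i)
    fr$forces <- evaluate_toy(fr, init$topo, ff)$forces
    fr
  })
  structure(list(frames = frames, topo = init$topo, initial = init$frame,
                 spec = spec, ff = ff,
                 hash = .hash_obj(list(spec = unclass(spec),
                                       ff = unclass(ff)))),
            class = "cg_dataset")
}

#' @export
print.cg_dataset <- function(x, ...) {
  cat(sprintf("cg_dataset: %d frames of %d beads (%s, %d lipids), hash %s\n",
              length(x$frames), x$topo$n_beads, x$spec$geometry,
              x$spec$n_lipids, substr(x$hash, 1, 8)))
  invisible(x)
}

#' Expand a CG dataset to pseudo-atomistic frames
#'
#' Each bead is replaced by `atoms_per_bead` atoms with random masses (drawn
#' once into the emitted mapping scheme) and random positions whose
#' mass-weighted mean equals the bead position exactly; per-atom forces are
#' drawn so group sums equal the bead forces exactly. Mapping the expansion
#' back therefore reproduces bead coordinates and forces to machine
#' precision.
#'
#' @param dataset a `cg_dataset` (or list of [cg_frame()]s plus `topo`).
#' @param atoms_per_bead atoms per bead (>= 1).
#' @param seed expansion seed.
#' @return List with `frames` (list of [atomistic_frame()]s) and `scheme`
#'   (the [mapping_scheme()] that inverts the expansion).
#' @export
expand_pseudo_atomistic <- function(dataset, atoms_per_bead = 3L, seed = 1L) {
  stopifnot(atoms_per_bead >= 1L)
  frames <- dataset$frames; topo <- dataset$topo
  nb_per_lipid <- sum(topo$lipid_index == 1L)
  type_labs <- .code_to_label(topo$bead_types[seq_len(nb_per_lipid)],
                              topo$type_codes)
  apb <- as.integer(atoms_per_bead)
  old <- .Random.seed_save(); set.seed(seed)
  mass_tab <- matrix(stats::runif(nb_per_lipid * apb, 1, 16), apb, nb_per_lipid)
  beads <- lapply(seq_len(nb_per_lipid), function(j)
    list(label = paste0("B", j), type = type_labs[j],
         atoms = ((j - 1L) * apb + 1L):(j * apb), masses = mass_tab[, j]))
  labels <- vapply(beads, `[[`, "", "label")
  local_bonds <- lapply(seq_len(nrow(topo$bond_pairs %||% matrix(0, 0, 2))), function(e) {
    p <- topo$bond_pairs[e, ]
    if (all(p <= nb_per_lipid)) labels[p] else NULL
  })
  local_bonds <- Filter(Negate(is.null), local_bonds)
  scheme <- mapping_scheme("TOYEXP", beads, bonds = local_bonds,
                           n_atoms = nb_per_lipid * apb)
  n_beads <- topo$n_beads
  out_frames <- lapply(frames, function(fr) {
    coords <- matrix(0, n_beads * apb, 3L)
    forces <- matrix(0, n_beads * apb, 3L)
    masses <- numeric(n_beads * apb)
    for (bead in seq_len(n_beads)) {
      slot <- ((bead - 1L) %% nb_per_lipid) + 1L
      m <- mass_tab[, slot]
      rows <- ((bead - 1L) * apb + 1L):(bead * apb)
      disp <- matrix(stats::rnorm(apb * 3, sd = 0.5), apb, 3L)
      disp <- sweep(disp, 2L, colSums(disp * m) / sum(m))  # COM-free exactly
      coords[rows, ] <- sweep(disp, 2L, fr$coords[bead, ], "+")
      xi <- matrix(stats::rnorm(apb * 3), apb, 3L)
      xi <- sweep(xi, 2L, colMeans(xi))                    # sum-free exactly
      forces[rows, ] <- sweep(xi, 2L, fr$forces[bead, ] / apb, "+")
      masses[rows] <- m
    }
    atomistic_frame(coords, forces, masses,
                    lipid_index = rep(unique(topo$lipid_index),
                                      each = nb_per_lipid * apb),
                    lipid_type = "TOYEXP", box = fr$box)
  })
  .Random.seed_restore(old)
  list(frames = out_frames, scheme = scheme)
}
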