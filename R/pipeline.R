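## Pipeline helpers: fit priors from mapped frames, build force-matching
## datasets of delta forces, and the end-to-end closed-loop recovery check.

#' Collect bond-length samples per bond type
#'
#' @param frames list of [cg_frame()]s.
#' @param topo matching topology.
#' @return Named list of numeric vectors, one per bond type.
#' @export
collect_bond_distances <- function(frames, topo) {
  bp <- topo$bond_pairs
  out <- lapply(split(seq_len(nrow(bp)), topo$bond_type), function(rows) {
    unlist(lapply(frames, function(fr) {
      d <- min_image(fr$coords[bp[rows, 1], , drop = FALSE] -
                       fr$coords[bp[rows, 2], , drop = FALSE], fr$box)
      sqrt(rowSums(d * d))
    }))
  })
  out
}

#' Collect non-bonded pair distances per bead-type pair
#'
#' @param frames list of [cg_frame()]s.
#' @param topo matching topology.
#' @param cutoff collection cutoff (A).
#' @param max_frames subsample at most this many frames (evenly spaced).
#' @return Named list of numeric vectors keyed by type pair ("A:B").
#' @export
collect_pair_distances <- function(frames, topo, cutoff = 12, max_frames = 50L) {
  idx <- unique(round(seq(1, length(frames), length.out = min(max_frames, length(frames)))))
  acc <- list()
  for (i in idx) {
    fr <- frames[[i]]
    pairs <- .exclude_bonded(neighbor_pairs(fr, cutoff), topo)
    if (length(pairs$r) == 0L) next
    labs <- .code_to_label(fr$bead_types, topo$type_codes)
    keys <- pair_key(labs[pairs$i], labs[pairs$j])
    for (k in unique(keys))
      acc[[k]] <- c(acc[[k]], pairs$r[keys == k])
  }
  acc
}

#' Fit the full prior force field from mapped frames
#'
#' Harmonic bond terms by Boltzmann inversion (moment matching of the
#' Jacobian-corrected distribution) for every bond type; repulsive terms by
#' a least-squares fit of `4 eps r^-6` to the rising wall of each type pair's
#' PMF. Type pairs with too little close-contact data fall back to a zero
#' repulsion (with a message), which leaves the trained model to absorb that
#' interaction.
#'
#' @param frames list of [cg_frame()]s (mapped reference data).
#' @param topo matching topology.
#' @param temperature ensemble temperature (K).
#' @param cutoff nonbonded cutoff of the resulting prior (A).
#' @return A [prior_force_field()].
#' @export
fit_priors_from_frames <- function(frames, topo, temperature, cutoff = 12) {
  bonds <- lapply(collect_bond_distances(frames, topo),
                  fit_bond_prior, temperature = temperature)
  dists <- collect_pair_distances(frames, topo, cutoff)
  type_labs <- names(topo$type_codes)
  grid <- expand.grid(a = type_labs, b = type_labs, stringsAsFactors = FALSE)
  grid <- grid[grid$a <= grid$b, ]
  keys <- pair_key(grid$a, grid$b)
  repulsions <- stats::setNames(lapply(keys, function(k) {
    d <- dists[[k]]
    tryCatch(fit_repulsive_prior(d, temperature),
             error = function(e) {
               message(sprintf("pair %s: %s -- using zero repulsion", k,
                               conditionMessage(e)))
               repulsive_prior(0, 0)
             })
  }), keys)
  prior_force_field(bonds = bonds, repulsions = repulsions, cutoff = cutoff)
}

#' Build a force-matching dataset of delta forces
#'
#' Evaluates the prior on every frame, subtracts its forces from the mapped
#' forces and pairs each frame with the resulting delta-force target.
#'
#' @param frames list of [cg_frame()]s carrying mapped forces.
#' @param topo matching topology.
#' @param prior a [prior_force_field()] (or toy force field).
#' @param val_fraction,seed passed to [fm_dataset()].
#' @return An [fm_dataset()].
#' @export
make_fm_dataset <- function(frames, topo, prior, val_fraction = 0.1, seed = 1L) {
  targets <- lapply(frames, function(fr)
    compute_delta_forces(fr, total_force_field(fr, topo, prior)$forces))
  fm_dataset(frames, targets, val_fraction = val_fraction, seed = seed,
             provenance = list(kind = "delta-forces", n_frames = length(frames)))
}

#' Position of the first RDF peak
#' @param rdf an `rdf_result`.
#' @param r_search_max search window upper bound (A).
#' @return The bin center (A) of the maximum of g(r) within the window.
#' @export
rdf_first_peak <- function(rdf, r_search_max = 8) {
  sel <- rdf$r <= r_search_max
  rdf$r[sel][which.max(rdf$g[sel])]
}

#' End-to-end closed-loop recovery on a toy fixture
#'
#' Mirrors the full development workflow on synthetic ground truth:
#' generate reference data from the toy force field, fit the priors, form
#' delta forces, train a residual potential by force matching, simulate with
#' prior + trained model, and compare observables against the truth
#' simulation. Any stage failure is reported with the stage name.
#'
#' @param spec a [fixture_spec()] (<= 50 lipids, <= 2000 frames).
#' @param train_cfg a [train_config()].
#' @param model_type "spline" (pairwise B-spline baseline; the toy truth is
#'   pairwise-representable, so this is the cleanest recovery target) or
#'   "graph".
#' @param graph_cfg a [graph_config()] when `model_type = "graph"`.
#' @param sim_steps production steps for the observable comparison runs.
#' @param rdf_bins bins for the tail-bead RDF comparison.
#' @return Report list: fitted-vs-true bond parameters and relative errors,
#'   initial and final validation force RMSE, RDF first-peak positions of
#'   truth and learned simulations, and the underlying objects.
#' @export
end_to_end_recovery <- function(spec, train_cfg = train_config(),
                                model_type = c("spline", "graph"),
                                graph_cfg = NULL, sim_steps = 10000L,
                                rdf_bins = 60L) {
  model_type <- match.arg(model_type)
  if (spec$n_lipids > 50L || spec$n_frames > 2000L)
    stop("recovery fixtures are desk-scale: <= 50 lipids, <= 2000 frames")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  ds <- stage("generate", generate_cg_dataset(spec))
  topo <- ds$topo

  prior <- stage("fit-priors",
                 fit_priors_from_frames(ds$frames, topo, spec$temperature,
                                        cutoff = ds$ff$cutoff))
  bond_report <- do.call(rbind, lapply(names(prior$bonds), function(bt) {
    data.frame(bond_type = bt,
               k_true = ds$ff$bonds[[bt]]$k, k_fit = prior$bonds[[bt]]$k,
               r0_true = ds$ff$bonds[[bt]]$r0, r0_fit = prior$bonds[[bt]]$r0)
  }))
  bond_report$k_rel_err <- abs(bond_report$k_fit / bond_report$k_true - 1)
  bond_report$r0_rel_err <- abs(bond_report$r0_fit / bond_report$r0_true - 1)

  data <- stage("delta-forces",
                make_fm_dataset(ds$frames, topo, prior, seed = spec$seed))
  model0 <- stage("model-init", {
    if (model_type == "spline")
      spline_pair_potential(topo$type_codes, cutoff = ds$ff$cutoff)
    else
      graph_potential(graph_cfg %||% graph_config(n_layers = 2L, width = 32L,
                                                  n_rbf = 12L, cutoff = ds$ff$cutoff,
                                                  head_width = 16L),
                      topo$type_codes, seed = spec$seed)
  })
  val_frames <- data$frames[data$val_idx]
  rmse0 <- stage("rmse", force_rmse(model0, prior, val_frames, topo))
  fit <- stage("train", train_potential(model0, data, train_cfg))
  rmse1 <- force_rmse(fit$model, prior, val_frames, topo)

  sim_cfg <- function(seed) langevin_config(temperature = spec$temperature,
                                            damping = spec$damping,
                                            timestep = spec$timestep,
                                            n_steps = sim_steps,
                                            save_every = spec$save_every,
                                            seed = seed,
                                            masses = bead_masses(topo, ds$ff$masses))
  truth_traj <- stage("simulate-truth",
                      run_simulation(ds$initial, topo, prior = ds$ff,
                                     model = NULL, cfg = sim_cfg(spec$seed + 1L)))
  learned_traj <- stage("simulate-learned",
                        run_simulation(ds$initial, topo, prior = prior,
                                       model = fit$model, cfg = sim_cfg(spec$seed + 1L)))
  tails <- which(.code_to_label(topo$bead_types, topo$type_codes) %in% c("T1", "T2"))
  drop_first <- function(traj) {  # discard the cold-start frame
    traj$coords <- traj$coords[, , -1, drop = FALSE]; traj
  }
  rdf_truth <- stage("analyze", compute_rdf(drop_first(truth_traj), tails,
                                            n_bins = rdf_bins))
  rdf_learned <- compute_rdf(drop_first(learned_traj), tails, n_bins = rdf_bins)
  list(bond_report = bond_report,
       rmse_initial = rmse0, rmse_final = rmse1,
       rmse_ratio = rmse1 / rmse0,
       rdf_peak_truth = rdf_first_peak(rdf_truth),
       rdf_peak_learned = rdf_first_peak(rdf_learned),
       rdf_bin_width = diff(rdf_truth$r)[1],
       history = fit$history, model = fit$model, prior = prior,
       rdf_truth = rdf_truth, rdf_learned = rdf_learned)
}
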