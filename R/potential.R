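## Trainable potential contract shared by the graph network and the
## pairwise B-spline baseline:
##   energy_and_forces(model, frame) -> list(energy, forces)
##   param_vector(model) / set_param_vector(model, v)
##   fm_loss_grad(model, frame, target) -> list(loss, grad)  [per frame]

#' Energy and forces of a trainable potential
#'
#' The energy is a single scalar per frame; the returned forces are the exact
#' negative gradient of that energy with respect to the bead coordinates.
#' Both implementations depend on coordinates only through minimum-image pair
#' distances, so the energy is translation invariant and invariant under
#' permutation of identical-type beads.
#'
#' @param model a trainable potential ([graph_potential()] or
#'   [spline_pair_potential()]).
#' @param frame a [cg_frame()].
#' @param ... passed to methods.
#' @return List with `energy` (kcal mol^-1) and `forces` (N x 3 matrix).
#' @export
energy_and_forces <- function(model, frame, ...) UseMethod("energy_and_forces")

#' Flatten model parameters to a numeric vector
#' @param model a trainable potential.
#' @return Numeric parameter vector.
#' @export
param_vector <- function(model) UseMethod("param_vector")

#' Replace model parameters from a flat vector
#' @param model a trainable potential.
#' @param v numeric vector of length `length(param_vector(model))`.
#' @return The model with parameters replaced.
#' @export
set_param_vector <- function(model, v) UseMethod("set_param_vector")

#' Per-frame force-matching loss and parameter gradient
#'
#' Computes `1/(3N) sum_I |target_I - F_model,I|^2` for one frame together
#' with its exact gradient with respect to the flattened model parameters.
#'
#' @param model a trainable potential.
#' @param frame a [cg_frame()].
#' @param target N x 3 matrix of target (delta) forces.
#' @return List with `loss` and `grad`.
#' @export
fm_loss_grad <- function(model, frame, target) UseMethod("fm_loss_grad")

.check_vocab <- function(model, frame) {
  if (!all(frame$bead_types %in% model$type_codes))
    stop("frame contains bead types outside the model vocabulary (vocabulary error)")
}

## Smooth cosine cutoff envelope and its derivative.
.envelope <- function(r, rc) 0.5 * (cos(pi * r / rc) + 1)
.envelope_d <- function(r, rc) -0.5 * pi / rc * sin(pi * r / rc)

## Shifted softplus and logistic helpers (overflow-safe).
.ssp <- function(x) pmax(x, 0) + log1p(exp(-abs(x))) - log(2)
.sig <- function(x) stats::plogis(x)

#' Total CG force field: prior plus trained potential
#'
#' The production CG force field is the sum of the physics-based prior and
#' the trained residual model; forces add elementwise. Either component may
#' be NULL.
#'
#' @param frame a [cg_frame()].
#' @param topo matching [build_topology()] result (needed by the prior).
#' @param prior a [prior_force_field()], a [toy_force_field()], or NULL.
#' @param model a trainable potential or NULL.
#' @return List with `energy` and `forces` (N x 3).
#' @export
total_force_field <- function(frame, topo, prior = NULL, model = NULL) {
  n <- nrow(frame$coords)
  energy <- 0; forces <- matrix(0, n, 3L)
  if (!is.null(prior)) {
    ep <- if (inherits(prior, "toy_force_field"))
      evaluate_toy(frame, topo, prior) else evaluate_prior(frame, topo, prior)
    energy <- energy + ep$energy; forces <- forces + ep$forces
  }
  if (!is.null(model)) {
    em <- energy_and_forces(model, frame)
    energy <- energy + em$energy; forces <- forces + em$forces
  }
  list(energy = energy, forces = forces)
}

## ======================================================================
## Pairwise B-spline baseline
## ======================================================================

#' Pairwise B-spline potential
#'
#' A classical tabulated-potential baseline: for every unordered bead-type
#' pair, a cubic B-spline on `[0, cutoff]` multiplied by a smooth cosine
#' envelope so that the potential and its first derivative vanish at the
#' cutoff. The energy is linear in the coefficients, which makes
#' force-matching a well-conditioned (linear) problem.
#'
#' @param type_codes named integer vector, bead-type label -> code.
#' @param cutoff pair cutoff (A).
#' @param n_knots number of uniform knot sites on `[0, cutoff]` (>= 4).
#' @return Object of class `spline_pair_potential` (also
#'   `trainable_potential`) with zero-initialized coefficients.
#' @export
spline_pair_potential <- function(type_codes, cutoff = 12, n_knots = 10L) {
  stopifnot(cutoff > 0, n_knots >= 4L)
  sites <- seq(0, cutoff, length.out = n_knots)
  knots <- c(rep(0, 4L), sites[-c(1L, n_knots)], rep(cutoff, 4L))
  nb <- length(knots) - 4L
  codes <- sort(unname(type_codes))
  grid <- expand.grid(a = codes, b = codes)
  grid <- grid[grid$a <= grid$b, ]
  keys <- pair_key(grid$a, grid$b)
  coefs <- matrix(0, nb, length(keys), dimnames = list(NULL, keys))
  structure(list(type_codes = type_codes, cutoff = cutoff, knots = knots,
                 coefs = coefs),
            class = c("spline_pair_potential", "trainable_potential"))
}

#' @export
print.spline_pair_potential <- function(x, ...) {
  cat(sprintf("spline_pair_potential: %d basis functions x %d type pairs, cutoff %.1f A\n",
              nrow(x$coefs), ncol(x$coefs), x$cutoff))
  invisible(x)
}

## Per-pair basis terms: value row W0 and r-derivative row W1 of the
## enveloped basis, plus the column index of each pair's type pair.
.spline_edges <- function(model, frame) {
  pairs <- neighbor_pairs(frame, model$cutoff)
  E <- length(pairs$r)
  if (E == 0L) return(list(pairs = pairs, E = 0L))
  keys <- pair_key(frame$bead_types[pairs$i], frame$bead_types[pairs$j])
  col <- match(keys, colnames(model$coefs))
  if (anyNA(col)) stop("frame contains bead types outside the model vocabulary (vocabulary error)")
  B <- splines::splineDesign(model$knots, pairs$r, ord = 4L)
  Bd <- splines::splineDesign(model$knots, pairs$r, ord = 4L,
                              derivs = rep(1L, E))
  env <- .envelope(pairs$r, model$cutoff)
  envd <- .envelope_d(pairs$r, model$cutoff)
  list(pairs = pairs, E = E, col = col,
       W0 = B * env, W1 = Bd * env + B * envd)
}

#' @export
energy_and_forces.spline_pair_potential <- function(model, frame, ...) {
  .check_vocab(model, frame)
  n <- nrow(frame$coords)
  ed <- .spline_edges(model, frame)
  if (ed$E == 0L) return(list(energy = 0, forces = matrix(0, n, 3L)))
  C <- t(model$coefs[, ed$col, drop = FALSE])      # E x nb
  V <- rowSums(ed$W0 * C)
  g <- rowSums(ed$W1 * C)                          # dV/dr per pair
  list(energy = sum(V), forces = .central_forces(n, ed$pairs, g))
}

#' @export
param_vector.spline_pair_potential <- function(model) as.vector(model$coefs)

#' @export
set_param_vector.spline_pair_potential <- function(model, v) {
  stopifnot(length(v) == length(model$coefs))
  model$coefs[] <- v
  model
}

#' @export
fm_loss_grad.spline_pair_potential <- function(model, frame, target) {
  n <- nrow(frame$coords)
  ed <- .spline_edges(model, frame)
  if (ed$E == 0L) {
    return(list(loss = sum(target^2) / (3 * n),
                grad = numeric(length(model$coefs))))
  }
  C <- t(model$coefs[, ed$col, drop = FALSE])
  g <- rowSums(ed$W1 * C)
  Fp <- .central_forces(n, ed$pairs, g)
  resid <- Fp - target
  loss <- sum(resid^2) / (3 * n)
  S <- resid * (2 / (3 * n))                       # dL/dF
  u <- ed$pairs$dx / ed$pairs$r
  lambda <- rowSums(u * (S[ed$pairs$j, , drop = FALSE] -
                           S[ed$pairs$i, , drop = FALSE]))
  gc <- matrix(0, nrow(model$coefs), ncol(model$coefs))
  contrib <- rowsum(ed$W1 * lambda, ed$col)        # groups x nb
  gc[, as.integer(rownames(contrib))] <- t(contrib)
  list(loss = loss, grad = as.vector(gc))
}

## ======================================================================
## Checkpoints
## ======================================================================

#' Save a trainable potential checkpoint
#'
#' Parameters are serialized as full-precision ("%.17g") decimal strings so
#' that a save/load round trip is bit-stable.
#'
#' @param model a trainable potential.
#' @param path output path (JSON). Written atomically.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(format_version = 1L,
              model_class = class(model)[1],
              type_codes = as.list(model$type_codes),
              params = sprintf("%.17g", param_vector(model)))
  if (inherits(model, "spline_pair_potential")) {
    obj$config <- list(cutoff = model$cutoff,
                       n_knots = length(model$knots) - 6L)
    obj$knots <- sprintf("%.17g", model$knots)
    obj$pair_keys <- colnames(model$coefs)
  } else if (inherits(model, "graph_potential")) {
    obj$config <- unclass(model$config)
    obj$seed <- model$seed
  } else stop("unknown model class")
  .atomic_write_json(obj, path)
  invisible(path)
}

#' Load a trainable potential checkpoint
#' @param path path written by [save_checkpoint()].
#' @return The reconstructed model.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint '%s' not found", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  tc <- unlist(obj$type_codes)
  v <- as.numeric(obj$params)
  if (identical(obj$model_class, "spline_pair_potential")) {
    knots <- as.numeric(obj$knots)
    nb <- length(knots) - 4L
    coefs <- matrix(v, nb, length(obj$pair_keys),
                    dimnames = list(NULL, unlist(obj$pair_keys)))
    model <- structure(list(type_codes = tc, cutoff = obj$config$cutoff,
                            knots = knots, coefs = coefs),
                       class = c("spline_pair_potential", "trainable_potential"))
  } else if (identical(obj$model_class, "graph_potential")) {
    cfg <- do.call(graph_config, obj$config)
    model <- graph_potential(cfg, tc, seed = obj$seed %||% 1L)
    model <- set_param_vector(model, v)
  } else stop("unknown checkpoint model class")
  model
}
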