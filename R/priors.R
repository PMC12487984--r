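## Prior force field: Boltzmann-inverted harmonic bonds + r^-6 repulsion,
## delta forces, and the B-spline bonded alternative.

#' Harmonic bond prior term
#'
#' Convention: `V(r) = k (r - r0)^2 + V0` (the spring constant absorbs the
#' conventional 1/2).
#'
#' @param k spring constant (kcal mol^-1 A^-2), > 0.
#' @param r0 equilibrium distance (A), > 0.
#' @param V0 base potential (kcal mol^-1); does not affect forces.
#' @return Object of class `bond_prior`.
#' @export
bond_prior <- function(k, r0, V0 = 0) {
  if (k <= 0) stop("k must be positive")
  if (r0 <= 0) stop("r0 must be positive")
  structure(list(k = k, r0 = r0, V0 = V0), class = "bond_prior")
}

#' Pairwise repulsive prior term
#'
#' Lennard-Jones-inspired repulsion `V(r) = 4 epsilon r^-6 + V0`.
#'
#' @param epsilon repulsive constant (kcal mol^-1 A^6), >= 0.
#' @param V0 base potential (kcal mol^-1).
#' @return Object of class `repulsive_prior`.
#' @export
repulsive_prior <- function(epsilon, V0 = 0) {
  if (epsilon < 0) stop("epsilon must be non-negative")
  structure(list(epsilon = epsilon, V0 = V0), class = "repulsive_prior")
}

#' Fit a harmonic bond prior by Boltzmann inversion
#'
#' With the Jacobian correction the radial samples are reweighted by 1/r^2 so
#' that the inverted potential refers to p(r)/r^2, the distribution a harmonic
#' bond generates along the bond coordinate. The harmonic parameters are then
#' obtained by moment matching: `r0` is the (weighted) mean and
#' `k = kB T / (2 sigma^2)` from the (weighted) variance, which is exact for
#' the Gaussian implied by the harmonic form.
#'
#' @param distances bond-length samples (A), at least 100.
#' @param temperature temperature of the sampled ensemble (K).
#' @param jacobian apply the 1/r^2 radial Jacobian correction (default TRUE).
#' @return A [bond_prior()] with `V0 = 0`.
#' @export
fit_bond_prior <- function(distances, temperature, jacobian = TRUE) {
  r <- as.numeric(distances)
  if (length(r) < 100L) stop("need at least 100 bond samples (sample-size error)")
  w <- if (jacobian) 1 / r^2 else rep(1, length(r))
  w <- w / sum(w)
  mu <- sum(w * r)
  v <- sum(w * (r - mu)^2)
  if (v <= 0 || !is.finite(v) || v < .Machine$double.eps * mu^2)
    stop("bond samples have zero variance (degenerate-distribution error)")
  bond_prior(k = .kB * temperature / (2 * v), r0 = mu, V0 = 0)
}

#' Fit the repulsive prior to a pair potential of mean force
#'
#' Builds the pair PMF `-kB T log g(r)` from the sampled pair distances
#' (shell-normalized histogram) and least-squares fits `4 epsilon r^-6 + V0`
#' over `fit_range`, which should cover only the rising repulsive wall. The
#' constant offset is absorbed into `V0`; if the unconstrained fit turns
#' attractive, `epsilon` is clipped at zero.
#'
#' @param pair_distances sampled pair distances (A).
#' @param temperature ensemble temperature (K).
#' @param fit_range length-2 vector `(r_lo, r_hi)` (A). Defaults to the
#'   smallest observed distance up to the distance where the shell-normalized
#'   histogram first reaches its plateau level.
#' @param n_bins histogram bins across the sample range.
#' @return A [repulsive_prior()].
#' @export
fit_repulsive_prior <- function(pair_distances, temperature,
                                fit_range = NULL, n_bins = 100L) {
  r <- as.numeric(pair_distances)
  if (length(r) < 10L) stop("too few pair samples")
  breaks <- seq(min(r), max(r), length.out = n_bins + 1L)
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  centers <- h$mids
  gshell <- h$counts / centers^2          # unnormalized shell density
  if (is.null(fit_range)) {
    plateau <- stats::median(gshell[gshell > 0])
    above <- which(gshell >= plateau)
    fit_range <- c(min(r), if (length(above)) centers[above[1]] else max(r))
  }
  sel <- centers >= fit_range[1] & centers <= fit_range[2] & h$counts > 0
  if (!any(sel)) stop("no samples inside the fit range (fit-domain error)")
  pmf <- -.kB * temperature * log(gshell[sel])
  X <- cbind(4 * centers[sel]^-6, 1)
  beta <- stats::lm.fit(X, pmf)$coefficients
  eps <- max(beta[1], 0)
  repulsive_prior(epsilon = unname(eps), V0 = unname(beta[2]))
}

#' Assemble a prior force field
#'
#' @param bonds named list of [bond_prior()] terms keyed by bond type label
#'   ("A-B" with bead-type labels in sorted order), covering every bond type
#'   of the topology it will be evaluated on.
#' @param repulsions named list of [repulsive_prior()] terms keyed by
#'   unordered bead-type pair label ("A:B"), covering every type pair.
#' @param cutoff nonbonded cutoff (A).
#' @param r_guard guard distance (A): below it the diverging r^-7 repulsive
#'   force is held at its `r_guard` value (linear energy continuation) and a
#'   near-singularity warning is emitted.
#' @param exclusion exclusion rule; only "bonded12" (directly bonded pairs
#'   excluded from the repulsion) is implemented.
#' @return Object of class `prior_force_field`.
#' @export
prior_force_field <- function(bonds, repulsions, cutoff = 12,
                              r_guard = 0.5, exclusion = "bonded12") {
  stopifnot(cutoff > 0, identical(exclusion, "bonded12"))
  structure(list(bonds = bonds, repulsions = repulsions, cutoff = cutoff,
                 r_guard = r_guard, exclusion = exclusion,
                 format_version = 1L),
            class = "prior_force_field")
}

#' @export
print.prior_force_field <- function(x, ...) {
  cat(sprintf("prior_force_field: %d bond terms, %d repulsive terms, cutoff %.1f A\n",
              length(x$bonds), length(x$repulsions), x$cutoff))
  invisible(x)
}

.code_to_label <- function(codes, type_codes) {
  names(type_codes)[match(codes, type_codes)]
}

#' Evaluate the prior force field on a frame
#'
#' Energy is the sum of harmonic bond terms over the topology bonds plus
#' repulsive terms over all non-excluded pairs within the cutoff under the
#' minimum-image convention. Forces are the exact negative analytic gradient;
#' pairwise contributions obey Newton's third law.
#'
#' @param frame a [cg_frame()].
#' @param topo the matching [build_topology()] result.
#' @param prior a [prior_force_field()].
#' @return List with `energy` (kcal mol^-1) and `forces` (N x 3).
#' @export
evaluate_prior <- function(frame, topo, prior) {
  n <- nrow(frame$coords)
  if (n != topo$n_beads) stop("topology inconsistent with frame")
  energy <- 0
  forces <- matrix(0, n, 3L)

  bp <- topo$bond_pairs
  if (!is.null(bp) && nrow(bp) > 0L) {
    dx <- min_image(frame$coords[bp[, 1], , drop = FALSE] -
                      frame$coords[bp[, 2], , drop = FALSE], frame$box)
    r <- sqrt(rowSums(dx * dx))
    k_by <- vapply(prior$bonds, `[[`, 0, "k")
    r0_by <- vapply(prior$bonds, `[[`, 0, "r0")
    V0_by <- vapply(prior$bonds, `[[`, 0, "V0")
    if (!all(topo$bond_type %in% names(prior$bonds)))
      stop("missing bond prior for bond type(s): ",
           paste(setdiff(unique(topo$bond_type), names(prior$bonds)), collapse = ", "))
    k <- unname(k_by[topo$bond_type])
    r0 <- unname(r0_by[topo$bond_type])
    V0 <- unname(V0_by[topo$bond_type])
    energy <- energy + sum(k * (r - r0)^2 + V0)
    dVdr <- 2 * k * (r - r0)
    fvec <- dx * (-dVdr / r)
    forces <- forces + .accumulate_rows(n, c(bp[, 1], bp[, 2]), rbind(fvec, -fvec))
  }

  pairs <- .exclude_bonded(neighbor_pairs(frame, prior$cutoff), topo)
  if (length(pairs$r) > 0L) {
    tpos <- match(frame$bead_types, topo$type_codes)
    epsM <- .pair_param_matrix(prior$repulsions, "epsilon", topo$type_codes)
    V0M <- .pair_param_matrix(prior$repulsions, "V0", topo$type_codes)
    idx <- cbind(tpos[pairs$i], tpos[pairs$j])
    eps <- epsM[idx]; V0 <- V0M[idx]
    if (anyNA(eps)) {
      labs <- .code_to_label(frame$bead_types, topo$type_codes)
      bad <- pair_key(labs[pairs$i], labs[pairs$j])[is.na(eps)]
      stop("missing repulsive prior for type pair(s): ",
           paste(unique(bad), collapse = ", "))
    }
    r <- pairs$r
    guard <- r < prior$r_guard & eps > 0
    if (any(guard))
      warning(sprintf("%d pair(s) below the guard distance %.2f A; repulsive force capped",
                      sum(guard), prior$r_guard))
    rg <- prior$r_guard
    V <- ifelse(guard,
                4 * eps * rg^-6 + V0 + 24 * eps * rg^-7 * (rg - r),
                4 * eps * r^-6 + V0)
    dVdr <- ifelse(guard, -24 * eps * rg^-7, -24 * eps * r^-7)
    energy <- energy + sum(V)
    forces <- forces + .central_forces(n, pairs, dVdr)
  }
  list(energy = energy, forces = forces)
}

#' Delta forces: mapped atomistic forces minus prior forces
#'
#' The residual the trainable potential is fitted to, so that
#' `mapped = prior + delta` holds elementwise to machine precision.
#'
#' @param mapped a [cg_frame()] carrying mapped forces, or an N x 3 matrix.
#' @param prior_forces N x 3 matrix of prior forces.
#' @return N x 3 matrix of delta forces.
#' @export
compute_delta_forces <- function(mapped, prior_forces) {
  f <- if (inherits(mapped, "cg_frame")) mapped$forces else mapped
  if (is.null(f)) stop("frame carries no forces")
  if (!all(dim(f) == dim(prior_forces)))
    stop("shape mismatch between mapped and prior forces (dimension error)")
  f - prior_forces
}

## --- B-spline bonded alternative ---------------------------------------

#' Fit a B-spline bonded term to a bond-length distribution
#'
#' Computes the Jacobian-corrected bond potential of mean force
#' `-kB T log(p(r)/r^2) + const` on a histogram and least-squares fits a
#' cubic B-spline to it. Unlike the harmonic prior this can represent
#' non-Gaussian (e.g. bimodal) bond-length distributions such as the
#' flexible second tail bond of a lipid. Empty interior bins are simply
#' omitted from the fit (the spline interpolates across them) with a warning;
#' outside the knot range the potential continues linearly with the boundary
#' slope (C1 extrapolation guard).
#'
#' @param distances bond-length samples (A).
#' @param temperature ensemble temperature (K).
#' @param n_knots number of interior knots (>= 4) spread uniformly across the
#'   sampled range.
#' @param n_bins histogram bins.
#' @return Object of class `spline_bond_term` with `knots` (full cubic knot
#'   vector) and `coefficients`.
#' @export
fit_spline_bond <- function(distances, temperature, n_knots = 12L, n_bins = 80L) {
  r <- as.numeric(distances)
  if (n_knots < 4L) stop("n_knots must be >= 4")
  if (length(r) < 100L) stop("too few samples")
  lo <- min(r); hi <- max(r)
  h <- graphics::hist(r, breaks = seq(lo, hi, length.out = n_bins + 1L), plot = FALSE)
  centers <- h$mids
  dens <- h$counts / centers^2
  keep <- dens > 0
  if (any(!keep))
    warning(sprintf("%d empty histogram bin(s) inside the knot range; interpolated by the spline",
                    sum(!keep)))
  pmf <- -.kB * temperature * log(dens[keep])
  pmf <- pmf - min(pmf)
  knots <- c(rep(lo, 4L), seq(lo, hi, length.out = n_knots)[-c(1L, n_knots)],
             rep(hi, 4L))
  B <- splines::splineDesign(knots, centers[keep], ord = 4L)
  coef <- stats::lm.fit(B, pmf)$coefficients
  coef[!is.finite(coef)] <- 0
  structure(list(knots = knots, coefficients = unname(coef),
                 temperature = temperature),
            class = "spline_bond_term")
}

#' Evaluate a B-spline bonded term
#'
#' @param term a `spline_bond_term` from [fit_spline_bond()].
#' @param r distances (A) at which to evaluate.
#' @param deriv 0 for the potential, 1 for dV/dr.
#' @return Numeric vector; outside the knot range the potential continues
#'   linearly (constant first derivative).
#' @export
eval_spline_bond <- function(term, r, deriv = 0L) {
  kn <- term$knots
  lo <- kn[1]; hi <- kn[length(kn)]
  r <- as.numeric(r)
  out <- numeric(length(r))
  inside <- r >= lo & r <= hi
  bval <- function(x, d) {
    if (length(x) == 0L) return(numeric(0))
    drop(splines::splineDesign(kn, x, ord = 4L, derivs = rep(d, length(x))) %*%
           term$coefficients)
  }
  if (any(inside)) out[inside] <- bval(r[inside], deriv)
  for (side in c("lo", "hi")) {
    sel <- if (side == "lo") r < lo else r > hi
    if (!any(sel)) next
    x0 <- if (side == "lo") lo else hi
    if (deriv == 0L) {
      out[sel] <- bval(x0, 0L) + bval(x0, 1L) * (r[sel] - x0)
    } else {
      out[sel] <- bval(x0, 1L)
    }
  }
  out
}

## --- serialization ------------------------------------------------------

#' Write a prior force field to structured text (JSON)
#' @param prior a [prior_force_field()].
#' @param path output file path.
#' @return `path`, invisibly. Written atomically (temp file + rename).
#' @export
write_prior <- function(prior, path) {
  obj <- list(format_version = 1L, cutoff = prior$cutoff,
              r_guard = prior$r_guard, exclusion = prior$exclusion,
              bonds = lapply(prior$bonds, function(b)
                list(k = b$k, r0 = b$r0, V0 = b$V0)),
              repulsions = lapply(prior$repulsions, function(p)
                list(epsilon = p$epsilon, V0 = p$V0)))
  .atomic_write_json(obj, path)
  invisible(path)
}

#' Read a prior force field written by [write_prior()]
#' @param path file path.
#' @return A [prior_force_field()].
#' @export
read_prior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(obj$format_version)) stop("not a prior force field file")
  prior_force_field(
    bonds = lapply(obj$bonds, function(b) bond_prior(b$k, b$r0, b$V0)),
    repulsions = lapply(obj$repulsions, function(p) repulsive_prior(p$epsilon, p$V0)),
    cutoff = obj$cutoff, r_guard = obj$r_guard, exclusion = obj$exclusion)
}

.atomic_write_json <- function(obj, path, digits = NA) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = digits, null = "null")
  file.rename(tmp, path)
}
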