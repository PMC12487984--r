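## Membrane observables: RDF, z-density, thickness map, order parameters,
## lateral MSD and diffusion constant.

.sel_idx <- function(traj, selection) {
  idx <- if (is.logical(selection)) which(selection) else as.integer(selection)
  if (length(idx) == 0L) stop("empty selection (selection error)")
  if (any(idx < 1L | idx > dim(traj$coords)[1])) stop("selection out of range")
  idx
}

#' Radial distribution function
#'
#' Three-dimensional shell-normalized pair histogram under the minimum-image
#' convention, averaged over frames. For identical selections self-pairs are
#' excluded and the ideal-gas normalization uses N(N-1)/2 pairs; for disjoint
#' selections all cross pairs are counted.
#'
#' @param traj a [cg_trajectory()].
#' @param selection_a,selection_b integer (or logical) bead selections.
#' @param r_max histogram range (A); must not exceed half the smallest box
#'   edge.
#' @param n_bins number of bins.
#' @return Object of class `rdf_result`: data.frame-like list with `r` (bin
#'   centers), `g`, `counts`, `n_frames` and the selections.
#' @export
compute_rdf <- function(traj, selection_a, selection_b = selection_a,
                        r_max = NULL, n_bins = 100L) {
  box <- traj$box
  if (is.null(r_max)) r_max <- min(box) / 2
  if (r_max > min(box) / 2 + 1e-9)
    stop("r_max exceeds half the smallest box edge (geometry error)")
  a <- .sel_idx(traj, selection_a); b <- .sel_idx(traj, selection_b)
  same <- identical(sort(a), sort(b))
  breaks <- seq(0, r_max, length.out = n_bins + 1L)
  counts <- numeric(n_bins)
  nt <- n_frames(traj)
  for (t in seq_len(nt)) {
    x <- traj$coords[, , t, drop = TRUE]
    if (same) {
      pr <- expand.grid(i = a, j = a)
      pr <- pr[pr$i < pr$j, ]
    } else {
      pr <- expand.grid(i = a, j = b)
      pr <- pr[pr$i != pr$j, ]
    }
    d <- min_image(x[pr$i, , drop = FALSE] - x[pr$j, , drop = FALSE], box)
    r <- sqrt(rowSums(d * d))
    counts <- counts + graphics::hist(r[r < r_max], breaks = breaks, plot = FALSE)$counts
  }
  vol <- prod(box)
  shell <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-(n_bins + 1L)]^3)
  npairs <- if (same) length(a) * (length(a) - 1) / 2 else length(a) * length(b)
  g <- counts / nt / (npairs / vol * shell)
  structure(list(r = (breaks[-1] + breaks[-(n_bins + 1L)]) / 2, g = g,
                 counts = counts, n_frames = nt,
                 selection_a = a, selection_b = b),
            class = "rdf_result")
}

#' Area-normalized z-density profile
#'
#' Histogram of the z-coordinates of the selected beads, recentered per frame
#' so the bilayer midplane (mean z of all beads) sits at z = 0, and
#' normalized to unit integral over z.
#'
#' @param traj a [cg_trajectory()].
#' @param selection bead selection (integer indices or logical).
#' @param n_bins histogram bins.
#' @param z_range length-2 range (A) about the midplane; defaults to
#'   `c(-box_z/2, box_z/2)`.
#' @param recenter recenter each frame on the bead midplane (default TRUE).
#' @return Object of class `density_profile` with `z` (bin centers) and
#'   `density` (1/A, unit integral).
#' @export
compute_zdensity <- function(traj, selection, n_bins = 100L, z_range = NULL,
                             recenter = TRUE) {
  sel <- .sel_idx(traj, selection)
  if (is.null(z_range)) z_range <- c(-traj$box[3] / 2, traj$box[3] / 2)
  breaks <- seq(z_range[1], z_range[2], length.out = n_bins + 1L)
  counts <- numeric(n_bins)
  for (t in seq_len(n_frames(traj))) {
    z <- traj$coords[, 3, t]
    if (recenter) z <- z - mean(z)
    zs <- z[sel]
    zs <- zs[zs >= z_range[1] & zs < z_range[2]]
    counts <- counts + graphics::hist(zs, breaks = breaks, plot = FALSE)$counts
  }
  dz <- diff(breaks)[1]
  dens <- counts / (sum(counts) * dz)
  structure(list(z = (breaks[-1] + breaks[-(n_bins + 1L)]) / 2,
                 density = dens, n_frames = n_frames(traj)),
            class = "density_profile")
}

#' Membrane thickness map and mean headgroup-to-headgroup distance
#'
#' Leaflets are assigned per frame by the sign of z relative to the frame
#' midplane (mean z of the headgroup selection). The xy plane is divided
#' into square cells (10 x 10 A by default); each cell's thickness is the
#' mean upper-leaflet headgroup z minus the mean lower-leaflet headgroup z.
#' Cells lacking beads in either leaflet are flagged unoccupied and excluded
#' (never imputed as zero). The scalar thickness is the occupancy-weighted
#' mean over cells and frames.
#'
#' @param traj a [cg_trajectory()].
#' @param hg_selection headgroup bead selection.
#' @param cell_size xy grid cell edge (A).
#' @return Object of class `thickness_map` with `grid` (mean per-cell
#'   thickness, NA where never occupied), `occupancy` (cell weights),
#'   `thickness` (scalar, A) and grid geometry.
#' @export
compute_thickness <- function(traj, hg_selection, cell_size = 10) {
  sel <- .sel_idx(traj, hg_selection)
  box <- traj$box
  nx <- max(1L, floor(box[1] / cell_size))
  ny <- max(1L, floor(box[2] / cell_size))
  sum_thk <- matrix(0, nx, ny); wsum <- matrix(0, nx, ny)
  for (t in seq_len(n_frames(traj))) {
    xyz <- traj$coords[sel, , t, drop = FALSE]
    dim(xyz) <- dim(xyz)[1:2]
    mid <- mean(xyz[, 3])
    upper <- xyz[, 3] >= mid
    if (!any(upper) || all(upper))
      stop("a leaflet is empty (leaflet-assignment error)")
    cx <- pmin(nx, 1L + floor((xyz[, 1] %% box[1]) / box[1] * nx))
    cy <- pmin(ny, 1L + floor((xyz[, 2] %% box[2]) / box[2] * ny))
    cell <- (cy - 1L) * nx + cx
    zu <- tapply(xyz[upper, 3], cell[upper], mean)
    nu <- tapply(xyz[upper, 3], cell[upper], length)
    zl <- tapply(xyz[!upper, 3], cell[!upper], mean)
    nl <- tapply(xyz[!upper, 3], cell[!upper], length)
    common <- intersect(names(zu), names(zl))
    for (cc in common) {
      ci <- as.integer(cc)
      w <- nu[[cc]] + nl[[cc]]
      sum_thk[ci] <- sum_thk[ci] + w * (zu[[cc]] - zl[[cc]])
      wsum[ci] <- wsum[ci] + w
    }
  }
  grid <- ifelse(wsum > 0, sum_thk / wsum, NA_real_)
  thickness <- sum(sum_thk) / sum(wsum)
  structure(list(grid = grid, occupancy = wsum, thickness = thickness,
                 cell_size = c(box[1] / nx, box[2] / ny), n_frames = n_frames(traj)),
            class = "thickness_map")
}

#' Orientational bond order parameter
#'
#' Second-order Legendre polynomial of the angle between selected bond
#' vectors and the membrane normal (the box z-axis):
#' `S = <(3 cos^2 theta - 1)/2>`, averaged over bonds and frames. S is 1 for
#' bonds parallel to the normal, -0.5 for in-plane bonds and 0 at the magic
#' angle; isotropic orientations average to 0.
#'
#' @param traj a [cg_trajectory()].
#' @param bond_pairs E x 2 integer matrix of bead index pairs defining the
#'   bond vectors (e.g. all T1-T2 bonds from the topology).
#' @param normal_axis axis index of the membrane normal (3 = z).
#' @return Object of class `order_params` with `S`, standard error `se`
#'   (over frames; NA for a single frame) and the `per_frame` series.
#' @export
compute_order_parameter <- function(traj, bond_pairs, normal_axis = 3L) {
  bp <- as.matrix(bond_pairs)
  if (ncol(bp) != 2L) stop("bond_pairs must be an E x 2 matrix")
  per_frame <- vapply(seq_len(n_frames(traj)), function(t) {
    x <- traj$coords[, , t, drop = TRUE]
    d <- min_image(x[bp[, 1], , drop = FALSE] - x[bp[, 2], , drop = FALSE],
                   traj$box)
    len2 <- rowSums(d * d)
    if (any(len2 == 0)) stop("zero-length bond vector (degenerate-bond error)")
    c2 <- d[, normal_axis]^2 / len2
    mean(0.5 * (3 * c2 - 1))
  }, 0)
  nf <- length(per_frame)
  structure(list(S = mean(per_frame),
                 se = if (nf > 1L) stats::sd(per_frame) / sqrt(nf) else NA_real_,
                 per_frame = per_frame),
            class = "order_params")
}

#' Lateral mean square displacement and diffusion constant
#'
#' Squared in-plane (xy) displacement averaged over all time origins and all
#' selected beads (typically the MG beads, one per lipid). The diffusion
#' constant is a quarter of the slope of the MSD curve, from a weighted
#' linear fit (weights = number of origin pairs per lag) over the configured
#' lag window.
#'
#' @param traj a [cg_trajectory()] with unwrapped coordinates.
#' @param selection bead selection.
#' @param max_lag maximum lag in frames (default: half the trajectory).
#' @param fit_window length-2 fractions of `max_lag` used for the diffusion
#'   fit; the default (0.1, 0.5) avoids the ballistic start and the poorly
#'   averaged tail.
#' @return Object of class `msd_result` with `lag_time` (fs), `msd` (A^2),
#'   `n_origins`, `D` (A^2/fs), its standard error `D_se` and the fit window.
#' @export
compute_msd <- function(traj, selection, max_lag = NULL,
                        fit_window = c(0.1, 0.5)) {
  sel <- .sel_idx(traj, selection)
  nt <- n_frames(traj)
  if (nt < 3L) stop("need at least 3 frames")
  xy <- traj$coords[sel, 1:2, , drop = FALSE]
  if (!isTRUE(traj$unwrapped)) {
    jumps <- abs(xy[, , -1, drop = FALSE] - xy[, , -nt, drop = FALSE])
    if (any(jumps[, 1, ] > traj$box[1] / 2) || any(jumps[, 2, ] > traj$box[2] / 2))
      stop("coordinates appear wrapped across the periodic boundary; unwrap before MSD (unwrap error)")
  }
  max_lag <- max_lag %||% (nt %/% 2)
  max_lag <- min(max_lag, nt - 1L)
  msd <- numeric(max_lag + 1L)
  nor <- integer(max_lag + 1L)
  nor[1] <- nt
  for (lag in seq_len(max_lag)) {
    d <- xy[, , (1 + lag):nt, drop = FALSE] - xy[, , 1:(nt - lag), drop = FALSE]
    msd[lag + 1L] <- mean(d[, 1, ]^2 + d[, 2, ]^2)
    nor[lag + 1L] <- nt - lag
  }
  dt_frame <- if (length(traj$times) >= 2) diff(traj$times)[1] else 1
  lag_time <- (0:max_lag) * dt_frame
  lo <- max(1L, floor(fit_window[1] * max_lag))
  hi <- max(lo + 1L, ceiling(fit_window[2] * max_lag))
  sel_fit <- (lo:hi) + 1L
  fit <- stats::lm(msd[sel_fit] ~ lag_time[sel_fit], weights = nor[sel_fit])
  slope <- unname(stats::coef(fit)[2])
  slope_se <- tryCatch(summary(fit)$coefficients[2, 2], error = function(e) NA_real_)
  structure(list(lag_time = lag_time, msd = msd, n_origins = nor,
                 D = slope / 4, D_se = slope_se / 4,
                 fit_window_frames = c(lo, hi)),
            class = "msd_result")
}

#' Unwrap a trajectory across periodic boundaries
#'
#' Makes coordinates continuous in time by accumulating minimum-image
#' displacements between consecutive frames (valid when no bead moves more
#' than half a box edge between stored frames).
#'
#' @param traj a [cg_trajectory()].
#' @return The unwrapped trajectory (`unwrapped = TRUE`).
#' @export
unwrap_trajectory <- function(traj) {
  nt <- n_frames(traj)
  out <- traj$coords
  for (t in 2:nt) {
    ## minimum-image inter-frame displacement, applied cumulatively
    step <- min_image(traj$coords[, , t] - traj$coords[, , t - 1], traj$box)
    out[, , t] <- out[, , t - 1] + step
  }
  traj$coords <- out
  traj$unwrapped <- TRUE
  traj
}

#' Write an observable result to CSV
#'
#' @param x an `rdf_result`, `density_profile`, `thickness_map`,
#'   `order_params` or `msd_result`.
#' @param path output CSV path; written atomically.
#' @return `path`, invisibly.
#' @export
write_observable <- function(x, path) {
  df <- switch(class(x)[1],
    rdf_result = data.frame(r = x$r, g = x$g, counts = x$counts),
    density_profile = data.frame(z = x$z, density = x$density),
    thickness_map = {
      idx <- which(!is.na(x$grid), arr.ind = TRUE)
      data.frame(cell_x = idx[, 1], cell_y = idx[, 2],
                 thickness = x$grid[idx], occupancy = x$occupancy[idx])
    },
    order_params = data.frame(frame = seq_along(x$per_frame), S = x$per_frame),
    msd_result = data.frame(lag_time = x$lag_time, msd = x$msd,
                            n_origins = x$n_origins),
    stop("unsupported observable"))
  tmp <- paste0(path, ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
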