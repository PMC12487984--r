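## Frame containers: plain matrices with light S3 wrappers, bio3d-style.

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_mat3 <- function(x, name) {
  if (!is.matrix(x) || ncol(x) != 3L || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix with 3 columns", name))
  invisible(x)
}

#' Construct a pseudo-atomistic frame
#'
#' Holds one snapshot of an atomistic (or pseudo-atomistic) system: per-atom
#' coordinates and instantaneous forces, masses, and the lipid each atom
#' belongs to. Units are Angstrom, kcal mol^-1 A^-1 and amu.
#'
#' @param coords n x 3 coordinate matrix (A).
#' @param forces n x 3 force matrix (kcal mol^-1 A^-1).
#' @param masses length-n positive masses (amu).
#' @param lipid_index length-n integer, which lipid each atom belongs to
#'   (1-based, contiguous).
#' @param lipid_type length-n character, lipid type label per atom.
#' @param box length-3 orthorhombic box edges (A), all positive.
#' @return Object of class `atomistic_frame`.
#' @export
atomistic_frame <- function(coords, forces, masses, lipid_index, lipid_type, box) {
  .check_mat3(coords, "coords"); .check_mat3(forces, "forces")
  if (!all(dim(coords) == dim(forces)))
    stop("coordinates and forces must have identical shape")
  n <- nrow(coords)
  if (length(masses) != n || any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be length-n, finite and strictly positive")
  if (length(lipid_index) != n) stop("lipid_index must have one entry per atom")
  if (length(lipid_type) == 1L) lipid_type <- rep(lipid_type, n)
  if (length(lipid_type) != n) stop("lipid_type must have one entry per atom")
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive edge lengths")
  structure(list(coords = coords, forces = forces, masses = as.numeric(masses),
                 lipid_index = as.integer(lipid_index),
                 lipid_type = as.character(lipid_type),
                 box = as.numeric(box)),
            class = "atomistic_frame")
}

#' Construct a coarse-grained frame
#'
#' One snapshot of the bead-level system: bead coordinates and (optionally)
#' bead forces, integer bead-type codes, the owning lipid of each bead and
#' the periodic box.
#'
#' @param coords N x 3 bead coordinates (A).
#' @param forces N x 3 bead forces (kcal mol^-1 A^-1) or NULL.
#' @param bead_types length-N integer bead type codes.
#' @param lipid_index length-N integer lipid assignment.
#' @param box length-3 box edges (A).
#' @return Object of class `cg_frame`.
#' @export
cg_frame <- function(coords, forces = NULL, bead_types, lipid_index, box) {
  .check_mat3(coords, "coords")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (!is.null(forces)) {
    .check_mat3(forces, "forces")
    if (!all(dim(forces) == dim(coords))) stop("forces shape must match coords")
    if (any(!is.finite(forces))) stop("forces must be finite")
  }
  n <- nrow(coords)
  if (length(bead_types) != n) stop("bead_types must have one entry per bead")
  if (length(lipid_index) != n) stop("lipid_index must have one entry per bead")
  if (length(box) != 3L || any(box <= 0)) stop("box must be three positive edges")
  structure(list(coords = coords, forces = forces,
                 bead_types = as.integer(bead_types),
                 lipid_index = as.integer(lipid_index),
                 box = as.numeric(box)),
            class = "cg_frame")
}

#' @export
print.cg_frame <- function(x, ...) {
  cat(sprintf("cg_frame: %d beads, %d lipids, box %.2f x %.2f x %.2f A, forces: %s\n",
              nrow(x$coords), length(unique(x$lipid_index)),
              x$box[1], x$box[2], x$box[3],
              if (is.null(x$forces)) "absent" else "present"))
  invisible(x)
}

#' Construct a coarse-grained trajectory
#'
#' @param coords N x 3 x T array of bead coordinates (A).
#' @param box length-3 box edges (A), fixed over the run (NVT).
#' @param bead_types,lipid_index per-bead metadata as in [cg_frame()].
#' @param times optional length-T frame times (fs).
#' @param forces optional N x 3 x T array of forces.
#' @param unwrapped logical, TRUE if coordinates are continuous across
#'   periodic images (required by [compute_msd()]).
#' @return Object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(coords, box, bead_types, lipid_index,
                          times = NULL, forces = NULL, unwrapped = FALSE) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be an N x 3 x T array")
  nt <- dim(coords)[3]
  structure(list(coords = coords, box = as.numeric(box),
                 bead_types = as.integer(bead_types),
                 lipid_index = as.integer(lipid_index),
                 times = times %||% seq_len(nt) - 1,
                 forces = forces, unwrapped = isTRUE(unwrapped)),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d beads x %d frames, box %.1f x %.1f x %.1f A\n",
              dim(x$coords)[1], dim(x$coords)[3], x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cg_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame of a trajectory as a `cg_frame`
#' @param traj a `cg_trajectory`.
#' @param i frame index.
#' @return A [cg_frame()].
#' @export
traj_frame <- function(traj, i) {
  cg_frame(traj$coords[, , i, drop = TRUE],
           forces = if (!is.null(traj$forces)) traj$forces[, , i, drop = TRUE],
           bead_types = traj$bead_types, lipid_index = traj$lipid_index,
           box = traj$box)
}

## --- periodic geometry -------------------------------------------------

#' Minimum-image displacement in an orthorhombic box
#'
#' @param d displacement matrix (rows are 3-vectors) or a single 3-vector.
#' @param box length-3 box edges (A).
#' @return Displacements folded into `[-box/2, box/2)` per component.
#' @export
min_image <- function(d, box) {
  if (is.null(dim(d))) d <- matrix(d, ncol = 3L)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

## Row-wise accumulation of E x 3 contributions onto an N x 3 matrix.
.accumulate_rows <- function(n, idx, vals) {
  if (length(idx) == 0L) return(matrix(0, n, 3L))
  .rowsum_into(vals, idx, n)
}

## Row-wise accumulation of an E x d matrix into n x d by integer group.
.rowsum_into <- function(vals, idx, n) {
  out <- matrix(0, n, ncol(vals))
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s)), ] <- s
  out
}
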