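## Portable dataset container: a directory holding a meta.json sidecar plus
## little-endian float64 arrays (column-major). Lossless for float64 payloads
## and readable from any language with a JSON parser and raw file access.
##
## Layout:
##   meta.json        format_version, kind, units, dims [N,3,T], box,
##                    bead_types, lipid_index, type_codes, times, provenance
##   coordinates.bin  N*3*T float64, little-endian, column-major
##   forces.bin       optional, same shape
##   masses.bin       optional (atomistic payloads), length n

.write_bin <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(as.numeric(x)), con, size = 8L, endian = "little")
}

.read_bin <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "double", n = n, size = 8L, endian = "little")
}

#' Write a CG trajectory or dataset to the portable container
#'
#' @param x a [cg_trajectory()], `cg_dataset`, or list of [cg_frame()]s.
#' @param path output directory (created; existing containers overwritten
#'   atomically via a temporary directory + rename).
#' @param units coordinate unit label recorded in the metadata ("angstrom").
#' @param provenance list recorded verbatim (e.g. spec hash, seeds, configs).
#' @param type_codes optional named label -> code map recorded for
#'   selections.
#' @return `path`, invisibly.
#' @export
write_container <- function(x, path, units = "angstrom", provenance = NULL,
                            type_codes = NULL) {
  if (inherits(x, "cg_dataset")) {
    provenance <- provenance %||% list(spec = unclass(x$spec), hash = x$hash,
                                       ff = unclass(x$ff)[c("bonds", "pairs", "cutoff")])
    type_codes <- type_codes %||% as.list(x$topo$type_codes)
    x <- frames_to_trajectory(x$frames)
  } else if (is.list(x) && !inherits(x, "cg_trajectory")) {
    x <- frames_to_trajectory(x)
  }
  dims <- dim(x$coords)
  tmp <- paste0(path, ".tmp.", Sys.getpid())
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  .write_bin(x$coords, file.path(tmp, "coordinates.bin"))
  has_forces <- !is.null(x$forces)
  if (has_forces) .write_bin(x$forces, file.path(tmp, "forces.bin"))
  meta <- list(format_version = 1L, kind = "cg_dataset",
               units = list(coordinates = units,
                            forces = "kcal/mol/angstrom",
                            time = "fs", masses = "amu"),
               dims = dims, box = x$box,
               bead_types = x$bead_types, lipid_index = x$lipid_index,
               type_codes = type_codes, times = x$times,
               unwrapped = isTRUE(x$unwrapped),
               has_forces = has_forces,
               provenance = provenance)
  .atomic_write_json(meta, file.path(tmp, "meta.json"))
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a portable container
#'
#' Coordinates are converted to Angstrom on read based on the recorded unit
#' ("angstrom"/"A" or "nm"); an unrecognized unit is an error, never a
#' silent guess.
#'
#' @param path container directory.
#' @return A [cg_trajectory()] with a `meta` element.
#' @export
read_container <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop(sprintf("'%s' is not a dataset container", path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$format_version)) stop("container missing format version")
  dims <- as.integer(meta$dims)
  n <- prod(dims)
  scale <- switch(tolower(meta$units$coordinates %||% ""),
                  "angstrom" = 1, "a" = 1, "nm" = 10,
                  stop(sprintf("unknown coordinate unit '%s' in container",
                               meta$units$coordinates)))
  coords <- array(.read_bin(file.path(path, "coordinates.bin"), n) * scale, dims)
  forces <- NULL
  if (isTRUE(meta$has_forces))
    forces <- array(.read_bin(file.path(path, "forces.bin"), n), dims)
  traj <- cg_trajectory(coords, box = as.numeric(meta$box) * scale,
                        bead_types = meta$bead_types,
                        lipid_index = meta$lipid_index,
                        times = meta$times, forces = forces,
                        unwrapped = isTRUE(meta$unwrapped))
  traj$meta <- meta
  traj
}

#' Stack CG frames into a trajectory
#' @param frames non-empty list of [cg_frame()]s with a common box.
#' @return A [cg_trajectory()] (with forces if every frame carries them).
#' @export
frames_to_trajectory <- function(frames) {
  stopifnot(length(frames) > 0L)
  n <- nrow(frames[[1]]$coords)
  nt <- length(frames)
  coords <- array(0, c(n, 3L, nt))
  has_forces <- all(vapply(frames, function(f) !is.null(f$forces), TRUE))
  forces <- if (has_forces) array(0, c(n, 3L, nt))
  for (t in seq_len(nt)) {
    coords[, , t] <- frames[[t]]$coords
    if (has_forces) forces[, , t] <- frames[[t]]$forces
  }
  cg_trajectory(coords, frames[[1]]$box, frames[[1]]$bead_types,
                frames[[1]]$lipid_index, forces = forces)
}

#' Split a trajectory into CG frames
#' @param traj a [cg_trajectory()].
#' @return List of [cg_frame()]s.
#' @export
trajectory_to_frames <- function(traj) {
  lapply(seq_len(n_frames(traj)), function(i) traj_frame(traj, i))
}

#' Read coordinates from standard formats or the container
#'
#' Supports the portable container (directory), PDB files (via bio3d;
#' Angstrom by construction) and DCD trajectories (via bio3d, with a PDB
#' topology for bead metadata). Unsupported extensions raise an explicit
#' error.
#'
#' @param path container directory, .pdb or .dcd file.
#' @param topology_path PDB file providing residue assignment when `path`
#'   is a DCD trajectory.
#' @return A [cg_trajectory()].
#' @export
read_trajectory <- function(path, topology_path = NULL) {
  if (dir.exists(path)) return(read_container(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path)
    x <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z)
    return(cg_trajectory(array(x, c(nrow(x), 3L, 1L)), box = .pdb_box(path),
                         bead_types = rep(1L, nrow(x)),
                         lipid_index = as.integer(factor(pdb$atom$resno))))
  }
  if (ext == "dcd") {
    if (is.null(topology_path)) stop("a PDB topology is required to read DCD")
    pdb <- bio3d::read.pdb(topology_path)
    dcd <- bio3d::read.dcd(path, cell = FALSE, verbose = FALSE)
    nt <- nrow(dcd); n <- ncol(dcd) / 3
    coords <- array(0, c(n, 3L, nt))
    for (t in seq_len(nt)) coords[, , t] <- matrix(dcd[t, ], ncol = 3, byrow = TRUE)
    return(cg_trajectory(coords, box = .pdb_box(topology_path),
                         bead_types = rep(1L, n),
                         lipid_index = as.integer(factor(pdb$atom$resno))))
  }
  stop(sprintf("unsupported trajectory format '.%s'", ext))
}

## Orthorhombic box from a PDB CRYST1 record (bio3d does not surface it).
.pdb_box <- function(path) {
  ln <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(ln) == 0L)
    stop("PDB lacks a CRYST1 record; cannot infer the periodic box")
  abc <- as.numeric(c(substr(ln[1], 7, 15), substr(ln[1], 16, 24),
                      substr(ln[1], 25, 33)))
  if (anyNA(abc) || any(abc <= 0)) stop("malformed CRYST1 record")
  abc
}

#' Write one CG frame as a PDB snapshot
#'
#' @param frame a [cg_frame()].
#' @param path output .pdb path.
#' @param type_codes optional named label -> code map for element naming.
#' @return `path`, invisibly.
#' @export
write_frame_pdb <- function(frame, path, type_codes = NULL) {
  n <- nrow(frame$coords)
  labs <- if (!is.null(type_codes))
    .code_to_label(frame$bead_types, type_codes) else paste0("B", frame$bead_types)
  xyz <- as.vector(t(frame$coords))
  tmp <- paste0(path, ".tmp")
  bio3d::write.pdb(file = tmp, xyz = xyz, resno = frame$lipid_index,
                   resid = rep("LIP", n), elety = substr(labs, 1, 4))
  file.rename(tmp, path)
  invisible(path)
}

## --- mapping scheme config files ---------------------------------------

#' Write a mapping scheme to YAML
#' @param scheme a [mapping_scheme()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  obj <- list(lipid_type = scheme$lipid_type, n_atoms = scheme$n_atoms,
              beads = lapply(scheme$beads, function(b)
                list(label = b$label, type = b$type,
                     atoms = as.integer(b$atoms), masses = as.numeric(b$masses))),
              bonds = lapply(scheme$bonds, as.list))
  tmp <- paste0(path, ".tmp")
  yaml::write_yaml(obj, tmp, precision = 15L)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a mapping scheme from YAML
#' @param path path written by [write_scheme()] (or hand-authored).
#' @return A [mapping_scheme()].
#' @export
read_scheme <- function(path) {
  obj <- yaml::read_yaml(path)
  mapping_scheme(obj$lipid_type,
                 beads = lapply(obj$beads, function(b)
                   list(label = b$label, type = b$type,
                        atoms = as.integer(unlist(b$atoms)),
                        masses = as.numeric(unlist(b$masses)))),
                 bonds = lapply(obj$bonds, unlist),
                 n_atoms = obj$n_atoms)
}

## --- atomistic containers ----------------------------------------------

#' Write pseudo-atomistic frames to a portable container
#' @param frames list of [atomistic_frame()]s (common box and composition).
#' @param path output directory.
#' @param provenance list recorded verbatim.
#' @return `path`, invisibly.
#' @export
write_atomistic_container <- function(frames, path, provenance = NULL) {
  stopifnot(length(frames) > 0L)
  f1 <- frames[[1]]
  n <- nrow(f1$coords); nt <- length(frames)
  coords <- array(0, c(n, 3L, nt)); forces <- array(0, c(n, 3L, nt))
  for (t in seq_len(nt)) {
    coords[, , t] <- frames[[t]]$coords
    forces[, , t] <- frames[[t]]$forces
  }
  tmp <- paste0(path, ".tmp.", Sys.getpid())
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  .write_bin(coords, file.path(tmp, "coordinates.bin"))
  .write_bin(forces, file.path(tmp, "forces.bin"))
  .write_bin(f1$masses, file.path(tmp, "masses.bin"))
  meta <- list(format_version = 1L, kind = "atomistic_dataset",
               units = list(coordinates = "angstrom",
                            forces = "kcal/mol/angstrom", masses = "amu"),
               dims = c(n, 3L, nt), box = f1$box,
               lipid_index = f1$lipid_index, lipid_type = f1$lipid_type,
               has_forces = TRUE, provenance = provenance)
  .atomic_write_json(meta, file.path(tmp, "meta.json"))
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a pseudo-atomistic container
#' @param path directory written by [write_atomistic_container()].
#' @return List of [atomistic_frame()]s.
#' @export
read_atomistic_container <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  if (!identical(meta$kind, "atomistic_dataset"))
    stop("not an atomistic container")
  dims <- as.integer(meta$dims); n <- prod(dims)
  coords <- array(.read_bin(file.path(path, "coordinates.bin"), n), dims)
  forces <- array(.read_bin(file.path(path, "forces.bin"), n), dims)
  masses <- .read_bin(file.path(path, "masses.bin"), dims[1])
  lapply(seq_len(dims[3]), function(t)
    atomistic_frame(coords[, , t], forces[, , t], masses,
                    lipid_index = meta$lipid_index,
                    lipid_type = meta$lipid_type, box = meta$box))
}
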