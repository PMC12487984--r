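## cg_mapping: atoms -> six-bead center-of-mass representation.

#' Define a per-lipid-type mapping scheme
#'
#' A mapping scheme assigns every atom of one lipid type to exactly one CG
#' bead and records the intra-lipid bond topology between beads. The standard
#' lipid scheme uses six beads: a headgroup bead (HG, phosphate plus
#' choline/serine), a middle bead (MG, glycerol plus esters) and two tail
#' beads per acyl chain (T1 = first half, T2 = second half), connected as
#' HG-MG, MG-T1a, T1a-T2a, MG-T1b, T1b-T2b.
#'
#' @param lipid_type character label, e.g. "DOPC".
#' @param beads list of bead definitions, each a list with elements
#'   `label` (unique within the lipid), `type` (bead type label, e.g. "T1"),
#'   `atoms` (integer atom indices within the lipid) and `masses`
#'   (positive amu, same length as `atoms`).
#' @param bonds list of length-2 character vectors of bead labels.
#' @param n_atoms total number of atoms in one lipid of this type.
#' @return Object of class `mapping_scheme`.
#' @examples
#' scheme <- mapping_scheme("TOY",
#'   beads = list(list(label = "A", type = "HG", atoms = 1:2, masses = c(1, 2)),
#'                list(label = "B", type = "T1", atoms = 3:4, masses = c(1, 1))),
#'   bonds = list(c("A", "B")), n_atoms = 4)
#' @export
mapping_scheme <- function(lipid_type, beads, bonds, n_atoms) {
  labels <- vapply(beads, function(b) b$label, "")
  if (anyDuplicated(labels)) stop("bead labels must be unique")
  atoms <- unlist(lapply(beads, function(b) b$atoms))
  if (length(atoms) != n_atoms || !setequal(atoms, seq_len(n_atoms)) ||
      anyDuplicated(atoms))
    stop("every atom of the lipid must appear in exactly one bead group")
  for (b in beads) {
    if (length(b$atoms) == 0L) stop("bead groups must be non-empty")
    if (length(b$masses) != length(b$atoms)) stop("masses must match atoms")
    if (any(b$masses <= 0)) stop("masses must be strictly positive")
  }
  for (bd in bonds) {
    if (length(bd) != 2L || !all(bd %in% labels))
      stop("bonds must reference two existing bead labels")
    if (bd[1] == bd[2]) stop("self-bonds are not allowed")
  }
  structure(list(lipid_type = lipid_type, beads = beads,
                 bonds = lapply(bonds, as.character),
                 n_atoms = as.integer(n_atoms)),
            class = "mapping_scheme")
}

#' @export
print.mapping_scheme <- function(x, ...) {
  cat(sprintf("mapping_scheme '%s': %d atoms -> %d beads, %d bonds\n",
              x$lipid_type, x$n_atoms, length(x$beads), length(x$bonds)))
  invisible(x)
}

.scheme_list <- function(schemes) {
  if (inherits(schemes, "mapping_scheme")) {
    out <- list(schemes); names(out) <- schemes$lipid_type; return(out)
  }
  names(schemes) <- vapply(schemes, function(s) s$lipid_type, "")
  schemes
}

## Shared walk over lipids; fn(scheme, atom_rows_of_lipid) -> 6 x 3-ish rows.
.map_frame_core <- function(frame, schemes, per_bead) {
  schemes <- .scheme_list(schemes)
  lipids <- sort(unique(frame$lipid_index))
  out <- vector("list", length(lipids))
  for (li in seq_along(lipids)) {
    rows <- which(frame$lipid_index == lipids[li])
    type <- frame$lipid_type[rows[1]]
    sch <- schemes[[type]]
    if (is.null(sch))
      stop(sprintf("no mapping scheme for lipid type '%s'", type))
    if (length(rows) != sch$n_atoms)
      stop(sprintf("lipid %d has %d atoms but scheme '%s' covers %d (mapping coverage error)",
                   lipids[li], length(rows), type, sch$n_atoms))
    out[[li]] <- do.call(rbind, lapply(sch$beads, per_bead, rows = rows, sch = sch))
  }
  do.call(rbind, out)
}

#' Map atomistic coordinates to bead centers of mass
#'
#' Each bead is placed at the mass-weighted mean position of its atom group.
#' Atoms of a group are first unwrapped relative to the group's first atom by
#' the minimum-image convention so that lipids straddling the periodic
#' boundary map correctly. Bead order is (lipid index ascending, then scheme
#' bead order) and is the ordering convention used throughout the package.
#'
#' @param frame an [atomistic_frame()].
#' @param schemes a [mapping_scheme()] or list of schemes keyed by lipid type.
#' @return N x 3 matrix of bead coordinates (A), N = beads over all lipids.
#' @export
map_coordinates <- function(frame, schemes) {
  box <- frame$box
  .map_frame_core(frame, schemes, function(b, rows, sch) {
    idx <- rows[b$atoms]
    m <- b$masses
    tm <- sum(m)
    if (tm <= 0) stop("zero total group mass (degenerate group)")
    x <- frame$coords[idx, , drop = FALSE]
    ref <- x[1, ]
    x <- sweep(min_image(sweep(x, 2L, ref), box), 2L, ref, "+")
    colSums(x * m) / tm
  })
}

#' Map atomistic forces onto beads
#'
#' For a center-of-mass coordinate map with disjoint atom groups the
#' consistent force mapping is the plain sum of the atomic forces in each
#' group; the total force is conserved exactly.
#'
#' @inheritParams map_coordinates
#' @return N x 3 matrix of bead forces (kcal mol^-1 A^-1).
#' @export
map_forces <- function(frame, schemes) {
  .map_frame_core(frame, schemes, function(b, rows, sch) {
    colSums(frame$forces[rows[b$atoms], , drop = FALSE])
  })
}

#' Map a full atomistic frame to a CG frame
#'
#' Convenience wrapper running [map_coordinates()] and [map_forces()] and
#' attaching bead types and lipid indices consistent with [build_topology()].
#'
#' @inheritParams map_coordinates
#' @param type_codes optional named integer vector bead-type label -> code;
#'   derived from the schemes when omitted.
#' @return A [cg_frame()] with mapped coordinates and forces.
#' @export
map_frame <- function(frame, schemes, type_codes = NULL) {
  schemes <- .scheme_list(schemes)
  if (is.null(type_codes)) type_codes <- .derive_type_codes(schemes)
  lipids <- sort(unique(frame$lipid_index))
  types <- integer(0); lidx <- integer(0)
  for (li in seq_along(lipids)) {
    rows <- which(frame$lipid_index == lipids[li])
    sch <- schemes[[frame$lipid_type[rows[1]]]]
    types <- c(types, type_codes[vapply(sch$beads, function(b) b$type, "")])
    lidx <- c(lidx, rep(li, length(sch$beads)))
  }
  cg_frame(map_coordinates(frame, schemes), forces = map_forces(frame, schemes),
           bead_types = types, lipid_index = lidx, box = frame$box)
}

.derive_type_codes <- function(schemes) {
  labs <- unique(unlist(lapply(schemes, function(s)
    vapply(s$beads, function(b) b$type, ""))))
  stats::setNames(seq_along(labs), labs)
}

#' Build the global CG bonded topology
#'
#' Global bead indexing follows the [map_coordinates()] ordering: lipids in
#' the order given by `lipid_counts`, beads in scheme order within each lipid.
#'
#' @param schemes a [mapping_scheme()] or list of schemes keyed by lipid type.
#' @param lipid_counts named integer vector, lipids per type (>= 1).
#' @return Object of class `cg_topology` with elements `bond_pairs`
#'   (E x 2 integer matrix), `bond_type` (character, "A-B" bead-type labels),
#'   `bead_types` (integer codes per bead), `type_codes` (named map),
#'   `lipid_index` and `n_beads`.
#' @export
build_topology <- function(schemes, lipid_counts) {
  schemes <- .scheme_list(schemes)
  if (length(lipid_counts) == 0L || any(lipid_counts < 1L))
    stop("lipid counts must be >= 1 (config error)")
  if (is.null(names(lipid_counts)) && length(schemes) == 1L)
    names(lipid_counts) <- names(schemes)
  unknown <- setdiff(names(lipid_counts), names(schemes))
  if (length(unknown)) stop(sprintf("unknown lipid type '%s' (config error)", unknown[1]))
  type_codes <- .derive_type_codes(schemes)

  pairs <- list(); btype <- character(0)
  bead_types <- integer(0); lipid_index <- integer(0)
  offset <- 0L; lip <- 0L
  for (tname in names(lipid_counts)) {
    sch <- schemes[[tname]]
    labels <- vapply(sch$beads, function(b) b$label, "")
    tlabs <- vapply(sch$beads, function(b) b$type, "")
    nb <- length(labels)
    local_bonds <- do.call(rbind, lapply(sch$bonds, function(bd)
      c(match(bd[1], labels), match(bd[2], labels))))
    for (i in seq_len(lipid_counts[[tname]])) {
      lip <- lip + 1L
      if (!is.null(local_bonds)) {
        pairs[[length(pairs) + 1L]] <- local_bonds + offset
        btype <- c(btype, vapply(seq_len(nrow(local_bonds)), function(k)
          paste(sort(tlabs[local_bonds[k, ]]), collapse = "-"), ""))
      }
      bead_types <- c(bead_types, type_codes[tlabs])
      lipid_index <- c(lipid_index, rep(lip, nb))
      offset <- offset + nb
    }
  }
  bp <- do.call(rbind, pairs)
  if (!is.null(bp)) {
    key <- paste(pmin(bp[, 1], bp[, 2]), pmax(bp[, 1], bp[, 2]))
    if (anyDuplicated(key)) stop("duplicate bond pairs")
    if (any(bp[, 1] == bp[, 2])) stop("self-bonds are not allowed")
  }
  structure(list(bond_pairs = bp, bond_type = btype,
                 bead_types = unname(bead_types), type_codes = type_codes,
                 lipid_index = lipid_index, n_beads = offset),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("cg_topology: %d beads, %d bonds, %d bead types\n",
              x$n_beads, if (is.null(x$bond_pairs)) 0L else nrow(x$bond_pairs),
              length(x$type_codes)))
  invisible(x)
}
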