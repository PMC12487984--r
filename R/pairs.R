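## Pair search under the minimum-image convention (orthorhombic boxes).

#' Enumerate bead pairs within a cutoff
#'
#' Returns exactly the unordered pairs whose minimum-image distance is below
#' `cutoff`. An all-pairs search is used; systems of a few thousand beads are
#' well within its range.
#'
#' @param frame a [cg_frame()] (or any list with `coords` and `box`).
#' @param cutoff pair cutoff (A), must be positive.
#' @param require_half_box if TRUE, error when `cutoff` exceeds half the
#'   smallest box edge (minimum image would be ambiguous).
#' @return List with integer vectors `i`, `j` (i < j), matrix `dx`
#'   (minimum-image displacement `x_i - x_j`) and vector `r` of distances.
#' @export
neighbor_pairs <- function(frame, cutoff, require_half_box = TRUE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  box <- frame$box
  if (require_half_box && cutoff > min(box) / 2)
    stop("cutoff exceeds half the smallest box edge (geometry error)")
  x <- frame$coords
  n <- nrow(x)
  if (n < 2L)
    return(list(i = integer(0), j = integer(0),
                dx = matrix(0, 0, 3), r = numeric(0)))
  ut <- .upper_pairs(n)
  i <- ut$i; j <- ut$j
  dx <- min_image(x[i, , drop = FALSE] - x[j, , drop = FALSE], box)
  r <- sqrt(rowSums(dx * dx))
  keep <- r < cutoff
  list(i = i[keep], j = j[keep], dx = dx[keep, , drop = FALSE], r = r[keep])
}

## Cached i<j index pairs per system size (the all-pairs enumeration is the
## only O(N^2) allocation on the force path).
.pair_cache <- new.env(parent = emptyenv())
.upper_pairs <- function(n) {
  key <- as.character(n)
  hit <- .pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  j <- rep.int(2:n, 1:(n - 1))
  i <- sequence(1:(n - 1))
  out <- list(i = i, j = j)
  .pair_cache[[key]] <- out
  out
}

## Drop directly bonded (1-2) pairs from a pair list.
.exclude_bonded <- function(pairs, topo) {
  if (is.null(topo$bond_pairs) || length(pairs$r) == 0L) return(pairs)
  n <- topo$n_beads
  bkey <- pmin(topo$bond_pairs[, 1], topo$bond_pairs[, 2]) * (n + 1) +
    pmax(topo$bond_pairs[, 1], topo$bond_pairs[, 2])
  pkey <- pairs$i * (n + 1) + pairs$j
  keep <- !(pkey %in% bkey)
  list(i = pairs$i[keep], j = pairs$j[keep],
       dx = pairs$dx[keep, , drop = FALSE], r = pairs$r[keep])
}

## Scatter per-pair central forces (dV/dr per pair) onto beads.
## Returns N x 3 forces: F_i += -dVdr * dx/r, F_j -= the same.
.central_forces <- function(n, pairs, dVdr) {
  if (length(pairs$r) == 0L) return(matrix(0, n, 3))
  fvec <- pairs$dx * (-dVdr / pairs$r)
  .accumulate_rows(n, c(pairs$i, pairs$j), rbind(fvec, -fvec))
}

#' Canonical unordered type-pair key
#'
#' @param a,b bead-type labels (or codes), vectorized.
#' @return Character keys like "T1:T2" with the two entries in sorted order.
#' @export
pair_key <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  paste(lo, hi, sep = ":")
}

## Expand "A:B"-keyed per-pair parameters into a symmetric T x T matrix
## indexed by position in `type_codes` (fast numeric lookup on hot paths).
.pair_param_matrix <- function(terms, field, type_codes, default = NA_real_) {
  labs <- names(type_codes)
  M <- matrix(default, length(labs), length(labs))
  for (key in names(terms)) {
    ab <- strsplit(key, ":", fixed = TRUE)[[1]]
    ia <- match(ab[1], labs); ib <- match(ab[2], labs)
    if (is.na(ia) || is.na(ib)) next
    M[ia, ib] <- M[ib, ia] <- terms[[key]][[field]]
  }
  M
}
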