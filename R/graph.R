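## Graph message-passing potential (continuous-filter convolution family).
##
## The network is written directly in R with hand-derived gradients:
##  - forward pass: type embedding -> interaction layers (radial-basis
##    filtered neighbor aggregation with a smooth cutoff envelope) -> MLP
##    head contracting node features to per-bead energies, summed to E.
##  - reverse pass: exact dE/d(pair distance), hence exact forces.
##  - forward-over-reverse pass: exact parameter gradient of the
##    force-matching loss (which needs d(forces)/d(parameters)).

#' Graph potential configuration
#'
#' @param n_layers number of interaction layers (>= 1; four in the standard
#'   setup).
#' @param width node embedding / feature width.
#' @param n_rbf number of Gaussian radial basis functions on `[0, cutoff]`.
#' @param cutoff neighbor cutoff (A).
#' @param head_width hidden width of the output head.
#' @return Object of class `graph_config`.
#' @export
graph_config <- function(n_layers = 4L, width = 128L, n_rbf = 18L,
                         cutoff = 12, head_width = 64L) {
  stopifnot(n_layers >= 1L, width >= 1L, n_rbf >= 2L, cutoff > 0, head_width >= 1L)
  structure(list(n_layers = as.integer(n_layers), width = as.integer(width),
                 n_rbf = as.integer(n_rbf), cutoff = cutoff,
                 head_width = as.integer(head_width)),
            class = "graph_config")
}

#' Create a graph message-passing potential
#'
#' Parameters are initialized deterministically from `seed` (scaled normal
#' init; the last head layer starts near zero so the untrained model is a
#' small perturbation).
#'
#' @param config a [graph_config()].
#' @param type_codes named integer vector, bead-type label -> code.
#' @param seed integer init seed; recorded in the model and its checkpoints.
#' @return Object of class `graph_potential` (also `trainable_potential`).
#' @export
graph_potential <- function(config, type_codes, seed = 1L) {
  stopifnot(inherits(config, "graph_config"))
  d <- config$width; K <- config$n_rbf; d2 <- config$head_width
  TT <- length(type_codes)
  old <- .Random.seed_save()
  set.seed(seed)
  rn <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  layers <- lapply(seq_len(config$n_layers), function(l) list(
    W1 = rn(d, d, 1 / sqrt(d)), b1 = numeric(d),
    Wf1 = rn(K, d, 1 / sqrt(K)), bf1 = numeric(d),
    Wf2 = rn(d, d, 1 / sqrt(d)), bf2 = numeric(d),
    W2 = rn(d, d, 1 / sqrt(d)), b2 = numeric(d),
    W3 = rn(d, d, 1 / sqrt(d)), b3 = numeric(d)))
  params <- list(emb = rn(TT, d, 1),
                 layers = layers,
                 head = list(Wo1 = rn(d, d2, 1 / sqrt(d)), bo1 = numeric(d2),
                             Wo2 = rn(d2, 1L, 0.01 / sqrt(d2)), bo2 = numeric(1)))
  .Random.seed_restore(old)
  mu <- seq(0, config$cutoff, length.out = K)
  w <- mu[2] - mu[1]
  structure(list(config = config, type_codes = type_codes, seed = as.integer(seed),
                 params = params, rbf_mu = mu, rbf_w = w),
            class = c("graph_potential", "trainable_potential"))
}

#' @export
print.graph_potential <- function(x, ...) {
  cat(sprintf("graph_potential: %d layers, width %d, %d radial bases, cutoff %.1f A, %d parameters\n",
              x$config$n_layers, x$config$width, x$config$n_rbf,
              x$config$cutoff, length(param_vector(x))))
  invisible(x)
}

## Preserve the caller's RNG stream around deterministic init.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
param_vector.graph_potential <- function(model) unlist(model$params, use.names = FALSE)

#' @export
set_param_vector.graph_potential <- function(model, v) {
  stopifnot(length(v) == length(param_vector(model)))
  model$params <- utils::relist(v, model$params)
  model
}

## Directed edge structure from the undirected pair list.
.graph_edges <- function(model, frame) {
  pairs <- neighbor_pairs(frame, model$config$cutoff)
  E0 <- length(pairs$r)
  if (E0 == 0L)
    return(list(pairs = pairs, E0 = 0L, src = integer(0), dst = integer(0)))
  rdir <- rep(pairs$r, 2L)
  mu <- model$rbf_mu; w <- model$rbf_w
  B <- exp(-outer(rdir, mu, function(r, m) ((r - m) / w)^2))
  dBdr <- B * outer(rdir, mu, function(r, m) -2 * (r - m) / w^2)
  list(pairs = pairs, E0 = E0,
       src = c(pairs$j, pairs$i), dst = c(pairs$i, pairs$j),
       r = rdir, B = B, dBdr = dBdr,
       env = .envelope(rdir, model$config$cutoff),
       envd = .envelope_d(rdir, model$config$cutoff))
}

.graph_forward <- function(model, frame, edges) {
  p <- model$params
  n <- nrow(frame$coords)
  d <- model$config$width
  tidx <- match(frame$bead_types, model$type_codes)
  h <- p$emb[tidx, , drop = FALSE]
  L <- model$config$n_layers
  cache <- list(tidx = tidx, n = n, layers = vector("list", L))
  for (l in seq_len(L)) {
    pl <- p$layers[[l]]
    y <- h %*% pl$W1 + rep(pl$b1, each = n)
    if (edges$E0 > 0L) {
      ys <- y[edges$src, , drop = FALSE]
      P1 <- edges$B %*% pl$Wf1 + rep(pl$bf1, each = nrow(edges$B))
      A1 <- .ssp(P1)
      P2 <- A1 %*% pl$Wf2 + rep(pl$bf2, each = nrow(A1))
      Fm <- P2 * edges$env
      M <- .rowsum_into(ys * Fm, edges$dst, n)
    } else {
      ys <- P1 <- A1 <- P2 <- Fm <- matrix(0, 0, d)
      M <- matrix(0, n, d)
    }
    Q <- M %*% pl$W2 + rep(pl$b2, each = n)
    U <- .ssp(Q)
    V <- U %*% pl$W3 + rep(pl$b3, each = n)
    cache$layers[[l]] <- list(h = h, y = y, ys = ys, P1 = P1, A1 = A1,
                              P2 = P2, Fm = Fm, M = M, Q = Q, U = U)
    h <- h + V
  }
  G <- h %*% p$head$Wo1 + rep(p$head$bo1, each = n)
  Hh <- .ssp(G)
  Ea <- Hh %*% p$head$Wo2 + p$head$bo2
  cache$hL <- h; cache$G <- G; cache$Hh <- Hh; cache$Ea <- Ea
  cache
}

## Reverse pass: dE/d(rbf matrix) and dE/d(envelope), folded to per-pair
## dE/dr; returns energy, per-pair distance gradient and node adjoints.
.graph_reverse_forces <- function(model, frame, edges, cache) {
  p <- model$params
  n <- cache$n
  ah <- (.sig(cache$G) * matrix(p$head$Wo2[, 1], n, length(p$head$bo1),
                                byrow = TRUE)) %*% t(p$head$Wo1)
  nE <- nrow(edges$B %||% matrix(0, 0, 0))
  aB <- if (edges$E0 > 0L) matrix(0, nE, model$config$n_rbf)
  aenv <- numeric(if (edges$E0 > 0L) nE else 0L)
  for (l in rev(seq_len(model$config$n_layers))) {
    pl <- p$layers[[l]]; cl <- cache$layers[[l]]
    aV <- ah
    aU <- aV %*% t(pl$W3)
    aQ <- aU * .sig(cl$Q)
    aM <- aQ %*% t(pl$W2)
    if (edges$E0 > 0L) {
      aMe <- aM[edges$dst, , drop = FALSE]
      ays <- aMe * cl$Fm
      aFm <- aMe * cl$ys
      aP2 <- aFm * edges$env
      aenv <- aenv + rowSums(aFm * cl$P2)
      aA1 <- aP2 %*% t(pl$Wf2)
      aP1 <- aA1 * .sig(cl$P1)
      aB <- aB + aP1 %*% t(pl$Wf1)
      ay <- .rowsum_into(ays, edges$src, n)
      ah <- ah + ay %*% t(pl$W1)
    }
  }
  g_pair <- NULL
  if (edges$E0 > 0L) {
    gdir <- rowSums(aB * edges$dBdr) + aenv * edges$envd
    g_pair <- gdir[seq_len(edges$E0)] + gdir[edges$E0 + seq_len(edges$E0)]
  }
  list(energy = sum(cache$Ea), g_pair = g_pair)
}

#' @export
energy_and_forces.graph_potential <- function(model, frame, ...) {
  .check_vocab(model, frame)
  if (model$config$cutoff > min(frame$box) / 2)
    stop("cutoff exceeds half the smallest box edge (geometry error)")
  n <- nrow(frame$coords)
  edges <- .graph_edges(model, frame)
  cache <- .graph_forward(model, frame, edges)
  rev <- .graph_reverse_forces(model, frame, edges, cache)
  forces <- if (edges$E0 > 0L)
    .central_forces(n, edges$pairs, rev$g_pair) else matrix(0, n, 3L)
  list(energy = rev$energy, forces = forces)
}

## Zero-filled gradient skeleton matching model$params.
.graph_zero_grad <- function(p) utils::relist(numeric(length(unlist(p, use.names = FALSE))), p)

#' @export
fm_loss_grad.graph_potential <- function(model, frame, target) {
  .check_vocab(model, frame)
  p <- model$params
  n <- nrow(frame$coords)
  edges <- .graph_edges(model, frame)
  cache <- .graph_forward(model, frame, edges)
  rev <- .graph_reverse_forces(model, frame, edges, cache)
  if (edges$E0 == 0L) {
    return(list(loss = sum(target^2) / (3 * n),
                grad = numeric(length(param_vector(model)))))
  }
  Fp <- .central_forces(n, edges$pairs, rev$g_pair)
  resid <- Fp - target
  loss <- sum(resid^2) / (3 * n)
  S <- resid * (2 / (3 * n))
  u <- edges$pairs$dx / edges$pairs$r
  lambda <- rowSums(u * (S[edges$pairs$j, , drop = FALSE] -
                           S[edges$pairs$i, , drop = FALSE]))
  rdot <- rep(lambda, 2L)

  ## ---- tangent (forward-mode) pass in the direction rdot -------------
  d <- model$config$width
  L <- model$config$n_layers
  Bd_t <- edges$dBdr * rdot
  envd_t <- edges$envd * rdot
  hd <- matrix(0, n, d)
  tcache <- vector("list", L)
  for (l in seq_len(L)) {
    pl <- p$layers[[l]]; cl <- cache$layers[[l]]
    yd <- hd %*% pl$W1
    ysd <- yd[edges$src, , drop = FALSE]
    P1d <- Bd_t %*% pl$Wf1
    A1d <- .sig(cl$P1) * P1d
    P2d <- A1d %*% pl$Wf2
    Fmd <- P2d * edges$env + cl$P2 * envd_t
    Md <- .rowsum_into(ysd * cl$Fm + cl$ys * Fmd, edges$dst, n)
    Qd <- Md %*% pl$W2
    Ud <- .sig(cl$Q) * Qd
    Vd <- Ud %*% pl$W3
    tcache[[l]] <- list(hd = hd, yd = yd, ysd = ysd, P1d = P1d, A1d = A1d,
                        P2d = P2d, Fmd = Fmd, Md = Md, Qd = Qd, Ud = Ud)
    hd <- hd + Vd
  }
  Gd <- hd %*% p$head$Wo1
  Hhd <- .sig(cache$G) * Gd

  ## ---- combined reverse pass (adjoints of primal `a*` and tangent `b*`)
  g <- .graph_zero_grad(p)
  sigG <- .sig(cache$G); sigpG <- sigG * (1 - sigG)
  bEa <- matrix(1, n, 1L)
  bHh <- matrix(p$head$Wo2[, 1], n, model$config$head_width, byrow = TRUE)
  g$head$Wo2 <- g$head$Wo2 + t(Hhd) %*% bEa
  bG <- bHh * sigG
  aG <- bHh * sigpG * Gd
  bh <- bG %*% t(p$head$Wo1)
  ah <- aG %*% t(p$head$Wo1)
  g$head$Wo1 <- g$head$Wo1 + t(hd) %*% bG + t(cache$hL) %*% aG
  g$head$bo1 <- g$head$bo1 + colSums(aG)

  for (l in rev(seq_len(L))) {
    pl <- p$layers[[l]]; cl <- cache$layers[[l]]; tl <- tcache[[l]]
    sigQ <- .sig(cl$Q); sigpQ <- sigQ * (1 - sigQ)
    sigP1 <- .sig(cl$P1); sigpP1 <- sigP1 * (1 - sigP1)
    aV <- ah; bV <- bh
    aU <- aV %*% t(pl$W3); bU <- bV %*% t(pl$W3)
    g$layers[[l]]$W3 <- g$layers[[l]]$W3 + t(cl$U) %*% aV + t(tl$Ud) %*% bV
    g$layers[[l]]$b3 <- g$layers[[l]]$b3 + colSums(aV)
    aQ <- aU * sigQ + bU * sigpQ * tl$Qd
    bQ <- bU * sigQ
    aM <- aQ %*% t(pl$W2); bM <- bQ %*% t(pl$W2)
    g$layers[[l]]$W2 <- g$layers[[l]]$W2 + t(cl$M) %*% aQ + t(tl$Md) %*% bQ
    g$layers[[l]]$b2 <- g$layers[[l]]$b2 + colSums(aQ)
    aMe <- aM[edges$dst, , drop = FALSE]; bMe <- bM[edges$dst, , drop = FALSE]
    ays <- aMe * cl$Fm + bMe * tl$Fmd
    aFm <- aMe * cl$ys + bMe * tl$ysd
    bys <- bMe * cl$Fm
    bFm <- bMe * cl$ys
    aP2 <- aFm * edges$env + bFm * envd_t
    bP2 <- bFm * edges$env
    aA1 <- aP2 %*% t(pl$Wf2); bA1 <- bP2 %*% t(pl$Wf2)
    g$layers[[l]]$Wf2 <- g$layers[[l]]$Wf2 + t(cl$A1) %*% aP2 + t(tl$A1d) %*% bP2
    g$layers[[l]]$bf2 <- g$layers[[l]]$bf2 + colSums(aP2)
    aP1 <- aA1 * sigP1 + bA1 * sigpP1 * tl$P1d
    bP1 <- bA1 * sigP1
    g$layers[[l]]$Wf1 <- g$layers[[l]]$Wf1 + t(edges$B) %*% aP1 + t(Bd_t) %*% bP1
    g$layers[[l]]$bf1 <- g$layers[[l]]$bf1 + colSums(aP1)
    ay <- .rowsum_into(ays, edges$src, n)
    by <- .rowsum_into(bys, edges$src, n)
    g$layers[[l]]$W1 <- g$layers[[l]]$W1 + t(cl$h) %*% ay + t(tl$hd) %*% by
    g$layers[[l]]$b1 <- g$layers[[l]]$b1 + colSums(ay)
    ah <- ah + ay %*% t(pl$W1)
    bh <- bh + by %*% t(pl$W1)
  }
  ge <- .rowsum_into(ah, cache$tidx, nrow(p$emb))
  g$emb <- g$emb + ge
  list(loss = loss, grad = unlist(g, use.names = FALSE))
}
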