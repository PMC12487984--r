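## Variational force matching: dataset handling, the loss, and the
## gradient-descent training loop.

#' Force-matching loss
#'
#' The variational force-matching functional, evaluated empirically: the mean
#' over frames of `1/(3N) sum_I |target_I - predicted_I|^2`, where the
#' targets are the (delta) forces mapped from the reference trajectory and
#' the predictions are the model forces (the negative energy gradient). It is
#' non-negative and zero exactly at a perfect fit.
#'
#' @param predicted N x 3 matrix or list of matrices (one per frame).
#' @param target matching matrix or list of matrices.
#' @param n_beads N; defaults to the row count.
#' @return Scalar loss (kcal^2 mol^-2 A^-2).
#' @export
fm_loss <- function(predicted, target, n_beads = NULL) {
  if (is.matrix(predicted)) { predicted <- list(predicted); target <- list(target) }
  if (length(predicted) != length(target)) stop("frame count mismatch (dimension error)")
  vals <- mapply(function(p, t) {
    if (!all(dim(p) == dim(t))) stop("shape mismatch (dimension error)")
    n <- n_beads %||% nrow(p)
    sum((t - p)^2) / (3 * n)
  }, predicted, target)
  mean(vals)
}

#' Assemble a force-matching dataset
#'
#' Frames paired with delta-force targets, split by frame into train and
#' validation sets under a seeded shuffle. No frame belongs to both splits.
#'
#' @param frames list of [cg_frame()]s.
#' @param targets list of N x 3 delta-force matrices (defaults to the frames'
#'   own `forces`).
#' @param val_fraction fraction of frames held out for validation.
#' @param seed split seed.
#' @param provenance free-form provenance record stored with the dataset.
#' @return Object of class `fm_dataset`.
#' @export
fm_dataset <- function(frames, targets = NULL, val_fraction = 0.1, seed = 1L,
                       provenance = NULL) {
  if (is.null(targets)) targets <- lapply(frames, `[[`, "forces")
  if (length(frames) != length(targets)) stop("frames and targets differ in length")
  ok <- vapply(targets, function(t) !is.null(t) && all(is.finite(t)), TRUE)
  if (!all(ok)) stop("targets must be present and finite for every frame")
  nf <- length(frames)
  old <- .Random.seed_save(); set.seed(seed)
  perm <- sample.int(nf)
  .Random.seed_restore(old)
  nval <- max(if (nf > 1L) 1L else 0L, floor(val_fraction * nf))
  val_idx <- sort(perm[seq_len(nval)])
  train_idx <- sort(setdiff(seq_len(nf), val_idx))
  if (length(train_idx) == 0L) stop("training split is empty")
  structure(list(frames = frames, targets = targets,
                 train_idx = train_idx, val_idx = val_idx,
                 seed = as.integer(seed), provenance = provenance),
            class = "fm_dataset")
}

#' @export
print.fm_dataset <- function(x, ...) {
  cat(sprintf("fm_dataset: %d frames (%d train / %d validation), %d beads each\n",
              length(x$frames), length(x$train_idx), length(x$val_idx),
              nrow(x$frames[[1]]$coords)))
  invisible(x)
}

#' Training configuration
#'
#' @param batch_size frames per gradient step.
#' @param lr initial learning rate (Adam).
#' @param max_epochs maximum epochs.
#' @param seed training seed (shuffling; recorded in the history).
#' @param patience early-stop patience: stop after this many epochs without
#'   validation improvement (also the plateau window for halving the learning
#'   rate). Use `Inf` to disable.
#' @param lr_decay multiplicative decay applied when the validation loss
#'   plateaus for `ceiling(patience / 2)` epochs.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, lr = 5e-3, max_epochs = 50L,
                         seed = 1L, patience = 10L, lr_decay = 0.5) {
  stopifnot(batch_size >= 1L, max_epochs >= 1L, lr > 0)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 patience = patience, lr_decay = lr_decay),
            class = "train_config")
}

#' Train a potential by variational force matching
#'
#' Minimizes [fm_loss()] over the model parameters with Adam on mini-batches
#' of frames. Per-epoch train and validation losses are logged; the
#' parameters with the best validation loss are retained. Runs are fully
#' reproducible under a fixed seed.
#'
#' @param model a trainable potential.
#' @param data an [fm_dataset()].
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return List with `model` (best-validation parameters), `history`
#'   (data.frame epoch/train_loss/val_loss/lr) and `best_epoch`.
#' @export
train_potential <- function(model, data, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(data, "fm_dataset"))
  theta <- param_vector(model)
  mom <- numeric(length(theta)); vel <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  lr <- cfg$lr; tstep <- 0L
  val_loss <- function(m) {
    if (length(data$val_idx) == 0L) return(NA_real_)
    mean(vapply(data$val_idx, function(i)
      fm_loss(energy_and_forces(m, data$frames[[i]])$forces, data$targets[[i]]),
      0))
  }
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  since_best <- 0L; since_decay <- 0L
  old <- .Random.seed_save(); set.seed(cfg$seed)
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- data$train_idx[sample.int(length(data$train_idx))]
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    ep_loss_sum <- 0; ep_n <- 0L
    for (b in batches) {
      gl <- lapply(b, function(i)
        fm_loss_grad(set_param_vector(model, theta), data$frames[[i]], data$targets[[i]]))
      losses <- vapply(gl, `[[`, 0, "loss")
      if (any(!is.finite(losses)))
        stop(sprintf("non-finite loss in batch containing frame(s) %s (divergence error)",
                     paste(b[!is.finite(losses)], collapse = ",")))
      grad <- Reduce(`+`, lapply(gl, `[[`, "grad")) / length(b)
      ep_loss_sum <- ep_loss_sum + sum(losses); ep_n <- ep_n + length(b)
      if (lr > 0) {
        tstep <- tstep + 1L
        mom <- beta1 * mom + (1 - beta1) * grad
        vel <- beta2 * vel + (1 - beta2) * grad^2
        mhat <- mom / (1 - beta1^tstep)
        vhat <- vel / (1 - beta2^tstep)
        theta <- theta - lr * mhat / (sqrt(vhat) + adam_eps)
      }
    }
    vl <- val_loss(set_param_vector(model, theta))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss_sum / ep_n,
                                         val_loss = vl, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.6g  val %.6g  lr %.3g",
                      epoch, ep_loss_sum / ep_n, vl, lr))
    track <- if (is.na(vl)) ep_loss_sum / ep_n else vl
    if (track < best$loss - 1e-12) {
      best <- list(loss = track, theta = theta, epoch = epoch)
      since_best <- 0L; since_decay <- 0L
    } else {
      since_best <- since_best + 1L; since_decay <- since_decay + 1L
      if (is.finite(cfg$patience) && since_decay >= ceiling(cfg$patience / 2)) {
        lr <- lr * cfg$lr_decay; since_decay <- 0L
      }
      if (is.finite(cfg$patience) && since_best >= cfg$patience) break
    }
  }
  .Random.seed_restore(old)
  list(model = set_param_vector(model, best$theta), history = history,
       best_epoch = best$epoch)
}

#' Root-mean-square force error of prior + model against mapped forces
#'
#' Diagnostic companion to the force-matching loss: the RMS over all force
#' components of `mapped - (prior + model)`.
#'
#' @param model a trainable potential or NULL.
#' @param prior a [prior_force_field()] (or toy force field) or NULL.
#' @param frames list of [cg_frame()]s carrying mapped forces.
#' @param topo topology for the prior evaluation.
#' @return Scalar RMSE (kcal mol^-1 A^-1).
#' @export
force_rmse <- function(model, prior, frames, topo = NULL) {
  sq <- 0; cnt <- 0
  for (fr in frames) {
    if (is.null(fr$forces)) stop("frames must carry mapped forces")
    pred <- total_force_field(fr, topo, prior = prior, model = model)$forces
    sq <- sq + sum((fr$forces - pred)^2)
    cnt <- cnt + length(pred)
  }
  sqrt(sq / cnt)
}

#' Write a training history to CSV
#' @param history the `history` data.frame from [train_potential()].
#' @param path output CSV path; written atomically.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(history, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
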