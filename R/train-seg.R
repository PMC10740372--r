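# Segmentation training: Adam at lr 3e-4, plateau-triggered learning-rate
# decay (divide by 5), and windowed convergence rules.
#
# "Decrease in the average training loss over w epochs" is read as the mean
# loss of the last w epochs compared with the mean of the w epochs before
# them; the plateau rule re-arms after each decay (it needs 2*w fresh epochs
# before it can fire again).  Training stops when the convergence window
# shows a decrease below its threshold, when the learning rate falls below
# the floor, or at max_epochs.

#' Training schedule for the segmentation network
#'
#' Defaults follow the reference protocol: Adam with initial learning rate
#' `3e-4` for up to 1000 epochs; the learning rate is divided by 5 when the
#' mean training loss over the last 30 epochs has decreased by less than
#' `5e-3` relative to the preceding 30; training converges when the same
#' decrease over 60-epoch windows is below `5e-3` or the learning rate drops
#' below `1e-6`.
#'
#' @param lr0 Initial learning rate.
#' @param max_epochs Epoch cap.
#' @param decay_factor Learning-rate division factor on plateau.
#' @param plateau_window,plateau_eps Plateau rule: window length (epochs)
#'   and minimal mean-loss decrease.
#' @param converge_window,converge_eps Convergence rule: window length and
#'   minimal decrease.
#' @param lr_floor Stop once the learning rate falls below this.
#' @return An object of class `train_schedule`.
#' @export
train_schedule <- function(lr0 = 3e-4, max_epochs = 1000L, decay_factor = 5,
                           plateau_window = 30L, plateau_eps = 5e-3,
                           converge_window = 60L, converge_eps = 5e-3,
                           lr_floor = 1e-6) {
  assert_that(lr0 > lr_floor && lr_floor > 0, "need lr0 > lr_floor > 0")
  assert_that(is_count(plateau_window) && plateau_window >= 1 &&
                is_count(converge_window) && converge_window >= 1,
              "windows must be positive integers")
  structure(list(lr0 = lr0, max_epochs = as.integer(max_epochs),
                 decay_factor = decay_factor,
                 plateau_window = as.integer(plateau_window),
                 plateau_eps = plateau_eps,
                 converge_window = as.integer(converge_window),
                 converge_eps = converge_eps, lr_floor = lr_floor),
            class = "train_schedule")
}

#' Plateau learning-rate scheduler
#'
#' A stateful scheduler that consumes one epoch-average loss at a time and
#' reports the learning rate for the next epoch, whether a decay fired, and
#' whether training should stop.  It is the exact component the training
#' loop uses, and can be driven with synthetic loss traces.
#'
#' @param schedule A [train_schedule()].
#' @return An object of class `plateau_scheduler`; advance it with
#'   [scheduler_step()].
#' @export
plateau_scheduler <- function(schedule) {
  e <- new.env(parent = emptyenv())
  e$schedule <- schedule
  e$lr <- schedule$lr0
  e$trace <- numeric(0)
  e$since_decay <- 0L
  class(e) <- "plateau_scheduler"
  e
}

windowed_decrease <- function(trace, w) {
  t <- length(trace)
  mean(trace[(t - 2 * w + 1):(t - w)]) - mean(trace[(t - w + 1):t])
}

#' Advance the scheduler by one epoch
#'
#' @param sched A [plateau_scheduler()].
#' @param loss The epoch-average training loss.
#' @return A list with `lr` (rate for the next epoch), `decayed`, `stop`,
#'   and `reason` (`NA`, `"converged"`, `"lr_floor"` or `"max_epochs"`).
#' @export
scheduler_step <- function(sched, loss) {
  s <- sched$schedule
  sched$trace <- c(sched$trace, loss)
  sched$since_decay <- sched$since_decay + 1L
  t <- length(sched$trace)
  decayed <- FALSE
  if (sched$since_decay >= 2L * s$plateau_window &&
      windowed_decrease(sched$trace, s$plateau_window) < s$plateau_eps) {
    sched$lr <- sched$lr / s$decay_factor
    sched$since_decay <- 0L
    decayed <- TRUE
  }
  reason <- NA_character_
  if (t >= 2L * s$converge_window &&
      windowed_decrease(sched$trace, s$converge_window) < s$converge_eps) {
    reason <- "converged"
  } else if (sched$lr < s$lr_floor) {
    reason <- "lr_floor"
  } else if (t >= s$max_epochs) {
    reason <- "max_epochs"
  }
  list(lr = sched$lr, decayed = decayed, stop = !is.na(reason), reason = reason)
}

# Sample one training patch.  With probability fg_prob the patch is centered
# on a random foreground voxel (lesions are tiny; pure uniform sampling
# would mostly show background), else its origin is uniform.
sample_patch <- function(img, lab, patch, fg_prob = 0.5) {
  d <- dim(img)
  if (stats::runif(1) < fg_prob && any(lab > 0L)) {
    fg <- which(lab > 0L)
    v <- fg[sample.int(length(fg), 1L)] - 1L
    ctr <- c(v %% d[1], (v %/% d[1]) %% d[2], v %/% (d[1] * d[2]))
    org <- pmin(pmax(ctr - patch %/% 2L, 0L), d - patch)
  } else {
    org <- vapply(1:3, function(a) sample.int(d[a] - patch + 1L, 1L) - 1L, integer(1))
  }
  ix <- (org[1] + 1):(org[1] + patch)
  iy <- (org[2] + 1):(org[2] + patch)
  iz <- (org[3] + 1):(org[3] + patch)
  list(img = img[ix, iy, iz], lab = lab[ix, iy, iz])
}

#' Train a segmentation network
#'
#' Adam on the compound Dice + cross-entropy loss over randomly sampled
#' patches (foreground-centered with probability `fg_prob`).  The per-epoch
#' average loss drives the [plateau_scheduler()]: the learning rate is
#' divided by the decay factor when the plateau rule fires and training
#' stops at the convergence rule, the learning-rate floor, or `max_epochs`.
#'
#' @param model A [build_segnet()] model.
#' @param dataset List of samples, each a list with `img` (3D array,
#'   z-scored) and `lab` (integer 3D array of class labels).
#' @param schedule A [train_schedule()].
#' @param seed Integer seed for patch sampling.
#' @param batches_per_epoch,batch_size Patch batches per epoch and patches
#'   per batch.
#' @param fg_prob Probability of centering a patch on foreground.
#' @param verbose Print per-epoch progress.
#' @return The model, with the training curve (a tibble with `epoch`,
#'   `loss`, `lr`, `decayed`) attached as attribute `"curve"`.
#' @export
train_segmenter <- function(model, dataset, schedule = train_schedule(),
                            seed = 1L, batches_per_epoch = 10L, batch_size = 2L,
                            fg_prob = 0.5, verbose = FALSE) {
  assert_that(length(dataset) >= 1, "`dataset` must be non-empty")
  if (schedule$lr_floor > schedule$lr0) {
    stop_cs("schedule has lr_floor > lr0: no trainable epoch", "cs_argument_error")
  }
  patch <- model$config$patch_size
  K <- model$config$num_classes
  layers <- segnet_layers(model)
  sched <- plateau_scheduler(schedule)
  curve <- list()
  with_preserved_rng(seed, {
    lr <- schedule$lr0
    step_t <- 0L
    for (epoch in seq_len(schedule$max_epochs)) {
      losses <- numeric(batches_per_epoch)
      for (b in seq_len(batches_per_epoch)) {
        ps <- lapply(seq_len(batch_size), function(i) {
          s <- dataset[[sample.int(length(dataset), 1L)]]
          sample_patch(s$img, s$lab, patch, fg_prob)
        })
        x <- array(unlist(lapply(ps, `[[`, "img")), dim = c(patch, patch, patch, batch_size))
        v <- one_hot(unlist(lapply(ps, `[[`, "lab")), K)
        zero_grads(layers)
        fw <- segnet_forward(model, x, training = TRUE)
        losses[b] <- total_loss(fw$probs, v)
        segnet_backward(model, total_loss_logit_grad(fw$probs, v))
        step_t <- step_t + 1L
        adam_step(layers, lr, step_t)
      }
      st <- scheduler_step(sched, mean(losses))
      curve[[epoch]] <- tibble::tibble(epoch = epoch, loss = mean(losses),
                                       lr = lr, decayed = st$decayed)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  lr %.2e%s", epoch, mean(losses),
                        lr, if (st$decayed) "  [decay]" else ""))
      }
      lr <- st$lr
      if (st$stop) break
    }
  })
  attr(model, "curve") <- structure(dplyr::bind_rows(curve),
                                    class = c("cs_training_curve",
                                              class(dplyr::bind_rows(curve))))
  model
}
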