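#' @include AllClasses.R cgan_models.R
NULL

# Losses, optimization loop and variant orchestration. The discriminator
# maximizes the adversarial objective (equivalently minimizes binary
# cross-entropy with real/fake labels); the generator minimizes a
# non-saturating adversarial term plus gamma times the L1 reconstruction
# term. All loss arithmetic uses numerically stable log-sigmoid forms.

logSigmoid <- function(x) -log1p(exp(-abs(x))) + pmin(x, 0)
softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

#' Adversarial loss value
#'
#' The GAN objective evaluated from discriminator logits:
#' `mean(log D(real)) + mean(log(1 - D(fake)))`, computed with
#' numerically stable log-sigmoid terms (never forming probabilities 0 or
#' 1). The discriminator seeks to maximize this; its training step
#' minimizes the equivalent binary cross-entropy.
#'
#' @param d_real_logits,d_fake_logits finite logit vectors.
#' @return scalar loss value.
#' @examples
#' adversarialLoss(0, 0)  # 2 log 0.5 = -1.386
#' @export
adversarialLoss <- function(d_real_logits, d_fake_logits) {
  mean(logSigmoid(d_real_logits)) + mean(logSigmoid(-d_fake_logits))
}

#' L1 reconstruction loss
#'
#' Mean absolute difference over all pixels and batch entries; keeps the
#' generated patches content-consistent with their targets.
#'
#' @param fake_patch,target_patch equal-shape numeric arrays.
#' @return scalar mean absolute error.
#' @export
l1Loss <- function(fake_patch, target_patch) {
  if (!all(dim(fake_patch) == dim(target_patch)) &&
      length(fake_patch) != length(target_patch))
    stop("shape mismatch between fake and target patches")
  mean(abs(fake_patch - target_patch))
}

#' Combined generator objective
#'
#' `adv_term + gamma * l1_term`, the balance (gamma = 0.5 by default)
#' between the adversarial and reconstruction terms.
#'
#' @param adv_term adversarial term value.
#' @param l1_term L1 term value.
#' @param gamma non-negative balance weight.
#' @return scalar objective.
#' @export
generatorObjective <- function(adv_term, l1_term, gamma = 0.5) {
  if (gamma < 0) stop("gamma must be >= 0")
  adv_term + gamma * l1_term
}

# ---- batch assembly --------------------------------------------------------

batchTensors <- function(pairs) {
  n <- length(pairs)
  cs <- nrow(pairs[[1]]@cyto); rs <- nrow(pairs[[1]]@receptor)
  cyto <- array(0, dim = c(cs, cs, 1, n))
  target <- array(0, dim = c(rs, rs, 1, n))
  for (i in seq_len(n)) {
    cyto[, , 1, i] <- pairs[[i]]@cyto
    target[, , 1, i] <- pairs[[i]]@receptor
  }
  list(cyto = 2 * cyto - 1, target = 2 * target - 1,
       areas = vapply(pairs, function(p) p@area, character(1)))
}

# ---- training state --------------------------------------------------------

#' Initialize cGAN training state
#'
#' Builds the generator and discriminator for the configured variant and
#' wraps them with fresh Adam states, an epoch/step counter and a loss
#' history.
#'
#' @param config a [TrainingConfig-class].
#' @param gen_spec a [GeneratorSpec-class] (its variant must match).
#' @param disc_spec optional [DiscriminatorSpec-class]; defaults to the
#'   four-layer discriminator at the generator's output side, conditional
#'   iff the variant is `cond_multi_area`.
#' @return a `cganTrainState` list.
#' @export
initTrainState <- function(config, gen_spec, disc_spec = NULL) {
  if (gen_spec@variant != config@variant)
    stop("generator spec variant does not match the training config")
  if (is.null(disc_spec)) {
    # four conv layers by default, fewer when the receptor patch is too
    # small for four halvings
    nl <- min(4L, as.integer(floor(log2(gen_spec@output_side_px))))
    disc_spec <- discriminatorSpec(
      input_side_px = gen_spec@output_side_px, n_layers = nl,
      conditional = config@variant == "cond_multi_area")
  }
  gen <- buildGenerator(gen_spec, seed = childSeed(config@seed, "gen_init"))
  disc <- buildDiscriminator(disc_spec,
                             seed = childSeed(config@seed, "disc_init"))
  structure(list(gen = gen, disc = disc, opt_g = newAdamState(),
                 opt_d = newAdamState(), config = config, epoch = 0L,
                 step = 0L, history = list()),
            class = "cganTrainState")
}

#' @export
print.cganTrainState <- function(x, ...) {
  cat(sprintf("cganTrainState [%s]: epoch %d, step %d\n",
              x$config@variant, x$epoch, x$step))
  invisible(x)
}

#' One adversarial training step
#'
#' Performs one discriminator update (binary cross-entropy on real vs
#' generated patches) followed by one generator update (adversarial term
#' plus gamma x L1), with global-norm gradient clipping on both networks.
#' Noise tensors are drawn from the current RNG stream, so a fixed seed
#' before the call makes the step fully reproducible.
#'
#' @param state a `cganTrainState` from [initTrainState()].
#' @param batch non-empty list of [PatchPair-class] objects.
#' @return list with the updated `state` and `losses`: `d_loss`, `g_adv`,
#'   `g_l1` (per-pixel mean), `g_l1_norm` (patch 1-norm, the optimized
#'   term), `g_total`, `adv_value` and the pre-clip gradient norms.
#' @export
trainStep <- function(state, batch) {
  if (length(batch) == 0) stop("batch must be non-empty")
  cfg <- state$config
  bt <- batchTensors(batch)
  n <- length(batch)
  condition <- if (cfg@variant == "cond_multi_area") bt$areas else NULL
  d <- dim(bt$cyto)
  z <- array(rnorm(prod(d)), dim = d)
  xin <- assembleGenInput(state$gen, bt$cyto, z, condition)
  gf <- genForwardCore(state$gen, xin, training = TRUE)
  state$gen <- gf$gen
  fake <- gf$out                               # (rs, rs, 1, n), in (-1, 1)

  # -- discriminator update
  xr <- assembleDiscInput(state$disc, bt$target, condition)
  xf <- assembleDiscInput(state$disc, fake, condition)
  fr <- discForwardCore(state$disc, xr, training = TRUE)
  state$disc <- fr$disc
  ff <- discForwardCore(state$disc, xf, training = TRUE)
  state$disc <- ff$disc
  d_loss <- mean(softplus(-fr$logits)) + mean(softplus(ff$logits))
  gr <- (plogis(fr$logits) - 1) / n
  gfk <- plogis(ff$logits) / n
  br <- discBackwardCore(state$disc, fr$caches, gr)
  bf <- discBackwardCore(state$disc, ff$caches, gfk)
  gd <- mapply(function(a, b) mapply(`+`, a, b, SIMPLIFY = FALSE),
               br$grads, bf$grads, SIMPLIFY = FALSE)
  gd <- clipGradients(gd, cfg@clip_norm)
  upd <- adamStep(state$disc$layers, gd, state$opt_d, cfg@learning_rate,
                  cfg@beta1, cfg@beta2)
  state$disc$layers <- upd$layers; state$opt_d <- upd$opt

  # -- generator update (through the updated discriminator)
  ff2 <- discForwardCore(state$disc, assembleDiscInput(state$disc, fake,
                                                       condition),
                         training = TRUE)
  state$disc <- ff2$disc
  if (cfg@adv_mode == "non_saturating") {
    g_adv <- mean(softplus(-ff2$logits))
    gl <- (plogis(ff2$logits) - 1) / n
  } else {  # literal minimax: minimize log(1 - D(fake))
    g_adv <- -mean(softplus(ff2$logits))
    gl <- -plogis(ff2$logits) / n
  }
  bfk <- discBackwardCore(state$disc, ff2$caches, gl)
  dfake <- bfk$dx[, , 1, , drop = FALSE]       # strip condition channel
  # the reconstruction term is the patch 1-norm (sum of absolute pixel
  # differences) averaged over the batch; its gradient therefore scales
  # with the patch area and dominates the adversarial term, keeping
  # generated patches content-consistent with their targets
  l1 <- mean(abs(fake - bt$target))
  l1_norm <- sum(abs(fake - bt$target)) / n
  dl1 <- sign(fake - bt$target) / n
  gout <- dfake + cfg@gamma * dl1
  gb <- genBackwardCore(state$gen, gf$caches, gout)
  gg <- clipGradients(gb$grads, cfg@clip_norm)
  upd <- adamStep(state$gen$layers, gg, state$opt_g, cfg@learning_rate,
                  cfg@beta1, cfg@beta2)
  state$gen$layers <- upd$layers; state$opt_g <- upd$opt

  losses <- list(d_loss = d_loss, g_adv = g_adv, g_l1 = l1,
                 g_l1_norm = l1_norm,
                 g_total = generatorObjective(g_adv, l1_norm, cfg@gamma),
                 adv_value = adversarialLoss(fr$logits, ff$logits),
                 d_grad_norm = attr(gd, "norm"),
                 g_grad_norm = attr(gg, "norm"))
  if (!all(vapply(losses, is.finite, logical(1))))
    stop("non-finite loss encountered; aborting training step")
  state$step <- state$step + 1L
  list(state = state, losses = losses)
}

#' Section-level train/test split
#'
#' Splits a dataset at the section level so that no section contributes
#' patches to both partitions (leakage guard); deterministic per seed.
#'
#' @param dataset a [PatchDataset-class] with at least two sections.
#' @param train_fraction fraction of sections assigned to training.
#' @param scheme split scheme (only `"by_section"`).
#' @param seed RNG seed.
#' @return list with `train` and `test` [PatchDataset-class] objects.
#' @export
makeSplits <- function(dataset, train_fraction = 0.8,
                       scheme = "by_section", seed = 1L) {
  scheme <- match.arg(scheme, "by_section")
  secs <- unique(dataset@section_ids)
  if (length(secs) < 2)
    stop("at least two distinct section ids are required for a split")
  n_train <- max(1L, min(length(secs) - 1L,
                         round(train_fraction * length(secs))))
  train_secs <- withSeed(seed, sample(secs, n_train))
  list(train = dataset[dataset@section_ids %in% train_secs],
       test = dataset[!dataset@section_ids %in% train_secs])
}

checkVariantLabels <- function(variant, dataset) {
  areas <- unique(vapply(dataset@pairs, function(p) p@area, character(1)))
  recs <- unique(vapply(dataset@pairs, function(p) p@receptor_type,
                        character(1)))
  if (length(recs) != 1)
    stop("all pairs must share one receptor type")
  if (variant == "single_area" && length(areas) != 1)
    stop("single_area training requires a single-area dataset")
  if (variant != "single_area" && length(areas) < 2)
    stop("multi-area variants need patches from both areas")
  invisible(TRUE)
}

#' Train a cGAN on a patch dataset
#'
#' Runs `epochs` passes of [trainStep()] over shuffled minibatches,
#' logging per-epoch mean losses and optionally writing checkpoints.
#' Training is reproducible bit-for-bit under a fixed config seed.
#'
#' @param config a [TrainingConfig-class].
#' @param dataset a [PatchDataset-class] whose labels match the variant
#'   (single-area: one area; multi-area: both areas, one receptor).
#' @param gen_spec optional [GeneratorSpec-class]; inferred from the patch
#'   dimensions by default.
#' @param checkpoint_dir optional directory for per-epoch checkpoints.
#' @param checkpoint_every write a checkpoint every this many epochs.
#' @param verbose print per-epoch losses.
#' @return the final `cganTrainState`; its `history` element is a
#'   data.frame with one row per epoch (epoch, d_loss, g_adv, g_l1,
#'   g_total).
#' @export
fitCGAN <- function(config, dataset, gen_spec = NULL, checkpoint_dir = NULL,
                    checkpoint_every = 50L, verbose = FALSE) {
  checkVariantLabels(config@variant, dataset)
  p1 <- dataset@pairs[[1]]
  if (is.null(gen_spec))
    gen_spec <- generatorSpec(variant = config@variant,
                              input_side_px = nrow(p1@cyto),
                              output_side_px = nrow(p1@receptor))
  state <- initTrainState(config, gen_spec)
  n <- length(dataset@pairs)
  hist <- vector("list", config@epochs)
  withSeed(childSeed(config@seed, "train"), {
    for (ep in seq_len(config@epochs)) {
      ord <- sample.int(n)
      splits <- split(ord, ceiling(seq_along(ord) / config@batch_size))
      ep_losses <- NULL
      for (bi in splits) {
        st <- trainStep(state, dataset@pairs[bi])
        state <- st$state
        ep_losses <- rbind(ep_losses,
                           as.data.frame(st$losses[c("d_loss", "g_adv",
                                                     "g_l1", "g_total")]))
      }
      state$epoch <- ep
      hist[[ep]] <- data.frame(epoch = ep, t(colMeans(ep_losses)))
      if (verbose)
        message(sprintf("epoch %3d  d %.4f  adv %.4f  l1 %.4f", ep,
                        hist[[ep]]$d_loss, hist[[ep]]$g_adv,
                        hist[[ep]]$g_l1))
      if (!is.null(checkpoint_dir) &&
          (ep %% checkpoint_every == 0 || ep == config@epochs))
        saveCheckpoint(state, checkpoint_dir)
    }
  })
  state$history <- do.call(rbind, hist)
  state
}

#' Save / load a training checkpoint
#'
#' The checkpoint holds generator and discriminator parameters, optimizer
#' moments, counters and the RNG-relevant config, so training can resume
#' bit-identically.
#'
#' @param state a `cganTrainState`.
#' @param dir checkpoint directory (created if needed).
#' @return `saveCheckpoint` returns the file path; `loadCheckpoint`
#'   returns the restored state.
#' @export
saveCheckpoint <- function(state, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("checkpoint_epoch%04d.rds", state$epoch))
  saveRDS(state, path)
  sidecar <- file.path(dir, sprintf("checkpoint_epoch%04d.json",
                                    state$epoch))
  jsonlite::write_json(list(epoch = state$epoch, step = state$step,
                            variant = state$config@variant,
                            seed = state$config@seed),
                       sidecar, auto_unbox = TRUE)
  path
}

#' @rdname saveCheckpoint
#' @param path an RDS checkpoint file written by [saveCheckpoint()].
#' @export
loadCheckpoint <- function(path) readRDS(path)
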