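# Adversarial training loop: per training sample per epoch, one discriminator
# update (real pair labeled 1, fake pair labeled 0) followed by one generator
# update (non-saturating adversarial term plus lambda * L1), with Adam on both
# networks, per-iteration loss logging, per-epoch checkpointing, and
# MSSIM-based checkpoint selection on held-out data.

#' Training configuration
#'
#' Defaults are the full-scale settings: generator learning rate 2e-4,
#' discriminator learning rate 1e-6 (the deliberately unbalanced pair that
#' keeps the adversarial loss from oscillating or diverging), Adam with
#' `beta1 = 0.5`, 200 epochs, batch size 1, `lambda = 100`.
#'
#' @param lr_g,lr_d Generator and discriminator learning rates.
#' @param epochs Training epochs; a checkpoint is saved after each.
#' @param batch_size Samples per update (the reference setting is 1).
#' @param lambda Weight of the L1 reconstruction term.
#' @param beta1,beta2 Adam momentum parameters.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(lr_g = 2e-4, lr_d = 1e-6, epochs = 200L,
                         batch_size = 1L, lambda = 100, beta1 = 0.5,
                         beta2 = 0.999, seed = 1L) {
  stopifnot(lr_g > 0, lr_d > 0, epochs >= 1, batch_size >= 1, lambda > 0)
  structure(list(lr_g = lr_g, lr_d = lr_d, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lambda = lambda,
                 beta1 = beta1, beta2 = beta2, seed = as.integer(seed)),
            class = "train_config")
}

#' Total iteration count of a training run
#'
#' `epochs * ceiling(n_train / batch_size)`; with batch size 1 this is
#' `epochs * n_train` (200 x 367 = 73,400 for a 367-sample training set).
#'
#' @param cfg A [train_config()].
#' @param n_train Number of training samples.
#' @return Integer iteration count.
#' @export
count_iterations <- function(cfg, n_train) {
  stopifnot(inherits(cfg, "train_config"), n_train >= 1)
  as.integer(cfg$epochs * ceiling(n_train / cfg$batch_size))
}

# Normalize a pair for the network: each volume independently min-max mapped
# to [-1, 1], padded to the generator grid.
prepare_pair <- function(pair, depth) {
  sn <- normalize_minmax(pair$source)
  tn <- normalize_minmax(pair$target)
  sp <- fit_to_network_grid(sn$data, depth)
  tp <- fit_to_network_grid(tn$data, depth)
  list(source = sp$data, target = tp$data, padding = sp$padding,
       source_norm = sn, target_norm = tn, modality = pair$modality)
}

#' Train the 3D pix2pix model
#'
#' Runs the adversarial loop over the training split of `dataset`: per sample,
#' one discriminator step then one generator step, both Adam. The three loss
#' curves (the real and fake cGAN terms and the generator composite
#' `lambda * L1 + adversarial`) are logged every iteration; weights are
#' checkpointed at every epoch boundary. Fully reproducible given `cfg$seed`.
#' Training aborts with a diagnostic if any loss becomes non-finite
#' (divergence).
#'
#' @param dataset A `phantom_dataset`, or a plain list of `image_pair`s (all
#'   used for training).
#' @param gcfg,dcfg [generator_config()] and [discriminator_config()].
#' @param cfg A [train_config()].
#' @param checkpoint_dir Directory for the per-epoch weight files (created;
#'   defaults to a fresh temporary directory).
#' @return An `epigan_training`: list with `store` (a `checkpoint_store`),
#'   `log` (tibble: iteration, epoch, d_real, d_fake, g_adv, g_l1, g_total),
#'   and the configurations.
#' @export
train_gan <- function(dataset, gcfg, dcfg, cfg,
                      checkpoint_dir = tempfile("ckpts_")) {
  pairs <- if (inherits(dataset, "phantom_dataset")) {
    dataset_pairs(dataset, "train")
  } else {
    dataset
  }
  n <- length(pairs)
  if (n < 1) stop("training split is empty")
  prepped <- lapply(pairs, prepare_pair, depth = gcfg$depth)
  shp <- dim(prepped[[1]]$source)
  dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)

  set.seed(cfg$seed)
  netG <- build_generator(gcfg, shp)
  netD <- build_discriminator(dcfg, shp)
  stateG <- adam_init(netG$params)
  stateD <- adam_init(netD$params)

  total_iter <- count_iterations(cfg, n)
  log_rows <- vector("list", total_iter)
  ckpt_rows <- vector("list", cfg$epochs)
  iter <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    order <- sample(n)
    for (s in order) {
      iter <- iter + 1L
      pp <- prepped[[s]]
      # generator forward (dropout + batch statistics); reused for both steps
      fw <- forward_generator(netG, pp$source, train = TRUE,
                              keep_cache = TRUE)
      netG$buffers <- fw$buffers
      fake <- fw$out

      # --- discriminator step ---
      fr <- forward_discriminator(netD, pp$source, pp$target, train = TRUE,
                                  keep_cache = TRUE)
      netD$buffers <- fr$buffers
      ff <- forward_discriminator(netD, pp$source, fake, train = TRUE,
                                  keep_cache = TRUE)
      netD$buffers <- ff$buffers
      dl <- d_loss_from_probs(fr$probs, ff$probs)
      npatch <- length(fr$probs)
      # d(-mean log sigmoid(a))/da = (sigmoid(a) - 1)/npatch;
      # d(-mean log(1 - sigmoid(a)))/da = sigmoid(a)/npatch
      br <- backward_discriminator(netD, fr$cache,
                                   (fr$probs - 1) / npatch)
      bf <- backward_discriminator(netD, ff$cache, ff$probs / npatch)
      gradsD <- purrr::map2(br$grads, bf$grads[names(br$grads)], `+`)
      upd <- adam_step(netD$params, gradsD, stateD, cfg$lr_d,
                       cfg$beta1, cfg$beta2)
      netD$params <- upd$params
      stateD <- upd$state

      # --- generator step (through the updated discriminator) ---
      fg <- forward_discriminator(netD, pp$source, fake, train = TRUE,
                                  keep_cache = TRUE)
      netD$buffers <- fg$buffers
      gl <- g_loss_from_probs(fg$probs, pp$target, fake, cfg$lambda)
      bg <- backward_discriminator(netD, fg$cache,
                                   (fg$probs - 1) / length(fg$probs))
      nvox <- length(fake)
      dfake <- bg$d_cand +
        cfg$lambda * sign(fake - as_channels(pp$target)) / nvox
      gb <- backward_generator(netG, fw$cache, dfake)
      updG <- adam_step(netG$params, gb$grads, stateG, cfg$lr_g,
                        cfg$beta1, cfg$beta2)
      netG$params <- updG$params
      stateG <- updG$state

      if (!all(is.finite(c(dl$total, gl$total)))) {
        stop(sprintf(
          "training diverged at iteration %d (epoch %d): non-finite loss (D = %g, G = %g)",
          iter, epoch, dl$total, gl$total))
      }
      log_rows[[iter]] <- c(iteration = iter, epoch = epoch,
                            d_real = dl$d_real, d_fake = dl$d_fake,
                            g_adv = gl$g_adv, g_l1 = gl$g_l1,
                            g_total = gl$total)
    }
    file <- file.path(checkpoint_dir,
                      sprintf("ckpt_e%03d_i%06d.rds", epoch, iter))
    save_checkpoint(file, netG, netD, epoch = epoch, iteration = iter)
    ckpt_rows[[epoch]] <- tibble(epoch = epoch, iteration = iter,
                                 file = file)
  }
  log <- as_tibble(do.call(rbind, log_rows))
  manifest <- dplyr::bind_rows(ckpt_rows)
  store <- structure(list(dir = checkpoint_dir, checkpoints = manifest),
                     class = "checkpoint_store")
  jsonlite::write_json(manifest, file.path(checkpoint_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(store = store, log = log, gcfg = gcfg, dcfg = dcfg,
                 cfg = cfg, n_train = n),
            class = "epigan_training")
}

#' @export
tidy.epigan_training <- function(x, ...) x$log

#' @export
glance.epigan_training <- function(x, ...) {
  first <- dplyr::filter(x$log, .data$epoch == 1)
  last <- dplyr::filter(x$log, .data$epoch == max(x$log$epoch))
  tibble(epochs = max(x$log$epoch), iterations = nrow(x$log),
         n_train = x$n_train,
         g_l1_first_epoch = mean(first$g_l1),
         g_l1_final_epoch = mean(last$g_l1),
         g_total_final_epoch = mean(last$g_total))
}

#' Predict a corrected, brain-extracted volume
#'
#' Normalizes the source to `[-1, 1]`, zero-pads it to the generator grid,
#' runs the generator in inference mode (dropout off, running batch-norm
#' statistics), crops back, and rescales to the `[0, 1]` display range.
#' Deterministic.
#'
#' @param model A `gan_generator`, an `epigan_training`, a checkpoint file
#'   path, or a loaded checkpoint list.
#' @param source Numeric 3D array (the biased full-head volume).
#' @return 3D array in `[0, 1]` with the input's shape.
#' @export
predict_volume <- function(model, source) {
  netG <- resolve_generator(model)
  depth <- netG$cfg$depth
  sn <- normalize_minmax(source)
  sp <- fit_to_network_grid(sn$data, depth)
  out <- forward_generator(netG, sp$data, train = FALSE)$out
  out <- crop_to_original(drop_channel(out), sp$padding)
  rescale_display(out)
}

resolve_generator <- function(model) {
  if (inherits(model, "gan_generator")) return(model)
  if (inherits(model, "epigan_training")) {
    sel <- tail(model$store$checkpoints, 1)
    return(load_checkpoint(sel$file)$netG)
  }
  if (is.character(model)) return(load_checkpoint(model)$netG)
  if (is.list(model) && !is.null(model$netG)) return(model$netG)
  stop("cannot resolve a generator from the given model object")
}

# Display-scale (target, prediction) list for one eval pair under a generator.
predict_display_pair <- function(netG, pair) {
  pred <- predict_volume(netG, pair$source)
  targ <- rescale_display(normalize_minmax(pair$target))
  list(target = targ, prediction = pred, modality = pair$modality)
}

#' Evaluate every checkpoint on held-out pairs
#'
#' For each saved epoch the generator predicts each evaluation source; CAD,
#' L2 norm and MSSIM are computed against the display-rescaled target and
#' aggregated (mean/SD) per checkpoint.
#'
#' @param store A `checkpoint_store` (or `epigan_training`).
#' @param eval_pairs List of `image_pair`s.
#' @param cfg An [mssim_config()].
#' @return A tibble sorted by epoch with per-metric mean/SD columns; the
#'   per-volume table is attached as attribute `"per_volume"`.
#' @export
evaluate_checkpoints <- function(store, eval_pairs, cfg = mssim_config()) {
  if (inherits(store, "epigan_training")) store <- store$store
  stopifnot(inherits(store, "checkpoint_store"), length(eval_pairs) >= 1)
  ck <- store$checkpoints
  per_volume <- purrr::map_dfr(seq_len(nrow(ck)), function(i) {
    netG <- load_checkpoint(ck$file[i])$netG
    purrr::map_dfr(seq_along(eval_pairs), function(j) {
      dp <- predict_display_pair(netG, eval_pairs[[j]])
      tibble(epoch = ck$epoch[i], iteration = ck$iteration[i],
             file = ck$file[i], pair = j, modality = dp$modality %||% NA,
             cad = cad(dp$target, dp$prediction),
             l2 = l2_norm(dp$target, dp$prediction),
             mssim = mssim(dp$target, dp$prediction, cfg)$mssim)
    })
  })
  report <- dplyr::arrange(dplyr::summarise(
    dplyr::group_by(per_volume, .data$epoch, .data$iteration, .data$file),
    cad_mean = mean(.data$cad), cad_sd = sd(.data$cad),
    l2_mean = mean(.data$l2), l2_sd = sd(.data$l2),
    mssim_mean = mean(.data$mssim), mssim_sd = sd(.data$mssim),
    .groups = "drop"), .data$epoch)
  attr(report, "per_volume") <- per_volume
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the best checkpoint by mean MSSIM
#'
#' The checkpoint maximizing mean MSSIM over the evaluation set; ties are
#' broken by the earliest epoch. MSSIM is used because it tracks visual
#' quality more closely than CAD or the L2 norm.
#'
#' @param report Tibble from [evaluate_checkpoints()].
#' @return List with `epoch`, `iteration`, `file`, `mssim_mean` and
#'   `criterion`.
#' @export
select_best <- function(report) {
  stopifnot(nrow(report) >= 1)
  best <- which.max(report$mssim_mean) # which.max takes the first maximum
  list(epoch = report$epoch[best], iteration = report$iteration[best],
       file = report$file[best], mssim_mean = report$mssim_mean[best],
       criterion = "highest mean MSSIM on evaluation data; ties -> earliest epoch")
}

#' Learning-rate grid search with early divergence rejection
#'
#' Runs a short training probe for every (lr_G, lr_D) candidate pair. A pair
#' is rejected if the probe aborts with a non-finite loss, if the per-epoch
#' mean of the generator composite exceeds `divergence_factor` times its
#' first-epoch mean (divergence), if the oscillation amplitude of the
#' composite in the final epoch exceeds `oscillation_factor` times its
#' first-epoch SD, or if the adversarial game breaks down with one side too
#' strong (the discriminator assigns the generator's outputs a median
#' probability below `saturation_prob`, leaving no usable adversarial
#' gradient). Among survivors the pair with the lowest final-epoch mean
#' composite wins.
#'
#' @param candidates_g,candidates_d Numeric vectors of learning rates.
#' @param probe_epochs Epochs per probe.
#' @param dataset Dataset (as in [train_gan()]).
#' @param gcfg,dcfg Network configurations.
#' @param seed Seed shared by all probes.
#' @param lambda L1 weight during probes.
#' @param divergence_factor,oscillation_factor,saturation_prob Rejection
#'   thresholds.
#' @return List with `lr_g`, `lr_d` and `trace` (tibble of all probes with
#'   status and final loss).
#' @export
grid_search_lr <- function(candidates_g, candidates_d, probe_epochs, dataset,
                           gcfg, dcfg, seed = 1L, lambda = 100,
                           divergence_factor = 10, oscillation_factor = 5,
                           saturation_prob = 1e-4) {
  stopifnot(length(candidates_g) >= 1, length(candidates_d) >= 1)
  grid <- expand.grid(lr_g = candidates_g, lr_d = candidates_d)
  trace <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    lr_g <- grid$lr_g[i]
    lr_d <- grid$lr_d[i]
    cfg <- train_config(lr_g = lr_g, lr_d = lr_d, epochs = probe_epochs,
                        lambda = lambda, seed = seed)
    res <- tryCatch(train_gan(dataset, gcfg, dcfg, cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      return(tibble(lr_g = lr_g, lr_d = lr_d, status = "diverged",
                    final_loss = NA_real_,
                    note = conditionMessage(res)))
    }
    by_epoch <- dplyr::summarise(dplyr::group_by(res$log, .data$epoch),
                                 m = mean(.data$g_total), .groups = "drop")
    first_mean <- by_epoch$m[1]
    first_sd <- sd(res$log$g_total[res$log$epoch == 1])
    last <- res$log$g_total[res$log$epoch == probe_epochs]
    last_gadv <- res$log$g_adv[res$log$epoch == probe_epochs]
    status <- "ok"
    if (any(by_epoch$m > divergence_factor * first_mean)) {
      status <- "diverged"
    } else if (probe_epochs > 1 && is.finite(first_sd) && first_sd > 0 &&
               (max(last) - min(last)) / 2 > oscillation_factor * first_sd) {
      status <- "oscillating"
    } else if (stats::median(last_gadv) > -log(saturation_prob)) {
      status <- "unbalanced"
    }
    tibble(lr_g = lr_g, lr_d = lr_d, status = status,
           final_loss = mean(last), note = NA_character_)
  })
  ok <- dplyr::filter(trace, .data$status == "ok")
  if (nrow(ok) == 0) {
    stop(paste0("all learning-rate candidates were rejected:\n",
                paste(utils::capture.output(print(trace)), collapse = "\n")))
  }
  winner <- ok[which.min(ok$final_loss), ]
  list(lr_g = winner$lr_g, lr_d = winner$lr_d, trace = trace)
}
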