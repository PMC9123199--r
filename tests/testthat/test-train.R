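test_that("iteration accounting matches epochs x ceiling(n / batch)", {
  cfg <- train_config(epochs = 200)
  expect_identical(count_iterations(cfg, 367), 73400L)
  expect_identical(count_iterations(cfg, 74), 14800L)
  expect_identical(count_iterations(cfg, 447), 89400L)
  expect_identical(count_iterations(train_config(epochs = 1), 1), 1L)
  expect_identical(count_iterations(train_config(epochs = 3, batch_size = 2), 5),
                   9L)
})

test_that("training logs one record per iteration and checkpoints per epoch", {
  pairs <- micro_pairs(2)
  fit <- train_gan(pairs, micro_gcfg(), micro_dcfg(),
                   train_config(epochs = 3, seed = 1))
  expect_identical(nrow(fit$log), 6L)
  expect_identical(nrow(fit$store$checkpoints), 3L)
  expect_identical(fit$log$iteration, as.numeric(1:6))
  expect_identical(nrow(fit$log),
                   as.integer(count_iterations(train_config(epochs = 3), 2)))
  expect_true(all(file.exists(fit$store$checkpoints$file)))
  expect_true(all(is.finite(as.matrix(fit$log[, -1]))))
  # composite equals adversarial + lambda * L1 in every record
  expect_equal(fit$log$g_total, fit$log$g_adv + 100 * fit$log$g_l1,
               tolerance = 1e-10)
  unlink(fit$store$dir, recursive = TRUE)
})

test_that("training is bit-reproducible under a fixed seed", {
  pairs <- micro_pairs(2)
  f1 <- train_gan(pairs, micro_gcfg(), micro_dcfg(),
                  train_config(epochs = 2, seed = 7))
  f2 <- train_gan(pairs, micro_gcfg(), micro_dcfg(),
                  train_config(epochs = 2, seed = 7))
  expect_identical(f1$log, f2$log)
  g1 <- load_checkpoint(tail(f1$store$checkpoints$file, 1))$netG
  g2 <- load_checkpoint(tail(f2$store$checkpoints$file, 1))$netG
  expect_identical(g1$params, g2$params)
  f3 <- train_gan(pairs, micro_gcfg(), micro_dcfg(),
                  train_config(epochs = 2, seed = 8))
  expect_false(identical(f1$log, f3$log))
  unlink(c(f1$store$dir, f2$store$dir, f3$store$dir), recursive = TRUE)
})

test_that("one epoch of updates on a single pair reduces its L1 loss", {
  pairs <- micro_pairs(1)
  fit <- train_gan(pairs, micro_gcfg(dropout_layers = 0), micro_dcfg(),
                   train_config(epochs = 8, seed = 3))
  expect_lt(fit$log$g_l1[8], fit$log$g_l1[1])
  unlink(fit$store$dir, recursive = TRUE)
})

test_that("checkpoint evaluation is deterministic and selection is argmax", {
  pairs <- micro_pairs(3)
  fit <- train_gan(pairs[1:2], micro_gcfg(), micro_dcfg(),
                   train_config(epochs = 2, seed = 2))
  # the same weights listed under two epoch stamps give identical rows
  store <- fit$store
  dup <- store$checkpoints[c(1, 1, 2), ]
  dup$epoch[2] <- 99L
  store$checkpoints <- dup
  rep <- evaluate_checkpoints(store, pairs[3])
  expect_equal(rep$mssim_mean[rep$epoch == 1], rep$mssim_mean[rep$epoch == 99],
               tolerance = 1e-12)
  expect_equal(rep$cad_mean[rep$epoch == 1], rep$cad_mean[rep$epoch == 99],
               tolerance = 1e-12)
  unlink(fit$store$dir, recursive = TRUE)
})

test_that("best-checkpoint selection maximizes mean MSSIM with earliest-epoch ties", {
  rep <- tibble::tibble(epoch = 1:3, iteration = c(2, 4, 6),
                        file = c("a", "b", "c"),
                        mssim_mean = c(0.90, 0.95, 0.93))
  expect_identical(select_best(rep)$file, "b")
  rep$mssim_mean <- c(0.9, 0.9, 0.9)
  expect_identical(select_best(rep)$epoch, 1L)
  # selection agrees with an independent re-aggregation of per-volume scores
  pairs <- micro_pairs(3)
  fit <- train_gan(pairs[1:2], micro_gcfg(), micro_dcfg(),
                   train_config(epochs = 3, seed = 4))
  tab <- evaluate_checkpoints(fit, pairs[3])
  pv <- attr(tab, "per_volume")
  agg <- tapply(pv$mssim, pv$epoch, mean)
  expect_identical(select_best(tab)$epoch,
                   as.integer(names(agg)[which.max(agg)]))
  unlink(fit$store$dir, recursive = TRUE)
})

test_that("prediction is deterministic and lands in the display range", {
  pairs <- micro_pairs(1)
  set.seed(5)
  net <- build_generator(micro_gcfg(), c(8, 8, 8))
  p1 <- predict_volume(net, pairs[[1]]$source)
  p2 <- predict_volume(net, pairs[[1]]$source)
  expect_identical(p1, p2)
  expect_identical(dim(p1), dim(pairs[[1]]$source))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_error(predict_volume(net, array(1, c(8, 8, 8))), "degenerate")
})

test_that("learning-rate probes keep stable pairs and reject runaway ones", {
  pairs <- micro_pairs(3)
  res <- grid_search_lr(2e-4, 1e-6, probe_epochs = 3, dataset = pairs,
                        gcfg = micro_gcfg(), dcfg = micro_dcfg(), seed = 6)
  expect_equal(res$lr_g, 2e-4)
  expect_equal(res$lr_d, 1e-6)
  expect_identical(res$trace$status, "ok")
  # a discriminator rate >= 1 makes D win outright: the game is unbalanced
  res2 <- grid_search_lr(2e-4, c(1e-6, 1), probe_epochs = 3, dataset = pairs,
                         gcfg = micro_gcfg(), dcfg = micro_dcfg(), seed = 6)
  expect_equal(res2$lr_d, 1e-6)
  expect_identical(res2$trace$status[res2$trace$lr_d == 1], "unbalanced")
  # every candidate rejected -> explicit failure listing the trace
  expect_error(
    grid_search_lr(2e-4, 1, probe_epochs = 3, dataset = pairs,
                   gcfg = micro_gcfg(), dcfg = micro_dcfg(), seed = 6),
    "rejected")
})

test_that("training logs expose the three loss curves for plotting", {
  pairs <- micro_pairs(2)
  fit <- train_gan(pairs, micro_gcfg(), micro_dcfg(),
                   train_config(epochs = 2, seed = 9))
  expect_true(all(c("d_real", "d_fake", "g_adv", "g_l1", "g_total") %in%
                    names(tidy(fit))))
  gl <- glance(fit)
  expect_identical(gl$iterations, 4L)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    expect_s3_class(plot_training_log(fit), "ggplot")
  }
  unlink(fit$store$dir, recursive = TRUE)
})
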