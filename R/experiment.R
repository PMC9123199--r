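# End-to-end experiment driver: simulate -> split -> train -> evaluate all
# checkpoints -> select best -> predict on the test split -> metric report,
# with every stage's artifacts written to the output directory and a manifest
# written last. Three experiment flavors mirror the study design: GE-only,
# SE-only and mixed.

#' Experiment configuration
#'
#' @param experiment `"GE_only"`, `"SE_only"` or `"mixed"`; the modality
#'   counts must match (`GE_only` requires `n_se = 0`, etc.).
#' @param n_ge,n_se Pairs per modality.
#' @param test_fraction Held-out proportion (default 0.1).
#' @param train A [train_config()].
#' @param gen A [generator_config()].
#' @param disc A [discriminator_config()].
#' @param mssim An [mssim_config()].
#' @param base_spec Template [phantom_spec()] for the simulated cohort.
#' @param out_dir Output directory for all artifacts.
#' @param seed Master seed; stage seeds are derived from it by stage name.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(experiment = c("GE_only", "SE_only", "mixed"),
                              n_ge = 10L, n_se = 0L, test_fraction = 0.1,
                              train = train_config(),
                              gen = generator_config(),
                              disc = discriminator_config(),
                              mssim = mssim_config(),
                              base_spec = phantom_spec(),
                              out_dir = tempfile("experiment_"),
                              seed = 1L) {
  experiment <- match.arg(experiment)
  if (experiment == "GE_only" && (n_se != 0 || n_ge < 2)) {
    stop("GE_only requires n_se = 0 and n_ge >= 2")
  }
  if (experiment == "SE_only" && (n_ge != 0 || n_se < 2)) {
    stop("SE_only requires n_ge = 0 and n_se >= 2")
  }
  if (experiment == "mixed" && (n_ge < 1 || n_se < 1)) {
    stop("mixed requires at least one pair of each modality")
  }
  structure(list(experiment = experiment, n_ge = as.integer(n_ge),
                 n_se = as.integer(n_se), test_fraction = test_fraction,
                 train = train, gen = gen, disc = disc, mssim = mssim,
                 base_spec = base_spec, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

config_fingerprint <- function(cfg) {
  ser <- yaml::as.yaml(rapply(unclass(cfg), unclass, how = "replace"))
  hash_string(ser)
}

#' Run one full experiment
#'
#' Simulates the phantom cohort, trains the GAN on the training split, logs
#' the loss curves (CSV), checkpoints each epoch, evaluates every checkpoint
#' on the test split, selects the best by mean MSSIM (JSON), predicts on the
#' test split and writes the per-pair metric report (CSV, with modality tags
#' so mixed runs can be partitioned), then writes a run manifest listing all
#' artifacts. Stages whose artifacts already exist on disk (training log +
#' checkpoints) are reused rather than recomputed, so a run can be resumed.
#'
#' @param cfg An [experiment_config()].
#' @return A `run_manifest`: list with `config_hash`, `seed`, `selected`,
#'   `files`, `report` (the test-split `metric_report`) and `log`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(config = file.path(cfg$out_dir, "config.yaml"),
                log = file.path(cfg$out_dir, "training_log.csv"),
                selection = file.path(cfg$out_dir, "selection.json"),
                selection_table = file.path(cfg$out_dir,
                                            "checkpoint_metrics.csv"),
                report = file.path(cfg$out_dir, "test_metrics.csv"),
                manifest = file.path(cfg$out_dir, "manifest.json"))
  ckpt_dir <- file.path(cfg$out_dir, "checkpoints")

  resolved <- rapply(unclass(cfg), unclass, how = "replace")
  yaml::write_yaml(resolved, paths$config)

  dataset <- make_dataset(cfg$n_ge, cfg$n_se, cfg$test_fraction,
                          seed = derive_seed(cfg$seed, "dataset"),
                          base_spec = cfg$base_spec)
  tcfg <- cfg$train
  tcfg$seed <- derive_seed(cfg$seed, "train")

  n_ck <- length(list.files(ckpt_dir, pattern = "^ckpt_.*\\.rds$"))
  if (file.exists(paths$log) && n_ck == tcfg$epochs) {
    log <- as_tibble(utils::read.csv(paths$log))
    manifest_ck <- as_tibble(jsonlite::read_json(
      file.path(ckpt_dir, "manifest.json"), simplifyVector = TRUE))
    store <- structure(list(dir = ckpt_dir, checkpoints = manifest_ck),
                       class = "checkpoint_store")
    fit <- structure(list(store = store, log = log, gcfg = cfg$gen,
                          dcfg = cfg$disc, cfg = tcfg,
                          n_train = sum(dataset$split == "train")),
                     class = "epigan_training")
  } else {
    fit <- train_gan(dataset, cfg$gen, cfg$disc, tcfg,
                     checkpoint_dir = ckpt_dir)
    write.csv(fit$log, paths$log, row.names = FALSE)
  }

  test_pairs <- dataset_pairs(dataset, "test")
  sel_table <- evaluate_checkpoints(fit$store, test_pairs, cfg$mssim)
  write.csv(sel_table[, setdiff(names(sel_table), "file")],
            paths$selection_table, row.names = FALSE)
  best <- select_best(sel_table)
  jsonlite::write_json(best, paths$selection, auto_unbox = TRUE, digits = NA)

  netG <- load_checkpoint(best$file)$netG
  disp <- lapply(test_pairs, function(p) predict_display_pair(netG, p))
  report <- metric_report(disp, cfg$mssim)
  write.csv(report$per_pair, paths$report, row.names = FALSE)

  files <- c(unlist(paths[c("config", "log", "selection",
                            "selection_table", "report")]),
             fit$store$checkpoints$file)
  manifest <- list(config_hash = config_fingerprint(cfg), seed = cfg$seed,
                   experiment = cfg$experiment,
                   package_version = as.character(utils::packageVersion("epigan")),
                   selected = best[c("epoch", "iteration", "file")],
                   files = c(files, paths$manifest))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  structure(c(manifest, list(report = report, log = fit$log,
                             selection = sel_table, dataset = dataset,
                             best = best)),
            class = "run_manifest")
}

#' Cross-modality evaluation of trained models
#'
#' Applies each model to each modality subset of a mixed test set and
#' tabulates mean and SD of CAD, L2 norm, MSSIM and Dice per (model,
#' modality) cell, reproducing the familiar-vs-unfamiliar comparison. A model
#' whose input grid is incompatible with the data is recorded as a missing
#' cell rather than aborting.
#'
#' @param models Named list of generators (any form [predict_volume()]
#'   accepts).
#' @param test_pairs List of `image_pair`s spanning the modalities.
#' @param cfg An [mssim_config()].
#' @return Tibble with one row per (model, modality) cell.
#' @export
cross_modality_eval <- function(models, test_pairs, cfg = mssim_config()) {
  stopifnot(length(models) >= 1, length(test_pairs) >= 1)
  modalities <- vapply(test_pairs, function(p) p$modality, character(1))
  purrr::map_dfr(names(models), function(mn) {
    netG <- tryCatch(resolve_generator(models[[mn]]),
                     error = function(e) NULL)
    purrr::map_dfr(unique(modalities), function(md) {
      subset <- test_pairs[modalities == md]
      cell <- tryCatch({
        rep <- metric_report(lapply(subset,
                                    function(p) predict_display_pair(netG, p)),
                             cfg)
        s <- rep$summary
        get_m <- function(metric, col) {
          s[[col]][s$metric == metric]
        }
        tibble(model = mn, modality = md, n = length(subset),
               cad_mean = get_m("cad", "mean"), cad_sd = get_m("cad", "sd"),
               l2_mean = get_m("l2", "mean"), l2_sd = get_m("l2", "sd"),
               mssim_mean = get_m("mssim", "mean"),
               mssim_sd = get_m("mssim", "sd"),
               dice_mean = get_m("dice", "mean"),
               dice_sd = get_m("dice", "sd"),
               error = NA_character_)
      }, error = function(e) {
        tibble(model = mn, modality = md, n = length(subset),
               cad_mean = NA_real_, cad_sd = NA_real_, l2_mean = NA_real_,
               l2_sd = NA_real_, mssim_mean = NA_real_, mssim_sd = NA_real_,
               dice_mean = NA_real_, dice_sd = NA_real_,
               error = conditionMessage(e))
      })
      if (is.null(netG)) cell$error <- "model could not be loaded"
      cell
    })
  })
}

#' Plot the three training loss curves
#'
#' Line plot of the discriminator real/fake terms and the generator composite
#' over iterations (requires ggplot2).
#'
#' @param log Training log tibble (or an `epigan_training`).
#' @return A ggplot object.
#' @export
plot_training_log <- function(log) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_training_log requires ggplot2")
  }
  if (inherits(log, "epigan_training")) log <- log$log
  long <- tidyr::pivot_longer(
    log[, c("iteration", "d_real", "d_fake", "g_total")],
    -"iteration", names_to = "curve", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$loss,
                                     color = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "loss", color = NULL)
}
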