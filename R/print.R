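#' @export
print.phantom_dataset <- function(x, ...) {
  cat("Synthetic EPI phantom dataset:", length(x$pairs), "pairs",
      sprintf("(grid %s)\n",
              paste(x$pairs[[1]]$spec$grid_shape, collapse = "x")))
  print(x$composition)
  invisible(x)
}

#' @export
print.epigan_training <- function(x, ...) {
  cat(sprintf("3D pix2pix training run: %d epochs x %d pairs = %d iterations\n",
              x$cfg$epochs, x$n_train, nrow(x$log)))
  cat(sprintf("final-epoch mean L1 %.4f (first epoch %.4f); checkpoints in %s\n",
              mean(x$log$g_l1[x$log$epoch == x$cfg$epochs]),
              mean(x$log$g_l1[x$log$epoch == 1]), x$store$dir))
  invisible(x)
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("%s-EPI phantom pair, grid %s, %d brain voxels\n", x$modality,
              paste(dim(x$source), collapse = "x"), sum(x$brain_mask)))
  invisible(x)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Experiment %s (seed %d, config %s)\n", x$experiment, x$seed,
              x$config_hash))
  cat(sprintf("selected checkpoint: epoch %d (iteration %d)\n",
              x$selected$epoch, x$selected$iteration))
  print(x$report$summary)
  invisible(x)
}
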