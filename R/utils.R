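#' Derive a child seed from a master seed and a stage name
#'
#' Pipeline stages (phantom generation, splitting, training, ...) each draw
#' their own seed from the run's master seed keyed by the stage name, so that
#' inserting a stage never shifts the randomness of the stages downstream.
#'
#' @param master Integer master seed.
#' @param stage Character scalar naming the stage.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "split")
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483629 # largest prime below 2^31
  h <- abs(as.double(master)) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed_local <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# FNV-1a hash of a character scalar, returned as hex. Used to stamp run
# manifests with a stable configuration fingerprint.
hash_string <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  h <- 2166136261
  for (code in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Ensure a 3D array has an explicit trailing channel axis.
as_channels <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("expected a 3D volume or a 4D (x, y, z, channel) array")
  }
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

drop_channel <- function(x) {
  d <- dim(x)
  if (length(d) == 4L && d[4] == 1L) dim(x) <- d[1:3]
  x
}
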