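#' Configuration of the multi-layer fusion feature extractor
#'
#' The backbone is a shallow trunk of `n_blocks` identical convolutional
#' blocks: a `conv_kernel x conv_kernel` convolution with
#' `filters_per_block` filters (stride 1, zero padding for "same" output),
#' batch normalization, ReLU, and a `pool_kernel x pool_kernel` max pool with
#' stride equal to its kernel (floor division of the grid). After every
#' block the output map is additionally tapped with a *global* max pool and
#' flattened to a `filters_per_block`-dimensional feature vector
#' (`f1 ... f4`); the fused embedding is the componentwise mean of the taps
#' selected by `fusion_subset`. For 96-pixel inputs the trunk map sizes are
#' 96 -> 32 -> 10 -> 3 -> 1, so `f4` is naturally a global feature.
#'
#' @param input_size Input image side in pixels (default 96).
#' @param input_channels Number of input channels (default 3, RGB).
#' @param n_blocks Number of convolutional blocks (default 4).
#' @param filters_per_block Convolution filters per block (default 64).
#' @param conv_kernel Convolution kernel side (default 3; only 3 supported).
#' @param pool_kernel Trunk max-pool kernel = stride (default 3).
#' @param fusion_subset Nonempty subset of `1:n_blocks` whose taps are
#'   averaged into the embedding (default all blocks). `fusion_subset = 4`
#'   is the plain global-feature baseline.
#' @return An `extractor_config` object.
#' @export
extractor_config <- function(input_size = 96L, input_channels = 3L,
                             n_blocks = 4L, filters_per_block = 64L,
                             conv_kernel = 3L, pool_kernel = 3L,
                             fusion_subset = seq_len(n_blocks)) {
  if (conv_kernel != 3L)
    stopf("only 3x3 convolutions are implemented (conv_kernel = 3)")
  fusion_subset <- sort(unique(as.integer(fusion_subset)))
  if (!length(fusion_subset) || any(fusion_subset < 1L | fusion_subset > n_blocks))
    stopf("fusion_subset must be a nonempty subset of 1..%d", n_blocks)
  sizes <- trunk_sizes(input_size, n_blocks, pool_kernel)
  if (min(sizes) < 1L)
    stopf("input_size %d collapses below 1 pixel along the trunk (sizes: %s)",
          input_size, paste(sizes, collapse = " -> "))
  structure(
    list(input_size = as.integer(input_size),
         input_channels = as.integer(input_channels),
         n_blocks = as.integer(n_blocks),
         filters_per_block = as.integer(filters_per_block),
         conv_kernel = as.integer(conv_kernel),
         pool_kernel = as.integer(pool_kernel),
         fusion_subset = fusion_subset),
    class = "extractor_config"
  )
}

#' Spatial map sizes along the trunk
#'
#' Repeated floor division by the pool stride: 96 -> 32 -> 10 -> 3 -> 1 at
#' the defaults.
#'
#' @param input_size Input side in pixels.
#' @param n_blocks Number of blocks.
#' @param pool_kernel Pool kernel = stride.
#' @return Integer vector of length `n_blocks` with the post-pool map sizes.
#' @export
trunk_sizes <- function(input_size = 96L, n_blocks = 4L, pool_kernel = 3L) {
  out <- integer(n_blocks)
  s <- as.integer(input_size)
  for (i in seq_len(n_blocks)) {
    s <- s %/% as.integer(pool_kernel)
    out[i] <- as.integer(s)
  }
  out
}

#' Instantiate a fresh extractor model
#'
#' Weights use fan-in-scaled Gaussian initialization (He): conv weights
#' `N(0, sqrt(2 / fan_in))`, biases zero, batch-norm scale 1 / shift 0,
#' running mean 0 / running variance 1. The model starts in training mode;
#' see [set_mode()].
#'
#' @param config An [extractor_config()].
#' @param seed Integer seed for the weight initialization.
#' @return An `mlf_model` object: parameters, batch-norm running statistics,
#'   configuration and mode flag.
#' @export
mlf_model <- function(config = extractor_config(), seed = 1L) {
  stopifnot(inherits(config, "extractor_config"))
  F <- config$filters_per_block
  kk <- config$conv_kernel^2
  params <- vector("list", config$n_blocks)
  running <- vector("list", config$n_blocks)
  with_seed(derive_seed(seed, 0L), {
    for (i in seq_len(config$n_blocks)) {
      cin <- if (i == 1L) config$input_channels else F
      fan_in <- kk * cin
      params[[i]] <- list(
        W = matrix(rnorm(kk * cin * F, sd = sqrt(2 / fan_in)), kk * cin, F),
        b = numeric(F),
        gamma = rep(1, F),
        beta = numeric(F)
      )
      running[[i]] <- list(mean = numeric(F), var = rep(1, F))
    }
  })
  structure(
    list(config = config, params = params, running = running,
         mode = "train", bn_eps = 1e-5),
    class = "mlf_model"
  )
}

#' Switch a model between training and frozen/evaluation mode
#'
#' In `"eval"` (frozen) mode batch normalization uses the stored running
#' statistics, making the forward pass a deterministic function of its
#' input; in `"train"` mode it uses batch statistics.
#'
#' @param model An `mlf_model`.
#' @param mode `"train"` or `"eval"`.
#' @return The model with the mode flag set.
#' @export
set_mode <- function(model, mode = c("train", "eval")) {
  model$mode <- match.arg(mode)
  model
}

#' @export
print.mlf_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<mlf_model> %d blocks x %d filters, input %dx%dx%d, mode=%s\n",
              cfg$n_blocks, cfg$filters_per_block, cfg$input_size,
              cfg$input_size, cfg$input_channels, x$mode))
  cat(sprintf("  fusion subset: {%s}; learnable parameters: %d\n",
              paste(cfg$fusion_subset, collapse = ","),
              count_parameters(x, "unique")))
  invisible(x)
}

## ---- forward / backward ----------------------------------------------------

#' @noRd
bn_stats_update <- function(run, mu, v, momentum) {
  list(mean = (1 - momentum) * run$mean + momentum * mu,
       var = (1 - momentum) * run$var + momentum * v)
}

#' Forward pass through the trunk, collecting the per-block taps
#'
#' @param model An `mlf_model`.
#' @param x `(H, W, B, C)` batch array in `[0, 1]`.
#' @param keep_cache Keep intermediate activations for a backward pass.
#' @param update_running In training mode, also return updated running
#'   statistics (momentum `momentum`).
#' @param momentum Batch-norm running-statistic momentum.
#' @return List with `taps` (list of `B x filters` matrices, one per block),
#'   `cache` (or `NULL`), and `running` (updated statistics, training only).
#' @noRd
mlf_forward <- function(model, x, keep_cache = FALSE,
                        update_running = FALSE, momentum = 0.1) {
  cfg <- model$config
  d <- dim(x)
  if (length(d) != 4L || d[1] != cfg$input_size || d[2] != cfg$input_size ||
      d[4] != cfg$input_channels)
    stopf("input batch must be (%d, %d, B, %d), got (%s)",
          cfg$input_size, cfg$input_size, cfg$input_channels,
          paste(d, collapse = ", "))
  training <- model$mode == "train"
  nb <- cfg$n_blocks
  Fn <- cfg$filters_per_block
  taps <- vector("list", nb)
  cache <- if (keep_cache) vector("list", nb) else NULL
  running <- model$running
  B <- d[3]
  for (i in seq_len(nb)) {
    p <- model$params[[i]]
    din <- dim(x)
    zdim <- c(din[1], din[2], B, Fn)
    P <- im2col3_cpp(x)
    A <- P %*% p$W
    # The conv bias precedes batch normalization, so it shifts only the mean:
    # in training mode it cancels exactly (zero gradient); running statistics
    # record the mean of the biased conv output so frozen mode matches.
    if (training) {
      st <- colstats_cpp(A)
      if (update_running)
        running[[i]] <- bn_stats_update(
          running[[i]], st$mean + p$b, st$var, momentum)
      invstd <- 1 / sqrt(st$var + model$bn_eps)
      bn_xhat_inplace_cpp(A, st$mean, invstd)  # A is now xhat
      Z <- relu_affine_cpp(A, p$gamma, p$beta, zdim)
    } else {
      invstd <- 1 / sqrt(model$running[[i]]$var + model$bn_eps)
      Z <- bn_relu_eval_cpp(A, model$running[[i]]$mean - p$b, invstd,
                            p$gamma, p$beta, zdim)
    }
    pl <- maxpool_fwd_cpp(Z, cfg$pool_kernel)
    gp <- gpool_fwd_cpp(pl$out)
    taps[[i]] <- gp$out
    if (keep_cache) {
      cache[[i]] <- list(P = P, xhat = A, invstd = invstd,
                         din = din, zdim = zdim,
                         pool_idx = pl$idx, pool_dim = dim(pl$out),
                         gpool_idx = gp$idx)
    }
    x <- pl$out
  }
  list(taps = taps, cache = cache,
       running = if (training && update_running) running else model$running)
}

#' Backward pass: gradients of a scalar loss w.r.t. all learnable parameters
#'
#' @param model An `mlf_model` (training mode assumed; the cache must come
#'   from a training-mode forward pass).
#' @param cache Cache from `mlf_forward(..., keep_cache = TRUE)`.
#' @param dtaps List over blocks of `B x filters` gradient matrices w.r.t.
#'   the taps (`NULL` entries for blocks outside the fusion subset).
#' @return List over blocks of `list(W, b, gamma, beta)` gradients.
#' @noRd
mlf_backward <- function(model, cache, dtaps) {
  cfg <- model$config
  nb <- cfg$n_blocks
  grads <- vector("list", nb)
  dx_above <- NULL
  for (i in rev(seq_len(nb))) {
    cc <- cache[[i]]
    p <- model$params[[i]]
    pd <- cc$pool_dim
    # gradient arriving at the block output (pooled map)
    g_out <- if (!is.null(dtaps[[i]]))
      gpool_bwd_cpp(dtaps[[i]], cc$gpool_idx, pd[1], pd[2], pd[3], pd[4])
    else
      array(0, pd)
    if (!is.null(dx_above)) g_out <- g_out + dx_above
    zd <- cc$zdim
    g <- maxpool_bwd_cpp(g_out, cc$pool_idx, zd[1], zd[2], zd[3], zd[4])
    dim(g) <- c(zd[1] * zd[2] * zd[3], zd[4])
    # fused ReLU mask + batch-norm backward; g becomes the conv-output gradient
    bb <- bn_relu_bwd_inplace_cpp(g, cc$xhat, p$gamma, p$beta, cc$invstd)
    dW <- crossprod(cc$P, g)
    # batch norm subtracts the batch mean, so the conv bias has exactly zero
    # gradient in training mode
    db <- numeric(cfg$filters_per_block)
    if (i > 1L) {
      dP <- g %*% t(p$W)
      din <- cc$din
      dx_above <- col2im3_cpp(dP, din[1], din[2], din[3], din[4])
    }
    grads[[i]] <- list(W = dW, b = db, gamma = bb$dgamma, beta = bb$dbeta)
  }
  grads
}

## ---- public feature API ----------------------------------------------------

#' Extract the per-block pooled feature stack for one image
#'
#' Runs the image through the four-block trunk and returns the four global
#' max-pooled, flattened 64-dimensional feature vectors `f1 ... f4`. All
#' components are nonnegative because the taps are taken after ReLU.
#'
#' @param model An `mlf_model`; use frozen mode ([set_mode()]) for
#'   deterministic features.
#' @param pixels A `size x size x 3` pixel array in `[0, 1]`.
#' @return A `feature_stack`: list of numeric vectors `f1 ... f4`.
#' @export
forward_features <- function(model, pixels) {
  d <- dim(pixels)
  if (length(d) != 3L)
    stopf("expected a single (H, W, C) image, got dims (%s)",
          paste(d, collapse = ", "))
  x <- array(pixels, c(d[1], d[2], 1L, d[3]))
  fw <- mlf_forward(model, x)
  structure(
    setNames(lapply(fw$taps, function(t) as.numeric(t[1, ])),
             paste0("f", seq_along(fw$taps))),
    class = "feature_stack"
  )
}

#' Fuse a feature stack into a single embedding
#'
#' The fused embedding is the arithmetic componentwise mean of the selected
#' per-block feature vectors; with `subset = 4` it is exactly `f4` (the
#' plain global-feature baseline).
#'
#' @param stack A `feature_stack` from [forward_features()], or a plain list
#'   of equal-length numeric vectors.
#' @param subset Nonempty integer subset of the block indices.
#' @return Numeric embedding vector (componentwise nonnegative when the
#'   stack comes from the extractor).
#' @export
fuse <- function(stack, subset = seq_along(stack)) {
  subset <- as.integer(subset)
  if (!length(subset)) stopf("fusion subset must be nonempty")
  if (any(subset < 1L | subset > length(stack)))
    stopf("fusion subset out of range 1..%d", length(stack))
  Reduce(`+`, stack[subset]) / length(subset)
}

#' Embed a batch of images into fused embeddings
#'
#' @param model An `mlf_model`.
#' @param x Either an `image_collection`, a list of records, or a
#'   `(H, W, B, C)` batch array.
#' @param subset Fusion subset; defaults to the model's configured subset.
#' @param chunk Images per forward pass (memory control).
#' @return `B x filters` matrix of embeddings, one row per image.
#' @export
embed_images <- function(model, x, subset = model$config$fusion_subset,
                         chunk = 64L) {
  if (inherits(x, "image_collection")) x <- x$records
  if (is.list(x)) x <- stack_pixels(x)
  B <- dim(x)[3]
  E <- matrix(0, B, model$config$filters_per_block)
  for (start in seq(1L, B, by = chunk)) {
    ix <- start:min(start + chunk - 1L, B)
    fw <- mlf_forward(model, x[, , ix, , drop = FALSE])
    E[ix, ] <- Reduce(`+`, fw$taps[subset]) / length(subset)
  }
  E
}

## ---- parameter accounting --------------------------------------------------

#' Count learnable parameters of the extractor
#'
#' A block's learnable parameters are its convolution weights and biases
#' plus the batch-norm scale and shift; batch-norm running statistics are
#' excluded. `mode = "branch"` reports, for each tap `f_i`, the cumulative
#' count of blocks `1..i` (the cost of computing that tap from the input)
#' together with the sum over branches; the branch sum double-counts the
#' shared trunk and is reported alongside `mode = "unique"`, the
#' deduplicated trunk count (equal to the deepest branch).
#'
#' @param x An `extractor_config` or an `mlf_model` (counted by enumerating
#'   its actual parameter arrays).
#' @param mode `"branch"` or `"unique"`.
#' @return For `"branch"`, a data frame with columns `branch`, `parameters`
#'   and `thousands` (including a `total` row); for `"unique"`, a single
#'   count.
#' @export
count_parameters <- function(x, mode = c("branch", "unique")) {
  UseMethod("count_parameters")
}

#' @export
count_parameters.extractor_config <- function(x, mode = c("branch", "unique")) {
  mode <- match.arg(mode)
  F <- x$filters_per_block
  kk <- x$conv_kernel^2
  per_block <- vapply(seq_len(x$n_blocks), function(i) {
    cin <- if (i == 1L) x$input_channels else F
    (kk * cin * F + F) + 2L * F
  }, numeric(1))
  branch <- cumsum(per_block)
  if (mode == "unique") return(unname(branch[x$n_blocks]))
  data.frame(
    branch = c(paste0("f", seq_len(x$n_blocks)), "total"),
    parameters = c(branch, sum(branch)),
    thousands = round(c(branch, sum(branch)) / 1000, 2)
  )
}

#' @export
count_parameters.mlf_model <- function(x, mode = c("branch", "unique")) {
  mode <- match.arg(mode)
  per_block <- vapply(x$params, function(p)
    length(p$W) + length(p$b) + length(p$gamma) + length(p$beta), numeric(1))
  branch <- cumsum(per_block)
  if (mode == "unique") return(unname(branch[length(branch)]))
  data.frame(
    branch = c(paste0("f", seq_along(branch)), "total"),
    parameters = c(branch, sum(branch)),
    thousands = round(c(branch, sum(branch)) / 1000, 2)
  )
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized file holding the parameters, running
#' statistics and the embedded configuration.
#'
#' @param model An `mlf_model`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("checkpoint not found: %s", path)
  m <- readRDS(path)
  if (!inherits(m, "mlf_model")) stopf("%s is not an mlf_model checkpoint", path)
  m
}
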