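#' Meta-training configuration
#'
#' Defaults follow the reference schedule: 100 epochs of 150 episodes,
#' Adam with initial learning rate `1e-3`, halved every 20 epochs
#' (`lr_schedule = "periodic"`: `lr * 0.5^floor(epoch / 20)`; the literal
#' single-halving reading is available as `"single"`).
#'
#' @param epochs Number of training epochs.
#' @param episodes_per_epoch Episodes (tasks) per epoch.
#' @param initial_lr Initial Adam learning rate.
#' @param lr_halving_period Epochs between halvings.
#' @param lr_schedule `"periodic"` (default) or `"single"`.
#' @param seed Seed controlling initialization-independent training
#'   randomness (episode draws); identical configs and seeds reproduce the
#'   run bit for bit.
#' @param episode An [episode_config()].
#' @param metric A [divergence_config()].
#' @param fusion_subset Fusion subset used for the embeddings (default: the
#'   model's configured subset).
#' @param augment_rotations Apply rotation class augmentation to the source
#'   collection before sampling (default `TRUE`).
#' @param bn_momentum Batch-norm running-statistic momentum.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decay rates and
#'   stabilizer (standard defaults).
#' @param verbose Emit one structured log line per epoch.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 100L, episodes_per_epoch = 150L,
                         initial_lr = 1e-3, lr_halving_period = 20L,
                         lr_schedule = c("periodic", "single"),
                         seed = 1L,
                         episode = episode_config(),
                         metric = divergence_config(),
                         fusion_subset = NULL,
                         augment_rotations = TRUE,
                         bn_momentum = 0.1,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8,
                         verbose = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  structure(
    list(epochs = as.integer(epochs),
         episodes_per_epoch = as.integer(episodes_per_epoch),
         initial_lr = initial_lr,
         lr_halving_period = as.integer(lr_halving_period),
         lr_schedule = lr_schedule,
         seed = as.integer(seed),
         episode = episode, metric = metric,
         fusion_subset = fusion_subset,
         augment_rotations = isTRUE(augment_rotations),
         bn_momentum = bn_momentum,
         adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
         adam_eps = adam_eps,
         verbose = isTRUE(verbose)),
    class = "train_config"
  )
}

#' Learning rate at a given (0-based) epoch
#'
#' @param config A [train_config()].
#' @param epoch 0-based epoch index.
#' @return The scheduled learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  p <- config$lr_halving_period
  if (config$lr_schedule == "periodic")
    config$initial_lr * 0.5^(epoch %/% p)
  else
    config$initial_lr * ifelse(epoch >= p, 0.5, 1)
}

#' @noRd
adam_init <- function(params) {
  lapply(params, function(p) list(
    m = lapply(p, function(a) a * 0),
    v = lapply(p, function(a) a * 0)
  ))
}

#' @noRd
adam_step <- function(params, grads, state, t, lr, b1, b2, eps) {
  for (i in seq_along(params)) {
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      state[[i]]$m[[nm]] <- b1 * state[[i]]$m[[nm]] + (1 - b1) * g
      state[[i]]$v[[nm]] <- b2 * state[[i]]$v[[nm]] + (1 - b2) * g * g
      mhat <- state[[i]]$m[[nm]] / (1 - b1^t)
      vhat <- state[[i]]$v[[nm]] / (1 - b2^t)
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

#' One gradient step on a single episode (internal; also used by tests)
#'
#' @return list(model, loss, accuracy) with updated parameters and running
#'   statistics; `opt` carries Adam state across calls.
#' @noRd
train_step <- function(model, collection, episode, config, opt = NULL, lr = NULL) {
  subset <- config$fusion_subset %||% model$config$fusion_subset
  N <- episode$config$n_way
  K <- episode$config$k_shot
  qn <- episode$config$n_query
  s_idx <- as.vector(episode$support)   # column-major: class index cycles fastest
  q_idx <- as.vector(episode$query)
  s_labels <- rep(seq_len(N), K)
  q_labels <- rep(seq_len(N), qn)
  x <- stack_pixels(collection$records, c(s_idx, q_idx))
  fw <- mlf_forward(model, x, keep_cache = TRUE, update_running = TRUE,
                    momentum = config$bn_momentum)
  E <- Reduce(`+`, fw$taps[subset]) / length(subset)
  S <- N * K
  hg <- episode_head_grad(E[seq_len(S), , drop = FALSE], s_labels,
                          E[S + seq_len(N * qn), , drop = FALSE], q_labels,
                          config$metric)
  if (!is.finite(hg$loss))
    stopf("non-finite loss; offending episode:\n%s",
          episode_to_json(episode, collection))
  dFFO <- rbind(hg$dEs, hg$dEq)
  dtaps <- vector("list", model$config$n_blocks)
  for (i in subset) dtaps[[i]] <- dFFO / length(subset)
  grads <- mlf_backward(model, fw$cache, dtaps)
  model$running <- fw$running
  if (is.null(opt)) opt <- list(state = adam_init(model$params), t = 0L)
  opt$t <- opt$t + 1L
  upd <- adam_step(model$params, grads, opt$state, opt$t,
                   lr %||% config$initial_lr,
                   config$adam_beta1, config$adam_beta2, config$adam_eps)
  model$params <- upd$params
  opt$state <- upd$state
  list(model = model, opt = opt, loss = hg$loss, accuracy = hg$accuracy)
}

#' Episodic meta-training
#'
#' For every episode: sample an N-way K-shot task from the (rotation
#' augmented) source collection, embed support and query images, form
#' prototypes, compute the softmax posteriors and the mean negative
#' log-probability of the true classes, and take one Adam step on all
#' backbone parameters. Fully reproducible given the config seed.
#'
#' @param model An `mlf_model` (freshly initialized or a checkpoint).
#' @param source Source-role `image_collection`.
#' @param config A [train_config()].
#' @return List with `model` (trained, still in training mode) and
#'   `history`, a data frame with one row per epoch: `epoch`, `lr`,
#'   `mean_loss`, `mean_accuracy`. Attribute `episode_log` holds the
#'   per-episode losses and accuracies.
#' @export
train <- function(model, source, config = train_config()) {
  stopifnot(inherits(model, "mlf_model"), inherits(source, "image_collection"))
  if (config$augment_rotations) source <- augment_with_rotations(source)
  index <- class_index(source)
  model <- set_mode(model, "train")
  opt <- list(state = adam_init(model$params), t = 0L)
  n_ep <- config$episodes_per_epoch
  hist_epoch <- data.frame(epoch = integer(), lr = numeric(),
                           mean_loss = numeric(), mean_accuracy = numeric())
  ep_loss <- numeric(config$epochs * n_ep)
  ep_acc <- numeric(config$epochs * n_ep)
  with_seed(derive_seed(config$seed, 1L), {
    for (e in seq_len(config$epochs) - 1L) {
      lr <- lr_at_epoch(config, e)
      for (j in seq_len(n_ep)) {
        epi <- sample_episode(source, config$episode, index)
        st <- train_step(model, source, epi, config, opt, lr)
        model <- st$model
        opt <- st$opt
        k <- e * n_ep + j
        ep_loss[k] <- st$loss
        ep_acc[k] <- st$accuracy
      }
      rows <- e * n_ep + seq_len(n_ep)
      hist_epoch <- rbind(hist_epoch, data.frame(
        epoch = e, lr = lr,
        mean_loss = mean(ep_loss[rows]),
        mean_accuracy = mean(ep_acc[rows])
      ))
      if (config$verbose)
        message(sprintf("epoch=%d lr=%.2e loss=%.4f acc=%.4f",
                        e, lr, mean(ep_loss[rows]), mean(ep_acc[rows])))
    }
  })
  attr(hist_epoch, "episode_log") <- data.frame(
    episode = seq_along(ep_loss), loss = ep_loss, accuracy = ep_acc)
  list(model = model, history = hist_epoch)
}

#' Frozen-model evaluation over test episodes
#'
#' The model is frozen (evaluation mode: batch norm uses running
#' statistics; no parameter updates occur) and every image of the target
#' collection is embedded once; episodes are then sampled and scored in
#' embedding space. Accuracy is the fraction of correctly predicted query
#' images, averaged over episodes, with a normal-approximation 95%
#' confidence interval from the per-episode dispersion.
#'
#' @param model An `mlf_model`.
#' @param target Target-role `image_collection` (class-disjoint from the
#'   training source).
#' @param n_episodes Number of test episodes (default 2000).
#' @param episode An [episode_config()].
#' @param metric A [divergence_config()].
#' @param fusion_subset Fusion subset (default: model's configured subset).
#' @param augment_rotations Apply rotation class augmentation to the target
#'   before sampling (default `TRUE`, mirroring the training protocol).
#' @param seed Seed for the episode draws.
#' @return An `eval_report`: `n_episodes`, `mean_accuracy`, `std_error`,
#'   `ci_halfwidth` (1.96 SE) and the per-episode accuracies.
#' @export
evaluate <- function(model, target, n_episodes = 2000L,
                     episode = episode_config(),
                     metric = divergence_config(),
                     fusion_subset = NULL,
                     augment_rotations = TRUE,
                     seed = 1L) {
  stopifnot(inherits(model, "mlf_model"), inherits(target, "image_collection"))
  subset <- fusion_subset %||% model$config$fusion_subset
  model <- set_mode(model, "eval")
  if (augment_rotations) target <- augment_with_rotations(target)
  E <- embed_images(model, target, subset = subset)
  index <- class_index(target)
  N <- episode$n_way; K <- episode$k_shot; qn <- episode$n_query
  s_labels <- rep(seq_len(N), K)
  q_labels <- rep(seq_len(N), qn)
  acc <- numeric(n_episodes)
  with_seed(derive_seed(seed, 2L), {
    for (t in seq_len(n_episodes)) {
      epi <- sample_episode(target, episode, index)
      Es <- E[as.vector(epi$support), , drop = FALSE]
      Eq <- E[as.vector(epi$query), , drop = FALSE]
      proto <- compute_prototypes(Es, s_labels)
      P <- class_posteriors(Eq, proto, metric)
      acc[t] <- mean(predict_classes(P) == q_labels)
    }
  })
  se <- sd(acc) / sqrt(n_episodes)
  structure(
    list(n_episodes = as.integer(n_episodes),
         mean_accuracy = mean(acc),
         std_error = se,
         ci_halfwidth = 1.96 * se,
         per_episode = acc,
         episode = episode, metric = metric, fusion_subset = subset),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d-way %d-shot, %d episodes: accuracy %.4f +/- %.4f (95%% CI)\n",
    x$episode$n_way, x$episode$k_shot, x$n_episodes,
    x$mean_accuracy, x$ci_halfwidth))
  invisible(x)
}

#' Fusion-subset ablation sweep
#'
#' Trains and evaluates one model per (fusion subset, divergence kind,
#' K-shot) cell, all cells sharing the same initialization and episode
#' seeds, and returns a tidy results table. The `subset = 4` cell is the
#' plain global-feature baseline by construction.
#'
#' @param source,target Source/target `image_collection`s (class-disjoint).
#' @param subsets List of fusion subsets (integer vectors).
#' @param metrics Character vector of divergence kinds.
#' @param k_shots Integer vector of K values.
#' @param base_config A [train_config()] providing the (possibly reduced)
#'   budget; its episode's `k_shot` is overridden per cell.
#' @param n_eval_episodes Test episodes per cell.
#' @param model_seed Seed for the shared model initialization.
#' @return Data frame: `subset`, `metric`, `k_shot`, `mean_accuracy`,
#'   `ci_halfwidth`, `train_loss` (final epoch).
#' @export
ablation_sweep <- function(source, target,
                           subsets = list(4L, c(1L, 4L), c(1L, 2L, 4L), 1:4),
                           metrics = c("euclidean", "relative_entropy"),
                           k_shots = c(1L, 5L),
                           base_config = train_config(),
                           n_eval_episodes = 200L,
                           model_seed = 1L) {
  assert_disjoint_classes(source, target)
  rows <- list()
  for (sub in subsets) for (met in metrics) for (K in k_shots) {
    cfg <- base_config
    cfg$episode <- episode_config(base_config$episode$n_way, K,
                                  base_config$episode$n_query)
    cfg$metric <- divergence_config(met,
                                    epsilon = base_config$metric$epsilon,
                                    log_base = base_config$metric$log_base,
                                    direction = base_config$metric$direction)
    cfg$fusion_subset <- sub
    model <- mlf_model(extractor_config(fusion_subset = sub), seed = model_seed)
    fit <- train(model, source, cfg)
    rep <- evaluate(fit$model, target, n_episodes = n_eval_episodes,
                    episode = cfg$episode, metric = cfg$metric,
                    fusion_subset = sub, seed = cfg$seed)
    rows[[length(rows) + 1L]] <- data.frame(
      subset = paste(sub, collapse = ","),
      metric = met, k_shot = K,
      mean_accuracy = rep$mean_accuracy,
      ci_halfwidth = rep$ci_halfwidth,
      train_loss = fit$history$mean_loss[nrow(fit$history)]
    )
  }
  do.call(rbind, rows)
}
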