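pf <- asNamespace("protofuse")

test_that("the learning-rate schedule halves every period (0-based epochs)", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 0), 1e-3)
  expect_equal(lr_at_epoch(cfg, 19), 1e-3)
  expect_equal(lr_at_epoch(cfg, 20), 5e-4)
  expect_equal(lr_at_epoch(cfg, 39), 5e-4)
  expect_equal(lr_at_epoch(cfg, 40), 2.5e-4)
  single <- train_config(lr_schedule = "single")
  expect_equal(lr_at_epoch(single, 40), 5e-4)
  expect_equal(lr_at_epoch(single, 99), 5e-4)
})

test_that("training history bookkeeping matches the configured budget", {
  m <- mlf_model(extractor_config(), seed = 1)
  cfg <- train_config(epochs = 1, episodes_per_epoch = 2,
                      episode = episode_config(5, 1, 1), seed = 4)
  fit <- train(m, tiny_source(), cfg)
  expect_equal(nrow(fit$history), 1L)
  expect_equal(nrow(attr(fit$history, "episode_log")), 2L)
  expect_true(all(is.finite(fit$history$mean_loss)))
  expect_equal(fit$history$lr, 1e-3)
  expect_s3_class(fit$model, "mlf_model")
})

test_that("a small-step gradient update decreases the episode loss", {
  src <- augment_with_rotations(tiny_source())
  for (kind in c("euclidean", "relative_entropy")) {
    m <- mlf_model(extractor_config(), seed = 8)
    cfg <- train_config(episode = episode_config(5, 1, 2),
                        metric = divergence_config(kind))
    set.seed(21)
    ep <- sample_episode(src, cfg$episode)
    s1 <- pf$train_step(m, src, ep, cfg, NULL, 1e-4)
    s2 <- pf$train_step(s1$model, src, ep, cfg, NULL, 1e-4)
    expect_lt(s2$loss, s1$loss)
  }
})

test_that("identical configs and seeds reproduce checkpoints and reports exactly", {
  cfg <- train_config(epochs = 1, episodes_per_epoch = 3,
                      episode = episode_config(5, 1, 2), seed = 13)
  fit1 <- train(mlf_model(extractor_config(), seed = 2), tiny_source(), cfg)
  fit2 <- train(mlf_model(extractor_config(), seed = 2), tiny_source(), cfg)
  expect_identical(model_hash(fit1$model), model_hash(fit2$model))
  expect_identical(fit1$history, fit2$history)
  other <- train(mlf_model(extractor_config(), seed = 3), tiny_source(), cfg)
  expect_false(identical(model_hash(fit1$model), model_hash(other$model)))
  tgt <- generate_collection(fixture_spec(2, 6, class_separation = 1, seed = 30), "target")
  r1 <- evaluate(fit1$model, tgt, n_episodes = 40,
                 episode = episode_config(5, 1, 2), seed = 6)
  r2 <- evaluate(fit2$model, tgt, n_episodes = 40,
                 episode = episode_config(5, 1, 2), seed = 6)
  expect_identical(r1$per_episode, r2$per_episode)
  expect_identical(r1$mean_accuracy, r2$mean_accuracy)
})

test_that("frozen evaluation mutates neither parameters nor running statistics", {
  m <- mlf_model(extractor_config(), seed = 5)
  tgt <- generate_collection(fixture_spec(2, 6, class_separation = 1, seed = 30), "target")
  h_before <- model_hash(m)
  invisible(evaluate(m, tgt, n_episodes = 20, episode = episode_config(5, 1, 2),
                     seed = 1))
  expect_identical(model_hash(m), h_before)
})

test_that("checkpoints round-trip through disk", {
  m <- mlf_model(extractor_config(), seed = 7)
  path <- file.path(tempdir(), "ck.rds")
  save_checkpoint(m, path)
  expect_identical(model_hash(load_checkpoint(path)), model_hash(m))
  expect_error(load_checkpoint(file.path(tempdir(), "absent.rds")), "not found")
})

test_that("the ablation sweep tabulates every cell and nests the baseline", {
  src <- tiny_source()
  tgt <- generate_collection(fixture_spec(2, 6, class_separation = 1, seed = 30), "target")
  base <- train_config(epochs = 1, episodes_per_epoch = 2,
                       episode = episode_config(5, 1, 2), seed = 9)
  tab <- ablation_sweep(src, tgt, subsets = list(4L, c(1L, 4L)),
                        metrics = "euclidean", k_shots = 1L,
                        base_config = base, n_eval_episodes = 20,
                        model_seed = 11)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$subset, c("4", "1,4"))
  expect_true(all(tab$mean_accuracy >= 0 & tab$mean_accuracy <= 1))
  # the subset-{4} cell is bit-for-bit a standalone global-feature baseline run
  cfg4 <- base
  cfg4$fusion_subset <- 4L
  cfg4$metric <- divergence_config("euclidean")
  fit4 <- train(mlf_model(extractor_config(fusion_subset = 4L), seed = 11), src, cfg4)
  r4 <- evaluate(fit4$model, tgt, n_episodes = 20, episode = base$episode,
                 metric = cfg4$metric, fusion_subset = 4L, seed = base$seed)
  expect_equal(tab$mean_accuracy[tab$subset == "4"], r4$mean_accuracy)
})
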