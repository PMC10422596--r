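# Shared fixtures, generated once per test run and memoized.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small separable source/target pair used by training tests.
sep1_source <- function() cached("sep1_src",
  generate_collection(fixture_spec(10, 10, class_separation = 1, seed = 5), "source"))
sep1_target <- function() cached("sep1_tgt",
  generate_collection(fixture_spec(10, 10, class_separation = 1, seed = 5), "target"))

# Zero-separation target: every class shares one motif, so any classifier
# performs at chance. A generous record pool (16 classes x 25 images) keeps
# the dataset-conditional accuracy of a fixed pool close to the asymptotic
# 1/N; with few records that conditional value itself wanders by ~0.01 and
# no number of episodes averages it away.
sep0_target <- function() cached("sep0_tgt",
  generate_collection(fixture_spec(16, 25, class_separation = 0, seed = 5), "target"))

# Tiny collection for bookkeeping tests: 2 base classes -> 8 after rotation
# augmentation, 6 images each (enough for 5-way 1-shot, q = 5).
tiny_source <- function() cached("tiny_src",
  generate_collection(fixture_spec(2, 6, class_separation = 1, seed = 3), "source"))

# Raw-pixel nearest-prototype 5-way episode accuracy on a collection:
# the simple independent baseline used to characterize fixture separability.
raw_pixel_np_accuracy <- function(collection, n_episodes = 500, k_shot = 1,
                                  seed = 99) {
  X <- t(vapply(collection$records, function(r) as.numeric(r$pixels),
                numeric(length(collection$records[[1]]$pixels))))
  idx <- split(seq_along(collection$records), collection_labels(collection))
  ec <- episode_config(5, k_shot, 5)
  s_lab <- rep(1:5, k_shot); q_lab <- rep(1:5, 5)
  set.seed(seed)
  acc <- replicate(n_episodes, {
    ep <- sample_episode(collection, ec, idx)
    pro <- compute_prototypes(X[as.vector(ep$support), , drop = FALSE], s_lab)
    P <- class_posteriors(X[as.vector(ep$query), , drop = FALSE], pro,
                          divergence_config())
    mean(predict_classes(P) == q_lab)
  })
  list(mean = mean(acc), se = sd(acc) / sqrt(n_episodes))
}

# Independent plain prototypical-network classifier (nearest centroid under
# squared Euclidean distance, softmax posterior), written with explicit
# loops as an oracle for the vectorized metric head.
protonet_oracle_posteriors <- function(support, s_labels, queries) {
  n_cls <- max(s_labels)
  d <- ncol(support)
  proto <- matrix(0, n_cls, d)
  for (n in seq_len(n_cls))
    proto[n, ] <- colMeans(support[s_labels == n, , drop = FALSE])
  P <- matrix(0, nrow(queries), n_cls)
  for (qi in seq_len(nrow(queries))) {
    dists <- numeric(n_cls)
    for (n in seq_len(n_cls)) {
      s <- 0
      for (j in seq_len(d)) s <- s + (queries[qi, j] - proto[n, j])^2
      dists[n] <- s
    }
    e <- exp(-(dists - min(dists)))
    P[qi, ] <- e / sum(e)
  }
  P
}

# Random probability vector (normalized exponentials).
random_prob <- function(d) {
  v <- rexp(d)
  v / sum(v)
}
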