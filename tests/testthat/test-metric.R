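test_that("prototypes are support centroids with the expected symmetries", {
  v <- runif(64)
  expect_equal(compute_prototypes(list(v))[1, ], v)
  two <- rbind(c(0, 2, rep(0, 62)), c(2, 0, rep(0, 62)))
  expect_equal(compute_prototypes(list(two))[1, ], c(1, 1, rep(0, 62)))
  set.seed(2)
  m <- matrix(runif(5 * 64), 5, 64)
  expect_equal(compute_prototypes(list(m)), compute_prototypes(list(m[sample(5), ])),
               ignore_attr = TRUE)
  expect_error(compute_prototypes(matrix(runif(4), 2, 2), labels = c(1, 3)),
               "no support")
})

test_that("probability-vector conversion smooths, normalizes and handles zeros", {
  cfg <- divergence_config("relative_entropy")
  expect_equal(to_probability_vector(rep(1, 64), cfg), rep(1 / 64, 64))
  expect_equal(to_probability_vector(rep(0, 64), cfg), rep(1 / 64, 64))
  v <- c(3, 1, rep(0, 62))
  p <- to_probability_vector(v, cfg)
  expect_equal(p[1:2], c(0.75, 0.25), tolerance = 1e-9)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p > 0))
  cfg0 <- divergence_config("relative_entropy", epsilon = 0)
  expect_error(to_probability_vector(rep(0, 8), cfg0), "all-zero")
  expect_error(to_probability_vector(c(-1, 2), cfg), "nonnegative")
})

test_that("relative entropy is zero at identity, positive elsewhere, asymmetric", {
  cfg <- divergence_config("relative_entropy")
  set.seed(3)
  for (i in 1:20) {
    x <- random_prob(16)
    expect_equal(divergence(x, x, cfg), 0, tolerance = 1e-12)
  }
  # fixed pair, verified against the direct two-term sum
  x <- c(0.5, 0.5); y <- c(0.25, 0.75)
  expect_equal(divergence(x, y, cfg), 0.5 * log(2) + 0.5 * log(2 / 3),
               tolerance = 1e-12)
  expect_equal(divergence(x, y, cfg), 0.14384, tolerance = 1e-4)
  expect_equal(divergence(y, x, cfg), 0.13081, tolerance = 1e-4)
  expect_false(isTRUE(all.equal(divergence(x, y, cfg), divergence(y, x, cfg))))
  # direction swaps the arguments; base-2 rescales nats to bits
  rev_cfg <- divergence_config("relative_entropy", direction = "prototype_to_query")
  expect_equal(divergence(x, y, rev_cfg), divergence(y, x, cfg))
  bits <- divergence_config("relative_entropy", log_base = "2")
  expect_equal(divergence(x, y, bits), divergence(x, y, cfg) / log(2))
  expect_error(divergence(c(0.5, 0.5), c(1, 2, 3), cfg), "mismatch")
  expect_error(divergence(c(NA, 1), c(0.5, 0.5), cfg), "non-finite")
})

test_that("Gibbs inequality holds on 1000 random probability pairs", {
  cfg <- divergence_config("relative_entropy")
  set.seed(4)
  kl <- replicate(1000, divergence(random_prob(32), random_prob(32), cfg))
  expect_true(all(kl >= 0))
  expect_true(all(kl > 0))  # random pairs are almost surely distinct
})

test_that("euclidean divergence is the (squared) distance on raw embeddings", {
  a <- c(1, 2, 3); b <- c(4, 0, 3)
  expect_equal(divergence(a, b, divergence_config("euclidean")), 13)
  expect_equal(divergence(a, b, divergence_config("euclidean", squared = FALSE)),
               sqrt(13))
})

test_that("posteriors are a shift-invariant softmax over negated divergences", {
  # closed form: divergences (0, log 2) -> posteriors (2/3, 1/3)
  proto <- rbind(c(1, rep(0, 63)), c(1 + sqrt(log(2)), rep(0, 63)))
  q <- c(1, rep(0, 63))
  p <- class_posteriors(q, proto, divergence_config("euclidean"))
  expect_equal(p, c(2 / 3, 1 / 3), tolerance = 1e-9)
  # equal divergences -> uniform
  protos <- rbind(c(2, rep(0, 63)), c(0, 2, rep(0, 62)), c(0, 0, 2, rep(0, 61)))
  expect_equal(class_posteriors(rep(0, 64), protos, divergence_config("euclidean")),
               rep(1 / 3, 3), tolerance = 1e-12)
  # normalization on random batches
  set.seed(5)
  Q <- matrix(abs(rnorm(20 * 64)), 20, 64)
  Cm <- matrix(abs(rnorm(5 * 64)), 5, 64)
  for (cfg in list(divergence_config("euclidean"),
                   divergence_config("relative_entropy"))) {
    P <- class_posteriors(Q, Cm, cfg)
    expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  }
  # shift invariance of the softmax itself
  D <- matrix(runif(12), 3, 4)
  sm <- function(D) t(apply(-D, 1, function(z) exp(z - max(z)) / sum(exp(z - max(z)))))
  expect_equal(sm(D), sm(D + 5), tolerance = 1e-12)
})

test_that("episode loss is the mean negative log true-class probability", {
  perfect <- diag(5)
  expect_equal(episode_loss(perfect, 1:5), 0)
  uniform <- matrix(1 / 5, 4, 5)
  expect_equal(episode_loss(uniform, c(1, 2, 3, 4)), log(5), tolerance = 1e-12)
  two <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(episode_loss(two, c(1, 1)), (log(2) + log(4)) / 2, tolerance = 1e-12)
  expect_equal(episode_loss(two, c(1, 1)), 1.0397, tolerance = 1e-4)
  degenerate <- rbind(c(1, 0))
  expect_warning(l <- episode_loss(degenerate, 2L), "floor")
  expect_true(is.finite(l) && l > 0)
})

test_that("prediction is argmax with lowest-index ties, monotone-invariant", {
  expect_equal(predict_classes(c(0.1, 0.7, 0.2)), 2L)
  expect_equal(predict_classes(c(0.5, 0.5)), 1L)
  set.seed(6)
  P <- matrix(runif(40), 8, 5)
  expect_equal(predict_classes(P), predict_classes(sqrt(P)))
})

test_that("the squared-Euclidean head reproduces an independent prototypical classifier", {
  set.seed(7)
  for (rep in 1:5) {
    Es <- matrix(abs(rnorm(15 * 64)), 15, 64)
    s_lab <- rep(1:5, each = 3)
    Eq <- matrix(abs(rnorm(10 * 64)), 10, 64)
    proto <- compute_prototypes(Es, s_lab)
    P <- class_posteriors(Eq, proto, divergence_config("euclidean"))
    P_oracle <- protonet_oracle_posteriors(Es, s_lab, Eq)
    expect_lt(max(abs(P - P_oracle)), 1e-6)
  }
})

test_that("posteriors are stable under epsilon in [1e-14, 1e-10]", {
  set.seed(8)
  Eq <- matrix(runif(6 * 64, min = 0.05), 6, 64)
  Cm <- matrix(runif(4 * 64, min = 0.05), 4, 64)
  ref <- class_posteriors(Eq, Cm, divergence_config("relative_entropy", epsilon = 1e-12))
  for (eps in c(1e-14, 1e-11, 1e-10)) {
    P <- class_posteriors(Eq, Cm, divergence_config("relative_entropy", epsilon = eps))
    tv <- max(rowSums(abs(P - ref)) / 2)
    expect_lt(tv, 1e-6)
  }
})
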