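#' Configuration of the prototype comparison function
#'
#' Queries are compared to class prototypes with one of two divergences:
#' the squared Euclidean distance on raw embeddings (the classical
#' prototypical-network choice), or the relative entropy (Kullback-Leibler
#' divergence) between epsilon-smoothed, sum-normalized probability vectors
#' derived from the embeddings. Relative entropy is asymmetric; `direction`
#' selects which side carries the query.
#'
#' @param kind `"euclidean"` or `"relative_entropy"`.
#' @param epsilon Smoothing constant added to every embedding component
#'   before normalization (guards `log 0` and division by zero); must be
#'   `>= 0`, default `1e-12`.
#' @param log_base `"e"` (nats, default) or `"2"` (bits).
#' @param direction `"query_to_prototype"` (default): `KL(query || prototype)`;
#'   or `"prototype_to_query"`.
#' @param squared For the Euclidean kind, use the squared distance (default
#'   `TRUE`, the form used inside the prototypical softmax).
#' @return A `divergence_config` object.
#' @export
divergence_config <- function(kind = c("euclidean", "relative_entropy"),
                              epsilon = 1e-12,
                              log_base = c("e", "2"),
                              direction = c("query_to_prototype",
                                            "prototype_to_query"),
                              squared = TRUE) {
  kind <- match.arg(kind)
  log_base <- match.arg(log_base)
  direction <- match.arg(direction)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stopf("epsilon must be a nonnegative scalar")
  structure(
    list(kind = kind, epsilon = epsilon, log_base = log_base,
         direction = direction, squared = isTRUE(squared)),
    class = "divergence_config"
  )
}

#' @noRd
log_scale <- function(config) if (config$log_base == "2") log(2) else 1

#' Class prototypes: centroids of the support embeddings
#'
#' @param support_embeddings Either a list with one `K_n x d` matrix (or a
#'   single vector when `K_n = 1`) per class, or a `S x d` matrix together
#'   with `labels` giving each row's task-local class index.
#' @param labels Integer class index per row (matrix form only).
#' @return `N x d` matrix of prototypes, one row per class, with attribute
#'   `counts` holding the per-class support counts `K_n`.
#' @export
compute_prototypes <- function(support_embeddings, labels = NULL) {
  if (is.matrix(support_embeddings) && !is.null(labels)) {
    n_cls <- max(labels)
    support_embeddings <- lapply(seq_len(n_cls), function(n) {
      support_embeddings[labels == n, , drop = FALSE]
    })
  }
  mats <- lapply(support_embeddings, function(m) {
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    m
  })
  counts <- vapply(mats, nrow, integer(1))
  if (any(counts == 0L))
    stopf("class %d has no support embeddings", which(counts == 0L)[1])
  proto <- t(vapply(mats, colMeans, numeric(ncol(mats[[1]]))))
  attr(proto, "counts") <- counts
  proto
}

#' Convert a nonnegative embedding to a probability vector
#'
#' Adds `epsilon` to every component and divides by the resulting sum, so
#' the output is strictly positive and sums to exactly 1. An all-zero
#' vector maps to the uniform distribution (and is an error when
#' `epsilon = 0`).
#'
#' @param v Nonnegative numeric vector, or a matrix treated row-wise.
#' @param config A [divergence_config()] (only `epsilon` is used).
#' @return Probability vector (or matrix of row distributions).
#' @export
to_probability_vector <- function(v, config = divergence_config("relative_entropy")) {
  eps <- config$epsilon
  if (is.matrix(v)) {
    if (any(v < 0)) stopf("embeddings must be componentwise nonnegative")
    tot <- rowSums(v) + ncol(v) * eps
    if (any(tot == 0)) stopf("all-zero embedding with epsilon = 0: undefined distribution")
    return((v + eps) / tot)
  }
  if (any(v < 0)) stopf("embeddings must be componentwise nonnegative")
  tot <- sum(v) + length(v) * eps
  if (tot == 0) stopf("all-zero embedding with epsilon = 0: undefined distribution")
  (v + eps) / tot
}

#' Divergence between two vectors
#'
#' For `kind = "relative_entropy"` both arguments must already be strictly
#' positive probability vectors (see [to_probability_vector()]); the result
#' is `sum(a * log(a / b))` in the configured base, with the first
#' distribution taken from the query side under the default direction. For
#' `kind = "euclidean"` the raw embeddings are compared directly and the
#' (squared) Euclidean distance is returned.
#'
#' @param a,b Numeric vectors of equal length: query-side first.
#' @param config A [divergence_config()].
#' @return Nonnegative scalar.
#' @export
divergence <- function(a, b, config = divergence_config()) {
  if (length(a) != length(b))
    stopf("length mismatch: %d vs %d", length(a), length(b))
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stopf("non-finite input to divergence")
  if (config$kind == "euclidean") {
    d2 <- sum((a - b)^2)
    return(if (config$squared) d2 else sqrt(d2))
  }
  if (any(a <= 0) || any(b <= 0))
    stopf("relative entropy requires strictly positive probability vectors")
  if (config$direction == "prototype_to_query") { tmp <- a; a <- b; b <- tmp }
  sum(a * log(a / b)) / log_scale(config)
}

#' Divergence matrix between query embeddings and prototypes
#'
#' Vectorized form used by the classifier: raw embeddings go in; the
#' relative-entropy kind performs the epsilon smoothing and normalization
#' internally.
#'
#' @param queries `Q x d` matrix of query embeddings.
#' @param prototypes `N x d` matrix of prototypes.
#' @param config A [divergence_config()].
#' @return `Q x N` matrix of nonnegative divergences.
#' @export
divergence_matrix <- function(queries, prototypes, config = divergence_config()) {
  if (ncol(queries) != ncol(prototypes))
    stopf("embedding dimension mismatch: %d vs %d", ncol(queries), ncol(prototypes))
  if (config$kind == "euclidean") {
    D <- matrix(rowSums(queries^2), nrow(queries), nrow(prototypes)) +
      matrix(rowSums(prototypes^2), nrow(queries), nrow(prototypes), byrow = TRUE) -
      2 * queries %*% t(prototypes)
    D[D < 0] <- 0
    if (!config$squared) D <- sqrt(D)
    return(D)
  }
  X <- to_probability_vector(queries, config)
  Y <- to_probability_vector(prototypes, config)
  lX <- log(X); lY <- log(Y)
  D <- if (config$direction == "query_to_prototype")
    matrix(rowSums(X * lX), nrow(X), nrow(Y)) - X %*% t(lY)
  else
    matrix(rowSums(Y * lY), nrow(X), nrow(Y), byrow = TRUE) - lX %*% t(Y)
  D / log_scale(config)
}

#' Class posteriors: softmax over negated divergences
#'
#' `p(y = n | x) = exp(-d(x, c_n)) / sum_n' exp(-d(x, c_n'))`. Smaller
#' divergence means larger posterior; adding a constant to every divergence
#' leaves the posteriors unchanged.
#'
#' @param query_embedding A single embedding vector or a `Q x d` matrix.
#' @param prototypes `N x d` prototype matrix ([compute_prototypes()]).
#' @param config A [divergence_config()].
#' @return `Q x N` matrix (or vector for a single query) of probabilities
#'   summing to 1 per query.
#' @export
class_posteriors <- function(query_embedding, prototypes,
                             config = divergence_config()) {
  single <- is.null(dim(query_embedding))
  Q <- if (single) matrix(query_embedding, nrow = 1L) else query_embedding
  D <- divergence_matrix(Q, prototypes, config)
  if (any(!is.finite(D))) stopf("non-finite divergence in posterior computation")
  P <- softmax_rows(-D)
  if (single) P[1, ] else P
}

#' @noRd
softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Episodic loss: mean negative log-probability of the true class
#'
#' Equals `log(N)` for uniform posteriors and 0 for perfect ones.
#' Probabilities are floored at `1e-30` (with a warning) before the log, a
#' numerical guard that is never active at the default smoothing.
#'
#' @param posteriors `Q x N` posterior matrix (rows sum to 1).
#' @param true_labels Integer vector of task-local true class indices (1-based).
#' @return Nonnegative scalar loss.
#' @export
episode_loss <- function(posteriors, true_labels) {
  if (is.null(dim(posteriors))) posteriors <- matrix(posteriors, nrow = 1L)
  assert_prob_rows(posteriors)
  p_true <- posteriors[cbind(seq_len(nrow(posteriors)), true_labels)]
  if (any(p_true < 1e-30)) {
    warning("true-class probability underflow; flooring at 1e-30", call. = FALSE)
    p_true <- pmax(p_true, 1e-30)
  }
  -mean(log(p_true))
}

#' Predicted class per query
#'
#' Argmax of the posterior; exact ties resolve to the lowest task-local
#' class index, making predictions invariant to any strictly increasing
#' transform of the posteriors.
#'
#' @param posteriors `Q x N` posterior matrix or a single posterior vector.
#' @return Integer vector of predicted class indices.
#' @export
predict_classes <- function(posteriors) {
  if (is.null(dim(posteriors))) posteriors <- matrix(posteriors, nrow = 1L)
  max.col(posteriors, ties.method = "first")
}

## ---- analytic gradients for the training loop ------------------------------

#' Loss and gradients w.r.t. support and query embeddings for one episode.
#'
#' @param Es `S x d` support embeddings; `s_labels` task-local class per row.
#' @param Eq `Q x d` query embeddings; `q_labels` task-local class per row.
#' @return list(loss, posteriors, accuracy, dEs, dEq)
#' @noRd
episode_head_grad <- function(Es, s_labels, Eq, q_labels, config) {
  proto <- compute_prototypes(Es, s_labels)
  counts <- attr(proto, "counts")
  N <- nrow(proto); Qn <- nrow(Eq); d <- ncol(Eq)
  D <- divergence_matrix(Eq, proto, config)
  P <- softmax_rows(-D)
  loss <- episode_loss(P, q_labels)
  acc <- mean(predict_classes(P) == q_labels)
  onehot <- matrix(0, Qn, N)
  onehot[cbind(seq_len(Qn), q_labels)] <- 1
  dD <- (onehot - P) / Qn  # loss is -log softmax(-D): signs flip twice on z = -D
  if (config$kind == "euclidean") {
    if (!config$squared) stopf("training supports the squared Euclidean form")
    dEq <- 2 * (Eq * rowSums(dD) - dD %*% proto)
    dC <- 2 * (proto * colSums(dD) - t(dD) %*% Eq)
  } else {
    eps <- config$epsilon
    lb <- log_scale(config)
    Tq <- rowSums(Eq) + d * eps
    Tc <- rowSums(proto) + d * eps
    X <- (Eq + eps) / Tq
    Y <- (proto + eps) / Tc
    lX <- log(X); lY <- log(Y)
    if (config$direction == "query_to_prototype") {
      gX <- (rowSums(dD) * (lX + 1) - dD %*% lY) / lb
      gY <- -(t(dD) %*% X) / Y / lb
    } else {
      gY <- (colSums(dD) * (lY + 1) - t(dD) %*% lX) / lb
      gX <- -(dD %*% Y) / X / lb
    }
    dEq <- (gX - rowSums(gX * X)) / Tq
    dC <- (gY - rowSums(gY * Y)) / Tc
  }
  dEs <- dC[s_labels, , drop = FALSE] / counts[s_labels]
  list(loss = loss, posteriors = P, accuracy = acc, dEs = dEs, dEq = dEq)
}
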