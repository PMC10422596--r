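#' Episode configuration
#'
#' One episode (task) is an N-way classification problem with K labeled
#' support images and q query images per class: support size `S = N * K`,
#' query size `Q = N * q`. Defaults follow the 5-way, 1/5-shot, q = 5
#' protocol.
#'
#' @param n_way Number of classes per episode (N).
#' @param k_shot Support images per class (K).
#' @param n_query Query images per class (q).
#' @return An `episode_config` object.
#' @export
episode_config <- function(n_way = 5L, k_shot = 1L, n_query = 5L) {
  if (n_way < 2L || k_shot < 1L || n_query < 1L)
    stopf("need n_way >= 2, k_shot >= 1, n_query >= 1")
  structure(
    list(n_way = as.integer(n_way), k_shot = as.integer(k_shot),
         n_query = as.integer(n_query)),
    class = "episode_config"
  )
}

#' Quarter-turn rotation of a pixel array
#'
#' Exact (lossless) 90-degree array rotation, applied `k` times.
#'
#' @param pixels `(H, W, C)` array (square spatial grid).
#' @param k Number of 90-degree turns (0-3).
#' @return Rotated array of the same shape.
#' @export
rotate_pixels <- function(pixels, k) {
  k <- k %% 4L
  for (i in seq_len(k)) {
    w <- dim(pixels)[2]
    pixels <- aperm(pixels[, w:1, , drop = FALSE], c(2L, 1L, 3L))
  }
  pixels
}

#' Rotation-based class augmentation
#'
#' Every class `c` spawns four classes `c_rot0, c_rot90, c_rot180,
#' c_rot270`, each holding the correspondingly rotated copies of all of
#' `c`'s images: the class and record counts both grow exactly 4-fold.
#' Because the procedure treats each rotation as a distinct category, it is
#' only informative when class appearance is anisotropic.
#'
#' @param collection An `image_collection`.
#' @return The augmented `image_collection` (same role).
#' @export
augment_with_rotations <- function(collection) {
  degs <- c(0L, 90L, 180L, 270L)
  records <- vector("list", 4L * length(collection$records))
  k <- 0L
  for (r in collection$records) {
    for (j in seq_along(degs)) {
      k <- k + 1L
      records[[k]] <- list(
        id = sprintf("%s_rot%d", r$id, degs[j]),
        class = sprintf("%s_rot%d", r$class, degs[j]),
        path = NA_character_,
        pixels = rotate_pixels(r$pixels, j - 1L)
      )
    }
  }
  new_collection(collection$role, records)
}

#' @noRd
class_index <- function(collection) {
  split(seq_along(collection$records), collection_labels(collection))
}

#' Sample one N-way K-shot episode
#'
#' Classes are drawn uniformly without replacement; within each class,
#' `K + q` records are drawn uniformly without replacement and split into
#' support and query, so the two sets are disjoint by construction. The
#' draw consumes the global R random stream: `set.seed()` before the call
#' makes it deterministic.
#'
#' @param collection An `image_collection` with at least `n_way` classes and
#'   `k_shot + n_query` records in every sampled class.
#' @param config An [episode_config()].
#' @param index Optional precomputed class index (internal use).
#' @return An `fs_episode`: `class_map` (task-local index -> class label),
#'   `support` and `query` (`N x K` / `N x q` matrices of record indices),
#'   and the config.
#' @export
sample_episode <- function(collection, config = episode_config(),
                           index = NULL) {
  if (is.null(index)) index <- class_index(collection)
  N <- config$n_way; K <- config$k_shot; q <- config$n_query
  if (length(index) < N)
    stopf("collection has %d classes, need at least N = %d", length(index), N)
  short <- names(index)[vapply(index, length, integer(1)) < K + q]
  if (length(short))
    stopf("class '%s' has fewer than K + q = %d records", short[1], K + q)
  chosen <- sample(names(index), N)
  support <- matrix(0L, N, K)
  query <- matrix(0L, N, q)
  for (n in seq_len(N)) {
    draw <- sample(index[[chosen[n]]], K + q)
    support[n, ] <- draw[seq_len(K)]
    query[n, ] <- draw[K + seq_len(q)]
  }
  structure(
    list(class_map = chosen, support = support, query = query, config = config),
    class = "fs_episode"
  )
}

#' Dump an episode as JSON (debugging aid)
#'
#' @param episode An `fs_episode`.
#' @param collection The collection it was sampled from (for record ids).
#' @return JSON string listing the class map and record ids per slot.
#' @export
episode_to_json <- function(episode, collection) {
  ids <- vapply(collection$records, function(r) r$id, character(1))
  jsonlite::toJSON(list(
    class_map = episode$class_map,
    support = apply(episode$support, 1L, function(i) ids[i], simplify = FALSE),
    query = apply(episode$query, 1L, function(i) ids[i], simplify = FALSE)
  ), auto_unbox = FALSE, pretty = TRUE)
}
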