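#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code under a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a valid 32-bit seed from a master seed and a stream index.
#' Keeps every derived seed strictly below 2^31 so set.seed() accepts it.
#' @noRd
derive_seed <- function(master, stream) {
  (abs(master) %% 1000003) * 2039 + (stream %% 2039)
}

#' Stable content hash of a model or any R object.
#'
#' Hashes the numeric content of parameters and running statistics (not
#' attribute order), so two models trained with the same configuration and
#' seed hash identically.
#'
#' @param x An object; for `mlf_model` objects the parameters, running
#'   statistics and configuration are hashed.
#' @return A character scalar (128-bit hash, hex).
#' @export
model_hash <- function(x) {
  if (inherits(x, "mlf_model")) {
    x <- list(params = x$params, running = x$running, config = unclass(x$config))
  }
  rlang::hash(x)
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
assert_prob_rows <- function(p, tol = 1e-6) {
  if (any(!is.finite(p))) stopf("non-finite probabilities")
  s <- rowSums(p)
  if (any(abs(s - 1) > tol)) stopf("posterior rows must sum to 1")
  invisible(TRUE)
}
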