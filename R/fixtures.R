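#' Specification for a procedural image collection
#'
#' Defines a reproducible synthetic collection that emulates the few-shot
#' regime of small curated image sets: many visually distinct classes, few
#' images per class, within-class appearance jitter. Each class is a
#' procedural motif — a shape family crossed with a hue and an oriented
#' stripe grating — drawn with per-record translation/scale jitter and
#' additive noise. Stripe orientations are non-multiples of 90 degrees, so
#' rotating a class by 90/180/270 degrees genuinely produces a new class.
#'
#' `class_separation` interpolates every class motif between a single shared
#' reference motif (0: all classes identical, classifiers perform at chance)
#' and the class's own motif (1: maximally distinct).
#'
#' @param n_classes Number of classes (>= 2).
#' @param n_per_class Images per class (>= 2); classes are exactly balanced.
#' @param image_size Square image side in pixels (default 96).
#' @param class_separation Real in `[0, 1]`.
#' @param noise_level Amplitude of additive uniform pixel noise (>= 0).
#' @param seed Master seed; identical specs generate bit-identical pixels.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_classes, n_per_class, image_size = 96L,
                         class_separation = 1, noise_level = 0.05,
                         seed = 1L) {
  if (n_classes < 2L) stopf("n_classes must be >= 2")
  if (n_per_class < 2L) stopf("n_per_class must be >= 2")
  if (class_separation < 0 || class_separation > 1)
    stopf("class_separation must lie in [0, 1]")
  if (noise_level < 0) stopf("noise_level must be >= 0")
  structure(
    list(n_classes = as.integer(n_classes),
         n_per_class = as.integer(n_per_class),
         image_size = as.integer(image_size),
         class_separation = class_separation,
         noise_level = noise_level,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# Motif library: 5 shape families x 8 hues x 6 stripe orientations = 240
# distinct class motifs. Orientations avoid multiples of 90 degrees so the
# stripe attribute is anisotropic under quarter-turn rotation.
.motif_shapes <- c("disc", "square", "cross", "ring", "diamond")
.motif_hues <- matrix(c(
  0.90, 0.15, 0.15,
  0.15, 0.80, 0.20,
  0.20, 0.35, 0.95,
  0.95, 0.85, 0.10,
  0.85, 0.20, 0.85,
  0.10, 0.85, 0.85,
  0.95, 0.55, 0.10,
  0.60, 0.60, 0.60
), ncol = 3, byrow = TRUE)
.motif_angles <- c(15, 35, 55, 75, 105, 125) * pi / 180

#' Number of distinct class motifs the generator can produce
#' @return Integer capacity of the motif library.
#' @export
motif_capacity <- function() {
  length(.motif_shapes) * nrow(.motif_hues) * length(.motif_angles)
}

#' @noRd
motif_params <- function(combo) {
  ns <- length(.motif_shapes); nh <- nrow(.motif_hues)
  list(
    shape = .motif_shapes[combo %% ns + 1L],
    fg = .motif_hues[(combo %/% ns) %% nh + 1L, ],
    angle = .motif_angles[(combo %/% (ns * nh)) %% length(.motif_angles) + 1L],
    freq = 3 + combo %% 3
  )
}

#' @noRd
render_motif <- function(p, size, jit) {
  ax <- seq(-1, 1, length.out = size)
  gx <- matrix(ax, size, size)              # varies along rows
  gy <- matrix(ax, size, size, byrow = TRUE)
  x <- gx - jit$dx; y <- gy - jit$dy
  s <- jit$scale
  r <- sqrt(x^2 + y^2)
  mask <- switch(p$shape,
    disc    = r <= 0.55 * s,
    square  = pmax(abs(x), abs(y)) <= 0.50 * s,
    cross   = (abs(x) <= 0.18 * s & abs(y) <= 0.60 * s) |
              (abs(y) <= 0.18 * s & abs(x) <= 0.60 * s),
    ring    = r <= 0.55 * s & r >= 0.32 * s,
    diamond = abs(x) + abs(y) <= 0.72 * s
  )
  strp <- 0.65 + 0.35 * sin(2 * pi * p$freq * (x * cos(p$angle) + y * sin(p$angle)) +
                            2 * pi * jit$phase)
  bg <- c(0.12, 0.12, 0.14)
  img <- array(0, c(size, size, 3L))
  for (k in 1:3)
    img[, , k] <- bg[k] + mask * (p$fg[k] * strp - bg[k])
  img
}

#' Generate a synthetic labeled image collection
#'
#' Deterministic given the spec: one master seed spawns an independent random
#' stream per class, so adding classes never perturbs existing ones. Source
#' and target roles draw disjoint blocks of the motif library (`target`
#' classes start after the source block), guaranteeing class-disjoint splits
#' when both roles are generated from one spec.
#'
#' @param spec A [fixture_spec()].
#' @param role `"source"` or `"target"`.
#' @return An `image_collection` with `n_classes` balanced classes named
#'   `<role>_cNN`.
#' @export
generate_collection <- function(spec, role = c("source", "target")) {
  role <- match.arg(role)
  stopifnot(inherits(spec, "fixture_spec"))
  offset <- if (role == "target") spec$n_classes else 0L
  if (offset + spec$n_classes > motif_capacity())
    stopf("n_classes=%d (role=%s) exceeds the motif library capacity of %d distinct classes",
          spec$n_classes, role, motif_capacity())
  base_p <- motif_params(0L)
  sep <- spec$class_separation
  records <- vector("list", spec$n_classes * spec$n_per_class)
  k <- 0L
  for (ci in seq_len(spec$n_classes)) {
    combo <- ((offset + ci - 1L) * 53L) %% motif_capacity()
    cls_p <- motif_params(combo)
    cls_name <- sprintf("%s_c%02d", role, ci)
    with_seed(derive_seed(spec$seed, offset + ci), {
      for (j in seq_len(spec$n_per_class)) {
        jit <- list(dx = runif(1, -0.05, 0.05), dy = runif(1, -0.05, 0.05),
                    scale = runif(1, 0.94, 1.06), phase = runif(1, 0, 0.12))
        img <- render_motif(cls_p, spec$image_size, jit)
        if (sep < 1) {
          base_img <- render_motif(base_p, spec$image_size, jit)
          img <- (1 - sep) * base_img + sep * img
        }
        if (spec$noise_level > 0) {
          img <- img + array(runif(length(img), -spec$noise_level, spec$noise_level),
                             dim(img))
        }
        img[img < 0] <- 0; img[img > 1] <- 1
        k <- k + 1L
        records[[k]] <- list(id = sprintf("%s/im%03d", cls_name, j),
                             class = cls_name, path = NA_character_,
                             pixels = img)
      }
    })
  }
  new_collection(role, records)
}

#' Write a collection to disk as a directory-per-class PNG tree
#'
#' Produces the on-disk layout that [load_collection()] reads, plus a
#' `manifest.csv` in `dir`.
#'
#' @param collection An `image_collection`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(collection$records)) {
    r <- collection$records[[i]]
    cls_dir <- file.path(dir, r$class)
    dir.create(cls_dir, showWarnings = FALSE)
    fname <- paste0(basename(r$id), ".png")
    EBImage::writeImage(EBImage::Image(r$pixels, colormode = "Color"),
                        file.path(cls_dir, fname))
    collection$records[[i]]$path <- file.path(r$class, fname)
  }
  write_manifest(collection, file.path(dir, "manifest.csv"))
  invisible(dir)
}
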