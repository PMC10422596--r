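test_that("preprocessing normalizes size, channels and range, and is idempotent", {
  set.seed(1)
  big <- array(runif(224 * 224 * 3), c(224, 224, 3))
  px <- preprocess_pixels(big)
  expect_equal(dim(px), c(96L, 96L, 3L))
  expect_true(all(px >= 0 & px <= 1))
  # idempotence: a conforming image passes through unchanged
  expect_identical(preprocess_pixels(px), px)
  # 8-bit integer range is rescaled
  eightbit <- array(sample(0:255, 96 * 96 * 3, replace = TRUE), c(96, 96, 3))
  expect_true(max(preprocess_pixels(eightbit)) <= 1)
  # grayscale replicated, alpha dropped
  expect_equal(dim(preprocess_pixels(matrix(runif(96 * 96), 96, 96))), c(96L, 96L, 3L))
  expect_equal(dim(preprocess_pixels(array(runif(96 * 96 * 4), c(96, 96, 4)))),
               c(96L, 96L, 3L))
})

test_that("load_collection reads a class-per-directory tree with sorted classes", {
  root <- file.path(tempdir(), "tree1")
  unlink(root, recursive = TRUE)
  coll0 <- generate_collection(fixture_spec(2, 3, image_size = 48, seed = 21), "source")
  write_collection(coll0, root)
  # write one larger image to exercise resizing on ingest
  big <- EBImage::Image(array(runif(224 * 224 * 3), c(224, 224, 3)), colormode = "Color")
  EBImage::writeImage(big, file.path(root, coll0$classes[1], "big.png"))
  coll <- load_collection(root, "source")
  expect_s3_class(coll, "image_collection")
  expect_equal(length(coll$records), 7L)  # 2 x 3 + the extra image
  expect_identical(coll$classes, sort(coll$classes))
  expect_true(all(vapply(coll$records, function(r)
    identical(dim(r$pixels), c(96L, 96L, 3L)), logical(1))))
  rng <- range(unlist(lapply(coll$records, function(r) range(r$pixels))))
  expect_true(rng[1] >= 0 && rng[2] <= 1)
})

test_that("load_collection fails on missing roots and empty classes, skips bad files", {
  expect_error(load_collection(file.path(tempdir(), "no-such-dir"), "source"),
               "not found")
  root <- file.path(tempdir(), "tree2")
  unlink(root, recursive = TRUE)
  write_collection(generate_collection(fixture_spec(2, 2, image_size = 32, seed = 4),
                                       "source"), root)
  dir.create(file.path(root, "zz_empty"))
  expect_error(load_collection(root, "source"), "no decodable images")
  unlink(file.path(root, "zz_empty"), recursive = TRUE)
  # an undecodable file is skipped with a warning and reported
  writeLines("not an image", file.path(root, list.dirs(root, recursive = FALSE,
                                                       full.names = FALSE)[1], "junk.png"))
  expect_warning(coll <- load_collection(root, "source"), "undecodable")
  expect_length(attr(coll, "load_report"), 1L)
  expect_equal(length(coll$records), 4L)
})

test_that("manifest round-trip preserves role, classes and per-class counts", {
  coll <- generate_collection(fixture_spec(3, 4, image_size = 16, seed = 8), "target")
  mf <- file.path(tempdir(), "manifest_rt.csv")
  write_manifest(coll, mf)
  m <- read_manifest(mf)
  expect_identical(m$role, "target")
  expect_identical(m$classes, coll$classes)
  expect_identical(unname(m$counts), rep(4L, 3L))
})

test_that("a 28-class x 15-image manifest holds 420 records", {
  df <- expand.grid(img = seq_len(15), class = sprintf("species%02d", 1:28))
  df <- data.frame(
    id = sprintf("%s/im%02d", df$class, df$img),
    path = NA_character_,
    class = as.character(df$class),
    role = "source", stringsAsFactors = FALSE)
  mf <- file.path(tempdir(), "manifest_420.csv")
  write.csv(df, mf, row.names = FALSE)
  m <- read_manifest(mf)
  expect_equal(sum(m$counts), 420L)
  expect_length(m$classes, 28L)
})

test_that("malformed or inconsistent manifests fail with diagnostics", {
  mf <- file.path(tempdir(), "manifest_bad.csv")
  writeLines(c("id,who,class", "a,b,c"), mf)
  expect_error(read_manifest(mf), "expected columns")
  writeLines(c("id,path,class,role", "a,p.png,c1,source", ",q.png,c2,source"), mf)
  expect_error(read_manifest(mf), "line")
  writeLines(c("id,path,class,role", "a,p.png,c1,elsewhere"), mf)
  expect_error(read_manifest(mf), "role")
  # a manifest referencing a missing file names the offending id
  root <- file.path(tempdir(), "tree3")
  unlink(root, recursive = TRUE)
  coll <- generate_collection(fixture_spec(2, 2, image_size = 16, seed = 2), "source")
  write_collection(coll, root)
  m <- read_manifest(file.path(root, "manifest.csv"), validate_root = root)
  expect_s3_class(m, "collection_manifest")
  unlink(file.path(root, m$entries$path[1]))
  expect_error(read_manifest(file.path(root, "manifest.csv"), validate_root = root),
               m$entries$id[1], fixed = TRUE)
})

test_that("source/target class-set disjointness is enforced", {
  src <- generate_collection(fixture_spec(2, 2, image_size = 16, seed = 2), "source")
  tgt <- generate_collection(fixture_spec(2, 2, image_size = 16, seed = 2), "target")
  expect_true(assert_disjoint_classes(src, tgt))
  expect_error(assert_disjoint_classes(src, src), "overlap")
})
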