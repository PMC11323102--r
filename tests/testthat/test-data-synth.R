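# Dataset I/O, preprocessing, augmentation, fold assignment and the
# synthetic lesion generator.

test_that("png pair round trip preserves sample count and labels", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset(3, 16)
  write_dataset(ds, dir, manifest = list(seed = 42))
  loaded <- load_dataset(dir, "png_pairs")
  expect_length(loaded, 3L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  for (i in 1:3) expect_equal(loaded[[i]]$mask, ds[[i]]$mask)
})

test_that("missing masks and shape mismatches are reported by name", {
  dir <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 8, 8), file.path(dir, "lonely.png"))
  expect_error(load_dataset(dir, "png_pairs"), "lonely")
  dir2 <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 64, 64), file.path(dir2, "bad.png"))
  png::writePNG(matrix(0, 32, 32), file.path(dir2, "bad_mask.png"))
  expect_error(load_dataset(dir2, "png_pairs"), "64x64.*32x32")
})

test_that("nifti volumes slice to per-slice samples matching an independent reader", {
  dir <- withr::local_tempdir()
  set.seed(3)
  vol <- array(runif(16 * 16 * 10), c(16, 16, 10))
  msk <- array(as.integer(runif(16 * 16 * 10) < 0.1), c(16, 16, 10))
  ip <- file.path(dir, "vol.nii.gz"); mp <- file.path(dir, "vol_mask.nii.gz")
  RNifti::writeNifti(vol, ip); RNifti::writeNifti(msk, mp)
  samples <- load_dataset(ip, "nifti_slices", mask_path = mp)
  expect_length(samples, 10L)
  ref <- as.array(RNifti::readNifti(mp))
  for (i in 1:10) expect_equal(sum(samples[[i]]$mask), sum(ref[, , i]))
  # mismatched shapes refuse loudly
  RNifti::writeNifti(vol[, , 1:5], mp)
  expect_error(load_dataset(ip, "nifti_slices", mask_path = mp), "16x16x10")
})

test_that("preprocess resizes, normalizes per channel, and keeps labels integral", {
  s <- tiny_dataset(1, 128, frac = 0.04)[[1]]
  out <- preprocess(s, target_size = 64)
  expect_equal(dim(out$image), c(64L, 64L, 1L))
  expect_true(all(out$mask %in% 0:1))
  expect_lt(abs(mean(out$image)), 1e-6)
  expect_lt(abs(sd(as.vector(out$image)) - 1), 1e-6)
})

test_that("constant channels normalize to zero instead of NaN", {
  s <- image_sample("flat", matrix(0.7, 32, 32), matrix(0L, 32, 32))
  out <- preprocess(s, 32)
  expect_true(all(out$image == 0))
  expect_error(preprocess(image_sample("bad", matrix(NaN, 8, 8),
                                       matrix(0L, 8, 8)), 8),
               "non-finite")
})

test_that("CLAHE output still satisfies the Z-score contract", {
  checker <- matrix(rep(c(0, 1), length.out = 64 * 64), 64, 64)
  checker <- checker + matrix(runif(64 * 64, 0, 0.2), 64, 64)
  s <- image_sample("chk", checker, matrix(0L, 64, 64))
  out <- preprocess(s, 64, clahe = TRUE)
  expect_lt(abs(mean(out$image)), 1e-6)
  expect_lt(abs(sd(as.vector(out$image)) - 1), 1e-6)
})

test_that("normalization is idempotent", {
  s <- tiny_dataset(1, 32)[[1]]
  once <- preprocess(s, 32)
  twice <- preprocess(once, 32)
  expect_lt(abs(mean(twice$image) - mean(once$image)), 1e-6)
  expect_lt(abs(sd(as.vector(twice$image)) - sd(as.vector(once$image))), 1e-6)
})

test_that("augmentation applies the same exact transform to image and mask", {
  s <- tiny_dataset(1, 32)[[1]]
  ident <- augment(s, ops = "rotation", rng_seed = 1, angle = 0)
  expect_identical(ident$image, s$image)
  expect_identical(ident$mask, s$mask)
  r <- s
  for (k in 1:4) r <- augment(r, ops = "rotation", rng_seed = 1, angle = 90)
  expect_identical(r$image, s$image)
  expect_identical(r$mask, s$mask)
  a1 <- augment(s, rng_seed = 99)
  a2 <- augment(s, rng_seed = 99)
  expect_identical(a1, a2)
  # a 90-degree rotation moves the lesion with the image
  rot <- augment(s, ops = "rotation", rng_seed = 1, angle = 90)
  expect_equal(sum(rot$mask), sum(s$mask))
  expect_true(all(sort(unique(as.vector(rot$mask))) %in%
                  sort(unique(as.vector(s$mask)))))
})

test_that("synthetic generator is deterministic and respects the imbalance target", {
  cfg <- synth_config(50, 64, 0.03, seed = 7)
  d1 <- generate_synthetic(cfg)
  d2 <- generate_synthetic(cfg)
  expect_identical(d1, d2)
  d3 <- generate_synthetic(synth_config(50, 64, 0.03, seed = 8))
  expect_false(identical(d1[[1]]$image, d3[[1]]$image))
  frac <- mean(vapply(d3, function(s) mean(s$mask > 0), 0))
  expect_gt(frac, 0.03 * 0.7)
  expect_lt(frac, 0.03 * 1.3)
  expect_error(synth_config(10, 64, 0.6), "imbalance")
})

test_that("single-lesion configs yield one connected component", {
  ds <- generate_synthetic(synth_config(20, 64, 0.03,
                                        n_lesions_range = c(1, 1), seed = 5))
  comps <- vapply(ds, function(s) max(EBImage::bwlabel(s$mask)), 0)
  expect_true(all(comps == 1))
})

test_that("fold assignment partitions evenly and deterministically", {
  ds <- tiny_dataset(10, 16)
  f <- split_folds(ds, 5, seed = 1)
  expect_equal(as.integer(table(vapply(f, function(s) s$fold, 0L))),
               rep(2L, 5))
  ds11 <- tiny_dataset(11, 16)
  f11 <- split_folds(ds11, 5, seed = 1)
  expect_equal(sort(as.integer(table(vapply(f11, function(s) s$fold, 0L))),
                    decreasing = TRUE), c(3L, 2L, 2L, 2L, 2L))
  g <- split_folds(ds, 5, seed = 1)
  expect_identical(vapply(f, function(s) s$fold, 0L),
                   vapply(g, function(s) s$fold, 0L))
  expect_error(split_folds(ds, 11, seed = 1), "exceeds")
})
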