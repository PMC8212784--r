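test_that("case round-trips through NIfTI write/read", {
  root <- withr::local_tempdir()
  case <- generate_case(small_spec(seed = 4L))
  write_case(case$image, case$labels, root, "case1")
  back <- read_case(root)
  expect_equal(back$image$data, case$image$data, tolerance = 1e-6)
  expect_identical(back$labels, case$labels)
})

test_that("missing modality and absent segmentation are handled explicitly", {
  root <- withr::local_tempdir()
  case <- generate_case(small_spec(seed = 4L))
  write_case(case$image, case$labels, root, "case1")
  file.remove(file.path(root, "case1_t2.nii.gz"))
  expect_error(read_case(root), "t2")

  root2 <- withr::local_tempdir()
  write_case(case$image, NULL, root2, "case2")
  back <- read_case(root2)
  expect_null(back$labels)
  expect_s3_class(back$image, "multimodal_volume")
})

test_that("t1 file matching does not swallow the t1ce file", {
  root <- withr::local_tempdir()
  case <- generate_case(small_spec(seed = 8L))
  write_case(case$image, case$labels, root, "x")
  back <- read_case(root)
  expect_equal(back$image$data[, , , 2], case$image$data[, , , 2],
               tolerance = 1e-6)
  expect_equal(back$image$data[, , , 3], case$image$data[, , , 3],
               tolerance = 1e-6)
})

test_that("zscore_normalize standardizes and handles degenerate input", {
  x <- withr::with_seed(1, array(rnorm(16^3, mean = 5, sd = 3), dim = c(16, 16, 16)))
  z <- zscore_normalize(x)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sd(z) - 1), 1e-6)
  # idempotent up to tolerance on standardized input
  expect_equal(zscore_normalize(z), z, tolerance = 1e-8)
  expect_warning(z0 <- zscore_normalize(array(7, dim = c(4, 4, 4))), "constant")
  expect_true(all(z0 == 0))
})

test_that("nonzero-only statistics ignore the background", {
  x <- array(0, dim = c(8, 8, 8))
  x[1:4, , ] <- withr::with_seed(2, rnorm(4 * 64, mean = 10))
  z <- zscore_normalize(x, nonzero_only = TRUE)
  inside <- z[1:4, , ]
  expect_lt(abs(mean(inside)), 1e-6)
  expect_lt(abs(sd(inside) - 1), 1e-3)
})

test_that("stack_modalities enforces order and congruence", {
  mk <- function(v) array(v, dim = c(5, 6, 7))
  vol <- stack_modalities(mk(1), mk(2), mk(3), mk(4))
  expect_equal(dim(vol$data), c(5L, 6L, 7L, 4L))
  for (c in 1:4) expect_true(all(vol$data[, , , c] == c))
  expect_error(stack_modalities(mk(1), mk(2), mk(3), array(4, dim = c(5, 6, 8))),
               "differ")
})

test_that("one-hot encoding maps labels to channels and inverts exactly", {
  labs <- random_labels(c(7L, 6L, 5L), seed = 3)
  oh <- encode_labels_onehot(labs)
  expect_equal(dim(oh), c(7L, 6L, 5L, 4L))
  expect_true(all(apply(oh, 1:3, sum) == 1))
  expect_identical(decode_onehot(oh), labs)

  zero <- array(0L, dim = c(3, 3, 3))
  ohz <- encode_labels_onehot(zero)
  expect_true(all(ohz[, , , 1] == 1))
  expect_true(all(ohz[, , , 2:4] == 0))

  one4 <- zero; one4[2, 2, 2] <- 4L
  oh4 <- encode_labels_onehot(one4)
  expect_equal(oh4[2, 2, 2, 4], 1)      # enhancing tumor lives in channel 3 (0-based)
  expect_equal(sum(oh4[, , , 4]), 1)

  bad <- zero; bad[1] <- 3L
  expect_error(encode_labels_onehot(bad), "unexpected values: 3")
})

test_that("grid patching covers the volume and reassembles exactly", {
  case <- generate_case(small_spec(seed = 6L))
  oh <- encode_labels_onehot(case$labels)
  pp <- extract_patches(case$image, oh, c(16L, 16L, 16L), mode = "grid",
                        stride = c(16L, 16L, 16L))
  expect_length(pp, 8)
  cover <- array(0L, dim = c(32, 32, 32))
  rebuilt <- array(NA_real_, dim = dim(case$image$data))
  for (p in pp) {
    i1 <- p$origin + 1L; i2 <- p$origin + 16L
    cover[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]] <-
      cover[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]] + 1L
    rebuilt[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3], ] <- p$image
  }
  expect_true(all(cover >= 1))
  expect_identical(rebuilt, case$image$data)
})

test_that("whole-volume patch is a single tile at the origin", {
  case <- generate_case(small_spec(seed = 6L))
  pp <- extract_patches(case$image, NULL, c(32L, 32L, 32L), mode = "grid")
  expect_length(pp, 1)
  expect_equal(pp[[1]]$origin, c(0L, 0L, 0L))
  expect_error(extract_patches(case$image, NULL, c(64L, 32L, 32L)), "exceeds")
})

test_that("tumor-forced random patches always intersect tumor", {
  case <- generate_case(small_spec(seed = 9L))
  oh <- encode_labels_onehot(case$labels)
  pp <- extract_patches(case$image, oh, c(16L, 16L, 16L), mode = "random",
                        n_patches = 20L, tumor_fraction = 1, seed = 2L)
  counts <- vapply(pp, function(p) sum(p$mask[, , , 2:4]), 0)
  expect_true(all(counts >= 1))
  # determinism under the seed
  pp2 <- extract_patches(case$image, oh, c(16L, 16L, 16L), mode = "random",
                         n_patches = 20L, tumor_fraction = 1, seed = 2L)
  expect_identical(lapply(pp, `[[`, "origin"), lapply(pp2, `[[`, "origin"))
})
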