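test_that("region binarization implements the nested ET/TC/WT definitions", {
  labs <- array(0L, dim = c(3, 1, 1))
  labs[1] <- 1L; labs[2] <- 2L; labs[3] <- 4L
  expect_equal(sum(region_binarize(labs, "ET")), 1)
  expect_equal(sum(region_binarize(labs, "TC")), 2)
  expect_equal(sum(region_binarize(labs, "WT")), 3)
  expect_error(region_binarize(labs, "XX"), "unknown region")

  zero <- array(0L, dim = c(2, 2, 2))
  for (r in c("ET", "WT", "TC"))
    expect_false(any(region_binarize(zero, r)))

  labs2 <- random_labels(c(6L, 6L, 6L), seed = 8)
  et <- region_binarize(labs2, "ET")
  tc <- region_binarize(labs2, "TC")
  wt <- region_binarize(labs2, "WT")
  expect_true(all(!et | tc))
  expect_true(all(!tc | wt))
})

test_that("confusion counts enumerate the four cells exactly", {
  gt <- array(c(TRUE, TRUE, FALSE, FALSE), dim = c(2, 2, 1))
  pred <- array(c(TRUE, FALSE, TRUE, FALSE), dim = c(2, 2, 1))
  cc <- confusion_counts(gt, pred)
  expect_equal(cc, list(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  m <- random_mask(c(5, 5, 5), seed = 1)
  cc2 <- confusion_counts(m, random_mask(c(5, 5, 5), p = 0.5, seed = 2))
  expect_equal(cc2$TP + cc2$FP + cc2$FN + cc2$TN, 125)
  expect_error(confusion_counts(m, random_mask(c(4, 5, 5))), "mismatch")
})

test_that("dice follows the formula and the empty-region conventions", {
  expect_equal(dice_score(list(TP = 2, FP = 1, FN = 1, TN = 10)), 4 / 6)
  # both empty -> 1; gt empty with any false positive -> 0
  expect_equal(dice_score(list(TP = 0, FP = 0, FN = 0, TN = 8)), 1)
  expect_equal(dice_score(list(TP = 0, FP = 1, FN = 0, TN = 7)), 0)
  # identical masks
  expect_equal(dice_score(list(TP = 5, FP = 0, FN = 0, TN = 3)), 1)
})

test_that("sensitivity and specificity handle saturation and undefined cases", {
  cc <- confusion_counts(array(c(TRUE, TRUE, FALSE, FALSE), dim = c(4, 1, 1)),
                         array(c(TRUE, FALSE, TRUE, FALSE), dim = c(4, 1, 1)))
  ss <- sensitivity_specificity(cc)
  expect_equal(unname(ss), c(0.5, 0.5))
  perfect <- sensitivity_specificity(list(TP = 4, FP = 0, FN = 0, TN = 4))
  expect_equal(unname(perfect), c(1, 1))
  allpos <- sensitivity_specificity(list(TP = 4, FP = 4, FN = 0, TN = 0))
  expect_equal(unname(allpos), c(1, 0))
  und <- sensitivity_specificity(list(TP = 0, FP = 0, FN = 0, TN = 8))
  expect_true(is.na(und[["sensitivity"]]))
})

test_that("hausdorff95 handles identical, separated and empty masks", {
  m <- random_mask(c(6, 6, 6), seed = 3)
  expect_equal(hausdorff95(m, m), 0)
  a <- array(FALSE, dim = c(9, 3, 3)); a[2, 2, 2] <- TRUE
  b <- array(FALSE, dim = c(9, 3, 3)); b[5, 2, 2] <- TRUE
  expect_equal(hausdorff95(a, b), 3)
  expect_equal(hausdorff95(a, b, spacing = c(2, 1, 1)), 6)
  empty <- array(FALSE, dim = c(9, 3, 3))
  expect_true(is.na(hausdorff95(a, empty)))
  expect_true(is.na(hausdorff95(empty, empty)))
})

test_that("hausdorff95 equals the brute-force percentile oracle", {
  withr::with_seed(21, {
    for (rep in 1:8) {
      shp <- sample(4:8, 3, replace = TRUE)
      gt <- array(runif(prod(shp)) < 0.3, dim = shp)
      pred <- array(runif(prod(shp)) < 0.3, dim = shp)
      if (!any(gt)) gt[1] <- TRUE
      if (!any(pred)) pred[2] <- TRUE
      expect_equal(hausdorff95(gt, pred), brute_force_hd95(gt, pred),
                   tolerance = 1e-9)
    }
  })
})

test_that("ET post-processing respects the strict 500-voxel threshold", {
  mk <- function(n_et) {
    labs <- array(0L, dim = c(12, 12, 12))
    labs[seq_len(400)] <- 1L
    if (n_et > 0) labs[400 + seq_len(n_et)] <- 4L
    labs
  }
  p499 <- postprocess_enhancing_tumor(mk(499))
  expect_equal(sum(p499 == 4L), 0)
  expect_equal(sum(p499 == 1L), 400 + 499)
  p500 <- postprocess_enhancing_tumor(mk(500))
  expect_equal(sum(p500 == 4L), 500)
  expect_identical(postprocess_enhancing_tumor(mk(0)), mk(0))
  expect_error(postprocess_enhancing_tumor(mk(10), threshold = -1), ">= 0")

  # WT and TC binary regions invariant; ET count never increases
  labs <- mk(123)
  post <- postprocess_enhancing_tumor(labs)
  expect_identical(region_binarize(labs, "WT"), region_binarize(post, "WT"))
  expect_identical(region_binarize(labs, "TC"), region_binarize(post, "TC"))
  expect_lte(sum(post == 4L), sum(labs == 4L))
})

test_that("case_metrics gives perfect scores when prediction equals truth", {
  labs <- generate_case(small_spec(seed = 12L))$labels
  m <- case_metrics(labs, labs)
  expect_equal(m$dice, rep(1, 3))
  expect_equal(m$sensitivity, rep(1, 3))
  expect_equal(m$specificity, rep(1, 3))
  expect_equal(m$hausdorff95, rep(0, 3))
})

test_that("summary excludes undefined Hausdorff cases and counts them", {
  labs <- array(0L, dim = c(4, 4, 4))          # empty ground truth
  m <- rbind(case_metrics(labs, labs, case = "a"),
             case_metrics(generate_case(small_spec(seed = 1L))$labels,
                          generate_case(small_spec(seed = 1L))$labels,
                          case = "b"))
  s <- summarize_metrics(m)
  expect_equal(s$hausdorff95_excluded[s$region == "ET"], 1)
  expect_equal(s$dice_mean, rep(1, 3))         # conventions give 1 for empty/empty
})
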