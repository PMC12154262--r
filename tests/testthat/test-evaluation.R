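test_that("Dice handles identity, disjoint, shifted, and empty-mask conventions", {
  m <- matrix(0L, 20, 20); m[5:14, 3:12] <- 1L
  expect_equal(dice_coef(m, m), 1)
  shifted <- matrix(0L, 20, 20); shifted[5:14, 8:17] <- 1L
  expect_equal(dice_coef(m, shifted), 2 * 50 / 200)   # 10x10 blocks, 5-col shift
  disjoint <- matrix(0L, 20, 20); disjoint[16:19, 16:19] <- 1L
  expect_equal(dice_coef(m, disjoint), 0)
  none <- matrix(0L, 20, 20)
  expect_equal(dice_coef(none, none), 1)              # both empty: agreement
  expect_equal(dice_coef(m, none), 0)
  expect_error(dice_coef(m, matrix(0L, 10, 10)), "mismatch")
})

test_that("IoU modes match pixel counting and the foreground identity with Dice", {
  m <- matrix(0L, 20, 20); m[5:14, 3:12] <- 1L
  shifted <- matrix(0L, 20, 20); shifted[5:14, 8:17] <- 1L
  expect_equal(iou_score(m, shifted, "foreground"), 50 / 150)
  expect_equal(iou_score(m, m, "foreground"), 1)
  expect_equal(iou_score(m, m, "global"), 1)
  cnt <- oracle_overlap_counts(m, shifted)
  expect_equal(iou_score(m, shifted, "global"),
               (cnt$tp / (cnt$tp + cnt$fp + cnt$fn) +
                  cnt$tn / (cnt$tn + cnt$fp + cnt$fn)) / 2)
  set.seed(14)
  for (i in 1:25) {
    a <- matrix(rbinom(144, 1, 0.3), 12)
    b <- matrix(rbinom(144, 1, 0.3), 12)
    d <- dice_coef(a, b)
    expect_equal(iou_score(a, b, "foreground"), d / (2 - d), tolerance = 1e-12)
  }
})

test_that("fold plans form contiguous test blocks that partition the subjects", {
  ids <- sprintf("P%03d", 1:300)
  plan <- make_fold_plan(ids, 10)
  expect_equal(plan[[1]]$test, ids[1:30])
  expect_equal(plan[[2]]$test, ids[31:60])
  all_test <- unlist(lapply(plan, `[[`, "test"))
  expect_setequal(all_test, ids)
  expect_equal(length(all_test), 300)                 # pairwise disjoint
  for (f in plan) {
    expect_setequal(c(f$test, f$val, f$train), ids)
    ## 8:1 train:val on the remainder
    expect_equal(length(f$val), 30)
    expect_equal(length(f$train), 240)
  }
})

test_that("leave-one-subject-out and uneven splits degrade gracefully", {
  ids <- letters[1:10]
  plan <- make_fold_plan(ids, 10)
  expect_true(all(vapply(plan, function(f) length(f$test), 1L) == 1))
  uneven <- make_fold_plan(sprintf("s%02d", 1:23), 5)
  sizes <- vapply(uneven, function(f) length(f$test), 1L)
  expect_equal(sum(sizes), 23)
  expect_true(max(sizes) - min(sizes) <= 1)
  expect_error(make_fold_plan(letters[1:5], 10), "exceeds")
  expect_error(make_fold_plan(c("a", "a", "b"), 2), "unique")
})

test_that("fold evaluation separates all-image and retained-set metrics", {
  set.seed(6)
  truths <- lapply(1:6, function(i)
    rasterize_ellipse(ellipse_params(30 + 2 * i, 30, 12, 9, 10 * i), 64))
  preds <- truths
  preds[[6]] <- matrix(0L, 64, 64); preds[[6]][2:6, 2:6] <- 1L   # one failure
  acc_ms <- lapply(1:6, function(i)
    structure(list(provenance = NULL, accepted = i != 6,
                   rejection_reason = if (i == 6) "fit_failed" else "none",
                   diameter_px = 20, diameter_mm = 14, ellipse = NULL),
              class = "aod_measurement"))
  fm <- evaluate_fold(preds, truths, acc_ms, fold_id = 1)
  expect_equal(fm$n_images, 6)
  expect_equal(fm$n_retained, 5)
  expect_equal(fm$dice_retained, 1)
  expect_lt(fm$dice_all, 1)
  expect_gte(fm$dice_retained, fm$dice_all)
  ## oracle: recomputing without the worst image
  expect_equal(fm$dice_all, mean(vapply(1:6, function(i)
    dice_coef(preds[[i]], truths[[i]]), 1)))
  ## accept-everything stream reproduces the no-rejection metrics exactly
  all_acc <- lapply(acc_ms, function(m) { m$accepted <- TRUE; m })
  fm2 <- evaluate_fold(preds, truths, all_acc)
  expect_identical(fm2$dice_retained, fm2$dice_all)
  expect_identical(fm2$iou_retained, fm2$iou_all)
  ## empty retained set: undefined, not zero
  none_acc <- lapply(acc_ms, function(m) { m$accepted <- FALSE; m })
  fm3 <- evaluate_fold(preds, truths, none_acc)
  expect_true(is.na(fm3$dice_retained))
  expect_gt(fm3$dice_all, 0)
})

test_that("fold averaging is an unweighted mean, permutation-invariant, fixed on constants", {
  pf <- reference_fold_metrics("sanet")
  agg <- aggregate_folds(pf)
  perm <- aggregate_folds(pf[sample(nrow(pf)), ])
  expect_identical(agg[-1], perm[-1])
  const <- data.frame(dice_all = rep(0.8, 4), dice_retained = rep(0.9, 4),
                      iou_all = rep(0.7, 4), iou_retained = rep(0.75, 4))
  aggc <- aggregate_folds(const)
  expect_equal(unlist(aggc[c("dice_all", "dice_retained", "iou_all",
                             "iou_retained")], use.names = FALSE),
               c(0.8, 0.9, 0.7, 0.75))
  expect_error(aggregate_folds(pf[0, ]), "at least one fold")
})

test_that("AoD summaries use interpolated quantiles and only accepted measurements", {
  s <- aod_error_summary(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(s$mean_abs_error_mm, 0)
  expect_equal(s$median_mm, 2.5)
  expect_equal(unname(s$iqr_mm), c(1.75, 3.25))
  ms <- lapply(1:4, function(i)
    structure(list(accepted = i != 2, rejection_reason = "none",
                   diameter_mm = i + 0.5), class = "aod_measurement"))
  s2 <- aod_error_summary(ms, truth_mm = 1:4)
  expect_equal(s2$n, 3)
  expect_equal(s2$mean_abs_error_mm, 0.5)
  expect_error(aod_error_summary(list(), numeric(0)), "no accepted")
  expect_error(aod_error_summary(c(1, 2), c(1, 2, 3)), "one-to-one")
})
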