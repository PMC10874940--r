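test_that("centroids map to tissues by T2 brightness regardless of order", {
  m <- tissue_assignment(c(30, 120, 200))
  expect_equal(m, c(vessel = 30, brain = 120, csf = 200))
  expect_equal(tissue_assignment(c(200, 30, 120)), m)
  expect_error(tissue_assignment(c(50, 50, 200)), "unresolvable")
  expect_error(tissue_assignment(c(1, 2)), "three centroids")
})

test_that("tissue proportions count hard assignments and sum to 100", {
  u <- rbind(matrix(rep(c(0.9, 0.05, 0.05), 10), ncol = 3, byrow = TRUE),
             matrix(rep(c(0.1, 0.8, 0.1), 10), ncol = 3, byrow = TRUE))
  p <- tissue_proportions(u)
  expect_equal(unname(p), c(50, 50, 0))
  set.seed(2)
  u2 <- matrix(runif(300), ncol = 3)
  u2 <- u2 / rowSums(u2)
  expect_equal(sum(tissue_proportions(u2)), 100, tolerance = 1e-6)
  # ties go to the lower tissue class index
  expect_equal(unname(tissue_proportions(rbind(c(0.4, 0.4, 0.2)))),
               c(100, 0, 0))
})

test_that("compactness index is the vessel/brain ratio, scale invariant", {
  expect_equal(compactness_index(c(vessel = 30, brain = 60, csf = 10)), 0.5)
  p <- c(vessel = 30.9, brain = 52.2, csf = 16.8)
  expect_equal(compactness_index(p), compactness_index(p * 3.7))
  expect_equal(compactness_index(p), 30.9 / 52.2)
  expect_error(compactness_index(c(vessel = 10, brain = 0, csf = 90)),
               "undefined")
})

test_that("segmentation is unchanged under affine intensity rescaling", {
  ph <- test_phantom(shape = 32L, radius = 11, seed = 14L)
  params <- fcm_params(seed = 2)
  a <- segment_bavm(ph$t2, ph$dose, ph$spec$margin_dose, params,
                    ph$grid, ph$grid)
  b <- segment_bavm(ph$t2 * 3.1 + 40, ph$dose, ph$spec$margin_dose, params,
                    ph$grid, ph$grid)
  expect_equal(a$proportions, b$proportions, tolerance = 1e-9)
  expect_equal(a$compactness_index, b$compactness_index, tolerance = 1e-9)
  expect_identical(a$hard_labels, b$hard_labels)
})

test_that("repeated segmentation of the same phantom is identical", {
  ph <- test_phantom(shape = 32L, radius = 11, seed = 15L)
  params <- fcm_params(seed = 7)
  a <- segment_bavm(ph$t2, ph$dose, ph$spec$margin_dose, params,
                    ph$grid, ph$grid)
  b <- segment_bavm(ph$t2, ph$dose, ph$spec$margin_dose, params,
                    ph$grid, ph$grid)
  expect_identical(a$proportions, b$proportions)
  expect_identical(a$centroids, b$centroids)
  expect_identical(a$hard_labels, b$hard_labels)
})

test_that("segmentation recovers truth proportions and orders compact above diffuse", {
  compact <- test_phantom(proportions = c(45, 45, 10), fwhm = 6, seed = 31L)
  diffuse <- test_phantom(proportions = c(25, 60, 15), fwhm = 3, seed = 32L)
  params <- fcm_params(seed = 1)
  seg_c <- segment_bavm(compact$t2, compact$dose, compact$spec$margin_dose,
                        params, compact$grid, compact$grid)
  seg_d <- segment_bavm(diffuse$t2, diffuse$dose, diffuse$spec$margin_dose,
                        params, diffuse$grid, diffuse$grid)
  expect_true(all(abs(seg_c$proportions - truth_proportions(compact)) <= 2))
  # for the diffuse texture, intensity overlap at class borders caps what any
  # intensity-only classifier can recover: compare against the nearest-true-
  # mean assignment of the same voxels, which FCM should track closely
  roi_vals <- diffuse$t2[diffuse$truth_labels != 0]
  bayes_cls <- apply(abs(outer(roi_vals, diffuse$spec$intensity_means, `-`)),
                     1, which.min)
  bayes <- 100 * tabulate(bayes_cls, 3) / length(roi_vals)
  expect_true(all(abs(seg_d$proportions - bayes) <= 2))
  expect_gt(seg_c$compactness_index, seg_d$compactness_index)
  # ROI voxel count within 5% of the true nidus voxel count
  expect_lt(abs(seg_c$roi_voxels / sum(compact$truth_labels != 0) - 1), 0.05)
})

test_that("the worked diffuse case (truth CI 0.43) is classified diffuse at 0.63", {
  ph <- test_phantom(proportions = c(27, 62.8, 10.2), fwhm = 3, seed = 33L)
  expect_equal(compactness_index(truth_proportions(ph)), 0.43,
               tolerance = 0.01)
  seg <- segment_bavm(ph$t2, ph$dose, ph$spec$margin_dose,
                      fcm_params(seed = 1), ph$grid, ph$grid)
  expect_lt(abs(seg$compactness_index - 0.43), 0.05)
  expect_equal(classify_morphology(seg$compactness_index), "diffuse")
})

test_that("stage failures are reported with the failing stage name", {
  ph <- test_phantom(shape = 24L, radius = 8, seed = 16L)
  expect_error(
    segment_bavm(ph$t2, ph$dose, margin_dose = 1e6, fcm_params(),
                 ph$grid, ph$grid),
    "prescription_roi")
  expect_error(prescription_roi(array(1, c(4, 4, 4)), 2),
               "no voxel reaches")
  expect_error(prescription_roi(array(1, c(4, 4, 4)), -1), "positive")
  # uniform 20 Gy field vs margin 17.5: every voxel is in the ROI
  roi <- prescription_roi(array(20, c(4, 4, 4)), 17.5)
  expect_true(all(roi))
})
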