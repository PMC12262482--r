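test_that("sphere masks follow the strict-inequality lattice rule", {
  expect_equal(sum(makeSignalMask(c(50, 50, 50), radius = 4)), 251)
  expect_equal(sum(makeSignalMask(c(9, 9, 9), radius = 1)), 1)
  # oracle: exhaustive integer-point enumeration for radii 1..6
  for (r in 1:6) {
    dims <- rep(2 * r + 9, 3)
    expect_equal(sum(makeSignalMask(dims, radius = r)),
                 latticeSphereCount(r), info = paste("radius", r))
  }
  expect_warning(m0 <- makeSignalMask(c(9, 9, 9), radius = 0), "empty")
  expect_equal(sum(m0), 0)
  expect_error(makeSignalMask(c(6, 6, 6), radius = 5), "fit")
})

test_that("simulated cohorts realize the configured conditions", {
  cfg <- simConfig(nSubjects = 300, dims = c(10, 10, 10), radius = 3,
                   effect = 0.4, prevalence = 0.5, seed = 33)
  vm <- simulateCohort(cfg)
  dx <- SummarizedExperiment::colData(vm)$Dx
  expect_equal(sum(dx), 150)                        # exact prevalence
  truth <- S4Vectors::metadata(vm)$truth
  expect_equal(sum(truth), latticeSphereCount(3))

  Y <- voxelValues(vm)
  sig <- which(truth)
  diffMeans <- rowMeans(Y[sig, dx == 1, drop = FALSE]) -
    rowMeans(Y[sig, dx == 0, drop = FALSE])
  # case-minus-control mean at signal voxels ~ effect +- 2/sqrt(n)
  expect_lt(abs(mean(diffMeans) - 0.4), 2 / sqrt(300))
  # null voxels: no shift, unit variance
  nullIdx <- which(!truth)[1:200]
  expect_lt(abs(mean(Y[nullIdx, ])), 0.02)
  expect_lt(abs(mean(apply(Y[nullIdx, ], 1, var)) - 1), 0.05)

  # d = 0 is a true null configuration
  vm0 <- simulateCohort(simConfig(nSubjects = 300, dims = c(8, 8, 8),
                                  radius = 2, effect = 0, seed = 34))
  dx0 <- SummarizedExperiment::colData(vm0)$Dx
  t0 <- S4Vectors::metadata(vm0)$truth
  Y0 <- voxelValues(vm0)
  d0 <- rowMeans(Y0[which(t0), dx0 == 1, drop = FALSE]) -
    rowMeans(Y0[which(t0), dx0 == 0, drop = FALSE])
  expect_lt(abs(mean(d0)), 3 / sqrt(300))

  # reproducible bit-for-bit from the seed
  vmB <- simulateCohort(cfg)
  expect_identical(voxelValues(vm), voxelValues(vmB))
})

test_that("MCAR injection removes exactly round(m*n) subjects per voxel", {
  cfg <- simConfig(nSubjects = 50, dims = c(6, 6, 6), radius = 2, seed = 35)
  vm <- simulateCohort(cfg)
  expect_identical(injectMissingness(vm, 0), vm)          # m = 0 untouched

  vm4 <- injectMissingness(vm, 0.4, seed = 7)
  # oracle: independent recount per voxel
  miss <- rowSums(is.na(voxelValues(vm4)))
  expect_true(all(miss == round(0.4 * 50)))
  expect_equal(unname(nObserved(vm4)), rep(30, 216))
  # observed values are untouched
  keep <- !is.na(voxelValues(vm4))
  expect_identical(voxelValues(vm4)[keep], voxelValues(vm)[keep])

  vm1 <- injectMissingness(vm, 1, seed = 7)
  expect_true(all(is.na(voxelValues(vm1))))

  lw <- injectMissingness(vm, 0.2, seed = 8, listwise = TRUE)
  expect_equal(sum(colSums(is.na(voxelValues(lw))) == 216), 10)
})

test_that("ROC scoring matches the all-pairs probability", {
  # perfect separation and label permutation
  expect_equal(scoreROC(c(1:5, 11:15), rep(c(FALSE, TRUE), each = 5))$auc, 1)
  set.seed(36)
  s <- rnorm(2000)
  expect_lt(abs(scoreROC(s, rep_len(c(TRUE, FALSE), 2000))$auc - 0.5), 0.04)

  # oracle: brute-force pairwise comparison on 200-voxel fixtures
  for (i in 1:5) {
    stat <- round(rnorm(200), 1)          # coarse grid forces ties
    truth <- runif(200) < 0.3
    if (!any(truth) || all(truth)) next
    r <- scoreROC(stat, truth)
    expect_equal(r$auc, pairwiseAUC(stat[truth], stat[!truth]),
                 tolerance = 1e-12)
    # cross-check against an independent ROC implementation
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- suppressMessages(pROC::auc(pROC::roc(truth, stat,
                                                  direction = "<")))
      expect_equal(r$auc, as.numeric(ref), tolerance = 1e-10)
    }
    # curve is monotone in both coordinates
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
  }

  # sensitivity definition: exceedance of the empirical null quantile
  stat <- c(rnorm(500), rnorm(50) + 2)
  truth <- rep(c(FALSE, TRUE), c(500, 50))
  r <- scoreROC(stat, truth)
  thr <- quantile(stat[!truth], 0.95, names = FALSE)
  expect_equal(r$sensitivity, mean(stat[truth] > thr))

  # undefined when one class has no finite statistic
  expect_true(is.na(scoreROC(c(NA, NA, 1), c(TRUE, TRUE, FALSE))$auc))
})

test_that("engine statistics equal the classical two-sample t at m = 0", {
  cfg <- simConfig(nSubjects = 60, dims = c(5, 5, 4), radius = 1.5,
                   effect = 0.5, seed = 37)
  vm <- simulateCohort(cfg)
  res <- runMega(vm, modelSpec(Brain ~ Dx))
  Y <- voxelValues(vm)
  dx <- SummarizedExperiment::colData(vm)$Dx
  # oracle: direct group-means / pooled-variance computation
  tref <- apply(Y, 1, twoSampleT, grp = dx)
  expect_equal(unname(res@statistic[, "Dx"]), tref, tolerance = 1e-10)
})

test_that("sensitivity tracks the closed-form approximation over the sweep", {
  # scaled-down study: same per-voxel two-group design, smaller grid
  cfg <- simConfig(nSubjects = 400, dims = c(16, 16, 16), radius = 4,
                   effect = 0.35, seed = 38)
  lv <- c(0, 0.3, 0.6)
  sw <- missingnessSweep(cfg, levels = lv, nSegments = 3)
  expect_identical(sw$m, lv)
  for (i in seq_along(lv)) {
    delta <- 0.35 * sqrt((1 - lv[i]) * 400 / 4)
    sensRef <- pnorm(delta - qnorm(0.95))
    expect_lt(abs(sw$sensitivity[i] - sensRef), 0.075)
    aucRef <- pnorm(delta / sqrt(2))
    expect_lt(abs(sw$auc[i] - aucRef), 0.03)
  }
  # performance decreases (weakly) with missingness
  expect_true(all(diff(sw$auc) < 0.02))

  # bit-for-bit reproducibility of the sweep from (config, seed)
  sw2 <- missingnessSweep(cfg, levels = lv, nSegments = 3)
  expect_identical(sw, sw2)
})

test_that("complete-case analysis collapses once any cell is missing", {
  cfg <- simConfig(nSubjects = 40, dims = c(6, 6, 6), radius = 2,
                   effect = 0.8, seed = 39)
  # at m = 0 the two estimators coincide
  b0a <- benchmarkAtMissingness(cfg, 0, estimator = "available_case",
                                nSegments = 2)
  b0c <- benchmarkAtMissingness(cfg, 0, estimator = "complete_case",
                                nSegments = 2)
  expect_equal(b0a$auc, b0c$auc)
  expect_equal(b0a$sensitivity, b0c$sensitivity)

  # any per-voxel missingness removes every voxel from complete-case
  bc <- benchmarkAtMissingness(cfg, 0.2, estimator = "complete_case",
                               nSegments = 2)
  expect_equal(bc$nRetained, 0)
  expect_true(is.na(bc$auc))
  ba <- benchmarkAtMissingness(cfg, 0.2, estimator = "available_case",
                               nSegments = 2)
  expect_equal(ba$nRetained, 216)
  expect_gt(ba$auc, 0.5)
})
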