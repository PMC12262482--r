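test_that("Stouffer combination reproduces the closed forms", {
  # single-study identity
  expect_equal(stoufferCombine(matrix(2.5, 1, 1))$z, 2.5)
  # unweighted two-study case
  s <- stoufferCombine(matrix(c(1.96, 1.96), 1))
  expect_equal(s$z, 3.92 / sqrt(2), tolerance = 1e-12)
  expect_equal(s$k, 2)
  # weighted with w = sqrt(n); oracle: scalar recomputation
  w <- sqrt(c(100, 400))
  expect_equal(stoufferCombine(matrix(c(1, 2), 1), matrix(c(100, 400), 1),
                               weighted = TRUE)$z,
               sum(w * c(1, 2)) / sqrt(sum(w^2)), tolerance = 1e-12)
  expect_equal(stoufferCombine(matrix(c(1, 2), 1), matrix(c(100, 400), 1),
                               weighted = TRUE)$z, 50 / sqrt(500),
               tolerance = 1e-12)
  # w = n variant
  expect_equal(stoufferCombine(matrix(c(1, 2), 1), matrix(c(100, 400), 1),
                               weighted = TRUE, weightType = "n")$z,
               (100 + 800) / sqrt(100^2 + 400^2), tolerance = 1e-12)
  # equal weights equals unweighted exactly
  z <- matrix(rnorm(30), 10, 3)
  n <- matrix(50, 10, 3)
  expect_equal(stoufferCombine(z, n, weighted = TRUE)$z,
               stoufferCombine(z)$z, tolerance = 1e-12)
  # missing sites drop out; all-missing features report k = 0 and NA
  z[1, ] <- NA; z[2, 2:3] <- NA
  cmb <- stoufferCombine(z)
  expect_true(is.na(cmb$z[1]) && cmb$k[1] == 0)
  expect_equal(cmb$z[2], z[2, 1])
  expect_error(stoufferCombine(z, weighted = TRUE), "sample sizes")
})

test_that("Fisher combination reproduces the closed forms", {
  f1 <- fisherCombine(matrix(1, 1, 1))
  expect_equal(f1$statistic, 0)
  expect_equal(f1$p, 1)
  f2 <- fisherCombine(matrix(c(0.05, 0.05), 1))
  expect_equal(f2$statistic, -2 * (2 * log(0.05)), tolerance = 1e-12)
  expect_equal(f2$df, 4)
  # oracle: independent chi-square tail evaluation
  expect_equal(f2$p, pchisq(11.98293, df = 4, lower.tail = FALSE),
               tolerance = 1e-5)
  f3 <- fisherCombine(matrix(1, 1, 3))
  expect_equal(f3$statistic, 0)
  expect_equal(f3$df, 6)
  expect_equal(f3$p, 1)
  expect_error(fisherCombine(matrix(c(0.5, 1.5), 1)), "lie in")
  expect_warning(fisherCombine(matrix(c(0, 0.5), 1)), "clamped")
})

test_that("combined p-values are uniform under the global null", {
  set.seed(42)
  nf <- 10000
  z <- matrix(rnorm(nf * 4), nf, 4)
  p <- stoufferCombine(z)$p
  # two-sided p of a standard normal statistic is U(0,1); KS below the
  # 1% critical value 1.63/sqrt(n)
  ks <- suppressWarnings(ks.test(p, "punif"))$statistic
  expect_lt(unname(ks), 1.63 / sqrt(nf))
  pf <- fisherCombine(matrix(runif(nf * 3), nf, 3))$p
  ksf <- suppressWarnings(ks.test(pf, "punif"))$statistic
  expect_lt(unname(ksf), 1.63 / sqrt(nf))
})

test_that("Fisher and Stouffer rank rejections identically on symmetric sites", {
  set.seed(7)
  zi <- abs(rnorm(200))
  z <- cbind(zi, zi)              # two sites, equal positive Z
  st <- stoufferCombine(z)$z
  fi <- fisherCombine(2 * pnorm(-abs(z)))$statistic
  expect_equal(cor(rank(st), rank(fi)), 1)
})

test_that("per-site fitting stratifies, skips and tallies correctly", {
  set.seed(8)
  n <- 48
  site <- rep(c("SiteA", "SiteB", "SiteC"), times = c(20, 16, 12))
  cd <- data.frame(site_id = site,
                   subject_id = sprintf("%02d", 1:n),
                   Sex = c(sample(c("F", "M"), 36, TRUE), rep("F", 12)),
                   Dx = rep_len(0:1, n), stringsAsFactors = FALSE)
  cd$fID <- paste(cd$site_id, cd$subject_id, sep = "_")
  Y <- matrix(rnorm(20 * n), 20, n)
  Y[cbind(sample(20, 30, TRUE), sample(n, 30, TRUE))] <- NA
  vm <- voxelmeta:::newVoxelMatrix(Y, cd)

  # single-sex SiteC is rank-deficient for a Sex model and is skipped
  expect_warning(sr <- runPerSite(vm, modelSpec(Brain ~ Sex + Dx),
                                  minSiteN = 10), "rank-deficient")
  expect_setequal(names(sr), c("SiteA", "SiteB"))
  expect_identical(attr(sr, "skipped")$reason, "rank_deficient")

  # a model with a site term is rejected outright
  expect_error(runPerSite(vm, modelSpec(Brain ~ Dx + (1|Site))),
               "random site term")

  # per-site n maps sum to the mega n_obs map when subject sets coincide
  sr2 <- runPerSite(vm, modelSpec(Brain ~ Dx), minSiteN = 10)
  nSum <- Reduce(`+`, lapply(sr2, function(r) r@fit[, "n_obs"]))
  mega <- runMega(vm, modelSpec(Brain ~ Dx))
  expect_equal(unname(nSum), unname(mega@fit[, "n_obs"]))

  # sites below the minimum are excluded with a warning
  expect_warning(sr3 <- runPerSite(vm, modelSpec(Brain ~ Dx), minSiteN = 14),
                 "excluded")
  expect_setequal(names(sr3), c("SiteA", "SiteB"))
  expect_identical(attr(sr3, "skipped")$reason, "too_small")
})

test_that("meta combination is feature-wise consistent with site results", {
  set.seed(9)
  n <- 40
  cd <- data.frame(fID = sprintf("S%d_%02d", rep(1:2, each = 20), 1:n),
                   site_id = rep(c("SiteA", "SiteB"), each = 20),
                   subject_id = sprintf("%02d", 1:n),
                   Dx = rep_len(0:1, n), stringsAsFactors = FALSE)
  Y <- matrix(rnorm(15 * n), 15, n)
  Y[2, 1:20] <- NA                 # SiteA entirely missing at feature 2
  Y[3, ] <- NA                     # nobody observed at feature 3
  vm <- voxelmeta:::newVoxelMatrix(Y, cd)
  spec <- modelSpec(Brain ~ Dx)
  meta <- runMeta(vm, spec, minSiteN = 10)

  sr <- runPerSite(vm, spec, minSiteN = 10)
  # k map matches per-site contribution pattern
  expect_equal(unname(meta@k[1, "Dx"]), 2)
  expect_equal(unname(meta@k[2, "Dx"]), 1)
  expect_equal(unname(meta@k[3, "Dx"]), 0)
  expect_true(is.na(meta@statistic[3, "Dx"]))
  # single-contributing-site features equal that site's Z (weighted or not)
  expect_equal(meta@statistic[2, "Dx"], sr$SiteB@z[2, "Dx"],
               tolerance = 1e-10)
  # manual Stouffer at feature 1
  zz <- c(sr$SiteA@z[1, "Dx"], sr$SiteB@z[1, "Dx"])
  nn <- c(sr$SiteA@fit[1, "n_obs"], sr$SiteB@fit[1, "n_obs"])
  w <- sqrt(nn)
  expect_equal(unname(meta@statistic[1, "Dx"]),
               sum(w * zz) / sqrt(sum(w^2)), tolerance = 1e-10)

  fisher <- runMeta(vm, spec, method = "fisher", minSiteN = 10)
  expect_equal(unname(fisher@statistic[1, "Dx"]),
               -2 * sum(log(c(sr$SiteA@p[1, "Dx"], sr$SiteB@p[1, "Dx"]))),
               tolerance = 1e-10)
})
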