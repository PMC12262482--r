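test_that("segment plans partition features into near-equal ranges", {
  p <- planSegments(10, 3)
  expect_identical(p$end - p$start + 1L, c(4L, 3L, 3L))
  p1 <- planSegments(125000, 1)
  expect_identical(c(p1$start, p1$end), c(1L, 125000L))
  expect_error(planSegments(5, 6), "nSegments")

  # oracle: covered indices equal the full range, sizes differ by <= 1
  set.seed(4)
  for (i in 1:20) {
    nf <- sample(1:500, 1)
    ns <- sample(seq_len(nf), 1)
    pl <- planSegments(nf, ns)
    covered <- unlist(Map(seq, pl$start, pl$end))
    expect_identical(sort(covered), seq_len(nf))
    expect_lte(diff(range(pl$end - pl$start + 1L)), 1L)
  }
})

test_that("model specs classify estimators and reject random slopes", {
  s1 <- modelSpec("Brain ~ Age + Sex + Dx")
  expect_identical(s1@estimator, "ols")
  s2 <- modelSpec("Brain ~ Age + Sex + Dx + (1|Site)")
  expect_identical(s2@estimator, "mixed")
  expect_identical(s2@randomGroups, "Site")
  s3 <- modelSpec("Dx ~ Age + Brain", family = "binomial")
  expect_identical(s3@estimator, "glm")
  expect_error(modelSpec("Brain ~ Age + (Age|Site)"), "random intercepts")
  expect_error(modelSpec("Brain ~ Dx + (1|Site)", family = "binomial"),
               "gaussian")
})

test_that("single-feature OLS matches hand-computed least squares", {
  spec <- modelSpec(Brain ~ x)
  res <- fitFeature(c(1, 2, 3, 4), data.frame(x = c(0, 0, 1, 1)), spec,
                    minN = 4)
  expect_equal(unname(res$estimate), c(1.5, 2.0))
  # closed-form normal equations: RSS = 1, df = 2, s2 = 0.5
  X <- cbind(1, c(0, 0, 1, 1))
  or <- olsOracle(c(1, 2, 3, 4), X)
  expect_equal(unname(res$se), or$se, tolerance = 1e-12)
  expect_equal(unname(res$statistic), or$t, tolerance = 1e-12)
  expect_equal(unname(res$fit["residual_df"]), 2)
  expect_equal(unname(res$fit["sigma"]), sqrt(0.5))
})

test_that("degenerate and undersized features return NA with a reason", {
  spec <- modelSpec(Brain ~ x)
  d <- data.frame(x = rnorm(8))
  rConst <- fitFeature(rep(2, 8), d, spec)
  expect_identical(rConst$reason, "degenerate")
  expect_true(all(is.na(rConst$estimate)))
  rSmall <- fitFeature(rnorm(3), d[1:3, , drop = FALSE], spec)
  expect_identical(rSmall$reason, "insufficient_n")
  # collinear design
  d2 <- data.frame(x = rnorm(10)); d2$y2 <- 2 * d2$x
  rColl <- fitFeature(rnorm(10), d2, modelSpec(Brain ~ x + y2))
  expect_identical(rColl$reason, "degenerate")
})

test_that("engine equals closed-form least squares on random designs", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(8:20, 1)
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    cd <- data.frame(X)
    cd <- cbind(fID = sprintf("S_%02d", seq_len(n)), site_id = "S",
                subject_id = sprintf("%02d", seq_len(n)), cd)
    nf <- 6
    Y <- matrix(rnorm(nf * n), nf, n)
    Y[sample(length(Y), round(0.15 * length(Y)))] <- NA
    vm <- voxelmeta:::newVoxelMatrix(Y, cd)
    spec <- modelSpec(as.formula(paste("Brain ~",
                                       paste(colnames(X), collapse = "+"))))
    res <- runMega(vm, spec)
    for (f in seq_len(nf)) {
      obs <- which(!is.na(Y[f, ]))
      if (length(obs) < p + 1 + 3) {
        expect_identical(res@reasons[f], "insufficient_n")
        next
      }
      or <- olsOracle(Y[f, obs], cbind(1, X[obs, , drop = FALSE]))
      expect_equal(unname(res@estimate[f, ]), or$coef, tolerance = 1e-10)
      expect_equal(unname(res@se[f, ]), or$se, tolerance = 1e-10)
      expect_equal(unname(res@statistic[f, ]), or$t, tolerance = 1e-10)
      expect_equal(unname(res@fit[f, "residual_df"]), or$df)
      expect_equal(unname(res@fit[f, "n_obs"]), length(obs))
    }
  }
})

test_that("engine agrees with the single-feature reference path", {
  set.seed(12)
  cfg <- simConfig(nSubjects = 30, dims = c(4, 4, 4), radius = 1.5,
                   effect = 0.6, seed = 12)
  vm <- injectMissingness(simulateCohort(cfg), 0.2, seed = 3)
  spec <- modelSpec(Brain ~ Dx)
  res <- runMega(vm, spec)
  Y <- voxelValues(vm)
  cd <- as.data.frame(SummarizedExperiment::colData(vm))
  for (f in c(1, 17, 40, 64)) {
    obs <- is.finite(Y[f, ])
    ref <- fitFeature(Y[f, obs], cd[obs, , drop = FALSE], spec)
    expect_equal(unname(res@estimate[f, ]), unname(ref$estimate),
                 tolerance = 1e-10)
    expect_equal(unname(res@p[f, ]), unname(ref$p), tolerance = 1e-10)
    expect_equal(unname(res@z[f, ]), unname(ref$z), tolerance = 1e-8)
    expect_equal(unname(res@fit[f, c("AIC", "BIC", "logLik", "sigma", "R2")]),
                 unname(ref$fit[c("AIC", "BIC", "logLik", "sigma", "R2")]),
                 tolerance = 1e-8)
  }
})

test_that("results are invariant to segmentation and missingness-local", {
  set.seed(13)
  cfg <- simConfig(nSubjects = 25, dims = c(5, 5, 2), radius = 1,
                   effect = 0.5, seed = 13)
  vm <- injectMissingness(simulateCohort(cfg), 0.2, seed = 5)
  spec <- modelSpec(Brain ~ Dx)
  r1 <- runMega(vm, spec, nSegments = 1)
  r3 <- runMega(vm, spec, nSegments = 3)
  r7 <- runMega(vm, spec, nSegments = 7)
  expect_identical(r1@estimate, r3@estimate)
  expect_identical(r1@estimate, r7@estimate)
  expect_identical(r1@se, r7@se)
  expect_identical(r1@fit, r7@fit)
  expect_identical(r1@p, r7@p)

  # n_obs equals an independent per-voxel tally
  expect_equal(unname(r1@fit[, "n_obs"]),
               unname(rowSums(!is.na(voxelValues(vm)))))

  # a feature with zero missingness fits identically to the intact cohort
  intact <- simulateCohort(cfg)
  full <- runMega(intact, spec)
  # per-voxel MCAR removes the same count everywhere, so force one feature
  Y <- voxelValues(vm); Y[1, ] <- voxelValues(intact)[1, ]
  vm2 <- vm; SummarizedExperiment::assay(vm2, "values") <- Y
  r2 <- runMega(vm2, spec)
  expect_identical(r2@estimate[1, ], full@estimate[1, ])
  expect_identical(r2@se[1, ], full@se[1, ])
})

test_that("mixed models recover the site variance on two-site cohorts", {
  # oracle: simulation with known parameters; REML estimates of the
  # random-intercept variance average to the generating value
  set.seed(21)
  tau2 <- 0.5; nRep <- 120; nPerSite <- 30
  spec <- modelSpec(Brain ~ Dx + (1|Site))
  est <- numeric(nRep); zs <- numeric(nRep)
  for (r in seq_len(nRep)) {
    sites <- rep(c("A", "B", "C", "D"), each = nPerSite)
    off <- rnorm(4, 0, sqrt(tau2))[match(sites, c("A", "B", "C", "D"))]
    dx <- rep_len(0:1, length(sites))
    y <- 1 + 0.4 * dx + off + rnorm(length(sites))
    fit <- fitFeature(y, data.frame(Dx = dx, Site = sites), spec)
    est[r] <- fit$varcomp[["Site"]]
    zs[r] <- fit$z[["Dx"]]
  }
  se <- sd(est) / sqrt(nRep)
  expect_lt(abs(mean(est) - tau2), 3 * se + 0.02)
  # the Dx Wald statistic is centered on a clearly positive effect
  expect_gt(mean(zs), 1)
  # REML criterion and sigma are reported
  fit <- fitFeature(rnorm(40) + rep(rnorm(2), each = 20),
                    data.frame(Dx = rep_len(0:1, 40),
                               Site = rep(c("A", "B"), each = 20)), spec)
  expect_true(is.finite(fit$fit[["REML"]]))
  expect_true(is.finite(fit$fit[["sigma"]]))
})

test_that("GLM features fit by IRLS and report deviance-based fit", {
  set.seed(31)
  n <- 60
  x <- rnorm(n)
  pr <- plogis(-0.3 + 1.1 * x)
  y <- rbinom(n, 1, pr)
  spec <- modelSpec(Brain ~ x, family = "binomial")
  fit <- fitFeature(y, data.frame(x = x), spec)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$estimate), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$fit["AIC"]), AIC(ref), tolerance = 1e-6)
  expect_equal(unname(fit$fit["R2"]),
               1 - ref$deviance / ref$null.deviance, tolerance = 1e-8)
})

test_that("compiled maps reconstruct per-term statistics and n_obs", {
  cfg <- simConfig(nSubjects = 20, dims = c(4, 4, 3), radius = 1,
                   seed = 9)
  vm <- injectMissingness(simulateCohort(cfg), 0.25, seed = 2)
  res <- runMega(vm, modelSpec(Brain ~ Dx))
  dir <- file.path(tempdir(), "compile1")
  unlink(dir, recursive = TRUE)
  files <- compileResults(res, dir)
  for (k in c("estimate", "se", "statistic", "p", "z"))
    expect_true(file.exists(file.path(dir, paste0("Dx_", k, ".nii.gz"))))
  nmap <- readVolume(file.path(dir, "fit_n_obs.nii.gz"))$data
  # voxel sum of the n_obs map equals the total observed cells
  expect_equal(sum(nmap), sum(!is.na(voxelValues(vm))))
  zmap <- readVolume(file.path(dir, "Dx_z.nii.gz"))$data
  expect_equal(as.numeric(zmap[analysisMask(vm)]), unname(res@z[, "Dx"]),
               tolerance = 1e-6)
})

test_that("diagnostics count skip reasons", {
  Y <- rbind(rnorm(10), rep(1, 10), rnorm(10))
  Y[3, 1:8] <- NA
  cd <- data.frame(fID = sprintf("S_%d", 1:10), site_id = "S",
                   subject_id = as.character(1:10), x = rnorm(10))
  vm <- voxelmeta:::newVoxelMatrix(Y, cd)
  res <- runMega(vm, modelSpec(Brain ~ x))
  dc <- diagnosticCounts(res)
  expect_equal(unname(dc["fitted"]), 1)
  expect_equal(unname(dc["degenerate"]), 1)
  expect_equal(unname(dc["insufficient_n"]), 1)
})
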