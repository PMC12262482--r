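#' Parse a model specification
#'
#' Accepts standard formula syntax with the imaging feature as a placeholder
#' response, e.g. `Brain ~ Age + Sex + Dx` or
#' `Brain ~ Age + Sex + Dx + (1|Site)`. Random effects are restricted to
#' random intercepts; random slopes raise an error. The estimator follows
#' from the formula and family: Gaussian fixed-effects models use closed-form
#' least squares, non-Gaussian families use IRLS via [stats::glm()], and
#' formulas with a random intercept use REML via [lme4::lmer()].
#'
#' @param formula model formula or a character string.
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @return A [ModelSpec-class].
#' @examples
#' modelSpec("Brain ~ Age + Sex + Dx + (1|Site)")
#' @export
modelSpec <- function(formula, family = c("gaussian", "binomial", "poisson")) {
  family <- match.arg(family)
  if (is.character(formula)) formula <- as.formula(formula)
  bars <- lme4::findbars(formula)
  groups <- character()
  if (length(bars)) {
    for (b in bars) {
      if (!identical(b[[2L]], 1))
        stop("only random intercepts are supported; offending term: (",
             deparse(b), ")")
      groups <- c(groups, deparse(b[[3L]]))
    }
  }
  fixed <- lme4::nobars(formula)
  estimator <- if (length(groups)) "mixed"
               else if (family == "gaussian") "ols" else "glm"
  if (estimator == "mixed" && family != "gaussian")
    stop("random intercepts are supported for the gaussian family only")
  resp <- if (length(formula) == 3L) deparse(formula[[2L]]) else "Brain"
  new("ModelSpec", formula = formula, fixedFormula = fixed, response = resp,
      randomGroups = groups, family = family, estimator = estimator)
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", deparse(object@formula), "\n  family:", object@family,
      "| estimator:", object@estimator, "\n")
})

# variables the model needs from the covariate table
modelVariables <- function(spec) {
  setdiff(unique(c(all.vars(spec@fixedFormula), spec@randomGroups)),
          spec@response)
}

# fixed-effect design matrix on a covariate data.frame; text columns get
# standard treatment contrasts (reference = lexicographically first level)
fixedDesign <- function(spec, data) {
  rhs <- spec@fixedFormula
  rhs <- if (length(rhs) == 3L) rhs[-2L] else rhs
  data <- as.data.frame(data)
  for (v in all.vars(rhs))
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
  model.matrix(rhs, data)
}

cleanTermNames <- function(x) sub("^\\(Intercept\\)$", "intercept", x)

#' Plan contiguous feature segments
#'
#' Partitions `[1, nFeatures]` into `nSegments` contiguous ranges whose
#' sizes differ by at most one, for memory-bounded chunked fitting.
#'
#' @param nFeatures total feature count.
#' @param nSegments number of segments, `1 <= nSegments <= nFeatures`.
#' @return `data.frame` with 1-based inclusive `start` and `end` columns.
#' @examples
#' planSegments(10, 3)   # sizes 4, 3, 3
#' @export
planSegments <- function(nFeatures, nSegments) {
  nFeatures <- as.integer(nFeatures); nSegments <- as.integer(nSegments)
  if (nSegments < 1L || nSegments > nFeatures)
    stop("nSegments must lie in [1, nFeatures]; got ", nSegments, " for ",
         nFeatures, " features")
  size <- rep(nFeatures %/% nSegments, nSegments)
  extra <- nFeatures %% nSegments
  if (extra > 0L) size[seq_len(extra)] <- size[seq_len(extra)] + 1L
  end <- cumsum(size)
  data.frame(start = c(1L, head(end, -1L) + 1L), end = end)
}

#' Build the subject-by-feature matrix from images
#'
#' Reads every volume in the manifest, checks that it sits on the analysis
#' grid (dims exactly, affine within 1e-4), flattens it over the analysis
#' mask with per-subject missingness, and assembles a [VoxelMatrix-class]
#' whose columns follow the covariate table's row order. Features with zero
#' observed subjects are retained; they yield missing results downstream.
#'
#' @param manifest from [discoverImages()].
#' @param table subject table from [loadSubjectTable()]; every manifest fID
#'   must appear in it.
#' @param masks a [MaskStack-class] on the analysis grid.
#' @param zeroSentinel passed to [flattenVolume()].
#' @return A [VoxelMatrix-class].
#' @export
buildVoxelMatrix <- function(manifest, table, masks, zeroSentinel = FALSE) {
  absent <- setdiff(manifest$fID, table$fID)
  if (length(absent))
    stop("manifest fIDs absent from the covariate table: ",
         paste(head(absent, 5L), collapse = ", "))
  keep <- table$fID %in% manifest$fID
  table <- table[keep, , drop = FALSE]
  paths <- manifest$path[match(table$fID, manifest$fID)]
  nf <- sum(masks@analysis)
  vals <- matrix(NA_real_, nrow = nf, ncol = nrow(table))
  for (s in seq_along(paths)) {
    v <- readVolume(paths[s])
    if (!sameGrid(v$grid, masks@grid))
      stop("volume off the analysis grid: ", paths[s])
    vals[, s] <- flattenVolume(v$data, masks, fID = table$fID[s],
                               zeroSentinel = zeroSentinel)
  }
  newVoxelMatrix(vals, table, grid = masks@grid, mask = masks@analysis)
}

# internal constructor shared by the image, CSV and simulation paths
newVoxelMatrix <- function(values, table, grid = NULL, mask = NULL,
                           featureNames = NULL) {
  coords <- if (!is.null(mask)) maskCoords(mask)
            else data.frame(feature = featureNames %||% seq_len(nrow(values)))
  se <- SummarizedExperiment(
    assays = list(values = values),
    rowData = DataFrame(coords),
    colData = DataFrame(table, row.names = table$fID))
  out <- new("VoxelMatrix", se)
  metadata(out)$grid <- grid
  metadata(out)$mask <- mask
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a plain subject-by-feature CSV matrix
#'
#' Alternative input path for non-image features: a CSV with an `fID` column
#' and one numeric column per feature (empty cells = missing).
#'
#' @param path CSV file.
#' @param table subject table; every matrix fID must appear in it.
#' @return A [VoxelMatrix-class] without grid geometry (results compile to
#'   CSV rather than NIfTI).
#' @export
loadFeatureMatrix <- function(path, table) {
  m <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"fID" %in% names(m)) stop("feature matrix needs an fID column")
  absent <- setdiff(m$fID, table$fID)
  if (length(absent))
    stop("matrix fIDs absent from the covariate table: ",
         paste(head(absent, 5L), collapse = ", "))
  table <- table[table$fID %in% m$fID, , drop = FALSE]
  feats <- setdiff(names(m), "fID")
  vals <- t(as.matrix(m[match(table$fID, m$fID), feats, drop = FALSE]))
  newVoxelMatrix(unname(vals), table, featureNames = feats)
}

#' Fit the model at a single feature (reference path)
#'
#' Available-case fit for one feature: `y` and `data` must already be
#' restricted to the subjects observed at this feature. This is the
#' single-feature reference implementation that the vectorized engine in
#' [runMega()] is tested against; it is also the production path for GLM and
#' mixed estimators.
#'
#' Features with `n < p_fixed + 3`, zero response variance, a rank-deficient
#' design, or a non-converging mixed fit return all-`NA` statistics with the
#' reason (`"insufficient_n"`, `"degenerate"`, `"nonconverged"`) — never
#' fabricated zeros.
#'
#' @param y numeric response values (observed subjects only).
#' @param data covariate data.frame, rows matching `y`.
#' @param spec a [ModelSpec-class].
#' @param minN minimum sample size; defaults to `p_fixed + 3`.
#' @return List with `terms`, `estimate`, `se`, `statistic`, `p`, `z`,
#'   `fit` (named fit measures), `reason` (`NA` if fitted) and, for mixed
#'   models, `varcomp` (random-intercept and residual variances).
#' @export
fitFeature <- function(y, data, spec, minN = NULL) {
  data <- as.data.frame(data)
  ok <- is.finite(y)
  y <- y[ok]; data <- data[ok, , drop = FALSE]
  X <- fixedDesign(spec, data)
  termNames <- cleanTermNames(colnames(X))
  p <- ncol(X)
  if (is.null(minN)) minN <- p + 3L
  blank <- function(reason) {
    na <- setNames(rep(NA_real_, p), termNames)
    fit <- emptyFitRow()
    fit["n_obs"] <- length(y)
    list(terms = termNames, estimate = na, se = na, statistic = na, p = na,
         z = na, fit = fit, reason = reason)
  }
  n <- length(y)
  if (n < minN) return(blank("insufficient_n"))
  if (var(y) == 0) return(blank("degenerate"))

  if (spec@estimator == "ols") {
    if (qr(X)$rank < p) return(blank("degenerate"))
    fm <- lm(y ~ X - 1)
    est <- setNames(coef(fm), termNames)
    sev <- setNames(sqrt(diag(vcov(fm))), termNames)
    tv <- est / sev
    df <- n - p
    lp <- logPFromT(tv, df)
    sm <- summary(fm)
    fit <- emptyFitRow()
    fit[c("n_obs", "df", "residual_df")] <- c(n, p, df)
    fit[c("AIC", "BIC", "logLik")] <- c(AIC(fm), BIC(fm), as.numeric(logLik(fm)))
    fit["sigma"] <- sm$sigma
    fit["R2"] <- 1 - sum(fm$residuals^2) / sum((y - mean(y))^2)
    list(terms = termNames, estimate = est, se = sev, statistic = tv,
         p = setNames(exp(lp), termNames),
         z = setNames(signedZFromLogP(lp, est), termNames),
         fit = fit, reason = NA_character_)
  } else if (spec@estimator == "glm") {
    if (qr(X)$rank < p) return(blank("degenerate"))
    dat <- data; dat[[spec@response]] <- y
    fam <- get(spec@family, mode = "function")()
    fm <- tryCatch(
      glm(spec@fixedFormula, data = dat, family = fam,
          control = list(epsilon = 1e-8, maxit = 100)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fm) || !fm$converged) return(blank("nonconverged"))
    cf <- summary(fm)$coefficients
    est <- setNames(cf[, 1L], termNames)
    sev <- setNames(cf[, 2L], termNames)
    zv <- est / sev
    lp <- logPFromZ(zv)
    fit <- emptyFitRow()
    fit[c("n_obs", "df", "residual_df")] <- c(n, p, fm$df.residual)
    fit[c("AIC", "BIC", "logLik")] <- c(AIC(fm), BIC(fm), as.numeric(logLik(fm)))
    fit["R2"] <- 1 - fm$deviance / fm$null.deviance
    list(terms = termNames, estimate = est, se = sev, statistic = zv,
         p = setNames(exp(lp), termNames),
         z = setNames(signedZFromLogP(lp, est), termNames),
         fit = fit, reason = NA_character_)
  } else {
    dat <- data
    for (g in spec@randomGroups) dat[[g]] <- factor(dat[[g]])
    dat[[spec@response]] <- y
    fm <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(spec@formula, data = dat, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore")))),
      error = function(e) NULL)
    if (is.null(fm)) return(blank("nonconverged"))
    est <- lme4::fixef(fm)
    sev <- sqrt(diag(as.matrix(vcov(fm))))
    names(est) <- names(sev) <- termNames
    zv <- est / sev            # Wald statistic on the standard normal
    lp <- logPFromZ(zv)
    vc <- as.data.frame(lme4::VarCorr(fm))
    varcomp <- setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual", vc$grp))
    fit <- emptyFitRow()
    fit[c("n_obs", "df", "residual_df")] <- c(n, p, n - p)
    fit[c("AIC", "BIC", "logLik")] <- c(AIC(fm), BIC(fm), as.numeric(logLik(fm)))
    fit["REML"] <- lme4::REMLcrit(fm)
    fit["sigma"] <- sigma(fm)
    list(terms = termNames, estimate = est, se = sev, statistic = zv,
         p = setNames(exp(lp), termNames),
         z = setNames(signedZFromLogP(lp, est), termNames),
         fit = fit, reason = NA_character_, varcomp = varcomp)
  }
}

#' Run the mega-analytic mass-univariate engine
#'
#' Fits `spec` independently at every feature of a [VoxelMatrix-class],
#' using only the subjects observed at that feature, in contiguous segments
#' (see [planSegments()]). Subjects missing a model covariate are dropped for
#' this model (and only this model). Results are a deterministic ordered
#' concatenation of per-segment results, so outputs do not depend on the
#' segmentation.
#'
#' Gaussian fixed-effects models use a compiled closed-form least-squares
#' kernel; GLM and mixed models call [fitFeature()] per feature.
#'
#' @param vm a [VoxelMatrix-class].
#' @param spec a [ModelSpec-class].
#' @param nSegments number of contiguous feature segments.
#' @param minN per-feature minimum sample size; default `p_fixed + 3`.
#' @return A [VoxelResults-class]. `failureReasons()` distinguishes
#'   `insufficient_n`, `degenerate` and `nonconverged` features.
#' @export
runMega <- function(vm, spec, nSegments = 1L, minN = NULL) {
  stopifnot(is(vm, "VoxelMatrix"), is(spec, "ModelSpec"))
  cd <- as.data.frame(colData(vm))
  vars <- modelVariables(spec)
  absent <- setdiff(vars, names(cd))
  if (length(absent))
    stop("model terms without a covariate column: ",
         paste(absent, collapse = ", "))
  keep <- complete.cases(cd[, vars, drop = FALSE])
  cd <- cd[keep, , drop = FALSE]
  Y <- assay(vm, "values")[, keep, drop = FALSE]
  X <- fixedDesign(spec, cd)
  termNames <- cleanTermNames(colnames(X))
  p <- ncol(X)
  if (is.null(minN)) minN <- p + 3L
  nf <- nrow(Y)
  plan <- planSegments(nf, nSegments)

  mk <- function() matrix(NA_real_, nf, p, dimnames = list(NULL, termNames))
  estimate <- mk(); se <- mk(); statistic <- mk(); pmat <- mk(); zmat <- mk()
  fit <- matrix(NA_real_, nf, length(fitMeasureNames()),
                dimnames = list(NULL, fitMeasureNames()))
  reasons <- rep(NA_character_, nf)

  if (spec@estimator == "ols") {
    for (sgi in seq_len(nrow(plan))) {
      rows <- plan$start[sgi]:plan$end[sgi]
      blk <- .olsFitBlock(Y[rows, , drop = FALSE], X, as.integer(minN))
      ok <- blk$reason == 0L
      estimate[rows, ] <- blk$estimate
      se[rows, ] <- blk$se
      n <- blk$nobs
      fit[rows, "n_obs"] <- n
      reasons[rows][blk$reason == 1L] <- "insufficient_n"
      reasons[rows][blk$reason == 2L] <- "degenerate"
      if (any(ok)) {
        r <- rows[ok]
        tv <- blk$estimate[ok, , drop = FALSE] / blk$se[ok, , drop = FALSE]
        statistic[r, ] <- tv
        df <- n[ok] - p
        lp <- logPFromT(tv, df)
        pmat[r, ] <- exp(lp)
        zmat[r, ] <- signedZFromLogP(lp, blk$estimate[ok, , drop = FALSE])
        rss <- blk$rss[ok]; nn <- n[ok]
        ll <- -nn / 2 * (log(2 * pi) + log(rss / nn) + 1)
        fit[r, "df"] <- p
        fit[r, "residual_df"] <- df
        fit[r, "logLik"] <- ll
        fit[r, "AIC"] <- -2 * ll + 2 * (p + 1)
        fit[r, "BIC"] <- -2 * ll + log(nn) * (p + 1)
        fit[r, "sigma"] <- sqrt(rss / df)
        fit[r, "R2"] <- 1 - rss / blk$sst[ok]
      }
    }
  } else {
    cdf <- as.data.frame(cd)
    for (sgi in seq_len(nrow(plan))) {
      for (f in plan$start[sgi]:plan$end[sgi]) {
        y <- Y[f, ]
        obs <- is.finite(y)
        res <- fitFeature(y[obs], cdf[obs, , drop = FALSE], spec, minN = minN)
        estimate[f, ] <- res$estimate
        se[f, ] <- res$se
        statistic[f, ] <- res$statistic
        pmat[f, ] <- res$p
        zmat[f, ] <- res$z
        fit[f, ] <- res$fit
        fit[f, "n_obs"] <- sum(obs)
        reasons[f] <- res$reason
      }
    }
  }
  new("VoxelResults", terms = termNames, estimate = estimate, se = se,
      statistic = statistic, p = pmat, z = zmat, fit = fit,
      reasons = reasons, coords = featureCoords(vm), model = spec,
      grid = metadata(vm)$grid, mask = metadata(vm)$mask)
}

#' Compile results into statistic and fit-measure maps
#'
#' Writes one NIfTI volume per (term, statistic kind) — estimate, standard
#' error, statistic, p, signed Z — plus one per fit measure (`n_obs` always
#' included), named `<term>_<kind>.nii.gz` and `fit_<measure>.nii.gz`.
#' Features without results carry `NA` in every map. For grid-less (CSV)
#' matrices the same tables are written as CSV instead.
#'
#' @param res a [VoxelResults-class].
#' @param dir output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
compileResults <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  kinds <- c(estimate = "estimate", se = "se", statistic = "statistic",
             p = "p", z = "z")
  safe <- function(x) gsub("[^A-Za-z0-9._-]", "", x)
  if (is.null(res@grid)) {
    for (term in res@terms) {
      f <- file.path(dir, paste0(safe(term), "_stats.csv"))
      write.csv(cbind(res@coords, termStats(res, term)), f, row.names = FALSE)
      files <- c(files, f)
    }
    f <- file.path(dir, "fit_measures.csv")
    write.csv(cbind(res@coords, as.data.frame(res@fit)), f, row.names = FALSE)
    return(invisible(c(files, f)))
  }
  for (term in res@terms) {
    for (k in names(kinds)) {
      f <- file.path(dir, paste0(safe(term), "_", kinds[[k]], ".nii.gz"))
      reconstructMap(slot(res, k)[, term], res@grid, res@mask, file = f)
      files <- c(files, f)
    }
  }
  for (m in colnames(res@fit)) {
    if (all(is.na(res@fit[, m])) && m != "n_obs") next
    f <- file.path(dir, paste0("fit_", m, ".nii.gz"))
    reconstructMap(res@fit[, m], res@grid, res@mask, file = f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Summarize per-feature failure reasons
#'
#' @param res a [VoxelResults-class].
#' @return Named integer vector of counts by reason (fitted features under
#'   `"fitted"`).
#' @export
diagnosticCounts <- function(res) {
  r <- res@reasons
  out <- c(fitted = sum(is.na(r)), table(r))
  out
}
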