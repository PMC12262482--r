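#' Stouffer combination of site-level signed Z values
#'
#' Combines per-site signed Z statistics feature-wise:
#' `Z_meta = sum(w_i z_i) / sqrt(sum(w_i^2))`, with `w_i = 1` in the
#' unweighted case (so `Z_meta = sum(z_i)/sqrt(k)`), `w_i = sqrt(n_i)` for
#' the default sample-size weighting, or `w_i = n_i` when
#' `weightType = "n"`. Sites missing at a feature simply drop out; features
#' with no contributing site are `NA` with `k = 0`. The combined two-sided p
#' comes from the standard normal, with the sign retained in `z`.
#'
#' @param z numeric matrix (features x sites) of signed Z values, or a
#'   vector for a single feature.
#' @param n matching matrix/vector of per-site observed sample sizes
#'   (required when `weighted`).
#' @param weighted use sample-size weights.
#' @param weightType `"sqrt_n"` (standard) or `"n"`.
#' @return `data.frame` with `z`, `p` (two-sided) and `k` per feature.
#' @examples
#' stoufferCombine(matrix(c(1.96, 1.96), 1))          # z = 2.772
#' stoufferCombine(matrix(c(1, 2), 1), matrix(c(100, 400), 1),
#'                 weighted = TRUE)                    # z = 2.236
#' @export
stoufferCombine <- function(z, n = NULL, weighted = FALSE,
                            weightType = c("sqrt_n", "n")) {
  weightType <- match.arg(weightType)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (!is.null(n) && is.null(dim(n))) n <- matrix(n, nrow = 1L)
  ok <- is.finite(z)
  if (weighted) {
    if (is.null(n)) stop("weighted combination needs per-site sample sizes")
    w <- if (weightType == "sqrt_n") sqrt(n) else n
  } else {
    w <- array(1, dim(z))
  }
  w[!ok] <- 0
  z0 <- z; z0[!ok] <- 0
  k <- rowSums(ok)
  num <- rowSums(w * z0)
  den <- sqrt(rowSums(w * w))
  zc <- ifelse(k > 0L, num / den, NA_real_)
  lp <- logPFromZ(zc)
  data.frame(z = zc, p = exp(lp), k = k)
}

#' Fisher combination of site-level p-values
#'
#' `X^2 = -2 sum(log p_i)` on `df = 2k` degrees of freedom; the combined p
#' is the upper chi-square tail. Fisher's method is direction-blind: it is
#' applied to two-sided p-values. Zero p-values are clamped to the smallest
#' positive normal double with a warning.
#'
#' @param p matrix (features x sites) of p-values in (0, 1], or a vector
#'   for a single feature.
#' @return `data.frame` with `statistic` (X^2), `df`, `p`, `k`.
#' @examples
#' fisherCombine(matrix(c(0.05, 0.05), 1))   # X^2 = 11.98, df = 4
#' @export
fisherCombine <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  if (any(p[is.finite(p)] < 0 | p[is.finite(p)] > 1))
    stop("p-values must lie in [0, 1]")
  if (any(p[is.finite(p)] == 0)) {
    warning("zero p-values clamped to .Machine$double.xmin")
    p[is.finite(p) & p == 0] <- .Machine$double.xmin
  }
  ok <- is.finite(p)
  lp <- log(p); lp[!ok] <- 0
  k <- rowSums(ok)
  x2 <- -2 * rowSums(lp)
  df <- 2L * k
  pc <- ifelse(k > 0L, pchisq(x2, df = df, lower.tail = FALSE), NA_real_)
  x2[k == 0L] <- NA_real_
  data.frame(statistic = x2, df = df, p = pc, k = k)
}

#' Fit the model independently within each site
#'
#' Runs the mass-univariate engine ([runMega()]) on each site's subjects
#' separately. The model must contain no site term — site is the
#' stratification variable. Sites below `minSiteN` subjects are excluded
#' with a warning; sites whose design is rank-deficient for this model
#' (e.g. a single-sex site with Sex in the model) are skipped entirely,
#' with the reason logged.
#'
#' @param vm a [VoxelMatrix-class] whose `colData` contains `site_id`.
#' @param spec a fixed-effects [ModelSpec-class].
#' @param minSiteN minimum subjects for a site to contribute (default 10).
#' @param nSegments segments per site fit.
#' @return Named list of [VoxelResults-class], one per retained site, with
#'   a `"skipped"` attribute (`data.frame` of site, reason).
#' @export
runPerSite <- function(vm, spec, minSiteN = 10L, nSegments = 1L) {
  if (length(spec@randomGroups))
    stop("per-site models must not contain a random site term")
  cd <- as.data.frame(colData(vm))
  if (!"site_id" %in% names(cd)) stop("colData lacks a site_id column")
  sites <- sort(unique(cd$site_id))
  out <- list()
  skipped <- data.frame(site = character(), reason = character())
  for (s in sites) {
    sel <- cd$site_id == s
    if (sum(sel) < minSiteN) {
      warning("site ", s, " excluded: ", sum(sel), " < ", minSiteN, " subjects")
      skipped <- rbind(skipped, data.frame(site = s, reason = "too_small"))
      next
    }
    sub <- cd[sel, , drop = FALSE]
    vars <- modelVariables(spec)
    cc <- complete.cases(sub[, vars, drop = FALSE])
    X <- tryCatch(fixedDesign(spec, sub[cc, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(X) || qr(X)$rank < ncol(X)) {
      warning("site ", s, " skipped: rank-deficient design for this model")
      skipped <- rbind(skipped, data.frame(site = s, reason = "rank_deficient"))
      next
    }
    out[[s]] <- runMega(vm[, sel], spec, nSegments = nSegments)
  }
  if (!length(out)) stop("no site met the inclusion rules")
  attr(out, "skipped") <- skipped
  out
}

#' Meta-analysis: site-wise fits plus feature-wise combination
#'
#' Fits `spec` per site via [runPerSite()], then combines site-level results
#' feature-wise for every model term: Stouffer's method (default, optionally
#' sample-size weighted with `w = sqrt(n)`) on signed Z values, or Fisher's
#' method on two-sided p-values. `k` tracks the number of sites contributing
#' at each feature; a site missing at a feature drops out there only.
#'
#' @param vm a [VoxelMatrix-class] with `site_id` in `colData`.
#' @param spec fixed-effects [ModelSpec-class].
#' @param method `"stouffer"` or `"fisher"`.
#' @param weighted sample-size weighting (Stouffer only).
#' @param weightType `"sqrt_n"` or `"n"`.
#' @param minSiteN minimum site size.
#' @param nSegments segments per site fit.
#' @return A [MetaResults-class].
#' @export
runMeta <- function(vm, spec, method = c("stouffer", "fisher"),
                    weighted = TRUE, weightType = "sqrt_n", minSiteN = 10L,
                    nSegments = 1L) {
  method <- match.arg(method)
  siteRes <- runPerSite(vm, spec, minSiteN = minSiteN, nSegments = nSegments)
  sites <- names(siteRes)
  terms <- siteRes[[1L]]@terms
  nf <- nrow(siteRes[[1L]]@estimate)
  siteN <- vapply(siteRes, function(r) r@fit[, "n_obs"], numeric(nf))
  if (is.null(dim(siteN))) siteN <- matrix(siteN, nrow = nf)
  colnames(siteN) <- sites
  mk <- function() matrix(NA_real_, nf, length(terms),
                          dimnames = list(NULL, terms))
  stat <- mk(); pm <- mk(); km <- mk()
  for (term in terms) {
    if (method == "stouffer") {
      zmat <- vapply(siteRes, function(r) r@z[, term], numeric(nf))
      if (is.null(dim(zmat))) zmat <- matrix(zmat, nrow = nf)
      cmb <- stoufferCombine(zmat, siteN, weighted = weighted,
                             weightType = weightType)
      stat[, term] <- cmb$z; pm[, term] <- cmb$p; km[, term] <- cmb$k
    } else {
      pmat <- vapply(siteRes, function(r) r@p[, term], numeric(nf))
      if (is.null(dim(pmat))) pmat <- matrix(pmat, nrow = nf)
      cmb <- fisherCombine(pmat)
      stat[, term] <- cmb$statistic; pm[, term] <- cmb$p; km[, term] <- cmb$k
    }
  }
  siteSummary <- data.frame(
    site = sites,
    n_subjects = vapply(siteRes, function(r) max(r@fit[, "n_obs"], na.rm = TRUE),
                        numeric(1)),
    features_contributed = vapply(siteRes, function(r) sum(is.na(r@reasons)),
                                  numeric(1)))
  new("MetaResults", method = method,
      weighted = weighted && method == "stouffer", terms = terms,
      statistic = stat, p = pm, k = km, sites = siteSummary, siteN = siteN,
      coords = siteRes[[1L]]@coords, grid = siteRes[[1L]]@grid,
      mask = siteRes[[1L]]@mask)
}

#' Write meta-analytic maps
#'
#' One volume per term for the combined statistic (Z or X^2), combined p and
#' contributing-site count `k`, plus a per-site CSV summary.
#'
#' @param meta a [MetaResults-class].
#' @param dir output directory.
#' @return Written file paths, invisibly.
#' @export
compileMetaResults <- function(meta, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  safe <- function(x) gsub("[^A-Za-z0-9._-]", "", x)
  statName <- if (meta@method == "stouffer") "z" else "chisq"
  files <- character()
  for (term in meta@terms) {
    for (k in c("statistic", "p", "k")) {
      nm <- if (k == "statistic") statName else k
      f <- file.path(dir, paste0(safe(term), "_meta_", nm, ".nii.gz"))
      if (is.null(meta@grid)) {
        f <- sub("\\.nii\\.gz$", ".csv", f)
        write.csv(cbind(meta@coords, value = slot(meta, k)[, term]), f,
                  row.names = FALSE)
      } else {
        reconstructMap(slot(meta, k)[, term], meta@grid, meta@mask, file = f)
      }
      files <- c(files, f)
    }
  }
  f <- file.path(dir, "site_summary.csv")
  write.csv(meta@sites, f, row.names = FALSE)
  invisible(c(files, f))
}
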