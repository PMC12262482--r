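#' Spherical ground-truth signal mask
#'
#' Lattice sphere: voxel (i,j,k) belongs to the signal iff its Euclidean
#' distance to `center` is *strictly* less than `radius`. The strict rule is
#' deliberate: for radius 4 it contains 251 lattice points (the benchmark's
#' signal count), whereas `<=` would give 257.
#'
#' @param dims grid dimensions.
#' @param center sphere center, 1-based voxel coordinates (default the
#'   central voxel `floor(dims/2) + 1`; an integer center is what makes the
#'   radius-4 lattice count come out at 251).
#' @param radius radius in voxels; `<= 0` yields an empty mask with a
#'   warning.
#' @return Logical array of `dims`.
#' @examples
#' sum(makeSignalMask(c(50, 50, 50), radius = 4))   # 251
#' sum(makeSignalMask(c(9, 9, 9), radius = 1))      # 1
#' @export
makeSignalMask <- function(dims, center = floor(dims / 2) + 1, radius = 4) {
  if (radius <= 0) {
    warning("radius <= 0: empty signal mask")
    return(array(FALSE, dims))
  }
  if (any(center - radius < 0) || any(center + radius > dims + 1))
    stop("sphere does not fit inside the grid")
  di <- (seq_len(dims[1]) - center[1])^2
  dj <- (seq_len(dims[2]) - center[2])^2
  dk <- (seq_len(dims[3]) - center[3])^2
  d2 <- outer(outer(di, dj, `+`), dk, `+`)
  array(d2 < radius^2, dims)
}

#' Simulate a synthetic case-control cohort
#'
#' Generates `nSubjects` volumes of iid Gaussian noise (`mu`, `sigma`),
#' assigns exactly `round(prevalence * n)` randomly chosen subjects as cases
#' (`Dx = 1`), and adds `effect` at every signal voxel for cases only —
#' with unit noise an additive shift of 0.2 realizes Cohen's d = 0.2.
#' Fully reproducible from `config@seed`.
#'
#' @param config a [SimConfig-class].
#' @return A [VoxelMatrix-class] over the whole grid (analysis mask
#'   all-`TRUE`) whose `colData` holds `Dx`, with the ground-truth signal
#'   mask in `metadata(.)$truth` and the config in `metadata(.)$config`.
#' @export
simulateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nSubjects
  dims <- config@dims
  nf <- prod(dims)
  truth <- makeSignalMask(dims, config@center, config@radius)
  vals <- matrix(rnorm(as.double(nf) * n, mean = config@mu, sd = config@sigma),
                 nrow = nf, ncol = n)
  nCase <- round(config@prevalence * n)
  dx <- integer(n)
  dx[sample.int(n, nCase)] <- 1L
  if (any(truth) && nCase > 0)
    vals[which(truth), dx == 1L] <-
      vals[which(truth), dx == 1L] + config@effect
  table <- data.frame(fID = sprintf("Sim_%04d", seq_len(n)),
                      site_id = "Sim",
                      subject_id = sprintf("%04d", seq_len(n)),
                      Dx = dx, stringsAsFactors = FALSE)
  mask <- array(TRUE, dims)
  vm <- newVoxelMatrix(vals, table, grid = voxelGrid(dims), mask = mask)
  metadata(vm)$truth <- truth
  metadata(vm)$config <- config
  metadata(vm)$missingness <- 0
  vm
}

#' Inject per-voxel MCAR missingness
#'
#' At every voxel independently, a uniformly random subset of exactly
#' `round(m * n)` subjects is marked missing, so each voxel's observed n is
#' exactly `(1-m) * n` (missing completely at random, per voxel). With
#' `listwise = TRUE` whole subjects are deleted instead, making all voxels
#' share one subject subset.
#'
#' @param vm a [VoxelMatrix-class].
#' @param m missingness fraction in `[0, 1]`; `0` returns `vm` unchanged,
#'   `1` empties every voxel (downstream results and metrics become
#'   missing, not zero).
#' @param seed RNG seed for the missingness pattern.
#' @param listwise delete whole subjects rather than per-voxel cells.
#' @return A [VoxelMatrix-class] with `NA` at the removed cells.
#' @export
injectMissingness <- function(vm, m, seed = 1L, listwise = FALSE) {
  stopifnot(m >= 0, m <= 1)
  if (m == 0) return(vm)
  vals <- assay(vm, "values")
  n <- ncol(vals)
  k <- round(m * n)
  if (k > 0) {
    set.seed(seed)
    if (listwise) {
      vals[, sample.int(n, k)] <- NA_real_
    } else {
      for (f in seq_len(nrow(vals)))
        vals[f, sample.int(n, k)] <- NA_real_
    }
  }
  out <- vm
  SummarizedExperiment::assay(out, "values") <- vals
  metadata(out)$missingness <- m
  out
}

#' Score a statistic map against the ground truth by ROC
#'
#' Ranks voxels by the signed statistic (one-sided, cases > controls
#' direction). AUC is the rank-sum (Mann-Whitney) probability that a random
#' signal voxel outranks a random null voxel, ties counted half.
#' Sensitivity at the target FPR is the fraction of signal voxels exceeding
#' the empirical `(1 - targetFpr)` quantile of null-voxel statistics.
#'
#' @param stat numeric vector of per-voxel statistics (NA allowed).
#' @param truth logical vector of signal membership, same length.
#' @param targetFpr target false positive rate (default 0.05).
#' @return List with `auc`, `sensitivity`, `threshold`, `curve`
#'   (`data.frame` of FPR/TPR points, monotone in both coordinates),
#'   `nSignal`, `nNull`. Metrics are `NA` when no finite statistic exists
#'   on either side.
#' @export
scoreROC <- function(stat, truth, targetFpr = 0.05) {
  stopifnot(length(stat) == length(truth))
  ok <- is.finite(stat)
  s <- stat[ok]; tr <- truth[ok]
  nS <- sum(tr); nN <- sum(!tr)
  if (nS < 1L || nN < 1L)
    return(list(auc = NA_real_, sensitivity = NA_real_,
                threshold = NA_real_, curve = NULL,
                nSignal = nS, nNull = nN))
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[tr]) - nS * (nS + 1) / 2) / (as.double(nS) * nN)
  thr <- quantile(s[!tr], 1 - targetFpr, names = FALSE)
  sens <- mean(s[tr] > thr)
  ord <- order(s, decreasing = TRUE)
  curve <- data.frame(fpr = cumsum(!tr[ord]) / nN,
                      tpr = cumsum(tr[ord]) / nS)
  list(auc = auc, sensitivity = sens, threshold = thr, curve = curve,
       nSignal = nS, nNull = nN)
}

#' Run the benchmark at one missingness level
#'
#' Simulates the cohort (or reuses a supplied one), injects per-voxel MCAR
#' missingness at level `m`, fits the two-group model `Brain ~ Dx` at every
#' voxel on the observed subjects (available-case) — or only at voxels with
#' complete data (complete-case) — and scores the signed Dx statistic map
#' against the ground truth.
#'
#' Under complete-case analysis, any voxel with at least one missing
#' subject is dropped: AUC is computed over the retained voxels only, while
#' sensitivity counts dropped signal voxels as misses.
#'
#' @param config a [SimConfig-class].
#' @param m missingness fraction.
#' @param estimator `"available_case"` or `"complete_case"`.
#' @param targetFpr target FPR for sensitivity.
#' @param nSegments feature segments for the engine.
#' @param cohort optional pre-simulated [VoxelMatrix-class] (avoids
#'   regeneration across levels of a sweep).
#' @return List with `auc`, `sensitivity`, `m`, `stat` (per-voxel signed
#'   statistic vector), `truth`, `nRetained`.
#' @export
benchmarkAtMissingness <- function(config, m, estimator = "available_case",
                                   targetFpr = 0.05, nSegments = 10L,
                                   cohort = NULL) {
  vm <- cohort %||% simulateCohort(config)
  if (m > 0)
    vm <- injectMissingness(vm, m, seed = config@seed + as.integer(round(1000 * m)))
  truth <- metadata(vm)$truth[analysisMask(vm)]
  spec <- modelSpec(Brain ~ Dx)
  res <- runMega(vm, spec, nSegments = min(nSegments, nrow(vm)))
  stat <- res@statistic[, "Dx"]
  if (estimator == "complete_case") {
    n <- ncol(vm)
    complete <- res@fit[, "n_obs"] == n
    stat[!complete] <- NA_real_
    roc <- scoreROC(stat, truth, targetFpr)
    # dropped signal voxels are misses: rescale sensitivity to all signal
    if (!is.na(roc$sensitivity))
      roc$sensitivity <- roc$sensitivity * sum(truth & complete) / sum(truth)
    nRet <- sum(complete)
  } else {
    roc <- scoreROC(stat, truth, targetFpr)
    nRet <- sum(is.finite(stat))
  }
  list(auc = roc$auc, sensitivity = roc$sensitivity, m = m, stat = stat,
       truth = truth, nRetained = nRet)
}

#' Sweep performance over missingness levels
#'
#' Runs [benchmarkAtMissingness()] at each level on one simulated cohort
#' and tabulates AUC and sensitivity at the target FPR. Reproducible
#' bit-for-bit from (`config`, its seed).
#'
#' @param config a [SimConfig-class].
#' @param levels missingness fractions (default 0 to 1 in steps of 0.05).
#' @param estimator `"available_case"` or `"complete_case"`.
#' @param targetFpr target FPR.
#' @param nSegments engine segments.
#' @return `data.frame` with columns `m`, `auc`, `sensitivity`,
#'   `n_retained`. Levels where no voxel can be fit report `NA` metrics.
#' @export
missingnessSweep <- function(config, levels = seq(0, 1, by = 0.05),
                             estimator = c("available_case", "complete_case"),
                             targetFpr = 0.05, nSegments = 10L) {
  estimator <- match.arg(estimator)
  cohort <- simulateCohort(config)
  rows <- lapply(levels, function(m) {
    b <- benchmarkAtMissingness(config, m, estimator = estimator,
                                targetFpr = targetFpr,
                                nSegments = nSegments, cohort = cohort)
    data.frame(m = m, auc = b$auc, sensitivity = b$sensitivity,
               n_retained = b$nRetained)
  })
  do.call(rbind, rows)
}
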