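#' Voxel grid geometry
#'
#' Dimensions, affine and flattening convention shared by every volume in an
#' analysis. The flattening order is fixed to R's native column-major order
#' (first spatial axis varies fastest), so feature order is a pure function
#' of (dims, analysis mask).
#'
#' @slot dims integer(3), voxel dimensions.
#' @slot affine 4x4 voxel-to-world transform (NIfTI sform convention).
#' @slot flattenOrder character, always `"ijk"` in this version.
#' @export
setClass("VoxelGrid",
  representation(dims = "integer", affine = "matrix", flattenOrder = "character"),
  prototype(flattenOrder = "ijk"))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims must be three positive integers")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (!identical(object@flattenOrder, "ijk"))
    msg <- c(msg, "flattenOrder must be 'ijk' (first axis fastest)")
  if (length(msg)) msg else TRUE
})

#' Construct a [VoxelGrid-class]
#'
#' @param dims three positive integers.
#' @param affine 4x4 voxel-to-world matrix; defaults to identity (1 mm
#'   isotropic, origin at voxel (0,0,0)).
#' @return A [VoxelGrid-class] object.
#' @examples
#' voxelGrid(c(50L, 50L, 50L))
#' @export
voxelGrid <- function(dims, affine = diag(4)) {
  new("VoxelGrid", dims = as.integer(dims), affine = affine)
}

#' Analysis mask plus optional per-subject masks
#'
#' @slot grid the shared [VoxelGrid-class].
#' @slot analysis logical array on the grid; `TRUE` marks in-analysis voxels.
#' @slot subjects named list (by fID) of logical arrays, possibly empty.
#' @export
setClass("MaskStack",
  representation(grid = "VoxelGrid", analysis = "array", subjects = "list"))

setValidity("MaskStack", function(object) {
  msg <- character()
  if (!identical(dim(object@analysis), as.integer(object@grid@dims)))
    msg <- c(msg, "analysis mask is not on the declared grid")
  if (!any(object@analysis))
    msg <- c(msg, "analysis mask has no TRUE voxel")
  bad <- vapply(object@subjects, function(m)
    !identical(dim(m), as.integer(object@grid@dims)), logical(1))
  if (any(bad))
    msg <- c(msg, paste("subject masks off-grid:",
                        paste(names(object@subjects)[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a [MaskStack-class]
#'
#' @param analysis logical array (the analysis mask) or `NULL` for all-TRUE.
#' @param grid a [VoxelGrid-class]; inferred from `analysis` when missing.
#' @param subjects optional named list of per-subject logical arrays keyed
#'   by fID.
#' @return A [MaskStack-class].
#' @export
maskStack <- function(analysis, grid = NULL, subjects = list()) {
  if (is.null(grid)) grid <- voxelGrid(dim(analysis))
  if (is.null(analysis)) analysis <- array(TRUE, grid@dims)
  storage.mode(analysis) <- "logical"
  subjects <- lapply(subjects, function(m) { storage.mode(m) <- "logical"; m })
  new("MaskStack", grid = grid, analysis = analysis, subjects = subjects)
}

#' Subject-by-feature value container
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one assay
#' `"values"` with features (voxels or named columns of a CSV matrix) as rows
#' and subjects as columns. Missing cells are stored as `NA`; the `NA` mark is
#' authoritative. `rowData` carries the feature-to-voxel map (0-based i,j,k
#' indices) for image-backed matrices; `colData` is the subject covariate
#' table keyed by `fID`. `metadata(x)$grid` and `metadata(x)$mask` retain the
#' geometry needed to reconstruct maps.
#'
#' @export
setClass("VoxelMatrix", contains = "SummarizedExperiment")

setValidity("VoxelMatrix", function(object) {
  msg <- character()
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'values' is required")
  cd <- colData(object)
  if (!"fID" %in% colnames(cd))
    msg <- c(msg, "colData must contain an fID column")
  else if (anyDuplicated(cd$fID))
    msg <- c(msg, "fID values must be unique")
  if (length(msg)) msg else TRUE
})

#' Per-feature model results
#'
#' Per-term statistic matrices (features x terms) and per-feature fit
#' measures from a mass-univariate run. Features failing the minimum-n rule
#' or with a degenerate design carry `NA` everywhere, with the reason in
#' `failureReasons()`.
#'
#' @slot terms model term names (column order of the statistic matrices).
#' @slot estimate,se,statistic,p,z features-x-terms numeric matrices.
#' @slot fit features x fit-measure matrix (`n_obs`, `df`, `residual_df`,
#'   `AIC`, `BIC`, `logLik`, `REML`, `sigma`, `R2`).
#' @slot reasons character per feature: NA for fitted features, otherwise
#'   one of `"insufficient_n"`, `"degenerate"`, `"nonconverged"`.
#' @slot coords data.frame of 0-based voxel indices (i,j,k) or feature names.
#' @slot model the [ModelSpec-class] that was fit.
#' @slot grid the [VoxelGrid-class] (or NULL-grid for CSV-backed features).
#' @slot mask logical array analysis mask used for reconstruction.
#' @export
setClass("VoxelResults",
  representation(terms = "character", estimate = "matrix", se = "matrix",
                 statistic = "matrix", p = "matrix", z = "matrix",
                 fit = "matrix", reasons = "character", coords = "data.frame",
                 model = "ANY", grid = "ANY", mask = "ANY"))

setValidity("VoxelResults", function(object) {
  n <- nrow(object@estimate)
  ok <- all(vapply(list(object@se, object@statistic, object@p, object@z),
                   function(m) nrow(m) == n, logical(1))) &&
    nrow(object@fit) == n && length(object@reasons) == n
  if (!ok) "statistic matrices, fit matrix and reasons must share the feature dimension"
  else TRUE
})

#' Statistical model specification
#'
#' Parsed from a formula such as `Brain ~ Age + Sex + Dx + (1|Site)`. The
#' response name is a placeholder for the imaging feature. Random effects are
#' restricted to random intercepts; random slopes are rejected.
#'
#' @slot formula the full model formula (with random terms if any).
#' @slot fixedFormula fixed-effects-only right-hand side.
#' @slot response placeholder response name (informational).
#' @slot randomGroups character vector of random-intercept grouping columns.
#' @slot family one of `"gaussian"`, `"binomial"`, `"poisson"`.
#' @slot estimator `"ols"`, `"glm"` or `"mixed"`.
#' @export
setClass("ModelSpec",
  representation(formula = "formula", fixedFormula = "formula",
                 response = "character", randomGroups = "character",
                 family = "character", estimator = "character"))

#' Combined (meta-analytic) per-feature results
#'
#' @slot method `"stouffer"` or `"fisher"`.
#' @slot weighted logical; sample-size weighting (Stouffer only).
#' @slot terms model term names.
#' @slot statistic features x terms combined Z (Stouffer) or X^2 (Fisher).
#' @slot p features x terms combined p-values.
#' @slot k features x terms count of contributing sites.
#' @slot sites per-site summary data.frame (site, n subjects, features).
#' @slot siteN features x sites matrix of per-site observed n.
#' @slot coords,grid,mask geometry, as in [VoxelResults-class].
#' @export
setClass("MetaResults",
  representation(method = "character", weighted = "logical",
                 terms = "character", statistic = "matrix", p = "matrix",
                 k = "matrix", sites = "data.frame", siteN = "matrix",
                 coords = "data.frame", grid = "ANY", mask = "ANY"))

#' Synthetic cohort configuration
#'
#' Defaults are the benchmark's study conditions: 1,000 subjects, a 50x50x50
#' grid of iid standard-normal voxels, a central spherical signal region of
#' radius 4 voxels (251 voxels under the strict-inequality lattice rule), a
#' binary diagnosis at 50% prevalence, and an additive shift of 0.2 at signal
#' voxels for cases (Cohen's d = 0.2 against unit noise).
#'
#' @slot nSubjects number of simulated subjects.
#' @slot dims grid dimensions.
#' @slot mu,sigma noise mean and SD.
#' @slot center sphere center (1-based voxel coordinates).
#' @slot radius sphere radius in voxels.
#' @slot effect additive case shift at signal voxels.
#' @slot prevalence case fraction.
#' @slot seed RNG seed.
#' @export
setClass("SimConfig",
  representation(nSubjects = "integer", dims = "integer", mu = "numeric",
                 sigma = "numeric", center = "numeric", radius = "numeric",
                 effect = "numeric", prevalence = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@prevalence <= 0 || object@prevalence >= 1)
    msg <- c(msg, "prevalence must lie in (0,1)")
  if (object@radius < 0) msg <- c(msg, "radius must be >= 0")
  if (any(object@center - object@radius < 0) ||
      any(object@center + object@radius > object@dims + 1))
    msg <- c(msg, "sphere does not fit inside the grid")
  if (length(msg)) msg else TRUE
})

#' Construct a [SimConfig-class]
#'
#' @param nSubjects,dims,mu,sigma,center,radius,effect,prevalence,seed see
#'   [SimConfig-class]; `center` defaults to the central voxel
#'   `floor(dims/2) + 1`.
#' @return A validated [SimConfig-class].
#' @examples
#' simConfig()                    # the benchmark conditions
#' simConfig(nSubjects = 50, dims = c(20, 20, 20), seed = 7)
#' @export
simConfig <- function(nSubjects = 1000L, dims = c(50L, 50L, 50L), mu = 0,
                      sigma = 1, center = floor(dims / 2) + 1, radius = 4,
                      effect = 0.2, prevalence = 0.5, seed = 42L) {
  new("SimConfig", nSubjects = as.integer(nSubjects), dims = as.integer(dims),
      mu = mu, sigma = sigma, center = as.numeric(center), radius = radius,
      effect = effect, prevalence = prevalence, seed = as.integer(seed))
}

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid", paste(object@dims, collapse = " x "),
      "| flatten order", object@flattenOrder, "\n")
})

setMethod("show", "MaskStack", function(object) {
  cat("MaskStack on", paste(object@grid@dims, collapse = "x"), "grid:",
      sum(object@analysis), "in-mask voxels,",
      length(object@subjects), "subject masks\n")
})

setMethod("show", "VoxelResults", function(object) {
  cat("VoxelResults:", nrow(object@estimate), "features x",
      length(object@terms), "terms (", paste(object@terms, collapse = ", "),
      ")\n  estimator:", object@model@estimator,
      "| fitted:", sum(is.na(object@reasons)),
      "| skipped:", sum(!is.na(object@reasons)), "\n")
})

setMethod("show", "MetaResults", function(object) {
  cat("MetaResults (", object@method,
      if (object@weighted) ", weighted" else ", unweighted", "): ",
      nrow(object@statistic), " features x ", length(object@terms),
      " terms, ", nrow(object@sites), " sites\n", sep = "")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSubjects, "subjects on",
      paste(object@dims, collapse = "x"), "grid; sphere r =", object@radius,
      "; effect =", object@effect, "; prevalence =", object@prevalence,
      "; seed =", object@seed, "\n")
})
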