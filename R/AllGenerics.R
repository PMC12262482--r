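#' @name accessors
#' @title Accessors for voxelmeta containers
#'
#' @description Slot access for the S4 containers goes through these
#' accessors. `voxelValues` returns the subject-by-feature assay (features in
#' rows, `NA` = missing); `analysisMask` the logical analysis mask;
#' `featureCoords` the feature-to-voxel map (0-based i,j,k);
#' `nObserved` the per-feature count of observed subjects; `termStats` the
#' per-term statistic table; `fitStats` the per-feature model-fit measures;
#' `failureReasons` the per-feature skip reason (`NA` where fitted).
#'
#' @param x a voxelmeta object.
#' @param term model term name (e.g. `"Dx"`).
#' @return See the individual accessor descriptions.
NULL

#' @rdname accessors
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @rdname accessors
#' @export
setGeneric("analysisMask", function(x) standardGeneric("analysisMask"))

#' @rdname accessors
#' @export
setGeneric("featureCoords", function(x) standardGeneric("featureCoords"))

#' @rdname accessors
#' @export
setGeneric("nObserved", function(x) standardGeneric("nObserved"))

#' @rdname accessors
#' @export
setGeneric("termStats", function(x, term) standardGeneric("termStats"))

#' @rdname accessors
#' @export
setGeneric("fitStats", function(x) standardGeneric("fitStats"))

#' @rdname accessors
#' @export
setGeneric("failureReasons", function(x) standardGeneric("failureReasons"))

#' @rdname accessors
setMethod("voxelValues", "VoxelMatrix", function(x) assay(x, "values"))

#' @rdname accessors
setMethod("analysisMask", "MaskStack", function(x) x@analysis)

#' @rdname accessors
setMethod("analysisMask", "VoxelMatrix", function(x) metadata(x)$mask)

#' @rdname accessors
setMethod("analysisMask", "VoxelResults", function(x) x@mask)

#' @rdname accessors
setMethod("featureCoords", "VoxelMatrix",
          function(x) as.data.frame(rowData(x)))

#' @rdname accessors
setMethod("featureCoords", "VoxelResults", function(x) x@coords)

#' @rdname accessors
setMethod("nObserved", "VoxelMatrix",
          function(x) rowSums(!is.na(assay(x, "values"))))

#' @rdname accessors
setMethod("nObserved", "VoxelResults", function(x) x@fit[, "n_obs"])

#' @rdname accessors
setMethod("termStats", "VoxelResults", function(x, term) {
  stopifnot(term %in% x@terms)
  data.frame(estimate = x@estimate[, term], se = x@se[, term],
             statistic = x@statistic[, term], p = x@p[, term],
             z = x@z[, term])
})

#' @rdname accessors
setMethod("termStats", "MetaResults", function(x, term) {
  stopifnot(term %in% x@terms)
  data.frame(statistic = x@statistic[, term], p = x@p[, term],
             k = x@k[, term])
})

#' @rdname accessors
setMethod("fitStats", "VoxelResults", function(x) x@fit)

#' @rdname accessors
setMethod("failureReasons", "VoxelResults", function(x) x@reasons)
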