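#' Load a subject covariate table keyed by fID
#'
#' Reads a delimited text file (`.csv`/`.tsv`/`.txt`) or spreadsheet
#' (`.xlsx`) of subject-level covariates and validates the composite subject
#' key `fID = SiteID_SubjectID`. When no `fID` column exists it is built from
#' the two id columns; when only `fID` exists, `site_id` and `subject_id` are
#' recovered by splitting at the first underscore. Column names are
#' case-sensitive.
#'
#' Rows with missing covariate values are never dropped here: dropping
#' happens per model at fit time. Use [flagIncomplete()] to list the rows
#' that a given model would lose.
#'
#' @param path file path.
#' @param idColumns names of the site and subject id columns, in that order,
#'   used only when the table has no `fID` column.
#' @return A `data.frame` with columns `fID`, `site_id`, `subject_id` and the
#'   covariates.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(SiteID = "Site1", SubjectID = "1234", Age = 30),
#'           tf, row.names = FALSE)
#' loadSubjectTable(tf)$fID   # "Site1_1234"
#' @export
loadSubjectTable <- function(path, idColumns = c("SiteID", "SubjectID")) {
  if (!file.exists(path)) stop("covariate table not found: ", path)
  ext <- tolower(tools::file_ext(path))
  tab <- switch(ext,
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading .xlsx covariate tables requires the readxl package")
      as.data.frame(readxl::read_excel(path))
    },
    tsv = read.delim(path, stringsAsFactors = FALSE),
    txt = read.delim(path, stringsAsFactors = FALSE),
    csv = read.csv(path, stringsAsFactors = FALSE),
    stop("unsupported covariate table format: .", ext))
  if (!"fID" %in% names(tab)) {
    missing <- setdiff(idColumns, names(tab))
    if (length(missing))
      stop("id columns not found in covariate table: ",
           paste(missing, collapse = ", "))
    tab$site_id <- as.character(tab[[idColumns[1L]]])
    tab$subject_id <- as.character(tab[[idColumns[2L]]])
    tab$fID <- paste(tab$site_id, tab$subject_id, sep = "_")
  } else {
    tab$fID <- as.character(tab$fID)
    if (!"site_id" %in% names(tab))
      tab$site_id <- sub("_.*$", "", tab$fID)
    if (!"subject_id" %in% names(tab))
      tab$subject_id <- sub("^[^_]*_", "", tab$fID)
  }
  bad <- tab$fID != paste(tab$site_id, tab$subject_id, sep = "_")
  if (any(bad))
    stop("fID does not equal site_id + '_' + subject_id for: ",
         paste(head(tab$fID[bad], 5L), collapse = ", "))
  dup <- unique(tab$fID[duplicated(tab$fID)])
  if (length(dup))
    stop("duplicate fID values: ", paste(dup, collapse = ", "))
  front <- c("fID", "site_id", "subject_id")
  tab[, c(front, setdiff(names(tab), front)), drop = FALSE]
}

#' Flag rows missing a model-required covariate
#'
#' @param table a subject table from [loadSubjectTable()].
#' @param covariates character vector of required covariate columns.
#' @return Logical vector, `TRUE` where the row lacks at least one covariate.
#' @export
flagIncomplete <- function(table, covariates) {
  missing <- setdiff(covariates, names(table))
  if (length(missing))
    stop("covariates absent from the table: ", paste(missing, collapse = ", "))
  !complete.cases(table[, covariates, drop = FALSE])
}

#' Discover per-subject volumes in site subdirectories
#'
#' Recursively searches `root` for files whose names end with the literal
#' suffix `pattern`; the leading part of the filename is the subject id and
#' the first-level subdirectory name the site id, so each file yields
#' `fID = site_subject`.
#'
#' @param root imaging data directory containing one subdirectory per site.
#' @param pattern literal filename suffix appended to the subject id, e.g.
#'   `"_rsfc_z.nii.gz"`.
#' @param table optional subject table; subjects in the table without a
#'   matched file are reported via the `"unmatched"` attribute and a warning.
#' @return A manifest `data.frame` with columns `fID`, `site_id`, `path`.
#' @export
discoverImages <- function(root, pattern, table = NULL) {
  if (!dir.exists(root)) stop("imaging root does not exist: ", root)
  files <- list.files(root, recursive = TRUE, full.names = TRUE)
  hit <- endsWith(basename(files), pattern)
  files <- files[hit]
  if (!length(files))
    stop("no files matching pattern '", pattern, "' under ", root)
  rel <- substring(files, nchar(root) + 2L)
  site <- sub("/.*$", "", rel)
  noSite <- !grepl("/", rel)
  if (any(noSite))
    stop("files must live in site subdirectories; found at top level: ",
         paste(basename(files[noSite]), collapse = ", "))
  # the suffix is literal: strip by length rather than regex
  subject <- basename(files)
  subject <- substr(subject, 1L, nchar(subject) - nchar(pattern))
  fID <- paste(site, subject, sep = "_")
  dup <- unique(fID[duplicated(fID)])
  if (length(dup))
    stop("multiple files match one fID: ", paste(dup, collapse = ", "))
  man <- data.frame(fID = fID, site_id = site, path = files,
                    stringsAsFactors = FALSE)
  man <- man[order(man$fID), , drop = FALSE]
  rownames(man) <- NULL
  if (!is.null(table)) {
    unmatched <- setdiff(table$fID, man$fID)
    if (length(unmatched))
      warning(length(unmatched), " subject(s) in the table have no image: ",
              paste(head(unmatched, 5L), collapse = ", "))
    attr(man, "unmatched") <- unmatched
  }
  man
}

#' Export an image manifest as CSV
#'
#' @param manifest from [discoverImages()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
exportManifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a 3-D NIfTI volume
#'
#' @param path `.nii`/`.nii.gz` file.
#' @return List with `data` (numeric 3-D array) and `grid`
#'   ([VoxelGrid-class] carrying the volume's xform).
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))   # plain numeric array
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("not a 3-D volume: ", path)
  aff <- structure(RNifti::xform(img), class = NULL)
  attr(aff, "code") <- NULL
  attr(aff, "imagedim") <- NULL
  list(data = arr, grid = voxelGrid(dim(arr), affine = matrix(aff, 4, 4)))
}

#' Write a 3-D array as NIfTI on a grid
#'
#' @param data numeric 3-D array.
#' @param grid a [VoxelGrid-class]; its affine becomes the sform.
#' @param path output `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(data, grid, path) {
  img <- RNifti::asNifti(array(as.numeric(data), dim = grid@dims))
  img <- RNifti::`sform<-`(img, structure(grid@affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a mask volume as a logical array
#'
#' Nonzero, finite voxels are `TRUE`.
#'
#' @param path NIfTI mask file.
#' @return List with `mask` (logical array) and `grid`.
#' @export
readMaskVolume <- function(path) {
  v <- readVolume(path)
  m <- is.finite(v$data) & v$data != 0
  list(mask = m, grid = v$grid)
}

#' Flatten a volume to the in-mask feature vector
#'
#' Converts a 3-D volume to the one-dimensional feature vector used by the
#' engine. Order is fixed: column-major over the analysis mask (first axis
#' fastest), identical for every subject and run. A value becomes missing
#' (`NA`) when the subject's own mask excludes the voxel, when the stored
#' value is non-finite, or — only if `zeroSentinel = TRUE` — when it equals
#' exactly zero. Exact zeros are valid statistics and are kept by default.
#'
#' @param volume numeric 3-D array on the grid of `masks`.
#' @param masks a [MaskStack-class].
#' @param fID subject id used to look up a subject-specific mask, if any.
#' @param zeroSentinel treat exact zeros as a missing-data sentinel.
#' @return Numeric vector of length `sum(analysisMask(masks))` with `NA`
#'   marking missing features.
#' @export
flattenVolume <- function(volume, masks, fID = NULL, zeroSentinel = FALSE) {
  if (!identical(dim(volume), as.integer(masks@grid@dims)))
    stop("volume dimensions ", paste(dim(volume), collapse = "x"),
         " do not match the analysis grid ",
         paste(masks@grid@dims, collapse = "x"))
  v <- volume[masks@analysis]
  v[!is.finite(v)] <- NA_real_
  if (zeroSentinel) v[!is.na(v) & v == 0] <- NA_real_
  if (!is.null(fID) && fID %in% names(masks@subjects))
    v[!masks@subjects[[fID]][masks@analysis]] <- NA_real_
  as.numeric(v)
}

#' Reconstruct a flat feature vector into a 3-D map
#'
#' Inverse of [flattenVolume()]: in-mask voxels receive `values` in the
#' retained feature order; out-of-mask voxels receive `fill`.
#'
#' @param values numeric vector, length equal to the in-mask voxel count.
#' @param grid a [VoxelGrid-class].
#' @param mask logical analysis mask on the grid.
#' @param fill out-of-mask fill value (default `NA`).
#' @param file optional NIfTI output path; written with the grid's affine.
#' @return The reconstructed 3-D array (invisibly when `file` is given).
#' @export
reconstructMap <- function(values, grid, mask, fill = NA_real_, file = NULL) {
  if (length(values) != sum(mask))
    stop("value vector has length ", length(values), " but the mask has ",
         sum(mask), " voxels")
  out <- array(fill, grid@dims)
  out[mask] <- values
  if (!is.null(file)) {
    writeVolume(out, grid, file)
    return(invisible(out))
  }
  out
}
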