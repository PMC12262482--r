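#' Parse a run configuration
#'
#' Reads the parameter file driving an end-to-end run. Two dialects are
#' accepted: a structured YAML text file (canonical), or a tabbed
#' spreadsheet with sheets `data_path` (name/value rows: `clinical_data`,
#' `imaging_root`, optionally `output`, `mask`, `mode`, `n_segments`,
#' `seed`), `data_pattern` (the filename suffix), `predictors` (one column
#' of covariate names) and `models` (one column of model strings). Both
#' parse to the identical structure.
#'
#' A model entry is a formula string, optionally prefixed by a family:
#' `"Brain ~ Age + Sex + Dx + (1|Site)"`,
#' `"binomial: Dx ~ Age + Brain"`. Unknown prefixes raise an error listing
#' the supported estimators. Every formula term must appear among the
#' predictors or the clinical table's columns; offending terms are named.
#' `mode = "meta"` forbids random site terms (site is the stratification
#' variable there).
#'
#' @param path YAML (`.yaml`/`.yml`) or spreadsheet (`.xlsx`) config file.
#' @return A validated named list (class `"voxelmetaConfig"`) with elements
#'   `clinical_data`, `imaging_root`, `data_pattern`, `predictors`,
#'   `models` (list of [ModelSpec-class]), `model_strings`, `mode`,
#'   `mask`, `n_segments`, `seed`, `output`, `correction`, `meta`,
#'   `zero_sentinel`.
#' @export
parseRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "xlsx") {
    readConfigSheets(path)
  } else stop("config must be .yaml/.yml or .xlsx, got .", ext)

  need <- function(field) {
    if (is.null(raw[[field]]))
      stop("config is missing required field '", field, "'")
    raw[[field]]
  }
  cfg <- list(
    clinical_data = as.character(need("clinical_data")),
    imaging_root = if (!is.null(raw$imaging_root))
      as.character(raw$imaging_root) else NULL,
    feature_matrix = if (!is.null(raw$feature_matrix))
      as.character(raw$feature_matrix) else NULL,
    data_pattern = if (!is.null(raw$data_pattern))
      as.character(raw$data_pattern) else NULL,
    predictors = as.character(need("predictors")),
    model_strings = as.character(need("models")),
    mode = tolower(raw$mode %||% "mega"),
    mask = if (!is.null(raw$mask)) as.character(raw$mask) else NULL,
    n_segments = as.integer(raw$n_segments %||% 1L),
    seed = as.integer(raw$seed %||% 1L),
    output = as.character(raw$output %||% "Results"),
    zero_sentinel = isTRUE(raw$zero_sentinel),
    correction = utils::modifyList(
      list(fdr = TRUE, ptfce = FALSE, cluster_threshold = 3.1,
           connectivity = 26L, n_thresholds = 100L),
      as.list(raw$correction %||% list())),
    meta = utils::modifyList(
      list(method = "stouffer", weighted = TRUE, min_site_n = 10L),
      as.list(raw$meta %||% list())))

  if (is.null(cfg$imaging_root) && is.null(cfg$feature_matrix))
    stop("config needs either 'imaging_root' (with 'data_pattern') or ",
         "'feature_matrix'")
  if (!is.null(cfg$imaging_root) && is.null(cfg$data_pattern))
    stop("config is missing required field 'data_pattern'")
  if (!cfg$mode %in% c("mega", "meta", "both"))
    stop("mode must be one of mega, meta, both")

  cfg$models <- lapply(cfg$model_strings, parseModelString)
  names(cfg$models) <- paste0("model", seq_along(cfg$models))

  known <- cfg$predictors
  if (file.exists(cfg$clinical_data))
    known <- union(known, names(loadSubjectTable(cfg$clinical_data)))
  for (spec in cfg$models) {
    vars <- modelVariables(spec)
    bad <- setdiff(vars, known)
    if (length(bad))
      stop("model '", deparse(spec@formula),
           "' references unknown term(s): ", paste(bad, collapse = ", "))
    if (cfg$mode %in% c("meta", "both") && length(spec@randomGroups))
      if (cfg$mode == "meta")
        stop("mode 'meta' forbids random site terms; remove (1|",
             spec@randomGroups[1L], ")")
  }
  class(cfg) <- "voxelmetaConfig"
  cfg
}

# "family: formula" model strings; bare strings are gaussian
parseModelString <- function(s) {
  s <- trimws(s)
  fam <- "gaussian"
  if (grepl("^[A-Za-z._]+\\s*:", s) ) {
    fam <- trimws(sub(":.*$", "", s))
    s <- trimws(sub("^[A-Za-z._]+\\s*:", "", s))
  }
  supported <- c("gaussian", "binomial", "poisson")
  if (!fam %in% supported)
    stop("unknown model family/estimator '", fam, "'; supported: ",
         paste(supported, collapse = ", "),
         " (random intercepts via (1|group) in the formula)")
  modelSpec(s, family = fam)
}

readConfigSheets <- function(path) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("reading .xlsx configs requires the readxl package")
  sheets <- readxl::excel_sheets(path)
  need <- c("data_path", "data_pattern", "predictors", "models")
  missing <- setdiff(need, sheets)
  if (length(missing))
    stop("config spreadsheet is missing sheet(s): ",
         paste(missing, collapse = ", "))
  kv <- as.data.frame(readxl::read_excel(path, sheet = "data_path",
                                         col_names = c("name", "value"),
                                         col_types = "text", skip = 0))
  raw <- as.list(setNames(kv$value, kv$name))
  pat <- as.data.frame(readxl::read_excel(path, sheet = "data_pattern",
                                          col_names = "pattern",
                                          col_types = "text"))
  raw$data_pattern <- pat$pattern[1L]
  pred <- as.data.frame(readxl::read_excel(path, sheet = "predictors",
                                           col_names = "predictor",
                                           col_types = "text"))
  raw$predictors <- pred$predictor
  mods <- as.data.frame(readxl::read_excel(path, sheet = "models",
                                           col_names = "model",
                                           col_types = "text"))
  raw$models <- mods$model
  if (!is.null(raw$n_segments)) raw$n_segments <- as.integer(raw$n_segments)
  if (!is.null(raw$seed)) raw$seed <- as.integer(raw$seed)
  raw
}

#' @export
print.voxelmetaConfig <- function(x, ...) {
  cat("voxelmeta run config\n",
      " clinical_data:", x$clinical_data, "\n",
      " imaging_root:", x$imaging_root %||% "(feature matrix)", "\n",
      " mode:", x$mode, "| segments:", x$n_segments, "| seed:", x$seed, "\n",
      " models:\n")
  for (m in x$model_strings) cat("   -", m, "\n")
  invisible(x)
}
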