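#' Run the configured end-to-end pipeline
#'
#' Executes the full workflow for every model in the config: load the
#' covariate table, discover and flatten the images (or load the CSV
#' feature matrix), fit the mega-analytic model and/or the site-wise
#' meta-analysis, apply the configured corrections, extract cluster tables,
#' and (in `both` mode) compute the mega-vs-meta overlap conjunction.
#' A per-step wall-time log is written to `steps_time.csv`, and every stage
#' failure is recorded with its stage name (partial outputs are preserved).
#' Reruns with an identical config and seed produce identical numerical
#' outputs.
#'
#' @param config a parsed config from [parseRunConfig()], or a path to one.
#' @return The output directory, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- parseRunConfig(config)
  out <- config$output
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  timings <- data.frame(step = character(), seconds = numeric())
  clock <- function(step, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e)
      stop("stage '", step, "' failed: ", conditionMessage(e), call. = FALSE))
    timings <<- rbind(timings,
                      data.frame(step = step,
                                 seconds = proc.time()[["elapsed"]] - t0))
    write.csv(timings, file.path(out, "steps_time.csv"), row.names = FALSE)
    r
  }

  table <- clock("load_subject_table", loadSubjectTable(config$clinical_data))
  vm <- clock("build_feature_matrix", {
    if (!is.null(config$feature_matrix)) {
      loadFeatureMatrix(config$feature_matrix, table)
    } else {
      manifest <- discoverImages(config$imaging_root, config$data_pattern,
                                 table = table)
      masks <- if (!is.null(config$mask)) {
        mk <- readMaskVolume(config$mask)
        maskStack(mk$mask, mk$grid)
      } else {
        g <- readVolume(manifest$path[1L])$grid
        maskStack(array(TRUE, g@dims), g)
      }
      buildVoxelMatrix(manifest, table, masks,
                       zeroSentinel = config$zero_sentinel)
    }
  })
  write.csv(as.data.frame(colData(vm)), file.path(out, "subjects.csv"),
            row.names = FALSE)

  for (mi in seq_along(config$models)) {
    spec <- config$models[[mi]]
    mname <- names(config$models)[mi]
    megaRes <- NULL; metaRes <- NULL
    if (config$mode %in% c("mega", "both")) {
      megaRes <- clock(paste0(mname, "_mega_fit"),
                       runMega(vm, spec, nSegments = config$n_segments))
      mdir <- file.path(out, "mega", mname)
      clock(paste0(mname, "_mega_compile"), compileResults(megaRes, mdir))
      clock(paste0(mname, "_mega_correct"),
            correctAndCluster(megaRes, mdir, config))
    }
    if (config$mode %in% c("meta", "both")) {
      sspec <- spec
      if (length(spec@randomGroups))   # site is the stratifier in meta mode
        sspec <- modelSpec(spec@fixedFormula, family = spec@family)
      metaRes <- clock(paste0(mname, "_meta_fit"),
                       runMeta(vm, sspec, method = config$meta$method,
                               weighted = isTRUE(config$meta$weighted),
                               minSiteN = config$meta$min_site_n,
                               nSegments = config$n_segments))
      mdir <- file.path(out, "meta", mname)
      clock(paste0(mname, "_meta_compile"), compileMetaResults(metaRes, mdir))
    }
    if (config$mode == "both" && metaRes@method == "stouffer") {
      cdir <- file.path(out, "conjunction", mname)
      dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
      clock(paste0(mname, "_conjunction"), {
        for (term in intersect(megaRes@terms, metaRes@terms)) {
          cj <- conjunctionMap(list(megaRes@z[, term],
                                    metaRes@statistic[, term]),
                               method = "overlap",
                               threshold = config$correction$cluster_threshold)
          safe <- gsub("[^A-Za-z0-9._-]", "", term)
          if (!is.null(megaRes@grid)) {
            reconstructMap(as.numeric(cj$map), megaRes@grid, megaRes@mask,
                           file = file.path(cdir,
                                            paste0(safe, "_overlap.nii.gz")))
          } else {
            write.csv(cbind(megaRes@coords, label = cj$map),
                      file.path(cdir, paste0(safe, "_overlap.csv")),
                      row.names = FALSE)
          }
          legend <- cj$legend
          legend$inputs <- sub("^1$", "mega", sub("^2$", "meta",
                               sub("^all$", "mega+meta", legend$inputs)))
          write.csv(legend, file.path(cdir, paste0(safe, "_legend.csv")),
                    row.names = FALSE)
        }
      })
    }
  }
  invisible(out)
}

# FDR maps, optional pTFCE, and cluster tables for every term of a result
correctAndCluster <- function(res, dir, config) {
  safe <- function(x) gsub("[^A-Za-z0-9._-]", "", x)
  for (term in res@terms) {
    fc <- fdrCorrect(res@p[, term])
    if (!is.null(res@grid)) {
      reconstructMap(fc$q, res@grid, res@mask,
                     file = file.path(dir, paste0(safe(term), "_q_fdr.nii.gz")))
      zmap <- reconstructMap(res@z[, term], res@grid, res@mask)
      cl <- extractClusters(zmap,
                            threshold = config$correction$cluster_threshold,
                            connectivity = config$correction$connectivity,
                            grid = res@grid)
      write.csv(cl, file.path(dir, paste0(safe(term), "_clusters.csv")),
                row.names = FALSE)
      if (isTRUE(config$correction$ptfce)) {
        enh <- ptfce(zmap, mask = res@mask,
                     nThresholds = config$correction$n_thresholds)
        writeVolume(enh$z, res@grid,
                    file.path(dir, paste0(safe(term), "_z_ptfce.nii.gz")))
      }
    } else {
      write.csv(data.frame(res@coords, q = fc$q),
                file.path(dir, paste0(safe(term), "_q_fdr.csv")),
                row.names = FALSE)
    }
  }
  invisible(NULL)
}
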