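# Static HTML report over a completed run directory.

htmlTable <- function(df) {
  if (is.null(df) || nrow(df) == 0)
    return("<p><em>No rows (empty table).</em></p>")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  hdr <- paste0("<tr>", paste0("<th>", names(df), "</th>", collapse = ""),
                "</tr>")
  rows <- apply(df, 1L, function(r)
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>"))
  paste0("<table border='1' cellpadding='4' cellspacing='0'>", hdr,
         paste(rows, collapse = "\n"), "</table>")
}

sliceImage <- function(zmap, file, threshold = NULL) {
  d <- dim(zmap)
  grDevices::png(file, width = 900, height = 320)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  mids <- c(round(d[1] / 2), round(d[2] / 2), round(d[3] / 2))
  sl <- list(zmap[mids[1], , ], zmap[, mids[2], ], zmap[, , mids[3]])
  titles <- c("sagittal", "coronal", "axial")
  for (i in 1:3) {
    m <- sl[[i]]
    m[!is.finite(m)] <- 0
    graphics::image(m, axes = FALSE, main = titles[i],
                    col = grDevices::hcl.colors(64, "viridis"))
  }
  invisible(file)
}

#' Render a static HTML report for a run directory
#'
#' Builds `report.html` inside a completed [runPipeline()] directory:
#' per-site demographic summaries, significant-cluster tables (from the
#' run's `*_clusters.csv`, default display threshold Z >= 3.1), and
#' orthogonal-slice images of each Z map. Every rendered table is also
#' written as CSV. Missing maps are noted rather than fatal.
#'
#' @param runDir output directory of a completed run.
#' @return Path to `report.html`, invisibly.
#' @export
renderReport <- function(runDir) {
  if (!dir.exists(runDir)) stop("run directory not found: ", runDir)
  parts <- c("<html><head><title>voxelmeta report</title></head><body>",
             "<h1>voxelmeta analysis report</h1>")
  imgDir <- file.path(runDir, "report_files")
  dir.create(imgDir, showWarnings = FALSE)

  subjFile <- file.path(runDir, "subjects.csv")
  if (file.exists(subjFile)) {
    subj <- read.csv(subjFile, stringsAsFactors = FALSE)
    num <- names(subj)[vapply(subj, is.numeric, logical(1))]
    num <- setdiff(num, c("fID", "site_id", "subject_id"))
    demo <- do.call(rbind, lapply(split(subj, subj$site_id), function(s) {
      row <- data.frame(site = s$site_id[1L], n = nrow(s))
      for (v in num) {
        row[[paste0(v, "_mean")]] <- mean(s[[v]], na.rm = TRUE)
        row[[paste0(v, "_sd")]] <- sd(s[[v]], na.rm = TRUE)
      }
      row
    }))
    rownames(demo) <- NULL
    write.csv(demo, file.path(runDir, "report_demographics.csv"),
              row.names = FALSE)
    parts <- c(parts, "<h2>Per-site demographics</h2>", htmlTable(demo))
  } else {
    parts <- c(parts, "<p><em>subjects.csv missing; demographics omitted.</em></p>")
  }

  clFiles <- list.files(runDir, pattern = "_clusters\\.csv$",
                        recursive = TRUE, full.names = TRUE)
  parts <- c(parts, "<h2>Significant voxel clusters</h2>")
  if (!length(clFiles)) {
    parts <- c(parts, "<p><em>No cluster tables found.</em></p>")
  } else {
    for (f in clFiles) {
      parts <- c(parts, paste0("<h3>", substring(f, nchar(runDir) + 2L),
                               "</h3>"), htmlTable(read.csv(f)))
    }
  }

  zFiles <- list.files(runDir, pattern = "_(z|meta_z|z_ptfce)\\.nii\\.gz$",
                       recursive = TRUE, full.names = TRUE)
  parts <- c(parts, "<h2>Statistic maps</h2>")
  if (!length(zFiles)) {
    parts <- c(parts, "<p><em>No Z maps found.</em></p>")
  } else {
    for (f in zFiles) {
      rel <- substring(f, nchar(runDir) + 2L)
      png <- file.path(imgDir, paste0(gsub("[/\\\\]", "_",
                                           sub("\\.nii\\.gz$", "", rel)),
                                      ".png"))
      ok <- tryCatch({ sliceImage(readVolume(f)$data, png); TRUE },
                     error = function(e) FALSE)
      parts <- c(parts, paste0("<h3>", rel, "</h3>"))
      parts <- c(parts,
        if (ok) paste0("<img src='report_files/", basename(png),
                       "' width='800'/>")
        else "<p><em>slice rendering failed for this map</em></p>")
    }
  }

  tFile <- file.path(runDir, "steps_time.csv")
  if (file.exists(tFile))
    parts <- c(parts, "<h2>Step timings</h2>", htmlTable(read.csv(tFile)))

  parts <- c(parts, "</body></html>")
  outFile <- file.path(runDir, "report.html")
  writeLines(parts, outFile)
  invisible(outFile)
}
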