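# Programmatic fixtures: tiny image trees, covariate tables, and
# spreadsheet configs (built at test time; nothing binary is stored).

fixtureTable <- function(n = 12, sites = c("Site1", "Site2"), seed = 1) {
  set.seed(seed)
  site <- rep(sites, length.out = n)
  subj <- sprintf("%04d", 1200 + seq_len(n))
  data.frame(SiteID = site, SubjectID = subj,
             Age = round(runif(n, 18, 65)),
             Sex = sample(c("F", "M"), n, replace = TRUE),
             Dx = rep_len(c(0L, 0L, 1L, 1L), n),  # varies within each site
             stringsAsFactors = FALSE)
}

# writes an image tree <root>/<site>/<subject><pattern> of random volumes
# and the matching covariate CSV; returns paths plus the generating arrays
fixtureImageTree <- function(dir, table, dims = c(6, 6, 6),
                             pattern = "_stat.nii.gz", seed = 2) {
  set.seed(seed)
  grid <- voxelGrid(dims)
  vols <- list()
  for (i in seq_len(nrow(table))) {
    siteDir <- file.path(dir, table$SiteID[i])
    dir.create(siteDir, showWarnings = FALSE, recursive = TRUE)
    v <- array(rnorm(prod(dims)), dims)
    fID <- paste(table$SiteID[i], table$SubjectID[i], sep = "_")
    vols[[fID]] <- v
    writeVolume(v, grid, file.path(siteDir,
                                   paste0(table$SubjectID[i], pattern)))
  }
  csv <- file.path(dir, "subjects.csv")
  write.csv(table, csv, row.names = FALSE)
  list(root = dir, csv = csv, grid = grid, vols = vols, pattern = pattern)
}

# builds an .xlsx workbook from a named list of data.frames via the
# system python's openpyxl (no header rows are written)
writeXlsxFixture <- function(path, sheets) {
  tmp <- tempfile(fileext = ".json")
  payload <- lapply(sheets, function(df) {
    lapply(seq_len(nrow(df)), function(i)
      as.list(unname(vapply(df[i, , drop = FALSE], as.character,
                            character(1)))))
  })
  writeLines(jsonlite::toJSON(payload, auto_unbox = FALSE), tmp)
  script <- sprintf(
    "import json, sys\nfrom openpyxl import Workbook\nwith open('%s') as fh:\n    data = json.load(fh)\nwb = Workbook()\nwb.remove(wb.active)\nfor name, rows in data.items():\n    ws = wb.create_sheet(title=name)\n    for row in rows:\n        ws.append([c[0] if isinstance(c, list) else c for c in row])\nwb.save('%s')\n",
    tmp, path)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = TRUE, stderr = TRUE)
  if (!file.exists(path))
    stop("xlsx fixture generation failed: ", paste(status, collapse = "\n"))
  path
}
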