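#' Benjamini-Hochberg FDR adjustment over tested features
#'
#' Step-up FDR-adjusted p-values (q-values). The number of tests `m` counts
#' only features with a finite p — features skipped by the engine (all-`NA`)
#' do not inflate the correction; since the engine tests every in-mask
#' voxel, `m` equals the in-mask count in a complete run. `NA` positions are
#' preserved in the output.
#'
#' @param p numeric vector of p-values (may contain `NA`).
#' @return List with `q` (adjusted values, same length/order as `p`) and
#'   `nTests` (the `m` actually used).
#' @examples
#' fdrCorrect(c(0.01, 0.02, 0.03, 0.04))$q   # all 0.04
#' @export
fdrCorrect <- function(p) {
  ok <- is.finite(p)
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  list(q = q, nTests = sum(ok))
}

#' Extract suprathreshold clusters from a Z map
#'
#' Connected components of `{Z >= threshold}` under 6-, 18- or
#' 26-neighborhood connectivity (default 26, the common volumetric
#' convention). Rows are sorted by size descending, ties broken by peak |Z|.
#'
#' @param zmap numeric 3-D array.
#' @param threshold Z cutoff (default 3.1, the usual display threshold).
#' @param connectivity 6, 18 or 26.
#' @param grid optional [VoxelGrid-class]; when given, peak world
#'   coordinates are added via the affine.
#' @return `data.frame` with `cluster`, `size`, `peak_z`, `peak_i/j/k`
#'   (0-based voxel indices) and, with a grid, `peak_x/y/z`. Zero rows when
#'   nothing survives.
#' @export
extractClusters <- function(zmap, threshold = 3.1, connectivity = 26L,
                            grid = NULL) {
  stopifnot(length(dim(zmap)) == 3L, is.finite(threshold),
            connectivity %in% c(6L, 18L, 26L))
  supra <- is.finite(zmap) & zmap >= threshold
  lab <- .labelComponents(as.logical(supra), as.integer(dim(zmap)),
                          as.integer(connectivity))
  ncl <- attr(lab, "nClusters")
  if (ncl == 0L)
    return(data.frame(cluster = integer(), size = integer(),
                      peak_z = numeric(), peak_i = integer(),
                      peak_j = integer(), peak_k = integer()))
  rows <- lapply(seq_len(ncl), function(cl) {
    idx <- which(lab == cl)
    pk <- idx[which.max(abs(zmap[idx]))]
    d <- dim(zmap)
    data.frame(cluster = cl, size = length(idx), peak_z = zmap[pk],
               peak_i = (pk - 1L) %% d[1L],
               peak_j = ((pk - 1L) %/% d[1L]) %% d[2L],
               peak_k = (pk - 1L) %/% (d[1L] * d[2L]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$size, -abs(out$peak_z)), , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(grid)) {
    w <- grid@affine %*% rbind(out$peak_i, out$peak_j, out$peak_k, 1)
    out$peak_x <- w[1L, ]; out$peak_y <- w[2L, ]; out$peak_z_mm <- w[3L, ]
  }
  out
}
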