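# internal numerical helpers

# signed Z from a two-sided p-value held in log space: avoids the
# qnorm(p/2) underflow to -Inf that direct computation hits near p = 0.
# logp is log(p_two_sided); sgn the sign of the estimate.
signedZFromLogP <- function(logp, sgn) {
  z <- qnorm(logp - log(2), lower.tail = FALSE, log.p = TRUE)
  out <- sign(sgn) * z
  out[sgn == 0] <- 0
  out[!is.finite(logp)] <- NA_real_
  out
}

# two-sided log p from a t statistic
logPFromT <- function(tval, df) {
  log(2) + pt(abs(tval), df = df, lower.tail = FALSE, log.p = TRUE)
}

# two-sided log p from a normal statistic
logPFromZ <- function(zval) {
  log(2) + pnorm(abs(zval), lower.tail = FALSE, log.p = TRUE)
}

# column names of the per-feature fit-measure matrix
fitMeasureNames <- function() {
  c("n_obs", "df", "residual_df", "AIC", "BIC", "logLik", "REML", "sigma", "R2")
}

emptyFitRow <- function() {
  setNames(rep(NA_real_, length(fitMeasureNames())), fitMeasureNames())
}

# affine check with the documented tolerance; dims must match exactly
sameGrid <- function(a, b, tol = 1e-4) {
  identical(as.integer(a@dims), as.integer(b@dims)) &&
    max(abs(a@affine - b@affine)) <= tol
}

# 0-based (i,j,k) coordinates of TRUE voxels in column-major (i fastest) order
maskCoords <- function(mask) {
  idx <- which(mask)
  d <- dim(mask)
  i <- (idx - 1L) %% d[1L]
  j <- ((idx - 1L) %/% d[1L]) %% d[2L]
  k <- (idx - 1L) %/% (d[1L] * d[2L])
  data.frame(i = i, j = j, k = k)
}
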