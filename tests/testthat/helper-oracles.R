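# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# brute-force Benjamini-Hochberg step-up
bhStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- (m / seq_len(m)) * p[o]
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# closed-form least squares via explicit normal equations
olsOracle <- function(y, X) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  list(coef = as.numeric(b), se = as.numeric(se),
       t = as.numeric(b) / as.numeric(se), df = df, rss = sum(res^2))
}

# naive flood fill connected-component labeling on a logical 3-D array
floodFillLabels <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ad <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- ad > 0 & switch(as.character(connectivity),
                          "6" = ad <= 1, "18" = ad <= 2, "26" = ad <= 3)
  offs <- offs[keep, ]
  lab <- array(0L, d)
  cur <- 0L
  for (v in which(mask)) {
    if (lab[v] > 0L) next
    cur <- cur + 1L
    stack <- v
    lab[v] <- cur
    while (length(stack)) {
      s <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ii <- (s - 1L) %% d[1] + 1L
      jj <- ((s - 1L) %/% d[1]) %% d[2] + 1L
      kk <- (s - 1L) %/% (d[1] * d[2]) + 1L
      for (r in seq_len(nrow(offs))) {
        x <- ii + offs$dx[r]; y <- jj + offs$dy[r]; z <- kk + offs$dz[r]
        if (x < 1 || y < 1 || z < 1 || x > d[1] || y > d[2] || z > d[3]) next
        w <- x + (y - 1L) * d[1] + (z - 1L) * d[1] * d[2]
        if (mask[w] && lab[w] == 0L) { lab[w] <- cur; stack <- c(stack, w) }
      }
    }
  }
  lab
}

# exhaustive integer-lattice count of points strictly inside a sphere
latticeSphereCount <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  sum(g$x^2 + g$y^2 + g$z^2 < radius^2)
}

# all-pairs Mann-Whitney AUC with half-credit ties
pairwiseAUC <- function(statSig, statNull) {
  tot <- 0
  for (s in statSig) tot <- tot + sum(s > statNull) + 0.5 * sum(s == statNull)
  tot / (length(statSig) * length(statNull))
}

# classical pooled-variance two-sample t statistic (case minus control)
twoSampleT <- function(y, grp) {
  y1 <- y[grp == 1]; y0 <- y[grp == 0]
  n1 <- length(y1); n0 <- length(y0)
  sp2 <- ((n1 - 1) * var(y1) + (n0 - 1) * var(y0)) / (n1 + n0 - 2)
  (mean(y1) - mean(y0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
}
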