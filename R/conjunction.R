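#' Conjunction of two or more aligned signed-Z maps
#'
#' Combines aligned statistic maps under one of five rules to identify
#' agreement across analyses (e.g. mega vs meta, or two software packages).
#' Conjunction is one-sided per direction: with `direction = "negative"`
#' every map's sign is flipped first, so "agreement" always means effects of
#' the same sign. Compute both directions separately for a full picture.
#'
#' Methods:
#' \describe{
#'   \item{overlap}{logical-AND membership at `threshold`. The combined map
#'     is an integer label: bit `i` set when input `i` passes, so for two
#'     inputs 3 = both agree, 1 = first only, 2 = second only, 0 = none.
#'     The label legend is attached as the `"legend"` attribute.}
#'   \item{minimum}{the minimum statistic across inputs; significant iff
#'     `min >= threshold`. Membership is identical to overlap at the same
#'     threshold (`min >= t` iff all `>= t`).}
#'   \item{conjunction_null}{the minimum-statistic decision rule at the
#'     standard single-map threshold — a valid test that *all* effects are
#'     non-null; numerically the minimum map, reported separately because
#'     its inferential claim differs from descriptive overlap.}
#'   \item{global}{`sum(Z_i)/sqrt(k)` over the inputs finite at the voxel —
#'     a Stouffer-style average with a standard normal null, so a consistent
#'     moderate effect can pass even if no single input does.}
#'   \item{probabilistic}{graded joint score `prod(1 - p_i)` with `p_i` the
#'     one-sided p of input `i`; a graded map in `[0, 1]`, no thresholding.}
#' }
#'
#' overlap/minimum/conjunction_null are defined only where every input is
#' finite; global/probabilistic use the finite inputs with `k` tracked.
#'
#' @param maps list of >= 2 numeric arrays/vectors on a shared grid & mask.
#' @param method one of `"overlap"`, `"minimum"`, `"conjunction_null"`,
#'   `"global"`, `"probabilistic"`.
#' @param threshold Z cutoff for the thresholded methods (default 3.1).
#' @param direction `"positive"` or `"negative"`.
#' @return List with `map` (combined statistic/label, same shape as the
#'   inputs), `method`, `threshold`, `k` (contributing-input count, for
#'   global/probabilistic), and for overlap a `legend` data.frame.
#' @examples
#' a <- c(3.5, 2.5, 0); b <- c(4.0, 2.5, 0)
#' conjunctionMap(list(a, b), "minimum")$map    # 3.5 2.5 0.0
#' conjunctionMap(list(a, b), "global")$map[2]  # 5/sqrt(2) = 3.54
#' @export
conjunctionMap <- function(maps,
                           method = c("overlap", "minimum",
                                      "conjunction_null", "global",
                                      "probabilistic"),
                           threshold = 3.1,
                           direction = c("positive", "negative")) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  if (!is.list(maps) || length(maps) < 2L)
    stop("conjunction needs a list of at least 2 maps")
  dims <- lapply(maps, function(m) dim(m) %||% length(m))
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("maps do not share a common grid")
  sgn <- if (direction == "negative") -1 else 1
  arr <- vapply(maps, function(m) sgn * as.numeric(m),
                numeric(length(maps[[1L]])))
  shape <- function(x) {
    if (!is.null(dim(maps[[1L]]))) array(x, dim(maps[[1L]])) else x
  }
  fin <- is.finite(arr)
  allFin <- rowSums(fin) == ncol(arr)
  k <- rowSums(fin)

  out <- list(method = method, threshold = threshold, direction = direction)
  if (method == "overlap") {
    pass <- fin & arr >= threshold
    lab <- as.integer(pass %*% 2^(seq_len(ncol(arr)) - 1L))
    lab[!allFin] <- NA_integer_
    codes <- 0:(2^ncol(arr) - 1L)
    member <- vapply(codes, function(cd) {
      w <- which(bitwAnd(cd, 2^(seq_len(ncol(arr)) - 1L)) > 0)
      if (!length(w)) "none"
      else if (length(w) == ncol(arr)) "all"
      else paste(w, collapse = "+")
    }, character(1))
    out$map <- shape(lab)
    out$legend <- data.frame(label = codes, inputs = member)
  } else if (method %in% c("minimum", "conjunction_null")) {
    m <- apply(arr, 1L, min)
    m[!allFin] <- NA_real_
    out$map <- shape(m)
    out$significant <- shape(!is.na(m) & m >= threshold)
  } else if (method == "global") {
    a0 <- arr; a0[!fin] <- 0
    g <- ifelse(k > 0, rowSums(a0) / sqrt(k), NA_real_)
    out$map <- shape(g)
    out$k <- shape(k)
  } else {
    p1 <- pnorm(arr, lower.tail = FALSE)      # one-sided p per input
    p1[!fin] <- NA
    score <- apply(1 - p1, 1L, prod, na.rm = TRUE)
    score[k == 0] <- NA_real_
    out$map <- shape(score)
    out$k <- shape(k)
  }
  out
}
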