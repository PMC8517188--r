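# Internal numeric helpers shared across metric modules.

# Weighted mean with graceful handling of empty input.
wmean <- function(x, w) {
  if (!length(x) || sum(w) <= 0) return(0)
  sum(x * w) / sum(w)
}

# Population-style weighted SD (frequency weights normalized away).
wsd <- function(x, w) {
  if (!length(x) || sum(w) <= 0) return(0)
  m <- wmean(x, w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

# Total length of the union of closed intervals [l_i, r_i].
intervalUnionLength <- function(l, r) {
  keep <- r > l
  l <- l[keep]; r <- r[keep]
  if (!length(l)) return(0)
  o <- order(l)
  l <- l[o]; r <- r[o]
  tot <- 0
  curL <- l[1]; curR <- r[1]
  if (length(l) > 1L) for (i in 2:length(l)) {
    if (l[i] > curR) {
      tot <- tot + (curR - curL)
      curL <- l[i]; curR <- r[i]
    } else if (r[i] > curR) curR <- r[i]
  }
  tot + (curR - curL)
}

# Exact area of a union of axis-aligned rectangles given as a data.frame
# with columns x0, x1, y0, y1. Sweeps over y-bands; within a band the
# covering set is constant so the x-union length applies to the whole band.
rectUnionArea <- function(rects) {
  keep <- rects$x1 > rects$x0 & rects$y1 > rects$y0
  rects <- rects[keep, , drop = FALSE]
  if (!nrow(rects)) return(0)
  ys <- sort(unique(c(rects$y0, rects$y1)))
  area <- 0
  for (i in seq_len(length(ys) - 1L)) {
    lo <- ys[i]; hi <- ys[i + 1L]
    sel <- rects$y0 <= lo & rects$y1 >= hi
    if (any(sel))
      area <- area + (hi - lo) *
        intervalUnionLength(rects$x0[sel], rects$x1[sel])
  }
  area
}

# Area of the erosion of a stack of leaf-row rectangles by a square
# structuring element of half-width d. Rows are given as vectors l, r
# (x-extent) and y0, y1 (row span), assumed sorted by y0 and non-overlapping
# in y. A point (x, y) survives erosion iff [y-d, y+d] is fully covered by
# contiguous rows and [x-d, x+d] lies inside every covering row's x-extent.
erodedRowsArea <- function(l, r, y0, y1, d) {
  keep <- r > l & y1 > y0
  l <- l[keep]; r <- r[keep]; y0 <- y0[keep]; y1 <- y1[keep]
  n <- length(l)
  if (!n) return(0)
  bp <- sort(unique(c(y0 + d, y1 - d, y0 - d, y1 + d)))
  bp <- bp[bp > min(y0) & bp < max(y1)]
  bp <- sort(unique(c(min(y0), bp, max(y1))))
  area <- 0
  for (i in seq_len(length(bp) - 1L)) {
    lo <- bp[i]; hi <- bp[i + 1L]
    ym <- (lo + hi) / 2
    covers <- y0 < ym + d & y1 > ym - d
    if (!any(covers)) next
    idx <- which(covers)
    # the covering rows must tile [ym-d, ym+d] with no vertical gap
    if (min(y0[idx]) > ym - d || max(y1[idx]) < ym + d) next
    if (length(idx) > 1L && any(y0[idx][-1] - y1[idx][-length(idx)] > 1e-9))
      next
    len <- min(r[idx]) - max(l[idx]) - 2 * d
    if (len > 0) area <- area + len * (hi - lo)
  }
  area
}

# Deterministic sub-seed derivation; keeps results < 2^31.
subSeed <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483629
}
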