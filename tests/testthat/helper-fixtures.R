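# Shared fixture builders. Everything is generated in code at test time.

# A small 10-pair machine with 10 mm leaves spanning -50..50 mm.
toyMachine <- function(nPairs = 10, leafWidth = 10, ...) {
  machineSpec("toy", seq(-nPairs * leafWidth / 2, nPairs * leafWidth / 2,
                         by = leafWidth), ...)
}

# Arc with given bank matrices; defaults give equal meterset increments and
# wide-open jaws.
toyArc <- function(bankA, bankB, totalMU = 100, weights = NULL,
                   jaws = c(-100, 100, -100, 100), angles = NULL,
                   direction = "CW") {
  n <- nrow(bankA)
  if (is.null(weights)) weights <- seq(0, 1, length.out = n)
  if (is.null(angles)) angles <- (180 + 2.0341 * (0:(n - 1))) %% 360
  arc("a1", totalMU, angles, weights, bankA, bankB, jaws,
      gantryDirection = direction)
}

# Static rectangular plan on the toy machine: pairs `pairs` open at
# [-halfGap, halfGap] for n control points.
rectPlan <- function(n = 4, pairs = 4:7, halfGap = 25, nPairs = 10,
                     totalMU = 100, fractionDose = 2,
                     machine = toyMachine(nPairs)) {
  bankA <- matrix(0, n, nPairs)
  bankB <- matrix(0, n, nPairs)
  bankA[, pairs] <- -halfGap
  bankB[, pairs] <- halfGap
  rtPlan("rect", machine, list(toyArc(bankA, bankB, totalMU = totalMU)),
         fractionDose)
}

# Pixel-counting oracle for aperture area/perimeter of a set of rectangles,
# rasterized at `px` mm. Perimeter = exposed pixel-edge count times px.
rasterOracle <- function(rects, px = 0.1, pad = 2) {
  x0 <- min(rects$x0) - pad; x1 <- max(rects$x1) + pad
  y0 <- min(rects$y0) - pad; y1 <- max(rects$y1) + pad
  xs <- seq(x0 + px / 2, x1 - px / 2, by = px)
  ys <- seq(y0 + px / 2, y1 - px / 2, by = px)
  m <- matrix(FALSE, length(ys), length(xs))
  for (i in seq_len(nrow(rects)))
    m[ys > rects$y0[i] & ys < rects$y1[i],
      xs > rects$x0[i] & xs < rects$x1[i]] <- TRUE
  area <- sum(m) * px^2
  padm <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  edges <- sum(padm[-1, ] != padm[-nrow(padm), ]) +
           sum(padm[, -1] != padm[, -ncol(padm)])
  list(area = area, perimeter = edges * px)
}

# Independent brute-force gamma oracle: same stated definition (fine grid of
# the evaluated plane at distMm/interpFactor over the reference extent plus
# the search radius; minimization within the radius), but computed by plain
# nested loops with its own pointwise bilinear interpolation.
gammaOracle <- function(ref, ev, crit, interpFactor = 10, searchFactor = 3) {
  normDose <- max(ref@values)
  dd <- crit@dosePct / 100 * normDose
  dta <- crit@distMm
  step <- dta / interpFactor
  radius <- searchFactor * dta
  rx <- ref@origin[1] + (seq_len(ncol(ref@values)) - 1) * ref@spacing[1]
  ry <- ref@origin[2] + (seq_len(nrow(ref@values)) - 1) * ref@spacing[2]
  ex <- ev@origin[1] + (seq_len(ncol(ev@values)) - 1) * ev@spacing[1]
  ey <- ev@origin[2] + (seq_len(nrow(ev@values)) - 1) * ev@spacing[2]
  # row-wise bilinear interpolation at fixed y, written independently of
  # the implementation's stencil machinery
  interpRow <- function(xs, y) {
    out <- rep(NA_real_, length(xs))
    if (y < ey[1] || y > ey[length(ey)]) return(out)
    jrow <- max(1, min(length(ey) - 1, findInterval(y, ey)))
    ty <- (y - ey[jrow]) / (ey[jrow + 1] - ey[jrow])
    inx <- xs >= ex[1] & xs <= ex[length(ex)]
    icol <- pmax(1, pmin(length(ex) - 1, findInterval(xs[inx], ex)))
    tx <- (xs[inx] - ex[icol]) / (ex[icol + 1] - ex[icol])
    lo <- ev@values[jrow, icol] * (1 - tx) + ev@values[jrow, icol + 1] * tx
    hi <- ev@values[jrow + 1, icol] * (1 - tx) + ev@values[jrow + 1, icol + 1] * tx
    out[inx] <- lo * (1 - ty) + hi * ty
    out
  }
  span <- floor(radius / step + 1e-9)
  dxs <- (-span:span) * step
  thr <- crit@thresholdPct / 100 * normDose
  gam <- matrix(NA_real_, nrow(ref@values), ncol(ref@values))
  for (i in seq_along(ry)) for (j in seq_along(rx)) {
    Dr <- ref@values[i, j]
    if (Dr < thr) next
    best <- Inf
    for (di in -span:span) {
      dy <- di * step
      inRad <- dxs^2 + dy^2 <= radius^2 + 1e-9
      if (!any(inRad)) next
      de <- interpRow(rx[j] + dxs[inRad], ry[i] + dy)
      g2 <- (dxs[inRad]^2 + dy^2) / dta^2 + (de - Dr)^2 / dd^2
      mn <- suppressWarnings(min(g2, na.rm = TRUE))
      if (is.finite(mn) && mn < best) best <- mn
    }
    if (is.finite(best)) gam[i, j] <- sqrt(best)
  }
  gam
}

# Smooth random dose plane for gamma tests.
smoothPlane <- function(seed, n = 21, spacing = 2.5, scale = 100) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n), n, n)
  for (k in 1:4)
    m <- (m + m[c(1, 1:(n - 1)), ] + m[c(2:n, n), ] +
            m[, c(1, 1:(n - 1))] + m[, c(2:n, n)]) / 5
  dosePlane(m * scale, spacing = spacing)
}

# The seed-pinned 200-plan study cohort used by the acceptance suite.
# Built once per test run and cached.
studyCohort <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- cohortSpec(nPlans = 200)
    plans <- simulateCohort(spec, seed = 7)
    conv <- as.data.frame(do.call(rbind, lapply(plans, extractConventional)))
    pf <- as.data.frame(do.call(rbind, lapply(plans, extractPlanomics)))
    gprTab <- simulateGPR(plans, spec, seed = 7, conventional = conv)
    cache <<- list(spec = spec, plans = plans, conv = conv, pf = pf,
                   gprTab = gprTab)
    cache
  }
})
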