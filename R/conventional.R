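# 48 conventional plan-complexity metrics.
#
# All aperture-derived quantities share one vectorized per-arc geometry
# pass (arcGeometry); the exported operation functions recompute it for
# convenience at small scale.

# Vectorized per-arc aperture geometry: open mask, clipped extents, areas
# and perimeters for every control point.
arcGeometry <- function(arcObj, machine, clipToJaws = TRUE) {
  n <- nControlPoints(arcObj)
  np <- machine@nLeafPairs
  b <- machine@leafBoundaries
  y0 <- matrix(b[-length(b)], n, np, byrow = TRUE)
  y1 <- matrix(b[-1], n, np, byrow = TRUE)
  gap <- arcObj@bankB - arcObj@bankA
  if (clipToJaws) {
    left <- pmax(arcObj@bankA, arcObj@jaws[, 1])
    right <- pmin(arcObj@bankB, arcObj@jaws[, 2])
    ry0 <- pmax(y0, arcObj@jaws[, 3])
    ry1 <- pmin(y1, arcObj@jaws[, 4])
  } else {
    left <- arcObj@bankA; right <- arcObj@bankB
    ry0 <- y0; ry1 <- y1
  }
  open <- gap > machine@minLeafGap & ry1 > ry0 & right > left
  w <- pmax(right - left, 0) * pmax(ry1 - ry0, 0)
  areas <- rowSums(w * open)
  perims <- numeric(n)
  for (i in seq_len(n))
    perims[i] <- rowStackPerimeter(left[i, ], right[i, ], ry0[i, ], ry1[i, ],
                                   open[i, ])
  st <- segmentTiming(arcObj, machine)
  list(open = open, gap = gap, left = left, right = right,
       ry0 = ry0, ry1 = ry1, areas = areas, perims = perims,
       muCP = controlPointMU(arcObj), seg = st, totalMU = arcObj@totalMU)
}

planGeometry <- function(plan, clipToJaws = TRUE)
  lapply(plan@arcs, arcGeometry, machine = plan@machine,
         clipToJaws = clipToJaws)

#' Leaf speed and acceleration record for an arc
#'
#' Speeds are per (leaf, segment) finite differences
#' \eqn{|\Delta pos| / \Delta t} (cm/s) and accelerations per (leaf,
#' interior control point) \eqn{|v_{j+1} - v_j| / \bar{\Delta t}} (cm/s^2)
#' with the centered segment-mean duration. By default only leaves of a
#' pair that is dosimetrically open at at least one flanking control point
#' contribute (the moving-leaf mask); zero-duration segments are excluded
#' and counted.
#'
#' @param arc an \linkS4class{Arc}
#' @param machine a \linkS4class{MachineSpec}
#' @param movingMask apply the moving-leaf mask (default TRUE); FALSE
#'   samples all leaf pairs
#' @param clipToJaws open/closed classification clips to the jaws
#' @return list with pooled sample vectors \code{speeds} (cm/s) and
#'   \code{accels} (cm/s^2), \code{speedWeights} (per-sample delivery
#'   weights used by the total modulation index), per-leaf travel
#'   (\code{travelMm}) over masked segments, and \code{nZeroDt}
#' @export
leafKinematics <- function(arc, machine, movingMask = TRUE,
                           clipToJaws = TRUE, geometry = NULL) {
  g <- if (is.null(geometry)) arcGeometry(arc, machine, clipToJaws)
       else geometry
  n <- nControlPoints(arc)
  np <- machine@nLeafPairs
  dt <- g$seg$dt
  # per-segment pair mask: open at either flanking control point
  segMask <- g$open[-n, , drop = FALSE] | g$open[-1, , drop = FALSE]
  if (!movingMask) segMask[] <- TRUE
  dA <- abs(diff(arc@bankA)) / 10       # cm
  dB <- abs(diff(arc@bankB)) / 10
  ok <- dt > 0
  nZeroDt <- sum(!ok)
  vA <- dA / dt; vB <- dB / dt          # (n-1) x np, cm/s
  vA[!ok, ] <- NA; vB[!ok, ] <- NA
  vA[!segMask] <- NA; vB[!segMask] <- NA
  speeds <- c(vA, vB)
  # delivery-variation weight of each segment (dose-rate and gantry-speed
  # changes relative to machine maxima), for the total modulation index
  dr <- ifelse(ok, g$seg$dMU / dt * 60, 0)
  gs <- ifelse(ok, g$seg$dTheta / dt, 0)
  wSeg <- (1 + c(0, abs(diff(dr))) / machine@maxDoseRate) *
          (1 + c(0, abs(diff(gs))) / machine@maxGantrySpeed)
  speedWeights <- c(matrix(wSeg, n - 1, np), matrix(wSeg, n - 1, np))
  keep <- !is.na(speeds)
  accel <- function(v) {
    if (nrow(v) < 2) return(matrix(numeric(0), 0, np))
    dtm <- (dt[-1] + dt[-length(dt)]) / 2
    a <- abs(diff(v)) / dtm
    a
  }
  aA <- accel(vA); aB <- accel(vB)
  accels <- c(aA, aB)
  travel <- function(d, v) {
    dm <- d * 10
    dm[is.na(v)] <- 0
    colSums(dm)
  }
  anyMask <- colSums(segMask & ok) > 0
  travelMm <- c(travel(dA, vA), travel(dB, vB))
  structure(list(speeds = speeds[keep], accels = accels[!is.na(accels)],
                 speedWeights = speedWeights[keep],
                 travelMm = travelMm, movingLeaf = c(anyMask, anyMask),
                 nZeroDt = nZeroDt),
            class = "KinematicsRecord")
}

# Pool kinematics records over arcs.
poolKinematics <- function(records) {
  structure(list(
    speeds = unlist(lapply(records, `[[`, "speeds")),
    accels = unlist(lapply(records, `[[`, "accels")),
    speedWeights = unlist(lapply(records, `[[`, "speedWeights")),
    nZeroDt = sum(vapply(records, `[[`, numeric(1), "nZeroDt"))
  ), class = "KinematicsRecord")
}

#' Binned speed/acceleration proportions and their moments
#'
#' Speed bins at a = 0, 0.4, 0.8, 1.2, 1.6, 2.0 cm/s and acceleration bins
#' at b = 0, 1, 2, 4, 6 cm/s^2; the last bin is right-closed and absorbs
#' samples beyond the grid. Returns the 13 named values S_* (5), A_* (4),
#' ALS, SLS, ALA, SLA.
#'
#' @param k a kinematics record from \code{\link{leafKinematics}}
#' @return named numeric of length 13
#' @export
kinematicHistogramFeatures <- function(k) {
  sEdges <- c(0, 0.4, 0.8, 1.2, 1.6, 2.0)
  aEdges <- c(0, 1, 2, 4, 6)
  binProp <- function(x, edges) {
    nb <- length(edges) - 1L
    if (!length(x)) return(rep(0, nb))
    xi <- pmin(x, edges[length(edges)] - 1e-12)  # overflow -> last bin
    idx <- findInterval(xi, edges, rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1L), nb)
    tabulate(idx, nb) / length(x)
  }
  if (!length(k$speeds))
    warning("empty kinematics record; histogram features are all zero")
  s <- binProp(k$speeds, sEdges)
  a <- binProp(k$accels, aEdges)
  mom <- function(x) if (length(x)) c(mean(x), stats::sd(x)) else c(0, 0)
  ms <- mom(k$speeds); ma <- mom(k$accels)
  out <- c(s, a, ms[1], ifelse(is.na(ms[2]), 0, ms[2]),
           ma[1], ifelse(is.na(ma[2]), 0, ma[2]))
  names(out) <- c("S_0-0.4", "S_0.4-0.8", "S_0.8-1.2", "S_1.2-1.6",
                  "S_1.6-2.0", "A_0-1", "A_1-2", "A_2-4", "A_4-6",
                  "ALS", "SLS", "ALA", "SLA")
  out
}

#' Modulation indices for speed, acceleration and total modulation
#'
#' \eqn{MI(f) = \int_0^f z(x) dx} where \eqn{z(x)} is the fraction of
#' samples exceeding \eqn{x \sigma} (trapezoid rule, step 0.01). The total
#' index uses the speed integrand with each sample weighted by the
#' delivery-variation weight of its segment. A zero sample SD yields
#' MI = 0 by convention.
#'
#' @param k a kinematics record
#' @param f upper integration limit (in units of sample SDs)
#' @return named numeric c(MI_s, MI_a, MI_t)
#' @export
modulationIndices <- function(k, f) miAt(k, f)

# z(x) over the integration grid via one pass on sorted samples; MI is the
# cumulative trapezoid at x = f (grid step 0.01 in units of the sample SD).
miAt <- function(k, f) {
  miOf <- function(x, w = NULL) {
    if (!length(x)) return(0)
    sdv <- stats::sd(x)
    if (!is.finite(sdv) || sdv <= 0) return(0)
    xs <- seq(0, f, by = 0.01)
    o <- order(x)
    xo <- x[o]
    if (is.null(w)) {
      tail <- (length(x) - findInterval(xs * sdv, xo)) / length(x)
    } else {
      cw <- cumsum(w[o])
      sw <- cw[length(cw)]
      idx <- findInterval(xs * sdv, xo)
      tail <- (sw - c(0, cw)[idx + 1L]) / sw
    }
    sum((tail[-1] + tail[-length(tail)]) / 2) * 0.01
  }
  c(MI_s = miOf(k$speeds), MI_a = miOf(k$accels),
    MI_t = miOf(k$speeds, k$speedWeights))
}

# ---- aperture-based scores --------------------------------------------------

# Per-control-point LSV for one bank: positional variability of consecutive
# open leaves, normalized by the open-position range. A flat bank (range 0)
# or a single open leaf scores 1.
bankLSV <- function(pos) {
  nOpen <- length(pos)
  if (nOpen <= 1L) return(1)
  posMax <- max(pos) - min(pos)
  if (posMax <= 0) return(1)
  sum(posMax - abs(diff(pos))) / ((nOpen - 1) * posMax)
}

# LSV and AAV series for one arc from its geometry.
arcLSVAAV <- function(arcObj, g) {
  n <- nrow(g$open)
  lsv <- numeric(n); aav <- numeric(n)
  # per-pair maximum clipped opening over the arc
  wMax <- pmax(g$right - g$left, 0)
  wMax[!g$open] <- 0
  hRow <- pmax(g$ry1 - g$ry0, 0)
  unionArea <- sum(apply(wMax * hRow, 2, max))
  for (i in seq_len(n)) {
    op <- g$open[i, ]
    if (!any(op)) { lsv[i] <- 0; aav[i] <- 0; next }
    lsv[i] <- bankLSV(arcObj@bankA[i, op]) * bankLSV(arcObj@bankB[i, op])
    aav[i] <- if (unionArea > 0) g$areas[i] / unionArea else 0
  }
  list(lsv = lsv, aav = aav)
}

#' Aperture-based complexity scores
#'
#' Small aperture scores SAS(l) for l = 5, 10, 20 mm (MU-weighted fraction
#' of open leaf pairs with gap below l), the mean asymmetry distance MAD,
#' and the modulation complex score MCS with its leaf-sequence (LSV) and
#' aperture-area (AAV) components. Plan values are MU-weighted over arcs.
#'
#' @param plan an \linkS4class{RTPlan}
#' @param clipToJaws clip apertures to the jaws
#' @return named numeric c(SAS5, SAS10, SAS20, MAD, MCS, LSV, AAV)
#' @export
apertureScores <- function(plan, clipToJaws = TRUE, geometry = NULL) {
  geo <- if (is.null(geometry)) planGeometry(plan, clipToJaws) else geometry
  gapAll <- numeric(0); wPair <- numeric(0); madAll <- numeric(0)
  mcsArc <- numeric(length(geo)); lsvArc <- numeric(length(geo))
  aavArc <- numeric(length(geo)); muArc <- numeric(length(geo))
  for (k in seq_along(geo)) {
    g <- geo[[k]]
    n <- nrow(g$open)
    for (i in seq_len(n)) {
      op <- g$open[i, ]
      if (!any(op)) next
      gp <- g$gap[i, op]
      gapAll <- c(gapAll, gp)
      wPair <- c(wPair, rep(g$muCP[i], sum(op)))
      mid <- (g$left[i, op] + g$right[i, op]) / 2
      aw <- pmax(0, g$right[i, op] - g$left[i, op]) *
            pmax(0, g$ry1[i, op] - g$ry0[i, op])
      centroid <- sum(mid * aw) / sum(aw)
      madAll <- c(madAll, mean(abs(mid - centroid)))
    }
    la <- arcLSVAAV(plan@arcs[[k]], g)
    wCP <- g$muCP / sum(g$muCP)
    mcsArc[k] <- sum(wCP * la$lsv * la$aav)
    lsvArc[k] <- sum(wCP * la$lsv)
    aavArc[k] <- sum(wCP * la$aav)
    muArc[k] <- g$totalMU
  }
  if (!length(gapAll)) stop("no deliverable aperture in the plan")
  # MAD needs its own per-CP weights (one entry per CP with an aperture)
  madW <- numeric(0)
  for (g in geo) {
    has <- rowSums(g$open) > 0
    madW <- c(madW, g$muCP[has])
  }
  c(SAS5 = wmean(gapAll < 5, wPair), SAS10 = wmean(gapAll < 10, wPair),
    SAS20 = wmean(gapAll < 20, wPair), MAD = wmean(madAll, madW),
    MCS = wmean(mcsArc, muArc), LSV = wmean(lsvArc, muArc),
    AAV = wmean(aavArc, muArc))
}

# Connected components of an aperture: consecutive open rows whose
# x-intervals overlap belong to one component; returns a component id per
# open row (in row order).
apertureComponents <- function(left, right, openIdx) {
  ncomp <- 0L
  ids <- integer(length(openIdx))
  for (j in seq_along(openIdx)) {
    newComp <- j == 1L || openIdx[j] != openIdx[j - 1] + 1L ||
      min(right[j], right[j - 1]) <= max(left[j], left[j - 1])
    if (newComp) ncomp <- ncomp + 1L
    ids[j] <- ncomp
  }
  ids
}

#' Plan-level aperture shape metrics
#'
#' PA (MU-weighted mean aperture area, mm^2), PI (MU-weighted mean
#' circle-normalized irregularity perimeter^2 / 4 pi area), PM
#' (1 - PA / UAA), PMU (plan MU per Gy of fraction dose), UAA (area of the
#' union of all apertures, mm^2), EM (MU-weighted mean perimeter/area,
#' 1/mm), CAM (MU-weighted mean over open pairs of gap / (gap + 2 d_edge)),
#' EAM (MU-weighted mean fraction of aperture area within d_edge of the
#' aperture boundary) and C/A (as EM but computed per connected aperture
#' component). Control points with zero aperture area are excluded from the
#' ratio metrics.
#'
#' @param plan an \linkS4class{RTPlan}
#' @param dEdge edge-zone width for CAM/EAM (mm, default 5)
#' @param clipToJaws clip apertures to the jaws
#' @return named numeric c(PA, PI, PM, PMU, UAA, EM, CAM, EAM, CA)
#' @export
planShapeMetrics <- function(plan, dEdge = 5, clipToJaws = TRUE,
                             geometry = NULL) {
  geo <- if (is.null(geometry)) planGeometry(plan, clipToJaws) else geometry
  areas <- numeric(0); pis <- numeric(0); ems <- numeric(0)
  eams <- numeric(0); cas <- numeric(0); wCP <- numeric(0)
  camVals <- numeric(0); camW <- numeric(0)
  rects <- list()
  for (g in geo) {
    n <- nrow(g$open)
    for (i in seq_len(n)) {
      op <- which(g$open[i, ])
      if (!length(op)) next
      a <- g$areas[i]; p <- g$perims[i]
      l <- g$left[i, op]; r <- g$right[i, op]
      y0 <- g$ry0[i, op]; y1 <- g$ry1[i, op]
      rects[[length(rects) + 1L]] <-
        data.frame(x0 = l, x1 = r, y0 = y0, y1 = y1)
      areas <- c(areas, a)
      pis <- c(pis, p^2 / (4 * pi * a))
      ems <- c(ems, p / a)
      er <- erodedRowsArea(l, r, y0, y1, dEdge)
      eams <- c(eams, (a - er) / a)
      ids <- apertureComponents(l, r, op)
      compPA <- vapply(split(seq_along(op), ids), function(jj) {
        sub <- seq_along(op) %in% jj
        ca <- sum((r[sub] - l[sub]) * (y1[sub] - y0[sub]))
        cp <- rowStackPerimeter(l[sub], r[sub], y0[sub], y1[sub],
                                rep(TRUE, sum(sub)))
        cp / ca
      }, numeric(1))
      cas <- c(cas, mean(compPA))
      wCP <- c(wCP, g$muCP[i])
      gp <- g$gap[i, op]
      camVals <- c(camVals, gp / (gp + 2 * dEdge))
      camW <- c(camW, rep(g$muCP[i], length(op)))
    }
  }
  if (!length(areas)) stop("no deliverable aperture in the plan")
  uaa <- rectUnionArea(do.call(rbind, rects))
  pa <- wmean(areas, wCP)
  c(PA = pa, PI = wmean(pis, wCP), PM = 1 - pa / uaa,
    PMU = plan@totalMU / plan@fractionDose, UAA = uaa,
    EM = wmean(ems, wCP), CAM = wmean(camVals, camW),
    EAM = wmean(eams, wCP), CA = wmean(cas, wCP))
}

#' Leaf-travel, leaf-gap and dose-rate metrics
#'
#' ALT (mean total leaf travel over moving leaves, mm, MU-weighted over
#' arcs), ALTMCS (ALT x MCS), ALG/SLG (MU-weighted mean/SD of open-pair
#' gaps, mm), ADR/SDR (mean/SD of per-segment dose rate, MU/min) and the
#' prescribed fraction dose (Gy).
#'
#' @param plan an \linkS4class{RTPlan}
#' @param clipToJaws clip apertures to the jaws
#' @return named numeric c(ALT, ALTMCS, ALG, SLG, ADR, SDR, dose)
#' @export
travelDeliveryMetrics <- function(plan, clipToJaws = TRUE,
                                  geometry = NULL, kinematics = NULL,
                                  mcs = NULL) {
  geo <- if (is.null(geometry)) planGeometry(plan, clipToJaws) else geometry
  muArc <- vapply(plan@arcs, totalMU, numeric(1))
  altArc <- numeric(length(plan@arcs))
  gaps <- numeric(0); gw <- numeric(0); dr <- numeric(0)
  for (k in seq_along(plan@arcs)) {
    rec <- if (is.null(kinematics)) leafKinematics(plan@arcs[[k]],
                 plan@machine, clipToJaws = clipToJaws,
                 geometry = geo[[k]]) else kinematics[[k]]
    mv <- rec$movingLeaf
    altArc[k] <- if (any(mv)) mean(rec$travelMm[mv]) else 0
    g <- geo[[k]]
    for (i in seq_len(nrow(g$open))) {
      op <- g$open[i, ]
      if (!any(op)) next
      gaps <- c(gaps, g$gap[i, op])
      gw <- c(gw, rep(g$muCP[i], sum(op)))
    }
    ok <- g$seg$dt > 0
    dr <- c(dr, g$seg$dMU[ok] / g$seg$dt[ok] * 60)
  }
  alt <- wmean(altArc, muArc)
  if (is.null(mcs))
    mcs <- unname(apertureScores(plan, clipToJaws, geometry = geo)["MCS"])
  c(ALT = alt, ALTMCS = alt * mcs, ALG = wmean(gaps, gw),
    SLG = wsd(gaps, gw), ADR = mean(dr),
    SDR = if (length(dr) > 1) stats::sd(dr) else 0,
    dose = plan@fractionDose)
}

#' Extract the 48 conventional complexity features of a plan
#'
#' Deterministic, fixed-order named vector: 12 modulation indices
#' (MI_s/MI_a/MI_t at f = 0.2, 0.5, 1, 2), 13 kinematic histogram values,
#' SAS5/SAS10/SAS20/MAD, MCS/LSV/AAV, PA/PI/PM/PMU/UAA, EM, CAM/EAM/CA,
#' ALT/ALTMCS, ALG/SLG, ADR/SDR/dose.
#'
#' @param plan an \linkS4class{RTPlan}
#' @param clipToJaws clip apertures to the jaws (default TRUE)
#' @param dEdge edge-zone width for CAM/EAM (mm)
#' @return named numeric of length 48
#' @examples
#' spec <- cohortSpec(nPlans = 1, cpPerArc = 24, arcRange = c(2, 2))
#' v <- extractConventional(simulatePlan(spec, 1, seed = 7))
#' length(v)
#' @export
extractConventional <- function(plan, clipToJaws = TRUE, dEdge = 5) {
  geo <- planGeometry(plan, clipToJaws)
  recs <- lapply(seq_along(plan@arcs), function(i)
    leafKinematics(plan@arcs[[i]], plan@machine, clipToJaws = clipToJaws,
                   geometry = geo[[i]]))
  k <- poolKinematics(recs)
  fs <- c(0.2, 0.5, 1, 2)
  mi <- vapply(fs, function(f) miAt(k, f), numeric(3))
  miv <- c(mi["MI_s", ], mi["MI_a", ], mi["MI_t", ])
  names(miv) <- c(paste0("MIs_", fs), paste0("MIa_", fs), paste0("MIt_", fs))
  ap <- apertureScores(plan, clipToJaws, geometry = geo)
  out <- c(miv,
           kinematicHistogramFeatures(k),
           ap,
           planShapeMetrics(plan, dEdge, clipToJaws, geometry = geo),
           travelDeliveryMetrics(plan, clipToJaws, geometry = geo,
                                 kinematics = recs, mcs = unname(ap["MCS"])))
  stopifnot(length(out) == 48L)
  out
}
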