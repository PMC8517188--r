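#' Construct a VMAT arc
#'
#' @param beamId beam identifier
#' @param totalMU arc monitor units
#' @param gantryAngles deg (IEC 61217), one per control point
#' @param cumWeights cumulative meterset weights in [0, 1], non-decreasing,
#'   starting at 0 and ending at 1
#' @param bankA,bankB leaf position matrices (mm), control points x pairs;
#'   bank A is the negative-side bank
#' @param jaws either a length-4 vector c(x1, x2, y1, y2) applied to all
#'   control points or an nCP x 4 matrix
#' @param gantryDirection "CW" or "CC"
#' @return an \linkS4class{Arc}
#' @export
arc <- function(beamId, totalMU, gantryAngles, cumWeights, bankA, bankB,
                jaws, gantryDirection = "CW") {
  n <- length(cumWeights)
  if (is.null(dim(jaws))) jaws <- matrix(jaws, n, 4, byrow = TRUE)
  colnames(jaws) <- c("x1", "x2", "y1", "y2")
  new("Arc", beamId = as.character(beamId), totalMU = totalMU,
      gantryAngles = as.numeric(gantryAngles),
      gantryDirection = gantryDirection,
      cumWeights = as.numeric(cumWeights),
      bankA = as.matrix(bankA), bankB = as.matrix(bankB), jaws = jaws)
}

#' Construct a VMAT plan
#'
#' @param planId plan identifier
#' @param machine a \linkS4class{MachineSpec}
#' @param arcs list of \linkS4class{Arc}
#' @param fractionDose prescribed dose per fraction (Gy)
#' @return an \linkS4class{RTPlan}
#' @export
rtPlan <- function(planId, machine, arcs, fractionDose) {
  new("RTPlan", planId = as.character(planId), machine = machine,
      arcs = arcs, fractionDose = fractionDose,
      totalMU = sum(vapply(arcs, function(a) a@totalMU, numeric(1))))
}

#' Per-segment monitor units, gantry travel and delivery time
#'
#' A VMAT segment (the interval between consecutive control points) is
#' delivered at whichever of the dose-rate or gantry-speed limits binds:
#' \eqn{\Delta t_i = \max(\Delta MU_i / \dot{MU}_{max},\;
#' \Delta\theta_i / \dot{\theta}_{max})}.
#'
#' @param arc an \linkS4class{Arc}
#' @param machine a \linkS4class{MachineSpec}
#' @return data.frame with one row per segment: \code{dMU} (MU),
#'   \code{dTheta} (deg), \code{dt} (s), and \code{degenerate} flagging
#'   zero-duration segments with leaf motion
#' @examples
#' ms <- machineSpec("demo", seq(-50, 50, by = 10))
#' a <- arc("b1", 100, c(180, 182.0341), c(0, 1),
#'          matrix(-20, 2, 10), matrix(20, 2, 10), c(-50, 50, -50, 50))
#' segmentTiming(a, ms)
#' @export
segmentTiming <- function(arc, machine) {
  w <- arc@cumWeights
  dMU <- arc@totalMU * diff(w)
  dTheta <- abs(angularDiff(arc@gantryAngles))
  dt <- pmax(dMU / (machine@maxDoseRate / 60), dTheta / machine@maxGantrySpeed)
  motion <- rowSums(abs(diff(arc@bankA)) + abs(diff(arc@bankB))) > 1e-9
  data.frame(dMU = dMU, dTheta = dTheta, dt = dt,
             degenerate = dt <= 0 & motion)
}

# Signed shortest angular difference between consecutive gantry angles,
# tolerant of the 0/360 wrap.
angularDiff <- function(theta) {
  d <- diff(theta)
  d <- (d + 180) %% 360 - 180
  d
}

#' Aperture geometry at one control point
#'
#' A leaf pair is dosimetrically open iff its gap exceeds the machine's
#' minimum leaf gap and its leaf row is not fully outside the y-jaw span.
#' Open gaps are clipped to the x jaws and rows to the y jaws
#' (\code{clipToJaws = FALSE} disables both clips). The area is the summed
#' clipped rectangle area; the perimeter traces the jagged outline of the
#' union of the clipped per-pair rectangles.
#'
#' @param bankA,bankB leaf positions (mm) for one control point
#' @param jaws length-4 numeric c(x1, x2, y1, y2)
#' @param machine a \linkS4class{MachineSpec}
#' @param clipToJaws clip apertures to the jaw rectangle (default TRUE)
#' @return an \linkS4class{Aperture}
#' @export
apertureGeometry <- function(bankA, bankB, jaws, machine, clipToJaws = TRUE) {
  b <- machine@leafBoundaries
  y0 <- b[-length(b)]; y1 <- b[-1]
  gap <- bankB - bankA
  if (clipToJaws) {
    left <- pmax(bankA, jaws[1]); right <- pmin(bankB, jaws[2])
    ry0 <- pmax(y0, jaws[3]); ry1 <- pmin(y1, jaws[4])
  } else {
    left <- bankA; right <- bankB
    ry0 <- y0; ry1 <- y1
  }
  open <- gap > machine@minLeafGap & ry1 > ry0 & right > left
  idx <- which(open)
  if (!length(idx))
    return(new("Aperture",
               openPairs = data.frame(pair = integer(), gap = numeric(),
                                      left = numeric(), right = numeric(),
                                      y0 = numeric(), y1 = numeric()),
               area = 0, perimeter = 0))
  op <- data.frame(pair = idx, gap = gap[idx], left = left[idx],
                   right = right[idx], y0 = ry0[idx], y1 = ry1[idx])
  area <- sum((op$right - op$left) * (op$y1 - op$y0))
  new("Aperture", openPairs = op, area = area,
      perimeter = rowStackPerimeter(left, right, ry0, ry1, open))
}

# Perimeter of a union of leaf-row rectangles stacked along y. Vertical
# contributions are the row heights on both sides; horizontal contributions
# come from each interface between consecutive rows (closed rows count as
# empty), plus the caps of the first and last open rows. Rows whose
# intervals do not overlap share no boundary, which the overlap term
# handles automatically. Vectorized over rows.
rowStackPerimeter <- function(left, right, y0, y1, open) {
  len <- ifelse(open, right - left, 0)
  h <- ifelse(open, y1 - y0, 0)
  n <- length(len)
  l <- ifelse(open, left, Inf); r <- ifelse(open, right, -Inf)
  lenPad <- c(0, len, 0)
  lPad <- c(Inf, l, Inf); rPad <- c(-Inf, r, -Inf)
  ov <- pmax(0, pmin(rPad[-1], rPad[-(n + 2)]) - pmax(lPad[-1], lPad[-(n + 2)]))
  horiz <- sum(lenPad[-1] + lenPad[-(n + 2)] - 2 * ov)
  2 * sum(h) + horiz
}

# All apertures of an arc as a list (one per control point).
arcApertures <- function(arc, machine, clipToJaws = TRUE) {
  lapply(seq_len(nControlPoints(arc)), function(i)
    apertureGeometry(arc@bankA[i, ], arc@bankB[i, ], arc@jaws[i, ],
                     machine, clipToJaws))
}

# Per-control-point MU series of an arc: meterset-weight differences
# assigned to the segment's end control point; the first control point
# takes the first segment's MU.
controlPointMU <- function(arc) {
  d <- arc@totalMU * diff(arc@cumWeights)
  c(d[1], d)
}
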