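#' @import methods
NULL

#' Machine specification for a VMAT delivery unit
#'
#' Describes the MLC geometry and delivery limits needed to interpret a plan:
#' leaf-pair boundaries projected to the isocenter plane (mm, cross-leaf axis),
#' the maximum dose rate (MU/min), maximum gantry speed (deg/s), maximum leaf
#' speed (cm/s) and the dosimetric minimum leaf gap (mm) below which a pair is
#' treated as closed.
#'
#' @slot name machine name (matched against the DICOM TreatmentMachineName)
#' @slot nLeafPairs number of opposed leaf pairs
#' @slot leafBoundaries numeric of length \code{nLeafPairs + 1}, strictly
#'   increasing leaf-side boundaries (mm at isocenter)
#' @slot maxDoseRate MU/min
#' @slot maxGantrySpeed deg/s
#' @slot maxLeafSpeed cm/s
#' @slot minLeafGap mm; gaps at or below this are dosimetrically closed
#' @exportClass MachineSpec
setClass("MachineSpec",
  representation(
    name = "character",
    nLeafPairs = "integer",
    leafBoundaries = "numeric",
    maxDoseRate = "numeric",
    maxGantrySpeed = "numeric",
    maxLeafSpeed = "numeric",
    minLeafGap = "numeric"
  )
)

setValidity("MachineSpec", function(object) {
  msg <- character()
  if (length(object@leafBoundaries) != object@nLeafPairs + 1L)
    msg <- c(msg, "leafBoundaries must have length nLeafPairs + 1")
  if (any(diff(object@leafBoundaries) <= 0))
    msg <- c(msg, "leafBoundaries must be strictly increasing")
  for (s in c("maxDoseRate", "maxGantrySpeed", "maxLeafSpeed"))
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be > 0"))
  if (object@minLeafGap < 0) msg <- c(msg, "minLeafGap must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A single VMAT arc (beam)
#'
#' Control-point state is stored columnwise: per-control-point gantry angles
#' and cumulative meterset weights, leaf-bank position matrices (rows =
#' control points, columns = leaf pairs; bank A carries the negative-side
#' leaves under IEC 61217) and a jaw matrix with columns x1, x2, y1, y2 (mm).
#'
#' @slot beamId beam identifier
#' @slot totalMU total monitor units of the arc
#' @slot gantryAngles deg, IEC 61217, one per control point
#' @slot gantryDirection "CW" or "CC"
#' @slot cumWeights cumulative meterset weight in [0, 1], non-decreasing,
#'   first 0 and last 1
#' @slot bankA,bankB position matrices (mm), nCP x nLeafPairs
#' @slot jaws nCP x 4 matrix, columns x1, x2, y1, y2 (mm)
#' @exportClass Arc
setClass("Arc",
  representation(
    beamId = "character",
    totalMU = "numeric",
    gantryAngles = "numeric",
    gantryDirection = "character",
    cumWeights = "numeric",
    bankA = "matrix",
    bankB = "matrix",
    jaws = "matrix"
  )
)

setValidity("Arc", function(object) {
  msg <- character()
  n <- length(object@cumWeights)
  if (n < 2L) msg <- c(msg, "an arc needs at least 2 control points")
  if (length(object@gantryAngles) != n)
    msg <- c(msg, "gantryAngles length must match cumWeights")
  if (n >= 2L) {
    if (abs(object@cumWeights[1L]) > 1e-9)
      msg <- c(msg, "first cumulative meterset weight must be 0")
    if (abs(object@cumWeights[n] - 1) > 1e-9)
      msg <- c(msg, "last cumulative meterset weight must be 1")
    if (any(diff(object@cumWeights) < -1e-9))
      msg <- c(msg, "cumulative meterset weights must be non-decreasing")
  }
  if (nrow(object@bankA) != n || nrow(object@bankB) != n)
    msg <- c(msg, "bank matrices must have one row per control point")
  if (ncol(object@bankA) != ncol(object@bankB))
    msg <- c(msg, "bank matrices must have equal numbers of leaf pairs")
  if (nrow(object@jaws) != n || ncol(object@jaws) != 4L)
    msg <- c(msg, "jaws must be an nCP x 4 matrix (x1, x2, y1, y2)")
  # opposed leaves may not interdigitate past a small tolerance
  if (nrow(object@bankA) == n && any(object@bankB - object@bankA < -1e-6))
    msg <- c(msg, "bank B positions must not fall below bank A positions")
  if (object@totalMU <= 0) msg <- c(msg, "totalMU must be > 0")
  if (!object@gantryDirection %in% c("CW", "CC"))
    msg <- c(msg, "gantryDirection must be 'CW' or 'CC'")
  if (length(msg)) msg else TRUE
})

#' A VMAT treatment plan
#'
#' @slot planId plan identifier (RT Plan label)
#' @slot machine a \linkS4class{MachineSpec}
#' @slot arcs list of \linkS4class{Arc} objects
#' @slot fractionDose prescribed dose to the primary target per fraction (Gy)
#' @slot totalMU plan total MU (sum over arcs)
#' @exportClass RTPlan
setClass("RTPlan",
  representation(
    planId = "character",
    machine = "MachineSpec",
    arcs = "list",
    fractionDose = "numeric",
    totalMU = "numeric"
  )
)

setValidity("RTPlan", function(object) {
  msg <- character()
  if (length(object@arcs) < 1L) msg <- c(msg, "a plan needs at least one arc")
  if (!all(vapply(object@arcs, is, logical(1), "Arc")))
    msg <- c(msg, "arcs must be a list of Arc objects")
  if (object@fractionDose <= 0) msg <- c(msg, "fractionDose must be > 0")
  np <- object@machine@nLeafPairs
  for (a in object@arcs)
    if (ncol(a@bankA) != np) {
      msg <- c(msg, "arc leaf-pair count does not match the machine spec")
      break
    }
  mu <- sum(vapply(object@arcs, function(a) a@totalMU, numeric(1)))
  if (abs(mu - object@totalMU) > 1e-6 * max(1, mu))
    msg <- c(msg, "totalMU must equal the sum of arc MUs")
  if (length(msg)) msg else TRUE
})

#' Beam aperture at one control point
#'
#' Produced by \code{\link{apertureGeometry}}. \code{openPairs} holds, per
#' dosimetrically open leaf pair, the physical gap and the jaw-clipped
#' rectangle (left/right leaf edges, lower/upper leaf-row bounds, all mm).
#'
#' @slot openPairs data.frame with columns pair, gap, left, right, y0, y1
#' @slot area jaw-clipped aperture area (mm^2)
#' @slot perimeter length of the jagged aperture outline (mm)
#' @exportClass Aperture
setClass("Aperture",
  representation(openPairs = "data.frame", area = "numeric",
                 perimeter = "numeric")
)

setValidity("Aperture", function(object) {
  msg <- character()
  if (object@area < 0) msg <- c(msg, "area must be >= 0")
  if ((object@perimeter == 0) != (object@area == 0))
    msg <- c(msg, "perimeter must be 0 exactly when area is 0")
  if (length(msg)) msg else TRUE
})

#' A 2-D dose plane
#'
#' @slot values dose matrix (rows = y, columns = x), arbitrary dose units
#' @slot spacing pixel spacing (mm), c(x, y)
#' @slot origin position of values[1, 1] (mm), c(x, y)
#' @exportClass DosePlane
setClass("DosePlane",
  representation(values = "matrix", spacing = "numeric", origin = "numeric")
)

setValidity("DosePlane", function(object) {
  msg <- character()
  if (length(object@spacing) != 2L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be two positive numbers")
  if (length(object@origin) != 2L) msg <- c(msg, "origin must have length 2")
  if (any(object@values < 0)) msg <- c(msg, "dose values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A gamma-analysis acceptance criterion
#'
#' @slot dosePct dose-difference criterion, percent of the global
#'   normalization dose
#' @slot distMm distance-to-agreement criterion (mm)
#' @slot thresholdPct low-dose threshold, percent of the normalization dose;
#'   reference points below it are not evaluated
#' @slot actionLimit gamma passing rate (percent) at or above which a plan
#'   passes QA
#' @slot normalization "global" (normalization dose = max of the reference)
#' @exportClass GammaCriterion
setClass("GammaCriterion",
  representation(dosePct = "numeric", distMm = "numeric",
                 thresholdPct = "numeric", actionLimit = "numeric",
                 normalization = "character")
)

setValidity("GammaCriterion", function(object) {
  msg <- character()
  if (object@dosePct <= 0) msg <- c(msg, "dosePct must be > 0")
  if (object@distMm <= 0) msg <- c(msg, "distMm must be > 0")
  if (object@thresholdPct <= 0) msg <- c(msg, "thresholdPct must be > 0")
  if (object@actionLimit < 0 || object@actionLimit > 100)
    msg <- c(msg, "actionLimit must be in [0, 100]")
  if (!identical(object@normalization, "global"))
    msg <- c(msg, "only global normalization is supported")
  if (length(msg)) msg else TRUE
})

#' Result of a 2-D gamma analysis
#'
#' @slot gamma gamma map on the reference grid; NA where the reference dose
#'   is below the evaluation threshold
#' @slot gpr gamma passing rate, percent of evaluated points with gamma <= 1
#' @slot nEvaluated number of evaluated reference points
#' @slot criterion the \linkS4class{GammaCriterion} used
#' @exportClass GammaResult
setClass("GammaResult",
  representation(gamma = "matrix", gpr = "numeric", nEvaluated = "integer",
                 criterion = "GammaCriterion")
)

setValidity("GammaResult", function(object) {
  msg <- character()
  if (any(object@gamma < 0, na.rm = TRUE)) msg <- c(msg, "gamma must be >= 0")
  if (object@gpr < 0 || object@gpr > 100) msg <- c(msg, "gpr must be in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Planomics histogram configuration
#'
#' Maps each control-point metric to a fixed bin grid and to the histogram
#' variants computed from it: "T" (control-point-count proportions) and "TR"
#' (per-control-point-MU weighted proportions). Feature names follow the
#' template \code{<METRIC>_<VARIANT>_<lo>-<hi>}.
#'
#' @slot metrics named list; each entry is list(edges = numeric, variants =
#'   character subset of c("T", "TR"))
#' @exportClass PlanomicsConfig
setClass("PlanomicsConfig", representation(metrics = "list"))

setValidity("PlanomicsConfig", function(object) {
  msg <- character()
  if (is.null(names(object@metrics)) || any(names(object@metrics) == ""))
    msg <- c(msg, "metrics must be a named list")
  for (nm in names(object@metrics)) {
    m <- object@metrics[[nm]]
    if (!is.numeric(m$edges) || length(m$edges) < 2L || any(diff(m$edges) <= 0))
      msg <- c(msg, paste0(nm, ": edges must be strictly increasing, length >= 2"))
    if (!all(m$variants %in% c("T", "TR")) || !length(m$variants))
      msg <- c(msg, paste0(nm, ": variants must be a subset of T, TR"))
  }
  if (length(msg)) msg else TRUE
})
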