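#' @include AllClasses.R
NULL

#' Plan identifier
#' @param x an \linkS4class{RTPlan}
#' @return character plan id
#' @export
setGeneric("planId", function(x) standardGeneric("planId"))

#' Machine specification of a plan
#' @param x an \linkS4class{RTPlan}
#' @return the \linkS4class{MachineSpec}
#' @export
setGeneric("machine", function(x) standardGeneric("machine"))

#' List of arcs in a plan
#' @param x an \linkS4class{RTPlan}
#' @return list of \linkS4class{Arc}
#' @export
setGeneric("arcs", function(x) standardGeneric("arcs"))

#' Number of control points
#' @param x an \linkS4class{Arc} or \linkS4class{RTPlan}
#' @return integer count (summed over arcs for a plan)
#' @export
setGeneric("nControlPoints", function(x) standardGeneric("nControlPoints"))

#' Total monitor units
#' @param x an \linkS4class{Arc} or \linkS4class{RTPlan}
#' @return MU
#' @export
setGeneric("totalMU", function(x) standardGeneric("totalMU"))

#' Prescribed dose per fraction
#' @param x an \linkS4class{RTPlan}
#' @return Gy
#' @export
setGeneric("fractionDose", function(x) standardGeneric("fractionDose"))

#' Gamma passing rate of a gamma result
#' @param x a \linkS4class{GammaResult}
#' @return percent in [0, 100]
#' @export
setGeneric("gpr", function(x) standardGeneric("gpr"))

#' Feature names defined by a planomics configuration
#' @param x a \linkS4class{PlanomicsConfig}
#' @return character vector, fixed order
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname planId
#' @export
setMethod("planId", "RTPlan", function(x) x@planId)

#' @rdname machine
#' @export
setMethod("machine", "RTPlan", function(x) x@machine)

#' @rdname arcs
#' @export
setMethod("arcs", "RTPlan", function(x) x@arcs)

#' @rdname nControlPoints
#' @export
setMethod("nControlPoints", "Arc", function(x) length(x@cumWeights))

#' @rdname nControlPoints
#' @export
setMethod("nControlPoints", "RTPlan", function(x)
  sum(vapply(x@arcs, nControlPoints, integer(1))))

#' @rdname totalMU
#' @export
setMethod("totalMU", "Arc", function(x) x@totalMU)

#' @rdname totalMU
#' @export
setMethod("totalMU", "RTPlan", function(x) x@totalMU)

#' @rdname fractionDose
#' @export
setMethod("fractionDose", "RTPlan", function(x) x@fractionDose)

#' @rdname gpr
#' @export
setMethod("gpr", "GammaResult", function(x) x@gpr)

setMethod("show", "MachineSpec", function(object) {
  cat("MachineSpec:", object@name, "\n")
  cat(" ", object@nLeafPairs, "leaf pairs spanning [",
      min(object@leafBoundaries), ",", max(object@leafBoundaries), "] mm\n")
  cat("  max dose rate", object@maxDoseRate, "MU/min; max gantry speed",
      object@maxGantrySpeed, "deg/s; max leaf speed", object@maxLeafSpeed,
      "cm/s; min leaf gap", object@minLeafGap, "mm\n")
})

setMethod("show", "Arc", function(object) {
  cat("Arc", object@beamId, ":", nControlPoints(object), "control points,",
      format(object@totalMU, digits = 6), "MU,", object@gantryDirection, "\n")
})

setMethod("show", "RTPlan", function(object) {
  cat("RTPlan", object@planId, "on", object@machine@name, "\n")
  cat(" ", length(object@arcs), "arc(s),", nControlPoints(object),
      "control points,", format(object@totalMU, digits = 6), "MU,",
      object@fractionDose, "Gy/fraction\n")
})

setMethod("show", "GammaCriterion", function(object) {
  cat(sprintf("GammaCriterion %g%%/%g mm, threshold %g%%, action limit %g%% (%s)\n",
              object@dosePct, object@distMm, object@thresholdPct,
              object@actionLimit, object@normalization))
})

setMethod("show", "GammaResult", function(object) {
  cat(sprintf("GammaResult: GPR %.2f%% over %d evaluated points at %g%%/%g mm\n",
              object@gpr, object@nEvaluated, object@criterion@dosePct,
              object@criterion@distMm))
})

setMethod("show", "DosePlane", function(object) {
  cat("DosePlane", nrow(object@values), "x", ncol(object@values),
      "at", object@spacing[1], "x", object@spacing[2], "mm\n")
})

setMethod("show", "PlanomicsConfig", function(object) {
  n <- vapply(names(object@metrics), function(nm) {
    m <- object@metrics[[nm]]
    (length(m$edges) - 1L) * length(m$variants)
  }, integer(1))
  cat("PlanomicsConfig:", length(object@metrics), "metrics,", sum(n),
      "features\n")
  for (nm in names(object@metrics)) {
    m <- object@metrics[[nm]]
    cat(sprintf("  %-5s %4d bins x {%s}\n", nm, length(m$edges) - 1L,
                paste(m$variants, collapse = ",")))
  }
})
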