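# Control-point-resolved ("planomics") metric series and histogram
# featurization.

#' Per-control-point complexity metric series
#'
#' One row per control point (all arcs concatenated) with: MU (the
#' control point's monitor units from meterset-weight differences; the
#' first control point of an arc takes the first segment's MU), AA
#' (aperture area, mm^2), MUAP (MU x AA, MU mm^2), PSR (circle-normalized
#' irregularity perimeter^2 / 4 pi area; 0 at closed apertures), SF (mean
#' open-leaf speed of the flanking segments, cm/s), RF (segment dose rate
#' assigned to the segment's end control point, MU/min) and GAP (mean open
#' leaf-pair gap, mm).
#'
#' @param plan an \linkS4class{RTPlan}
#' @param clipToJaws clip apertures to the jaws
#' @return data.frame with columns arc, cp, MU, AA, MUAP, PSR, SF, RF, GAP
#' @export
perControlPointSeries <- function(plan, clipToJaws = TRUE) {
  geo <- planGeometry(plan, clipToJaws)
  out <- vector("list", length(geo))
  nClosed <- 0L
  for (k in seq_along(geo)) {
    g <- geo[[k]]
    n <- nrow(g$open)
    aa <- g$areas
    psr <- ifelse(aa > 0, g$perims^2 / (4 * pi * pmax(aa, 1e-12)), 0)
    nClosed <- nClosed + sum(aa <= 0)
    # mean open-leaf speed of flanking segments
    arcObj <- plan@arcs[[k]]
    dt <- g$seg$dt
    segMask <- g$open[-n, , drop = FALSE] | g$open[-1, , drop = FALSE]
    ok <- dt > 0
    vA <- abs(diff(arcObj@bankA)) / 10 / dt
    vB <- abs(diff(arcObj@bankB)) / 10 / dt
    vA[!ok | !segMask] <- NA; vB[!ok | !segMask] <- NA
    segSpeed <- rowMeans(cbind(vA, vB), na.rm = TRUE)
    segSpeed[is.nan(segSpeed)] <- 0
    sf <- numeric(n)
    sf[1] <- segSpeed[1]; sf[n] <- segSpeed[n - 1]
    if (n > 2) sf[2:(n - 1)] <- (segSpeed[-(n - 1)] + segSpeed[-1]) / 2
    rfSeg <- ifelse(ok, g$seg$dMU / dt * 60, 0)
    rf <- c(rfSeg[1], rfSeg)
    gapMean <- vapply(seq_len(n), function(i) {
      op <- g$open[i, ]
      if (any(op)) mean(g$gap[i, op]) else 0
    }, numeric(1))
    out[[k]] <- data.frame(arc = k, cp = seq_len(n), MU = g$muCP, AA = aa,
                           MUAP = g$muCP * aa, PSR = psr, SF = sf, RF = rf,
                           GAP = gapMean)
  }
  res <- do.call(rbind, out)
  attr(res, "nClosed") <- nClosed
  res
}

#' Construct a planomics configuration
#'
#' @param metrics named list; each entry list(edges = strictly increasing
#'   numeric bin edges, variants = subset of c("T", "TR"))
#' @return a \linkS4class{PlanomicsConfig}
#' @export
planomicsConfig <- function(metrics) new("PlanomicsConfig", metrics = metrics)

#' The shipped default planomics configuration (2,476 features)
#'
#' Fixed bin grids per metric: MUAP 0-60000 by 200 (300 bins, T and TR;
#' the grid contains the 24200-24400 band), MU 0-20 by 0.1 (200 bins, T
#' and TR), AA 0-30000 by 200 (150 bins, T and TR), GAP 0-150 by 1 mm
#' (150 bins, T and TR), PSR 0-47 by 0.25 (188 bins, T and TR), SF 0-2.5
#' by 0.01 cm/s (250 bins, T), RF 0-800 by 3.2 MU/min (250 bins, T);
#' 2 x (300 + 200 + 150 + 150 + 188) + 250 + 250 = 2,476 features.
#'
#' @return a \linkS4class{PlanomicsConfig}
#' @export
defaultPlanomicsConfig <- function() {
  planomicsConfig(list(
    MUAP = list(edges = seq(0, 60000, by = 200), variants = c("T", "TR")),
    MU   = list(edges = seq(0, 20, by = 0.1),    variants = c("T", "TR")),
    AA   = list(edges = seq(0, 30000, by = 200), variants = c("T", "TR")),
    GAP  = list(edges = seq(0, 150, by = 1),     variants = c("T", "TR")),
    PSR  = list(edges = seq(0, 47, by = 0.25),   variants = c("T", "TR")),
    SF   = list(edges = seq(0, 2.5, by = 0.01),  variants = "T"),
    RF   = list(edges = seq(0, 800, by = 3.2),   variants = "T")
  ))
}

fmtEdge <- function(x) {
  s <- sprintf("%.10g", x)
  s
}

#' @rdname featureNames
#' @export
setMethod("featureNames", "PlanomicsConfig", function(x) {
  unlist(lapply(names(x@metrics), function(nm) {
    m <- x@metrics[[nm]]
    lo <- fmtEdge(m$edges[-length(m$edges)])
    hi <- fmtEdge(m$edges[-1])
    unlist(lapply(m$variants, function(v)
      paste0(nm, "_", v, "_", lo, "-", hi)))
  }), use.names = FALSE)
})

#' Histogram featurization of a control-point metric series
#'
#' Variant "T" is the proportion of control points whose metric value
#' falls in each bin; variant "TR" weights each control point by its MU.
#' Values outside the grid are absorbed into the edge bins, so each
#' (metric, variant) block sums to 1 for a nonempty series.
#'
#' @param series data.frame from \code{\link{perControlPointSeries}}
#' @param config a \linkS4class{PlanomicsConfig}
#' @return named numeric vector (the planomics vector)
#' @export
histogramFeaturize <- function(series, config) {
  validObject(config)
  if (is.null(series) || !nrow(series)) {
    warning("empty control-point series; planomics vector is all zero")
    out <- rep(0, length(featureNames(config)))
    names(out) <- featureNames(config)
    return(out)
  }
  blocks <- lapply(names(config@metrics), function(nm) {
    m <- config@metrics[[nm]]
    x <- series[[nm]]
    if (is.null(x)) stop("series lacks metric column '", nm, "'")
    nb <- length(m$edges) - 1L
    xi <- pmin(pmax(x, m$edges[1]), m$edges[length(m$edges)] - 1e-12)
    idx <- pmin(pmax(findInterval(xi, m$edges, rightmost.closed = TRUE), 1L), nb)
    unlist(lapply(m$variants, function(v) {
      w <- if (v == "TR") series$MU else rep(1, length(x))
      h <- numeric(nb)
      agg <- rowsum(w, idx)
      h[as.integer(rownames(agg))] <- agg[, 1]
      h / sum(w)
    }))
  })
  out <- unlist(blocks)
  names(out) <- featureNames(config)
  out
}

#' Extract the planomics feature vector of a plan
#'
#' @param plan an \linkS4class{RTPlan}
#' @param config a \linkS4class{PlanomicsConfig}; the shipped default
#'   yields exactly 2,476 features
#' @param clipToJaws clip apertures to the jaws
#' @return named numeric vector of fixed length and order
#' @examples
#' spec <- cohortSpec(nPlans = 1, cpPerArc = 24, arcRange = c(2, 2))
#' v <- extractPlanomics(simulatePlan(spec, 1, seed = 7))
#' length(v)   # 2476
#' @export
extractPlanomics <- function(plan, config = defaultPlanomicsConfig(),
                             clipToJaws = TRUE) {
  histogramFeaturize(perControlPointSeries(plan, clipToJaws), config)
}
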