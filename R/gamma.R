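# 2-D gamma-index engine (global normalization, reference-anchored).

#' Construct a dose plane
#'
#' @param values dose matrix (rows = y, columns = x)
#' @param spacing pixel spacing c(x, y) in mm (a scalar is recycled)
#' @param origin position of values[1, 1] in mm, c(x, y)
#' @return a \linkS4class{DosePlane}
#' @export
dosePlane <- function(values, spacing = c(1, 1), origin = c(0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 2)
  new("DosePlane", values = as.matrix(values), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a gamma criterion
#'
#' @param dosePct dose difference (\% of the global normalization dose)
#' @param distMm distance to agreement (mm)
#' @param thresholdPct low-dose threshold (\% of the normalization dose)
#' @param actionLimit QA action limit on the GPR (\%)
#' @return a \linkS4class{GammaCriterion}
#' @export
gammaCriterion <- function(dosePct, distMm, thresholdPct = 10,
                           actionLimit = 95) {
  new("GammaCriterion", dosePct = dosePct, distMm = distMm,
      thresholdPct = thresholdPct, actionLimit = actionLimit,
      normalization = "global")
}

#' The three clinical gamma criteria with strict action limits
#'
#' 3\%/3 mm (limit 99\%), 3\%/2 mm (limit 98\%) and 2\%/2 mm (limit 95\%),
#' all with a 10\% dose threshold and global normalization.
#'
#' @return named list of \linkS4class{GammaCriterion}
#' @export
defaultCriteria <- function() {
  list(gpr_3_3 = gammaCriterion(3, 3, 10, 99),
       gpr_3_2 = gammaCriterion(3, 2, 10, 98),
       gpr_2_2 = gammaCriterion(2, 2, 10, 95))
}

planeAxes <- function(p) {
  list(x = p@origin[1] + (seq_len(ncol(p@values)) - 1L) * p@spacing[1],
       y = p@origin[2] + (seq_len(nrow(p@values)) - 1L) * p@spacing[2])
}

#' Compute a 2-D gamma map and gamma passing rate
#'
#' Reference-anchored gamma with global normalization: for each reference
#' point with dose at or above the threshold,
#' \deqn{\gamma = \min_p \sqrt{ \|r - p\|^2 / d^2 + (D_e(p) - D_r(r))^2 /
#' (\Delta D)^2 }}
#' over evaluated-plane positions \eqn{p} within \code{searchFactor x
#' distMm} of \eqn{r}, where candidate positions form a stencil of step
#' \code{distMm / interpFactor} anchored at each reference point and the
#' evaluated dose is bilinearly interpolated there. \eqn{\Delta D} is \code{dosePct}\% of the
#' reference maximum.
#'
#' @param ref reference \linkS4class{DosePlane} (defines the evaluation
#'   grid and the normalization dose)
#' @param ev evaluated \linkS4class{DosePlane}
#' @param crit a \linkS4class{GammaCriterion}
#' @param interpFactor evaluated-plane resampling factor (default 10, i.e.
#'   a step of distMm / 10)
#' @param searchFactor search radius in units of distMm (default 3)
#' @return a \linkS4class{GammaResult}
#' @examples
#' r <- dosePlane(matrix(1, 11, 11) * outer(dnorm(-5:5, sd = 4),
#'                                          dnorm(-5:5, sd = 4)) * 1e3,
#'                spacing = 2.5)
#' g <- gammaMap(r, r, gammaCriterion(3, 3))
#' gpr(g)   # 100
#' @export
gammaMap <- function(ref, ev, crit, interpFactor = 10, searchFactor = 3) {
  validObject(ref); validObject(ev); validObject(crit)
  normDose <- max(ref@values)
  if (normDose <= 0) stop("reference plane has no dose (max = 0)")
  rax <- planeAxes(ref)
  eax <- planeAxes(ev)
  if (max(rax$x) < min(eax$x) || min(rax$x) > max(eax$x) ||
      max(rax$y) < min(eax$y) || min(rax$y) > max(eax$y))
    stop("reference and evaluated planes do not overlap")
  dd <- crit@dosePct / 100 * normDose
  dta <- crit@distMm
  step <- dta / interpFactor
  radius <- searchFactor * dta
  thr <- crit@thresholdPct / 100 * normDose
  # candidate stencil anchored at each reference point (offset 0 included,
  # so identical planes give gamma exactly 0)
  span <- floor(radius / step + 1e-9)
  offs <- expand.grid(dx = (-span:span) * step, dy = (-span:span) * step)
  keep <- offs$dx^2 + offs$dy^2 <= radius^2 + 1e-9
  odx <- offs$dx[keep]; ody <- offs$dy[keep]
  d2n <- (odx^2 + ody^2) / dta^2
  ex <- eax$x; ey <- eax$y
  nex <- length(ex); ney <- length(ey)
  nref <- nrow(ref@values); ncref <- ncol(ref@values)
  gam <- matrix(NA_real_, nref, ncref)
  v <- ev@values
  for (i in seq_len(nref)) {
    py <- rax$y[i] + ody
    okY <- py >= ey[1] & py <= ey[ney]
    for (j in seq_len(ncref)) {
      Dr <- ref@values[i, j]
      if (Dr < thr) next
      px <- rax$x[j] + odx
      ok <- okY & px >= ex[1] & px <= ex[nex]
      if (!any(ok)) next
      xi <- pmin(pmax(findInterval(px[ok], ex), 1L), nex - 1L)
      yi <- pmin(pmax(findInterval(py[ok], ey), 1L), ney - 1L)
      fxw <- (px[ok] - ex[xi]) / (ex[xi + 1L] - ex[xi])
      fyw <- (py[ok] - ey[yi]) / (ey[yi + 1L] - ey[yi])
      de <- v[cbind(yi, xi)] * (1 - fxw) * (1 - fyw) +
            v[cbind(yi, xi + 1L)] * fxw * (1 - fyw) +
            v[cbind(yi + 1L, xi)] * (1 - fxw) * fyw +
            v[cbind(yi + 1L, xi + 1L)] * fxw * fyw
      g2 <- d2n[ok] + (de - Dr)^2 / dd^2
      gam[i, j] <- sqrt(min(g2))
    }
  }
  evaluated <- !is.na(gam)
  n <- sum(evaluated)
  gprVal <- if (n) 100 * sum(gam[evaluated] <= 1) / n else 0
  new("GammaResult", gamma = gam, gpr = gprVal, nEvaluated = as.integer(n),
      criterion = crit)
}

#' QA pass/fail decision at an action limit
#'
#' A plan passes iff its GPR is at or above the criterion's action limit
#' (boundary inclusive).
#'
#' @param gprValue GPR in percent, or a \linkS4class{GammaResult}
#' @param crit a \linkS4class{GammaCriterion}
#' @return "pass" or "fail"
#' @export
passFail <- function(gprValue, crit) {
  if (is(gprValue, "GammaResult")) gprValue <- gprValue@gpr
  stopifnot(gprValue >= 0, gprValue <= 100)
  if (gprValue >= crit@actionLimit) "pass" else "fail"
}

#' Write a dose plane as CSV with spacing metadata
#'
#' Plain-text format: comment header lines \code{# spacing_x}, \code{#
#' spacing_y}, \code{# origin_x}, \code{# origin_y} followed by the dose
#' matrix as comma-separated rows (row 1 = first y).
#'
#' @param plane a \linkS4class{DosePlane}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeDosePlane <- function(plane, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# spacing_x %.10g", plane@spacing[1]),
               sprintf("# spacing_y %.10g", plane@spacing[2]),
               sprintf("# origin_x %.10g", plane@origin[1]),
               sprintf("# origin_y %.10g", plane@origin[2])), con)
  utils::write.table(plane@values, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a dose plane written by \code{\link{writeDosePlane}}
#'
#' @param path CSV file with spacing metadata header
#' @return a \linkS4class{DosePlane}
#' @export
readDosePlane <- function(path) {
  hdr <- readLines(path, n = 4)
  meta <- vapply(strsplit(hdr, " "), function(p) as.numeric(p[3]), numeric(1))
  vals <- as.matrix(utils::read.csv(path, header = FALSE, comment.char = "#"))
  dimnames(vals) <- NULL
  dosePlane(vals, spacing = meta[1:2], origin = meta[3:4])
}
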