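# Minimal DICOM codec (explicit VR little endian) for the RT Plan subset
# this package models. Only the elements written by writeRTPlan are
# interpreted on read; unknown elements are skipped tolerantly.

.LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
.RTPLAN_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.481.5"
.EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
.IMPLEMENTATION_UID <- "1.2.826.0.1.3680043.9.7433.1.0.1"

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) {
  # writeBin caps at .Machine$integer.max; encode manually
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

padEven <- function(txt, pad = charToRaw(" ")) {
  r <- charToRaw(txt)
  if (length(r) %% 2L) r <- c(r, pad)
  r
}

formatDS <- function(x) {
  # DICOM DS is limited to 16 bytes; %.9g stays well inside
  paste(sprintf("%.9g", x), collapse = "\\")
}

dcmElement <- function(group, elem, vr, valueRaw) {
  hdr <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (vr %in% .LONG_VRS) {
    c(hdr, as.raw(c(0, 0)), u32le(length(valueRaw)), valueRaw)
  } else {
    stopifnot(length(valueRaw) < 65536)
    c(hdr, u16le(length(valueRaw)), valueRaw)
  }
}

dcmText <- function(group, elem, vr, txt, pad = charToRaw(" "))
  dcmElement(group, elem, vr, padEven(paste(txt, collapse = "\\"), pad))

dcmDS <- function(group, elem, x) dcmText(group, elem, "DS", formatDS(x))
dcmIS <- function(group, elem, x)
  dcmText(group, elem, "IS", paste(sprintf("%d", as.integer(x)), collapse = "\\"))

dcmItem <- function(contentRaw)
  c(u16le(0xFFFE), u16le(0xE000), u32le(length(contentRaw)), contentRaw)

dcmSequence <- function(group, elem, itemsRaw) {
  body <- do.call(c, c(list(raw(0)), itemsRaw))
  dcmElement(group, elem, "SQ", body)
}

# ---- writer -----------------------------------------------------------------

planInstanceUID <- function(planId) {
  # deterministic pseudo-UID derived from the plan id
  codes <- utf8ToInt(planId)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 1e12
  sprintf("2.25.%012.0f%d", h, length(codes))
}

beamRaw <- function(arcObj, beamNumber, machineName, boundaries) {
  n <- length(arcObj@cumWeights)
  bld <- list(
    dcmItem(c(dcmText(0x300A, 0x00B8, "CS", "ASYMX"),
              dcmIS(0x300A, 0x00BC, 1))),
    dcmItem(c(dcmText(0x300A, 0x00B8, "CS", "ASYMY"),
              dcmIS(0x300A, 0x00BC, 1))),
    dcmItem(c(dcmText(0x300A, 0x00B8, "CS", "MLCX"),
              dcmIS(0x300A, 0x00BC, length(boundaries) - 1L),
              dcmDS(0x300A, 0x00BE, boundaries)))
  )
  cps <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- list(
      dcmItem(c(dcmText(0x300A, 0x00B8, "CS", "ASYMX"),
                dcmDS(0x300A, 0x011C, arcObj@jaws[i, 1:2]))),
      dcmItem(c(dcmText(0x300A, 0x00B8, "CS", "ASYMY"),
                dcmDS(0x300A, 0x011C, arcObj@jaws[i, 3:4]))),
      dcmItem(c(dcmText(0x300A, 0x00B8, "CS", "MLCX"),
                dcmDS(0x300A, 0x011C, c(arcObj@bankA[i, ], arcObj@bankB[i, ]))))
    )
    cps[[i]] <- dcmItem(c(
      dcmIS(0x300A, 0x0112, i - 1L),
      dcmSequence(0x300A, 0x011A, pos),
      dcmDS(0x300A, 0x011E, arcObj@gantryAngles[i]),
      dcmText(0x300A, 0x011F, "CS", arcObj@gantryDirection),
      dcmDS(0x300A, 0x0134, arcObj@cumWeights[i])
    ))
  }
  dcmItem(c(
    dcmText(0x300A, 0x00B2, "SH", machineName),
    dcmSequence(0x300A, 0x00B6, bld),
    dcmIS(0x300A, 0x00C0, beamNumber),
    dcmText(0x300A, 0x00C2, "LO", arcObj@beamId),
    dcmText(0x300A, 0x00C4, "CS", "DYNAMIC"),
    dcmText(0x300A, 0x00C6, "CS", "PHOTON"),
    dcmDS(0x300A, 0x010E, 1),
    dcmIS(0x300A, 0x0110, length(arcObj@cumWeights)),
    dcmSequence(0x300A, 0x0111, cps)
  ))
}

#' Write a plan as a DICOM-RT Plan file
#'
#' Emits an explicit-VR little-endian RT Plan with full per-control-point
#' state (gantry angle, cumulative meterset weight, jaw and MLC positions),
#' readable by \code{\link{readRTPlan}} and by standard DICOM toolkits.
#'
#' @param plan a valid \linkS4class{RTPlan}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeRTPlan <- function(plan, path) {
  validObject(plan)
  for (a in plan@arcs) validObject(a)
  sopInstance <- planInstanceUID(plan@planId)
  meta <- c(
    dcmElement(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcmText(0x0002, 0x0002, "UI", .RTPLAN_SOP_CLASS, pad = as.raw(0)),
    dcmText(0x0002, 0x0003, "UI", sopInstance, pad = as.raw(0)),
    dcmText(0x0002, 0x0010, "UI", .EXPLICIT_VR_LE, pad = as.raw(0)),
    dcmText(0x0002, 0x0012, "UI", .IMPLEMENTATION_UID, pad = as.raw(0))
  )
  metaGroup <- c(dcmElement(0x0002, 0x0000, "UL", u32le(length(meta))), meta)

  refBeams <- lapply(seq_along(plan@arcs), function(i)
    dcmItem(c(dcmDS(0x300A, 0x0086, plan@arcs[[i]]@totalMU),
              dcmIS(0x300C, 0x0006, i))))
  fg <- dcmItem(c(
    dcmIS(0x300A, 0x0071, 1),
    dcmIS(0x300A, 0x0078, 1),
    dcmIS(0x300A, 0x0080, length(plan@arcs)),
    dcmSequence(0x300C, 0x0004, refBeams)
  ))
  doseRef <- dcmItem(c(
    dcmText(0x300A, 0x0020, "CS", "TARGET"),
    dcmDS(0x300A, 0x0026, plan@fractionDose)
  ))
  beams <- lapply(seq_along(plan@arcs), function(i)
    beamRaw(plan@arcs[[i]], i, plan@machine@name,
            plan@machine@leafBoundaries))

  ds <- c(
    dcmText(0x0008, 0x0016, "UI", .RTPLAN_SOP_CLASS, pad = as.raw(0)),
    dcmText(0x0008, 0x0018, "UI", sopInstance, pad = as.raw(0)),
    dcmText(0x0008, 0x0060, "CS", "RTPLAN"),
    dcmText(0x0010, 0x0010, "PN", "Synthetic^Phantom"),
    dcmText(0x0010, 0x0020, "LO", plan@planId),
    dcmText(0x300A, 0x0002, "SH", plan@planId),
    dcmText(0x300A, 0x000C, "CS", "TREATMENT_DEVICE"),
    dcmSequence(0x300A, 0x0010, list(doseRef)),
    dcmSequence(0x300A, 0x0070, list(fg)),
    dcmSequence(0x300A, 0x00B0, beams)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(metaGroup, ds), con)
  invisible(path)
}

# ---- reader -----------------------------------------------------------------

readU16 <- function(buf, pos) sum(as.integer(buf[pos + 0:1]) * c(1, 256))
readU32 <- function(buf, pos)
  sum(as.numeric(buf[pos + 0:3]) * c(1, 256, 65536, 16777216))

# Parse an explicit-VR-LE element stream in buf[pos..end] into a named list
# keyed "GGGGEEEE" (uppercase hex). SQ values become lists of item datasets.
parseDataset <- function(buf, pos, end) {
  out <- list()
  while (pos + 7 <= end + 1) {
    group <- readU16(buf, pos); elem <- readU16(buf, pos + 2)
    pos <- pos + 4
    if (group == 0xFFFE) {            # delimitation items
      len <- readU32(buf, pos); pos <- pos + 4
      if (elem %in% c(0xE00D, 0xE0DD)) return(list(data = out, pos = pos))
      stop("unexpected item tag outside a sequence")
    }
    vr <- rawToChar(buf[pos + 0:1]); pos <- pos + 2
    if (vr %in% .LONG_VRS) {
      pos <- pos + 2
      len <- readU32(buf, pos); pos <- pos + 4
    } else {
      len <- readU16(buf, pos); pos <- pos + 2
    }
    key <- sprintf("%04X%04X", group, elem)
    if (vr == "SQ") {
      items <- list()
      if (len == 4294967295) {        # undefined length
        repeat {
          g2 <- readU16(buf, pos); e2 <- readU16(buf, pos + 2)
          l2 <- readU32(buf, pos + 4); pos <- pos + 8
          if (g2 == 0xFFFE && e2 == 0xE0DD) break
          stopifnot(g2 == 0xFFFE, e2 == 0xE000)
          if (l2 == 4294967295) {
            r <- parseDataset(buf, pos, end)
          } else {
            r <- parseDataset(buf, pos, pos + l2 - 1)
            r$pos <- pos + l2
          }
          items[[length(items) + 1L]] <- r$data
          pos <- r$pos
        }
      } else {
        sqEnd <- pos + len - 1
        while (pos <= sqEnd) {
          g2 <- readU16(buf, pos); e2 <- readU16(buf, pos + 2)
          l2 <- readU32(buf, pos + 4); pos <- pos + 8
          stopifnot(g2 == 0xFFFE, e2 == 0xE000)
          if (l2 == 4294967295) {
            r <- parseDataset(buf, pos, sqEnd)
          } else {
            r <- parseDataset(buf, pos, pos + l2 - 1)
            r$pos <- pos + l2
          }
          items[[length(items) + 1L]] <- r$data
          pos <- r$pos
        }
      }
      out[[key]] <- items
    } else {
      val <- buf[pos + seq_len(len) - 1]
      pos <- pos + len
      out[[key]] <- decodeValue(vr, val)
    }
  }
  list(data = out, pos = pos)
}

decodeValue <- function(vr, val) {
  if (vr %in% c("DS", "IS")) {
    txt <- trimws(rawToChar(val))
    if (!nzchar(txt)) return(numeric(0))
    as.numeric(strsplit(txt, "\\", fixed = TRUE)[[1]])
  } else if (vr %in% c("CS", "SH", "LO", "ST", "LT", "PN", "AE", "DA", "TM",
                       "UI", "AS", "DT")) {
    sub("[ \\x00]+$", "", rawToChar(val))
  } else if (vr == "UL") {
    readU32(val, 1)
  } else if (vr == "US") {
    readU16(val, 1)
  } else val
}

getEl <- function(ds, group, elem) ds[[sprintf("%04X%04X", group, elem)]]

#' Read a DICOM-RT Plan file
#'
#' Parses an explicit-VR little-endian RT Plan into an
#' \linkS4class{RTPlan}: one \linkS4class{Arc} per dynamic beam with full
#' control-point state. Cumulative meterset weights are normalized to
#' [0, 1] and the machine is resolved by treatment-machine name.
#'
#' @param path DICOM file
#' @param machines named list of \linkS4class{MachineSpec} used to resolve
#'   the TreatmentMachineName (default \code{\link{defaultMachines}()})
#' @return an \linkS4class{RTPlan}
#' @export
readRTPlan <- function(path, machines = defaultMachines()) {
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  # file meta group: group length element at offset 133
  stopifnot(readU16(buf, 133) == 0x0002)
  metaLen <- readU32(buf, 141)
  meta <- parseDataset(buf, 145, 144 + metaLen)$data
  ts <- getEl(meta, 0x0002, 0x0010)
  if (!identical(ts, .EXPLICIT_VR_LE))
    stop("unsupported transfer syntax: ", ts)
  ds <- parseDataset(buf, 145 + metaLen, length(buf))$data

  planLabel <- getEl(ds, 0x300A, 0x0002)
  if (is.null(planLabel)) planLabel <- "plan"
  fg <- getEl(ds, 0x300A, 0x0070)
  if (is.null(fg)) stop("RT Plan lacks a FractionGroupSequence")
  fg <- fg[[1]]
  refBeams <- getEl(fg, 0x300C, 0x0004)
  beamMU <- vapply(refBeams, function(it) getEl(it, 0x300A, 0x0086), numeric(1))
  names(beamMU) <- vapply(refBeams, function(it)
    as.character(getEl(it, 0x300C, 0x0006)), character(1))

  doseRef <- getEl(ds, 0x300A, 0x0010)
  nFrac <- getEl(fg, 0x300A, 0x0078)
  if (is.null(nFrac) || !length(nFrac)) nFrac <- 1
  fracDose <- if (!is.null(doseRef))
    getEl(doseRef[[1]], 0x300A, 0x0026) / nFrac else 2

  beams <- getEl(ds, 0x300A, 0x00B0)
  if (is.null(beams)) stop("RT Plan lacks a BeamSequence")
  machineName <- getEl(beams[[1]], 0x300A, 0x00B2)
  mach <- resolveMachine(machineName, machines)

  arcsOut <- list()
  for (b in beams) {
    beamName <- getEl(b, 0x300A, 0x00C2)
    if (is.null(beamName)) beamName <- as.character(getEl(b, 0x300A, 0x00C0))
    beamType <- getEl(b, 0x300A, 0x00C4)
    if (identical(beamType, "STATIC"))
      stop("unsupported technique: beam '", beamName, "' is STATIC, not a VMAT arc")
    cps <- getEl(b, 0x300A, 0x0111)
    if (is.null(cps) || length(cps) < 2L)
      stop("beam '", beamName, "' has no usable ControlPointSequence")
    finalW <- getEl(b, 0x300A, 0x010E)
    if (is.null(finalW) || finalW <= 0) finalW <- 1
    n <- length(cps)
    nPairs <- mach@nLeafPairs
    bankA <- matrix(NA_real_, n, nPairs)
    bankB <- matrix(NA_real_, n, nPairs)
    jaws <- matrix(NA_real_, n, 4)
    ang <- numeric(n); cw <- numeric(n)
    dir <- "CW"
    lastJaws <- c(-200, 200, -200, 200)
    lastA <- NULL; lastB <- NULL; lastAng <- NA_real_
    for (i in seq_len(n)) {
      cp <- cps[[i]]
      a <- getEl(cp, 0x300A, 0x011E)
      if (!is.null(a)) lastAng <- a
      ang[i] <- lastAng
      d <- getEl(cp, 0x300A, 0x011F)
      if (!is.null(d) && d %in% c("CW", "CC")) dir <- d
      cw[i] <- getEl(cp, 0x300A, 0x0134)
      bld <- getEl(cp, 0x300A, 0x011A)
      if (is.null(bld)) {
        if (i == 1L)
          stop("parse error in beam '", beamName,
               "': first control point lacks a BeamLimitingDevicePositionSequence")
        bankA[i, ] <- lastA; bankB[i, ] <- lastB; jaws[i, ] <- lastJaws
        next
      }
      sawMLC <- FALSE
      for (it in bld) {
        typ <- getEl(it, 0x300A, 0x00B8)
        posv <- getEl(it, 0x300A, 0x011C)
        if (typ %in% c("X", "ASYMX")) lastJaws[1:2] <- posv
        else if (typ %in% c("Y", "ASYMY")) lastJaws[3:4] <- posv
        else if (typ %in% c("MLCX", "MLCY")) {
          if (length(posv) != 2 * nPairs)
            stop("beam '", beamName, "': MLC bank length ", length(posv) / 2,
                 " does not match the machine spec (", nPairs, " pairs)")
          lastA <- posv[seq_len(nPairs)]
          lastB <- posv[nPairs + seq_len(nPairs)]
          sawMLC <- TRUE
        }
      }
      if (i == 1L && !sawMLC)
        stop("parse error in beam '", beamName,
             "': no MLC positions in the first control point")
      bankA[i, ] <- lastA; bankB[i, ] <- lastB; jaws[i, ] <- lastJaws
    }
    cw <- cw / finalW
    beamNo <- as.character(getEl(b, 0x300A, 0x00C0))
    mu <- if (beamNo %in% names(beamMU)) beamMU[[beamNo]]
          else sum(beamMU) / length(beams)
    arcsOut[[length(arcsOut) + 1L]] <-
      arc(beamName, mu, ang, cw, bankA, bankB, jaws, gantryDirection = dir)
  }
  rtPlan(planLabel, mach, arcsOut, fracDose)
}
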