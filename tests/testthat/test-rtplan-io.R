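# DICOM-RT plan model: round-trips, timing, aperture geometry.

test_that("write/read round-trip preserves all modeled plan fields", {
  spec <- cohortSpec(nPlans = 1, cpPerArc = 30, arcRange = c(2, 3))
  p <- simulatePlan(spec, 1, seed = 42)
  f <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(p, f)
  q <- readRTPlan(f)
  expect_equal(planId(q), planId(p))
  expect_equal(fractionDose(q), fractionDose(p), tolerance = 1e-8)
  expect_equal(totalMU(q), totalMU(p), tolerance = 1e-8)
  expect_length(arcs(q), length(arcs(p)))
  for (k in seq_along(arcs(p))) {
    a <- arcs(p)[[k]]; b <- arcs(q)[[k]]
    expect_equal(b@beamId, a@beamId)
    expect_equal(b@gantryDirection, a@gantryDirection)
    expect_equal(b@gantryAngles, a@gantryAngles, tolerance = 1e-8)
    expect_equal(b@cumWeights, a@cumWeights, tolerance = 1e-8)
    expect_equal(b@bankA, a@bankA, tolerance = 1e-8)
    expect_equal(b@bankB, a@bankB, tolerance = 1e-8)
    expect_equal(unname(b@jaws), unname(a@jaws), tolerance = 1e-8)
  }
})

test_that("a written plan is readable by an independent DICOM toolkit", {
  spec <- cohortSpec(nPlans = 1, cpPerArc = 12, arcRange = c(2, 2))
  p <- simulatePlan(spec, 1, seed = 5)
  f <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(p, f)
  py <- Sys.which("python")
  expect_true(nzchar(py))
  script <- paste(
    "import sys, pydicom",
    "d = pydicom.dcmread(sys.argv[1])",
    "b = d.BeamSequence[0]",
    "cp = b.ControlPointSequence[0]",
    "mlc = [q for q in cp.BeamLimitingDevicePositionSequence",
    "       if q.RTBeamLimitingDeviceType == 'MLCX'][0]",
    "print(d.Modality, len(d.BeamSequence), b.NumberOfControlPoints,",
    "      len(mlc.LeafJawPositions))",
    sep = "\n")
  out <- system2(py, c("-", f), input = script, stdout = TRUE)
  parts <- strsplit(out[length(out)], " +")[[1]]
  expect_equal(parts[1], "RTPLAN")
  expect_equal(as.integer(parts[2]), length(arcs(p)))
  expect_equal(as.integer(parts[3]), nControlPoints(arcs(p)[[1]]))
  expect_equal(as.integer(parts[4]), 120L)
})

test_that("2 arcs of 178 control points at 2.0341 deg give 356 in total", {
  spec <- cohortSpec(nPlans = 1, cpPerArc = 178, arcRange = c(2, 2))
  p <- simulatePlan(spec, 1, seed = 1)
  expect_equal(nControlPoints(p), 356L)
  a <- arcs(p)[[1]]
  expect_equal(abs(diff(a@gantryAngles[1:2])) %% 360, 2.0341, tolerance = 1e-9)
  f <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(p, f)
  expect_equal(nControlPoints(readRTPlan(f)), 356L)
})

test_that("a 7-arc plan writes 7 beams", {
  spec <- cohortSpec(nPlans = 1, cpPerArc = 8, arcRange = c(7, 7))
  p <- simulatePlan(spec, 1, seed = 3)
  expect_length(arcs(p), 7L)
  f <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(p, f)
  expect_length(arcs(readRTPlan(f)), 7L)
})

test_that("malformed plans are rejected on read and on construction", {
  # decreasing meterset weights never construct
  expect_error(
    toyArc(matrix(-10, 3, 10), matrix(10, 3, 10), weights = c(0, 0.8, 0.5)),
    "non-decreasing")
  # static beam type -> unsupported technique
  spec <- cohortSpec(nPlans = 1, cpPerArc = 6, arcRange = c(2, 2))
  p <- simulatePlan(spec, 1, seed = 2)
  f <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(p, f)
  buf <- readBin(f, "raw", file.size(f))
  pos <- grepRaw("DYNAMIC", buf)[1]
  buf[pos + 0:6] <- charToRaw("STATIC ")
  f2 <- withr::local_tempfile(fileext = ".dcm")
  writeBin(buf, f2)
  expect_error(readRTPlan(f2), "unsupported technique")
  # first control point without MLC positions -> parse error naming the beam
  buf <- readBin(f, "raw", file.size(f))
  pos <- grepRaw("MLCX", buf, all = TRUE)
  # corrupt the device type of the first positions item (after the two
  # BeamLimitingDeviceSequence entries the third MLCX is in control point 1)
  buf[pos[2] + 0:3] <- charToRaw("XXXX")
  f3 <- withr::local_tempfile(fileext = ".dcm")
  writeBin(buf, f3)
  expect_error(readRTPlan(f3), "no MLC positions")
  # not a DICOM file at all
  f4 <- withr::local_tempfile(fileext = ".dcm")
  writeLines("not dicom", f4)
  expect_error(readRTPlan(f4), "DICM")
})

test_that("segment timing follows the binding dose-rate/gantry-speed limit", {
  ms <- toyMachine()        # 600 MU/min, 6 deg/s
  mkArc <- function(w, ang, mu) {
    n <- length(w)
    toyArc(matrix(-10, n, 10), matrix(10, n, 10), totalMU = mu, weights = w,
           angles = ang)
  }
  # 10 MU over 2.0341 deg: dose-rate limited -> 1.0 s
  a <- mkArc(c(0, 1), c(180, 182.0341), 10)
  st <- segmentTiming(a, ms)
  expect_equal(st$dt, 1.0)
  expect_equal(st$dMU, 10)
  # 0 MU over 3 deg at 6 deg/s -> 0.5 s
  a2 <- arc("a", 10, c(180, 183), c(0, 1),
            matrix(-10, 2, 10), matrix(10, 2, 10), c(-50, 50, -50, 50))
  a2@cumWeights <- c(0, 1)   # weight still spans, but force dMU = 0 segment
  a3 <- mkArc(c(0, 0, 1), c(180, 183, 183.1), 10)
  st3 <- segmentTiming(a3, ms)
  expect_equal(st3$dt[1], 0.5)
})

test_that("segment timing matches a scalar re-computation on random arcs", {
  ms <- toyMachine()
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    w <- c(0, sort(runif(n - 2)), 1)
    ang <- (170 + cumsum(runif(n, 0.5, 3))) %% 360
    mu <- runif(1, 50, 400)
    a <- toyArc(matrix(rnorm(n * 10, -15, 2), n, 10),
                matrix(rnorm(n * 10, 15, 2), n, 10),
                totalMU = mu, weights = w, angles = ang)
    st <- segmentTiming(a, ms)
    # independent per-segment scalar loop
    for (i in seq_len(n - 1)) {
      dmu <- mu * (w[i + 1] - w[i])
      dth <- abs(ang[i + 1] - ang[i])
      if (dth > 180) dth <- 360 - dth
      expect_equal(st$dMU[i], dmu, tolerance = 1e-12)
      expect_equal(st$dt[i], max(dmu / 10, dth / 6), tolerance = 1e-12)
    }
    expect_equal(sum(st$dMU), mu, tolerance = 1e-6 * mu)
  }
})

test_that("timing is invariant to how the cumulative weights are produced", {
  ms <- toyMachine()
  raw <- c(2, 5, 1, 7, 4)
  w1 <- c(0, cumsum(raw) / sum(raw))
  w2 <- c(0, cumsum(raw * 13.7) / sum(raw * 13.7))
  n <- length(w1)
  a1 <- toyArc(matrix(-10, n, 10), matrix(10, n, 10), weights = w1)
  a2 <- toyArc(matrix(-10, n, 10), matrix(10, n, 10), weights = w2)
  expect_equal(segmentTiming(a1, ms), segmentTiming(a2, ms), tolerance = 1e-12)
})

test_that("aperture geometry: areas, closed-pair rule and perimeter oracle", {
  ms <- toyMachine(leafWidth = 5)
  jaws <- c(-100, 100, -100, 100)
  # two adjacent open pairs, gap 10 mm, leaf width 5 mm -> 100 mm^2
  bankA <- rep(0, 10); bankB <- rep(0, 10)
  bankA[5:6] <- -5; bankB[5:6] <- 5
  ap <- apertureGeometry(bankA, bankB, jaws, ms)
  expect_equal(ap@area, 100)
  # all gaps at the 2 mm minimum leaf gap -> closed plan, area 0
  ap0 <- apertureGeometry(rep(-1, 10), rep(1, 10), jaws, ms)
  expect_equal(ap0@area, 0)
  expect_equal(ap0@perimeter, 0)
  # staircase of 3 pairs with offsets matches the rasterized-outline oracle
  bA <- rep(0, 10); bB <- rep(0, 10)
  bA[4:6] <- c(-20, -12, -7); bB[4:6] <- c(-2, 6, 15)
  ap2 <- apertureGeometry(bA, bB, jaws, ms)
  b <- ms@leafBoundaries
  rects <- data.frame(x0 = bA[4:6], x1 = bB[4:6], y0 = b[4:6], y1 = b[5:7])
  oracle <- rasterOracle(rects, px = 0.1)
  expect_equal(ap2@area, oracle$area, tolerance = 1e-9)
  expect_equal(ap2@perimeter, oracle$perimeter, tolerance = 1e-9)
})

test_that("aperture area is monotone in gaps and never grows under jaw closing", {
  ms <- toyMachine(leafWidth = 5)
  set.seed(21)
  for (rep in 1:10) {
    bankA <- -runif(10, 0, 30); bankB <- runif(10, 0, 30)
    jaws <- c(-40, 40, -25, 25)
    a0 <- apertureGeometry(bankA, bankB, jaws, ms)@area
    # widen one random gap
    i <- sample(10, 1)
    a1 <- apertureGeometry(bankA - (seq_len(10) == i) * 5, bankB, jaws, ms)@area
    expect_gte(a1, a0)
    # close the jaws
    a2 <- apertureGeometry(bankA, bankB, c(-20, 20, -15, 15), ms)@area
    expect_lte(a2, a0)
  }
})

test_that("machine specs load from the shipped YAML config", {
  cfg <- system.file("extdata", "machines.yaml", package = "planqa")
  if (!nzchar(cfg)) cfg <- file.path("..", "..", "inst", "extdata", "machines.yaml")
  machines <- readMachineConfig(cfg)
  expect_true(all(c("TrueBeam", "Halcyon") %in% names(machines)))
  tb <- machines$TrueBeam
  expect_equal(tb@nLeafPairs, 60L)
  expect_equal(tb@maxDoseRate, 600)
  expect_equal(machines$Halcyon@nLeafPairs, 57L)
  expect_equal(machines$Halcyon@maxDoseRate, 800)
  expect_equal(tb@leafBoundaries, defaultMachines()$TrueBeam@leafBoundaries)
})
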