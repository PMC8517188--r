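# Conventional complexity metrics: kinematics, histograms, modulation
# indices, aperture scores, shape metrics, travel/delivery metrics.

test_that("leaf kinematics match a direct finite-difference oracle", {
  ms <- toyMachine()
  # static MLC: all speeds and accelerations zero
  a0 <- toyArc(matrix(-10, 5, 10), matrix(10, 5, 10))
  k0 <- leafKinematics(a0, ms)
  expect_true(all(k0$speeds == 0))
  expect_true(all(k0$accels == 0))
  # one leaf moves 10 mm over a 1.0 s segment -> 1.0 cm/s
  bankA <- matrix(-10, 2, 10); bankB <- matrix(10, 2, 10)
  bankB[2, 4] <- 20
  a1 <- toyArc(bankA, bankB, totalMU = 10, weights = c(0, 1),
               angles = c(180, 182.0341))   # dt = 1 s at 600 MU/min
  k1 <- leafKinematics(a1, ms)
  expect_equal(max(k1$speeds), 1.0)
  # random trajectories against an independent scalar loop
  set.seed(31)
  n <- 12
  bankA <- matrix(runif(n * 10, -30, -5), n, 10)
  bankB <- matrix(runif(n * 10, 5, 30), n, 10)
  w <- c(0, sort(runif(n - 2)), 1)
  a <- toyArc(bankA, bankB, totalMU = 150, weights = w)
  k <- leafKinematics(a, ms, movingMask = FALSE)
  st <- segmentTiming(a, ms)
  oracle <- c()
  for (leafM in list(bankA, bankB))
    for (p in 1:10) for (i in 1:(n - 1))
      oracle <- c(oracle, abs(leafM[i + 1, p] - leafM[i, p]) / 10 / st$dt[i])
  expect_equal(sort(k$speeds), sort(oracle), tolerance = 1e-12)
  # accelerations
  oracleA <- c()
  for (leafM in list(bankA, bankB))
    for (p in 1:10) for (j in 2:(n - 1)) {
      v1 <- abs(leafM[j, p] - leafM[j - 1, p]) / 10 / st$dt[j - 1]
      v2 <- abs(leafM[j + 1, p] - leafM[j, p]) / 10 / st$dt[j]
      oracleA <- c(oracleA, abs(v2 - v1) / mean(st$dt[c(j - 1, j)]))
    }
  expect_equal(sort(k$accels), sort(oracleA), tolerance = 1e-12)
})

test_that("kinematic histograms bin correctly and sum to one", {
  mkRec <- function(speeds, accels = numeric(0))
    structure(list(speeds = speeds, accels = accels,
                   speedWeights = rep(1, length(speeds))),
              class = "KinematicsRecord")
  h0 <- kinematicHistogramFeatures(mkRec(rep(0, 5)))
  expect_equal(unname(h0["S_0-0.4"]), 1)
  expect_equal(unname(sum(h0[paste0("S_", c("0.4-0.8", "0.8-1.2",
                                            "1.2-1.6", "1.6-2.0"))])), 0)
  expect_equal(unname(h0[c("ALS", "SLS")]), c(0, 0))
  h1 <- kinematicHistogramFeatures(mkRec(c(0.5, 0.5, 1.5)))
  expect_equal(unname(h1["S_0.4-0.8"]), 2 / 3)
  expect_equal(unname(h1["S_1.2-1.6"]), 1 / 3)
  expect_equal(unname(h1["ALS"]), 0.8333, tolerance = 1e-4)
  # random record: proportions equal a counting oracle and sum to 1
  set.seed(5)
  sp <- c(runif(200, 0, 3))          # includes overflow beyond 2.0
  ac <- c(runif(150, 0, 9))
  h <- kinematicHistogramFeatures(mkRec(sp, ac))
  sEdges <- c(0, 0.4, 0.8, 1.2, 1.6, 2.0)
  for (i in 1:4)
    expect_equal(unname(h[i]), mean(sp >= sEdges[i] & sp < sEdges[i + 1]))
  expect_equal(unname(h[5]), mean(sp >= 1.6))    # last bin absorbs overflow
  expect_equal(sum(h[1:5]), 1)
  expect_equal(sum(h[6:9]), 1)
  expect_equal(unname(h["SLA"]), sd(ac), tolerance = 1e-12)
})

test_that("modulation indices: degenerate conventions and Riemann oracle", {
  mkRec <- function(speeds, w = rep(1, length(speeds)))
    structure(list(speeds = speeds, accels = numeric(0), speedWeights = w),
              class = "KinematicsRecord")
  # equal nonzero speeds -> sigma 0 -> MI 0
  expect_equal(unname(modulationIndices(mkRec(rep(1.3, 10)), 1)["MI_s"]), 0)
  # construction with z = 1 on [0, f]: huge samples, tiny sigma around them
  x <- 1e6 + c(-1, 1) * 1e-3
  expect_equal(unname(modulationIndices(mkRec(rep(x, 50)), 2)["MI_s"]), 2,
               tolerance = 1e-6)
  # N(1, 0.2) speeds vs a fine Riemann-sum oracle
  set.seed(77)
  sp <- rnorm(400, 1, 0.2)
  mi <- unname(modulationIndices(mkRec(sp), 1)["MI_s"])
  sdv <- sd(sp)
  xs <- seq(0, 1, by = 1e-4)
  oracle <- sum(vapply(xs, function(u) mean(sp > u * sdv), numeric(1))) * 1e-4
  expect_equal(mi, oracle, tolerance = 1e-3)
})

test_that("aperture scores: SAS counting, identity case and MCS oracle", {
  ms <- toyMachine(leafWidth = 5)
  # one CP with open gaps {3, 7, 15} mm -> SAS5 = 1/3, SAS10 = 2/3, SAS20 = 1
  bankA <- matrix(0, 2, 10); bankB <- matrix(0, 2, 10)
  bankA[, 4:6] <- matrix(rep(c(-1.5, -3.5, -7.5), each = 2), 2)
  bankB[, 4:6] <- matrix(rep(c(1.5, 3.5, 7.5), each = 2), 2)
  p <- rtPlan("sas", ms, list(toyArc(bankA, bankB)), 2)
  sc <- apertureScores(p)
  expect_equal(unname(sc["SAS5"]), 1 / 3)
  expect_equal(unname(sc["SAS10"]), 2 / 3)
  expect_equal(unname(sc["SAS20"]), 1)
  # identical flat rectangular apertures -> LSV = AAV = MCS = 1
  r <- rectPlan(n = 5)
  s1 <- apertureScores(r)
  expect_equal(unname(s1[c("MCS", "LSV", "AAV")]), c(1, 1, 1))
  # 3-CP toy arc against a term-by-term hand computation
  bA <- rbind(c(-20, -15, -10), c(-15, -15, -15), c(-10, -20, -15))
  bB <- rbind(c(10, 15, 12), c(20, 15, 10), c(15, 10, 20))
  ms3 <- machineSpec("m3", c(-15, -5, 5, 15))
  w <- c(0, 0.4, 1)
  p3 <- rtPlan("mcs", ms3, list(
    arc("a", 100, c(180, 182, 184), w, bA, bB, c(-50, 50, -50, 50))), 2)
  got <- apertureScores(p3)
  # hand evaluation: per-CP LSV per bank over the 3 open pairs, AAV against
  # per-pair maximum gaps, MU weights (0.4, 0.4, 0.6)/1.4 of 100 MU
  lsvBank <- function(pos) {
    pm <- max(pos) - min(pos)
    if (pm == 0) return(1)
    sum(pm - abs(diff(pos))) / (2 * pm)
  }
  lsv <- vapply(1:3, function(i) lsvBank(bA[i, ]) * lsvBank(bB[i, ]),
                numeric(1))
  gapM <- apply(bB - bA, 2, max)
  aav <- vapply(1:3, function(i) sum((bB[i, ] - bA[i, ]) * 10) /
                  sum(gapM * 10), numeric(1))
  muCP <- c(40, 40, 60)
  mcsOracle <- sum(muCP / 140 * lsv * aav)
  expect_equal(unname(got["MCS"]), mcsOracle, tolerance = 1e-12)
  expect_equal(unname(got["LSV"]), sum(muCP / 140 * lsv), tolerance = 1e-12)
  expect_equal(unname(got["AAV"]), sum(muCP / 140 * aav), tolerance = 1e-12)
})

test_that("MCS weakly decreases when aperture variability grows", {
  ms <- toyMachine(leafWidth = 5)
  base <- rectPlan(n = 4, pairs = 4:7, halfGap = 20, machine = ms)
  varied <- base
  a <- varied@arcs[[1]]
  a@bankB[2, 4:7] <- a@bankB[2, 4:7] - c(10, 5, 12, 3)   # shrink/vary CP2
  a@bankA[3, 4:7] <- a@bankA[3, 4:7] + c(8, 2, 6, 10)
  varied@arcs[[1]] <- a
  expect_lte(apertureScores(varied)["MCS"], apertureScores(base)["MCS"])
})

test_that("plan shape metrics: squares, disjoint unions and raster oracle", {
  # single 100 x 100 mm square aperture (10 pairs x 10 mm, fully open)
  ms <- toyMachine()
  bankA <- matrix(-50, 2, 10); bankB <- matrix(50, 2, 10)
  p <- rtPlan("sq", ms, list(toyArc(bankA, bankB, jaws = c(-50, 50, -50, 50))), 2)
  m <- planShapeMetrics(p)
  expect_equal(unname(m["PA"]), 1e4)
  expect_equal(unname(m["PI"]), 4 / pi, tolerance = 1e-12)
  expect_equal(unname(m["PM"]), 0)
  expect_equal(unname(m["UAA"]), 1e4)
  expect_equal(unname(m["EM"]), 400 / 1e4)
  # two disjoint identical apertures alternating across CPs, equal MU
  bA <- matrix(0, 2, 10); bB <- matrix(0, 2, 10)
  bA[1, 3] <- -10; bB[1, 3] <- 10
  bA[2, 8] <- -10; bB[2, 8] <- 10
  p2 <- rtPlan("alt", ms, list(toyArc(bA, bB, weights = c(0, 1))), 2)
  m2 <- planShapeMetrics(p2)
  expect_equal(unname(m2["UAA"]), 2 * 200)
  expect_equal(unname(m2["PM"]), 0.5)
  # random staircases: UAA equals the pixel-union counting oracle
  set.seed(13)
  n <- 4
  bA <- matrix(0, n, 10); bB <- matrix(0, n, 10)
  bA[, 4:7] <- -round(matrix(runif(n * 4, 5, 30), n), 1)
  bB[, 4:7] <- round(matrix(runif(n * 4, 5, 30), n), 1)
  p3 <- rtPlan("st", ms, list(toyArc(bA, bB)), 2)
  m3 <- planShapeMetrics(p3)
  b <- ms@leafBoundaries
  rects <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(x0 = bA[i, 4:7], x1 = bB[i, 4:7], y0 = b[4:7], y1 = b[5:8])))
  expect_equal(unname(m3["UAA"]), rasterOracle(rects, px = 0.1)$area,
               tolerance = 1e-9)
})

test_that("edge-zone metrics agree with a raster erosion oracle", {
  ms <- toyMachine()
  set.seed(41)
  bA <- matrix(0, 3, 10); bB <- matrix(0, 3, 10)
  bA[, 4:7] <- -round(matrix(runif(12, 8, 30), 3), 1)
  bB[, 4:7] <- round(matrix(runif(12, 8, 30), 3), 1)
  p <- rtPlan("eam", ms, list(toyArc(bA, bB)), 2)
  m <- planShapeMetrics(p, dEdge = 5)
  # per-CP raster oracle: fraction of aperture pixels whose Chebyshev
  # distance to the outside is at most 5 mm
  b <- ms@leafBoundaries
  eamCP <- vapply(1:3, function(i) {
    px <- 0.25
    xs <- seq(-35 + px / 2, 35 - px / 2, by = px)
    ys <- seq(-35 + px / 2, 35 - px / 2, by = px)
    mask <- matrix(FALSE, length(ys), length(xs))
    for (j in 4:7)
      mask[ys > b[j] & ys < b[j + 1], xs > bA[i, j] & xs < bB[i, j]] <- TRUE
    k <- ceiling(5 / px)
    shift <- function(mm, dr, dc) {
      out <- matrix(FALSE, nrow(mm), ncol(mm))
      rs <- seq_len(nrow(mm)) + dr; cs <- seq_len(ncol(mm)) + dc
      ok_r <- rs >= 1 & rs <= nrow(mm); ok_c <- cs >= 1 & cs <= ncol(mm)
      out[ok_r, ok_c] <- mm[rs[ok_r], cs[ok_c]]
      out
    }
    # square erosion as the intersection of shifted masks over [-k, k]^2
    # (0.5 mm offset sampling)
    er <- mask
    for (dr in seq(-k, k, by = 2)) for (dc in seq(-k, k, by = 2))
      er <- er & shift(mask, dr, dc)
    1 - sum(er) / sum(mask)
  }, numeric(1))
  expect_equal(unname(m["EAM"]), mean(eamCP), tolerance = 0.05)
})

test_that("travel and delivery metrics: degenerate and forced cases", {
  # static MLC -> ALT = 0, ALTMCS = 0
  r <- rectPlan(n = 5)
  tm <- travelDeliveryMetrics(r)
  expect_equal(unname(tm["ALT"]), 0)
  expect_equal(unname(tm["ALTMCS"]), 0)
  # all gaps 10 mm -> ALG = 10, SLG = 0
  ms <- toyMachine()
  bA <- matrix(-5, 3, 10); bB <- matrix(5, 3, 10)
  p <- rtPlan("alg", ms, list(toyArc(bA, bB)), 2)
  tm2 <- travelDeliveryMetrics(p)
  expect_equal(unname(tm2["ALG"]), 10)
  expect_equal(unname(tm2["SLG"]), 0)
  # dose-rate-limited segments -> ADR = 600 MU/min, SDR = 0
  n <- 4
  a <- toyArc(matrix(-10, n, 10), matrix(10, n, 10), totalMU = 300,
              weights = seq(0, 1, length.out = n),
              angles = rep(180, n))    # no gantry motion: dose rate binds
  p3 <- rtPlan("adr", toyMachine(), list(a), 2)
  tm3 <- travelDeliveryMetrics(p3)
  expect_equal(unname(tm3["ADR"]), 600)
  expect_equal(unname(tm3["SDR"]), 0)
  expect_equal(unname(tm3["dose"]), 2)
})

test_that("extractConventional is a deterministic 48-vector with exact MU scaling", {
  spec <- cohortSpec(nPlans = 1, cpPerArc = 30, arcRange = c(2, 2))
  p <- simulatePlan(spec, 1, seed = 9)
  v1 <- extractConventional(p)
  expect_length(v1, 48L)
  expect_true(all(is.finite(v1)))
  expect_identical(v1, extractConventional(p))
  # doubling MU on all arcs: MU-weighted shape metrics unchanged, PMU doubled
  p2 <- p
  p2@arcs <- lapply(p@arcs, function(a) { a@totalMU <- 2 * a@totalMU; a })
  p2@totalMU <- 2 * p@totalMU
  v2 <- extractConventional(p2)
  for (nm in c("PA", "PI", "SAS5", "SAS10", "SAS20", "ALG", "SLG", "MCS",
               "LSV", "AAV", "UAA", "PM", "EAM", "CAM"))
    expect_equal(unname(v2[nm]), unname(v1[nm]), tolerance = 1e-9)
  expect_equal(unname(v2["PMU"]), 2 * unname(v1["PMU"]), tolerance = 1e-12)
})

test_that("metric bounds and orderings hold on random plans", {
  spec <- cohortSpec(nPlans = 3, cpPerArc = 25, arcRange = c(2, 3))
  for (i in 1:3) {
    v <- extractConventional(simulatePlan(spec, i, seed = 99))
    for (nm in c("LSV", "AAV", "MCS", "SAS5", "SAS10", "SAS20", "PM",
                 "EAM", "CAM"))
      expect_true(v[nm] >= 0 && v[nm] <= 1, label = nm)
    expect_gte(v["PI"], 1)
    expect_lte(v["SAS5"], v["SAS10"])
    expect_lte(v["SAS10"], v["SAS20"])
    expect_equal(unname(sum(v[c("S_0-0.4", "S_0.4-0.8", "S_0.8-1.2",
                                "S_1.2-1.6", "S_1.6-2.0")])), 1,
                 tolerance = 1e-12)
    expect_equal(unname(sum(v[c("A_0-1", "A_1-2", "A_2-4", "A_4-6")])), 1,
                 tolerance = 1e-12)
  }
})

test_that("splitting a control point's MU in half preserves MU-weighted metrics", {
  ms <- toyMachine()
  set.seed(55)
  n <- 6
  bA <- matrix(runif(n * 10, -30, -5), n, 10)
  bB <- matrix(runif(n * 10, 5, 30), n, 10)
  w <- c(0, 0.2, 0.5, 0.7, 0.9, 1)
  p1 <- rtPlan("a", ms, list(toyArc(bA, bB, weights = w)), 2)
  # replicate CP 3 with identical state; its MU splits across two segments
  dup <- c(1, 2, 3, 3, 4, 5, 6)
  w2 <- c(0, 0.2, 0.35, 0.5, 0.7, 0.9, 1)
  p2 <- rtPlan("b", ms, list(toyArc(bA[dup, ], bB[dup, ], weights = w2)), 2)
  s1 <- apertureScores(p1); s2 <- apertureScores(p2)
  for (nm in c("SAS5", "SAS10", "SAS20", "MAD"))
    expect_equal(unname(s2[nm]), unname(s1[nm]), tolerance = 1e-9)
  m1 <- planShapeMetrics(p1); m2 <- planShapeMetrics(p2)
  for (nm in c("PA", "PI", "PM", "UAA", "EM", "CAM", "EAM", "CA"))
    expect_equal(unname(m2[nm]), unname(m1[nm]), tolerance = 1e-9)
  t1 <- travelDeliveryMetrics(p1); t2 <- travelDeliveryMetrics(p2)
  for (nm in c("ALG", "SLG"))
    expect_equal(unname(t2[nm]), unname(t1[nm]), tolerance = 1e-9)
})
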