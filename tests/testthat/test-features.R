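# one water at the origin plus protein carbon atoms at given positions
waterWithNeighbors <- function(neighborXyz, names = NULL, resname = "GLY",
                               waterB = 20, waterOcc = 1) {
  rows <- list()
  if (length(neighborXyz)) {
    neighborXyz <- matrix(neighborXyz, ncol = 3)
    if (is.null(names)) names <- rep("CB", nrow(neighborXyz))
    for (i in seq_len(nrow(neighborXyz)))
      rows[[i]] <- atomRow(i, names[i], "C", resname, "A", i,
                           neighborXyz[i, 1], neighborXyz[i, 2],
                           neighborXyz[i, 3])
  }
  rows[[length(rows) + 1L]] <- atomRow(9999L, "O", "O", "HOH", "A", 1000L,
                                       0, 0, 0, waterOcc, waterB,
                                       role = "water")
  m <- StructureModel("feat", do.call(rbind, rows))
  list(model = m, site = waterSites(m)[1, ])
}

test_that("atom density counts protein atoms inclusively at 3.6 A", {
  f <- waterWithNeighbors(rbind(c(1, 0, 0), c(0, 3.6, 0), c(0, 0, 3.61)))
  expect_equal(atomDensity(f$site, f$model), 2)
  empty <- waterWithNeighbors(c(5, 0, 0))
  expect_equal(atomDensity(empty$site, empty$model), 0)
})

test_that("atom density equals a double-loop count on a 500-atom cloud", {
  set.seed(7)
  xyz <- matrix(runif(1500, -6, 6), ncol = 3)
  f <- waterWithNeighbors(xyz)
  brute <- 0
  for (i in seq_len(500))
    if (sqrt(sum(xyz[i, ]^2)) <= 3.6) brute <- brute + 1
  expect_equal(atomDensity(f$site, f$model), brute)
})

test_that("propensity sums match closed forms and an independent loop", {
  tab1 <- data.frame(residue = "GLY", atom = "CB", h = 1, l = 1)
  f <- waterWithNeighbors(c(1, 0, 0))  # r = d0 = 1
  expect_equal(hydrophilicity(f$site, f$model, tab1), exp(-1))
  expect_equal(hydrophobicity(f$site, f$model, tab1), exp(-1))
  none <- waterWithNeighbors(c(4.5, 0, 0))
  expect_equal(hydrophilicity(none$site, none$model, tab1), 0)

  set.seed(13)
  xyz <- matrix(runif(15, -2, 2), ncol = 3)
  nm <- paste0("X", 1:5)
  tab <- data.frame(residue = "GLY", atom = nm,
                    h = runif(5, 0, 1), l = runif(5, 0, 1))
  f5 <- waterWithNeighbors(xyz, names = nm)
  expectH <- 0; expectL <- 0
  for (i in 1:5) {
    r <- sqrt(sum(xyz[i, ]^2))
    if (r <= 4.0) {
      expectH <- expectH + tab$h[i] * exp(-r / 1.0)
      expectL <- expectL + tab$l[i] * exp(-r / 1.0)
    }
  }
  expect_equal(hydrophilicity(f5$site, f5$model, tab), expectH,
               tolerance = 1e-12)
  expect_equal(hydrophobicity(f5$site, f5$model, tab), expectL,
               tolerance = 1e-12)
})

test_that("identical propensity tables make the two sums coincide", {
  set.seed(19)
  xyz <- matrix(runif(9, -2, 2), ncol = 3)
  tab <- data.frame(residue = "*", atom = "ELEM:C", h = 0.37, l = 0.37)
  f <- waterWithNeighbors(xyz)
  expect_equal(hydrophilicity(f$site, f$model, tab),
               hydrophobicity(f$site, f$model, tab))
})

test_that("the printed positive-exponent variant is available as a switch", {
  tab1 <- data.frame(residue = "GLY", atom = "CB", h = 1, l = 1)
  f <- waterWithNeighbors(c(2, 0, 0))
  cfg <- featureConfig(positiveExponent = TRUE)
  expect_equal(hydrophilicity(f$site, f$model, tab1, cfg), exp(2))
  # hydrophobicity always uses the negative exponent
  expect_equal(hydrophobicity(f$site, f$model, tab1, cfg), exp(-2))
})

test_that("unknown atom types fall back to the default with a warning", {
  tab <- data.frame(residue = "GLY", atom = "CB", h = 1, l = 1)
  f <- waterWithNeighbors(c(1, 0, 0), names = "ZQ", resname = "XXX")
  expect_warning(v <- hydrophilicity(f$site, f$model, tab),
                 "not in the propensity table")
  expect_equal(v, 0)
})

test_that("SASA of an isolated water equals the bare sphere area", {
  f <- waterWithNeighbors(matrix(numeric(0), ncol = 3))
  expect_equal(sasa(f$site, f$model), 4 * pi * (1.52 + 1.4)^2,
               tolerance = 0.02)
})

test_that("SASA of a fully caged water is zero", {
  cage <- fibonacciSphere(200) * 2.0
  f <- waterWithNeighbors(cage)
  expect_equal(sasa(f$site, f$model), 0)
})

test_that("SASA matches the two-sphere spherical-cap closed form", {
  d <- 4.0
  f <- waterWithNeighbors(c(d, 0, 0))
  R <- 1.52 + 1.4          # water sphere
  r2 <- 1.70 + 1.4         # probe-expanded carbon
  cosTheta <- (R^2 + d^2 - r2^2) / (2 * R * d)
  analytic <- 4 * pi * R^2 - 2 * pi * R^2 * (1 - cosTheta)
  expect_equal(sasa(f$site, f$model), analytic, tolerance = 0.02)
})

test_that("SASA is bounded and converges with the point count", {
  set.seed(23)
  xyz <- matrix(runif(30, -4, 4), ncol = 3)
  f <- waterWithNeighbors(xyz)
  Rmax <- 4 * pi * (1.52 + 1.4)^2
  v960 <- sasa(f$site, f$model, featureConfig(sasaPoints = 960L))
  v1920 <- sasa(f$site, f$model, featureConfig(sasaPoints = 1920L))
  expect_gte(v960, 0)
  expect_lte(v960, Rmax)
  expect_lt(abs(v960 - v1920), 0.01 * Rmax)
})

test_that("B-factor passes through verbatim and the MSD converter is exact", {
  f <- waterWithNeighbors(matrix(numeric(0), ncol = 3), waterB = 23.74)
  expect_equal(bfactor(f$site), 23.74)
  expect_equal(msdToBfactor(0), 0)
  expect_equal(msdToBfactor(1), 8 * pi^2)
})

test_that("mobility normalizes by the structure-wide water baseline", {
  waters <- data.frame(bfactor = c(20, 20, 20), occupancy = c(1, 1, 1))
  site <- list(bfactor = 20, occupancy = 1)
  expect_equal(mobility(site, waters), 1)
  # B twice the mean, occupancy at the mean -> 2
  waters2 <- data.frame(bfactor = c(10, 20, 30), occupancy = c(1, 1, 1))
  expect_equal(mobility(list(bfactor = 40, occupancy = 1), waters2), 2)
  # independent two-pass computation on 20 random waters
  set.seed(29)
  w <- data.frame(bfactor = runif(20, 5, 60), occupancy = runif(20, 0.5, 1))
  mB <- sum(w$bfactor) / 20; mO <- sum(w$occupancy) / 20
  for (i in c(1, 9, 20)) {
    manual <- (w$bfactor[i] / mB) / (w$occupancy[i] / mO)
    expect_equal(mobility(w[i, ], w), manual, tolerance = 1e-12)
  }
})

test_that("degenerate mobility inputs fail loudly", {
  zeroB <- data.frame(bfactor = c(0, 0), occupancy = c(1, 1))
  expect_error(mobility(list(bfactor = 0, occupancy = 1), zeroB),
               "mean water B-factor is zero")
  ok <- data.frame(bfactor = c(10, 20), occupancy = c(1, 1))
  expect_error(mobility(list(bfactor = 10, occupancy = 0), ok),
               "zero occupancy")
})

test_that("a buried quiet water looks conserved, an exposed hot one free", {
  cage <- fibonacciSphere(150) * 2.5
  rows <- do.call(rbind, lapply(seq_len(150), function(i)
    atomRow(i, "CB", "C", "ALA", "A", i, cage[i, 1], cage[i, 2],
            cage[i, 3])))
  buried <- atomRow(400L, "O", "O", "HOH", "A", 1001L, 0, 0, 0, 1, 12,
                    role = "water")
  exposed <- atomRow(401L, "O", "O", "HOH", "A", 1002L, 30, 0, 0, 0.9, 55,
                     role = "water")
  m <- StructureModel("pattern", rbind(rows, buried, exposed))
  ws <- waterSites(m)
  fb <- featurize(ws[1, ], m)
  fe <- featurize(ws[2, ], m)
  expect_gt(fb[["A"]], fe[["A"]])
  expect_equal(fb[["F"]], 0)
  expect_lt(fb[["B"]], 1)
  expect_gt(fe[["F"]], 0)
  expect_gt(fe[["B"]], 1)
})

test_that("features ignore atoms beyond every cutoff", {
  set.seed(31)
  xyz <- matrix(runif(15, -3, 3), ncol = 3)
  f0 <- waterWithNeighbors(xyz)
  far <- rbind(xyz, c(20, 20, 20))  # beyond density, propensity and SASA reach
  f1 <- waterWithNeighbors(far)
  for (fun in list(atomDensity, hydrophilicity, hydrophobicity, sasa))
    expect_equal(fun(f1$site, f1$model), fun(f0$site, f0$model))
})

test_that("the feature vector is invariant to atom order and rigid moves", {
  pair <- generateHomologPair(structureSimSpec(seed = 37))
  m <- pair$reference
  ws <- waterSites(m)
  site <- ws[3, ]
  v0 <- featurize(site, m)
  # permute atom rows
  set.seed(5)
  perm <- StructureModel("perm", atoms(m)[sample(nrow(atoms(m))), ])
  expect_equal(featurize(site, perm), v0)
  # rigid move of everything, including the probed site
  R <- randomRotation(); tr <- runif(3, -15, 15)
  mMoved <- rigidCopy(m, R, tr)
  siteMoved <- waterSites(mMoved)[3, ]
  v1 <- featurize(siteMoved, mMoved)
  expect_equal(v1[c("A", "B", "C", "D", "E")], v0[c("A", "B", "C", "D", "E")],
               tolerance = 1e-8)
  # sampled SASA is rotation-invariant only up to the angular resolution of
  # the point set
  expect_lt(abs(v1[["F"]] - v0[["F"]]), 2.0)
})
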