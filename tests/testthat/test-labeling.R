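supWithRmsd <- function(r) {
  new("SuperpositionResult", rotation = diag(3), translation = c(0, 0, 0),
      rmsd = r, nMatched = 4L)
}

test_that("the RMSD filter is inclusive at the threshold", {
  cfg <- labelingConfig()
  expect_true(pairPassesFilter(supWithRmsd(2.0), cfg))
  expect_false(pairPassesFilter(supWithRmsd(2.0001), cfg))
  expect_true(pairPassesFilter(supWithRmsd(0), cfg))
})

test_that("pocket membership is inclusive at the ligand-distance cutoff", {
  m <- miniModel(c(3, 0, 0))
  a <- atoms(m)
  extra <- rbind(
    atomRow(90L, "CB", "C", "ALA", "A", 50L, 6.9, 0, 0),
    atomRow(91L, "CB", "C", "ALA", "A", 51L, 7.0, 0, 0),
    atomRow(92L, "CB", "C", "ALA", "A", 52L, 7.1, 0, 0))
  m2 <- StructureModel("edge", rbind(a, extra))
  pocket <- definePocket(m2)
  expect_true(90L %in% pocket$proteinAtoms$serial)
  expect_true(91L %in% pocket$proteinAtoms$serial)
  expect_false(92L %in% pocket$proteinAtoms$serial)
})

test_that("pocket membership equals an all-pairs brute force on 500 atoms", {
  set.seed(31)
  n <- 500
  prot <- atomRow(seq_len(n), "CA", "C", "GLY", "A", seq_len(n),
                  runif(n, -12, 12), runif(n, -12, 12), runif(n, -12, 12))
  lig <- atomRow(n + 1:3, paste0("C", 1:3), "C", "LIG", "A", 900L,
                 runif(3, -1, 1), runif(3, -1, 1), runif(3, -1, 1),
                 role = "ligand")
  m <- StructureModel("cloud", rbind(prot, lig))
  pocket <- definePocket(m)
  # independent double-loop oracle
  ligXyz <- as.matrix(lig[, c("x", "y", "z")])
  inPocket <- logical(n)
  for (i in seq_len(n)) {
    dmin <- Inf
    for (j in 1:3)
      dmin <- min(dmin, sqrt(sum((as.numeric(prot[i, c("x", "y", "z")]) -
                                    ligXyz[j, ])^2)))
    inPocket[i] <- dmin <= 7.0
  }
  expect_setequal(pocket$proteinAtoms$serial, prot$serial[inPocket])
})

test_that("pocket definition requires a ligand", {
  m <- miniModel(c(3, 0, 0))
  a <- atoms(m)
  noLig <- StructureModel("nolig", a[a$role != "ligand", ])
  expect_error(definePocket(noLig), "no ligand atoms")
})

test_that("nearest-water distance is the minimum over partners", {
  site <- list(x = 0, y = 0, z = 0)
  partners <- data.frame(x = c(0.8, 2.5, 4.0), y = 0, z = 0)
  expect_equal(nearestWaterDistance(site, partners), 0.8)
  expect_equal(nearestWaterDistance(site, partners[0, ]), Inf)
  # 50-water random fixture vs double-loop brute force
  set.seed(41)
  waters <- data.frame(x = runif(50, -9, 9), y = runif(50, -9, 9),
                       z = runif(50, -9, 9))
  for (i in c(1, 17, 50)) {
    brute <- Inf
    for (j in seq_len(50)[-i])
      brute <- min(brute, sqrt(sum((as.numeric(waters[i, ]) -
                                      as.numeric(waters[j, ]))^2)))
    expect_equal(nearestWaterDistance(waters[i, ], waters[-i, ]), brute)
  }
})

test_that("an identical homolog makes every pocket water a CWM at NED 0", {
  m <- miniModel(rbind(c(3, 0, 0), c(0, 4, 0), c(0, 0, 5)))
  labs <- labelWaters(m, m, matching = data.frame(ref = 1:4, mobile = 1:4))
  expect_true(all(labs$label == "CWM"))
  expect_true(all(labs$ned < 1e-10))
  expect_true(all(labs$in_pocket))
})

test_that("the NED threshold is inclusive: exactly 1.2 A is conserved", {
  ref <- miniModel(rbind(c(3, 0, 0), c(0, 4, 0)))
  hom <- miniModel(rbind(c(3, 1.2, 0), c(0, 4, 1.2 + 1e-9)), id = "hom")
  labs <- labelWaters(ref, hom, superposition = identitySuperposition())
  expect_equal(labs$ned, c(1.2, 1.2 + 1e-9))
  expect_equal(labs$label, c("CWM", "FWM"))
})

test_that("a homolog with no waters yields FWM labels, not an error", {
  ref <- miniModel(c(3, 0, 0))
  hom <- miniModel(matrix(numeric(0), ncol = 3), id = "dry")
  labs <- labelWaters(ref, hom, matching = data.frame(ref = 1:4, mobile = 1:4))
  expect_equal(labs$label, "FWM")
  expect_equal(labs$ned, Inf)
})

test_that("a pair failing the RMSD filter is rejected explicitly", {
  ref <- miniModel(c(3, 0, 0))
  expect_error(
    labelWaters(ref, ref, superposition = supWithRmsd(2.5)),
    "pair rejected \\(RMSD\\)")
})

test_that("planted ground truth is recovered and labels partition the pocket", {
  pair <- generateHomologPair(structureSimSpec(seed = 17))
  labs <- labelWaters(pair$reference, pair$homolog)
  pocket <- labs[labs$in_pocket, ]
  hit <- merge(pocket[, c("chain", "resnum", "label")], pair$truth)
  expect_equal(nrow(hit), nrow(pair$truth))
  expect_equal(hit$label, hit$truth)
  # |CWM| + |FWM| = pocket waters; non-pocket waters stay unlabeled
  expect_equal(sum(labs$label %in% c("CWM", "FWM")), sum(labs$in_pocket))
  expect_true(all(labs$label[!labs$in_pocket] == "unlabeled"))
})

test_that("labels are invariant under a common rigid transform", {
  pair <- generateHomologPair(structureSimSpec(seed = 23))
  labs0 <- labelWaters(pair$reference, pair$homolog)
  set.seed(99)
  R <- randomRotation(); tr <- runif(3, -20, 20)
  labs1 <- labelWaters(rigidCopy(pair$reference, R, tr),
                       rigidCopy(pair$homolog, R, tr))
  expect_equal(labs1$label, labs0$label)
  expect_equal(labs1$ned, labs0$ned, tolerance = 1e-6)
})

test_that("raising the NED threshold never demotes a CWM", {
  pair <- generateHomologPair(structureSimSpec(seed = 29,
                                               jitterSd = 0.3))
  thresholds <- c(0.4, 1.2, 2.5)
  sets <- lapply(thresholds, function(th) {
    labs <- labelWaters(pair$reference, pair$homolog,
                        labelingConfig(nedThreshold = th))
    labs$resnum[labs$label == "CWM"]
  })
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})
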