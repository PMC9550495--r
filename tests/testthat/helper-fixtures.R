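# in-code fixtures shared across test files

atomRow <- function(serial, name, element, resname, chain, resnum,
                    x, y, z, occupancy = 1, bfactor = 20,
                    role = "protein") {
  data.frame(serial = serial, name = name, element = element,
             resname = resname, chain = chain, resnum = resnum,
             x = x, y = y, z = z, occupancy = occupancy, bfactor = bfactor,
             role = role, stringsAsFactors = FALSE)
}

# a minimal structure: four CA atoms (non-collinear), one ligand atom at the
# origin and waters at given offsets from the origin
miniModel <- function(waterXyz, waterB = NULL, waterOcc = NULL,
                      id = "mini") {
  ca <- rbind(c(4, 0, 0), c(0, 4, 0), c(0, 0, 4), c(3, 3, 1))
  rows <- lapply(1:4, function(i)
    atomRow(i, "CA", "C", "GLY", "A", i, ca[i, 1], ca[i, 2], ca[i, 3]))
  rows[[5]] <- atomRow(5L, "C1", "C", "LIG", "A", 900L, 0, 0, 0,
                       role = "ligand")
  if (length(waterXyz)) {
    waterXyz <- matrix(waterXyz, ncol = 3)
    if (is.null(waterB)) waterB <- rep(20, nrow(waterXyz))
    if (is.null(waterOcc)) waterOcc <- rep(1, nrow(waterXyz))
    for (i in seq_len(nrow(waterXyz)))
      rows[[5 + i]] <- atomRow(5L + i, "O", "O", "HOH", "A", 1000L + i,
                               waterXyz[i, 1], waterXyz[i, 2],
                               waterXyz[i, 3], waterOcc[i], waterB[i],
                               role = "water")
  }
  StructureModel(id, do.call(rbind, rows))
}

identitySuperposition <- function(n = 4L) {
  new("SuperpositionResult", rotation = diag(3), translation = c(0, 0, 0),
      rmsd = 0, nMatched = as.integer(n))
}

randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

rigidCopy <- function(model, rotation, translation) {
  applyTransform(model, list(rotation = rotation, translation = translation))
}

toyPdbPath <- function() {
  system.file("extdata", "toy_site.pdb", package = "conswat")
}

# small separable dataset: label decided by a threshold on feature A
separableDataset <- function(n = 60, seed = 5) {
  set.seed(seed)
  a <- c(runif(n / 2, 0, 0.4), runif(n / 2, 0.6, 1))
  data.frame(A = a, B = runif(n), C = runif(n),
             label = rep(c("FWM", "CWM"), each = n / 2))
}
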