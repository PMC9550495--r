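AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Specification for a synthetic homolog structure pair
#'
#' Describes a toy protein-ligand crystal structure and its homolog with
#' planted conserved/free water ground truth. The reference is a spherical
#' protein cage (residues with N/CA/C/O atoms at radii 3-10 Angstrom around
#' a central ligand), pocket waters placed within the ligand-distance pocket
#' with a minimum mutual separation, and distant waters outside it. The
#' homolog is a copy in which conserved waters are jittered by much less
#' than the NED threshold, non-conserved waters are displaced well beyond
#' it (and away from every reference water), and the whole structure is
#' then moved by a rigid transform. By construction the planted labels are
#' unambiguous: the spec requires `displacementMin > 1.2` and
#' `jitterSd < 0.4`.
#'
#' @param nProteinResidues number of cage residues (4 atoms each).
#' @param nPocketWaters number of binding-pocket waters.
#' @param nFarWaters number of waters far outside the pocket.
#' @param conservedFraction fraction of pocket waters planted as conserved.
#' @param displacementMin Angstrom; minimum displacement of non-conserved
#'   homolog waters (must exceed the 1.2 Angstrom NED threshold).
#' @param jitterSd Angstrom; per-coordinate jitter of conserved homolog
#'   waters (must stay below 0.4 so labels cannot become ambiguous).
#' @param transform optional list(rotation, translation) applied to the
#'   homolog; `NULL` draws a random rigid transform from the seed.
#' @param seed integer seed; the single source of randomness.
#' @return object of class `"structureSimSpec"`.
#' @export
structureSimSpec <- function(nProteinResidues = 60L, nPocketWaters = 12L,
                             nFarWaters = 4L, conservedFraction = 0.5,
                             displacementMin = 2.0, jitterSd = 0.15,
                             transform = NULL, seed = 1L) {
  stopifnot(displacementMin > 1.2, jitterSd < 0.4, jitterSd > 0,
            conservedFraction >= 0, conservedFraction <= 1,
            nProteinResidues >= 3, nPocketWaters >= 0, nFarWaters >= 0)
  structure(list(nProteinResidues = as.integer(nProteinResidues),
                 nPocketWaters = as.integer(nPocketWaters),
                 nFarWaters = as.integer(nFarWaters),
                 conservedFraction = conservedFraction,
                 displacementMin = displacementMin, jitterSd = jitterSd,
                 transform = transform, seed = as.integer(seed)),
            class = "structureSimSpec")
}

.randUnit <- function(n = 1L) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

.randRotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# rejection-sample n points in a radial shell with a minimum mutual
# separation and a minimum clearance from `avoid` points
.packPoints <- function(n, rmin, rmax, minSep, avoid = NULL,
                        avoidSep = minSep, maxTries = 50000L) {
  pts <- matrix(numeric(0), ncol = 3)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("could not place ", n, " points with separation ", minSep,
           " in shell [", rmin, ", ", rmax, "]")
    r <- (stats::runif(1, rmin^3, rmax^3))^(1 / 3)
    p <- .randUnit(1L) * r
    ok <- TRUE
    if (nrow(pts))
      ok <- min(sqrt(rowSums(sweep(pts, 2, p)^2))) >= minSep
    if (ok && !is.null(avoid) && nrow(avoid))
      ok <- min(sqrt(rowSums(sweep(avoid, 2, p)^2))) >= avoidSep
    if (ok) pts <- rbind(pts, p)
  }
  pts
}

.atomRow <- function(serial, name, element, resname, chain, resnum, xyz,
                     occupancy, bfactor, role) {
  data.frame(serial = serial, name = name, element = element,
             resname = resname, chain = chain, resnum = resnum,
             x = xyz[1], y = xyz[2], z = xyz[3], occupancy = occupancy,
             bfactor = bfactor, role = role, stringsAsFactors = FALSE)
}

#' Generate a synthetic homolog pair with planted water labels
#'
#' Builds the reference and homolog [StructureModel-class]s described by a
#' [structureSimSpec()], together with the planted per-water truth. Feeding
#' the pair to [labelWaters()] recovers the planted labels exactly whenever
#' the spec invariants hold (see the vignette for the margin argument).
#'
#' @param spec a [structureSimSpec()].
#' @param dir optional directory; when given, `reference.pdb`,
#'   `homolog.pdb` and `truth.tsv` are written there.
#' @return list with `reference`, `homolog` (both
#'   [StructureModel-class]s), `truth` (data.frame `chain`, `resnum`,
#'   `truth` for the pocket waters) and `transform`.
#' @examples
#' pair <- generateHomologPair(structureSimSpec(seed = 42))
#' table(pair$truth$truth)
#' @export
generateHomologPair <- function(spec = structureSimSpec(), dir = NULL) {
  stopifnot(inherits(spec, "structureSimSpec"))
  set.seed(spec$seed)

  # ligand: small cluster at the origin
  ligXyz <- rbind(c(0, 0, 0), .randUnit(4L) * stats::runif(4, 0.8, 1.2))
  ligNames <- c("C1", "C2", "O1", "N1", "C3")
  ligElems <- c("C", "C", "O", "N", "C")

  # protein cage: residues at radii 3-10 A, four atoms each
  resCenters <- .packPoints(spec$nProteinResidues, 3.0, 10.0, 2.0,
                            avoid = ligXyz, avoidSep = 2.0)
  resNames <- sample(AA3, spec$nProteinResidues, replace = TRUE)
  atomNames <- c("N", "CA", "C", "O")
  atomElems <- c("N", "C", "C", "O")

  # waters: pocket shell within 6.8 A of the ligand, far shell outside
  pocketXyz <- .packPoints(spec$nPocketWaters, 2.0, 6.8, 2.5,
                           avoid = ligXyz, avoidSep = 1.8)
  farXyz <- .packPoints(spec$nFarWaters, 15.0, 19.0, 2.5)

  nCons <- round(spec$conservedFraction * spec$nPocketWaters)
  conserved <- rep(FALSE, spec$nPocketWaters)
  if (nCons > 0)
    conserved[sample.int(spec$nPocketWaters, nCons)] <- TRUE

  rows <- list()
  serial <- 0L
  for (i in seq_len(spec$nProteinResidues)) {
    offs <- rbind(c(0, 0, 0), .randUnit(3L) * stats::runif(3, 0.8, 1.4))
    # CA first so offsets hang off it
    ord <- c(2L, 1L, 3L, 4L)
    for (j in seq_len(4)) {
      serial <- serial + 1L
      k <- ord[j]
      rows[[length(rows) + 1L]] <- .atomRow(
        serial, atomNames[k], atomElems[k], resNames[i], "A", i,
        resCenters[i, ] + offs[j, ], 1.0,
        round(stats::runif(1, 10, 20), 2), "protein")
    }
  }
  for (j in seq_len(nrow(ligXyz))) {
    serial <- serial + 1L
    rows[[length(rows) + 1L]] <- .atomRow(
      serial, ligNames[j], ligElems[j], "LIG", "A", 900L, ligXyz[j, ],
      1.0, 15.0, "ligand")
  }
  waterB <- ifelse(conserved,
                   pmax(2, round(stats::rnorm(spec$nPocketWaters, 22, 6), 2)),
                   pmax(2, round(stats::rnorm(spec$nPocketWaters, 45, 10), 2)))
  waterO <- ifelse(conserved, 1.0,
                   round(stats::runif(spec$nPocketWaters, 0.8, 1.0), 2))
  for (i in seq_len(spec$nPocketWaters)) {
    serial <- serial + 1L
    rows[[length(rows) + 1L]] <- .atomRow(
      serial, "O", "O", "HOH", "A", 1000L + i, pocketXyz[i, ],
      waterO[i], waterB[i], "water")
  }
  for (i in seq_len(spec$nFarWaters)) {
    serial <- serial + 1L
    rows[[length(rows) + 1L]] <- .atomRow(
      serial, "O", "O", "HOH", "A", 2000L + i, farXyz[i, ],
      1.0, round(stats::runif(1, 30, 50), 2), "water")
  }
  refAtoms <- do.call(rbind, rows)
  reference <- StructureModel("synthetic-ref", refAtoms, resolution = 1.5)

  # homolog: jitter conserved waters (bounded), displace the rest far from
  # every reference water, jitter the protein slightly, then move rigidly
  homAtoms <- refAtoms
  prot <- homAtoms$role == "protein"
  homAtoms[prot, c("x", "y", "z")] <- homAtoms[prot, c("x", "y", "z")] +
    matrix(stats::rnorm(3 * sum(prot), 0, 0.03), ncol = 3)
  allRefWaters <- rbind(pocketXyz, farXyz)
  widx <- which(homAtoms$role == "water" & homAtoms$resnum < 2000L)
  for (i in seq_along(widx)) {
    if (conserved[i]) {
      jit <- stats::rnorm(3, 0, spec$jitterSd)
      nrm <- sqrt(sum(jit^2))
      if (nrm > 0.9) jit <- jit * 0.9 / nrm
      homAtoms[widx[i], c("x", "y", "z")] <- pocketXyz[i, ] + jit
    } else {
      repeat {
        mag <- spec$displacementMin + stats::runif(1, 0, 1.5)
        p <- pocketXyz[i, ] + as.numeric(.randUnit(1L)) * mag
        if (min(sqrt(rowSums(sweep(allRefWaters, 2, p)^2))) >= 1.5) break
      }
      homAtoms[widx[i], c("x", "y", "z")] <- p
    }
  }
  transform <- spec$transform
  if (is.null(transform))
    transform <- list(rotation = .randRotation(),
                      translation = stats::runif(3, -10, 10))
  xyz <- as.matrix(homAtoms[, c("x", "y", "z")]) %*% t(transform$rotation)
  homAtoms$x <- xyz[, 1] + transform$translation[1]
  homAtoms$y <- xyz[, 2] + transform$translation[2]
  homAtoms$z <- xyz[, 3] + transform$translation[3]
  homolog <- StructureModel("synthetic-hom", homAtoms, resolution = 1.6)

  truth <- data.frame(chain = "A", resnum = 1000L + seq_len(spec$nPocketWaters),
                      truth = ifelse(conserved, "CWM", "FWM"),
                      stringsAsFactors = FALSE)
  out <- list(reference = reference, homolog = homolog, truth = truth,
              transform = transform)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writePdb(reference, file.path(dir, "reference.pdb"))
    writePdb(homolog, file.path(dir, "homolog.pdb"))
    writeReport(truth, file.path(dir, "truth.tsv"))
  }
  out
}

# class-wise feature summaries (location, lower and upper truncation) used
# as generator defaults; locations are the class means and bounds the
# class-wise minima/maxima observed in a published large-scale survey
.featureSimDefaults <- function() {
  list(
    FWM = data.frame(
      row.names = FEATURE_LETTERS,
      loc = c(1.146, 1.673, 36.371, 0.029, 0.049, 21.877),
      min = c(0, 0, 0, 0, 0, 0),
      max = c(7.000, 8.992, 99.930, 0.147, 0.249, 84.949)),
    CWM = data.frame(
      row.names = FEATURE_LETTERS,
      loc = c(3.033, 1.099, 23.740, 0.071, 0.116, 6.683),
      min = c(0.000, 0.027, 0.000, 0.005, 0.000, 0.000),
      max = c(12.000, 12.289, 94.670, 0.243, 0.505, 40.877)))
}

#' Specification for a synthetic labeled feature table
#'
#' Per-class truncated-normal distributions for the six features. Defaults
#' place each class at its published class-wise mean, truncated to the
#' published class-wise [min, max] range, with the scale chosen so that
#' roughly 99% of the untruncated mass falls inside the bounds
#' (`sd = min(loc - min, max - loc) / 2.576`). The location parameter is
#' solved so that the mean of the *truncated* distribution equals the
#' target, so sample means are centered on the published class means rather
#' than on truncation-shifted values. The class ratio
#' defaults to 1.25 conserved waters per free water.
#'
#' @param n total number of rows.
#' @param classRatio CWM rows per FWM row (default 1.25).
#' @param params list with `FWM` and `CWM` data.frames (`loc`, `min`,
#'   `max`, rows = feature letters); default as above.
#' @param separation multiplier moving the class locations apart around
#'   their per-feature midpoint (1 = defaults; larger = easier problem).
#' @param seed integer seed.
#' @return object of class `"featureSimSpec"`.
#' @export
featureSimSpec <- function(n = 4500L, classRatio = 1.25, params = NULL,
                           separation = 1, seed = 17L) {
  if (is.null(params)) params <- .featureSimDefaults()
  stopifnot(n >= 2, classRatio > 0, separation >= 0,
            all(c("FWM", "CWM") %in% names(params)))
  for (cls in c("FWM", "CWM")) {
    p <- params[[cls]]
    if (any(p$loc < p$min | p$loc > p$max) || any(p$max <= p$min))
      stop("infeasible truncation bounds for class ", cls)
  }
  structure(list(n = as.integer(n), classRatio = classRatio,
                 params = params, separation = separation,
                 seed = as.integer(seed)),
            class = "featureSimSpec")
}

# truncated-normal draws by inverse-CDF; exact and vectorized
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

.truncMean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd; b <- (upper - mu) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / Z
}

# location parameter whose truncated-normal mean equals the target, so the
# generated sample mean is centered on the target and not on a
# truncation-shifted value
.truncLocation <- function(target, sd, lower, upper) {
  f <- function(mu) .truncMean(mu, sd, lower, upper) - target
  stats::uniroot(f, lower = lower - 5 * sd, upper = upper + 5 * sd,
                 tol = 1e-10)$root
}

#' Generate a labeled synthetic feature table
#'
#' Draws `n` rows of the six features from per-class truncated normals (see
#' [featureSimSpec()]), with `round(n / (1 + classRatio))` FWM rows and the
#' rest CWM. Feature A (atom density) is rounded to an integer count.
#' Deterministic given the seed.
#'
#' @param spec a [featureSimSpec()].
#' @return data.frame with columns `A`..`F` and `label`.
#' @examples
#' tab <- generateFeatureTable(featureSimSpec(n = 100, seed = 3))
#' table(tab$label)
#' @export
generateFeatureTable <- function(spec = featureSimSpec()) {
  stopifnot(inherits(spec, "featureSimSpec"))
  set.seed(spec$seed)
  nF <- round(spec$n / (1 + spec$classRatio))
  nC <- spec$n - nF
  counts <- c(FWM = nF, CWM = nC)
  blocks <- lapply(c("FWM", "CWM"), function(cls) {
    p <- spec$params[[cls]]
    other <- spec$params[[setdiff(c("FWM", "CWM"), cls)]]
    mid <- (p$loc + other$loc) / 2
    loc <- mid + spec$separation * (p$loc - mid)
    loc <- pmin(pmax(loc, p$min + 1e-9), p$max - 1e-9)
    sdv <- pmin(loc - p$min, p$max - loc) / stats::qnorm(0.995)
    sdv[sdv <= 0] <- 1e-6
    cols <- lapply(seq_along(FEATURE_LETTERS), function(j) {
      mu <- .truncLocation(loc[j], sdv[j], p$min[j], p$max[j])
      .rtruncnorm(counts[[cls]], mu, sdv[j], p$min[j], p$max[j])
    })
    names(cols) <- FEATURE_LETTERS
    df <- as.data.frame(cols)
    df$label <- cls
    df
  })
  out <- do.call(rbind, blocks)
  out$A <- round(out$A)
  rownames(out) <- NULL
  out
}
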