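#' Microenvironment features of a water site
#'
#' Six features characterize the microenvironment of a binding-site water
#' oxygen (Table-style lettering used throughout the package):
#'
#' * **A, atom density** -- number of protein atoms within `densityRadius`
#'   (default 3.6 Angstrom) of the water oxygen.
#' * **B, mobility** -- B-factor of the water normalized by the mean water
#'   B-factor, divided by its occupancy normalized by the mean water
#'   occupancy.
#' * **C, temperature B-factor** -- the crystallographic B-factor column of
#'   the water oxygen, in squared Angstrom.
#' * **D, atomic hydrophilicity** -- `sum_i h_i * exp(-r_i/d0)` over protein
#'   atoms within `propensityRadius` (default 4.0 Angstrom), `h_i` the
#'   hydration propensity of atom `i` and `r_i` its distance to the water.
#' * **E, atomic hydrophobicity** -- the same sum with the carbon propensity
#'   `l_i` in place of `h_i`.
#' * **F, SASA** -- solvent-accessible surface area of the water-oxygen
#'   sphere (van der Waals radius + probe) in the context of the protein
#'   atoms, squared Angstrom.
#'
#' All distance cutoffs are inclusive.
#'
#' @name waterFeatures
NULL

FEATURE_LETTERS <- c("A", "B", "C", "D", "E", "F")
FEATURE_NAMES <- c(A = "atom_density", B = "mobility", C = "bfactor",
                   D = "hydrophilicity", E = "hydrophobicity", F = "sasa")

.siteXyz <- function(site) c(site$x, site$y, site$z)

.protDistances <- function(site, model) {
  p <- proteinAtoms(model)
  if (!nrow(p)) return(list(atoms = p, r = numeric(0)))
  s <- .siteXyz(site)
  list(atoms = p,
       r = sqrt((p$x - s[1])^2 + (p$y - s[2])^2 + (p$z - s[3])^2))
}

#' @describeIn waterFeatures count of protein atoms within `densityRadius`
#'   of the water oxygen (feature A).
#' @param site one row of a [waterSites()] table.
#' @param model the [StructureModel-class] the water belongs to.
#' @param config a [FeatureConfig-class].
#' @return `atomDensity()`: a non-negative integer.
#' @export
atomDensity <- function(site, model, config = featureConfig()) {
  d <- .protDistances(site, model)
  sum(d$r <= config@densityRadius)
}

.propensitySum <- function(site, model, table, config, column) {
  d <- .protDistances(site, model)
  sel <- which(d$r <= config@propensityRadius)
  if (!length(sel)) return(0)
  a <- d$atoms[sel, , drop = FALSE]
  hl <- .lookupPropensity(table, a$resname, a$name, a$element)
  sgn <- if (config@positiveExponent) 1 else -1
  sum(hl[, column] * exp(sgn * d$r[sel] / config@d0))
}

#' @describeIn waterFeatures distance-weighted hydration-propensity sum over
#'   protein atoms within `propensityRadius` (feature D).
#' @param table a propensity table (see [defaultPropensityTable()]).
#' @export
hydrophilicity <- function(site, model, table = defaultPropensityTable(),
                           config = featureConfig()) {
  .propensitySum(site, model, table, config, "h")
}

#' @describeIn waterFeatures distance-weighted carbon-propensity sum
#'   (feature E); always uses the negative exponent `exp(-r/d0)`.
#' @export
hydrophobicity <- function(site, model, table = defaultPropensityTable(),
                           config = featureConfig()) {
  cfg <- config
  cfg@positiveExponent <- FALSE
  .propensitySum(site, model, table, cfg, "l")
}

#' @describeIn waterFeatures solvent-accessible surface area of the water
#'   oxygen sphere (feature F), by deterministic sphere-point sampling
#'   (Shrake-Rupley style with a Fibonacci point set). The water sphere has
#'   radius `vdw(O) + probeRadius`; a sample point is accessible when it lies
#'   outside every context atom's probe-expanded sphere. Context atoms are
#'   the protein atoms (default) or all non-water atoms
#'   (`sasaContext = "all"`); other waters never occlude.
#' @export
sasa <- function(site, model, config = featureConfig()) {
  vdw <- config@vdwRadii
  if (!"O" %in% names(vdw)) stop("no van der Waals radius for element O")
  R <- vdw[["O"]] + config@probeRadius
  ctx <- if (config@sasaContext == "all") {
    a <- atoms(model); a[a$role %in% c("protein", "ligand", "other"), ,
                         drop = FALSE]
  } else proteinAtoms(model)
  pts <- sweep(fibonacciSphere(config@sasaPoints) * R, 2, .siteXyz(site), "+")
  if (nrow(ctx)) {
    missing <- setdiff(unique(ctx$element), names(vdw))
    if (length(missing))
      stop("no van der Waals radius for element(s): ",
           paste(missing, collapse = ", "))
    rad <- vdw[ctx$element] + config@probeRadius
    d2 <- outer(rowSums(pts^2), rep(1, nrow(ctx))) +
      outer(rep(1, nrow(pts)), rowSums(as.matrix(ctx[, c("x", "y", "z")])^2)) -
      2 * tcrossprod(pts, as.matrix(ctx[, c("x", "y", "z")]))
    accessible <- rowSums(d2 < outer(rep(1, nrow(pts)), rad^2)) == 0
  } else {
    accessible <- rep(TRUE, nrow(pts))
  }
  4 * pi * R^2 * mean(accessible)
}

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Fibonacci (golden-angle spiral) point set; deterministic, so SASA values
#' are reproducible without a random seed.
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' @describeIn waterFeatures the water oxygen's B-factor column, verbatim
#'   (feature C).
#' @export
bfactor <- function(site) site$bfactor

#' Convert mean-square displacement to a B-factor
#'
#' `B = 8 * pi^2 * msd`, the crystallographic relation between an atom's
#' isotropic mean-square displacement (squared Angstrom) and its temperature
#' factor. Used by the synthetic generator; parsed structures report the
#' B-factor column verbatim.
#'
#' @param msd mean-square displacement, squared Angstrom.
#' @return B-factor, squared Angstrom.
#' @examples
#' msdToBfactor(1) # 8 * pi^2
#' @export
msdToBfactor <- function(msd) {
  stopifnot(all(msd >= 0))
  8 * pi^2 * msd
}

#' @describeIn waterFeatures mobility of the water (feature B):
#'   `(BF_i / mean(BF)) / (O_i / mean(O))` with the means taken over all
#'   water oxygens of the structure (or only pocket waters when
#'   `mobilityScope = "pocket"`; then `allWaters` must already be the pocket
#'   subset).
#' @param allWaters the water table supplying the normalization baseline,
#'   typically [waterSites()] of the whole structure.
#' @export
mobility <- function(site, allWaters) {
  if (!nrow(allWaters)) stop("mobility needs at least one baseline water")
  meanB <- mean(allWaters$bfactor)
  meanO <- mean(allWaters$occupancy)
  if (meanB <= 0)
    stop("degenerate input: mean water B-factor is zero")
  if (site$occupancy <= 0 || meanO <= 0)
    stop("degenerate input: zero occupancy in the mobility denominator")
  (site$bfactor / meanB) / (site$occupancy / meanO)
}

#' @describeIn waterFeatures assemble the six features A-F for one water
#'   site; deterministic given inputs and config.
#' @return `featurize()`: named numeric vector with elements `A` to `F`.
#' @export
featurize <- function(site, model, table = defaultPropensityTable(),
                      config = featureConfig()) {
  baseline <- waterSites(model)
  c(A = as.numeric(atomDensity(site, model, config)),
    B = mobility(site, baseline),
    C = as.numeric(bfactor(site)),
    D = hydrophilicity(site, model, table, config),
    E = hydrophobicity(site, model, table, config),
    F = sasa(site, model, config))
}

#' Feature table for the pocket waters of a structure
#'
#' Runs [featurize()] on every water in the ligand binding pocket of
#' `model`. When `labels` (e.g. the output of [labelWaters()]) is given, its
#' `label` column is joined on (chain, resnum).
#'
#' @param model a [StructureModel-class] with a ligand.
#' @param labels optional labeled water table from [labelWaters()].
#' @param table a propensity table.
#' @param config a [FeatureConfig-class].
#' @param labelConfig a [LabelingConfig-class] (pocket definition).
#' @return data.frame with columns `structure_id`, `chain`, `resnum`,
#'   `A`..`F` and `label`.
#' @export
featurizeStructure <- function(model, labels = NULL,
                               table = defaultPropensityTable(),
                               config = featureConfig(),
                               labelConfig = labelingConfig()) {
  pocket <- definePocket(model, labelConfig)
  waters <- pocket$waters[pocket$waters$in_pocket, , drop = FALSE]
  baseline <- waterSites(model)
  feats <- t(vapply(seq_len(nrow(waters)), function(i) {
    s <- waters[i, ]
    c(A = as.numeric(atomDensity(s, model, config)),
      B = mobility(s, baseline),
      C = as.numeric(bfactor(s)),
      D = hydrophilicity(s, model, table, config),
      E = hydrophobicity(s, model, table, config),
      F = sasa(s, model, config))
  }, numeric(6)))
  out <- data.frame(structure_id = waters$structure_id, chain = waters$chain,
                    resnum = waters$resnum, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(feats))
  out$label <- "unlabeled"
  if (!is.null(labels)) {
    hit <- match(paste(out$chain, out$resnum),
                 paste(labels$chain, labels$resnum))
    out$label[!is.na(hit)] <- labels$label[hit[!is.na(hit)]]
  }
  rownames(out) <- NULL
  out
}
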