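#' @import methods
NULL

ATOM_COLUMNS <- c("serial", "name", "element", "resname", "chain",
                  "resnum", "x", "y", "z", "occupancy", "bfactor", "role")

ATOM_ROLES <- c("protein", "ligand", "water", "other")

#' Parsed crystal structure
#'
#' An S4 container for one crystal structure: a flat atom table (one row per
#' atom, after altloc resolution) in which every atom carries the columns the
#' downstream water features need -- coordinates in Angstrom, occupancy, the
#' crystallographic temperature B-factor -- plus a role classification into
#' protein, ligand, water or other. Water molecules are represented by their
#' oxygen atom only.
#'
#' @slot structureId single string identifying the structure.
#' @slot atoms data.frame with columns serial, name, altloc, element, resname,
#'   chain, resnum, x, y, z, occupancy, bfactor, role.
#' @slot resolution crystallographic resolution in Angstrom, or `NA_real_`
#'   when the header does not state one.
#'
#' @seealso [parsePdb()], [waterSites()], [atoms()]
#' @export
setClass("StructureModel",
  representation(structureId = "character",
                 atoms = "data.frame",
                 resolution = "numeric"),
  prototype(structureId = "structure", atoms = data.frame(),
            resolution = NA_real_))

setValidity("StructureModel", function(object) {
  msg <- character()
  if (length(object@structureId) != 1L || is.na(object@structureId))
    msg <- c(msg, "structureId must be a single non-NA string")
  a <- object@atoms
  missing_cols <- setdiff(ATOM_COLUMNS, names(a))
  if (length(missing_cols))
    msg <- c(msg, paste("atoms is missing columns:",
                        paste(missing_cols, collapse = ", ")))
  if (!length(msg) && nrow(a)) {
    if (anyDuplicated(a$serial))
      msg <- c(msg, "atom serial numbers must be unique within a model")
    if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
      msg <- c(msg, "atom coordinates must be finite")
    if (any(a$bfactor < 0, na.rm = TRUE))
      msg <- c(msg, "B-factors must be non-negative")
    if (any(a$occupancy < 0 | a$occupancy > 1, na.rm = TRUE))
      msg <- c(msg, "occupancies must lie in [0, 1]")
    if (!all(a$role %in% ATOM_ROLES))
      msg <- c(msg, "every atom role must be one of protein/ligand/water/other")
  }
  if (length(msg)) msg else TRUE
})

#' Rigid-body superposition result
#'
#' Optimal least-squares rigid transform (Kabsch fit) mapping a mobile
#' structure onto a reference, together with the root-mean-square deviation
#' over the matched atom pairs. The transform acts as
#' `y = R x + t` on mobile coordinates `x` (rows).
#'
#' @slot rotation 3x3 proper orthonormal matrix (determinant +1).
#' @slot translation length-3 numeric, Angstrom.
#' @slot rmsd RMSD in Angstrom over the matched pairs after the fit.
#' @slot nMatched number of matched atom pairs used.
#'
#' @seealso [superpose()], [applyTransform()]
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", nMatched = "integer"))

setValidity("SuperpositionResult", function(object) {
  msg <- character()
  R <- object@rotation
  if (!identical(dim(R), c(3L, 3L)))
    msg <- c(msg, "rotation must be a 3x3 matrix")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      msg <- c(msg, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-6)
      msg <- c(msg, "rotation must be proper (determinant +1)")
  }
  if (length(object@translation) != 3L)
    msg <- c(msg, "translation must have length 3")
  if (length(object@rmsd) != 1L || object@rmsd < 0)
    msg <- c(msg, "rmsd must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Labeling thresholds
#'
#' Holds the three distance thresholds of the homolog-superposition labeling
#' procedure. All boundaries are inclusive. Defaults: homolog pairs are kept
#' when the superposition RMSD is at most 2.0 Angstrom; the binding pocket is
#' every protein atom / water oxygen within 7.0 Angstrom of any ligand atom;
#' a pocket water is conserved (CWM) when its nearest-water Euclidean distance
#' (NED) to the superposed homolog's waters is at most 1.2 Angstrom, free
#' (FWM) otherwise.
#'
#' @slot rmsdMax Angstrom; RMSD filter for homolog pairs.
#' @slot pocketRadius Angstrom; ligand-distance pocket cutoff.
#' @slot nedThreshold Angstrom; CWM/FWM decision threshold on the NED.
#' @slot pocketMode `"any-atom"` (distance to any ligand atom, the default) or
#'   `"center"` (distance to the ligand centroid).
#'
#' @seealso [labelingConfig()], [labelWaters()]
#' @export
setClass("LabelingConfig",
  representation(rmsdMax = "numeric", pocketRadius = "numeric",
                 nedThreshold = "numeric", pocketMode = "character"),
  prototype(rmsdMax = 2.0, pocketRadius = 7.0, nedThreshold = 1.2,
            pocketMode = "any-atom"))

setValidity("LabelingConfig", function(object) {
  msg <- character()
  for (s in c("rmsdMax", "pocketRadius", "nedThreshold")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, paste(s, "must be a single positive number"))
  }
  if (!object@pocketMode %in% c("any-atom", "center"))
    msg <- c(msg, "pocketMode must be 'any-atom' or 'center'")
  if (length(msg)) msg else TRUE
})

#' Feature-extraction settings
#'
#' Radii, scales and sampling parameters for the six microenvironment
#' features. All cutoffs are inclusive.
#'
#' @slot densityRadius Angstrom; protein-atom count cutoff for atom density
#'   (default 3.6).
#' @slot propensityRadius Angstrom; neighborhood for the hydrophilicity /
#'   hydrophobicity sums (default 4.0).
#' @slot d0 Angstrom; interaction distance scale in the exponential weight
#'   (default 1.0).
#' @slot positiveExponent use `exp(+r/d0)` instead of `exp(-r/d0)` in the
#'   hydrophilicity sum (default `FALSE`; see the vignette).
#' @slot probeRadius Angstrom; solvent probe for SASA (default 1.4).
#' @slot sasaPoints number of sphere sample points for SASA (default 960,
#'   minimum 92).
#' @slot vdwRadii named numeric, van der Waals radius per element (Angstrom).
#' @slot sasaContext `"protein"` (default) or `"all"`: which atoms occlude the
#'   water sphere in the SASA calculation.
#' @slot mobilityScope `"structure"` (default) or `"pocket"`: which waters
#'   form the normalization baseline of the mobility feature.
#'
#' @seealso [featureConfig()], [featurize()]
#' @export
setClass("FeatureConfig",
  representation(densityRadius = "numeric", propensityRadius = "numeric",
                 d0 = "numeric", positiveExponent = "logical",
                 probeRadius = "numeric", sasaPoints = "integer",
                 vdwRadii = "numeric", sasaContext = "character",
                 mobilityScope = "character"),
  prototype(densityRadius = 3.6, propensityRadius = 4.0, d0 = 1.0,
            positiveExponent = FALSE, probeRadius = 1.4, sasaPoints = 960L,
            vdwRadii = c(O = 1.52, N = 1.55, C = 1.70, S = 1.80,
                         H = 1.20, P = 1.80),
            sasaContext = "protein", mobilityScope = "structure"))

setValidity("FeatureConfig", function(object) {
  msg <- character()
  for (s in c("densityRadius", "propensityRadius", "d0", "probeRadius")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, paste(s, "must be a single positive number"))
  }
  if (object@sasaPoints < 92L)
    msg <- c(msg, "sasaPoints must be at least 92")
  if (is.null(names(object@vdwRadii)) || any(object@vdwRadii <= 0))
    msg <- c(msg, "vdwRadii must be a named vector of positive radii")
  if (!object@sasaContext %in% c("protein", "all"))
    msg <- c(msg, "sasaContext must be 'protein' or 'all'")
  if (!object@mobilityScope %in% c("structure", "pocket"))
    msg <- c(msg, "mobilityScope must be 'structure' or 'pocket'")
  if (length(msg)) msg else TRUE
})

#' @describeIn LabelingConfig-class constructor with the default thresholds.
#' @param rmsdMax,pocketRadius,nedThreshold,pocketMode see slots.
#' @export
labelingConfig <- function(rmsdMax = 2.0, pocketRadius = 7.0,
                           nedThreshold = 1.2, pocketMode = "any-atom") {
  new("LabelingConfig", rmsdMax = as.numeric(rmsdMax),
      pocketRadius = as.numeric(pocketRadius),
      nedThreshold = as.numeric(nedThreshold), pocketMode = pocketMode)
}

#' @describeIn FeatureConfig-class constructor with the default settings.
#' @param densityRadius,propensityRadius,d0,positiveExponent see slots.
#' @param probeRadius,sasaPoints,vdwRadii,sasaContext,mobilityScope see slots.
#' @export
featureConfig <- function(densityRadius = 3.6, propensityRadius = 4.0,
                          d0 = 1.0, positiveExponent = FALSE,
                          probeRadius = 1.4, sasaPoints = 960L,
                          vdwRadii = NULL, sasaContext = "protein",
                          mobilityScope = "structure") {
  proto <- new("FeatureConfig")
  if (is.null(vdwRadii)) vdwRadii <- proto@vdwRadii
  new("FeatureConfig", densityRadius = as.numeric(densityRadius),
      propensityRadius = as.numeric(propensityRadius), d0 = as.numeric(d0),
      positiveExponent = isTRUE(positiveExponent),
      probeRadius = as.numeric(probeRadius),
      sasaPoints = as.integer(sasaPoints), vdwRadii = vdwRadii,
      sasaContext = sasaContext, mobilityScope = mobilityScope)
}

#' Construct a StructureModel from an atom table
#'
#' Low-level constructor; most users will obtain models from [parsePdb()] or
#' [generateHomologPair()].
#'
#' @param structureId single string.
#' @param atoms data.frame with the atom columns (see
#'   [StructureModel-class]).
#' @param resolution Angstrom or `NA`.
#' @return A validated [StructureModel-class] object.
#' @export
StructureModel <- function(structureId, atoms, resolution = NA_real_) {
  atoms <- as.data.frame(atoms)
  rownames(atoms) <- NULL
  new("StructureModel", structureId = as.character(structureId),
      atoms = atoms, resolution = as.numeric(resolution))
}
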