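#' RMSD filter for homolog pairs
#'
#' A homolog pair enters the labeling pipeline only when its superposition
#' RMSD is at most `rmsdMax` (inclusive boundary).
#'
#' @param result a [SuperpositionResult-class].
#' @param config a [LabelingConfig-class].
#' @return `TRUE` iff `rmsd <= rmsdMax`.
#' @export
pairPassesFilter <- function(result, config = labelingConfig()) {
  stopifnot(is(result, "SuperpositionResult"), is(config, "LabelingConfig"))
  result@rmsd <= config@rmsdMax
}

#' Define the ligand binding pocket
#'
#' The pocket is every protein atom, and every water oxygen, whose minimum
#' Euclidean distance to any ligand atom is at most `pocketRadius`
#' (inclusive). With `pocketMode = "center"` the distance is measured to the
#' ligand centroid instead.
#'
#' @param model a [StructureModel-class] containing at least one ligand atom.
#' @param config a [LabelingConfig-class].
#' @return list with `proteinAtoms` (pocket subset of the atom table) and
#'   `waters` (the [waterSites()] table with `in_pocket` filled in).
#' @export
definePocket <- function(model, config = labelingConfig()) {
  stopifnot(is(model, "StructureModel"), is(config, "LabelingConfig"))
  lig <- ligandAtoms(model)
  if (!nrow(lig))
    stop("cannot define a binding pocket: structure '", structureId(model),
         "' has no ligand atoms (check the ligand selector)")
  ligXyz <- as.matrix(lig[, c("x", "y", "z")])
  if (config@pocketMode == "center")
    ligXyz <- matrix(colMeans(ligXyz), ncol = 3)
  prot <- proteinAtoms(model)
  pd <- minDistToSet(as.matrix(prot[, c("x", "y", "z")]), ligXyz)
  waters <- waterSites(model)
  wd <- minDistToSet(as.matrix(waters[, c("x", "y", "z")]), ligXyz)
  waters$in_pocket <- wd <= config@pocketRadius
  list(proteinAtoms = prot[pd <= config@pocketRadius, , drop = FALSE],
       waters = waters)
}

# row-wise min Euclidean distance from points (n x 3) to a set (m x 3)
minDistToSet <- function(points, set) {
  if (!nrow(points)) return(numeric(0))
  if (!nrow(set)) return(rep(Inf, nrow(points)))
  d2 <- outer(rowSums(points^2), rep(1, nrow(set))) +
    outer(rep(1, nrow(points)), rowSums(set^2)) -
    2 * tcrossprod(points, set)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Nearest-water Euclidean distance (NED)
#'
#' Minimum oxygen-oxygen distance from one water site to a set of partner
#' waters (already expressed in the same frame, e.g. the superposed homolog's
#' waters). An empty partner set yields `Inf`, which downstream labeling
#' turns into FWM.
#'
#' @param site one row of a [waterSites()] table (or any list with `x`, `y`,
#'   `z`).
#' @param partners data.frame of partner waters with `x`, `y`, `z` columns.
#' @return distance in Angstrom (`Inf` when `partners` is empty).
#' @export
nearestWaterDistance <- function(site, partners) {
  if (is.null(partners) || !nrow(partners)) return(Inf)
  min(sqrt((partners$x - site$x)^2 + (partners$y - site$y)^2 +
           (partners$z - site$z)^2))
}

#' Label binding-site waters by homolog superposition
#'
#' The four-step labeling procedure: (1) superpose the homolog onto the
#' reference over matched atoms; (2) keep the pair only when the RMSD is at
#' most `rmsdMax`, otherwise fail explicitly; (3) define the reference
#' binding pocket around the ligand; (4) for each pocket water of the
#' reference, compute the NED to the superposed homolog's waters and label it
#' CWM when `ned <= nedThreshold` (inclusive), FWM otherwise (including when
#' the homolog has no waters at all). Waters outside the pocket stay
#' `"unlabeled"` with `ned = NA`.
#'
#' All waters of the homolog are candidate NED partners, not only those in
#' its own pocket.
#'
#' @param reference [StructureModel-class] with a ligand and waters.
#' @param homolog [StructureModel-class]; its waters supply the NED partners.
#' @param config a [LabelingConfig-class].
#' @param matching optional explicit atom pairing (see [superpose()]).
#' @param superposition optional precomputed [SuperpositionResult-class]
#'   (e.g. when the pair was aligned externally); skips the internal fit.
#' @return the [waterSites()] table of `reference` with `ned`, `in_pocket`
#'   and `label` filled in; the [SuperpositionResult-class] is attached as
#'   attribute `"superposition"`.
#' @examples
#' pair <- generateHomologPair(structureSimSpec(seed = 7))
#' labs <- labelWaters(pair$reference, pair$homolog)
#' table(labs$label)
#' @export
labelWaters <- function(reference, homolog, config = labelingConfig(),
                        matching = NULL, superposition = NULL) {
  stopifnot(is(reference, "StructureModel"), is(homolog, "StructureModel"),
            is(config, "LabelingConfig"))
  sup <- if (is.null(superposition)) superpose(reference, homolog, matching)
         else superposition
  if (!pairPassesFilter(sup, config))
    stop(sprintf("pair rejected (RMSD): %.3f A exceeds rmsdMax %.3f A",
                 sup@rmsd, config@rmsdMax))
  pocket <- definePocket(reference, config)
  waters <- pocket$waters
  partnerXyz <- as.matrix(waterAtoms(homolog)[, c("x", "y", "z")])
  if (nrow(partnerXyz)) partnerXyz <- applyTransform(partnerXyz, sup)
  partners <- data.frame(x = partnerXyz[, 1], y = partnerXyz[, 2],
                         z = partnerXyz[, 3])
  idx <- which(waters$in_pocket)
  for (i in idx) {
    ned <- nearestWaterDistance(waters[i, ], partners)
    waters$ned[i] <- ned
    waters$label[i] <- if (ned <= config@nedThreshold) "CWM" else "FWM"
  }
  attr(waters, "superposition") <- sup
  waters
}
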