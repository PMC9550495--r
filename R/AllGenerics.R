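#' Accessors for StructureModel
#'
#' @param x a [StructureModel-class].
#' @return `atoms()` returns the full atom data.frame; `structureId()` the
#'   identifier string; `structureResolution()` the resolution in Angstrom or
#'   `NA`; `proteinAtoms()`, `ligandAtoms()` and `waterAtoms()` the
#'   role-restricted subsets of the atom table.
#' @name StructureModel-accessors
NULL

#' @rdname StructureModel-accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname StructureModel-accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname StructureModel-accessors
#' @export
setGeneric("structureResolution",
           function(x) standardGeneric("structureResolution"))

#' @rdname StructureModel-accessors
#' @export
setGeneric("proteinAtoms", function(x) standardGeneric("proteinAtoms"))

#' @rdname StructureModel-accessors
#' @export
setGeneric("ligandAtoms", function(x) standardGeneric("ligandAtoms"))

#' @rdname StructureModel-accessors
#' @export
setGeneric("waterAtoms", function(x) standardGeneric("waterAtoms"))

#' @rdname StructureModel-accessors
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' @rdname StructureModel-accessors
#' @export
setMethod("structureId", "StructureModel", function(x) x@structureId)

#' @rdname StructureModel-accessors
#' @export
setMethod("structureResolution", "StructureModel", function(x) x@resolution)

#' @rdname StructureModel-accessors
#' @export
setMethod("proteinAtoms", "StructureModel",
          function(x) x@atoms[x@atoms$role == "protein", , drop = FALSE])

#' @rdname StructureModel-accessors
#' @export
setMethod("ligandAtoms", "StructureModel",
          function(x) x@atoms[x@atoms$role == "ligand", , drop = FALSE])

#' @rdname StructureModel-accessors
#' @export
setMethod("waterAtoms", "StructureModel",
          function(x) x@atoms[x@atoms$role == "water", , drop = FALSE])

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel '", object@structureId, "'\n", sep = "")
  cat("  ", nrow(a), " atoms (",
      sum(a$role == "protein"), " protein, ",
      sum(a$role == "ligand"), " ligand, ",
      sum(a$role == "water"), " water, ",
      sum(a$role == "other"), " other)\n", sep = "")
  if (!is.na(object@resolution))
    cat("  resolution: ", format(object@resolution), " A\n", sep = "")
  invisible(object)
})

setMethod("show", "SuperpositionResult", function(object) {
  cat("SuperpositionResult: rmsd ", sprintf("%.4f", object@rmsd),
      " A over ", object@nMatched, " matched atom pairs\n", sep = "")
  invisible(object)
})

setMethod("show", "LabelingConfig", function(object) {
  cat("LabelingConfig: rmsdMax ", object@rmsdMax,
      " A, pocketRadius ", object@pocketRadius,
      " A, nedThreshold ", object@nedThreshold,
      " A, pocketMode '", object@pocketMode, "'\n", sep = "")
  invisible(object)
})

setMethod("show", "FeatureConfig", function(object) {
  cat("FeatureConfig: densityRadius ", object@densityRadius,
      " A, propensityRadius ", object@propensityRadius,
      " A, d0 ", object@d0,
      " A, probe ", object@probeRadius,
      " A, sasaPoints ", object@sasaPoints, "\n", sep = "")
  invisible(object)
})
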