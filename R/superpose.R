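#' Optimal rigid-body superposition (Kabsch fit)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' matched atom pairs of two structures, by singular value decomposition of
#' the cross-covariance of the centered coordinate sets. Reflections are
#' excluded: the returned rotation always has determinant +1.
#'
#' @param reference,mobile [StructureModel-class] objects.
#' @param matching data.frame with integer columns `ref` and `mobile`
#'   (row indices into each model's atom table), e.g. from [matchAtoms()].
#'   When `NULL`, [matchAtoms()] is called with its defaults.
#' @return A [SuperpositionResult-class]; applying it to `mobile` (see
#'   [applyTransform()]) realizes the reported RMSD.
#' @examples
#' ref <- generateHomologPair(structureSimSpec(seed = 1))$reference
#' superpose(ref, ref)
#' @export
superpose <- function(reference, mobile, matching = NULL) {
  stopifnot(is(reference, "StructureModel"), is(mobile, "StructureModel"))
  if (is.null(matching)) matching <- matchAtoms(reference, mobile)
  if (nrow(matching) < 3L)
    stop("superposition needs at least 3 matched atom pairs, got ",
         nrow(matching))
  P <- as.matrix(atoms(mobile)[matching$mobile, c("x", "y", "z")])
  Q <- as.matrix(atoms(reference)[matching$ref, c("x", "y", "z")])
  fit <- kabsch(P, Q)
  new("SuperpositionResult", rotation = fit$rotation,
      translation = fit$translation, rmsd = fit$rmsd,
      nMatched = nrow(matching))
}

# Core Kabsch solve on n x 3 coordinate matrices: returns R, t with
# Q ~ P %*% t(R) + t.
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L, ncol(Q) == 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  # degenerate sets (coincident or collinear points) leave the rotation
  # under-determined about an axis
  if (any(svd(Pc)$d[1:2] < 1e-8 * max(1, svd(Pc)$d[1])))
    stop("degenerate (collinear or coincident) matched point set")
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(cq - R %*% cp)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates or a structure
#'
#' @param x an n x 3 coordinate matrix or a [StructureModel-class].
#' @param result a [SuperpositionResult-class] (or a list with `rotation`
#'   and `translation`).
#' @return The transformed coordinates, or a copy of the model with
#'   transformed atom coordinates.
#' @export
applyTransform <- function(x, result) {
  R <- if (is(result, "SuperpositionResult")) result@rotation else result$rotation
  tr <- if (is(result, "SuperpositionResult")) result@translation else result$translation
  if (is(x, "StructureModel")) {
    a <- atoms(x)
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
    a$x <- xyz[, 1] + tr[1]; a$y <- xyz[, 2] + tr[2]; a$z <- xyz[, 3] + tr[3]
    return(StructureModel(structureId(x), a, structureResolution(x)))
  }
  sweep(as.matrix(x) %*% t(R), 2, tr, "+")
}

#' Pair atoms of two structures for superposition
#'
#' Default pairing for homolog superposition: the C-alpha atoms of residues
#' paired by a global (Needleman-Wunsch) alignment of the two chains'
#' sequences, computed with `Biostrings::pairwiseAlignment`. For structures
#' with identical residue numbering, `method = "resnum"` pairs C-alpha atoms
#' by (chain, residue number) directly. An explicit user-provided pairing can
#' always be passed to [superpose()] instead.
#'
#' @param reference,mobile [StructureModel-class] objects.
#' @param method `"align"` (sequence-alignment pairing, default) or
#'   `"resnum"`.
#' @return data.frame with columns `ref` and `mobile`: paired row indices
#'   into the two atom tables.
#' @export
matchAtoms <- function(reference, mobile, method = c("align", "resnum")) {
  method <- match.arg(method)
  ca_r <- .calphaTable(reference)
  ca_m <- .calphaTable(mobile)
  if (method == "resnum") {
    key_r <- paste(ca_r$chain, ca_r$resnum)
    key_m <- paste(ca_m$chain, ca_m$resnum)
    hit <- match(key_r, key_m)
    ok <- !is.na(hit)
    return(data.frame(ref = ca_r$row[ok], mobile = ca_m$row[hit[ok]]))
  }
  seq_r <- .oneLetter(ca_r$resname)
  seq_m <- .oneLetter(ca_m$resname)
  alphabet <- sort(unique(c(seq_r, seq_m, LETTERS)))
  submat <- matrix(-1, length(alphabet), length(alphabet),
                   dimnames = list(alphabet, alphabet))
  diag(submat) <- 2
  aln <- Biostrings::pairwiseAlignment(
    paste(seq_r, collapse = ""), paste(seq_m, collapse = ""),
    type = "global", substitutionMatrix = submat,
    gapOpening = 10, gapExtension = 0.5)
  ref_pos <- .alignedPositions(as.character(Biostrings::pattern(aln)))
  mob_pos <- .alignedPositions(as.character(Biostrings::subject(aln)))
  n <- min(length(ref_pos), length(mob_pos))
  keep <- !is.na(ref_pos[seq_len(n)]) & !is.na(mob_pos[seq_len(n)])
  data.frame(ref = ca_r$row[ref_pos[seq_len(n)][keep]],
             mobile = ca_m$row[mob_pos[seq_len(n)][keep]])
}

.calphaTable <- function(model) {
  a <- atoms(model)
  sel <- which(a$role == "protein" & a$name == "CA" & a$element == "C")
  if (!length(sel))
    stop("no C-alpha atoms in structure '", structureId(model), "'")
  ord <- sel[order(a$chain[sel], a$resnum[sel])]
  data.frame(row = ord, chain = a$chain[ord], resnum = a$resnum[ord],
             resname = a$resname[ord], stringsAsFactors = FALSE)
}

.oneLetter <- function(resname) {
  one <- bio3d::aa321(resname)
  one[is.na(one) | one == "X" | nchar(one) != 1] <- "X"
  one
}

# map alignment-column index -> original sequence position (NA at gaps)
.alignedPositions <- function(alignedString) {
  chars <- strsplit(alignedString, "")[[1]]
  pos <- cumsum(chars != "-")
  pos[chars == "-"] <- NA
  pos
}
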