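WATER_RESNAMES <- c("HOH", "WAT", "DOD")

#' Parse a PDB file into a StructureModel
#'
#' Reads a PDB-format crystal structure (via `bio3d::read.pdb`) and classifies
#' every atom as protein, ligand, water or other. `ATOM` records become
#' protein atoms; `HETATM` records whose residue name is in `waterNames`
#' become waters; `HETATM` records matched by `ligand` become ligand atoms;
#' all remaining `HETATM` records are `other`. Occupancy and B-factor columns
#' are preserved verbatim. For waters only the oxygen atom is retained (the
#' water site position); water hydrogens and deuteriums, if present, are
#' dropped.
#'
#' Alternate locations are resolved per (chain, residue, atom name): the
#' conformer with the highest occupancy survives, ties going to the
#' alphabetically first altloc. Multi-model files contribute MODEL 1 only.
#'
#' @param path path to an existing PDB file with at least one coordinate
#'   record.
#' @param ligand ligand selector: either a residue-name string (e.g.
#'   `"LIG"`), or a list with any of `resname`, `chain`, `resnum` which must
#'   all match. `NULL` leaves every non-water HETATM as `other`.
#' @param waterNames residue names treated as water.
#' @param requireLigand error when the selector matches no atom (set by
#'   callers that need a pocket downstream).
#' @return A [StructureModel-class].
#' @examples
#' pdb <- system.file("extdata", "toy_site.pdb", package = "conswat")
#' mod <- parsePdb(pdb, ligand = "LIG")
#' mod
#' @export
parsePdb <- function(path, ligand = NULL, waterNames = WATER_RESNAMES,
                     requireLigand = FALSE) {
  if (!file.exists(path))
    stop("PDB file not found: ", path)
  .checkCoordinateLines(path)
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  atoms <- data.frame(
    serial    = as.integer(at$eleno),
    name      = trimws(at$elety),
    altloc    = ifelse(is.na(at$alt), "", at$alt),
    element   = .elementOf(at$elesy, at$elety),
    resname   = trimws(at$resid),
    chain     = ifelse(is.na(at$chain), "", at$chain),
    resnum    = as.integer(at$resno),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    bfactor   = ifelse(is.na(at$b), 0, at$b),
    role      = "other",
    type      = at$type,
    stringsAsFactors = FALSE)
  atoms <- .resolveAltlocs(atoms)

  is_water_res <- atoms$type == "HETATM" & atoms$resname %in% waterNames
  atoms$role[atoms$type == "ATOM"] <- "protein"
  atoms$role[is_water_res] <- "water"
  if (!is.null(ligand)) {
    lig <- .matchLigand(atoms, ligand) & atoms$type == "HETATM" & !is_water_res
    if (requireLigand && !any(lig))
      stop("ligand selector matched no atoms in ", path)
    atoms$role[lig] <- "ligand"
  } else if (requireLigand) {
    stop("a ligand selector is required but none was given")
  }
  # waters are represented by their oxygen only
  drop <- atoms$role == "water" & atoms$element != "O"
  atoms <- atoms[!drop, setdiff(names(atoms), "type"), drop = FALSE]
  rownames(atoms) <- NULL
  StructureModel(structureId = sub("\\.(pdb|ent)$", "", basename(path)),
                 atoms = atoms,
                 resolution = .scanResolution(path))
}

# Pre-scan coordinate lines so a malformed record fails with its line number
# (the delegated parser reports only a generic failure).
.checkCoordinateLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  if (!any(rec))
    stop("no ATOM/HETATM records in ", path)
  # first MODEL only, mirroring the parse
  endmdl <- which(grepl("^ENDMDL", lines))
  if (length(endmdl)) rec[seq_along(lines) > endmdl[1]] <- FALSE
  for (i in which(rec)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(is.na(xyz)))
      stop("unparseable coordinate line ", i, " in ", path, ": ",
           trimws(lines[i]))
  }
  invisible(TRUE)
}

.scanResolution <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hit <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(hit)) return(NA_real_)
  m <- regmatches(hit[1], regexpr("[0-9]+\\.[0-9]+", hit[1]))
  if (!length(m)) NA_real_ else as.numeric(m)
}

.elementOf <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  guess <- toupper(sub("^[0-9']*", "", trimws(elety)))
  two <- c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA", "CU", "SE")
  fallback <- ifelse(substr(guess, 1, 2) %in% two,
                     substr(guess, 1, 2), substr(guess, 1, 1))
  ifelse(el == "", fallback, el)
}

.resolveAltlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resnum, atoms$resname, atoms$name, sep = "|")
  if (!anyDuplicated(key)) {
    atoms$altloc <- NULL
    return(atoms)
  }
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    occ <- atoms$occupancy[idx]
    best <- idx[occ == max(occ)]
    if (length(best) > 1L) best <- best[order(atoms$altloc[best])][1L]
    best
  }), use.names = FALSE)
  atoms <- atoms[sort(keep), , drop = FALSE]
  atoms$altloc <- NULL
  atoms
}

.matchLigand <- function(atoms, ligand) {
  if (is.character(ligand) && length(ligand) >= 1L)
    return(atoms$resname %in% ligand)
  if (is.list(ligand)) {
    ok <- rep(TRUE, nrow(atoms))
    if (!is.null(ligand$resname)) ok <- ok & atoms$resname %in% ligand$resname
    if (!is.null(ligand$chain))   ok <- ok & atoms$chain %in% ligand$chain
    if (!is.null(ligand$resnum))  ok <- ok & atoms$resnum %in% ligand$resnum
    return(ok)
  }
  stop("ligand selector must be a residue name or a list(resname=, chain=, resnum=)")
}

#' Water sites of a structure
#'
#' One row per water oxygen, ordered by (chain, residue number). The
#' returned table is the seed of the labeling pipeline: `ned`, `label` and
#' `in_pocket` start out unset.
#'
#' @param model a [StructureModel-class].
#' @return data.frame with columns `structure_id`, `chain`, `resnum`, `x`,
#'   `y`, `z`, `occupancy`, `bfactor`, `ned`, `in_pocket`, `label`.
#' @export
waterSites <- function(model) {
  stopifnot(is(model, "StructureModel"))
  w <- waterAtoms(model)
  w <- w[order(w$chain, w$resnum), , drop = FALSE]
  out <- data.frame(
    structure_id = rep(structureId(model), nrow(w)),
    chain = w$chain, resnum = w$resnum,
    x = w$x, y = w$y, z = w$z,
    occupancy = w$occupancy, bfactor = w$bfactor,
    ned = rep(NA_real_, nrow(w)),
    in_pocket = rep(NA, nrow(w)),
    label = rep("unlabeled", nrow(w)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a StructureModel as a PDB file
#'
#' Fixed-column PDB writer: protein atoms as `ATOM`, everything else as
#' `HETATM`. Optionally encodes a per-water label in the B-factor column
#' (CWM = 1, FWM = 2, unlabeled = 0) for visualization.
#'
#' @param model a [StructureModel-class].
#' @param path output file.
#' @param labelInBfactor optional data.frame with columns `chain`, `resnum`,
#'   `label`; matching waters get their label encoded in the B-factor column.
#' @return `path`, invisibly.
#' @export
writePdb <- function(model, path, labelInBfactor = NULL) {
  a <- atoms(model)
  b <- a$bfactor
  if (!is.null(labelInBfactor)) {
    code <- c(CWM = 1, FWM = 2, unlabeled = 0)
    key <- paste(a$chain, a$resnum)
    lk <- paste(labelInBfactor$chain, labelInBfactor$resnum)
    hit <- match(key, lk)
    sel <- !is.na(hit) & a$role == "water"
    b[sel] <- code[labelInBfactor$label[hit[sel]]]
  }
  rec <- ifelse(a$role == "protein", "ATOM  ", "HETATM")
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  sprintf(" %-3s", a$name))
  lines <- sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, a$serial, name4, substr(a$resname, 1, 3),
                   substr(paste0(a$chain, " "), 1, 1), a$resnum,
                   a$x, a$y, a$z, a$occupancy, b, a$element)
  header <- character()
  if (!is.na(structureResolution(model)))
    header <- sprintf("REMARK   2 RESOLUTION. %8.2f ANGSTROMS.",
                      structureResolution(model))
  writeLines(c(header, lines, "END"), path)
  invisible(path)
}

#' Write a tabular report as TSV
#'
#' Fixed column order (as given), floats formatted to a configurable number
#' of decimals so reruns are byte-identical.
#'
#' @param rows data.frame; zero rows writes a header-only file.
#' @param path output file.
#' @param digits decimals for numeric columns (default 3).
#' @return `path`, invisibly.
#' @export
writeReport <- function(rows, path, digits = 3) {
  rows <- as.data.frame(rows)
  for (j in seq_along(rows)) {
    if (is.double(rows[[j]]))
      rows[[j]] <- ifelse(is.na(rows[[j]]), "NA",
                          formatC(rows[[j]], format = "f", digits = digits))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
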