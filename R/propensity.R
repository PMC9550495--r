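#' Atomic hydration / carbon propensity tables
#'
#' The hydrophilicity and hydrophobicity features weight each neighboring
#' protein atom by a hydration propensity `h` (how often that atom type is
#' hydrated when surface-exposed) and a carbon/lipophilic propensity `l`.
#' The package ships a default table of heuristic per-atom-class values
#' (polar and charged side-chain oxygens/nitrogens carry the largest `h`;
#' carbons carry `l = 1`) under `inst/extdata/propensities.tsv`; it is fully
#' user-replaceable via `readPropensityTable()`.
#'
#' Lookup order for a protein atom: exact `(residue, atom)` key, then the
#' wildcard residue `"*"` with the atom name, then the element-class row
#' `("*", "ELEM:<symbol>")`, else the configured `default` (with one warning
#' per call).
#'
#' @param path TSV file with columns `residue`, `atom`, `h`, `l`.
#' @return data.frame with columns `residue`, `atom`, `h`, `l`.
#' @examples
#' head(defaultPropensityTable())
#' @name propensities
NULL

#' @rdname propensities
#' @export
defaultPropensityTable <- function() {
  readPropensityTable(system.file("extdata", "propensities.tsv",
                                  package = "conswat"))
}

#' @rdname propensities
#' @export
readPropensityTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "atom", "h", "l")
  if (!all(need %in% names(tab)))
    stop("propensity table must have columns residue, atom, h, l")
  if (any(tab$h < 0) || any(tab$l < 0))
    stop("propensities must be non-negative")
  tab[need]
}

# vectorized lookup -> two-column matrix cbind(h, l)
.lookupPropensity <- function(table, resname, atomname, element,
                              default = 0) {
  exact <- match(paste(resname, atomname), paste(table$residue, table$atom))
  wild <- match(paste("*", atomname), paste(table$residue, table$atom))
  elem <- match(paste("*", paste0("ELEM:", element)),
                paste(table$residue, table$atom))
  pick <- ifelse(!is.na(exact), exact, ifelse(!is.na(wild), wild, elem))
  h <- ifelse(is.na(pick), default, table$h[pick])
  l <- ifelse(is.na(pick), default, table$l[pick])
  if (anyNA(pick))
    warning(sum(is.na(pick)), " atom type(s) not in the propensity table; ",
            "using default ", default, call. = FALSE)
  cbind(h = h, l = l)
}
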