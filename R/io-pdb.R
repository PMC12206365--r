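#' Read a PDB structure
#'
#' Fixed-column PDB (v3.3) reading built on [bio3d::read.pdb()], returning
#' the atom table as a data.frame. Alternate locations are resolved by
#' keeping the highest-occupancy copy of each `(chain, resno, atom)` (ties:
#' first in file order). The element symbol comes from PDB columns 77-78,
#' falling back to an atom-name heuristic when absent. HETATM records are
#' ignored unless `het = TRUE`; waters are always excluded.
#'
#' @param path path to a PDB file.
#' @param model model number to keep for multi-model files.
#' @param het also keep non-water HETATM records.
#' @return data.frame with columns `chain`, `resno`, `resid`, `atom`,
#'   `element`, `x`, `y`, `z`, `occupancy`.
#' @export
readPDB <- function(path, model = 1L, het = FALSE) {
    if (!file.exists(path)) stop("PDB file not found: ", path)
    pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                           verbose = FALSE)
    at <- pdb$atom
    if (!het) at <- at[at$type == "ATOM", , drop = FALSE]
    at <- at[at$resid != "HOH", , drop = FALSE]
    if (!nrow(at)) stop("no ATOM records in ", path)
    # altloc resolution: highest occupancy, ties -> first in file order
    at$.ord <- seq_len(nrow(at))
    at$.occ <- ifelse(is.na(at$o), 1, at$o)
    key <- paste(at$chain, at$resno, at$elety, sep = "\r")
    keep <- at[order(key, -at$.occ, at$.ord), , drop = FALSE]
    keep <- keep[!duplicated(sort(key)), , drop = FALSE]
    keep <- keep[order(keep$.ord), , drop = FALSE]
    elem <- trimws(keep$elesy)
    miss <- is.na(elem) | !nzchar(elem)
    elem[miss] <- .elementFromAtomName(keep$elety[miss])
    out <- data.frame(chain = keep$chain, resno = keep$resno,
                      resid = keep$resid, atom = keep$elety,
                      element = toupper(elem),
                      x = keep$x, y = keep$y, z = keep$z,
                      occupancy = keep$.occ, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

# first alphabetic character of the atom name, with the two-letter
# element special cases seen in protein/DNA chains
.elementFromAtomName <- function(atom_names) {
    vapply(atom_names, function(a) {
        a <- toupper(trimws(a))
        if (grepl("^(CL|BR|FE|ZN|MG|MN|NA|CA2)", a) && nchar(a) >= 2L &&
            a %in% c("CL", "BR", "FE", "ZN", "MG", "MN"))
            return(a)
        first <- regmatches(a, regexpr("[A-Z]", a))
        if (!length(first)) "C" else first
    }, "", USE.NAMES = FALSE)
}

#' Write an atom table as PDB text
#'
#' Emits fixed-column ATOM records (PDB v3.3) for a structure atom table of
#' the shape returned by [readPDB()]. Used by the toy-structure generator so
#' its output round-trips through the reader.
#'
#' @param atoms data.frame with `chain`, `resno`, `resid`, `atom`,
#'   `element`, `x`, `y`, `z` (and optional `occupancy`).
#' @param path output path, or `NULL` to return the lines.
#' @return the PDB lines, invisibly when written to a file.
#' @export
writePDBText <- function(atoms, path = NULL) {
    occ <- if ("occupancy" %in% names(atoms)) atoms$occupancy else
        rep(1, nrow(atoms))
    lines <- vapply(seq_len(nrow(atoms)), function(i) {
        name <- atoms$atom[i]
        # atom name column alignment: 1-letter elements start in column 14
        namef <- if (nchar(name) < 4L) sprintf(" %-3s", name) else
            sprintf("%-4s", name)
        sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                i, namef, atoms$resid[i], atoms$chain[i], atoms$resno[i],
                atoms$x[i], atoms$y[i], atoms$z[i], occ[i], 0,
                atoms$element[i])
    }, "")
    lines <- c(lines, "END")
    if (is.null(path)) return(lines)
    writeLines(lines, path)
    invisible(lines)
}
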