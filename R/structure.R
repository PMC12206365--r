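#' Van der Waals radii table
#'
#' Bondi-style radii (Angstrom) used by the contact criterion: C 1.70,
#' N 1.55, O 1.52, S 1.80, P 1.80, H 1.20; unknown elements fall back to the
#' default 1.70 with a warning. Shipped as plain-text data and overridable.
#'
#' @param path optional path to a two-column `element<TAB>radius` table with
#'   a `default` row.
#' @return named numeric vector including a `default` entry.
#' @export
vdwRadii <- function(path = system.file("extdata", "vdw_radii.tsv",
                                        package = "VariantScape")) {
    x <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    stats::setNames(x$radius, toupper(x$element))
}

.atomRadii <- function(elements, radii) {
    el <- toupper(elements)
    unknown <- !el %in% names(radii)
    if (any(unknown & el != "DEFAULT"))
        warning("unknown element(s) assigned default radius: ",
                paste(unique(el[unknown]), collapse = ", "))
    r <- radii[el]
    r[unknown] <- radii[["DEFAULT"]]
    unname(r)
}

#' Inter-chain residue contacts by van der Waals overlap
#'
#' Two atoms are in contact when their van der Waals overlap
#' `r_i + r_j - d_ij` is at least `cutoff` (default -0.4 Angstrom, the
#' Chimera contact default with zero hydrogen-bond allowance). A residue
#' pair is reported when any atom pair qualifies; hydrogens are used if
#' present in the structure.
#'
#' @param atoms structure atom table (see [readPDB()]).
#' @param chainA,chainB chain identifiers (both must have atoms).
#' @param cutoff overlap cutoff in Angstrom.
#' @param radii radii table from [vdwRadii()].
#' @return a [ContactSet-class]; the contact table reports per residue pair
#'   the maximal atom-pair overlap.
#' @export
findContacts <- function(atoms, chainA, chainB, cutoff = -0.4,
                         radii = vdwRadii()) {
    a <- atoms[atoms$chain == chainA, , drop = FALSE]
    b <- atoms[atoms$chain == chainB, , drop = FALSE]
    if (!nrow(a) || !nrow(b))
        stop("both chains must be present with >= 1 atom")
    ra <- .atomRadii(a$element, radii)
    rb <- .atomRadii(b$element, radii)
    # all-pairs distances (chains are residue-scale, this stays small)
    dx <- outer(a$x, b$x, "-"); dy <- outer(a$y, b$y, "-")
    dz <- outer(a$z, b$z, "-")
    dist <- sqrt(dx^2 + dy^2 + dz^2)
    overlap <- outer(ra, rb, "+") - dist
    hit <- which(overlap >= cutoff, arr.ind = TRUE)
    if (!nrow(hit)) {
        ct <- data.frame(resno_a = integer(0), resid_a = character(0),
                         resno_b = integer(0), resid_b = character(0),
                         max_overlap = numeric(0), stringsAsFactors = FALSE)
    } else {
        df <- data.frame(resno_a = a$resno[hit[, 1L]],
                         resid_a = a$resid[hit[, 1L]],
                         resno_b = b$resno[hit[, 2L]],
                         resid_b = b$resid[hit[, 2L]],
                         overlap = overlap[hit], stringsAsFactors = FALSE)
        sp <- split(df, paste(df$resno_a, df$resno_b, sep = "\r"))
        ct <- do.call(rbind, lapply(sp, function(g)
            data.frame(resno_a = g$resno_a[1L], resid_a = g$resid_a[1L],
                       resno_b = g$resno_b[1L], resid_b = g$resid_b[1L],
                       max_overlap = max(g$overlap),
                       stringsAsFactors = FALSE)))
        ct <- ct[order(ct$resno_a, ct$resno_b), , drop = FALSE]
        rownames(ct) <- NULL
    }
    new("ContactSet", chainA = chainA, chainB = chainB, cutoff = cutoff,
        contacts = ct)
}

#' Interface residues of one chain
#'
#' Unique residues of the requested chain appearing in any contact of a
#' [ContactSet-class], sorted by residue number.
#'
#' @param contactSet a [ContactSet-class].
#' @param chain chain identifier (must be one of the two chains).
#' @return data.frame with `resno` and `resid`.
#' @export
interfaceResidues <- function(contactSet, chain) {
    ct <- contacts(contactSet)
    if (chain == contactSet@chainA) {
        df <- unique(data.frame(resno = ct$resno_a, resid = ct$resid_a,
                                stringsAsFactors = FALSE))
    } else if (chain == contactSet@chainB) {
        df <- unique(data.frame(resno = ct$resno_b, resid = ct$resid_b,
                                stringsAsFactors = FALSE))
    } else stop("chain not in contact set: ", chain)
    df <- df[order(df$resno), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Flag protein variants at structural interfaces
#'
#' Annotates protein variant groups with whether their position lies at the
#' DNA-binding interface, the dimerization interface, neither, or is absent
#' from the modeled structure (`unmodeled`). Structure residue numbering is
#' reconciled to reference-isoform positions with a configurable offset
#' (structure resno = isoform position + offset).
#'
#' @param groups protein group table (from [groupByProtein()]`$groups`).
#' @param dnaInterface,dimerInterface residue tables from
#'   [interfaceResidues()] (or integer vectors of residue numbers).
#' @param modeledResidues integer vector of residue numbers present in the
#'   structure chain; positions outside it are `unmodeled`.
#' @param offset numbering offset (0 when author numbering equals isoform
#'   positions).
#' @return `groups` with added columns `dna_interface`, `dimer_interface`,
#'   `interface_class`.
#' @export
annotateInterfaceVariants <- function(groups, dnaInterface, dimerInterface,
                                      modeledResidues = NULL, offset = 0L) {
    rn <- function(x) if (is.data.frame(x)) x$resno else as.integer(x)
    pos <- groups$position + offset
    dna <- pos %in% rn(dnaInterface)
    dim_ <- pos %in% rn(dimerInterface)
    unmod <- if (is.null(modeledResidues)) rep(FALSE, length(pos)) else
        !pos %in% modeledResidues
    groups$dna_interface <- dna & !unmod
    groups$dimer_interface <- dim_ & !unmod
    groups$interface_class <- ifelse(unmod, "unmodeled",
        ifelse(dna & dim_, "dna+dimer",
        ifelse(dna, "dna_interface",
        ifelse(dim_, "dimer_interface", "neither"))))
    groups
}
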