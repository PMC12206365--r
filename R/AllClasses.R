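#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Block-based genome-build coordinate map
#'
#' A `ChainMap` holds the liftover blocks used to convert 1-based genomic
#' positions between two genome builds (e.g. hg19 and GRCh38). Each block maps
#' the source interval `[sourceStart, sourceEnd]` onto the target starting at
#' `targetStart`; blocks must not overlap on the source side.
#'
#' @slot blocks data.frame with columns `source_chrom`, `source_start`,
#'   `source_end`, `target_chrom`, `target_start`, `strand` ("+" or "-"),
#'   1-based inclusive coordinates, sorted by source chromosome and start.
#'
#' @seealso [readChainMap()], [liftoverPositions()]
#' @export
setClass("ChainMap", slots = c(blocks = "data.frame"))

setValidity("ChainMap", function(object) {
    b <- object@blocks
    need <- c("source_chrom", "source_start", "source_end",
              "target_chrom", "target_start", "strand")
    if (!all(need %in% names(b)))
        return(paste("blocks must have columns:", paste(need, collapse = ", ")))
    if (nrow(b) == 0L) return(TRUE)
    if (any(b$source_end < b$source_start))
        return("source_end < source_start in some block")
    if (!all(b$strand %in% c("+", "-")))
        return("strand must be '+' or '-'")
    # non-overlap on source, checked per chromosome
    for (chr in unique(b$source_chrom)) {
        bb <- b[b$source_chrom == chr, , drop = FALSE]
        bb <- bb[order(bb$source_start), , drop = FALSE]
        if (nrow(bb) > 1L &&
            any(bb$source_start[-1L] <= bb$source_end[-nrow(bb)]))
            return(sprintf("overlapping source blocks on %s", chr))
    }
    TRUE
})

#' Single-exon gene model with nested isoforms
#'
#' Describes the genomic extent of a single-exon gene, the CDS of each protein
#' isoform, and the flank size used when filtering variants to the gene
#' region. Isoform CDS intervals are expected to nest on the coding-start
#' side (a contains b contains c), the situation for genes whose isoforms
#' differ only by N-terminal extensions.
#'
#' @slot chrom character(1) chromosome name.
#' @slot geneStart,geneEnd integer(1), 1-based gene bounds.
#' @slot cds named list of `c(start, end)` integer pairs, one per isoform
#'   (e.g. `a`, `b`, `c`).
#' @slot flank integer(1), flank in bp kept on each side when region-filtering.
#' @slot proteinLengths named integer vector of isoform protein lengths (aa).
#'
#' @seealso [readGeneModel()], [filterGeneRegion()], [annotateIsoforms()]
#' @export
setClass("GeneModel", slots = c(
    chrom = "character", geneStart = "integer", geneEnd = "integer",
    cds = "list", flank = "integer", proteinLengths = "integer"))

setValidity("GeneModel", function(object) {
    if (length(object@chrom) != 1L) return("chrom must be length 1")
    if (object@geneEnd < object@geneStart) return("geneEnd < geneStart")
    if (!"b" %in% names(object@cds)) return("isoform 'b' CDS is required")
    for (iso in names(object@cds)) {
        cc <- object@cds[[iso]]
        if (length(cc) != 2L || cc[2L] < cc[1L])
            return(sprintf("malformed CDS for isoform %s", iso))
    }
    b <- object@cds[["b"]]
    if (b[1L] < object@geneStart || b[2L] > object@geneEnd)
        return("isoform b CDS outside gene bounds")
    TRUE
})

#' Variant records from one source database
#'
#' Rows normalized from one database export dialect. Coordinates are 1-based
#' on the declared build; symbolic allele encodings (ins/del/dup strings) are
#' preserved verbatim.
#'
#' @slot sourceName character(1), one of `clinvar`, `lovd`, `decipher`,
#'   `cosmic`, `tcga`, `gnomad`, `generic`.
#' @slot build character(1), `hg19` or `GRCh38`.
#' @slot variants data.frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optional `protein_change`, `isoform`, `rsid`, `pathogenicity`,
#'   `allele_frequency`, `sample_id`, `cancer_type`, `pos_hg19`.
#'
#' @seealso [readVariantTable()], [mergeGenomic()]
#' @export
setClass("SourceVariantTable", slots = c(
    sourceName = "character", build = "character", variants = "data.frame"))

.SOURCE_NAMES <- c("clinvar", "lovd", "decipher", "cosmic", "tcga",
                   "gnomad", "generic")

setValidity("SourceVariantTable", function(object) {
    if (!object@sourceName %in% .SOURCE_NAMES)
        return(paste("sourceName must be one of:",
                     paste(.SOURCE_NAMES, collapse = ", ")))
    if (!object@build %in% c("hg19", "GRCh38"))
        return("build must be 'hg19' or 'GRCh38'")
    v <- object@variants
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(v)))
        return(paste("variants must have columns:", paste(need, collapse = ", ")))
    if (nrow(v) && any(v$pos < 1L, na.rm = TRUE)) return("pos must be >= 1")
    TRUE
})

#' Harmonized variant table
#'
#' Unique genomic variants merged across sources on GRCh38, keyed on
#' `(chrom, pos, ref, alt)`, with per-source provenance, rsID conflict flags,
#' allele-frequency class, isoform membership and protein-change annotation.
#' Row bookkeeping is exact: every input row is either represented in
#' `variants` provenance or listed in `removed` with a reason.
#'
#' @slot variants data.frame, one row per unique variant.
#' @slot provenance data.frame, one row per (variant key, source) pair with
#'   per-source labels, counts and merge path (`grch38`, `hg19_exact`,
#'   `hg19_lifted`).
#' @slot removed data.frame of dropped input rows with `reason`.
#' @slot conflicts data.frame of rsID / allele conflicts.
#'
#' @seealso [mergeGenomic()], [groupByProtein()]
#' @export
setClass("HarmonizedVariantTable", slots = c(
    variants = "data.frame", provenance = "data.frame",
    removed = "data.frame", conflicts = "data.frame"))

setValidity("HarmonizedVariantTable", function(object) {
    v <- object@variants
    if (nrow(v)) {
        key <- paste(v$chrom, v$pos, v$ref, v$alt)
        if (anyDuplicated(key)) return("duplicate (chrom,pos,ref,alt) keys")
    }
    TRUE
})

#' Alignment-column to reference-position map
#'
#' Bijection between alignment columns and the ungapped residue positions of
#' a chosen reference sequence, strictly increasing in both coordinates.
#'
#' @slot referenceId character(1) id of the reference sequence.
#' @slot map data.frame with columns `column` and `position`.
#'
#' @seealso [buildPositionMap()]
#' @export
setClass("PositionMap", slots = c(referenceId = "character", map = "data.frame"))

setValidity("PositionMap", function(object) {
    m <- object@map
    if (!all(c("column", "position") %in% names(m)))
        return("map needs 'column' and 'position' columns")
    if (nrow(m) > 1L) {
        if (any(diff(m$column) <= 0) || any(diff(m$position) <= 0))
            return("map must be strictly increasing in both coordinates")
    }
    if (nrow(m) && !identical(m$position, seq_len(nrow(m))))
        return("positions must cover 1..n of the ungapped reference")
    TRUE
})

#' Inter-chain residue contacts
#'
#' Residue pairs of two chains with at least one atom pair whose van der
#' Waals overlap (r_i + r_j - d_ij) reaches the cutoff. Symmetric in chain
#' arguments after orientation normalization.
#'
#' @slot chainA,chainB character(1) chain identifiers.
#' @slot cutoff numeric(1) overlap cutoff in Angstrom.
#' @slot contacts data.frame with columns `resno_a`, `resid_a`, `resno_b`,
#'   `resid_b`, `max_overlap`.
#'
#' @seealso [findContacts()], [interfaceResidues()]
#' @export
setClass("ContactSet", slots = c(
    chainA = "character", chainB = "character",
    cutoff = "numeric", contacts = "data.frame"))

## ---- show methods ----

setMethod("show", "ChainMap", function(object) {
    cat(sprintf("ChainMap with %d block(s)\n", nrow(object@blocks)))
    if (nrow(object@blocks)) print(utils::head(object@blocks, 5L))
})

setMethod("show", "GeneModel", function(object) {
    cat(sprintf("GeneModel on %s:%d-%d (flank %d bp)\n", object@chrom,
                object@geneStart, object@geneEnd, object@flank))
    for (iso in names(object@cds))
        cat(sprintf("  isoform %s: CDS %d-%d (%s aa)\n", iso,
                    object@cds[[iso]][1L], object@cds[[iso]][2L],
                    if (iso %in% names(object@proteinLengths))
                        object@proteinLengths[[iso]] else "?"))
})

setMethod("show", "SourceVariantTable", function(object) {
    cat(sprintf("SourceVariantTable '%s' (%s): %d row(s)\n",
                object@sourceName, object@build, nrow(object@variants)))
})

setMethod("show", "HarmonizedVariantTable", function(object) {
    cat(sprintf(paste0("HarmonizedVariantTable: %d unique variant(s), ",
                       "%d provenance row(s), %d removed, %d conflict(s)\n"),
                nrow(object@variants), nrow(object@provenance),
                nrow(object@removed), nrow(object@conflicts)))
})

setMethod("show", "PositionMap", function(object) {
    cat(sprintf("PositionMap for '%s': %d mapped position(s)\n",
                object@referenceId, nrow(object@map)))
})

setMethod("show", "ContactSet", function(object) {
    cat(sprintf("ContactSet %s vs %s (overlap cutoff %.2f A): %d residue pair(s)\n",
                object@chainA, object@chainB, object@cutoff,
                nrow(object@contacts)))
})
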