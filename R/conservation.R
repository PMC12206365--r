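## Physicochemical property classes (Taylor/Livingstone-Barton) used by the
## conservation score. A gap has no properties.
.AA_PROPERTIES <- list(
    hydrophobic = c("A","C","F","G","H","I","K","L","M","T","V","W","Y"),
    polar       = c("C","D","E","H","K","N","Q","R","S","T","W","Y"),
    small       = c("A","C","D","G","N","P","S","T","V"),
    tiny        = c("A","C","G","S"),
    aliphatic   = c("I","L","V"),
    aromatic    = c("F","H","W","Y"),
    positive    = c("H","K","R"),
    negative    = c("D","E"),
    charged     = c("D","E","H","K","R"),
    proline     = c("P"))

.propertyMatrix <- local({
    m <- NULL
    function() {
        if (is.null(m)) {
            aas <- c("A","C","D","E","F","G","H","I","K","L","M","N","P",
                     "Q","R","S","T","V","W","Y")
            mm <- sapply(.AA_PROPERTIES, function(cls) aas %in% cls)
            rownames(mm) <- aas
            m <<- mm
        }
        m
    }
})

#' Per-column alignment metrics
#'
#' Computes, for each alignment column, the JalView-style summary metrics:
#'
#' * `consensus`: modal non-gap residue (alphabetical on ties, flagged);
#' * `consensus_support`: percent of *all* sequences (gapped included in the
#'   denominator) carrying the consensus residue;
#' * `occupancy`: number of non-gap residues;
#' * `quality`: mean BLOSUM62 score over all unordered non-gap residue pairs
#'   in the column, min-max rescaled to `[0, 1]` across the alignment;
#' * `conservation`: 0-11 physicochemical conservation. A score of 11 means
#'   a single identical residue with no gaps. Otherwise the score counts
#'   (0-10) the property classes that are conserved in the column, i.e.
#'   present in every sequence or absent from every sequence; a gap carries
#'   no properties, so any gap caps the score at the number of
#'   all-absent properties. An all-gap column scores 0 with a gap consensus.
#'
#' @param aln an alignment ([Biostrings::AAMultipleAlignment] or named
#'   character vector).
#' @param columns integer vector of columns (default: all).
#' @return data.frame with one row per requested column: `column`,
#'   `consensus`, `consensus_support`, `occupancy`, `quality`,
#'   `conservation`, `consensus_tie`.
#' @export
columnMetrics <- function(aln, columns = NULL) {
    m <- alignmentMatrix(aln)
    n_seq <- nrow(m)
    if (is.null(columns)) columns <- seq_len(ncol(m))
    if (any(columns < 1L | columns > ncol(m)))
        stop("column index out of range")
    raw_quality <- vapply(seq_len(ncol(m)), function(j)
        .columnPairScore(m[, j]), 0)
    fin <- is.finite(raw_quality)
    qlo <- if (any(fin)) min(raw_quality[fin]) else 0
    qhi <- if (any(fin)) max(raw_quality[fin]) else 1
    quality <- rep(0, ncol(m))
    quality[fin] <- if (qhi > qlo)
        (raw_quality[fin] - qlo) / (qhi - qlo) else 1
    out <- do.call(rbind, lapply(columns, function(j) {
        col <- m[, j]
        res <- col[col != "-"]
        occ <- length(res)
        if (!occ) {
            return(data.frame(column = j, consensus = "-",
                              consensus_support = 0, occupancy = 0L,
                              quality = 0, conservation = 0L,
                              consensus_tie = FALSE,
                              stringsAsFactors = FALSE))
        }
        tab <- sort(table(res), decreasing = TRUE)
        top <- names(tab)[tab == tab[1L]]
        cons <- sort(top)[1L]
        support <- 100 * sum(res == cons) / n_seq
        data.frame(column = j, consensus = cons,
                   consensus_support = support, occupancy = occ,
                   quality = quality[j],
                   conservation = .amasConservation(col),
                   consensus_tie = length(top) > 1L,
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

.amasConservation <- function(col) {
    res <- col[col != "-"]
    if (!length(res)) return(0L)
    has_gap <- length(res) < length(col)
    u <- unique(res)
    if (!has_gap && length(u) == 1L) return(11L)
    pm <- .propertyMatrix()
    known <- u[u %in% rownames(pm)]
    if (!length(known)) return(0L)
    present <- colSums(pm[known, , drop = FALSE] > 0) == length(known)
    absent <- colSums(pm[known, , drop = FALSE] > 0) == 0L
    # a gap has no properties: with a gap present no property is carried by
    # every sequence, so only all-absent properties remain conserved
    if (has_gap) sum(absent) else sum(present | absent)
}

.blosum62 <- local({
    m <- NULL
    function() {
        if (is.null(m)) {
            e <- new.env()
            utils::data("BLOSUM62", package = "Biostrings", envir = e)
            m <<- e$BLOSUM62
        }
        m
    }
})

.columnPairScore <- function(col) {
    blo <- .blosum62()
    res <- col[col != "-"]
    res <- res[res %in% rownames(blo)]
    if (length(res) < 2L) return(NA_real_)
    sub <- blo[res, res, drop = FALSE]
    mean(sub[upper.tri(sub)])
}

#' Map alignment columns to reference positions
#'
#' Builds the bijection between alignment columns and the ungapped residue
#' positions of the reference sequence: the k-th non-gap reference residue
#' maps to its column.
#'
#' @param aln an alignment.
#' @param referenceId id of the reference sequence.
#' @param expectedLength optional expected ungapped reference length; a
#'   mismatch raises a warning.
#' @return a [PositionMap-class].
#' @examples
#' aln <- c(ref = "A-CD", s2 = "AQCD")
#' positionMap(buildPositionMap(aln, "ref"))
#' @export
buildPositionMap <- function(aln, referenceId, expectedLength = NULL) {
    s <- alignmentStrings(aln)
    if (!referenceId %in% names(s))
        stop("reference id not in alignment: ", referenceId)
    chars <- strsplit(s[[referenceId]], "", fixed = TRUE)[[1L]]
    cols <- which(chars != "-")
    if (!is.null(expectedLength) && length(cols) != expectedLength)
        warning(sprintf("ungapped reference length %d != expected %d",
                        length(cols), expectedLength))
    new("PositionMap", referenceId = referenceId,
        map = data.frame(column = cols, position = seq_along(cols)))
}

#' Species whose residue matches a human variant
#'
#' For a protein variant at a reference position, lists the alignment
#' sequences (other than the reference itself) whose residue at the mapped
#' column equals the variant's alternate amino acid.
#'
#' @param aln an alignment.
#' @param pmap a [PositionMap-class] for the reference sequence.
#' @param position protein position in the reference frame.
#' @param altAa single-letter alternate amino acid.
#' @param useSpecies return species labels parsed from ids where available.
#' @return character vector of sequence ids (or species labels).
#' @export
speciesMatches <- function(aln, pmap, position, altAa, useSpecies = FALSE) {
    m <- alignmentMatrix(aln)
    pm <- positionMap(pmap)
    j <- pm$column[match(position, pm$position)]
    if (is.na(j)) stop("position not mapped: ", position)
    hit <- m[, j] == toupper(altAa)
    hit[rownames(m) == pmap@referenceId] <- FALSE
    ids <- rownames(m)[hit]
    if (useSpecies) {
        sp <- speciesFromIds(ids)
        ids <- ifelse(nzchar(sp), sp, ids)
    }
    ids
}

#' Annotate protein variant groups with conservation metrics
#'
#' Joins each protein variant group to the column metrics of its mapped
#' position and the list of species matching its alternate residue, and
#' emits a companion table covering every reference position (including
#' those with no reported variant).
#'
#' @param groups protein group table from [groupByProtein()] (`$groups`).
#' @param aln the reference-species alignment.
#' @param pmap a [PositionMap-class].
#' @param metrics optional precomputed [columnMetrics()] table.
#' @return list with `annotated` (variant groups plus metric columns,
#'   `species_matches` and an `unmapped` flag) and `positions` (one row per
#'   reference position with its metrics).
#' @export
annotateVariants <- function(groups, aln, pmap, metrics = NULL) {
    pm <- positionMap(pmap)
    if (is.null(metrics)) metrics <- columnMetrics(aln, pm$column)
    metmap <- metrics[match(pm$column, metrics$column), , drop = FALSE]
    positions <- cbind(position = pm$position, metmap)
    rownames(positions) <- NULL
    if (!nrow(groups)) return(list(annotated = groups, positions = positions))
    idx <- match(groups$position, pm$position)
    mappable <- groups$isoform == "b" & !is.na(idx)
    ann <- groups
    for (cc in c("consensus", "consensus_support", "occupancy", "quality",
                 "conservation"))
        ann[[cc]] <- ifelse(mappable, metmap[[cc]][idx], NA)
    ann$unmapped <- !mappable
    ann$species_matches <- vapply(seq_len(nrow(ann)), function(i) {
        if (!mappable[i] || !ann$alt_aa[i] %in% LETTERS) return("")
        paste(speciesMatches(aln, pmap, ann$position[i], ann$alt_aa[i],
                             useSpecies = TRUE), collapse = ",")
    }, "")
    list(annotated = ann, positions = positions)
}
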