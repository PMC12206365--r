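#' Read a protein multiple alignment
#'
#' Reads an aligned protein FASTA or Clustal file into a
#' [Biostrings::AAMultipleAlignment]. The Clustal reader accepts both classic
#' `CLUSTAL W` and `CLUSTAL O` headers, with or without ruler/conservation
#' lines and cumulative residue counts. `.` gap characters are normalized to
#' `-`. Record order is preserved from the file.
#'
#' @param path path to the alignment file.
#' @param format `"clustal"` or `"fasta"`.
#' @return an [Biostrings::AAMultipleAlignment].
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACDE", ">s2", "AC-E"), tf)
#' aln <- readAlignment(tf, format = "fasta")
#' ncol(aln)
#' @export
readAlignment <- function(path, format = c("clustal", "fasta")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("alignment file not found: ", path)
    if (format == "fasta") {
        seqs <- Biostrings::readAAStringSet(path)
        seqs <- .checkAlignedSet(as.character(seqs), names(seqs))
    } else {
        seqs <- .readClustalTolerant(path)
    }
    Biostrings::AAMultipleAlignment(
        Biostrings::AAStringSet(seqs))
}

# Tolerant line-based Clustal parser (fallback convention; handles classic
# CLUSTAL W, CLUSTAL O, MUSCLE-style headers, optional conservation lines
# and trailing cumulative counts).
.readClustalTolerant <- function(path) {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || !grepl("^(CLUSTAL|MUSCLE)", lines[1L],
                                 ignore.case = TRUE))
        stop("not a Clustal file (missing CLUSTAL header): ", path)
    lines <- lines[-1L]
    seqs <- character(0)
    order <- character(0)
    for (ln in lines) {
        if (!nzchar(trimws(ln))) next
        # conservation lines contain only space/.:*
        if (grepl("^[ .:*]+$", ln)) next
        m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z.\\-]+)(\\s+\\d+)?\\s*$", ln))[[1L]]
        if (length(m) < 3L)
            stop("unparseable Clustal line: ", substr(ln, 1L, 60L))
        id <- m[2L]; block <- m[3L]
        if (id %in% order) {
            seqs[[id]] <- paste0(seqs[[id]], block)
        } else {
            order <- c(order, id)
            seqs[[id]] <- block
        }
    }
    .checkAlignedSet(unlist(seqs[order]), order)
}

.checkAlignedSet <- function(seqs, ids) {
    if (is.null(ids) || any(!nzchar(ids)))
        stop("alignment contains records with empty ids")
    if (anyDuplicated(ids))
        stop("duplicate sequence id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (length(seqs) < 2L) stop("an alignment needs >= 2 records")
    seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
    w <- nchar(seqs)
    if (length(unique(w)) != 1L) {
        bad <- ids[w != stats::median(w)]
        stop("ragged alignment; offending id(s): ",
             paste(bad, collapse = ", "))
    }
    names(seqs) <- ids
    seqs
}

#' Write an alignment as aligned FASTA
#'
#' @param aln an [Biostrings::AAMultipleAlignment] or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAlignmentFasta <- function(aln, path) {
    seqs <- alignmentStrings(aln)
    out <- character(2L * length(seqs))
    out[c(TRUE, FALSE)] <- paste0(">", names(seqs))
    out[c(FALSE, TRUE)] <- unname(seqs)
    writeLines(out, path)
    invisible(path)
}

#' Alignment rows as a named character vector / character matrix
#'
#' `alignmentStrings` returns the aligned sequences as a named character
#' vector; `alignmentMatrix` as a character matrix (rows = sequences,
#' columns = alignment columns) with `-` gaps.
#'
#' @param aln an [Biostrings::AAMultipleAlignment] or named character vector
#'   of equal-length aligned sequences.
#' @return character vector or matrix.
#' @export
alignmentStrings <- function(aln) {
    if (is(aln, "AAMultipleAlignment") || is(aln, "MultipleAlignment")) {
        s <- as.character(Biostrings::unmasked(aln))
    } else if (is.character(aln)) {
        s <- aln
    } else stop("unsupported alignment object of class ", class(aln)[1L])
    toupper(gsub(".", "-", s, fixed = TRUE))
}

#' @rdname alignmentStrings
#' @export
alignmentMatrix <- function(aln) {
    s <- alignmentStrings(aln)
    m <- do.call(rbind, strsplit(s, "", fixed = TRUE))
    rownames(m) <- names(s)
    m
}

#' Parse species labels from sequence ids
#'
#' Sequence ids of the form `Genus_species[_...]` or descriptions containing
#' a bracketed organism (`[Genus species]`) yield a species label; otherwise
#' an empty string is returned.
#'
#' @param ids character vector of sequence ids/descriptions.
#' @return character vector of species labels (possibly empty strings).
#' @export
speciesFromIds <- function(ids) {
    out <- character(length(ids))
    br <- regmatches(ids, regexpr("\\[[^]]+\\]", ids))
    has_br <- grepl("\\[[^]]+\\]", ids)
    out[has_br] <- gsub("^\\[|\\]$", "", regmatches(ids, regexpr("\\[[^]]+\\]", ids)))
    m <- regexec("^([A-Z][a-z]+)_([a-z]+)", ids)
    mm <- regmatches(ids, m)
    plain <- !has_br & lengths(mm) == 3L
    out[plain] <- vapply(mm[plain], function(x) paste(x[2L], x[3L]), "")
    out
}
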