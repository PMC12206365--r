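#' Read a plain-text key=value config file
#'
#' Lines of the form `key = value`; `#` starts a comment; blank lines are
#' ignored. Used for dialect column maps and gene models so that database
#' export headers and gene definitions stay configuration, not code.
#'
#' @param path config file path.
#' @return named character vector.
#' @export
readConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
    bad <- lengths(kv) != 3L
    if (any(bad)) stop("malformed config line: ", lines[bad][1L])
    vals <- vapply(kv, function(x) trimws(x[3L]), "")
    names(vals) <- vapply(kv, function(x) trimws(x[2L]), "")
    vals
}

.CANONICAL_FIELDS <- c("chrom", "pos", "ref", "alt", "protein_change",
                       "isoform", "rsid", "pathogenicity",
                       "allele_frequency", "sample_id", "cancer_type",
                       "pos_hg19")

.dialectConfigPath <- function(dialect) {
    if (file.exists(dialect)) return(dialect)
    p <- system.file("extdata", "dialects", paste0(dialect, ".cfg"),
                     package = "VariantScape")
    if (!nzchar(p)) stop("unknown dialect (no config found): ", dialect)
    p
}

#' Read a variant table in a database export dialect
#'
#' Reads a TSV/CSV export and normalizes it to the canonical variant fields
#' via a dialect column map (a plain-text config; shipped dialects:
#' `clinvar`, `lovd`, `decipher`, `cosmic`, `tcga`, `gnomad`, `generic`).
#' Protein-change strings that do not parse as HGVS-p-like substitutions are
#' preserved verbatim and flagged in the `protein_change_unparsed` column.
#'
#' @param path table path.
#' @param dialect dialect name or path to a dialect config file. The config
#'   maps canonical fields (`chrom`, `pos`, `ref`, `alt`, ...) to the
#'   export's column names and may set `build` and `sep`.
#' @param build override the build declared in the dialect config.
#' @return a [SourceVariantTable-class].
#' @export
readVariantTable <- function(path, dialect = "generic", build = NULL) {
    cfg <- readConfig(.dialectConfigPath(dialect))
    src <- if ("source" %in% names(cfg)) cfg[["source"]] else
        if (basename(dialect) %in% paste0(.SOURCE_NAMES, ".cfg") ||
            dialect %in% .SOURCE_NAMES)
            sub("\\.cfg$", "", basename(dialect)) else "generic"
    sep <- if ("sep" %in% names(cfg) && cfg[["sep"]] == "comma") "," else "\t"
    if (is.null(build))
        build <- if ("build" %in% names(cfg)) cfg[["build"]] else "GRCh38"
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             colClasses = "character", check.names = FALSE,
                             quote = "\"", comment.char = "")
    colmap <- cfg[names(cfg) %in% .CANONICAL_FIELDS]
    mandatory <- c("chrom", "pos", "ref", "alt")
    missing_map <- setdiff(mandatory, names(colmap))
    missing_col <- names(colmap)[!colmap %in% names(raw) &
                                 names(colmap) %in% mandatory]
    if (length(missing_map) || length(missing_col))
        stop("missing mandatory column(s): ",
             paste(unique(c(missing_map, colmap[missing_col])), collapse = ", "))
    v <- data.frame(row.names = seq_len(nrow(raw)))
    for (f in .CANONICAL_FIELDS) {
        v[[f]] <- if (f %in% names(colmap) && colmap[[f]] %in% names(raw))
            raw[[colmap[[f]]]] else NA_character_
    }
    pos <- suppressWarnings(as.integer(v$pos))
    if (any(is.na(pos) & !is.na(v$pos) & nzchar(v$pos)))
        stop("unparseable position value(s): ",
             paste(utils::head(v$pos[is.na(pos) & nzchar(v$pos)], 3L),
                   collapse = ", "))
    v$pos <- pos
    v$pos_hg19 <- suppressWarnings(as.integer(v$pos_hg19))
    v$allele_frequency <- suppressWarnings(as.numeric(v$allele_frequency))
    if (any(v$allele_frequency < 0 | v$allele_frequency > 1, na.rm = TRUE))
        stop("allele_frequency outside [0,1]")
    pc <- parseProteinChange(v$protein_change)
    v$protein_change_unparsed <- !is.na(v$protein_change) &
        nzchar(v$protein_change) & is.na(pc$position)
    new("SourceVariantTable", sourceName = src, build = build, variants = v)
}

#' Read a genome-build coordinate map
#'
#' Accepts either a UCSC chain-format subset or a 6-column TSV
#' (`source_chrom`, `source_start`, `source_end`, `target_chrom`,
#' `target_start`, `strand`; 1-based inclusive). Blocks are sorted by source
#' position and must not overlap on the source side.
#'
#' @param path file path.
#' @return a [ChainMap-class].
#' @export
readChainMap <- function(path) {
    if (!file.exists(path)) stop("chain map file not found: ", path)
    first <- readLines(path, n = 1L, warn = FALSE)
    b <- if (grepl("^chain\\b", first)) .readUcscChain(path)
         else utils::read.table(path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    for (cc in c("source_start", "source_end", "target_start"))
        b[[cc]] <- as.integer(b[[cc]])
    b <- b[order(b$source_chrom, b$source_start), , drop = FALSE]
    rownames(b) <- NULL
    new("ChainMap", blocks = b)
}

# UCSC chain: 0-based half-open, q coordinates on qStrand
.readUcscChain <- function(path) {
    lines <- trimws(readLines(path, warn = FALSE))
    out <- list()
    i <- 1L
    while (i <= length(lines)) {
        ln <- lines[i]
        if (!nzchar(ln)) { i <- i + 1L; next }
        if (!grepl("^chain\\b", ln)) stop("malformed chain file near: ", ln)
        f <- strsplit(ln, "\\s+")[[1L]]
        tName <- f[3L]; tStart <- as.numeric(f[6L])
        qName <- f[8L]; qSize <- as.numeric(f[9L])
        qStrand <- f[10L]; qStart <- as.numeric(f[11L])
        i <- i + 1L
        repeat {
            f2 <- strsplit(lines[i], "\\s+")[[1L]]
            size <- as.numeric(f2[1L])
            out[[length(out) + 1L]] <- data.frame(
                source_chrom = tName,
                source_start = tStart + 1, source_end = tStart + size,
                target_chrom = qName,
                target_start = if (qStrand == "+") qStart + 1 else
                    qSize - qStart,
                strand = qStrand, stringsAsFactors = FALSE)
            if (length(f2) < 3L) { i <- i + 1L; break }
            tStart <- tStart + size + as.numeric(f2[2L])
            qStart <- qStart + size + as.numeric(f2[3L])
            i <- i + 1L
        }
    }
    do.call(rbind, out)
}

#' Write a ChainMap as 6-column TSV
#' @param map a [ChainMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeChainMap <- function(map, path) {
    utils::write.table(blocks(map), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a gene model config
#'
#' Keys: `chrom`, `gene_start`, `gene_end`, `flank`, `cds_<iso>_start`,
#' `cds_<iso>_end`, `protein_length_<iso>` for isoforms `a`, `b`, `c` (only
#' `b` is mandatory).
#'
#' @param path config path; defaults to the shipped single-exon TREX1 model.
#' @return a [GeneModel-class].
#' @export
readGeneModel <- function(path = system.file("extdata",
                                             "gene_model_trex1.cfg",
                                             package = "VariantScape")) {
    cfg <- readConfig(path)
    isos <- unique(sub("^cds_([a-z]+)_start$", "\\1",
                       grep("^cds_[a-z]+_start$", names(cfg), value = TRUE)))
    cds <- lapply(isos, function(iso)
        as.integer(c(cfg[[paste0("cds_", iso, "_start")]],
                     cfg[[paste0("cds_", iso, "_end")]])))
    names(cds) <- isos
    plen <- vapply(isos, function(iso) {
        k <- paste0("protein_length_", iso)
        if (k %in% names(cfg)) as.integer(cfg[[k]]) else NA_integer_
    }, 1L)
    new("GeneModel", chrom = cfg[["chrom"]],
        geneStart = as.integer(cfg[["gene_start"]]),
        geneEnd = as.integer(cfg[["gene_end"]]),
        cds = cds, flank = as.integer(cfg[["flank"]]),
        proteinLengths = plen)
}

#' Read an external model-score table
#'
#' A TSV with one row per protein variant label (e.g. `G23D`) and numeric
#' score columns from stability / pathogenicity predictors (e.g. FoldX and
#' INPS-3D delta-delta-G of folding in kcal/mol, AlphaMissense pathogenicity
#' in `[0, 1]`).
#'
#' @param path TSV path; first column must be `variant`.
#' @return data.frame with unique `variant` labels and numeric score columns.
#' @export
readModelScores <- function(path) {
    x <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
    if (names(x)[1L] != "variant") stop("first column must be 'variant'")
    if (anyDuplicated(x$variant))
        stop("duplicate variant label(s): ",
             paste(unique(x$variant[duplicated(x$variant)]), collapse = ", "))
    for (j in seq_along(x)[-1L])
        if (!is.numeric(x[[j]]) && !all(is.na(x[[j]])))
            x[[j]] <- suppressWarnings(as.numeric(x[[j]]))
    x
}
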