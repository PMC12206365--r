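#' Parse HGVS-p-like protein change strings
#'
#' Accepts one- and three-letter substitution strings with or without the
#' `p.` prefix and surrounding parentheses (`E266G`, `p.Glu266Gly`,
#' `p.(R114H)`), frameshifts (`C99fs`, `C99Mfs*3`), and stop gains
#' (`R164*`, `p.Arg164Ter`). Anything else is returned unparsed
#' (`NA` position).
#'
#' @param x character vector of protein change strings.
#' @return data.frame with columns `ref_aa`, `position`, `alt_aa`, `kind`
#'   (`missense`, `synonymous`, `stop`, `frameshift` or `NA`).
#' @export
parseProteinChange <- function(x) {
    three <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
               Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
               Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
               Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
               Ter = "*")
    n <- length(x)
    out <- data.frame(ref_aa = rep(NA_character_, n),
                      position = rep(NA_integer_, n),
                      alt_aa = rep(NA_character_, n),
                      kind = rep(NA_character_, n),
                      stringsAsFactors = FALSE)
    if (!n) return(out)
    y <- gsub("^p\\.", "", trimws(ifelse(is.na(x), "", x)))
    y <- gsub("[()]", "", y)
    # three-letter -> one-letter
    for (t in names(three))
        y <- gsub(t, three[[t]], y, fixed = TRUE)
    m <- regmatches(y, regexec("^([A-Z\\*])([0-9]+)([A-Z\\*]|=|[A-Z]?fs.*)$",
                               y))
    ok <- lengths(m) == 4L
    if (any(ok)) {
        ref <- vapply(m[ok], `[`, "", 2L)
        pos <- as.integer(vapply(m[ok], `[`, "", 3L))
        alt <- vapply(m[ok], `[`, "", 4L)
        kind <- ifelse(grepl("fs", alt), "frameshift",
                ifelse(alt == "*", "stop",
                ifelse(alt == ref | alt == "=", "synonymous", "missense")))
        alt[alt == "="] <- ref[alt == "="]
        alt[kind == "frameshift"] <- "fs"
        out$ref_aa[ok] <- ref
        out$position[ok] <- pos
        out$alt_aa[ok] <- alt
        out$kind[ok] <- kind
    }
    out
}

#' Classify a population allele frequency
#'
#' Strict threshold at 0.0011 (the suggested cutoff for pathogenic variants
#' of the reference gene): `af > 0.0011` is `Elevated`; `af <= 0.0011`
#' (including the threshold itself, which "does not exceed" it) is `Low`;
#' missing frequencies are `NA`.
#'
#' @param af numeric vector of allele frequencies in `[0, 1]` (NA allowed).
#' @param threshold frequency threshold (default 0.0011).
#' @return character vector over `{"Elevated", "Low", NA}`.
#' @examples
#' classifyFrequency(c(0.00174, 0.0011, NA))
#' @export
classifyFrequency <- function(af, threshold = 0.0011) {
    if (any(af < 0 | af > 1, na.rm = TRUE))
        stop("allele frequency outside [0,1]")
    ifelse(is.na(af), NA_character_,
           ifelse(af > threshold, "Elevated", "Low"))
}

#' Lift genomic positions between builds
#'
#' Maps 1-based positions through the containing block of a [ChainMap-class],
#' with strand handling. Positions in no block are returned as explicit
#' misses (`mapped = FALSE`), never dropped.
#'
#' @param chrom character vector of chromosomes.
#' @param pos integer vector of 1-based positions.
#' @param chainMap a [ChainMap-class].
#' @return data.frame with columns `chrom`, `pos` (target coordinates, NA
#'   when unmapped) and `mapped`.
#' @export
liftoverPositions <- function(chrom, pos, chainMap) {
    stopifnot(is(chainMap, "ChainMap"), length(chrom) == length(pos))
    if (any(pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
    b <- blocks(chainMap)
    n <- length(pos)
    out <- data.frame(chrom = rep(NA_character_, n),
                      pos = rep(NA_integer_, n),
                      mapped = rep(FALSE, n), stringsAsFactors = FALSE)
    if (!n || !nrow(b)) return(out)
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    s <- GenomicRanges::GRanges(b$source_chrom,
                                IRanges::IRanges(b$source_start,
                                                 b$source_end))
    hits <- GenomicRanges::findOverlaps(q, s, select = "first")
    hit <- !is.na(hits)
    if (any(hit)) {
        bi <- hits[hit]
        off <- pos[hit] - b$source_start[bi]
        tgt <- ifelse(b$strand[bi] == "+",
                      b$target_start[bi] + off,
                      b$target_start[bi] - off)
        out$chrom[hit] <- b$target_chrom[bi]
        out$pos[hit] <- as.integer(tgt)
        out$mapped[hit] <- TRUE
    }
    out
}

#' Minimal representation of variant alleles
#'
#' Trims the shared allele suffix, then the shared prefix (always keeping at
#' least one base on each side), adjusting the position for trimmed prefix
#' bases. Symbolic (non-ACGT) encodings are preserved verbatim. Applied
#' before merging so that dialect differences in indel padding do not cause
#' spurious non-merges.
#'
#' @param pos,ref,alt parallel vectors describing variants.
#' @return data.frame with normalized `pos`, `ref`, `alt`.
#' @export
normalizeVariantAlleles <- function(pos, ref, alt) {
    n <- length(pos)
    for (i in seq_len(n)) {
        r <- ref[i]; a <- alt[i]
        if (is.na(r) || is.na(a) ||
            !grepl("^[ACGT]+$", r) || !grepl("^[ACGT]+$", a)) next
        rs <- strsplit(r, "")[[1L]]; as_ <- strsplit(a, "")[[1L]]
        # suffix
        while (length(rs) > 1L && length(as_) > 1L &&
               rs[length(rs)] == as_[length(as_)]) {
            rs <- rs[-length(rs)]; as_ <- as_[-length(as_)]
        }
        # prefix
        while (length(rs) > 1L && length(as_) > 1L && rs[1L] == as_[1L]) {
            rs <- rs[-1L]; as_ <- as_[-1L]; pos[i] <- pos[i] + 1L
        }
        ref[i] <- paste(rs, collapse = ""); alt[i] <- paste(as_, collapse = "")
    }
    data.frame(pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Merge variant tables from heterogeneous sources at the genomic level
#'
#' Merges records on GRCh38 `(chrom, pos, ref, alt)` keys after allele
#' normalization. GRCh38-build tables merge directly. For hg19-build tables,
#' rows whose hg19 coordinates exactly match the recorded hg19 coordinates of
#' an already-merged record merge directly (`hg19_exact`); remaining rows are
#' lifted through `chainMap` and then merged (`hg19_lifted`); unmapped
#' positions are reported in the removed table, never silently dropped.
#' Duplicate rows within one source collapse with counts. Records at the
#' same position with disagreeing reference alleles are both kept and
#' flagged as `allele_conflict`.
#'
#' The merge is idempotent and invariant to source-table order (up to row
#' ordering, which is canonical by position).
#'
#' @param tables list of [SourceVariantTable-class].
#' @param chainMap optional [ChainMap-class] for hg19 -> GRCh38 conversion;
#'   required if any hg19 table lacks recorded GRCh38 matches.
#' @return a [HarmonizedVariantTable-class].
#' @export
mergeGenomic <- function(tables, chainMap = NULL) {
    if (is(tables, "SourceVariantTable")) tables <- list(tables)
    rows <- do.call(rbind, lapply(tables, function(tb) {
        v <- variants(tb)
        if (!nrow(v)) return(NULL)
        v$source <- tb@sourceName
        v$build <- tb@build
        v
    }))
    removed <- data.frame(source = character(0), chrom = character(0),
                          pos = integer(0), ref = character(0),
                          alt = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
    if (is.null(rows) || !nrow(rows))
        return(new("HarmonizedVariantTable",
                   variants = .emptyHarmonized(), provenance = removed,
                   removed = removed, conflicts = .emptyConflicts()))
    norm <- normalizeVariantAlleles(rows$pos, rows$ref, rows$alt)
    rows$pos <- norm$pos; rows$ref <- norm$ref; rows$alt <- norm$alt
    # canonical source order keeps the output independent of input order
    rows <- rows[order(match(rows$source, .SOURCE_NAMES), rows$chrom,
                       rows$pos, rows$ref, rows$alt), , drop = FALSE]

    g38 <- rows[rows$build == "GRCh38", , drop = FALSE]
    h19 <- rows[rows$build == "hg19", , drop = FALSE]
    g38$key <- if (nrow(g38)) paste(g38$chrom, g38$pos, g38$ref, g38$alt,
                                    sep = ":") else character(0)
    g38$merge_path <- rep("grch38", nrow(g38))

    # hg19 keys of already-merged records (sources reporting both builds)
    hg19key <- function(df) ifelse(is.na(df$pos_hg19), NA_character_,
                                   paste(df$chrom, df$pos_hg19, df$ref,
                                         df$alt, sep = ":"))
    known19 <- unique(stats::na.omit(data.frame(
        k19 = hg19key(g38), key = g38$key, stringsAsFactors = FALSE)))

    if (nrow(h19)) {
        k19 <- paste(h19$chrom, h19$pos, h19$ref, h19$alt, sep = ":")
        idx <- match(k19, known19$k19)
        exact <- !is.na(idx)
        h19$key <- NA_character_
        h19$merge_path <- NA_character_
        h19$key[exact] <- known19$key[idx[exact]]
        h19$merge_path[exact] <- "hg19_exact"
        h19$pos_hg19[exact] <- h19$pos[exact]
        if (any(!exact)) {
            if (is.null(chainMap))
                stop("hg19 rows present but no chainMap supplied")
            lift <- liftoverPositions(h19$chrom[!exact], h19$pos[!exact],
                                      chainMap)
            drop <- !lift$mapped
            sub <- which(!exact)
            if (any(drop)) {
                dd <- h19[sub[drop], c("source", "chrom", "pos", "ref", "alt")]
                dd$reason <- "liftover_unmapped"
                removed <- rbind(removed, dd)
            }
            keep <- sub[!drop]
            h19$pos_hg19[keep] <- h19$pos[keep]
            h19$chrom[keep] <- lift$chrom[!drop]
            h19$pos[keep] <- lift$pos[!drop]
            h19$key[keep] <- paste(h19$chrom[keep], h19$pos[keep],
                                   h19$ref[keep], h19$alt[keep], sep = ":")
            h19$merge_path[keep] <- "hg19_lifted"
            h19 <- h19[!is.na(h19$key), , drop = FALSE]
        }
    }
    all_rows <- rbind(g38, h19)

    # provenance: collapse duplicates within (key, source) with counts
    prov_key <- paste(all_rows$key, all_rows$source, sep = "\r")
    prov <- all_rows[!duplicated(prov_key), , drop = FALSE]
    prov$n_records <- as.integer(table(prov_key)[
        paste(prov$key, prov$source, sep = "\r")])
    provenance <- data.frame(
        key = prov$key, source = prov$source,
        pathogenicity = prov$pathogenicity, rsid = prov$rsid,
        sample_id = prov$sample_id, cancer_type = prov$cancer_type,
        protein_change = prov$protein_change, isoform = prov$isoform,
        merge_path = prov$merge_path, n_records = prov$n_records,
        stringsAsFactors = FALSE)

    # unique variants
    u <- all_rows[!duplicated(all_rows$key), , drop = FALSE]
    agg <- function(vals) {
        sp <- split(vals, all_rows$key)
        vapply(sp[u$key], function(x) {
            x <- unique(stats::na.omit(x))
            x <- x[nzchar(x)]
            if (!length(x)) NA_character_ else x[1L]
        }, "")
    }
    af <- vapply(split(all_rows$allele_frequency, all_rows$key)[u$key],
                 function(x) {
                     x <- stats::na.omit(x)
                     if (!length(x)) NA_real_ else max(x)
                 }, 0)
    rsids <- split(all_rows$rsid, all_rows$key)[u$key]
    rsid1 <- vapply(rsids, function(x) {
        x <- unique(stats::na.omit(x[nzchar(ifelse(is.na(x), "", x))]))
        if (!length(x)) NA_character_ else x[1L]
    }, "")
    rsid_conf <- vapply(rsids, function(x) {
        length(unique(stats::na.omit(x[nzchar(ifelse(is.na(x), "", x))]))) > 1L
    }, TRUE)
    srcs <- vapply(split(all_rows$source, all_rows$key)[u$key],
                   function(x) paste(sort(unique(x)), collapse = ","), "")
    vout <- data.frame(
        key = u$key, chrom = u$chrom, pos = u$pos, ref = u$ref, alt = u$alt,
        pos_hg19 = u$pos_hg19,
        rsid = rsid1, rsid_conflict = rsid_conf,
        allele_frequency = af,
        frequency_class = classifyFrequency(af),
        protein_change = agg(all_rows$protein_change),
        isoform = agg(all_rows$isoform),
        sources = srcs,
        n_sources = lengths(lapply(strsplit(srcs, ","), unique)),
        stringsAsFactors = FALSE)
    vout <- vout[order(vout$chrom, vout$pos, vout$ref, vout$alt), ,
                 drop = FALSE]
    rownames(vout) <- NULL

    # allele conflicts: same (chrom,pos) with different ref alleles
    confl <- .emptyConflicts()
    posk <- paste(vout$chrom, vout$pos)
    for (pk in unique(posk[duplicated(posk)])) {
        grp <- vout[posk == pk, , drop = FALSE]
        if (length(unique(grp$ref)) > 1L)
            confl <- rbind(confl, data.frame(
                kind = "allele_conflict", key = grp$key,
                detail = paste("ref alleles:",
                               paste(unique(grp$ref), collapse = "/")),
                stringsAsFactors = FALSE))
    }
    new("HarmonizedVariantTable", variants = vout, provenance = provenance,
        removed = removed, conflicts = confl)
}

.emptyHarmonized <- function()
    data.frame(key = character(0), chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               pos_hg19 = integer(0), rsid = character(0),
               rsid_conflict = logical(0), allele_frequency = numeric(0),
               frequency_class = character(0), protein_change = character(0),
               isoform = character(0), sources = character(0),
               n_sources = integer(0), stringsAsFactors = FALSE)

.emptyConflicts <- function()
    data.frame(kind = character(0), key = character(0),
               detail = character(0), stringsAsFactors = FALSE)

#' Filter variants to the gene region
#'
#' Keeps rows on the gene chromosome within
#' `[geneStart - flank, geneEnd + flank]` (boundaries inclusive); everything
#' else goes to the removed table with a reason, so
#' `nrow(in) == nrow(kept) + nrow(removed)`.
#'
#' @param x a [HarmonizedVariantTable-class] or a data.frame with `chrom`
#'   and `pos`.
#' @param geneModel a [GeneModel-class].
#' @return for a harmonized table, a filtered [HarmonizedVariantTable-class]
#'   whose removed table is extended; for a data.frame, a list
#'   `list(kept, removed)`.
#' @export
filterGeneRegion <- function(x, geneModel) {
    lo <- geneModel@geneStart - geneModel@flank
    hi <- geneModel@geneEnd + geneModel@flank
    df <- if (is(x, "HarmonizedVariantTable")) variants(x) else x
    keep <- df$chrom == geneModel@chrom & df$pos >= lo & df$pos <= hi
    keep[is.na(keep)] <- FALSE
    reason <- ifelse(df$chrom != geneModel@chrom, "off_chromosome",
                     "outside_gene_region")[!keep]
    rem <- df[!keep, , drop = FALSE]
    if (nrow(rem)) rem$reason <- reason
    if (is(x, "HarmonizedVariantTable")) {
        rcols <- c("chrom", "pos", "ref", "alt", "reason")
        rem2 <- if (nrow(rem)) {
            rr <- rem[, intersect(rcols, names(rem)), drop = FALSE]
            rr$source <- "merged"
            rr[, c("source", setdiff(names(rr), "source"))]
        } else x@removed[0, , drop = FALSE]
        x@variants <- df[keep, , drop = FALSE]
        x@provenance <- x@provenance[x@provenance$key %in% x@variants$key, ,
                                     drop = FALSE]
        if (nrow(rem2)) {
            common <- union(names(x@removed), names(rem2))
            for (cc in setdiff(common, names(x@removed)))
                if (nrow(x@removed)) x@removed[[cc]] <- NA else
                    x@removed[[cc]] <- character(0)
            for (cc in setdiff(common, names(rem2))) rem2[[cc]] <- NA
            x@removed <- rbind(x@removed[, common, drop = FALSE],
                               rem2[, common, drop = FALSE])
        }
        return(x)
    }
    list(kept = df[keep, , drop = FALSE], removed = rem)
}

#' Isoform membership of genomic positions
#'
#' Returns, for each position, the set of isoforms whose CDS contains it,
#' plus `upstream` / `downstream` labels relative to the canonical b-isoform
#' CDS for positions in the gene region but outside the b CDS.
#'
#' @param pos integer vector of 1-based positions (gene chromosome assumed).
#' @param geneModel a [GeneModel-class].
#' @return character vector of comma-joined membership sets.
#' @export
annotateIsoforms <- function(pos, geneModel) {
    b <- geneModel@cds[["b"]]
    vapply(pos, function(p) {
        mem <- character(0)
        for (iso in names(geneModel@cds)) {
            cc <- geneModel@cds[[iso]]
            if (!is.na(p) && p >= cc[1L] && p <= cc[2L]) mem <- c(mem, iso)
        }
        if (!is.na(p) && p < b[1L]) mem <- c(mem, "upstream")
        if (!is.na(p) && p > b[2L]) mem <- c(mem, "downstream")
        paste(mem, collapse = ",")
    }, "")
}

#' Convert a protein position between isoform frames
#'
#' Isoform a has 55 extra N-terminal residues relative to b; isoform b has
#' 10 extra residues relative to c. Positions outside the target isoform
#' return `NA`.
#'
#' @param pos integer vector of protein positions in the source frame.
#' @param from,to isoform letters (`"a"`, `"b"`, `"c"`).
#' @param geneModel a [GeneModel-class] supplying isoform protein lengths.
#' @return integer vector of positions in the target frame (NA when outside).
#' @examples
#' convertIsoformPosition(1, "b", "a")   # 56
#' convertIsoformPosition(177, "b", "c") # 167
#' @export
convertIsoformPosition <- function(pos, from, to,
                                   geneModel = readGeneModel()) {
    offs <- c(a = -55L, b = 0L, c = 10L)   # position in b frame = pos + offs
    stopifnot(from %in% names(offs), to %in% names(offs))
    bpos <- pos + offs[[from]]
    out <- bpos - offs[[to]]
    lens <- geneModel@proteinLengths
    maxlen <- if (to %in% names(lens) && !is.na(lens[[to]])) lens[[to]] else Inf
    out[out < 1L | out > maxlen] <- NA_integer_
    as.integer(out)
}

#' Group harmonized variants by protein consequence
#'
#' All DNA variants resulting in the same protein change (normalized to the
#' b-isoform frame) are grouped. Unparseable protein-change strings are
#' quarantined to a report; protein positions inconsistent with the codon
#' interval implied by the CDS are flagged (`frame_mismatch`), not dropped.
#'
#' @param hvt a [HarmonizedVariantTable-class].
#' @param geneModel a [GeneModel-class].
#' @return list with `groups` (one row per protein change: `isoform`,
#'   `position`, `ref_aa`, `alt_aa`, `kind`, `label`, `n_members`,
#'   `members`, `synonymous`, `frame_mismatch`, `disease_context`) and
#'   `quarantined` (variant keys with raw strings).
#' @export
groupByProtein <- function(hvt, geneModel = readGeneModel()) {
    v <- variants(hvt)
    pc <- parseProteinChange(v$protein_change)
    has <- !is.na(v$protein_change) & nzchar(ifelse(is.na(v$protein_change),
                                                    "", v$protein_change))
    quarantined <- data.frame(key = v$key[has & is.na(pc$position)],
                              protein_change = v$protein_change[
                                  has & is.na(pc$position)],
                              stringsAsFactors = FALSE)
    ok <- has & !is.na(pc$position)
    if (!any(ok))
        return(list(groups = data.frame(), quarantined = quarantined))
    iso <- ifelse(is.na(v$isoform) | !v$isoform %in% c("a", "b", "c"),
                  "b", v$isoform)[ok]
    bpos <- mapply(function(p, f) convertIsoformPosition(p, f, "b", geneModel),
                   pc$position[ok], iso)
    label <- ifelse(is.na(bpos),
                    paste0(iso, ":", pc$ref_aa[ok], pc$position[ok],
                           pc$alt_aa[ok]),
                    paste0("b:", pc$ref_aa[ok], bpos, pc$alt_aa[ok]))
    # frame check: genomic position must fall in the codon implied by the
    # b-frame protein position (single-exon gene, + strand)
    cdsb <- geneModel@cds[["b"]]
    lo <- cdsb[1L] + 3L * (bpos - 1L)
    hi <- lo + 2L
    frame_ok <- !is.na(bpos) & !is.na(v$pos[ok]) &
        v$pos[ok] >= lo & v$pos[ok] <= hi
    # frameshift/stop groups and non-b-frame labels skip the codon check
    frame_check_applies <- pc$kind[ok] %in% c("missense", "synonymous") &
        !is.na(bpos)
    mismatch <- frame_check_applies & !frame_ok

    prov <- provenance(hvt)
    ctx_for <- function(keys) {
        srcs <- unique(prov$source[prov$key %in% keys])
        ctx <- character(0)
        if (any(srcs %in% c("cosmic", "tcga"))) ctx <- c(ctx, "cancer")
        if (any(srcs %in% c("clinvar", "lovd", "decipher")))
            ctx <- c(ctx, "autoimmune")
        if ("gnomad" %in% srcs) ctx <- c(ctx, "population")
        paste(ctx, collapse = ",")
    }
    keys <- v$key[ok]
    sp <- split(seq_along(label), label)
    groups <- do.call(rbind, lapply(names(sp), function(lb) {
        ii <- sp[[lb]]
        data.frame(label = lb,
                   isoform = sub(":.*", "", lb),
                   position = if (!is.na(bpos[ii[1L]])) bpos[ii[1L]] else
                       pc$position[ok][ii[1L]],
                   ref_aa = pc$ref_aa[ok][ii[1L]],
                   alt_aa = pc$alt_aa[ok][ii[1L]],
                   kind = pc$kind[ok][ii[1L]],
                   synonymous = pc$kind[ok][ii[1L]] == "synonymous",
                   n_members = length(ii),
                   members = paste(keys[ii], collapse = ";"),
                   frame_mismatch = any(mismatch[ii]),
                   disease_context = ctx_for(keys[ii]),
                   stringsAsFactors = FALSE)
    }))
    groups <- groups[order(groups$position, groups$alt_aa), , drop = FALSE]
    rownames(groups) <- NULL
    list(groups = groups, quarantined = quarantined)
}

#' rsID concordance check across merged sources
#'
#' Reports both conflict directions: one merged variant carrying two or more
#' distinct rsIDs across sources, and one rsID attached to two or more
#' distinct variants. Conflicts never block merging; they are returned as a
#' machine-readable report.
#'
#' @param hvt a [HarmonizedVariantTable-class].
#' @return data.frame with columns `kind` (`multi_rsid` / `duplicate_rsid`),
#'   `key` and `detail`.
#' @export
checkRsidConcordance <- function(hvt) {
    prov <- provenance(hvt)
    prov <- prov[!is.na(prov$rsid) & nzchar(prov$rsid), , drop = FALSE]
    out <- .emptyConflicts()
    if (!nrow(prov)) return(out)
    by_key <- split(prov$rsid, prov$key)
    for (k in names(by_key)) {
        u <- unique(by_key[[k]])
        if (length(u) > 1L)
            out <- rbind(out, data.frame(
                kind = "multi_rsid", key = k,
                detail = paste(sort(u), collapse = ","),
                stringsAsFactors = FALSE))
    }
    by_rs <- split(prov$key, prov$rsid)
    for (rs in names(by_rs)) {
        u <- unique(by_rs[[rs]])
        if (length(u) > 1L)
            out <- rbind(out, data.frame(
                kind = "duplicate_rsid", key = rs,
                detail = paste(sort(u), collapse = ","),
                stringsAsFactors = FALSE))
    }
    rownames(out) <- NULL
    out
}

#' Pairwise Pearson correlations between model score columns
#'
#' Pairwise-complete Pearson correlation matrix over the numeric score
#' columns of a model-score table (see [readModelScores()]). Pairs with
#' fewer than 3 complete rows, or with a zero-variance column, yield `NA`
#' and are flagged.
#'
#' @param scores data.frame with a `variant` column and numeric score columns.
#' @return a symmetric correlation matrix with unit diagonal; attribute
#'   `"flagged"` lists undefined pairs.
#' @examples
#' s <- data.frame(variant = letters[1:5], x = 1:5, y = 2 * (1:5) + 1)
#' correlateModelScores(s)
#' @export
correlateModelScores <- function(scores) {
    num <- scores[vapply(scores, is.numeric, TRUE)]
    if (ncol(num) < 2L) stop("need >= 2 numeric score columns")
    k <- ncol(num)
    r <- diag(1, k)
    dimnames(r) <- list(names(num), names(num))
    flagged <- character(0)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        xy <- stats::complete.cases(num[[i]], num[[j]])
        if (sum(xy) < 3L || stats::sd(num[[i]][xy]) == 0 ||
            stats::sd(num[[j]][xy]) == 0) {
            r[i, j] <- r[j, i] <- NA_real_
            flagged <- c(flagged, paste(names(num)[i], names(num)[j],
                                        sep = ":"))
        } else {
            r[i, j] <- r[j, i] <- stats::cor(num[[i]][xy], num[[j]][xy])
        }
    }
    attr(r, "flagged") <- flagged
    r
}
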