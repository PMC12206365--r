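# Shared fixtures built in code.

# simple +100000 offset chain map covering the gene region (hg19 -> GRCh38)
fixtureChainMap <- function() {
    new("ChainMap", blocks = data.frame(
        source_chrom = "chr3", source_start = 48300000L,
        source_end = 48600000L, target_chrom = "chr3",
        target_start = 48400000L, strand = "+",
        stringsAsFactors = FALSE))
}

fixtureGeneModel <- function() readGeneModel()

# wrap a plain variant data.frame as a generic SourceVariantTable
asSourceTable <- function(df, source = "generic", build = "GRCh38") {
    base <- data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref,
                       alt = df$alt, stringsAsFactors = FALSE)
    for (f in c("protein_change", "isoform", "rsid", "pathogenicity",
                "sample_id", "cancer_type")) {
        base[[f]] <- if (f %in% names(df)) df[[f]] else NA_character_
    }
    base$allele_frequency <- if ("allele_frequency" %in% names(df))
        df$allele_frequency else NA_real_
    base$pos_hg19 <- if ("pos_hg19" %in% names(df)) df$pos_hg19 else
        NA_integer_
    base$protein_change_unparsed <- FALSE
    new("SourceVariantTable", sourceName = source, build = build,
        variants = base)
}

# independent brute-force log-rank (O-E / hypergeometric V at event times)
bruteLogrank <- function(time, event, group) {
    g1 <- levels(factor(group))[1L]
    ts <- sort(unique(time[event]))
    OE <- 0; V <- 0
    for (t in ts) {
        at_risk <- time >= t
        n <- sum(at_risk)
        n1 <- sum(at_risk & group == g1)
        d <- sum(event & time == t)
        d1 <- sum(event & time == t & group == g1)
        OE <- OE + d1 - d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (OE^2) / V
}

# independent brute-force product-limit estimator at given times
bruteKM <- function(time, event, at) {
    vapply(at, function(t0) {
        s <- 1
        for (t in sort(unique(time[event & time <= t0]))) {
            n <- sum(time >= t)
            d <- sum(event & time == t)
            s <- s * (1 - d / n)
        }
        s
    }, 0)
}

# independent enumeration oracle for perfect (mismatch-free) inverted
# repeats: a triple (start, stem, loop) is a maximal hit iff all stem pairs
# are complementary and extending outward by one is impossible
enumInvertedRepeats <- function(seq, minStem, maxLoop, rna = FALSE) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "?")
    pair <- function(x, y) {
        if (x == "N" || y == "N") return(FALSE)
        ok <- comp[[x]] == y || (x == "A" && y == "U") ||
            (x == "T" && y == "A") || (x == "U" && y == "A")
        ok || (rna && ((x == "G" && y == "U") || (x == "U" && y == "G")))
    }
    chars <- strsplit(toupper(seq), "")[[1]]
    n <- length(chars)
    hits <- list()
    for (start in 1:n) for (stem in minStem:n) for (loop in 0:maxLoop) {
        l <- start + stem - 1L
        r <- l + loop + 1L
        end <- r + stem - 1L
        if (end > n) next
        ok <- all(vapply(1:stem, function(k)
            pair(chars[l - k + 1L], chars[r + k - 1L]), TRUE))
        if (!ok) next
        extensible <- start > 1L && end < n &&
            pair(chars[start - 1L], chars[end + 1L])
        if (extensible) next
        hits[[length(hits) + 1L]] <-
            c(start = start, stem = stem, loop = loop)
    }
    if (!length(hits)) return(character(0))
    sort(unique(vapply(hits, paste, "", collapse = ":")))
}


# exhaustive enumeration of all non-crossing pairings for small n
enumMaxPairs <- function(seq, minLoop = 3L, rna = FALSE) {
    chars <- strsplit(toupper(seq), "")[[1]]
    n <- length(chars)
    pairable <- function(i, j) {
        x <- chars[i]; y <- chars[j]
        if (x == "N" || y == "N") return(FALSE)
        wc <- paste0(sort(c(x, y)), collapse = "") %in%
            c("AT", "CG", "AU", "GU"[rna])
        wc && j - i - 1L >= minLoop
    }
    best <- 0L
    recurse <- function(pos, pairs) {
        if (pos > n) {
            best <<- max(best, nrow(pairs))
            return(invisible())
        }
        if (nrow(pairs) && any(pairs[, 1] == pos | pairs[, 2] == pos)) {
            recurse(pos + 1L, pairs)
            return(invisible())
        }
        recurse(pos + 1L, pairs)          # pos unpaired
        for (q in seq_len(n)[-seq_len(pos)]) {
            if (!pairable(pos, q)) next
            if (nrow(pairs) &&
                any((pairs[, 1] < pos & pairs[, 2] > pos &
                     pairs[, 2] < q) |
                    (pairs[, 1] > pos & pairs[, 1] < q &
                     pairs[, 2] > q))) next
            if (nrow(pairs) && any(pairs[, 1] == q | pairs[, 2] == q)) next
            recurse(pos + 1L, rbind(pairs, c(pos, q)))
        }
    }
    recurse(1L, matrix(integer(0), ncol = 2))
    best
}

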