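test_that("protein change strings parse across HGVS-p spellings", {
    pc <- parseProteinChange(c("E266G", "p.Glu266Gly", "p.(R114H)",
                               "C99fs", "C99Mfs*3", "R164*", "Y177=",
                               "c.290G>A", NA))
    expect_equal(pc$position, c(266L, 266L, 114L, 99L, 99L, 164L, 177L,
                                NA, NA))
    expect_identical(pc$kind[1:7],
                     c("missense", "missense", "missense", "frameshift",
                       "frameshift", "stop", "synonymous"))
    expect_identical(pc$alt_aa[4], "fs")
})

test_that("frequency classification is a strict threshold and monotone", {
    expect_identical(classifyFrequency(0.00174), "Elevated")
    expect_identical(classifyFrequency(0.0011), "Low")   # does not exceed
    expect_true(is.na(classifyFrequency(NA)))
    expect_error(classifyFrequency(1.2), "\\[0,1\\]")
    # monotone in af: once Elevated, always Elevated on a sorted grid
    af <- sort(runif(50))
    cl <- classifyFrequency(af)
    first_elev <- match("Elevated", cl)
    if (!is.na(first_elev))
        expect_true(all(cl[first_elev:length(cl)] == "Elevated"))
})

test_that("liftover maps through blocks and reports misses", {
    # identity map leaves positions unchanged
    ident <- new("ChainMap", blocks = data.frame(
        source_chrom = "chr3", source_start = 1L, source_end = 10000000L,
        target_chrom = "chr3", target_start = 1L, strand = "+"))
    expect_equal(liftoverPositions("chr3", 1234L, ident)$pos, 1234L)

    # block chr3:1000-2000 -> 1100: pos 1500 -> 1600
    cm <- new("ChainMap", blocks = data.frame(
        source_chrom = "chr3", source_start = 1000L, source_end = 2000L,
        target_chrom = "chr3", target_start = 1100L, strand = "+"))
    out <- liftoverPositions(c("chr3", "chr3", "chrX"),
                             c(1500L, 999L, 1500L), cm)
    expect_equal(out$pos[1], 1600L)
    expect_false(out$mapped[2])   # outside block: an explicit miss
    expect_false(out$mapped[3])   # wrong chromosome

    # minus-strand block
    cmm <- new("ChainMap", blocks = data.frame(
        source_chrom = "chr1", source_start = 100L, source_end = 200L,
        target_chrom = "chr1", target_start = 5000L, strand = "-"))
    expect_equal(liftoverPositions("chr1", 110L, cmm)$pos, 4990L)
})

test_that("liftover agrees with an exhaustive block scan", {
    set.seed(12)
    nb <- 15L
    starts <- sort(sample(seq(1, 1e6, by = 2000), nb))
    b <- data.frame(source_chrom = "chr3", source_start = starts,
                    source_end = starts + sample(200:1500, nb, TRUE),
                    target_chrom = "chr3",
                    target_start = sample.int(2e6, nb),
                    strand = sample(c("+", "-"), nb, TRUE),
                    stringsAsFactors = FALSE)
    cm <- new("ChainMap", blocks = b)
    pos <- sample.int(1.1e6, 10000L)
    lift <- liftoverPositions(rep("chr3", length(pos)), pos, cm)
    for (i in sample(length(pos), 500)) {   # spot-check a dense subset
        hit <- which(b$source_start <= pos[i] & b$source_end >= pos[i])
        if (!length(hit)) {
            expect_false(lift$mapped[i])
        } else {
            off <- pos[i] - b$source_start[hit]
            want <- if (b$strand[hit] == "+") b$target_start[hit] + off
                    else b$target_start[hit] - off
            expect_equal(lift$pos[i], want)
        }
    }
})

test_that("identical variants in two sources merge to one record", {
    df <- data.frame(chrom = "chr3", pos = 48466700L, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
    h <- mergeGenomic(list(asSourceTable(df, "clinvar"),
                           asSourceTable(df, "cosmic")))
    expect_equal(nrow(variants(h)), 1L)
    expect_equal(variants(h)$n_sources, 2L)
    expect_equal(nrow(provenance(h)), 2L)
})

test_that("indel padding differences do not block merging", {
    a <- data.frame(chrom = "chr3", pos = 48466700L, ref = "CA", alt = "CG",
                    stringsAsFactors = FALSE)
    b <- data.frame(chrom = "chr3", pos = 48466701L, ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
    h <- mergeGenomic(list(asSourceTable(a, "clinvar"),
                           asSourceTable(b, "cosmic")))
    expect_equal(nrow(variants(h)), 1L)
    expect_equal(variants(h)$pos, 48466701L)
})

test_that("hg19 rows merge by exact match first, then liftover", {
    cm <- fixtureChainMap()
    # GRCh38 record that also records its hg19 position
    g38 <- data.frame(chrom = "chr3", pos = 48466700L, ref = "A",
                      alt = "G", pos_hg19 = 48366700L,
                      stringsAsFactors = FALSE)
    # one hg19 row exact-matching it, one hg19 row needing liftover
    h19 <- data.frame(chrom = "chr3", pos = c(48366700L, 48366800L),
                      ref = c("A", "C"), alt = c("G", "T"),
                      stringsAsFactors = FALSE)
    h <- mergeGenomic(list(asSourceTable(g38, "clinvar"),
                           asSourceTable(h19, "tcga", build = "hg19")), cm)
    v <- variants(h)
    expect_equal(nrow(v), 2L)
    prov <- provenance(h)
    paths <- prov$merge_path[prov$source == "tcga"]
    expect_setequal(paths, c("hg19_exact", "hg19_lifted"))
    expect_true(48466800L %in% v$pos)   # lifted +100000
    # the exact-matched row merged rather than duplicated
    expect_equal(v$n_sources[v$pos == 48466700L], 2L)

    # unmapped hg19 position is reported, not dropped
    far <- data.frame(chrom = "chr3", pos = 1000L, ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
    h2 <- mergeGenomic(list(asSourceTable(far, "tcga", build = "hg19")), cm)
    expect_equal(nrow(variants(h2)), 0L)
    expect_identical(removedRows(h2)$reason, "liftover_unmapped")
})

test_that("generator truth is recovered: counts, partition, conflicts", {
    cm <- fixtureChainMap()
    g <- genVariantSources(60, nSources = 4, hg19Fraction = 0.25,
                           duplicateRate = 0.35, rsidConflictRate = 0.1,
                           chainMap = cm, seed = 13)
    h <- mergeGenomic(g$tables, cm)
    expect_equal(nrow(variants(h)), g$truth$n_unique)

    # planted rsID conflicts recovered exactly
    rc <- checkRsidConcordance(h)
    expect_equal(sum(rc$kind == "multi_rsid"), g$truth$n_rsid_conflicts)

    # planted protein partition recovered exactly
    gp <- groupByProtein(h, fixtureGeneModel())
    impl <- lapply(split(strsplit(gp$groups$members, ";"),
                         gp$groups$label), function(x) sort(unlist(x)))
    tru <- lapply(g$truth$protein_partition, sort)
    names(tru) <- paste0("b:", sub("^p\\.", "", names(tru)))
    expect_identical(impl[sort(names(impl))], tru[sort(names(impl))])
    expect_false(any(gp$groups$frame_mismatch))

    # duplicate_rate = 0 with one source: output count == planted count
    g0 <- genVariantSources(25, nSources = 1, duplicateRate = 0, seed = 3)
    expect_equal(nrow(variants(mergeGenomic(g0$tables))), 25L)
})

test_that("merging is idempotent and order-invariant", {
    cm <- fixtureChainMap()
    g <- genVariantSources(30, nSources = 3, hg19Fraction = 1 / 3,
                           duplicateRate = 0.4, chainMap = cm, seed = 21)
    h <- mergeGenomic(g$tables, cm)
    h_rev <- mergeGenomic(rev(g$tables), cm)
    expect_identical(variants(h_rev)$key, variants(h)$key)
    expect_identical(variants(h_rev)$sources, variants(h)$sources)
    # re-harmonizing the harmonized variants is a no-op on keys
    again <- mergeGenomic(asSourceTable(variants(h)))
    expect_identical(variants(again)$key, variants(h)$key)
})

test_that("allele conflicts at one position are kept and flagged", {
    a <- data.frame(chrom = "chr3", pos = 48466700L, ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
    b <- data.frame(chrom = "chr3", pos = 48466700L, ref = "C", alt = "G",
                    stringsAsFactors = FALSE)
    h <- mergeGenomic(list(asSourceTable(a, "clinvar"),
                           asSourceTable(b, "cosmic")))
    expect_equal(nrow(variants(h)), 2L)
    expect_true(any(conflicts(h)$kind == "allele_conflict"))
})

test_that("degenerate codon variants group to one protein change", {
    gm <- fixtureGeneModel()
    cdsb <- gm@cds[["b"]]
    codon266 <- cdsb[1] + 3L * 265L   # first base of codon 266
    df <- data.frame(chrom = "chr3", pos = c(codon266 + 1L, codon266 + 2L),
                     ref = c("A", "G"), alt = c("G", "A"),
                     protein_change = "p.E266G", isoform = "b",
                     stringsAsFactors = FALSE)
    h <- mergeGenomic(asSourceTable(df, "clinvar"))
    gp <- groupByProtein(h, gm)
    expect_equal(nrow(gp$groups), 1L)
    expect_equal(gp$groups$n_members, 2L)
    expect_false(gp$groups$frame_mismatch)

    # synonymous change flagged; frame mismatch detected for wrong codon
    df2 <- data.frame(chrom = "chr3", pos = codon266 + 2L, ref = "A",
                      alt = "G", protein_change = "p.Y177=", isoform = "b",
                      stringsAsFactors = FALSE)
    gp2 <- groupByProtein(mergeGenomic(asSourceTable(df2)), gm)
    expect_true(gp2$groups$synonymous)
    expect_true(gp2$groups$frame_mismatch)

    # unparseable strings are quarantined, not silently lost
    df3 <- data.frame(chrom = "chr3", pos = codon266, ref = "A", alt = "G",
                      protein_change = "oddball", stringsAsFactors = FALSE)
    gp3 <- groupByProtein(mergeGenomic(asSourceTable(df3)), gm)
    expect_equal(nrow(gp3$quarantined), 1L)
})

test_that("gene-region filtering partitions rows with reasons", {
    gm <- fixtureGeneModel()
    df <- data.frame(chrom = c("chr3", "chrX", "chr3", "chr3"),
                     pos = c(gm@geneStart, 500000L,
                             gm@geneStart - gm@flank - 1L,
                             gm@geneEnd + gm@flank),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
    out <- filterGeneRegion(df, gm)
    expect_equal(nrow(out$kept) + nrow(out$removed), nrow(df))
    expect_equal(out$kept$pos, c(gm@geneStart, gm@geneEnd + gm@flank))
    expect_setequal(out$removed$reason,
                    c("off_chromosome", "outside_gene_region"))

    # random rows against a brute-force interval test
    set.seed(31)
    rnd <- data.frame(chrom = sample(c("chr3", "chr7"), 200, TRUE),
                      pos = sample(seq(gm@geneStart - 5000L,
                                       gm@geneEnd + 5000L), 200),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
    out2 <- filterGeneRegion(rnd, gm)
    brute <- rnd$chrom == "chr3" &
        rnd$pos >= gm@geneStart - gm@flank &
        rnd$pos <= gm@geneEnd + gm@flank
    expect_equal(nrow(out2$kept), sum(brute))

    # harmonized-table flavor keeps the row ledger exact
    h <- mergeGenomic(asSourceTable(df))
    h2 <- filterGeneRegion(h, gm)
    expect_equal(nrow(variants(h2)) +
                 sum(removedRows(h2)$reason != "liftover_unmapped"),
                 nrow(df))
})

test_that("isoform membership follows CDS nesting", {
    gm <- fixtureGeneModel()
    inside_c <- gm@cds[["c"]][1] + 5L
    expect_identical(annotateIsoforms(inside_c, gm), "a,b,c")
    between <- gm@cds[["a"]][1] + 5L   # in a, upstream of b
    expect_identical(annotateIsoforms(between, gm), "a,upstream")
    after <- gm@cds[["b"]][2] + 10L
    expect_identical(annotateIsoforms(after, gm), "downstream")
    # brute force on random positions
    set.seed(8)
    pos <- sample(seq(gm@geneStart, gm@geneEnd), 300)
    got <- annotateIsoforms(pos, gm)
    for (i in sample(300, 50)) {
        want <- character(0)
        for (iso in names(gm@cds)) {
            cc <- gm@cds[[iso]]
            if (pos[i] >= cc[1] && pos[i] <= cc[2]) want <- c(want, iso)
        }
        if (pos[i] < gm@cds[["b"]][1]) want <- c(want, "upstream")
        if (pos[i] > gm@cds[["b"]][2]) want <- c(want, "downstream")
        expect_identical(got[i], paste(want, collapse = ","))
    }
})

test_that("isoform position conversion uses the N-terminal offsets", {
    expect_equal(convertIsoformPosition(1, "b", "a"), 56L)
    expect_equal(convertIsoformPosition(177, "b", "c"), 167L)
    expect_true(is.na(convertIsoformPosition(5, "b", "c")))
    # compositions are consistent
    expect_equal(convertIsoformPosition(
        convertIsoformPosition(100, "b", "a"), "a", "b"), 100L)
    expect_equal(convertIsoformPosition(
        convertIsoformPosition(100, "b", "c"), "c", "b"), 100L)
    # beyond the target length (or before its start) -> NA
    expect_true(is.na(convertIsoformPosition(306, "c", "b")))  # b:316 > 314
    expect_true(is.na(convertIsoformPosition(20, "a", "b")))   # before b

})

test_that("rsID concordance reports both conflict directions", {
    df1 <- data.frame(chrom = "chr3", pos = 48466700L, ref = "A",
                      alt = "G", rsid = "rs1", stringsAsFactors = FALSE)
    df2 <- df1; df2$rsid <- "rs2"
    h <- mergeGenomic(list(asSourceTable(df1, "clinvar"),
                           asSourceTable(df2, "lovd")))
    rc <- checkRsidConcordance(h)
    expect_equal(sum(rc$kind == "multi_rsid"), 1L)

    # one rsID on two loci -> duplicate-rsid conflict
    df3 <- data.frame(chrom = "chr3", pos = c(48466700L, 48466800L),
                      ref = "A", alt = "G", rsid = "rs9",
                      stringsAsFactors = FALSE)
    rc2 <- checkRsidConcordance(mergeGenomic(asSourceTable(df3)))
    expect_equal(sum(rc2$kind == "duplicate_rsid"), 1L)

    # consistent rsIDs -> empty report
    h3 <- mergeGenomic(list(asSourceTable(df1, "clinvar"),
                            asSourceTable(df1, "lovd")))
    expect_equal(nrow(checkRsidConcordance(h3)), 0L)
})

test_that("model score correlations hit exact algebraic cases", {
    s <- data.frame(variant = paste0("v", 1:6), x = 1:6,
                    y = 2 * (1:6) + 1, z = -(1:6),
                    stringsAsFactors = FALSE)
    r <- correlateModelScores(s)
    expect_equal(unname(r["x", "y"]), 1)
    expect_equal(unname(r["x", "z"]), -1)
    expect_equal(unname(diag(r)), rep(1, 3))
    expect_true(isSymmetric(unclass(r)))

    # zero-variance column flagged as undefined
    s$w <- 5
    r2 <- correlateModelScores(s)
    expect_true(is.na(r2["x", "w"]))
    expect_true(any(grepl("w", attr(r2, "flagged"))))

    # pairwise-complete handling with missing cells
    s2 <- data.frame(variant = paste0("v", 1:6), x = 1:6,
                     y = c(2, 4, NA, 8, 10, 12))
    r3 <- correlateModelScores(s2)
    expect_equal(unname(r3["x", "y"]), 1)
})
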