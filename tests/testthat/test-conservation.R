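test_that("fully conserved columns score 11 with 100% support", {
    aln <- setNames(rep("D", 159), paste0("s", 1:159))
    m <- columnMetrics(aln)
    expect_equal(m$conservation, 11L)
    expect_equal(m$consensus_support, 100)
    expect_identical(m$consensus, "D")
    expect_equal(m$occupancy, 159L)
})

test_that("mixed columns report modal consensus and all-sequence support", {
    aln <- setNames(c(rep("Q", 6), rep("E", 4)), paste0("s", 1:10))
    m <- columnMetrics(aln)
    expect_identical(m$consensus, "Q")
    expect_equal(m$consensus_support, 60)
    expect_equal(m$occupancy, 10L)
    expect_lt(m$conservation, 11L)

    # support denominator includes gapped sequences: 67 R / 159 = 42.14%
    aln2 <- setNames(c(rep("R", 67), rep("-", 30), rep("K", 62)),
                     paste0("s", 1:159))
    m2 <- columnMetrics(aln2)
    expect_identical(m2$consensus, "R")
    expect_equal(round(m2$consensus_support, 2), 42.14)
    expect_equal(m2$occupancy, 129L)
})

test_that("consensus ties break alphabetically and are flagged", {
    aln <- setNames(c("Q", "E", "Q", "E"), paste0("s", 1:4))
    m <- columnMetrics(aln)
    expect_identical(m$consensus, "E")
    expect_true(m$consensus_tie)
})

test_that("all-gap columns yield gap consensus and zero scores", {
    aln <- setNames(c("-A", "-A", "-A"), paste0("s", 1:3))
    m <- columnMetrics(aln, 1L)
    expect_identical(m$consensus, "-")
    expect_equal(m$consensus_support, 0)
    expect_equal(m$occupancy, 0L)
    expect_equal(m$conservation, 0L)
})

test_that("conservation counts conserved property classes", {
    # D vs E: both negative/charged/polar; D also small -> not conserved.
    # conserved: negative, charged, polar (present in all) + absent-in-all
    # classes (tiny? D small+tiny? D is small & tiny? tiny={A,C,G,S}: no;
    # aliphatic, aromatic, positive, proline, hydrophobic absent in both)
    aln <- setNames(c("D", "E"), c("s1", "s2"))
    m <- columnMetrics(aln)
    # present-in-all: polar, negative, charged; absent-in-all: hydrophobic,
    # tiny, aliphatic, aromatic, positive, proline -> small differs -> 9
    expect_equal(m$conservation, 9L)

    # one gap drops all present-in-all properties, keeps absent-in-all
    aln2 <- setNames(c("D", "E", "-"), paste0("s", 1:3))
    m2 <- columnMetrics(aln2)
    expect_equal(m2$conservation, 6L)
})

test_that("conservation is permutation-invariant and duplication-safe", {
    set.seed(42)
    for (rep in 1:20) {
        col <- sample(c("A", "D", "K", "P", "W", "-"), 12, replace = TRUE)
        aln <- setNames(col, paste0("s", seq_along(col)))
        m1 <- columnMetrics(aln)
        perm <- sample(length(col))
        m2 <- columnMetrics(setNames(col[perm], names(aln)))
        expect_equal(m2$conservation, m1$conservation)
        expect_equal(m2$consensus_support, m1$consensus_support)
        # duplicating an existing sequence never changes conservation
        m3 <- columnMetrics(setNames(c(col, col[1]),
                                     paste0("s", seq_len(length(col) + 1))))
        expect_equal(m3$conservation, m1$conservation)
        # conservation 11 implies full support and occupancy
        if (m1$conservation == 11L) {
            expect_equal(m1$consensus_support, 100)
            expect_equal(m1$occupancy, length(col))
        }
    }
    # duplicating a consensus-carrying sequence never decreases support
    aln <- setNames(c("Q", "Q", "E"), paste0("s", 1:3))
    s1 <- columnMetrics(aln)$consensus_support
    s2 <- columnMetrics(setNames(c("Q", "Q", "E", "Q"),
                                 paste0("s", 1:4)))$consensus_support
    expect_gte(s2, s1)
})

test_that("generator truth columns are reproduced by the metrics", {
    prof <- c(list(list(type = "conserved", residue = "D"),
                   list(type = "conserved", residue = "W"),
                   list(type = "property", class = "negative"),
                   list(type = "property", class = "aromatic")),
              replicate(6, list(type = "random"), simplify = FALSE))
    for (seed in c(1, 7, 23)) {
        g <- genAlignment(30, prof, gapRate = 0.15, seed = seed)
        m <- columnMetrics(g$alignment)
        tr <- g$truth
        cons <- tr$type == "conserved"
        expect_equal(m$conservation[cons], tr$expected_conservation[cons])
        expect_equal(m$consensus_support[cons], tr$expected_support[cons])
        expect_equal(m$occupancy, tr$occupancy)
        expect_true(all(m$conservation >= tr$min_conservation))
    }
})

test_that("position maps account for reference gaps", {
    # gapless reference -> identity
    aln <- c(ref = "ACDEF", s2 = "ACDEF")
    pm <- buildPositionMap(aln, "ref")
    expect_equal(positionMap(pm)$column, 1:5)
    expect_equal(positionMap(pm)$position, 1:5)

    # spec toy: reference "A-CD" maps {1<->1, 2<->3, 3<->4}
    pm2 <- buildPositionMap(c(ref = "A-CD", s2 = "AQCD"), "ref")
    expect_equal(positionMap(pm2)$column, c(1L, 3L, 4L))
    expect_equal(positionMap(pm2)$position, 1:3)

    # random gapped references vs a brute-force scan
    set.seed(9)
    for (rep in 1:10) {
        chars <- sample(c("A", "C", "G", "-"), 40, replace = TRUE,
                        prob = c(0.3, 0.3, 0.3, 0.1))
        ref <- paste(chars, collapse = "")
        pm3 <- buildPositionMap(c(ref = ref, s2 = strrep("A", 40)), "ref")
        brute <- which(chars != "-")
        expect_equal(positionMap(pm3)$column, brute)
        expect_equal(positionMap(pm3)$position, seq_along(brute))
    }

    expect_error(buildPositionMap(aln, "nope"), "reference id")
    expect_warning(buildPositionMap(aln, "ref", expectedLength = 314),
                   "expected 314")
})

test_that("species matches recover planted residues and exclude the reference", {
    aln <- c(Homo_sapiens = "ARND",
             Mus_musculus = "ASND",
             Callithrix_jacchus = "ASND",
             Bos_taurus = "ARND")
    pm <- buildPositionMap(aln, "Homo_sapiens")
    hit <- speciesMatches(aln, pm, position = 2, altAa = "S")
    expect_setequal(hit, c("Mus_musculus", "Callithrix_jacchus"))
    sp <- speciesMatches(aln, pm, 2, "S", useSpecies = TRUE)
    expect_setequal(sp, c("Mus musculus", "Callithrix jacchus"))
    # residue matching the reference itself is excluded
    expect_identical(speciesMatches(aln, pm, 2, "R"), "Bos_taurus")
    # residue absent from the column -> empty
    expect_length(speciesMatches(aln, pm, 2, "W"), 0L)
})

test_that("variant annotation joins metrics and covers every position", {
    g <- genAlignment(20, c(list(list(type = "conserved", residue = "G")),
                            replicate(9, list(type = "random"),
                                      simplify = FALSE)),
                      gapRate = 0, seed = 5)
    aln <- g$alignment
    names(aln)[1] <- "Homo_sapiens"
    pm <- buildPositionMap(aln, "Homo_sapiens")
    groups <- data.frame(label = c("b:G1D", "b:X5Y"), isoform = "b",
                         position = c(1L, 5L), ref_aa = c("G", "X"),
                         alt_aa = c("D", "Y"), kind = "missense",
                         stringsAsFactors = FALSE)
    ann <- annotateVariants(groups, aln, pm)
    expect_equal(nrow(ann$positions), 10L)   # every reference position
    expect_equal(ann$annotated$conservation[1], 11L)
    expect_false(any(ann$annotated$unmapped))
    expect_equal(nrow(ann$annotated), nrow(groups))  # row conservation
})
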