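## Synthetic-data generators with ground truth for every pipeline stage.
## All randomness comes from R's Mersenne-Twister via set.seed(seed): one
## seed governs one generated dataset, byte-identically across platforms.

.AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
           "S","T","V","W","Y")

#' Generate a protein alignment with controlled column structure
#'
#' Columns are generated from a profile of column types:
#' * `list(type = "conserved", residue = "D")` - the residue in every
#'   sequence, no gaps (conservation 11, support 100 by construction);
#' * `list(type = "property", class = "negative")` - residues drawn
#'   uniformly from a property class of [columnMetrics()]'s conservation
#'   alphabet, gaps at `gapRate`;
#' * `list(type = "random")` - residues drawn uniformly from all 20 amino
#'   acids, gaps at `gapRate`.
#'
#' @param nSeq number of sequences (>= 2).
#' @param columnProfile list of column specs (non-empty).
#' @param gapRate per-cell gap probability for non-conserved columns
#'   (in `[0, 0.5]`).
#' @param seed integer seed.
#' @return list with `alignment` (named character vector, ids `seq_1..n`)
#'   and `truth` (per column: `type`, `residue_or_class`,
#'   `expected_conservation`, `expected_support`, `occupancy`,
#'   `min_conservation`).
#' @export
genAlignment <- function(nSeq, columnProfile, gapRate = 0.1, seed = 1L) {
    if (nSeq < 2L) stop("nSeq must be >= 2")
    if (!length(columnProfile)) stop("empty column profile")
    if (gapRate < 0 || gapRate > 0.5) stop("gapRate must be in [0, 0.5]")
    set.seed(seed)
    cols <- vector("list", length(columnProfile))
    truth <- vector("list", length(columnProfile))
    for (j in seq_along(columnProfile)) {
        spec <- columnProfile[[j]]
        if (spec$type == "conserved") {
            col <- rep(spec$residue, nSeq)
            tr <- data.frame(column = j, type = "conserved",
                             residue_or_class = spec$residue,
                             expected_conservation = 11L,
                             expected_support = 100,
                             occupancy = nSeq, min_conservation = 11L)
        } else {
            pool <- if (spec$type == "property")
                .AA_PROPERTIES[[spec$class]] else .AA20
            col <- sample(pool, nSeq, replace = TRUE)
            gaps <- stats::runif(nSeq) < gapRate
            col[gaps] <- "-"
            occ <- sum(!gaps)
            minc <- if (spec$type == "property" && !any(gaps)) {
                pm <- .propertyMatrix()
                sub <- pm[pool, , drop = FALSE]
                sum(colSums(sub) == nrow(sub) | colSums(sub) == 0L)
            } else 0L
            tr <- data.frame(column = j, type = spec$type,
                             residue_or_class =
                                 if (spec$type == "property") spec$class
                                 else NA_character_,
                             expected_conservation = NA_integer_,
                             expected_support = NA_real_,
                             occupancy = occ, min_conservation = minc)
        }
        cols[[j]] <- col
        truth[[j]] <- tr
    }
    m <- do.call(cbind, cols)
    aln <- apply(m, 1L, paste, collapse = "")
    names(aln) <- paste0("seq_", seq_len(nSeq))
    list(alignment = aln, truth = do.call(rbind, truth))
}

#' Evolve sequences along a tree under a 20-state Poisson process
#'
#' Simulates gap-free protein sequences along a known tree under the
#' equal-rates 20-state (Jukes-Cantor-like) model, the generative
#' counterpart of the Poisson distance correction: over a branch of length
#' `t` substitutions/site, a site differs from its ancestor with
#' probability `(19/20) * (1 - exp(-(20/19) t))`, uniformly over the other
#' 19 residues.
#'
#' @param nTaxa number of taxa (>= 4, so that topology recovery is
#'   testable), ignored when `tree` is given.
#' @param nSites sequence length (sites).
#' @param branchLengths branch length(s) in substitutions/site, recycled
#'   over the tree's edges; ignored when `tree` carries its own.
#' @param seed integer seed.
#' @param tree optional [ape::phylo] to use instead of a random topology.
#' @return list with `tree` ([ape::phylo]) and `alignment` (named character
#'   vector).
#' @export
genTreeSequences <- function(nTaxa = 6L, nSites = 1000L,
                             branchLengths = 0.1, seed = 1L, tree = NULL) {
    set.seed(seed)
    if (is.null(tree)) {
        if (nTaxa < 4L) stop("nTaxa must be >= 4")
        tree <- ape::rtree(nTaxa, rooted = FALSE, br = NULL)
        tree$edge.length <- rep_len(branchLengths, nrow(tree$edge))
    }
    if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
    n_tip <- length(tree$tip.label)
    n_node <- n_tip + tree$Nnode
    seqs <- vector("list", n_node)
    root <- n_tip + 1L
    seqs[[root]] <- sample(.AA20, nSites, replace = TRUE)
    # pre-order edge walk (ape edges are already parent-before-child after
    # reorder)
    tree2 <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tree2$edge))) {
        par <- tree2$edge[e, 1L]; child <- tree2$edge[e, 2L]
        t <- tree2$edge.length[e]
        anc <- seqs[[par]]
        p_diff <- (19 / 20) * (1 - exp(-(20 / 19) * t))
        change <- stats::runif(nSites) < p_diff
        out <- anc
        if (any(change)) {
            out[change] <- vapply(anc[change], function(a)
                sample(setdiff(.AA20, a), 1L), "")
        }
        seqs[[child]] <- out
    }
    aln <- vapply(seq_len(n_tip), function(i)
        paste(seqs[[i]], collapse = ""), "")
    names(aln) <- tree$tip.label
    list(tree = tree, alignment = aln)
}

#' Generate multi-source variant tables with known merge truth
#'
#' Plants `nTrueVariants` unique GRCh38 SNVs in the coding region of the
#' gene model, each with a codon-consistent protein-change label, and
#' scatters them over `nSources` source tables. A fraction of sources is
#' emitted on hg19 (positions pushed through the inverse of `chainMap`);
#' additional source memberships occur at `duplicateRate`; a planted number
#' of rsID conflicts (`round(rsidConflictRate * nTrueVariants)`) give one
#' variant two distinct rsIDs in two sources.
#'
#' @param nTrueVariants number of unique DNA variants.
#' @param nSources number of source tables (>= 1).
#' @param hg19Fraction fraction of sources emitted with hg19 coordinates.
#' @param duplicateRate probability that a variant also appears in each
#'   additional source.
#' @param rsidConflictRate fraction of variants given conflicting rsIDs.
#' @param chainMap a [ChainMap-class] mapping hg19 -> GRCh38; must cover the
#'   generated positions.
#' @param geneModel a [GeneModel-class].
#' @param seed integer seed.
#' @return list with `tables` (list of [SourceVariantTable-class]) and
#'   `truth` (`n_unique`, `variants` data.frame with keys and protein
#'   labels, `protein_partition` named list, `n_rsid_conflicts`).
#' @export
genVariantSources <- function(nTrueVariants, nSources = 3L,
                              hg19Fraction = 0, duplicateRate = 0.3,
                              rsidConflictRate = 0, chainMap = NULL,
                              geneModel = readGeneModel(), seed = 1L) {
    stopifnot(nTrueVariants >= 1L, nSources >= 1L)
    set.seed(seed)
    cdsb <- geneModel@cds[["b"]]
    n_codons <- (cdsb[2L] - cdsb[1L] + 1L - 3L) %/% 3L   # exclude stop
    # sample codon + base offset; allow shared codons (protein grouping)
    codons <- sample(n_codons, nTrueVariants, replace = TRUE)
    offs <- sample(0:2, nTrueVariants, replace = TRUE)
    pos <- cdsb[1L] + 3L * (codons - 1L) + offs
    # unique genomic positions
    while (anyDuplicated(pos)) {
        dup <- which(duplicated(pos))
        codons[dup] <- sample(n_codons, length(dup), replace = TRUE)
        offs[dup] <- sample(0:2, length(dup), replace = TRUE)
        pos[dup] <- cdsb[1L] + 3L * (codons[dup] - 1L) + offs[dup]
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nTrueVariants, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    # codon-consistent protein labels; same codon -> same label, so several
    # DNA variants can share one protein group
    codon_aa <- stats::setNames(
        sample(.AA20, n_codons, replace = TRUE), NULL)
    codon_alt <- vapply(seq_len(n_codons), function(k)
        sample(setdiff(.AA20, codon_aa[k]), 1L), "")
    protein <- sprintf("p.%s%d%s", codon_aa[codons], codons,
                       codon_alt[codons])
    rsid <- ifelse(stats::runif(nTrueVariants) < 0.6,
                   sprintf("rs%07d", sample(1e6, nTrueVariants)),
                   NA_character_)
    key <- sprintf("%s:%d:%s:%s", geneModel@chrom, pos, ref, alt)

    # source membership: each variant in >= 1 source
    membership <- lapply(seq_len(nTrueVariants), function(i) {
        first <- sample(nSources, 1L)
        extra <- which(stats::runif(nSources) < duplicateRate)
        sort(unique(c(first, extra)))
    })
    # planted rsID conflicts: variant in >= 2 sources gets a second rsID
    n_confl <- round(rsidConflictRate * nTrueVariants)
    confl_ids <- integer(0)
    if (n_confl > 0) {
        multi <- which(lengths(membership) >= 2L & !is.na(rsid))
        if (length(multi) < n_confl) {
            need <- setdiff(which(!is.na(rsid)), multi)[
                seq_len(n_confl - length(multi))]
            for (i in need)
                membership[[i]] <- sort(unique(c(membership[[i]],
                    sample(setdiff(seq_len(nSources), membership[[i]]), 1L))))
            multi <- which(lengths(membership) >= 2L & !is.na(rsid))
        }
        confl_ids <- sort(sample(multi, n_confl))
    }
    confl_rsid <- stats::setNames(
        sprintf("rs9%06d", sample(1e6, length(confl_ids))), confl_ids)

    if (nSources > 7L) stop("at most 7 sources (one per source name)")
    n_hg19 <- round(hg19Fraction * nSources)
    hg19_sources <- if (n_hg19 > 0) seq_len(n_hg19) else integer(0)
    # distinct source names so per-source provenance stays separable;
    # hg19-build sources take tcga-like names first
    name_pool <- c("tcga", "clinvar", "lovd", "cosmic", "gnomad",
                   "decipher", "generic")
    src_names <- character(nSources)
    src_names[hg19_sources] <- name_pool[seq_along(hg19_sources)]
    src_names[setdiff(seq_len(nSources), hg19_sources)] <-
        setdiff(name_pool, src_names)[seq_len(nSources - n_hg19)]
    if (length(hg19_sources)) {
        if (is.null(chainMap)) stop("hg19 sources requested but no chainMap")
        inv <- .invertChainMap(chainMap)
        back <- liftoverPositions(rep(geneModel@chrom, nTrueVariants), pos,
                                  inv)
        if (any(!back$mapped))
            stop("chain map does not cover generated positions")
    }
    tables <- lapply(seq_len(nSources), function(s) {
        idx <- which(vapply(membership, function(mm) s %in% mm, TRUE))
        is19 <- s %in% hg19_sources
        rs_out <- rsid[idx]
        # the conflicting rsID goes into the variant's second source
        for (i in idx[idx %in% confl_ids]) {
            if (s == membership[[i]][2L])
                rs_out[idx == i] <- confl_rsid[[as.character(i)]]
        }
        df <- data.frame(
            chrom = if (is19) back$chrom[idx] else
                rep(geneModel@chrom, length(idx)),
            pos = if (is19) back$pos[idx] else pos[idx],
            ref = ref[idx], alt = alt[idx],
            protein_change = protein[idx], isoform = "b",
            rsid = rs_out, pathogenicity = NA_character_,
            allele_frequency = NA_real_, sample_id = NA_character_,
            cancer_type = NA_character_, pos_hg19 = NA_integer_,
            protein_change_unparsed = FALSE, stringsAsFactors = FALSE)
        new("SourceVariantTable", sourceName = src_names[s],
            build = if (is19) "hg19" else "GRCh38", variants = df)
    })
    truth_df <- data.frame(key = key, chrom = geneModel@chrom, pos = pos,
                           ref = ref, alt = alt, protein_change = protein,
                           rsid = rsid, n_sources = lengths(membership),
                           stringsAsFactors = FALSE)
    list(tables = tables,
         truth = list(n_unique = nTrueVariants, variants = truth_df,
                      protein_partition = split(key, protein),
                      n_rsid_conflicts = length(confl_ids),
                      conflict_keys = key[confl_ids]))
}

# swap source and target sides of a + strand chain map
.invertChainMap <- function(chainMap) {
    b <- blocks(chainMap)
    if (any(b$strand != "+"))
        stop("only + strand chain maps can be inverted")
    new("ChainMap", blocks = data.frame(
        source_chrom = b$target_chrom, source_start = b$target_start,
        source_end = b$target_start + (b$source_end - b$source_start),
        target_chrom = b$source_chrom, target_start = b$source_start,
        strand = "+", stringsAsFactors = FALSE))
}

#' Generate a CNA / arm-status / survival cohort with planted truth
#'
#' Per cancer type, samples get a GISTIC level (loss with probability
#' `p_loss`, split 9:1 shallow:deep; gain with `p_gain`, split 9:1
#' gain:amplification), an arm status (`loss` with probability
#' `p_arm_loss_given_loss` for gene-loss samples, `pArmLossOther`
#' otherwise), and survival times drawn from an exponential with hazard
#' `baselineHazard * hazard_ratio_loss^loss`, independently censored by an
#' exponential with hazard `censor_rate`.
#'
#' @param perType data.frame with columns `cancer_type`, `n`, `p_loss`,
#'   `p_gain`, `p_arm_loss_given_loss`, `hazard_ratio_loss`, `censor_rate`.
#' @param baselineHazard baseline exponential hazard (events per time unit).
#' @param pArmLossOther arm-loss probability for samples without gene loss.
#' @param arm arm label for the status table.
#' @param seed integer seed.
#' @return list with `cna`, `armStatus`, `survival` data.frames and `truth`
#'   (the planted `perType` parameters and `baselineHazard`).
#' @export
genCnaSurvival <- function(perType, baselineHazard = 0.1,
                           pArmLossOther = 0.1, arm = "3p", seed = 1L) {
    need <- c("cancer_type", "n", "p_loss", "p_gain",
              "p_arm_loss_given_loss", "hazard_ratio_loss", "censor_rate")
    if (!all(need %in% names(perType)))
        stop("perType needs columns: ", paste(need, collapse = ", "))
    if (any(perType$p_loss + perType$p_gain > 1))
        stop("p_loss + p_gain must be <= 1")
    set.seed(seed)
    out <- lapply(seq_len(nrow(perType)), function(r) {
        p <- perType[r, ]
        ids <- sprintf("%s_%04d", p$cancer_type, seq_len(p$n))
        u <- stats::runif(p$n)
        level <- ifelse(u < p$p_loss,
                        ifelse(stats::runif(p$n) < 0.9, -1L, -2L),
                 ifelse(u < p$p_loss + p$p_gain,
                        ifelse(stats::runif(p$n) < 0.9, 1L, 2L), 0L))
        loss <- level < 0L
        arm_loss <- ifelse(loss, stats::runif(p$n) < p$p_arm_loss_given_loss,
                           stats::runif(p$n) < pArmLossOther)
        hz <- baselineHazard * ifelse(loss, p$hazard_ratio_loss, 1)
        t_event <- stats::rexp(p$n, rate = hz)
        t_cens <- if (p$censor_rate > 0)
            stats::rexp(p$n, rate = p$censor_rate) else rep(Inf, p$n)
        list(cna = data.frame(sample_id = ids, cancer_type = p$cancer_type,
                              gistic_level = level,
                              stringsAsFactors = FALSE),
             armStatus = data.frame(sample_id = ids, arm = arm,
                                    status = ifelse(arm_loss, "loss",
                                                    "unchanged"),
                                    stringsAsFactors = FALSE),
             survival = data.frame(sample_id = ids, endpoint = "OS",
                                   time = pmin(t_event, t_cens),
                                   event = t_event <= t_cens,
                                   stringsAsFactors = FALSE))
    })
    list(cna = do.call(rbind, lapply(out, `[[`, "cna")),
         armStatus = do.call(rbind, lapply(out, `[[`, "armStatus")),
         survival = do.call(rbind, lapply(out, `[[`, "survival")),
         truth = list(perType = perType, baselineHazard = baselineHazard,
                      pArmLossOther = pArmLossOther))
}

#' Generate a toy multi-chain structure with known contacts
#'
#' Builds CA-only chains with random coordinates and computes the
#' ground-truth contact set by an exhaustive pairwise distance check with
#' the same radii table the contact module uses.
#'
#' @param chainSpecs named list: per chain either an `n x 3` coordinate
#'   matrix or `list(n =, center =, spread =)` for uniform random
#'   coordinates in a cube of half-width `spread` around `center`.
#' @param cutoff overlap cutoff used for the truth contacts.
#' @param radii radii table.
#' @param seed integer seed.
#' @return list with `atoms` (structure table), `pdbText`, and `truth`
#'   (data.frame of contacting residue pairs per chain pair).
#' @export
genToyStructure <- function(chainSpecs, cutoff = -0.4, radii = vdwRadii(),
                            seed = 1L) {
    set.seed(seed)
    atoms <- do.call(rbind, lapply(names(chainSpecs), function(ch) {
        spec <- chainSpecs[[ch]]
        xyz <- if (is.matrix(spec)) spec else
            matrix(stats::runif(spec$n * 3L, -spec$spread, spec$spread),
                   ncol = 3L) +
            matrix(rep(spec$center, each = spec$n), ncol = 3L)
        data.frame(chain = ch, resno = seq_len(nrow(xyz)), resid = "ALA",
                   atom = "CA", element = "C",
                   x = round(xyz[, 1L], 3), y = round(xyz[, 2L], 3),
                   z = round(xyz[, 3L], 3), occupancy = 1,
                   stringsAsFactors = FALSE)
    }))
    chains <- names(chainSpecs)
    r_ca <- .atomRadii(atoms$element, radii)
    truth <- list()
    for (i in seq_along(chains)[-length(chains)])
        for (j in (i + 1L):length(chains)) {
            ai <- which(atoms$chain == chains[i])
            aj <- which(atoms$chain == chains[j])
            for (u in ai) for (v in aj) {
                d <- sqrt((atoms$x[u] - atoms$x[v])^2 +
                          (atoms$y[u] - atoms$y[v])^2 +
                          (atoms$z[u] - atoms$z[v])^2)
                ov <- r_ca[u] + r_ca[v] - d
                if (ov >= cutoff)
                    truth[[length(truth) + 1L]] <- data.frame(
                        chain_a = chains[i], resno_a = atoms$resno[u],
                        chain_b = chains[j], resno_b = atoms$resno[v],
                        overlap = ov, stringsAsFactors = FALSE)
            }
        }
    truth <- if (length(truth)) do.call(rbind, truth) else
        data.frame(chain_a = character(0), resno_a = integer(0),
                   chain_b = character(0), resno_b = integer(0),
                   overlap = numeric(0), stringsAsFactors = FALSE)
    list(atoms = atoms, pdbText = writePDBText(atoms), truth = truth)
}
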