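#' Observed proportion of differences under pairwise deletion
#'
#' Sites where either sequence carries a gap are excluded for that pair
#' only; `p` is the fraction of mismatches among the remaining sites.
#'
#' @param a,b aligned sequences of equal length (character strings).
#' @return list with `p`, `n_valid` and `saturated` (TRUE when no valid
#'   sites remain).
#' @examples
#' pDistance("AC-E", "AG-E")  # p = 1/3 over 3 valid sites
#' @export
pDistance <- function(a, b) {
    x <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
    y <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
    if (length(x) != length(y)) stop("sequences must have equal length")
    valid <- x != "-" & y != "-"
    n <- sum(valid)
    if (!n) return(list(p = NA_real_, n_valid = 0L, saturated = TRUE))
    list(p = sum(x[valid] != y[valid]) / n, n_valid = n, saturated = FALSE)
}

#' Gamma-corrected Poisson distance
#'
#' Corrects the observed proportion of amino acid differences `p` for
#' multiple hits under a Poisson substitution process with gamma-distributed
#' rates across sites: `d = a * ((1 - p)^(-1/a) - 1)` with shape `a`. As
#' `a -> Inf` this approaches the plain Poisson correction `-log(1 - p)`.
#' Saturated inputs (`p >= 1 - 1e-9`) are set to `cap` and flagged.
#'
#' @param p observed difference proportion(s) in `[0, 1)`.
#' @param shape gamma shape parameter `a > 0` (default 1, p/(1-p)).
#' @param cap distance assigned to saturated pairs.
#' @return numeric vector of distances with attribute `"saturated"`.
#' @examples
#' gammaPoissonDistance(0.5, shape = 1)   # 1.0
#' @export
gammaPoissonDistance <- function(p, shape = 1, cap = 10) {
    if (any(shape <= 0)) stop("gamma shape must be > 0")
    if (any(p < 0, na.rm = TRUE)) stop("p must be >= 0")
    n <- max(length(p), length(shape))
    p <- rep_len(p, n)
    shape <- rep_len(shape, n)
    sat <- !is.na(p) & p >= 1 - 1e-9
    d <- shape * ((1 - p)^(-1 / shape) - 1)
    d[sat] <- cap
    attr(d, "saturated") <- sat
    d
}

#' Pairwise distance matrix from a protein alignment
#'
#' Pairwise-deletion p-distances corrected with [gammaPoissonDistance()].
#'
#' @param aln an alignment.
#' @param shape gamma shape parameter (`Inf` for the plain Poisson
#'   correction).
#' @param cap saturation cap.
#' @return symmetric numeric matrix with zero diagonal; attribute
#'   `"saturated"` marks capped entries.
#' @export
distanceMatrix <- function(aln, shape = 1, cap = 10) {
    m <- alignmentMatrix(aln)
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    sat <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        valid <- m[i, ] != "-" & m[j, ] != "-"
        nv <- sum(valid)
        if (!nv) { d[i, j] <- d[j, i] <- cap; sat[i, j] <- sat[j, i] <- TRUE; next }
        p <- sum(m[i, valid] != m[j, valid]) / nv
        if (p >= 1 - 1e-9) {
            d[i, j] <- d[j, i] <- cap
            sat[i, j] <- sat[j, i] <- TRUE
        } else {
            d[i, j] <- d[j, i] <- if (is.finite(shape))
                shape * ((1 - p)^(-1 / shape) - 1) else -log(1 - p)
        }
    }
    attr(d, "saturated") <- sat
    d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler Q criterion.
#' Joins are tie-broken by the smallest `(i, j)` index pair in the current
#' matrix order; negative estimated branch lengths are clamped to zero with
#' the total clamped deficit recorded in the `"clamped_deficit"` attribute.
#'
#' @param d symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @param allowCapped proceed even when the matrix carries saturated
#'   (capped) entries.
#' @return an unrooted [ape::phylo].
#' @export
njTree <- function(d, allowCapped = FALSE) {
    sat <- attr(d, "saturated")
    if (!allowCapped && !is.null(sat) && any(sat))
        stop("distance matrix has saturated entries; set allowCapped = TRUE")
    n <- nrow(d)
    if (n < 3L) stop("need >= 3 taxa")
    labels <- rownames(d)
    if (is.null(labels)) labels <- paste0("t", seq_len(n))
    node <- as.list(labels)          # newick fragment per active node
    D <- d
    deficit <- 0
    while (length(node) > 3L) {
        r <- length(node)
        R <- rowSums(D)
        Q <- (r - 2) * D - outer(R, R, "+")
        diag(Q) <- Inf
        # smallest (i,j), row-major over i < j
        best <- c(NA_integer_, NA_integer_); bq <- Inf
        for (i in seq_len(r - 1L)) for (j in (i + 1L):r) {
            if (Q[i, j] < bq - 1e-12) { bq <- Q[i, j]; best <- c(i, j) }
        }
        i <- best[1L]; j <- best[2L]
        vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
        vj <- D[i, j] - vi
        if (vi < 0) { deficit <- deficit - vi; vj <- min(vj - vi, D[i, j]); vi <- 0 }
        if (vj < 0) { deficit <- deficit - vj; vi <- min(vi - vj, D[i, j]); vj <- 0 }
        merged <- sprintf("(%s:%.10g,%s:%.10g)", node[[i]], vi, node[[j]], vj)
        newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
        keep <- setdiff(seq_len(r), c(i, j))
        D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                    c(newd[keep], 0))
        node <- c(node[keep], merged)
        D <- D2
    }
    if (length(node) == 3L) {
        v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
        v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
        v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
        for (v in c("v1", "v2", "v3")) {
            val <- get(v)
            if (val < 0) { deficit <- deficit - val; assign(v, 0) }
        }
        txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                       node[[1L]], v1, node[[2L]], v2, node[[3L]], v3)
    } else stop("internal error: unexpected node count")
    tr <- ape::read.tree(text = txt)
    attr(tr, "clamped_deficit") <- deficit
    tr
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, infers an NJ tree per
#' replicate from [distanceMatrix()], and labels each internal edge of the
#' original tree with the percentage of replicates containing its
#' bipartition. Replicates with an undefined (saturated) pairwise distance
#' are dropped and counted.
#'
#' @param aln an alignment.
#' @param nReplicates number of bootstrap replicates.
#' @param shape gamma shape parameter for the distance correction.
#' @param seed integer seed.
#' @return the NJ tree with `node.label` supports (percent); attributes
#'   `"dropped_replicates"` and `"supports"` (named by split key).
#' @export
bootstrapSupport <- function(aln, nReplicates = 100L, shape = 1,
                             seed = 1L) {
    stopifnot(nReplicates >= 1L)
    m <- alignmentMatrix(aln)
    d0 <- distanceMatrix(m2strings(m), shape = shape)
    tree <- njTree(d0)
    orig <- bipartitions(tree)
    counts <- stats::setNames(numeric(length(orig)), orig)
    dropped <- 0L
    set.seed(seed)
    for (b in seq_len(nReplicates)) {
        cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
        db <- distanceMatrix(m2strings(m[, cols, drop = FALSE]),
                             shape = shape)
        if (any(attr(db, "saturated"))) { dropped <- dropped + 1L; next }
        bp <- bipartitions(njTree(db))
        hit <- orig %in% bp
        counts[hit] <- counts[hit] + 1
    }
    used <- nReplicates - dropped
    supports <- if (used > 0) 100 * counts / used else counts * NA
    tree <- .labelSupports(tree, supports)
    attr(tree, "dropped_replicates") <- dropped
    attr(tree, "supports") <- supports
    tree
}

# rebuild strings from a character matrix (helper for resampling)
m2strings <- function(m) {
    s <- apply(m, 1L, paste, collapse = "")
    names(s) <- rownames(m)
    s
}

# attach split supports as internal node labels
.labelSupports <- function(tree, supports) {
    n <- length(tree$tip.label)
    lab <- rep("", tree$Nnode)
    anchor <- sort(tree$tip.label)[1L]
    for (nd in seq_len(tree$Nnode)) {
        node_id <- n + nd
        tips <- ape::extract.clade(tree, node_id)$tip.label
        side <- if (anchor %in% tips) setdiff(tree$tip.label, tips) else tips
        if (length(side) < 2L || length(side) > n - 2L) next
        key <- paste(sort(side), collapse = "|")
        if (key %in% names(supports))
            lab[nd] <- sprintf("%g", round(supports[[key]], 1))
    }
    tree$node.label <- lab
    tree
}

#' Reroot a tree on an outgroup
#'
#' @param tree an [ape::phylo].
#' @param outgroup tip label(s) of the outgroup.
#' @return rooted [ape::phylo].
#' @export
rerootOutgroup <- function(tree, outgroup) {
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
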