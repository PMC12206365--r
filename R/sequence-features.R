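.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")

.basesPair <- function(x, y, rna = FALSE) {
    # Watson-Crick, plus GU wobble in RNA mode; N never pairs
    if (x == "N" || y == "N") return(FALSE)
    wc <- (.COMPLEMENT[[x]] == y) || (x == "T" && y == "A") ||
        (x == "A" && y %in% c("T", "U"))
    if (wc) return(TRUE)
    rna && ((x == "G" && y == "U") || (x == "U" && y == "G"))
}

.seqChars <- function(seq) {
    chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
    if (any(!chars %in% c("A", "C", "G", "T", "U", "N")))
        stop("sequence must be over {A,C,G,T/U,N}")
    chars
}

#' Find palindromic inverted repeats
#'
#' Enumerates, for every loop placement (loop length 0..`maxLoop`), the
#' maximal outward extension of two reverse-complementary stems with at most
#' `maxMismatch` mismatched pairs; stems always end on a matching pair. All
#' hits with stem length at least `minStem` are reported, sorted by start
#' and then by descending stem length. `N` never pairs.
#'
#' @param seq nucleotide sequence over `{A,C,G,T/U,N}`.
#' @param minStem minimal stem length (>= 2).
#' @param maxLoop maximal loop length.
#' @param maxMismatch maximal mismatched pairs per stem.
#' @param rna allow GU wobble pairs.
#' @return data.frame with `start` (1-based), `stem_length`, `loop_length`,
#'   `mismatches`, `sequence`.
#' @examples
#' findInvertedRepeats("GAATTC", minStem = 3, maxLoop = 0)
#' @export
findInvertedRepeats <- function(seq, minStem = 4L, maxLoop = 10L,
                                maxMismatch = 0L, rna = FALSE) {
    stopifnot(minStem >= 2L)
    chars <- .seqChars(seq)
    n <- length(chars)
    hits <- list()
    for (loop in 0:maxLoop) {
        # loop occupies positions (l+1)..(l+loop); stems extend outward
        for (l in seq_len(n)) {      # l = last stem1 position candidate
            r <- l + loop + 1L       # first stem2 position
            if (r > n) next
            stem <- 0L; mm <- 0L
            i <- l; j <- r
            while (i >= 1L && j <= n) {
                if (.basesPair(chars[i], chars[j], rna)) {
                    stem <- stem + 1L
                } else {
                    if (mm + 1L > maxMismatch) break
                    mm <- mm + 1L
                    stem <- stem + 1L
                }
                i <- i - 1L; j <- j + 1L
            }
            # trim to end on a matching pair
            while (stem > 0L &&
                   !.basesPair(chars[l - stem + 1L], chars[r + stem - 1L],
                               rna))
                stem <- stem - 1L
            # recount mismatches inside the trimmed stem
            if (stem >= minStem) {
                mm2 <- sum(!vapply(seq_len(stem), function(k)
                    .basesPair(chars[l - k + 1L], chars[r + k - 1L], rna),
                    TRUE))
                start <- l - stem + 1L
                hits[[length(hits) + 1L]] <- data.frame(
                    start = start, stem_length = stem, loop_length = loop,
                    mismatches = mm2,
                    sequence = paste(chars[start:(r + stem - 1L)],
                                     collapse = ""),
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(hits))
        return(data.frame(start = integer(0), stem_length = integer(0),
                          loop_length = integer(0), mismatches = integer(0),
                          sequence = character(0), stringsAsFactors = FALSE))
    out <- unique(do.call(rbind, hits))
    out <- out[order(out$start, -out$stem_length, out$loop_length), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Maximum base pairing (Nussinov)
#'
#' Nussinov dynamic program maximizing the number of Watson-Crick (plus GU
#' wobble in RNA mode) base pairs with hairpin loops of at least `minLoop`
#' unpaired bases. Returns the optimal count and one optimal pairing (the
#' traceback prefers leaving `i` unpaired, then the smallest pairing
#' partner, which makes the returned structure deterministic).
#'
#' @param seq nucleotide sequence.
#' @param minLoop minimal hairpin loop length (default 3).
#' @param rna allow GU wobble pairs.
#' @return list with `count`, `pairs` (two-column matrix of 1-based
#'   positions) and `dotBracket`.
#' @examples
#' maxBasePairs("GGGAAAACCC")$count   # 3
#' @export
maxBasePairs <- function(seq, minLoop = 3L, rna = FALSE) {
    chars <- .seqChars(seq)
    n <- length(chars)
    if (n == 0L) stop("empty sequence")
    N <- matrix(0L, n, n)
    if (n > 1L) {
        for (span in seq_len(n - 1L)) {
            for (i in seq_len(n - span)) {
                j <- i + span
                best <- N[i + 1L, j]             # i unpaired
                for (k in (i + 1L):j) {          # i pairs with k in (i, j]
                    if (k - i - 1L < minLoop) next
                    if (!.basesPair(chars[i], chars[k], rna)) next
                    inner <- if (k - 1L >= i + 1L) N[i + 1L, k - 1L] else 0L
                    rest <- if (k + 1L <= j) N[k + 1L, j] else 0L
                    best <- max(best, 1L + inner + rest)
                }
                N[i, j] <- best
            }
        }
    }
    # traceback: prefer i unpaired, then smallest k
    pairs <- matrix(integer(0), ncol = 2)
    stack <- list(c(1L, n))
    while (length(stack)) {
        ij <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        i <- ij[1L]; j <- ij[2L]
        if (i >= j) next
        if (N[i, j] == N[i + 1L, j]) {
            stack[[length(stack) + 1L]] <- c(i + 1L, j)
            next
        }
        for (k in (i + 1L):j) {
            if (k - i - 1L < minLoop || !.basesPair(chars[i], chars[k], rna))
                next
            inner <- if (k - 1L >= i + 1L) N[i + 1L, k - 1L] else 0L
            rest <- if (k + 1L <= j) N[k + 1L, j] else 0L
            if (N[i, j] == 1L + inner + rest) {
                pairs <- rbind(pairs, c(i, k))
                if (k - 1L >= i + 1L)
                    stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
                if (k + 1L <= j)
                    stack[[length(stack) + 1L]] <- c(k + 1L, j)
                break
            }
        }
    }
    db <- rep(".", n)
    if (nrow(pairs)) { db[pairs[, 1L]] <- "("; db[pairs[, 2L]] <- ")" }
    list(count = if (n > 1L) N[1L, n] else 0L,
         pairs = pairs[order(pairs[, 1L]), , drop = FALSE],
         dotBracket = paste(db, collapse = ""))
}

#' Reverse complement
#' @param seq DNA sequence string.
#' @return reverse-complemented string.
#' @export
reverseComplement <- function(seq) {
    chars <- rev(.seqChars(seq))
    paste(.COMPLEMENT[chars], collapse = "")
}
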