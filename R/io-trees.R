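#' Read and write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that keep
#' branch lengths to full precision and preserve internal node (support)
#' labels. `readNewick` accepts a file path or a literal Newick string.
#'
#' @param x a Newick string or a path to a Newick file.
#' @param tree an [ape::phylo] object.
#' @param path output path, or `NULL` to return the Newick text.
#' @return `readNewick` returns an [ape::phylo]; `writeNewick` returns the
#'   Newick text (invisibly when written to a file).
#' @examples
#' tr <- readNewick("(A:1,B:2,(C:1,D:1):0.5);")
#' writeNewick(tr)
#' @export
readNewick <- function(x) {
    txt <- if (length(x) == 1L && !grepl("[(;]", x) && file.exists(x))
        paste(readLines(x, warn = FALSE), collapse = "") else x
    if (.parenBalance(txt) != 0L)
        stop("malformed Newick: unbalanced parentheses at position ",
             .parenFailPos(txt))
    tr <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
    if (is.null(tr)) stop("Newick parse error: no tree in input")
    tr
}

.parenBalance <- function(txt) {
    chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
    sum(chars == "(") - sum(chars == ")")
}

.parenFailPos <- function(txt) {
    chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
    depth <- cumsum((chars == "(") - (chars == ")"))
    if (any(depth < 0)) which(depth < 0)[1L] else length(chars)
}

#' @rdname readNewick
#' @export
writeNewick <- function(tree, path = NULL) {
    txt <- ape::write.tree(tree, digits = 10)
    if (is.null(path)) return(txt)
    writeLines(txt, path)
    invisible(txt)
}

#' Unrooted bipartitions of a tree
#'
#' Returns the set of non-trivial bipartitions (splits) of an unrooted tree
#' as canonical strings: for each internal edge, the leaf-name set on the
#' side not containing the alphabetically first taxon, sorted and
#' pipe-joined. Two trees have the same unrooted topology iff their
#' bipartition sets are equal.
#'
#' @param tree an [ape::phylo].
#' @return character vector of canonical split keys (possibly empty).
#' @export
bipartitions <- function(tree) {
    tree <- ape::unroot(tree)
    n <- length(tree$tip.label)
    if (n < 4L) return(character(0))
    anchor <- sort(tree$tip.label)[1L]
    parts <- ape::prop.part(tree)
    labs <- attr(parts, "labels")
    keys <- vapply(parts, function(idx) {
        side <- labs[idx]
        if (anchor %in% side) side <- setdiff(labs, side)
        if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
        paste(sort(side), collapse = "|")
    }, "")
    sort(unique(keys[!is.na(keys)]))
}
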