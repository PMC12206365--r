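#' Accessors for VariantScape objects
#'
#' @param x an object.
#' @return `blocks` returns the block table of a [ChainMap-class];
#'   `variants` the variant table of a [SourceVariantTable-class] or
#'   [HarmonizedVariantTable-class]; `provenance`, `removedRows` and
#'   `conflicts` the bookkeeping tables of a
#'   [HarmonizedVariantTable-class]; `positionMap` the column/position table
#'   of a [PositionMap-class]; `contacts` the residue-pair table of a
#'   [ContactSet-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))
#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("removedRows", function(x) standardGeneric("removedRows"))
#' @rdname accessors
#' @export
setGeneric("conflicts", function(x) standardGeneric("conflicts"))
#' @rdname accessors
#' @export
setGeneric("positionMap", function(x) standardGeneric("positionMap"))
#' @rdname accessors
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))

#' @rdname accessors
#' @export
setMethod("blocks", "ChainMap", function(x) x@blocks)
#' @rdname accessors
#' @export
setMethod("variants", "SourceVariantTable", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("variants", "HarmonizedVariantTable", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("provenance", "HarmonizedVariantTable", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("removedRows", "HarmonizedVariantTable", function(x) x@removed)
#' @rdname accessors
#' @export
setMethod("conflicts", "HarmonizedVariantTable", function(x) x@conflicts)
#' @rdname accessors
#' @export
setMethod("positionMap", "PositionMap", function(x) x@map)
#' @rdname accessors
#' @export
setMethod("contacts", "ContactSet", function(x) x@contacts)
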