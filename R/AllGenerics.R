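#' Accessors for pipeline result objects
#'
#' \code{exponents()} returns the signed slopes of an [ExponentSet] as a
#' named numeric vector (NA where a quantity could not be fitted);
#' \code{communityTable()} and \code{communityMembers()} expose the node
#' table and membership lists of a [CommunityTree]; \code{treeDepth()} is
#' the deepest level present; \code{traceSteps()} / \code{traceSummary()}
#' expose a [RegulatorTraceSet].
#'
#' @param object a result object.
#' @param ... unused.
#' @return See details above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exponents", function(object, ...) standardGeneric("exponents"))

#' @rdname accessors
#' @export
setGeneric("communityTable",
    function(object, ...) standardGeneric("communityTable"))

#' @rdname accessors
#' @export
setGeneric("communityMembers",
    function(object, ...) standardGeneric("communityMembers"))

#' @rdname accessors
#' @export
setGeneric("treeDepth", function(object, ...) standardGeneric("treeDepth"))

#' @rdname accessors
#' @export
setGeneric("traceSteps", function(object, ...) standardGeneric("traceSteps"))

#' @rdname accessors
#' @export
setGeneric("traceSummary",
    function(object, ...) standardGeneric("traceSummary"))

#' @rdname accessors
#' @export
setMethod("exponents", "ExponentSet", function(object, ...) {
    vapply(object@fits, function(f) {
        if (is.null(f)) NA_real_ else f@sign * f@exponent
    }, numeric(1))
})

#' @rdname accessors
#' @export
setMethod("communityTable", "CommunityTree", function(object, ...) object@table)

#' @rdname accessors
#' @export
setMethod("communityMembers", "CommunityTree",
    function(object, ...) object@members)

#' @rdname accessors
#' @export
setMethod("treeDepth", "CommunityTree",
    function(object, ...) max(object@table$level))

#' @rdname accessors
#' @export
setMethod("traceSteps", "RegulatorTraceSet", function(object, ...) object@steps)

#' @rdname accessors
#' @export
setMethod("traceSummary", "RegulatorTraceSet",
    function(object, ...) object@summary)

setMethod("show", "PowerLawFit", function(object) {
    cat(sprintf("PowerLawFit [%s]\n", object@kind))
    cat(sprintf("  exponent: %.4f (sign %+d), xmin = %g, n_tail = %d\n",
                object@exponent, as.integer(object@sign), object@xmin,
                object@nTail))
    cat(sprintf("  ks = %.4f, bootstrap p = %s (n_boot = %d)\n",
                object@ks,
                ifelse(is.na(object@bootstrapP), "NA",
                       sprintf("%.3f", object@bootstrapP)),
                object@nBoot))
    invisible(NULL)
})

setMethod("show", "ExponentSet", function(object) {
    cat("ExponentSet (signed slopes):\n")
    print(round(exponents(object), 4))
    invisible(NULL)
})

setMethod("show", "CommunityTree", function(object) {
    tab <- object@table
    cat(sprintf(
        "CommunityTree: %d tree nodes over levels 0..%d\n",
        nrow(tab), max(tab$level)))
    cat(sprintf("  motifs: %d, residual leaves: %d, network: %d nodes / %d edges\n",
        sum(tab$isMotif), sum(tab$isResidual),
        igraph::vcount(object@graph), igraph::ecount(object@graph)))
    invisible(NULL)
})

setMethod("show", "RegulatorTraceSet", function(object) {
    s <- object@summary
    cat(sprintf("RegulatorTraceSet: %d genes traced, %d key regulators\n",
                nrow(s), sum(s$isKR)))
    invisible(NULL)
})

setMethod("show", "KnockoutReport", function(object) {
    cat(sprintf("KnockoutReport: removed %d gene(s): %s\n",
                length(object@removed),
                paste(object@removed, collapse = ", ")))
    cat(sprintf("  nodes -%d, edges -%d\n", object@nodeDelta,
                object@edgeDelta))
    cat("  deltaHE by level:\n")
    print(object@he)
    invisible(NULL)
})
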