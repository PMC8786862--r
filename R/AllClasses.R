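## S4 containers for the pipeline's results.

#' ExpressionDataset: two-group log2 expression matrix
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' genes x samples matrix of log2 intensities (assay \code{"log2"}) and a
#' per-sample \code{group} column restricted to \code{"control"} /
#' \code{"case"}.  Gene labels must be unique (probe collapsing, if any,
#' happens upstream via [collapseProbes()]).
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [ExpressionDataset()] for the constructor, [screenDEGs()].
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
    msg <- character()
    if (!"log2" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'log2' is required")
    cd <- colData(object)
    if (!"group" %in% colnames(cd)) {
        msg <- c(msg, "colData must have a 'group' column")
    } else {
        grp <- as.character(cd$group)
        if (!all(grp %in% c("control", "case")))
            msg <- c(msg, "group labels must be 'control' or 'case'")
        if (sum(grp == "control") < 1L || sum(grp == "case") < 1L)
            msg <- c(msg, "both groups must be non-empty")
    }
    rn <- rownames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "gene labels must be present and unique")
    if (length(msg)) msg else TRUE
})

#' PowerLawFit: fitted power-law exponent with bootstrap validation
#'
#' Result of [fitDegreeDistribution()] (discrete maximum-likelihood fit of
#' \eqn{P(x) \propto x^{-\alpha}} for \eqn{x \ge x_{min}}) or of
#' [fitCurveExponent()] (weighted log-log regression of a degree-indexed
#' curve).  \code{exponent} is the magnitude; \code{sign} carries the slope
#' direction (+1 increasing, -1 decaying), so the signed slope is
#' \code{sign * exponent} for regression fits and \code{-exponent} for
#' distribution fits.
#'
#' @slot exponent numeric(1), magnitude of the fitted exponent.
#' @slot sign numeric(1), +1 or -1.
#' @slot xmin numeric(1), lower cut-off of the fitted tail (1 for curves).
#' @slot ks numeric(1), Kolmogorov-Smirnov distance (distribution fits) or
#'   root-mean-square log-residual (curve fits).
#' @slot bootstrapP numeric(1), parametric-bootstrap goodness-of-fit
#'   p-value, NA when not requested.
#' @slot nBoot integer(1), bootstrap resamples used (0 when not requested).
#' @slot nTail integer(1), observations at or above \code{xmin}.
#' @slot kind character(1), "mle_distribution" or "loglog_regression".
#' @slot seed integer(1), bootstrap seed (NA when no bootstrap).
#' @export
setClass("PowerLawFit",
    representation(
        exponent = "numeric", sign = "numeric", xmin = "numeric",
        ks = "numeric", bootstrapP = "numeric", nBoot = "integer",
        nTail = "integer", kind = "character", seed = "integer"))

setValidity("PowerLawFit", function(object) {
    msg <- character()
    if (!is.finite(object@exponent)) msg <- c(msg, "exponent must be finite")
    if (!object@sign %in% c(-1, 1)) msg <- c(msg, "sign must be -1 or +1")
    if (!object@kind %in% c("mle_distribution", "loglog_regression"))
        msg <- c(msg, "unknown fit kind")
    if (length(msg)) msg else TRUE
})

#' ExponentSet: the six topology exponents of a network
#'
#' Holds one [PowerLawFit] per topological quantity: \code{gamma} for the
#' degree distribution P(k), \code{alpha} for the clustering curve C(k),
#' \code{beta} for neighborhood connectivity CN(k) (sign meaningful:
#' positive = assortative), \code{delta} for closeness CC(k), \code{mu} for
#' betweenness CB(k) and \code{tau} for eigenvector centrality CE(k).
#'
#' @slot fits named list of [PowerLawFit] (possibly NULL entries when a
#'   curve had too few points to fit).
#' @seealso [fitAllExponents()], [exponents()], [classifyNetwork()].
#' @export
setClass("ExponentSet", representation(fits = "list"))

setValidity("ExponentSet", function(object) {
    wanted <- c("gamma", "alpha", "beta", "delta", "mu", "tau")
    if (!identical(names(object@fits), wanted))
        return("fits must be named gamma, alpha, beta, delta, mu, tau")
    ok <- vapply(object@fits, function(f) is.null(f) || is(f, "PowerLawFit"),
                 logical(1))
    if (!all(ok)) return("fits entries must be PowerLawFit or NULL")
    TRUE
})

#' CommunityTree: recursive community decomposition of a network
#'
#' Produced by [decomposeNetwork()].  Level 0 is the whole network; each
#' accepted community contains at least one triangle and is split
#' recursively with the leading-eigenvector method until a triangular motif
#' (3 nodes, 3 edges), a no-split verdict, or \code{maxLevel} is reached.
#' Triangle-free fragments are kept as "residual" leaves so that the node
#' accounting closes, but are not treated as communities.
#'
#' @slot graph the igraph object that was decomposed.
#' @slot table data.frame with one row per tree node: \code{id},
#'   \code{parent} (NA for the root), \code{level}, \code{nNodes},
#'   \code{nEdges}, \code{isMotif}, \code{isResidual}, \code{isTerminal}.
#' @slot members named list, community id -> character vector of gene labels.
#' @seealso [communityTable()], [communityMembers()], [levelPartition()],
#'   [hamiltonianEnergy()], [traceKeyRegulators()].
#' @export
setClass("CommunityTree",
    representation(graph = "ANY", table = "data.frame", members = "list"))

setValidity("CommunityTree", function(object) {
    tab <- object@table
    need <- c("id", "parent", "level", "nNodes", "nEdges",
              "isMotif", "isResidual", "isTerminal")
    if (!all(need %in% colnames(tab))) return("table is missing columns")
    if (sum(tab$level == 0L) != 1L) return("exactly one level-0 root required")
    if (!identical(sort(tab$id), sort(names(object@members))))
        return("members must be keyed by community id")
    ## children partition the parent's node set
    for (id in tab$id[!tab$isTerminal]) {
        kids <- tab$id[!is.na(tab$parent) & tab$parent == id]
        if (!length(kids)) next
        pool <- sort(unlist(object@members[kids], use.names = FALSE))
        if (!identical(pool, sort(object@members[[id]])))
            return(sprintf("children of %s do not partition it", id))
    }
    TRUE
})

#' RegulatorTraceSet: gene traces through a community tree
#'
#' Produced by [traceKeyRegulators()].  \code{steps} has one row per gene
#' and tree level on its root-to-leaf path with the gene's intra-community
#' edge count \code{x}, the community edge count \code{E} and the regulator
#' probability \code{pY = x/E}.  \code{summary} has one row per gene with
#' its terminal level and the key-regulator call (terminal community is a
#' triangular motif containing the gene).
#'
#' @slot steps data.frame: gene, level, community, x, E, pY, isMotif.
#' @slot summary data.frame: gene, terminalLevel, terminalCommunity,
#'   terminalKind, isKR, deepNotKR.
#' @export
setClass("RegulatorTraceSet",
    representation(steps = "data.frame", summary = "data.frame"))

#' KnockoutReport: before/after comparison for a regulator knockout
#'
#' Produced by [knockoutExperiment()].  Stores node/edge accounting for the
#' removal of the gene set theta, per-level Hamiltonian-energy differences
#' \code{deltaHE = HE_original - HE_knockout}, and per-level exponent sets
#' for the original and knocked-out networks.
#'
#' @slot removed character, genes actually removed.
#' @slot nodeDelta integer(1) nodes lost; @slot edgeDelta integer(1) edges lost.
#' @slot he data.frame: level, heOriginal, heKnockout, deltaHE.
#' @slot exponents data.frame: level, quantity, slopeOriginal, slopeKnockout.
#' @slot original [ExponentSet] of the intact network (level 0).
#' @slot knockout [ExponentSet] of the knocked-out network (level 0).
#' @export
setClass("KnockoutReport",
    representation(
        removed = "character", nodeDelta = "integer", edgeDelta = "integer",
        he = "data.frame", exponents = "data.frame",
        original = "ANY", knockout = "ANY"))
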