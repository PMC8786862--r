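#' Rank network hubs by degree
#'
#' @param net igraph object with named vertices.
#' @param top number of hubs to keep, default 100 (all nodes, with a
#'   warning, when the network is smaller).
#' @return data.frame: gene, degree, rank; sorted by decreasing degree,
#'   ties broken by gene label.
#' @export
rankHubs <- function(net, top = 100L) {
    stopifnot(igraph::is_igraph(net))
    if (igraph::vcount(net) == 0L) stop("empty network")
    deg <- igraph::degree(net)
    ord <- order(-deg, names(deg))
    if (top > length(ord)) {
        warning("top exceeds node count; returning all nodes")
        top <- length(ord)
    }
    sel <- ord[seq_len(top)]
    data.frame(gene = names(deg)[sel], degree = as.integer(deg[sel]),
               rank = seq_len(top), row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Trace genes through the community tree to the motif level
#'
#' Follows each candidate gene's community membership from the full
#' network (level 0) down its root-to-leaf path, recording at each level
#' the gene's intra-community edge count \eqn{x^{[l]}}, the community's
#' edge count \eqn{E^{[l]}} and the regulator probability
#' \eqn{P_y^{[l]} = x^{[l]} / E^{[l]}}.  A gene is called a key regulator
#' (KR) when its terminal community is a triangular motif; inside a motif
#' \eqn{P_y = 2/3} is forced (2 incident edges of 3).  Genes whose path
#' reaches the deepest tree level without ending in a motif are flagged
#' \code{deepNotKR}.
#'
#' @param tree a [CommunityTree-class].
#' @param candidates character vector of genes, default all network nodes;
#'   genes absent from the network are skipped with a warning.
#' @return a [RegulatorTraceSet-class].
#' @export
traceKeyRegulators <- function(tree, candidates = NULL) {
    stopifnot(is(tree, "CommunityTree"))
    g <- tree@graph
    nodes <- igraph::V(g)$name
    if (is.null(candidates)) candidates <- nodes
    absent <- setdiff(candidates, nodes)
    if (length(absent))
        warning("skipping genes not in the network: ",
                paste(absent, collapse = ", "))
    candidates <- intersect(candidates, nodes)
    tab <- communityTable(tree)
    mem <- communityMembers(tree)
    children_of <- split(tab$id, factor(tab$parent, levels = tab$id))
    root <- tab$id[tab$level == 0L]
    depth <- treeDepth(tree)
    steps <- list(); summ <- list()
    for (gene in candidates) {
        id <- root
        path <- id
        repeat {
            kids <- children_of[[id]]
            hit <- kids[vapply(kids, function(cid) gene %in% mem[[cid]],
                               logical(1))]
            if (!length(hit)) break
            id <- hit[[1L]]
            path <- c(path, id)
        }
        rows <- tab[match(path, tab$id), ]
        x <- vapply(path, function(cid) {
            sub <- igraph::induced_subgraph(g, mem[[cid]])
            as.integer(igraph::degree(sub)[gene])
        }, integer(1))
        E <- rows$nEdges
        steps[[gene]] <- data.frame(
            gene = gene, level = rows$level, community = rows$id,
            x = x, E = E, pY = ifelse(E > 0, x / E, NA_real_),
            isMotif = rows$isMotif, stringsAsFactors = FALSE)
        leaf <- rows[nrow(rows), ]
        kind <- if (leaf$isMotif) "motif"
                else if (leaf$isResidual) "residual" else "nonmotif_terminal"
        summ[[gene]] <- data.frame(
            gene = gene, terminalLevel = leaf$level,
            terminalCommunity = leaf$id, terminalKind = kind,
            isKR = leaf$isMotif,
            deepNotKR = !leaf$isMotif && leaf$level == depth,
            stringsAsFactors = FALSE)
    }
    new("RegulatorTraceSet",
        steps = if (length(steps)) do.call(rbind, c(steps, make.row.names = FALSE))
                else data.frame(),
        summary = if (length(summ)) do.call(rbind, c(summ, make.row.names = FALSE))
                  else data.frame())
}

#' Per-level regulator probabilities of a traced gene
#'
#' @param trace a [RegulatorTraceSet-class].
#' @param gene gene label present in the trace.
#' @return named numeric vector of \eqn{P_y} values, names = levels.
#' @export
regulatorProbability <- function(trace, gene) {
    stopifnot(is(trace, "RegulatorTraceSet"))
    st <- traceSteps(trace)
    st <- st[st$gene == gene, , drop = FALSE]
    if (!nrow(st)) stop("gene not present in the trace: ", gene)
    setNames(st$pY, st$level)
}

#' Pooled within-community exponents at a tree level
#'
#' For the partition at a level (see [levelPartition()]), node metrics are
#' computed inside each community's own subgraph, pooled across the
#' level's communities, aggregated into degree curves, and the six
#' exponents are fitted (gamma by log-log regression here, since
#' per-level pools can be small).  Communities whose subgraph has no edges
#' are skipped.
#'
#' @param tree a [CommunityTree-class].
#' @param level level index.
#' @return an [ExponentSet-class].
#' @export
levelExponents <- function(tree, level) {
    part <- levelPartition(tree, level)
    g <- tree@graph
    mem <- communityMembers(tree)
    pooled <- do.call(rbind, lapply(part$id, function(id) {
        sub <- igraph::induced_subgraph(g, mem[[id]])
        if (igraph::ecount(sub) == 0L) return(NULL)
        computeNodeMetrics(sub)
    }))
    if (is.null(pooled) || !nrow(pooled))
        stop("no community with edges at this level")
    fitAllExponents(curves = degreeCurves(pooled), gammaMethod = "regression")
}

#' Knockout experiment: remove regulators and re-analyze
#'
#' Removes the gene set theta from the network (edges of newly isolated
#' nodes are gone, the nodes are dropped from the re-analysis), then
#' recomputes the full characterization on the knockout network: exponent
#' sets at level 0 and per level (pooled within communities, see
#' [levelExponents()]), the community tree, and per-level Hamiltonian
#' energies, reporting \eqn{\Delta HE = HE_{orig} - HE_{\theta}} on the
#' levels both trees share.  \code{mode = "sequential"} additionally
#' removes theta one gene at a time, recording HE after each step in
#' attribute \code{"sequential"} of the report's \code{he} slot.
#'
#' @param net igraph object with named vertices.
#' @param theta non-empty character vector of genes to remove; genes not
#'   in the network are ignored with a warning.
#' @param gammaRes CPM resolution for the energy accounting.
#' @param maxLevel decomposition depth cap.
#' @param nBoot bootstrap resamples for the level-0 degree fits (0 skips).
#' @param seed bootstrap seed.
#' @param mode \code{"set"} (default): theta removed at once;
#'   \code{"sequential"}: one-by-one with intermediate energies.
#' @param levels how many tree levels to fit exponents for (default 0 =
#'   level 0 only; per-level fits on small communities can be fragile).
#' @return a [KnockoutReport-class].
#' @export
knockoutExperiment <- function(net, theta, gammaRes = 0.5, maxLevel = 10L,
                               nBoot = 0L, seed = 1L,
                               mode = c("set", "sequential"), levels = 0L) {
    mode <- match.arg(mode)
    stopifnot(igraph::is_igraph(net))
    if (!length(theta)) stop("theta must be non-empty")
    present <- intersect(unique(theta), igraph::V(net)$name)
    if (!length(present))
        warning("no theta gene is in the network; report compares the ",
                "network with itself")
    net <- sort_vertices(igraph::simplify(net))
    ## newly isolated nodes are retained (flagged) so node accounting
    ## stays exact: |nodes| - |theta ∩ nodes|
    knocked <- if (length(present)) removeNodes(net, present) else net
    if (igraph::ecount(knocked) == 0L)
        stop("knockout removed every edge of the network")
    tree0 <- decomposeNetwork(net, maxLevel)
    tree1 <- decomposeNetwork(knocked, maxLevel)
    he0 <- hamiltonianEnergy(tree0, gammaRes)
    he1 <- hamiltonianEnergy(tree1, gammaRes)
    shared <- intersect(he0$level, he1$level)
    he <- data.frame(level = shared,
                     heOriginal = he0$he[match(shared, he0$level)],
                     heKnockout = he1$he[match(shared, he1$level)])
    he$deltaHE <- he$heOriginal - he$heKnockout
    if (mode == "sequential" && length(present) > 1L) {
        g <- net; seqrows <- list()
        for (i in seq_along(present)) {
            g <- removeNodes(g, present[i])
            ht <- hamiltonianEnergy(decomposeNetwork(g, maxLevel), gammaRes)
            seqrows[[i]] <- data.frame(step = i, removed = present[i],
                                       heLevel0 = ht$he[ht$level == 0L])
        }
        attr(he, "sequential") <- do.call(rbind, seqrows)
    }
    es0 <- fitAllExponents(net, nBoot = nBoot, seed = seed)
    es1 <- fitAllExponents(knocked, nBoot = nBoot, seed = seed)
    expo <- list(data.frame(level = 0L,
                            quantity = names(exponents(es0)),
                            slopeOriginal = unname(exponents(es0)),
                            slopeKnockout = unname(exponents(es1))))
    for (l in seq_len(min(levels, treeDepth(tree0), treeDepth(tree1)))) {
        e0 <- tryCatch(exponents(levelExponents(tree0, l)),
                       error = function(e) NULL)
        e1 <- tryCatch(exponents(levelExponents(tree1, l)),
                       error = function(e) NULL)
        if (is.null(e0) || is.null(e1)) next
        expo[[length(expo) + 1L]] <- data.frame(
            level = l, quantity = names(e0),
            slopeOriginal = unname(e0), slopeKnockout = unname(e1))
    }
    new("KnockoutReport",
        removed = present,
        nodeDelta = length(present),
        edgeDelta = as.integer(igraph::ecount(net) - igraph::ecount(knocked)),
        he = he, exponents = do.call(rbind, expo),
        original = es0, knockout = es1)
}
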