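#' Leading-eigenvector bipartition of a connected graph
#'
#' Newman's spectral split: the modularity matrix
#' \eqn{B = A - k k^T / 2m} is built from the (sub)graph's own degrees;
#' the sign pattern of its leading eigenvector defines the bipartition.
#' No split is returned when the graph has fewer than 2 nodes or no edges,
#' when the leading eigenvalue is not positive, when all eigenvector
#' entries fall on one side, or when the modularity gain
#' \eqn{Q = s^T B s / 4m} of the proposed split is not positive.
#' Zero eigenvector entries are assigned to the positive side; vertices
#' are processed in sorted-label order so the outcome is deterministic.
#'
#' @param net a connected igraph object with named vertices (connected
#'   components are the caller's responsibility; [decomposeNetwork()]
#'   handles them).
#' @param tol numerical tolerance for the eigenvalue/modularity guards.
#' @return NULL (no split) or a list of two character vectors of gene
#'   labels; the part containing the smallest label comes first.
#' @export
levSplit <- function(net, tol = 1e-10) {
    stopifnot(igraph::is_igraph(net))
    n <- igraph::vcount(net)
    m <- igraph::ecount(net)
    if (n < 2L || m < 1L) return(NULL)
    net <- sort_vertices(net)
    A <- as.matrix(igraph::as_adjacency_matrix(net))
    k <- igraph::degree(net)
    B <- A - outer(k, k) / (2 * m)
    ev <- eigen(B, symmetric = TRUE)
    if (ev$values[1L] <= tol) return(NULL)
    v <- ev$vectors[, 1L]
    ## orient so zero entries land on the positive side deterministically
    if (v[1L] < 0) v <- -v
    s <- ifelse(v >= 0, 1, -1)
    if (all(s == s[1L])) return(NULL)
    q <- as.numeric(t(s) %*% B %*% s) / (4 * m)
    if (q <= tol) return(NULL)
    names <- igraph::V(net)$name
    parts <- list(names[s > 0], names[s < 0])
    if (min(parts[[2L]]) < min(parts[[1L]])) parts <- rev(parts)
    parts
}

#' Recursive community decomposition down to triangular motifs
#'
#' Level 0 is the whole network.  Each community is split recursively:
#' disconnected pieces separate into their connected components, connected
#' ones by [levSplit()].  A child is accepted as a community only if it
#' contains at least one triangle; triangle-free fragments are kept as
#' terminal "residual" leaves (so the children of any community always
#' partition it exactly) but are not split further.  Recursion also stops
#' at triangular motifs (3 nodes, 3 edges), at a no-split verdict, and at
#' \code{maxLevel}.
#'
#' @param net igraph object with named vertices.
#' @param maxLevel recursion depth cap, default 10.
#' @return a [CommunityTree-class].
#' @export
decomposeNetwork <- function(net, maxLevel = 10L) {
    stopifnot(igraph::is_igraph(net))
    if (igraph::vcount(net) < 1L) stop("empty network")
    net <- sort_vertices(igraph::simplify(net))
    rows <- list(); members <- list()
    nxt <- new.env(); nxt$i <- 0L
    new_id <- function() { nxt$i <- nxt$i + 1L; sprintf("c%04d", nxt$i) }
    add <- function(sub, level, parent, residual) {
        id <- new_id()
        motif <- is_motif_graph(sub) && !residual
        terminal <- residual || motif || level >= maxLevel
        kids <- NULL
        if (!terminal) {
            comp <- igraph::components(sub)
            if (comp$no > 1L) {
                kids <- split(igraph::V(sub)$name, comp$membership)
            } else {
                kids <- levSplit(sub)
            }
        }
        if (is.null(kids)) terminal <- TRUE
        rows[[id]] <<- data.frame(
            id = id, parent = if (is.null(parent)) NA_character_ else parent,
            level = level, nNodes = igraph::vcount(sub),
            nEdges = igraph::ecount(sub), isMotif = motif,
            isResidual = residual, isTerminal = terminal,
            stringsAsFactors = FALSE)
        members[[id]] <<- sort(igraph::V(sub)$name)
        if (!terminal) {
            for (part in kids) {
                child <- igraph::induced_subgraph(sub, part)
                add(child, level + 1L, id, residual = n_triangles(child) == 0L)
            }
        }
        id
    }
    add(net, 0L, NULL, residual = n_triangles(net) == 0L)
    tab <- do.call(rbind, rows[order(names(rows))])
    rownames(tab) <- NULL
    new("CommunityTree", graph = net, table = tab,
        members = members[tab$id])
}

#' Partition of the network at a given level
#'
#' The communities "present" at level \eqn{l}: every tree node at exactly
#' level \eqn{l}, plus terminal leaves from shallower levels carried
#' forward unchanged, so each level is a complete partition of the
#' network's node set and per-level accounting (Hamiltonian energy,
#' pooled metrics) closes exactly.
#'
#' @param tree a [CommunityTree-class].
#' @param level integer in \code{0:treeDepth(tree)}.
#' @return data.frame of the participating communities (rows of
#'   [communityTable()]).
#' @export
levelPartition <- function(tree, level) {
    stopifnot(is(tree, "CommunityTree"))
    tab <- communityTable(tree)
    if (level < 0L || level > max(tab$level))
        stop("level out of range")
    tab[tab$level == level |
        (tab$isTerminal & tab$level < level), , drop = FALSE]
}

#' Constant Potts Model Hamiltonian energy per level
#'
#' Each community contributes \eqn{-(e_c - \gamma_{res} n_c^2)} where
#' \eqn{e_c} and \eqn{n_c} are its edge and node counts and
#' \eqn{\gamma_{res}} is the resolution parameter (default 0.5, acting as
#' an edge-density threshold); the level energy is the exact sum over the
#' level's partition (see [levelPartition()]).
#'
#' @param tree a [CommunityTree-class].
#' @param gammaRes resolution parameter, default 0.5 (must be > 0).
#' @return data.frame: level, he, nCommunities; attribute
#'   \code{"perCommunity"} holds the per-community contributions
#'   (id, level, eC, nC, contribution).
#' @export
hamiltonianEnergy <- function(tree, gammaRes = 0.5) {
    stopifnot(is(tree, "CommunityTree"), gammaRes > 0)
    levels <- 0:treeDepth(tree)
    per <- list()
    out <- lapply(levels, function(l) {
        part <- levelPartition(tree, l)
        contrib <- -(part$nEdges - gammaRes * part$nNodes^2)
        per[[as.character(l)]] <<- data.frame(
            id = part$id, level = l, eC = part$nEdges, nC = part$nNodes,
            contribution = contrib, stringsAsFactors = FALSE)
        data.frame(level = l, he = sum(contrib), nCommunities = nrow(part))
    })
    res <- do.call(rbind, out)
    attr(res, "perCommunity") <- do.call(rbind, per)
    res
}

#' Local-community-paradigm compactness of a network
#'
#' For every edge (u, v), CN is the number of common neighbors of u and v
#' and LCL the number of edges among those common neighbors (the local
#' community links, bounded by \eqn{CN(CN-1)/2}).  The LCP correlation is
#' the Pearson correlation of CN and LCL over the edges with CN > 1; it
#' is undefined (NA, with \code{defined = FALSE}) when fewer than 2 such
#' edges exist or either variable has zero variance.
#'
#' @param net igraph object.
#' @return list: \code{edges} (data.frame from, to, cn, lcl over edges
#'   with cn > 1), \code{lcpCorr} (numeric, NA when undefined),
#'   \code{defined} (logical).
#' @export
lcpCorrelation <- function(net) {
    stopifnot(igraph::is_igraph(net))
    net <- sort_vertices(igraph::simplify(net))
    el <- igraph::as_edgelist(net, names = FALSE)
    nms <- igraph::V(net)$name %||%
        as.character(seq_len(igraph::vcount(net)))
    adj <- igraph::as_adj_list(net)
    adj <- lapply(adj, as.integer)
    A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
    cn <- integer(nrow(el)); lcl <- integer(nrow(el))
    for (i in seq_len(nrow(el))) {
        common <- intersect(adj[[el[i, 1L]]], adj[[el[i, 2L]]])
        cn[i] <- length(common)
        lcl[i] <- if (length(common) > 1L)
            sum(A[common, common]) %/% 2L else 0L
    }
    qual <- cn > 1L
    edges <- data.frame(from = nms[el[qual, 1L]], to = nms[el[qual, 2L]],
                        cn = cn[qual], lcl = lcl[qual],
                        stringsAsFactors = FALSE)
    defined <- nrow(edges) >= 2L && sd(edges$cn) > 0 && sd(edges$lcl) > 0
    list(edges = edges,
         lcpCorr = if (defined) cor(edges$cn, edges$lcl) else NA_real_,
         defined = defined)
}

#' Per-level mean LCP correlation of a community tree
#'
#' Computes [lcpCorrelation()] inside every community of each level's
#' partition and averages the defined values (communities with undefined
#' LCP correlation are excluded from the mean, not counted as zero).
#'
#' @param tree a [CommunityTree-class].
#' @return data.frame: level, meanLcpCorr, nDefined, nCommunities.
#' @export
lcpByLevel <- function(tree) {
    stopifnot(is(tree, "CommunityTree"))
    g <- tree@graph
    do.call(rbind, lapply(0:treeDepth(tree), function(l) {
        part <- levelPartition(tree, l)
        vals <- vapply(part$id, function(id) {
            sub <- igraph::induced_subgraph(g, communityMembers(tree)[[id]])
            lcpCorrelation(sub)$lcpCorr
        }, numeric(1))
        data.frame(level = l,
                   meanLcpCorr = if (any(!is.na(vals)))
                       mean(vals, na.rm = TRUE) else NA_real_,
                   nDefined = sum(!is.na(vals)),
                   nCommunities = nrow(part))
    }))
}
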