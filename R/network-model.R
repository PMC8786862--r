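#' Build an interaction network from a scored pair table
#'
#' Induces the subgraph of a STRING-style scored interaction table on a
#' gene set of interest: rows whose two endpoints are both in \code{keep}
#' and whose score is strictly greater than \code{scoreCut} become edges.
#' Self-loops are dropped; duplicate pairs (in either order) collapse to a
#' single edge carrying the maximum score; genes left without any
#' surviving interaction are excluded, so every node has degree >= 1.
#'
#' @param interactions data.frame with columns \code{gene_a},
#'   \code{gene_b}, and optionally \code{score} in [0, 1] (missing score
#'   column means all rows pass).
#' @param keep character vector of genes to retain (e.g. merged DEGs).
#' @param scoreCut confidence threshold, default 0.40 (exclusive).
#' @return an igraph object with named vertices and edge attribute
#'   \code{score}.
#' @export
buildNetwork <- function(interactions, keep, scoreCut = 0.40) {
    stopifnot(all(c("gene_a", "gene_b") %in% colnames(interactions)))
    a <- as.character(interactions$gene_a)
    b <- as.character(interactions$gene_b)
    score <- if ("score" %in% colnames(interactions))
        as.numeric(interactions$score) else rep(1, length(a))
    if (any(!is.na(score) & (score < 0 | score > 1)))
        stop("interaction scores must lie in [0, 1]")
    ok <- !is.na(score) & score > scoreCut & a != b &
        a %in% keep & b %in% keep
    a <- a[ok]; b <- b[ok]; score <- score[ok]
    if (!length(a))
        stop("no interactions survive the score threshold and gene filter")
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "\r")
    score <- vapply(split(score, key), max, numeric(1))
    pairs <- do.call(rbind, strsplit(names(score), "\r", fixed = TRUE))
    g <- igraph::graph_from_data_frame(
        data.frame(from = pairs[, 1L], to = pairs[, 2L],
                   score = as.numeric(score)),
        directed = FALSE)
    sort_vertices(g)
}

#' Remove genes from a network
#'
#' Deletes the given genes and their incident edges.  Genes not present
#' are ignored with a warning.  Nodes left without any edge by the removal
#' are retained and flagged in the logical vertex attribute
#' \code{isolated}, keeping the node accounting exact:
#' the result has \code{|nodes| - |genes ∩ nodes|} nodes.
#'
#' @param net igraph object with named vertices.
#' @param genes character vector of genes to remove.
#' @return the reduced igraph object.
#' @export
removeNodes <- function(net, genes) {
    stopifnot(igraph::is_igraph(net))
    genes <- unique(as.character(genes))
    absent <- setdiff(genes, igraph::V(net)$name)
    if (length(absent))
        warning("ignoring genes not in the network: ",
                paste(absent, collapse = ", "))
    present <- setdiff(genes, absent)
    if (length(present) == igraph::vcount(net))
        stop("refusing to remove every node of the network")
    g <- igraph::delete_vertices(net, present)
    igraph::set_vertex_attr(g, "isolated", value = igraph::degree(g) == 0L)
}
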