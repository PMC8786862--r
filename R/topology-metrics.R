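#' Node-level topological metrics
#'
#' Computes, per node: degree \eqn{k}; local clustering coefficient
#' \eqn{C = 2e_i / (k_i (k_i - 1))} (0 for degree < 2); betweenness
#' centrality \eqn{C_B(v) = \sum_{i \ne j \ne v} d_{ij}(v)/d_{ij}} counted
#' over unordered pairs, endpoints excluded, unnormalized; closeness
#' \eqn{C_C(i) = n_i / \sum_j d_{ij}} where \eqn{n_i} is the number of
#' nodes reachable from \eqn{i} (per-component; unreachable pairs are
#' excluded); eigenvector centrality as the principal eigenvector of the
#' adjacency matrix of the largest connected component, non-negative and
#' normalized to unit Euclidean norm (nodes outside that component get 0);
#' and neighborhood connectivity \eqn{C_N(i)} = mean degree of \eqn{i}'s
#' neighbors.
#'
#' Only the log-log slopes of these quantities are consumed downstream, so
#' the betweenness normalization convention is immaterial there; it is
#' fixed as above for reproducibility.
#'
#' @param net a non-empty igraph object with named vertices.
#' @return data.frame: node, k, C, CN, CB, CC, CE.
#' @seealso [degreeCurves()] for the degree-indexed averages.
#' @export
computeNodeMetrics <- function(net) {
    stopifnot(igraph::is_igraph(net))
    if (igraph::vcount(net) == 0L) stop("empty network")
    net <- sort_vertices(igraph::simplify(net))
    n <- igraph::vcount(net)
    k <- igraph::degree(net)
    ## clustering: 0 (not NaN) for k < 2
    C <- igraph::transitivity(net, type = "local", isolates = "zero")
    ## neighborhood connectivity: mean neighbor degree; 0 for isolates
    CN <- if (igraph::ecount(net) > 0L) {
        v <- suppressWarnings(igraph::knn(net)$knn)
        v[is.nan(v)] <- 0
        v
    } else rep(0, n)
    CB <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
    ## closeness: reachable-count over summed geodesics, per component
    d <- igraph::distances(net)
    finite <- is.finite(d) & d > 0
    reach <- rowSums(finite)
    d[!finite] <- 0              # unreachable pairs are excluded
    dsum <- rowSums(d)
    CC <- ifelse(dsum > 0, reach / dsum, 0)
    ## eigenvector centrality on the largest component, unit 2-norm
    CE <- rep(0, n)
    if (igraph::ecount(net) == 0L)
        stop("eigenvector centrality undefined for an edgeless graph")
    comp <- igraph::components(net)
    giant <- which(comp$membership == which.max(comp$csize))
    sub <- igraph::induced_subgraph(net, giant)
    A <- as.matrix(igraph::as_adjacency_matrix(sub))
    ev <- eigen(A, symmetric = TRUE)
    v1 <- ev$vectors[, 1L]
    if (sum(v1) < 0) v1 <- -v1
    v1 <- abs(v1)               # Perron vector is non-negative
    CE[giant] <- v1 / sqrt(sum(v1^2))
    data.frame(node = igraph::V(net)$name, k = as.integer(k),
               C = C, CN = CN, CB = CB, CC = CC, CE = CE,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Degree-indexed topology curves
#'
#' Aggregates node metrics per occurring degree \eqn{k}: the degree
#' distribution \eqn{P(k) = n_k / N} and the arithmetic means of C, CN,
#' CB, CC and CE over the \eqn{n_k} nodes of degree exactly \eqn{k}
#' (no log-binning).
#'
#' @param metrics data.frame from [computeNodeMetrics()].
#' @return data.frame keyed by \code{k}: nK, Pk, C, CN, CB, CC, CE;
#'   \code{sum(Pk) == 1}.
#' @export
degreeCurves <- function(metrics) {
    stopifnot(all(c("k", "C", "CN", "CB", "CC", "CE") %in% colnames(metrics)))
    ks <- sort(unique(metrics$k))
    agg <- lapply(ks, function(kk) {
        rows <- metrics[metrics$k == kk, , drop = FALSE]
        data.frame(k = kk, nK = nrow(rows), Pk = nrow(rows) / nrow(metrics),
                   C = mean(rows$C), CN = mean(rows$CN), CB = mean(rows$CB),
                   CC = mean(rows$CC), CE = mean(rows$CE))
    })
    do.call(rbind, agg)
}
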