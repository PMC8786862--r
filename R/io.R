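## Readers/writers for the plain-text interchange formats: expression TSV
## with a sidecar group file, 2/3-column edge lists, SIF, and node tables.

#' Expression matrix I/O
#'
#' The matrix is written as a TSV with gene labels in the first column
#' (header \code{gene}) and sample IDs as the remaining header fields; the
#' group design goes to a two-column sidecar TSV (\code{sample},
#' \code{group}).
#'
#' @param ds an [ExpressionDataset-class].
#' @param path matrix TSV path.
#' @param groupPath sidecar path; defaults to \code{<path>.groups.tsv}.
#' @return \code{writeExpression} returns \code{path} invisibly;
#'   \code{readExpression} returns an [ExpressionDataset-class].
#' @export
writeExpression <- function(ds, path, groupPath = paste0(path, ".groups.tsv")) {
    stopifnot(is(ds, "ExpressionDataset"))
    m <- assay(ds, "log2")
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(
        data.frame(sample = colnames(m),
                   group = as.character(colData(ds)$group)),
        groupPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeExpression
#' @export
readExpression <- function(path, groupPath = paste0(path, ".groups.tsv")) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    grp <- read.delim(groupPath, stringsAsFactors = FALSE)
    ExpressionDataset(m, grp$group[match(colnames(m), grp$sample)])
}

#' Edge-list and SIF graph I/O
#'
#' \code{writeEdgeList}/\code{readEdgeList} use a TSV with columns
#' \code{gene_a}, \code{gene_b} and, when present, \code{score};
#' \code{writeSIF}/\code{readSIF} use the Cytoscape SIF convention
#' \code{"nodeA <relation> nodeB"} (isolated nodes written as bare
#' single-field lines).  Round-trips preserve node and edge sets.
#'
#' @param net igraph object with named vertices.
#' @param path file path.
#' @param relation SIF relation string, default \code{"interacts"}.
#' @return writers return \code{path} invisibly; readers an igraph object.
#' @export
writeEdgeList <- function(net, path) {
    el <- igraph::as_data_frame(net, what = "edges")
    names(el)[1:2] <- c("gene_a", "gene_b")
    write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_a", "gene_b") %in% colnames(df)))
    sort_vertices(igraph::graph_from_data_frame(df, directed = FALSE))
}

#' @rdname writeEdgeList
#' @export
writeSIF <- function(net, path, relation = "interacts") {
    el <- igraph::as_edgelist(net)
    lines <- if (nrow(el))
        paste(el[, 1L], relation, el[, 2L], sep = "\t") else character(0)
    iso <- igraph::V(net)$name[igraph::degree(net) == 0L]
    writeLines(c(lines, iso), path)
    invisible(path)
}

#' @rdname writeEdgeList
#' @export
readSIF <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "[\t ]+")
    edges <- do.call(rbind, lapply(parts[lengths(parts) >= 3L],
                                   function(p) p[c(1L, 3L)]))
    singles <- unlist(lapply(parts[lengths(parts) == 1L], `[[`, 1L))
    g <- igraph::make_empty_graph(directed = FALSE) +
        igraph::vertices(unique(c(as.vector(t(edges)), singles)))
    if (!is.null(edges))
        g <- igraph::add_edges(g, as.vector(t(edges)))
    sort_vertices(igraph::simplify(g))
}

#' Write a node-attribute table
#'
#' @param df data.frame keyed by a \code{node} column.
#' @param path TSV path.
#' @return \code{path}, invisibly.
#' @export
writeNodeTable <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
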