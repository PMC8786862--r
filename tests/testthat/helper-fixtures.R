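# graph fixtures built in code; labels sorted so vertex order is stable

two_k4 <- function() {
    makeGraph(syntheticSpec(graphModel = "two_clique",
                            graphParams = list(m = 4), seed = 1))
}

named_full_graph <- function(n) {
    g <- igraph::make_full_graph(n)
    igraph::V(g)$name <- sprintf("g%02d", seq_len(n))
    g
}

named_path_graph <- function(labels) {
    g <- igraph::make_ring(length(labels), circular = FALSE)
    igraph::V(g)$name <- labels
    g
}

named_star_graph <- function(n_leaves) {
    g <- igraph::make_star(n_leaves + 1L, mode = "undirected", center = 1)
    igraph::V(g)$name <- c("hub", sprintf("leaf%02d", seq_len(n_leaves)))
    g
}

# G(n, p) with stable labels, at least one edge
random_named_gnp <- function(n, p, seed) {
    g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
    igraph::V(g)$name <- sprintf("g%02d", seq_len(n))
    if (igraph::ecount(g) == 0L)
        g <- igraph::add_edges(g, c(1L, 2L))
    g
}

hier_fixture <- function(depth, nonmotif = 0L, seed = 1L) {
    makeGraph(syntheticSpec(
        graphModel = "hierarchical_triangle",
        graphParams = list(depth = depth, nonmotifLeaves = nonmotif),
        seed = seed))
}

# K4 on a..d plus a fifth node adjacent to a, b, c
k4_plus_one <- function() {
    g <- igraph::graph_from_literal(a - b, a - c, a - d, b - c, b - d,
                                    c - d, e - a, e - b, e - c)
    sorted <- igraph::permute(g, match(igraph::V(g)$name,
                                       sort(igraph::V(g)$name)))
    sorted
}

# align vertex order with the package's sorted-label convention
sort_vertices_for_test <- function(g) {
    igraph::permute(g, match(igraph::V(g)$name, sort(igraph::V(g)$name)))
}
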