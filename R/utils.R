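## internal helpers

## evaluate expr under an explicit seed without touching global RNG state
with_explicit_seed <- function(seed, expr) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), expr)
}

## deterministic sorted-label vertex order; all graph code funnels through
## this so eigenvector sign conventions and tie-breaks are reproducible
sort_vertices <- function(g) {
    nm <- igraph::V(g)$name
    if (is.null(nm)) return(g)   # unnamed: keep creation order
    igraph::permute(g, match(nm, sort(nm)))
}

## count of triangles in a graph (total, not per vertex)
n_triangles <- function(g) {
    if (igraph::vcount(g) < 3L) return(0L)
    sum(igraph::count_triangles(g)) %/% 3L
}

is_motif_graph <- function(g) {
    igraph::vcount(g) == 3L && igraph::ecount(g) == 3L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
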