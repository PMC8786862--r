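# Independent brute-force oracles: hand-rolled BFS, exhaustive shortest-path
# enumeration, power iteration, exhaustive modularity search.  These share no
# code path with the package implementation.

oracle_adjacency <- function(g) {
    n <- igraph::vcount(g)
    A <- matrix(0L, n, n)
    el <- igraph::as_edgelist(g, names = FALSE)
    for (i in seq_len(nrow(el))) {
        A[el[i, 1L], el[i, 2L]] <- 1L
        A[el[i, 2L], el[i, 1L]] <- 1L
    }
    A
}

# all-pairs shortest-path lengths by BFS from each source
oracle_distances <- function(A) {
    n <- nrow(A)
    D <- matrix(Inf, n, n)
    for (s in seq_len(n)) {
        D[s, s] <- 0
        frontier <- s
        d <- 0
        while (length(frontier)) {
            d <- d + 1
            nxt <- integer(0)
            for (v in frontier)
                for (w in which(A[v, ] == 1L))
                    if (D[s, w] > d) { D[s, w] <- d; nxt <- c(nxt, w) }
            frontier <- unique(nxt)
        }
    }
    D
}

# enumerate every shortest path between each unordered pair; count per-path
# interior vertices for betweenness
oracle_betweenness <- function(A) {
    n <- nrow(A)
    D <- oracle_distances(A)
    CB <- numeric(n)
    paths_between <- function(i, j) {
        # returns list of vertex sequences, each a shortest i->j path
        if (i == j) return(list(i))
        out <- list()
        for (w in which(A[i, ] == 1L)) {
            if (is.finite(D[w, j]) && D[w, j] == D[i, j] - 1) {
                for (pp in paths_between(w, j)) out <- c(out, list(c(i, pp)))
            }
        }
        out
    }
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        if (!is.finite(D[i, j])) next
        ps <- paths_between(i, j)
        sigma <- length(ps)
        interior <- unlist(lapply(ps, function(p) p[-c(1L, length(p))]))
        if (length(interior)) {
            tab <- table(interior)
            idx <- as.integer(names(tab))
            CB[idx] <- CB[idx] + as.numeric(tab) / sigma
        }
    }
    CB
}

oracle_metrics <- function(g) {
    A <- oracle_adjacency(g)
    n <- nrow(A)
    k <- rowSums(A)
    # clustering
    C <- numeric(n)
    for (i in seq_len(n)) {
        nb <- which(A[i, ] == 1L)
        if (length(nb) >= 2L)
            C[i] <- sum(A[nb, nb]) / (length(nb) * (length(nb) - 1L))
    }
    # neighborhood connectivity
    CN <- numeric(n)
    for (i in seq_len(n)) {
        nb <- which(A[i, ] == 1L)
        if (length(nb)) CN[i] <- mean(k[nb])
    }
    D <- oracle_distances(A)
    reach <- rowSums(is.finite(D) & D > 0)
    dsum <- rowSums(ifelse(is.finite(D), D, 0))
    CC <- ifelse(dsum > 0, reach / dsum, 0)
    CB <- oracle_betweenness(A)
    # eigenvector centrality: power iteration on the largest component
    comp <- rep(0L, n); cid <- 0L
    for (s in seq_len(n)) {
        if (comp[s] != 0L) next
        cid <- cid + 1L
        frontier <- s; comp[s] <- cid
        while (length(frontier)) {
            nxt <- integer(0)
            for (v in frontier) for (w in which(A[v, ] == 1L))
                if (comp[w] == 0L) { comp[w] <- cid; nxt <- c(nxt, w) }
            frontier <- nxt
        }
    }
    sizes <- tabulate(comp)
    giant <- which(comp == which.max(sizes))
    CE <- numeric(n)
    if (sum(A) > 0) {
        ## iterate on A + I: same Perron vector, converges on bipartite too
        Ag <- A[giant, giant, drop = FALSE] + diag(length(giant))
        v <- rep(1, length(giant))
        for (it in seq_len(100000L)) {
            v2 <- as.numeric(Ag %*% v)
            v2 <- v2 / sqrt(sum(v2^2))
            if (max(abs(v2 - v)) < 1e-14) { v <- v2; break }
            v <- v2
        }
        CE[giant] <- abs(v)
    }
    data.frame(node = igraph::V(g)$name, k = as.integer(k), C = C, CN = CN,
               CB = CB, CC = CC, CE = CE, stringsAsFactors = FALSE)
}

# exhaustive max-modularity bipartition: returns list(q, parts) with parts
# a list of two label vectors (NULL when no bipartition has q > 0)
oracle_best_bipartition <- function(g) {
    A <- oracle_adjacency(g)
    n <- nrow(A)
    k <- rowSums(A); m <- sum(A) / 2
    B <- A - outer(k, k) / (2 * m)
    best_q <- 0; best <- NULL
    for (mask in seq_len(2^(n - 1L) - 1L)) {
        s <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0, 1, -1)
        q <- as.numeric(t(s) %*% B %*% s) / (4 * m)
        if (q > best_q + 1e-12) {
            best_q <- q
            best <- list(igraph::V(g)$name[s > 0], igraph::V(g)$name[s < 0])
        }
    }
    list(q = best_q, parts = best)
}

# per-edge common-neighbor / local-community-link enumeration
oracle_lcp <- function(g) {
    A <- oracle_adjacency(g)
    el <- igraph::as_edgelist(g, names = FALSE)
    cn <- integer(nrow(el)); lcl <- integer(nrow(el))
    for (i in seq_len(nrow(el))) {
        u <- el[i, 1L]; v <- el[i, 2L]
        common <- which(A[u, ] == 1L & A[v, ] == 1L)
        cn[i] <- length(common)
        cnt <- 0L
        if (length(common) > 1L)
            for (a in common) for (b in common)
                if (a < b && A[a, b] == 1L) cnt <- cnt + 1L
        lcl[i] <- cnt
    }
    keep <- cn > 1L
    list(cn = cn, lcl = lcl,
         corr = if (sum(keep) >= 2L && sd(cn[keep]) > 0 && sd(lcl[keep]) > 0)
             cor(cn[keep], lcl[keep]) else NA_real_)
}

# upper-tail hypergeometric by direct enumeration of dhyper masses
oracle_ease_p <- function(n_study, n_hits, n_term, n_bg) {
    a <- n_hits - 1L
    if (a <= 0L) return(1)
    xs <- seq.int(a, min(n_term, n_study))
    sum(stats::dhyper(xs, n_term, n_bg - n_term, n_study))
}
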