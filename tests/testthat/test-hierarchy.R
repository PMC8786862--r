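test_that("leading-eigenvector split matches the exhaustive modularity oracle", {
    g <- two_k4()
    got <- levSplit(g)
    want <- oracle_best_bipartition(g)
    expect_false(is.null(got))
    expect_setequal(got[[1L]], want$parts[[1L]])
    expect_setequal(got[[2L]], want$parts[[2L]])
    ## the split severs the single bridge into the two cliques
    expect_equal(lengths(got), c(4L, 4L))
})

test_that("graphs with no positive-modularity bipartition yield no-split", {
    expect_null(levSplit(named_full_graph(5)))
    expect_equal(oracle_best_bipartition(named_full_graph(5))$q, 0)
    expect_null(levSplit(named_path_graph(c("a", "b"))))
    one <- igraph::make_empty_graph(1, directed = FALSE)
    igraph::V(one)$name <- "a"
    expect_null(levSplit(one))
})

test_that("split modularity is positive on random splittable graphs", {
    for (s in 1:10) {
        g <- random_named_gnp(10, 0.3, seed = 400 + s)
        got <- levSplit(g)
        want <- oracle_best_bipartition(g)
        if (!is.null(got)) {
            ## recompute Q of the returned split against the oracle matrix
            A <- oracle_adjacency(sort_vertices_for_test(g))
            k <- rowSums(A); m <- sum(A) / 2
            B <- A - outer(k, k) / (2 * m)
            nm <- sort(igraph::V(g)$name)
            sv <- ifelse(nm %in% got[[1L]], 1, -1)
            q <- as.numeric(t(sv) %*% B %*% sv) / (4 * m)
            expect_gt(q, 0)
            expect_lte(q, want$q + 1e-12)
        }
    }
})

test_that("decomposition partitions parents and stops at motifs", {
    h <- hier_fixture(2)
    tr <- decomposeNetwork(h)
    expect_true(validObject(tr))
    tab <- communityTable(tr)
    expect_true(all(tab$isMotif[tab$isTerminal]))
    expect_gte(treeDepth(tr), 2L)

    ## single triangle: level-0 community is itself the terminal motif
    t0 <- decomposeNetwork(hier_fixture(0))
    tab0 <- communityTable(t0)
    expect_equal(nrow(tab0), 1L)
    expect_true(tab0$isMotif & tab0$isTerminal)
    expect_equal(treeDepth(t0), 0L)
})

test_that("sparse random graphs decompose with triangle-gated communities", {
    g <- random_named_gnp(30, 0.05, seed = 77)
    tr <- decomposeNetwork(g, maxLevel = 6L)
    tab <- communityTable(tr)
    expect_lte(treeDepth(tr), 6L)
    for (i in seq_len(nrow(tab))) {
        sub <- igraph::induced_subgraph(
            tr@graph, communityMembers(tr)[[tab$id[i]]])
        if (!tab$isResidual[i] && tab$level[i] > 0L)
            expect_gte(sum(igraph::count_triangles(sub)), 3L)
        if (tab$isResidual[i])
            expect_equal(sum(igraph::count_triangles(sub)), 0L)
    }
    ## children partition each parent exactly (validity already enforces it)
    expect_true(validObject(tr))
})

test_that("Hamiltonian contributions follow the Potts formula", {
    ## single triangle: -(3 - 0.5 * 9) = +1.5
    expect_equal(hamiltonianEnergy(decomposeNetwork(hier_fixture(0)))$he, 1.5)
    ## K4 as one community: -(6 - 0.5 * 16) = +2
    k4 <- named_full_graph(4)
    he_k4 <- hamiltonianEnergy(decomposeNetwork(k4))
    expect_equal(he_k4$he[he_k4$level == 0L], 2)
    ## two-K4: level 0 as one community -(13 - 32) = 19; split cliques 2 + 2
    tr <- decomposeNetwork(two_k4())
    he <- hamiltonianEnergy(tr)
    expect_equal(he$he[he$level == 0L], 19)
    expect_equal(he$he[he$level == 1L], 4)
    ## additivity: level energy = sum of per-community contributions
    per <- attr(he, "perCommunity")
    for (l in he$level)
        expect_equal(sum(per$contribution[per$level == l]),
                     he$he[he$level == l])
})

test_that("Hamiltonian energy decreases with depth on hierarchical fixtures", {
    for (depth in 2:4) {
        he <- hamiltonianEnergy(decomposeNetwork(hier_fixture(depth)))
        expect_true(all(diff(he$he) < 0))
    }
})

test_that("gammaRes is configurable and must be positive", {
    tr <- decomposeNetwork(hier_fixture(0))
    expect_equal(hamiltonianEnergy(tr, gammaRes = 1)$he, -(3 - 9))
    expect_error(hamiltonianEnergy(tr, gammaRes = 0))
})

test_that("LCP matches exhaustive enumeration and flags degenerate cases", {
    ## K4: all edges CN = 2, LCL = 1 -> zero variance -> undefined
    r <- lcpCorrelation(named_full_graph(4))
    expect_false(r$defined)
    expect_true(is.na(r$lcpCorr))
    expect_true(all(r$edges$cn == 2L & r$edges$lcl == 1L))

    g <- k4_plus_one()
    got <- lcpCorrelation(g)
    want <- oracle_lcp(g)
    keep <- want$cn > 1L
    expect_setequal(paste(got$edges$cn, got$edges$lcl),
                    paste(want$cn[keep], want$lcl[keep]))
    expect_equal(got$lcpCorr, want$corr)

    for (s in 1:15) {
        g <- random_named_gnp(8 + s %% 7, 0.45, seed = 500 + s)
        got <- lcpCorrelation(g)
        want <- oracle_lcp(g)
        expect_equal(sort(got$edges$cn), sort(want$cn[want$cn > 1L]))
        expect_equal(sort(got$edges$lcl), sort(want$lcl[want$cn > 1L]))
        expect_equal(got$lcpCorr, want$corr, tolerance = 1e-12)
        ## LCL bound
        expect_true(all(got$edges$lcl <= choose(got$edges$cn, 2)))
        if (got$defined)
            expect_true(got$lcpCorr >= -1 && got$lcpCorr <= 1)
    }
})

test_that("perfectly linear LCL = CN - 1 gives correlation one", {
    ## chain of overlapping cliques gives varying CN with LCL tracking it
    g <- igraph::graph_from_literal(
        a - b, a - c, b - c,            # CN(a,b) varies with clique size
        a - d, b - d, c - d,
        a - e, b - e, c - e, d - e)
    igraph::V(g)$name <- igraph::V(g)$name
    r <- lcpCorrelation(g)
    ## K5: every edge has CN = 3, LCL = 3 -> zero variance, undefined
    expect_false(r$defined)

    ## build explicit fixture: two triangles sharing an edge plus a K4
    ## sharing an edge -> qualifying edges with (CN, LCL) = (2,1) and (3,2)?
    g2 <- igraph::graph_from_literal(
        a - b, a - c, b - c, a - d, b - d,         # shared edge a-b: CN 2
        p - q, p - r, q - r, p - s, q - s, r - s,  # K4: edges CN 2, LCL 1
        a - p)
    r2 <- lcpCorrelation(g2)
    ## check against the oracle rather than hand-derived values
    want2 <- oracle_lcp(g2)
    expect_equal(r2$lcpCorr, want2$corr)
})

test_that("per-level LCP averages skip undefined communities", {
    tr <- decomposeNetwork(hier_fixture(2))
    out <- lcpByLevel(tr)
    ## terminal triangles have no CN>1 edge: undefined, excluded
    expect_equal(out$nDefined[out$level == treeDepth(tr)], 0L)
    expect_true(is.na(out$meanLcpCorr[out$level == treeDepth(tr)]))
    expect_equal(out$nCommunities, levels_sizes <- vapply(
        0:treeDepth(tr), function(l) nrow(levelPartition(tr, l)), integer(1)))
})

test_that("level partitions carry terminal leaves forward and close accounting", {
    h <- hier_fixture(3, nonmotif = 1L)
    tr <- decomposeNetwork(h)
    n_total <- igraph::vcount(h)
    for (l in 0:treeDepth(tr)) {
        part <- levelPartition(tr, l)
        nodes <- unlist(communityMembers(tr)[part$id], use.names = FALSE)
        expect_equal(sort(nodes), sort(igraph::V(h)$name))
        expect_equal(sum(part$nNodes), n_total)
    }
    expect_error(levelPartition(tr, treeDepth(tr) + 1L), "range")
})
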