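test_that("hub ranking sorts by degree with deterministic tie order", {
    star <- named_star_graph(5)
    hubs <- rankHubs(star, top = 3)
    expect_identical(hubs$gene[1L], "hub")
    expect_equal(hubs$degree[1L], 5L)

    k4 <- named_full_graph(4)
    t4 <- rankHubs(k4, top = 4)
    expect_identical(t4$gene, sort(igraph::V(k4)$name))  # ties by label
    expect_identical(t4$rank, 1:4)

    expect_warning(all5 <- rankHubs(k4, top = 10), "node count")
    expect_equal(nrow(all5), 4L)

    ## sort oracle on a preferential-attachment fixture
    g <- makeGraph(syntheticSpec(graphModel = "scale_free",
        graphParams = list(n = 200, m = 2), seed = 4))
    hubs <- rankHubs(g, top = 50)
    deg <- igraph::degree(g)
    want <- names(deg)[order(-deg, names(deg))][1:50]
    expect_identical(hubs$gene, want)
    expect_true(all(diff(hubs$degree) <= 0))
})

test_that("planted deep regulators are recovered exactly, stars are not", {
    h <- hier_fixture(3, nonmotif = 2L, seed = 1)
    tr <- decomposeNetwork(h)
    tab <- communityTable(tr)
    motif_nodes <- unname(unlist(communityMembers(tr)[tab$id[tab$isMotif]]))
    h <- plantRegulator(h, motif_nodes[1:3])

    trace <- traceKeyRegulators(tr)
    s <- traceSummary(trace)
    ## exact recovery: KR flags iff terminal community is a motif
    expect_setequal(s$gene[s$isKR], motif_nodes)
    expect_true(all(plantedRegulators(h) %in% s$gene[s$isKR]))
    ## star-leaf nodes (triangle-free residuals) are never flagged
    star_nodes <- setdiff(igraph::V(h)$name, motif_nodes)
    expect_false(any(s$isKR[s$gene %in% star_nodes]))
    expect_true(all(s$terminalKind[s$gene %in% star_nodes] == "residual"))
})

test_that("motif-level regulator probability is exactly 2/3", {
    tr <- decomposeNetwork(hier_fixture(2))
    trace <- traceKeyRegulators(tr)
    st <- traceSteps(trace)
    expect_true(all(abs(st$pY[st$isMotif] - 2 / 3) < 1e-12))
    s <- traceSummary(trace)
    expect_true(all(st$pY > 0 & st$pY <= 1))
    ## trace paths are root-to-leaf: length = terminal level + 1
    for (g in s$gene[s$isKR]) {
        p <- regulatorProbability(trace, g)
        expect_equal(length(p), s$terminalLevel[s$gene == g] + 1L)
        expect_true(all(diff(p) >= -1e-12))      # non-decreasing with depth
    }
})

test_that("traces are consistent with the tree and single-triangle networks are all-KR", {
    tr <- decomposeNetwork(hier_fixture(0))
    s <- traceSummary(traceKeyRegulators(tr))
    expect_equal(nrow(s), 3L)
    expect_true(all(s$isKR))
    expect_true(all(s$terminalLevel == 0L))

    tr2 <- decomposeNetwork(hier_fixture(2))
    trace2 <- traceKeyRegulators(tr2)
    st2 <- traceSteps(trace2)
    mem <- communityMembers(tr2)
    ## child membership nested in parent membership along every path
    for (g in unique(st2$gene)) {
        path <- st2$community[st2$gene == g]
        for (i in seq_along(path)[-1L])
            expect_true(all(mem[[path[i]]] %in% mem[[path[i - 1L]]]))
    }
    expect_warning(traceKeyRegulators(tr2, c("g1", "nope")), "nope")
})

test_that("regulator probability follows x/E on explicit communities", {
    st <- data.frame(gene = "z", level = 0L, community = "c0001",
                     x = 5L, E = 50L, pY = 5 / 50, isMotif = FALSE)
    tr <- new("RegulatorTraceSet", steps = st,
              summary = data.frame(gene = "z", terminalLevel = 0L,
                  terminalCommunity = "c0001",
                  terminalKind = "nonmotif_terminal",
                  isKR = FALSE, deepNotKR = TRUE))
    expect_equal(unname(regulatorProbability(tr, "z")), 0.1)
    expect_error(regulatorProbability(tr, "missing"), "not present")
})

test_that("knockout accounting is exact and matches closed-form energy", {
    g <- two_k4()
    ko <- suppressWarnings(knockoutExperiment(g, "g1"))
    expect_equal(ko@nodeDelta, 1L)
    expect_equal(ko@edgeDelta, 4L)     # clique degree 3 + bridge
    ## closed form at level 0: 8 nodes 13 edges -> 7 nodes 9 edges
    ## HE 19 -> -(9 - 0.5*49) = 15.5
    expect_equal(ko@he$heOriginal[ko@he$level == 0L], 19)
    expect_equal(ko@he$heKnockout[ko@he$level == 0L], 15.5)
    expect_equal(ko@he$deltaHE[ko@he$level == 0L], 3.5)

    expect_error(knockoutExperiment(g, character(0)), "non-empty")
    w <- capture_warnings(ko2 <- knockoutExperiment(g, "absent"))
    expect_match(w, "no theta gene", all = FALSE)
    expect_equal(ko2@nodeDelta, 0L)
    expect_equal(ko2@he$deltaHE, rep(0, nrow(ko2@he)))
})

test_that("sequential knockout records intermediate energies", {
    g <- hier_fixture(2)
    ko <- suppressWarnings(
        knockoutExperiment(g, c("g1", "g4"), mode = "sequential"))
    seq_tab <- attr(ko@he, "sequential")
    expect_equal(nrow(seq_tab), 2L)
    expect_identical(seq_tab$removed, c("g1", "g4"))
    ## the final sequential energy equals the set-mode knockout energy
    expect_equal(seq_tab$heLevel0[2L],
                 ko@he$heKnockout[ko@he$level == 0L])
})

test_that("hub knockout perturbs the degree exponent more than leaf knockout", {
    hits <- vapply(1:20, function(s) {
        g <- makeGraph(syntheticSpec(graphModel = "scale_free",
            graphParams = list(n = 600, m = 2), seed = 900 + s))
        deg <- igraph::degree(g)
        hubs <- names(sort(deg, decreasing = TRUE))[1:3]
        leaves <- names(sort(deg))[1:3]
        g0 <- fitDegreeDistribution(deg, nBoot = 0)@exponent
        gh <- fitDegreeDistribution(
            igraph::degree(removeNodes(g, hubs)), nBoot = 0)@exponent
        gl <- fitDegreeDistribution(
            igraph::degree(removeNodes(g, leaves)), nBoot = 0)@exponent
        abs(gh - g0) > abs(gl - g0)
    }, logical(1))
    expect_gte(mean(hits), 0.8)
})
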