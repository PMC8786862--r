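test_that("a strongly planted gene is called with the right direction", {
    ds <- makeExpression(syntheticSpec(nGenes = 200,
        plantedEffects = c(g3 = 2, g7 = -2), noiseSd = 0.01, seed = 2))
    degs <- screenDEGs(ds)
    expect_setequal(degs$gene, c("g3", "g7"))
    expect_equal(degs$logFC[degs$gene == "g3"], 2, tolerance = 0.05)
    expect_identical(degs$direction[degs$gene == "g3"], "up")
    expect_identical(degs$direction[degs$gene == "g7"], "down")
    expect_lt(max(degs$p), 1e-6)
})

test_that("sub-threshold fold changes are never emitted, however significant", {
    ds <- makeExpression(syntheticSpec(nGenes = 100,
        plantedEffects = c(g1 = 0.5), noiseSd = 0.01, seed = 4))
    degs <- screenDEGs(ds)
    expect_false("g1" %in% degs$gene)
    ## the gene is highly significant, only the fold-change cut stops it
    stats <- degStats(ds)
    expect_lt(stats$p[stats$gene == "g1"], 1e-6)
})

test_that("every emitted record satisfies both cut-offs", {
    for (s in 1:5) {
        ds <- makeExpression(syntheticSpec(nGenes = 500, noiseSd = 1.2,
            plantedEffects = setNames(rnorm(10, 0, 2), paste0("g", 1:10)),
            seed = s))
        degs <- screenDEGs(ds)
        if (nrow(degs)) {
            expect_true(all(abs(degs$logFC) >= 1))
            expect_true(all(degs$p < 0.05))
        }
    }
})

test_that("degenerate variance cases are handled", {
    m <- rbind(flat = rep(5, 8), shift = rep(c(1, 3), each = 4))
    colnames(m) <- paste0("s", 1:8)
    ds <- ExpressionDataset(m, rep(c("control", "case"), each = 4))
    st <- degStats(ds)
    expect_equal(st$p[st$gene == "flat"], 1)     # no variance, no difference
    expect_equal(st$p[st$gene == "shift"], 0)    # no variance, pure shift
    ds1 <- ExpressionDataset(m[, 1:3], c("control", "control", "case"))
    expect_error(degStats(ds1), "2 samples per group")
})

test_that("merging unions per direction and resolves conflicts by max |logFC|", {
    mk <- function(gene, lfc) data.frame(gene = gene, logFC = lfc,
        p = 1e-4, padjBH = 1e-3,
        direction = ifelse(lfc > 0, "up", "down"),
        stringsAsFactors = FALSE)
    ds1 <- rbind(mk("A", 1.5), mk("B", 2), mk("X", 1.2))
    ds2 <- rbind(mk("B", 1.1), mk("C", 3), mk("D", -2), mk("X", -2.1))
    merged <- mergeDEGs(list(one = ds1, two = ds2))
    expect_setequal(merged$up, c("A", "B", "C"))
    expect_setequal(merged$down, c("D", "X"))     # |-2.1| beats |1.2|
    expect_identical(merged$conflicts, "X")
    expect_length(intersect(merged$up, merged$down), 0)

    single <- mergeDEGs(list(only = ds1))
    expect_setequal(single$up, c("A", "B", "X"))
    expect_identical(single$down, character(0))
})

test_that("EASE p-values match exhaustive hypergeometric enumeration", {
    bg <- paste0("g", 1:1000)
    term <- paste0("g", 1:40)
    study <- c(paste0("g", 1:3), paste0("g", 500:506))   # 3 hits of 10
    expect_equal(easeTest(study, term, bg),
                 oracle_ease_p(10L, 3L, 40L, 1000L))
    ## penalized-out single hit
    expect_equal(easeTest(c("g1", paste0("g", 900:908)), term, bg), 1)
    ## degenerate: study = term = background
    expect_equal(easeTest(bg, bg, bg), oracle_ease_p(1000L, 1000L, 1000L, 1000L))
    expect_equal(easeTest(bg, bg, bg), 1)
    expect_error(easeTest("a", "a", character(0)), "background")
    expect_error(easeTest("zz", "g1", bg), "subset")
})

test_that("EASE p is monotone non-increasing in the hit count", {
    bg <- paste0("g", 1:500)
    term <- paste0("g", 1:50)
    ## study of size 20 with 2..20 hits
    p <- vapply(2:20, function(h) {
        filler <- if (h < 20L) paste0("g", 400L + seq_len(20L - h))
                  else character(0)
        easeTest(c(paste0("g", seq_len(h)), filler), term, bg)
    }, numeric(1))
    expect_true(all(diff(p) <= 1e-12))
    expect_true(all(p > 0 & p <= 1))
})

test_that("probe collapsing averages log2 values per gene and drops unannotated", {
    m <- matrix(1:12, nrow = 4,
                dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
    genes <- c("B", "A", "B", NA)
    out <- collapseProbes(m, genes)
    expect_identical(rownames(out), c("A", "B"))
    expect_equal(out["B", ], colMeans(m[c(1, 3), ]))
    expect_equal(out["A", ], m[2, ])
})
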