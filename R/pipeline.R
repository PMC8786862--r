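#' Pipeline configuration
#'
#' Collects the thresholds, seeds and input paths of the end-to-end run.
#' Defaults are the field-standard values used throughout the package:
#' |log2 fold change| >= 1, p < 0.05, interaction score > 0.40,
#' 2500 bootstrap resamples, CPM resolution 0.5, top-100 hub table.  The
#' config is echoed verbatim into every JSON report for provenance.
#'
#' @param expressionPaths character vector of expression matrix TSVs (one
#'   per dataset, each with a \code{<path>.groups.tsv} sidecar); may be
#'   empty when \code{geneList} is supplied.
#' @param interactionsPath scored interaction TSV (gene_a, gene_b, score).
#' @param geneList optional character vector of genes to keep, bypassing
#'   the DEG stage (edge-list-only mode).
#' @param outDir output directory (created if needed).
#' @param lfcCut,pCut DEG cut-offs.
#' @param scoreCut interaction-score threshold.
#' @param nBoot bootstrap resamples for the degree-distribution fit.
#' @param gammaRes CPM resolution parameter.
#' @param topHubs hub-table size.
#' @param maxLevel decomposition depth cap.
#' @param knockout optional character vector: genes to knock out.
#' @param seed RNG seed for all stochastic stages.
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(expressionPaths = character(0),
                           interactionsPath, geneList = NULL,
                           outDir = tempfile("keyregnet_run_"),
                           lfcCut = 1, pCut = 0.05, scoreCut = 0.40,
                           nBoot = 2500L, gammaRes = 0.5, topHubs = 100L,
                           maxLevel = 10L, knockout = NULL, seed = 1L) {
    cfg <- list(expressionPaths = expressionPaths,
                interactionsPath = interactionsPath, geneList = geneList,
                outDir = outDir, lfcCut = lfcCut, pCut = pCut,
                scoreCut = scoreCut, nBoot = as.integer(nBoot),
                gammaRes = gammaRes, topHubs = as.integer(topHubs),
                maxLevel = as.integer(maxLevel), knockout = knockout,
                seed = as.integer(seed))
    class(cfg) <- "PipelineConfig"
    cfg
}

cfg_echo <- function(cfg) {
    cfg$geneList <- NULL      # potentially huge; files carry it
    unclass(cfg)
}

stage_fail <- function(stage, e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
}

#' Run the full key-regulator pipeline
#'
#' Stages, in order: (1) DEG screening of every expression dataset and
#' merge (skipped in edge-list-only mode); (2) network construction from
#' the scored interaction table restricted to the kept genes; (3) node
#' metrics, degree curves and the six exponent fits with bootstrap
#' validation of P(k); (4) recursive leading-eigenvector decomposition;
#' (5) Hamiltonian-energy and LCP accounting per level; (6) hub ranking
#' and key-regulator tracing; (7) optional knockout experiment.  Every
#' stage writes its artifacts (TSV tables, JSON reports embedding the
#' config) into \code{cfg$outDir} and logs in/out gene counts; reruns
#' with the same config and inputs are byte-identical.
#'
#' @param cfg a [pipelineConfig()].
#' @param quiet suppress stage log messages.
#' @return (invisibly) a list with the main in-memory results: degs,
#'   network, metrics, curves, exponentSet, labels, tree, he, lcp, hubs,
#'   trace, knockout (NULL when not requested), outDir.
#' @export
runPipeline <- function(cfg, quiet = FALSE) {
    stopifnot(inherits(cfg, "PipelineConfig"))
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    say <- function(...) if (!quiet) message(sprintf(...))
    out <- function(f) file.path(cfg$outDir, f)
    jwrite <- function(x, f)
        write_json(c(x, list(config = cfg_echo(cfg))), out(f),
                   auto_unbox = TRUE, digits = NA, pretty = TRUE)

    ## stage 1: DEGs
    degs <- NULL
    keep <- cfg$geneList
    if (length(cfg$expressionPaths)) {
        degs <- tryCatch({
            per <- lapply(cfg$expressionPaths, function(p) {
                ds <- readExpression(p)
                screenDEGs(ds, cfg$lfcCut, cfg$pCut)
            })
            names(per) <- basename(cfg$expressionPaths)
            mergeDEGs(per)
        }, error = function(e) stage_fail("deg", e))
        keep <- unique(c(keep, degs$up, degs$down))
        say("deg: %d datasets -> %d up / %d down (%d conflicts)",
            length(cfg$expressionPaths), length(degs$up),
            length(degs$down), length(degs$conflicts))
        write.table(degs$records, out("deg_records.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        jwrite(list(up = degs$up, down = degs$down,
                    conflicts = degs$conflicts), "deg_summary.json")
    }
    if (is.null(keep) || !length(keep))
        stop("[stage deg] no genes to keep: supply expression data or geneList")

    ## stage 2: network
    net <- tryCatch({
        interactions <- read.delim(cfg$interactionsPath,
                                   stringsAsFactors = FALSE)
        buildNetwork(interactions, keep, cfg$scoreCut)
    }, error = function(e) stage_fail("net", e))
    say("net: %d kept genes -> %d nodes / %d edges", length(keep),
        igraph::vcount(net), igraph::ecount(net))
    writeEdgeList(net, out("network_edges.tsv"))
    writeSIF(net, out("network.sif"))

    ## stage 3: topology + fits
    res <- tryCatch({
        metrics <- computeNodeMetrics(net)
        curves <- degreeCurves(metrics)
        es <- fitAllExponents(net, curves = curves, gammaMethod = "mle",
                              nBoot = cfg$nBoot, seed = cfg$seed,
                              degrees = as.integer(igraph::degree(net)))
        list(metrics = metrics, curves = curves, es = es)
    }, error = function(e) stage_fail("topo", e))
    labels <- classifyNetwork(res$es)
    say("topo: gamma = %.3f, labels = {%s}",
        exponents(res$es)[["gamma"]], paste(labels, collapse = ", "))
    writeNodeTable(res$metrics, out("node_metrics.tsv"))
    write.table(res$curves, out("degree_curves.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    gfit <- res$es@fits$gamma
    jwrite(list(
        exponents = as.list(exponents(res$es)), labels = labels,
        gammaFit = list(xmin = gfit@xmin, ks = gfit@ks,
                        bootstrapP = gfit@bootstrapP, nBoot = gfit@nBoot,
                        nTail = gfit@nTail, seed = gfit@seed)),
        "exponents.json")

    ## stages 4-5: decomposition + energy/compactness
    tree <- tryCatch(decomposeNetwork(net, cfg$maxLevel),
                     error = function(e) stage_fail("decompose", e))
    he <- hamiltonianEnergy(tree, cfg$gammaRes)
    lcp <- lcpByLevel(tree)
    say("decompose: depth %d, %d motifs", treeDepth(tree),
        sum(communityTable(tree)$isMotif))
    tt <- communityTable(tree)
    jwrite(list(tree = lapply(seq_len(nrow(tt)), function(i) c(
        as.list(tt[i, ]), list(nodes = communityMembers(tree)[[tt$id[i]]])))),
        "community_tree.json")
    write.table(merge(he, lcp, by = "level"), out("levels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    ## stage 6: hubs + tracing
    hubs <- rankHubs(net, min(cfg$topHubs, igraph::vcount(net)))
    trace <- traceKeyRegulators(tree)
    ts <- traceSummary(trace)
    say("trace: %d genes, %d key regulators", nrow(ts), sum(ts$isKR))
    writeNodeTable(hubs, out("hubs.tsv"))
    write.table(traceSteps(trace), out("trace_steps.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jwrite(list(keyRegulators = ts$gene[ts$isKR],
                deepNotKR = ts$gene[ts$deepNotKR]), "key_regulators.json")

    ## stage 7: knockout
    ko <- NULL
    if (length(cfg$knockout)) {
        ko <- tryCatch(
            knockoutExperiment(net, cfg$knockout, gammaRes = cfg$gammaRes,
                               maxLevel = cfg$maxLevel, seed = cfg$seed),
            error = function(e) stage_fail("knockout", e))
        say("knockout: removed %d genes, deltaHE(level 0) = %.2f",
            length(ko@removed), ko@he$deltaHE[ko@he$level == 0L])
        jwrite(list(removed = ko@removed, nodeDelta = ko@nodeDelta,
                    edgeDelta = ko@edgeDelta, he = ko@he,
                    exponents = ko@exponents), "knockout.json")
    }

    invisible(list(degs = degs, network = net, metrics = res$metrics,
                   curves = res$curves, exponentSet = res$es,
                   labels = labels, tree = tree, he = he, lcp = lcp,
                   hubs = hubs, trace = trace, knockout = ko,
                   outDir = cfg$outDir))
}
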