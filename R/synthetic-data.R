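#' Specification for synthetic pipeline inputs
#'
#' Bundles every knob of the synthetic-data generators: expression-matrix
#' dimensions and planted log2 fold changes for [makeExpression()], and the
#' benchmark graph model and its parameters for [makeGraph()].  The seed is
#' an explicit field; generators never touch the global RNG state, and the
#' same spec always reproduces the same output bit for bit.
#'
#' @param nGenes number of genes in the expression matrix.
#' @param nControl,nCase samples per group (each at least 2).
#' @param plantedEffects named numeric vector, gene label -> log2 fold
#'   change added to the case group.  Names must be gene labels of the
#'   form \code{paste0(labelPrefix, 1:nGenes)}.
#' @param noiseSd positive Gaussian noise s.d. on the log2 scale.
#' @param seed integer RNG seed.
#' @param graphModel one of \code{"scale_free"}, \code{"random"},
#'   \code{"hierarchical_triangle"}, \code{"two_clique"},
#'   \code{"planted_partition"}.
#' @param graphParams model-specific parameter list, see [makeGraph()].
#' @param labelPrefix prefix for generated gene labels.
#' @return An object of class \code{SyntheticSpec}.
#' @examples
#' sp <- syntheticSpec(nGenes = 100, plantedEffects = c(g1 = 2), seed = 1)
#' ds <- makeExpression(sp)
#' @export
syntheticSpec <- function(nGenes = 1000L, nControl = 4L, nCase = 4L,
                          plantedEffects = numeric(0), noiseSd = 0.25,
                          seed = 1L, graphModel = "scale_free",
                          graphParams = list(), labelPrefix = "g") {
    new("SyntheticSpec",
        nGenes = as.integer(nGenes), nControl = as.integer(nControl),
        nCase = as.integer(nCase),
        plantedEffects = plantedEffects, noiseSd = noiseSd,
        seed = as.integer(seed), graphModel = graphModel,
        graphParams = graphParams, labelPrefix = labelPrefix)
}

#' @rdname syntheticSpec
#' @export
setClass("SyntheticSpec",
    representation(
        nGenes = "integer", nControl = "integer", nCase = "integer",
        plantedEffects = "numeric", noiseSd = "numeric", seed = "integer",
        graphModel = "character", graphParams = "list",
        labelPrefix = "character"))

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (object@nControl < 2L || object@nCase < 2L)
        msg <- c(msg, "need at least 2 samples per group")
    if (!is.finite(object@noiseSd) || object@noiseSd <= 0)
        msg <- c(msg, "noiseSd must be > 0")
    if (length(object@plantedEffects)) {
        if (is.null(names(object@plantedEffects)))
            msg <- c(msg, "plantedEffects must be named by gene")
        if (!all(is.finite(object@plantedEffects)))
            msg <- c(msg, "planted effect sizes must be finite")
    }
    models <- c("scale_free", "random", "hierarchical_triangle",
                "two_clique", "planted_partition")
    if (!object@graphModel %in% models)
        msg <- c(msg, paste("graphModel must be one of:",
                            paste(models, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Generate a two-group expression matrix with planted fold changes
#'
#' Simulates log2 intensities as gene baselines (N(7, 1)) plus i.i.d.
#' Gaussian noise; case samples of a planted gene are shifted by its log2
#' fold change, so the expected case-minus-control difference equals the
#' planted effect exactly.
#'
#' @param spec a [syntheticSpec()].
#' @return An [ExpressionDataset-class].
#' @export
makeExpression <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    validObject(spec)
    genes <- paste0(spec@labelPrefix, seq_len(spec@nGenes))
    eff <- spec@plantedEffects
    if (length(eff) && !all(names(eff) %in% genes))
        stop("plantedEffects names must be generated gene labels")
    nS <- spec@nControl + spec@nCase
    group <- c(rep("control", spec@nControl), rep("case", spec@nCase))
    samples <- c(paste0("ctrl_", seq_len(spec@nControl)),
                 paste0("case_", seq_len(spec@nCase)))
    mat <- with_explicit_seed(spec@seed, {
        base <- rnorm(spec@nGenes, mean = 7, sd = 1)
        m <- matrix(rnorm(spec@nGenes * nS, sd = spec@noiseSd),
                    nrow = spec@nGenes) + base
        if (length(eff))
            m[match(names(eff), genes), group == "case"] <-
                m[match(names(eff), genes), group == "case"] + eff
        m
    })
    dimnames(mat) <- list(genes, samples)
    ExpressionDataset(mat, group)
}

#' Generate a benchmark graph with known structure
#'
#' Models (selected by \code{graphModel}; parameters in
#' \code{graphParams}):
#' \describe{
#' \item{scale_free}{shifted-linear preferential attachment, attachment
#'   kernel \eqn{k + A} with \eqn{A = (\gamma_t - 3)m}, so the degree
#'   distribution has target exponent \code{targetExponent} (default 2.5);
#'   parameters \code{n} (default \code{nGenes}), \code{m} edges per new
#'   node (default 2), \code{targetExponent}.  The exponent is asymptotic
#'   and is verified empirically, not guaranteed analytically.}
#' \item{random}{Erdos-Renyi G(n, p); parameters \code{n}, \code{p}.}
#' \item{hierarchical_triangle}{deterministic recursive triangle
#'   replication: depth-0 units are triangles; a depth-\code{d} unit chains
#'   \code{branching} (default 2) depth-\code{d-1} units with single bridge
#'   edges.  \code{nonmotifLeaves} (default 0) replaces that many leaf
#'   triangles with triangle-free 4-node stars, giving ground-truth
#'   negatives for regulator tracing.  Parameters \code{depth},
#'   \code{branching}, \code{nonmotifLeaves}.}
#' \item{two_clique}{two \eqn{K_m} cliques joined by a single edge;
#'   parameter \code{m}.}
#' \item{planted_partition}{stochastic block model; parameters
#'   \code{blockSizes}, \code{pIn}, \code{pOut}; block of each node stored
#'   in vertex attribute \code{block}.}
#' }
#' All outputs are simple undirected labelled graphs.
#'
#' @param spec a [syntheticSpec()].
#' @return An igraph object with named vertices.
#' @examples
#' g <- makeGraph(syntheticSpec(graphModel = "two_clique",
#'                              graphParams = list(m = 4), seed = 1))
#' igraph::vcount(g); igraph::ecount(g)   # 8 nodes, 13 edges
#' @export
makeGraph <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    validObject(spec)
    p <- spec@graphParams
    g <- switch(spec@graphModel,
        scale_free = {
            n <- as.integer(p$n %||% spec@nGenes)
            m <- as.integer(p$m %||% 2L)
            gamma_t <- p$targetExponent %||% 2.5
            if (m >= n) stop("scale_free: m must be < n")
            if (gamma_t <= 2)
                stop("scale_free: targetExponent must be > 2")
            with_explicit_seed(spec@seed,
                pa_graph(n, m, appeal = (gamma_t - 3) * m,
                         prefix = spec@labelPrefix))
        },
        random = {
            n <- as.integer(p$n %||% spec@nGenes)
            prob <- p$p %||% (2 / n)
            g0 <- with_explicit_seed(spec@seed,
                igraph::sample_gnp(n, prob))
            igraph::V(g0)$name <- paste0(spec@labelPrefix, seq_len(n))
            g0
        },
        hierarchical_triangle = {
            depth <- as.integer(p$depth %||% 2L)
            branching <- as.integer(p$branching %||% 2L)
            nonmotif <- as.integer(p$nonmotifLeaves %||% 0L)
            if (depth < 0L || branching < 2L)
                stop("hierarchical_triangle: depth >= 0, branching >= 2")
            hier_triangle_graph(depth, branching, nonmotif,
                                prefix = spec@labelPrefix)
        },
        two_clique = {
            m <- as.integer(p$m %||% 4L)
            if (m < 2L) stop("two_clique: m must be >= 2")
            two_clique_graph(m, prefix = spec@labelPrefix)
        },
        planted_partition = {
            sizes <- as.integer(p$blockSizes %||% c(20L, 20L))
            pin <- p$pIn %||% 0.4
            pout <- p$pOut %||% 0.02
            pm <- matrix(pout, length(sizes), length(sizes))
            diag(pm) <- pin
            g0 <- with_explicit_seed(spec@seed,
                igraph::sample_sbm(sum(sizes), pref.matrix = pm,
                                   block.sizes = sizes))
            igraph::V(g0)$name <-
                paste0(spec@labelPrefix, seq_len(sum(sizes)))
            igraph::V(g0)$block <- rep(seq_along(sizes), sizes)
            g0
        })
    g <- igraph::simplify(g)
    sort_vertices(g)
}

#' Mark ground-truth deep regulators on a benchmark graph
#'
#' Records the designated genes in the logical vertex attribute
#' \code{plantedKR} so that regulator tracing can be scored against a known
#' answer.  The genes must exist in the graph; their placement (inside or
#' outside a terminal triangle) is deliberately unconstrained so both
#' positive and negative controls can be planted.
#'
#' @param net an igraph object with named vertices.
#' @param genes character vector of gene labels to mark.
#' @return The graph with the \code{plantedKR} vertex attribute set.
#' @export
plantRegulator <- function(net, genes) {
    stopifnot(igraph::is_igraph(net))
    missing <- setdiff(genes, igraph::V(net)$name)
    if (length(missing))
        stop("genes absent from the graph: ",
             paste(missing, collapse = ", "))
    flag <- igraph::V(net)$plantedKR %||%
        rep(FALSE, igraph::vcount(net))
    flag[match(genes, igraph::V(net)$name)] <- TRUE
    igraph::set_vertex_attr(net, "plantedKR", value = flag)
}

#' @return genes planted with [plantRegulator()] (character(0) if none).
#' @rdname plantRegulator
#' @export
plantedRegulators <- function(net) {
    flag <- igraph::V(net)$plantedKR
    if (is.null(flag)) character(0) else igraph::V(net)$name[flag]
}

## shifted-linear preferential attachment; appeal in (-m, Inf)
pa_graph <- function(n, m, appeal, prefix = "g") {
    if (appeal <= -m) stop("attachment shift must exceed -m")
    deg <- integer(n)
    ## seed: (m+1)-clique so every weight is positive from the start
    n0 <- m + 1L
    from <- integer(0); to <- integer(0)
    cmb <- utils::combn(n0, 2L)
    from <- cmb[1L, ]; to <- cmb[2L, ]
    deg[seq_len(n0)] <- m
    edges <- vector("list", n)
    edges[[1L]] <- rbind(from, to)
    for (i in seq.int(n0 + 1L, length.out = n - n0)) {
        w <- deg[seq_len(i - 1L)] + appeal
        tgt <- sample.int(i - 1L, size = m, replace = FALSE, prob = w)
        deg[tgt] <- deg[tgt] + 1L
        deg[i] <- m
        edges[[i]] <- rbind(rep.int(i, m), tgt)
    }
    em <- do.call(cbind, edges)
    g <- igraph::make_graph(as.vector(em), n = n, directed = FALSE)
    igraph::V(g)$name <- paste0(prefix, seq_len(n))
    g
}

## deterministic recursive triangle-replication benchmark
hier_triangle_graph <- function(depth, branching, nonmotifLeaves,
                                prefix = "g") {
    nLeaves <- branching^depth
    if (nonmotifLeaves < 0L || nonmotifLeaves >= nLeaves)
        stop("nonmotifLeaves must be in [0, branching^depth)")
    leaf_star <- seq_len(nLeaves) <= nonmotifLeaves
    counter <- new.env()
    counter$next_id <- 1L
    counter$leaf <- 0L
    new_nodes <- function(k) {
        ids <- seq.int(counter$next_id, length.out = k)
        counter$next_id <- counter$next_id + k
        ids
    }
    ## returns list(edges = 2-row matrix, port = node id)
    build <- function(level) {
        if (level == 0L) {
            counter$leaf <- counter$leaf + 1L
            if (leaf_star[counter$leaf]) {
                v <- new_nodes(4L)   # star: triangle-free residual leaf
                list(edges = rbind(v[1L], v[2:4]), port = v[1L])
            } else {
                v <- new_nodes(3L)
                list(edges = rbind(v[c(1L, 2L, 1L)], v[c(2L, 3L, 3L)]),
                     port = v[1L])
            }
        } else {
            parts <- lapply(seq_len(branching), function(i) build(level - 1L))
            ports <- vapply(parts, `[[`, integer(1), "port")
            bridges <- rbind(ports[-length(ports)], ports[-1L])
            list(edges = cbind(do.call(cbind, lapply(parts, `[[`, "edges")),
                               bridges),
                 port = ports[1L])
        }
    }
    res <- build(depth)
    nV <- counter$next_id - 1L
    g <- igraph::make_graph(as.vector(res$edges), n = nV, directed = FALSE)
    igraph::V(g)$name <- paste0(prefix, seq_len(nV))
    g
}

two_clique_graph <- function(m, prefix = "g") {
    g <- igraph::disjoint_union(igraph::make_full_graph(m),
                                igraph::make_full_graph(m))
    g <- igraph::add_edges(g, c(1L, m + 1L))
    igraph::V(g)$name <- paste0(prefix, seq_len(2L * m))
    g
}
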