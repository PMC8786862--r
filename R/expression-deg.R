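#' Construct an ExpressionDataset
#'
#' @param values numeric matrix of log2 intensities, rownames = unique gene
#'   labels, colnames = sample labels.
#' @param group character/factor of length \code{ncol(values)} with values
#'   \code{"control"} / \code{"case"}.
#' @return An [ExpressionDataset-class].
#' @export
ExpressionDataset <- function(values, group) {
    values <- as.matrix(values)
    if (is.null(colnames(values)))
        colnames(values) <- paste0("s", seq_len(ncol(values)))
    se <- SummarizedExperiment(
        assays = list(log2 = values),
        colData = DataFrame(group = as.character(group),
                            row.names = colnames(values)))
    new("ExpressionDataset", se)
}

#' Collapse probe-level rows to gene level
#'
#' Multiple probes mapping to the same gene are collapsed to the arithmetic
#' mean of their log2 values; probes without a gene annotation (NA or empty
#' label) are dropped.
#'
#' @param values probe x sample numeric matrix.
#' @param genes character vector, gene label per probe.
#' @return gene x sample matrix with unique rownames.
#' @export
collapseProbes <- function(values, genes) {
    stopifnot(nrow(values) == length(genes))
    keep <- !is.na(genes) & nzchar(genes)
    values <- values[keep, , drop = FALSE]
    genes <- genes[keep]
    out <- rowsum(values, group = genes) / as.vector(table(genes)[sort(unique(genes))])
    out[order(rownames(out)), , drop = FALSE]
}

#' Per-gene differential-expression statistics
#'
#' Computes, for every gene, the log2 fold change (case mean minus control
#' mean) and a two-sided Welch t-test p-value, plus a
#' Benjamini-Hochberg-adjusted p-value column for information.  Genes with
#' zero variance in both groups and zero fold change get p = 1 (no call);
#' zero-variance genes with a non-zero difference get p = 0.
#'
#' @param ds an [ExpressionDataset-class] with at least 2 samples per group.
#' @return data.frame: gene, logFC, p, padjBH, direction ("up"/"down"/NA
#'   for logFC == 0).
#' @seealso [screenDEGs()] which applies the DEG cut-offs.
#' @export
degStats <- function(ds) {
    stopifnot(is(ds, "ExpressionDataset"))
    validObject(ds)
    grp <- as.character(colData(ds)$group)
    m <- assay(ds, "log2")
    n1 <- sum(grp == "case"); n0 <- sum(grp == "control")
    if (n1 < 2L || n0 < 2L)
        stop("Welch t-test needs at least 2 samples per group")
    x1 <- m[, grp == "case", drop = FALSE]
    x0 <- m[, grp == "control", drop = FALSE]
    m1 <- rowMeans(x1); m0 <- rowMeans(x0)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
    v0 <- rowSums((x0 - m0)^2) / (n0 - 1L)
    lfc <- m1 - m0
    se2 <- v1 / n1 + v0 / n0
    tstat <- lfc / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v0 / n0)^2 / (n0 - 1L))
    p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
    degenerate <- se2 == 0
    p[degenerate & lfc == 0] <- 1
    p[degenerate & lfc != 0] <- 0
    data.frame(
        gene = rownames(m), logFC = lfc, p = p,
        padjBH = p.adjust(p, method = "BH"),
        direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", NA)),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen a dataset for differentially expressed genes
#'
#' Applies the standard microarray DEG cut-offs: absolute log2 fold change
#' at least \code{lfcCut} and raw Welch-test p-value below \code{pCut}.
#' No multiple-testing correction is applied to the call (the adjusted
#' column from [degStats()] is carried along for information).
#'
#' @inheritParams degStats
#' @param lfcCut minimum |log2 fold change| (default 1).
#' @param pCut p-value cut-off (default 0.05, exclusive).
#' @return data.frame of passing records (columns as [degStats()]).
#' @export
screenDEGs <- function(ds, lfcCut = 1, pCut = 0.05) {
    tab <- degStats(ds)
    tab[abs(tab$logFC) >= lfcCut & tab$p < pCut, , drop = FALSE]
}

#' Merge DEG lists across datasets
#'
#' Takes per-dataset DEG tables (as from [screenDEGs()]) and forms merged
#' up- and down-regulated gene lists by union.  A gene called in both
#' directions across datasets is assigned the direction of its largest
#' absolute log2 fold change and recorded in the conflict list, so the
#' merged lists are disjoint.
#'
#' @param perDataset list of DEG data.frames; names are dataset labels.
#' @return list with elements \code{up}, \code{down} (character vectors),
#'   \code{conflicts} (character vector) and \code{records} (row-bound
#'   table with a \code{dataset} column).
#' @export
mergeDEGs <- function(perDataset) {
    stopifnot(is.list(perDataset), length(perDataset) >= 1L)
    if (is.null(names(perDataset)))
        names(perDataset) <- paste0("dataset", seq_along(perDataset))
    recs <- do.call(rbind, lapply(names(perDataset), function(nm) {
        df <- perDataset[[nm]]
        if (!nrow(df)) return(NULL)
        cbind(dataset = nm, df, stringsAsFactors = FALSE)
    }))
    if (is.null(recs) || !nrow(recs))
        return(list(up = character(0), down = character(0),
                    conflicts = character(0),
                    records = data.frame()))
    dir_of <- vapply(split(recs, recs$gene), function(df) {
        df$direction[which.max(abs(df$logFC))]
    }, character(1))
    both <- vapply(split(recs, recs$gene),
                   function(df) length(unique(df$direction)) > 1L,
                   logical(1))
    list(up = sort(names(dir_of)[dir_of == "up"]),
         down = sort(names(dir_of)[dir_of == "down"]),
         conflicts = sort(names(both)[both]),
         records = recs)
}

#' EASE-score enrichment test
#'
#' One-sided Fisher exact test of a study set against a gene-set term over
#' a finite background, with the conservative EASE penalization: one hit is
#' removed from the overlap cell before computing the hypergeometric upper
#' tail.  With one or zero hits the penalized overlap is empty and the
#' p-value is 1.
#'
#' @param studyGenes character vector, must be a subset of background.
#' @param termGenes character vector (intersected with background).
#' @param background character vector of all testable genes.
#' @return p-value in (0, 1].
#' @export
easeTest <- function(studyGenes, termGenes, background) {
    background <- unique(background)
    if (!length(background)) stop("empty background")
    studyGenes <- unique(studyGenes)
    if (!all(studyGenes %in% background))
        stop("studyGenes must be a subset of background")
    termGenes <- intersect(unique(termGenes), background)
    hits <- length(intersect(studyGenes, termGenes))
    if (hits - 1L <= 0L) return(1)
    ## P(X >= hits - 1), X ~ Hypergeom(|term|, |bg| - |term|, |study|)
    phyper(hits - 2L, length(termGenes),
           length(background) - length(termGenes),
           length(studyGenes), lower.tail = FALSE)
}
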