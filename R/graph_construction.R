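# Building the initial annotated graph: DE gene selection, expression
# filtering, optional TF enrichment, role assignment.

#' Select differentially expressed genes
#'
#' A gene is called DE when \code{baseMean > deBaseMeanMin}, its adjusted
#' p-value is present and \code{< dePadjMax}, and
#' \code{|log2fc| > deAbsLfcMin} (all comparisons strict; missing
#' adjusted p counts as non-significant).
#'
#' @param de DE table from [readDETable()].
#' @param cfg a [runConfig()] list.
#' @return list with character vectors \code{up}, \code{down} and
#'   \code{selected} (the direction requested by \code{cfg$direction}).
#' @export
selectDEGenes <- function(de, cfg = runConfig()) {
    keep <- de$baseMean > cfg$deBaseMeanMin &
        !is.na(de$padj) & de$padj < cfg$dePadjMax &
        abs(de$log2fc) > cfg$deAbsLfcMin
    up <- de$gene[keep & de$log2fc > 0]
    down <- de$gene[keep & de$log2fc < 0]
    selected <- switch(cfg$direction, up = up, down = down,
                       both = c(up, down))
    if (!length(selected))
        stop("no genes pass the DE filters (baseMean > ", cfg$deBaseMeanMin,
             ", padj < ", cfg$dePadjMax, ", |log2FC| > ", cfg$deAbsLfcMin,
             ", direction = ", cfg$direction, "); consider looser cutoffs")
    list(up = up, down = down, selected = selected)
}

#' Filter genes to those detectably expressed
#'
#' With a raw count matrix, a gene is expressed when it has a positive
#' count in at least \code{minSamples} samples; without one, presence in
#' the dataset universe (the DE table's genes) is used as the weakest
#' defensible proxy.
#'
#' @param genes candidate symbols.
#' @param counts optional genes x samples count matrix with rownames.
#' @param datasetGenes universe fallback (usually the DE table's genes).
#' @param minSamples samples with count > 0 required.
#' @return the expressed subset of \code{genes}.
#' @export
filterExpressed <- function(genes, counts = NULL, datasetGenes = NULL,
                            minSamples = 1L) {
    if (!is.null(counts)) {
        m <- as.matrix(counts)
        expressed <- rownames(m)[rowSums(m > 0) >= minSamples]
        genes[genes %in% expressed]
    } else if (!is.null(datasetGenes)) {
        genes[genes %in% datasetGenes]
    } else genes
}

#' Hypergeometric enrichment of transcription-factor targets
#'
#' For each TF with targets \code{n} in the universe of \code{N} genes,
#' of which \code{K} are DE and \code{x} of the TF's targets are DE, the
#' raw p-value is the upper cumulative hypergeometric probability
#' \eqn{P(X \ge x)}.  P-values are adjusted over the tested TFs and a TF
#' is called enriched when its adjusted p is below \code{alpha}.
#'
#' @param tfTargets named list, TF -> character vector of target genes.
#' @param deGenes DE gene symbols.
#' @param universe all genes in the dataset.
#' @param correction \code{"fdr"} (Benjamini-Hochberg) or
#'   \code{"bonferroni"}.
#' @param alpha adjusted-p cutoff.
#' @return data.frame (tf, n_targets, x_hits, p, p_adj, enriched) sorted
#'   by raw p.
#' @export
hypergeomEnrichTFs <- function(tfTargets, deGenes, universe,
                               correction = c("fdr", "bonferroni"),
                               alpha = 0.05) {
    correction <- match.arg(correction)
    universe <- unique(universe)
    if (!length(universe)) stop("empty gene universe")
    deGenes <- intersect(unique(deGenes), universe)
    N <- length(universe)
    K <- length(deGenes)
    rows <- lapply(names(tfTargets), function(tf) {
        tg <- intersect(tfTargets[[tf]], universe)
        n <- length(tg)
        if (n == 0L) return(NULL)
        x <- length(intersect(tg, deGenes))
        p <- phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
        data.frame(tf = tf, n_targets = n, x_hits = x, p = p,
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(tf = character(), n_targets = integer(),
                          x_hits = integer(), p = numeric(),
                          p_adj = numeric(), enriched = logical()))
    out <- do.call(rbind, rows)
    out$p_adj <- p.adjust(out$p, method = if (correction == "fdr") "BH"
                                          else "bonferroni")
    out$enriched <- out$p_adj < alpha
    out <- out[.radixOrder(out$p, out$tf), ]
    rownames(out) <- NULL
    out
}

#' Build the initial annotated signal graph
#'
#' Restricts the PPI network to expressed genes, drops isolated nodes,
#' attaches the |log2FC| node weight (0 for genes absent from the DE
#' table), and assigns roles: expressed receptors are sources (a gene
#' that is both receptor and DE stays a source, preserving its upstream
#' role), DE genes of the chosen direction -- or the supplied enriched
#' TFs -- are targets, everything else is internal.
#'
#' @param ppi PPI table from [readPPI()].
#' @param de DE table from [readDETable()].
#' @param receptors receptor symbols.
#' @param cfg a [runConfig()] list.
#' @param tfNodes optional character vector of enriched TFs to use as
#'   targets instead of the DE genes.
#' @param counts optional raw count matrix for the expression filter.
#' @return a [SignalGraph-class].
#' @export
buildInitialGraph <- function(ppi, de, receptors, cfg = runConfig(),
                              tfNodes = NULL, counts = NULL) {
    universe <- de$gene
    ppiGenes <- unique(c(ppi$gene_a, ppi$gene_b))
    expressed <- unique(c(
        filterExpressed(ppiGenes, counts, universe, cfg$minExpressedSamples),
        filterExpressed(receptors, counts, universe, cfg$minExpressedSamples)))
    keep <- ppi$gene_a %in% expressed & ppi$gene_b %in% expressed
    edges <- ppi[keep, , drop = FALSE]
    if (nrow(edges) == 0L)
        stop("no PPI edges connect expressed genes")

    g <- igraph::graph_from_data_frame(
        edges[c("gene_a", "gene_b")], directed = FALSE,
        vertices = data.frame(name = sort(unique(c(edges$gene_a, edges$gene_b)))))
    igraph::E(g)$confidence <- edges$confidence

    lfc <- setNames(abs(de$log2fc), de$gene)
    nm <- igraph::V(g)$name
    w <- unname(lfc[nm]); w[is.na(w)] <- 0
    igraph::V(g)$abs_log2fc <- w

    sources <- intersect(receptors, nm)
    targetsWanted <- if (!is.null(tfNodes)) unique(tfNodes)
                     else selectDEGenes(de, cfg)$selected
    targets <- setdiff(intersect(targetsWanted, nm), sources)
    if (!length(sources))
        stop("no source nodes: none of the receptors are expressed and in the PPI graph")
    if (!length(targets))
        stop("no target nodes: no ", if (is.null(tfNodes)) "DE gene"
             else "enriched TF", " is expressed and in the PPI graph ",
             "(after removing receptor overlaps)")

    role <- rep("internal", length(nm))
    role[nm %in% targets] <- "target"
    role[nm %in% sources] <- "source"    # receptor precedence over DE
    igraph::V(g)$role <- role

    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0L))
    if (!any(igraph::V(g)$role == "source"))
        stop("no source nodes remain after dropping isolated nodes")
    if (!any(igraph::V(g)$role == "target"))
        stop("no target nodes remain after dropping isolated nodes")
    new("SignalGraph", graph = g)
}
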