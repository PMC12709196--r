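# End-to-end orchestration: construction -> path stage -> optimization
# -> refinement -> knockout ranking -> optional permutation null.

# Internal: path stage + optimization + refinement + ranking on an
# already-built SignalGraph.  Used by both the public pipeline and the
# permutation null.
.corePipeline <- function(sg, cfg, refine = TRUE) {
    ps0 <- enumeratePaths(sg, cfg)
    if (!pathCount(ps0))
        stop("no source-target path of at most ", cfg$K, " nodes exists")
    ps0 <- scorePaths(ps0, sg, cfg$gamma)
    dist <- fitScoreDistribution(ps0@paths$score)
    psSig <- filterSignificant(ps0, dist, cfg$pathPCutoff)
    if (!pathCount(psSig))
        stop("no path passes the significance cutoff p < ", cfg$pathPCutoff)
    psTop <- selectTopN(psSig, cfg$topN)
    # shift anchored at the weakest retained path (its log2 s' term is 0),
    # then frozen for the whole run so refinement and knockout scores stay
    # on one scale
    shiftRef <- min(psTop@paths$score)

    opt <- pruneToOptimal(psTop, lambda = cfg$lambda, sg = sg,
                          shiftRef = shiftRef)
    lambda <- opt$lambda
    refineRes <- if (refine && cfg$t > 0L) {
        refineNetwork(opt$network, sg, cfg, lambda, shiftRef, dist = dist)
    } else list(network = opt$network,
                history = data.frame(iteration = integer(),
                                     n_edges_added = integer(),
                                     s_q = numeric(), accepted = logical(),
                                     stagnant = integer()))
    final <- refineRes$network
    ranking <- rankGenes(final)
    list(graph = sg, pathsEnumerated = pathCount(ps0),
         pathsSignificant = pathCount(psSig),
         pathsRetained = pathCount(psTop),
         scoreDistribution = dist, shiftRef = shiftRef, lambda = lambda,
         trajectory = opt$trajectory, elbow = opt$elbow,
         refinement = refineRes$history, network = final,
         ranking = ranking)
}

#' Run the full inference pipeline
#'
#' Builds the initial annotated graph, enumerates and scores
#' source-target paths, filters them by Gaussian significance, keeps the
#' top N per pair, prunes to the elbow of the regularized-score curve,
#' refines the network by stochastic edge injection until convergence,
#' and ranks every gene of the converged network by in-silico knockout.
#' With \code{cfg$permutations > 0} a degree-preserving permutation null
#' adds empirical p-values to the ranking.
#'
#' All randomness (refinement proposals, permutations) is governed by
#' \code{cfg$seed}; identical inputs and configuration give identical
#' output.
#'
#' @param ppi PPI table ([readPPI()]).
#' @param de DE table ([readDETable()]).
#' @param receptors receptor symbols ([readReceptors()]).
#' @param cfg a [runConfig()] list.
#' @param tfTargets optional named list (GMT, [readTFTargets()]); when
#'   given, enriched TFs replace DE genes as targets.
#' @param counts optional raw count matrix for the expression filter.
#' @return list with elements \code{ranking} (data.frame),
#'   \code{network} ([CandidateNetwork-class]), \code{graph}
#'   ([SignalGraph-class]), \code{report} (nested list; see
#'   [writeRunReport()]), plus \code{lambda}, \code{trajectory},
#'   \code{refinement}, \code{null} (when permutations were run).
#' @examples
#' sim <- generateInteractome(12, 6, 120, seed = 1)
#' imp <- implantCascade(sim, receptorFrac = 0.3, seed = 1)
#' res <- runPipeline(interactomeToPPI(sim), imp$de,
#'                    receptorNames(sim), runConfig(seed = 1, t = 2))
#' head(res$ranking)
#' @export
runPipeline <- function(ppi, de, receptors, cfg = runConfig(),
                        tfTargets = NULL, counts = NULL) {
    set.seed(cfg$seed)
    tfNodes <- NULL
    if (!is.null(tfTargets)) {
        deSel <- selectDEGenes(de, cfg)
        enr <- hypergeomEnrichTFs(tfTargets, deSel$selected, de$gene,
                                  correction = cfg$tfCorrection,
                                  alpha = cfg$tfAlpha)
        tfNodes <- enr$tf[enr$enriched]
        if (!length(tfNodes))
            stop("no TF is enriched at adjusted p < ", cfg$tfAlpha)
    }
    sg <- buildInitialGraph(ppi, de, receptors, cfg, tfNodes = tfNodes,
                            counts = counts)
    res <- .corePipeline(sg, cfg, refine = TRUE)
    null <- NULL
    if (cfg$permutations > 0L) {
        null <- buildNull(sg, cfg, nRuns = cfg$permutations)
        res$ranking <- rankGenes(res$network, null = null)
    }
    diag <- if (nrow(res$ranking) >= 3L) degreeBiasDiagnostic(res$ranking)
            else NULL
    g <- asIgraph(sg)
    report <- list(
        config = unclass(cfg),
        counts = list(nodes = igraph::vcount(g), edges = igraph::ecount(g),
                      sources = length(sourceNodes(sg)),
                      targets = length(targetNodes(sg)),
                      internals = length(internalNodes(sg)),
                      paths_enumerated = res$pathsEnumerated,
                      paths_significant = res$pathsSignificant,
                      paths_retained = res$pathsRetained,
                      paths_final = pathCount(res$network),
                      final_nodes = igraph::vcount(asIgraph(res$network)),
                      final_edges = igraph::ecount(asIgraph(res$network))),
        lambda = res$lambda,
        shift_reference = res$shiftRef,
        score_distribution = res$scoreDistribution,
        elbow_index = res$elbow,
        final_score = networkScore(res$network),
        refinement = res$refinement,
        n_significant = if (!is.null(null)) sum(res$ranking$significant)
                        else NA_integer_,
        null_threshold = if (!is.null(null)) null$threshold else NA_real_,
        degree_bias = diag)
    list(ranking = res$ranking, network = res$network, graph = sg,
         report = report, lambda = res$lambda,
         trajectory = res$trajectory, refinement = res$refinement,
         null = null)
}

#' Export the top-k subnetwork
#'
#' Induces the subgraph of the final network on the k best-ranked genes
#' and (by default) drops nodes outside its largest connected component,
#' the usual preparation for visualization.  Knockout score and rank are
#' attached as node attributes.
#'
#' @param ranking data.frame from [rankGenes()].
#' @param net the final [CandidateNetwork-class].
#' @param k genes to keep (capped at the ranking length).
#' @param dropDisconnected drop nodes outside the largest component.
#' @return list: \code{graph} (\pkg{igraph}), \code{kept},
#'   \code{dropped} (counts).
#' @export
exportTopK <- function(ranking, net, k = 100L, dropDisconnected = TRUE) {
    k <- min(k, nrow(ranking))
    top <- ranking$gene[order(ranking$rank)][seq_len(k)]
    g <- igraph::induced_subgraph(asIgraph(net),
                                  igraph::V(asIgraph(net))$name %in% top)
    idx <- match(igraph::V(g)$name, ranking$gene)
    igraph::V(g)$ko_score <- ranking$ko_score[idx]
    igraph::V(g)$rank <- ranking$rank[idx]
    dropped <- 0L
    if (dropDisconnected && igraph::vcount(g) > 0L) {
        comp <- igraph::components(g)
        main <- which.max(comp$csize)
        dropped <- sum(comp$membership != main)
        g <- igraph::induced_subgraph(g, comp$membership == main)
    }
    list(graph = g, kept = igraph::vcount(g), dropped = dropped)
}

#' Write the machine-readable run report
#'
#' Serializes the pipeline report (configuration echo, stage counts,
#' score trajectory summary, refinement history, diagnostics) as JSON.
#'
#' @param result list returned by [runPipeline()].
#' @param path output JSON file.
#' @export
writeRunReport <- function(result, path) {
    rep <- result$report
    rep$trajectory_summary <- list(
        points = nrow(result$trajectory),
        s_q_first = result$trajectory$s_q[1L],
        s_q_elbow = result$trajectory$s_q[rep$elbow_index],
        s_q_last = result$trajectory$s_q[nrow(result$trajectory)])
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    invisible(path)
}
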