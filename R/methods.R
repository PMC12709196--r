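# Accessor and show methods for the S4 containers.

#' @rdname accessors
#' @export
setMethod("asIgraph", "SignalGraph", function(x) x@graph)

#' @rdname accessors
#' @export
setMethod("asIgraph", "CandidateNetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setMethod("asIgraph", "SyntheticInteractome", function(x) x@graph)

#' @rdname accessors
#' @export
setMethod("nodeNames", "SignalGraph", function(x) igraph::V(x@graph)$name)

#' @rdname accessors
#' @export
setMethod("nodeNames", "CandidateNetwork", function(x) igraph::V(x@graph)$name)

#' @rdname accessors
#' @export
setMethod("nodeRoles", "SignalGraph", function(x)
    setNames(igraph::V(x@graph)$role, igraph::V(x@graph)$name))

#' @rdname accessors
#' @export
setMethod("sourceNodes", "SignalGraph", function(x) {
    v <- igraph::V(x@graph)
    v$name[v$role == "source"]
})

#' @rdname accessors
#' @export
setMethod("targetNodes", "SignalGraph", function(x) {
    v <- igraph::V(x@graph)
    v$name[v$role == "target"]
})

#' @rdname accessors
#' @export
setMethod("internalNodes", "SignalGraph", function(x) {
    v <- igraph::V(x@graph)
    v$name[v$role == "internal"]
})

#' @rdname accessors
#' @export
setMethod("nodeWeights", "SignalGraph", function(x)
    setNames(igraph::V(x@graph)$abs_log2fc, igraph::V(x@graph)$name))

#' @rdname accessors
#' @export
setMethod("pathCount", "PathSet", function(x) nrow(x@paths))

#' @rdname accessors
#' @export
setMethod("pathCount", "CandidateNetwork", function(x) nrow(x@paths@paths))

#' @rdname accessors
#' @export
setMethod("retainedPaths", "CandidateNetwork", function(x) x@paths)

#' @rdname accessors
#' @export
setMethod("networkScore", "CandidateNetwork", function(x) x@score)

#' @rdname accessors
#' @export
setMethod("scoreTerm", "CandidateNetwork", function(x) x@scoreTerm)

#' @rdname accessors
#' @export
setMethod("avgDegree", "CandidateNetwork", function(x) x@avgDegree)

#' @rdname accessors
#' @export
setMethod("lambdaValue", "CandidateNetwork", function(x) x@lambda)

#' @rdname accessors
#' @export
setMethod("implantedNodes", "CascadeTruth", function(x)
    c(x@receptors, x@tfs, x@genes))

#' Coerce a PathSet to a data.frame
#'
#' @param x a [PathSet-class].
#' @param ... unused.
#' @return data.frame with one row per path; the node sequence is
#'   returned as a `|`-joined string in column \code{path}.
#' @export
as.data.frame.PathSet <- function(x, ...) {
    p <- x@paths
    data.frame(source = p$source, target = p$target,
               path = vapply(p$nodes, paste, character(1), collapse = "|"),
               k = p$k, score = p$score, prob_score = p$prob_score,
               pvalue = p$pvalue, stringsAsFactors = FALSE)
}

setMethod("show", "SignalGraph", function(object) {
    g <- object@graph
    r <- table(factor(igraph::V(g)$role, levels = .ROLES))
    cat(sprintf("SignalGraph: %d nodes (%d sources, %d targets, %d internal), %d edges\n",
                igraph::vcount(g), r[["source"]], r[["target"]],
                r[["internal"]], igraph::ecount(g)))
})

setMethod("show", "PathSet", function(object) {
    p <- object@paths
    cat(sprintf("PathSet: %d paths, %d (source,target) pairs\n",
                nrow(p), nrow(unique(p[c("source", "target")]))))
    if (nrow(p) && !all(is.na(p$score)))
        cat(sprintf("  score range [%.3f, %.3f]\n",
                    min(p$score, na.rm = TRUE), max(p$score, na.rm = TRUE)))
})

setMethod("show", "CandidateNetwork", function(object) {
    cat(sprintf(paste0("CandidateNetwork: %d paths over %d nodes / %d edges\n",
                       "  score %.4f = scoreTerm %.4f - lambda %.4f * avgDegree %.4f\n"),
                nrow(object@paths@paths), igraph::vcount(object@graph),
                igraph::ecount(object@graph), object@score,
                object@scoreTerm, object@lambda, object@avgDegree))
})

setMethod("show", "CascadeTruth", function(object) {
    cat(sprintf("CascadeTruth: %d receptors + %d TFs + %d genes (log2FC = %g)\n",
                length(object@receptors), length(object@tfs),
                length(object@genes), object@lfc))
})

setMethod("show", "SyntheticInteractome", function(object) {
    g <- object@graph
    l <- table(factor(igraph::V(g)$layer, levels = c("receptor", "tf", "gene")))
    cat(sprintf("SyntheticInteractome: %d receptors, %d TFs, %d genes; %d edges\n",
                l[["receptor"]], l[["tf"]], l[["gene"]], igraph::ecount(g)))
})
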