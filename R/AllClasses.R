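#' @import methods
#' @importFrom stats pnorm phyper p.adjust quantile rnorm runif sd cor.test aggregate setNames
#' @importFrom utils head read.delim write.table
NULL

setOldClass("igraph")

.ROLES <- c("source", "target", "internal")

#' SignalGraph: an annotated condition-specific interaction graph
#'
#' An undirected gene interaction graph whose vertices carry a signaling
#' role (\code{source} = expressed receptor, \code{target} = differentially
#' expressed gene or enriched transcription factor, \code{internal} =
#' any other expressed gene) and an \code{abs_log2fc} weight (the absolute
#' log2 fold change between conditions, 0 for genes absent from the DE
#' table), and whose edges carry an interaction \code{confidence} in (0, 1].
#'
#' @slot graph an \pkg{igraph} object with vertex attributes \code{name},
#'   \code{role}, \code{abs_log2fc} and edge attribute \code{confidence}.
#' @seealso [buildInitialGraph()] which constructs the object from a PPI
#'   table, DE results and a receptor list.
#' @export
setClass("SignalGraph", representation(graph = "igraph"))

setValidity("SignalGraph", function(object) {
    g <- object@graph
    msgs <- character()
    va <- igraph::vertex_attr_names(g)
    if (!all(c("name", "role", "abs_log2fc") %in% va))
        msgs <- c(msgs, "vertices must carry 'name', 'role' and 'abs_log2fc'")
    else {
        nm <- igraph::V(g)$name
        if (anyDuplicated(nm) || any(!nzchar(nm)))
            msgs <- c(msgs, "vertex names must be unique and non-empty")
        if (!all(igraph::V(g)$role %in% .ROLES))
            msgs <- c(msgs, "roles must be one of source/target/internal")
        w <- igraph::V(g)$abs_log2fc
        if (!is.numeric(w) || any(!is.finite(w)) || any(w < 0))
            msgs <- c(msgs, "abs_log2fc must be finite and >= 0")
    }
    if (igraph::ecount(g) > 0) {
        if (!"confidence" %in% igraph::edge_attr_names(g))
            msgs <- c(msgs, "edges must carry 'confidence'")
        else {
            cf <- igraph::E(g)$confidence
            if (any(!is.finite(cf)) || any(cf <= 0) || any(cf > 1))
                msgs <- c(msgs, "edge confidence must lie in (0, 1]")
        }
        if (any(igraph::which_loop(g)))
            msgs <- c(msgs, "self-loops are not allowed")
    }
    if (length(msgs)) msgs else TRUE
})

#' PathSet: a collection of scored source-target paths
#'
#' Holds one row per candidate path: the ordered node sequence, its
#' source and target endpoints, node count, additive path score, the
#' propagation-likelihood score used for top-N selection, and the
#' Gaussian upper-tail p-value.  Score columns are \code{NA} until the
#' corresponding stage has run.
#'
#' @slot paths a \code{data.frame} with columns \code{source},
#'   \code{target}, \code{nodes} (list of character vectors), \code{k},
#'   \code{score}, \code{prob_score}, \code{pvalue}.
#' @export
setClass("PathSet", representation(paths = "data.frame"))

setValidity("PathSet", function(object) {
    need <- c("source", "target", "nodes", "k", "score", "prob_score", "pvalue")
    if (!all(need %in% names(object@paths)))
        return(paste("paths data.frame needs columns:",
                     paste(need, collapse = ", ")))
    p <- object@paths
    if (nrow(p)) {
        if (!is.list(p$nodes)) return("'nodes' must be a list column")
        kk <- vapply(p$nodes, length, integer(1))
        if (!all(kk == p$k)) return("k must equal length(nodes)")
        first <- vapply(p$nodes, `[`, character(1), 1L)
        last <- vapply(p$nodes, function(x) x[length(x)], character(1))
        if (!all(first == p$source) || !all(last == p$target))
            return("paths must start at their source and end at their target")
    }
    TRUE
})

#' CandidateNetwork: a retained path set with its regularized score
#'
#' The union graph of a set of retained paths together with the
#' decomposed regularized network score: a score term (sum of log2 of the
#' shifted path scores), the average node degree of the union graph, the
#' regularization strength lambda, and the total
#' \code{score = score_term - lambda * avg_degree}.
#'
#' @slot paths a [PathSet-class] of the retained paths (with shifted
#'   scores in column \code{score_shifted}).
#' @slot graph the induced union \pkg{igraph} of all retained paths.
#' @slot scoreTerm numeric(1), sum over paths of log2 shifted score.
#' @slot avgDegree numeric(1), 2|E|/|V| of the union graph.
#' @slot lambda numeric(1), regularization coefficient.
#' @slot score numeric(1), the regularized network score.
#' @export
setClass("CandidateNetwork",
         representation(paths = "PathSet", graph = "igraph",
                        scoreTerm = "numeric", avgDegree = "numeric",
                        lambda = "numeric", score = "numeric"))

setValidity("CandidateNetwork", function(object) {
    if (abs(object@score - (object@scoreTerm - object@lambda * object@avgDegree)) > 1e-9)
        return("score must equal scoreTerm - lambda * avgDegree")
    TRUE
})

#' CascadeTruth: ground truth of an implanted signaling cascade
#'
#' Records which receptors, transcription factors and downstream genes
#' were implanted into a synthetic interactome, and the log2 fold change
#' assigned to cascade members.
#'
#' @slot receptors,tfs,genes character vectors of implanted symbols.
#' @slot lfc numeric(1), the log2 fold change given to cascade members.
#' @export
setClass("CascadeTruth",
         representation(receptors = "character", tfs = "character",
                        genes = "character", lfc = "numeric"))

setValidity("CascadeTruth", function(object) {
    sets <- list(object@receptors, object@tfs, object@genes)
    all2 <- unlist(sets)
    if (anyDuplicated(all2))
        return("implanted receptor/TF/gene sets must be disjoint")
    TRUE
})

#' SyntheticInteractome: a layered synthetic interaction network
#'
#' An undirected weighted graph over three node classes (receptors on the
#' periphery, transcription factors as mid-layer hubs, genes as the
#' backbone), generated by [generateInteractome()].
#'
#' @slot graph an \pkg{igraph} with vertex attributes \code{name} and
#'   \code{layer} (one of \code{receptor}, \code{tf}, \code{gene}) and
#'   edge attribute \code{confidence}.
#' @export
setClass("SyntheticInteractome", representation(graph = "igraph"))

setValidity("SyntheticInteractome", function(object) {
    g <- object@graph
    if (!all(c("name", "layer") %in% igraph::vertex_attr_names(g)))
        return("vertices must carry 'name' and 'layer'")
    if (!all(igraph::V(g)$layer %in% c("receptor", "tf", "gene")))
        return("layer must be receptor/tf/gene")
    if (igraph::ecount(g) > 0 && !"confidence" %in% igraph::edge_attr_names(g))
        return("edges must carry 'confidence'")
    TRUE
})
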