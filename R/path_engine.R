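# Source-target path enumeration and scoring.
#
# Enumeration follows the minimal-length formulation: for every
# (source, target) pair, all unweighted-shortest simple paths are kept,
# rejected when even the shortest route needs more than K nodes.  Scores
# combine log2 edge confidences with gamma-weighted node |log2FC| terms;
# significance comes from a Gaussian fitted to the pooled score
# population.

.pathKey <- function(nodes) vapply(nodes, paste, character(1), collapse = "|")

.emptyPathFrame <- function() {
    data.frame(source = character(), target = character(),
               nodes = I(list()), k = integer(), score = numeric(),
               prob_score = numeric(), pvalue = numeric(),
               stringsAsFactors = FALSE)
}

.makePathSet <- function(df) {
    rownames(df) <- NULL
    new("PathSet", paths = df)
}

#' Enumerate candidate source-target paths
#'
#' For each (source, target) pair, finds all unweighted-shortest simple
#' paths (edge weights are ignored during enumeration) and keeps those
#' with at most \code{K} nodes, endpoints included; pairs whose shortest
#' route needs more than \code{K} nodes contribute nothing.  With
#' \code{cfg$allPaths = TRUE} every simple path up to \code{K} nodes is
#' enumerated instead (exhaustive; small graphs only).  Paths are
#' returned in a deterministic order (source, target, length, node
#' sequence).
#'
#' @param sg a [SignalGraph-class].
#' @param cfg a [runConfig()] list.
#' @return an unscored [PathSet-class].
#' @export
enumeratePaths <- function(sg, cfg = runConfig()) {
    g <- sg@graph
    sources <- sort(sourceNodes(sg), method = "radix")
    targets <- targetNodes(sg)
    if (!length(sources) || !length(targets))
        stop("graph needs at least one source and one target")
    K <- cfg$K
    nm <- igraph::V(g)$name
    # plain integer-vector paths: far cheaper than igraph.vs sequences
    oldOpt <- igraph::igraph_options(return.vs.es = FALSE)
    on.exit(igraph::igraph_options(oldOpt), add = TRUE)
    # only request paths to targets within the node budget
    dmat <- igraph::distances(g, v = sources, to = targets)
    acc <- vector("list", length(sources))
    for (i in seq_along(sources)) {
        s <- sources[i]
        reachable <- targets[is.finite(dmat[i, ]) & dmat[i, ] <= K - 1L]
        if (!length(reachable) && !cfg$allPaths) next
        vp <- if (cfg$allPaths) {
            igraph::all_simple_paths(g, from = s, to = targets,
                                     cutoff = K - 1L)
        } else {
            suppressWarnings(
                igraph::all_shortest_paths(g, from = s,
                                           to = reachable,
                                           mode = "all")$res)
        }
        if (!length(vp)) next
        nodes <- lapply(vp, function(v) nm[as.integer(v)])
        kk <- lengths(nodes)
        keepIdx <- kk <= K & kk >= 2L
        nodes <- nodes[keepIdx]
        if (!length(nodes)) next
        tgt <- vapply(nodes, function(x) x[length(x)], character(1))
        ok <- tgt %in% targets
        acc[[i]] <- list(nodes = nodes[ok], target = tgt[ok])
    }
    acc <- acc[!vapply(acc, is.null, logical(1))]
    if (!length(acc)) return(.makePathSet(.emptyPathFrame()))
    nodes <- do.call(c, lapply(acc, `[[`, "nodes"))
    df <- data.frame(
        source = vapply(nodes, `[`, character(1), 1L),
        target = do.call(c, lapply(acc, `[[`, "target")),
        k = lengths(nodes), stringsAsFactors = FALSE)
    df$nodes <- nodes
    key <- .pathKey(nodes)
    ord <- .radixOrder(df$source, df$target, df$k, key)
    df <- df[ord, c("source", "target", "nodes", "k")]
    df$score <- NA_real_
    df$prob_score <- NA_real_
    df$pvalue <- NA_real_
    if (cfg$allPaths)  # duplicate routes possible only under allPaths
        df <- df[!duplicated(key[ord]), ]
    .makePathSet(df)
}

# Vectorized evaluation of both path scores for a list of node-name
# vectors.  Returns data.frame(score, prob_score).
.scoreNodeLists <- function(nodesList, g, gamma) {
    nm <- igraph::V(g)$name
    lens <- lengths(nodesList)
    vid <- match(unlist(nodesList, use.names = FALSE), nm)
    if (anyNA(vid)) stop("path references a node absent from the graph")
    pid <- rep.int(seq_along(nodesList), lens)
    vw <- igraph::V(g)$abs_log2fc
    nodeSum <- as.numeric(rowsum(vw[vid], pid, reorder = TRUE))

    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    from <- vid[-ends]
    to <- vid[-starts]
    eidPath <- rep.int(seq_along(nodesList), lens - 1L)
    pairs <- as.vector(rbind(from, to))
    eids <- igraph::get_edge_ids(g, pairs)
    if (any(eids == 0L))
        stop("path uses an edge absent from the graph")
    elog2 <- log2(igraph::E(g)$confidence)[eids]
    edgeSum <- as.numeric(rowsum(elog2, eidPath, reorder = TRUE))
    probTerms <- elog2 + vw[from] + vw[to]
    probSum <- as.numeric(rowsum(probTerms, eidPath, reorder = TRUE))
    data.frame(score = edgeSum + gamma * nodeSum, prob_score = probSum)
}

#' Score the paths of a PathSet
#'
#' Fills in both per-path scores: the additive path score
#' \eqn{s(P) = \sum_{e \in P} \log_2 W(e) + \gamma \sum_{v \in P} |\log_2 W(v)|}
#' (edge confidences \eqn{W(e)}, node fold changes \eqn{W(v)} stored as
#' \code{abs_log2fc}), and the propagation-likelihood score used for
#' top-N selection, \eqn{\sum_{e} [\log_2 W(e) + |\log_2 W(se)| +
#' |\log_2 W(te)|]} where \eqn{se, te} are the endpoints of edge
#' \eqn{e} (interior nodes are counted once per incident path edge, as
#' the formula reads).
#'
#' @param ps a [PathSet-class] from [enumeratePaths()].
#' @param sg the [SignalGraph-class] the paths live in.
#' @param gamma node-term weight.
#' @return the PathSet with \code{score} and \code{prob_score} filled.
#' @export
scorePaths <- function(ps, sg, gamma = 1.0) {
    df <- ps@paths
    if (!nrow(df)) return(ps)
    sc <- .scoreNodeLists(df$nodes, asIgraph(sg), gamma)
    df$score <- sc$score
    df$prob_score <- sc$prob_score
    .makePathSet(df)
}

#' Score a single path
#'
#' @param nodes ordered character vector of node names.
#' @param sg a [SignalGraph-class].
#' @param gamma node-term weight.
#' @return the additive path score.
#' @export
pathScore <- function(nodes, sg, gamma = 1.0)
    .scoreNodeLists(list(nodes), asIgraph(sg), gamma)$score

#' Propagation-likelihood score of a single path
#'
#' @inheritParams pathScore
#' @return the per-edge likelihood sum used for top-N selection.
#' @export
pathProbScore <- function(nodes, sg)
    .scoreNodeLists(list(nodes), asIgraph(sg), 1.0)$prob_score

#' Fit the Gaussian score distribution
#'
#' Path scores are modeled as Gaussian; the empirical mean and sample
#' standard deviation (denominator n - 1) of the pooled score population
#' parameterize the upper-tail significance test.
#'
#' @param scores numeric vector of path scores (>= 2 values).
#' @return list with \code{mu}, \code{sigma}, \code{n}.
#' @export
fitScoreDistribution <- function(scores) {
    scores <- scores[is.finite(scores)]
    if (length(scores) < 2L)
        stop("need at least 2 finite scores to fit a distribution")
    s <- sd(scores)
    if (s == 0)
        stop("constant path scores: Gaussian significance is undefined")
    list(mu = mean(scores), sigma = s, n = length(scores))
}

#' Gaussian upper-tail p-value of a path score
#'
#' \eqn{P(s) = 1 - \frac{1}{2}[1 + \mathrm{erf}((s - \mu)/(\sigma\sqrt 2))]},
#' i.e. the upper tail of the fitted Gaussian; strictly decreasing in
#' \code{s}.
#'
#' @param s path score(s).
#' @param dist fit from [fitScoreDistribution()].
#' @return p-value(s) in (0, 1).
#' @export
pathPValue <- function(s, dist)
    pnorm(s, mean = dist$mu, sd = dist$sigma, lower.tail = FALSE)

#' Keep statistically significant paths
#'
#' Fills the \code{pvalue} column and keeps paths with
#' \code{p < cutoff}.
#'
#' @param ps a scored [PathSet-class].
#' @param dist fit from [fitScoreDistribution()].
#' @param cutoff retention threshold on the Gaussian tail p.
#' @return the filtered [PathSet-class].
#' @export
filterSignificant <- function(ps, dist, cutoff = 0.01) {
    df <- ps@paths
    if (!nrow(df)) return(ps)
    df$pvalue <- pathPValue(df$score, dist)
    .makePathSet(df[df$pvalue < cutoff, , drop = FALSE])
}

#' Keep the top N most probable paths per (source, target) pair
#'
#' Ranking within a pair is by higher \code{prob_score}, ties broken by
#' higher path score, then lexicographic node sequence; pairs with fewer
#' than N paths keep all of them.
#'
#' @param ps a scored [PathSet-class].
#' @param N paths retained per pair.
#' @return the reduced [PathSet-class].
#' @export
selectTopN <- function(ps, N = 5L) {
    df <- ps@paths
    if (!nrow(df)) return(ps)
    key <- .pathKey(df$nodes)
    ord <- .radixOrder(df$source, df$target, -df$prob_score, -df$score, key)
    df <- df[ord, , drop = FALSE]
    pair <- paste(df$source, df$target, sep = "\r")
    pos <- stats::ave(seq_along(pair), pair, FUN = seq_along)
    .makePathSet(df[pos <= N, , drop = FALSE])
}
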