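# Regularized network scoring, greedy backward pruning with elbow
# selection, and stochastic iterative refinement.
#
# The network score of a retained path set Q is
#   s(Q) = sum_{P in Q} log2 s'(P)  -  lambda * AvgDegree(Q)
# where s'(P) is the affinely shifted path score (global minimum mapped
# to 1 so every log2 term is finite and >= 0) and AvgDegree(Q) =
# 2|E|/|V| of the union graph of the retained paths.

#' Shift path scores to a positive scale
#'
#' Applies the order-preserving affine shift \code{s' = s - min(s) + 1}
#' so the minimum shifted score is 1 and every \code{log2 s'} is finite
#' and non-negative.  When a \code{reference} minimum is supplied (the
#' pipeline freezes it at the initial enumeration so scores stay
#' comparable across refinement iterations and knockouts), scores below
#' it clamp at 1.
#'
#' @param scores numeric path scores.
#' @param reference optional frozen minimum to shift against.
#' @return numeric vector of shifted scores (all >= 1).
#' @export
shiftPathScores <- function(scores, reference = NULL) {
    if (!length(scores)) return(numeric())
    ref <- if (is.null(reference)) min(scores) else reference
    pmax(scores - ref + 1, 1)
}

# Internal: union-graph statistics of a set of paths.  Returns the
# igraph (with vertex attributes copied from `sg` when given) plus
# |V|, |E|.
.unionGraph <- function(nodesList, sg = NULL) {
    vs <- unique(unlist(nodesList, use.names = FALSE))
    lens <- lengths(nodesList)
    allv <- unlist(nodesList, use.names = FALSE)
    ends <- cumsum(lens); starts <- ends - lens + 1L
    from <- allv[-ends]; to <- allv[-starts]
    lo <- pmin(from, to); hi <- pmax(from, to)
    keep <- !duplicated(paste(lo, hi, sep = "\r"))
    g <- igraph::graph_from_data_frame(
        data.frame(from = lo[keep], to = hi[keep]),
        directed = FALSE, vertices = data.frame(name = sort(vs)))
    if (!is.null(sg)) {
        parent <- asIgraph(sg)
        idx <- match(igraph::V(g)$name, igraph::V(parent)$name)
        igraph::V(g)$role <- igraph::V(parent)$role[idx]
        igraph::V(g)$abs_log2fc <- igraph::V(parent)$abs_log2fc[idx]
        el <- igraph::as_edgelist(g, names = TRUE)
        if (nrow(el)) {
            pidx <- match(as.vector(t(el)), igraph::V(parent)$name)
            eids <- igraph::get_edge_ids(parent, pidx)
            if (all(eids > 0L))
                igraph::E(g)$confidence <- igraph::E(parent)$confidence[eids]
        }
    }
    g
}

#' Regularized network score of a retained path set
#'
#' Computes the score term (sum of log2 shifted path scores), the
#' average node degree of the union graph of the paths, and the total
#' \code{score_term - lambda * avg_degree}.  An empty path set scores 0
#' by convention.
#'
#' @param ps a scored [PathSet-class]; shifted scores are taken from a
#'   \code{score_shifted} column if present, otherwise computed with
#'   \code{shiftRef}.
#' @param lambda regularization coefficient.
#' @param sg optional parent [SignalGraph-class] used to copy node/edge
#'   attributes onto the union graph.
#' @param shiftRef frozen shift reference (see [shiftPathScores()]).
#' @return a [CandidateNetwork-class].
#' @export
networkScoreOf <- function(ps, lambda, sg = NULL, shiftRef = NULL) {
    df <- ps@paths
    if (!nrow(df)) {
        return(new("CandidateNetwork", paths = .makePathSet(.emptyPathFrame()),
                   graph = igraph::make_empty_graph(0, directed = FALSE),
                   scoreTerm = 0, avgDegree = 0, lambda = lambda, score = 0))
    }
    if (is.null(df$score_shifted))
        df$score_shifted <- shiftPathScores(df$score, shiftRef)
    g <- .unionGraph(df$nodes, sg)
    st <- sum(log2(df$score_shifted))
    ad <- 2 * igraph::ecount(g) / igraph::vcount(g)
    new("CandidateNetwork", paths = .makePathSet(df), graph = g,
        scoreTerm = st, avgDegree = ad, lambda = lambda,
        score = st - lambda * ad)
}

#' Automatic regularization strength
#'
#' lambda is the ratio between the mean score term and the mean average
#' degree across the internal networks of a lambda = 0 pilot pruning
#' sweep.
#'
#' @param trajectory data.frame with columns \code{score_term} and
#'   \code{avg_degree} (one row per internal network).
#' @return lambda.
#' @export
autoLambda <- function(trajectory) {
    if (!nrow(trajectory)) stop("empty pruning trajectory")
    ms <- mean(trajectory$score_term)
    md <- mean(trajectory$avg_degree)
    if (ms == 0) return(0)
    if (md == 0) stop("mean average degree is zero; cannot set lambda")
    ms / md
}

#' Greedy backward pruning
#'
#' Repeatedly removes the lowest-scoring path (ties broken by
#' lexicographic node sequence) and records the regularized score of
#' every intermediate network, from the full set down to a single path.
#' Statistics are maintained incrementally so the sweep is linear in the
#' total path length.
#'
#' @param ps a scored [PathSet-class] (shift applied internally with
#'   \code{shiftRef}).
#' @param lambda regularization coefficient.
#' @param shiftRef frozen shift reference.
#' @return list with \code{trajectory} (data.frame: removed, score_term,
#'   avg_degree, s_q) and \code{order} (removal order as row indices
#'   into \code{ps}).
#' @export
greedyPrune <- function(ps, lambda, shiftRef = NULL) {
    df <- ps@paths
    if (!nrow(df)) stop("cannot prune an empty path set")
    shifted <- shiftPathScores(df$score, shiftRef)
    key <- .pathKey(df$nodes)
    rmOrder <- .radixOrder(df$score, key)

    # usage counts of nodes and edges across retained paths
    nodesList <- df$nodes
    lens <- lengths(nodesList)
    allv <- unlist(nodesList, use.names = FALSE)
    ends <- cumsum(lens); starts <- ends - lens + 1L
    vkeys <- unique(allv)
    vcnt <- setNames(integer(length(vkeys)), vkeys)
    tv <- table(allv); vcnt[names(tv)] <- as.integer(tv)
    from <- allv[-ends]; to <- allv[-starts]
    ekeyAll <- paste(pmin(from, to), pmax(from, to), sep = "\r")
    ekeys <- unique(ekeyAll)
    ecnt <- setNames(integer(length(ekeys)), ekeys)
    te <- table(ekeyAll); ecnt[names(te)] <- as.integer(te)
    # per-path node names / edge keys for decrementing
    pathEdgeIdx <- rep.int(seq_along(nodesList), lens - 1L)
    edgeKeyByPath <- split(ekeyAll, pathEdgeIdx)
    nodeKeyByPath <- nodesList

    nV <- length(vkeys); nE <- length(ekeys)
    st <- sum(log2(shifted))
    P <- nrow(df)
    out <- data.frame(removed = 0:(P - 1L), score_term = NA_real_,
                      avg_degree = NA_real_, s_q = NA_real_)
    for (i in seq_len(P)) {
        ad <- if (nV > 0L) 2 * nE / nV else 0
        out$score_term[i] <- st
        out$avg_degree[i] <- ad
        out$s_q[i] <- st - lambda * ad
        if (i == P) break
        rm <- rmOrder[i]
        st <- st - log2(shifted[rm])
        nk <- nodeKeyByPath[[rm]]
        vcnt[nk] <- vcnt[nk] - 1L
        nV <- nV - sum(vcnt[nk] == 0L)
        ek <- edgeKeyByPath[[rm]]
        ecnt[ek] <- ecnt[ek] - 1L
        nE <- nE - sum(ecnt[ek] == 0L)
    }
    list(trajectory = out, order = rmOrder)
}

#' Elbow selection on a pruning trajectory
#'
#' Picks the trajectory point with maximum perpendicular distance to the
#' chord joining the first and last points of the s(Q)-versus-removals
#' curve (a knee/elbow detector); ties resolve toward fewer removals
#' (the larger network).  With fewer than 3 points the first point is
#' returned.  An alternative detector, the maximum second difference, is
#' available via \code{method = "secondDiff"}.
#'
#' @param trajectory data.frame from [greedyPrune()] with columns
#'   \code{removed} and \code{s_q}.
#' @param method elbow estimator.
#' @return 1-based row index of the selected network.
#' @export
selectElbow <- function(trajectory, method = c("chord", "secondDiff")) {
    method <- match.arg(method)
    n <- nrow(trajectory)
    if (n < 3L) return(1L)
    x <- trajectory$removed; y <- trajectory$s_q
    if (method == "secondDiff") {
        d2 <- abs(diff(y, differences = 2))
        return(which.max(d2) + 1L)
    }
    dx <- x[n] - x[1L]; dy <- y[n] - y[1L]
    d <- abs(dy * (x - x[1L]) - dx * (y - y[1L]))   # ~ distance to chord
    which.max(d)                                     # first max = fewer removals
}

# Internal: materialize the CandidateNetwork after `nRemoved` removals.
.networkAt <- function(ps, order, nRemoved, lambda, sg, shiftRef) {
    df <- ps@paths
    df$score_shifted <- shiftPathScores(df$score, shiftRef)
    keep <- setdiff(seq_len(nrow(df)), order[seq_len(nRemoved)])
    networkScoreOf(.makePathSet(df[keep, , drop = FALSE]), lambda,
                   sg = sg, shiftRef = shiftRef)
}

#' Prune to the locally optimal network
#'
#' Runs the greedy sweep and returns the elbow network.  When
#' \code{lambda = "auto"} a lambda = 0 pilot sweep sets lambda first
#' (see [autoLambda()]); lambda is then fixed for the real sweep.
#'
#' @param ps a scored [PathSet-class].
#' @param lambda number or \code{"auto"}.
#' @param sg parent [SignalGraph-class] for attribute transfer.
#' @param shiftRef frozen shift reference.
#' @param elbowMethod passed to [selectElbow()].
#' @return list: \code{network} ([CandidateNetwork-class]),
#'   \code{trajectory}, \code{elbow} (row index), \code{lambda}.
#' @export
pruneToOptimal <- function(ps, lambda = "auto", sg = NULL, shiftRef = NULL,
                           elbowMethod = "chord") {
    if (identical(lambda, "auto")) {
        pilot <- greedyPrune(ps, lambda = 0, shiftRef = shiftRef)
        lambda <- autoLambda(pilot$trajectory)
    }
    pr <- greedyPrune(ps, lambda = lambda, shiftRef = shiftRef)
    eb <- selectElbow(pr$trajectory, method = elbowMethod)
    net <- .networkAt(ps, pr$order, pr$trajectory$removed[eb], lambda,
                      sg, shiftRef)
    list(network = net, trajectory = pr$trajectory, elbow = eb,
         lambda = lambda)
}

# Internal: run enumeration -> scoring -> significance -> top-N on a
# working SignalGraph; returns a scored PathSet (possibly empty).  A
# frozen score distribution (from the initial enumeration) can be
# supplied so the significance scale stays comparable across refinement
# iterations; otherwise one is fitted to the local population.
.pathStage <- function(sg, cfg, dist = NULL) {
    ps <- enumeratePaths(sg, cfg)
    if (!pathCount(ps)) return(ps)
    ps <- scorePaths(ps, sg, cfg$gamma)
    if (is.null(dist))
        dist <- tryCatch(fitScoreDistribution(ps@paths$score),
                         error = function(e) NULL)
    if (is.null(dist)) return(.makePathSet(.emptyPathFrame()))
    ps <- filterSignificant(ps, dist, cfg$pathPCutoff)
    if (!pathCount(ps)) return(ps)
    selectTopN(ps, cfg$topN)
}

#' Iterative refinement of the locally optimal network
#'
#' Escapes local optima of the greedy search: each iteration injects a
#' small random sample of full-graph edges absent from the current
#' network, re-runs the whole path stage (enumeration, scoring, Gaussian
#' refit, significance filter, top-N) on the augmented graph over all
#' original nodes, re-prunes to a new elbow network, and accepts the
#' proposal only if its score improves the incumbent by at least a
#' fraction \code{v}.  Refinement stops after \code{t} consecutive
#' non-improving iterations (or when no edges remain to add).
#'
#' @param initial the [CandidateNetwork-class] from [pruneToOptimal()].
#' @param fullGraph the initial [SignalGraph-class].
#' @param cfg a [runConfig()] list; \code{v}, \code{t} and
#'   \code{nRandomEdges} control the loop.  RNG state is taken as-is;
#'   seed upstream for reproducibility.
#' @param lambda frozen regularization coefficient.
#' @param shiftRef frozen shift reference.
#' @param dist frozen Gaussian score distribution from the initial
#'   enumeration, so path significance means the same thing in every
#'   iteration.
#' @return list: \code{network} (best accepted [CandidateNetwork-class]),
#'   \code{history} (data.frame: iteration, n_edges_added, s_q, accepted,
#'   stagnant).
#' @export
refineNetwork <- function(initial, fullGraph, cfg, lambda, shiftRef,
                          dist = NULL) {
    current <- initial
    full <- asIgraph(fullGraph)
    fullKeys <- {
        el <- igraph::as_edgelist(full, names = TRUE)
        paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "\r")
    }
    hist <- list()
    stagnant <- 0L
    it <- 0L
    while (stagnant < cfg$t) {
        it <- it + 1L
        curEl <- igraph::as_edgelist(current@graph, names = TRUE)
        curKeys <- if (nrow(curEl))
            paste(pmin(curEl[, 1L], curEl[, 2L]),
                  pmax(curEl[, 1L], curEl[, 2L]), sep = "\r") else character()
        # candidate edges touch the current network: they either densify
        # it or recruit a neighboring node into it
        curNodes <- igraph::V(current@graph)$name
        fullEl <- igraph::as_edgelist(full, names = TRUE)
        touches <- fullEl[, 1L] %in% curNodes | fullEl[, 2L] %in% curNodes
        addable <- which(touches & !(fullKeys %in% curKeys))
        if (!length(addable)) break
        nAdd <- if (!is.null(cfg$nRandomEdges)) cfg$nRandomEdges
                else max(1L, ceiling(0.01 * igraph::ecount(current@graph)))
        nAdd <- min(nAdd, length(addable))
        chosen <- sample(addable, nAdd)

        keepEdge <- fullKeys %in% c(curKeys, fullKeys[chosen])
        work <- igraph::subgraph_from_edges(full, which(keepEdge),
                                            delete.vertices = FALSE)
        workSg <- new("SignalGraph", graph = work)
        ps <- .pathStage(workSg, cfg, dist = dist)
        proposal <- if (pathCount(ps)) {
            pruneToOptimal(ps, lambda = lambda, sg = fullGraph,
                           shiftRef = shiftRef)$network
        } else NULL

        oldScore <- current@score
        newScore <- if (is.null(proposal)) -Inf else proposal@score
        improved <- if (oldScore == 0) (newScore - oldScore) >= cfg$v
                    else newScore >= oldScore + cfg$v * abs(oldScore)
        if (improved) {
            current <- proposal
            stagnant <- 0L
        } else stagnant <- stagnant + 1L
        hist[[it]] <- data.frame(iteration = it, n_edges_added = nAdd,
                                 s_q = if (is.finite(newScore)) newScore else NA_real_,
                                 accepted = improved, stagnant = stagnant)
    }
    list(network = current,
         history = if (length(hist)) do.call(rbind, hist)
                   else data.frame(iteration = integer(),
                                   n_edges_added = integer(), s_q = numeric(),
                                   accepted = logical(), stagnant = integer()))
}
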