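# Shared fixtures, built in code at test time.

# A SignalGraph from explicit parts.  `edges` is a data.frame
# (from, to, confidence); lfc and roles are named vectors (defaults:
# weight 0, role internal).
makeSignalGraph <- function(edges, lfc = NULL, sources = character(),
                            targets = character()) {
    g <- igraph::graph_from_data_frame(
        edges[, 1:2], directed = FALSE,
        vertices = data.frame(name = sort(unique(c(edges[[1]], edges[[2]])))))
    igraph::E(g)$confidence <- edges$confidence
    nm <- igraph::V(g)$name
    w <- rep(0, length(nm))
    if (!is.null(lfc)) {
        idx <- match(names(lfc), nm)
        ok <- !is.na(idx)
        w[idx[ok]] <- unname(lfc)[ok]
    }
    igraph::V(g)$abs_log2fc <- w
    role <- rep("internal", length(nm))
    role[nm %in% targets] <- "target"
    role[nm %in% sources] <- "source"
    igraph::V(g)$role <- role
    new("SignalGraph", graph = g)
}

# Chain S - a - b - ... - T with uniform confidence.
chainGraph <- function(nodes, confidence = 1, lfc = NULL) {
    n <- length(nodes)
    makeSignalGraph(
        data.frame(from = nodes[-n], to = nodes[-1],
                   confidence = rep(confidence, n - 1)),
        lfc = lfc, sources = nodes[1], targets = nodes[n])
}

# A scored PathSet built directly from node lists + scores (bypasses
# enumeration; for optimizer/ranking tests).
makePathSet <- function(nodesList, scores, probScores = scores) {
    if (!length(nodesList)) {
        df <- data.frame(source = character(), target = character(),
                         k = integer(), stringsAsFactors = FALSE)
        df$nodes <- list()
        df$score <- numeric()
        df$prob_score <- numeric()
        df$pvalue <- numeric()
        return(new("PathSet",
                   paths = df[, c("source", "target", "nodes", "k", "score",
                                  "prob_score", "pvalue")]))
    }
    df <- data.frame(
        source = vapply(nodesList, `[`, character(1), 1L),
        target = vapply(nodesList, function(x) x[length(x)], character(1)),
        k = lengths(nodesList), stringsAsFactors = FALSE)
    df$nodes <- nodesList
    df$score <- scores
    df$prob_score <- probScores
    df$pvalue <- NA_real_
    rownames(df) <- NULL
    new("PathSet", paths = df)
}

# Random connected-ish test graph with roles, for property tests.
randomSignalGraph <- function(nNodes, pEdge = 0.35, nSources = 2,
                              nTargets = 2, seed = 1) {
    set.seed(seed)
    repeat {
        g <- igraph::sample_gnp(nNodes, pEdge)
        if (igraph::ecount(g) >= nNodes - 1) break
    }
    nm <- sprintf("n%02d", seq_len(nNodes))
    el <- igraph::as_edgelist(g)
    edges <- data.frame(from = nm[el[, 1]], to = nm[el[, 2]],
                        confidence = runif(nrow(el), 0.3, 1))
    connected <- nm[nm %in% c(edges$from, edges$to)]
    roles <- sample(connected)
    lfc <- setNames(round(runif(nNodes, 0, 2), 2), nm)
    makeSignalGraph(edges, lfc = lfc,
                    sources = roles[seq_len(nSources)],
                    targets = roles[nSources + seq_len(nTargets)])
}

# Independent brute-force path oracle: every simple path from each
# source to each target (DFS on the adjacency list), filtered to the
# per-pair minimum length, capped at K nodes.
bruteForceShortestPaths <- function(sg, K) {
    g <- asIgraph(sg)
    nm <- igraph::V(g)$name
    adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)),
                  function(v) nm[as.integer(v)])
    names(adj) <- nm
    out <- list()
    dfs <- function(path, target) {
        last <- path[length(path)]
        if (last == target) { out[[length(out) + 1L]] <<- path; return() }
        if (length(path) >= K) return()
        for (nb in adj[[last]])
            if (!nb %in% path) dfs(c(path, nb), target)
    }
    acc <- list()
    for (s in sourceNodes(sg)) for (t in targetNodes(sg)) {
        out <- list()
        dfs(s, t)
        if (length(out)) {
            kmin <- min(lengths(out))
            acc <- c(acc, out[lengths(out) == kmin])
        }
    }
    acc
}
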