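# In-silico knockout scoring, gene ranking, and the degree-preserving
# permutation null.

#' Knockout score of a single gene
#'
#' Removes node \code{gene} and all incident edges from the converged
#' network -- every retained path through it dies -- and returns the
#' change in regularized network score,
#' \code{score(surviving paths) - score(network)}.  The same lambda and
#' shifted path scores are reused: knockout is a perturbation of the
#' fixed network, not a re-inference, so no re-tuning happens.
#'
#' @param net the converged [CandidateNetwork-class].
#' @param gene a node of the network.
#' @return the knockout score (usually <= 0; more negative = more
#'   important).
#' @export
knockoutScore <- function(net, gene) {
    df <- net@paths@paths
    if (!gene %in% igraph::V(net@graph)$name)
        stop("gene '", gene, "' is not a node of the network")
    hit <- vapply(df$nodes, function(x) gene %in% x, logical(1))
    surviving <- .makePathSet(df[!hit, , drop = FALSE])
    networkScoreOf(surviving, net@lambda)@score - net@score
}

#' Rank all genes of a network by in-silico knockout
#'
#' Computes the knockout score of every node, ranks ascending (most
#' negative first, i.e. the genes whose removal hurts the network most
#' get rank 1), breaking ties lexicographically by gene so runs are
#' reproducible.
#'
#' @param net the converged [CandidateNetwork-class].
#' @param null optional null distribution from [buildNull()]; when
#'   given, each gene receives an empirical p-value (fraction of pooled
#'   background |score| at least as extreme) and a significance call at
#'   p <= 0.05.
#' @return data.frame: gene, ko_score, rank, empirical_p, significant,
#'   role, abs_log2fc, degree.
#' @export
rankGenes <- function(net, null = NULL) {
    g <- net@graph
    nm <- igraph::V(g)$name
    if (!length(nm)) stop("cannot rank an empty network")
    df <- net@paths@paths
    # membership matrix computed once: paths containing each gene
    lens <- lengths(df$nodes)
    pid <- rep.int(seq_len(nrow(df)), lens)
    allv <- unlist(df$nodes, use.names = FALSE)
    byGene <- split(pid, allv)
    base <- net@score
    ko <- vapply(nm, function(gene) {
        hit <- unique(byGene[[gene]])
        keep <- setdiff(seq_len(nrow(df)), hit)
        networkScoreOf(.makePathSet(df[keep, , drop = FALSE]),
                       net@lambda)@score - base
    }, numeric(1))
    role <- igraph::V(g)$role
    lfcAttr <- igraph::V(g)$abs_log2fc
    out <- data.frame(gene = nm, ko_score = unname(ko),
                      role = if (is.null(role)) NA_character_ else role,
                      abs_log2fc = if (is.null(lfcAttr)) NA_real_ else lfcAttr,
                      degree = igraph::degree(g), stringsAsFactors = FALSE)
    out <- out[.radixOrder(out$ko_score, out$gene), ]
    out$rank <- seq_len(nrow(out))
    if (!is.null(null)) {
        out$empirical_p <- vapply(abs(out$ko_score), function(s)
            mean(null$scores >= s), numeric(1))
        out$significant <- out$empirical_p <= 0.05
    } else {
        out$empirical_p <- NA_real_
        out$significant <- NA
    }
    rownames(out) <- NULL
    out[c("gene", "ko_score", "rank", "empirical_p", "significant",
          "role", "abs_log2fc", "degree")]
}

#' Degree-preserving permutation of a signal graph
#'
#' Rewires the edges by repeated double-edge swaps, preserving every
#' node's degree exactly (hence node count and the degree distribution);
#' node attributes are untouched and each rewired edge keeps its
#' original confidence.  Graphs too small to admit a simplicity-
#' preserving swap are returned unchanged with a warning.
#'
#' @param sg a [SignalGraph-class].
#' @param nSwaps double-edge-swap attempts; default \code{10 * |E|} for
#'   adequate mixing.  RNG state is used; seed upstream.
#' @return a rewired [SignalGraph-class].
#' @export
permuteNetwork <- function(sg, nSwaps = NULL) {
    g <- asIgraph(sg)
    m <- igraph::ecount(g)
    if (m < 2L) {
        warning("fewer than 2 edges; returning the graph unchanged")
        return(sg)
    }
    if (is.null(nSwaps)) nSwaps <- 10L * m
    el <- igraph::as_edgelist(g, names = FALSE)
    conf <- igraph::E(g)$confidence
    seen <- new.env(hash = TRUE, parent = emptyenv())
    ekey <- function(a, b) paste(min(a, b), max(a, b))
    for (i in seq_len(m)) assign(ekey(el[i, 1L], el[i, 2L]), TRUE, seen)
    done <- 0L
    for (i in seq_len(nSwaps)) {
        pick <- sample.int(m, 2L)
        a <- el[pick[1L], 1L]; b <- el[pick[1L], 2L]
        c_ <- el[pick[2L], 1L]; d <- el[pick[2L], 2L]
        # propose (a,b),(c,d) -> (a,d),(c,b); keeps every degree
        if (a == d || c_ == b) next
        if (length(unique(c(a, b, c_, d))) < 4L) next
        k1 <- ekey(a, d); k2 <- ekey(c_, b)
        if (exists(k1, seen, inherits = FALSE) ||
            exists(k2, seen, inherits = FALSE)) next
        rm(list = c(ekey(a, b), ekey(c_, d)), envir = seen)
        assign(k1, TRUE, seen); assign(k2, TRUE, seen)
        el[pick[1L], 2L] <- d
        el[pick[2L], 2L] <- b
        done <- done + 1L
    }
    if (done == 0L) {
        warning("graph admits no degree-preserving swap; returned unchanged")
        return(sg)
    }
    g2 <- igraph::graph_from_edgelist(el, directed = FALSE)
    # carry over isolated vertices and all vertex attributes
    if (igraph::vcount(g2) < igraph::vcount(g))
        g2 <- igraph::add_vertices(g2, igraph::vcount(g) - igraph::vcount(g2))
    for (at in igraph::vertex_attr_names(g))
        g2 <- igraph::set_vertex_attr(g2, at,
                                      value = igraph::vertex_attr(g, at))
    igraph::E(g2)$confidence <- NA_real_
    eids <- igraph::get_edge_ids(g2, as.vector(t(el)))
    igraph::E(g2)$confidence[eids] <- conf   # each edge keeps its confidence
    new("SignalGraph", graph = g2)
}

#' Build an empirical null distribution of knockout scores
#'
#' Runs the whole inference pipeline on \code{nRuns} degree-preserving
#' permutations of the initial graph and pools the absolute knockout
#' scores of every gene in every permuted final network.  The
#' significance threshold is the empirical 95th percentile of the pooled
#' background (corresponding to p = 0.05); permuted runs that yield no
#' network contribute nothing.
#'
#' @param sg the initial [SignalGraph-class].
#' @param cfg a [runConfig()] list.
#' @param nRuns permutation runs.
#' @param refine run the refinement stage inside each permuted run
#'   (default TRUE, matching the real run).
#' @return list: \code{scores} (pooled |knockout| values), \code{nRuns},
#'   \code{threshold}.
#' @export
buildNull <- function(sg, cfg = runConfig(), nRuns = 10L, refine = TRUE) {
    pooled <- numeric()
    done <- 0L
    for (i in seq_len(nRuns)) {
        perm <- permuteNetwork(sg)
        res <- tryCatch(
            .corePipeline(perm, cfg, refine = refine),
            error = function(e) NULL)
        if (is.null(res) || !nrow(res$ranking)) next
        pooled <- c(pooled, abs(res$ranking$ko_score))
        done <- done + 1L
    }
    if (!length(pooled))
        stop("no permuted run produced a network; null is empty")
    list(scores = pooled, nRuns = done,
         threshold = unname(quantile(pooled, 0.95, type = 7)))
}

#' Degree-bias diagnostic
#'
#' Spearman correlation between a gene's degree in the final network and
#' the magnitude of its knockout score; reported so users can check that
#' prioritization is not driven by connectivity alone.
#'
#' @param records ranking data.frame from [rankGenes()].
#' @return list: \code{rho}, \code{p} (both NA with a \code{note} when
#'   degrees or scores are constant), \code{n}.
#' @export
degreeBiasDiagnostic <- function(records) {
    if (nrow(records) < 3L) stop("need at least 3 ranked genes")
    d <- records$degree
    s <- abs(records$ko_score)
    if (sd(d) == 0 || sd(s) == 0)
        return(list(rho = NA_real_, p = NA_real_, n = nrow(records),
                    note = "constant degrees or scores; correlation undefined"))
    ct <- suppressWarnings(cor.test(d, s, method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(records),
         note = NULL)
}
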