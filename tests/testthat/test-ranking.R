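# Knockout scoring, gene ranking, permutation null, degree diagnostic.

# build a CandidateNetwork from node lists + scores at a given lambda
makeNet <- function(nodesList, scores, lambda) {
    ps <- makePathSet(nodesList, scores)
    ps@paths$score_shifted <- shiftPathScores(scores)
    networkScoreOf(ps, lambda = lambda)
}

# independent oracle: recompute the regularized score of the surviving
# path set from scratch
oracleKnockout <- function(nodesList, scores, lambda, gene) {
    shifted <- shiftPathScores(scores)
    keep <- !vapply(nodesList, function(x) gene %in% x, logical(1))
    full <- makeNet(nodesList, scores, lambda)
    if (!any(keep)) return(0 - networkScore(full))
    sub <- makePathSet(nodesList[keep], scores[keep])
    sub@paths$score_shifted <- shifted[keep]
    networkScore(networkScoreOf(sub, lambda)) - networkScore(full)
}

test_that("knocking out the only path's interior node forfeits the whole score", {
    net <- makeNet(list(c("S", "m", "T")), scores = 3, lambda = 0.5)
    expect_equal(knockoutScore(net, "m"), 0 - networkScore(net))
    expect_error(knockoutScore(net, "zz"), "not a node")
})

test_that("knockout of one of two disjoint paths removes exactly its contribution", {
    nodes <- list(c("S1", "a", "T1"), c("S2", "b", "T2"))
    scores <- c(2, 2)
    lam <- 0.8
    net <- makeNet(nodes, scores, lam)
    got <- knockoutScore(net, "a")
    expect_equal(got, oracleKnockout(nodes, scores, lam, "a"), tolerance = 1e-9)
    # decomposition: -log2 s'(P) + lambda * (degree change)
    shifted <- shiftPathScores(scores)
    adFull <- avgDegree(net)
    adLeft <- 2 * 2 / 3
    expect_equal(got, -log2(shifted[1]) + lam * (adFull - adLeft),
                 tolerance = 1e-9)
})

test_that("knockout scores equal from-scratch recomputation for every node (property)", {
    set.seed(31)
    for (rep in 1:5) {
        nP <- sample(3:8, 1)
        pool <- c("S1", "S2", letters[1:8], "T1", "T2")
        nodes <- lapply(seq_len(nP), function(i) {
            mid <- sample(letters[1:8], sample(1:3, 1))
            c(sample(c("S1", "S2"), 1), mid, sample(c("T1", "T2"), 1))
        })
        scores <- round(rnorm(nP, 0, 2), 3)
        lam <- runif(1, 0, 3)
        net <- makeNet(nodes, scores, lam)
        for (gene in igraph::V(asIgraph(net))$name)
            expect_equal(knockoutScore(net, gene),
                         oracleKnockout(nodes, scores, lam, gene),
                         tolerance = 1e-9)
    }
})

test_that("ranking orders by ascending knockout score with lexicographic ties", {
    # single 3-node path: every knockout kills it; ties resolved by name
    net <- makeNet(list(c("S", "m", "T")), scores = 3, lambda = 0.2)
    r <- rankGenes(net)
    expect_equal(nrow(r), 3L)
    expect_equal(r$gene, c("S", "T", "m"))   # equal scores -> lexicographic
    expect_equal(r$rank, 1:3)
    expect_equal(length(unique(r$ko_score)), 1L)

    # hub shared by all three paths ranks first
    nodes <- list(c("S1", "hub", "T1"), c("S2", "hub", "T2"),
                  c("S3", "hub", "T3"))
    netH <- makeNet(nodes, scores = c(1, 2, 3), lambda = 0.3)
    rH <- rankGenes(netH)
    expect_equal(rH$gene[1], "hub")
    expect_equal(nrow(rH), igraph::vcount(asIgraph(netH)))
})

test_that("total knockout score is non-positive when lambda is zero", {
    set.seed(41)
    nodes <- lapply(1:6, function(i)
        c("S", sample(letters[1:5], sample(1:3, 1)), "T"))
    net <- makeNet(nodes, scores = rnorm(6, 1), lambda = 0)
    r <- rankGenes(net)
    expect_lte(sum(r$ko_score), 1e-12)
    expect_true(all(r$ko_score <= 1e-12))   # removals only delete score terms
})

test_that("permutation preserves the degree multiset exactly and keeps attributes", {
    sg <- randomSignalGraph(30, pEdge = 0.25, seed = 51)
    degIn <- sort(igraph::degree(asIgraph(sg)))
    set.seed(1)
    perm <- permuteNetwork(sg)
    expect_equal(sort(igraph::degree(asIgraph(perm))), degIn)
    expect_setequal(igraph::V(asIgraph(perm))$name,
                    igraph::V(asIgraph(sg))$name)
    # node attributes untouched
    expect_equal(nodeWeights(perm)[names(nodeWeights(sg))], nodeWeights(sg))
    expect_equal(nodeRoles(perm)[names(nodeRoles(sg))], nodeRoles(sg))
    # confidences travel with edges: multiset unchanged
    expect_equal(sort(igraph::E(asIgraph(perm))$confidence),
                 sort(igraph::E(asIgraph(sg))$confidence))
    # determinism
    set.seed(7); a <- permuteNetwork(sg)
    set.seed(7); b <- permuteNetwork(sg)
    expect_identical(igraph::as_edgelist(asIgraph(a)),
                     igraph::as_edgelist(asIgraph(b)))
})

test_that("degenerate graphs warn and pass through permutation unchanged", {
    tiny <- makeSignalGraph(data.frame(from = "A", to = "B", confidence = 0.5),
                            sources = "A", targets = "B")
    expect_warning(permuteNetwork(tiny), "unchanged")
    tri <- makeSignalGraph(
        data.frame(from = c("A", "B", "C"), to = c("B", "C", "A"),
                   confidence = 0.5),
        sources = "A", targets = "B")
    set.seed(1)
    res <- tryCatch(permuteNetwork(tri), warning = function(w) tri)
    expect_equal(sort(igraph::degree(asIgraph(res))), sort(c(2, 2, 2)),
                 ignore_attr = TRUE)
})

test_that("empirical null thresholds knockout scores at the 95th percentile", {
    sg <- randomSignalGraph(16, pEdge = 0.4, seed = 61)
    cfg <- runConfig(seed = 61, pathPCutoff = 0.9, topN = 3, t = 1)
    set.seed(61)
    null <- buildNull(sg, cfg, nRuns = 3, refine = FALSE)
    expect_gt(length(null$scores), 0)
    expect_equal(null$threshold,
                 unname(quantile(null$scores, 0.95, type = 7)))
    # significance monotonicity: a higher percentile can only lose genes
    ps <- scorePaths(enumeratePaths(sg, cfg), sg, 1)
    shiftRef <- min(ps@paths$score)
    opt <- pruneToOptimal(ps, "auto", sg, shiftRef)
    r <- rankGenes(opt$network, null = null)
    sig95 <- abs(r$ko_score) > null$threshold
    sig99 <- abs(r$ko_score) > unname(quantile(null$scores, 0.99, type = 7))
    expect_true(all(which(sig99) %in% which(sig95)))
    # empirical p in [0,1] and non-decreasing as |score| shrinks
    expect_true(all(r$empirical_p >= 0 & r$empirical_p <= 1))
    ord <- order(-abs(r$ko_score))
    expect_true(all(diff(r$empirical_p[ord]) >= -1e-12))
})

test_that("degree-bias diagnostic reports Spearman correlation and handles degenerate input", {
    rec <- data.frame(gene = letters[1:6], ko_score = -c(1, 2, 3, 4, 5, 6),
                      degree = c(1, 2, 3, 4, 5, 6))
    d <- degreeBiasDiagnostic(rec)
    expect_equal(d$rho, 1)
    # order invariance
    d2 <- degreeBiasDiagnostic(rec[sample(6), ])
    expect_equal(d2$rho, d$rho)
    flat <- data.frame(gene = letters[1:4], ko_score = -2, degree = 1:4)
    expect_true(is.na(degreeBiasDiagnostic(flat)$rho))
    expect_error(degreeBiasDiagnostic(rec[1:2, ]), "at least 3")
})
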