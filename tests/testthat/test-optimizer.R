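# Regularized network score, greedy pruning, elbow selection, refinement.

test_that("score shift maps the minimum to 1 and preserves order", {
    expect_equal(shiftPathScores(c(-3, 0, 2)), c(1, 4, 6))
    expect_equal(shiftPathScores(c(2, 5)), c(1, 4))  # applied even when positive
    set.seed(2)
    s <- rnorm(50)
    expect_equal(order(shiftPathScores(s)), order(s))
    # frozen reference: scores below it clamp at 1
    expect_equal(shiftPathScores(c(-5, 0), reference = -2), c(1, 3))
})

test_that("network score decomposes into score term and degree penalty", {
    ps <- makePathSet(list(c("A", "B", "C")), scores = 2)
    ps@paths$score_shifted <- 2
    net0 <- networkScoreOf(ps, lambda = 0)
    expect_equal(networkScore(net0), 1.0)      # log2(2), no penalty
    net1 <- networkScoreOf(ps, lambda = 1)
    expect_equal(avgDegree(net1), 4 / 3)       # 3 nodes, 2 edges
    expect_equal(networkScore(net1), 1 - 4 / 3, tolerance = 1e-12)
    # a second path over the same nodes raises the score term only
    ps2 <- makePathSet(list(c("A", "B", "C"), c("A", "B", "C")), scores = c(2, 2))
    ps2@paths$score_shifted <- c(2, 2)
    net2 <- networkScoreOf(ps2, lambda = 1)
    expect_equal(scoreTerm(net2), 2)
    expect_equal(avgDegree(net2), 4 / 3)
    # empty set scores 0 by convention
    empty <- makePathSet(list(), numeric(0))
    expect_equal(networkScore(networkScoreOf(empty, lambda = 3)), 0)
})

test_that("candidate network score is self-consistent to 1e-9", {
    set.seed(9)
    nodes <- lapply(1:6, function(i)
        c("S", sample(letters[1:6], sample(1:3, 1)), "T"))
    ps <- makePathSet(nodes, scores = rnorm(6))
    ps@paths$score_shifted <- shiftPathScores(ps@paths$score)
    net <- networkScoreOf(ps, lambda = 1.7)
    recomputed <- sum(log2(ps@paths$score_shifted)) -
        1.7 * (2 * igraph::ecount(asIgraph(net)) / igraph::vcount(asIgraph(net)))
    expect_equal(networkScore(net), recomputed, tolerance = 1e-9)
})

test_that("automatic lambda is the ratio of trajectory means", {
    expect_equal(autoLambda(data.frame(score_term = c(10, 6),
                                       avg_degree = c(2, 2))), 4)
    expect_equal(autoLambda(data.frame(score_term = 5, avg_degree = 2.5)), 2)
    expect_equal(autoLambda(data.frame(score_term = c(0, 0),
                                       avg_degree = c(2, 1))), 0)
    expect_error(autoLambda(data.frame(score_term = 3, avg_degree = 0)),
                 "lambda")
})

test_that("greedy pruning removes paths in ascending score order and matches brute force", {
    set.seed(11)
    nodes <- list(c("S", "a", "T"), c("S", "b", "T"), c("S", "c", "T"),
                  c("S", "a", "b", "T"), c("S", "c", "d", "T"),
                  c("S", "d", "T"))
    scores <- c(3, -1, 2, 5, 0, 2)   # one tie (paths 3 and 6)
    ps <- makePathSet(nodes, scores)
    pr <- greedyPrune(ps, lambda = 1.3)
    expect_equal(nrow(pr$trajectory), 6L)
    expect_equal(pr$trajectory$removed, 0:5)
    # ascending score, tie broken by lexicographic node sequence:
    # path 3 = S|c|T sorts after path 6 = S|d|T?  "S|c|T" < "S|d|T"
    expect_equal(ps@paths$score[pr$order], sort(scores))
    tieFirst <- ps@paths$nodes[[pr$order[3]]]
    expect_equal(tieFirst, c("S", "c", "T"))

    # brute-force oracle: recompute the full score for every suffix
    shifted <- shiftPathScores(scores)
    for (i in seq_along(nodes)) {
        keep <- pr$order[i:length(nodes)]
        sub <- makePathSet(nodes[keep], scores[keep])
        sub@paths$score_shifted <- shifted[keep]
        expect_equal(pr$trajectory$s_q[i],
                     networkScore(networkScoreOf(sub, lambda = 1.3)),
                     tolerance = 1e-9)
    }
})

test_that("elbow picks the maximum distance to the endpoint chord", {
    tr <- data.frame(removed = 0:4, s_q = c(10, 9.8, 9.6, 5, 1))
    expect_equal(selectElbow(tr), 3L)    # last point before the plunge
    lin <- data.frame(removed = 0:4, s_q = seq(10, 2, length.out = 5))
    expect_equal(selectElbow(lin), 1L)   # degenerate: ties go to fewer removals
    expect_equal(selectElbow(data.frame(removed = 0:1, s_q = c(3, 1))), 1L)
})

test_that("refinement obeys its stopping contract and is deterministic", {
    sg <- randomSignalGraph(14, pEdge = 0.4, seed = 21)
    cfg <- runConfig(seed = 21, pathPCutoff = 0.9, topN = 3)
    ps <- scorePaths(enumeratePaths(sg, cfg), sg, 1)
    expect_gt(pathCount(ps), 1)
    shiftRef <- min(ps@paths$score)
    opt <- pruneToOptimal(ps, lambda = "auto", sg = sg, shiftRef = shiftRef)

    # v effectively infinite: nothing accepted, stops after exactly t rounds
    cfgV <- runConfig(seed = 21, v = 1e9, t = 4, pathPCutoff = 0.9, topN = 3)
    set.seed(1)
    r1 <- refineNetwork(opt$network, sg, cfgV, opt$lambda, shiftRef)
    expect_true(nrow(r1$history) <= 4 || all(!r1$history$accepted))
    expect_false(any(r1$history$accepted))
    expect_identical(networkScore(r1$network), networkScore(opt$network))

    # t = 1 with a non-improving first proposal: exactly one iteration
    cfgT <- runConfig(seed = 21, v = 1e9, t = 1, pathPCutoff = 0.9, topN = 3)
    set.seed(1)
    rT <- refineNetwork(opt$network, sg, cfgT, opt$lambda, shiftRef)
    expect_equal(nrow(rT$history), 1L)

    # determinism under a fixed seed
    cfgR <- runConfig(seed = 21, t = 3, pathPCutoff = 0.9, topN = 3)
    set.seed(99); a <- refineNetwork(opt$network, sg, cfgR, opt$lambda, shiftRef)
    set.seed(99); b <- refineNetwork(opt$network, sg, cfgR, opt$lambda, shiftRef)
    expect_equal(a$history, b$history)
    expect_equal(networkScore(a$network), networkScore(b$network))
})

test_that("accepted refinement scores increase by at least the v fraction", {
    for (seed in c(3, 17, 29)) {
        sg <- randomSignalGraph(14, pEdge = 0.35, seed = seed)
        cfg <- runConfig(seed = seed, pathPCutoff = 0.9, topN = 3, t = 3,
                         v = 0.05)
        ps <- scorePaths(enumeratePaths(sg, cfg), sg, 1)
        if (pathCount(ps) < 2) next
        shiftRef <- min(ps@paths$score)
        opt <- pruneToOptimal(ps, "auto", sg, shiftRef)
        set.seed(seed)
        ref <- refineNetwork(opt$network, sg, cfg, opt$lambda, shiftRef)
        acc <- c(networkScore(opt$network),
                 ref$history$s_q[ref$history$accepted])
        if (length(acc) > 1)
            for (i in 2:length(acc))
                expect_gte(acc[i], acc[i - 1] + cfg$v * abs(acc[i - 1]) - 1e-9)
        expect_lte(max(ref$history$stagnant), cfg$t)
    }
})
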