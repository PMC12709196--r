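# Synthetic interactome generation, cascade implantation, noise models,
# recovery metrics.

smallSim <- function(seed = 1) generateInteractome(
    nReceptors = 12, nTFs = 6, nGenes = 150, tfDegreeMeanlog = log(12),
    seed = seed)

test_that("interactome generation is deterministic with the stated layer sizes", {
    a <- smallSim(3); b <- smallSim(3)
    expect_identical(igraph::as_edgelist(asIgraph(a)),
                     igraph::as_edgelist(asIgraph(b)))
    expect_identical(igraph::E(asIgraph(a))$confidence,
                     igraph::E(asIgraph(b))$confidence)
    l <- table(igraph::V(asIgraph(a))$layer)
    expect_equal(unname(l[c("receptor", "tf", "gene")]),
                 c(12L, 6L, 150L), ignore_attr = TRUE)
    expect_length(receptorNames(a), 12L)
})

test_that("generated degree distribution is heavy-tailed and mostly connected", {
    net <- generateInteractome(seed = 5)
    deg <- igraph::degree(asIgraph(net))
    expect_gte(max(deg), 3 * median(deg))
    comp <- igraph::components(asIgraph(net))
    expect_gte(max(comp$csize), 0.9 * igraph::vcount(asIgraph(net)))
    conf <- igraph::E(asIgraph(net))$confidence
    expect_true(all(conf >= 0.5 & conf <= 1))
})

test_that("fraction-to-count selection reproduces the published cascade arithmetic", {
    expect_equal(countFromFraction(172, 0.05), 8L)
    expect_equal(countFromFraction(296, 0.05), 14L)
    expect_equal(countFromFraction(3, 0.05), 1L)    # floor with minimum 1
    expect_equal(countFromFraction(10, 1), 10L)
})

test_that("cascade implantation marks disjoint classes with the stated DE signal", {
    net <- smallSim(7)
    imp <- implantCascade(net, receptorFrac = 0.25, seed = 7)
    tr <- imp$truth
    expect_length(tr@receptors, 3L)     # floor(0.25 * 12)
    expect_gte(length(tr@tfs), 1L)
    all3 <- implantedNodes(tr)
    expect_equal(anyDuplicated(all3), 0L)
    de <- imp$de
    expect_setequal(de$gene, igraph::V(asIgraph(net))$name)
    expect_true(all(de$log2fc[de$gene %in% all3] == 1.0))
    expect_true(all(de$padj[de$gene %in% all3] == 1e-6))
    expect_true(all(de$log2fc[!de$gene %in% all3] == 0))
    expect_true(all(de$padj[!de$gene %in% all3] == 1))
    # optional sub-threshold background scatter never creates targets
    sc <- implantCascade(net, receptorFrac = 0.25, backgroundLfcSd = 0.2,
                         seed = 7)$de
    bg <- sc[!sc$gene %in% all3, ]
    expect_gt(sd(bg$log2fc), 0)
    expect_true(all(bg$padj == 1))
    # every implanted TF reachable from an implanted receptor within 3 hops
    d <- igraph::distances(asIgraph(net), v = tr@receptors, to = tr@tfs)
    expect_true(all(apply(d, 2, min) <= 3))
    # full receptor fraction implants every receptor
    impAll <- implantCascade(net, receptorFrac = 1, seed = 7)
    expect_setequal(impAll$truth@receptors, receptorNames(net))
})

test_that("gaussian noise perturbs exactly the chosen fraction, deterministically", {
    net <- smallSim(9)
    de <- implantCascade(net, receptorFrac = 0.25, seed = 9)$de
    noisy <- addGaussianNoise(de, frac = 0.10, seed = 4)
    expect_equal(sum(noisy$log2fc != de$log2fc), floor(0.10 * nrow(de)))
    expect_equal(noisy$padj, de$padj)   # only log2FC is perturbed
    expect_identical(addGaussianNoise(de, 0.10, seed = 4), noisy)
    expect_false(identical(addGaussianNoise(de, 0.10, seed = 5), noisy))
})

test_that("dropout noise zeroes the chosen fraction of informative values", {
    net <- smallSim(9)
    de <- implantCascade(net, receptorFrac = 0.5, seed = 9)$de
    nz <- sum(de$log2fc != 0)
    drop <- addDropoutNoise(de, frac = 0.2, seed = 4)
    expect_equal(sum(de$log2fc != 0) - sum(drop$log2fc != 0),
                 floor(0.2 * nz))
    changed <- which(drop$log2fc != de$log2fc)
    expect_true(all(drop$padj[changed] == 1))
    full <- addDropoutNoise(de, frac = 1, seed = 4)
    expect_true(all(full$log2fc == 0))
    expect_identical(addDropoutNoise(de, 0.2, seed = 4), drop)
})

test_that("recovery metrics implement precision, recall and F1 per class", {
    net <- smallSim(11)
    layers <- igraph::V(asIgraph(net))$layer
    nm <- igraph::V(asIgraph(net))$name
    recs <- nm[layers == "receptor"]
    tfs <- nm[layers == "tf"]
    truth <- new("CascadeTruth", receptors = recs[1:2], tfs = tfs[1],
                 genes = character(), lfc = 1)
    # ranking: 2 implanted + 6 other receptors in the list, 1 implanted TF
    ranked <- c(recs[1:8], tfs[1])
    ranking <- data.frame(gene = ranked, ko_score = -seq_along(ranked),
                          rank = seq_along(ranked))
    m <- suppressWarnings(evaluateRecovery(ranking, truth, net, topK = 100))
    rr <- m[m$class == "receptor", ]
    expect_equal(rr$recall, 1.0)
    expect_equal(rr$precision, 2 / 8)
    expect_equal(rr$f1, 2 * 0.25 * 1 / 1.25)   # 0.4: harmonic mean
    tt <- m[m$class == "tf", ]
    expect_equal(tt$precision, 1)
    expect_equal(tt$recall, 1)
    expect_equal(tt$f1, 1)
})

test_that("top-k overlap handles short rankings and boundary cases", {
    a <- data.frame(gene = letters[1:10], rank = 1:10)
    b <- data.frame(gene = c(letters[1:5], LETTERS[1:5]), rank = 1:10)
    expect_equal(topOverlap(a, b, k = 10), 0.5)
    expect_equal(topOverlap(a, a, k = 100), 1.0)   # k capped at length
    expect_equal(topOverlap(letters[1:3], letters[3:1], k = 2),
                 0.5)   # head(a,2)={a,b}, head(b,2)={c,b}
})

test_that("a zero-noise control replicate reproduces the clean ranking exactly", {
    net <- smallSim(13)
    imp <- implantCascade(net, receptorFrac = 0.25, seed = 13)
    cfg <- runConfig(seed = 13, t = 2)
    ppi <- interactomeToPPI(net)
    clean <- runPipeline(ppi, imp$de, receptorNames(net), cfg)$ranking
    again <- runPipeline(ppi, imp$de, receptorNames(net), cfg)$ranking
    expect_identical(clean, again)
    expect_equal(topOverlap(clean, again, k = 100), 1.0)
})

test_that("robustness study produces one row per condition-replicate with overlaps in [0,1]", {
    net <- smallSim(17)
    imp <- implantCascade(net, receptorFrac = 0.25, seed = 17)
    cfg <- runConfig(seed = 17, t = 1)
    st <- robustnessStudy(net, imp$de, cfg, noiseKinds = "dropout",
                          fracs = c(0.05, 0.2), nReps = 2, k = 20)
    expect_equal(nrow(st$runs), 4L)
    expect_true(all(st$runs$overlap >= 0 & st$runs$overlap <= 1, na.rm = TRUE))
    expect_equal(nrow(st$summary), 2L)
    st2 <- robustnessStudy(net, imp$de, cfg, noiseKinds = "dropout",
                           fracs = c(0.05, 0.2), nReps = 2, k = 20,
                           cleanRanking = st$clean)
    expect_equal(st$runs$overlap, st2$runs$overlap)
})
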