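# Synthetic layered interactomes with an implanted signaling cascade:
# the built-in validation harness.  Receptors sit on the periphery, TFs
# are mid-layer hubs wired into a preferential-attachment gene backbone,
# and a randomly seeded receptor->TF->gene cascade receives log2FC = 1.

#' Convert a fraction of a set to a count
#'
#' \code{floor(frac * n)} with a minimum of 1, the rule used for every
#' fraction-based selection in the simulator (e.g. 5\% of 172 receptors
#' = 8; top 5\% of 296 TF candidates = 14).
#'
#' @param n set size.
#' @param frac fraction in (0, 1].
#' @return integer count.
#' @export
countFromFraction <- function(n, frac) {
    stopifnot(n >= 1, frac > 0, frac <= 1)
    max(1L, as.integer(floor(frac * n)))
}

#' Generate a layered synthetic interactome
#'
#' Builds a degree-heterogeneous gene backbone by preferential
#' attachment, attaches each transcription factor as a mid-layer hub to
#' a heavy-tailed number of backbone genes (chosen preferentially by
#' degree), and attaches each receptor peripherally to a few genes.
#' Edge confidences are i.i.d. from \code{confidenceRange} (uniform).
#' The generated graph must keep at least 90\% of its nodes in the giant
#' component.
#'
#' @param nReceptors,nTFs,nGenes layer sizes.
#' @param geneEdgesPerNode preferential-attachment edges per new
#'   backbone gene.
#' @param tfDegreeMeanlog,tfDegreeSdlog log-normal parameters of the TF
#'   attachment degree (heavy-tailed hubs; defaults give a mean of
#'   roughly 45 targets per TF, so a handful of kept TFs span a cascade
#'   of about 5\% of a 2000-gene backbone).
#' @param receptorDegrees candidate peripheral degrees for receptors;
#'   the default keeps receptors above the backbone's mean degree,
#'   mirroring the above-average connectivity of curated receptors in
#'   experimental PPI resources.
#' @param confidenceRange uniform range of edge confidences.
#' @param seed RNG seed; generation is a pure function of the arguments.
#' @return a [SyntheticInteractome-class].
#' @export
generateInteractome <- function(nReceptors = 100L, nTFs = 50L,
                                nGenes = 2000L, geneEdgesPerNode = 2L,
                                tfDegreeMeanlog = log(40),
                                tfDegreeSdlog = 0.5,
                                receptorDegrees = 6:18,
                                confidenceRange = c(0.5, 1.0),
                                seed = 1L) {
    stopifnot(nReceptors >= 1, nTFs >= 1, nGenes >= 3)
    set.seed(seed)
    geneNames <- sprintf("G%04d", seq_len(nGenes))
    tfNames <- sprintf("TF%03d", seq_len(nTFs))
    recNames <- sprintf("R%03d", seq_len(nReceptors))

    backbone <- igraph::sample_pa(nGenes, m = geneEdgesPerNode,
                                  directed = FALSE)
    el <- igraph::as_edgelist(backbone, names = FALSE)
    edges <- data.frame(from = geneNames[el[, 1L]], to = geneNames[el[, 2L]],
                        stringsAsFactors = FALSE)
    prob <- igraph::degree(backbone) + 1

    tfDeg <- pmin(nGenes,
                  pmax(3L, round(stats::rlnorm(nTFs, tfDegreeMeanlog,
                                               tfDegreeSdlog))))
    tfEdges <- do.call(rbind, lapply(seq_len(nTFs), function(i) {
        tg <- sample.int(nGenes, tfDeg[i], prob = prob)
        data.frame(from = tfNames[i], to = geneNames[tg],
                   stringsAsFactors = FALSE)
    }))
    recDeg <- sample(receptorDegrees, nReceptors, replace = TRUE)
    recEdges <- do.call(rbind, lapply(seq_len(nReceptors), function(i) {
        tg <- sample.int(nGenes, recDeg[i], prob = prob)
        data.frame(from = recNames[i], to = geneNames[tg],
                   stringsAsFactors = FALSE)
    }))
    edges <- rbind(edges, tfEdges, recEdges)
    lo <- pmin(edges$from, edges$to); hi <- pmax(edges$from, edges$to)
    keep <- !duplicated(paste(lo, hi, sep = "\r")) & lo != hi
    edges <- data.frame(from = lo[keep], to = hi[keep],
                        stringsAsFactors = FALSE)

    verts <- data.frame(
        name = c(recNames, tfNames, geneNames),
        layer = rep(c("receptor", "tf", "gene"),
                    c(nReceptors, nTFs, nGenes)),
        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = verts)
    igraph::E(g)$confidence <- runif(igraph::ecount(g),
                                     confidenceRange[1L], confidenceRange[2L])
    comp <- igraph::components(g)
    if (max(comp$csize) < 0.9 * igraph::vcount(g))
        stop("generated interactome is too fragmented ",
             "(giant component < 90% of nodes); increase edge density")
    new("SyntheticInteractome", graph = g)
}

#' Receptor layer of a synthetic interactome
#'
#' @param net a [SyntheticInteractome-class].
#' @return character vector of receptor names (the full layer -- the
#'   receptor list fed to the pipeline, since cascade membership is
#'   unknown in a real experiment).
#' @export
receptorNames <- function(net) {
    v <- igraph::V(net@graph)
    v$name[v$layer == "receptor"]
}

#' Export a synthetic interactome as a PPI edge table
#'
#' @param net a [SyntheticInteractome-class].
#' @return data.frame (gene_a, gene_b, confidence) accepted by
#'   [buildInitialGraph()] and writable as TSV.
#' @export
interactomeToPPI <- function(net) {
    el <- igraph::as_edgelist(net@graph, names = TRUE)
    data.frame(gene_a = el[, 1L], gene_b = el[, 2L],
               confidence = igraph::E(net@graph)$confidence,
               stringsAsFactors = FALSE)
}

#' Implant a signaling cascade into a synthetic interactome
#'
#' Selects \code{floor(receptorFrac * nReceptors)} receptors (minimum
#' 1) uniformly at random, traces all nodes within \code{maxHops} edges
#' of them, keeps the top \code{floor(tfTopFrac * candidates)} most
#' connected reached TFs, and collects the gene-layer neighbors of the
#' kept TFs (optionally only the top \code{geneTopFrac} by degree).
#' Cascade members receive \code{log2FC = lfc} (expression doubled at
#' the default 1.0), adjusted p \code{1e-6} and baseMean 100; all other
#' nodes get log2FC 0 and adjusted p 1.
#'
#' @param net a [SyntheticInteractome-class].
#' @param receptorFrac fraction of receptors to implant.
#' @param tfTopFrac fraction of reached TFs to keep (by degree).
#' @param maxHops hop bound from implanted receptors.
#' @param geneTopFrac fraction of downstream genes kept (by degree).
#' @param lfc log2 fold change given to cascade members.
#' @param backgroundLfcSd optional standard deviation of measured
#'   log2FC scatter on non-cascade genes (their adjusted p stays 1, so
#'   they never become targets).  The default 0 gives the clean
#'   two-level table; a small positive value emulates the
#'   sub-threshold scatter real DE tables carry and smooths the
#'   path-score population.
#' @param seed RNG seed for the receptor draw and background scatter.
#' @return list: \code{truth} ([CascadeTruth-class]) and \code{de} (a DE
#'   table covering every node of the interactome).
#' @export
implantCascade <- function(net, receptorFrac = 0.05, tfTopFrac = 0.05,
                           maxHops = 3L, geneTopFrac = 1.0, lfc = 1.0,
                           backgroundLfcSd = 0, seed = 1L) {
    stopifnot(receptorFrac > 0, receptorFrac <= 1,
              tfTopFrac > 0, tfTopFrac <= 1,
              geneTopFrac > 0, geneTopFrac <= 1, maxHops >= 1)
    set.seed(seed)
    g <- net@graph
    rec <- sort(receptorNames(net), method = "radix")
    sel <- sort(sample(rec, countFromFraction(length(rec), receptorFrac)),
                method = "radix")

    reach <- unique(igraph::V(g)$name[unlist(
        lapply(igraph::ego(g, order = maxHops, nodes = sel), as.integer))])
    layers <- setNames(igraph::V(g)$layer, igraph::V(g)$name)
    candTFs <- reach[layers[reach] == "tf"]
    if (!length(candTFs))
        stop("no TF reachable within ", maxHops,
             " hops of the implanted receptors; increase maxHops")
    deg <- igraph::degree(g)
    candTFs <- candTFs[.radixOrder(-deg[candTFs], candTFs)]
    keptTFs <- candTFs[seq_len(countFromFraction(length(candTFs), tfTopFrac))]

    down <- unique(igraph::V(g)$name[unlist(
        lapply(igraph::adjacent_vertices(g, keptTFs), as.integer))])
    down <- down[layers[down] == "gene"]
    if (length(down) && geneTopFrac < 1) {
        down <- down[.radixOrder(-deg[down], down)]
        down <- down[seq_len(countFromFraction(length(down), geneTopFrac))]
    }
    # gene-layer intermediates on the traced receptor -> kept-TF routes are
    # cascade members too: the doubled signal must span the whole trace
    mids <- unlist(lapply(sel, function(r) {
        sp <- igraph::all_simple_paths(g, from = r, to = keptTFs,
                                       cutoff = maxHops)
        unlist(lapply(sp, function(v) igraph::V(g)$name[as.integer(v)]))
    }))
    mids <- unique(mids)
    mids <- mids[layers[mids] == "gene"]
    down <- setdiff(sort(unique(c(down, mids)), method = "radix"),
                    c(sel, keptTFs))

    implanted <- c(sel, keptTFs, down)
    nm <- igraph::V(g)$name
    bg <- if (backgroundLfcSd > 0) rnorm(length(nm), 0, backgroundLfcSd)
          else numeric(length(nm))
    de <- data.frame(gene = nm, baseMean = 100,
                     log2fc = ifelse(nm %in% implanted, lfc, bg),
                     padj = ifelse(nm %in% implanted, 1e-6, 1),
                     stringsAsFactors = FALSE)
    list(truth = new("CascadeTruth", receptors = sel, tfs = keptTFs,
                     genes = down, lfc = lfc),
         de = de)
}

#' Add Gaussian noise to a DE table
#'
#' Perturbs the log2 fold change of a uniformly chosen
#' \code{floor(frac * nrow(de))} subset of genes with N(0, sd^2) draws;
#' other rows are untouched.
#'
#' @param de DE table.
#' @param frac fraction of genes perturbed.
#' @param sd noise standard deviation on the log2FC scale (default 0.5,
#'   comparable to but below the implanted effect of 1.0).
#' @param seed RNG seed.
#' @return the perturbed DE table.
#' @export
addGaussianNoise <- function(de, frac, sd = 0.5, seed = 1L) {
    stopifnot(frac > 0, frac <= 1)
    set.seed(seed)
    n <- floor(frac * nrow(de))
    if (n == 0L) return(de)
    idx <- sample.int(nrow(de), n)
    de$log2fc[idx] <- de$log2fc[idx] + rnorm(n, 0, sd)
    de
}

#' Add dropout noise to a DE table
#'
#' Sets the log2 fold change of a uniformly chosen fraction of the rows
#' carrying a nonzero log2FC to 0 and forces their adjusted p to 1
#' (signal loss).  The fraction applies to the nonzero rows: those are
#' the values a dropout can actually erase.
#'
#' @param de DE table.
#' @param frac fraction of nonzero-log2FC genes dropped.
#' @param seed RNG seed.
#' @return the perturbed DE table.
#' @export
addDropoutNoise <- function(de, frac, seed = 1L) {
    stopifnot(frac > 0, frac <= 1)
    set.seed(seed)
    eligible <- which(de$log2fc != 0)
    n <- floor(frac * length(eligible))
    if (n == 0L) return(de)
    idx <- sample(eligible, n)
    de$log2fc[idx] <- 0
    de$padj[idx] <- 1
    de
}

#' Precision, recall and F1 of cascade recovery
#'
#' Evaluates a knockout ranking against the implanted cascade truth:
#' within the top \code{topK} ranked genes, per class (receptor, TF),
#' precision = implanted members of the class in the top list / all
#' predicted members of that class in the top list, recall = implanted
#' members recovered / implanted members, F1 their harmonic mean.
#'
#' @param ranking data.frame from [rankGenes()].
#' @param truth a [CascadeTruth-class].
#' @param net the [SyntheticInteractome-class] (provides class labels).
#' @param topK list length considered (capped at the ranking length,
#'   with a warning).
#' @return data.frame with one row per class: class, n_implanted,
#'   n_predicted, n_recovered, precision, recall, f1.
#' @export
evaluateRecovery <- function(ranking, truth, net, topK = 100L) {
    if (!nrow(ranking)) stop("empty ranking")
    if (topK > nrow(ranking)) {
        warning("topK (", topK, ") exceeds ranking length (", nrow(ranking),
                "); using the full ranking")
        topK <- nrow(ranking)
    }
    top <- ranking$gene[order(ranking$rank)][seq_len(topK)]
    layers <- setNames(igraph::V(net@graph)$layer,
                       igraph::V(net@graph)$name)
    evalClass <- function(class, implanted) {
        predicted <- top[layers[top] == class]
        recovered <- intersect(implanted, top)
        precision <- if (length(predicted))
            length(intersect(implanted, predicted)) / length(predicted)
            else NA_real_
        recall <- if (length(implanted))
            length(recovered) / length(implanted) else NA_real_
        f1 <- if (!is.na(precision) && !is.na(recall) &&
                  (precision + recall) > 0)
            2 * precision * recall / (precision + recall) else 0
        data.frame(class = class, n_implanted = length(implanted),
                   n_predicted = length(predicted),
                   n_recovered = length(recovered),
                   precision = precision, recall = recall, f1 = f1,
                   stringsAsFactors = FALSE)
    }
    rbind(evalClass("receptor", truth@receptors),
          evalClass("tf", truth@tfs))
}

#' Top-k overlap between two rankings
#'
#' \code{|A ∩ B| / k} between the k best genes of two rankings; when
#' either ranking is shorter than k, the common usable length is used
#' instead.
#'
#' @param rankingA,rankingB ranking data.frames (or character vectors
#'   already ordered best-first).
#' @param k list length.
#' @return overlap fraction in [0, 1].
#' @export
topOverlap <- function(rankingA, rankingB, k = 100L) {
    topOf <- function(r) {
        if (is.data.frame(r)) r$gene[order(r$rank)] else r
    }
    a <- topOf(rankingA); b <- topOf(rankingB)
    kEff <- min(k, length(a), length(b))
    if (kEff == 0L) return(NA_real_)
    length(intersect(head(a, kEff), head(b, kEff))) / kEff
}

#' Noise-robustness study
#'
#' Re-runs the pipeline on noise-perturbed DE tables and reports the
#' top-k overlap of each noisy ranking with the clean one, across noise
#' kinds, perturbation fractions and seeded replicates.
#'
#' @param net a [SyntheticInteractome-class].
#' @param de the clean DE table (from [implantCascade()]).
#' @param cfg a [runConfig()] list (its seed drives the pipeline; the
#'   replicate noise seeds are derived from \code{seed}).
#' @param noiseKinds subset of \code{c("gaussian", "dropout")}.
#' @param fracs perturbation fractions.
#' @param nReps replicates per (kind, fraction).
#' @param k overlap list length.
#' @param gaussianSd sd of the Gaussian perturbation.
#' @param cleanRanking optional precomputed clean ranking (saves one
#'   run).
#' @return list: \code{runs} (data.frame noise/frac/rep/seed/overlap),
#'   \code{summary} (min/mean/max per condition), \code{clean} (the
#'   clean ranking).
#' @export
robustnessStudy <- function(net, de, cfg = runConfig(),
                            noiseKinds = c("gaussian", "dropout"),
                            fracs = c(0.05, 0.10, 0.20), nReps = 10L,
                            k = 100L, gaussianSd = 0.5,
                            cleanRanking = NULL) {
    noiseKinds <- match.arg(noiseKinds, several.ok = TRUE)
    ppi <- interactomeToPPI(net)
    receptors <- receptorNames(net)
    if (is.null(cleanRanking))
        cleanRanking <- runPipeline(ppi, de, receptors, cfg)$ranking
    rows <- list()
    ri <- 0L
    for (kind in noiseKinds) {
        for (frac in fracs) {
            for (rep in seq_len(nReps)) {
                ri <- ri + 1L
                noiseSeed <- (cfg$seed + 7919L * ri) %% .Machine$integer.max
                noisy <- if (kind == "gaussian")
                    addGaussianNoise(de, frac, sd = gaussianSd,
                                     seed = noiseSeed)
                else addDropoutNoise(de, frac, seed = noiseSeed)
                ov <- tryCatch({
                    r <- runPipeline(ppi, noisy, receptors, cfg)$ranking
                    topOverlap(r, cleanRanking, k = k)
                }, error = function(e) NA_real_)
                rows[[ri]] <- data.frame(noise = kind, frac = frac,
                                         rep = rep, seed = noiseSeed,
                                         overlap = ov,
                                         stringsAsFactors = FALSE)
            }
        }
    }
    runs <- do.call(rbind, rows)
    summ <- aggregate(overlap ~ noise + frac, data = runs,
                      na.action = stats::na.pass,
                      FUN = function(x) {
                          x <- x[!is.na(x)]
                          if (!length(x)) return(c(min = NA_real_,
                                                   mean = NA_real_,
                                                   max = NA_real_))
                          c(min = min(x), mean = mean(x), max = max(x))
                      })
    summ <- do.call(data.frame, summ)
    names(summ) <- c("noise", "frac", "min", "mean", "max")
    list(runs = runs, summary = summ, clean = cleanRanking)
}
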