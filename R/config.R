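#' Run configuration
#'
#' Collects every tunable of the inference pipeline with its default.
#' Defaults follow the method's standard settings: paths of at most
#' \code{K = 5} nodes, node-term weight \code{gamma = 1}, Gaussian path
#' p-value cutoff 0.01, top \code{N = 5} paths per (source, target) pair,
#' refinement acceptance threshold \code{v = 0.05} (5\% relative
#' improvement) with \code{t = 5} permitted stagnant iterations, and DE
#' gene filters baseMean > 50, adjusted p < 0.05, |log2FC| > 0.6.
#'
#' @param K maximum nodes per path, endpoints included (integer >= 2).
#' @param gamma weight of the node fold-change term in the path score.
#' @param pathPCutoff Gaussian upper-tail p-value below which a path is
#'   retained, in (0, 1).
#' @param topN number of most probable paths kept per (source, target)
#'   pair.
#' @param v minimum relative network-score improvement for a refinement
#'   iteration to count as progress.
#' @param t number of consecutive non-improving refinement iterations
#'   after which refinement stops.
#' @param deBaseMeanMin,dePadjMax,deAbsLfcMin differential-expression
#'   filters: baseMean strictly above, adjusted p strictly below,
#'   |log2FC| strictly above.
#' @param direction which DE genes become targets: \code{"up"},
#'   \code{"down"} or \code{"both"}.
#' @param lambda regularization coefficient for the network score;
#'   \code{"auto"} sets it to the ratio of the mean score term to the
#'   mean average degree over a lambda = 0 pilot pruning sweep, or give a
#'   fixed number.
#' @param nRandomEdges edges injected per refinement iteration;
#'   \code{NULL} means \code{max(1, ceiling(0.01 * |E(current)|))}.
#' @param seed integer seed controlling all randomness.
#' @param permutations degree-preserving permutation runs for the
#'   empirical null (0 = skip).
#' @param allPaths enumerate every simple path up to \code{K} nodes
#'   instead of only unweighted-shortest paths (small graphs only).
#' @param tfCorrection multiple-testing correction for TF enrichment,
#'   \code{"fdr"} (Benjamini-Hochberg) or \code{"bonferroni"}.
#' @param tfAlpha adjusted-p cutoff for calling a TF enriched.
#' @param minExpressedSamples samples with a positive count needed to
#'   call a gene expressed when a count matrix is supplied.
#' @return a validated list of class \code{"sigflow_config"}.
#' @examples
#' cfg <- runConfig(seed = 7)
#' cfg$K
#' @export
runConfig <- function(K = 5L, gamma = 1.0, pathPCutoff = 0.01, topN = 5L,
                      v = 0.05, t = 5L,
                      deBaseMeanMin = 50, dePadjMax = 0.05, deAbsLfcMin = 0.6,
                      direction = c("both", "up", "down"),
                      lambda = "auto", nRandomEdges = NULL,
                      seed = 1L, permutations = 0L, allPaths = FALSE,
                      tfCorrection = c("fdr", "bonferroni"), tfAlpha = 0.05,
                      minExpressedSamples = 1L) {
    direction <- match.arg(direction)
    tfCorrection <- match.arg(tfCorrection)
    stopifnot(K >= 2, gamma >= 0, pathPCutoff > 0, pathPCutoff < 1,
              topN >= 1, v >= 0, t >= 0, deBaseMeanMin >= 0,
              dePadjMax >= 0, dePadjMax <= 1, deAbsLfcMin >= 0,
              is.null(nRandomEdges) || nRandomEdges >= 1,
              permutations >= 0, tfAlpha > 0, tfAlpha <= 1,
              minExpressedSamples >= 1)
    if (!identical(lambda, "auto") && !(is.numeric(lambda) && lambda >= 0))
        stop("'lambda' must be \"auto\" or a non-negative number")
    cfg <- list(K = as.integer(K), gamma = gamma, pathPCutoff = pathPCutoff,
                topN = as.integer(topN), v = v, t = as.integer(t),
                deBaseMeanMin = deBaseMeanMin, dePadjMax = dePadjMax,
                deAbsLfcMin = deAbsLfcMin, direction = direction,
                lambda = lambda, nRandomEdges = nRandomEdges,
                seed = as.integer(seed), permutations = as.integer(permutations),
                allPaths = isTRUE(allPaths), tfCorrection = tfCorrection,
                tfAlpha = tfAlpha,
                minExpressedSamples = as.integer(minExpressedSamples))
    class(cfg) <- "sigflow_config"
    cfg
}

#' @export
print.sigflow_config <- function(x, ...) {
    cat("sigflow run configuration\n")
    for (nm in names(x)) {
        val <- x[[nm]]
        cat(sprintf("  %-20s %s\n", nm,
                    if (is.null(val)) "auto" else paste(val, collapse = ",")))
    }
    invisible(x)
}

# radix order: locale-independent, so path/gene ordering is reproducible
.radixOrder <- function(...) order(..., method = "radix")
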