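# Readers and writers for the external formats: PPI edge tables,
# DESeq2-style DE results, receptor lists, GMT TF-target maps,
# GraphML/SIF/TSV network exports and the ranking TSV.

#' Read a weighted protein-protein interaction table
#'
#' Accepts a minimal 3-column TSV (gene_a, gene_b, confidence) or a wider
#' HIPPIE-like layout (columns 1 and 3 are gene symbols, the last numeric
#' column is the confidence).  A header line is auto-detected by a
#' non-numeric confidence field.  Self-loops are dropped, duplicate
#' unordered pairs are collapsed keeping the maximum confidence, and
#' confidences are normalized into (0, 1]: values above 1 are rescaled by
#' the maximum, values at or below 0 are dropped (their log2 is undefined
#' downstream).
#'
#' @param path TSV file path.
#' @param minConfidence optional filter; edges strictly below it are
#'   discarded after normalization.
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{confidence}.
#' @export
readPPI <- function(path, minConfidence = NULL) {
    raw <- read.delim(path, header = FALSE, sep = "\t",
                      colClasses = "character", quote = "",
                      blank.lines.skip = FALSE)
    blank <- apply(raw, 1L, function(r) all(!nzchar(trimws(r))))
    lineNo <- seq_len(nrow(raw))
    raw <- raw[!blank, , drop = FALSE]
    lineNo <- lineNo[!blank]
    if (nrow(raw) == 0L) stop("PPI file '", path, "' is empty")
    if (ncol(raw) < 3L) stop("PPI file needs at least 3 tab-separated columns")

    confCol <- if (ncol(raw) == 3L) 3L else {
        # wide layout: last column whose data rows are numeric
        cand <- rev(seq(3L, ncol(raw)))
        hit <- NA_integer_
        for (j in cand) {
            v <- suppressWarnings(as.numeric(raw[[j]][-1L]))
            if (length(v) && all(!is.na(v))) { hit <- j; break }
        }
        if (is.na(hit)) stop("no numeric confidence column found in PPI file")
        hit
    }
    geneCols <- if (ncol(raw) == 3L) c(1L, 2L) else c(1L, 3L)

    # header detection: non-numeric confidence field on the first row
    hasHeader <- is.na(suppressWarnings(as.numeric(raw[[confCol]][1L])))
    if (hasHeader) { raw <- raw[-1L, , drop = FALSE]; lineNo <- lineNo[-1L] }
    if (nrow(raw) == 0L) stop("PPI file '", path, "' has a header but no rows")

    a <- trimws(raw[[geneCols[1L]]])
    b <- trimws(raw[[geneCols[2L]]])
    conf <- suppressWarnings(as.numeric(raw[[confCol]]))
    bad <- !nzchar(a) | !nzchar(b) | is.na(conf)
    if (any(bad))
        stop("malformed PPI row at line ", lineNo[which(bad)[1L]],
             " of '", path, "' (empty gene symbol or non-numeric confidence)")

    keep <- conf > 0
    a <- a[keep]; b <- b[keep]; conf <- conf[keep]
    if (!length(a)) stop("no PPI edges with positive confidence")
    if (max(conf) > 1) conf <- conf / max(conf)

    keep <- a != b                       # drop self-loops
    a <- a[keep]; b <- b[keep]; conf <- conf[keep]
    if (!length(a)) stop("no PPI edges left after removing self-loops")

    lo <- pmin(a, b); hi <- pmax(a, b)   # collapse unordered duplicates
    key <- paste(lo, hi, sep = "\r")
    ord <- .radixOrder(key, -conf)
    first <- !duplicated(key[ord])
    out <- data.frame(gene_a = lo[ord][first], gene_b = hi[ord][first],
                      confidence = conf[ord][first], stringsAsFactors = FALSE)
    if (!is.null(minConfidence)) out <- out[out$confidence >= minConfidence, ]
    if (nrow(out) == 0L) stop("no PPI edges pass the confidence filter")
    rownames(out) <- NULL
    out
}

#' Read a DESeq2-style differential-expression results table
#'
#' Expects a TSV with columns for the gene symbol, \code{baseMean},
#' \code{log2FoldChange} and \code{padj} (header match is
#' case-insensitive; the gene column may be named \code{gene},
#' \code{symbol}, \code{gene_id}, \code{id} or be the usual unnamed
#' row-name column of a written DESeq2 results frame).  \code{"NA"}
#' adjusted p-values become missing and are treated as non-significant
#' downstream.
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{gene}, \code{baseMean},
#'   \code{log2fc}, \code{padj}.
#' @export
readDETable <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(tab) == 0L) stop("DE table '", path, "' has no rows")
    hdr <- tolower(names(tab))
    pick <- function(cands) {
        j <- which(hdr %in% cands)
        if (length(j)) j[1L] else NA_integer_
    }
    gi <- pick(c("gene", "genes", "symbol", "gene_id", "gene_name", "id", ""))
    bi <- pick("basemean")
    li <- pick(c("log2foldchange", "log2fc", "lfc"))
    pi <- pick(c("padj", "p_adj", "fdr", "adj.p.val"))
    missing <- c(gene = gi, baseMean = bi, log2FoldChange = li, padj = pi)
    if (anyNA(missing))
        stop("DE table is missing column(s) ",
             paste(names(missing)[is.na(missing)], collapse = ", "),
             "; found headers: ", paste(names(tab), collapse = ", "))
    gene <- trimws(as.character(tab[[gi]]))
    if (anyDuplicated(gene))
        stop("duplicate gene rows in DE table (first: ",
             gene[anyDuplicated(gene)], "); fold change would be ambiguous")
    de <- data.frame(gene = gene,
                     baseMean = as.numeric(tab[[bi]]),
                     log2fc = as.numeric(tab[[li]]),
                     padj = suppressWarnings(as.numeric(tab[[pi]])),
                     stringsAsFactors = FALSE)
    if (any(!nzchar(de$gene))) stop("empty gene symbol in DE table")
    if (any(is.na(de$baseMean)) || any(is.na(de$log2fc)))
        stop("non-numeric baseMean or log2FoldChange in DE table")
    de
}

#' Read a receptor gene list
#'
#' One symbol per line; blank lines and \code{#} comments are ignored.
#'
#' @param path file path.
#' @return character vector of unique symbols.
#' @export
readReceptors <- function(path) {
    x <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
    x <- unique(x[nzchar(x)])
    if (!length(x)) stop("receptor list '", path, "' contains no symbols")
    x
}

#' Read a GMT transcription-factor target map
#'
#' Standard GMT: one set per line, tab-separated as
#' \code{TF<TAB>description<TAB>target1<TAB>target2...}.
#'
#' @param path file path.
#' @return named list of character target vectors, one per TF.
#' @export
readTFTargets <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("GMT file '", path, "' is empty")
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) < 3L
    if (any(bad)) stop("GMT line ", which(bad)[1L], " has fewer than 3 fields")
    setNames(lapply(parts, function(p) unique(trimws(p[-(1:2)]))),
             vapply(parts, `[`, character(1), 1L))
}

#' Write a network to GraphML, SIF or TSV
#'
#' GraphML preserves all node attributes (role, abs_log2fc and, when
#' present, knockout score and rank) and the edge confidence, and
#' round-trips through [readNetwork()].  SIF writes edge lines
#' \code{a pp b}; TSV writes a 3-column edge table with confidences.
#'
#' @param x a [SignalGraph-class], [CandidateNetwork-class] or
#'   \pkg{igraph} object.
#' @param path output file.
#' @param fmt one of \code{"graphml"}, \code{"sif"}, \code{"tsv"}.
#' @export
writeNetwork <- function(x, path, fmt = c("graphml", "sif", "tsv")) {
    fmt <- match.arg(fmt)
    g <- if (is(x, "SignalGraph") || is(x, "CandidateNetwork")) asIgraph(x)
         else if (igraph::is_igraph(x)) x
         else stop("cannot write object of class ", class(x)[1L])
    if (igraph::vcount(g) == 0L) stop("refusing to write an empty network")
    if (fmt == "graphml") {
        igraph::write_graph(g, path, format = "graphml")
    } else {
        el <- igraph::as_edgelist(g, names = TRUE)
        if (fmt == "sif") {
            writeLines(if (nrow(el)) paste(el[, 1L], "pp", el[, 2L]) else character(),
                       path)
        } else {
            conf <- if ("confidence" %in% igraph::edge_attr_names(g))
                igraph::E(g)$confidence else rep(NA_real_, nrow(el))
            write.table(data.frame(gene_a = el[, 1L], gene_b = el[, 2L],
                                   confidence = conf),
                        path, sep = "\t", quote = FALSE, row.names = FALSE)
        }
    }
    invisible(path)
}

#' Read a GraphML network written by [writeNetwork()]
#'
#' @param path GraphML file.
#' @return an \pkg{igraph} object with its attributes.
#' @export
readNetwork <- function(path) igraph::read_graph(path, format = "graphml")

#' Write a knockout ranking table
#'
#' Emits a TSV sorted by rank (most negative knockout score first, ties
#' broken lexicographically by gene).
#'
#' @param records ranking data.frame from [rankGenes()].
#' @param path output file.
#' @export
writeRanking <- function(records, path) {
    cols <- c("gene", "rank", "ko_score", "empirical_p", "significant",
              "role", "abs_log2fc", "degree")
    if (nrow(records)) {
        for (cc in setdiff(cols, names(records))) records[[cc]] <- NA
        records <- records[.radixOrder(records$rank, records$gene), cols]
    } else {
        records <- as.data.frame(setNames(rep(list(logical(0)), length(cols)),
                                          cols))
    }
    write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
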