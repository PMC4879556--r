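## Discriminative array selection: score arrays by how strongly a positive
## gene list concentrates in the extreme expression quantiles.

#' Genes in the extreme quantiles of one array
#'
#' Returns the union of the k highest- and k lowest-valued genes of a
#' column, with k = floor(q * n). Ranking is by (value, gene id) with
#' C-locale id order, so boundary ties are deterministic: the low tail
#' prefers lexicographically smaller ids, the high tail larger ids.
#'
#' @param values numeric vector of one array's intensities.
#' @param geneIds gene identifiers, same length as \code{values}.
#' @param q extreme-quantile fraction per tail, in (0, 0.5].
#' @return character vector of gene ids in the pooled extremes.
#' @examples
#' extremeQuantileMembership(1:8, paste0("g", 1:8), 0.25)
#' @export
extremeQuantileMembership <- function(values, geneIds, q) {
    n <- length(values)
    stopifnot(length(geneIds) == n, n >= 2L, q > 0, q <= 0.5)
    k <- floor(q * n)
    if (k < 1L) stop("quantile too small for n: floor(q*n) = 0")
    ord <- order(values, geneIds, method = "radix")
    unique(geneIds[c(ord[seq_len(k)], ord[seq.int(n - k + 1L, n)])])
}

#' Discriminative score of one array
#'
#' Fraction of the positive-list genes (restricted to genes present in the
#' matrix) that fall into the array's pooled extreme quantiles.
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param arrayId array to score.
#' @param positiveList character vector of positive gene ids.
#' @param q extreme-quantile fraction per tail.
#' @return score in [0, 1].
#' @export
scoreArray <- function(m, arrayId, positiveList, q = 0.25) {
    stopifnot(is(m, "ExpressionMatrix"))
    if (!arrayId %in% arrayIds(m)) stop("unknown array id: ", arrayId)
    present <- intersect(positiveList, geneIds(m))
    if (!length(present))
        stop("no positive-list gene is present in the matrix")
    if (length(present) < length(positiveList))
        message("scoreArray: ", length(positiveList) - length(present),
                " positive-list gene(s) absent from the matrix; ",
                "excluded from the denominator")
    ext <- extremeQuantileMembership(exprValues(m)[, arrayId], geneIds(m), q)
    length(intersect(present, ext)) / length(present)
}

#' Select discriminative arrays
#'
#' Scores every array by \code{\link{scoreArray}} and selects those with
#' score strictly greater than \code{f} ("more than" the stated fraction).
#' Default parameters are the study settings q = 0.25 (25\% highest or
#' lowest signal) and f = 0.70.
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param positiveList character vector of positive gene ids.
#' @param q extreme-quantile fraction per tail, in (0, 0.5].
#' @param f minimum list fraction in the extremes, in (0, 1]; strict
#'   inequality.
#' @return An \linkS4class{ArraySelection}, sorted by decreasing score
#'   (ties by array id).
#' @export
selectDiscriminativeArrays <- function(m, positiveList, q = 0.25, f = 0.70) {
    stopifnot(is(m, "ExpressionMatrix"))
    stopifnot(q > 0, q <= 0.5, f > 0, f <= 1)
    v <- exprValues(m)
    ids <- geneIds(m)
    present <- intersect(positiveList, ids)
    if (!length(present))
        stop("no positive-list gene is present in the matrix")
    if (length(present) < length(positiveList))
        message("selectDiscriminativeArrays: ",
                length(positiveList) - length(present),
                " positive-list gene(s) absent from the matrix; ",
                "excluded from the denominator")
    scores <- vapply(seq_len(ncol(v)), function(j) {
        ext <- extremeQuantileMembership(v[, j], ids, q)
        length(intersect(present, ext)) / length(present)
    }, numeric(1L))
    tb <- data.frame(array_id = colnames(v), score = scores,
                     selected = scores > f, stringsAsFactors = FALSE)
    tb <- tb[order(-tb$score, tb$array_id, method = "radix"), , drop = FALSE]
    rownames(tb) <- NULL
    if (!any(tb$selected))
        warning("no array passed the selection threshold; ",
                "downstream network will be empty")
    new("ArraySelection", table = tb, params = list(q = q, f = f))
}

#' @describeIn accessors full score table of an ArraySelection
#' @export
setMethod("selectionTable", "ArraySelection", function(object) object@table)

#' @describeIn accessors ids of the selected arrays
#' @export
setMethod("selectedArrays", "ArraySelection", function(object)
    object@table$array_id[object@table$selected])

setMethod("show", "ArraySelection", function(object) {
    cat("ArraySelection:", sum(object@table$selected), "of",
        nrow(object@table), "arrays selected (q =", object@params$q,
        ", f =", object@params$f, ", score > f)\n")
})

#' Write an ArraySelection as TSV (array_id, score, selected)
#'
#' @param sel an \linkS4class{ArraySelection}.
#' @param path output file.
#' @export
writeArraySelection <- function(sel, path) {
    stopifnot(is(sel, "ArraySelection"))
    tb <- selectionTable(sel)
    tb$score <- sprintf("%.17g", tb$score)
    tb$selected <- ifelse(tb$selected, "TRUE", "FALSE")
    write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
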