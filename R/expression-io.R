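## Reading, validating and normalizing gene x array expression matrices.

#' @describeIn accessors gene identifiers of an ExpressionMatrix
#' @export
setMethod("geneIds", "ExpressionMatrix", function(object) rownames(object@exprs))

#' @describeIn accessors array identifiers of an ExpressionMatrix
#' @export
setMethod("arrayIds", "ExpressionMatrix", function(object) colnames(object@exprs))

#' @describeIn accessors numeric matrix of an ExpressionMatrix
#' @export
setMethod("exprValues", "ExpressionMatrix", function(object) object@exprs)

#' @describeIn accessors intensity scale ("linear" or "log2")
#' @export
setMethod("scaleTag", "ExpressionMatrix", function(object) object@scaleTag)

setMethod("show", "ExpressionMatrix", function(object) {
    cat("ExpressionMatrix:", nrow(object@exprs), "genes x",
        ncol(object@exprs), "arrays [", object@scaleTag, "scale ]\n")
})

#' Read an expression matrix from a delimited text file
#'
#' The first row holds array ids, the first column gene ids. Rows whose
#' body contains a non-numeric or missing cell are dropped with a message
#' reporting the count; duplicated ids or an empty body are hard errors
#' naming the offender.
#'
#' @param path file to read.
#' @param delimiter field separator (default tab).
#' @param scaleTag scale of the stored intensities ("linear" or "log2").
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readExpressionMatrix <- function(path, delimiter = "\t",
                                 scaleTag = c("linear", "log2")) {
    scaleTag <- match.arg(scaleTag)
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, sep = delimiter, header = TRUE,
                     check.names = FALSE, stringsAsFactors = FALSE,
                     colClasses = "character", quote = "")
    if (ncol(df) < 2L) stop("malformed header: need gene id column plus ",
                            "at least one array column in ", path)
    gene_ids <- df[[1L]]
    array_ids <- colnames(df)[-1L]
    dup <- unique(gene_ids[duplicated(gene_ids)])
    if (length(dup)) stop("duplicate gene id: ", dup[1L])
    dupa <- unique(array_ids[duplicated(array_ids)])
    if (length(dupa)) stop("duplicate array id: ", dupa[1L])
    body <- suppressWarnings(
        vapply(df[-1L], as.numeric, numeric(nrow(df))))
    body <- matrix(body, nrow = nrow(df),
                   dimnames = list(gene_ids, array_ids))
    bad <- apply(body, 1L, function(r) any(!is.finite(r)))
    if (any(bad))
        message("readExpressionMatrix: dropped ", sum(bad),
                " row(s) with missing or non-numeric values")
    body <- body[!bad, , drop = FALSE]
    if (nrow(body) == 0L) stop("empty matrix after dropping invalid rows: ",
                               path)
    ExpressionMatrix(body, scaleTag)
}

#' Write an expression matrix to a delimited text file
#'
#' Values are written with full double precision so that a read/write
#' round-trip is exact.
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param path output file.
#' @param delimiter field separator.
#' @export
writeExpressionMatrix <- function(m, path, delimiter = "\t") {
    stopifnot(is(m, "ExpressionMatrix"))
    v <- exprValues(m)
    chr <- matrix(sprintf("%.17g", v), nrow = nrow(v))
    out <- cbind(gene_id = rownames(v), chr)
    colnames(out) <- c("gene_id", colnames(v))
    write.table(out, path, sep = delimiter, quote = FALSE,
                row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Log2-transform a linear-scale expression matrix
#'
#' @param m an \linkS4class{ExpressionMatrix} on the linear scale.
#' @param offset positive shift added before taking logs; every
#'   value + offset must be strictly positive.
#' @return An \linkS4class{ExpressionMatrix} tagged \code{log2}.
#' @export
log2Transform <- function(m, offset = 1) {
    stopifnot(is(m, "ExpressionMatrix"))
    if (scaleTag(m) != "linear")
        stop("log2Transform expects a linear-scale matrix")
    v <- exprValues(m) + offset
    if (any(v <= 0))
        stop("nonpositive value after offset; cannot log-transform")
    ExpressionMatrix(log2(v), "log2")
}

#' Quantile-normalize an expression matrix
#'
#' Forces every array (column) to share the across-array mean of the sorted
#' columns, preserving within-array ranks; ties receive the mean of the
#' reference values they span (\code{limma::normalizeQuantiles} with
#' \code{ties = TRUE}). The operation is idempotent and a single-column
#' matrix is returned unchanged with a warning.
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @return A quantile-normalized \linkS4class{ExpressionMatrix} with the
#'   same scale tag.
#' @export
quantileNormalize <- function(m) {
    stopifnot(is(m, "ExpressionMatrix"))
    v <- exprValues(m)
    if (ncol(v) < 2L) {
        warning("quantileNormalize: single array, returning input unchanged")
        return(m)
    }
    if (nrow(v) < 2L) stop("need at least 2 genes to quantile-normalize")
    nv <- limma::normalizeQuantiles(v, ties = TRUE)
    dimnames(nv) <- dimnames(v)
    ExpressionMatrix(nv, scaleTag(m))
}

#' Read a gene list (one id per line, '#' comments allowed)
#'
#' @param path file to read.
#' @return character vector of unique gene ids, input order preserved.
#' @export
readGeneList <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    x <- readLines(path, warn = FALSE)
    x <- sub("#.*$", "", x)
    x <- trimws(x)
    x <- x[nzchar(x)]
    if (!length(x)) stop("empty gene list: ", path)
    unique(x)
}

#' Write a gene list, one id per line
#'
#' @param ids character vector of gene ids.
#' @param path output file.
#' @export
writeGeneList <- function(ids, path) {
    writeLines(ids, path)
    invisible(path)
}
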