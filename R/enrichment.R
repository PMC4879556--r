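## Right-sided hypergeometric GO-term enrichment per gene cluster with
## Bonferroni step-down (Holm) correction.

#' Construct a GOAnnotation
#'
#' @param mapping data.frame with columns \code{gene_id}, \code{term_id}
#'   (duplicates dropped).
#' @param universe gene universe; defaults to the annotated genes.
#' @return A \linkS4class{GOAnnotation}.
#' @export
GOAnnotation <- function(mapping, universe = NULL) {
    mapping <- unique(mapping[, c("gene_id", "term_id")])
    rownames(mapping) <- NULL
    if (is.null(universe)) universe <- unique(mapping$gene_id)
    new("GOAnnotation", mapping = mapping, universe = unique(universe))
}

#' @describeIn accessors gene-to-term mapping table
#' @export
setMethod("annotationMapping", "GOAnnotation",
    function(object) object@mapping)

#' @describeIn accessors gene universe of the annotation
#' @export
setMethod("annotationUniverse", "GOAnnotation",
    function(object) object@universe)

setMethod("show", "GOAnnotation", function(object) {
    cat("GOAnnotation:", length(unique(object@mapping$term_id)),
        "terms over", length(object@universe), "universe genes\n")
})

#' Read a gene-to-GO annotation
#'
#' Either a two-column TSV (gene_id, term_id; '#' comment lines and an
#' optional header are tolerated) or GAF 2.x, from which columns 2 (gene)
#' and 5 (term) are taken; '!' comment lines are skipped.
#'
#' @param path input file.
#' @param format \code{"tsv"} or \code{"gaf"}.
#' @param universe optional explicit gene universe.
#' @return A \linkS4class{GOAnnotation}.
#' @export
readGeneAnnotation <- function(path, format = c("tsv", "gaf"),
                               universe = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "tsv") {
        lines <- readLines(path, warn = FALSE)
        lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
        parts <- strsplit(lines, "\t", fixed = TRUE)
        if (any(lengths(parts) < 2L))
            stop("malformed annotation line in ", path)
        df <- data.frame(gene_id = vapply(parts, `[`, "", 1L),
                         term_id = vapply(parts, `[`, "", 2L),
                         stringsAsFactors = FALSE)
        if (identical(tolower(df$gene_id[1L]), "gene_id"))
            df <- df[-1L, , drop = FALSE]
    } else {
        lines <- readLines(path, warn = FALSE)
        lines <- lines[!grepl("^!", lines) & nzchar(lines)]
        parts <- strsplit(lines, "\t", fixed = TRUE)
        if (any(lengths(parts) < 5L)) stop("malformed GAF line in ", path)
        df <- data.frame(gene_id = vapply(parts, `[`, "", 2L),
                         term_id = vapply(parts, `[`, "", 5L),
                         stringsAsFactors = FALSE)
    }
    GOAnnotation(df, universe)
}

#' Write an annotation as two-column TSV
#'
#' @param annot a \linkS4class{GOAnnotation}.
#' @param path output file.
#' @export
writeGeneAnnotation <- function(annot, path) {
    stopifnot(is(annot, "GOAnnotation"))
    write.table(annotationMapping(annot), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Right-sided hypergeometric p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing n genes (the
#' cluster) from a universe of N genes of which K carry the term.
#'
#' @param k cluster genes carrying the term.
#' @param K universe genes carrying the term.
#' @param n cluster genes in the universe.
#' @param N universe size.
#' @return the right tail probability, in (0, 1].
#' @export
hypergeomPvalueRight <- function(k, K, n, N) {
    stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L,
              length(N) == 1L)
    if (k < 0 || K < 0 || n < 0 || N < 0 || K > N || n > N ||
        k > min(n, K))
        stop("hypergeometric arguments out of bounds")
    if (k == 0) return(1)
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Holm (Bonferroni step-down) adjustment
#'
#' Sort ascending, set adjusted_(i) = max_{j <= i} min(1, (m-j+1) p_(j)),
#' and return in the original order — the classical step-down procedure,
#' computed by \code{stats::p.adjust(method = "holm")}.
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
holmAdjust <- function(p) {
    if (!length(p)) return(numeric())
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "holm")
}

#' GO-term enrichment of one gene cluster
#'
#' Tests every term with at least one universe gene and at least one
#' cluster gene (k >= 1) with the right-sided hypergeometric test, then
#' applies the Holm correction across all tested terms of the cluster.
#' Cluster genes outside the universe are excluded with a message.
#'
#' @param cluster character vector of cluster gene ids.
#' @param annot a \linkS4class{GOAnnotation}.
#' @return data.frame (term_id, k, n, K, N, p_raw, p_adj) sorted by
#'   p_adj, then p_raw, then term id.
#' @export
enrichCluster <- function(cluster, annot) {
    stopifnot(is(annot, "GOAnnotation"))
    cluster <- unique(cluster)
    uni <- annotationUniverse(annot)
    inside <- intersect(cluster, uni)
    if (!length(inside))
        stop("no cluster gene is in the annotation universe")
    if (length(inside) < length(cluster))
        message("enrichCluster: ", length(cluster) - length(inside),
                " cluster gene(s) outside the universe; excluded")
    mp <- annotationMapping(annot)
    term2genes <- split(mp$gene_id, mp$term_id)
    N <- length(uni)
    n <- length(inside)
    rows <- lapply(names(term2genes), function(tid) {
        genes <- term2genes[[tid]]
        k <- length(intersect(genes, inside))
        if (k < 1L) return(NULL)
        K <- length(unique(genes))
        data.frame(term_id = tid, k = k, n = n, K = K, N = N,
                   p_raw = hypergeomPvalueRight(k, K, n, N),
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1L))]
    if (!length(rows))
        return(data.frame(term_id = character(), k = integer(),
                          n = integer(), K = integer(), N = integer(),
                          p_raw = numeric(), p_adj = numeric()))
    out <- do.call(rbind, rows)
    out$p_adj <- holmAdjust(out$p_raw)
    out <- out[order(out$p_adj, out$p_raw, out$term_id,
                     method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
    out
}
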