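#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats cor phyper p.adjust rnorm runif
#' @importFrom utils read.delim write.table head
NULL

#' ExpressionMatrix: a gene-by-array expression compendium
#'
#' Thin S4 container for a numeric gene x array matrix together with a tag
#' recording whether values are on the linear or log2 intensity scale.
#' Row names are gene identifiers (e.g. AGI locus codes), column names are
#' array identifiers; both must be unique and all values finite.
#'
#' @slot exprs numeric matrix (genes x arrays) with complete dimnames.
#' @slot scaleTag either \code{"linear"} or \code{"log2"}.
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
    representation(exprs = "matrix", scaleTag = "character"))

setValidity("ExpressionMatrix", function(object) {
    m <- object@exprs
    msg <- character()
    if (!is.numeric(m))
        msg <- c(msg, "expression values must be numeric")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "gene and array identifiers (dimnames) are required")
    else {
        dg <- rownames(m)[duplicated(rownames(m))]
        da <- colnames(m)[duplicated(colnames(m))]
        if (length(dg)) msg <- c(msg, paste0("duplicate gene id: ", dg[1L]))
        if (length(da)) msg <- c(msg, paste0("duplicate array id: ", da[1L]))
    }
    if (length(m) == 0L)
        msg <- c(msg, "empty expression matrix")
    if (is.numeric(m) && length(m) && !all(is.finite(m)))
        msg <- c(msg, "expression values must be finite (no NA/NaN/Inf)")
    if (length(object@scaleTag) != 1L ||
        !object@scaleTag %in% c("linear", "log2"))
        msg <- c(msg, "scaleTag must be \"linear\" or \"log2\"")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix with gene row names and array column names.
#' @param scaleTag \code{"linear"} or \code{"log2"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("a1", "a2")))
#' ExpressionMatrix(m, "linear")
#' @export
ExpressionMatrix <- function(values, scaleTag = c("linear", "log2")) {
    scaleTag <- match.arg(scaleTag)
    storage.mode(values) <- "double"
    new("ExpressionMatrix", exprs = values, scaleTag = scaleTag)
}

#' ArraySelection: per-array discriminative scores and selection status
#'
#' @slot table data.frame with columns \code{array_id}, \code{score},
#'   \code{selected}, sorted by decreasing score.
#' @slot params list with elements \code{q} (extreme-quantile fraction) and
#'   \code{f} (minimum fraction of positive-list genes in the extremes;
#'   selection requires score strictly greater than \code{f}).
#' @exportClass ArraySelection
setClass("ArraySelection",
    representation(table = "data.frame", params = "list"))

setValidity("ArraySelection", function(object) {
    tb <- object@table
    need <- c("array_id", "score", "selected")
    if (!all(need %in% names(tb)))
        return("table must have columns array_id, score, selected")
    if (any(tb$score < 0 | tb$score > 1))
        return("scores must lie in [0, 1]")
    p <- object@params
    if (!is.numeric(p$q) || p$q <= 0 || p$q > 0.5)
        return("q must lie in (0, 0.5]")
    if (!is.numeric(p$f) || p$f <= 0 || p$f > 1)
        return("f must lie in (0, 1]")
    if (!identical(tb$selected, tb$score > p$f))
        return("selected must equal (score > f)")
    TRUE
})

#' CoexpressionNetwork: Pearson-thresholded co-expression graph
#'
#' Undirected graph over candidate genes; an edge (a, b) is present iff the
#' sample Pearson correlation of the two expression profiles over the chosen
#' arrays is >= r0 (signed, inclusive). Zero-variance genes are excluded.
#'
#' @slot nodes character vector of gene ids in the network.
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{r}; \code{gene_a < gene_b} lexicographically, one row per edge.
#' @slot params list with \code{r0} and \code{minClusterSize}.
#' @slot excluded character vector of zero-variance genes left out.
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork",
    representation(nodes = "character", edges = "data.frame",
                   params = "list", excluded = "character"))

setValidity("CoexpressionNetwork", function(object) {
    e <- object@edges
    if (!all(c("gene_a", "gene_b", "r") %in% names(e)))
        return("edges must have columns gene_a, gene_b, r")
    if (nrow(e)) {
        if (any(e$gene_a == e$gene_b)) return("self-edges are not allowed")
        if (any(e$gene_a >= e$gene_b))
            return("edges must satisfy gene_a < gene_b")
        if (anyDuplicated(paste(e$gene_a, e$gene_b)))
            return("duplicate edge")
        if (!all(e$gene_a %in% object@nodes) ||
            !all(e$gene_b %in% object@nodes))
            return("edge endpoint not among nodes")
        if (any(e$r < object@params$r0 - 1e-12))
            return("edge weight below threshold r0")
    }
    if (anyDuplicated(object@nodes)) return("duplicate node id")
    TRUE
})

#' GeneClusterSet: connected-component gene clusters of a network
#'
#' Clusters are the connected components with at least
#' \code{minClusterSize} members, labelled C0, C1, ... in decreasing size
#' order (ties broken by the lexicographically smallest member). Nodes in
#' smaller components form the remainder.
#'
#' @slot clusters named list (C0, C1, ...) of sorted gene-id vectors.
#' @slot remainder sorted character vector of unclustered genes.
#' @exportClass GeneClusterSet
setClass("GeneClusterSet",
    representation(clusters = "list", remainder = "character"))

setValidity("GeneClusterSet", function(object) {
    all_ids <- unlist(object@clusters, use.names = FALSE)
    if (anyDuplicated(c(all_ids, object@remainder)))
        return("clusters and remainder must be disjoint")
    TRUE
})

#' PromoterSet: extracted core promoter sequences
#'
#' Promoters are stored 5'->3' with respect to their gene's strand, ending
#' immediately before the gene start. Repeat-masked (lowercase in the
#' source) positions are uppercased in \code{sequences} but flagged in
#' \code{mask}; masked positions never host motif sites or pattern matches.
#'
#' @slot sequences \link[Biostrings]{DNAStringSet} named by gene id.
#' @slot mask list of logical vectors (one per promoter, TRUE = masked).
#' @slot info data.frame with gene_id, chrom, strand, start, end (1-based
#'   inclusive genomic coordinates of the promoter window).
#' @slot params list with Lmax, Lmin, stopAtNeighbour, useRepeatMask.
#' @exportClass PromoterSet
setClass("PromoterSet",
    representation(sequences = "DNAStringSet", mask = "list",
                   info = "data.frame", params = "list"))

setValidity("PromoterSet", function(object) {
    n <- length(object@sequences)
    if (length(object@mask) != n)
        return("mask must have one entry per sequence")
    w <- Biostrings::width(object@sequences)
    if (n && !identical(unname(lengths(object@mask)), as.integer(w)))
        return("mask lengths must equal sequence widths")
    if (is.null(names(object@sequences)) && n)
        return("sequences must be named by gene id")
    TRUE
})

#' MarkovBackground: order-k Markov model of promoter sequence
#'
#' Stores conditional probabilities P(base | preceding j-mer) for all
#' orders j = 0..k so that the first k positions of a sequence can be
#' scored with the appropriate lower-order chain.
#'
#' @slot order integer, the maximal order k.
#' @slot logp list of length k+1; element j+1 is a 4^j x 4 matrix of log
#'   conditional probabilities (rows = contexts in lexicographic A<C<G<T
#'   order, columns = A, C, G, T).
#' @slot alpha pseudocount added to every transition count.
#' @slot bothStrands logical; TRUE if counts included reverse complements.
#' @exportClass MarkovBackground
setClass("MarkovBackground",
    representation(order = "integer", logp = "list", alpha = "numeric",
                   bothStrands = "logical"))

setValidity("MarkovBackground", function(object) {
    k <- object@order
    if (length(object@logp) != k + 1L)
        return("logp must hold orders 0..k")
    for (j in 0:k) {
        pm <- exp(object@logp[[j + 1L]])
        if (!all(dim(pm) == c(4^j, 4L)))
            return(sprintf("order-%d matrix has wrong dimensions", j))
        if (any(abs(rowSums(pm) - 1) > 1e-12))
            return("conditional probabilities must sum to 1 per context")
    }
    TRUE
})

#' PWMotif: a discovered or library position probability matrix
#'
#' @slot name motif identifier.
#' @slot ppm w x 4 matrix of column probabilities (columns A, C, G, T);
#'   every row sums to 1.
#' @slot sites data.frame (gene_id, offset, strand, sequence) of the ZOOPS
#'   site list; offsets are 0-based on the promoter's forward orientation.
#' @slot llr log-likelihood ratio of the converged ZOOPS model vs the
#'   background-only model.
#' @slot trace numeric vector of the (penalized) EM objective per
#'   iteration; non-decreasing by the EM guarantee.
#' @slot meta list of bookkeeping (seed start, lambda, width, ...).
#' @exportClass PWMotif
setClass("PWMotif",
    representation(name = "character", ppm = "matrix", sites = "data.frame",
                   llr = "numeric", trace = "numeric", meta = "list"))

setValidity("PWMotif", function(object) {
    p <- object@ppm
    if (ncol(p) != 4L) return("ppm must have 4 columns (A, C, G, T)")
    if (any(p < -1e-12)) return("ppm entries must be non-negative")
    if (any(abs(rowSums(p) - 1) > 1e-9))
        return("each ppm row must sum to 1")
    TRUE
})

#' GOAnnotation: gene-to-GO-term mapping over a gene universe
#'
#' @slot mapping data.frame with columns \code{gene_id}, \code{term_id}.
#' @slot universe character vector of gene ids; every annotated gene is a
#'   member.
#' @exportClass GOAnnotation
setClass("GOAnnotation",
    representation(mapping = "data.frame", universe = "character"))

setValidity("GOAnnotation", function(object) {
    mp <- object@mapping
    if (!all(c("gene_id", "term_id") %in% names(mp)))
        return("mapping must have columns gene_id, term_id")
    if (!all(mp$gene_id %in% object@universe))
        return("every annotated gene must be in the universe")
    if (anyDuplicated(object@universe)) return("duplicate universe gene id")
    TRUE
})
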