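## Pearson-thresholded co-expression network over candidate genes and
## cluster extraction as connected components.

#' Sample Pearson correlation with the package's preconditions
#'
#' Wrapper around \code{stats::cor} that enforces equal lengths >= 3 and
#' flags zero-variance inputs as undefined (NA with a warning) rather than
#' erroring, mirroring how such genes are excluded from the network.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1], or NA if either vector has zero
#'   variance.
#' @export
pearsonCorrelation <- function(x, y) {
    if (length(x) != length(y)) stop("vectors must have equal length")
    if (length(x) < 3L) stop("need at least 3 observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("zero variance: correlation undefined")
        return(NA_real_)
    }
    stats::cor(x, y)
}

#' Build the co-expression network
#'
#' Computes all pairwise Pearson correlations of the candidate genes over
#' the given arrays and keeps an edge (a, b) iff r(a, b) >= r0 (signed,
#' inclusive). Genes with zero variance across the arrays are excluded and
#' recorded; candidate genes absent from the matrix are dropped with a
#' message.
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param candidates character vector of candidate gene ids.
#' @param arrays array ids to use (e.g. the selected discriminative
#'   arrays); at least 3.
#' @param r0 correlation threshold (study value 0.90, inclusive).
#' @param minClusterSize minimum component size carried in the params and
#'   used by \code{\link{extractClusters}}.
#' @return A \linkS4class{CoexpressionNetwork}.
#' @export
buildNetwork <- function(m, candidates, arrays, r0 = 0.90,
                         minClusterSize = 5L) {
    stopifnot(is(m, "ExpressionMatrix"))
    stopifnot(r0 > -1, r0 <= 1, minClusterSize >= 1)
    arrays <- as.character(arrays)
    if (length(arrays) < 3L)
        stop("need at least 3 arrays for a stable correlation")
    if (!all(arrays %in% arrayIds(m)))
        stop("unknown array id among the selected arrays")
    cand <- intersect(unique(candidates), geneIds(m))
    if (length(cand) < length(unique(candidates)))
        message("buildNetwork: ", length(unique(candidates)) - length(cand),
                " candidate gene(s) absent from the matrix")
    if (length(cand) < 2L)
        stop("need at least 2 candidate genes present in the matrix")
    sub <- exprValues(m)[cand, arrays, drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    excluded <- cand[sds == 0]
    if (length(excluded))
        message("buildNetwork: excluded ", length(excluded),
                " zero-variance gene(s)")
    keep <- cand[sds > 0]
    nodes <- sort(keep, method = "radix")
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        r = numeric(), stringsAsFactors = FALSE)
    if (length(nodes) >= 2L) {
        cc <- stats::cor(t(sub[nodes, , drop = FALSE]))
        idx <- which(upper.tri(cc) & cc >= r0, arr.ind = TRUE)
        if (nrow(idx)) {
            a <- nodes[idx[, 1L]]
            b <- nodes[idx[, 2L]]
            swap <- a > b
            tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
            edges <- data.frame(gene_a = a, gene_b = b,
                                r = cc[idx], stringsAsFactors = FALSE)
            edges <- edges[order(edges$gene_a, edges$gene_b,
                                 method = "radix"), , drop = FALSE]
            rownames(edges) <- NULL
        }
    }
    new("CoexpressionNetwork", nodes = nodes, edges = edges,
        params = list(r0 = r0, minClusterSize = as.integer(minClusterSize)),
        excluded = sort(excluded, method = "radix"))
}

#' @describeIn accessors node gene ids of a CoexpressionNetwork
#' @export
setMethod("networkNodes", "CoexpressionNetwork",
    function(object) object@nodes)

#' @describeIn accessors edge table (gene_a, gene_b, r)
#' @export
setMethod("networkEdges", "CoexpressionNetwork",
    function(object) object@edges)

#' @describeIn accessors zero-variance genes excluded from the network
#' @export
setMethod("excludedGenes", "CoexpressionNetwork",
    function(object) object@excluded)

#' @describeIn accessors network parameters (r0, minClusterSize)
#' @export
setMethod("networkParams", "CoexpressionNetwork",
    function(object) object@params)

setMethod("show", "CoexpressionNetwork", function(object) {
    cat("CoexpressionNetwork:", length(object@nodes), "nodes,",
        nrow(object@edges), "edges (r0 =", object@params$r0, ")\n")
})

#' Extract gene clusters as connected components
#'
#' Components with at least \code{minClusterSize} members become clusters
#' C0, C1, ... ordered by decreasing size, ties broken by the
#' lexicographically smallest member id. Everything else goes to the
#' remainder, so clusters plus remainder partition the node set exactly.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param minClusterSize minimum cluster size; defaults to the value
#'   carried in the network params.
#' @return A \linkS4class{GeneClusterSet}.
#' @export
extractClusters <- function(net, minClusterSize = NULL) {
    stopifnot(is(net, "CoexpressionNetwork"))
    if (is.null(minClusterSize))
        minClusterSize <- net@params$minClusterSize
    nodes <- networkNodes(net)
    ed <- networkEdges(net)
    if (!length(nodes))
        return(new("GeneClusterSet", clusters = list(),
                   remainder = character()))
    g <- igraph::graph_from_data_frame(
        ed[, c("gene_a", "gene_b")], directed = FALSE,
        vertices = data.frame(name = nodes))
    cmp <- igraph::components(g)
    comp_members <- split(nodes, cmp$membership[nodes])
    comp_members <- lapply(comp_members,
                           function(x) sort(x, method = "radix"))
    sizes <- lengths(comp_members)
    keep <- sizes >= minClusterSize
    clusters <- comp_members[keep]
    remainder <- unlist(comp_members[!keep], use.names = FALSE)
    remainder <- if (length(remainder))
        sort(remainder, method = "radix") else character()
    if (length(clusters)) {
        first_member <- vapply(clusters, `[`, character(1L), 1L)
        ord <- order(-lengths(clusters), first_member, method = "radix")
        clusters <- clusters[ord]
        names(clusters) <- paste0("C", seq_along(clusters) - 1L)
    }
    new("GeneClusterSet", clusters = clusters, remainder = remainder)
}

#' @describeIn accessors named list of cluster member vectors
#' @export
setMethod("clusterMembers", "GeneClusterSet",
    function(object) object@clusters)

#' @describeIn accessors named integer vector of cluster sizes
#' @export
setMethod("clusterSizes", "GeneClusterSet",
    function(object) lengths(object@clusters))

#' @describeIn accessors genes in components below the size cutoff
#' @export
setMethod("remainderGenes", "GeneClusterSet",
    function(object) object@remainder)

setMethod("show", "GeneClusterSet", function(object) {
    sz <- clusterSizes(object)
    cat("GeneClusterSet:", length(sz), "cluster(s)",
        if (length(sz)) paste0("[", paste(sz, collapse = ", "), "]") else "",
        "+", length(object@remainder), "remainder gene(s)\n")
})

#' Write a network as an edge-list TSV or GraphML file
#'
#' The edge list has columns gene_a, gene_b, r with gene_a < gene_b and
#' full double precision, so a read-back reproduces the network exactly.
#' GraphML is written through igraph with the correlation stored in the
#' \code{weight} edge attribute and r0/minClusterSize as graph attributes.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param path output file.
#' @param format \code{"edge-list"} or \code{"graphml"}.
#' @export
writeNetwork <- function(net, path, format = c("edge-list", "graphml")) {
    stopifnot(is(net, "CoexpressionNetwork"))
    format <- match.arg(format)
    if (format == "edge-list") {
        ed <- networkEdges(net)
        ed$r <- sprintf("%.17g", ed$r)
        con <- file(path, "w")
        on.exit(close(con))
        writeLines(paste0("#nodes\t", paste(networkNodes(net),
                                            collapse = ",")), con)
        write.table(ed, con, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
        g <- asIgraph(net)
        igraph::write_graph(g, path, format = "graphml")
    }
    invisible(path)
}

#' Convert a CoexpressionNetwork to an igraph graph
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @return an undirected \pkg{igraph} graph with a \code{weight} edge
#'   attribute.
#' @export
asIgraph <- function(net) {
    stopifnot(is(net, "CoexpressionNetwork"))
    ed <- networkEdges(net)
    g <- igraph::graph_from_data_frame(
        data.frame(from = ed$gene_a, to = ed$gene_b, weight = ed$r),
        directed = FALSE, vertices = data.frame(name = networkNodes(net)))
    g <- igraph::set_graph_attr(g, "r0", net@params$r0)
    igraph::set_graph_attr(g, "minClusterSize",
                           net@params$minClusterSize)
}

#' Read a network written by \code{\link{writeNetwork}}
#'
#' @param path input file.
#' @param format \code{"edge-list"} or \code{"graphml"}.
#' @param r0,minClusterSize parameters to attach when reading an edge
#'   list (GraphML carries them as graph attributes).
#' @return A \linkS4class{CoexpressionNetwork}.
#' @export
readNetwork <- function(path, format = c("edge-list", "graphml"),
                        r0 = 0.90, minClusterSize = 5L) {
    format <- match.arg(format)
    if (format == "edge-list") {
        first <- readLines(path, n = 1L)
        if (!startsWith(first, "#nodes\t"))
            stop("malformed edge-list file: missing #nodes header")
        nodes <- strsplit(sub("^#nodes\t", "", first), ",", fixed = TRUE)[[1L]]
        if (identical(nodes, "")) nodes <- character()
        ed <- read.delim(path, skip = 1L, stringsAsFactors = FALSE)
        if (!nrow(ed)) ed <- data.frame(gene_a = character(),
                                        gene_b = character(), r = numeric())
        new("CoexpressionNetwork", nodes = nodes, edges = ed,
            params = list(r0 = r0,
                          minClusterSize = as.integer(minClusterSize)),
            excluded = character())
    } else {
        g <- igraph::read_graph(path, format = "graphml")
        ed <- igraph::as_data_frame(g, what = "edges")
        nodes <- igraph::V(g)$name
        edges <- data.frame(gene_a = ed$from, gene_b = ed$to,
                            r = if (nrow(ed)) ed$weight else numeric(),
                            stringsAsFactors = FALSE)
        if (nrow(edges)) {
            swap <- edges$gene_a > edges$gene_b
            tmp <- edges$gene_a[swap]
            edges$gene_a[swap] <- edges$gene_b[swap]
            edges$gene_b[swap] <- tmp
            edges <- edges[order(edges$gene_a, edges$gene_b,
                                 method = "radix"), , drop = FALSE]
            rownames(edges) <- NULL
        }
        gr0 <- igraph::graph_attr(g, "r0")
        gmcs <- igraph::graph_attr(g, "minClusterSize")
        new("CoexpressionNetwork", nodes = sort(nodes, method = "radix"),
            edges = edges,
            params = list(r0 = if (is.null(gr0)) r0 else gr0,
                          minClusterSize = as.integer(
                              if (is.null(gmcs)) minClusterSize else gmcs)),
            excluded = character())
    }
}

#' Write cluster membership as TSV (cluster_id, gene_id)
#'
#' The remainder is written with cluster_id \code{"remainder"}.
#'
#' @param clusters a \linkS4class{GeneClusterSet}.
#' @param path output file.
#' @export
writeClusters <- function(clusters, path) {
    stopifnot(is(clusters, "GeneClusterSet"))
    cm <- clusterMembers(clusters)
    df <- data.frame(
        cluster_id = c(rep(names(cm), lengths(cm)),
                       rep("remainder", length(remainderGenes(clusters)))),
        gene_id = c(unlist(cm, use.names = FALSE),
                    remainderGenes(clusters)),
        stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
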