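test_that("pearson correlation wrapper handles the documented cases", {
    expect_equal(pearsonCorrelation(c(1, 2, 3), c(2, 4, 6)), 1)
    expect_equal(pearsonCorrelation(c(1, 2, 3), c(3, 2, 1)), -1)
    expect_equal(pearsonCorrelation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
    expect_error(pearsonCorrelation(1:3, 1:4), "equal length")
    expect_error(pearsonCorrelation(1:2, 2:1), "at least 3")
    expect_warning(r <- pearsonCorrelation(c(1, 1, 1), 1:3),
                   "zero variance")
    expect_true(is.na(r))
})

.net_fixture <- function() {
    v <- rbind(g1 = c(1, 2, 3, 4),
               g2 = c(2, 4, 6, 8),      # identical profile shape to g1
               g3 = c(4, 3, 2, 1),      # anti-correlated with g1
               g4 = c(5, 5, 5, 5))      # zero variance
    colnames(v) <- paste0("a", 1:4)
    ExpressionMatrix(v, "log2")
}

test_that("network edges use a signed inclusive threshold", {
    m <- .net_fixture()
    expect_message(net <- buildNetwork(m, rownames(exprValues(m)),
                                       paste0("a", 1:4), r0 = 0.90),
                   "zero-variance")
    ed <- networkEdges(net)
    expect_equal(nrow(ed), 1L)
    expect_equal(ed$gene_a, "g1")
    expect_equal(ed$gene_b, "g2")
    expect_equal(ed$r, 1)
    # anti-correlated pair (r = -1) yields no edge under the signed rule
    expect_false(any(ed$gene_a == "g3" | ed$gene_b == "g3"))
    expect_identical(excludedGenes(net), "g4")
    expect_error(buildNetwork(m, c("g1", "g2"), c("a1", "a2")),
                 "at least 3 arrays")
})

test_that("network is invariant to positive affine transforms", {
    set.seed(21)
    v <- matrix(rnorm(15 * 8), 15, 8,
                dimnames = list(sprintf("g%02d", 1:15), paste0("a", 1:8)))
    m1 <- ExpressionMatrix(v, "log2")
    v2 <- v
    v2[3, ] <- 2.5 * v2[3, ] + 7          # positive scale + shift
    m2 <- ExpressionMatrix(v2, "log2")
    n1 <- buildNetwork(m1, rownames(v), colnames(v), r0 = 0.3)
    n2 <- buildNetwork(m2, rownames(v), colnames(v), r0 = 0.3)
    expect_equal(networkEdges(n1), networkEdges(n2), tolerance = 1e-12)
})

test_that("edges and components match brute-force oracles", {
    for (sd in c(7, 8, 9)) {
        set.seed(sd)
        n <- sample(10:50, 1)
        v <- matrix(rnorm(n * 10), n, 10,
                    dimnames = list(sprintf("g%02d", seq_len(n)),
                                    paste0("a", 1:10)))
        # plant a few highly correlated pairs so the edge set is non-empty
        for (i in 1:4) v[i + 4, ] <- v[i, ] + rnorm(10, sd = 0.05)
        m <- ExpressionMatrix(v, "log2")
        r0 <- 0.5
        net <- buildNetwork(m, rownames(v), colnames(v), r0 = r0,
                            minClusterSize = 1L)
        ora <- oracle_edges(v, r0)
        expect_equal(networkEdges(net), ora, ignore_attr = TRUE,
                     tolerance = 1e-12)
        cl <- extractClusters(net)
        got <- unname(c(clusterMembers(cl),
                        as.list(remainderGenes(cl))))
        got <- got[order(-lengths(got),
                         vapply(got, `[`, character(1), 1))]
        expect_equal(got, oracle_components(networkNodes(net), ora))
    }
})

test_that("clusters are labelled by size with deterministic ties", {
    ed <- data.frame(gene_a = c("a", "b", "d"),
                     gene_b = c("b", "c", "e"), r = c(0.95, 0.95, 0.99))
    net <- new("CoexpressionNetwork",
               nodes = c("a", "b", "c", "d", "e", "z"), edges = ed,
               params = list(r0 = 0.9, minClusterSize = 2L),
               excluded = character())
    cl <- extractClusters(net)
    expect_identical(clusterMembers(cl),
                     list(C0 = c("a", "b", "c"), C1 = c("d", "e")))
    expect_identical(remainderGenes(cl), "z")
    # clusters + remainder partition the node set exactly
    expect_setequal(c(unlist(clusterMembers(cl)), remainderGenes(cl)),
                    networkNodes(net))
    # empty edge set: everything in the remainder
    net0 <- new("CoexpressionNetwork", nodes = c("a", "b"),
                edges = ed[0, ],
                params = list(r0 = 0.9, minClusterSize = 2L),
                excluded = character())
    cl0 <- extractClusters(net0)
    expect_length(clusterMembers(cl0), 0L)
    expect_identical(remainderGenes(cl0), c("a", "b"))
})

test_that("network files round-trip", {
    set.seed(31)
    v <- matrix(rnorm(8 * 6), 8, 6,
                dimnames = list(paste0("g", 1:8), paste0("a", 1:6)))
    v[2, ] <- v[1, ] + rnorm(6, sd = 0.01)
    net <- buildNetwork(ExpressionMatrix(v, "log2"), rownames(v),
                        colnames(v), r0 = 0.4)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeNetwork(net, tsv, "edge-list")
    back <- readNetwork(tsv, "edge-list", r0 = 0.4)
    expect_identical(networkEdges(back), networkEdges(net))
    expect_identical(networkNodes(back), networkNodes(net))
    gml <- withr::local_tempfile(fileext = ".graphml")
    writeNetwork(net, gml, "graphml")
    g <- igraph::read_graph(gml, format = "graphml")
    expect_equal(igraph::ecount(g), nrow(networkEdges(net)))
    back2 <- readNetwork(gml, "graphml")
    expect_equal(networkEdges(back2), networkEdges(net),
                 tolerance = 1e-9)
    expect_error(writeNetwork(net, tsv, "dot"))
})
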