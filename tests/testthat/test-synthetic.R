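test_that("generators are fully deterministic under a fixed seed", {
    s1 <- simulateExpression(seed = 5)
    s2 <- simulateExpression(seed = 5)
    expect_identical(exprValues(s1$expression), exprValues(s2$expression))
    expect_identical(s1$truth, s2$truth)
    p1 <- simulatePromoters(seed = 5)
    p2 <- simulatePromoters(seed = 5)
    expect_identical(as.character(promoterSequences(p1$promoters)),
                     as.character(promoterSequences(p2$promoters)))
    a1 <- simulateGoAnnotation(paste0("g", 1:100), seed = 5)
    a2 <- simulateGoAnnotation(paste0("g", 1:100), seed = 5)
    expect_identical(annotationMapping(a1$annotation),
                     annotationMapping(a2$annotation))
})

test_that("planted modules reach the requested correlation", {
    sim <- simulateExpression(seed = 2)
    v <- exprValues(sim$expression)
    mod <- sim$truth$moduleAssignment
    for (m in c("M1", "M2", "M3")) {
        genes <- names(mod)[mod == m]
        if (length(genes) < 10) next    # estimate too noisy below 10
        cc <- cor(t(v[genes, ]))
        mean_r <- mean(cc[upper.tri(cc)])
        expect_lt(abs(mean_r - 0.95), 0.03)
    }
})

test_that("discriminative truth is consistent with the matrix", {
    sim <- simulateExpression(seed = 3)
    v <- exprValues(sim$expression)
    disc <- sim$truth$discriminativeArrays
    signs <- sim$truth$shiftSigns
    # shifted genes sit on the side their fixed sign dictates
    for (a in disc) {
        z <- v[names(signs), a]
        expect_true(all(sign(z) == sign(signs)))
        expect_gt(mean(abs(z)), 3)
    }
    expect_error(simulateExpression(moduleCor = 1.2), "infeasible")
})

test_that("a zero shift leaves selection scores at the null level", {
    # with no planted signal the expected score is 2q (half the genes lie
    # in the pooled 25% tails); check the mean over seeds against 2q
    scores <- unlist(lapply(1:10, function(sd) {
        sim <- simulateExpression(shift = 0, seed = sd)
        selectionTable(suppressWarnings(selectDiscriminativeArrays(
            sim$expression, sim$positiveList)))$score
    }))
    se <- sd(scores) / sqrt(length(scores))
    expect_lt(abs(mean(scores) - 0.5), 3 * se + 0.01)
})

test_that("planted promoter instances exist verbatim at their offsets", {
    sim <- simulatePromoters(seed = 9, plantedConsensus = "GCCGNM",
                             nCarriers = 10)
    seqs <- as.character(promoterSequences(sim$promoters))
    for (g in sim$truth$carriers) {
        off <- sim$truth$offsets[[g]]
        inst <- sim$truth$instances[[g]]
        expect_identical(substr(seqs[[g]], off + 1, off + nchar(inst)),
                         inst)
        # the instance matches the degenerate consensus
        expect_equal(nrow(oracle_scan(inst, sim$truth$consensus,
                                      bothStrands = FALSE)), 1L)
    }
    # the degenerate pattern scan finds at least every carrier
    sc <- scanConsensus(sim$promoters, "GCCGNM")
    expect_gte(sum(sc$presence$present), 10L)
})

test_that("planted GO terms dominate their module's enrichment", {
    mod <- sprintf("g%03d", 1:20)
    uni <- sprintf("g%03d", 1:500)
    sim <- simulateGoAnnotation(uni, planted = list(
        list(genes = mod, term = "GO:PLANT", fraction = 0.9)), seed = 5)
    res <- enrichCluster(mod, sim$annotation)
    expect_identical(res$term_id[1], "GO:PLANT")
    expect_true(res$p_adj[1] < min(res$p_adj[-1]))
})

test_that("study files on disk reload with zero dropped records", {
    dir <- withr::local_tempdir()
    p <- simulateStudyFiles(dir, seed = 2, nGenes = 60, nArrays = 30,
                            nDiscriminative = 5, positiveListSize = 10,
                            moduleSizes = c(8L, 6L),
                            promoterLength = 120L)
    m <- readExpressionMatrix(p$expressionFile, scaleTag = "log2")
    expect_equal(dim(exprValues(m)), c(60L, 30L))
    expect_identical(exprValues(m),
                     exprValues(simulateExpression(
                         nGenes = 60, nArrays = 30, nDiscriminative = 5,
                         positiveListSize = 10, moduleSizes = c(8L, 6L),
                         seed = discoex:::.deriveSeed(2, 1))$expression))
    expect_length(readGeneList(p$positiveListFile), 10L)
    expect_length(readGeneList(p$candidateListFile), 60L)
    proms <- readPromoterFasta(p$promoterFile)
    expect_length(promoterSequences(proms), 60L)
    annot <- readGeneAnnotation(p$annotationFile)
    expect_true(all(annotationUniverse(annot) %in% geneIds(m)))
    lib <- readMemeMotifs(p$tfbsFile)
    expect_true("planted_synthetic" %in% names(lib))
    truth <- jsonlite::read_json(p$truthFile)
    expect_identical(unlist(truth$promoters$consensus), "CACGTGGC")
})
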