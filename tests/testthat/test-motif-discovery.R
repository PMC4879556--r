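.uniform_bg <- function() {
    suppressWarnings(trainMarkovBackground("ACGTACGTACGTACGTACGT", k = 0,
                                           alpha = 1, bothStrands = TRUE))
}

test_that("ZOOPS likelihood collapses to background for a flat motif", {
    bg <- .uniform_bg()
    ppm <- matrix(0.25, 6, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    s <- c(x = "ACGTACGTACGT", y = "GGGTTTAAACCC")
    ll <- zoopsLogLikelihood(ppm, s, bg, lambda = 0.4)
    bg_only <- sum(vapply(s, function(z) backgroundLogProb(bg, z),
                          numeric(1)))
    expect_lt(abs(ll - bg_only), 1e-9)
    # a near-deterministic motif matching a present site scores higher
    ppm2 <- matrix(0.01, 6, 4)
    hit <- match(strsplit("ACGTAC", "")[[1]], c("A", "C", "G", "T"))
    ppm2[cbind(1:6, hit)] <- 0.97
    expect_gt(zoopsLogLikelihood(ppm2, s, bg, lambda = 0.5), bg_only)
    # sequences shorter than the motif contribute background only
    short <- c(z = "ACG")
    expect_equal(zoopsLogLikelihood(ppm, short, bg, lambda = 0.4),
                 backgroundLogProb(bg, "ACG"))
})

test_that("ZOOPS likelihood equals a brute-force mixture enumeration", {
    bg <- .uniform_bg()
    base <- c("A", "C", "G", "T")
    ppm <- matrix(c(0.7, 0.1, 0.1, 0.1,
                    0.1, 0.7, 0.1, 0.1,
                    0.1, 0.1, 0.7, 0.1,
                    0.1, 0.1, 0.1, 0.7,
                    0.4, 0.3, 0.2, 0.1,
                    0.25, 0.25, 0.25, 0.25), 6, 4, byrow = TRUE)
    seqs <- c(s1 = "TTACGTACTT", s2 = "GGGGGGACGT")
    lambda <- 0.37
    # independent enumeration: for every sequence sum over all
    # offset/strand windows of P(window | ppm) / P(window | bg)
    enum <- 0
    for (s in seqs) {
        ch <- strsplit(s, "")[[1]]
        L <- length(ch)
        terms <- c()
        for (j in 1:(L - 6 + 1)) {
            win <- match(ch[j:(j + 5)], base)
            pf <- prod(ppm[cbind(1:6, win)]) / 0.25^6
            pr <- prod(ppm[cbind(1:6, 5 - rev(win))]) / 0.25^6
            terms <- c(terms, pf, pr)
        }
        enum <- enum + log((1 - lambda) + lambda * mean(terms)) +
            backgroundLogProb(bg, s)
    }
    expect_equal(zoopsLogLikelihood(ppm, seqs, bg, lambda), enum,
                 tolerance = 1e-9)
})

test_that("EM recovers a planted motif with a monotone objective", {
    for (sd in c(3, 11)) {
        sim <- simulatePromoters(seed = sd)
        mo <- discoverMotifs(sim$promoters, sim$backgroundModel,
                             nMotifs = 1, wMin = 8, wMax = 8, seed = sd)
        expect_length(mo, 1L)
        m <- mo[[1]]
        expect_lte(consensus_distance(motifConsensus(m),
                                      sim$truth$consensus), 1L)
        expect_true(all(diff(emTrace(m)) >= -1e-9))
        expect_true(all(abs(rowSums(motifPPM(m)) - 1) < 1e-9))
        expect_gte(countGeneSupport(m), 4L)
        # every reported site is a real slice of its promoter
        seqs <- as.character(promoterSequences(sim$promoters))
        st <- motifSites(m)
        for (i in seq_len(nrow(st))) {
            slice <- substr(seqs[[st$gene_id[i]]], st$offset[i] + 1,
                            st$offset[i] + 8)
            expect_identical(
                if (st$strand[i] == "-") revcomp_chr(slice) else slice,
                st$sequence[i])
        }
    }
})

test_that("motif discovery is deterministic for identical inputs", {
    sim <- simulatePromoters(seed = 4, nSeqs = 12, length = 200,
                             nCarriers = 8)
    m1 <- discoverMotifs(sim$promoters, sim$backgroundModel, nMotifs = 1,
                         wMin = 8, wMax = 8, seed = 4)
    m2 <- discoverMotifs(sim$promoters, sim$backgroundModel, nMotifs = 1,
                         wMin = 8, wMax = 8, seed = 4)
    expect_identical(motifPPM(m1[[1]]), motifPPM(m2[[1]]))
    expect_identical(motifSites(m1[[1]]), motifSites(m2[[1]]))
})

test_that("site erasure keeps later motifs off earlier sites", {
    sim <- simulatePromoters(seed = 6, nSeqs = 15, length = 250,
                             nCarriers = 12)
    mo <- discoverMotifs(sim$promoters, sim$backgroundModel, nMotifs = 2,
                         wMin = 8, wMax = 8, seed = 6)
    if (length(mo) == 2L) {
        s1 <- motifSites(mo[[1]]); s2 <- motifSites(mo[[2]])
        for (g in intersect(s1$gene_id, s2$gene_id)) {
            a <- s1[s1$gene_id == g, ]; b <- s2[s2$gene_id == g, ]
            expect_true(b$offset + 8 <= a$offset ||
                        a$offset + 8 <= b$offset)
        }
    }
    # objectives are reported in decreasing order
    llrs <- vapply(mo, motifLLR, numeric(1))
    expect_true(all(diff(llrs) <= 1e-9))
})
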