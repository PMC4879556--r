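test_that("consensus scanning matches the documented examples", {
    sc <- scanConsensus(c(s1 = "ACGTACGT"), "ACGT", bothStrands = FALSE)
    expect_equal(sc$occurrences$start, c(0L, 4L))
    sc2 <- scanConsensus(c(s1 = "TTGCCGTAGG"), "GCCGNM",
                         bothStrands = FALSE)
    expect_equal(sc2$occurrences$start, 2L)
    expect_equal(sc2$occurrences$match, "GCCGTA")
    # noov keeps one of three overlapping poly-A windows
    expect_equal(nrow(scanConsensus(c(s1 = "AAAAAA"), "AAAA",
                                    bothStrands = FALSE,
                                    noOverlap = TRUE)$occurrences), 1L)
    expect_equal(nrow(scanConsensus(c(s1 = "AAAAAA"), "AAAA",
                                    bothStrands = FALSE,
                                    noOverlap = FALSE)$occurrences), 3L)
    expect_error(scanConsensus(c(s1 = "ACGT"), "ACGJ"), "invalid IUPAC")
})

test_that("reverse-strand matches come from the pattern's complement", {
    # GCCGNM has a match on the minus strand of the RC of TTGCCGTAGG
    s <- revcomp_chr("TTGCCGTAGG")
    sc <- scanConsensus(setNames(s, "s1"), "GCCGNM", bothStrands = TRUE)
    expect_equal(sc$occurrences$strand, "-")
    expect_equal(sc$occurrences$match, "GCCGTA")
    # strand symmetry: scanning rc(P) on rc(S) mirrors the matches of P
    # on S (positions reflected, strand labels preserved), while
    # scanning P itself on rc(S) returns the same matches strand-swapped
    set.seed(23)
    for (i in 1:5) {
        sq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                    collapse = "")
        a <- scanConsensus(setNames(sq, "x"), "GCCGNM",
                           noOverlap = FALSE)$occurrences
        b <- scanConsensus(setNames(revcomp_chr(sq), "x"),
                           revcomp_chr("GCCGNM"),
                           noOverlap = FALSE)$occurrences
        mirror <- data.frame(start = 60 - b$start - 6, strand = b$strand)
        expect_setequal(paste(a$start, a$strand),
                        paste(mirror$start, mirror$strand))
        d <- scanConsensus(setNames(revcomp_chr(sq), "x"), "GCCGNM",
                           noOverlap = FALSE)$occurrences
        swap <- data.frame(start = 60 - d$start - 6,
                           strand = ifelse(d$strand == "+", "-", "+"))
        expect_setequal(paste(a$start, a$strand),
                        paste(swap$start, swap$strand))
    }
})

test_that("scanning equals the naive window oracle on random input", {
    set.seed(29)
    pats <- c("ACGT", "GCCGNM", "WWSSA", "CANNTG")
    for (i in 1:40) {
        sq <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                    collapse = "")
        pat <- sample(pats, 1)
        for (noov in c(TRUE, FALSE)) {
            got <- scanConsensus(setNames(sq, "x"), pat,
                                 bothStrands = TRUE,
                                 noOverlap = noov)$occurrences
            ora <- oracle_scan(sq, pat, bothStrands = TRUE,
                               noOverlap = noov)
            expect_setequal(paste(got$start, got$strand),
                            paste(ora$start0, ora$strand))
        }
    }
})

test_that("masked positions never match", {
    ps <- PromoterSet(c(p1 = "ACGTacgtACGT"))
    sc <- scanConsensus(ps, "ACGT", bothStrands = FALSE)
    expect_equal(sc$occurrences$start, c(0L, 8L))
})

test_that("gene support counts distinct genes", {
    ps <- PromoterSet(c(p1 = "ACGTGGACGTGG", p2 = "TTTTTTTT",
                        p3 = "CCACGTGG", p4 = "GGGGGGGG",
                        p5 = "ACGTGGTT"))
    # pattern twice in p1 still counts p1 once
    expect_equal(countGeneSupport("ACGTGG", ps, bothStrands = FALSE), 3L)
    expect_equal(countGeneSupport("ACGTGG",
                                  PromoterSet(c(p1 = "ACGTGGACGTGG")),
                                  bothStrands = FALSE), 1L)
    # order invariance
    ps2 <- PromoterSet(c(p5 = "ACGTGGTT", p3 = "CCACGTGG",
                         p4 = "GGGGGGGG", p2 = "TTTTTTTT",
                         p1 = "ACGTGGACGTGG"))
    expect_equal(countGeneSupport("ACGTGG", ps2, bothStrands = FALSE), 3L)
})

.fake_motif <- function(genes, w = 6) {
    ppm <- matrix(0.25, w, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    new("PWMotif", name = "m", ppm = ppm,
        sites = data.frame(gene_id = genes, offset = 0L, strand = "+",
                           sequence = strrep("A", w),
                           posterior = 0.9),
        llr = 1, trace = numeric(), meta = list())
}

test_that("the >= 4-gene support filter keeps and drops correctly", {
    m4 <- .fake_motif(paste0("g", 1:4))
    m3 <- .fake_motif(paste0("g", 1:3))
    kept <- filterMotifsByGeneSupport(list(m4, m3), minGenes = 4)
    expect_length(kept, 1L)
    expect_identical(motifSites(kept[[1]])$gene_id, paste0("g", 1:4))
    expect_length(filterMotifsByGeneSupport(list(), 4), 0L)
})

test_that("PWM library comparison finds self, shifts and orientation", {
    set.seed(37)
    mk <- function(w) {
        p <- matrix(rgamma(4 * w, 0.4), w, 4)
        p <- p / rowSums(p)
        colnames(p) <- c("A", "C", "G", "T")
        p
    }
    lib <- list(t1 = mk(8), t2 = mk(10), t3 = mk(7))
    cmp <- compareMotifToLibrary(lib$t1, lib, nShuffles = 100, seed = 2)
    expect_identical(cmp$target[1], "t1")
    expect_equal(cmp$offset[1], 0L, ignore_attr = TRUE)
    expect_identical(cmp$orientation[1], "+")
    expect_equal(cmp$score[1], 8)       # 8 perfectly matching columns
    expect_lte(cmp$p_value[1], 1 / 101 + 1e-12)
    # query = columns 3..8 of t2 -> t2 found at the matching offset
    q <- lib$t2[3:8, ]
    cmp2 <- compareMotifToLibrary(q, lib, nShuffles = 100, seed = 2)
    expect_identical(cmp2$target[1], "t2")
    expect_equal(cmp2$score[1], 6)
    expect_equal(cmp2$offset[1], -2L, ignore_attr = TRUE)
    # query = reverse complement of t3 -> orientation "-"
    cmp3 <- compareMotifToLibrary(discoex:::.pwmRevComp(lib$t3), lib,
                                  nShuffles = 100, seed = 2)
    expect_identical(cmp3$target[1], "t3")
    expect_identical(cmp3$orientation[1], "-")
    expect_error(compareMotifToLibrary(lib$t1, list()), "empty")
    expect_error(compareMotifToLibrary(lib$t1, lib, nShuffles = 10),
                 "100")
})

test_that("IUPAC consensus rendering follows the inclusion threshold", {
    ppm <- rbind(c(1, 0, 0, 0),
                 c(0.5, 0.5, 0, 0),
                 c(0.25, 0.25, 0.25, 0.25),
                 c(0.1, 0.2, 0.3, 0.4))
    colnames(ppm) <- c("A", "C", "G", "T")
    expect_identical(pwmToConsensus(ppm, 0.25), "AMNK")
    # threshold above every entry maps to N
    expect_identical(substr(pwmToConsensus(ppm, 0.6), 3, 3), "N")
    expect_identical(motifConsensus(ppm), "AAAT")
})

test_that("minimal MEME motif format round-trips", {
    set.seed(41)
    p <- matrix(rgamma(32, 1), 8, 4)
    p <- p / rowSums(p)
    colnames(p) <- c("A", "C", "G", "T")
    path <- withr::local_tempfile(fileext = ".meme")
    writeMemeMotifs(list(mA = p), path,
                    bgFreqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
    lib <- readMemeMotifs(path)
    expect_identical(names(lib), "mA")
    expect_lt(max(abs(lib$mA - p)), 1e-6)
    expect_error(readMemeMotifs(withr::local_tempfile(lines = "x")),
                 "no motifs")
})
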