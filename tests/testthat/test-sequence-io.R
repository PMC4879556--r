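# small linear genome with genes placed to exercise every truncation rule
.seq_fixture <- function() {
    set.seed(17)
    chr1 <- paste(sample(c("A", "C", "G", "T"), 8000, replace = TRUE),
                  collapse = "")
    genome <- c(chr1 = chr1)
    gff <- c("##gff-version 3",
        # upstream neighbour ends at 4500; gene starts at 5001 -> 500 bp
        "chr1\tx\tgene\t4001\t4500\t.\t-\t.\tID=gNb",
        "chr1\tx\tgene\t5001\t5300\t.\t+\t.\tID=gA",
        # open upstream space -> full 1000 bp
        "chr1\tx\tgene\t7000\t7200\t.\t+\t.\tID=gB",
        # 30 bp gap to the neighbour (< Lmin) -> dropped
        "chr1\tx\tgene\t1001\t1100\t.\t+\t.\tID=gUp",
        "chr1\tx\tgene\t1131\t1400\t.\t+\t.\tID=gC",
        # minus-strand gene with open downstream-genomic space
        "chr1\tx\tgene\t2000\t2200\t.\t-\t.\tID=gD")
    gff_path <- tempfile(fileext = ".gff3")
    writeLines(gff, gff_path)
    fa_path <- tempfile(fileext = ".fa")
    writeLines(c(">chr1 test chromosome", chr1), fa_path)
    list(genome = genome, gff = gff_path, fa = fa_path)
}

test_that("FASTA and GFF3 readers parse and validate", {
    fx <- .seq_fixture()
    genome <- readFastaSequences(fx$fa)
    expect_identical(names(genome), "chr1")
    expect_equal(nchar(genome[["chr1"]]), 8000L)
    genes <- readGeneModels(fx$gff, genome)
    expect_setequal(genes$gene_id,
                    c("gNb", "gA", "gB", "gUp", "gC", "gD"))
    gA <- genes[genes$gene_id == "gA"]
    expect_equal(GenomicRanges::start(gA), 5001L)
    expect_equal(GenomicRanges::end(gA), 5300L)
    expect_equal(as.character(GenomicRanges::strand(gA)), "+")
    # coordinates beyond the chromosome are rejected by name
    bad <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "chr1\tx\tgene\t7990\t9000\t.\t+\t.\tID=gBad"), bad)
    expect_error(readGeneModels(bad, genome), "gBad")
})

test_that("promoter extraction follows length and neighbour rules", {
    fx <- .seq_fixture()
    genes <- readGeneModels(fx$gff, fx$genome)
    expect_message(ps <- extractPromoters(genes, fx$genome),
                   "dropped")
    info <- promoterInfo(ps)
    w <- setNames(Biostrings::width(promoterSequences(ps)),
                  names(promoterSequences(ps)))
    expect_equal(unname(w["gA"]), 500L)     # truncated by gNb at 4500
    expect_equal(info$start[info$gene_id == "gA"], 4501L)
    expect_equal(info$end[info$gene_id == "gA"], 5000L)
    expect_equal(unname(w["gB"]), 1000L)    # no neighbour within 1000 bp
    expect_false("gC" %in% names(w))        # 30 bp gap < Lmin
    expect_true(all(w >= 50L & w <= 1000L))
    # promoters never overlap an annotated gene body
    st <- GenomicRanges::start(genes); en <- GenomicRanges::end(genes)
    for (i in seq_len(nrow(info)))
        expect_false(any(st <= info$end[i] & en >= info$start[i]))
    # promoter sequence of a + gene is the literal upstream slice
    expect_identical(as.character(promoterSequences(ps)[["gA"]]),
                     toupper(substr(fx$genome[["chr1"]], 4501, 5000)))
    # minus-strand promoter is the reverse complement of the slice
    gD_info <- info[info$gene_id == "gD", ]
    slice <- substr(fx$genome[["chr1"]], gD_info$start, gD_info$end)
    expect_identical(as.character(promoterSequences(ps)[["gD"]]),
                     revcomp_chr(toupper(slice)))
})

test_that("extraction commutes with reverse-complementing the genome", {
    fx <- .seq_fixture()
    genes <- readGeneModels(fx$gff, fx$genome)
    ps <- suppressMessages(extractPromoters(genes, fx$genome))
    # flip the chromosome and mirror all coordinates/strands
    L <- nchar(fx$genome[["chr1"]])
    flipped <- c(chr1 = revcomp_chr(fx$genome[["chr1"]]))
    gr <- GenomicRanges::GRanges(
        "chr1",
        IRanges::IRanges(L - GenomicRanges::end(genes) + 1L,
                         L - GenomicRanges::start(genes) + 1L),
        strand = ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                        "-", "+"))
    gr$gene_id <- genes$gene_id
    ps2 <- suppressMessages(extractPromoters(gr, flipped))
    for (g in names(promoterSequences(ps)))
        expect_identical(as.character(promoterSequences(ps2)[[g]]),
                         as.character(promoterSequences(ps)[[g]]))
})

test_that("promoter FASTA round-trips with mask lowercase", {
    seqs <- c(p1 = "ACGTacgtACGT", p2 = "TTTTGGGGCCCC")
    ps <- PromoterSet(seqs)
    expect_identical(as.character(promoterSequences(ps)[["p1"]]),
                     "ACGTACGTACGT")
    expect_identical(which(promoterMask(ps)[[1]]), 5:8)
    fa <- withr::local_tempfile(fileext = ".fa")
    writePromoterFasta(ps, fa)
    back <- readPromoterFasta(fa)
    expect_identical(as.character(promoterSequences(back)),
                     as.character(promoterSequences(ps)))
    expect_identical(promoterMask(back), promoterMask(ps))
})
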