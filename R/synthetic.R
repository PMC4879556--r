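## Synthetic-data generators: expression compendia with planted
## discriminative arrays and co-expression modules, promoters with planted
## motif instances over a random order-k Markov background, and GO
## annotations with planted enriched terms. Every generator returns the
## ground truth alongside the data so each pipeline stage is testable
## without external downloads.

.withSeed <- function(seed, expr) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
    force(expr)
}

#' Simulate an expression compendium with planted structure
#'
#' Background entries are i.i.d. N(0, noiseSd^2) on the (already
#' normalized, log-like) scale. Each module is driven by a single latent
#' factor: a module gene's profile is
#' noiseSd * (sqrt(rho) * factor + sqrt(1 - rho) * eps), giving expected
#' within-module pairwise Pearson correlation rho. In the planted
#' discriminative arrays every positive-list gene is shifted by
#' +/- shift * noiseSd (sign fixed per gene), placing it in the extreme
#' quantiles of those arrays.
#'
#' @param nGenes,nArrays compendium dimensions (defaults 200 x 100).
#' @param nDiscriminative number of planted discriminative arrays (10).
#' @param positiveListSize size of the positive gene list (20).
#' @param moduleSizes sizes of the planted co-expression modules
#'   (default 20, 15, 10).
#' @param moduleCor target within-module correlation(s) (default 0.95).
#' @param shift discriminative shift in within-array SD units (4).
#' @param noiseSd background standard deviation (1).
#' @param seed RNG seed.
#' @return list with \code{expression} (an
#'   \linkS4class{ExpressionMatrix}), \code{positiveList},
#'   \code{candidates} (all gene ids) and \code{truth} (discriminative
#'   array ids, module assignment, shift signs, parameters).
#' @export
simulateExpression <- function(nGenes = 200L, nArrays = 100L,
                               nDiscriminative = 10L,
                               positiveListSize = 20L,
                               moduleSizes = c(20L, 15L, 10L),
                               moduleCor = 0.95, shift = 4,
                               noiseSd = 1, seed = 1L) {
    moduleCor <- rep_len(moduleCor, length(moduleSizes))
    if (any(moduleCor > 1)) stop("infeasible module correlation > 1")
    if (any(moduleCor < 0)) stop("module correlation must be >= 0")
    stopifnot(sum(moduleSizes) + positiveListSize <= nGenes,
              nDiscriminative <= nArrays)
    .withSeed(seed, {
        genes <- sprintf("g%03d", seq_len(nGenes))
        arrays <- sprintf("a%03d", seq_len(nArrays))
        v <- matrix(rnorm(nGenes * nArrays, sd = noiseSd), nGenes, nArrays,
                    dimnames = list(genes, arrays))
        assign_mod <- stats::setNames(rep("background", nGenes), genes)
        at <- 0L
        for (mi in seq_along(moduleSizes)) {
            idx <- at + seq_len(moduleSizes[mi])
            rho <- moduleCor[mi]
            fac <- rnorm(nArrays)
            eps <- matrix(rnorm(moduleSizes[mi] * nArrays),
                          moduleSizes[mi], nArrays)
            v[idx, ] <- noiseSd * (sqrt(rho) * rep(1, moduleSizes[mi]) %o%
                                   fac + sqrt(1 - rho) * eps)
            assign_mod[idx] <- paste0("M", mi)
            at <- at + moduleSizes[mi]
        }
        pos <- genes[at + seq_len(positiveListSize)]
        disc <- sort(sample(arrays, nDiscriminative))
        signs <- stats::setNames(sample(c(-1, 1), positiveListSize,
                                        replace = TRUE), pos)
        v[pos, disc] <- v[pos, disc] + signs * shift * noiseSd
        truth <- list(seed = seed,
                      params = list(nGenes = nGenes, nArrays = nArrays,
                                    nDiscriminative = nDiscriminative,
                                    positiveListSize = positiveListSize,
                                    moduleSizes = moduleSizes,
                                    moduleCor = moduleCor, shift = shift,
                                    noiseSd = noiseSd),
                      discriminativeArrays = disc,
                      moduleAssignment = assign_mod,
                      positiveList = pos,
                      shiftSigns = signs)
        list(expression = ExpressionMatrix(v, "log2"),
             positiveList = pos, candidates = genes, truth = truth)
    })
}

## a random order-k Markov chain; Dirichlet(8) conditionals give the
## mild compositional bias typical of real upstream regions rather than
## a pathologically spiky chain
.randomMarkovBackground <- function(k, seed) {
    .withSeed(seed, {
        logp <- lapply(0:k, function(j) {
            g <- matrix(stats::rgamma(4^j * 4L, shape = 8), 4^j, 4L)
            lp <- log(g / rowSums(g))
            colnames(lp) <- .BASES
            lp
        })
        new("MarkovBackground", order = as.integer(k), logp = logp,
            alpha = 0, bothStrands = FALSE)
    })
}

.resolveIupac <- function(consensus) {
    sets <- strsplit(Biostrings::IUPAC_CODE_MAP[
        .checkIupac(toupper(consensus))], "", fixed = TRUE)
    paste(vapply(sets, function(b)
        if (length(b) == 1L) b else sample(b, 1L), character(1L)),
        collapse = "")
}

#' Simulate promoters with planted motif instances
#'
#' Sequences are sampled from a random order-k Markov chain (its
#' parameters drawn with \code{backgroundSourceSeed}); one exact instance
#' of the planted consensus (degenerate positions resolved uniformly per
#' instance) is inserted at a uniform random offset in each carrier.
#'
#' @param nSeqs number of promoters (30).
#' @param length promoter length in bp (500).
#' @param backgroundOrder Markov order of the generating chain (3).
#' @param backgroundSourceSeed seed for the chain parameters.
#' @param plantedConsensus IUPAC consensus to plant (default CACGTGGC).
#' @param nCarriers number of carrier promoters (20).
#' @param seed RNG seed for sequences, carriers and offsets.
#' @param ids optional promoter names (default s001, s002, ...).
#' @param carriers optional explicit carrier ids (overrides nCarriers).
#' @return list with \code{promoters} (a \linkS4class{PromoterSet}) and
#'   \code{truth} (carriers, 0-based offsets, inserted instances,
#'   consensus, seeds).
#' @export
simulatePromoters <- function(nSeqs = 30L, length = 500L,
                              backgroundOrder = 3L,
                              backgroundSourceSeed = 97L,
                              plantedConsensus = "CACGTGGC",
                              nCarriers = 20L, seed = 1L, ids = NULL,
                              carriers = NULL) {
    w <- nchar(plantedConsensus)
    stopifnot(w <= length)
    if (is.null(ids)) ids <- sprintf("s%03d", seq_len(nSeqs))
    stopifnot(length(ids) == nSeqs)
    bg <- .randomMarkovBackground(backgroundOrder, backgroundSourceSeed)
    .withSeed(seed, {
        seqs <- sampleBackgroundSequences(bg, nSeqs, length)
        names(seqs) <- ids
        if (is.null(carriers)) {
            stopifnot(nCarriers <= nSeqs)
            carriers <- sort(sample(ids, nCarriers))
        } else stopifnot(all(carriers %in% ids))
        offsets <- integer(0); instances <- character(0)
        for (cid in carriers) {
            inst <- .resolveIupac(plantedConsensus)
            off <- sample.int(length - w + 1L, 1L) - 1L
            s <- seqs[[cid]]
            substr(s, off + 1L, off + w) <- inst
            seqs[[cid]] <- s
            offsets <- c(offsets, off)
            instances <- c(instances, inst)
        }
        truth <- list(seed = seed,
                      backgroundSourceSeed = backgroundSourceSeed,
                      backgroundOrder = backgroundOrder,
                      consensus = plantedConsensus,
                      width = w,
                      carriers = carriers,
                      offsets = stats::setNames(offsets, carriers),
                      instances = stats::setNames(instances, carriers))
        # the generating chain doubles as the "pre-calculated genome-wide"
        # background a motif search would use, so planted sites are not
        # absorbed into a background trained on the very input promoters
        list(promoters = PromoterSet(seqs), truth = truth,
             backgroundModel = bg)
    })
}

#' Simulate a GO annotation with planted enriched terms
#'
#' Decoy terms draw genes uniformly from the universe; each planted term
#' contains the stated fraction of its module's genes plus uniform fill
#' from the rest of the universe up to a size drawn from
#' \code{termSizeRange}.
#'
#' @param universe character vector of gene ids.
#' @param nTerms number of decoy terms (50).
#' @param termSizeRange inclusive size range of terms (default 10-40).
#' @param planted list of \code{list(genes = ..., term = ..., fraction =
#'   ...)} entries describing enriched terms (may be empty).
#' @param seed RNG seed.
#' @return list with \code{annotation} (a \linkS4class{GOAnnotation} over
#'   the full universe) and \code{truth} (planted term-gene sets).
#' @export
simulateGoAnnotation <- function(universe, nTerms = 50L,
                                 termSizeRange = c(10L, 40L),
                                 planted = list(), seed = 1L) {
    stopifnot(termSizeRange[2L] <= length(universe),
              termSizeRange[1L] >= 1L)
    .withSeed(seed, {
        rows <- list()
        for (i in seq_len(nTerms)) {
            sz <- sample(seq.int(termSizeRange[1L], termSizeRange[2L]), 1L)
            rows[[length(rows) + 1L]] <- data.frame(
                gene_id = sample(universe, sz),
                term_id = sprintf("GO:D%04d", i), stringsAsFactors = FALSE)
        }
        planted_truth <- list()
        for (pl in planted) {
            stopifnot(all(pl$genes %in% universe),
                      pl$fraction > 0, pl$fraction <= 1)
            nin <- max(1L, round(pl$fraction * length(pl$genes)))
            core <- sample(pl$genes, nin)
            sz <- sample(seq.int(termSizeRange[1L], termSizeRange[2L]), 1L)
            fill <- sample(setdiff(universe, pl$genes),
                           max(0L, sz - nin))
            rows[[length(rows) + 1L]] <- data.frame(
                gene_id = c(core, fill), term_id = pl$term,
                stringsAsFactors = FALSE)
            planted_truth[[pl$term]] <- list(term = pl$term,
                                             genes = c(core, fill),
                                             coreGenes = core,
                                             fraction = pl$fraction)
        }
        mapping <- do.call(rbind, rows)
        truth <- list(seed = seed, nTerms = nTerms,
                      termSizeRange = termSizeRange,
                      planted = planted_truth)
        list(annotation = GOAnnotation(mapping, universe), truth = truth)
    })
}

#' Write a synthetic-truth record as JSON
#'
#' @param truth truth list from a generator.
#' @param path output file.
#' @export
writeSyntheticTruth <- function(truth, path) {
    jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Generate a complete synthetic study on disk
#'
#' Runs all three generators with seeds derived from one master seed and
#' writes every file the pipeline reads: expression TSV, positive and
#' candidate gene lists, promoter FASTA (promoters for every gene, with
#' the consensus planted in the first module's genes), annotation TSV
#' (one planted term per module), a small TFBS library in MEME format
#' containing the planted consensus, and a truth JSON.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @param promoterLength promoter length in bp (default 300 to keep the
#'   motif stage quick at desk scale).
#' @param ... passed to \code{\link{simulateExpression}}.
#' @return list of file paths plus the three truth records.
#' @export
simulateStudyFiles <- function(dir, seed = 1L, promoterLength = 300L,
                               ...) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sim <- simulateExpression(seed = .deriveSeed(seed, 1L), ...)
    genes <- geneIds(sim$expression)
    mod <- sim$truth$moduleAssignment
    m1 <- names(mod)[mod == "M1"]
    simp <- simulatePromoters(
        nSeqs = length(genes), length = promoterLength,
        backgroundSourceSeed = .deriveSeed(seed, 2L),
        seed = .deriveSeed(seed, 3L), ids = genes, carriers = sort(m1))
    modules <- setdiff(unique(mod), "background")
    planted <- lapply(seq_along(modules), function(i)
        list(genes = names(mod)[mod == modules[i]],
             term = sprintf("GO:P%04d", i), fraction = 0.9))
    sima <- simulateGoAnnotation(genes, planted = planted,
                                 seed = .deriveSeed(seed, 4L))
    paths <- list(
        expressionFile = file.path(dir, "expression.tsv"),
        positiveListFile = file.path(dir, "positive_list.txt"),
        candidateListFile = file.path(dir, "candidates.txt"),
        promoterFile = file.path(dir, "promoters.fasta"),
        annotationFile = file.path(dir, "annotation.tsv"),
        tfbsFile = file.path(dir, "tfbs_synthetic.meme"),
        truthFile = file.path(dir, "truth.json"))
    writeExpressionMatrix(sim$expression, paths$expressionFile)
    writeGeneList(sim$positiveList, paths$positiveListFile)
    writeGeneList(sim$candidates, paths$candidateListFile)
    writePromoterFasta(simp$promoters, paths$promoterFile)
    writeGeneAnnotation(sima$annotation, paths$annotationFile)
    cons <- strsplit(simp$truth$consensus, "", fixed = TRUE)[[1L]]
    ppm <- matrix(0.01, length(cons), 4L,
                  dimnames = list(NULL, .BASES))
    for (i in seq_along(cons)) {
        allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[[cons[i]]], "",
                            fixed = TRUE)[[1L]]
        ppm[i, allowed] <- (1 - 0.01 * (4 - length(allowed))) /
            length(allowed)
    }
    lib <- stats::setNames(list(ppm), "planted_synthetic")
    lib$decoy_at_rich <- matrix(rep(c(0.45, 0.05, 0.05, 0.45), 8L),
                                8L, 4L, byrow = TRUE,
                                dimnames = list(NULL, .BASES))
    lib$decoy_gc_rich <- matrix(rep(c(0.05, 0.45, 0.45, 0.05), 6L),
                                6L, 4L, byrow = TRUE,
                                dimnames = list(NULL, .BASES))
    writeMemeMotifs(lib, paths$tfbsFile)
    writeSyntheticTruth(list(expression = sim$truth,
                             promoters = simp$truth,
                             annotation = sima$truth),
                        paths$truthFile)
    c(paths, list(expressionTruth = sim$truth,
                  promoterTruth = simp$truth,
                  annotationTruth = sima$truth))
}
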