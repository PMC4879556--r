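## End-to-end orchestration: normalize -> select arrays -> network ->
## clusters -> per-cluster motif discovery, support filter, TFBS
## comparison, consensus scans -> GO enrichment; all stage outputs are
## written to the output directory together with a machine-readable
## report. All randomness flows from one master seed via per-stage
## derived seeds, so a rerun with the same configuration is
## byte-identical.

.deriveSeed <- function(master, idx) {
    as.integer(((as.numeric(master) %% 1048576) * 1009 +
                idx * 9973) %% 2147483647)
}

#' Assemble and validate a pipeline configuration
#'
#' Every study parameter is a named, defaulted field: q = 0.25 and
#' f = 0.70 (array selection), r0 = 0.90 (network threshold), promoter
#' handling upstream, 10 motifs of width 6-12 over an order-3 background,
#' and the >= 4-gene motif support rule.
#'
#' @param expressionFile gene x array TSV.
#' @param positiveListFile positive gene list (one id per line).
#' @param candidateListFile candidate (responsive) gene list.
#' @param promoterFile promoter FASTA
#'   (\code{gene_id|chrom|strand|start-end} or bare gene-id headers).
#' @param annotationFile gene-to-GO TSV or GAF.
#' @param outDir output directory.
#' @param tfbsFile optional known-TFBS library in MEME format.
#' @param q,f array-selection parameters.
#' @param r0,minClusterSize network parameters.
#' @param nMotifs,wMin,wMax,backgroundOrder motif-discovery parameters.
#' @param nRefine EM starting points refined per width.
#' @param minMotifGenes motif support filter (default 4).
#' @param consensusPatterns named character vector of IUPAC patterns to
#'   scan per cluster (may be empty).
#' @param normalize quantile-normalize the matrix first (default TRUE).
#' @param scaleTag scale of the stored expression values.
#' @param seed master seed.
#' @return validated configuration list (class \code{discoexConfig}).
#' @export
pipelineConfig <- function(expressionFile, positiveListFile,
                           candidateListFile, promoterFile,
                           annotationFile, outDir, tfbsFile = NULL,
                           q = 0.25, f = 0.70, r0 = 0.90,
                           minClusterSize = 5L, nMotifs = 10L,
                           wMin = 6L, wMax = 12L, backgroundOrder = 3L,
                           nRefine = 5L,
                           minMotifGenes = 4L,
                           consensusPatterns = character(),
                           normalize = TRUE,
                           scaleTag = "log2", seed = 1L) {
    cfg <- list(expressionFile = expressionFile,
                positiveListFile = positiveListFile,
                candidateListFile = candidateListFile,
                promoterFile = promoterFile,
                annotationFile = annotationFile,
                tfbsFile = tfbsFile, outDir = outDir, q = q, f = f,
                r0 = r0, minClusterSize = as.integer(minClusterSize),
                nMotifs = as.integer(nMotifs), wMin = as.integer(wMin),
                wMax = as.integer(wMax),
                backgroundOrder = as.integer(backgroundOrder),
                nRefine = as.integer(nRefine),
                minMotifGenes = as.integer(minMotifGenes),
                consensusPatterns = consensusPatterns,
                normalize = isTRUE(normalize), scaleTag = scaleTag,
                seed = as.integer(seed))
    for (fl in c("expressionFile", "positiveListFile",
                 "candidateListFile", "promoterFile", "annotationFile"))
        if (!file.exists(cfg[[fl]]))
            stop("configuration error: ", fl, " not found: ", cfg[[fl]])
    if (!is.null(tfbsFile) && !file.exists(tfbsFile))
        stop("configuration error: tfbsFile not found: ", tfbsFile)
    if (!(cfg$q > 0 && cfg$q <= 0.5))
        stop("configuration error: q must lie in (0, 0.5]")
    if (!(cfg$f > 0 && cfg$f <= 1))
        stop("configuration error: f must lie in (0, 1]")
    if (!(cfg$r0 > -1 && cfg$r0 <= 1))
        stop("configuration error: r0 must lie in (-1, 1]")
    if (cfg$wMin > cfg$wMax || cfg$wMin < 2L)
        stop("configuration error: invalid motif width range")
    if (cfg$minMotifGenes < 1L)
        stop("configuration error: minMotifGenes must be >= 1")
    if (length(cfg$consensusPatterns))
        invisible(lapply(cfg$consensusPatterns, .checkIupac))
    class(cfg) <- "discoexConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' Relative input paths are resolved against the YAML file's directory.
#'
#' @param path YAML file with fields matching the arguments of
#'   \code{\link{pipelineConfig}}.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    y <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    for (fl in c("expressionFile", "positiveListFile", "candidateListFile",
                 "promoterFile", "annotationFile", "tfbsFile", "outDir"))
        if (!is.null(y[[fl]]) && !grepl("^(/|[A-Za-z]:)", y[[fl]]))
            y[[fl]] <- file.path(base, y[[fl]])
    if (!is.null(y$consensusPatterns))
        y$consensusPatterns <- unlist(y$consensusPatterns)
    do.call(pipelineConfig, y)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full discriminative co-expression pipeline
#'
#' Executes normalize, select-arrays, network, clusters, per-cluster
#' motif discovery + support filter + TFBS comparison + consensus scans,
#' and GO enrichment, writing all stage outputs plus \code{report.json}
#' and \code{run.log} into the configured output directory. Reruns with
#' the same configuration are byte-identical.
#'
#' @param config a configuration from \code{\link{pipelineConfig}} or
#'   \code{\link{readPipelineConfig}}.
#' @return invisibly, a list with the report, the stage objects and the
#'   output paths.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "discoexConfig"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    log_lines <- character()
    note <- function(...) {
        log_lines <<- c(log_lines, paste0(...))
    }
    cfg_path <- file.path(config$outDir, "config_used.yaml")
    cfg_plain <- unclass(config)
    cfg_plain$outDir <- NULL        # run-local, kept out of the hash
    cfg_plain <- cfg_plain[!vapply(cfg_plain, is.null, logical(1L))]
    yaml::write_yaml(cfg_plain, cfg_path)
    cfg_hash <- unname(tools::md5sum(cfg_path))
    note("discoex pipeline; master seed ", config$seed,
         "; config md5 ", cfg_hash)

    m <- .stage("read-expression",
        readExpressionMatrix(config$expressionFile,
                             scaleTag = config$scaleTag))
    note("expression: ", nrow(exprValues(m)), " genes x ",
         ncol(exprValues(m)), " arrays")
    if (config$normalize)
        m <- .stage("normalize", suppressWarnings(quantileNormalize(m)))
    pos <- .stage("read-positive-list",
                  readGeneList(config$positiveListFile))
    cand <- .stage("read-candidate-list",
                   readGeneList(config$candidateListFile))

    sel <- .stage("select-arrays", suppressWarnings(
        selectDiscriminativeArrays(m, pos, q = config$q, f = config$f)))
    writeArraySelection(sel, file.path(config$outDir,
                                       "array_selection.tsv"))
    arrays <- selectedArrays(sel)
    note("selected ", length(arrays), " of ", ncol(exprValues(m)),
         " arrays (q = ", config$q, ", f = ", config$f, ")")

    net <- .stage("network",
        buildNetwork(m, cand, arrays, r0 = config$r0,
                     minClusterSize = config$minClusterSize))
    writeNetwork(net, file.path(config$outDir, "network_edges.tsv"),
                 "edge-list")
    writeNetwork(net, file.path(config$outDir, "network.graphml"),
                 "graphml")
    clusters <- .stage("clusters", extractClusters(net))
    writeClusters(clusters, file.path(config$outDir, "clusters.tsv"))
    cm <- clusterMembers(clusters)
    note("network: ", length(networkNodes(net)), " nodes, ",
         nrow(networkEdges(net)), " edges; ", length(cm), " cluster(s) [",
         paste(lengths(cm), collapse = ", "), "] + ",
         length(remainderGenes(clusters)), " remainder")

    promoters <- .stage("read-promoters",
                        readPromoterFasta(config$promoterFile))
    bg <- .stage("background",
        trainMarkovBackground(promoters, k = config$backgroundOrder))
    lib <- if (!is.null(config$tfbsFile))
        .stage("read-tfbs", readMemeMotifs(config$tfbsFile)) else NULL

    annot <- .stage("read-annotation",
                    readGeneAnnotation(config$annotationFile))

    motif_report <- list()
    scan_rows <- list()
    comp_rows <- list()
    enr_rows <- list()
    motifs_by_cluster <- list()
    for (ci in seq_along(cm)) {
        cname <- names(cm)[ci]
        members <- cm[[ci]]
        prom_c <- subsetPromoters(promoters, members)
        n_prom <- length(promoterSequences(prom_c))
        motifs <- list()
        kept <- list()
        if (n_prom >= 2L) {
            motifs <- .stage(paste0("motifs-", cname),
                discoverMotifs(prom_c, bg, nMotifs = config$nMotifs,
                               wMin = config$wMin, wMax = config$wMax,
                               seed = .deriveSeed(config$seed, 10L + ci),
                               nRefine = config$nRefine))
            kept <- filterMotifsByGeneSupport(motifs,
                                              config$minMotifGenes)
            if (length(kept)) {
                writeMemeMotifs(kept,
                    file.path(config$outDir,
                              paste0("motifs_", cname, ".meme")),
                    bgFreqs = backgroundLetterFreqs(bg))
                writeMotifSites(kept,
                    file.path(config$outDir,
                              paste0("motif_sites_", cname, ".tsv")))
            }
            if (length(kept) && !is.null(lib)) {
                for (mo in kept) {
                    cmp <- compareMotifToLibrary(
                        mo, lib,
                        seed = .deriveSeed(config$seed, 100L + ci))
                    cmp <- cbind(cluster = cname,
                                 motif = motifName(mo), cmp)
                    comp_rows[[length(comp_rows) + 1L]] <- cmp
                }
            }
        } else note("cluster ", cname,
                    ": fewer than 2 promoters; motif discovery skipped")
        pat_support <- list()
        for (pi in seq_along(config$consensusPatterns)) {
            pat <- config$consensusPatterns[[pi]]
            pname <- names(config$consensusPatterns)[pi]
            if (is.null(pname) || !nzchar(pname)) pname <- pat
            if (n_prom) {
                sc <- scanConsensus(prom_c, pat)
                if (nrow(sc$occurrences))
                    scan_rows[[length(scan_rows) + 1L]] <-
                        cbind(cluster = cname, pattern = pname,
                              sc$occurrences)
                pat_support[[pname]] <- sum(sc$presence$present)
            } else pat_support[[pname]] <- 0L
        }
        enr <- .stage(paste0("enrichment-", cname),
                      suppressMessages(enrichCluster(members, annot)))
        if (nrow(enr))
            enr_rows[[length(enr_rows) + 1L]] <- cbind(cluster = cname,
                                                       enr)
        motif_report[[cname]] <- list(
            nPromoters = n_prom,
            motifsDiscovered = length(motifs),
            motifsRetained = length(kept),
            retainedConsensus = vapply(kept, pwmToConsensus,
                                       character(1L)),
            patternSupport = pat_support,
            enrichedTerms = sum(enr$p_adj < 0.05))
        motifs_by_cluster[[cname]] <- list(all = motifs, kept = kept)
    }
    .writeStageTable(comp_rows, config$outDir, "tfbs_comparisons.tsv",
        c("cluster", "motif", "target", "offset", "orientation",
          "score", "p_value"))
    .writeStageTable(scan_rows, config$outDir, "pattern_occurrences.tsv",
        c("cluster", "pattern", "gene_id", "start", "strand", "match"))
    .writeStageTable(enr_rows, config$outDir, "enrichment.tsv",
        c("cluster", "term_id", "k", "n", "K", "N", "p_raw", "p_adj"))

    report <- list(
        seed = config$seed,
        configHash = cfg_hash,
        nArrays = ncol(exprValues(m)),
        nArraysSelected = length(arrays),
        nCandidates = length(cand),
        nNetworkNodes = length(networkNodes(net)),
        nNetworkEdges = nrow(networkEdges(net)),
        nExcludedGenes = length(excludedGenes(net)),
        clusterSizes = as.list(lengths(cm)),
        nRemainder = length(remainderGenes(clusters)),
        clusters = motif_report)
    jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(config$outDir, "run.log"))
    invisible(list(report = report, selection = sel, network = net,
                   clusters = clusters, motifs = motifs_by_cluster,
                   enrichment = if (length(enr_rows))
                       do.call(rbind, enr_rows) else NULL,
                   configHash = cfg_hash, outDir = config$outDir))
}

.writeStageTable <- function(rows, dir, name, cols) {
    df <- if (length(rows)) do.call(rbind, rows) else
        stats::setNames(as.data.frame(
            replicate(length(cols), character(), simplify = FALSE)), cols)
    if (nrow(df)) {
        num <- vapply(df, is.numeric, logical(1L))
        df[num] <- lapply(df[num], function(x)
            ifelse(x == round(x) & abs(x) < 2^31, sprintf("%d",
                as.integer(round(x))), sprintf("%.17g", x)))
    }
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(NULL)
}
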