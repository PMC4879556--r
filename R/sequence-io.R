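## Genome/annotation input and core-promoter extraction under the length
## and neighbour-truncation rules (Lmax = 1000, Lmin = 50, stop at
## neighbouring gene, keep repeat masking as lowercase flags).

.revcompChar <- function(x) {
    vapply(x, function(s) {
        s <- chartr("ACGTacgtNn", "TGCAtgcaNn", s)
        paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
    }, character(1L), USE.NAMES = FALSE)
}

#' Read FASTA sequences preserving case
#'
#' Repeat-masked genomes mark repeats as lowercase; case is preserved here
#' (sequences are returned as plain character strings) and interpreted by
#' \code{\link{extractPromoters}}. Names are the first whitespace-delimited
#' header token.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readFastaSequences <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    x <- Biostrings::readBStringSet(path)
    names(x) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1L), 1L)
    stats::setNames(as.character(x), names(x))
}

#' Read gene models from a GFF3 file
#'
#' Keeps records of type \code{gene}; the gene id is taken from the ID
#' attribute (falling back to Name). Coordinates are 1-based inclusive as
#' in GFF3; if a genome is supplied, coordinates beyond the chromosome
#' length raise an error naming the record.
#'
#' @param path GFF3 file.
#' @param genome optional named character vector of chromosome sequences
#'   (as from \code{\link{readFastaSequences}}) used for validation.
#' @return a \link[GenomicRanges]{GRanges} of genes with a \code{gene_id}
#'   metadata column.
#' @export
readGeneModels <- function(path, genome = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    gr <- rtracklayer::import(path)
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
    if (all(is.na(ids)) && !is.null(gr$Name)) ids <- as.character(gr$Name)
    if (any(is.na(ids) | !nzchar(ids)))
        stop("gene record without ID/Name attribute in ", path)
    S4Vectors::mcols(gr)$gene_id <- ids
    if (any(!as.character(GenomicRanges::strand(gr)) %in% c("+", "-")))
        stop("gene with undefined strand in ", path)
    if (!is.null(genome)) {
        chr <- as.character(GenomicRanges::seqnames(gr))
        bad <- !chr %in% names(genome)
        if (any(bad))
            stop("gene ", ids[bad][1L], " on unknown chromosome ",
                 chr[bad][1L])
        lens <- nchar(genome)[chr]
        over <- GenomicRanges::end(gr) > lens | GenomicRanges::start(gr) < 1L
        if (any(over))
            stop("gene ", ids[over][1L],
                 " has coordinates beyond the chromosome length")
    }
    gr
}

#' Construct a PromoterSet from raw sequences
#'
#' Lowercase positions are recorded as masked and the stored sequence is
#' uppercased.
#'
#' @param seqs named character vector of promoter sequences (5'->3' with
#'   respect to the gene).
#' @param info optional data.frame (gene_id, chrom, strand, start, end);
#'   synthesized if missing.
#' @param params list of extraction parameters kept for provenance.
#' @return A \linkS4class{PromoterSet}.
#' @export
PromoterSet <- function(seqs, info = NULL, params = list()) {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
        stop("promoter sequences must be named by gene id")
    mask <- lapply(seqs, function(s) {
        ch <- strsplit(s, "", fixed = TRUE)[[1L]]
        ch %in% c("a", "c", "g", "t", "n")
    })
    names(mask) <- NULL
    up <- toupper(seqs)
    if (is.null(info))
        info <- data.frame(gene_id = names(seqs), chrom = NA_character_,
                           strand = NA_character_, start = NA_integer_,
                           end = NA_integer_, stringsAsFactors = FALSE)
    new("PromoterSet",
        sequences = Biostrings::DNAStringSet(up),
        mask = mask, info = info, params = params)
}

#' @describeIn accessors promoter DNAStringSet (uppercased)
#' @export
setMethod("promoterSequences", "PromoterSet",
    function(object) object@sequences)

#' @describeIn accessors list of logical mask vectors (TRUE = masked)
#' @export
setMethod("promoterMask", "PromoterSet", function(object) object@mask)

#' @describeIn accessors promoter coordinate table
#' @export
setMethod("promoterInfo", "PromoterSet", function(object) object@info)

setMethod("show", "PromoterSet", function(object) {
    w <- Biostrings::width(object@sequences)
    cat("PromoterSet:", length(w), "promoters",
        if (length(w)) sprintf("(widths %d-%d)", min(w), max(w)) else "",
        "\n")
})

#' Extract core promoters upstream of annotated genes
#'
#' For a + strand gene the promoter is the up-to-\code{Lmax} bases ending
#' immediately before the gene start, truncated where the body of any
#' other annotated gene (either strand) intrudes; for a - strand gene the
#' symmetric window on the 3' genomic side is taken and
#' reverse-complemented, so all promoters read 5'->3' towards the gene.
#' Promoters shorter than \code{Lmin} (including genes at a sequence edge)
#' are dropped with a message. Lowercase (repeat-masked) genome positions
#' are carried into the promoter mask.
#'
#' @param genes \link[GenomicRanges]{GRanges} with a \code{gene_id}
#'   column, as from \code{\link{readGeneModels}}.
#' @param genome named character vector of chromosome sequences.
#' @param Lmax maximum promoter length (default 1000).
#' @param Lmin minimum promoter length (default 50).
#' @param stopAtNeighbour truncate at neighbouring gene bodies (default
#'   TRUE).
#' @return A \linkS4class{PromoterSet}.
#' @export
extractPromoters <- function(genes, genome, Lmax = 1000L, Lmin = 50L,
                             stopAtNeighbour = TRUE) {
    stopifnot(is(genes, "GRanges"), Lmin >= 1L, Lmax >= Lmin)
    ids <- genes$gene_id
    chr <- as.character(GenomicRanges::seqnames(genes))
    std <- as.character(GenomicRanges::strand(genes))
    gs <- GenomicRanges::start(genes)
    ge <- GenomicRanges::end(genes)
    if (any(!chr %in% names(genome)))
        stop("gene on a chromosome absent from the genome")
    chrlen <- nchar(genome)
    seqs <- character(); keep <- character()
    info <- list()
    dropped <- 0L
    for (i in seq_along(genes)) {
        L <- chrlen[[chr[i]]]
        if (std[i] == "+") {
            wstart <- max(1L, gs[i] - Lmax); wend <- gs[i] - 1L
        } else {
            wstart <- ge[i] + 1L; wend <- min(L, ge[i] + Lmax)
        }
        if (wend >= wstart && stopAtNeighbour) {
            nb <- which(chr == chr[i] & seq_along(genes) != i &
                        gs <= wend & ge >= wstart)
            if (length(nb)) {
                if (std[i] == "+")
                    wstart <- max(wstart, max(ge[nb]) + 1L)
                else
                    wend <- min(wend, min(gs[nb]) - 1L)
            }
        }
        plen <- wend - wstart + 1L
        if (plen < Lmin) { dropped <- dropped + 1L; next }
        s <- substr(genome[[chr[i]]], wstart, wend)
        if (std[i] == "-") s <- .revcompChar(s)
        seqs <- c(seqs, s); keep <- c(keep, ids[i])
        info[[length(info) + 1L]] <- data.frame(
            gene_id = ids[i], chrom = chr[i], strand = std[i],
            start = wstart, end = wend, stringsAsFactors = FALSE)
    }
    if (dropped)
        message("extractPromoters: dropped ", dropped,
                " gene(s) with promoter shorter than Lmin = ", Lmin)
    names(seqs) <- keep
    info <- if (length(info)) do.call(rbind, info) else
        data.frame(gene_id = character(), chrom = character(),
                   strand = character(), start = integer(),
                   end = integer(), stringsAsFactors = FALSE)
    PromoterSet(seqs, info,
                params = list(Lmax = Lmax, Lmin = Lmin,
                              stopAtNeighbour = stopAtNeighbour,
                              useRepeatMask = TRUE))
}

#' Read a promoter FASTA (headers "gene_id|chrom|strand|start-end")
#'
#' Plain headers with just a gene id are also accepted. Lowercase letters
#' become masked positions.
#'
#' @param path FASTA file.
#' @param Lmax,Lmin length bounds recorded in the params.
#' @return A \linkS4class{PromoterSet}.
#' @export
readPromoterFasta <- function(path, Lmax = 1000L, Lmin = 50L) {
    x <- Biostrings::readBStringSet(path)
    hdr <- vapply(strsplit(names(x), "\\s+"), `[`, character(1L), 1L)
    parts <- strsplit(hdr, "|", fixed = TRUE)
    gid <- vapply(parts, `[`, character(1L), 1L)
    info <- data.frame(gene_id = gid,
                       chrom = vapply(parts, function(p)
                           if (length(p) >= 2L) p[2L] else NA_character_,
                           character(1L)),
                       strand = vapply(parts, function(p)
                           if (length(p) >= 3L) p[3L] else NA_character_,
                           character(1L)),
                       stringsAsFactors = FALSE)
    rng <- vapply(parts, function(p)
        if (length(p) >= 4L) p[4L] else NA_character_, character(1L))
    se <- t(vapply(strsplit(rng, "-", fixed = TRUE), function(p)
        if (length(p) == 2L) as.integer(p) else c(NA_integer_, NA_integer_),
        integer(2L)))
    info$start <- se[, 1L]; info$end <- se[, 2L]
    seqs <- stats::setNames(as.character(x), gid)
    PromoterSet(seqs, info, params = list(Lmax = Lmax, Lmin = Lmin))
}

#' Write a PromoterSet as FASTA, restoring mask lowercase
#'
#' Headers are "gene_id|chrom|strand|start-end" when coordinates are
#' known, else the bare gene id.
#'
#' @param promoters a \linkS4class{PromoterSet}.
#' @param path output file.
#' @export
writePromoterFasta <- function(promoters, path) {
    stopifnot(is(promoters, "PromoterSet"))
    seqs <- as.character(promoterSequences(promoters))
    msk <- promoterMask(promoters)
    info <- promoterInfo(promoters)
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(seqs)) {
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
        ch[msk[[i]]] <- tolower(ch[msk[[i]]])
        hdr <- names(seqs)[i]
        if (!is.na(info$chrom[i]))
            hdr <- paste0(hdr, "|", info$chrom[i], "|", info$strand[i],
                          "|", info$start[i], "-", info$end[i])
        writeLines(c(paste0(">", hdr), paste(ch, collapse = "")), con)
    }
    invisible(path)
}

#' Subset a PromoterSet by gene ids
#'
#' @param promoters a \linkS4class{PromoterSet}.
#' @param ids gene ids to keep (order preserved; absent ids are dropped
#'   silently).
#' @return A \linkS4class{PromoterSet}.
#' @export
subsetPromoters <- function(promoters, ids) {
    stopifnot(is(promoters, "PromoterSet"))
    nm <- names(promoterSequences(promoters))
    keep <- which(nm %in% ids)
    new("PromoterSet",
        sequences = promoterSequences(promoters)[keep],
        mask = promoterMask(promoters)[keep],
        info = promoterInfo(promoters)[
            match(nm[keep], promoterInfo(promoters)$gene_id), ,
            drop = FALSE],
        params = promoters@params)
}
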