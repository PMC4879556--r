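## Motif support counting, the >= 4-gene support filter, IUPAC consensus
## scanning on both strands with optional non-overlap, and Tomtom-style
## comparison of discovered PWMs against a known-TFBS library.

.IUPAC_REV <- local({
    mp <- Biostrings::IUPAC_CODE_MAP
    stats::setNames(names(mp), vapply(strsplit(mp, ""), function(b)
        paste(sort(b), collapse = ""), character(1L)))
})

.checkIupac <- function(pattern) {
    ch <- strsplit(pattern, "", fixed = TRUE)[[1L]]
    bad <- setdiff(ch, names(Biostrings::IUPAC_CODE_MAP))
    if (length(bad))
        stop("invalid IUPAC letter in pattern: ", bad[1L])
    invisible(ch)
}

#' Scan promoters for an IUPAC degenerate consensus pattern
#'
#' Finds all exact degenerate matches of the pattern. Reverse-strand
#' matches are found by matching the reverse complement of the pattern
#' against the forward sequence and reported with strand \code{-}. With
#' \code{noOverlap}, matches are thinned left-to-right greedily per
#' strand: after a match at \code{[i, i+w)} the next accepted match starts
#' at or after \code{i+w}. Matches covering masked positions are
#' discarded. Genes shorter than the pattern simply yield no matches.
#'
#' @param promoters a \linkS4class{PromoterSet} or named character vector.
#' @param pattern IUPAC degenerate string (e.g. "GCCGNM").
#' @param bothStrands also scan the reverse strand (study setting TRUE).
#' @param noOverlap prevent overlapping matches per strand (RSAT "noov";
#'   study setting TRUE).
#' @return list with \code{occurrences} (data.frame gene_id, start
#'   [0-based], strand, match — the matched sequence in pattern
#'   orientation) and \code{presence} (data.frame gene_id, n_occurrences,
#'   present).
#' @export
scanConsensus <- function(promoters, pattern, bothStrands = TRUE,
                          noOverlap = TRUE) {
    .checkIupac(toupper(pattern))
    pattern <- toupper(pattern)
    if (is(promoters, "PromoterSet")) {
        seqs <- as.character(promoterSequences(promoters))
        masks <- promoterMask(promoters)
    } else {
        seqs <- as.character(promoters)
        if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
        masks <- lapply(nchar(seqs), function(n) rep(FALSE, n))
    }
    w <- nchar(pattern)
    pat_f <- Biostrings::DNAString(pattern)
    pat_r <- Biostrings::reverseComplement(pat_f)
    occ <- list()
    n_occ <- stats::setNames(integer(length(seqs)), names(seqs))
    for (s in seq_along(seqs)) {
        if (nchar(seqs[s]) < w) next
        subj <- Biostrings::DNAString(seqs[s])
        msk <- c(0L, cumsum(masks[[s]]))
        strands <- if (bothStrands) c("+", "-") else "+"
        for (std in strands) {
            pat <- if (std == "+") pat_f else pat_r
            st <- Biostrings::start(
                Biostrings::matchPattern(pat, subj, fixed = "subject"))
            if (length(st))                      # drop masked windows
                st <- st[msk[st + w] - msk[st] == 0L]
            if (noOverlap && length(st) > 1L) {
                keep <- st[1L]; last_end <- st[1L] + w - 1L
                for (p in st[-1L]) if (p > last_end) {
                    keep <- c(keep, p); last_end <- p + w - 1L
                }
                st <- keep
            }
            for (p in st) {
                m <- substr(seqs[s], p, p + w - 1L)
                if (std == "-") m <- .revcompChar(m)
                occ[[length(occ) + 1L]] <- data.frame(
                    gene_id = names(seqs)[s], start = p - 1L,
                    strand = std, match = m, stringsAsFactors = FALSE)
            }
            n_occ[s] <- n_occ[s] + length(st)
        }
    }
    occurrences <- if (length(occ)) do.call(rbind, occ) else
        data.frame(gene_id = character(), start = integer(),
                   strand = character(), match = character(),
                   stringsAsFactors = FALSE)
    if (nrow(occurrences)) {
        occurrences <- occurrences[order(
            match(occurrences$gene_id, names(seqs)),
            occurrences$start, occurrences$strand,
            method = "radix"), , drop = FALSE]
        rownames(occurrences) <- NULL
    }
    presence <- data.frame(gene_id = names(seqs),
                           n_occurrences = as.integer(n_occ),
                           present = n_occ > 0L, stringsAsFactors = FALSE)
    rownames(presence) <- NULL
    list(occurrences = occurrences, presence = presence)
}

#' Number of distinct genes supporting a motif or pattern
#'
#' For a discovered \linkS4class{PWMotif} the ZOOPS site list is used
#' (discovery-time support, one site at most per gene); for an IUPAC
#' pattern string the promoters are scanned on both strands.
#'
#' @param x a \linkS4class{PWMotif} or IUPAC pattern string.
#' @param promoters a \linkS4class{PromoterSet}; required for patterns.
#' @param ... passed to \code{\link{scanConsensus}} for patterns.
#' @return integer count of distinct genes with at least one occurrence.
#' @export
countGeneSupport <- function(x, promoters = NULL, ...) {
    if (is(x, "PWMotif"))
        return(length(unique(motifSites(x)$gene_id)))
    if (is.character(x)) {
        if (is.null(promoters)) stop("promoters required to scan a pattern")
        if (is(promoters, "PromoterSet") &&
            !length(promoterSequences(promoters))) return(0L)
        sc <- scanConsensus(promoters, x, ...)
        return(sum(sc$presence$present))
    }
    stop("x must be a PWMotif or an IUPAC pattern string")
}

#' Filter motifs by distinct-gene support
#'
#' Keeps motifs whose site list covers at least \code{minGenes} distinct
#' genes (study rule: motifs found in the promoters of at least four
#' genes are carried forward to TFBS comparison).
#'
#' @param motifs list of \linkS4class{PWMotif}.
#' @param minGenes minimum number of distinct genes (default 4).
#' @return filtered list of \linkS4class{PWMotif}.
#' @export
filterMotifsByGeneSupport <- function(motifs, minGenes = 4L) {
    stopifnot(minGenes >= 1L)
    motifs[vapply(motifs, countGeneSupport, integer(1L)) >= minGenes]
}

## summed column-correlation alignment score between two PPMs (as in
## Tomtom, where per-column scores are summed over the overlap so longer
## faithful overlaps beat short coincidental ones); returns the best
## (score, offset) with overlap >= minOverlap. Query position i aligns
## target position i - d.
.pwmAlignScore <- function(Q, Tm, minOverlap) {
    wq <- nrow(Q); wt <- nrow(Tm)
    best <- list(score = -Inf, offset = NA_integer_)
    for (d in seq.int(-(wt - 1L), wq - 1L)) {
        i1 <- max(1L, d + 1L); i2 <- min(wq, wt + d)
        ov <- i2 - i1 + 1L
        if (ov < minOverlap) next
        cs <- vapply(seq.int(i1, i2), function(i) {
            a <- Q[i, ]; b <- Tm[i - d, ]
            if (stats::sd(a) == 0 || stats::sd(b) == 0) 0
            else stats::cor(a, b)
        }, numeric(1L))
        sc <- sum(cs)
        if (sc > best$score) best <- list(score = sc, offset = d)
    }
    best
}

.pwmRevComp <- function(Tm) {
    out <- Tm[rev(seq_len(nrow(Tm))), c(4L, 3L, 2L, 1L), drop = FALSE]
    colnames(out) <- .BASES
    out
}

.asPPMList <- function(lib) {
    if (is(lib, "PWMotif")) lib <- list(lib)
    if (is.list(lib) && length(lib) && is(lib[[1L]], "PWMotif")) {
        nm <- vapply(lib, motifName, character(1L))
        lib <- stats::setNames(lapply(lib, motifPPM), nm)
    }
    lib
}

#' Compare a discovered motif to a library of known TFBS models
#'
#' Tomtom-style alignment: for each library model and each orientation
#' (target as-is and reverse-complemented) every offset with at least
#' \code{minOverlap} aligned columns is scored by the summed Pearson
#' correlation of aligned probability columns; the empirical p-value is
#' obtained by re-aligning against \code{nShuffles} column-order-shuffled
#' versions of the target: p = (1 + #\{shuffled score >= observed\}) /
#' (1 + nShuffles). Results are ranked by p, then score.
#'
#' @param query a \linkS4class{PWMotif} or PPM matrix.
#' @param library named list of PPM matrices (as from
#'   \code{\link{readMemeMotifs}}) or of \linkS4class{PWMotif}.
#' @param minOverlap minimum aligned columns (default 4).
#' @param nShuffles number of column shuffles for the null (>= 100).
#' @param seed RNG seed for the shuffles.
#' @return data.frame (target, offset, orientation, score, p_value),
#'   one row per library model, ranked by p then score.
#' @export
compareMotifToLibrary <- function(query, library, minOverlap = 4L,
                                  nShuffles = 200L, seed = 1L) {
    if (is(query, "PWMotif")) query <- motifPPM(query)
    library <- .asPPMList(library)
    if (!length(library)) stop("empty TFBS library")
    if (nShuffles < 100L) stop("need at least 100 shuffles")
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
    rows <- lapply(names(library), function(nm) {
        Tm <- library[[nm]]
        if (minOverlap > min(nrow(query), nrow(Tm)))
            stop("minOverlap exceeds motif width for target ", nm)
        fw <- .pwmAlignScore(query, Tm, minOverlap)
        rv <- .pwmAlignScore(query, .pwmRevComp(Tm), minOverlap)
        obs <- if (fw$score >= rv$score)
            c(fw, orientation = "+") else c(rv, orientation = "-")
        ge <- 0L
        for (b in seq_len(nShuffles)) {
            Ts <- Tm[sample.int(nrow(Tm)), , drop = FALSE]
            sc <- max(.pwmAlignScore(query, Ts, minOverlap)$score,
                      .pwmAlignScore(query, .pwmRevComp(Ts),
                                     minOverlap)$score)
            if (sc >= obs$score) ge <- ge + 1L
        }
        data.frame(target = nm, offset = obs$offset,
                   orientation = obs$orientation, score = obs$score,
                   p_value = (1 + ge) / (1 + nShuffles),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$p_value, -out$score, out$target,
                     method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' IUPAC consensus string of a position probability matrix
#'
#' Per column, the set of bases with probability at least
#' \code{threshold} maps to its IUPAC degenerate code; an empty set maps
#' to N.
#'
#' @param motif a \linkS4class{PWMotif} or PPM matrix.
#' @param threshold inclusion probability threshold (default 0.25).
#' @return IUPAC consensus string.
#' @export
pwmToConsensus <- function(motif, threshold = 0.25) {
    stopifnot(threshold > 0, threshold <= 1)
    p <- if (is(motif, "PWMotif")) motifPPM(motif) else motif
    paste(apply(p, 1L, function(row) {
        bases <- .BASES[row >= threshold]
        if (!length(bases)) return("N")
        .IUPAC_REV[[paste(sort(bases), collapse = "")]]
    }), collapse = "")
}

#' Majority-base consensus of a motif
#'
#' @param motif a \linkS4class{PWMotif} or PPM matrix.
#' @return string of the highest-probability base per column.
#' @export
motifConsensus <- function(motif) {
    p <- if (is(motif, "PWMotif")) motifPPM(motif) else motif
    paste(.BASES[apply(p, 1L, which.max)], collapse = "")
}

#' Write motifs in minimal MEME motif text format
#'
#' @param motifs list of \linkS4class{PWMotif} or named list of PPM
#'   matrices.
#' @param path output file.
#' @param bgFreqs background letter frequencies written to the header.
#' @export
writeMemeMotifs <- function(motifs, path,
                            bgFreqs = c(A = 0.25, C = 0.25,
                                        G = 0.25, T = 0.25)) {
    is_pwm <- is.list(motifs) && length(motifs) &&
        is(motifs[[1L]], "PWMotif")
    ppms <- .asPPMList(motifs)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
                 "strands: + -", "", "Background letter frequencies",
                 paste(sprintf("%s %.5f", .BASES, bgFreqs[.BASES]),
                       collapse = " "), ""), con)
    for (i in seq_along(ppms)) {
        p <- ppms[[i]]
        nsites <- if (is_pwm)
            max(1L, nrow(motifs[[i]]@sites)) else 20L
        writeLines(c(paste("MOTIF", names(ppms)[i]),
                     sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                             nrow(p), nsites)), con)
        writeLines(apply(p, 1L, function(r)
            paste(sprintf("%10.6f", r), collapse = " ")), con)
        writeLines("", con)
    }
    invisible(path)
}

#' Read motifs from minimal MEME motif text format
#'
#' @param path MEME-format file.
#' @return named list of PPM matrices (w x 4, columns A, C, G, T) with an
#'   \code{nsites} attribute; usable as a TFBS library.
#' @export
readMemeMotifs <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    out <- list()
    i <- 1L
    while (i <= length(lines)) {
        if (grepl("^MOTIF\\s+", lines[i])) {
            nm <- strsplit(trimws(lines[i]), "\\s+")[[1L]][2L]
            j <- i + 1L
            while (j <= length(lines) &&
                   !grepl("^letter-probability matrix:", lines[j]))
                j <- j + 1L
            if (j > length(lines))
                stop("motif ", nm, " has no probability matrix")
            hdr <- lines[j]
            w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
            ns <- if (grepl("nsites=", hdr))
                as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr)) else NA
            rows <- lines[seq.int(j + 1L, j + w)]
            p <- do.call(rbind, lapply(rows, function(r)
                as.numeric(strsplit(trimws(r), "\\s+")[[1L]])))
            if (ncol(p) != 4L)
                stop("motif ", nm, " matrix does not have 4 columns")
            colnames(p) <- .BASES
            attr(p, "nsites") <- ns
            out[[nm]] <- p
            i <- j + w + 1L
        } else i <- i + 1L
    }
    if (!length(out)) stop("no motifs found in ", path)
    out
}

#' Write motif site lists as TSV
#'
#' @param motifs list of \linkS4class{PWMotif}.
#' @param path output file.
#' @export
writeMotifSites <- function(motifs, path) {
    rows <- lapply(motifs, function(m) {
        s <- motifSites(m)
        if (!nrow(s)) return(NULL)
        cbind(motif = motifName(m),
              s[, c("gene_id", "offset", "strand", "sequence")])
    })
    df <- do.call(rbind, rows)
    if (is.null(df))
        df <- data.frame(motif = character(), gene_id = character(),
                         offset = integer(), strand = character(),
                         sequence = character())
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write pattern occurrences as BED6 (promoter-relative coordinates)
#'
#' Coordinates are 0-based half-open on the promoter; the name field
#' carries the pattern, the score field the constant 0.
#'
#' @param occurrences occurrences data.frame from
#'   \code{\link{scanConsensus}}.
#' @param pattern pattern label for the name column.
#' @param path output file.
#' @export
writeOccurrencesBed <- function(occurrences, pattern, path) {
    w <- nchar(occurrences$match)
    bed <- data.frame(occurrences$gene_id, occurrences$start,
                      occurrences$start + w, pattern, 0L,
                      occurrences$strand)
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
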