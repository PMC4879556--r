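## ZOOPS (zero-or-one occurrence per sequence) expectation-maximization
## motif discovery against an order-k Markov background, in the spirit of
## MEME's ZOOPS model: per sequence the motif is either absent (prob
## 1 - lambda) or present once at an offset/strand drawn uniformly from
## the eligible windows. All windows of all sequences are pooled into one
## matrix so E- and M-steps run as a handful of vectorized operations.

## ---- internal machinery ---------------------------------------------------

## per-sequence scoring cache: integer codes, per-position background
## conditional log-probabilities and their cumulative sum
.seqCache <- function(seqs, bg) {
    lapply(seqs, function(s) {
        codes <- .dnaCodes(s)
        bglp <- .bgCondLogProb(bg, codes)
        list(codes = codes, bglp = bglp, cum = c(0, cumsum(bglp)))
    })
}

## eligible window start offsets (1-based) for width w under a mask
.eligibleOffsets <- function(codes, mask, w) {
    L <- length(codes)
    if (L < w) return(integer())
    bad <- is.na(codes) | mask
    if (!any(bad)) return(seq_len(L - w + 1L))
    cs <- c(0L, cumsum(bad))
    offs <- seq_len(L - w + 1L)
    offs[cs[offs + w] - cs[offs] == 0L]
}

## pooled window structure over all sequences for one width:
## D (N x w base codes), bgw (background log-prob of each window),
## offs/seqidx (window origin), noff (eligible windows per sequence)
.prepWindows <- function(caches, masks, w) {
    nseq <- length(caches)
    offs_l <- lapply(seq_len(nseq), function(s)
        .eligibleOffsets(caches[[s]]$codes, masks[[s]], w))
    noff <- lengths(offs_l)
    N <- sum(noff)
    if (!N)
        return(list(D = matrix(integer(), 0L, w), bgw = numeric(),
                    offs = integer(), seqidx = integer(), noff = noff,
                    N = 0L, nSeqs = nseq, rowsBySeq = list()))
    D <- do.call(rbind, lapply(seq_len(nseq), function(s) {
        offs <- offs_l[[s]]
        if (!length(offs)) return(NULL)
        matrix(caches[[s]]$codes[outer(offs - 1L, seq_len(w), "+")],
               length(offs), w)
    }))
    bgw <- unlist(lapply(seq_len(nseq), function(s) {
        offs <- offs_l[[s]]
        if (!length(offs)) return(numeric())
        caches[[s]]$cum[offs + w] - caches[[s]]$cum[offs]
    }), use.names = FALSE)
    seqidx <- rep.int(seq_len(nseq), noff)
    # Didx indexes the transposed w x 4 log-PPM laid out as a vector;
    # Bmat holds per-base indicator matrices for the M-step crossprods
    Didx <- D + matrix(rep((seq_len(w) - 1L) * 4L, each = N), N, w)
    Bmat <- lapply(1:4, function(b) (D == b) * 1)
    list(D = D, Didx = Didx, Bmat = Bmat, bgw = bgw,
         offs = unlist(offs_l, use.names = FALSE),
         seqidx = seqidx, noff = noff, N = N, nSeqs = nseq,
         rowsBySeq = split(seq_len(N), seqidx))
}

## one E-pass over the pooled windows; returns the relative
## log-likelihood (vs background-only) and optionally the posteriors
.zoopsEpass <- function(ww, ltheta, lambda, bothStrands,
                        wantPost = FALSE) {
    w <- ncol(ww$D)
    if (!ww$N)
        return(list(obj = 0, zp = numeric(), zm = numeric(),
                    Z = numeric(ww$nSeqs)))
    ltv <- as.vector(t(ltheta))
    sp <- rowSums(matrix(ltv[ww$Didx], ww$N, w))
    mp <- exp(pmin(sp - ww$bgw, 700))
    if (bothStrands) {
        lrc <- ltheta[rev(seq_len(w)), c(4L, 3L, 2L, 1L), drop = FALSE]
        sm <- rowSums(matrix(as.vector(t(lrc))[ww$Didx], ww$N, w))
        mm <- exp(pmin(sm - ww$bgw, 700))
    } else mm <- NULL
    S <- rowsum(if (bothStrands) mp + mm else mp, ww$seqidx,
                reorder = TRUE)[, 1L]
    present <- sort(unique(ww$seqidx))
    nOff <- ww$noff[present] * (1L + bothStrands)
    denom_p <- (1 - lambda) + lambda * S / nOff
    obj <- sum(log(denom_p))
    if (!wantPost)
        return(list(obj = obj))
    denom <- rep(1, ww$nSeqs); denom[present] <- denom_p
    nOffv <- rep(1, ww$nSeqs); nOffv[present] <- nOff
    fac <- (lambda / nOffv[ww$seqidx]) / denom[ww$seqidx]
    Z <- numeric(ww$nSeqs)
    Z[present] <- lambda * (S / nOff) / denom_p
    list(obj = obj, zp = mp * fac,
         zm = if (bothStrands) mm * fac else NULL, Z = Z)
}

## M-step: Dirichlet-smoothed column counts and lambda re-estimate; a
## reverse-strand site puts the complement of the base at forward window
## position i into motif column w + 1 - i
.zoopsMstep <- function(ww, ep, w, bothStrands, pseudo) {
    Cp <- vapply(1:4, function(b)
        as.numeric(crossprod(ww$Bmat[[b]], ep$zp)), numeric(w))
    counts <- matrix(pseudo, w, 4L) + Cp
    if (bothStrands) {
        Cm <- vapply(1:4, function(b)
            as.numeric(crossprod(ww$Bmat[[b]], ep$zm)), numeric(w))
        counts <- counts + Cm[rev(seq_len(w)), 4:1, drop = FALSE]
    }
    list(theta = counts / rowSums(counts),
         lambda = min(max(sum(ep$Z) / ww$nSeqs, 1e-8), 1 - 1e-8))
}

## fast starting-point search: every distinct window word is scored by an
## estimate of its converged ZOOPS objective — assume the motif sharpens
## to pSharp per column and occurs exactly where the word matches, so
## lambda-hat = (#sequences containing the word)/nSeqs and
##   score = sum_{matching s} log[(1-l) + l * exp(w log pSharp - bgw)/nOff]
##           + (nSeqs - m) log(1 - l).
## Exact enumeration of all substrings replaces stochastic subsampling.
.topSeedWords <- function(ww, w, bothStrands, nTop, pSharp = 0.9) {
    if (!ww$N) return(numeric())
    wc <- matrix(as.numeric(ww$D - 1L), ww$N, w)
    wc <- drop(wc %*% 4^(seq_len(w) - 1L))
    e <- exp(pmin(w * log(pSharp) - ww$bgw, 700))
    r <- e / (ww$noff[ww$seqidx] * (1L + bothStrands))
    key <- wc * ww$nSeqs + (ww$seqidx - 1L)
    ord <- order(key, -r, method = "radix")
    first <- !duplicated(key[ord])
    rr <- r[ord][first]                      # best window per (word, seq)
    word <- floor(key[ord][first] / ww$nSeqs)
    m <- rowsum(rep(1, length(rr)), word, reorder = TRUE)
    words <- as.numeric(rownames(m))
    m <- m[, 1L]
    lam <- pmin(m / ww$nSeqs, 1 - 1 / (2 * ww$nSeqs))
    lamv <- lam[match(word, words)]
    contrib <- log((1 - lamv) + lamv * rr)
    sc <- rowsum(contrib, word, reorder = TRUE)[, 1L] +
        (ww$nSeqs - m) * log(1 - lam)
    top <- order(-sc, words)[seq_len(min(nTop, length(words)))]
    words[top]
}

.decodeWord <- function(wc, w) {
    codes <- integer(w)
    for (i in seq_len(w)) {
        codes[i] <- wc %% 4 + 1
        wc <- wc %/% 4
    }
    codes
}

## plain EM loop from a starting theta
.zoopsEMcore <- function(ww, theta0, lambda0, w, bothStrands, maxIter,
                         tol, pseudo) {
    theta <- theta0
    lambda <- lambda0
    trace <- numeric()
    prev <- -Inf
    for (it in seq_len(maxIter)) {
        lt <- log(theta)
        ep <- .zoopsEpass(ww, lt, lambda, bothStrands, wantPost = TRUE)
        pen <- ep$obj + pseudo * sum(lt)
        trace <- c(trace, pen)
        if (is.finite(prev) && abs(pen - prev) < tol) break
        prev <- pen
        ms <- .zoopsMstep(ww, ep, w, bothStrands, pseudo)
        theta <- ms$theta
        lambda <- ms$lambda
    }
    llr <- .zoopsEpass(ww, log(theta), lambda, bothStrands)$obj
    list(theta = theta, lambda = lambda, llr = llr, trace = trace)
}

## EM with phase-shift moves: after convergence the motif is tried one
## column to the left and right (vacated column set to uniform) and
## re-optimized; a shift is kept while it improves the objective. This
## counters the well-known phase indeterminacy of window-based EM.
.zoopsEM <- function(ww, theta0, lambda0, w, bothStrands, maxIter, tol,
                     pseudo, shiftMoves = TRUE) {
    fit <- .zoopsEMcore(ww, theta0, lambda0, w, bothStrands, maxIter,
                        tol, pseudo)
    nshift <- 0L
    while (shiftMoves) {
        improved <- FALSE
        for (d in c(-1L, 1L)) {
            th <- if (d == 1L)
                rbind(fit$theta[-1L, , drop = FALSE], rep(0.25, 4L))
            else rbind(rep(0.25, 4L), fit$theta[-w, , drop = FALSE])
            cand <- .zoopsEMcore(ww, th, fit$lambda, w, bothStrands,
                                 maxIter, tol, pseudo)
            if (cand$llr > fit$llr + tol) {
                fit <- cand
                nshift <- nshift + 1L
                improved <- TRUE
            }
        }
        if (!improved || nshift >= 2L * w) break
    }
    fit$nShifts <- nshift
    fit
}

## posterior site assignment: one site per sequence when the total
## occurrence posterior exceeds the threshold
.zoopsSites <- function(ww, seq_names, seqs, theta, lambda, w,
                        bothStrands, threshold = 0.5) {
    ep <- .zoopsEpass(ww, log(theta), lambda, bothStrands,
                      wantPost = TRUE)
    rows <- list()
    for (s in seq_len(ww$nSeqs)) {
        if (ep$Z[s] <= threshold) next
        rr <- ww$rowsBySeq[[as.character(s)]]
        if (is.null(rr)) next
        zz <- c(ep$zp[rr], if (bothStrands) ep$zm[rr])
        j <- which.max(zz)
        strand <- "+"
        ri <- j
        if (j > length(rr)) { strand <- "-"; ri <- j - length(rr) }
        start1 <- ww$offs[rr[ri]]
        site <- substr(seqs[s], start1, start1 + w - 1L)
        if (strand == "-") site <- .revcompChar(site)
        rows[[length(rows) + 1L]] <- data.frame(
            gene_id = seq_names[s], offset = start1 - 1L, strand = strand,
            sequence = site, posterior = ep$Z[s],
            stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(gene_id = character(), offset = integer(),
                          strand = character(), sequence = character(),
                          posterior = numeric(), stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

## ---- exported operations --------------------------------------------------

#' ZOOPS log-likelihood of a motif over a promoter set
#'
#' Sum over sequences of
#' log[(1 - lambda) P(seq | bg) + lambda mean_offsets P(seq, site | theta, bg)],
#' with the mean running over all eligible (offset, strand) windows.
#' Sequences shorter than the motif width contribute the background-only
#' term.
#'
#' @param ppm w x 4 position probability matrix (columns A, C, G, T).
#' @param x a \linkS4class{PromoterSet} or character vector of sequences.
#' @param background a \linkS4class{MarkovBackground}.
#' @param lambda per-sequence occurrence prior in (0, 1).
#' @param bothStrands consider reverse-strand windows (default TRUE).
#' @return total log-likelihood (natural log).
#' @export
zoopsLogLikelihood <- function(ppm, x, background, lambda,
                               bothStrands = TRUE) {
    stopifnot(lambda > 0, lambda < 1, ncol(ppm) == 4L)
    seqs <- if (is(x, "PromoterSet"))
        as.character(promoterSequences(x)) else as.character(x)
    masks <- if (is(x, "PromoterSet")) promoterMask(x) else
        lapply(nchar(seqs), function(n) rep(FALSE, n))
    caches <- .seqCache(seqs, background)
    ww <- .prepWindows(caches, masks, nrow(ppm))
    rel <- .zoopsEpass(ww, log(ppm), lambda, bothStrands)$obj
    rel + sum(vapply(caches, function(ca) sum(ca$bglp), numeric(1L)))
}

#' Discover motifs with ZOOPS expectation-maximization
#'
#' For each motif slot and each width in \code{wMin:wMax}, every distinct
#' promoter substring of that width is a candidate starting point: words
#' are ranked by a fast approximate ZOOPS gain (summed over the sequences
#' containing them), the top \code{nRefine} are converted to a starting
#' PPM by giving probability \code{p0} to the observed base and run to EM
#' convergence with phase-shift refinement, and the motif maximizing the
#' log-likelihood-ratio objective over all widths is kept. Its site
#' positions are then erased (masked) before the next motif is sought.
#' Masked promoter positions never host sites and are skipped as seed
#' sources. The search is fully deterministic; \code{seed} is recorded
#' for provenance.
#'
#' @param promoters a \linkS4class{PromoterSet} (at least 2 promoters).
#' @param background a \linkS4class{MarkovBackground}.
#' @param nMotifs maximum number of motifs (study value 10).
#' @param wMin,wMax motif width range (study values 6 and 12).
#' @param maxIter,tol EM iteration cap and convergence tolerance on the
#'   objective (defaults 200 and 1e-6).
#' @param seed recorded in the motif metadata (the search itself is
#'   deterministic).
#' @param nRefine starting words run to full EM convergence per width.
#' @param p0 seed base probability (default 0.7).
#' @param pseudo Dirichlet pseudocount per base in the M-step.
#' @param bothStrands consider reverse-strand sites (default TRUE).
#' @param siteThreshold posterior occurrence probability above which a
#'   sequence is assigned its best site (default 0.5).
#' @return list of \linkS4class{PWMotif}, ordered by decreasing
#'   log-likelihood-ratio objective; fewer than \code{nMotifs} when no
#'   further motif improves on the background.
#' @export
discoverMotifs <- function(promoters, background, nMotifs = 10L,
                           wMin = 6L, wMax = 12L, maxIter = 200L,
                           tol = 1e-6, seed = 1L, nRefine = 5L,
                           p0 = 0.7, pseudo = 0.01, bothStrands = TRUE,
                           siteThreshold = 0.5) {
    stopifnot(is(promoters, "PromoterSet"), wMin <= wMax, nMotifs >= 1L)
    seqs <- as.character(promoterSequences(promoters))
    if (length(seqs) < 2L) stop("need at least 2 promoters")
    seq_names <- names(seqs)
    erased <- promoterMask(promoters)
    caches <- .seqCache(seqs, background)
    lambda0 <- 1 / sqrt(length(seqs))
    motifs <- list()
    for (mi in seq_len(nMotifs)) {
        best <- NULL
        for (w in seq.int(wMin, wMax)) {
            ww <- .prepWindows(caches, erased, w)
            if (ww$N < 2L) next
            words <- .topSeedWords(ww, w, bothStrands, nRefine)
            for (wc in words) {
                obs <- .decodeWord(wc, w)
                th <- matrix((1 - p0) / 3, w, 4L)
                th[cbind(seq_len(w), obs)] <- p0
                fit <- .zoopsEMcore(ww, th, lambda0, w, bothStrands,
                                    maxIter, tol, pseudo)
                if (is.null(best) || fit$llr > best$llr) {
                    best <- fit
                    best$w <- w
                    best$ww <- ww
                    best$seedWord <- wc
                }
            }
        }
        if (!is.null(best)) {        # phase-shift refinement of the winner
            ref <- .zoopsEM(best$ww, best$theta, best$lambda, best$w,
                            bothStrands, maxIter, tol, pseudo)
            ref$w <- best$w; ref$ww <- best$ww
            ref$seedWord <- best$seedWord
            best <- ref
        }
        if (is.null(best) || best$llr <= 0) {
            message("discoverMotifs: no further motif improves on the ",
                    "background; returning ", length(motifs), " motif(s)")
            break
        }
        sites <- .zoopsSites(best$ww, seq_names, seqs, best$theta,
                             best$lambda, best$w, bothStrands,
                             siteThreshold)
        if (!nrow(sites)) {
            message("discoverMotifs: best candidate has no confident ",
                    "sites; returning ", length(motifs), " motif(s)")
            break
        }
        colnames(best$theta) <- .BASES
        motifs[[length(motifs) + 1L]] <- new("PWMotif",
            name = paste0("motif_", length(motifs) + 1L),
            ppm = best$theta,
            sites = sites,
            llr = best$llr,
            trace = best$trace,
            meta = list(width = best$w, lambda = best$lambda,
                        seed = seed, seedWord = best$seedWord,
                        nShifts = best$nShifts,
                        nSitesGenes = length(unique(sites$gene_id))))
        for (ri in seq_len(nrow(sites))) {      # erase found sites
            s <- match(sites$gene_id[ri], seq_names)
            span <- seq.int(sites$offset[ri] + 1L,
                            sites$offset[ri] + best$w)
            erased[[s]][span] <- TRUE
        }
    }
    if (length(motifs) > 1L) {
        ord <- order(-vapply(motifs, function(m) m@llr, numeric(1L)))
        motifs <- motifs[ord]
        for (i in seq_along(motifs))
            motifs[[i]]@name <- paste0("motif_", i)
    }
    motifs
}

#' @describeIn accessors position probability matrix of a PWMotif
#' @export
setMethod("motifPPM", "PWMotif", function(object) object@ppm)

#' @describeIn accessors ZOOPS site list of a PWMotif
#' @export
setMethod("motifSites", "PWMotif", function(object) object@sites)

#' @describeIn accessors motif width
#' @export
setMethod("motifWidth", "PWMotif", function(object) nrow(object@ppm))

#' @describeIn accessors motif identifier
#' @export
setMethod("motifName", "PWMotif", function(object) object@name)

#' @describeIn accessors log-likelihood-ratio objective of the motif
#' @export
setMethod("motifLLR", "PWMotif", function(object) object@llr)

#' @describeIn accessors per-iteration EM objective trace
#' @export
setMethod("emTrace", "PWMotif", function(object) object@trace)

setMethod("show", "PWMotif", function(object) {
    cat("PWMotif", object@name, ": width", nrow(object@ppm),
        ", consensus", motifConsensus(object),
        ", sites in", length(unique(object@sites$gene_id)),
        "gene(s), LLR", format(object@llr, digits = 4L), "\n")
})
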