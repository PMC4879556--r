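## Order-k Markov background model of promoter sequence: training on both
## strands, per-position conditional log-probabilities, and sampling.

.BASES <- c("A", "C", "G", "T")

.dnaCodes <- function(seq) {
    match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]], .BASES)
}

## left-to-right lexicographic context index of the j bases preceding each
## position; codes is the integer-coded sequence, positions (j+1):L
.ctxIndex <- function(codes, j) {
    L <- length(codes)
    if (j == 0L) return(rep(1L, L))
    idx <- rep(1, L)
    for (t in seq_len(j))               # base i-t carries weight 4^(t-1)
        idx <- idx + c(rep(NA_real_, t), (codes[seq_len(L - t)] - 1)) * 4^(t - 1)
    as.integer(idx)
}

#' Train an order-k Markov background model
#'
#' Counts (j-mer context -> next base) transitions for all orders
#' j = 0..k over the sequences, and over their reverse complements when
#' \code{bothStrands = TRUE}, adding the pseudocount \code{alpha} to every
#' count. Contexts never observed get a uniform conditional. Masked
#' (lowercase-derived) positions take part in background counting; only
#' motif sites avoid them.
#'
#' @param x a \linkS4class{PromoterSet} or character vector of sequences.
#' @param k Markov order (study value 3).
#' @param alpha pseudocount per transition count (default 0.01; 0 gives
#'   pure maximum-likelihood frequencies).
#' @param bothStrands count on both strands (study setting TRUE).
#' @return A \linkS4class{MarkovBackground}.
#' @export
trainMarkovBackground <- function(x, k = 3L, alpha = 0.01,
                                  bothStrands = TRUE) {
    seqs <- if (is(x, "PromoterSet"))
        as.character(promoterSequences(x)) else as.character(x)
    if (!length(seqs) || !sum(nchar(seqs))) stop("empty input sequences")
    k <- as.integer(k)
    stopifnot(k >= 0L, alpha >= 0)
    total <- sum(nchar(seqs))
    while (k > 0L && total <= 4^k) {
        warning("total sequence length <= 4^k; falling back to order ",
                k - 1L)
        k <- k - 1L
    }
    if (bothStrands) seqs <- c(seqs, .revcompChar(seqs))
    codes_list <- lapply(seqs, .dnaCodes)
    logp <- vector("list", k + 1L)
    for (j in 0:k) {
        counts <- matrix(alpha, nrow = 4^j, ncol = 4L,
                         dimnames = list(NULL, .BASES))
        for (codes in codes_list) {
            L <- length(codes)
            if (L <= j) next
            ctx <- .ctxIndex(codes, j)
            pos <- seq.int(j + 1L, L)
            ok <- !is.na(codes[pos]) & !is.na(ctx[pos])
            if (!any(ok)) next
            tb <- table(factor(ctx[pos][ok], levels = seq_len(4^j)),
                        factor(codes[pos][ok], levels = 1:4))
            counts <- counts + as.matrix(tb)
        }
        tot <- rowSums(counts)
        pm <- counts / tot
        pm[tot == 0, ] <- 0.25   # unseen context -> uniform
        logp[[j + 1L]] <- log(pm)
    }
    new("MarkovBackground", order = k, logp = logp, alpha = alpha,
        bothStrands = isTRUE(bothStrands))
}

#' @describeIn accessors Markov order of a background model
#' @export
setMethod("backgroundOrder", "MarkovBackground",
    function(object) object@order)

setMethod("show", "MarkovBackground", function(object) {
    cat("MarkovBackground: order", object@order,
        "(alpha =", object@alpha,
        if (object@bothStrands) ", both strands)" else ")", "\n")
})

#' Background letter frequencies (order-0 marginal)
#'
#' @param bg a \linkS4class{MarkovBackground}.
#' @return named numeric vector over A, C, G, T.
#' @export
backgroundLetterFreqs <- function(bg) {
    stopifnot(is(bg, "MarkovBackground"))
    stats::setNames(as.numeric(exp(bg@logp[[1L]][1L, ])), .BASES)
}

## per-position conditional log-probabilities of an integer-coded
## sequence under the background; positions whose base or full context is
## not ACGT fall back to the order-0 conditional (or 0 when the base
## itself is unknown)
.bgCondLogProb <- function(bg, codes) {
    k <- bg@order
    L <- length(codes)
    out <- numeric(L)
    if (!L) return(out)
    ord_of <- pmin(seq_len(L) - 1L, k)
    for (j in unique(ord_of)) {
        pos <- which(ord_of == j)
        ctx <- .ctxIndex(codes, j)[pos]
        b <- codes[pos]
        val <- numeric(length(pos))
        known <- !is.na(b)
        ctx_ok <- known & !is.na(ctx)
        val[ctx_ok] <- bg@logp[[j + 1L]][cbind(ctx[ctx_ok], b[ctx_ok])]
        fb <- known & is.na(ctx)
        if (any(fb)) val[fb] <- bg@logp[[1L]][cbind(1L, b[fb])]
        out[pos] <- val
    }
    out
}

#' Log-probability of a sequence under the background model
#'
#' The first k positions are scored with the matching lower-order chain.
#'
#' @param bg a \linkS4class{MarkovBackground}.
#' @param seq a single character sequence.
#' @return total log-probability (natural log).
#' @export
backgroundLogProb <- function(bg, seq) {
    stopifnot(is(bg, "MarkovBackground"), length(seq) == 1L)
    sum(.bgCondLogProb(bg, .dnaCodes(seq)))
}

#' Sample sequences from a Markov background model
#'
#' Uses the current RNG state; seed management is the caller's job.
#'
#' @param bg a \linkS4class{MarkovBackground}.
#' @param n number of sequences.
#' @param length length of each sequence.
#' @return character vector of sequences.
#' @export
sampleBackgroundSequences <- function(bg, n, length) {
    stopifnot(is(bg, "MarkovBackground"))
    k <- bg@order
    vapply(seq_len(n), function(i) {
        codes <- integer(length)
        for (pos in seq_len(length)) {
            j <- min(pos - 1L, k)
            ctx <- if (j == 0L) 1L else
                1L + sum((codes[pos - seq_len(j)] - 1L) * 4^(seq_len(j) - 1L))
            p <- exp(bg@logp[[j + 1L]][ctx, ])
            codes[pos] <- sample.int(4L, 1L, prob = p)
        }
        paste(.BASES[codes], collapse = "")
    }, character(1L))
}
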