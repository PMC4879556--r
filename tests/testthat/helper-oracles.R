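# Independent reference implementations used to cross-check the package:
# deliberately naive, window-by-window / enumeration style.

.IUPAC_SETS <- strsplit(Biostrings::IUPAC_CODE_MAP, "", fixed = TRUE)

revcomp_chr <- function(s) {
    paste(rev(strsplit(chartr("ACGTRYKMBVDHacgtrykmbvdh",
                              "TGCAYRMKVBHDtgcayrmkvbhd", s), "",
                       fixed = TRUE)[[1]]), collapse = "")
}

hamming <- function(a, b) {
    stopifnot(nchar(a) == nchar(b))
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# hamming distance to a target consensus, allowing reverse complement
consensus_distance <- function(found, truth) {
    min(hamming(found, truth), hamming(revcomp_chr(found), truth))
}

# window-by-window degenerate scan; returns data.frame(start0, strand)
oracle_scan <- function(seq, pattern, bothStrands = TRUE,
                        noOverlap = TRUE, mask = NULL) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    if (is.null(mask)) mask <- rep(FALSE, length(chars))
    scan1 <- function(pat_sets) {
        w <- length(pat_sets)
        L <- length(chars)
        hits <- integer()
        j <- 1L
        while (j <= L - w + 1L) {
            win <- j:(j + w - 1L)
            ok <- !any(mask[win]) &&
                all(vapply(seq_len(w), function(i)
                    chars[win[i]] %in% pat_sets[[i]], logical(1)))
            if (ok) {
                hits <- c(hits, j)
                if (noOverlap) { j <- j + w; next }
            }
            j <- j + 1L
        }
        hits
    }
    pat_f <- .IUPAC_SETS[strsplit(pattern, "", fixed = TRUE)[[1]]]
    hf <- scan1(pat_f)
    out <- data.frame(start0 = hf - 1L,
                      strand = rep("+", length(hf)))
    if (bothStrands) {
        rc <- strsplit(revcomp_chr(pattern), "", fixed = TRUE)[[1]]
        hr <- scan1(.IUPAC_SETS[rc])
        out <- rbind(out, data.frame(start0 = hr - 1L,
                                     strand = rep("-", length(hr))))
    }
    out[order(out$start0, out$strand), , drop = FALSE]
}

# brute-force thresholded edge list over a genes x arrays matrix
oracle_edges <- function(vals, r0) {
    ids <- rownames(vals)
    out <- list()
    for (i in seq_len(nrow(vals) - 1L)) {
        for (j in seq.int(i + 1L, nrow(vals))) {
            if (sd(vals[i, ]) == 0 || sd(vals[j, ]) == 0) next
            r <- cor(vals[i, ], vals[j, ])
            if (r >= r0) {
                ab <- sort(c(ids[i], ids[j]))
                out[[length(out) + 1L]] <- data.frame(
                    gene_a = ab[1], gene_b = ab[2], r = r)
            }
        }
    }
    if (!length(out))
        return(data.frame(gene_a = character(), gene_b = character(),
                          r = numeric()))
    df <- do.call(rbind, out)
    df[order(df$gene_a, df$gene_b), , drop = FALSE]
}

# iterative depth-first-search connected components
oracle_components <- function(nodes, edges) {
    adj <- setNames(vector("list", length(nodes)), nodes)
    for (i in seq_len(nrow(edges))) {
        a <- edges$gene_a[i]; b <- edges$gene_b[i]
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
    }
    seen <- setNames(rep(FALSE, length(nodes)), nodes)
    comps <- list()
    for (v in nodes) {
        if (seen[v]) next
        stack <- v
        comp <- character()
        while (length(stack)) {
            u <- stack[length(stack)]
            stack <- stack[-length(stack)]
            if (seen[u]) next
            seen[u] <- TRUE
            comp <- c(comp, u)
            stack <- c(stack, adj[[u]][!seen[adj[[u]]]])
        }
        comps[[length(comps) + 1L]] <- sort(comp)
    }
    comps[order(-lengths(comps),
                vapply(comps, `[`, character(1), 1))]
}

# exact right-tail hypergeometric by enumeration of the mass function
oracle_hyper_right <- function(k, K, n, N) {
    if (k == 0) return(1)
    x <- k:min(n, K)
    sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# literal Holm step-down: sort, scale, cumulative max, cap, unsort
oracle_holm <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- pmin((m - seq_len(m) + 1) * p[o], 1)
    adj <- cummax(adj)
    out <- numeric(m)
    out[o] <- adj
    out
}

# comparison of predicted clustering against planted modules over all
# genes: remainder/background form their own class
module_ari <- function(clusters, truth_assignment) {
    genes <- names(truth_assignment)
    pred <- setNames(rep("remainder", length(genes)), genes)
    for (cn in names(clusterMembers(clusters)))
        pred[clusterMembers(clusters)[[cn]]] <- cn
    mclust::adjustedRandIndex(pred[genes], truth_assignment[genes])
}
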