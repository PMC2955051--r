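# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# textbook dynamic-programming Levenshtein distance
dpEdit <- function(x, y) {
    a <- strsplit(x, "")[[1L]]; b <- strsplit(y, "")[[1L]]
    n <- length(a); m <- length(b)
    d <- matrix(0L, n + 1L, m + 1L)
    d[, 1L] <- 0:n; d[1L, ] <- 0:m
    for (i in seq_len(n)) for (j in seq_len(m))
        d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                                 d[i, j] + (a[i] != b[j]))
    d[n + 1L, m + 1L]
}

# from-scratch Ward clustering: clusters carry explicit members; the
# dissimilarity between clusters is recomputed from centroids and weights
# at every step, Delta = (w1*w2/(w1+w2)) * ||g1-g2||^2, leaf weight 1/n.
# Tie-break mirrors the documented contract (lowest sorted pair of
# smallest member indices).
wardOracle <- function(mat) {
    n <- nrow(mat)
    cl <- lapply(seq_len(n), function(i) i)   # members
    code <- -seq_len(n)
    merges <- matrix(0L, 0L, 2L); heights <- numeric()
    delta <- function(m1, m2) {
        g1 <- colMeans(mat[m1, , drop = FALSE])
        g2 <- colMeans(mat[m2, , drop = FALSE])
        w1 <- length(m1) / n; w2 <- length(m2) / n
        (w1 * w2 / (w1 + w2)) * sum((g1 - g2)^2)
    }
    while (length(cl) > 1L) {
        best <- NULL
        for (i in seq_along(cl)) for (j in seq_along(cl)) {
            if (j <= i) next
            d <- delta(cl[[i]], cl[[j]])
            key <- c(d, sort(c(min(cl[[i]]), min(cl[[j]]))))
            if (is.null(best) || key[1L] < best$key[1L] - 1e-15 ||
                (abs(key[1L] - best$key[1L]) <= 1e-15 &&
                 (key[2L] < best$key[2L] ||
                  (key[2L] == best$key[2L] && key[3L] < best$key[3L]))))
                best <- list(i = i, j = j, key = key)
        }
        i <- best$i; j <- best$j
        merges <- rbind(merges, c(code[i], code[j]))
        heights <- c(heights, best$key[1L])
        cl[[i]] <- c(cl[[i]], cl[[j]])
        code[i] <- nrow(merges)
        cl <- cl[-j]; code <- code[-j]
    }
    list(merge = merges, height = heights)
}

# exact maximum support clique by exhaustive subset search (<= 12 vertices)
exactCliqueExists <- function(adj, seqs, minSeq) {
    nv <- nrow(adj)
    stopifnot(nv <= 12L)
    for (mask in seq_len(2^nv - 1L)) {
        v <- which(bitwAnd(mask, 2^(seq_len(nv) - 1L)) > 0L)
        if (length(unique(seqs[v])) < minSeq) next
        ok <- TRUE
        if (length(v) > 1L)
            for (a in seq_along(v)) for (b in seq_along(v))
                if (a < b && !adj[v[a], v[b]]) { ok <- FALSE }
        if (ok) return(TRUE)
    }
    FALSE
}

# small random family for property tests
randomFamily <- function(n, lenRange = c(30L, 90L)) {
    seqs <- vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"),
                     sample(lenRange[1L]:lenRange[2L], 1L),
                     replace = TRUE), collapse = ""), "")
    names(seqs) <- paste0("s", seq_len(n))
    seqs
}

# sorted occurrence frame for MR-list comparisons, row names dropped
occKey <- function(mrl) {
    t <- occurrenceTable(mrl)
    t <- t[order(t$word, t$seq, t$start, t$strand), ]
    rownames(t) <- NULL
    t
}
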