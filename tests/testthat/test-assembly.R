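test_that("edit distance matches the dynamic-programming oracle", {
    expect_equal(editDistance("", "ACG"), 3L)
    expect_equal(editDistance("ACGT", "ACGT"), 0L)
    expect_equal(editDistance("GATT", "GTAT"), 2L)
    set.seed(23)
    for (i in 1:25) {
        x <- paste(sample(c("A", "C", "G", "T"), sample(0:12, 1), TRUE),
                   collapse = "")
        y <- paste(sample(c("A", "C", "G", "T"), sample(0:12, 1), TRUE),
                   collapse = "")
        expect_equal(editDistance(x, y), dpEdit(x, y))
        expect_equal(editDistance(x, y), editDistance(y, x))  # symmetry
    }
})

# constructed association geometries: a 10-nt seed A and 5-nt next B on
# two sequences, with controllable spacers
fig2Family <- function(x1, x2, A = "GATTACAGGT", B = "CCGTG") {
    c(s1 = paste0("TTTT", A, x1, B, "AAAA"),
      s2 = paste0("GGGG", A, x2, B, "TTTT"))
}
fig2Pairs <- function(x1, x2, maxratio = 100) {
    fam <- fig2Family(x1, x2)
    seed <- data.frame(seq = 1:2, start = 4L, end = 14L)
    nxt <- data.frame(seq = 1:2,
                      start = c(14L + nchar(x1), 14L + nchar(x2)))
    nxt$end <- nxt$start + 5L
    collectPairs(seed, nxt, fam, maxratio)
}

test_that("spacer association cases behave as the association rules say", {
    # short spacer, below the smaller MR: candidate retained
    p <- fig2Pairs("AC", "AC")
    expect_equal(nrow(p), 2L)
    expect_true(all(p$orientation == "+"))
    expect_identical(p$spacer, c("AC", "AC"))

    # adjacent MRs: the empty spacer is a valid association
    p0 <- fig2Pairs("", "")
    expect_equal(nrow(p0), 2L)
    expect_identical(p0$spacer, c("", ""))

    # spacer longer than |A| * maxratio/100 is excluded
    long <- paste(rep("A", 12), collapse = "")
    expect_equal(nrow(fig2Pairs(long, long)), 0L)
    expect_equal(nrow(fig2Pairs("ACGTA", "ACGTA", maxratio = 40)), 0L)

    # identical spacers always connect in the compatibility graph
    g <- buildCompatibilityGraph(fig2Pairs("ACG", "ACG"))
    expect_true(g$adj[1L, 2L])

    # edit distance 2 between equal-length spacers, within both MR sizes
    g2 <- buildCompatibilityGraph(fig2Pairs("AAAA", "AAGG"))
    expect_equal(dpEdit("AAAA", "AAGG"), 2L)
    expect_true(g2$adj[1L, 2L])

    # edit distance 4, above the smaller MR size (5): rejected... use a
    # 3-nt flank to match: rebuild with smaller B
    fam <- fig2Family("ACAC", "GTGT", B = "CCG")
    seed <- data.frame(seq = 1:2, start = 4L, end = 14L)
    nxt <- data.frame(seq = 1:2, start = 18L, end = 21L)
    p3 <- collectPairs(seed, nxt, fam, 100)
    expect_equal(p3$b, c(3L, 3L))
    expect_equal(dpEdit("ACAC", "GTGT"), 4L)
    g3 <- buildCompatibilityGraph(p3)
    expect_false(g3$adj[1L, 2L])
})

test_that("clique search finds obvious cliques and honours its contract", {
    # complete graph over k distinct sequences
    p <- fig2Pairs("ACG", "ACG")
    g <- buildCompatibilityGraph(p)
    cl <- findSupportClique(g, 2)
    expect_equal(sort(p$seq[cl]), 1:2)

    # edgeless graph at minSequences 2: nothing
    fam <- fig2Family("ACAC", "GTGT", B = "CCG")
    seed <- data.frame(seq = 1:2, start = 4L, end = 14L)
    nxt <- data.frame(seq = 1:2, start = 18L, end = 21L)
    g0 <- buildCompatibilityGraph(collectPairs(seed, nxt, fam, 100))
    expect_null(findSupportClique(g0, 2))

    # heuristic vs exhaustive clique on random small graphs: the greedy
    # search may miss, but must never fabricate a clique
    set.seed(31)
    for (i in 1:20) {
        nv <- sample(4:9, 1)
        pairs <- data.frame(
            seedRow = seq_len(nv), nextRow = seq_len(nv),
            seq = sample(1:4, nv, TRUE), orientation = "+",
            spacer = "", b = 1L,
            start = seq_len(nv) * 100L, end = seq_len(nv) * 100L + 10L)
        adj <- matrix(runif(nv * nv) < 0.5, nv, nv)
        adj <- adj & t(adj); diag(adj) <- FALSE
        g <- list(pairs = pairs, adj = adj)
        cl <- findSupportClique(g, 2)
        if (!is.null(cl)) {
            for (a in cl) for (b in cl)
                if (a != b) expect_true(adj[a, b])
            expect_gte(length(unique(pairs$seq[cl])), 2L)
            # a found clique implies the exact search finds one too
            expect_true(exactCliqueExists(adj, pairs$seq, 2))
        }
    }
})

# planted three-copy family: A-block, constrained spacer, B-block
pairFixture <- function(spacers, flanks = NULL) {
    A <- "GGATCGTACCTGAGGTCGAT"   # 20 nt
    B <- "CATTGCGAGTCA"          # 12 nt
    set.seed(47)
    if (is.null(flanks))
        flanks <- replicate(2 * length(spacers),
            paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""))
    seqs <- vapply(seq_along(spacers), function(i)
        paste0(flanks[2 * i - 1], A, spacers[i], B, flanks[2 * i]), "")
    names(seqs) <- paste0("s", seq_along(spacers))
    seqs
}

test_that("buildPair picks the qualifying repeat in list order", {
    # spacers differ at both ends so they are not absorbed into the MRs
    fam <- pairFixture(c("ACGTA", "CGTAT", "TTACG"))
    L <- enumerateMaximalRepeats(fam, 3)
    tab <- moduleTable(L)
    iA <- which(tab$word == "GGATCGTACCTGAGGTCGAT")
    occ <- occurrenceTable(L)
    seed <- occ[occ$word == tab$word[iA], c("seq", "start", "end")]
    seed$start <- seed$start - 1L
    res <- buildPair(L, seed, iA + 1L, 3, 100, fam)
    expect_true(res$ok)
    expect_equal(tab$word[res$nextIndex], "CATTGCGAGTCA")
    expect_equal(sort(res$clique$seq), 1:3)
    # exhausting the list fails cleanly
    res2 <- buildPair(L, seed, length(L) + 1L, 3, 100, fam)
    expect_false(res2$ok)
})

test_that("modules assemble when spacers are compatible, not otherwise", {
    # compatible spacers (pairwise edit distance <= 5 <= |B| = 12), all
    # distinct so no two sequences share an identical block region:
    # one module spans both blocks in all 3 sequences
    fam <- pairFixture(c("ACGTA", "CGTAT", "TTACG"))
    cat1 <- detectModules(fam, minSizeModule = 25)
    occ <- compositionTable(cat1)
    main <- occ[occ$end - occ$start + 1 >= 35, ]
    expect_equal(nrow(main), 3L)
    expect_equal(length(unique(main$module_id)), 1L)

    # spacers pairwise further apart than the smaller block never merge:
    # e(x_i, x_j) > 12 for all pairs
    sp <- c(paste(rep("A", 16), collapse = ""),
            paste(rep("C", 16), collapse = ""),
            paste(rep("G", 16), collapse = ""))
    expect_true(all(utils::adist(sp, sp)[upper.tri(diag(3))] > 12))
    cat2 <- detectModules(pairFixture(sp), minSizeModule = 12)
    occ2 <- compositionTable(cat2)
    # no single occurrence may span both blocks (A starts at 31, B ends
    # at 78 in every sequence)
    expect_false(any(occ2$start <= 35 & occ2$end >= 70))
})

test_that("lowering maxratio never lengthens any emitted spacer", {
    arch <- plantedArchitecture(list(c(18, 12), 28), seed = 3)
    g <- generateFamily(arch, 6, seed = 3)
    prevMax <- Inf
    for (r in c(100, 75, 50, 25)) {
        cat <- detectModules(g$family, minSizeModule = 22, maxratio = r)
        spl <- unlist(lapply(cat@modules, function(m)
            unlist(lapply(m$spacers, nchar))))
        mx <- if (length(spl)) max(spl) else 0
        expect_lte(mx, prevMax)
        prevMax <- mx
        expect_true(isTRUE(verifyCatalog(cat, g$family)))
    }
})

test_that("emitted modules replay the length and distance conditions", {
    arch <- plantedArchitecture(list(c(20, 10), c(16, 14), 30), seed = 8)
    g <- generateFamily(arch, 8, seed = 8)
    cat <- detectModules(g$family, minSizeModule = 22, reverse = TRUE,
                         truncated = TRUE)
    expect_true(isTRUE(verifyCatalog(cat, g$family)))
})
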