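test_that("hand-checkable maximal repeats are found exactly", {
    # shorter repeats inside ACGTACGT are one-way extendable, so only the
    # full ACGT qualifies
    m <- enumerateMaximalRepeats(c(s = "ACGTACGT"))
    expect_equal(moduleTable(m)$word, "ACGT")
    expect_equal(occurrenceTable(m)$start, c(1L, 5L))

    # no shared word across these two sequences at support 2
    expect_equal(length(enumerateMaximalRepeats(c(a = "AAAA", b = "TTTT"),
                                                minSupport = 2)), 0L)

    # distinct sequence-end sentinels flank both copies, so the full word
    # is maximal
    m <- enumerateMaximalRepeats(c(a = "GATTACA", b = "GATTACA"),
                                 minSupport = 2)
    expect_true("GATTACA" %in% moduleTable(m)$word)
})

test_that("suffix-array enumeration equals the definitional oracle", {
    set.seed(101)
    for (t in 1:12) {
        seqs <- randomFamily(sample(1:4, 1), c(25L, 70L))
        for (ms in seq_along(seqs)) for (rv in c(FALSE, TRUE)) {
            a <- enumerateMaximalRepeats(seqs, ms, rv)
            b <- bruteForceMaximalRepeats(seqs, ms, rv)
            expect_identical(occKey(a), occKey(b))
        }
    }
    # adversarial: homopolymers, tandem structures, identical sequences,
    # perfect palindromes
    for (seqs in list(c(a = "AAAAAAA"), c(a = "ACACACAC", b = "ACACAC"),
                      c(a = "GGGG", b = "GGGG"), c(a = "ATATATAT"),
                      c(a = "ACGTNNACGT"))) {
        for (rv in c(FALSE, TRUE))
            expect_identical(occKey(enumerateMaximalRepeats(seqs, 1, rv)),
                             occKey(bruteForceMaximalRepeats(seqs, 1, rv)))
    }
})

test_that("every reported repeat is flanking-letter diverse and exact", {
    set.seed(5)
    seqs <- randomFamily(3, c(60L, 120L))
    m <- enumerateMaximalRepeats(seqs)
    occ <- occurrenceTable(m)
    for (w in moduleTable(m)$word) {
        o <- occ[occ$word == w & occ$strand == "+", ]
        expect_true(all(substr(seqs[o$seq], o$start, o$end) == w))
        left <- ifelse(o$start == 1L, paste0("<", o$seq, "L>"),
                       substr(seqs[o$seq], o$start - 1L, o$start - 1L))
        right <- ifelse(o$end == nchar(seqs[o$seq]),
                        paste0("<", o$seq, "R>"),
                        substr(seqs[o$seq], o$end + 1L, o$end + 1L))
        if (nrow(o) == sum(occ$word == w)) {   # all-direct repeats
            expect_gte(length(unique(left)), 2L)
            expect_gte(length(unique(right)), 2L)
        }
    }
})

test_that("reverse-complementing the family swaps strand labels", {
    set.seed(9)
    seqs <- randomFamily(3, c(40L, 80L))
    rcseqs <- revComp(seqs); names(rcseqs) <- names(seqs)
    a <- enumerateMaximalRepeats(seqs, 1, includeReverse = TRUE)
    b <- enumerateMaximalRepeats(rcseqs, 1, includeReverse = TRUE)
    ta <- moduleTable(a); tb <- moduleTable(b)
    expect_identical(sort(ta$word), sort(tb$word))
    oa <- occurrenceTable(a); ob <- occurrenceTable(b)
    # non-palindromic words must swap their strand counts
    for (w in ta$word) {
        if (w == revComp(w)) next
        expect_identical(sum(oa$strand[oa$word == w] == "+"),
                         sum(ob$strand[ob$word == w] == "-"))
        expect_identical(sum(oa$strand[oa$word == w] == "-"),
                         sum(ob$strand[ob$word == w] == "+"))
    }
})

test_that("the working list is sorted by length, count, word", {
    set.seed(13)
    seqs <- randomFamily(3, c(50L, 100L))
    tab <- moduleTable(enumerateMaximalRepeats(seqs))
    key <- order(-tab$length, -tab$occurrences, tab$word)
    expect_identical(key, seq_len(nrow(tab)))
})

test_that("pruning removes overlapping occurrences and enforces support", {
    set.seed(17)
    seqs <- randomFamily(3, c(50L, 80L))
    m <- enumerateMaximalRepeats(seqs, 2)
    # empty interval list: identity
    expect_identical(occKey(pruneOccurrences(m, NULL, 2)), occKey(m))
    # covering a whole sequence removes all its occurrences
    iv <- data.frame(seq = 1L, start = 0L, end = nchar(seqs[1L]))
    p <- pruneOccurrences(m, iv, 1)
    expect_false(any(occurrenceTable(p)$seq == 1L))
    # support filter drops repeats falling below the threshold
    p2 <- pruneOccurrences(m, iv, 2)
    expect_true(all(moduleTable(p2)$support >= 2L))
})

test_that("the brute-force oracle refuses oversized inputs", {
    expect_error(
        bruteForceMaximalRepeats(c(a = paste(rep("ACGT", 600), collapse = ""))),
        "too large")
})
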