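# planted family shared by several blocks of this file
detFixture <- function() {
    arch <- plantedArchitecture(list(c(20, 10), c(20, 12), 28),
        events = list(list(copy = 3, block = 1, type = "invert"),
                      list(copy = 4, block = 1, type = "truncate"),
                      list(copy = 5, block = 2, type = "delete"),
                      list(copy = 2, block = 2, type = "duplicate")),
        seed = 11)
    c(list(arch = arch), generateFamily(arch, 9, seed = 11))
}

test_that("widely shared blocks are discovered before rarer ones", {
    # block P in all 4 copies, block Q only in copies 3 and 4
    set.seed(61)
    P <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    Q <- paste(sample(c("A", "C", "G", "T"), 26, TRUE), collapse = "")
    fl <- function() paste(sample(c("A", "C", "G", "T"), 45, TRUE),
                           collapse = "")
    fam <- c(s1 = paste0(fl(), P, fl()),
             s2 = paste0(fl(), P, fl()),
             s3 = paste0(fl(), P, fl(), Q, fl()),
             s4 = paste0(fl(), P, fl(), Q, fl()))
    cat <- detectModules(fam, minSizeModule = 24)
    tab <- moduleTable(cat)
    occ <- compositionTable(cat)
    hits <- function(block) {
        pos <- vapply(fam, function(s) regexpr(block, s, fixed = TRUE), 1L)
        ids <- integer()
        for (s in which(pos > 0L)) {
            a <- pos[s]; b <- pos[s] + nchar(block) - 1L
            o <- occ[occ$sequence_id == names(fam)[s] & occ$start <= b &
                     occ$end >= a, ]
            ids <- c(ids, o$module_id)
        }
        unique(ids)
    }
    idP <- hits(P); idQ <- setdiff(hits(Q), hits(P))
    expect_true(length(idP) >= 1L && length(idQ) >= 1L)
    expect_lt(min(idP), min(idQ))   # discovery order = numbering
    expect_equal(tab$support[tab$module == min(idP)], 4L)
    expect_equal(tab$support[tab$module == min(idQ)], 2L)
})

test_that("an internal tandem duplication yields one module, two occurrences", {
    set.seed(67)
    unit <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
    fl <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    fl2 <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    fam <- c(only = paste0(fl, unit, "ACGT", unit, fl2))
    cat <- detectModules(fam, minSizeModule = 20)
    occ <- compositionTable(cat)
    expect_equal(nrow(occ), 2L)
    expect_equal(length(unique(occ$module_id)), 1L)
})

test_that("families shorter than MinSizeModule give an empty catalog", {
    fam <- c(a = "ACGTACGTAA", b = "ACGTACGTAA")
    expect_warning(cat <- detectModules(fam, minSizeModule = 50),
                   "MinSizeModule")
    expect_equal(nModules(cat), 0L)
})

test_that("inverted copies are reported as reverse occurrences", {
    d <- detFixture()
    cat <- detectModules(d$family, minSizeModule = 22, reverse = TRUE,
                         truncated = TRUE)
    ct <- compositionTable(cat)
    tr <- d$truth[!is.na(d$truth$start), ]
    inv <- tr[tr$event == "invert", ]
    sid <- sprintf("copy%02d", inv$copy)
    hit <- ct[ct$sequence_id == sid & ct$start <= inv$end &
              ct$end >= inv$start, ]
    expect_equal(hit$kind, "reverse")
    # and the reverse occurrence covers the inverted block
    expect_lte(hit$start, inv$start + 8)
    expect_gte(hit$end, inv$end - 8)
    # support at discovery counts both directions
    tab <- moduleTable(cat)
    expect_equal(tab$support[tab$module == hit$module_id], 8L)
})

test_that("detection is symmetric under reverse-complementing the family", {
    # re-detection on the mirrored family finds the mirrored module: the
    # planted block maps to the mirrored interval with the same strand
    # classification (the inverted copy stays the reverse occurrence)
    arch <- plantedArchitecture(list(c(18, 12)), events = list(
        list(copy = 2, block = 1, type = "invert")), seed = 29)
    g <- generateFamily(arch, 5, seed = 29)
    fam <- as.character(g$family); names(fam) <- names(g$family)
    rc <- revComp(fam); names(rc) <- names(fam)
    c1 <- detectModules(fam, minSizeModule = 22, reverse = TRUE)
    c2 <- detectModules(rc, minSizeModule = 22, reverse = TRUE)
    t1 <- compositionTable(c1); t2 <- compositionTable(c2)
    L <- nchar(fam)
    tr <- g$truth
    for (i in seq_len(nrow(tr))) {
        sid <- sprintf("copy%02d", tr$copy[i])
        h1 <- t1[t1$sequence_id == sid & t1$start <= tr$end[i] &
                 t1$end >= tr$start[i], ]
        # mirrored truth interval in the reverse-complemented family
        a <- L[tr$copy[i]] - tr$end[i] + 1L
        b <- L[tr$copy[i]] - tr$start[i] + 1L
        h2 <- t2[t2$sequence_id == sid & t2$start <= b & t2$end >= a, ]
        expect_equal(sort(h1$kind), sort(h2$kind))
    }
})

test_that("truncated occurrences keep the largest MR and exact fractions", {
    d <- detFixture()
    cat <- detectModules(d$family, minSizeModule = 22, reverse = TRUE,
                         truncated = TRUE)
    ct <- compositionTable(cat)
    tr <- d$truth[d$truth$event == "truncate", ]
    sid <- sprintf("copy%02d", tr$copy)
    hit <- ct[ct$sequence_id == sid & ct$start <= tr$end &
              ct$end >= tr$start, ]
    expect_equal(hit$kind, "truncated_direct")
    # block 1 = (20, 10): the kept 20-mer contributes 20/30
    expect_equal(hit$conserved_fraction, 20 / 30)
    # every truncated occurrence in the catalog retains the largest MR
    expect_true(isTRUE(verifyCatalog(cat, d$family)))
    # fractions are in (0,1) for truncated, exactly 1 for complete
    expect_true(all(ct$conserved_fraction[startsWith(ct$kind, "trunc")] < 1))
    expect_true(all(ct$conserved_fraction[ct$kind %in%
                                          c("direct", "reverse")] == 1))
})

test_that("module occurrences never overlap (partition condition)", {
    d <- detFixture()
    for (flags in list(c(FALSE, FALSE), c(TRUE, TRUE))) {
        cat <- detectModules(d$family, minSizeModule = 22,
                             reverse = flags[1], truncated = flags[2])
        occ <- compositionTable(cat)
        for (s in unique(occ$sequence_id)) {
            o <- occ[occ$sequence_id == s, ]
            o <- o[order(o$start), ]
            if (nrow(o) > 1L)
                expect_true(all(o$start[-1L] > o$end[-nrow(o)]))
        }
    }
})

test_that("planted architectures are recovered with tight boundaries", {
    d <- detFixture()
    cat <- detectModules(d$family, minSizeModule = 22, reverse = TRUE,
                         truncated = TRUE)
    ct <- compositionTable(cat)
    tr <- d$truth[!is.na(d$truth$start), ]
    maxSpacer <- 8L
    for (i in seq_len(nrow(tr))) {
        sid <- sprintf("copy%02d", tr$copy[i])
        o <- ct[ct$sequence_id == sid & ct$start <= tr$end[i] &
                ct$end >= tr$start[i], ]
        cov <- sum(pmin(o$end, tr$end[i]) - pmax(o$start, tr$start[i]) + 1)
        span <- tr$end[i] - tr$start[i] + 1L
        if (tr$event[i] == "truncate") {
            expect_gte(cov, 20L)      # the kept 20-mer
        } else {
            expect_gte(cov, span - maxSpacer)
            strand <- if (tr$event[i] == "invert") "-" else "+"
            kinds <- if (strand == "-") c("reverse", "truncated_reverse")
                     else c("direct", "truncated_direct")
            expect_true(all(o$kind %in% kinds))
        }
    }
})

test_that("detection is deterministic", {
    d <- detFixture()
    c1 <- detectModules(d$family, minSizeModule = 22, reverse = TRUE,
                        truncated = TRUE)
    c2 <- detectModules(d$family, minSizeModule = 22, reverse = TRUE,
                        truncated = TRUE)
    expect_identical(compositionTable(c1), compositionTable(c2))
    expect_identical(moduleTable(c1), moduleTable(c2))
})

test_that("standalone reverse/truncated searches match the catalog", {
    d <- detFixture()
    cat <- detectModules(d$family, minSizeModule = 22, reverse = TRUE,
                         truncated = TRUE)
    # a second search on the finalized catalog finds nothing new (all
    # regions already claimed)
    for (m in seq_len(nModules(cat))) {
        expect_equal(nrow(findReverseOccurrences(m, d$family, cat)), 0L)
        expect_equal(nrow(findTruncatedOccurrences(m, d$family, cat)), 0L)
    }
})
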