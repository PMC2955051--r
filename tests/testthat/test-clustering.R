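# a hand-built catalog for incidence tests
toyCatalog <- function(occ, n = 3L, m = 2L, reverse = TRUE,
                       truncated = TRUE) {
    mods <- lapply(seq_len(m), function(i)
        list(id = i, parts = "ACGTACGTAA", partLengths = 10L,
             totalMRLength = 10L, supportAtDiscovery = n,
             junctionAdded = character(), spacerSets = list(),
             spacers = list()))
    new("ModuleCatalog", modules = mods, occurrences = occ,
        seqnames = paste0("s", seq_len(n)),
        seqlengths = rep(200L, n),
        params = list(minSizeModule = 8L, maxratio = 100,
                      minSequences = NA_integer_, reverse = reverse,
                      truncated = truncated))
}

occRow <- function(module, seq, start, kind, fraction) {
    data.frame(module = module, seq = seq, start = start,
               end = start + 10L,
               strand = if (kind %in% c("reverse", "truncated_reverse"))
                   "-" else "+",
               kind = kind, fraction = fraction,
               conserved = "1")
}

test_that("incidence counters follow the attribute rules", {
    # one complete and one half-conserved truncated occurrence of module 2
    # in the same sequence: total attribute 1.5
    occ <- rbind(occRow(2L, 1L, 0L, "direct", 1),
                 occRow(2L, 1L, 50L, "truncated_direct", 0.5))
    mat <- buildIncidenceMatrix(toyCatalog(occ))
    expect_equal(unname(mat["s1", "M|rM2"]), 1.5)
    expect_equal(unname(mat["s1", "M2"]), 1.5)
    expect_equal(unname(mat["s1", "rM2"]), 0)

    # two direct + one reverse: (Mi, rMi, Mi|rMi) = (2, 1, 3)
    occ2 <- rbind(occRow(1L, 2L, 0L, "direct", 1),
                  occRow(1L, 2L, 30L, "direct", 1),
                  occRow(1L, 2L, 60L, "reverse", 1))
    mat2 <- buildIncidenceMatrix(toyCatalog(occ2))
    expect_equal(unname(mat2["s2", c("M1", "rM1", "M|rM1")]), c(2, 1, 3))

    # without the reverse option: one counter per module (m columns)
    mat3 <- buildIncidenceMatrix(toyCatalog(occ2), reverseOption = FALSE)
    expect_equal(dim(mat3), c(3L, 2L))
    expect_equal(unname(mat3["s2", "M1"]), 3)

    # empty catalog: zero columns
    e <- new("ModuleCatalog", modules = list(),
             occurrences = TEmodules:::.emptyOccDf(),
             seqnames = c("a", "b"), seqlengths = c(10L, 10L),
             params = list(reverse = FALSE, truncated = FALSE))
    expect_equal(dim(buildIncidenceMatrix(e)), c(2L, 0L))
})

test_that("the Ward merge cost matches its closed form", {
    expect_equal(wardDelta(c(1, 2, 3), c(1, 2, 3), 5), 0)
    expect_equal(wardDelta(c(1, 0), c(0, 1), 2), 0.5)
    expect_error(wardDelta(c(1, 2), c(1, 2, 3), 2), "length")
    # homogeneity: scaling vectors by c multiplies the cost by c^2
    x <- c(2, 0, 1); y <- c(0, 3, 1)
    expect_equal(wardDelta(3 * x, 3 * y, 4), 9 * wardDelta(x, y, 4))
})

test_that("two-row and duplicate-row clusterings are as expected", {
    m <- rbind(a = c(1, 0), b = c(0, 1))
    t2 <- hacWard(m)
    expect_equal(t2@height, wardDelta(c(1, 0), c(0, 1), 2))
    expect_equal(writeNewick(t2), "(a:0.5,b:0.5);")

    m3 <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 4))
    t3 <- hacWard(m3)
    expect_equal(t3@height[1L], 0)       # identical rows merge first
    expect_equal(t3@merge[1L, ], c(-1L, -2L))
})

test_that("Lance-Williams updates equal from-scratch recomputation", {
    set.seed(83)
    for (i in 1:8) {
        n <- sample(3:12, 1)
        p <- sample(2:6, 1)
        mat <- matrix(rpois(n * p, 1.5) + runif(n * p) * 0.5, n, p)
        rownames(mat) <- paste0("s", seq_len(n))
        got <- hacWard(mat)
        ref <- wardOracle(mat)
        expect_identical(got@merge, ref$merge)
        expect_equal(got@height, ref$height, tolerance = 1e-9)
    }
})

test_that("tree topology is invariant under uniform scaling", {
    set.seed(89)
    mat <- matrix(rpois(5 * 4, 2), 5, 4)
    rownames(mat) <- paste0("s", 1:5)
    t1 <- hacWard(mat)
    t2 <- hacWard(mat * 3)
    expect_identical(t1@merge, t2@merge)
    expect_equal(t2@height, 9 * t1@height, tolerance = 1e-12)
})

test_that("permuting sequences yields an isomorphic tree", {
    skip_if_not_installed("ape")
    set.seed(97)
    mat <- matrix(rpois(6 * 4, 2) + runif(24) * 0.1, 6, 4)
    rownames(mat) <- paste0("s", 1:6)
    perm <- sample(6)
    t1 <- ape::read.tree(text = writeNewick(hacWard(mat)))
    t2 <- ape::read.tree(text = writeNewick(hacWard(mat[perm, ])))
    expect_equal(as.numeric(suppressWarnings(ape::dist.topo(t1, t2))), 0)
    d1 <- ape::cophenetic.phylo(t1); d2 <- ape::cophenetic.phylo(t2)
    expect_equal(d1[rownames(d2), colnames(d2)], d2, tolerance = 1e-9)
})

test_that("Newick output round-trips through an external parser", {
    skip_if_not_installed("ape")
    expect_equal(writeNewick(hacWard(matrix(0, 1, 1,
        dimnames = list("solo", NULL)))), "solo;")
    set.seed(101)
    mat <- matrix(runif(8 * 3), 8, 3)
    rownames(mat) <- paste0("leaf", 1:8)
    tr <- hacWard(mat)
    f <- tempfile(fileext = ".nwk")
    writeNewick(tr, f)
    ph <- ape::read.tree(f)
    expect_setequal(ph$tip.label, paste0("leaf", 1:8))
    # leaf depths equal their cluster's final merge height
    expect_equal(max(ape::node.depth.edgelength(ph)),
                 max(tr@height), tolerance = 1e-9)
})
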