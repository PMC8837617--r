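test_that("Hamming distance treats an absent insertion as a symbol", {
    d <- defaultLibraryDesign()
    expect_equal(hammingDistance(wtGenotype(), wtGenotype(), d), 0L)
    expect_equal(hammingDistance(wtGenotype(), "PL-ILP", d), 1L)
    expect_equal(hammingDistance("P--ILP", "PLAILP", d), 2L)
    expect_error(hammingDistance("P--ILP", "P--ZZZ", d), "valid")
})

test_that("hash-built edge set equals the all-pairs oracle", {
    d <- defaultLibraryDesign()
    set.seed(7)
    for (n in c(120, 500)) {
        g <- sampleLibrary(d, n, seed = n)
        ssn <- buildSSN(g, d)
        expect_identical(ssnEdgeKeys(ssn), allPairsEdges(g))
    }
})

test_that("a two-option design graph is the 6-hypercube", {
    d <- tinyDesign()
    ssn <- buildSSN(enumerateGenotypes(d), d)
    g <- ssnGraph(ssn)
    expect_equal(igraph::vcount(g), 64)
    expect_equal(igraph::ecount(g), 64 * 6 / 2)   # n * d / 2 = 192
    expect_true(all(igraph::degree(g) == 6))      # degree regular
    expect_equal(largestComponent(ssn)$fraction, 1)
})

test_that("largest component extraction follows standard components", {
    d <- tinyDesign()
    # two disjoint triangles plus a singleton: fraction 3/7
    g <- igraph::make_graph(~ a-b, b-c, c-a, d-e, e-f, f-d) +
        igraph::make_empty_graph(1, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", 7, "z")
    ssn <- new("SSN", graph = g, design = d)
    lc <- largestComponent(ssn)
    expect_equal(lc$fraction, 3 / 7)
    # deterministic tie-break: the component holding "a" wins
    expect_true("a" %in% ssnGenotypes(lc$ssn))
})

test_that("partition quality matches a closed-form two-clique oracle", {
    d <- tinyDesign()
    g <- igraph::make_full_graph(10) + igraph::make_full_graph(10)
    g <- igraph::add_edges(g, c(1, 11))
    g <- igraph::set_vertex_attr(g, "name", value = sprintf("v%02d", 1:20))
    ssn <- new("SSN", graph = g, design = d)
    part <- partitionSSN(ssn, seed = 1)
    expect_equal(part$nClusters, 2)
    # closed form: m = 91, within = 45 + 45, cluster degree sums 91 each
    Qexp <- (45 / 91 - (91 / 182)^2) * 2
    expect_equal(part$modularity, Qexp, tolerance = 1e-12)
    expect_equal(ssnModularity(ssn, part$membership), Qexp, tolerance = 1e-12)
    # a single clique yields one cluster with Q = 0
    k <- igraph::make_full_graph(8)
    k <- igraph::set_vertex_attr(k, "name", value = letters[1:8])
    pk <- partitionSSN(new("SSN", graph = k, design = d), seed = 1)
    expect_equal(pk$nClusters, 1)
    expect_equal(pk$modularity, 0)
})

test_that("reported modularity is independently recomputable to 1e-12", {
    d <- defaultLibraryDesign()
    g <- sampleLibrary(d, 800, seed = 17)
    act <- g[hasPhiMotif(g, d)]
    ssn <- buildSSN(c(act, g[1:300]), d)
    lc <- largestComponent(ssn)
    for (method in c("leiden", "louvain")) {
        part <- partitionSSN(lc$ssn, method = method, seed = 5)
        expect_lt(abs(part$modularity - ssnModularity(lc$ssn, part$membership)),
                  1e-12)
    }
})

test_that("partitions are deterministic for a fixed seed", {
    d <- defaultLibraryDesign()
    g <- sampleLibrary(d, 600, seed = 23)
    ssn <- buildSSN(g[hasPhiMotif(g, d)], d)
    lc <- largestComponent(ssn)$ssn
    p1 <- partitionSSN(lc, seed = 11)
    p2 <- partitionSSN(lc, seed = 11)
    expect_identical(p1$membership, p2$membership)
})

test_that("centrality follows standard definitions", {
    d <- tinyDesign()
    # complete graph: degree n-1, betweenness 0
    k <- igraph::make_full_graph(6)
    k <- igraph::set_vertex_attr(k, "name", value = letters[1:6])
    ck <- centralitySummary(new("SSN", graph = k, design = d))
    expect_true(all(ck$degree == 5))
    expect_true(all(ck$betweenness == 0))
    # path of three: middle betweenness 1, ends 0
    p <- igraph::make_graph(~ a-b, b-c)
    cp <- centralitySummary(new("SSN", graph = p, design = d))
    expect_equal(cp$betweenness[match(c("a", "b", "c"), cp$genotype)],
                 c(0, 1, 0))
    # hypercube is degree regular
    cube <- centralitySummary(buildSSN(enumerateGenotypes(d), d))
    expect_equal(length(unique(cube$degree)), 1L)
    expect_true(all(is.finite(cube$eigenvector)))
})

test_that("cluster content exports frequencies and FASTA", {
    d <- tinyDesign()
    ssn <- buildSSN(enumerateGenotypes(d), d)
    membership <- setNames(rep(1L, 64), ssnGenotypes(ssn))
    out <- clusterContent(ssn, membership, 1L)
    expect_equal(dim(out$pfm), c(length(unique(unlist(allowedResidues(d)))), 6))
    expect_equal(unname(colSums(out$pfm)), rep(1, 6))
    # single-member cluster: one-hot columns
    m2 <- setNames(c(2L, rep(1L, 63)), ssnGenotypes(ssn))
    one <- clusterContent(ssn, m2, 2L)
    expect_true(all(apply(one$pfm, 2, max) == 1))
    fa <- withr::local_tempfile(fileext = ".fasta")
    clusterContent(ssn, membership, 1L, fasta = fa)
    seqs <- Biostrings::readAAStringSet(fa)
    expect_length(seqs, 64)
    expect_true(all(Biostrings::width(seqs) == 6))
})

test_that("a two-register landscape partitions by the 8a insertion", {
    # the Ala insertion re-phases the anchoring motif, so active variants
    # with and without 8a occupy disjoint regions of the network
    d <- smallDesign(c("A", "L", "I", "P"))
    ls <- twoRegisterLandscape(d)
    gts <- enumerateGenotypes(d)
    act <- gts[activityScore(gts, ls, d) >= 4]
    lc <- largestComponent(buildSSN(act, d))
    part <- partitionSSN(lc$ssn, seed = 19)
    reg <- substr(names(part$membership), 3, 3)  # "A" or "-" at 8a
    purity <- vapply(split(reg, part$membership),
                     function(x) max(table(x)) / length(x), 0)
    expect_true(all(purity == 1))
    expect_gt(part$nClusters, 1)
})
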