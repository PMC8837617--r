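test_that("single enrichment is f_obs / f_id with exact normalisation", {
    d <- tinyDesign()
    # the full library is perfectly balanced: enrichment 1 everywhere
    enr <- singleEnrichment(enumerateGenotypes(d), d)
    expect_equal(enr$enrichment, rep(1, nrow(enr)))
    expect_equal(sum(enr$f_obs[enr$position == "9"]), 1)
    # fixing position 9 to L in the default design gives 12x for L, 0 others
    dd <- defaultLibraryDesign()
    g <- sampleLibrary(dd, 600, seed = 2)
    g <- paste0(substr(g, 1, 3), "L", substr(g, 5, 6))
    e9 <- singleEnrichment(g, dd)
    e9 <- e9[e9$position == "9", ]
    expect_equal(e9$enrichment[e9$residue == "L"], 12)
    expect_equal(sum(e9$enrichment[e9$residue != "L"]), 0)
})

test_that("joint enrichment uses the ideal product null", {
    d <- defaultLibraryDesign()
    # only (9L,11A) and (9A,11L) equally: 0.5 / (1/144) = 72 at those cells
    g <- c(paste0("A--", "L", "A", "A"), paste0("A--", "A", "L", "A"))
    m <- jointEnrichment(rep(g, 10), d, c("9", "11"))
    expect_equal(m["L", "A"], 72)
    expect_equal(m["A", "L"], 72)
    expect_equal(sum(m > 0), 2)
    # full small library: 1 everywhere, frequencies normalised
    d2 <- tinyDesign()
    m2 <- jointEnrichment(enumerateGenotypes(d2), d2, c("6", "13"))
    expect_equal(unname(m2), matrix(1, 2, 2), ignore_attr = TRUE)
})

test_that("epistatic enrichment is 1 under independence, NA at empty marginals", {
    d <- defaultLibraryDesign()
    # a product distribution: every combination of two fixed sets
    g <- as.vector(outer(c("L", "A", "P"), c("I", "G"), function(a, b)
        paste0("A--", a, b, "P")))
    m <- epistaticEnrichment(rep(g, 5), d, c("9", "11"))
    expect_equal(unname(m[c("L", "A", "P"), c("I", "G")]),
                 matrix(1, 3, 2), ignore_attr = TRUE)
    expect_true(all(is.na(m["W", ])))  # W never observed at position 9
    # perfectly correlated binary pair: 2 on matched, 0 on mismatched cells
    g2 <- rep(c("A--LLA", "A--AAA"), 8)
    m2 <- epistaticEnrichment(g2, d, c("9", "11"))
    expect_equal(m2["L", "L"], 2)
    expect_equal(m2["A", "A"], 2)
    expect_equal(m2["L", "A"], 0)
})

test_that("marginal sums of joint frequencies reproduce single enrichment", {
    d <- defaultLibraryDesign()
    g <- sampleLibrary(d, 800, seed = 6)
    cnt <- ddscan:::jointCounts(g, d, c("7a", "13"))
    fobs <- cnt / length(g)
    single <- singleEnrichment(g, d)
    f7a <- single$f_obs[single$position == "7a"]
    expect_equal(unname(rowSums(fobs)), f7a)
    f13 <- single$f_obs[single$position == "13"]
    expect_equal(unname(colSums(fobs)), f13)
})

test_that("the Eq-4 identity links epistatic and joint enrichment", {
    d <- defaultLibraryDesign()
    g <- sampleLibrary(d, 700, seed = 8)
    pair <- c("9", "11")
    joint <- jointEnrichment(g, d, pair)
    epi <- epistaticEnrichment(g, d, pair)
    single <- singleEnrichment(g, d)
    fa <- single$f_obs[single$position == "9"]
    fb <- single$f_obs[single$position == "11"]
    fid <- outer(rep(1 / 12, 12), rep(1 / 12, 12))
    expected <- joint * fid / outer(fa, fb)
    ok <- !is.na(epi)
    expect_equal(epi[ok], expected[ok])
})

test_that("chi-squared tests use observed-marginal expecteds and Bonferroni", {
    d <- defaultLibraryDesign()
    # exactly independent counts: statistic 0, p 1
    g <- as.vector(outer(c("L", "A"), c("I", "G"),
                         function(a, b) paste0("A--", a, b, "P")))
    res <- chi2Pairwise(rep(g, 25), d, pairs = matrix(c("9", "11"), 1))
    expect_equal(res$statistic, 0)
    expect_equal(res$p_raw, 1)
    expect_equal(res$df, 1)
    # fully dependent binary pair at n = 1e4: chi2 = n, p_bonf < 1e-15
    g2 <- rep(c("A--LLA", "A--AAA"), 5000)
    res2 <- chi2Pairwise(g2, d, pairs = matrix(c("9", "11"), 1), nTests = 15)
    expect_equal(res2$statistic, 10000)
    expect_lt(res2$p_bonferroni, 1e-15)
    # all 15 pairs are tested for the default design
    expect_equal(nrow(positionPairs(d)), 15)
    full <- chi2Pairwise(sampleLibrary(d, 300, seed = 3), d)
    expect_equal(nrow(full), 15)
    expect_true(all(full$p_bonferroni >= full$p_raw - 1e-12))
    expect_true(all(full$p_bonferroni <= 1))
})

test_that("null chi-squared p-values are roughly uniform under permutation", {
    d <- tinyDesign()
    set.seed(99)
    praw <- replicate(60, {
        g <- independentGenotypes(d, 400)
        chi2Pairwise(g, d, pairs = matrix(c("9", "11"), 1))$p_raw
    })
    ks <- suppressWarnings(stats::ks.test(praw, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("motif scan respects adjacency and absent insertions", {
    d <- defaultLibraryDesign()
    expect_equal(motifScan(wtGenotype(), d),
                 matrix(c("9", "11"), 1, dimnames = list(NULL, c("pos_a", "pos_b"))))
    expect_equal(nrow(motifScan("L--AAL", d)), 0)
    m <- motifScan("AL-LAA", d)  # 7a = L, 9 = L
    expect_equal(unname(m[1, ]), c("7a", "9"))
    # a deleted 7a removes its pairs
    expect_equal(nrow(motifScan("L--AAA", d)), 0)
})

test_that("conditional profiles report preference shifts relative to the active set", {
    d <- defaultLibraryDesign()
    g <- sampleLibrary(d, 1200, seed = 13)
    # always-true condition: ratios 1 everywhere observed
    prof <- conditionalProfile(g, rep(TRUE, length(g)), d)
    ok <- !is.na(prof$ratio)
    expect_equal(prof$ratio[ok], rep(1, sum(ok)))
    expect_equal(attr(prof, "nSubset"), 1200L)
    expect_error(conditionalProfile(g, rep(FALSE, length(g)), d), "no variants")
})

test_that("planted-synergy conditioning relaxes and sharpens preferences as expected", {
    # the planted active landscape: all motif carriers of the library
    d <- defaultLibraryDesign()
    act <- sampleLibrary(d, 30000, seed = 41)
    act <- act[hasPhiMotif(act, d)]
    phi <- c("L", "I")
    # fixing the motif at 9/11 relaxes Phi enrichment elsewhere
    with_motif <- conditionalProfile(act, motifCondition(c("9", "11")), d)
    w13 <- with_motif[with_motif$position == "13", ]
    phiRatio <- mean(w13$ratio[w13$residue %in% phi], na.rm = TRUE)
    nonRatio <- mean(w13$ratio[!w13$residue %in% phi], na.rm = TRUE)
    expect_lt(phiRatio, 1)
    expect_gt(nonRatio, 1)
    # excluding Phi at both 9 and 11 leaves 6/7a as the only motif register,
    # so Phi becomes obligatory there
    without <- conditionalProfile(act, motifCondition(c("9", "11"),
                                                      include = FALSE), d)
    w7a <- without[without$position == "7a", ]
    expect_gt(mean(w7a$ratio[w7a$residue %in% phi], na.rm = TRUE), 1)
    expect_equal(sum(w7a$f_subset[w7a$residue %in% phi]), 1)
})
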