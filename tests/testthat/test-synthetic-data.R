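test_that("library sampling is uniform without replacement and seed-deterministic", {
    d <- tinyDesign()
    all <- sampleLibrary(d, librarySize(d), seed = 1)
    expect_setequal(all, enumerateGenotypes(d))
    expect_equal(length(unique(all)), librarySize(d))
    s1 <- sampleLibrary(defaultLibraryDesign(), 1000, seed = 1)
    s2 <- sampleLibrary(defaultLibraryDesign(), 1000, seed = 1)
    expect_identical(s1, s2)
    expect_false(identical(s1, sampleLibrary(defaultLibraryDesign(), 1000, seed = 2)))
    expect_true(all(isValidGenotype(s1, defaultLibraryDesign())))
    expect_error(sampleLibrary(d, librarySize(d) + 1), "cannot sample")
})

test_that("activity scores add per-position effects, motif bonus and pairwise terms", {
    d <- defaultLibraryDesign()
    ls <- defaultLandscape(d)
    # WT has I9/L11, an adjacent Phi pair: two effects + bonus
    expect_equal(activityScore(wtGenotype(), ls, d), 2 + ls@motifBonus)
    expect_equal(activityScore("A--AAA", ls, d), 0)
    # removing the bonus changes motif carriers by exactly the bonus
    ls0 <- ls; ls0@motifBonus <- 0
    expect_equal(activityScore(wtGenotype(), ls0, d),
                 activityScore(wtGenotype(), ls, d) - ls@motifBonus)
    # an absent 7a makes 6 and 9 adjacent
    expect_true(hasPhiMotif("L--IAA", d))
    expect_false(hasPhiMotif("LA-IAA", d))   # spacer residue at 7a breaks it
    expect_true(hasPhiMotif("L--ALL", d))  # 11,13 pair present
    pw <- data.frame(pos_a = "6", res_a = "P", pos_b = "13", res_b = "P",
                     effect = 2.5)
    lsp <- FitnessLandscape(positionEffects = list(), motifBonus = 0,
                            pairwiseEffects = pw, noiseSd = 0)
    expect_equal(activityScore("P--AAP", lsp, d), 2.5)
    expect_equal(activityScore("P--AAL", lsp, d), 0)
})

test_that("noise-free sorting with no misassignment is deterministic in activity", {
    d <- defaultLibraryDesign()
    ls <- defaultLandscape(d, noiseSd = 0)
    sc <- SortConfig(falsePositiveRate = 0, falseNegativeRate = 0)
    gts <- sampleLibrary(d, 300, seed = 5)
    beads <- simulateSort(gts, ls, sc, d, seed = 6)
    th <- sc@gateThresholds
    expected <- ifelse(beads$activity < th[1], "low",
                       ifelse(beads$activity >= th[2], "high", "medium"))
    expect_identical(as.character(beads$gate), expected)
    expect_equal(nrow(beads), length(gts) * sc@beadsPerVariant)
})

test_that("false negatives reproduce the coverage formula", {
    d <- defaultLibraryDesign()
    ls <- defaultLandscape(d, noiseSd = 0)
    sc <- SortConfig(falsePositiveRate = 0, falseNegativeRate = 0.5,
                     beadsPerVariant = 7L)
    gts <- sampleLibrary(d, 4000, seed = 7)
    beads <- simulateSort(gts, ls, sc, d, seed = 8)
    active <- unique(beads$genotype[beads$nominalGate == "high"])
    seen <- tapply(beads$gate == "high", beads$genotype, any)[active]
    frac <- mean(seen)
    p <- coverageProbability(0.5, 7)  # 0.992
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / length(active)) + 0.005)
})

test_that("high-gate positive predictive value matches the screen control", {
    # balanced active/inactive beads, no false negatives, fp ~ 8%:
    # PPV = 1 / (1 + fp) ~ 92.6%
    d <- defaultLibraryDesign()
    ls <- defaultLandscape(d, noiseSd = 0)
    sc <- SortConfig(falsePositiveRate = 0.08, falseNegativeRate = 0)
    gts <- sampleLibrary(d, 20000, seed = 9)
    act <- activityScore(gts, ls, d)
    balanced <- c(gts[act >= sc@gateThresholds[2]][1:900],
                  gts[act < sc@gateThresholds[1]][1:900])
    beads <- simulateSort(balanced, ls, sc, d, seed = 10)
    hi <- beads$gate == "high"
    ppv <- mean(beads$nominalGate[hi] == "high")
    expect_lt(abs(ppv - 1 / 1.08), 0.02)
})

test_that("encode/decode round-trips and insertion length bookkeeping", {
    d <- tinyDesign()
    gts <- enumerateGenotypes(d)
    dna <- encodeGenotypeDNA(gts, d)
    nIns <- 2L - (substr(gts, 2, 2) == "-") - (substr(gts, 3, 3) == "-")
    expect_equal(nchar(dna) - min(nchar(dna)), 3L * (nIns - min(nIns)))
    expect_equal(max(nchar(dna)) - min(nchar(dna)), 6L)
    wt_dna <- encodeGenotypeDNA(wtGenotype(), defaultLibraryDesign())
    insert <- findDDomain(wt_dna, defaultLibraryDesign())$insert
    expect_equal(translateInsert(insert)$protein, "MPKKKPTPIQLNPAPDG")
})

test_that("read generation is seed-deterministic and error-free reads decode", {
    d <- tinyDesign()
    ls <- defaultLandscape(d)
    sc <- SortConfig(readsPerBead = 4)
    gts <- enumerateGenotypes(d)[1:40]
    beads <- simulateSort(gts, ls, sc, d, seed = 3)
    dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
    out1 <- generateReads(beads, sc, d, dir1, seed = 4)
    out2 <- generateReads(beads, sc, d, dir2, seed = 4)
    for (g in c("low", "medium", "high")) {
        expect_identical(readLines(out1$fastq[[g]]), readLines(out2$fastq[[g]]))
    }
    # conservation: truth-table reads match the FASTQ line counts
    truth <- read.delim(out1$truth)
    expect_equal(sum(truth$reads_low + truth$reads_medium + truth$reads_high),
                 sum(unname(out1$readCounts)))
    # zero error rate: every read decodes to its source genotype
    pr <- processReads(out1$fastq[["high"]], d)
    expect_equal(unname(pr$summary[["accepted"]]), unname(pr$summary[["total"]]))
    cnt <- table(pr$calls$genotype)
    expect_equal(as.integer(cnt[truth$genotype[truth$reads_high > 0]]),
                 truth$reads_high[truth$reads_high > 0])
})

test_that("flank anchoring failures match the per-base error model", {
    d <- defaultLibraryDesign()
    e <- 5e-3
    sc <- SortConfig(readsPerBead = 8, perBaseErrorRate = e)
    ls <- defaultLandscape(d)
    gts <- sampleLibrary(d, 250, seed = 11)
    beads <- simulateSort(gts, ls, sc, d, seed = 12)
    dir <- withr::local_tempdir()
    out <- generateReads(beads, sc, d, dir, seed = 13)
    pr <- processReads(out$fastq[["low"]], d)
    Lf <- nchar(d@flank5) + nchar(d@flank3)
    expected <- 1 - (1 - e)^Lf
    observed <- sum(pr$calls$reason == "no-anchor", na.rm = TRUE) /
        unname(pr$summary[["total"]])
    n <- unname(pr$summary[["total"]])
    expect_lt(abs(observed - expected),
              4 * sqrt(expected * (1 - expected) / n) + 0.002)
})

test_that("gate-count shortcut reproduces exact truth counts", {
    d <- tinyDesign()
    ls <- defaultLandscape(d)
    sc <- SortConfig(readsPerBead = 5)
    beads <- simulateSort(enumerateGenotypes(d), ls, sc, d, seed = 21)
    gct <- simulateGateCounts(beads, sc, seed = 22)
    expect_s4_class(gct, "GateCountTable")
    # same seed drives generateReads: totals agree with the truth table
    dir <- withr::local_tempdir()
    out <- generateReads(beads, sc, d, dir, seed = 22)
    truth <- read.delim(out$truth)
    expect_equal(unname(gateCounts(gct)[truth$genotype, "high"]),
                 truth$reads_high)
})
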