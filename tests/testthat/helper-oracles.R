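## Shared fixtures and independent oracles, built in code at test time.

# reduced designs keep exhaustive checks cheap
smallDesign <- function(alphabet = c("A", "L", "P")) {
    defaultLibraryDesign(alphabet = alphabet)
}

tinyDesign <- function() {
    LibraryDesign(
        labels = c("6", "7a", "8a", "9", "11", "13"),
        allowed = list(c("A", "L"), c("L", "-"), c("A", "-"),
                       c("L", "I"), c("L", "A"), c("P", "L")),
        insertion = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
        refLocus = c(6, 7, 8, 9, 11, 13),
        referenceProtein = "MPKKKXTPXQXNXAPDG",
        flank5 = "ACGTGGTGAGAAGG", flank3 = "GGTAGCGGCTCTGA")
}

# brute-force alignment oracle: exhaustive enumeration over all global
# alignment paths, scoring gap runs directly from the cost definition
# (open + k * extend); no dynamic-programming matrices involved.
bruteAlignScore <- function(query, reference, scheme = ScoringScheme()) {
    q <- strsplit(query, "")[[1]]
    r <- strsplit(reference, "")[[1]]
    n <- length(q); m <- length(r)
    go <- scheme@gapOpen; ge <- scheme@gapExtend
    col <- function(a, b) {
        if (b == "X") scheme@xMatch
        else if (a == b) scheme@match
        else scheme@mismatch
    }
    rec <- function(i, j, last) {
        if (i == n && j == m) return(0)
        best <- -Inf
        if (i < n && j < m)
            best <- max(best, col(q[i + 1], r[j + 1]) + rec(i + 1, j + 1, "M"))
        if (i < n)
            best <- max(best,
                        -(if (last == "U") ge else go + ge) + rec(i + 1, j, "U"))
        if (j < m)
            best <- max(best,
                        -(if (last == "L") ge else go + ge) + rec(i, j + 1, "L"))
        best
    }
    rec(0L, 0L, "")
}

# independent mature implementation with the same scoring convention
biostringsAlignScore <- function(query, reference, scheme = ScoringScheme()) {
    alph <- sort(unique(c(strsplit(query, "")[[1]],
                          strsplit(reference, "")[[1]], "X")))
    sm <- matrix(scheme@mismatch, length(alph), length(alph),
                 dimnames = list(alph, alph))
    diag(sm) <- scheme@match
    sm["X", ] <- scheme@xMatch; sm[, "X"] <- scheme@xMatch
    Biostrings::pairwiseAlignment(
        Biostrings::AAString(query), Biostrings::AAString(reference),
        substitutionMatrix = sm, gapOpening = scheme@gapOpen,
        gapExtension = scheme@gapExtend, type = "global", scoreOnly = TRUE)
}

# quadratic all-pairs Hamming-1 edge set, as a sorted "a|b" key vector
allPairsEdges <- function(genotypes) {
    m <- ddscan:::symbolMatrix(genotypes)
    n <- nrow(m)
    d <- matrix(0L, n, n)
    for (i in seq_len(ncol(m)))
        d <- d + outer(m[, i], m[, i], "!=")
    idx <- which(d == 1L & upper.tri(d), arr.ind = TRUE)
    sort(paste(pmin(genotypes[idx[, 1]], genotypes[idx[, 2]]),
               pmax(genotypes[idx[, 1]], genotypes[idx[, 2]]), sep = "|"))
}

ssnEdgeKeys <- function(ssn) {
    e <- igraph::as_edgelist(ssnGraph(ssn))
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "|"))
}

# genotypes drawn independently per position: the exact independence null
independentGenotypes <- function(design, n) {
    cols <- lapply(allowedResidues(design), function(a)
        sample(a, n, replace = TRUE))
    do.call(paste0, cols)
}

adjacentChainPairs <- function() {
    list(c("6", "7a"), c("7a", "9"), c("9", "11"), c("11", "13"))
}
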