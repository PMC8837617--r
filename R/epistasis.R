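## Enrichment and epistasis statistics over the active set: single-position
## enrichment f_obs/f_id, pairwise joint enrichment f_ab/(f_a_id f_b_id),
## epistatic enrichment f_ab/(f_a_obs f_b_obs), chi-squared independence
## tests with Bonferroni correction, and conditional motif-subset profiles.

asGenotypes <- function(x) {
    if (is(x, "ActiveSet")) x@genotypes else as.character(x)
}

# observed residue frequencies at one position over (unique) variants
marginalFreq <- function(m, i, allowed) {
    p <- table(factor(m[, i], allowed)) / nrow(m)
    setNames(as.numeric(p), allowed)
}

#' Single-position enrichment profile
#'
#' Observed residue frequencies per position over the variants, divided by
#' the ideal balanced-library frequencies 1/K.
#'
#' @param active genotypes (character vector or \linkS4class{ActiveSet}).
#' @param design a \linkS4class{LibraryDesign}.
#' @return data.frame(position, residue, f_obs, f_id, enrichment), one row
#'   per allowed residue per position.
#' @export
singleEnrichment <- function(active, design) {
    g <- asGenotypes(active)
    if (!all(isValidGenotype(g, design))) stop("genotypes outside the design")
    m <- symbolMatrix(g)
    out <- lapply(seq_along(design@labels), function(i) {
        a <- design@allowed[[i]]
        fobs <- marginalFreq(m, i, a)
        data.frame(position = design@labels[i], residue = a,
                   f_obs = fobs, f_id = 1 / length(a),
                   enrichment = fobs * length(a), row.names = NULL)
    })
    do.call(rbind, out)
}

pairIndices <- function(design, pair) {
    idx <- match(pair, design@labels)
    if (anyNA(idx) || idx[1] == idx[2]) stop("pair must name two distinct positions")
    idx
}

#' All position pairs of a design
#'
#' @param design a \linkS4class{LibraryDesign}.
#' @return character matrix with two columns; 15 rows for six positions.
#' @export
positionPairs <- function(design) {
    t(combn(design@labels, 2L))
}

jointCounts <- function(g, design, pair) {
    idx <- pairIndices(design, pair)
    m <- symbolMatrix(g)
    table(factor(m[, idx[1]], design@allowed[[idx[1]]]),
          factor(m[, idx[2]], design@allowed[[idx[2]]]))
}

#' Pairwise joint enrichment (ideal-frequency null)
#'
#' Joint observed residue-pair frequencies divided by the ideal joint
#' proportions f_a_id * f_b_id of a perfectly balanced library.
#'
#' @param active genotypes (character vector or \linkS4class{ActiveSet}).
#' @param design a \linkS4class{LibraryDesign}.
#' @param pair two position labels, e.g. \code{c("9", "11")}.
#' @return matrix (residues of pair[1] x residues of pair[2]).
#' @export
jointEnrichment <- function(active, design, pair) {
    g <- asGenotypes(active)
    cnt <- jointCounts(g, design, pair)
    fobs <- cnt / length(g)
    fid <- 1 / (nrow(cnt) * ncol(cnt))
    unclass(fobs / fid)
}

#' Pairwise epistatic enrichment (observed-marginal null)
#'
#' Joint observed frequencies divided by the product of the observed
#' marginals; 1 everywhere when the two positions are statistically
#' independent. Cells whose marginal frequency is zero are undefined and
#' returned as NA (never 0 or Inf).
#'
#' @inheritParams jointEnrichment
#' @return matrix (residues x residues), NA where undefined.
#' @export
epistaticEnrichment <- function(active, design, pair) {
    g <- asGenotypes(active)
    cnt <- jointCounts(g, design, pair)
    fobs <- cnt / length(g)
    fa <- rowSums(fobs); fb <- colSums(fobs)
    denom <- outer(fa, fb)
    out <- unclass(fobs) / denom
    out[denom == 0] <- NA_real_
    out
}

#' Chi-squared independence tests for position pairs
#'
#' For each pair, tests the observed joint counts against the independence
#' expectation n * f_a_obs * f_b_obs (residues unobserved at a position are
#' dropped, so no expected cell is zero), with (K_a - 1)(K_b - 1) degrees of
#' freedom and Bonferroni correction over the number of pairs tested.
#'
#' @param active genotypes (character vector or \linkS4class{ActiveSet}).
#' @param design a \linkS4class{LibraryDesign}.
#' @param pairs two-column character matrix of position pairs (default: all
#'   15 pairs of the six positions).
#' @param nTests Bonferroni multiplier (default: number of pairs tested).
#' @return data.frame(pos_a, pos_b, statistic, df, p_raw, p_bonferroni).
#' @export
chi2Pairwise <- function(active, design, pairs = positionPairs(design),
                         nTests = nrow(pairs)) {
    g <- asGenotypes(active)
    out <- lapply(seq_len(nrow(pairs)), function(k) {
        cnt <- unclass(jointCounts(g, design, pairs[k, ]))
        cnt <- cnt[rowSums(cnt) > 0, colSums(cnt) > 0, drop = FALSE]
        if (nrow(cnt) < 2L || ncol(cnt) < 2L) {
            stat <- 0; df <- 0; p <- 1
        } else {
            ct <- suppressWarnings(chisq.test(cnt, correct = FALSE))
            stat <- unname(ct$statistic); df <- unname(ct$parameter)
            p <- unname(ct$p.value)
        }
        data.frame(pos_a = pairs[k, 1], pos_b = pairs[k, 2],
                   statistic = stat, df = df, p_raw = p,
                   p_bonferroni = min(1, p * nTests))
    })
    do.call(rbind, out)
}

#' Scan a genotype for adjacent Phi-X-Phi motif placements
#'
#' Checks the adjacent randomised-position pairs (6,7a), (7a,9), (9,11),
#' (11,13); a pair counts when both members carry a Phi residue, and an
#' absent 7a removes its two pairs from consideration.
#'
#' @param genotype a single genotype string.
#' @param design a \linkS4class{LibraryDesign}.
#' @param phiSet residues counted as Phi.
#' @return character matrix with columns pos_a, pos_b (zero rows if none).
#' @export
motifScan <- function(genotype, design, phiSet = c("L", "I")) {
    sym <- setNames(strsplit(genotype, "")[[1]], design@labels)
    chain <- chainPositions(design)
    pairs <- cbind(chain[-length(chain)], chain[-1])
    hit <- sym[pairs[, 1]] %in% phiSet & sym[pairs[, 2]] %in% phiSet &
        sym[pairs[, 1]] != DELETION & sym[pairs[, 2]] != DELETION
    out <- pairs[hit, , drop = FALSE]
    colnames(out) <- c("pos_a", "pos_b")
    rownames(out) <- NULL
    out
}

#' Condition builders for conditional profiles
#'
#' \code{motifCondition(pair)} selects variants carrying Phi at both
#' positions of the pair; with \code{include = FALSE} it selects variants
#' carrying anything but Phi at both.
#'
#' @param pair two position labels.
#' @param phiSet residues counted as Phi.
#' @param include select the motif-containing (TRUE) or motif-excluding
#'   subset.
#' @return a predicate function on genotype vectors.
#' @export
motifCondition <- function(pair, phiSet = c("L", "I"), include = TRUE) {
    force(pair); force(phiSet); force(include)
    function(genotypes, design) {
        idx <- pairIndices(design, pair)
        m <- symbolMatrix(genotypes)
        a <- m[, idx[1]] %in% phiSet
        b <- m[, idx[2]] %in% phiSet
        if (include) a & b else (!a) & (!b)
    }
}

#' Conditional enrichment profile relative to the full active set
#'
#' Residue frequencies in a subset of the active variants divided by the
#' frequencies in the full active set, per position: the change in sequence
#' preference induced by the condition (e.g. fixing a Phi-X-Phi motif).
#'
#' @param active genotypes (character vector or \linkS4class{ActiveSet}).
#' @param condition a predicate: either a logical vector over the variants or
#'   a function(genotypes, design) returning one (see
#'   \code{\link{motifCondition}}).
#' @param design a \linkS4class{LibraryDesign}.
#' @return data.frame(position, residue, f_subset, f_active, ratio) with
#'   attributes \code{nSubset} and \code{nActive}; ratio is NA where the
#'   active-set frequency is 0.
#' @export
conditionalProfile <- function(active, condition, design) {
    g <- asGenotypes(active)
    keep <- if (is.function(condition)) condition(g, design) else condition
    stopifnot(length(keep) == length(g))
    if (!any(keep)) stop("condition selects no variants")
    mAll <- symbolMatrix(g)
    mSub <- mAll[keep, , drop = FALSE]
    out <- lapply(seq_along(design@labels), function(i) {
        a <- design@allowed[[i]]
        fAll <- marginalFreq(mAll, i, a)
        fSub <- marginalFreq(mSub, i, a)
        data.frame(position = design@labels[i], residue = a,
                   f_subset = fSub, f_active = fAll,
                   ratio = ifelse(fAll > 0, fSub / fAll, NA_real_),
                   row.names = NULL)
    })
    out <- do.call(rbind, out)
    attr(out, "nSubset") <- sum(keep)
    attr(out, "nActive") <- length(g)
    out
}
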