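## Per-gate counting, read cutoffs, the active-set filter and per-position
## normalised Shannon entropy.

#' Construct a GateCountTable
#'
#' @param counts integer matrix, rows named by genotype, columns
#'   low/medium/high (reordered if named differently).
#' @return a \linkS4class{GateCountTable}.
#' @export
GateCountTable <- function(counts) {
    if (is.null(colnames(counts))) colnames(counts) <- GATES
    counts <- counts[, GATES, drop = FALSE]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(gate = GATES, row.names = GATES))
    new("GateCountTable", se)
}

#' Count genotype calls per gate
#'
#' @param callsByGate named list (low/medium/high) of accepted genotype
#'   character vectors, or of call data.frames from
#'   \code{\link{processReads}} (rejected rows are dropped).
#' @return a \linkS4class{GateCountTable} over the union of genotypes.
#' @export
countGenotypes <- function(callsByGate) {
    stopifnot(all(GATES %in% names(callsByGate)))
    vecs <- lapply(callsByGate[GATES], function(x) {
        if (is.data.frame(x)) x <- x$genotype[x$status == "ok"]
        x[!is.na(x)]
    })
    gts <- sort(unique(unlist(vecs)))
    counts <- vapply(vecs, function(v) as.integer(table(factor(v, gts))),
                     integer(length(gts)))
    if (length(gts) == 1L) counts <- matrix(counts, nrow = 1L,
                                            dimnames = list(gts, GATES))
    rownames(counts) <- gts
    GateCountTable(counts)
}

#' Accessors for GateCountTable
#'
#' @param x a \linkS4class{GateCountTable}.
#' @return \code{gateCounts}: the counts matrix; \code{gateTotals}: reads per
#'   gate; \code{gateFrequencies}: per-gate frequencies (columns sum to 1
#'   over observed genotypes; an empty gate yields zeros).
#' @export
gateCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @rdname gateCounts
#' @export
gateTotals <- function(x) colSums(gateCounts(x))

#' @rdname gateCounts
#' @export
gateFrequencies <- function(x) {
    tot <- gateTotals(x)
    sweep(gateCounts(x), 2L, pmax(tot, 1), "/")
}

setMethod("show", "GateCountTable", function(object) {
    cat("GateCountTable:", nrow(object), "genotypes\n")
    print(gateTotals(object))
})

#' Per-gate observed-variant sets under read cutoffs
#'
#' Applies the per-gate minimum read counts (defaults 3/5/10 for
#' low/medium/high) and reports the per-gate sets together with the Venn
#' region counts of their overlaps.
#'
#' @param table a \linkS4class{GateCountTable}.
#' @param cutoffs named numeric (low/medium/high), all >= 1.
#' @return list(sets = per-gate genotype vectors, union = union size,
#'   venn = named counts of the 7 Venn regions).
#' @export
applyReadCutoffs <- function(table, cutoffs = c(low = 3, medium = 5, high = 10)) {
    stopifnot(all(GATES %in% names(cutoffs)), all(cutoffs >= 1))
    cnt <- gateCounts(table)
    sets <- lapply(setNames(GATES, GATES),
                   function(g) rownames(cnt)[cnt[, g] >= cutoffs[[g]]])
    member <- vapply(sets, function(s) rownames(cnt) %in% s,
                     logical(nrow(cnt)))
    key <- paste0(ifelse(member[, "low"], "L", ""),
                  ifelse(member[, "medium"], "M", ""),
                  ifelse(member[, "high"], "H", ""))
    venn <- table(factor(key[key != ""],
                         c("L", "M", "H", "LM", "LH", "MH", "LMH")))
    list(sets = sets, union = sum(key != ""),
         venn = setNames(as.integer(venn), names(venn)))
}

#' The active-set filter
#'
#' A genotype is active when it has at least \code{highMin} reads in the high
#' gate (51 by default, the prevalence of the wild type) and, under the
#' default rule, its gate-normalised high-gate frequency strictly exceeds its
#' normalised frequency in both lower gates. \code{rule = "none"} keeps the
#' read-count clause only.
#'
#' @param table a \linkS4class{GateCountTable}.
#' @param highMin minimum high-gate reads.
#' @param rule \code{"freq_above_lower"} (default) or \code{"none"}.
#' @return an \linkS4class{ActiveSet}.
#' @export
activeSet <- function(table, highMin = 51, rule = c("freq_above_lower", "none")) {
    rule <- match.arg(rule)
    cnt <- gateCounts(table)
    if (sum(cnt[, "high"]) == 0L)
        warning("high gate is empty; active set is empty")
    keep <- cnt[, "high"] >= highMin
    if (rule == "freq_above_lower") {
        f <- gateFrequencies(table)
        keep <- keep & f[, "high"] > f[, "low"] & f[, "high"] > f[, "medium"]
    }
    new("ActiveSet", genotypes = rownames(cnt)[keep],
        highMin = highMin, rule = rule)
}

#' @rdname activeSet
#' @param x an \linkS4class{ActiveSet}.
#' @export
activeGenotypes <- function(x) x@genotypes

setMethod("show", "ActiveSet", function(object) {
    cat("ActiveSet:", length(object@genotypes), "genotypes",
        sprintf("(high >= %g, rule '%s')\n", object@highMin, object@rule))
})

setMethod("length", "ActiveSet", function(x) length(x@genotypes))

#' Normalised Shannon entropy per randomised position
#'
#' H = -sum(p_a log p_a) / log(K) over the K allowed residues of each
#' position, so a perfectly balanced position scores 1 and a fixed position
#' scores 0. Unweighted by default (one count per unique variant); read
#' weights give the read-weighted composition.
#'
#' @param genotypes character vector of genotypes (or an
#'   \linkS4class{ActiveSet}).
#' @param design a \linkS4class{LibraryDesign}.
#' @param weights optional non-negative weights, one per genotype.
#' @return named numeric in [0, 1], one entry per position.
#' @export
positionEntropy <- function(genotypes, design, weights = NULL) {
    if (is(genotypes, "ActiveSet")) genotypes <- genotypes@genotypes
    if (length(genotypes) == 0L) stop("no genotypes")
    if (is.null(weights)) weights <- rep(1, length(genotypes))
    m <- symbolMatrix(genotypes)
    vapply(seq_along(design@labels), function(i) {
        a <- design@allowed[[i]]
        w <- vapply(a, function(res) sum(weights[m[, i] == res]), 0)
        p <- w / sum(w)
        p <- p[p > 0]
        if (length(a) == 1L) return(0)
        -sum(p * log(p)) / log(length(a)) + 0  # + 0 normalises signed zero
    }, 0, USE.NAMES = FALSE) |> setNames(design@labels)
}
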