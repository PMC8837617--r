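## Combinatorial library design: constructors, accessors, design calculators.

# 12-residue substitution alphabet used at positions 6/9/11/13 and (plus
# absence) at 7a: hydrophobics L/I/F/M/V/W plus A/G/P/Y/D/K.
DEFAULT_ALPHABET <- c("A", "D", "F", "G", "I", "K", "L", "M", "P", "V", "W", "Y")

# one codon per amino acid; only the simulator uses this
DEFAULT_CODONS <- c(
    A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
    H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
    P = "CCG", Q = "CAG", R = "CGT", S = "AGC", T = "ACC", V = "GTT",
    W = "TGG", Y = "TAT")

#' Construct a LibraryDesign
#'
#' @param labels position labels, ordered along the sequence.
#' @param allowed named list of allowed residues per position ("-" = absent).
#' @param insertion named logical, TRUE for optional insertion positions.
#' @param refLocus named integer; X index for substitutions, "insert after"
#'   reference index for insertions.
#' @param referenceProtein degenerate reference ("X" at substitution loci).
#' @param flank5,flank3 constant DNA anchors around the domain insert.
#' @param codonMap named character, one codon per amino acid.
#' @return a validated \linkS4class{LibraryDesign}.
#' @export
LibraryDesign <- function(labels, allowed, insertion, refLocus,
                          referenceProtein, flank5, flank3,
                          codonMap = DEFAULT_CODONS) {
    new("LibraryDesign",
        labels = labels,
        allowed = setNames(lapply(allowed, as.character), labels),
        insertion = setNames(as.logical(insertion), labels),
        refLocus = setNames(as.integer(refLocus), labels),
        referenceProtein = referenceProtein,
        flank5 = flank5, flank3 = flank3, codonMap = codonMap)
}

#' The default six-position MKK1 D-domain design
#'
#' Positions 6, 9, 11, 13 draw from a 12-residue alphabet, insertion 7a from
#' the same alphabet or absence (13 options) and insertion 8a is Ala or absent
#' (2 options), on the reference \code{MPKKKXTPXQXNXAPDG}; ideal frequencies
#' are therefore 1/12, 1/13 and 1/2. The alphabet is configurable via
#' \code{alphabet}.
#'
#' @param alphabet residues allowed at the substitution positions.
#' @param flank5,flank3 constant DNA anchors used by the simulator/extractor.
#' @return a \linkS4class{LibraryDesign}.
#' @examples
#' librarySize(defaultLibraryDesign())  # 539136
#' @export
defaultLibraryDesign <- function(alphabet = DEFAULT_ALPHABET,
                                 flank5 = "ACGTGGTGAGAAGG",
                                 flank3 = "GGTAGCGGCTCTGA") {
    LibraryDesign(
        labels = c("6", "7a", "8a", "9", "11", "13"),
        allowed = list(alphabet, c(alphabet, DELETION), c("A", DELETION),
                       alphabet, alphabet, alphabet),
        insertion = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
        refLocus = c(6L, 7L, 8L, 9L, 11L, 13L),
        referenceProtein = "MPKKKXTPXQXNXAPDG",
        flank5 = flank5, flank3 = flank3)
}

#' @describeIn defaultLibraryDesign wild-type MKK1 genotype under a design
#'   (P at 6 and 13, no insertions, I at 9, L at 11).
#' @export
wtGenotype <- function() "P--ILP"

#' Accessors for LibraryDesign
#'
#' @param design a \linkS4class{LibraryDesign}.
#' @param position a position label such as \code{"7a"}; if missing, the full
#'   named list is returned.
#' @return \code{positionLabels}: character; \code{allowedResidues}: character
#'   vector (or named list); \code{referenceProtein}: the degenerate
#'   reference string.
#' @export
positionLabels <- function(design) design@labels

#' @rdname positionLabels
#' @export
allowedResidues <- function(design, position) {
    if (missing(position)) return(design@allowed)
    if (!position %in% design@labels)
        stop("unknown position label: ", position)
    design@allowed[[position]]
}

#' @rdname positionLabels
#' @export
referenceProtein <- function(design) design@referenceProtein

#' @rdname positionLabels
#' @export
idealFrequencies <- function(design) {
    lapply(design@allowed, function(a) setNames(rep(1 / length(a), length(a)), a))
}

setMethod("show", "LibraryDesign", function(object) {
    cat("LibraryDesign with", length(object@labels), "randomised positions on",
        object@referenceProtein, "\n")
    for (i in seq_along(object@labels)) {
        cat(sprintf("  %-3s %s[%d options] %s\n", object@labels[i],
                    if (object@insertion[i]) "(insertion) " else "",
                    length(object@allowed[[i]]),
                    paste(object@allowed[[i]], collapse = "")))
    }
    cat("Library size:", librarySize(object), "\n")
})

#' Number of variants encoded by a design
#'
#' The product of the allowed-set sizes over all randomised positions; the
#' default design yields 12^4 * 13 * 2 = 539,136 (a library of >500,000
#' variants).
#'
#' @param design a \linkS4class{LibraryDesign}.
#' @return integer count.
#' @export
librarySize <- function(design) {
    stopifnot(is(design, "LibraryDesign"))
    validObject(design)
    combinatorialExpansion(lengths(design@allowed))
}

#' Combinatorial expansion of per-position option counts
#'
#' @param counts integer vector of options per position, all >= 1.
#' @return the product. E.g. the single-mutant option counts
#'   \code{c(2, 3, 1, 3, 4, 6)} expand to 432.
#' @export
combinatorialExpansion <- function(counts) {
    counts <- as.numeric(counts)
    if (length(counts) == 0L || any(counts < 1))
        stop("all option counts must be >= 1")
    prod(counts)
}

#' All single-position mutational neighbours of a genotype
#'
#' @param genotype compact genotype string (e.g. \code{"P--ILP"}).
#' @param design a \linkS4class{LibraryDesign}.
#' @return character vector of genotypes differing at exactly one position;
#'   its length is \code{sum(lengths(allowedResidues(design)) - 1)} (57 for
#'   the default design: 13 + 44).
#' @export
singleMutantNeighborhood <- function(genotype, design) {
    stopifnot(isValidGenotype(genotype, design))
    sym <- strsplit(genotype, "")[[1]]
    out <- character(0)
    for (i in seq_along(sym)) {
        for (a in setdiff(design@allowed[[i]], sym[i])) {
            g <- sym; g[i] <- a
            out <- c(out, paste(g, collapse = ""))
        }
    }
    out
}

#' Probability that a functional variant is sorted correctly at least once
#'
#' With a per-bead false-negative rate r and k-fold oversampling, coverage is
#' 1 - r^k: sevenfold oversampling at r = 0.5 gives > 99%, threefold at
#' r = 0.35 gives > 95%.
#'
#' @param falseNegativeRate per-bead probability of missing a functional
#'   variant, in [0, 1].
#' @param oversampling beads screened per variant (>= 1).
#' @return probability in [0, 1].
#' @export
coverageProbability <- function(falseNegativeRate, oversampling) {
    if (falseNegativeRate < 0 || falseNegativeRate > 1)
        stop("falseNegativeRate must be in [0, 1]")
    if (oversampling < 1) stop("oversampling must be >= 1")
    1 - falseNegativeRate^oversampling
}

#' Recovery-PCR cycle number from sorted bead counts
#'
#' Evaluates the calibration y = -2.5 ln(x) + 39, where x is the number of
#' template beads per reaction, and rounds to the nearest integer. With gate
#' totals split into eight parallel reactions, the low/medium/high gates of
#' the screen (2.1e6 / 2.8e5 / 8.1e4 beads) need 8 / 13 / 16 cycles.
#'
#' @param nBeads total sorted beads for the gate (>= 1).
#' @param nReactions number of parallel recovery reactions (default 8).
#' @return integer cycle count.
#' @export
qpcrCycles <- function(nBeads, nReactions = 8) {
    if (any(nBeads < 1)) stop("nBeads must be >= 1")
    if (any(nReactions < 1)) stop("nReactions must be >= 1")
    as.integer(round(-2.5 * log(nBeads / nReactions) + 39))
}

## ---- design JSON round trip ----

#' Read or write a LibraryDesign as JSON
#'
#' @param design a \linkS4class{LibraryDesign}.
#' @param path file path.
#' @return \code{readLibraryDesign} returns a \linkS4class{LibraryDesign};
#'   \code{writeLibraryDesign} returns \code{path} invisibly.
#' @export
writeLibraryDesign <- function(design, path) {
    obj <- list(
        labels = design@labels,
        allowed = design@allowed,
        insertion = design@insertion,
        refLocus = design@refLocus,
        referenceProtein = design@referenceProtein,
        flank5 = design@flank5, flank3 = design@flank3,
        codonMap = as.list(design@codonMap))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}

#' @rdname writeLibraryDesign
#' @export
readLibraryDesign <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    LibraryDesign(
        labels = obj$labels,
        allowed = lapply(obj$allowed, as.character)[obj$labels],
        insertion = setNames(as.logical(obj$insertion), obj$labels),
        refLocus = setNames(as.integer(obj$refLocus), obj$labels),
        referenceProtein = obj$referenceProtein,
        flank5 = obj$flank5, flank3 = obj$flank3,
        codonMap = unlist(obj$codonMap))
}
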