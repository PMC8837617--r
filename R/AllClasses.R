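#' @import methods
#' @importFrom stats rnorm rpois rbinom runif setNames p.adjust chisq.test
#' @importFrom utils combn head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors DataFrame
NULL

DELETION <- "-"

#' LibraryDesign: a combinatorial randomisation scheme
#'
#' Describes a combinatorially randomised docking-domain library: the ordered
#' randomised positions with their allowed residue sets, whether each position
#' is an optional insertion (absence written as \code{"-"}), the degenerate
#' reference protein (\code{"X"} at substitution positions), the constant DNA
#' flanks used to anchor reads, and a codon table used only by the simulator.
#'
#' The default design models the six-position MKK1 D-domain library: four
#' substitution positions (6, 9, 11, 13; 12 residues each), an optional
#' insertion 7a (12 residues or absent) and an optional Ala insertion 8a,
#' randomised on the reference \code{MPKKKXTPXQXNXAPDG}.
#'
#' @slot labels character vector of position labels, e.g. \code{c("6","7a","8a","9","11","13")}.
#' @slot allowed named list of allowed single-letter residues per position
#'   (\code{"-"} marks an absent insertion).
#' @slot insertion named logical; \code{TRUE} for optional insertion positions.
#' @slot refLocus named integer: for substitution positions the index of the
#'   corresponding \code{"X"} in \code{referenceProtein}; for insertions the
#'   reference index \emph{after} which the residue is inserted.
#' @slot referenceProtein degenerate reference amino-acid string.
#' @slot flank5,flank3 constant DNA context on either side of the domain insert.
#' @slot codonMap named character, one codon per amino acid (simulator only).
#' @export
setClass("LibraryDesign", representation(
    labels = "character",
    allowed = "list",
    insertion = "logical",
    refLocus = "integer",
    referenceProtein = "character",
    flank5 = "character",
    flank3 = "character",
    codonMap = "character"
))

setValidity("LibraryDesign", function(object) {
    msg <- character()
    n <- length(object@labels)
    if (length(object@allowed) != n || length(object@insertion) != n ||
        length(object@refLocus) != n)
        msg <- c(msg, "labels, allowed, insertion and refLocus must have equal length")
    if (any(lengths(object@allowed) == 0L))
        msg <- c(msg, "every position needs a non-empty allowed set")
    ref <- strsplit(object@referenceProtein, "")[[1]]
    xloc <- which(ref == "X")
    sub <- !object@insertion
    if (length(msg) == 0L) {
        if (!setequal(object@refLocus[sub], xloc))
            msg <- c(msg, "substitution positions must map one-to-one onto the X loci of the reference")
        for (i in seq_len(n)) {
            a <- object@allowed[[i]]
            if (any(nchar(a) != 1L))
                msg <- c(msg, "allowed residues must be single characters")
            if (!object@insertion[i] && DELETION %in% a)
                msg <- c(msg, sprintf("'-' is only allowed at insertion positions (position %s)",
                                      object@labels[i]))
        }
    }
    if (length(msg)) msg else TRUE
})

#' FitnessLandscape: the activity model used by the simulator
#'
#' Deterministic activity of a genotype is the sum of per-position residue
#' effects, plus \code{motifBonus} when two residues from \code{phiSet} occupy
#' adjacent randomised positions (adjacency chain 6-7a-9-11-13, skipping an
#' absent 7a), plus any explicit pairwise terms. Per-bead Gaussian noise with
#' sd \code{noiseSd} is added at sort time.
#'
#' @slot phiSet residues counted as large hydrophobics (default L, I).
#' @slot motifBonus activity bonus for an adjacent Phi,Phi pair (>= 0).
#' @slot positionEffects named list (by position label) of named numeric
#'   per-residue additive effects; residues not listed contribute 0.
#' @slot pairwiseEffects data.frame with columns pos_a, res_a, pos_b, res_b,
#'   effect (may have zero rows).
#' @slot customTerm \code{NULL}, or a function taking the genotype symbol
#'   matrix (columns named by position) and returning one additive activity
#'   contribution per genotype; the hook for higher-order terms such as
#'   register-conditional motifs.
#' @slot noiseSd standard deviation of per-bead activity noise.
#' @export
setClass("FitnessLandscape", representation(
    phiSet = "character",
    motifBonus = "numeric",
    positionEffects = "list",
    pairwiseEffects = "data.frame",
    customTerm = "ANY",
    noiseSd = "numeric"
))

setValidity("FitnessLandscape", function(object) {
    if (object@motifBonus < 0) return("motifBonus must be >= 0")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    TRUE
})

#' SortConfig: bead sorting and sequencing parameters
#'
#' @slot beadsPerVariant beads screened per library variant (oversampling).
#' @slot gateThresholds length-2 numeric: noisy activity below the first value
#'   sorts low, at or above the second sorts high, otherwise medium.
#' @slot falsePositiveRate per-bead probability that a nominally low/medium
#'   bead is sorted into the high gate.
#' @slot falseNegativeRate per-bead probability that a nominally high bead is
#'   sorted into a lower gate (low or medium, equiprobably).
#' @slot readsPerBead mean of the Poisson read count per sequenced bead.
#' @slot perBaseErrorRate substitution error probability per sequenced base.
#' @export
setClass("SortConfig", representation(
    beadsPerVariant = "integer",
    gateThresholds = "numeric",
    falsePositiveRate = "numeric",
    falseNegativeRate = "numeric",
    readsPerBead = "numeric",
    perBaseErrorRate = "numeric"
))

setValidity("SortConfig", function(object) {
    rates <- c(object@falsePositiveRate, object@falseNegativeRate,
               object@perBaseErrorRate)
    if (any(rates < 0 | rates > 1)) return("rates must lie in [0, 1]")
    if (object@beadsPerVariant < 1L) return("beadsPerVariant must be >= 1")
    if (length(object@gateThresholds) != 2L ||
        diff(object@gateThresholds) < 0)
        return("gateThresholds must be two non-decreasing values")
    if (object@readsPerBead <= 0) return("readsPerBead must be positive")
    TRUE
})

#' ScoringScheme: alignment scores for the degenerate reference
#'
#' Column scores for global alignment against a reference containing
#' randomised \code{"X"} positions: identical residues score \code{match},
#' any residue against \code{"X"} scores \code{xMatch}, other substitutions
#' score \code{mismatch}. A gap of k columns costs
#' \code{gapOpen + k * gapExtend} (end gaps are penalised identically).
#'
#' @slot match,mismatch,xMatch column scores (+5, -1, +1 by default).
#' @slot gapOpen,gapExtend gap penalties (3 and 5 by default, both >= 0).
#' @export
setClass("ScoringScheme", representation(
    match = "numeric", mismatch = "numeric", xMatch = "numeric",
    gapOpen = "numeric", gapExtend = "numeric"
))

setValidity("ScoringScheme", function(object) {
    if (!(object@match > object@xMatch && object@xMatch > object@mismatch))
        return("scores must satisfy match > xMatch > mismatch")
    if (object@gapOpen < 0 || object@gapExtend < 0)
        return("gap penalties must be >= 0")
    TRUE
})

#' DomainAlignment: one global alignment against the degenerate reference
#'
#' @slot query,reference aligned strings of equal length, gaps as \code{"-"}.
#' @slot score total alignment score under the scheme used.
#' @slot ops per-column operation labels: match, mismatch, x-match,
#'   insertion (gap in reference), deletion (gap in query).
#' @export
setClass("DomainAlignment", representation(
    query = "character", reference = "character",
    score = "numeric", ops = "character"
))

setValidity("DomainAlignment", function(object) {
    qa <- strsplit(object@query, "")[[1]]
    ra <- strsplit(object@reference, "")[[1]]
    if (length(qa) != length(ra)) return("aligned strings must have equal length")
    if (length(object@ops) != length(qa)) return("one op label per column required")
    if (any(qa == "-" & ra == "-")) return("a column cannot be gap against gap")
    TRUE
})

#' GateCountTable: per-genotype read counts in the three activity gates
#'
#' A \linkS4class{SummarizedExperiment} with one \code{"counts"} assay whose
#' rows are genotypes (compact 6-character strings) and whose columns are the
#' gates \code{low}, \code{medium}, \code{high}.
#'
#' @export
setClass("GateCountTable", contains = "SummarizedExperiment")

setValidity("GateCountTable", function(object) {
    a <- SummarizedExperiment::assayNames(object)
    if (!"counts" %in% a) return("a 'counts' assay is required")
    if (!identical(colnames(object), GATES))
        return("columns must be the gates low, medium, high")
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt)))
        return("counts must be non-negative integers")
    if (is.null(rownames(object))) return("rows must be named by genotype")
    TRUE
})

GATES <- c("low", "medium", "high")

#' ActiveSet: genotypes passing the activity filter
#'
#' @slot genotypes character vector of genotypes in the active set.
#' @slot highMin minimum high-gate read count used by the filter.
#' @slot rule identifier of the enrichment rule used.
#' @export
setClass("ActiveSet", representation(
    genotypes = "character", highMin = "numeric", rule = "character"
))

#' SSN: a sequence similarity network over genotypes
#'
#' Simple undirected graph whose vertices are genotypes and whose edges join
#' pairs at Hamming distance exactly 1 over the six randomised positions
#' (an absent insertion is an ordinary symbol).
#'
#' @slot graph an \pkg{igraph} graph with vertex attribute \code{name}.
#' @slot design the \linkS4class{LibraryDesign} the genotypes belong to.
#' @export
setClass("SSN", representation(graph = "ANY", design = "LibraryDesign"))

#' PipelineConfig: resolved configuration of a simulate/analyze run
#'
#' @slot design a \linkS4class{LibraryDesign}.
#' @slot landscape a \linkS4class{FitnessLandscape} (simulation only).
#' @slot sortConfig a \linkS4class{SortConfig} (simulation only).
#' @slot scheme a \linkS4class{ScoringScheme}.
#' @slot cutoffs named numeric, per-gate minimum read counts (low/medium/high).
#' @slot highMin active-set minimum high-gate reads.
#' @slot rule active-set enrichment rule id.
#' @slot phiSet residues treated as Phi in motif analyses.
#' @slot partitionMethod,resolution community detection settings.
#' @slot nVariants number of library variants to simulate.
#' @slot seed global random seed.
#' @export
setClass("PipelineConfig", representation(
    design = "LibraryDesign", landscape = "FitnessLandscape",
    sortConfig = "SortConfig", scheme = "ScoringScheme",
    cutoffs = "numeric", highMin = "numeric", rule = "character",
    phiSet = "character", partitionMethod = "character",
    resolution = "numeric", nVariants = "integer", seed = "integer"
))
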