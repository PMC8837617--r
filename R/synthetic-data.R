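## Synthetic sort-seq generator: a ground-truthed emulation of the bead-based
## screen (activity landscape -> noisy per-bead gate assignment -> per-gate
## merged reads with substitution errors).

#' Construct a FitnessLandscape
#'
#' @param phiSet residues counted as large hydrophobics (default L and I).
#' @param motifBonus bonus for an adjacent Phi,Phi pair along the chain
#'   6-7a-9-11-13 (an absent 7a is skipped, making 6 and 9 adjacent).
#' @param positionEffects named list (position label -> named numeric residue
#'   effects); unlisted residues contribute 0.
#' @param pairwiseEffects data.frame(pos_a, res_a, pos_b, res_b, effect).
#' @param customTerm optional function(symbol matrix) -> numeric vector of
#'   additive higher-order contributions.
#' @param noiseSd per-bead Gaussian activity noise sd.
#' @return a \linkS4class{FitnessLandscape}.
#' @export
FitnessLandscape <- function(phiSet = c("L", "I"), motifBonus = 4,
                             positionEffects = list(),
                             pairwiseEffects = emptyPairwiseEffects(),
                             customTerm = NULL, noiseSd = 0.5) {
    new("FitnessLandscape", phiSet = phiSet, motifBonus = motifBonus,
        positionEffects = positionEffects, pairwiseEffects = pairwiseEffects,
        customTerm = customTerm, noiseSd = noiseSd)
}

#' @rdname FitnessLandscape
#' @export
emptyPairwiseEffects <- function() {
    data.frame(pos_a = character(), res_a = character(),
               pos_b = character(), res_b = character(),
               effect = numeric())
}

#' Default planted landscape for the D-domain library
#'
#' Each Phi residue (L/I) at a chain position contributes +1 and an adjacent
#' Phi,Phi pair adds a bonus of 4, so that with the default gate thresholds
#' (1.5 and 3.5 on the activity scale) the nominally high-sorting variants
#' are exactly the Phi-X-Phi motif carriers (~9.5% of the default library,
#' the same order as the screen's ~5.5% active fraction).
#'
#' @param design a \linkS4class{LibraryDesign} (supplies the chain positions).
#' @param motifBonus,noiseSd see \code{\link{FitnessLandscape}}.
#' @return a \linkS4class{FitnessLandscape}.
#' @export
defaultLandscape <- function(design = defaultLibraryDesign(),
                             motifBonus = 4, noiseSd = 0.5) {
    phi <- c("L", "I")
    eff <- lapply(setNames(chainPositions(design), chainPositions(design)),
                  function(p) {
                      a <- intersect(phi, design@allowed[[p]])
                      setNames(rep(1, length(a)), a)
                  })
    FitnessLandscape(phiSet = phi, motifBonus = motifBonus,
                     positionEffects = eff, noiseSd = noiseSd)
}

# positions participating in motif adjacency: every non-8a position, in order
chainPositions <- function(design) {
    setdiff(design@labels, "8a")
}

#' Two-register landscape: the 8a insertion re-phases the anchoring motif
#'
#' Emulates a registry shift caused by the optional Ala insertion at 8a:
#' variants carrying the insertion are active through a Phi,Phi motif at
#' positions (6, 7a), while variants without it anchor through (11, 13).
#' Because the two registers demand disjoint anchor positions, the active
#' variants with and without 8a are rarely one substitution apart, and the
#' sequence similarity network of the active set splits into an 8a-present
#' and an 8a-absent half.
#'
#' @param design a \linkS4class{LibraryDesign}.
#' @param phiSet residues counted as Phi.
#' @param bonus activity bonus for the register-matched motif.
#' @param noiseSd per-bead activity noise sd.
#' @return a \linkS4class{FitnessLandscape} with the register logic in its
#'   \code{customTerm}.
#' @export
twoRegisterLandscape <- function(design = defaultLibraryDesign(),
                                 phiSet = c("L", "I"), bonus = 4,
                                 noiseSd = 0.5) {
    force(phiSet); force(bonus)
    term <- function(m) {
        withIns <- m[, "8a"] != DELETION
        motifA <- m[, "6"] %in% phiSet & m[, "7a"] %in% phiSet
        motifB <- m[, "11"] %in% phiSet & m[, "13"] %in% phiSet
        bonus * ifelse(withIns, motifA, motifB)
    }
    FitnessLandscape(phiSet = phiSet, motifBonus = 0,
                     positionEffects = list(), customTerm = term,
                     noiseSd = noiseSd)
}

#' Construct a SortConfig
#'
#' Defaults mirror the screen's statistics: sevenfold oversampling, a ~50%
#' per-bead false-negative rate for nominally high beads, an ~8% per-bead
#' false-positive rate for nominally low/medium beads, Poisson(30) reads per
#' bead and no sequencing error.
#'
#' @param beadsPerVariant,gateThresholds,falsePositiveRate,falseNegativeRate
#'   see \linkS4class{SortConfig}.
#' @param readsPerBead,perBaseErrorRate see \linkS4class{SortConfig}.
#' @return a \linkS4class{SortConfig}.
#' @export
SortConfig <- function(beadsPerVariant = 7L, gateThresholds = c(1.5, 3.5),
                       falsePositiveRate = 0.08, falseNegativeRate = 0.5,
                       readsPerBead = 30, perBaseErrorRate = 0) {
    new("SortConfig", beadsPerVariant = as.integer(beadsPerVariant),
        gateThresholds = gateThresholds,
        falsePositiveRate = falsePositiveRate,
        falseNegativeRate = falseNegativeRate,
        readsPerBead = readsPerBead, perBaseErrorRate = perBaseErrorRate)
}

#' Sample genotypes uniformly without replacement
#'
#' @param design a \linkS4class{LibraryDesign}.
#' @param nVariants number of distinct genotypes (<= librarySize(design));
#'   asking for the full size enumerates the library exhaustively.
#' @param seed integer random seed (sampling is deterministic given the seed).
#' @return character vector of genotypes.
#' @export
sampleLibrary <- function(design, nVariants, seed = 1L) {
    N <- librarySize(design)
    if (nVariants > N)
        stop("cannot sample ", nVariants, " distinct variants from a library of ", N)
    if (nVariants == N) return(enumerateGenotypes(design))
    set.seed(seed)
    indexToGenotype(sample.int(N, nVariants), design)
}

#' Deterministic activity score of genotypes under a landscape
#'
#' Sum of per-position residue effects, plus \code{motifBonus} when any two
#' adjacent chain positions (6-7a-9-11-13, skipping an absent 7a) both carry
#' a Phi residue, plus explicit pairwise terms.
#'
#' @param genotypes character vector of genotypes.
#' @param landscape a \linkS4class{FitnessLandscape}.
#' @param design a \linkS4class{LibraryDesign}.
#' @return numeric vector of activities.
#' @export
activityScore <- function(genotypes, landscape, design) {
    m <- symbolMatrix(genotypes)
    colnames(m) <- design@labels
    score <- numeric(length(genotypes))
    for (p in names(landscape@positionEffects)) {
        eff <- landscape@positionEffects[[p]]
        hit <- match(m[, p], names(eff))
        score <- score + ifelse(is.na(hit), 0, eff[hit])
    }
    score <- score + landscape@motifBonus * hasPhiMotif(genotypes, design,
                                                       landscape@phiSet)
    pw <- landscape@pairwiseEffects
    if (nrow(pw)) {
        for (k in seq_len(nrow(pw))) {
            hit <- m[, pw$pos_a[k]] == pw$res_a[k] & m[, pw$pos_b[k]] == pw$res_b[k]
            score <- score + pw$effect[k] * hit
        }
    }
    if (!is.null(landscape@customTerm))
        score <- score + landscape@customTerm(m)
    unname(score)
}

#' @describeIn activityScore TRUE where a genotype carries at least one
#'   adjacent Phi,Phi pair along the chain (the planted Phi-X-Phi motif).
#' @param phiSet residues counted as Phi.
#' @export
hasPhiMotif <- function(genotypes, design, phiSet = c("L", "I")) {
    m <- symbolMatrix(genotypes)
    colnames(m) <- design@labels
    chain <- chainPositions(design)
    vapply(seq_along(genotypes), function(r) {
        s <- m[r, chain]
        s <- s[s != DELETION]
        any(s[-length(s)] %in% phiSet & s[-1] %in% phiSet)
    }, NA)
}

#' Simulate the bead sort of a genotype list
#'
#' Each genotype contributes \code{beadsPerVariant} beads; each bead receives
#' Gaussian activity noise and a nominal gate from the thresholds, then gate
#' misassignment: a nominally high bead is demoted (to low or medium,
#' equiprobably) with probability \code{falseNegativeRate}, and a nominally
#' low/medium bead is promoted to high with probability
#' \code{falsePositiveRate}.
#'
#' @param genotypes character vector of genotypes.
#' @param landscape a \linkS4class{FitnessLandscape}.
#' @param config a \linkS4class{SortConfig}.
#' @param design a \linkS4class{LibraryDesign}.
#' @param seed integer random seed.
#' @return data.frame with one row per bead: genotype, activity (noise-free),
#'   noisyActivity, nominalGate, gate.
#' @export
simulateSort <- function(genotypes, landscape, config, design, seed = 1L) {
    set.seed(seed)
    k <- config@beadsPerVariant
    g <- rep(genotypes, each = k)
    act <- rep(activityScore(genotypes, landscape, design), each = k)
    noisy <- act + rnorm(length(g), sd = landscape@noiseSd)
    th <- config@gateThresholds
    nominal <- ifelse(noisy < th[1], "low", ifelse(noisy >= th[2], "high", "medium"))
    gate <- nominal
    hi <- nominal == "high"
    demote <- hi & runif(length(g)) < config@falseNegativeRate
    gate[demote] <- sample(c("low", "medium"), sum(demote), replace = TRUE)
    promote <- !hi & runif(length(g)) < config@falsePositiveRate
    gate[promote] <- "high"
    data.frame(genotype = g, activity = act, noisyActivity = noisy,
               nominalGate = factor(nominal, GATES),
               gate = factor(gate, GATES))
}

#' DNA amplicon insert encoding a genotype
#'
#' Concatenates the 5' flank, one codon per residue of the full-length
#' protein (absent insertions contribute no codon) and the 3' flank.
#'
#' @param genotypes character vector of genotypes.
#' @param design a \linkS4class{LibraryDesign} (supplies flanks and codons).
#' @return character vector of DNA strings.
#' @export
encodeGenotypeDNA <- function(genotypes, design) {
    prot <- genotypeToProtein(genotypes, design)
    aa <- strsplit(prot, "")
    missing <- setdiff(unique(unlist(aa)), names(design@codonMap))
    if (length(missing))
        stop("no codon for residue(s): ", paste(missing, collapse = ", "))
    vapply(aa, function(p)
        paste0(design@flank5, paste(design@codonMap[p], collapse = ""),
               design@flank3), "")
}

#' Generate per-gate FASTQ files and a truth table from a simulated sort
#'
#' Each bead yields a Poisson(\code{readsPerBead}) number of merged reads of
#' its genotype's amplicon, with independent per-base substitution errors at
#' \code{perBaseErrorRate}. Reads are written as one FASTQ per gate (Sanger
#' encoding, constant quality), together with a per-genotype truth table TSV
#' (true activity plus bead and read counts per gate) and a JSON echo of the
#' configuration. Output is byte-identical for identical seed and config.
#'
#' @param beads bead table from \code{\link{simulateSort}}.
#' @param config a \linkS4class{SortConfig}.
#' @param design a \linkS4class{LibraryDesign}.
#' @param dir output directory (created if needed).
#' @param seed integer random seed.
#' @return invisibly, a list with fastq paths, the truth-table path, and the
#'   per-gate read counts.
#' @export
generateReads <- function(beads, config, design, dir, seed = 1L) {
    set.seed(seed)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    amplicon <- encodeGenotypeDNA(levels(factor(beads$genotype)), design)
    names(amplicon) <- levels(factor(beads$genotype))
    nreads <- rpois(nrow(beads), config@readsPerBead)
    fastq <- setNames(file.path(dir, paste0(GATES, ".fastq")), GATES)
    counts <- setNames(integer(3), GATES)
    for (g in GATES) {
        sel <- beads$gate == g
        dna <- rep(amplicon[as.character(beads$genotype[sel])], nreads[sel])
        dna <- addSequencingErrors(dna, config@perBaseErrorRate)
        ids <- sprintf("%s_read%06d", g, seq_along(dna))
        writeFastq(dna, ids, fastq[[g]])
        counts[[g]] <- length(dna)
    }
    truth <- truthTable(beads, nreads)
    truth_path <- file.path(dir, "truth.tsv")
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
        list(beadsPerVariant = config@beadsPerVariant,
             gateThresholds = config@gateThresholds,
             falsePositiveRate = config@falsePositiveRate,
             falseNegativeRate = config@falseNegativeRate,
             readsPerBead = config@readsPerBead,
             perBaseErrorRate = config@perBaseErrorRate, seed = seed),
        file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
    invisible(list(fastq = fastq, truth = truth_path, readCounts = counts))
}

# per-genotype bead/read counts by gate
truthTable <- function(beads, nreads) {
    gts <- sort(unique(beads$genotype))
    bead_tab <- table(factor(beads$genotype, gts), beads$gate)
    read_tab <- tapply(nreads, list(factor(beads$genotype, gts), beads$gate),
                       sum, default = 0L)
    act <- tapply(beads$activity, factor(beads$genotype, gts), `[`, 1L)
    data.frame(genotype = gts, activity = as.numeric(act),
               beads_low = as.integer(bead_tab[, "low"]),
               beads_medium = as.integer(bead_tab[, "medium"]),
               beads_high = as.integer(bead_tab[, "high"]),
               reads_low = as.integer(read_tab[, "low"]),
               reads_medium = as.integer(read_tab[, "medium"]),
               reads_high = as.integer(read_tab[, "high"]))
}

addSequencingErrors <- function(dna, rate) {
    if (rate <= 0 || length(dna) == 0L) return(dna)
    bases <- c("A", "C", "G", "T")
    L <- nchar(dna)
    nerr <- rbinom(length(dna), L, rate)
    for (i in which(nerr > 0L)) {
        pos <- sample.int(L[i], nerr[i])
        s <- strsplit(dna[i], "")[[1]]
        # substitute with a uniformly chosen different base
        s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1L), "")
        dna[i] <- paste(s, collapse = "")
    }
    dna
}

writeFastq <- function(dna, ids, path) {
    if (length(dna) == 0L) {
        file.create(path)
        return(invisible(path))
    }
    x <- Biostrings::DNAStringSet(dna)
    names(x) <- ids
    qual <- Biostrings::BStringSet(strrep("I", nchar(dna)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
    invisible(path)
}

#' Per-gate read counts straight from a bead table
#'
#' Draws the same Poisson read counts as \code{\link{generateReads}} and
#' aggregates them per genotype and gate without materialising read
#' sequences; the result is distributed identically to counting error-free
#' reads, and is the fast path for simulation studies.
#'
#' @param beads bead table from \code{\link{simulateSort}}.
#' @param config a \linkS4class{SortConfig}.
#' @param seed integer random seed.
#' @return a \linkS4class{GateCountTable}.
#' @export
simulateGateCounts <- function(beads, config, seed = 1L) {
    set.seed(seed)
    nreads <- rpois(nrow(beads), config@readsPerBead)
    gts <- sort(unique(beads$genotype))
    tab <- tapply(nreads, list(factor(beads$genotype, gts), beads$gate),
                  sum, default = 0L)
    GateCountTable(matrix(as.integer(tab), ncol = 3,
                          dimnames = list(gts, GATES)))
}
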