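## End-to-end plumbing: a resolved configuration object, the simulate stage
## (design -> per-gate FASTQ + truth) and the analyze stage (FASTQ -> calls
## -> counts -> active set -> enrichment/epistasis -> SSN), each writing its
## outputs and a machine-readable summary.

#' Construct a PipelineConfig
#'
#' @param design,landscape,sortConfig,scheme component configurations
#'   (defaults: the packaged D-domain design, the planted Phi-X-Phi
#'   landscape, the screen-like sort parameters, the degenerate scoring
#'   scheme).
#' @param cutoffs per-gate observation cutoffs (low/medium/high).
#' @param highMin,rule active-set filter parameters.
#' @param phiSet residues treated as Phi in motif analyses.
#' @param partitionMethod,resolution community detection settings.
#' @param nVariants number of variants to simulate.
#' @param seed global random seed.
#' @return a \linkS4class{PipelineConfig}.
#' @export
PipelineConfig <- function(design = defaultLibraryDesign(),
                           landscape = defaultLandscape(design),
                           sortConfig = SortConfig(),
                           scheme = ScoringScheme(),
                           cutoffs = c(low = 3, medium = 5, high = 10),
                           highMin = 51, rule = "freq_above_lower",
                           phiSet = c("L", "I"),
                           partitionMethod = "leiden", resolution = 1,
                           nVariants = 10000L, seed = 1L) {
    new("PipelineConfig", design = design, landscape = landscape,
        sortConfig = sortConfig, scheme = scheme, cutoffs = cutoffs,
        highMin = highMin, rule = rule, phiSet = phiSet,
        partitionMethod = partitionMethod, resolution = resolution,
        nVariants = as.integer(nVariants), seed = as.integer(seed))
}

configEcho <- function(config, dir) {
    sc <- config@sortConfig
    jsonlite::write_json(list(
        nVariants = config@nVariants, seed = config@seed,
        cutoffs = as.list(config@cutoffs), highMin = config@highMin,
        rule = config@rule, phiSet = config@phiSet,
        partitionMethod = config@partitionMethod,
        resolution = config@resolution,
        sortConfig = list(beadsPerVariant = sc@beadsPerVariant,
                          gateThresholds = sc@gateThresholds,
                          falsePositiveRate = sc@falsePositiveRate,
                          falseNegativeRate = sc@falseNegativeRate,
                          readsPerBead = sc@readsPerBead,
                          perBaseErrorRate = sc@perBaseErrorRate),
        version = as.character(utils::packageVersion("ddscan"))),
        file.path(dir, "run_config.json"), auto_unbox = TRUE, digits = NA)
}

#' Run the simulation stage
#'
#' Samples \code{nVariants} genotypes, simulates the bead sort and writes
#' three per-gate FASTQ files, the truth table and a config echo to
#' \code{dir}. Deterministic given \code{seed}.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param dir output directory.
#' @return invisibly, the \code{\link{generateReads}} result plus the design
#'   path.
#' @export
runSimulate <- function(config, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    genotypes <- sampleLibrary(config@design, config@nVariants, config@seed)
    beads <- simulateSort(genotypes, config@landscape, config@sortConfig,
                          config@design, seed = config@seed + 1L)
    if (!any(beads$gate == "high"))
        warning("no beads sorted into the high gate")
    out <- generateReads(beads, config@sortConfig, config@design, dir,
                         seed = config@seed + 2L)
    writeLibraryDesign(config@design, file.path(dir, "design.json"))
    configEcho(config, dir)
    invisible(c(out, list(design = file.path(dir, "design.json"))))
}

#' Run the analysis stage
#'
#' Processes the three per-gate FASTQs through extraction, alignment and
#' genotype calling, counts genotypes per gate, applies the read cutoffs and
#' the active-set filter, computes entropies, single/joint/epistatic
#' enrichment and chi-squared tests, builds and partitions the SSN, and
#' writes TSV/JSON/GraphML outputs plus a run summary to \code{dir}.
#'
#' @param fastq named character vector of FASTQ paths (low/medium/high).
#' @param config a \linkS4class{PipelineConfig}.
#' @param dir output directory.
#' @return invisibly, a list with the main in-memory results (calls, counts,
#'   active set, partition, summary).
#' @export
runAnalyze <- function(fastq, config, dir) {
    stopifnot(all(GATES %in% names(fastq)))
    missing <- !file.exists(fastq[GATES])
    if (any(missing))
        stop("missing input FASTQ: ", paste(fastq[GATES][missing], collapse = ", "))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    design <- config@design

    calls <- lapply(setNames(GATES, GATES), function(g)
        processReads(fastq[[g]], design, config@scheme))
    for (g in GATES)
        utils::write.table(calls[[g]]$calls,
                           file.path(dir, paste0("calls_", g, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    counts <- countGenotypes(lapply(calls, function(x) x$calls))
    utils::write.table(data.frame(genotype = rownames(gateCounts(counts)),
                                  gateCounts(counts)),
                       file.path(dir, "counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    observed <- applyReadCutoffs(counts, config@cutoffs)
    act <- activeSet(counts, highMin = config@highMin,
                     rule = if (config@rule == "none") "none" else "freq_above_lower")
    writeLines(activeGenotypes(act), file.path(dir, "active_set.txt"))
    entropy <- positionEntropy(rownames(gateCounts(counts)), design,
                               weights = gateCounts(counts)[, "low"])
    enr <- singleEnrichment(act, design)
    utils::write.table(enr, file.path(dir, "single_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    chi2 <- chi2Pairwise(act, design)
    utils::write.table(chi2, file.path(dir, "chi2_pairwise.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    if (length(act) > 0L) {
        ssn <- buildSSN(act, design)
        lc <- largestComponent(ssn)
        part <- partitionSSN(lc$ssn, method = config@partitionMethod,
                             resolution = config@resolution, seed = config@seed)
        exportSSN(ssn, graphml = file.path(dir, "ssn.graphml"),
                  edges = file.path(dir, "ssn_edges.tsv"))
        utils::write.table(
            data.frame(genotype = names(part$membership),
                       cluster = unname(part$membership)),
            file.path(dir, "clusters.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
    } else {
        warning("active set is empty; skipping the SSN stage")
        ssn <- NULL
        lc <- list(fraction = NA_real_)
        part <- list(membership = integer(0), nClusters = 0L,
                     modularity = NA_real_)
    }

    summary <- list(
        reads = lapply(calls, function(x) as.list(x$summary)),
        observedUnion = observed$union,
        activeSetSize = length(act),
        entropy = as.list(entropy),
        largestComponentFraction = lc$fraction,
        nClusters = part$nClusters,
        modularity = part$modularity)
    jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    configEcho(config, dir)
    invisible(list(calls = calls, counts = counts, active = act,
                   observed = observed, entropy = entropy, ssn = ssn,
                   partition = part, summary = summary))
}
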