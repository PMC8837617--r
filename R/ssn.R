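## Sequence similarity network: exact Hamming-distance-1 graph over active
## genotypes, built by neighbourhood hashing (per-position wildcard keys)
## rather than all-pairs comparison; components, Leiden/Louvain partitions,
## modularity and centrality summaries, per-cluster sequence content.

#' Hamming distance between genotypes
#'
#' Number of the randomised positions at which two genotypes differ; an
#' absent insertion is an ordinary symbol, so gaining or losing 7a/8a counts
#' as one difference.
#'
#' @param g1,g2 genotype strings (recycled to equal length).
#' @param design a \linkS4class{LibraryDesign}; both genotypes must validate.
#' @return integer vector of distances.
#' @export
hammingDistance <- function(g1, g2, design) {
    if (!all(isValidGenotype(g1, design)) || !all(isValidGenotype(g2, design)))
        stop("genotypes must be valid under the same design")
    n <- max(length(g1), length(g2))
    g1 <- rep_len(g1, n); g2 <- rep_len(g2, n)
    m1 <- symbolMatrix(g1); m2 <- symbolMatrix(g2)
    as.integer(rowSums(m1 != m2))
}

#' Build the sequence similarity network
#'
#' Vertices are the (unique) genotypes; edges join every pair at Hamming
#' distance exactly 1. Edges are found by hashing each genotype under six
#' per-position wildcard keys and joining all pairs within a bucket, which
#' is exact and avoids the quadratic all-pairs scan.
#'
#' @param active genotypes (character vector or \linkS4class{ActiveSet}).
#' @param design a \linkS4class{LibraryDesign}.
#' @return an \linkS4class{SSN}.
#' @export
buildSSN <- function(active, design) {
    g <- unique(asGenotypes(active))
    if (length(g) == 0L) stop("no genotypes")
    if (!all(isValidGenotype(g, design))) stop("genotypes outside the design")
    n <- length(g)
    L <- nchar(g[1])
    from <- integer(0); to <- integer(0)
    for (i in seq_len(L)) {
        key <- paste0(substr(g, 1L, i - 1L), "*", substr(g, i + 1L, L))
        buckets <- split(seq_len(n), key)
        buckets <- buckets[lengths(buckets) > 1L]
        for (b in buckets) {
            pr <- combn(b, 2L)
            from <- c(from, pr[1L, ]); to <- c(to, pr[2L, ])
        }
    }
    graph <- igraph::make_empty_graph(n, directed = FALSE)
    graph <- igraph::set_vertex_attr(graph, "name", value = g)
    if (length(from))
        graph <- igraph::add_edges(graph, rbind(from, to))
    new("SSN", graph = graph, design = design)
}

#' @rdname buildSSN
#' @param ssn an \linkS4class{SSN}.
#' @return \code{ssnGraph}: the underlying \pkg{igraph} graph;
#'   \code{ssnGenotypes}: the vertex genotypes.
#' @export
ssnGraph <- function(ssn) ssn@graph

#' @rdname buildSSN
#' @export
ssnGenotypes <- function(ssn) igraph::V(ssn@graph)$name

setMethod("show", "SSN", function(object) {
    cat("SSN:", igraph::vcount(object@graph), "genotypes,",
        igraph::ecount(object@graph), "Hamming-1 edges,",
        igraph::count_components(object@graph), "component(s)\n")
})

#' Largest connected subgraph of an SSN
#'
#' @param ssn an \linkS4class{SSN}.
#' @return list(ssn = the induced \linkS4class{SSN}, fraction = share of
#'   nodes retained). A size tie is broken towards the component containing
#'   the lexicographically smallest genotype.
#' @export
largestComponent <- function(ssn) {
    comp <- igraph::components(ssn@graph)
    big <- which(comp$csize == max(comp$csize))
    if (length(big) > 1L) {
        firsts <- vapply(big, function(k)
            min(igraph::V(ssn@graph)$name[comp$membership == k]), "")
        big <- big[order(firsts)[1L]]
    }
    keep <- which(comp$membership == big)
    sub <- igraph::induced_subgraph(ssn@graph, keep)
    list(ssn = new("SSN", graph = sub, design = ssn@design),
         fraction = length(keep) / igraph::vcount(ssn@graph))
}

#' Partition an SSN into communities
#'
#' Leiden (default, modularity objective) or Louvain community detection,
#' seed-controlled for determinism. The reported modularity is the standard
#' Newman-Girvan Q of the returned labels and can be recomputed independently
#' with \code{\link{ssnModularity}}.
#'
#' @param ssn an \linkS4class{SSN} (typically the largest component).
#' @param method \code{"leiden"} or \code{"louvain"}.
#' @param resolution resolution parameter (1 = plain modularity).
#' @param seed integer random seed.
#' @param nIterations Leiden refinement iterations.
#' @param nRestarts independent restarts; the partition with the best
#'   modularity is kept (community detection only finds local optima, so a
#'   few seeded restarts make the result much more stable).
#' @return list(membership = named integer cluster labels, modularity,
#'   method, nClusters).
#' @export
partitionSSN <- function(ssn, method = c("leiden", "louvain"),
                         resolution = 1, seed = 1L, nIterations = 10L,
                         nRestarts = 5L) {
    method <- match.arg(method)
    if (igraph::vcount(ssn@graph) == 0L) stop("empty graph")
    best <- NULL
    for (r in seq_len(nRestarts)) {
        set.seed(seed + r - 1L)
        cl <- if (method == "leiden") {
            igraph::cluster_leiden(ssn@graph,
                                   objective_function = "modularity",
                                   resolution = resolution,
                                   n_iterations = nIterations)
        } else {
            igraph::cluster_louvain(ssn@graph, resolution = resolution)
        }
        membership <- setNames(as.integer(igraph::membership(cl)),
                               igraph::V(ssn@graph)$name)
        Q <- igraph::modularity(ssn@graph, membership)
        if (is.null(best) || Q > best$modularity)
            best <- list(membership = membership, modularity = Q,
                         method = method,
                         nClusters = length(unique(membership)))
    }
    best
}

#' Recompute Newman-Girvan modularity from labels and edges
#'
#' Direct evaluation of Q = sum_c [ e_c/m - (d_c / 2m)^2 ] over clusters,
#' independent of the community-detection code path.
#'
#' @param ssn an \linkS4class{SSN}.
#' @param membership named (by genotype) or vertex-ordered cluster labels.
#' @return Q in [-0.5, 1].
#' @export
ssnModularity <- function(ssn, membership) {
    g <- ssn@graph
    if (!is.null(names(membership)))
        membership <- membership[igraph::V(g)$name]
    m <- igraph::ecount(g)
    if (m == 0L) return(0)
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    same <- membership[ends[, 1]] == membership[ends[, 2]]
    deg <- igraph::degree(g)
    e_c <- tapply(c(same, same) / 2, membership[c(ends[, 1], ends[, 2])], sum)
    d_c <- tapply(deg, membership, sum)
    clusters <- union(names(d_c), names(e_c))
    e_c <- ifelse(is.na(e_c[clusters]), 0, e_c[clusters])
    sum(e_c / m - (d_c[clusters] / (2 * m))^2)
}

#' Per-node centrality scores
#'
#' Degree, betweenness, closeness and eigenvector centrality; closeness and
#' eigenvector centrality are computed within each connected component.
#'
#' @param ssn an \linkS4class{SSN}.
#' @return data.frame(genotype, degree, betweenness, closeness, eigenvector).
#' @export
centralitySummary <- function(ssn) {
    g <- ssn@graph
    if (igraph::vcount(g) == 0L) stop("empty graph")
    out <- data.frame(
        genotype = igraph::V(g)$name,
        degree = unname(igraph::degree(g)),
        betweenness = unname(igraph::betweenness(g)),
        closeness = NA_real_, eigenvector = NA_real_)
    comp <- igraph::components(g)
    for (k in seq_len(comp$no)) {
        idx <- which(comp$membership == k)
        sub <- igraph::induced_subgraph(g, idx)
        out$closeness[idx] <- if (length(idx) > 1L)
            unname(igraph::closeness(sub)) else 0
        out$eigenvector[idx] <- unname(igraph::eigen_centrality(sub)$vector)
    }
    out
}

#' Position frequency matrix of a set of genotypes
#'
#' @param genotypes character vector of genotypes.
#' @param design a \linkS4class{LibraryDesign}.
#' @return numeric matrix, rows = residues (union of allowed sets, including
#'   \code{"-"}), columns = positions; each column sums to 1.
#' @export
positionFrequencyMatrix <- function(genotypes, design) {
    m <- symbolMatrix(genotypes)
    residues <- sort(unique(unlist(design@allowed)))
    out <- vapply(seq_along(design@labels), function(i)
        as.numeric(table(factor(m[, i], residues))) / length(genotypes),
        numeric(length(residues)))
    dimnames(out) <- list(residues, design@labels)
    out
}

#' Sequence content of one cluster
#'
#' @param ssn an \linkS4class{SSN}.
#' @param membership cluster labels from \code{\link{partitionSSN}}.
#' @param cluster a cluster label.
#' @param fasta optional path: writes the member sequences as FASTA
#'   (genotype-space records of fixed length, \code{"-"} for an absent
#'   insertion; with \code{fullLength = TRUE}, variable-length full-domain
#'   peptides instead).
#' @param fullLength write full-length peptides rather than 6-symbol
#'   genotypes.
#' @return list(genotypes = members in sorted order, pfm = position
#'   frequency matrix).
#' @export
clusterContent <- function(ssn, membership, cluster, fasta = NULL,
                           fullLength = FALSE) {
    members <- sort(names(membership)[membership == cluster])
    if (length(members) == 0L) stop("empty cluster")
    if (!is.null(fasta)) {
        seqs <- if (fullLength) genotypeToProtein(members, ssn@design) else members
        x <- Biostrings::AAStringSet(seqs)
        names(x) <- members
        Biostrings::writeXStringSet(x, fasta)
    }
    list(genotypes = members,
         pfm = positionFrequencyMatrix(members, ssn@design))
}

#' Export an SSN as GraphML and an edge-list TSV
#'
#' @param ssn an \linkS4class{SSN}.
#' @param graphml,edges output paths (either may be NULL to skip).
#' @return invisibly, the paths written.
#' @export
exportSSN <- function(ssn, graphml = NULL, edges = NULL) {
    if (!is.null(graphml))
        igraph::write_graph(ssn@graph, graphml, format = "graphml")
    if (!is.null(edges)) {
        e <- igraph::as_edgelist(ssn@graph)
        utils::write.table(data.frame(from = e[, 1], to = e[, 2]), edges,
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(c(graphml = graphml, edges = edges))
}
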