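## Genotype utilities. A genotype is a compact string with one symbol per
## randomised position in design order (default 6, 7a, 8a, 9, 11, 13); "-"
## marks an absent insertion. The long serialisation "6:P|7a:-|..." and the
## unicode delta alias are accepted on input.

#' Genotype validation and serialisation
#'
#' @param genotypes character vector of compact genotype strings.
#' @param design a \linkS4class{LibraryDesign}.
#' @return \code{isValidGenotype}: logical vector; \code{formatGenotype}: the
#'   long form \code{"6:P|7a:-|8a:-|9:I|11:L|13:P"}; \code{parseGenotype}:
#'   compact strings from either serialisation.
#' @export
isValidGenotype <- function(genotypes, design) {
    n <- length(design@labels)
    ok <- nchar(genotypes) == n
    if (!any(ok)) return(ok)
    m <- symbolMatrix(genotypes[ok])
    good <- rep(TRUE, sum(ok))
    for (i in seq_len(n))
        good <- good & m[, i] %in% design@allowed[[i]]
    ok[ok] <- good
    ok
}

#' @rdname isValidGenotype
#' @export
formatGenotype <- function(genotypes, design) {
    m <- symbolMatrix(genotypes)
    apply(m, 1L, function(s)
        paste(paste0(design@labels, ":", s), collapse = "|"))
}

#' @rdname isValidGenotype
#' @export
parseGenotype <- function(genotypes, design) {
    g <- gsub("\u0394", DELETION, genotypes)  # unicode delta alias
    long <- grepl("|", g, fixed = TRUE)
    g[long] <- vapply(strsplit(g[long], "|", fixed = TRUE), function(parts) {
        kv <- strsplit(parts, ":", fixed = TRUE)
        sym <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
        paste(sym[design@labels], collapse = "")
    }, "")
    bad <- !isValidGenotype(g, design)
    if (any(bad))
        stop("invalid genotype(s): ", paste(head(genotypes[bad], 5), collapse = ", "))
    g
}

# split genotypes into an n x positions character matrix
symbolMatrix <- function(genotypes) {
    matrix(unlist(strsplit(genotypes, ""), use.names = FALSE),
           nrow = length(genotypes), byrow = TRUE)
}

#' Full-length protein sequence of genotypes
#'
#' Substitutes the X positions of the reference and inserts the 7a/8a
#' residues after their reference loci; absent insertions contribute nothing.
#' The wild-type genotype \code{"P--ILP"} maps to \code{MPKKKPTPIQLNPAPDG}.
#'
#' @param genotypes character vector of genotype strings.
#' @param design a \linkS4class{LibraryDesign}.
#' @return character vector of protein sequences (length 17-19 by default).
#' @export
genotypeToProtein <- function(genotypes, design) {
    stopifnot(all(isValidGenotype(genotypes, design)))
    ref <- strsplit(design@referenceProtein, "")[[1]]
    m <- symbolMatrix(genotypes)
    sub <- which(!design@insertion)
    ins <- which(design@insertion)
    vapply(seq_along(genotypes), function(r) {
        s <- ref
        s[design@refLocus[sub]] <- m[r, sub]
        # insert from the rightmost locus so earlier indices stay valid
        for (i in ins[order(design@refLocus[ins], decreasing = TRUE)]) {
            if (m[r, i] != DELETION) {
                at <- design@refLocus[i]
                s <- append(s, m[r, i], after = at)
            }
        }
        paste(s, collapse = "")
    }, "")
}

# genotype at a given mixed-radix index (1-based) of the design product space
indexToGenotype <- function(idx, design) {
    sizes <- lengths(design@allowed)
    n <- length(sizes)
    out <- matrix("", nrow = length(idx), ncol = n)
    rem <- idx - 1
    for (i in n:1) {
        out[, i] <- design@allowed[[i]][(rem %% sizes[i]) + 1]
        rem <- rem %/% sizes[i]
    }
    apply(out, 1L, paste, collapse = "")
}

#' Enumerate every genotype of a (small) design
#'
#' @param design a \linkS4class{LibraryDesign}.
#' @return character vector of length \code{librarySize(design)}, in
#'   mixed-radix order.
#' @export
enumerateGenotypes <- function(design) {
    n <- librarySize(design)
    indexToGenotype(seq_len(n), design)
}
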