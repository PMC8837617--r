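## Variant recovery from merged amplicon reads: flank-anchored extraction,
## translation, global alignment to the degenerate reference and genotype
## calling with insertion-registry resolution.

#' Construct a ScoringScheme
#'
#' The degenerate-reference scheme: identical residues +5, any residue
#' against a randomised X position +1, other substitutions -1; a gap of k
#' columns costs gapOpen + k * gapExtend (3 + 5k by default), end gaps
#' included. These values make the wild-type 17-mer score 13*5 + 4*1 = 69
#' against \code{MPKKKXTPXQXNXAPDG}.
#'
#' @param match,mismatch,xMatch,gapOpen,gapExtend see \linkS4class{ScoringScheme}.
#' @return a \linkS4class{ScoringScheme}.
#' @export
ScoringScheme <- function(match = 5, mismatch = -1, xMatch = 1,
                          gapOpen = 3, gapExtend = 5) {
    new("ScoringScheme", match = match, mismatch = mismatch, xMatch = xMatch,
        gapOpen = gapOpen, gapExtend = gapExtend)
}

#' Extract the domain insert from merged reads
#'
#' Locates the constant 5' and 3' flanks and keeps the insert when its length
#' is a codon multiple consistent with 0..k insertions (k = number of
#' insertion positions in the design). Failures are categorised, never
#' raised: \code{no-anchor} (a flank missing), \code{ambiguous} (a flank
#' matching more than once), \code{bad-char} (non-ACGTN characters),
#' \code{bad-length}.
#'
#' @param reads character vector of merged read sequences.
#' @param design a \linkS4class{LibraryDesign}.
#' @return data.frame(read = input, insert, status, reason).
#' @export
findDDomain <- function(reads, design) {
    n <- length(reads)
    insert <- rep(NA_character_, n)
    reason <- rep(NA_character_, n)
    status <- rep("ok", n)
    bad <- grepl("[^ACGTN]", reads)
    status[bad] <- "rejected"; reason[bad] <- "bad-char"
    todo <- which(!bad)
    m5 <- gregexpr(design@flank5, reads[todo], fixed = TRUE)
    m3 <- gregexpr(design@flank3, reads[todo], fixed = TRUE)
    base_len <- 3L * nchar(design@referenceProtein)
    ok_len <- base_len + 3L * (0:sum(design@insertion))
    for (j in seq_along(todo)) {
        i <- todo[j]
        p5 <- m5[[j]]; p3 <- m3[[j]]
        if (p5[1] == -1L || p3[1] == -1L) {
            status[i] <- "rejected"; reason[i] <- "no-anchor"
        } else if (length(p5) > 1L || length(p3) > 1L) {
            status[i] <- "rejected"; reason[i] <- "ambiguous"
        } else {
            from <- p5[1] + nchar(design@flank5)
            to <- p3[1] - 1L
            len <- to - from + 1L
            if (!len %in% ok_len) {
                status[i] <- "rejected"; reason[i] <- "bad-length"
            } else insert[i] <- substr(reads[i], from, to)
        }
    }
    data.frame(read = reads, insert = insert, status = status, reason = reason)
}

#' Translate domain inserts with the standard genetic code
#'
#' @param dna character vector of in-frame DNA inserts.
#' @return data.frame(protein, status, reason); a codon containing N gives
#'   \code{ambiguous-base}, an in-frame stop gives \code{stop-codon}, a
#'   length not divisible by 3 gives \code{bad-length}.
#' @export
translateInsert <- function(dna) {
    n <- length(dna)
    protein <- rep(NA_character_, n)
    status <- rep("ok", n); reason <- rep(NA_character_, n)
    badlen <- nchar(dna) %% 3L != 0L
    status[badlen] <- "rejected"; reason[badlen] <- "bad-length"
    code <- Biostrings::GENETIC_CODE
    for (i in which(!badlen)) {
        codons <- substring(dna[i], seq(1, nchar(dna[i]), 3),
                            seq(3, nchar(dna[i]), 3))
        aa <- code[codons]
        if (anyNA(aa)) {
            status[i] <- "rejected"; reason[i] <- "ambiguous-base"
        } else if (any(aa == "*")) {
            status[i] <- "rejected"; reason[i] <- "stop-codon"
        } else protein[i] <- paste(aa, collapse = "")
    }
    data.frame(protein = protein, status = status, reason = reason)
}

# column score of query residue q against reference residue r
columnScore <- function(q, r, scheme) {
    ifelse(r == "X", scheme@xMatch,
           ifelse(q == r, scheme@match, scheme@mismatch))
}

#' Global alignment against the degenerate reference
#'
#' Needleman-Wunsch with affine gaps (Gotoh recursion); end gaps are
#' penalised like internal gaps because query and reference are both
#' full-length domains. Traceback ties are broken diagonal > up (gap in
#' reference) > left (gap in query), which never changes the score.
#'
#' @param query,reference protein strings (reference may contain X).
#' @param scheme a \linkS4class{ScoringScheme}.
#' @return a \linkS4class{DomainAlignment}.
#' @export
alignGlobal <- function(query, reference, scheme = ScoringScheme()) {
    q <- strsplit(query, "")[[1]]
    r <- strsplit(reference, "")[[1]]
    n <- length(q); m <- length(r)
    if (n == 0L || m == 0L) stop("sequences must be non-empty")
    go <- scheme@gapOpen; ge <- scheme@gapExtend
    NEG <- -1e9
    ## M: diagonal; U: gap in reference (consumes query); L: gap in query
    M <- U <- L <- matrix(NEG, n + 1L, m + 1L)
    M[1, 1] <- 0
    U[, 1] <- -(go + ge * (0:n)); U[1, 1] <- NEG
    L[1, ] <- -(go + ge * (0:m)); L[1, 1] <- NEG
    for (i in seq_len(n) + 1L) {
        si <- columnScore(q[i - 1L], r, scheme)
        for (j in seq_len(m) + 1L) {
            M[i, j] <- max(M[i - 1L, j - 1L], U[i - 1L, j - 1L],
                           L[i - 1L, j - 1L]) + si[j - 1L]
            U[i, j] <- max(M[i - 1L, j] - go, U[i - 1L, j],
                           L[i - 1L, j] - go) - ge
            L[i, j] <- max(M[i, j - 1L] - go, U[i, j - 1L] - go,
                           L[i, j - 1L]) - ge
        }
    }
    score <- max(M[n + 1L, m + 1L], U[n + 1L, m + 1L], L[n + 1L, m + 1L])
    ## traceback, preferring diagonal > up > left at every step
    qa <- ra <- character(0)
    i <- n + 1L; j <- m + 1L
    state <- which.max(c(M[i, j], U[i, j], L[i, j]))  # 1=M, 2=U, 3=L
    while (i > 1L || j > 1L) {
        if (state == 1L) {
            qa <- c(q[i - 1L], qa); ra <- c(r[j - 1L], ra)
            prev <- c(M[i - 1L, j - 1L], U[i - 1L, j - 1L], L[i - 1L, j - 1L])
            i <- i - 1L; j <- j - 1L
            state <- which.max(prev)
        } else if (state == 2L) {
            qa <- c(q[i - 1L], qa); ra <- c("-", ra)
            prev <- c(M[i - 1L, j] - go, U[i - 1L, j], L[i - 1L, j] - go)
            i <- i - 1L
            state <- which.max(prev)
        } else {
            qa <- c("-", qa); ra <- c(r[j - 1L], ra)
            prev <- c(M[i, j - 1L] - go, U[i, j - 1L] - go, L[i, j - 1L])
            j <- j - 1L
            state <- which.max(prev)
        }
        if (i == 1L && j > 1L) state <- 3L
        if (j == 1L && i > 1L) state <- 2L
    }
    ops <- ifelse(ra == "-", "insertion",
                  ifelse(qa == "-", "deletion",
                         ifelse(ra == "X", "x-match",
                                ifelse(qa == ra, "match", "mismatch"))))
    new("DomainAlignment", query = paste(qa, collapse = ""),
        reference = paste(ra, collapse = ""), score = score, ops = ops)
}

setMethod("show", "DomainAlignment", function(object) {
    cat(object@query, "\n", object@reference, "\n", sep = "")
    cat("score:", object@score, "\n")
})

## Left-normalise insertion columns: slide an inserted residue past an
## immediately preceding aligned column carrying the identical query residue.
## Score-tied gap placements then call identically (standard indel
## left-alignment); the swap never changes the score or the gap lengths.
normalizeInsertions <- function(qa, ra) {
    changed <- TRUE
    while (changed) {
        changed <- FALSE
        for (c in 2:length(qa)) {
            if (ra[c] == "-" && ra[c - 1L] != "-" && qa[c - 1L] != "-" &&
                qa[c] == qa[c - 1L]) {
                ra[c] <- ra[c - 1L]; ra[c - 1L] <- "-"
                changed <- TRUE
            }
        }
    }
    list(qa = qa, ra = ra)
}

#' Call a genotype from a reference alignment
#'
#' Residues aligned to the X columns fill the substitution positions; query
#' insertions are assigned to the insertion positions by reference registry
#' (a run inserted after reference residue 7 fills 7a, after residue 8 fills
#' 8a; a two-residue run fills both in order) after left-normalising
#' score-tied gap placements. Any non-X mismatch, deletion, out-of-registry
#' insertion or residue outside the design is a categorised rejection.
#'
#' @param alignment a \linkS4class{DomainAlignment} (query vs the design's
#'   degenerate reference).
#' @param design a \linkS4class{LibraryDesign}.
#' @return list(genotype = string or NA, status, reason).
#' @export
callGenotype <- function(alignment, design) {
    qa <- strsplit(alignment@query, "")[[1]]
    ra <- strsplit(alignment@reference, "")[[1]]
    norm <- normalizeInsertions(qa, ra)
    qa <- norm$qa; ra <- norm$ra
    reject <- function(why) list(genotype = NA_character_,
                                 status = "rejected", reason = why)
    if (any(qa == "-")) return(reject("deletion"))
    ref <- strsplit(design@referenceProtein, "")[[1]]
    sym <- setNames(rep(DELETION, length(design@labels)), design@labels)
    ins_after <- integer(0); ins_res <- character(0)
    refpos <- 0L
    for (c in seq_along(qa)) {
        if (ra[c] == "-") {
            ins_after <- c(ins_after, refpos)
            ins_res <- c(ins_res, qa[c])
        } else {
            refpos <- refpos + 1L
            if (ra[c] == "X") {
                lab <- design@labels[!design@insertion &
                                     design@refLocus == refpos]
                sym[lab] <- qa[c]
            } else if (qa[c] != ra[c]) {
                return(reject("mismatch"))
            }
        }
    }
    ## assign insertion runs to the insertion positions by registry
    ins_labels <- design@labels[design@insertion]
    ins_loci <- design@refLocus[ins_labels]
    if (length(ins_after)) {
        runs <- split(seq_along(ins_after), cumsum(
            c(TRUE, diff(ins_after) != 0L | diff(seq_along(ins_after)) != 1L)))
        for (run in runs) {
            after <- ins_after[run[1]]
            res <- ins_res[run]
            slots <- ins_labels[ins_loci >= after]
            if (!after %in% ins_loci || length(res) > length(slots))
                return(reject("insertion-misplaced"))
            if (length(res) == 1L) {
                at <- ins_labels[ins_loci == after]
                if (!res %in% design@allowed[[at]]) {
                    # e.g. a non-Ala residue placed after reference 8 by a
                    # score-tied alignment: re-register at the earlier slot
                    at <- slots[vapply(slots, function(s)
                        res %in% design@allowed[[s]], NA)][1]
                    if (is.na(at)) return(reject("illegal-residue"))
                }
                if (sym[at] != DELETION) return(reject("insertion-misplaced"))
                sym[at] <- res
            } else {
                take <- slots[seq_along(res)]
                if (any(sym[take] != DELETION))
                    return(reject("insertion-misplaced"))
                sym[take] <- res
            }
        }
    }
    g <- paste(sym, collapse = "")
    if (!isValidGenotype(g, design)) return(reject("illegal-residue"))
    list(genotype = g, status = "ok", reason = NA_character_)
}

#' Process a FASTQ of merged reads into genotype calls
#'
#' Runs extraction, translation, degenerate-reference alignment (memoised on
#' unique protein sequences) and genotype calling, and tallies rejection
#' reasons.
#'
#' @param fastq path to a FASTQ file of merged reads, or a character vector
#'   of read sequences.
#' @param design a \linkS4class{LibraryDesign}.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @return list with \code{calls} (data.frame: id, status, reason, genotype,
#'   score) and \code{summary} (named counts: total, accepted, plus one entry
#'   per rejection reason).
#' @export
processReads <- function(fastq, design, scheme = ScoringScheme()) {
    if (length(fastq) == 1L && file.exists(fastq)) {
        x <- Biostrings::readDNAStringSet(fastq, format = "fastq")
        reads <- as.character(x)
        ids <- names(x)
    } else {
        reads <- as.character(fastq)
        ids <- sprintf("read%06d", seq_along(reads))
    }
    ext <- findDDomain(reads, design)
    tr <- data.frame(protein = rep(NA_character_, length(reads)),
                     status = ext$status, reason = ext$reason)
    okx <- ext$status == "ok"
    tr[okx, ] <- translateInsert(ext$insert[okx])
    genotype <- rep(NA_character_, length(reads))
    score <- rep(NA_real_, length(reads))
    status <- tr$status; reason <- tr$reason
    okp <- which(tr$status == "ok")
    if (length(okp)) {
        prots <- tr$protein[okp]
        uniq <- unique(prots)
        res <- lapply(uniq, function(p) {
            aln <- alignGlobal(p, design@referenceProtein, scheme)
            c(callGenotype(aln, design), list(score = aln@score))
        })
        idx <- match(prots, uniq)
        genotype[okp] <- vapply(res, `[[`, "", "genotype")[idx]
        score[okp] <- vapply(res, `[[`, 0, "score")[idx]
        status[okp] <- vapply(res, `[[`, "", "status")[idx]
        reason[okp] <- vapply(res, function(z) as.character(z$reason), "")[idx]
    }
    calls <- data.frame(id = ids, status = status, reason = reason,
                        genotype = genotype, score = score)
    reasons <- table(reason[status != "ok"])
    summary <- c(total = length(reads), accepted = sum(status == "ok"),
                 setNames(as.integer(reasons), names(reasons)))
    list(calls = calls, summary = summary)
}
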