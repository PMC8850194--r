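## Context-preserving background simulation.
##
## The null model for IMD calibration shuffles every mutation to a uniformly
## random position on its own chromosome that carries the same +/-2 bp
## pentanucleotide, preserving the per-chromosome burden and the per-context
## counts exactly.  Matches on either strand of the pentanucleotide are
## accepted.

BASES <- c("A", "C", "G", "T")

## raw byte -> base code 0..3 lookup (NA for anything else, incl. N)
.baseCode <- local({
    tab <- rep(NA_integer_, 256L)
    tab[as.integer(charToRaw("A")) + 1L] <- 0L
    tab[as.integer(charToRaw("C")) + 1L] <- 1L
    tab[as.integer(charToRaw("G")) + 1L] <- 2L
    tab[as.integer(charToRaw("T")) + 1L] <- 3L
    tab
})

fivemerCode <- function(s) {
    ## vectorized 5-mer string -> integer code in 0..1023
    m <- matrix(.baseCode[as.integer(charToRaw(paste(s, collapse = ""))) + 1L],
                nrow = 5L)
    as.integer(colSums(m * c(256L, 64L, 16L, 4L, 1L)))
}

revcompString <- function(s) {
    as.character(reverseComplement(DNAStringSet(s)))
}

#' Pentanucleotide position index of a genome
#'
#' Precomputes, per chromosome, the genomic positions (of the centre base)
#' of every 5-mer.  Built once and reused by [simulateReplicates()] and
#' [ampliconEnrichmentTest()].
#'
#' @param genome [Biostrings::DNAStringSet].
#' @return opaque index object (class `ContextIndex`).
#' @export
buildContextIndex <- function(genome) {
    idx <- lapply(seq_along(genome), function(i) {
        b <- .baseCode[as.integer(charToRaw(as.character(genome[[i]]))) + 1L]
        n <- length(b)
        if (n < 5L) return(list())
        ctr <- 3:(n - 2L)
        code <- b[ctr - 2L] * 256L + b[ctr - 1L] * 64L + b[ctr] * 16L +
            b[ctr + 1L] * 4L + b[ctr + 2L]
        keep <- !is.na(code)
        split(ctr[keep], code[keep])
    })
    names(idx) <- names(genome)
    structure(list(positions = idx, chromLengths = lengths(genome)),
              class = "ContextIndex")
}

## candidate centre positions matching a canonical 5-mer on either strand
candidatePositions <- function(index, chrom, fivemer) {
    codes <- as.character(c(fivemerCode(fivemer),
                            fivemerCode(revcompString(fivemer))))
    tab <- index$positions[[chrom]]
    unlist(tab[codes], use.names = FALSE)
}

## reference 5-mers around mutation positions ("ambiguous" near edges / N)
fivemerAt <- function(mutations, genome) {
    out <- rep("ambiguous", length(mutations))
    ch <- as.character(seqnames(mutations))
    pos <- start(mutations)
    for (cc in unique(ch)) {
        i <- which(ch == cc)
        L <- length(genome[[cc]])
        ok <- pos[i] >= 3L & pos[i] <= L - 2L
        if (any(ok)) {
            v <- Biostrings::Views(genome[[cc]], start = pos[i][ok] - 2L,
                                   end = pos[i][ok] + 2L)
            s <- as.character(v)
            s[grepl("[^ACGT]", s)] <- "ambiguous"
            out[i][ok] <- s
        }
    }
    out
}

#' Mutation context category
#'
#' Reports the +/-2 bp pentanucleotide around each mutation with the mutated
#' pyrimidine at the centre; substitutions whose reference base is a purine
#' are reverse-complemented.  Indels are categorized by the 5-mer flanking
#' the first base of the inserted/deleted tract (strand-canonicalized to the
#' lexicographically smaller of the two strands).  Windows containing N or
#' running off a contig end give `"ambiguous"`.
#'
#' @param mutations mutation [GRanges].
#' @param genome [Biostrings::DNAStringSet].
#' @return character vector of category labels, e.g. `"AA[C>T]GT"` for a
#'   substitution or `"indel:AACGT"` for an indel.
#' @export
mutationContext <- function(mutations, genome) {
    fm <- fivemerAt(mutations, genome)
    mc <- mcols(mutations)
    out <- character(length(mutations))
    isSub <- mc$kind == "substitution"
    amb <- fm == "ambiguous"
    out[amb] <- "ambiguous"
    i <- which(isSub & !amb)
    if (length(i)) {
        ref <- mc$ref[i]; alt <- mc$alt[i]; s <- fm[i]
        flip <- ref %in% c("A", "G")
        s[flip] <- revcompString(s[flip])
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        ref[flip] <- comp[ref[flip]]
        alt[flip] <- comp[alt[flip]]
        out[i] <- paste0(substr(s, 1, 2), "[", ref, ">", alt, "]",
                         substr(s, 4, 5))
    }
    i <- which(!isSub & !amb)
    if (length(i)) {
        s <- fm[i]
        out[i] <- paste0("indel:", pmin(s, revcompString(s)))
    }
    out
}

#' Simulate background replicates of a sample
#'
#' Every replicate re-places each mutation at a uniformly random position on
#' its original chromosome drawn from the positions carrying its
#' pentanucleotide (either strand); per-chromosome and per-context counts
#' are therefore conserved exactly.  VAFs and alleles are carried over
#' unchanged.  Mutations with ambiguous context keep their original
#' position.  Within a replicate, positions colliding on a chromosome are
#' re-drawn (up to 100 times, then an error is raised).
#'
#' @param mutations one sample's mutation [GRanges].
#' @param genome [Biostrings::DNAStringSet].
#' @param n number of replicates (100 in routine use).
#' @param seed integer seed; the replicate set is deterministic given it.
#' @param index optional precomputed [buildContextIndex()] result.
#' @return list of `n` data.frames with columns `chrom`, `pos`, `ref`,
#'   `alt`, `vaf`, `kind`, `category`, each sorted by chromosome and
#'   position.
#' @export
simulateReplicates <- function(mutations, genome, n = 100L, seed = 1L,
                               index = NULL) {
    if (length(unique(mcols(mutations)$sample)) > 1L)
        stop("simulateReplicates() operates on a single sample")
    if (n == 0L) return(list())
    if (is.null(index)) index <- buildContextIndex(genome)
    set.seed(seed)
    fm <- fivemerAt(mutations, genome)
    ch <- as.character(seqnames(mutations))
    pos <- start(mutations)
    mc <- mcols(mutations)
    m <- length(mutations)

    grpKey <- paste0(ch, "|", fm)
    grpKey[fm == "ambiguous"] <- paste0("fixed|", seq_len(m))[fm == "ambiguous"]
    groups <- split(seq_len(m), grpKey)
    ## vectorized reverse complements of all distinct 5-mers at once
    fmU <- unique(fm[fm != "ambiguous"])
    rcU <- if (length(fmU)) stats::setNames(revcompString(fmU), fmU)
           else character()
    cand <- lapply(names(groups), function(k) {
        if (startsWith(k, "fixed|")) return(pos[groups[[k]]])
        parts <- strsplit(k, "|", fixed = TRUE)[[1]]
        codes <- as.character(fivemerCode(c(parts[2], rcU[[parts[2]]])))
        p <- unlist(index$positions[[parts[1]]][codes], use.names = FALSE)
        if (is.null(p) || length(p) == 0L)
            stop("no candidate positions for context ", parts[2],
                 " on ", parts[1])
        p
    })
    names(cand) <- names(groups)

    ## bulk draws: one m x n matrix of positions
    draws <- matrix(0L, nrow = m, ncol = n)
    for (k in names(groups)) {
        g <- groups[[k]]
        ck <- cand[[k]]
        if (startsWith(k, "fixed|")) {
            draws[g, ] <- pos[g]
        } else {
            draws[g, ] <- ck[sample.int(length(ck), length(g) * n,
                                        replace = TRUE)]
        }
    }
    grpOf <- integer(m)
    for (k in seq_along(groups)) grpOf[groups[[k]]] <- k

    chi <- match(ch, unique(ch))
    out <- vector("list", n)
    for (r in seq_len(n)) {
        p <- draws[, r]
        for (retry in seq_len(101L)) {
            dup <- which(duplicated(chi * 2^33 + p))
            if (!length(dup)) break
            if (retry > 100L)
                stop("could not resolve position collisions after 100 retries")
            for (j in dup) {
                ck <- cand[[grpOf[j]]]
                p[j] <- ck[sample.int(length(ck), 1L)]
            }
        }
        ord <- order(chi, p)
        out[[r]] <- data.frame(chrom = ch[ord], pos = p[ord],
                               ref = mc$ref[ord], alt = mc$alt[ord],
                               vaf = mc$vaf[ord], kind = mc$kind[ord],
                               category = grpKey[ord],
                               stringsAsFactors = FALSE)
    }
    out
}
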