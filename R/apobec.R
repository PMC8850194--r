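## APOBEC3A/3B-oriented RTCA vs YTCA enrichment.
##
## APOBEC3B preferentially deaminates the C of RTCA tetranucleotides
## (R = purine), APOBEC3A the C of YTCA (Y = pyrimidine).  The enrichment
## of each motif is computed over the +/-20 bp context of every C>N
## mutation, normalizing mutated-motif counts by motif availability:
##
##   E_RTCA = (M_RTCA * N_C) / (M_C * N_RTCA)
##
## with M_RTCA the number of TpCpA > TpKpA mutations at RTCA, M_C all C>N
## mutations considered, N_RTCA the RTCA occurrences in the 41-mers around
## the considered mutations (both strands) and N_C the cytosines in those
## 41-mers (both strands).

## Count occurrences of a 4-mer motif whose cytosine (3rd position) lies
## inside the central 41-mer of the extended (47-mer) windows.  The windows
## are extended +/-3 bp so that a motif centred on an edge base of the
## 41-mer is still evaluated against its true genomic context; restricting
## the count to motif-C positions inside the window keeps the availability
## normalization unbiased (no short-substring edge deficit).
countMotif <- function(extStrings, pattern) {
    lo <- 4L; hi <- 44L   # 41-mer spans positions 4..44 of the 47-mer
    sum(vapply(gregexpr(paste0("(?=", pattern, ")"), extStrings, perl = TRUE),
               function(m) {
                   m <- m[m > 0L]
                   sum(m + 2L >= lo & m + 2L <= hi)
               }, numeric(1)))
}

#' RTCA / YTCA enrichment scores
#'
#' @param mutations mutation [GRanges]; substitutions at cytosines
#'   (pyrimidine-normalized) with full 20-bp flanks are considered.
#' @param genome [Biostrings::DNAStringSet].
#' @return list (class `ApobecEnrichment`) with elements `E_RTCA`,
#'   `E_YTCA`, `fold` (= E_RTCA / E_YTCA) and the raw counts `M_RTCA`,
#'   `M_YTCA`, `M_C`, `N_RTCA`, `N_YTCA`, `N_C`.  All scores are `NA` with
#'   a `flag` when no C>N mutation is available.
#' @export
apobecEnrichment <- function(mutations, genome) {
    mutations <- mutations[mcols(mutations)$kind == "substitution"]
    ch <- as.character(seqnames(mutations))
    pos <- start(mutations)
    mc <- mcols(mutations)
    comp <- c(A = "T", C = "G", G = "C", T = "A")

    ## C>N mutations (pyrimidine-normalized) with full 41-mer windows
    isC <- mc$ref %in% c("C", "G")
    lens <- vapply(names(genome), function(n) length(genome[[n]]), numeric(1))
    inRange <- pos >= 24L & pos <= lens[ch] - 23L
    keep <- which(isC & inRange)
    out <- list(E_RTCA = NA_real_, E_YTCA = NA_real_, fold = NA_real_,
                M_RTCA = 0L, M_YTCA = 0L, M_C = 0L,
                N_RTCA = 0L, N_YTCA = 0L, N_C = 0L,
                flag = "no C>N mutations with full context")
    class(out) <- "ApobecEnrichment"
    if (!length(keep)) return(out)

    ## 41-mer windows extended +/-3 bp for edge-motif context
    ext <- character(length(keep))
    for (cc in unique(ch[keep])) {
        i <- which(ch[keep] == cc)
        v <- Biostrings::Views(genome[[cc]], start = pos[keep][i] - 23L,
                               end = pos[keep][i] + 23L)
        ext[i] <- as.character(v)
    }
    ## pyrimidine-normalize: flip windows of G>N mutations so the centre
    ## (position 24 of the 47-mer) is the mutated C
    flip <- mc$ref[keep] == "G"
    ext[flip] <- revcompString(ext[flip])
    alt <- mc$alt[keep]
    alt[flip] <- comp[alt[flip]]
    kmers <- substr(ext, 4L, 44L)

    centre4 <- substr(kmers, 19L, 22L)   # (N)TCA window: positions -2..+1
    isTCA <- substr(centre4, 2L, 4L) == "TCA"
    m5 <- substr(centre4, 1L, 1L)
    isK <- alt %in% c("T", "G")
    M_RTCA <- sum(isTCA & m5 %in% c("A", "G") & isK)
    M_YTCA <- sum(isTCA & m5 %in% c("C", "T") & isK)
    M_C <- length(keep)

    both <- c(ext, revcompString(ext))
    N_RTCA <- countMotif(both, "[AG]TCA")
    N_YTCA <- countMotif(both, "[CT]TCA")
    both41 <- c(kmers, revcompString(kmers))
    N_C <- sum(vapply(gregexpr("C", both41, fixed = TRUE),
                      function(m) sum(m > 0L), numeric(1)))

    E_R <- if (N_RTCA > 0) (M_RTCA * N_C) / (M_C * N_RTCA) else NA_real_
    E_Y <- if (N_YTCA > 0) (M_YTCA * N_C) / (M_C * N_YTCA) else NA_real_
    out$E_RTCA <- E_R; out$E_YTCA <- E_Y
    out$fold <- if (!is.na(E_R) && !is.na(E_Y) && E_Y > 0) E_R / E_Y
                else NA_real_
    out$M_RTCA <- M_RTCA; out$M_YTCA <- M_YTCA; out$M_C <- M_C
    out$N_RTCA <- N_RTCA; out$N_YTCA <- N_YTCA; out$N_C <- N_C
    out$flag <- NA_character_
    out
}

#' @export
print.ApobecEnrichment <- function(x, ...) {
    cat("APOBEC3 tetranucleotide enrichment\n")
    cat(sprintf("  E_RTCA = %.3f (M = %d, motifs = %d)\n",
                x$E_RTCA, x$M_RTCA, x$N_RTCA))
    cat(sprintf("  E_YTCA = %.3f (M = %d, motifs = %d)\n",
                x$E_YTCA, x$M_YTCA, x$N_YTCA))
    cat(sprintf("  RTCA/YTCA fold = %.3f over %d C>N mutations\n",
                x$fold, x$M_C))
    invisible(x)
}
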