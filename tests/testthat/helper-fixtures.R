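## Shared fixtures, built in code.

## A hand-written two-gene annotation: GP (+ strand, 3 exons) and GM
## (- strand, 3 exons), mirroring the synthetic cohort geometry.
miniAnnotation <- function() {
    exl <- GenomicRanges::GRangesList(
        GP.t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(
            c(1000, 1400, 1800), c(1099, 1499, 1899)), "+"),
        GM.t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(
            c(5000, 5400, 5800), c(5099, 5499, 5899)), "-"))
    GeneAnnotation(exl, c(GP.t1 = "GP", GM.t1 = "GM"))
}

## Small JunctionExperiment over the mini annotation; rows cover every
## annotation class by hand construction.
miniJunctions <- function(counts = NULL) {
    jx <- data.frame(
        chrom = "chr1",
        start = c(1100, 1500, 1100, 1100, 1150, 5100, 5500),
        end   = c(1399, 1799, 1799, 1350, 1399, 5399, 5799),
        strand = c("+", "+", "+", "+", "+", "-", "-"))
    ## by hand, against GP (+): 1100-1399 annotated; 1500-1799 annotated;
    ## 1100-1799 novel_combination (both sites known, pairing not);
    ## 1100-1350 novel_acceptor (donor known); 1150-1399 novel_donor.
    ## GM (-): both annotated.
    if (is.null(counts))
        counts <- matrix(20, nrow(jx), 2,
                         dimnames = list(NULL, c("s1", "s2")))
    JunctionExperiment(counts, jx, librarySizes = c(1e6, 1e6))
}

## Tiny cohort used by several modules (fast defaults).
miniCohort <- function(seed = 1, nPerGroup = 10, ...) {
    simulateCohort(cohortSpec(nGenes = 6,
                              nSamplesPerGroup = c(nPerGroup, nPerGroup),
                              seed = seed, ...))
}

## Brute-force BH: direct step-up definition on sorted p-values.
bruteForceBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    out <- numeric(m)
    out[o] <- vapply(seq_len(m), function(i)
        min(1, min(m * ps[i:m] / (i:m))), numeric(1))
    out
}
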