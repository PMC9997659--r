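#' Specification of a synthetic two-group junction cohort
#'
#' Describes a cohort of junction read counts for `nGenes` genes, each a
#' single-transcript chain of exons, in which selected "cassette genes"
#' additionally carry a hidden (non-annotated) cassette exon whose
#' inclusion fraction psi differs between the two groups.  Counts are
#' negative-binomial around `geneAbundance` expected junction reads,
#' scaled to a library size drawn uniformly from `libsizeRange`.
#'
#' @param nGenes number of genes.
#' @param nSamplesPerGroup integer pair, samples in groups A and B.
#' @param junctionsPerGene annotated junctions per gene (>= 2).
#' @param cassetteGenes data.frame with columns `gene`, `psiA`, `psiB`
#'   (inclusion fractions in `[0, 1]` per group).  Gene ids are
#'   `G1..GnGenes`; even-numbered genes sit on the minus strand.
#' @param geneAbundance expected reads per junction at the nominal
#'   library size.
#' @param nbDispersion negative-binomial dispersion (> 0; values below
#'   1e-8 switch to Poisson sampling).
#' @param libsizeRange pair of total library sizes.
#' @param cassetteWidth cassette exon width in nt (default 51, the
#'   TLN1-like exon length).
#' @param seed integer seed.
#' @return a validated `CohortSpec` list.
#' @export
cohortSpec <- function(nGenes = 30, nSamplesPerGroup = c(60, 60),
                       junctionsPerGene = 5,
                       cassetteGenes = data.frame(
                           gene = "G2", psiA = 0.7, psiB = 0.05),
                       geneAbundance = 100, nbDispersion = 0.1,
                       libsizeRange = c(8e5, 1.2e6),
                       cassetteWidth = 51, seed = 1) {
    spec <- list(nGenes = nGenes, nSamplesPerGroup = nSamplesPerGroup,
                 junctionsPerGene = junctionsPerGene,
                 cassetteGenes = cassetteGenes,
                 geneAbundance = geneAbundance,
                 nbDispersion = nbDispersion,
                 libsizeRange = libsizeRange,
                 cassetteWidth = cassetteWidth, seed = as.integer(seed))
    validateCohortSpec(spec)
    class(spec) <- c("CohortSpec", "list")
    spec
}

validateCohortSpec <- function(spec) {
    with(spec, {
        if (nGenes < 1 || junctionsPerGene < 2)
            stop("invalid spec: need >= 1 gene and >= 2 junctions per gene")
        if (length(nSamplesPerGroup) != 2 || any(nSamplesPerGroup < 1))
            stop("invalid spec: nSamplesPerGroup must be two positive counts")
        if (geneAbundance <= 0)
            stop("invalid spec: geneAbundance must be positive")
        if (nbDispersion <= 0)
            stop("invalid spec: nbDispersion must be positive")
        if (any(libsizeRange <= 0) || length(libsizeRange) != 2)
            stop("invalid spec: libsizeRange must be two positive totals")
        if (nrow(cassetteGenes)) {
            psi <- c(cassetteGenes$psiA, cassetteGenes$psiB)
            if (any(psi < 0 | psi > 1))
                stop("invalid spec: inclusion fractions must lie in [0, 1]")
            if (!all(cassetteGenes$gene %in% paste0("G", seq_len(nGenes))))
                stop("invalid spec: unknown cassette gene id")
        }
    })
    invisible(TRUE)
}

## Gene model geometry: gene g occupies a 100 kb slot on chr1; exons are
## 100 nt, introns 300 nt.  The cassette (if any) is centred in the
## middle intron.
cohortGeneModel <- function(spec) {
    J <- spec$junctionsPerGene
    E <- J + 1L
    lapply(seq_len(spec$nGenes), function(g) {
        off <- (g - 1L) * 100000L + 1000L
        ex_start <- off + (seq_len(E) - 1L) * 400L
        exons <- data.frame(start = ex_start, end = ex_start + 99L)
        jx <- data.frame(start = exons$end[-E] + 1L,
                         end = exons$start[-1] - 1L)
        strand <- if (g %% 2L == 0L) "-" else "+"
        gene <- paste0("G", g)
        cass <- NULL
        ci <- match(gene, spec$cassetteGenes$gene)
        if (!is.na(ci)) {
            m <- ceiling(J / 2)  # cassette lives in the middle intron
            w <- as.integer(spec$cassetteWidth)
            cstart <- jx$start[m] + 124L
            cass <- list(mid = m, start = cstart, end = cstart + w - 1L,
                         psiA = spec$cassetteGenes$psiA[ci],
                         psiB = spec$cassetteGenes$psiB[ci])
        }
        list(gene = gene, chrom = "chr1", strand = strand,
             exons = exons, junctions = jx, cassette = cass)
    })
}

#' Simulate a two-group junction-count cohort with hidden cassette exons
#'
#' Generates, for every gene, counts for all annotated junctions plus —
#' for each cassette gene — two inclusion junctions absent from the
#' annotation flanking the hidden exon, while the annotated middle
#' junction becomes the skipping junction.  Expected counts are
#' `geneAbundance * usage(psi)` scaled to the sample's library size and
#' drawn negative-binomially; the annotation returned omits the
#' cassette exon (that is the discovery problem).
#'
#' @param spec a [cohortSpec()].
#' @return list with elements `junctions` (a [JunctionExperiment] with
#'   `colData$group`), `annotation` (a [GeneAnnotation-class]), and
#'   `truth` (programmed per-gene psi, junction keys of each cassette
#'   trio, cassette interval, and differential status).
#' @examples
#' sim <- simulateCohort(cohortSpec(nGenes = 4, nSamplesPerGroup = c(3, 3)))
#' dim(counts(sim$junctions))
#' @export
simulateCohort <- function(spec) {
    validateCohortSpec(spec)
    genes <- cohortGeneModel(spec)
    nA <- spec$nSamplesPerGroup[1]; nB <- spec$nSamplesPerGroup[2]
    n <- nA + nB
    ## group A is the case (inclusion-high) group; levels put B first so
    ## a default second-minus-first contrast reads A vs B
    group <- factor(rep(c("A", "B"), c(nA, nB)), levels = c("B", "A"))

    ## assemble junction list and per-junction expected usage by group
    rows <- list()
    for (gm in genes) {
        psiA <- psiB <- NULL
        for (j in seq_len(nrow(gm$junctions))) {
            usageA <- usageB <- 1
            cassette_role <- "constitutive"
            if (!is.null(gm$cassette) && j == gm$cassette$mid) {
                usageA <- 1 - gm$cassette$psiA
                usageB <- 1 - gm$cassette$psiB
                cassette_role <- "skip"
            }
            rows[[length(rows) + 1L]] <- data.frame(
                gene = gm$gene, chrom = gm$chrom, strand = gm$strand,
                start = gm$junctions$start[j], end = gm$junctions$end[j],
                usageA = usageA, usageB = usageB, role = cassette_role)
        }
        if (!is.null(gm$cassette)) {
            cs <- gm$cassette
            jx <- gm$junctions[cs$mid, ]
            rows[[length(rows) + 1L]] <- data.frame(
                gene = gm$gene, chrom = gm$chrom, strand = gm$strand,
                start = jx$start, end = cs$start - 1L,
                usageA = cs$psiA, usageB = cs$psiB, role = "inc1")
            rows[[length(rows) + 1L]] <- data.frame(
                gene = gm$gene, chrom = gm$chrom, strand = gm$strand,
                start = cs$end + 1L, end = jx$end,
                usageA = cs$psiA, usageB = cs$psiB, role = "inc2")
        }
    }
    jdf <- do.call(rbind, rows)
    ord <- order(jdf$chrom, jdf$start, jdf$end)
    jdf <- jdf[ord, ]

    nominal <- mean(spec$libsizeRange)
    sim <- with_seed(spec$seed, {
        libs <- round(runif(n, spec$libsizeRange[1], spec$libsizeRange[2]))
        usage <- cbind(A = jdf$usageA, B = jdf$usageB)
        mu <- spec$geneAbundance *
            usage[, as.character(group), drop = FALSE] *
            rep(libs / nominal, each = nrow(jdf))
        cnt <- if (spec$nbDispersion < 1e-8)
            matrix(rpois(length(mu), mu), nrow(jdf), n)
        else
            matrix(rnbinom(length(mu), mu = mu,
                           size = 1 / spec$nbDispersion), nrow(jdf), n)
        list(libs = libs, cnt = cnt)
    })
    samples <- sprintf("%s_%02d", as.character(group),
                       unlist(lapply(c(nA, nB), seq_len)))
    colnames(sim$cnt) <- samples

    gr <- GRanges(jdf$chrom, IRanges(jdf$start, jdf$end),
                  strand = jdf$strand)
    libsizes <- pmax(sim$libs, colSums(sim$cnt))
    je <- JunctionExperiment(sim$cnt, gr, librarySizes = libsizes)
    colData(je)$group <- group
    rowData(je)$true_role <- jdf$role
    rowData(je)$true_gene <- jdf$gene

    ## annotation: exon chains without the cassette exon
    exl <- GRangesList(lapply(genes, function(gm)
        GRanges(gm$chrom, IRanges(gm$exons$start, gm$exons$end),
                strand = gm$strand)))
    names(exl) <- paste0(vapply(genes, `[[`, "", "gene"), ".t1")
    txg <- setNames(vapply(genes, `[[`, "", "gene"), names(exl))
    ann <- GeneAnnotation(exl, txg)

    truth <- lapply(genes[!vapply(genes, function(g)
        is.null(g$cassette), logical(1))], function(gm) {
        cs <- gm$cassette
        jx <- gm$junctions[cs$mid, ]
        key <- function(s, e) sprintf("%s:%d-%d:%s", gm$chrom, s, e,
                                      gm$strand)
        list(gene = gm$gene, psiA = cs$psiA, psiB = cs$psiB,
             differential = cs$psiA != cs$psiB,
             inc1 = key(jx$start, cs$start - 1L),
             inc2 = key(cs$end + 1L, jx$end),
             skip = key(jx$start, jx$end),
             cassette = list(chrom = gm$chrom, start = cs$start,
                             end = cs$end, strand = gm$strand))
    })
    names(truth) <- vapply(truth, `[[`, "", "gene")
    list(junctions = je, annotation = ann,
         truth = list(cassettes = truth, group = as.character(group),
                      spec = unclass(spec)))
}

#' Simulate a continuous trait coupled to exon inclusion
#'
#' `trait = coupling * psi + N(0, noiseSd)`, emulating e.g. a drug-AUC
#' or gene-dependency profile that tracks cassette-exon inclusion.
#'
#' @param psi named per-sample inclusion values (e.g. a [psiMatrix()]
#'   row).
#' @param coupling linear coefficient (negative for traits reduced by
#'   inclusion, such as AUC under a drug the inclusion sensitizes to).
#' @param noiseSd Gaussian noise sd.
#' @param seed integer seed.
#' @return named numeric trait vector.
#' @export
simulateTrait <- function(psi, coupling = -3, noiseSd = 0.1, seed = 1) {
    with_seed(as.integer(seed),
              setNames(coupling * as.numeric(psi) +
                       rnorm(length(psi), sd = noiseSd), names(psi)))
}

#' Write a simulated cohort to disk
#'
#' Emits per-sample STAR-style `SJ.out.tab` files, a merged junction
#' matrix TSV, the annotation GTF, and the truth record JSON.
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    je <- sim$junctions
    gr <- rowRanges(je)
    strand_code <- c(`*` = 0L, `+` = 1L, `-` = 2L)[
        as.character(strand(gr))]
    for (s in colnames(je)) {
        cnt <- counts(je)[, s]
        keep <- cnt > 0
        df <- data.frame(as.character(seqnames(gr))[keep],
                         start(gr)[keep], end(gr)[keep],
                         strand_code[keep], 0L, 0L, cnt[keep], 0L, 20L)
        write.table(df, file.path(dir, paste0(s, ".SJ.out.tab")),
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    }
    writeJunctionMatrix(je, file.path(dir, "junction_counts.tsv"))
    writeGeneAnnotation(sim$annotation, file.path(dir, "annotation.gtf"))
    write_json(sim$truth, file.path(dir, "truth.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}
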