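#' JunctionExperiment: splice-junction counts with genomic intron keys
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are
#' splice junctions keyed by intron coordinates (1-based first and last
#' intron base, STAR convention) and whose single assay `"counts"` holds
#' non-negative uniquely-mapping read counts.  `colData` carries
#' per-sample `library_size` totals used for logCPM normalization.
#'
#' Row names are junction keys `chrom:start-end:strand`.
#'
#' @export
setClass("JunctionExperiment", contains = "RangedSummarizedExperiment")

setValidity("JunctionExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- assay(object, "counts")
        if (any(cnt < 0, na.rm = TRUE))
            msg <- c(msg, "counts must be non-negative")
    }
    if (!"library_size" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain 'library_size'")
    else if ("counts" %in% assayNames(object)) {
        ls <- colData(object)$library_size
        if (any(ls <= 0)) msg <- c(msg, "library sizes must be positive")
        if (ncol(object) > 0 &&
            any(ls < colSums(assay(object, "counts"))))
            msg <- c(msg, "library sizes must be >= column sums of counts")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate junction keys")
    if (length(msg)) msg else TRUE
})

#' Construct a JunctionExperiment
#'
#' @param counts junction x sample matrix of non-negative counts.
#' @param junctions a [GenomicRanges::GRanges] of introns (start = first
#'   intron base, end = last intron base, both 1-based inclusive), or a
#'   data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @param librarySizes per-sample library totals; defaults to the column
#'   sums of `counts`.
#' @param rowData optional extra per-junction annotation.
#'
#' @return a [JunctionExperiment-class] with rownames
#'   `chrom:start-end:strand`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+")
#' je <- JunctionExperiment(matrix(5, 1, 2,
#'     dimnames = list(NULL, c("s1", "s2"))), gr)
#' librarySizes(je)
#' @export
JunctionExperiment <- function(counts, junctions, librarySizes = NULL,
                               rowData = NULL) {
    counts <- as.matrix(counts)
    if (is.data.frame(junctions)) {
        junctions <- GRanges(junctions$chrom,
                             IRanges(junctions$start, junctions$end),
                             strand = junctions$strand)
    }
    if (length(junctions) != nrow(counts))
        stop("number of junctions does not match number of count rows")
    if (is.null(librarySizes)) librarySizes <- colSums(counts)
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
    keys <- junctionKey(junctions)
    if (anyDuplicated(keys)) stop("duplicate junction keys")
    names(junctions) <- keys
    rownames(counts) <- keys
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowRanges = junctions,
        colData = DataFrame(library_size = as.numeric(librarySizes),
                            row.names = colnames(counts)))
    if (!is.null(rowData)) rowData(se)[colnames(rowData)] <- rowData
    new("JunctionExperiment", se)
}

#' Junction keys of the form `chrom:start-end:strand`
#' @param x a `GRanges` of introns or a `JunctionExperiment`.
#' @return character vector of keys.
#' @export
junctionKey <- function(x) {
    if (is(x, "SummarizedExperiment")) x <- rowRanges(x)
    sprintf("%s:%d-%d:%s", as.character(seqnames(x)), start(x), end(x),
            as.character(strand(x)))
}

#' @describeIn JunctionExperiment per-sample library-size totals.
#' @param object,x a `JunctionExperiment`.
#' @export
setGeneric("librarySizes", function(object) standardGeneric("librarySizes"))

#' @rdname JunctionExperiment
#' @export
setMethod("librarySizes", "JunctionExperiment", function(object)
    setNames(colData(object)$library_size, colnames(object)))

#' @rdname JunctionExperiment
#' @export
setMethod("counts", "JunctionExperiment", function(object)
    assay(object, "counts"))

setMethod("show", "JunctionExperiment", function(object) {
    cat("JunctionExperiment with", nrow(object), "junctions x",
        ncol(object), "samples\n")
    callNextMethod()
})

#' GeneAnnotation: transcript exon structures grouped by gene
#'
#' Holds the gene models used to annotate junctions: exons per
#' transcript (a `GRangesList`, exons ordered by genomic position), a
#' transcript-to-gene map, and per-gene span ranges.  Build one from a
#' GTF file with [readGeneAnnotation()].
#'
#' @slot exons `GRangesList` of exons, one element per transcript.
#' @slot txGene named character, transcript id -> gene id.
#' @slot genes `GRanges` of gene spans, names are gene ids.
#' @export
setClass("GeneAnnotation",
         representation(exons = "GRangesList", txGene = "character",
                        genes = "GRanges"))

setValidity("GeneAnnotation", function(object) {
    msg <- character()
    if (!all(names(object@exons) %in% names(object@txGene)))
        msg <- c(msg, "every transcript needs a gene assignment")
    ok <- vapply(object@exons, function(ex) {
        s <- start(ex)
        all(diff(s) > 0) && !any(isOverlapping(ex))
    }, logical(1))
    if (!all(ok))
        msg <- c(msg, "exons within a transcript must be ordered and non-overlapping")
    if (length(msg)) msg else TRUE
})

isOverlapping <- function(ex) {
    if (length(ex) < 2) return(FALSE)
    start(ex)[-1] <= end(ex)[-length(ex)]
}

#' Construct a GeneAnnotation from exon ranges
#'
#' @param exons `GRangesList` of exons per transcript (any order; sorted
#'   internally by genomic start).
#' @param txGene named character vector mapping transcript ids to gene
#'   ids.
#' @return a [GeneAnnotation-class].
#' @export
GeneAnnotation <- function(exons, txGene) {
    exons <- endoapply(exons, function(ex) ex[order(start(ex))])
    gene_of_tx <- txGene[names(exons)]
    spans <- unlist(range(exons), use.names = FALSE)
    gsp <- split(spans, unname(gene_of_tx))
    genes <- unlist(range(gsp))
    new("GeneAnnotation", exons = exons, txGene = txGene, genes = genes)
}

setMethod("show", "GeneAnnotation", function(object) {
    cat("GeneAnnotation:", length(object@genes), "genes,",
        length(object@exons), "transcripts\n")
})

#' @describeIn GeneAnnotation gene ids.
#' @param object a `GeneAnnotation`.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname GeneAnnotation
#' @export
setMethod("geneIds", "GeneAnnotation", function(object)
    names(object@genes))

#' ForceRampTrace: a bead-height time series under a force schedule
#'
#' Single-molecule magnetic-tweezers scan: bead height (nm) sampled
#' uniformly in time while the applied force follows either a linear
#' ramp `F(t) = f_start + r t` or a calibrated magnet law `F(d)`
#' evaluated along a magnet-distance series `d(t)`.
#'
#' @slot time numeric, seconds, strictly increasing and uniform.
#' @slot height numeric, nm, same length as time.
#' @slot schedule list; either `list(type = "linear", f_start, rate,
#'   f_max)` (pN, pN/s) or `list(type = "magnet", calibration =
#'   data.frame(d, force), d = numeric)` with `d` parallel to `time`.
#' @slot sampleRate numeric, Hz.
#' @export
setClass("ForceRampTrace",
         representation(time = "numeric", height = "numeric",
                        schedule = "list", sampleRate = "numeric"))

setValidity("ForceRampTrace", function(object) {
    msg <- character()
    if (length(object@time) != length(object@height))
        msg <- c(msg, "time and height lengths differ")
    dt <- diff(object@time)
    if (length(dt) && (any(dt <= 0) ||
        diff(range(dt)) > 1e-6 * mean(dt)))
        msg <- c(msg, "time must be strictly increasing and uniform")
    if (!object@schedule$type %in% c("linear", "magnet"))
        msg <- c(msg, "schedule type must be 'linear' or 'magnet'")
    if (length(msg)) msg else TRUE
})

#' Construct a ForceRampTrace
#' @param time,height numeric vectors (s, nm).
#' @param schedule force schedule list, see [ForceRampTrace-class].
#' @param sampleRate sampling rate in Hz; defaults to `1/median(diff(time))`.
#' @return a [ForceRampTrace-class].
#' @export
ForceRampTrace <- function(time, height, schedule,
                           sampleRate = 1 / median(diff(time))) {
    new("ForceRampTrace", time = as.numeric(time),
        height = as.numeric(height), schedule = schedule,
        sampleRate = sampleRate)
}

setMethod("show", "ForceRampTrace", function(object) {
    cat(sprintf(
        "ForceRampTrace: %d samples @ %.0f Hz, %.1f s, schedule: %s\n",
        length(object@time), object@sampleRate,
        diff(range(object@time)), object@schedule$type))
})
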