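#' Read a STAR SJ.out.tab junction file
#'
#' Parses the 9-column STAR splice-junction format.  Coordinates are the
#' 1-based first and last intron bases; strand codes 0/1/2 map to
#' `*`/`+`/`-`; uniquely-mapping read counts (column 7) are retained.
#'
#' @param path path to an `SJ.out.tab` file.
#' @param sample sample id; defaults to the file name without extension.
#' @param librarySize library total for logCPM; defaults to the sum of
#'   unique counts in the file.
#' @return a single-sample [JunctionExperiment].
#' @examples
#' f <- tempfile()
#' writeLines("chr9\t35718407\t35718500\t2\t2\t1\t42\t0\t38", f)
#' counts(readSJTab(f, sample = "s1"))
#' @export
readSJTab <- function(path, sample = NULL, librarySize = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (is.null(sample))
        sample <- sub("\\.[^.]*$", "", basename(path))
    if (length(lines) == 0L) {
        return(JunctionExperiment(
            matrix(numeric(), 0, 1, dimnames = list(NULL, sample)),
            GRanges(), librarySizes = max(1, librarySize %||% 1)))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 9)) {
        bad <- which(nf < 9)[1]
        stop(sprintf("malformed SJ.out.tab row at line %d: expected >= 9 fields, got %d",
                     bad, nf[bad]))
    }
    m <- do.call(rbind, fields)
    strand_code <- suppressWarnings(as.integer(m[, 4]))
    if (any(is.na(strand_code)) || any(!strand_code %in% 0:2)) {
        bad <- which(is.na(strand_code) | !strand_code %in% 0:2)[1]
        stop(sprintf("invalid strand code '%s' at line %d (expected 0, 1 or 2)",
                     m[bad, 4], bad))
    }
    st <- suppressWarnings(as.integer(m[, 2]))
    en <- suppressWarnings(as.integer(m[, 3]))
    cnt <- suppressWarnings(as.numeric(m[, 7]))
    if (any(is.na(st)) || any(is.na(en)) || any(is.na(cnt))) {
        bad <- which(is.na(st) | is.na(en) | is.na(cnt))[1]
        stop(sprintf("malformed SJ.out.tab row at line %d: non-numeric coordinates or count",
                     bad))
    }
    gr <- GRanges(m[, 1], IRanges(st, en),
                  strand = c("*", "+", "-")[strand_code + 1L])
    counts <- matrix(cnt, ncol = 1, dimnames = list(NULL, sample))
    JunctionExperiment(counts, gr,
                       librarySizes = librarySize %||% max(1, sum(cnt)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge single-sample junction tables into one experiment
#'
#' Takes the union of junction keys, zero-filling counts where a
#' junction was not observed in a sample, and orders junctions by
#' (chrom, intron start, intron end).
#'
#' @param ... `JunctionExperiment` fragments (or a single list of them).
#' @return a merged [JunctionExperiment].
#' @export
mergeSamples <- function(...) {
    frags <- list(...)
    if (length(frags) == 1L && is.list(frags[[1]]) &&
        !is(frags[[1]], "JunctionExperiment"))
        frags <- frags[[1]]
    if (length(frags) == 0L) stop("need at least one fragment")
    samples <- unlist(lapply(frags, colnames))
    if (anyDuplicated(samples))
        stop("duplicate sample id: ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    all_gr <- unique(do.call(c, lapply(frags, function(f)
        granges(rowRanges(f)))))
    ord <- order(as.character(seqnames(all_gr)), start(all_gr), end(all_gr))
    all_gr <- all_gr[ord]
    keys <- junctionKey(all_gr)
    cnt <- matrix(0, length(all_gr), length(samples),
                  dimnames = list(keys, samples))
    libs <- numeric(length(samples))
    names(libs) <- samples
    for (f in frags) {
        cnt[junctionKey(f), colnames(f)] <- counts(f)
        libs[colnames(f)] <- librarySizes(f)
    }
    JunctionExperiment(cnt, all_gr, librarySizes = libs)
}

#' Read a gene annotation from GTF
#'
#' Imports a GTF2.2 file (with `gene_id`/`transcript_id` attributes) and
#' assembles per-transcript exon structures.
#'
#' @param path GTF file path.
#' @return a [GeneAnnotation-class].
#' @export
readGeneAnnotation <- function(path) {
    gr <- rtracklayer::import(path, format = "gtf")
    ex <- gr[gr$type == "exon"]
    if (length(ex) == 0L) stop("no exon records in GTF")
    exl <- split(granges(ex), ex$transcript_id)
    tx2g <- tapply(as.character(ex$gene_id), ex$transcript_id,
                   function(g) g[1])
    GeneAnnotation(exl, setNames(as.character(tx2g), names(tx2g)))
}

#' Write a GeneAnnotation to GTF
#' @param ann a [GeneAnnotation-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneAnnotation <- function(ann, path) {
    ex <- unlist(ann@exons, use.names = FALSE)
    tx <- rep(names(ann@exons), lengths(ann@exons))
    ex$type <- "exon"
    ex$source <- "spliceforce"
    ex$transcript_id <- tx
    ex$gene_id <- unname(ann@txGene[tx])
    rtracklayer::export(ex, path, format = "gtf")
    invisible(path)
}

## Annotated intron structures per gene: for every transcript, introns
## between consecutive exons; returns data.frame(gene, start, end).
annotatedIntrons <- function(ann) {
    res <- lapply(names(ann@exons), function(tx) {
        ex <- ann@exons[[tx]]
        if (length(ex) < 2) return(NULL)
        data.frame(gene = unname(ann@txGene[tx]),
                   start = end(ex)[-length(ex)] + 1L,
                   end = start(ex)[-1] - 1L)
    })
    out <- do.call(rbind, res)
    if (is.null(out)) data.frame(gene = character(), start = integer(),
                                 end = integer()) else unique(out)
}

#' Annotate junctions against a gene model
#'
#' Assigns each junction to the gene whose span contains the whole
#' intron (ties broken by matching strand, then smallest gene span;
#' remaining ambiguity -> unassigned) and classifies it against the
#' annotated exon boundaries of that gene:
#'
#' * `annotated` — both splice sites and their pairing occur between
#'   consecutive exons of some transcript;
#' * `novel_combination` — both sites known, pairing not;
#' * `novel_donor` / `novel_acceptor` — only one site known; naming is
#'   strand-aware (donor = transcription-upstream site, so the donor of
#'   a minus-strand gene is the intron *end* boundary);
#' * `novel_both` — neither site known;
#' * `unassigned` — no (unambiguous) gene.
#'
#' A transcript-order index numbers each gene's junctions `1..n` along
#' the direction of transcription (minus-strand genes right-to-left).
#'
#' @param je a [JunctionExperiment].
#' @param ann a [GeneAnnotation-class].
#' @return `je` with rowData columns `gene_id`, `class`, `tx_index`.
#' @export
annotateJunctions <- function(je, ann) {
    gr <- rowRanges(je)
    n <- length(gr)
    gene_id <- rep(NA_character_, n)
    cls <- rep("unassigned", n)
    tx_index <- rep(NA_integer_, n)

    genes <- ann@genes
    hits <- findOverlaps(granges(gr), genes, type = "within",
                         ignore.strand = TRUE)
    if (length(hits)) {
        hl <- split(subjectHits(hits), queryHits(hits))
        for (qs in names(hl)) {
            q <- as.integer(qs)
            cand <- hl[[qs]]
            jstrand <- as.character(strand(gr))[q]
            if (jstrand != "*") {
                sm <- cand[as.character(strand(genes))[cand] == jstrand]
                if (length(sm)) cand <- sm
            }
            if (length(cand) > 1) {
                w <- width(genes)[cand]
                cand <- cand[w == min(w)]
            }
            if (length(cand) == 1) gene_id[q] <- names(genes)[cand]
        }
    }

    introns <- annotatedIntrons(ann)
    gstrand <- setNames(as.character(strand(genes)), names(genes))
    for (g in unique(gene_id[!is.na(gene_id)])) {
        idx <- which(gene_id == g)
        gi <- introns[introns$gene == g, ]
        pair_keys <- paste(gi$start, gi$end)
        js <- start(gr)[idx]
        je_ <- end(gr)[idx]
        known_start <- js %in% gi$start
        known_end <- je_ %in% gi$end
        known_pair <- paste(js, je_) %in% pair_keys
        minus <- gstrand[g] == "-"
        cls[idx] <- ifelse(known_pair, "annotated",
            ifelse(known_start & known_end, "novel_combination",
            ifelse(known_start & !known_end,
                   if (minus) "novel_donor" else "novel_acceptor",
            ifelse(!known_start & known_end,
                   if (minus) "novel_acceptor" else "novel_donor",
                   "novel_both"))))
        ## transcript-order index along the direction of transcription
        o <- if (minus) order(-je_, -js) else order(js, je_)
        tx_index[idx[o]] <- seq_along(idx)
    }

    rowData(je)$gene_id <- gene_id
    rowData(je)$class <- cls
    rowData(je)$tx_index <- tx_index
    je
}

#' Per-junction annotation status
#' @param je an annotated [JunctionExperiment].
#' @return `DataFrame` with `gene_id`, `class`, `tx_index`, row names
#'   the junction keys.
#' @export
junctionStatus <- function(je) {
    if (!"class" %in% colnames(rowData(je)))
        stop("junctions are not annotated; run annotateJunctions() first")
    rowData(je)[, c("gene_id", "class", "tx_index")]
}

#' Write/read a merged junction count matrix (TSV)
#'
#' Row ids are junction keys `chrom:start-end:strand` (intron
#' coordinates, 1-based inclusive); the first data row `__library_size`
#' stores the per-sample totals so a round trip is exact.
#'
#' @param je a [JunctionExperiment].
#' @param path TSV path.
#' @return `path` (write) / a [JunctionExperiment] (read).
#' @export
writeJunctionMatrix <- function(je, path) {
    m <- rbind(`__library_size` = librarySizes(je), counts(je))
    df <- data.frame(junction = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeJunctionMatrix
#' @export
readJunctionMatrix <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
    libs <- as.numeric(df[df$junction == "__library_size", -1])
    df <- df[df$junction != "__library_size", ]
    keys <- df$junction
    parts <- regmatches(keys,
        regexec("^(.+):([0-9]+)-([0-9]+):([+*-])$", keys))
    bad <- which(lengths(parts) != 5)
    if (length(bad)) stop("malformed junction key: ", keys[bad[1]])
    pm <- do.call(rbind, parts)
    gr <- GRanges(pm[, 2], IRanges(as.integer(pm[, 3]), as.integer(pm[, 4])),
                  strand = pm[, 5])
    cnt <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(cnt) <- "double"
    rownames(cnt) <- NULL
    JunctionExperiment(cnt, gr, librarySizes = libs)
}
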