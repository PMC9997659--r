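#' Detect cassette-exon events from junction trios
#'
#' A cassette event is a junction trio within one gene: two inclusion
#' junctions flanking the cassette exon and one skipping junction whose
#' intron spans exactly the union of the two flanking introns plus the
#' cassette.  Events may pair non-annotated flanking junctions with an
#' annotated skipping junction — the signature of a hidden exon inside
#' a known intron.
#'
#' @param je an annotated [JunctionExperiment].
#' @return a [GenomicRanges::GRanges] of cassette intervals (1-based
#'   inclusive) with metadata columns `gene_id`, `inc1`, `inc2`, `skip`
#'   (junction keys) and `flank_status`, `skip_status`.
#' @export
detectCassetteEvents <- function(je) {
    st <- junctionStatus(je)
    gr <- rowRanges(je)
    events <- list()
    for (g in unique(st$gene_id[!is.na(st$gene_id)])) {
        idx <- which(!is.na(st$gene_id) & st$gene_id == g)
        if (length(idx) < 3) next
        s <- start(gr)[idx]; e <- end(gr)[idx]
        for (a in seq_along(idx)) for (b in seq_along(idx)) {
            if (e[a] + 1L >= s[b]) next     # need room for a cassette
            skip <- which(s == s[a] & e == e[b])
            if (!length(skip)) next
            i1 <- idx[a]; i2 <- idx[b]; i3 <- idx[skip[1]]
            events[[length(events) + 1L]] <- list(
                gene_id = g,
                chrom = as.character(seqnames(gr))[i3],
                start = e[a] + 1L, end = s[b] - 1L,
                strand = as.character(strand(gr))[i3],
                inc1 = junctionKey(gr[i1]), inc2 = junctionKey(gr[i2]),
                skip = junctionKey(gr[i3]),
                flank_status = paste(st$class[i1], st$class[i2],
                                     sep = "/"),
                skip_status = st$class[i3])
        }
    }
    if (!length(events)) {
        out <- GRanges()
        mcols(out) <- DataFrame(gene_id = character(), inc1 = character(),
                                inc2 = character(), skip = character(),
                                flank_status = character(),
                                skip_status = character())
        return(out)
    }
    df <- do.call(rbind, lapply(events, as.data.frame))
    out <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
    mcols(out) <- DataFrame(df[, c("gene_id", "inc1", "inc2", "skip",
                                   "flank_status", "skip_status")])
    names(out) <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
    out
}

#' Percent spliced-in for one cassette event
#'
#' `psi_hat = mean(c_inc1, c_inc2) / (mean(c_inc1, c_inc2) + c_skip)`.
#' The mean (not the sum) of the two inclusion junctions keeps the
#' estimator unbiased for the inclusion fraction when both flanks have
#' equal expected depth.  Samples whose denominator falls below
#' `minCov` are reported missing.
#'
#' @param event one element of [detectCassetteEvents()] output (or any
#'   GRanges row with `inc1`, `inc2`, `skip` keys).
#' @param je the [JunctionExperiment] holding the counts.
#' @param minCov minimum informative coverage (default 10, matching the
#'   junction expression filter).
#' @return named per-sample psi values in `[0, 1]`, NA where coverage
#'   is insufficient.
#' @examples
#' # c_inc = (50, 50), c_skip = 0 -> psi 1; (30, 30) vs 30 -> 0.5
#' @export
computePsi <- function(event, je, minCov = 10) {
    keys <- c(event$inc1, event$inc2, event$skip)
    if (!all(keys %in% rownames(je)))
        stop("event junctions missing from the table")
    cnt <- counts(je)[keys, , drop = FALSE]
    inc <- (cnt[1, ] + cnt[2, ]) / 2
    denom <- inc + cnt[3, ]
    ifelse(denom >= minCov, inc / denom, NA_real_)
}

#' PSI matrix across events
#' @param events [detectCassetteEvents()] output.
#' @param je the [JunctionExperiment].
#' @param minCov see [computePsi()].
#' @return events x samples matrix of psi values.
#' @export
psiMatrix <- function(events, je, minCov = 10) {
    m <- matrix(NA_real_, length(events), ncol(je),
                dimnames = list(names(events), colnames(je)))
    for (i in seq_along(events))
        m[i, ] <- computePsi(events[i], je, minCov)
    m
}

#' Correlate PSI profiles across events
#'
#' Pearson correlation on pairwise-complete samples for every event
#' pair (or one requested pair), with BH adjustment across all tested
#' pairs — the screen for trans-mutually exclusive splicing (strongly
#' anti-correlated inclusion of exons in different genes).
#'
#' @param psi a [psiMatrix()].
#' @param eventA,eventB optional row names restricting to one pair (the
#'   pair's p-value is still BH-adjusted across all pairs of `psi`).
#' @param minN minimum complete pairs (default 3).
#' @return `DataFrame` with `eventA`, `eventB`, `r`, `n_used`, `p`,
#'   `fdr`, `degenerate` (TRUE where a constant vector made r
#'   undefined).
#' @export
correlateEvents <- function(psi, eventA = NULL, eventB = NULL, minN = 3) {
    ev <- rownames(psi)
    if (length(ev) < 2) stop("need at least two events")
    pairs <- t(utils::combn(ev, 2))
    res <- lapply(seq_len(nrow(pairs)), function(i) {
        x <- psi[pairs[i, 1], ]; y <- psi[pairs[i, 2], ]
        ok <- complete.cases(x, y)
        n <- sum(ok)
        if (n < minN)
            return(data.frame(r = NA_real_, n_used = n, p = NA_real_,
                              degenerate = FALSE))
        if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
            return(data.frame(r = NA_real_, n_used = n, p = NA_real_,
                              degenerate = TRUE))
        r <- cor(x[ok], y[ok])
        tv <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
        data.frame(r = r, n_used = n, p = 2 * pt(-abs(tv), n - 2),
                   degenerate = FALSE)
    })
    res <- do.call(rbind, res)
    out <- DataFrame(eventA = pairs[, 1], eventB = pairs[, 2], res)
    out$fdr <- bhFdr(out$p)
    if (!is.null(eventA)) {
        sel <- (out$eventA == eventA & out$eventB == eventB) |
            (out$eventA == eventB & out$eventB == eventA)
        if (!any(sel)) stop("requested event pair not found")
        out <- out[sel, ]
    }
    out
}

#' Write cassette events and PSI to disk
#'
#' Events as a BED-like TSV (1-based inclusive cassette interval plus
#' junction keys); PSI as events x samples TSV.
#'
#' @param events [detectCassetteEvents()] output.
#' @param psi a [psiMatrix()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeEvents <- function(events, psi, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    df <- data.frame(chrom = as.character(seqnames(events)),
                     start = start(events), end = end(events),
                     strand = as.character(strand(events)),
                     as.data.frame(mcols(events)))
    write.table(df, file.path(dir, "cassette_events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    pm <- data.frame(event = rownames(psi), psi, check.names = FALSE)
    write.table(pm, file.path(dir, "psi_matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}
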