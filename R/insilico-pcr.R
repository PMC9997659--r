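#' In-silico PCR: exact-match amplicon search
#'
#' Finds every product in which the forward primer matches the sense
#' strand upstream of a reverse-complemented match of the reverse
#' primer.  Matching is exact (the published 18-23-mers at stringent
#' annealing justify no mismatch model); multiple binding sites yield
#' all pairwise products up to `maxLen`, mirroring multi-band gels.
#'
#' @param template DNA sequence (character or `DNAString`).
#' @param fwd,rev primer sequences 5'->3' (A/C/G/T, length >= 10).
#' @param maxLen maximum product length in bp.
#' @return data.frame of amplicons (`start`, `end` 1-based inclusive on
#'   the template, `length`, `sequence`), sorted by length; zero rows
#'   when a primer does not bind.
#' @examples
#' fx <- makePcrFixture("TLN1-like")
#' findAmplicons(fx$templateSkipping, fx$primerFwd, fx$primerRev)$length
#' @export
findAmplicons <- function(template, fwd, rev, maxLen = 5000) {
    checkPrimer <- function(p) {
        if (nchar(p) < 10 || grepl("[^ACGT]", p))
            stop("primers must be >= 10 nt over A/C/G/T")
    }
    checkPrimer(fwd); checkPrimer(rev)
    tmpl <- DNAString(as.character(template))
    fhits <- matchPattern(fwd, tmpl)
    rhits <- matchPattern(as.character(reverseComplement(DNAString(rev))),
                          tmpl)
    out <- data.frame(start = integer(), end = integer(),
                      length = integer(), sequence = character())
    for (i in seq_along(fhits)) for (j in seq_along(rhits)) {
        fs <- start(fhits)[i]; fe <- end(fhits)[i]
        rs <- start(rhits)[j]; re <- end(rhits)[j]
        if (rs <= fe) next              # reverse site must lie downstream
        len <- re - fs + 1L
        if (len > maxLen) next
        out <- rbind(out, data.frame(
            start = fs, end = re, length = len,
            sequence = as.character(subseq(tmpl, fs, re))))
    }
    out[order(out$length), , drop = FALSE]
}

#' Translate the peptide inserted by an in-frame cassette
#'
#' Given the coding sequence without and with a contiguous insert at a
#' codon boundary, returns the inserted residues.  An insert whose
#' length is not divisible by 3 is a frameshift and raises an error; an
#' insert containing an in-frame stop is returned with attribute
#' `hasStop = TRUE` and a warning.
#'
#' @param cdsWithout,cdsWith coding sequences starting at the same
#'   reading frame (character or `DNAString`).
#' @return inserted peptide as a character string (empty for an empty
#'   insert).
#' @examples
#' # a 51-nt in-frame insert yields a 17-residue peptide
#' @export
translateInsert <- function(cdsWithout, cdsWith) {
    w0 <- as.character(cdsWithout)
    w1 <- as.character(cdsWith)
    L <- nchar(w1) - nchar(w0)
    if (L < 0) stop("'with' sequence is shorter than 'without'")
    if (L == 0) {
        if (w0 != w1) stop("equal-length sequences differ: not an insertion")
        return("")
    }
    if (L %% 3 != 0)
        stop(sprintf("frameshift: insert length %d is not divisible by 3", L))
    ## locate the insert via longest common prefix, verify the deletion
    ## identity, then diff at the peptide level to stay in frame
    p <- lcpLength(w0, w1)
    p <- min(p, nchar(w0))
    if (paste0(substr(w1, 1, p),
               substr(w1, p + L + 1L, nchar(w1))) != w0)
        stop("'with' is not 'without' plus one contiguous insert")
    tr <- function(s) {
        n <- 3L * (nchar(s) %/% 3L)
        as.character(translate(DNAString(substr(s, 1, n)),
                               if.fuzzy.codon = "solve"))
    }
    pep0 <- tr(w0); pep1 <- tr(w1)
    pp <- min(lcpLength(pep0, pep1), nchar(pep0))
    ins <- substr(pep1, pp + 1L, pp + L %/% 3L)
    if (grepl("\\*", ins)) {
        warning("insert contains an in-frame stop codon")
        attr(ins, "hasStop") <- TRUE
    }
    ins
}

## length of the longest common prefix of two strings
lcpLength <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    if (n == 0) return(0L)
    av <- utf8ToInt(substr(a, 1, n))
    bv <- utf8ToInt(substr(b, 1, n))
    d <- which(av != bv)
    if (length(d)) d[1] - 1L else n
}

#' Genomic interval length under an explicit coordinate convention
#'
#' @param chrom chromosome (recorded, not used in arithmetic).
#' @param start,end interval bounds.
#' @param convention `"one_based_inclusive"` (`end - start + 1`) or
#'   `"half_open"` (`end - start`).
#' @return interval length in nt.
#' @examples
#' intervalLength("chr9", 35718356, 35718406)   # 51
#' @export
intervalLength <- function(chrom, start, end,
                           convention = c("one_based_inclusive",
                                          "half_open")) {
    convention <- match.arg(convention)
    if (convention == "one_based_inclusive") {
        if (end < start) stop("end must be >= start (inclusive)")
        end - start + 1
    } else {
        if (end <= start) stop("end must be > start (half-open)")
        end - start
    }
}
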