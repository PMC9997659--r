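#' Synthetic RT-PCR template fixtures for cassette-exon validation
#'
#' Builds a pair of templates (cassette-skipping and cassette-including)
#' flanked by the published primer pair for the corresponding assay:
#'
#' * `"TLN1-like"`: the TLN1 exon-17b primers delimit a 183 bp product
#'   on the skipping template; the cassette is 51 nt, so the inclusion
#'   product is 234 bp.
#' * `"CLSTN1-like"`: the CLSTN1 exon-11 primers delimit a 278 bp
#'   product on the inclusion template; the cassette is 57 nt, so the
#'   skipping product is 221 bp.
#'
#' Sequence between and around the primer sites is random (seeded) and
#' re-drawn until each primer matches exactly once in its proper
#' orientation on each template.  The cassette is inserted at a codon
#' boundary of the amplicon interior, and both cassette lengths are
#' divisible by 3, so the fixtures are in frame.
#'
#' @param mode `"TLN1-like"` or `"CLSTN1-like"`.
#' @param flank nt of random flanking sequence outside the amplicon.
#' @param seed integer seed.
#' @return list with `templateInclusion`, `templateSkipping` (character
#'   sequences), `primerFwd`, `primerRev`, `cassette`, and
#'   `ampliconLengths` (named: inclusion, skipping).
#' @examples
#' fx <- makePcrFixture("TLN1-like")
#' fx$ampliconLengths
#' @export
makePcrFixture <- function(mode = c("TLN1-like", "CLSTN1-like"),
                           flank = 60, seed = 1) {
    mode <- match.arg(mode)
    if (mode == "TLN1-like") {
        fwd <- "CAAGCAGCTGGGAACGTG"          # TLN1_17b_fwd
        rev <- "CTGAAGTCCCGAGTCCTCTG"        # TLN1_17b_rev
        skipLen <- 183L
        cassLen <- 51L
    } else {
        fwd <- "GACTCTCTATGTGGATGGCACG"      # CLSTN1_11_fwd
        rev <- "CCTTGCAGGTATACAGACAGTCG"     # CLSTN1_11_rev
        skipLen <- 221L
        cassLen <- 57L
    }
    rcrev <- as.character(reverseComplement(DNAString(rev)))
    midLen <- skipLen - nchar(fwd) - nchar(rev)
    stopifnot(midLen > 0)

    randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")
    occursOnce <- function(tmpl) {
        all(vapply(c(fwd, rcrev), function(p)
            length(matchPattern(p, DNAString(tmpl))) == 1L, logical(1)))
    }
    with_seed(as.integer(seed), {
        for (attempt in 1:100) {
            mid <- randSeq(midLen)
            cassette <- randSeq(cassLen)
            left <- randSeq(flank)
            right <- randSeq(flank)
            skipping <- paste0(left, fwd, mid, rcrev, right)
            ## insert at a codon boundary of the amplicon interior
            ins_at <- nchar(left) + nchar(fwd) + 3L * (midLen %/% 6L)
            inclusion <- paste0(substr(skipping, 1, ins_at), cassette,
                                substr(skipping, ins_at + 1L,
                                       nchar(skipping)))
            if (occursOnce(skipping) && occursOnce(inclusion)) break
        }
        stopifnot(occursOnce(skipping), occursOnce(inclusion))
        list(templateInclusion = inclusion, templateSkipping = skipping,
             primerFwd = fwd, primerRev = rev, cassette = cassette,
             ampliconLengths = c(inclusion = skipLen + cassLen,
                                 skipping = skipLen))
    })
}

#' Write a PCR fixture as FASTA templates plus a primer TSV
#'
#' @param fx a [makePcrFixture()] result.
#' @param dir output directory (created).
#' @param name assay name used in file prefixes.
#' @return `dir`, invisibly.
#' @export
writePcrFixture <- function(fx, dir, name = "fixture") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    seqs <- DNAStringSet(c(inclusion = fx$templateInclusion,
                           skipping = fx$templateSkipping))
    Biostrings::writeXStringSet(seqs,
        file.path(dir, paste0(name, "_templates.fasta")))
    write.table(
        data.frame(name = name, fwd = fx$primerFwd, rev = fx$primerRev),
        file.path(dir, paste0(name, "_primers.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
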