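#' Biweight midcorrelation
#'
#' Robust correlation built on median/MAD standardization with Tukey
#' biweights (tuning constant 9): observations further than 9 MADs from
#' the median get zero weight, so single outliers cannot dominate the
#' coefficient.  A vector with zero MAD cannot be standardized; the
#' function then falls back to the Pearson coefficient and flags the
#' result with attribute `fallback = TRUE`.
#'
#' @param x,y numeric vectors; pairs with missing values are dropped.
#' @return correlation in `[-1, 1]`.
#' @examples
#' x <- rnorm(50)
#' bicor(x, 2 * x + 1)   # affine invariance: exactly 1
#' @export
bicor <- function(x, y) {
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop("need at least 3 paired finite values")
    bw <- function(v) {
        med <- median(v)
        madv <- mad(v, constant = 1)
        if (madv == 0) return(NULL)     # degenerate, caller falls back
        u <- (v - med) / (9 * madv)
        w <- (1 - u^2)^2 * (abs(u) < 1)
        (v - med) * w
    }
    xt <- bw(x); yt <- bw(y)
    if (is.null(xt) || is.null(yt)) {
        if (sd(x) == 0 || sd(y) == 0)
            stop("constant vector: correlation undefined")
        r <- cor(x, y)
        attr(r, "fallback") <- TRUE
        return(r)
    }
    r <- sum(xt * yt) / sqrt(sum(xt^2) * sum(yt^2))
    max(-1, min(1, r))
}

#' Associate feature profiles with continuous sample traits
#'
#' Computes the biweight midcorrelation of every (feature, trait) pair
#' on pairwise-complete overlapping samples, with a Student-t
#' approximate p-value on `n_used - 2` degrees of freedom and BH
#' adjustment across all pairs.  Results are ranked by `|rho|`.  The
#' radar export keeps pairs passing both the FDR and `|rho|` gates and
#' fixes the radial axis to `[-0.5, 0.5]`, the conventional display
#' range for these correlation profiles.
#'
#' @param features features x samples matrix (e.g. junction logCPM or
#'   event PSI), with sample column names.
#' @param traits traits x samples matrix (e.g. drug AUC or
#'   gene-dependency scores); missing values allowed.
#' @param alpha FDR gate for the radar export.
#' @param rhoMin |rho| gate for the radar export.
#' @param minN minimum overlapping complete pairs per test.
#' @return list with `associations` (`DataFrame`: feature, trait, rho,
#'   n_used, p, fdr, ranked by |rho|) and `radar` (list with
#'   `axis_range` and the gated records).
#' @export
associateTraits <- function(features, traits, alpha = 0.05,
                            rhoMin = 0.2, minN = 3) {
    shared <- intersect(colnames(features), colnames(traits))
    if (length(shared) < minN)
        stop("need at least ", minN, " overlapping samples")
    features <- features[, shared, drop = FALSE]
    traits <- traits[, shared, drop = FALSE]
    grid <- expand.grid(feature = rownames(features),
                        trait = rownames(traits),
                        stringsAsFactors = FALSE)
    res <- lapply(seq_len(nrow(grid)), function(i) {
        x <- features[grid$feature[i], ]
        y <- traits[grid$trait[i], ]
        ok <- complete.cases(x, y)
        n <- sum(ok)
        if (n < minN)
            return(data.frame(rho = NA_real_, n_used = n, p = NA_real_))
        rho <- tryCatch(as.numeric(bicor(x[ok], y[ok])),
                        error = function(e) NA_real_)
        if (is.na(rho))
            return(data.frame(rho = NA_real_, n_used = n, p = NA_real_))
        tv <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
        data.frame(rho = rho, n_used = n, p = 2 * pt(-abs(tv), n - 2))
    })
    res <- do.call(rbind, res)
    if (all(is.na(res$rho))) stop("no testable feature-trait pairs")
    out <- DataFrame(feature = grid$feature, trait = grid$trait, res)
    out$fdr <- bhFdr(out$p)
    out <- out[order(-abs(out$rho), na.last = TRUE), ]
    keep <- !is.na(out$fdr) & out$fdr < alpha & abs(out$rho) > rhoMin
    radar <- list(axis_range = c(-0.5, 0.5),
                  records = as.data.frame(out[keep, ]))
    list(associations = out, radar = radar)
}

#' Hypergeometric over-representation of a selected gene list
#'
#' For each gene set, the upper hypergeometric tail probability of the
#' observed overlap between the selection (e.g. top-ranked correlates)
#' and the set within the universe, BH-adjusted across sets.
#'
#' @param selected character vector of selected genes (must lie in the
#'   universe).
#' @param geneSets named list of character vectors; genes outside the
#'   universe are ignored.
#' @param universe character vector of all testable genes.
#' @return `DataFrame` with `set`, `overlap`, `set_size`,
#'   `selection_size`, `p`, `fdr`.
#' @export
overrepresent <- function(selected, geneSets, universe) {
    universe <- unique(universe)
    if (!length(universe)) stop("empty universe")
    if (!all(selected %in% universe))
        stop("selection contains genes outside the universe")
    selected <- unique(selected)
    k <- length(selected)
    N <- length(universe)
    res <- lapply(names(geneSets), function(nm) {
        set <- intersect(unique(geneSets[[nm]]), universe)
        m <- length(set)
        ov <- length(intersect(selected, set))
        p <- phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
        data.frame(set = nm, overlap = ov, set_size = m,
                   selection_size = k, p = p)
    })
    out <- DataFrame(do.call(rbind, res))
    out$fdr <- bhFdr(out$p)
    out[order(out$p), ]
}

#' Write trait associations (TSV) and the radar export (JSON)
#' @param assoc an [associateTraits()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeAssociations <- function(assoc, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.table(as.data.frame(assoc$associations),
                file.path(dir, "trait_associations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_json(assoc$radar, file.path(dir, "spliceradar.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}
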