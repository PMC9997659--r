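#' Filter junctions by mean read count
#'
#' Retains junctions whose across-sample mean count is at least
#' `minMean` (default 10, the standard expression threshold for
#' junction-level testing).  Library sizes are unchanged.
#'
#' @param je a [JunctionExperiment].
#' @param minMean minimum mean count (inclusive).
#' @return the filtered [JunctionExperiment].
#' @export
filterJunctions <- function(je, minMean = 10) {
    je[rowMeans(counts(je)) >= minMean, ]
}

#' Log2 counts per million
#'
#' `log2((count + 0.5) / (library_size + 1) * 1e6)`; the half-count and
#' unit-library offsets are the standard convention for variance-stable
#' log-cpm of counts.
#'
#' @param je a [JunctionExperiment].
#' @return junction x sample matrix of logCPM values.
#' @export
logCpm <- function(je) {
    libs <- librarySizes(je)
    if (any(libs == 0)) stop("zero library size")
    log2(t(t(counts(je) + 0.5) / (libs + 1)) * 1e6)
}

## Least-squares machinery shared by the weight and fit steps: row-wise
## (weighted) regression of E on the design.
rowFit <- function(E, design, weights = NULL) {
    n <- ncol(E); p <- ncol(design)
    if (n - p < 2) stop("need at least 2 residual degrees of freedom")
    nr <- nrow(E)
    coef <- matrix(NA_real_, nr, p)
    s2 <- numeric(nr)
    unscaled2 <- numeric(nr)  # var(beta_p) / sigma^2 (contrast column)
    fitted <- matrix(NA_real_, nr, n)
    for (i in seq_len(nr)) {
        w <- if (is.null(weights)) rep(1, n) else weights[i, ]
        sw <- sqrt(w)
        Xw <- design * sw
        yw <- E[i, ] * sw
        qr_ <- qr(Xw)
        b <- qr.coef(qr_, yw)
        res <- yw - Xw %*% b
        coef[i, ] <- b
        s2[i] <- sum(res^2) / (n - p)
        XtX_inv <- chol2inv(qr.R(qr_))
        unscaled2[i] <- XtX_inv[p, p]
        fitted[i, ] <- design %*% b
    }
    list(coef = coef, s2 = s2, unscaled2 = unscaled2, fitted = fitted,
         df = n - p)
}

#' Observation-level variance weights from the mean-variance trend
#'
#' Fits each junction's logCPM on the design, regresses the fourth-root
#' residual variance (sqrt of residual sd) on the mean logCPM with
#' lowess, and assigns each observation the weight
#' `(predicted sqrt-sd)^-4` — i.e. the inverse of the variance the
#' trend predicts at that observation's fitted value.  With a single
#' junction (no trend to fit) unit weights are returned.
#'
#' @param E logCPM matrix (junctions x samples).
#' @param design model matrix (samples x coefficients).
#' @param span lowess span.
#' @return weight matrix, same shape as `E`, strictly positive.
#' @export
varianceWeights <- function(E, design, span = 0.5) {
    E <- as.matrix(E)
    if (nrow(design) != ncol(E))
        stop("design rows must match number of samples")
    if (nrow(design) <= ncol(design))
        stop("fewer samples than design columns")
    if (nrow(E) < 2)
        return(matrix(1, nrow(E), ncol(E), dimnames = dimnames(E)))
    fit <- rowFit(E, design)
    sqrt_sd <- sqrt(sqrt(fit$s2))
    mean_e <- rowMeans(E)
    lo <- lowess(mean_e, sqrt_sd, f = span)
    trend <- approxfun(lo$x, lo$y, rule = 2)
    pred <- trend(fit$fitted)
    pred <- pmax(pred, 1e-4)
    w <- matrix(pred, nrow(E), ncol(E))^-4
    dimnames(w) <- dimnames(E)
    w
}

## Method-of-moments estimate of the scaled-F prior for residual
## variances (Smyth-style on log s^2): returns prior df d0 and prior
## variance s0^2.  d0 is capped to represent infinity finitely.
estimatePrior <- function(s2, df, cap = 1e6) {
    s2 <- pmax(s2, 1e-12)
    z <- log(s2)
    e <- z - digamma(df / 2) + log(df / 2)
    evar <- var(e)
    rhs <- evar - trigamma(df / 2)
    if (is.na(rhs) || rhs <= 0) {
        d0 <- cap
    } else {
        d0 <- 2 * trigammaInverse(rhs)
        d0 <- min(d0, cap)
    }
    s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    list(d0 = d0, s0sq = s0sq)
}

## Newton solve of trigamma(x) = y (y > 0), as used for the prior df.
trigammaInverse <- function(y) {
    if (y > 1e7) return(1 / sqrt(y))
    if (y < 1e-6) return(1 / y)
    x <- 0.5 + 1 / y
    for (i in 1:75) {
        tri <- trigamma(x)
        dif <- tri * (1 - tri / y) / psigamma(x, 2)
        x <- x + dif
        if (abs(dif) / x < 1e-8) break
    }
    x
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p p-values in `[0, 1]` (NA allowed; NAs are returned as NA and
#'   excluded from the adjustment).
#' @return adjusted values in `[0, 1]`, order-preserving.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhFdr <- function(p) {
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(p))
    pp <- p[ok]
    m <- length(pp)
    if (m) {
        o <- order(pp, decreasing = TRUE)
        ro <- order(o)
        out[ok] <- pmin(1, cummin(m / (m:1) * pp[o]))[ro]
    }
    out
}

#' Differential junction expression with moderated t-statistics
#'
#' Per junction, weighted least squares on logCPM gives the absolute
#' log2 fold change between the two groups; residual variances are
#' shrunk toward a prior estimated across junctions (method of moments
#' on `log s^2`), and two-sided p-values come from a t distribution
#' with `d0 + d` degrees of freedom.  The relative (usage) log fold
#' change of a junction is its absolute logFC minus the mean absolute
#' logFC of the gene's other retained junctions; its variance combines
#' the moderated variances of the junctions entering the contrast.
#' Each statistic is BH-adjusted separately.  A junction is classed
#' `up` iff `logFC_abs > cutoff` and both FDRs are below `alpha`
#' (`down` symmetric; otherwise `ns`), so significance requires a
#' coherent change in expression *and* usage.
#'
#' @param je an annotated, filtered [JunctionExperiment] (rowData needs
#'   `gene_id` and `class` from [annotateJunctions()]).
#' @param group two-level factor over samples; logFC is second level
#'   minus first.  Defaults to `colData(je)$group`.
#' @param weights optional observation weights; computed by
#'   [varianceWeights()] when `NULL`.
#' @param cutoff |logFC| significance cutoff in log2 units (1.0 for
#'   tumor/normal-style contrasts; 0.5 is conventional for milder
#'   condition contrasts).
#' @param alpha FDR level.
#' @param priorDf override the estimated prior df `d0` (0 gives the
#'   ordinary unmoderated t-test; `Inf`-like values are capped at 1e6).
#' @return a `DataFrame` (one row per junction) with `gene_id`,
#'   annotation `status`, `logFC_abs`, `logFC_rel`, `t_abs`, `t_rel`,
#'   `p_abs`, `p_rel`, `fdr_abs`, `fdr_rel`, `rel_tested`, `class`;
#'   moderation parameters and thresholds in `metadata()`.
#' @export
fitDJE <- function(je, group = NULL, weights = NULL, cutoff = 1,
                   alpha = 0.05, priorDf = NULL) {
    if (is.null(group)) group <- colData(je)$group
    group <- droplevels(as.factor(group))
    if (nlevels(group) != 2) stop("group must have exactly two levels")
    if (any(table(group) < 2)) stop("both groups need >= 2 samples")
    if (!"gene_id" %in% colnames(rowData(je)))
        stop("junctions are not annotated; run annotateJunctions() first")
    E <- logCpm(je)
    design <- cbind(intercept = 1,
                    contrast = as.numeric(group == levels(group)[2]))
    if (is.null(weights)) weights <- varianceWeights(E, design)
    fit <- rowFit(E, design, weights)
    d <- fit$df

    if (is.null(priorDf)) {
        prior <- estimatePrior(fit$s2, d)
    } else {
        prior <- list(d0 = min(priorDf, 1e6),
                      s0sq = estimatePrior(fit$s2, d)$s0sq)
    }
    d0 <- prior$d0
    s_post2 <- if (d0 == 0) fit$s2 else
        (d0 * prior$s0sq + d * fit$s2) / (d0 + d)

    lfc <- fit$coef[, 2]
    se_abs <- sqrt(s_post2 * fit$unscaled2)
    t_abs <- lfc / se_abs
    df_total <- d0 + d
    p_abs <- 2 * pt(-abs(t_abs), df_total)

    ## relative (usage) statistic per gene
    gene <- rowData(je)$gene_id
    nr <- nrow(je)
    lfc_rel <- rep(NA_real_, nr)
    t_rel <- rep(NA_real_, nr)
    p_rel <- rep(NA_real_, nr)
    var_abs <- s_post2 * fit$unscaled2
    for (g in unique(gene[!is.na(gene)])) {
        idx <- which(!is.na(gene) & gene == g)
        k <- length(idx)
        if (k < 2) next
        for (j in idx) {
            others <- setdiff(idx, j)
            lfc_rel[j] <- lfc[j] - mean(lfc[others])
            v <- var_abs[j] + sum(var_abs[others]) / (k - 1)^2
            t_rel[j] <- lfc_rel[j] / sqrt(v)
            p_rel[j] <- 2 * pt(-abs(t_rel[j]), df_total)
        }
    }
    rel_tested <- !is.na(p_rel)

    fdr_abs <- bhFdr(p_abs)
    fdr_rel <- rep(NA_real_, nr)
    fdr_rel[rel_tested] <- bhFdr(p_rel[rel_tested])

    cls <- rep("ns", nr)
    sig <- !is.na(fdr_abs) & fdr_abs < alpha &
        rel_tested & !is.na(fdr_rel) & fdr_rel < alpha
    cls[sig & lfc > cutoff] <- "up"
    cls[sig & lfc < -cutoff] <- "down"

    res <- DataFrame(
        gene_id = gene,
        status = rowData(je)$class,
        tx_index = rowData(je)$tx_index,
        logFC_abs = lfc, logFC_rel = lfc_rel,
        t_abs = t_abs, t_rel = t_rel,
        p_abs = p_abs, p_rel = p_rel,
        fdr_abs = fdr_abs, fdr_rel = fdr_rel,
        rel_tested = rel_tested, class = cls,
        row.names = rownames(je))
    metadata(res) <- list(
        moderation = list(d0 = d0, s0sq = prior$s0sq, df_resid = d),
        cutoff = cutoff, alpha = alpha,
        contrast = paste(levels(group)[2], "vs", levels(group)[1]))
    res
}

#' Export gene-wise splice-plot records
#'
#' One record per junction of the gene, in transcript order (indices
#' ascend along the direction of transcription, so right-to-left on the
#' genome for minus-strand genes): transcript-order index, absolute
#' logFC, color (`red` = up, `blue` = down, `black` = ns), and a novel
#' flag.  `labeled` marks the first, last and differentially expressed
#' junction indices, the ones a splice plot annotates on its x-axis.
#'
#' @param result a [fitDJE()] `DataFrame`.
#' @param gene gene id.
#' @param path optional JSON output path.
#' @return data.frame of plot records (invisibly written to `path` as
#'   JSON when given).
#' @export
exportSplicePlot <- function(result, gene, path = NULL) {
    idx <- which(!is.na(result$gene_id) & result$gene_id == gene)
    if (!length(idx)) stop("unknown gene: ", gene)
    r <- result[idx, ]
    o <- order(r$tx_index)
    r <- r[o, ]
    colmap <- c(up = "red", down = "blue", ns = "black")
    rec <- data.frame(
        junction = rownames(r),
        tx_index = r$tx_index,
        logFC_abs = r$logFC_abs,
        class = r$class,
        color = unname(colmap[r$class]),
        novel = r$status != "annotated",
        labeled = r$tx_index %in% c(min(r$tx_index), max(r$tx_index),
                                    r$tx_index[r$class != "ns"]))
    if (!is.null(path))
        write_json(list(gene = gene, cutoff = metadata(result)$cutoff,
                        junctions = rec),
                   path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rec
}

#' Write a DJE result table as TSV
#' @param result a [fitDJE()] `DataFrame`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeDJEResult <- function(result, path) {
    df <- as.data.frame(result)
    df <- cbind(junction = rownames(df), df)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
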