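test_that("expression filtering keeps junctions at or above the mean-count threshold", {
    cnt <- rbind(rep(9, 6), rep(10, 6), c(0, 0, 0, 0, 1, 59),
                 rep(100, 6))
    jx <- data.frame(chrom = "chr1", start = c(10, 30, 50, 70),
                     end = c(20, 40, 60, 80), strand = "+")
    je <- JunctionExperiment(cnt, jx, librarySizes = rep(1e5, 6))
    kept <- filterJunctions(je, minMean = 10)
    ## independent one-line oracle on the row means
    expect_identical(rownames(kept),
                     rownames(je)[rowMeans(cnt) >= 10])
    expect_identical(nrow(kept), 3L)          # mean 9 out, mean 10 in
    expect_identical(unname(librarySizes(kept)), rep(1e5, 6))
})

test_that("logCPM follows the offset convention and is monotone in counts", {
    jx <- data.frame(chrom = "c", start = c(1, 5), end = c(3, 8),
                     strand = "+")
    je <- JunctionExperiment(rbind(c(0, 499999), c(10, 20)), jx,
                             librarySizes = c(1e6 - 1, 1e6 - 1))
    E <- logCpm(je)
    expect_equal(E[1, 1], -1)                        # log2(0.5)
    expect_equal(E[1, 2], log2(499999.5), tolerance = 1e-12)
    je2 <- JunctionExperiment(rbind(c(0, 499999), c(20, 20)), jx,
                              librarySizes = c(1e6 - 1, 1e6 - 1))
    expect_gt(logCpm(je2)[2, 1], E[2, 1])            # doubling increases

    jz <- JunctionExperiment(matrix(1, 1, 1), jx[1, ], librarySizes = 1)
    jz@colData$library_size <- 0
    expect_error(logCpm(jz), "zero library size")
})

test_that("variance weights track the mean-variance trend", {
    design <- cbind(1, rep(0:1, each = 10))
    withr::with_seed(42, {
        ## homoskedastic: weights near-constant (within +/-20%)
        E <- matrix(rnorm(50 * 20, mean = 5), 50, 20)
        w <- varianceWeights(E, design)
        expect_true(all(w > 0), all(is.finite(w)))
        expect_lt(max(w) / median(w), 1.2)
        expect_gt(min(w) / median(w), 0.8)

        ## noisy low-mean block must be down-weighted
        E2 <- rbind(matrix(rnorm(25 * 20, mean = 0, sd = 3), 25, 20),
                    matrix(rnorm(25 * 20, mean = 8, sd = 0.5), 25, 20))
        w2 <- varianceWeights(E2, design)
        expect_lt(mean(w2[1:25, ]), mean(w2[26:50, ]))
    })
    ## degenerate single-junction input falls back to unit weights
    expect_identical(varianceWeights(matrix(rnorm(20), 1, 20), design),
                     matrix(1, 1, 20))
    expect_error(varianceWeights(matrix(rnorm(4), 2, 2), cbind(1, c(0, 1))),
                 "fewer samples|residual")
})

test_that("BH adjustment matches hand arithmetic and the brute-force definition", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFdr(0.3), 0.3)
    expect_error(bhFdr(c(0.1, 1.2)), "\\[0, 1\\]")
    expect_error(bhFdr(-0.1), "\\[0, 1\\]")

    pset <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.9)
    for (k in 1:6) {
        combos <- combn(6, k)
        for (j in seq_len(ncol(combos))) {
            p <- pset[combos[, j]]
            expect_equal(bhFdr(p), bruteForceBH(p))
            expect_equal(bhFdr(p), p.adjust(p, "BH"))
        }
    }
    ## order invariance
    p <- c(0.5, 0.001, 0.2, 0.04)
    o <- c(3, 1, 4, 2)
    expect_equal(bhFdr(p)[o], bhFdr(p[o]))
})

test_that("moderated t reduces to the ordinary weighted t at zero prior df", {
    sim <- miniCohort(seed = 21)
    je <- filterJunctions(annotateJunctions(sim$junctions,
                                            sim$annotation))
    E <- logCpm(je)
    design <- cbind(1, as.numeric(colData(je)$group == "A"))
    w <- varianceWeights(E, design)
    res <- fitDJE(je, weights = w, priorDf = 0)
    ## oracle: per-junction weighted lm
    for (i in c(1, 5, 10)) {
        fit <- lm(E[i, ] ~ design[, 2], weights = w[i, ])
        ct <- summary(fit)$coefficients[2, ]
        expect_equal(res$logFC_abs[i], unname(ct["Estimate"]),
                     tolerance = 1e-8)
        expect_equal(res$t_abs[i], unname(ct["t value"]),
                     tolerance = 1e-8)
        expect_equal(res$p_abs[i], unname(ct["Pr(>|t|)"]),
                     tolerance = 1e-8)
    }
})

test_that("posterior variances shrink toward the prior", {
    sim <- miniCohort(seed = 22)
    je <- filterJunctions(annotateJunctions(sim$junctions,
                                            sim$annotation))
    E <- logCpm(je)
    design <- cbind(1, as.numeric(colData(je)$group == "A"))
    fit <- spliceforce:::rowFit(E, design)
    prior <- spliceforce:::estimatePrior(fit$s2, fit$df)
    s_post2 <- (prior$d0 * prior$s0sq + fit$df * fit$s2) /
        (prior$d0 + fit$df)
    expect_true(all(s_post2 >= pmin(fit$s2, prior$s0sq) - 1e-12))
    expect_true(all(s_post2 <= pmax(fit$s2, prior$s0sq) + 1e-12))
    ## infinite prior df collapses all posteriors onto the prior
    s_inf <- (1e12 * prior$s0sq + fit$df * fit$s2) / (1e12 + fit$df)
    expect_equal(unname(s_inf), rep(prior$s0sq, length(fit$s2)),
                 tolerance = 1e-9)
})

test_that("moderated statistics agree with the limma reference route", {
    ## heterogeneous abundances so the mean-variance trend is real
    withr::with_seed(23, {
        mu <- rep(c(5, 20, 80, 300, 1200), each = 12)
        cnt <- matrix(rnbinom(60 * 30, mu = mu, size = 10), 60, 30,
                      dimnames = list(NULL, paste0("s", 1:30)))
    })
    jx <- data.frame(chrom = "chr1", start = seq(1, by = 1000, length = 60),
                     end = seq(500, by = 1000, length = 60), strand = "+")
    je <- JunctionExperiment(cnt, jx, librarySizes = rep(1e6, 30))
    rowData(je)$gene_id <- rep(paste0("g", 1:20), each = 3)
    rowData(je)$class <- "annotated"
    rowData(je)$tx_index <- rep(1:3, 20)
    design <- cbind(1, rep(0:1, 15))
    E <- logCpm(je)
    w <- varianceWeights(E, design)
    v <- limma::voom(counts(je), design, lib.size = librarySizes(je))
    ## same trend machinery: weights strongly correlated
    expect_gt(cor(as.vector(w), as.vector(v$weights)), 0.8)
    fit <- limma::eBayes(limma::lmFit(E, design, weights = w))
    mine <- fitDJE(je, group = factor(design[, 2]), weights = w)
    expect_gt(cor(mine$t_abs, fit$t[, 2]), 0.999)
    expect_equal(mine$logFC_abs, unname(fit$coefficients[, 2]),
                 tolerance = 1e-8)
})

test_that("the cassette cohort shows the two-up/one-down junction signature", {
    sim <- simulateCohort(cohortSpec(seed = 101))
    je <- filterJunctions(annotateJunctions(sim$junctions,
                                            sim$annotation))
    res <- fitDJE(je)
    tr <- sim$truth$cassettes$G2
    g2 <- res[!is.na(res$gene_id) & res$gene_id == "G2", ]
    expect_setequal(rownames(g2)[g2$class == "up"], c(tr$inc1, tr$inc2))
    expect_identical(rownames(g2)[g2$class == "down"], tr$skip)
    ## nothing outside the cassette gene is called
    expect_true(all(res$class[is.na(res$gene_id) |
                              res$gene_id != "G2"] == "ns"))
    ## the called junctions clear the |logFC| > 1 cutoff
    expect_true(all(abs(g2$logFC_abs[g2$class != "ns"]) > 1))
})

test_that("single-junction genes are excluded from relative testing", {
    jx <- data.frame(chrom = "chr1",
                     start = c(1100, 1500, 5100), end = c(1399, 1799, 5399),
                     strand = c("+", "+", "-"))
    withr::with_seed(1, {
        cnt <- matrix(rnbinom(3 * 8, mu = 50, size = 10), 3, 8,
                      dimnames = list(NULL, paste0("s", 1:8)))
    })
    je <- JunctionExperiment(cnt, jx, librarySizes = rep(1e5, 8))
    je <- annotateJunctions(je, miniAnnotation())
    res <- fitDJE(je, group = factor(rep(c("x", "y"), each = 4)))
    ## GM has a single retained junction: flagged, no relative statistic
    gm <- res[res$gene_id == "GM", ]
    expect_false(gm$rel_tested)
    expect_true(is.na(gm$logFC_rel))
    expect_true(all(res[res$gene_id == "GP", "rel_tested"]))
})

test_that("type-I error of the moderated test is controlled on a null cohort", {
    sim <- simulateCohort(cohortSpec(
        nGenes = 40, nSamplesPerGroup = c(30, 30),
        cassetteGenes = data.frame(gene = "G2", psiA = 0.5, psiB = 0.5),
        seed = 77))
    je <- filterJunctions(annotateJunctions(sim$junctions,
                                            sim$annotation))
    res <- fitDJE(je)
    n <- nrow(res)
    frac <- mean(res$fdr_abs < 0.05)
    expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("detection strength grows with the programmed inclusion switch", {
    score <- vapply(c(0.1, 0.35, 0.65), function(delta) {
        ts <- vapply(1:3, function(s) {
            sim <- simulateCohort(cohortSpec(
                nGenes = 8, nSamplesPerGroup = c(20, 20),
                cassetteGenes = data.frame(gene = "G2",
                                           psiA = 0.05 + delta,
                                           psiB = 0.05),
                seed = 300 + s))
            je <- filterJunctions(annotateJunctions(sim$junctions,
                                                    sim$annotation),
                                  minMean = 3)
            res <- fitDJE(je)
            tr <- sim$truth$cassettes$G2
            mean(abs(res[c(tr$inc1, tr$inc2), "t_abs"]))
        }, numeric(1))
        mean(ts)
    }, numeric(1))
    expect_true(all(diff(score) > 0))
})

test_that("splice-plot records carry transcript order, colors and novel flags", {
    sim <- simulateCohort(cohortSpec(seed = 101))
    je <- filterJunctions(annotateJunctions(sim$junctions,
                                            sim$annotation))
    res <- fitDJE(je)
    rec <- exportSplicePlot(res, "G2")
    expect_identical(rec$tx_index, seq_len(nrow(rec)))
    expect_identical(rec$color[rec$class == "up"], rep("red", 2))
    expect_identical(rec$color[rec$class == "down"], "blue")
    expect_true(all(rec$novel[rec$class == "up"]))
    expect_false(any(rec$novel[rec$class == "ns"]))
    ## G2 is minus-strand: transcript order descends along the genome
    ends <- as.integer(sub("^chr1:\\d+-(\\d+):.*$", "\\1", rec$junction))
    expect_true(all(diff(ends) <= 0))
    ## first, last and differential junctions are labeled
    expect_true(all(rec$labeled[c(1, nrow(rec))]))
    expect_true(all(rec$labeled[rec$class != "ns"]))

    ## all-ns gene is all black; unknown gene errors
    rec1 <- exportSplicePlot(res, "G1")
    expect_true(all(rec1$color == "black"))
    expect_error(exportSplicePlot(res, "nope"), "unknown gene")
})
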