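test_that("cohort simulation is deterministic and validates its spec", {
    s1 <- miniCohort(seed = 11)
    s2 <- miniCohort(seed = 11)
    expect_identical(counts(s1$junctions), counts(s2$junctions))
    expect_identical(librarySizes(s1$junctions), librarySizes(s2$junctions))
    s3 <- miniCohort(seed = 12)
    expect_false(identical(counts(s1$junctions), counts(s3$junctions)))

    expect_error(cohortSpec(geneAbundance = -1), "positive")
    expect_error(cohortSpec(nSamplesPerGroup = c(0, 5)), "positive")
    expect_error(cohortSpec(nbDispersion = 0), "positive")
    expect_error(cohortSpec(cassetteGenes = data.frame(
        gene = "G1", psiA = 1.2, psiB = 0)), "\\[0, 1\\]")
})

test_that("zero inclusion fraction gives zero inclusion counts at low dispersion", {
    sim <- simulateCohort(cohortSpec(
        nGenes = 4, nSamplesPerGroup = c(5, 5),
        cassetteGenes = data.frame(gene = "G2", psiA = 0, psiB = 0),
        nbDispersion = 1e-10, seed = 2))
    inc <- rowData(sim$junctions)$true_role %in% c("inc1", "inc2")
    expect_true(all(counts(sim$junctions)[inc, ] == 0))
    ## skipping junction carries the full gene abundance in expectation
    skip <- rowData(sim$junctions)$true_role == "skip"
    expect_gt(mean(counts(sim$junctions)[skip, ]), 50)
})

test_that("group-mean estimated PSI recovers the programmed inclusion fractions", {
    sim <- simulateCohort(cohortSpec(
        nGenes = 10, nSamplesPerGroup = c(60, 60),
        cassetteGenes = data.frame(gene = "G2", psiA = 0.7, psiB = 0.05),
        geneAbundance = 100, seed = 5))
    je <- annotateJunctions(sim$junctions, sim$annotation)
    ev <- detectCassetteEvents(filterJunctions(je, 1))
    ev <- ev[ev$gene_id == "G2"]
    psi <- computePsi(ev[1], je)
    grp <- sim$truth$group
    expect_lt(abs(mean(psi[grp == "A"], na.rm = TRUE) - 0.7), 0.05)
    expect_lt(abs(mean(psi[grp == "B"], na.rm = TRUE) - 0.05), 0.05)
})

test_that("isoform usage conserves gene abundance across the cassette trio", {
    ## expected inclusion-path + skipping-path reads = gene abundance:
    ## check on sample means at low dispersion and equal library sizes
    sim <- simulateCohort(cohortSpec(
        nGenes = 4, nSamplesPerGroup = c(40, 40),
        cassetteGenes = data.frame(gene = "G2", psiA = 0.3, psiB = 0.3),
        geneAbundance = 200, nbDispersion = 1e-10,
        libsizeRange = c(1e6, 1e6), seed = 3))
    cnt <- counts(sim$junctions)
    role <- rowData(sim$junctions)$true_role
    incMean <- mean(colMeans(cnt[role %in% c("inc1", "inc2"), ]))
    skipMean <- mean(cnt[role == "skip", ])
    expect_lt(abs(incMean + skipMean - 200) / 200, 0.05)
})

test_that("trace simulation matches the closed-form modal force and truth bookkeeping", {
    ## single domain engineered for a mid-range modal force
    kBT <- 4.114; dx <- 3; rate <- 1; fstar <- 12
    k0 <- bellEvansK0(fstar, dx, rate, kBT)
    expect_equal((kBT / dx) * log(rate * dx / (k0 * kBT)), fstar)
    forces <- vapply(1:500, function(s) {
        sim <- simulateTrace(traceSpec(
            fStart = 1, fMax = 40, sampleRate = 20, noiseSd = 0,
            domains = data.frame(k0 = k0, dx = dx, step = 25),
            kBT = kBT, seed = s))
        sim$truth$force
    }, numeric(1))
    d <- density(forces)
    expect_lt(abs(d$x[which.max(d$y)] - fstar) / fstar, 0.1)

    ## three well-separated domains unfold exactly once each, in range
    for (s in 1:20) {
        tr <- simulateTrace(traceSpec(seed = s))
        expect_identical(nrow(tr$truth), 3L)
        expect_true(all(tr$truth$resolved))
        expect_true(all(tr$truth$force > tr$trace@schedule$f_start))
    }
})

test_that("trace is reproducible, monotone without noise, and spec-validated", {
    a <- simulateTrace(traceSpec(seed = 4))
    b <- simulateTrace(traceSpec(seed = 4))
    expect_identical(a$trace@height, b$trace@height)

    nf <- simulateTrace(traceSpec(noiseSd = 0, seed = 4))
    expect_true(all(diff(nf$trace@height) >= 0))

    zero <- simulateTrace(traceSpec(
        domains = data.frame(k0 = numeric(), dx = numeric(),
                             step = numeric()), seed = 1))
    expect_identical(nrow(zero$truth), 0L)
    expect_lt(diff(range(zero$trace@height)), 10)

    expect_error(traceSpec(fMax = 120), "100 pN")
    expect_error(traceSpec(domains = data.frame(k0 = -1, dx = 1, step = 5)),
                 "positive")
})

test_that("PCR fixtures reproduce the published amplicon arithmetic", {
    for (mode in c("TLN1-like", "CLSTN1-like")) {
        fx <- makePcrFixture(mode)
        ## deleting the cassette from the inclusion template restores
        ## the skipping template
        expect_identical(sub(fx$cassette, "", fx$templateInclusion,
                             fixed = TRUE),
                         fx$templateSkipping)
        ## each primer binds exactly once per template in its orientation
        for (tmpl in c(fx$templateInclusion, fx$templateSkipping)) {
            t <- Biostrings::DNAString(tmpl)
            expect_length(Biostrings::matchPattern(fx$primerFwd, t), 1)
            expect_length(Biostrings::matchPattern(
                as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(fx$primerRev))), t), 1)
        }
    }
    expect_identical(makePcrFixture("TLN1-like")$ampliconLengths,
                     c(inclusion = 234L, skipping = 183L))
    expect_identical(makePcrFixture("CLSTN1-like")$ampliconLengths,
                     c(inclusion = 278L, skipping = 221L))
    ## seeded: same fixture twice
    expect_identical(makePcrFixture("TLN1-like", seed = 9),
                     makePcrFixture("TLN1-like", seed = 9))
})
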